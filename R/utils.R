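# Internal sequence helpers shared across modules.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over character vectors, delegating to
#' Biostrings so IUPAC ambiguity codes are handled correctly.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of a tag: lexicographic minimum of the tag and its
#' reverse complement. Makes strand handling explicit.
#' @param x character vector of DNA sequences.
#' @return character vector, same length.
#' @keywords internal
canonical_tag <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Validate a DNA string: only A/C/G/T/N allowed for genomes and reads.
assert_dna <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || !is.character(sequence) || !nzchar(sequence)) {
    stop(what, " must be a non-empty character string", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("invalid character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Seed helper: derive a stage seed from a base seed, staying in 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
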