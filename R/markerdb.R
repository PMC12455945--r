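#' In-silico type-IIB digestion of a DNA sequence
#'
#' Scans both strands of `sequence` for the enzyme's recognition pattern and
#' excises the fixed-length tag around every occurrence (flank + site +
#' flank). Tags truncated by the sequence ends or containing `N` are
#' dropped. Each tag is canonicalized as the lexicographic minimum of the
#' tag and its reverse complement, so a genome and its reverse complement
#' digest to identical tag sets.
#'
#' @param sequence a DNA string (characters `A`, `C`, `G`, `T`, `N`).
#' @param enzyme an [enzyme_spec()].
#' @return sorted character vector of distinct canonical tags.
#' @examples
#' e <- enzyme_spec()
#' site <- "CGAAAATTTTGC" # one concrete CGA-N6-TGC instance
#' seq <- paste0(strrep("A", 12), site, strrep("A", 12))
#' digest_sequence(seq, e) # exactly one 36-nt tag
#' @export
digest_sequence <- function(sequence, enzyme = enzyme_spec()) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  sequence <- toupper(sequence)
  assert_dna(sequence)

  subject <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enzyme$recognition)
  fl <- enzyme$flank_left
  fr <- enzyme$flank_right
  n <- nchar(sequence)

  windows <- character(0)

  # forward-strand site occurrences
  m <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  if (length(m) > 0L) {
    s <- Biostrings::start(m) - fl
    e <- Biostrings::end(m) + fr
    keep <- s >= 1L & e <= n
    if (any(keep)) {
      windows <- c(windows, substring(sequence, s[keep], e[keep]))
    }
  }
  # reverse-strand occurrences: the pattern's reverse complement on the
  # forward strand; flanks are swapped in forward coordinates
  m <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                                fixed = FALSE)
  if (length(m) > 0L) {
    s <- Biostrings::start(m) - fr
    e <- Biostrings::end(m) + fl
    keep <- s >= 1L & e <= n
    if (any(keep)) {
      windows <- c(windows, substring(sequence, s[keep], e[keep]))
    }
  }

  if (length(windows) == 0L) return(character(0))
  windows <- windows[!grepl("N", windows, fixed = TRUE)]
  if (length(windows) == 0L) return(character(0))
  sort(unique(canonical_tag(windows)))
}

#' Build a species-unique marker database
#'
#' Digests every genome in-silico, pools tags per species (union over that
#' species' sequences), and removes any tag observed in two or more species
#' from all of them, leaving marker sets that are pairwise disjoint and
#' unique to their species. Species whose every tag is shared end up with
#' zero usable markers; they are recorded as unprofilable rather than
#' silently dropped.
#'
#' @param genomes named list: species id -> character vector of genome
#'   sequences.
#' @param enzyme an [enzyme_spec()].
#' @return an object of class `marker_db` with elements
#'   `species_markers` (named list of sorted canonical tags),
#'   `theoretical_counts` (named integer vector `T_i`),
#'   `unprofilable` (character vector of species ids with no unique tag),
#'   and `enzyme`.
#' @export
build_marker_db <- function(genomes, enzyme = enzyme_spec()) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("genomes must be a named list (names = species ids)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate species id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  per_species <- lapply(genomes, function(seqs) {
    sort(unique(unlist(lapply(as.character(seqs), digest_sequence,
                              enzyme = enzyme))))
  })

  all_tags <- unlist(per_species, use.names = FALSE)
  # tags present in >= 2 species are not species-informative
  n_species_per_tag <- rowsum(rep(1L, length(all_tags)), all_tags)
  shared <- rownames(n_species_per_tag)[n_species_per_tag[, 1] >= 2L]

  species_markers <- lapply(per_species, function(tags) setdiff(tags, shared))
  names(species_markers) <- ids
  counts <- vapply(species_markers, length, integer(1))
  unprofilable <- ids[counts == 0L]
  species_markers <- species_markers[counts > 0L]

  structure(
    list(species_markers = species_markers,
         theoretical_counts = counts[counts > 0L],
         unprofilable = unprofilable,
         enzyme = enzyme),
    class = "marker_db"
  )
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf("<marker_db> %d species, %d unique markers (%s)\n",
              length(x$species_markers),
              sum(x$theoretical_counts),
              x$enzyme$name))
  if (length(x$unprofilable) > 0L) {
    cat("  unprofilable:", paste(x$unprofilable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read genomes from FASTA
#'
#' Loads a multi-FASTA file and groups sequences into species. Without a
#' species map, each FASTA record name (first word) is its own species id.
#' With a map (data.frame or TSV path with columns `sequence_id`,
#' `species_id`), sequences are grouped accordingly.
#'
#' @param fasta path to a FASTA file.
#' @param species_map optional data.frame or TSV path mapping sequence ids
#'   to species ids.
#' @return named list species id -> character vector of sequences, suitable
#'   for [build_marker_db()].
#' @export
read_genomes <- function(fasta, species_map = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  seq_ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  seq_chr <- as.character(seqs)
  if (is.null(species_map)) {
    out <- as.list(seq_chr)
    names(out) <- seq_ids
    return(out)
  }
  if (is.character(species_map)) {
    species_map <- utils::read.delim(species_map, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sequence_id", "species_id") %in% names(species_map)))
  idx <- match(seq_ids, species_map$sequence_id)
  if (anyNA(idx)) {
    stop("sequence id(s) missing from species map: ",
         paste(seq_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  split(seq_chr, species_map$species_id[idx])
}

#' Write a marker database to disk
#'
#' Serializes the marker sets as a two-column TSV (`species_id`, `tag`;
#' rows ordered by species then tag) plus a JSON sidecar holding the enzyme
#' specification, theoretical marker counts and unprofilable species.
#' Identical databases serialize byte-identically.
#'
#' @param db a `marker_db`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_marker_db <- function(db, dir) {
  stopifnot(inherits(db, "marker_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(names(db$species_markers))
  tab <- data.frame(
    species_id = rep(ids, vapply(db$species_markers[ids], length, integer(1))),
    tag = unlist(db$species_markers[ids], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  tsv <- file.path(dir, "markers.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- file.path(dir, "markers.json")
  jsonlite::write_json(
    list(enzyme = unclass(db$enzyme),
         theoretical_counts = as.list(db$theoretical_counts[ids]),
         unprofilable = db$unprofilable),
    meta, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(markers = tsv, meta = meta))
}

#' Read a marker database written by [write_marker_db()]
#' @param dir directory containing `markers.tsv` and `markers.json`.
#' @return a `marker_db`.
#' @export
read_marker_db <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "markers.tsv"),
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "markers.json"),
                              simplifyVector = TRUE)
  enzyme <- enzyme_spec(meta$enzyme$name, meta$enzyme$recognition,
                        meta$enzyme$flank_left, meta$enzyme$flank_right)
  species_markers <- split(tab$tag, tab$species_id)
  species_markers <- lapply(species_markers, sort)
  structure(
    list(species_markers = species_markers,
         theoretical_counts = vapply(species_markers, length, integer(1)),
         unprofilable = as.character(meta$unprofilable),
         enzyme = enzyme),
    class = "marker_db"
  )
}
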