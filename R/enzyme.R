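#' Type-IIB restriction enzyme specification
#'
#' Describes the recognition pattern and flank widths of a type-IIB
#' restriction enzyme used for in-silico tag extraction. A type-IIB enzyme
#' cuts on both sides of its (possibly degenerate) recognition site, so
#' every digestion product ("tag") has the same fixed length:
#' `flank_left + nchar(recognition) + flank_right`.
#'
#' The default models BcgI, the standard enzyme for restriction-tag
#' microbiome profiling: recognition `CGA-N6-TGC` with 12-nt flanks on each
#' side, yielding 36-nt tags. Short synthetic patterns are convenient for
#' testing.
#'
#' @param name enzyme name (free text).
#' @param recognition recognition pattern using IUPAC codes (e.g. `"CGANNNNNNTGC"`).
#' @param flank_left number of bases excised upstream of the site.
#' @param flank_right number of bases excised downstream of the site.
#' @return an object of class `enzyme_spec`.
#' @examples
#' enzyme_spec() # BcgI-like, 36-nt tags
#' enzyme_spec("toy", "ACGT", flank_left = 2, flank_right = 2)
#' @export
enzyme_spec <- function(name = "BcgI", recognition = "CGANNNNNNTGC",
                        flank_left = 12L, flank_right = 12L) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.character(recognition), length(recognition) == 1L,
            nzchar(recognition))
  recognition <- toupper(recognition)
  bad <- setdiff(unique(strsplit(recognition, "")[[1]]), IUPAC_CODES)
  if (length(bad) > 0L) {
    stop("recognition pattern contains non-IUPAC code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  flank_left <- as.integer(flank_left)
  flank_right <- as.integer(flank_right)
  stopifnot(flank_left >= 0L, flank_right >= 0L)
  structure(
    list(name = name, recognition = recognition,
         flank_left = flank_left, flank_right = flank_right),
    class = "enzyme_spec"
  )
}

#' Tag length of an enzyme specification
#' @param enzyme an [enzyme_spec()].
#' @return integer tag length.
#' @export
tag_length <- function(enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  enzyme$flank_left + nchar(enzyme$recognition) + enzyme$flank_right
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s: %s (+%d/-%d flanks, %d-nt tags)\n",
              x$name, x$recognition, x$flank_left, x$flank_right,
              tag_length(x)))
  invisible(x)
}
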