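#' Per-species G score
#'
#' Confidence statistic combining the reads assigned to a species' markers
#' (`S`) and the number of distinct markers hit (`t`). Species supported by
#' many reads spread over several distinct markers score high; single-marker
#' pileups — the typical false-positive signature in low-biomass samples —
#' score low. Two conventions are supported: `sqrt_product` returns
#' `sqrt(S * t)` (default), `product` returns `S * t`.
#'
#' @param S non-negative read count(s) on the species' markers.
#' @param t non-negative count(s) of distinct markers observed.
#' @param mode `"sqrt_product"` (default) or `"product"`.
#' @return numeric G score(s), zero exactly when `S` is zero.
#' @examples
#' g_score(25, 1)            # 5
#' g_score(5, 5, "product")  # 25
#' @export
g_score <- function(S, t, mode = c("sqrt_product", "product")) {
  mode <- match.arg(mode)
  if (any(S < 0) || any(t < 0)) {
    stop("S and t must be non-negative", call. = FALSE)
  }
  if (any(t > S)) {
    stop("t cannot exceed S (each observed marker needs at least one read)",
         call. = FALSE)
  }
  if (mode == "product") S * t else sqrt(S * t)
}

# Canonical tag -> species lookup table for a marker_db.
marker_lookup <- function(db) {
  stopifnot(inherits(db, "marker_db"))
  tags <- unlist(db$species_markers, use.names = FALSE)
  species <- rep(names(db$species_markers),
                 vapply(db$species_markers, length, integer(1)))
  list(tags = tags, species = species)
}

#' Assign reads to species markers
#'
#' Matches reads exactly against the canonical species-unique tags of a
#' marker database and tallies, per species, the reads assigned (`S`) and
#' the distinct markers observed (`t`). Because marker sets are disjoint
#' across species, each read contributes to at most one species. Reads of
#' exactly the tag length are canonicalized and looked up directly; longer
#' reads are digested and each excised tag is looked up (first match
#' counts). Reads shorter than the tag length, or containing `N`, are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param reads character vector of read sequences (or a `DNAStringSet`).
#' @param db a `marker_db` from [build_marker_db()].
#' @param sample_id sample label attached to the hits.
#' @param g_mode G-score convention, see [g_score()].
#' @return data.frame with columns `sample`, `species`, `S`, `t`, `T`,
#'   `g_score` (one row per species with `S > 0`), plus attributes
#'   `n_reads` and `n_skipped`.
#' @export
count_hits <- function(reads, db, sample_id = "sample",
                       g_mode = c("sqrt_product", "product")) {
  g_mode <- match.arg(g_mode)
  stopifnot(inherits(db, "marker_db"))
  if (length(db$species_markers) == 0L) {
    stop("marker database is empty", call. = FALSE)
  }
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  tl <- tag_length(db$enzyme)
  n_reads <- length(reads)

  usable <- nchar(reads) >= tl & !grepl("N", reads, fixed = TRUE)
  n_skipped <- sum(!usable)
  reads <- reads[usable]

  lk <- marker_lookup(db)
  hit_tag <- character(0)

  exact_len <- nchar(reads) == tl
  if (any(exact_len)) {
    canon <- canonical_tag(reads[exact_len])
    hit_tag <- c(hit_tag, canon[canon %in% lk$tags])
  }
  long <- reads[!exact_len]
  if (length(long) > 0L) {
    for (rd in long) {
      tags <- digest_sequence(rd, db$enzyme)
      found <- tags[tags %in% lk$tags]
      if (length(found) > 0L) hit_tag <- c(hit_tag, found[1L])
    }
  }

  if (length(hit_tag) == 0L) {
    out <- data.frame(sample = character(0), species = character(0),
                      S = integer(0), t = integer(0), T = integer(0),
                      g_score = numeric(0), stringsAsFactors = FALSE)
  } else {
    sp <- lk$species[match(hit_tag, lk$tags)]
    S <- as.integer(table(sp)[unique(sp)])
    tdist <- vapply(split(hit_tag, sp)[unique(sp)],
                    function(x) length(unique(x)), integer(1))
    out <- data.frame(
      sample = sample_id,
      species = unique(sp),
      S = S,
      t = tdist,
      T = as.integer(db$theoretical_counts[unique(sp)]),
      stringsAsFactors = FALSE
    )
    out$g_score <- g_score(out$S, out$t, g_mode)
    out <- out[order(out$species), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_reads") <- n_reads
  attr(out, "n_skipped") <- n_skipped
  attr(out, "g_mode") <- g_mode
  out
}

#' G-score false-positive filter
#'
#' Marks, per sample, the species whose G score reaches the threshold.
#' Species at exactly the threshold are retained.
#'
#' @param hits data.frame from [count_hits()] (rows from several samples may
#'   be bound together).
#' @param threshold minimum G score for a species call (default 5).
#' @return `hits` with an added logical column `retained`.
#' @export
filter_species <- function(hits, threshold = 5) {
  stopifnot(is.data.frame(hits), "g_score" %in% names(hits))
  hits$retained <- hits$g_score >= threshold
  hits
}

#' Marker-normalized relative abundance profile
#'
#' For each sample the abundance of species *i* is
#' `(S_i / T_i) / sum_j (S_j / T_j)` over the retained species: read counts
#' are normalized by the species' theoretical marker count `T_i` so that
#' species with many markers are not inflated, then rescaled to sum to one.
#' Samples with no retained species get a row of zeros (with a warning).
#'
#' @param hits data.frame from [count_hits()]/[filter_species()]. If a
#'   `retained` column is present only retained rows are used.
#' @param samples optional character vector fixing row order (defaults to
#'   the samples present in `hits`).
#' @return numeric matrix samples x species; rows sum to 1 where any species
#'   is retained. Attribute `total_matched` holds per-sample matched reads.
#' @export
relative_abundance <- function(hits, samples = NULL) {
  stopifnot(is.data.frame(hits),
            all(c("sample", "species", "S", "T") %in% names(hits)))
  used <- if ("retained" %in% names(hits)) hits[hits$retained, , drop = FALSE] else hits
  if (is.null(samples)) samples <- unique(hits$sample)
  species <- sort(unique(used$species))

  mat <- matrix(0, nrow = length(samples), ncol = length(species),
                dimnames = list(samples, species))
  if (nrow(used) > 0L) {
    if (any(used$T <= 0)) stop("theoretical marker count T must be positive",
                               call. = FALSE)
    w <- used$S / used$T
    for (s in samples) {
      rows <- used$sample == s
      if (!any(rows)) next
      mat[s, used$species[rows]] <- w[rows] / sum(w[rows])
    }
  }
  empty <- rownames(mat)[rowSums(mat) == 0]
  if (length(empty) > 0L) {
    warning("sample(s) with no retained species: ",
            paste(empty, collapse = ", "))
  }
  totals <- vapply(samples, function(s) sum(hits$S[hits$sample == s]),
                   numeric(1))
  attr(mat, "total_matched") <- totals
  mat
}

#' Profile a set of samples end to end
#'
#' Convenience wrapper: counts hits per sample, applies the G-score filter
#' and builds the relative-abundance matrix.
#'
#' @param read_sets named list: sample id -> character vector of reads.
#' @param db a `marker_db`.
#' @param g_mode,g_threshold G-score convention and threshold.
#' @return list with `hits` (bound per-sample data.frame, `retained`
#'   column) and `profile` (abundance matrix).
#' @export
profile_samples <- function(read_sets, db,
                            g_mode = c("sqrt_product", "product"),
                            g_threshold = 5) {
  g_mode <- match.arg(g_mode)
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  hits <- do.call(rbind, lapply(names(read_sets), function(s) {
    count_hits(read_sets[[s]], db, sample_id = s, g_mode = g_mode)
  }))
  hits <- filter_species(hits, g_threshold)
  profile <- relative_abundance(hits, samples = names(read_sets))
  list(hits = hits, profile = profile)
}

#' Screen negative-control contaminants
#'
#' Species called (post G-filter) in any negative control are flagged as
#' potential environmental or reagent-derived contaminants. Flagged species
#' are removed from the sample profile and the remaining abundances are
#' renormalized per sample. The report records, per flagged species, how
#' many clinical samples carried it — which may be none, in which case the
#' cleaned profile equals the input.
#'
#' @param profile abundance matrix (samples x species).
#' @param control_hits data.frame of control-sample hits from
#'   [count_hits()], already G-filtered (or carrying a `retained` column).
#' @return list with `flagged` (character vector), `cleaned` (renormalized
#'   profile) and `report` (data.frame species / n_samples_present).
#' @export
screen_contaminants <- function(profile, control_hits) {
  stopifnot(is.matrix(profile))
  ctrl <- control_hits
  if ("retained" %in% names(ctrl)) ctrl <- ctrl[ctrl$retained, , drop = FALSE]
  flagged <- sort(unique(ctrl$species))
  present <- vapply(flagged, function(sp) {
    if (sp %in% colnames(profile)) sum(profile[, sp] > 0) else 0L
  }, numeric(1))
  report <- data.frame(species = flagged,
                       n_samples_present = as.integer(present),
                       stringsAsFactors = FALSE)
  cleaned <- profile[, setdiff(colnames(profile), flagged), drop = FALSE]
  rs <- rowSums(cleaned)
  nz <- rs > 0
  cleaned[nz, ] <- cleaned[nz, , drop = FALSE] / rs[nz]
  attr(cleaned, "total_matched") <- attr(profile, "total_matched")
  list(flagged = flagged, cleaned = cleaned, report = report)
}

#' Read sequencing reads from FASTA/FASTQ
#'
#' @param path read file; format inferred from the extension
#'   (`.fq`/`.fastq[.gz]` vs `.fa`/`.fasta[.gz]`).
#' @return character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}
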