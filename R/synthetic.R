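# Synthetic-data generators: genomes with planted enzyme sites, two-group
# communities with planted differential species, reads with sequencing
# noise, and clinical covariates with the cohort's summary statistics.

# One concrete instance of an IUPAC pattern (N and friends resolved randomly).
instantiate_pattern <- function(pattern) {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  chars <- strsplit(pattern, "")[[1]]
  paste0(vapply(chars, function(ch) {
    opts <- expand[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# All forward+reverse occurrences of the recognition site in a sequence.
site_positions <- function(sequence, enzyme) {
  subject <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enzyme$recognition)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject, fixed = FALSE))
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(pat), subject, fixed = FALSE))
  sort(unique(c(fwd, rev)))
}

# Random A/C/G/T sequence with every recognition-site occurrence patched out.
clean_background <- function(len, enzyme, max_iter = 100L) {
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, len, replace = TRUE)
  for (i in seq_len(max_iter)) {
    pos <- site_positions(paste0(x, collapse = ""), enzyme)
    if (length(pos) == 0L) return(paste0(x, collapse = ""))
    for (p in pos) {
      x[p] <- sample(setdiff(bases, x[p]), 1L)
    }
  }
  stop("could not generate a site-free background sequence", call. = FALSE)
}

#' Generate genomes with planted restriction sites
#'
#' Builds one genome per species: a random background guaranteed free of
#' spurious recognition sites, with exactly `markers_per_species` planted
#' site instances at evenly spaced, non-overlapping positions. Optionally,
#' `shared_marker_pairs` tag windows are copied verbatim between species
#' pairs so that database construction has known cross-species collisions
#' to remove. A truth ledger records every planted canonical tag and its
#' owner.
#'
#' @param n_species number of species.
#' @param genome_length length of each genome (nt).
#' @param markers_per_species planted sites per genome (>= 1).
#' @param enzyme an [enzyme_spec()].
#' @param shared_marker_pairs number of consecutive species pairs
#'   (1&2, 3&4, ...) that share one identical tag.
#' @param seed random seed (mandatory for reproducibility).
#' @return list with `genomes` (named character vector), `truth`
#'   (data.frame `species`, `tag`, `shared`) and `enzyme`.
#' @export
gen_genomes <- function(n_species = 20, genome_length = 20000,
                        markers_per_species = 10,
                        enzyme = enzyme_spec(),
                        shared_marker_pairs = 0, seed = 1) {
  stopifnot(markers_per_species >= 1, n_species >= 1)
  stopifnot(shared_marker_pairs * 2 <= n_species)
  set.seed(seed)
  tl <- tag_length(enzyme)
  sl <- nchar(enzyme$recognition)
  gap <- tl + 10L
  need <- markers_per_species * gap + 2L * tl
  if (genome_length < need) {
    stop(sprintf("genome_length %d too short for %d sites (need >= %d)",
                 genome_length, markers_per_species, need), call. = FALSE)
  }

  plant_one <- function() {
    for (attempt in 1:25) {
      bg <- strsplit(clean_background(genome_length, enzyme), "")[[1]]
      slots <- floor(seq(from = tl + 1,
                         to = genome_length - tl - sl,
                         length.out = markers_per_species))
      for (p in slots) {
        bg[p:(p + sl - 1L)] <- strsplit(instantiate_pattern(enzyme$recognition),
                                        "")[[1]]
      }
      g <- paste0(bg, collapse = "")
      # verify: planting must not have created extra sites at junctions
      if (length(site_positions(g, enzyme)) == markers_per_species) {
        tags <- digest_sequence(g, enzyme)
        if (length(tags) == markers_per_species) {
          return(list(genome = g, tags = tags, slots = slots))
        }
      }
    }
    stop("failed to plant sites without side effects", call. = FALSE)
  }

  genomes <- character(n_species)
  names(genomes) <- sprintf("sp%02d", seq_len(n_species))
  tag_list <- vector("list", n_species)
  slot_list <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    repeat {
      g <- plant_one()
      # avoid accidental cross-species duplicates (vanishingly rare)
      if (!any(g$tags %in% unlist(tag_list))) break
    }
    genomes[i] <- g$genome
    tag_list[[i]] <- g$tags
    slot_list[[i]] <- g$slots
  }

  shared_flag <- lapply(tag_list, function(x) rep(FALSE, length(x)))
  if (shared_marker_pairs > 0L) {
    for (k in seq_len(shared_marker_pairs)) {
      a <- 2L * k - 1L; b <- 2L * k
      # copy species a's first tag window over species b's first slot
      pa <- slot_list[[a]][1L]
      window <- substr(genomes[a], pa - enzyme$flank_left,
                       pa + sl - 1L + enzyme$flank_right)
      pb <- slot_list[[b]][1L]
      gb <- genomes[b]
      substr(gb, pb - enzyme$flank_left,
             pb + sl - 1L + enzyme$flank_right) <- window
      # re-digest b; retry overall if the splice created side effects
      tags_b <- digest_sequence(gb, enzyme)
      if (length(tags_b) != markers_per_species) {
        stop("shared-marker splice created unexpected sites; re-run with a different seed",
             call. = FALSE)
      }
      genomes[b] <- gb
      tag_list[[b]] <- tags_b
      shared <- canonical_tag(window)
      shared_flag[[a]] <- tag_list[[a]] %in% shared
      shared_flag[[b]] <- tag_list[[b]] %in% shared
    }
  }

  truth <- data.frame(
    species = rep(names(genomes), vapply(tag_list, length, integer(1))),
    tag = unlist(tag_list),
    shared = unlist(shared_flag),
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  list(genomes = genomes, truth = truth, enzyme = enzyme)
}

#' Cohort simulation specification
#'
#' Parameters of the two-group synthetic cohort. Defaults mirror the study
#' conditions: 96 samples with a 19/96 positive (SIRS) fraction, planted
#' differential species, and a diversity deficit in the positive group.
#'
#' @param n_samples cohort size.
#' @param positive_fraction fraction of SIRS-positive samples.
#' @param n_species community richness.
#' @param n_differential number of planted differential species.
#' @param log2_fc absolute log2 fold-change of planted species (scalar or
#'   vector of length `n_differential`; alternating direction, first
#'   species enriched in the positive group).
#' @param diversity_deficit >= 0; composition tilt exponent `1 + deficit`
#'   applied to the positive group's mean composition, lowering its
#'   Shannon/Simpson diversity without changing species identity.
#' @param depth reads per sample (0 = compositions only).
#' @param error_rate per-base sequencing error rate of simulated reads.
#' @param sigma_species log-SD of the base log-normal species abundances.
#' @param sigma_sample per-sample log-normal noise around the group mean.
#' @param seed random seed (mandatory).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 96, positive_fraction = 19 / 96,
                        n_species = 20, n_differential = 5,
                        log2_fc = 2, diversity_deficit = 0.3,
                        depth = 5000, error_rate = 0.001,
                        sigma_species = 1, sigma_sample = 0.4,
                        seed = 1) {
  stopifnot(positive_fraction > 0, positive_fraction < 1,
            n_differential <= n_species, all(is.finite(log2_fc)),
            diversity_deficit >= 0, depth >= 0, error_rate >= 0,
            error_rate < 1)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples),
         positive_fraction = positive_fraction,
         n_species = as.integer(n_species),
         n_differential = as.integer(n_differential),
         log2_fc = rep_len(log2_fc, n_differential),
         diversity_deficit = diversity_deficit,
         depth = as.integer(depth),
         error_rate = error_rate,
         sigma_species = sigma_species,
         sigma_sample = sigma_sample,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# log-normal matched to a target median; sdlog from IQR on the log scale.
rlnorm_median <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}
# gamma with given shape, rescaled so the median hits the target.
rgamma_median <- function(n, median, shape = 6) {
  stats::rgamma(n, shape = shape, scale = median / stats::qgamma(0.5, shape))
}

#' Generate a synthetic clinical covariate table
#'
#' Draws per-patient covariates whose summary statistics match the cohort's
#' published characteristics: mean +/- SD fields from normal distributions,
#' skewed median (IQR) fields from log-normals matched on the log scale,
#' operative time from a median-matched gamma, and categorical fields from
#' the overall rates. By default only the three covariates that separated
#' the outcome groups differ by group: AGR (1.53 +/- 0.21 vs 1.40 +/- 0.28),
#' operative time (median 70 vs 100 min) and urinary leukocytes (median 63
#' vs 219 /uL).
#'
#' @param groups integer/logical vector of outcome labels (1 = SIRS).
#' @param seed random seed.
#' @return data.frame, one row per patient, including the `sirs` column.
#' @export
gen_clinical <- function(groups, seed = 1) {
  set.seed(seed)
  groups <- as.integer(groups)
  stopifnot(all(groups %in% c(0L, 1L)))
  n <- length(groups)
  pos <- groups == 1L

  agr <- ifelse(pos, stats::rnorm(n, 1.40, 0.28), stats::rnorm(n, 1.53, 0.21))
  agr <- pmax(agr, 0.5)  # AGR is a positive ratio
  optime <- numeric(n)
  optime[!pos] <- rgamma_median(sum(!pos), 70)
  optime[pos] <- rgamma_median(sum(pos), 100)
  uleuk <- numeric(n)
  uleuk[!pos] <- rlnorm_median(sum(!pos), 63, 1.75)
  uleuk[pos] <- rlnorm_median(sum(pos), 219, 1.60)

  data.frame(
    patient = sprintf("P%03d", seq_len(n)),
    age = round(pmin(pmax(stats::rnorm(n, 48.5, 14.3), 18), 90)),
    bmi = round(stats::rnorm(n, 24.2, 4.6), 1),
    gender = sample(c("male", "female"), n, replace = TRUE,
                    prob = c(0.594, 0.406)),
    hypertension = stats::rbinom(n, 1, 0.271),
    diabetes = stats::rbinom(n, 1, 0.115),
    urinary_leukocyte = round(uleuk, 1),
    urinary_nitrite = stats::rbinom(n, 1, 0.104),
    peripheral_leukocyte = round(stats::rnorm(n, 7.21, 1.99), 2),
    nlr = round(rlnorm_median(n, 2.21, 0.45), 2),
    plr = round(rlnorm_median(n, 117.95, 0.38), 2),
    lmr = round(rlnorm_median(n, 4.11, 0.32), 2),
    bun = round(rlnorm_median(n, 5.28, 0.33), 2),
    creatinine = round(rlnorm_median(n, 85, 0.28), 1),
    egfr = round(pmax(stats::rnorm(n, 81.79, 27.12), 5), 1),
    agr = round(agr, 2),
    asa = sample(c("II", "III"), n, replace = TRUE, prob = c(0.875, 0.125)),
    stone_volume = round(rlnorm_median(n, 1.66, 1.16), 2),
    stone_hu = round(pmax(stats::rnorm(n, 676.78, 215.83), 100)),
    side = sample(c("left", "right"), n, replace = TRUE,
                  prob = c(0.552, 0.448)),
    channel_size = sample(c("16F", "18F"), n, replace = TRUE,
                          prob = c(0.6875, 0.3125)),
    operative_time = round(optime, 1),
    sirs = groups,
    stringsAsFactors = FALSE
  )
}

# introduce per-base substitution errors into tag-length reads
mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(reads, ""))
  hit <- which(matrix(stats::runif(length(mat)) < error_rate, nrow = nrow(mat)))
  if (length(hit) > 0L) {
    mat[hit] <- vapply(mat[hit], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
  }
  apply(mat, 1, paste0, collapse = "")
}

#' Generate a two-group synthetic cohort
#'
#' Draws a log-normal base community, applies the planted log2 fold-changes
#' and the diversity-deficit tilt to the positive group's mean composition,
#' adds per-sample log-normal variation, and (optionally) samples reads
#' from the species' marker tags: the per-read species is multinomial with
#' probability proportional to `composition * T_i` (so marker-normalized
#' abundances recover the planted composition), the marker within a species
#' is uniform, the emitted strand is random, and substitution errors are
#' applied at `error_rate`. SIRS labels are assigned by group; the clinical
#' table is generated with [gen_clinical()].
#'
#' @param spec a [cohort_spec()].
#' @param markers optional named list species -> character vector of marker
#'   tags (e.g. `split(truth$tag, truth$species)` from [gen_genomes()], or
#'   `db$species_markers`). Required when `spec$depth > 0`.
#' @return list: `composition` (samples x species true compositions),
#'   `reads` (named list per sample, `NULL` when depth is 0), `clinical`
#'   (data.frame with `sirs`), `groups`, and `differential` (data.frame of
#'   planted species with signed log2 fold-changes).
#' @export
gen_cohort <- function(spec, markers = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  K <- spec$n_species
  n <- spec$n_samples
  n_pos <- max(1L, round(n * spec$positive_fraction))
  groups <- c(rep(1L, n_pos), rep(0L, n - n_pos))

  if (!is.null(markers)) {
    stopifnot(is.list(markers), length(markers) >= K)
    species <- names(markers)[seq_len(K)]
  } else {
    if (spec$depth > 0L) {
      stop("markers are required to simulate reads (depth > 0)", call. = FALSE)
    }
    species <- sprintf("sp%02d", seq_len(K))
  }

  base <- exp(stats::rnorm(K, 0, spec$sigma_species))
  base <- base / sum(base)
  names(base) <- species

  diff_idx <- if (spec$n_differential > 0L) {
    sort(sample.int(K, spec$n_differential))
  } else integer(0)
  signs <- rep_len(c(1, -1), length(diff_idx))  # +: enriched in positive group
  lfc <- spec$log2_fc * signs

  mean_pos <- base
  if (length(diff_idx) > 0L) {
    mean_pos[diff_idx] <- mean_pos[diff_idx] * 2^lfc
  }
  if (spec$diversity_deficit > 0) {
    mean_pos <- mean_pos^(1 + spec$diversity_deficit)
  }
  mean_pos <- mean_pos / sum(mean_pos)
  mean_neg <- base

  comp <- matrix(0, nrow = n, ncol = K,
                 dimnames = list(sprintf("S%03d", seq_len(n)), species))
  for (i in seq_len(n)) {
    m <- if (groups[i] == 1L) mean_pos else mean_neg
    p <- m * exp(stats::rnorm(K, 0, spec$sigma_sample))
    comp[i, ] <- p / sum(p)
  }

  reads <- NULL
  if (spec$depth > 0L) {
    Ti <- vapply(markers[species], length, integer(1))
    reads <- vector("list", n)
    names(reads) <- rownames(comp)
    for (i in seq_len(n)) {
      pr <- comp[i, ] * Ti
      counts <- as.integer(stats::rmultinom(1, spec$depth, pr / sum(pr)))
      rd <- unlist(lapply(seq_len(K), function(j) {
        if (counts[j] == 0L) return(character(0))
        tags <- markers[[species[j]]]
        sample(tags, counts[j], replace = TRUE)
      }), use.names = FALSE)
      if (length(rd) > 0L) {
        flip <- stats::runif(length(rd)) < 0.5
        rd[flip] <- revcomp(rd[flip])
        rd <- mutate_reads(rd, spec$error_rate)
      }
      reads[[i]] <- rd
    }
  }

  clinical <- gen_clinical(groups, seed = derive_seed(spec$seed, 101L))
  clinical$sample <- rownames(comp)

  differential <- data.frame(
    species = species[diff_idx],
    log2_fc = lfc,
    enriched_group = ifelse(lfc > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  list(composition = comp, reads = reads, clinical = clinical,
       groups = groups, differential = differential)
}

#' Write simulated reads as FASTA files
#' @param reads named list sample -> character vector of reads.
#' @param dir output directory.
#' @return invisibly, paths written.
#' @export
write_reads <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(reads), function(s) {
    p <- file.path(dir, paste0(s, ".fasta"))
    x <- Biostrings::DNAStringSet(reads[[s]])
    names(x) <- sprintf("%s_read%06d", s, seq_along(x))
    Biostrings::writeXStringSet(x, p)
    p
  }, character(1))
  invisible(paths)
}
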