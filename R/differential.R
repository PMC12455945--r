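# Differential-taxon analyses: per-taxon Wilcoxon, LDA effect sizes
# (lefse_lite), linear-model associations, indicator-species analysis, and
# the consensus candidate set.

# direction helper: group with the higher median (ties broken by mean)
enriched_by_location <- function(x, labels) {
  levs <- levels(labels)
  med <- tapply(x, labels, stats::median)
  if (med[1L] != med[2L]) {
    levs[which.max(med)]
  } else {
    mn <- tapply(x, labels, mean)
    if (mn[1L] == mn[2L]) NA_character_ else levs[which.max(mn)]
  }
}

check_two_groups <- function(profile, labels, min_per_group = 2L) {
  stopifnot(is.matrix(profile))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must define exactly two groups",
                                  call. = FALSE)
  if (length(labels) != nrow(profile)) {
    stop("labels must align with profile rows", call. = FALSE)
  }
  if (any(table(labels) < min_per_group)) {
    stop("each group needs at least ", min_per_group, " samples",
         call. = FALSE)
  }
  labels
}

#' Per-taxon Wilcoxon rank-sum tests
#'
#' Two-sided Wilcoxon rank-sum test of relative abundance per taxon
#' (exact at small n without ties, tie-corrected normal approximation
#' otherwise), with Benjamini-Hochberg adjustment across taxa. The
#' enriched group is the one with the higher median (tie: higher mean).
#' Taxa constant across all samples get `p = 1`.
#'
#' @param profile abundance matrix (samples x species).
#' @param labels two-group vector aligned with rows.
#' @param sig_q taxa with `q < sig_q` are marked significant (default 0.05).
#' @return data.frame: taxon, method, statistic, effect (difference of
#'   group means), p, q, enriched_group, significant.
#' @export
wilcoxon_by_taxon <- function(profile, labels, sig_q = 0.05) {
  labels <- check_two_groups(profile, labels)
  levs <- levels(labels)
  res <- lapply(colnames(profile), function(taxon) {
    x <- profile[, taxon]
    if (length(unique(x)) == 1L) {
      return(data.frame(taxon = taxon, method = "wilcoxon",
                        statistic = NA_real_, effect = 0, p = 1,
                        enriched_group = NA_character_,
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x[labels == levs[2L]], x[labels == levs[1L]])
    )
    data.frame(
      taxon = taxon, method = "wilcoxon",
      statistic = unname(wt$statistic),
      effect = mean(x[labels == levs[2L]]) - mean(x[labels == levs[1L]]),
      p = wt$p.value,
      enriched_group = enriched_by_location(x, labels),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < sig_q
  out[, c("taxon", "method", "statistic", "effect", "p", "q",
          "enriched_group", "significant")]
}

#' LDA effect sizes for differential taxa (lefse_lite)
#'
#' A two-stage procedure in the spirit of LEfSe, concretely specified for a
#' two-group design. Stage 1 screens each taxon with a Kruskal-Wallis test
#' at `kw_alpha`. Stage 2 scores each surviving taxon by the between-class
#' separation of its abundance (pre-scaled to the per-sample 1e6
#' convention): on each of `n_boot` within-class bootstrap subsamples the
#' absolute difference of class means is taken, the bootstrap average is the
#' effect size, and the LDA score is `log10` of that separation (floored at
#' 0), signed towards the enriched class. Taxa with `|score| >=
#' lda_threshold` are reported as discriminative.
#'
#' @param profile abundance matrix (rows sum to 1; rescaled to 1e6).
#' @param labels two-group vector (each group >= 3 samples).
#' @param kw_alpha stage-1 screen level (default 0.05).
#' @param lda_threshold minimum absolute LDA score (default 3.0).
#' @param n_boot bootstrap subsamples (default 30).
#' @param seed random seed for the bootstraps.
#' @return data.frame: taxon, method, statistic (KW chi-squared), effect
#'   (signed LDA score), p (KW), q (BH), enriched_group, significant
#'   (screen passed and `|score| >= lda_threshold`).
#' @export
lefse_lite <- function(profile, labels, kw_alpha = 0.05, lda_threshold = 3.0,
                       n_boot = 30, seed = 1) {
  labels <- check_two_groups(profile, labels, min_per_group = 3L)
  levs <- levels(labels)
  scaled <- profile * 1e6
  set.seed(seed)

  res <- lapply(colnames(profile), function(taxon) {
    x <- scaled[, taxon]
    if (length(unique(x)) == 1L) {
      kw_p <- 1; kw_stat <- 0
    } else {
      kw <- suppressWarnings(stats::kruskal.test(x, labels))
      kw_p <- kw$p.value; kw_stat <- unname(kw$statistic)
    }
    score <- 0
    enriched <- NA_character_
    if (is.finite(kw_p) && kw_p < kw_alpha) {
      i1 <- which(labels == levs[1L]); i2 <- which(labels == levs[2L])
      seps <- vapply(seq_len(n_boot), function(b) {
        b1 <- sample(i1, length(i1), replace = TRUE)
        b2 <- sample(i2, length(i2), replace = TRUE)
        mean(x[b2]) - mean(x[b1])
      }, numeric(1))
      sep <- mean(seps)
      score <- sign(sep) * log10(max(abs(sep), 1))
      enriched <- if (sep > 0) levs[2L] else levs[1L]
    }
    data.frame(taxon = taxon, method = "lefse", statistic = kw_stat,
               effect = score, p = kw_p, enriched_group = enriched,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < kw_alpha & abs(out$effect) >= lda_threshold
  out[, c("taxon", "method", "statistic", "effect", "p", "q",
          "enriched_group", "significant")]
}

# log2 transform with half-minimum pseudocount (MaAsLin2-style default)
log_transform_profile <- function(profile) {
  pos <- profile[profile > 0]
  if (length(pos) == 0L) stop("profile is all zero", call. = FALSE)
  global_half_min <- min(pos) / 2
  apply(profile, 2, function(x) {
    pc <- if (any(x > 0)) min(x[x > 0]) / 2 else global_half_min
    log2(x + pc)
  })
}

#' Linear-model associations of taxa with the outcome
#'
#' Per-taxon general linear model on log2-transformed total-sum-scaled
#' abundance (half-minimum pseudocount for zeros) with the group indicator
#' and optional covariates — the default analysis of multivariable
#' microbiome association tools. Reports the group coefficient, its Wald
#' p-value and BH q-value; associations at `q < q_threshold` are flagged.
#'
#' @param profile abundance matrix (samples x species, rows sum to 1).
#' @param labels two-group vector.
#' @param covariates optional data.frame of additional model terms.
#' @param q_threshold significance cut on BH q (default 0.25).
#' @return data.frame: taxon, method, statistic (t value), effect (group
#'   coefficient on the log2 scale), p, q, enriched_group, significant.
#'   All-zero/constant taxa are skipped with a warning.
#' @export
linear_assoc <- function(profile, labels, covariates = NULL,
                         q_threshold = 0.25) {
  labels <- check_two_groups(profile, labels)
  levs <- levels(labels)
  keep <- apply(profile, 2, function(x) length(unique(x)) > 1L)
  if (!all(keep)) {
    warning("skipping constant taxa: ",
            paste(colnames(profile)[!keep], collapse = ", "))
  }
  y_mat <- log_transform_profile(profile[, keep, drop = FALSE])
  grp <- as.integer(labels == levs[2L])
  dat0 <- data.frame(grp = grp)
  if (!is.null(covariates)) dat0 <- cbind(dat0, covariates)

  res <- lapply(colnames(y_mat), function(taxon) {
    dat <- dat0
    dat$y <- y_mat[, taxon]
    fit <- stats::lm(y ~ ., data = dat)
    co <- summary(fit)$coefficients
    if (!("grp" %in% rownames(co))) {
      warning("singular design for taxon ", taxon, "; skipped")
      return(NULL)
    }
    est <- co["grp", "Estimate"]
    data.frame(
      taxon = taxon, method = "linear_model",
      statistic = co["grp", "t value"],
      effect = est, p = co["grp", "Pr(>|t|)"],
      enriched_group = if (est > 0) levs[2L] else levs[1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_threshold
  out[, c("taxon", "method", "statistic", "effect", "p", "q",
          "enriched_group", "significant")]
}

# IndVal statistic for every taxon (columns) given a two-group labeling:
# A (specificity) = group mean / sum of group means, B (fidelity) =
# occurrence fraction; IndVal_g = A*B*100, reported as the max over groups.
indval_stat <- function(profile, labels) {
  levs <- levels(labels)
  means <- rbind(colMeans(profile[labels == levs[1L], , drop = FALSE]),
                 colMeans(profile[labels == levs[2L], , drop = FALSE]))
  occ <- rbind(colMeans(profile[labels == levs[1L], , drop = FALSE] > 0),
               colMeans(profile[labels == levs[2L], , drop = FALSE] > 0))
  tot <- pmax(colSums(means), .Machine$double.xmin)
  a <- sweep(means, 2, tot, "/")
  iv <- a * occ * 100
  best <- apply(iv, 2, which.max)
  list(indval = iv[cbind(best, seq_len(ncol(iv)))],
       group = levs[best])
}

#' Indicator species analysis
#'
#' For each taxon and group: specificity `A` = the group's mean abundance
#' over the sum of group mean abundances, fidelity `B` = the fraction of
#' the group's samples where the taxon occurs; `IndVal = A * B * 100`,
#' reported for the group maximizing it. Significance is assessed by
#' permuting the labels: all distinct assignments are enumerated when
#' `choose(n, n1) <= exact_limit` (`p = count/total`), otherwise `n_perm`
#' random permutations (`p = (1+count)/(1+n_perm)`). Taxa absent everywhere
#' are skipped.
#'
#' @param profile abundance matrix.
#' @param labels two-group vector.
#' @param n_perm random permutations (default 999).
#' @param seed random seed.
#' @param exact_limit exhaustive-enumeration cutoff (default 500).
#' @param sig_p significance level on the permutation p (default 0.05).
#' @return data.frame: taxon, method, statistic (IndVal in `[0, 100]`),
#'   effect (same), p, q (BH), enriched_group, significant.
#' @export
indval <- function(profile, labels, n_perm = 999, seed = 1,
                   exact_limit = 500, sig_p = 0.05) {
  labels <- check_two_groups(profile, labels)
  present <- colSums(profile > 0) > 0
  if (!all(present)) {
    warning("skipping taxa absent everywhere: ",
            paste(colnames(profile)[!present], collapse = ", "))
  }
  prof <- profile[, present, drop = FALSE]
  obs <- indval_stat(prof, labels)

  n <- nrow(prof)
  n1 <- sum(labels == levels(labels)[1L])
  n_assign <- choose(n, n1)
  if (n_assign <= exact_limit) {
    combos <- utils::combn(n, n1)
    count <- numeric(ncol(prof))
    for (j in seq_len(ncol(combos))) {
      lab <- factor(ifelse(seq_len(n) %in% combos[, j],
                           levels(labels)[1L], levels(labels)[2L]),
                    levels = levels(labels))
      count <- count + (indval_stat(prof, lab)$indval >= obs$indval - 1e-12)
    }
    p <- count / ncol(combos)
  } else {
    set.seed(seed)
    count <- numeric(ncol(prof))
    for (b in seq_len(n_perm)) {
      lab <- labels[sample.int(n)]
      count <- count + (indval_stat(prof, lab)$indval >= obs$indval - 1e-12)
    }
    p <- (1 + count) / (1 + n_perm)
  }

  out <- data.frame(
    taxon = colnames(prof), method = "indval",
    statistic = obs$indval, effect = obs$indval, p = p,
    enriched_group = obs$group, stringsAsFactors = FALSE
  )
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < sig_p
  rownames(out) <- NULL
  out[, c("taxon", "method", "statistic", "effect", "p", "q",
          "enriched_group", "significant")]
}

#' Consensus differential candidates
#'
#' Intersects the `top_n` most abundant species (by mean relative
#' abundance) with the union of taxa any method flagged as significant.
#' This is the biomarker pre-screen feeding random-forest selection:
#' abundant species called differential by at least one approach.
#'
#' @param results list of method result data.frames (each with `taxon` and
#'   `significant` columns).
#' @param profile abundance matrix used for the abundance ranking.
#' @param top_n_abundance size of the abundance short-list (default 50).
#' @return character vector of candidate taxa, ordered by decreasing mean
#'   abundance (possibly empty).
#' @export
consensus_candidates <- function(results, profile, top_n_abundance = 50) {
  stopifnot(is.list(results), length(results) >= 1L)
  flagged <- unique(unlist(lapply(results, function(r) {
    r$taxon[r$significant]
  })))
  mean_ab <- sort(colMeans(profile), decreasing = TRUE)
  top <- names(mean_ab)[seq_len(min(top_n_abundance, length(mean_ab)))]
  out <- top[top %in% flagged]
  if (length(out) == 0L) message("no consensus candidates")
  out
}
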