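#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: `S_obs + F1*(F1-1) / (2*(F2+1))`, where `F1` and
#' `F2` are the numbers of singletons and doubletons. Defined on integer
#' read counts only — relative abundances have no singletons.
#'
#' @param counts non-negative integer vector of per-species read counts for
#'   one sample.
#' @return Chao1 estimate (numeric scalar).
#' @examples
#' chao1(c(5, 5, 5))  # 3: no singletons
#' chao1(c(1, 1, 2))  # 3.5
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("chao1 requires non-negative integer counts", call. = FALSE)
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `H = -sum(p * log(p))` with `0 * log(0) := 0`. Input is renormalized
#' (with a warning) if it does not sum to one.
#'
#' @param p non-negative composition vector.
#' @return Shannon index (natural log).
#' @export
shannon <- function(p) {
  p <- normalize_composition(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini-Simpson diversity index
#'
#' `1 - sum(p^2)`, the probability that two random draws are different
#' species. Set `inverse = TRUE` for inverse Simpson `1 / sum(p^2)`.
#'
#' @param p non-negative composition vector.
#' @param inverse report inverse Simpson instead of Gini-Simpson.
#' @return Simpson index.
#' @export
simpson <- function(p, inverse = FALSE) {
  p <- normalize_composition(p)
  if (inverse) 1 / sum(p^2) else 1 - sum(p^2)
}

normalize_composition <- function(p) {
  if (any(p < 0)) stop("composition entries must be non-negative", call. = FALSE)
  s <- sum(p)
  if (s == 0) stop("all-zero composition", call. = FALSE)
  if (abs(s - 1) > 1e-9) {
    warning("composition does not sum to 1; renormalizing")
    p <- p / s
  }
  p
}

#' Per-sample alpha diversity table
#'
#' Chao1 is computed on integer read counts (`S` from the hit table),
#' Shannon and Simpson on relative abundances — respecting each
#' estimator's domain.
#'
#' @param profile abundance matrix (samples x species).
#' @param hits optional hit data.frame (with `sample`, `species`, `S`) used
#'   for Chao1; if absent, Chao1 is `NA`.
#' @return data.frame sample / chao1 / shannon / simpson.
#' @export
alpha_diversity <- function(profile, hits = NULL) {
  samples <- rownames(profile)
  ch <- rep(NA_real_, length(samples))
  if (!is.null(hits)) {
    used <- if ("retained" %in% names(hits)) hits[hits$retained, ] else hits
    ch <- vapply(samples, function(s) {
      cnt <- used$S[used$sample == s]
      if (length(cnt) == 0L) 0 else chao1(cnt)
    }, numeric(1))
  }
  data.frame(
    sample = samples,
    chao1 = ch,
    shannon = apply(profile, 1, function(p) if (sum(p) > 0) shannon(p) else 0),
    simpson = apply(profile, 1, function(p) if (sum(p) > 0) simpson(p) else 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Beta-diversity distance matrix
#'
#' Pairwise sample distances: Bray-Curtis (`sum|x-y| / sum(x+y)`), binary
#' Jaccard (`1 - |A∩B| / |A∪B|` on presence/absence) or Euclidean. Pairs of
#' all-zero samples get distance 0 with a warning.
#'
#' @param profile abundance matrix (samples x species), >= 2 samples.
#' @param metric `"bray_curtis"`, `"binary_jaccard"` or `"euclidean"`.
#' @return a `dist` object with attribute `metric`.
#' @export
distance_matrix <- function(profile,
                            metric = c("bray_curtis", "binary_jaccard",
                                       "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(profile), nrow(profile) >= 2L)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(profile, method = "bray"),
    binary_jaccard = vegan::vegdist(profile, method = "jaccard", binary = TRUE),
    euclidean = stats::dist(profile)
  )
  if (anyNA(d)) {
    warning("all-zero sample pair(s): distance set to 0")
    d[is.na(d)] <- 0
  }
  attr(d, "metric") <- metric
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers the squared distances and eigendecomposes the Gram
#' matrix. Axes with negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but excluded from the
#' variance-explained denominator.
#'
#' @param d a `dist` object.
#' @param k number of axes to return (`k < n`).
#' @return list with `coordinates` (n x k'), `eigenvalues` (all n),
#'   `variance_explained` (per returned axis, over positive eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  n <- attr(d, "Size")
  stopifnot(k >= 1, k < n)
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > 1e-8)
  if (k > n_pos) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axis/axes",
                    n_pos, n_pos))
    k <- n_pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(
    coordinates = coords,
    eigenvalues = eig,
    variance_explained = eig[seq_len(k)] / sum(eig[eig > 0])
  )
}

#' Two-group PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix.
#' The pseudo-F statistic is computed from the within/between decomposition
#' of squared distances: `SS_total = sum(d^2)/n`, `SS_within = sum_g
#' (within-group d^2)/n_g`, `F = (SS_between/(g-1)) / (SS_within/(n-g))`.
#' The p-value comes from label permutations: when the number of distinct
#' two-group assignments `choose(n, n1)` is at most `exact_limit` all of
#' them are enumerated and `p = #(F_perm >= F_obs) / total` (the observed
#' assignment is one of them); otherwise `n_perm` random permutations give
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param d a `dist` object.
#' @param labels two-group factor/vector aligned with the samples of `d`.
#' @param n_perm number of random permutations (default 999).
#' @param seed random seed for the permutations.
#' @param exact_limit enumerate exhaustively when `choose(n, n1)` is at
#'   most this (default 500).
#' @return list: `f` (pseudo-F), `p`, `n_perm_used`, `exact` (logical),
#'   `r2` (proportion of SS between groups).
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1, exact_limit = 500) {
  labels <- as.factor(labels)
  n <- attr(d, "Size")
  stopifnot(length(labels) == n, nlevels(labels) == 2L)
  if (any(table(labels) < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  d2 <- as.matrix(d)^2
  g <- nlevels(labels)

  f_stat <- function(lab) {
    ssw <- 0
    for (lev in levels(lab)) {
      idx <- which(lab == lev)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sst <- sum(d2) / (2 * n)
    ssb <- sst - ssw
    if (ssw <= .Machine$double.eps * sst) return(Inf)
    (ssb / (g - 1)) / (ssw / (n - g))
  }

  f_obs <- f_stat(labels)
  sst <- sum(d2) / (2 * n)
  if (sst <= .Machine$double.eps) {
    # constant (all-zero) distance matrix carries no group signal
    return(list(f = 0, p = 1, n_perm_used = 0L, exact = TRUE, r2 = 0))
  }
  ssw_obs <- sum(vapply(levels(labels), function(lev) {
    idx <- which(labels == lev)
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  r2 <- (sst - ssw_obs) / sst

  n1 <- sum(labels == levels(labels)[1L])
  n_assign <- choose(n, n1)
  if (n_assign <= exact_limit) {
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, function(idx) {
      lab <- factor(ifelse(seq_len(n) %in% idx, levels(labels)[1L],
                           levels(labels)[2L]), levels = levels(labels))
      f_stat(lab)
    })
    p <- sum(fs >= f_obs - 1e-12) / length(fs)
    return(list(f = f_obs, p = p, n_perm_used = length(fs), exact = TRUE,
                r2 = r2))
  }

  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    lab <- labels[sample.int(n)]
    if (f_stat(lab) >= f_obs - 1e-12) count <- count + 1L
  }
  list(f = f_obs, p = (1 + count) / (1 + n_perm),
       n_perm_used = as.integer(n_perm), exact = FALSE, r2 = r2)
}

#' Shared/unique species summary between two groups
#'
#' Counts the species present in both groups, and unique to each, from a
#' presence threshold on the abundance profile — the numbers behind a
#' two-set Venn diagram — and expresses each count as a percentage of the
#' total species pool. Alternatively pass pre-computed `counts` (named
#' vector: shared, then one entry per group).
#'
#' @param profile abundance matrix (samples x species).
#' @param labels two-group vector aligned with rows of `profile`.
#' @param counts optional named numeric vector of pre-computed counts
#'   (`shared` first); overrides `profile`/`labels`.
#' @return data.frame category / n / pct, plus attribute `total`.
#' @export
species_overlap <- function(profile = NULL, labels = NULL, counts = NULL) {
  if (is.null(counts)) {
    stopifnot(is.matrix(profile), !is.null(labels),
              length(labels) == nrow(profile))
    labels <- as.factor(labels)
    stopifnot(nlevels(labels) == 2L)
    present <- lapply(levels(labels), function(lev) {
      colnames(profile)[colSums(profile[labels == lev, , drop = FALSE] > 0) > 0]
    })
    shared <- length(intersect(present[[1L]], present[[2L]]))
    uniq <- vapply(1:2, function(i) {
      length(setdiff(present[[i]], present[[3L - i]]))
    }, numeric(1))
    counts <- c(shared = shared, uniq)
    names(counts)[2:3] <- paste0("unique_", levels(labels))
  }
  total <- sum(counts)
  out <- data.frame(
    category = names(counts),
    n = as.numeric(counts),
    pct = round(100 * as.numeric(counts) / total, 2),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  out
}
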