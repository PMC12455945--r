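# Independent brute-force oracles used to cross-check the implementation.
# Deliberately naive; they share no code with the package internals.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# IUPAC code -> character class, built independently of the package
oracle_iupac_class <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

oracle_pattern_regex <- function(pattern) {
  paste0(oracle_iupac_class[strsplit(pattern, "")[[1]]], collapse = "")
}

# position-by-position scan of both strands; returns canonical tag set
oracle_digest <- function(sequence, enzyme) {
  sl <- nchar(enzyme$recognition)
  tl <- enzyme$flank_left + sl + enzyme$flank_right
  n <- nchar(sequence)
  fwd_re <- paste0("^", oracle_pattern_regex(enzyme$recognition), "$")
  rev_re <- paste0("^", oracle_pattern_regex(oracle_revcomp(enzyme$recognition)), "$")
  tags <- character(0)
  for (i in seq_len(max(n - sl + 1L, 0L))) {
    site <- substr(sequence, i, i + sl - 1L)
    if (grepl(fwd_re, site)) {
      s <- i - enzyme$flank_left; e <- i + sl - 1L + enzyme$flank_right
      if (s >= 1L && e <= n) tags <- c(tags, substr(sequence, s, e))
    }
    if (grepl(rev_re, site)) {
      s <- i - enzyme$flank_right; e <- i + sl - 1L + enzyme$flank_left
      if (s >= 1L && e <= n) tags <- c(tags, substr(sequence, s, e))
    }
  }
  tags <- tags[!grepl("N", tags, fixed = TRUE)]
  sort(unique(oracle_canonical(tags)))
}

# naive pairwise distance loops
oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  d
}
oracle_jaccard <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- m[i, ] > 0; b <- m[j, ] > 0
    d[i, j] <- 1 - sum(a & b) / sum(a | b)
  }
  d
}
oracle_euclid <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  }
  d
}

# AUC by counting over all positive-negative score pairs
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# random fixture: two-group abundance profile with planted effects
random_profile <- function(n_per_group = 10, n_taxa = 20, seed = 1,
                           lfc = NULL) {
  set.seed(seed)
  n <- 2 * n_per_group
  base <- exp(rnorm(n_taxa))
  m <- matrix(0, n, n_taxa,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("taxon", seq_len(n_taxa))))
  groups <- rep(c(0L, 1L), each = n_per_group)
  for (i in seq_len(n)) {
    mu <- base
    if (!is.null(lfc) && groups[i] == 1L) {
      mu[seq_along(lfc)] <- mu[seq_along(lfc)] * 2^lfc
    }
    p <- mu * exp(rnorm(n_taxa, 0, 0.4))
    m[i, ] <- p / sum(p)
  }
  list(profile = m, groups = groups)
}
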