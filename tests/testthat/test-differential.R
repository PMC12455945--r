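# Differential-taxon methods and the consensus candidate set.

test_that("per-taxon Wilcoxon handles separation, constants and ties", {
  prof <- matrix(0, nrow = 10, ncol = 3,
                 dimnames = list(paste0("s", 1:10), c("sep", "flat", "same")))
  groups <- rep(c(0, 1), each = 5)
  prof[, "sep"] <- c(1:5, 11:15) / 100        # complete separation
  prof[, "flat"] <- 0.5                        # constant everywhere
  prof[, "same"] <- rep(c(0.2, 0.3, 0.4, 0.5, 0.6), 2)  # identical groups
  res <- wilcoxon_by_taxon(prof, groups)
  expect_equal(res$p[res$taxon == "sep"], 2 / 252)  # exact: 2 / choose(10,5)
  expect_equal(res$p[res$taxon == "flat"], 1)
  # identical distributions: rank-sum statistic at its null mean
  expect_equal(res$statistic[res$taxon == "same"], 5 * 5 / 2)
  expect_equal(res$enriched_group[res$taxon == "sep"], "1")
})

test_that("Wilcoxon p-values match an exhaustive rank-permutation oracle", {
  set.seed(211)
  n1 <- 4
  prof <- matrix(runif(8 * 30), nrow = 8,
                 dimnames = list(paste0("s", 1:8), paste0("t", 1:30)))
  prof <- prof / rowSums(prof)
  groups <- rep(c(0, 1), each = n1)
  res <- wilcoxon_by_taxon(prof, groups)
  splits <- utils::combn(8, n1)
  for (j in c(1, 7, 18, 30)) {
    x <- prof[, j]
    r <- rank(x)
    w_obs <- sum(r[groups == 1]) - n1 * (n1 + 1) / 2
    ws <- apply(splits, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    # two-sided exhaustive permutation p of the rank-sum statistic
    mu <- n1 * n1 / 2
    p_oracle <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
    expect_equal(res$p[j], p_oracle, tolerance = 1e-12)
  }
})

test_that("BH q-values are monotone in p-rank and bound p from above", {
  set.seed(213)
  fix <- random_profile(n_per_group = 6, n_taxa = 25, seed = 3,
                        lfc = c(2, -2))
  res <- wilcoxon_by_taxon(fix$profile, fix$groups)
  expect_true(all(res$q >= res$p - 1e-12))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
})

test_that("swapping group labels flips enrichment but not p-values", {
  fix <- random_profile(n_per_group = 8, n_taxa = 15, seed = 5,
                        lfc = c(2, -2, 1.5))
  labs <- ifelse(fix$groups == 1, "pos", "neg")
  swapped <- ifelse(fix$groups == 1, "neg", "pos")
  r1 <- wilcoxon_by_taxon(fix$profile, labs)
  r2 <- wilcoxon_by_taxon(fix$profile, swapped)
  expect_equal(r1$p, r2$p)
  keep <- !is.na(r1$enriched_group)
  expect_true(all(r1$enriched_group[keep] != r2$enriched_group[keep]))
  l1 <- linear_assoc(fix$profile, labs)
  l2 <- linear_assoc(fix$profile, swapped)
  expect_equal(l1$effect, -l2$effect)
  expect_equal(l1$p, l2$p)
})

test_that("lefse_lite screens flat features and scores planted effects", {
  set.seed(221)
  n <- 20
  groups <- rep(c("neg", "pos"), each = n / 2)
  # planted: 1e5 vs 1e1 on the 1e6 scale = 0.1 vs 1e-5 relative abundance
  strong <- c(abs(rnorm(n / 2, 1e-5, 2e-6)), abs(rnorm(n / 2, 0.1, 0.005)))
  flat <- rep(0.2, n)
  filler <- matrix(abs(rnorm(n * 8, 0.1, 0.02)), nrow = n)
  prof <- cbind(strong = strong, flat = flat, filler)
  colnames(prof)[3:10] <- paste0("f", 1:8)
  res <- lefse_lite(prof, groups, seed = 1)
  expect_false(res$significant[res$taxon == "flat"])
  srow <- res[res$taxon == "strong", ]
  expect_true(srow$significant)
  expect_gte(abs(srow$effect), 3)
  expect_equal(srow$enriched_group, "pos")
  expect_error(lefse_lite(prof[c(1:2, 11:12), ], groups[c(1:2, 11:12)]),
               "at least 3")
})

test_that("lefse_lite null discoveries are rare", {
  hits <- 0L
  n_feat <- 50
  for (s in 1:5) {
    fix <- random_profile(n_per_group = 10, n_taxa = n_feat, seed = 400 + s)
    res <- lefse_lite(fix$profile, fix$groups, seed = s)
    hits <- hits + sum(res$significant)
  }
  # discoveries bounded by the stage-1 KW screen's level (MC slack x2)
  expect_lte(hits / (5 * n_feat), 0.10)
})

test_that("linear associations recover a planted fold-change with its sign", {
  fix <- random_profile(n_per_group = 48, n_taxa = 20, seed = 231,
                        lfc = c(2, -2))
  labs <- ifelse(fix$groups == 1, "pos", "neg")
  res <- linear_assoc(fix$profile, labs)
  expect_true(res$significant[res$taxon == "taxon1"])
  expect_gt(res$effect[res$taxon == "taxon1"], 0)
  expect_equal(res$enriched_group[res$taxon == "taxon1"], "pos")
  expect_true(res$significant[res$taxon == "taxon2"])
  expect_lt(res$effect[res$taxon == "taxon2"], 0)
})

test_that("linear associations skip constant taxa and stay calibrated under the null", {
  fix <- random_profile(n_per_group = 10, n_taxa = 10, seed = 233)
  prof <- cbind(fix$profile, allzero = 0)
  expect_warning(res <- linear_assoc(prof, fix$groups), "constant")
  expect_false("allzero" %in% res$taxon)
  # permuted labels: q < 0.25 discoveries stay near zero
  hits <- 0L
  for (s in 1:10) {
    set.seed(500 + s)
    fixn <- random_profile(n_per_group = 10, n_taxa = 30, seed = 600 + s)
    hits <- hits + sum(linear_assoc(fixn$profile,
                                    sample(fixn$groups))$significant)
  }
  expect_lte(hits / (10 * 30), 0.1)
})

test_that("IndVal hits its closed-form values on perfect and even indicators", {
  prof <- rbind(s1 = c(0.5, 0.5), s2 = c(0.6, 0.4), s3 = c(0.7, 0.3),
                s4 = c(0, 1), s5 = c(0, 1), s6 = c(0, 1))
  colnames(prof) <- c("onlyneg", "everywhere")
  labs <- c("neg", "neg", "neg", "pos", "pos", "pos")
  res <- indval(prof, labs, seed = 1)
  # present in every negative sample, absent from positives -> IndVal 100
  expect_equal(res$statistic[res$taxon == "onlyneg"], 100)
  expect_equal(res$enriched_group[res$taxon == "onlyneg"], "neg")
  expect_true(res$statistic[res$taxon == "onlyneg"] <= 100)
  # equal group means, 100% occurrence in both groups -> IndVal 50
  prof2 <- rbind(s1 = c(0.3, 0.7), s2 = c(0.4, 0.6),
                 s3 = c(0.3, 0.7), s4 = c(0.4, 0.6))
  colnames(prof2) <- c("a", "b")
  res2 <- indval(prof2, c("neg", "neg", "pos", "pos"), seed = 1)
  expect_equal(res2$statistic, c(50, 50))
})

test_that("IndVal permutation p equals exhaustive enumeration at 3+3", {
  set.seed(241)
  prof <- matrix(rexp(6 * 8), nrow = 6,
                 dimnames = list(paste0("s", 1:6), paste0("t", 1:8)))
  prof <- prof / rowSums(prof)
  labs <- factor(rep(c("a", "b"), each = 3))
  res <- indval(prof, labs)
  # oracle: recompute IndVal and its null over all 20 splits, from scratch
  iv_max <- function(lab) {
    vapply(seq_len(ncol(prof)), function(j) {
      x <- prof[, j]
      ma <- mean(x[lab == "a"]); mb <- mean(x[lab == "b"])
      aa <- ma / (ma + mb); ab <- mb / (ma + mb)
      ba <- mean(x[lab == "a"] > 0); bb <- mean(x[lab == "b"] > 0)
      max(aa * ba, ab * bb) * 100
    }, numeric(1))
  }
  obs <- iv_max(labs)
  splits <- utils::combn(6, 3)
  null_iv <- apply(splits, 2, function(idx) {
    iv_max(factor(ifelse(seq_len(6) %in% idx, "a", "b"),
                  levels = c("a", "b")))
  })
  p_oracle <- rowMeans(null_iv >= obs - 1e-12)
  expect_equal(res$statistic, obs, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_true(all(res$statistic >= 0 & res$statistic <= 100))
})

test_that("consensus candidates intersect abundance rank with significance", {
  set.seed(251)
  n_taxa <- 60
  mean_ab <- sort(rexp(n_taxa), decreasing = TRUE)
  prof <- matrix(rep(mean_ab, each = 10), nrow = 10)
  colnames(prof) <- paste0("t", seq_len(n_taxa))
  prof <- prof / rowSums(prof)
  # one method flags 3 species inside the top 50 and one ranked 51st
  fake <- data.frame(taxon = c("t3", "t10", "t40", "t51"),
                     significant = TRUE)
  cand <- consensus_candidates(list(fake), prof, top_n_abundance = 50)
  expect_setequal(cand, c("t3", "t10", "t40"))
  expect_false("t51" %in% cand)
  # ordering follows mean abundance
  expect_equal(cand, c("t3", "t10", "t40"))
  # empty intersection -> empty list
  none <- data.frame(taxon = "t55", significant = TRUE)
  expect_message(c2 <- consensus_candidates(list(none), prof),
                 "no consensus")
  expect_length(c2, 0L)
})

test_that("consensus recovers planted differential species at high effect size", {
  rec <- numeric(3)
  for (s in 1:3) {
    spec <- cohort_spec(n_samples = 96, n_species = 25, n_differential = 5,
                        log2_fc = 3, diversity_deficit = 0, depth = 0,
                        seed = 800 + s)
    co <- gen_cohort(spec)
    res <- list(
      wilcoxon = wilcoxon_by_taxon(co$composition, co$groups),
      indval = indval(co$composition, co$groups, seed = s)
    )
    cand <- consensus_candidates(res, co$composition)
    rec[s] <- mean(co$differential$species %in% cand)
  }
  expect_gte(mean(rec), 0.8)
})
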