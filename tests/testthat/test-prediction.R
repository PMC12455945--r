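# Clinical comparisons, logistic modeling, ROC/AUC, RF selection, CV,
# Spearman correlations and the combined model.

test_that("cohort summary reports incidence to one decimal", {
  s <- cohort_summary(c(rep(1, 19), rep(0, 77)))
  expect_equal(s$n, 96L)
  expect_equal(s$events, 19L)
  expect_equal(s$incidence_pct, 19.8)
})

test_that("group comparison routes tests and matches Fisher enumeration", {
  # 2x2 table with perfect association: [[10,0],[0,10]]
  clin <- data.frame(
    flag = rep(c("yes", "no"), each = 10),
    sirs = rep(c(1L, 0L), each = 10)
  )
  res <- compare_groups(clin, "sirs")
  expect_equal(res$test, "fisher")
  # oracle: two-sided Fisher p by hypergeometric enumeration
  p_tab <- dhyper(0:10, 10, 10, 10)
  p_obs <- dhyper(10, 10, 10, 10)
  p_oracle <- sum(p_tab[p_tab <= p_obs + 1e-12])
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # identical groups: everything non-significant on a deterministic fixture
  clin2 <- data.frame(
    x_norm = rep(c(1.2, 3.4, 2.2, 4.8, 2.9, 3.3), 2),
    x_skew = rep(c(1, 2, 4, 8, 16, 32), 2),
    sirs = rep(c(0L, 1L), each = 6)
  )
  res2 <- compare_groups(clin2, "sirs")
  expect_true(all(res2$p > 0.99))
})

test_that("synthetic cohort flags AGR and operative time most of the time", {
  flags <- matrix(FALSE, 10, 2, dimnames = list(NULL, c("agr", "operative_time")))
  for (s in 1:10) {
    groups <- c(rep(1L, 19), rep(0L, 77))
    clin <- gen_clinical(groups, seed = 300 + s)
    res <- compare_groups(clin, "sirs",
                          variables = c("agr", "operative_time", "age", "bmi"))
    flags[s, "agr"] <- res$p[res$variable == "agr"] < 0.05
    flags[s, "operative_time"] <- res$p[res$variable == "operative_time"] < 0.05
  }
  # operative time (median 70 vs 100) is a strong effect; AGR (1.53 vs 1.40
  # with SDs 0.21/0.28 at 77 vs 19) has ~50% power at this design, so it is
  # only required to be flagged well above the 5% false-positive rate
  expect_gte(mean(flags[, "agr"]), 0.3)
  expect_gte(mean(flags[, "operative_time"]), 0.8)
})

test_that("univariate screen selects by Wald p and flags separation", {
  set.seed(311)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 1 * x))  # planted log-OR = 1
  clin <- data.frame(x = x, noise = rnorm(n), sirs = y)
  out <- univariate_screen(clin, "sirs")
  row <- out$report[out$report$source_variable == "x", ]
  expect_true(row$ci_low < exp(1) && exp(1) < row$ci_high)
  expect_true("x" %in% out$selected)
  # complete separation -> infinite-OR sentinel, excluded from selection
  clin2 <- data.frame(sep = c(rep(0, 20), rep(1, 20)),
                      sirs = c(rep(0L, 20), rep(1L, 20)))
  out2 <- suppressWarnings(univariate_screen(clin2, "sirs"))
  expect_true(out2$report$separated[1])
  expect_equal(out2$report$or[1], Inf)
  expect_length(out2$selected, 0L)
  # constant predictor errors
  clin3 <- data.frame(k = rep(1, 40), sirs = rep(c(0L, 1L), 20))
  expect_error(suppressWarnings(univariate_screen(clin3, "sirs")), "constant")
})

test_that("univariate screen holds its type-I error under the null", {
  hits <- 0L
  n_rep <- 300
  for (r in seq_len(n_rep)) {
    set.seed(4000 + r)
    clin <- data.frame(x = rnorm(80), sirs = rbinom(80, 1, 0.25))
    if (sum(clin$sirs) < 2) next
    out <- suppressWarnings(univariate_screen(clin, "sirs"))
    hits <- hits + length(out$selected)
  }
  expect_gte(hits / n_rep, 0.02)
  expect_lte(hits / n_rep, 0.08)
})

test_that("multivariate logistic matches univariate fits on orthogonal predictors", {
  # balanced orthogonal binary design, noiseless logistic structure
  set.seed(321)
  n <- 400
  x1 <- rep(c(0, 1), each = n / 2)
  x2 <- rep(c(0, 1), times = n / 2)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x1 - 0.8 * x2))
  clin <- data.frame(x1 = x1, x2 = x2, sirs = y)
  mv <- multivariate_logistic(clin, "sirs", c("x1", "x2"))
  expect_true(all(mv$report$or > 0))
  expect_true(all(mv$report$ci_low < mv$report$or &
                    mv$report$or < mv$report$ci_high))
  # planted coefficients recovered within Monte-Carlo tolerance
  expect_equal(log(mv$report$or[mv$report$variable == "x1"]), 1.2,
               tolerance = 0.45)
  expect_equal(log(mv$report$or[mv$report$variable == "x2"]), -0.8,
               tolerance = 0.45)
  # collinear duplicate predictor raises a singularity error
  clin$dup <- clin$x1
  expect_error(multivariate_logistic(clin, "sirs", c("x1", "dup")),
               "singular|aliased")
})

test_that("AUC follows the Mann-Whitney pairwise formulation", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(331)
  scores <- sample(seq(0, 1, by = 0.05), 20, replace = TRUE)  # with ties
  labels <- rbinom(20, 1, 0.5)
  if (sum(labels) %in% c(0, 20)) labels[1:2] <- c(0L, 1L)
  mine <- roc_auc(scores, labels)
  expect_equal(mine$auc, oracle_auc_pairs(scores, labels))
  # independent implementation cross-check
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
  expect_equal(mine$auc, proc_auc, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(3 * scores), labels)$auc, mine$auc)
})

test_that("random forest ranks a perfectly separating species on top", {
  set.seed(341)
  n <- 40
  groups <- rep(c(0L, 1L), each = n / 2)
  prof <- matrix(abs(rnorm(n * 6, 0.1, 0.05)), nrow = n)
  colnames(prof) <- paste0("sp", 1:6)
  prof[, "sp3"] <- ifelse(groups == 1, 0.5, 0.01) + rnorm(n, 0, 0.01)
  sel <- rf_select(prof, groups, seed = 2)
  expect_equal(sel$importance$species[1], "sp3")
  expect_true("sp3" %in% sel$selected)
  # infinite threshold empties the selection
  expect_length(rf_select(prof, groups, mdg_threshold = Inf,
                          seed = 2)$selected, 0L)
  # determinism under the seed
  sel2 <- rf_select(prof, groups, seed = 2)
  expect_identical(sel$importance, sel2$importance)
})

test_that("cross-validated AUC separates signal from permuted labels", {
  set.seed(351)
  n <- 60
  groups <- rep(c(0L, 1L), each = n / 2)
  strong <- matrix(c(rnorm(n / 2, 0), rnorm(n / 2, 4)), ncol = 1)
  cv <- cv_auc(strong, groups, k = 5, seed = 1)
  expect_gte(cv$mean_auc, 0.95)
  expect_length(cv$fold_auc, 5L)
  # label-permuted features hover around chance
  null_aucs <- vapply(1:10, function(s) {
    set.seed(900 + s)
    cv_auc(matrix(rnorm(n), ncol = 1), sample(groups), k = 5,
           seed = s)$mean_auc
  }, numeric(1))
  expect_gte(mean(null_aucs), 0.35)
  expect_lte(mean(null_aucs), 0.65)
  expect_error(cv_auc(strong, groups, k = 1), "at least 2")
  expect_warning(cv_auc(strong[1:10, , drop = FALSE], groups[c(1:5, 31:35)],
                        k = 10, seed = 1), "reducing k")
})

test_that("Spearman matrix handles monotone transforms, ties and constants", {
  x <- seq(-2, 2, length.out = 15)
  sp <- cbind(a = x, b = -x)
  clin <- data.frame(cubic = x^3, flat = rep(1, 15))
  out <- spearman_matrix(sp, clin)
  expect_equal(out$rho["a", "cubic"], 1)
  expect_equal(out$rho["b", "cubic"], -1)
  expect_true(is.na(out$rho["a", "flat"]))
  # random fixture vs rank-then-Pearson oracle
  set.seed(361)
  u <- rnorm(15); v <- round(rnorm(15), 1)  # ties in v
  out2 <- spearman_matrix(cbind(s = u), data.frame(w = v))
  expect_equal(out2$rho["s", "w"], cor(rank(u), rank(v)))
})

test_that("an empty species set reduces the combined model to clinical-only", {
  groups <- c(rep(1L, 10), rep(0L, 30))
  clin <- gen_clinical(groups, seed = 371)
  clin$sample <- sprintf("S%03d", seq_along(groups))
  empty <- matrix(numeric(0), nrow = length(groups), ncol = 0,
                  dimnames = list(clin$sample, NULL))
  cm <- combined_model(empty, clin, k = 5, seed = 3)
  ref <- suppressWarnings(stats::glm(
    sirs ~ scale(agr) + scale(operative_time), data = clin,
    family = stats::binomial()))
  expect_equal(cm$auc_insample, roc_auc(fitted(ref), clin$sirs)$auc,
               tolerance = 1e-9)
  # misaligned sample ids are named
  clin_bad <- clin
  clin_bad$sample <- rev(clin$sample)
  prof <- matrix(runif(length(groups) * 2), ncol = 2,
                 dimnames = list(clin$sample, c("spA", "spB")))
  expect_error(combined_model(prof, clin_bad), "misaligned")
})

test_that("microbial signal does not hurt: combined vs clinical CV-AUC", {
  wins <- 0L
  n_seeds <- 8
  deltas <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    spec <- cohort_spec(n_samples = 96, n_species = 20, n_differential = 5,
                        log2_fc = 3, diversity_deficit = 0.3, depth = 0,
                        seed = 1000 + s)
    co <- gen_cohort(spec)
    clin <- co$clinical
    feats_clin <- scale(as.matrix(clin[, c("agr", "operative_time")]))
    clin_cv <- cv_auc(feats_clin, co$groups, k = 5, seed = s)$mean_auc
    cm <- combined_model(co$composition[, co$differential$species,
                                        drop = FALSE],
                         clin, k = 5, seed = s)
    deltas[s] <- cm$auc_cv - clin_cv
    if (cm$auc_cv >= clin_cv) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.75)
  # and with zero planted signal the two stay close on average
  d0 <- vapply(1:6, function(s) {
    spec <- cohort_spec(n_samples = 96, n_species = 20, n_differential = 0,
                        diversity_deficit = 0, depth = 0, seed = 2000 + s)
    co <- gen_cohort(spec)
    clin <- co$clinical
    feats_clin <- scale(as.matrix(clin[, c("agr", "operative_time")]))
    clin_cv <- cv_auc(feats_clin, co$groups, k = 5, seed = s)$mean_auc
    cm <- combined_model(co$composition[, character(0), drop = FALSE],
                         clin, k = 5, seed = s)
    cm$auc_cv - clin_cv
  }, numeric(1))
  expect_lte(abs(mean(d0)), 0.05)
})
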