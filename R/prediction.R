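# Clinical risk-factor tests, logistic modeling, ROC/AUC, random-forest
# biomarker selection, Spearman correlations and the combined
# microbial+clinical prediction model.

#' Cohort outcome summary
#' @param outcome binary outcome vector (1 = event).
#' @return list: `n`, `events`, `incidence_pct` (one decimal).
#' @export
cohort_summary <- function(outcome) {
  outcome <- as.integer(outcome)
  stopifnot(all(outcome %in% c(0L, 1L)))
  list(n = length(outcome), events = sum(outcome),
       incidence_pct = round(100 * mean(outcome), 1))
}

#' Group comparisons of clinical covariates
#'
#' Produces a characteristics-table style report: continuous variables are
#' screened for normality (Shapiro-Wilk in each group) and routed to
#' Student's t-test (both normal) or the Wilcoxon rank-sum test; categorical
#' variables go to the chi-square test, or Fisher's exact test when any
#' expected or observed cell count is below 5. All-missing or constant
#' variables are skipped with a warning.
#'
#' @param clinical data.frame of covariates.
#' @param outcome name of the binary outcome column in `clinical`.
#' @param variables covariates to compare (default: all but the outcome and
#'   any `patient`/`sample` id column).
#' @param shapiro_alpha normality screen level (default 0.05).
#' @return data.frame: variable, type, test, statistic, p.
#' @export
compare_groups <- function(clinical, outcome = "sirs", variables = NULL,
                           shapiro_alpha = 0.05) {
  stopifnot(outcome %in% names(clinical))
  y <- as.factor(clinical[[outcome]])
  stopifnot(nlevels(y) == 2L)
  if (is.null(variables)) {
    variables <- setdiff(names(clinical), c(outcome, "patient", "sample"))
  }
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    if (all(is.na(x)) || length(unique(x[!is.na(x)])) < 2L) {
      warning("skipping constant/all-missing variable ", v)
      return(NULL)
    }
    if (is.numeric(x)) {
      sh <- vapply(levels(y), function(lev) {
        xs <- x[y == lev & !is.na(x)]
        if (length(unique(xs)) < 3L || length(xs) < 3L) return(0)
        stats::shapiro.test(xs)$p.value
      }, numeric(1))
      if (all(sh > shapiro_alpha)) {
        tt <- stats::t.test(x ~ y)
        data.frame(variable = v, type = "continuous", test = "t",
                   statistic = unname(tt$statistic), p = tt$p.value,
                   stringsAsFactors = FALSE)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x ~ y))
        data.frame(variable = v, type = "continuous", test = "wilcoxon",
                   statistic = unname(wt$statistic), p = wt$p.value,
                   stringsAsFactors = FALSE)
      }
    } else {
      tab <- table(x, y)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5) || any(tab < 5)) {
        ft <- stats::fisher.test(tab)
        data.frame(variable = v, type = "categorical", test = "fisher",
                   statistic = NA_real_, p = ft$p.value,
                   stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab))
        data.frame(variable = v, type = "categorical", test = "chisq",
                   statistic = unname(ct$statistic), p = ct$p.value,
                   stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Wald OR/CI/p extraction for one or more glm coefficients
logistic_report <- function(fit, terms = NULL) {
  co <- summary(fit)$coefficients
  if (is.null(terms)) terms <- setdiff(rownames(co), "(Intercept)")
  terms <- intersect(terms, rownames(co))
  est <- co[terms, "Estimate"]
  se <- co[terms, "Std. Error"]
  data.frame(
    variable = terms,
    or = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se),
    p = co[terms, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
}

# crude complete-separation detector for a fitted binomial glm
is_separated <- function(fit) {
  eps <- 1e-8
  probs <- stats::fitted(fit)
  all(probs < eps | probs > 1 - eps) ||
    any(abs(stats::coef(fit)[-1]) > 15 & !is.na(stats::coef(fit)[-1]))
}

#' Univariate logistic screen
#'
#' Fits a single-predictor logistic regression per variable (maximum
#' likelihood via IRLS) and selects variables with Wald `p < alpha` for the
#' multivariate model. Complete separation is detected and reported with an
#' infinite-OR sentinel; separated variables are excluded from selection.
#'
#' @param clinical data.frame of covariates.
#' @param outcome binary outcome column name.
#' @param variables candidate predictors (default: all others except id
#'   columns).
#' @param alpha selection threshold on the Wald p-value (default 0.05).
#' @return list: `report` (variable/or/ci/p/separated, one row per
#'   coefficient), `selected` (character vector of variables).
#' @export
univariate_screen <- function(clinical, outcome = "sirs", variables = NULL,
                              alpha = 0.05) {
  stopifnot(outcome %in% names(clinical))
  y <- as.integer(as.factor(clinical[[outcome]])) - 1L
  if (sum(y) < 10L) {
    warning("fewer than 10 events; univariate estimates may be unstable")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(clinical), c(outcome, "patient", "sample"))
  }
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      stop("constant predictor: ", v, call. = FALSE)
    }
    dat <- data.frame(y = y, x = x)
    fit <- suppressWarnings(stats::glm(y ~ x, data = dat, family = stats::binomial()))
    rep1 <- logistic_report(fit)
    rep1$variable <- sub("^x", v, rep1$variable)
    rep1$separated <- is_separated(fit)
    if (rep1$separated[1L]) {
      rep1$or <- Inf
      rep1$ci_low <- NA_real_; rep1$ci_high <- NA_real_
      rep1$p <- NA_real_
    }
    rep1$source_variable <- v
    rep1
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  sel <- unique(report$source_variable[!report$separated &
                                         !is.na(report$p) &
                                         report$p < alpha])
  list(report = report, selected = sel)
}

#' Multivariate logistic regression
#'
#' Joint maximum-likelihood logistic fit of the selected variables,
#' reporting odds ratios with Wald 95% confidence intervals and p-values.
#' Aliased (collinear) predictors and non-convergence raise errors.
#'
#' @param clinical data.frame of covariates.
#' @param outcome binary outcome column name.
#' @param variables predictors, typically from [univariate_screen()].
#' @return list: `report` (variable/or/ci_low/ci_high/p), `fit` (the glm),
#'   `fitted` (per-sample probabilities), `deviance`.
#' @export
multivariate_logistic <- function(clinical, outcome = "sirs", variables) {
  stopifnot(length(variables) >= 1L, all(variables %in% names(clinical)))
  y <- as.integer(as.factor(clinical[[outcome]])) - 1L
  dat <- clinical[, variables, drop = FALSE]
  dat$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = 100))
  )
  if (!fit$converged) {
    stop("logistic fit did not converge in 100 iterations (deviance ",
         round(fit$deviance, 3), ")", call. = FALSE)
  }
  if (anyNA(stats::coef(fit))) {
    stop("singular design: aliased predictor(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  list(report = logistic_report(fit), fit = fit,
       fitted = stats::fitted(fit), deviance = fit$deviance)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) formulation — the probability a random
#' positive scores above a random negative, ties counted half — with the
#' full sensitivity/specificity curve over all score thresholds.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels binary labels (1 = positive); both classes required.
#' @return list: `auc`, `curve` (data.frame threshold/sensitivity/
#'   specificity), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(scores[labels == 1L] >= t),
                         numeric(1)),
    specificity = vapply(th, function(t) mean(scores[labels == 0L] < t),
                         numeric(1))
  )
  list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg)
}

#' Random-forest biomarker selection by Mean Decrease Gini
#'
#' Fits a random forest on the candidate species' abundances and selects
#' the species whose Mean Decrease Gini importance is strictly greater
#' than `mdg_threshold`.
#'
#' @param profile abundance matrix restricted to candidate species
#'   (>= 2 columns).
#' @param labels binary outcome (>= 2 samples per class).
#' @param mdg_threshold strict importance cutoff (default 2).
#' @param n_trees forest size (default 500).
#' @param seed random seed.
#' @return list: `selected` (character vector), `importance` (data.frame
#'   species/mdg sorted decreasing), `forest` (the randomForest fit).
#' @export
rf_select <- function(profile, labels, mdg_threshold = 2, n_trees = 500,
                      seed = 1) {
  stopifnot(is.matrix(profile), ncol(profile) >= 2L)
  y <- as.factor(labels)
  if (any(table(y) < 2L)) stop("need >= 2 samples per class", call. = FALSE)
  set.seed(seed)
  x <- as.data.frame(profile)
  colnames(x) <- make.names(colnames(profile))
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  mdg <- fit$importance[, "MeanDecreaseGini"]
  imp <- data.frame(species = colnames(profile),
                    mdg = as.numeric(mdg),
                    stringsAsFactors = FALSE)
  imp <- imp[order(imp$mdg, decreasing = TRUE), ]
  rownames(imp) <- NULL
  list(selected = imp$species[imp$mdg > mdg_threshold],
       importance = imp, forest = fit)
}

# stratified fold assignment: each class split round-robin over k folds
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- sample(which(labels == lev))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated AUC
#'
#' Stratified k-fold cross-validation: the model is refit on each training
#' split and its AUC measured on the held-out fold; the mean of per-fold
#' AUCs is reported. If a class has fewer samples than `k`, `k` is reduced
#' (with a warning) so every fold contains both classes.
#'
#' @param features numeric matrix/data.frame of predictors.
#' @param labels binary outcome.
#' @param k number of folds (default 10).
#' @param seed random seed for fold assignment (and the forest).
#' @param model `"logistic"` (glm) or `"rf"` (randomForest).
#' @return list: `mean_auc`, `fold_auc` (numeric vector), `k`.
#' @export
cv_auc <- function(features, labels, k = 10, seed = 1,
                   model = c("logistic", "rf")) {
  model <- match.arg(model)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), nrow(features) == length(labels))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  min_class <- min(table(labels))
  if (min_class < k) {
    warning(sprintf("reducing k from %d to %d (smallest class size)", k,
                    min_class))
    k <- min_class
  }
  folds <- stratified_folds(labels, k, seed)
  fold_auc <- vapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    if (model == "logistic") {
      dat <- as.data.frame(features[tr, , drop = FALSE])
      dat$.y <- labels[tr]
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                         family = stats::binomial()))
      newd <- as.data.frame(features[te, , drop = FALSE])
      scores <- stats::predict(fit, newdata = newd, type = "response")
    } else {
      set.seed(derive_seed(seed, f))
      fit <- randomForest::randomForest(
        x = as.data.frame(features[tr, , drop = FALSE]),
        y = as.factor(labels[tr]), ntree = 500)
      scores <- stats::predict(fit,
                               newdata = as.data.frame(features[te, , drop = FALSE]),
                               type = "prob")[, "1"]
    }
    roc_auc(scores, labels[te])$auc
  }, numeric(1))
  list(mean_auc = mean(fold_auc), fold_auc = fold_auc, k = k)
}

#' Spearman correlation matrix between species and clinical variables
#'
#' Rank correlation with average ranks on ties and t-approximation
#' p-values, over every species x variable pair. Constant columns yield
#' `NA` (undefined correlation).
#'
#' @param species_profile abundance matrix (samples x species).
#' @param clinical_continuous data.frame/matrix of continuous covariates,
#'   row-aligned with the profile.
#' @return list: `rho` (species x variables), `p` (matching p-values).
#' @export
spearman_matrix <- function(species_profile, clinical_continuous) {
  x <- as.matrix(species_profile)
  yv <- as.matrix(clinical_continuous)
  stopifnot(nrow(x) == nrow(yv), nrow(x) >= 3L)
  rho <- matrix(NA_real_, ncol(x), ncol(yv),
                dimnames = list(colnames(x), colnames(yv)))
  pm <- rho
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(yv))) {
      xi <- x[, i]; yj <- yv[, j]
      ok <- !is.na(xi) & !is.na(yj)
      if (length(unique(xi[ok])) < 2L || length(unique(yj[ok])) < 2L) next
      ct <- suppressWarnings(
        stats::cor.test(xi[ok], yj[ok], method = "spearman", exact = FALSE)
      )
      rho[i, j] <- unname(ct$estimate)
      pm[i, j] <- ct$p.value
    }
  }
  list(rho = rho, p = pm)
}

#' Combined microbial + clinical prediction model
#'
#' Logistic model on standardized features: the selected species'
#' abundances (log2-transformed with half-minimum pseudocount, as in
#' [linear_assoc()]) together with clinical covariates. Reports both the
#' in-sample AUC and the stratified cross-validated AUC, labeled as such —
#' the two are not interchangeable.
#'
#' @param species_profile abundance matrix restricted to the selected
#'   species (may have zero columns: the model reduces to clinical-only).
#' @param clinical data.frame holding the clinical covariates and outcome.
#' @param clinical_vars clinical covariate names (default AGR + operative
#'   time).
#' @param outcome binary outcome column name.
#' @param k cross-validation folds (default 10).
#' @param seed random seed.
#' @return list: `fit` (glm), `auc_insample`, `auc_cv` (mean CV AUC),
#'   `cv` (full [cv_auc()] result), `features` (the standardized design).
#' @export
combined_model <- function(species_profile, clinical,
                           clinical_vars = c("agr", "operative_time"),
                           outcome = "sirs", k = 10, seed = 1) {
  stopifnot(all(clinical_vars %in% names(clinical)),
            outcome %in% names(clinical))
  y <- as.integer(clinical[[outcome]])
  sp <- as.matrix(species_profile)
  if (!is.null(rownames(sp)) && "sample" %in% names(clinical)) {
    if (!identical(rownames(sp), clinical$sample)) {
      bad <- which(rownames(sp) != clinical$sample)
      stop("misaligned sample ids at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  feats <- as.matrix(clinical[, clinical_vars, drop = FALSE])
  if (ncol(sp) > 0L) {
    feats <- cbind(log_transform_profile(sp), feats)
  }
  feats <- scale(feats)
  feats <- feats[, apply(feats, 2, function(z) all(is.finite(z))),
                 drop = FALSE]
  dat <- as.data.frame(feats)
  dat$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                     family = stats::binomial(),
                                     control = stats::glm.control(maxit = 100)))
  ins <- roc_auc(stats::fitted(fit), y)
  cv <- cv_auc(feats, y, k = k, seed = seed, model = "logistic")
  list(fit = fit, auc_insample = ins$auc, auc_cv = cv$mean_auc, cv = cv,
       features = feats)
}
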