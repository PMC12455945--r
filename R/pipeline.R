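# End-to-end orchestration: simulate -> db -> profile -> diversity ->
# differential -> prediction, driven by a single flat config, with a run
# manifest of output checksums for reproducibility.

#' Default pipeline configuration
#'
#' A flat list of stage toggles, thresholds and seeds. Every stochastic
#' stage has an explicit seed. The config round-trips through YAML
#' unchanged ([load_config()] / [save_config()]).
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "db", "profile", "diversity", "differential",
               "prediction"),
    # simulate
    n_species = 20L, genome_length = 20000L, markers_per_species = 10L,
    n_samples = 96L, positive_fraction = 19 / 96, n_differential = 5L,
    log2_fc = 2, diversity_deficit = 0.3, depth = 3000L,
    error_rate = 0.001,
    sim_seed = 1L,
    # enzyme
    enzyme_name = "BcgI", enzyme_recognition = "CGANNNNNNTGC",
    enzyme_flank_left = 12L, enzyme_flank_right = 12L,
    # profiler
    g_mode = "sqrt_product", g_threshold = 5,
    # diversity
    permanova_n_perm = 999L, permanova_seed = 17L,
    # differential
    kw_alpha = 0.05, lda_threshold = 3.0, lefse_n_boot = 30L,
    lefse_seed = 17L, q_threshold = 0.25, indval_n_perm = 999L,
    indval_seed = 17L, top_n_abundance = 50L,
    # prediction
    mdg_threshold = 2, rf_n_trees = 500L, rf_seed = 17L,
    cv_folds = 10L, cv_seed = 17L,
    clinical_vars = c("agr", "operative_time"), outcome = "sirs"
  )
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; missing keys are filled from [default_config()].
#' @return configuration list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- default_config()
  out[names(cfg)] <- cfg
  out
}

#' Save a pipeline configuration as YAML
#' @param config configuration list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rownames_as),
                    as.data.frame(x), check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on synthetic data (stage
#' `simulate`) or a supplied profile, writing one TSV/JSON per stage under
#' `out_dir` plus a run manifest with the resolved config and an MD5
#' checksum per output file. Re-running with an identical config reproduces
#' identical checksums.
#'
#' @param config configuration list (see [default_config()]); a YAML path
#'   is also accepted.
#' @param out_dir output directory.
#' @return invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  outputs <- character(0)
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)

  enzyme <- enzyme_spec(config$enzyme_name, config$enzyme_recognition,
                        config$enzyme_flank_left, config$enzyme_flank_right)

  genomes <- NULL; cohort <- NULL; db <- NULL
  hits <- NULL; profile <- NULL

  if ("simulate" %in% stages) {
    log_msg("simulate: genomes + cohort")
    genomes <- gen_genomes(config$n_species, config$genome_length,
                           config$markers_per_species, enzyme,
                           seed = config$sim_seed)
    spec <- cohort_spec(
      n_samples = config$n_samples,
      positive_fraction = config$positive_fraction,
      n_species = config$n_species,
      n_differential = config$n_differential,
      log2_fc = config$log2_fc,
      diversity_deficit = config$diversity_deficit,
      depth = config$depth, error_rate = config$error_rate,
      seed = derive_seed(config$sim_seed, 7L)
    )
    cohort <- gen_cohort(spec, markers = split(genomes$truth$tag,
                                               genomes$truth$species))
    outputs <- c(outputs,
                 write_tsv(cohort$clinical,
                           file.path(out_dir, "clinical.tsv")),
                 write_tsv(cohort$differential,
                           file.path(out_dir, "planted_differential.tsv")),
                 write_tsv(genomes$truth, file.path(out_dir, "truth.tsv")))
  }

  if ("db" %in% stages) {
    if (is.null(genomes)) stop("db stage requires the simulate stage (or pass genomes)",
                               call. = FALSE)
    log_msg("db: marker database")
    db <- build_marker_db(as.list(genomes$genomes), enzyme)
    outputs <- c(outputs, write_marker_db(db, file.path(out_dir, "db")))
  }

  if ("profile" %in% stages) {
    if (is.null(db) || is.null(cohort$reads)) {
      stop("profile stage requires db + simulated reads", call. = FALSE)
    }
    log_msg("profile: read assignment + G filter")
    prof <- profile_samples(cohort$reads, db, g_mode = config$g_mode,
                            g_threshold = config$g_threshold)
    hits <- prof$hits; profile <- prof$profile
    outputs <- c(outputs,
                 write_tsv(hits, file.path(out_dir, "hits.tsv")),
                 write_tsv(profile, file.path(out_dir, "abundance.tsv"),
                           rownames_as = "sample"))
  }

  labels <- cohort$groups
  if ("diversity" %in% stages && !is.null(profile)) {
    log_msg("diversity: alpha + beta + PERMANOVA")
    alpha <- alpha_diversity(profile, hits)
    stats_out <- list()
    for (metric in c("bray_curtis", "binary_jaccard", "euclidean")) {
      d <- suppressWarnings(distance_matrix(profile, metric))
      pv <- permanova(d, labels, n_perm = config$permanova_n_perm,
                      seed = config$permanova_seed)
      stats_out[[metric]] <- list(pseudo_f = pv$f, p = pv$p, r2 = pv$r2)
      outputs <- c(outputs,
                   write_tsv(as.matrix(d),
                             file.path(out_dir, paste0("dist_", metric, ".tsv")),
                             rownames_as = "sample"))
    }
    ov <- species_overlap(profile, labels)
    alpha_p <- vapply(c("chao1", "shannon", "simpson"), function(ix) {
      suppressWarnings(stats::wilcox.test(alpha[[ix]] ~ labels)$p.value)
    }, numeric(1))
    jpath <- file.path(out_dir, "diversity.json")
    jsonlite::write_json(
      list(permanova = stats_out,
           alpha_wilcoxon_p = as.list(alpha_p),
           overlap = ov, overlap_total = attr(ov, "total")),
      jpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs <- c(outputs, jpath,
                 write_tsv(alpha, file.path(out_dir, "alpha.tsv")))
  }

  candidates <- character(0)
  if ("differential" %in% stages && !is.null(profile)) {
    log_msg("differential: wilcoxon / lefse / linear / indval")
    res <- list(
      wilcoxon = wilcoxon_by_taxon(profile, labels),
      lefse = lefse_lite(profile, labels, kw_alpha = config$kw_alpha,
                         lda_threshold = config$lda_threshold,
                         n_boot = config$lefse_n_boot,
                         seed = config$lefse_seed),
      linear_model = linear_assoc(profile, labels,
                                  q_threshold = config$q_threshold),
      indval = indval(profile, labels, n_perm = config$indval_n_perm,
                      seed = config$indval_seed)
    )
    for (m in names(res)) {
      outputs <- c(outputs,
                   write_tsv(res[[m]],
                             file.path(out_dir, paste0("diff_", m, ".tsv"))))
    }
    candidates <- consensus_candidates(res, profile,
                                       top_n_abundance = config$top_n_abundance)
    outputs <- c(outputs,
                 write_tsv(data.frame(taxon = candidates),
                           file.path(out_dir, "consensus.tsv")))
  }

  if ("prediction" %in% stages && !is.null(profile)) {
    log_msg("prediction: risk factors + RF + combined model")
    clin <- cohort$clinical
    screen <- univariate_screen(clin, outcome = config$outcome,
                                variables = c("agr", "operative_time",
                                              "urinary_leukocyte", "age",
                                              "bmi"))
    pred_out <- list(univariate = screen$report,
                     selected_clinical = screen$selected)
    if (length(screen$selected) >= 1L) {
      mv <- multivariate_logistic(clin, outcome = config$outcome,
                                  variables = screen$selected)
      pred_out$multivariate <- mv$report
      pred_out$clinical_auc <- roc_auc(mv$fitted, clin[[config$outcome]])$auc
    }
    if (length(candidates) >= 2L) {
      sel <- rf_select(profile[, candidates, drop = FALSE], labels,
                       mdg_threshold = config$mdg_threshold,
                       n_trees = config$rf_n_trees, seed = config$rf_seed)
      outputs <- c(outputs,
                   write_tsv(sel$importance,
                             file.path(out_dir, "rf_importance.tsv")))
      pred_out$rf_selected <- sel$selected
      if (length(sel$selected) >= 1L) {
        micro_cv <- cv_auc(log_transform_profile(
          profile[, sel$selected, drop = FALSE]), labels,
          k = config$cv_folds, seed = config$cv_seed, model = "rf")
        pred_out$microbial_cv_auc <- micro_cv$mean_auc
        cm <- combined_model(profile[, sel$selected, drop = FALSE], clin,
                             clinical_vars = config$clinical_vars,
                             outcome = config$outcome,
                             k = config$cv_folds, seed = config$cv_seed)
        pred_out$combined_auc_insample <- cm$auc_insample
        pred_out$combined_auc_cv <- cm$auc_cv
      }
    }
    jpath <- file.path(out_dir, "prediction.json")
    jsonlite::write_json(pred_out, jpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    outputs <- c(outputs, jpath)
  }

  cfg_path <- save_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("urotag")),
    config = config,
    checksums = as.list(tools::md5sum(sort(unname(outputs))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
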