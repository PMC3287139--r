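#' Default pipeline configuration
#'
#' A flat key-value configuration covering every stage of the
#' end-to-end analysis. Every stochastic stage receives a child seed
#' derived deterministically from `seed`. Defaults mirror the study
#' conditions emulated by the synthetic generator: class-comparison
#' selection alpha 0.005/0.05, survival selection alpha 0.05 (0.01 as
#' the confirmatory setting), 67% percentile cutoff, 100 random
#' partitions, 1000 permutations.
#'
#' @param seed Master integer seed.
#' @return A named list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = TRUE,
    expression_tsv = NULL, clinical_tsv = NULL, probe_map_tsv = NULL,
    n_cancer = 90L, n_normal = 34L, n_train = 82L,
    n_features = 300L, n_replicates_per_feature = 4L,
    n_diff_features = 50L, diff_log2_effect = 1,
    n_hazard_features = 5L, hazard_log_effect = 1,
    n_pairs = 8L, pair_shift = 2,
    noise_sd = 1, class_noise_sd = 0.5,
    class_alpha = 0.05, class_report_alpha = 0.005,
    survival_alpha = 0.05,
    cutoff_percentile = 67,
    n_partitions = 100L,
    n_permutations = 1000L,
    lowess_span = 2/3,
    max_missing = 0.5,
    run_class_comparison = TRUE,
    run_survival = TRUE,
    run_pairs = TRUE,
    run_qpcr = TRUE
  )
}

#' Read a pipeline configuration file
#'
#' Flat key-value YAML; unknown keys are rejected, missing keys take
#' their defaults.
#'
#' @param path Path to a YAML config file.
#' @return A full configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(user)] <- user
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- simulate, preprocess
#' (replicate collapsing, masking filter/imputation), class comparison
#' (differential table and the six-classifier partition protocol),
#' survival screening, supervised-PC risk prediction (LOOCV risk
#' groups, Kaplan-Meier curves per group, permutation significance),
#' paired pre/post evaluation, and delta-delta-Ct qPCR analysis --
#' writing all stage outputs as TSV plus a machine-readable JSON run
#' report. Outputs are byte-identical across reruns with the same
#' configuration.
#'
#' @param config A configuration list ([default_run_config()]) or the
#'   path to a YAML file ([read_run_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6L)
  report <- list(package = "mirsig",
                 version = as.character(packageVersion("mirsig")),
                 config = config, warnings = character(0))
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      report$warnings <<- c(report$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  ## ---- inputs: simulate or load -------------------------------------
  if (isTRUE(config$simulate)) {
    class_cfg <- sim_config(
      n_cancer = config$n_cancer, n_normal = config$n_normal,
      n_features = config$n_features,
      n_replicates_per_feature = config$n_replicates_per_feature,
      n_diff_features = config$n_diff_features,
      diff_log2_effect = config$diff_log2_effect,
      n_hazard_features = config$n_hazard_features,
      hazard_log_effect = config$hazard_log_effect,
      n_pairs = config$n_pairs, pair_shift = config$pair_shift,
      noise_sd = config$class_noise_sd, seed = seeds[1L])
    class_cohort <- simulate_cancer_normal(class_cfg)
    surv_cfg <- sim_config(
      n_cancer = config$n_train, n_normal = 0L,
      n_features = config$n_features,
      n_replicates_per_feature = config$n_replicates_per_feature,
      n_diff_features = 0L,
      n_hazard_features = config$n_hazard_features,
      hazard_log_effect = config$hazard_log_effect,
      n_pairs = config$n_pairs, pair_shift = config$pair_shift,
      noise_sd = config$noise_sd, seed = seeds[2L])
    surv_cohort <- wcollect(simulate_survival_cohort(surv_cfg))
    write_cohort(class_cohort, file.path(out_dir, "simulated",
                                         "cancer_normal"))
    write_cohort(surv_cohort, file.path(out_dir, "simulated", "survival"))
  } else {
    expr <- read_expression_tsv(config$expression_tsv)
    clin <- read_clinical_tsv(config$clinical_tsv)
    map <- read.delim(config$probe_map_tsv, stringsAsFactors = FALSE)
    cohort <- list(expression = expr, clinical = clin,
                   probe_map = stats::setNames(map$feature_id,
                                               map$probe_id))
    class_cohort <- cohort
    surv_cohort <- cohort
  }

  ## ---- preprocess ----------------------------------------------------
  prep <- function(cohort) {
    collapsed <- collapse_replicates(cohort$expression, cohort$probe_map)
    filter_impute(collapsed, max_missing = config$max_missing)
  }
  x_class <- prep(class_cohort)
  x_surv <- prep(surv_cohort)

  ## ---- class comparison ----------------------------------------------
  if (isTRUE(config$run_class_comparison)) {
    labels <- class_cohort$clinical$class_label
    diff_tab <- t_test_per_feature(x_class, labels)
    diff_tab <- diff_tab[order(diff_tab$p), ]
    write.table(diff_tab, file.path(out_dir, "differential_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    part <- cross_partition_accuracy(
      x_class, labels, n_partitions = config$n_partitions,
      selection_alpha = config$class_alpha, seed = seeds[3L])
    write.table(
      data.frame(partition = seq_len(nrow(part$accuracy)), part$accuracy),
      file.path(out_dir, "partition_accuracy.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    report$class_comparison <- list(
      n_significant = sum(diff_tab$p < config$class_report_alpha,
                          na.rm = TRUE),
      median_accuracy = as.list(part$median_accuracy))
  }

  ## ---- survival screening + risk prediction ---------------------------
  if (isTRUE(config$run_survival)) {
    clin <- surv_cohort$clinical
    ttp <- clin$ttp_months
    event <- clin$event
    sel <- select_survival_features(x_surv, ttp, event,
                                    alpha = config$survival_alpha)
    tab <- sel$all
    tab$list <- ifelse(is.na(tab$p) | tab$p >= config$survival_alpha |
                         !tab$converged, "",
                       ifelse(tab$hazard_ratio > 1, "resistance",
                              "sensitivity"))
    write.table(tab[order(tab$p), ],
                file.path(out_dir, "survival_screen.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    model <- fit_risk_model(x_surv, ttp, event,
                            selection_alpha = config$survival_alpha,
                            cutoff_percentile = config$cutoff_percentile)
    risk_calls <- predict(model, x_surv)
    write.table(risk_calls, file.path(out_dir, "risk_calls_training.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cv <- wcollect(loocv_risk_groups(
      x_surv, ttp, event, selection_alpha = config$survival_alpha,
      cutoff_percentile = config$cutoff_percentile))
    write.table(cv, file.path(out_dir, "risk_groups_loocv.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (grp in c("low", "high")) {
      idx <- cv$group == grp
      if (any(idx)) {
        km <- km_estimate(ttp[idx], event[idx])
        write.table(km[, c("time", "survival")],
                    file.path(out_dir, sprintf("km_%s.tsv", grp)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    perm <- permutation_significance(
      x_surv, ttp, event, n_perm = config$n_permutations,
      seed = seeds[4L], selection_alpha = config$survival_alpha,
      cutoff_percentile = config$cutoff_percentile)
    report$survival <- list(
      n_selected = nrow(sel$resistance) + nrow(sel$sensitivity),
      n_resistance = nrow(sel$resistance),
      n_sensitivity = nrow(sel$sensitivity),
      logrank_cv = perm$lr_obs,
      permutation_p = perm$p,
      n_weak_folds = perm$n_weak_folds)

    ## ---- paired evaluation ------------------------------------------
    if (isTRUE(config$run_pairs) && isTRUE(config$simulate)) {
      pair_cohort <- simulate_pairs(surv_cohort, model$weights,
                                    pair_shift = config$pair_shift,
                                    seed = seeds[5L])
      x_pairs <- prep(pair_cohort)
      pair_res <- evaluate_pairs(model, x_pairs, pair_cohort$clinical)
      write.table(pair_res, file.path(out_dir, "pair_predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ps <- summarize_pairs(pair_res)
      report$pairs <- list(pre_low = unname(ps$pre_low["count"]),
                           overall_correct =
                             unname(ps$overall_correct["count"]),
                           total = unname(ps$pre_low["total"]),
                           pre_low_accuracy = ps$pre_low_accuracy,
                           overall_accuracy = ps$overall_accuracy)
    }
  }

  ## ---- qPCR ------------------------------------------------------------
  if (isTRUE(config$run_qpcr) && isTRUE(config$simulate)) {
    ct <- simulate_ct_table(seed = seeds[6L])
    qp <- qpcr_analyze(ct)
    write.table(qp$per_sample, file.path(out_dir, "qpcr_per_sample.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(qp$per_target, file.path(out_dir, "qpcr_per_target.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$qpcr <- list(targets = qp$per_target$target,
                        p = qp$per_target$p)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
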