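#' Simulation configuration for synthetic miRNA cohorts
#'
#' Defaults emulate the structure of a two-channel miRNA microarray study
#' of metastatic gastric cancer: ~1,667 mature miRNAs each measured by 4
#' replicate probes, 90 cancer and 34 normal mucosa samples, an
#' 82-patient survival training set with median time to progression
#' (TTP) around 3.1 months and ~20% independent censoring, and 8
#' pre/post-treatment responder pairs. Event and censoring times are
#' exponential (proportional hazards by construction); the baseline
#' hazard and censoring rate are calibrated analytically so that, with
#' no planted signal, the observed TTP median is 3.1 months and 20% of
#' patients are censored.
#'
#' @param n_cancer,n_normal Sample counts per class.
#' @param n_features Number of mature miRNA features.
#' @param n_replicates_per_feature Replicate probes per feature.
#' @param n_diff_features Number of planted cancer-vs-normal features.
#' @param diff_log2_effect Log2-units shift of planted differential
#'   features in cancer samples (half up, half down).
#' @param n_hazard_features Number of planted TTP-associated features.
#' @param hazard_log_effect Per-unit log hazard coefficient of planted
#'   hazard features (signs alternate across the planted set).
#' @param baseline_hazard Baseline event rate, events per month.
#' @param censor_rate Independent censoring rate, events per month.
#' @param n_pairs Number of pre/post-treatment sample pairs.
#' @param pair_shift Magnitude of the post-treatment shift along the
#'   resistance direction, in log2 units.
#' @param noise_sd Biological log2-ratio SD per feature; technical
#'   replicate noise has SD `noise_sd / 2`.
#' @param seed Integer seed; fully determines the cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cancer = 90L, n_normal = 34L,
                       n_features = 1667L, n_replicates_per_feature = 4L,
                       n_diff_features = min(50L, n_features),
                       diff_log2_effect = 2,
                       n_hazard_features = min(5L, n_features),
                       hazard_log_effect = 1,
                       baseline_hazard = log(2) * 0.8 / 3.1,
                       censor_rate = log(2) * 0.2 / 3.1,
                       n_pairs = 8L, pair_shift = 2,
                       noise_sd = 1, seed = 1L) {
  cfg <- list(n_cancer = as.integer(n_cancer), n_normal = as.integer(n_normal),
              n_features = as.integer(n_features),
              n_replicates_per_feature = as.integer(n_replicates_per_feature),
              n_diff_features = as.integer(n_diff_features),
              diff_log2_effect = diff_log2_effect,
              n_hazard_features = as.integer(n_hazard_features),
              hazard_log_effect = hazard_log_effect,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              n_pairs = as.integer(n_pairs), pair_shift = pair_shift,
              noise_sd = noise_sd, seed = as.integer(seed))
  counts <- c("n_cancer", "n_normal", "n_features",
              "n_replicates_per_feature", "n_diff_features",
              "n_hazard_features", "n_pairs")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L) {
      stop(sprintf("`%s` must be a nonnegative count", nm), call. = FALSE)
    }
  }
  if (cfg$n_diff_features > cfg$n_features) {
    stop("n_diff_features exceeds n_features", call. = FALSE)
  }
  if (cfg$n_hazard_features > cfg$n_features) {
    stop("n_hazard_features exceeds n_features", call. = FALSE)
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop("noise_sd must be > 0", call. = FALSE)
  }
  if (cfg$censor_rate < 0) stop("censor_rate must be >= 0", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

feature_ids <- function(n) sprintf("mir%04d", seq_len(n))

probe_layout <- function(cfg) {
  feats <- feature_ids(cfg$n_features)
  probes <- as.vector(t(outer(feats, seq_len(cfg$n_replicates_per_feature),
                              function(f, r) paste0(f, "_p", r))))
  stats::setNames(rep(feats, each = cfg$n_replicates_per_feature), probes)
}

# biological feature-by-sample values -> probe-by-sample with technical noise
probes_from_features <- function(bio, cfg, tech_sd = cfg$noise_sd / 2) {
  map <- probe_layout(cfg)
  nrep <- cfg$n_replicates_per_feature
  probe <- bio[rep(seq_len(nrow(bio)), each = nrep), , drop = FALSE]
  if (tech_sd > 0) {
    probe <- probe + matrix(rnorm(length(probe), 0, tech_sd),
                            nrow(probe), ncol(probe))
  }
  rownames(probe) <- names(map)
  list(expression = probe, probe_map = map)
}

#' Simulate a cancer-versus-normal expression cohort
#'
#' Biological log2 ratios are iid Normal(0, `noise_sd`^2); the planted
#' differential features are shifted by +/- `diff_log2_effect` in cancer
#' samples (half up, half down). Each feature is then expanded to
#' `n_replicates_per_feature` probes with independent technical noise of
#' SD `noise_sd / 2`.
#'
#' @param config A [sim_config()].
#' @return A list of class `mirna_cohort` with elements `expression`
#'   (probe-by-sample matrix), `probe_map`, `clinical`, `truth`
#'   (planted feature ids, roles and signed effects) and `config`.
#' @export
simulate_cancer_normal <- function(config = sim_config()) {
  cfg <- config
  local_seed(cfg$seed, {
    n <- cfg$n_cancer + cfg$n_normal
    samples <- c(sprintf("GC%03d", seq_len(cfg$n_cancer)),
                 sprintf("NRM%03d", seq_len(cfg$n_normal)))
    cls <- rep(c("cancer", "normal"), c(cfg$n_cancer, cfg$n_normal))
    feats <- feature_ids(cfg$n_features)
    bio <- matrix(rnorm(cfg$n_features * n, 0, cfg$noise_sd),
                  cfg$n_features, n, dimnames = list(feats, samples))
    truth <- data.frame(feature_id = character(0), role = character(0),
                        effect = numeric(0), stringsAsFactors = FALSE)
    if (cfg$n_diff_features > 0) {
      idx <- seq_len(cfg$n_diff_features)
      n_up <- ceiling(cfg$n_diff_features / 2)
      sign <- rep(c(1, -1), c(n_up, cfg$n_diff_features - n_up))
      shift <- sign * cfg$diff_log2_effect
      bio[idx, cls == "cancer"] <- bio[idx, cls == "cancer"] + shift
      truth <- data.frame(feature_id = feats[idx], role = "diff",
                          effect = shift, stringsAsFactors = FALSE)
    }
    pr <- probes_from_features(bio, cfg)
    clinical <- data.frame(sample_id = samples, class_label = cls,
                           ttp_months = NA_real_, event = NA_integer_,
                           pair_id = NA_character_, timepoint = "none",
                           stringsAsFactors = FALSE)
    structure(list(expression = pr$expression, probe_map = pr$probe_map,
                   biological = bio, clinical = clinical, truth = truth,
                   config = cfg),
              class = "mirna_cohort")
  })
}

#' Simulate a survival (TTP) training cohort
#'
#' Cancer samples only. A latent risk score `risk = sum(beta_j * x_j)`
#' over the planted hazard features drives exponential event times with
#' rate `baseline_hazard * exp(risk)`; censoring is exponential with rate
#' `censor_rate`; observed TTP is the minimum, in months, with a
#' progression-event flag.
#'
#' @param config A [sim_config()]; `n_cancer` is the cohort size
#'   (82 for the emulated training set).
#' @return A `mirna_cohort` whose clinical table carries `ttp_months`
#'   and `event`; `truth` lists the planted hazard features with signed
#'   log-hazard effects.
#' @export
simulate_survival_cohort <- function(config = sim_config(n_cancer = 82L)) {
  cfg <- config
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0",
                                     call. = FALSE)
  local_seed(cfg$seed + 1L, {
    n <- cfg$n_cancer
    samples <- sprintf("TRN%03d", seq_len(n))
    feats <- feature_ids(cfg$n_features)
    bio <- matrix(rnorm(cfg$n_features * n, 0, cfg$noise_sd),
                  cfg$n_features, n, dimnames = list(feats, samples))
    truth <- data.frame(feature_id = character(0), role = character(0),
                        effect = numeric(0), stringsAsFactors = FALSE)
    risk <- rep(0, n)
    if (cfg$n_hazard_features > 0) {
      idx <- seq_len(cfg$n_hazard_features)
      sign <- rep_len(c(1, -1), cfg$n_hazard_features)
      beta <- sign * cfg$hazard_log_effect
      risk <- drop(crossprod(bio[idx, , drop = FALSE], beta))
      truth <- data.frame(feature_id = feats[idx], role = "hazard",
                          effect = beta, stringsAsFactors = FALSE)
    }
    t_event <- rexp(n, cfg$baseline_hazard * exp(risk))
    t_cens <- if (cfg$censor_rate > 0) rexp(n, cfg$censor_rate) else
      rep(Inf, n)
    ttp <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    if (all(event == 0L)) {
      warning("all TTP observations are censored", call. = FALSE)
    }
    pr <- probes_from_features(bio, cfg)
    clinical <- data.frame(sample_id = samples, class_label = "cancer",
                           ttp_months = ttp, event = event,
                           pair_id = NA_character_, timepoint = "none",
                           stringsAsFactors = FALSE)
    structure(list(expression = pr$expression, probe_map = pr$probe_map,
                   biological = bio, clinical = clinical, truth = truth,
                   latent_risk = stats::setNames(risk, samples),
                   config = cfg),
              class = "mirna_cohort")
  })
}

#' Simulate pre/post-treatment sample pairs
#'
#' Pre-treatment profiles are drawn from the low-risk half of the latent
#' risk distribution (clinical responders); the matched post-treatment
#' profile is the pre profile shifted by `pair_shift` along the
#' unit-normalized resistance direction, plus fresh technical noise.
#'
#' @param cohort A `mirna_cohort` from [simulate_survival_cohort()]
#'   (defines features and the latent risk score).
#' @param direction Named numeric vector of feature weights (the
#'   resistance direction, e.g. a fitted risk model's `weights`).
#' @param pair_shift Shift magnitude in log2 units.
#' @param tech_sd Technical replicate noise SD (0 gives identical
#'   replicate probes).
#' @param seed Optional seed; defaults to `config$seed + 2`.
#' @return A list of class `pair_cohort` with probe-level `expression`
#'   for `2 * n_pairs` samples, `probe_map`, `clinical` (pair ids and
#'   timepoints) and `config`.
#' @export
simulate_pairs <- function(cohort, direction,
                           pair_shift = cohort$config$pair_shift,
                           tech_sd = cohort$config$noise_sd / 2,
                           seed = NULL) {
  cfg <- cohort$config
  if (length(direction) == 0L || all(direction == 0)) {
    stop("resistance direction is a zero vector", call. = FALSE)
  }
  if (is.null(names(direction))) {
    stop("`direction` must be named by feature id", call. = FALSE)
  }
  feats <- feature_ids(cfg$n_features)
  if (!all(names(direction) %in% feats)) {
    stop("`direction` contains features unknown to the cohort",
         call. = FALSE)
  }
  dir_full <- stats::setNames(rep(0, cfg$n_features), feats)
  dir_full[names(direction)] <- direction
  unit <- dir_full / sqrt(sum(dir_full^2))
  hazard <- cohort$truth[cohort$truth$role == "hazard", , drop = FALSE]
  beta_full <- stats::setNames(rep(0, cfg$n_features), feats)
  beta_full[hazard$feature_id] <- hazard$effect
  local_seed(if (is.null(seed)) cfg$seed + 2L else seed, {
    n_pairs <- cfg$n_pairs
    pre_bio <- matrix(NA_real_, cfg$n_features, n_pairs)
    for (k in seq_len(n_pairs)) {
      repeat {
        z <- rnorm(cfg$n_features, 0, cfg$noise_sd)
        if (sum(z * beta_full) < 0 || all(beta_full == 0)) break
      }
      pre_bio[, k] <- z
    }
    post_bio <- pre_bio + pair_shift * unit
    bio <- cbind(pre_bio, post_bio)
    rownames(bio) <- feats
    ids <- c(sprintf("P%02d_pre", seq_len(n_pairs)),
             sprintf("P%02d_post", seq_len(n_pairs)))
    colnames(bio) <- ids
    pr <- probes_from_features(bio, cfg, tech_sd = tech_sd)
    clinical <- data.frame(
      sample_id = ids, class_label = "cancer",
      ttp_months = NA_real_, event = NA_integer_,
      pair_id = rep(sprintf("pair%02d", seq_len(n_pairs)), 2L),
      timepoint = rep(c("pre", "post"), each = n_pairs),
      stringsAsFactors = FALSE)
    structure(list(expression = pr$expression, probe_map = pr$probe_map,
                   biological = bio, clinical = clinical, config = cfg),
              class = "pair_cohort")
  })
}

#' Simulate a qPCR Ct table
#'
#' Duplicate wells per sample for each target miRNA plus the RNU6
#' reference. Cancer samples shift the target Ct by `-shift_cycles`
#' (overexpression lowers the cycle threshold).
#'
#' @param targets Character vector of target miRNA names.
#' @param shift_cycles Named numeric (per target) or scalar Ct shift in
#'   cancer samples; positive = overexpressed in cancer.
#' @param n_cancer,n_normal Samples per group.
#' @param ct_sd Between-sample Ct SD; well replicate SD is `ct_sd / 3`.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `sample_id`, `group`, `well`,
#'   `target`, `ct`.
#' @export
simulate_ct_table <- function(targets = c("miR-A", "miR-B"),
                              shift_cycles = 1, n_cancer = 4L,
                              n_normal = 4L, ct_sd = 0.3, seed = 1L) {
  if (length(shift_cycles) == 1L) {
    shift_cycles <- stats::setNames(rep(shift_cycles, length(targets)),
                                    targets)
  }
  local_seed(seed, {
    samples <- c(sprintf("C%02d", seq_len(n_cancer)),
                 sprintf("N%02d", seq_len(n_normal)))
    grp <- rep(c("cancer", "normal"), c(n_cancer, n_normal))
    rows <- list()
    for (s in seq_along(samples)) {
      ref_mean <- rnorm(1, 20, ct_sd)
      for (tg in c(targets, "RNU6")) {
        mu <- if (tg == "RNU6") ref_mean else {
          rnorm(1, 25, ct_sd) + ref_mean - 20 -
            if (grp[s] == "cancer") shift_cycles[[tg]] else 0
        }
        for (w in 1:2) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = samples[s], group = grp[s], well = w,
            target = tg, ct = mu + rnorm(1, 0, ct_sd / 3),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `expression.tsv` (probe level), `clinical.tsv`,
#' `probe_map.tsv`, and, for cohorts with planted signal, `truth.tsv`
#' (feature id, role, effect).
#'
#' @param cohort A `mirna_cohort` or `pair_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             probe_map = file.path(dir, "probe_map.tsv"))
  write_expression_tsv(cohort$expression, paths["expression"],
                       feature_col = "probe_id")
  write_clinical_tsv(cohort$clinical, paths["clinical"])
  write.table(data.frame(probe_id = names(cohort$probe_map),
                         feature_id = unname(cohort$probe_map)),
              paths["probe_map"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cohort$truth) && nrow(cohort$truth) > 0) {
    paths <- c(paths, truth = file.path(dir, "truth.tsv"))
    write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' @export
print.mirna_cohort <- function(x, ...) {
  cat(sprintf("synthetic miRNA cohort: %d probes (%d features) x %d samples\n",
              nrow(x$expression), x$config$n_features, ncol(x$expression)))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$clinical$class_label)),
                            table(x$clinical$class_label)), collapse = ", ")))
  if (any(!is.na(x$clinical$ttp_months))) {
    cat(sprintf("  TTP: median %.2f months, %.0f%% events\n",
                median(x$clinical$ttp_months, na.rm = TRUE),
                100 * mean(x$clinical$event, na.rm = TRUE)))
  }
  if (nrow(x$truth) > 0) {
    cat(sprintf("  planted: %d %s feature(s)\n", nrow(x$truth),
                paste(unique(x$truth$role), collapse = "/")))
  }
  invisible(x)
}
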