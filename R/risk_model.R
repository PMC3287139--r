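#' Fit a supervised principal-component risk model
#'
#' Supervised principal-component survival risk prediction: features
#' are screened by univariate Cox regression against TTP
#' (`p < selection_alpha`), the first two principal components of the
#' centered, selected-feature submatrix (samples as observations, no
#' variance scaling) are computed, and a Cox model of TTP on the two PC
#' scores yields coefficients `(b1, b2)`. Each sample's predictive
#' index is `PI = b1*u1 + b2*u2` where `u_k` is the sample's score on
#' loading `k` -- equivalently a weighted sum of centered log
#' intensities with per-feature weights `w = b1*V1 + b2*V2`. A high PI
#' corresponds to rapid progression.
#'
#' @param x Feature-by-sample matrix of log2 values (no missing).
#' @param ttp Time to progression (months) per sample.
#' @param event 0/1 progression indicator per sample.
#' @param selection_alpha Cox screening p-value threshold.
#' @param cutoff_percentile Training-PI percentile delineating the
#'   high-risk group (strictly above = high).
#' @return An object of class `risk_model`: `selected_features`,
#'   `means`, `loadings` (features x 2, orthonormal columns),
#'   `pc_betas`, `weights`, `training_pi`, `cutoff_percentile`.
#' @export
fit_risk_model <- function(x, ttp, event, selection_alpha = 0.05,
                           cutoff_percentile = 67) {
  assert_expression_matrix(x)
  event <- assert_survival(ttp, event, ncol(x))
  if (ncol(x) <= 2L) stop("training requires n > 2 samples", call. = FALSE)
  screen <- cox_screen(x, ttp, event)
  keep <- !is.na(screen$p) & screen$p < selection_alpha & screen$converged
  if (sum(keep) < 2L) {
    stop(sprintf(paste0("only %d feature(s) passed Cox screening at alpha ",
                        "= %g; increase selection_alpha"),
                 sum(keep), selection_alpha), call. = FALSE)
  }
  sel <- screen$feature_id[keep]
  xs <- t(x[sel, , drop = FALSE])          # samples x features
  mu <- colMeans(xs)
  xc <- sweep(xs, 2L, mu)
  sv <- svd(xc, nu = 2L, nv = 2L)
  if (sv$d[1L] <= 0) stop("selected submatrix has no variance", call. = FALSE)
  rank2 <- length(sv$d) >= 2L && sv$d[2L] > 1e-8 * sv$d[1L]
  loadings <- sv$v
  # deterministic sign: largest-magnitude loading entry positive
  for (k in 1:2) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
  }
  scores <- xc %*% loadings             # = U D up to the sign fix
  ncomp <- if (rank2) 2L else 1L
  fit <- .cpp_cox_multi(scores[, seq_len(ncomp), drop = FALSE],
                        as.numeric(ttp), event)
  if (fit$flag != 0) {
    stop("Cox regression on the principal components did not converge",
         call. = FALSE)
  }
  pc_betas <- c(fit$beta, rep(0, 2L - ncomp))
  weights <- drop(loadings %*% pc_betas)
  training_pi <- drop(scores %*% pc_betas)
  structure(list(selected_features = sel,
                 means = stats::setNames(mu, sel),
                 loadings = `dimnames<-`(loadings, list(sel, c("PC1", "PC2"))),
                 pc_betas = pc_betas,
                 weights = stats::setNames(weights, sel),
                 training_pi = stats::setNames(training_pi, colnames(x)),
                 cutoff_percentile = cutoff_percentile,
                 selection_alpha = selection_alpha,
                 screen = screen,
                 n_train = ncol(x)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf(paste0("supervised-PC risk model: %d features (alpha = %g), ",
                     "%d training samples\n"),
              length(x$selected_features), x$selection_alpha, x$n_train))
  cat(sprintf("  PC Cox coefficients: %.4f, %.4f; cutoff percentile %g%%\n",
              x$pc_betas[1L], x$pc_betas[2L], x$cutoff_percentile))
  invisible(x)
}

#' Predictive index of new samples under a fitted risk model
#'
#' @param model A [fit_risk_model()] object.
#' @param x Feature-by-sample matrix (or named vector for one sample)
#'   covering the model's selected features.
#' @return Named numeric vector of predictive indices.
#' @export
predict_index <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L,
                                dimnames = list(names(x), "sample"))
  missing <- setdiff(model$selected_features, rownames(x))
  if (length(missing) > 0) {
    stop("sample(s) lack selected feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  xs <- x[model$selected_features, , drop = FALSE]
  if (anyNA(xs)) {
    bad <- model$selected_features[which(rowSums(is.na(xs)) > 0L)[1L]]
    stop("masked value in selected feature '", bad, "'", call. = FALSE)
  }
  drop(crossprod(xs - model$means, model$weights))
}

#' Percentile of a predictive index within the training distribution
#'
#' Midrank rule: `100 * (#{train < pi} + 0.5 * #{train == pi}) /
#' n_train`, so a test sample falling on the training median (odd n)
#' receives exactly 50%.
#'
#' @param model A fitted `risk_model`.
#' @param pi Predictive index value(s).
#' @return Percentile(s) in `[0, 100]`.
#' @export
pi_percentile <- function(model, pi) {
  ref <- model$training_pi
  vapply(pi, function(v) {
    100 * (sum(ref < v) + 0.5 * sum(ref == v)) / length(ref)
  }, numeric(1L))
}

#' Assign low/high risk group from a predictive-index percentile
#'
#' High risk (rapid progression expected) iff the percentile strictly
#' exceeds the cutoff.
#'
#' @param percentile Value(s) in `[0, 100]`.
#' @param cutoff Percentile cutoff (default 67).
#' @return Character vector, `"low"` or `"high"`.
#' @export
assign_risk_group <- function(percentile, cutoff = 67) {
  if (any(percentile < 0 | percentile > 100)) {
    stop("percentile must be in [0, 100]", call. = FALSE)
  }
  ifelse(percentile > cutoff, "high", "low")
}

#' Risk calls for new samples
#'
#' @param object A fitted `risk_model`.
#' @param newdata Feature-by-sample matrix covering the selected
#'   features.
#' @param ... Unused.
#' @return A `data.frame`: `sample_id`, `predictive_index`,
#'   `percentile`, `group`.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  pi <- predict_index(object, newdata)
  pct <- pi_percentile(object, pi)
  data.frame(sample_id = names(pi),
             predictive_index = unname(pi),
             percentile = unname(pct),
             group = assign_risk_group(unname(pct),
                                       object$cutoff_percentile),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated risk groups
#'
#' For each sample the entire model -- Cox screening, principal
#' components, PC Cox regression -- is refitted on the remaining n - 1
#' samples; the left-out sample's predictive index is converted to a
#' percentile against that fold's training indices and to a risk group.
#' Folds in which fewer than two features pass screening (or the PC Cox
#' fit fails) assign the left-out sample to the low-risk group; their
#' count is reported via a warning and the `weak_fold` column.
#'
#' @inheritParams fit_risk_model
#' @return A `data.frame`: `sample_id`, `predictive_index`,
#'   `percentile`, `group`, `weak_fold`, `n_selected`.
#' @export
loocv_risk_groups <- function(x, ttp, event, selection_alpha = 0.05,
                              cutoff_percentile = 67) {
  assert_expression_matrix(x)
  event <- assert_survival(ttp, event, ncol(x))
  if (ncol(x) < 10L) stop("LOOCV requires n >= 10 samples", call. = FALSE)
  if (anyNA(x)) stop("expression matrix contains masked values",
                     call. = FALSE)
  res <- .cpp_loocv(t(x), as.numeric(ttp), event, selection_alpha,
                    cutoff_percentile)
  nweak <- sum(res$weak_fold)
  if (nweak > 0L) {
    warning(sprintf(paste0("%d LOOCV fold(s) could not support a model; ",
                           "left-out samples assigned low risk"), nweak),
            call. = FALSE)
  }
  data.frame(sample_id = colnames(x),
             predictive_index = res$pi,
             percentile = res$percentile,
             group = ifelse(res$group == 1L, "high", "low"),
             weak_fold = res$weak_fold == 1L,
             n_selected = res$n_selected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param ttp Nonnegative event/censoring times (months).
#' @param event 0/1 event indicator.
#' @return A `data.frame`: `time`, `n_risk`, `n_event`, `survival`
#'   (one row per observed time point).
#' @export
km_estimate <- function(ttp, event) {
  event <- assert_survival(ttp, event)
  fit <- survival::survfit(survival::Surv(ttp, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv, row.names = NULL)
}

#' Two-group log-rank chi-square statistic
#'
#' Standard 1-df log-rank statistic `(O - E)^2 / V` over the pooled
#' event times, with the hypergeometric variance.
#'
#' @param groups Two-level group label per sample.
#' @param ttp Event/censoring times.
#' @param event 0/1 event indicator.
#' @return The chi-square statistic (scalar).
#' @export
logrank_statistic <- function(groups, ttp, event) {
  event <- assert_survival(ttp, event, length(groups))
  g <- as.character(groups)
  lev <- unique(g)
  if (length(lev) != 2L) {
    stop("exactly two nonempty groups required (got ", length(lev), ")",
         call. = FALSE)
  }
  .cpp_logrank(as.integer(g == lev[2L]), as.numeric(ttp), event)
}

#' Permutation significance of the cross-validated risk separation
#'
#' The observed statistic `LR_d` is the log-rank chi-square of the
#' leave-one-out cross-validated risk groups on the real survival data.
#' For each permutation the (TTP, event) pairs are jointly reshuffled
#' across samples and the full LOOCV pipeline -- screening, supervised
#' PCs, Cox on the PC scores, percentile grouping -- is re-run,
#' yielding a null distribution of the statistic. The reported p-value
#' is `(1 + #{LR_perm >= LR_d}) / (1 + n_perm)`.
#'
#' @inheritParams loocv_risk_groups
#' @param n_perm Number of permutations (>= 19).
#' @param seed Optional integer seed for the permutation stream.
#' @return A list of class `mirsig_permtest`: `p`, `lr_obs`, `lr_perm`,
#'   `groups` (observed cross-validated groups), `n_weak_folds`.
#' @export
permutation_significance <- function(x, ttp, event, n_perm = 1000L,
                                     seed = NULL, selection_alpha = 0.05,
                                     cutoff_percentile = 67) {
  assert_expression_matrix(x)
  event <- assert_survival(ttp, event, ncol(x))
  if (n_perm < 19L) stop("n_perm must be >= 19", call. = FALSE)
  n <- ncol(x)
  # canonical sample order, so the result is invariant to how the
  # input samples happen to be arranged
  ord <- order(colnames(x))
  x <- x[, ord, drop = FALSE]
  ttp <- ttp[ord]
  event <- event[ord]
  perm <- local_seed(seed,
                     vapply(seq_len(n_perm), function(b) sample.int(n),
                            integer(n)))
  res <- .cpp_perm_test(t(x), as.numeric(ttp), event, selection_alpha,
                        cutoff_percentile, perm - 1L)
  groups <- character(n)
  groups[ord] <- ifelse(res$group == 1L, "high", "low")  # back to input order
  res$group <- NULL
  structure(list(p = res$p, lr_obs = res$lr_obs,
                 lr_perm = as.numeric(res$lr_perm),
                 groups = groups,
                 n_weak_folds = sum(res$weak_fold),
                 n_perm = n_perm,
                 selection_alpha = selection_alpha,
                 cutoff_percentile = cutoff_percentile),
            class = "mirsig_permtest")
}

#' @export
print.mirsig_permtest <- function(x, ...) {
  cat(sprintf(paste0("cross-validated Kaplan-Meier permutation test: ",
                     "LR_d = %.3f, p = %.4g (%d permutations)\n"),
              x$lr_obs, x$p, x$n_perm))
  invisible(x)
}
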