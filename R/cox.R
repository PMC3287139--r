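#' Univariate Cox proportional-hazards fit for one feature
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) by Newton
#' iteration with step halving, to gradient norm below `tol`. Fits that
#' do not converge within `maxit` steps, or whose coefficient runs away
#' (monotone likelihood), are flagged non-converged and should be
#' excluded from selection. The p-value is the Wald test.
#'
#' @param x Per-sample feature values.
#' @param ttp Time to progression in months.
#' @param event 0/1 progression indicator (1 = progressed).
#' @param maxit Maximum Newton steps.
#' @param tol Gradient convergence tolerance.
#' @return A list: `beta`, `hazard_ratio`, `se`, `p`, `converged`,
#'   `iters`.
#' @export
cox_fit_single <- function(x, ttp, event, maxit = 50L, tol = 1e-8) {
  event <- assert_survival(ttp, event, length(x))
  if (sum(event) < 2L) stop("no events (fewer than 2 progression events)",
                            call. = FALSE)
  if (max(x) == min(x)) stop("no variation in feature values",
                             call. = FALSE)
  fit <- .cpp_cox_uni(as.numeric(x), as.numeric(ttp), event, maxit, tol)
  list(beta = fit$beta, hazard_ratio = exp(fit$beta),
       se = fit$se, p = fit$p,
       converged = fit$flag == 0, iters = as.integer(fit$iters))
}

#' Per-feature Cox screening of an expression matrix against TTP
#'
#' Fits one proportional-hazards model per feature, relating TTP to the
#' feature's (continuous) log2 expression. FDR (Benjamini-Hochberg) is
#' computed over all tested features.
#'
#' @param x Feature-by-sample matrix (no missing values).
#' @inheritParams cox_fit_single
#' @return A `data.frame`: `feature_id`, `beta`, `hazard_ratio`, `se`,
#'   `p`, `fdr`, `converged`.
#' @export
cox_screen <- function(x, ttp, event) {
  assert_expression_matrix(x)
  event <- assert_survival(ttp, event, ncol(x))
  if (anyNA(x)) stop("expression matrix contains masked values; run ",
                     "filter_impute() first", call. = FALSE)
  if (sum(event) < 2L) stop("no events (fewer than 2 progression events)",
                            call. = FALSE)
  fit <- .cpp_cox_screen(t(x), as.numeric(ttp), event, 50L, 1e-8)
  converged <- fit[, "flag"] == 0
  p <- fit[, "p"]
  data.frame(feature_id = rownames(x), beta = fit[, "beta"],
             hazard_ratio = exp(fit[, "beta"]), se = fit[, "se"],
             p = p, fdr = bh_fdr(p), converged = converged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select TTP-associated features and split by hazard direction
#'
#' Features with Wald `p < alpha` are partitioned into a
#' chemoresistance list (hazard ratio > 1: overexpression associated
#' with rapid progression) and a chemosensitivity list (hazard ratio
#' < 1: overexpression associated with delayed progression), each
#' sorted by ascending p-value.
#'
#' @inheritParams cox_screen
#' @param alpha Feature-selection p-value threshold in (0, 1).
#' @return A list: `resistance`, `sensitivity` (data.frames shaped like
#'   [cox_screen()] output), and `all` (the full screening table).
#' @export
select_survival_features <- function(x, ttp, event, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  tab <- cox_screen(x, ttp, event)
  sel <- tab[!is.na(tab$p) & tab$p < alpha & tab$converged, , drop = FALSE]
  sel <- sel[order(sel$p), , drop = FALSE]
  list(resistance = sel[sel$hazard_ratio > 1, , drop = FALSE],
       sensitivity = sel[sel$hazard_ratio < 1, , drop = FALSE],
       all = tab)
}
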