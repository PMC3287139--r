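#' Evaluate one pre/post-treatment sample pair
#'
#' Computes the predictive index and training percentile of both
#' samples under a fitted risk model. The pair is called `correct` iff
#' the post-treatment sample has a strictly higher predictive index
#' than the pre-treatment sample (ties count as incorrect); the
#' pre-treatment risk call uses the model's percentile cutoff.
#'
#' @param model A fitted [fit_risk_model()] object.
#' @param x_pre,x_post Named numeric vectors (or one-column matrices)
#'   of feature values covering the model's selected features.
#' @param pair_id Identifier for the pair.
#' @return A one-row `data.frame`: `pair_id`, `pre_pi`, `post_pi`,
#'   `pre_percentile`, `post_percentile`, `pre_group`, `overall`.
#' @export
evaluate_pair <- function(model, x_pre, x_post, pair_id = "pair") {
  to_vec <- function(v) if (is.matrix(v)) stats::setNames(v[, 1L],
                                                          rownames(v)) else v
  x_pre <- to_vec(x_pre)
  x_post <- to_vec(x_post)
  pi_pre <- predict_index(model, x_pre)
  pi_post <- predict_index(model, x_post)
  pct_pre <- pi_percentile(model, pi_pre)
  pct_post <- pi_percentile(model, pi_post)
  data.frame(pair_id = pair_id,
             pre_pi = unname(pi_pre), post_pi = unname(pi_post),
             pre_percentile = unname(pct_pre),
             post_percentile = unname(pct_post),
             pre_group = assign_risk_group(unname(pct_pre),
                                           model$cutoff_percentile),
             overall = if (pi_post > pi_pre) "correct" else "incorrect",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate all pre/post pairs of a cohort
#'
#' @param model A fitted `risk_model` (trained on the training cohort
#'   only; never refit with pair samples).
#' @param x Feature-by-sample matrix containing the pair samples.
#' @param clinical Clinical table with `sample_id`, `pair_id`,
#'   `timepoint` columns describing the pairs.
#' @return A `data.frame` with one row per pair (see [evaluate_pair()]).
#' @export
evaluate_pairs <- function(model, x, clinical) {
  has_pair <- !is.na(clinical$pair_id) & clinical$pair_id != ""
  pairs <- unique(clinical$pair_id[has_pair])
  if (length(pairs) == 0L) stop("no pairs in clinical table", call. = FALSE)
  out <- lapply(pairs, function(pid) {
    pre_id <- clinical$sample_id[has_pair & clinical$pair_id == pid &
                                   clinical$timepoint == "pre"]
    post_id <- clinical$sample_id[has_pair & clinical$pair_id == pid &
                                    clinical$timepoint == "post"]
    if (length(pre_id) != 1L || length(post_id) != 1L) {
      stop(sprintf("pair '%s' lacks a unique pre and post sample", pid),
           call. = FALSE)
    }
    evaluate_pair(model, x[, pre_id], x[, post_id], pair_id = pid)
  })
  do.call(rbind, out)
}

#' Summarize paired pre/post predictions
#'
#' Two proof-of-principle fractions: how many pre-treatment samples
#' were called low-risk, and how many pairs showed the expected
#' post-treatment increase in predictive index.
#'
#' @param results Output of [evaluate_pairs()] (>= 1 row).
#' @return A list: `pre_low` = c(count, total), `overall_correct` =
#'   c(count, total), and the corresponding `pre_low_accuracy`,
#'   `overall_accuracy`.
#' @export
summarize_pairs <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("no pair results to summarize", call. = FALSE)
  }
  n <- nrow(results)
  n_low <- sum(results$pre_group == "low")
  n_corr <- sum(results$overall == "correct")
  list(pre_low = c(count = n_low, total = n),
       overall_correct = c(count = n_corr, total = n),
       pre_low_accuracy = n_low / n,
       overall_accuracy = n_corr / n)
}
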