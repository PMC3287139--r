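#' Reference-normalized Ct (delta-Ct)
#'
#' `delta_ct = mean(target wells) - mean(reference wells)`; duplicate
#' wells are averaged before subtraction.
#'
#' @param target_ct Numeric Ct values of the target miRNA (wells).
#' @param reference_ct Numeric Ct values of the reference gene (RNU6).
#' @return The delta-Ct value (scalar).
#' @export
delta_ct <- function(target_ct, reference_ct) {
  if (length(reference_ct) == 0L || all(is.na(reference_ct))) {
    stop("missing reference (RNU6) wells", call. = FALSE)
  }
  if (length(target_ct) == 0L || all(is.na(target_ct))) {
    stop("missing target wells", call. = FALSE)
  }
  mean(target_ct, na.rm = TRUE) - mean(reference_ct, na.rm = TRUE)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddct = dct_test - dct_control`; relative expression is
#' `2^(-ddct)`; the reported fold change on the log2 scale is `-ddct`
#' (an FC of -1 means a 50% decrease).
#'
#' @param dct_test Delta-Ct of the test sample.
#' @param dct_control Delta-Ct (or baseline) of the control.
#' @return A list: `ddct`, `relative_expression`, `log2_fc`.
#' @export
ddct_expression <- function(dct_test, dct_control) {
  ddct <- dct_test - dct_control
  list(ddct = ddct, relative_expression = 2^(-ddct), log2_fc = -ddct)
}

#' Pooled-variance t-test on log2 fold changes between groups
#'
#' Two-sided Student t-test (pooled variance) comparing cancer and
#' normal log2-scale fold changes. Zero pooled variance is flagged
#' rather than raising an error.
#'
#' @param fc_case,fc_control Numeric log2 fold changes per group.
#' @return A list: `statistic`, `p`, `df`, `flagged` (TRUE when the
#'   test is undefined because of zero pooled variance).
#' @export
qpcr_group_compare <- function(fc_case, fc_control) {
  if (length(fc_case) < 2L || length(fc_control) < 2L) {
    stop(">= 2 samples per group required", call. = FALSE)
  }
  res <- tryCatch(t.test(fc_case, fc_control, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(list(statistic = NA_real_, p = NA_real_, df = NA_real_,
                flagged = TRUE))
  }
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), flagged = FALSE)
}

#' Full delta-delta-Ct analysis of a Ct table
#'
#' For each target miRNA: duplicate wells are averaged, Ct values are
#' normalized to the reference gene by subtraction (delta-Ct), each
#' sample is compared against the control baseline (the mean delta-Ct
#' of the control group, or a designated control sample) to give
#' delta-delta-Ct, relative expression `2^(-ddct)` and the log2 fold
#' change `-ddct`, and the two groups are compared with a
#' pooled-variance Student t-test on the log2 fold changes.
#'
#' @param ct A `data.frame` with columns `sample_id`, `group`, `well`,
#'   `target`, `ct` (the reference gene appears as one of the targets).
#' @param reference Reference gene name (default `"RNU6"`).
#' @param control_group Group providing the control baseline.
#' @param control_sample Optional single sample id to use as baseline
#'   instead of the control-group mean.
#' @return A list: `per_sample` (sample, group, target, delta_ct, ddct,
#'   relative_expression, log2_fc) and `per_target` (target, t
#'   statistic, p, flagged).
#' @export
qpcr_analyze <- function(ct, reference = "RNU6", control_group = "normal",
                         control_sample = NULL) {
  need <- c("sample_id", "group", "target", "ct")
  if (!all(need %in% colnames(ct))) {
    stop("ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  targets <- setdiff(unique(ct$target), reference)
  if (length(targets) == 0L) stop("no target miRNAs in table", call. = FALSE)
  samples <- unique(ct$sample_id)
  per_sample <- list()
  for (tg in targets) {
    dct <- vapply(samples, function(s) {
      delta_ct(ct$ct[ct$sample_id == s & ct$target == tg],
               ct$ct[ct$sample_id == s & ct$target == reference])
    }, numeric(1L))
    grp <- vapply(samples, function(s)
      ct$group[ct$sample_id == s][1L], character(1L))
    baseline <- if (is.null(control_sample)) {
      mean(dct[grp == control_group])
    } else {
      dct[[control_sample]]
    }
    dd <- ddct_expression(dct, baseline)
    per_sample[[tg]] <- data.frame(
      sample_id = samples, group = unname(grp), target = tg,
      delta_ct = unname(dct), ddct = unname(dd$ddct),
      relative_expression = unname(dd$relative_expression),
      log2_fc = unname(dd$log2_fc),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, per_sample)
  per_target <- do.call(rbind, lapply(targets, function(tg) {
    sub <- per_sample[per_sample$target == tg, ]
    cmp <- qpcr_group_compare(sub$log2_fc[sub$group != control_group],
                              sub$log2_fc[sub$group == control_group])
    data.frame(target = tg, statistic = cmp$statistic, p = cmp$p,
               flagged = cmp$flagged, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, per_target = per_target)
}
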