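#' Log2-transform a ratio matrix
#'
#' @param x Matrix of positive linear-scale ratios; `NA` entries stay masked.
#' @return Matrix of log2 values with the same dimnames.
#' @export
log2_transform <- function(x) {
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    show <- utils::head(bad, 5L)
    lab <- apply(show, 1L, function(ij) {
      sprintf("[%s, %s]",
              if (is.null(rownames(x))) ij[1L] else rownames(x)[ij[1L]],
              if (is.null(colnames(x))) ij[2L] else colnames(x)[ij[2L]])
    })
    stop("nonpositive unmasked values at ", paste(lab, collapse = ", "),
         if (nrow(bad) > 5L) sprintf(" (and %d more)", nrow(bad) - 5L) else "",
         call. = FALSE)
  }
  log2(x)
}

#' Lowess intensity-dependent normalization of one array
#'
#' Removes the intensity-dependent trend from the log-ratios of a
#' two-channel array: the classical robust lowess smoother (local
#' linear, robustifying iterations) is fitted to M (log2 ratio) versus
#' A (mean log2 intensity) and subtracted.
#'
#' @param m Numeric vector of per-probe log2 ratios (M); `NA` = masked.
#' @param a Numeric vector of per-probe mean log2 intensities (A).
#' @param span Lowess smoother span in (0, 1].
#' @param iter Number of robustifying iterations of the smoother.
#' @return Normalized M vector, same length and masking as `m`.
#' @export
lowess_normalize <- function(m, a, span = 2/3, iter = 3L) {
  if (length(m) != length(a)) stop("M and A must have equal length",
                                   call. = FALSE)
  if (!is.numeric(span) || span <= 0 || span > 1) {
    stop("`span` must be in (0, 1]", call. = FALSE)
  }
  ok <- !is.na(m) & !is.na(a)
  if (sum(ok) < 10L) {
    stop("fewer than 10 unmasked probes: smoother underdetermined",
         call. = FALSE)
  }
  mm <- m[ok]
  aa <- a[ok]
  fit <- lowess(aa, mm, f = span, iter = iter)
  trend <- approx(fit$x, fit$y, xout = aa, rule = 2, ties = mean)$y
  out <- m
  out[ok] <- mm - trend
  out
}

#' Lowess-normalize every array of an expression matrix
#'
#' @param m_matrix Probe-by-sample matrix of log2 ratios.
#' @param a_matrix Probe-by-sample matrix of mean log2 intensities.
#' @inheritParams lowess_normalize
#' @return Normalized log2-ratio matrix.
#' @export
lowess_normalize_matrix <- function(m_matrix, a_matrix, span = 2/3,
                                    iter = 3L) {
  if (!identical(dim(m_matrix), dim(a_matrix))) {
    stop("M and A matrices must have identical dimensions", call. = FALSE)
  }
  out <- m_matrix
  for (j in seq_len(ncol(m_matrix))) {
    out[, j] <- lowess_normalize(m_matrix[, j], a_matrix[, j],
                                 span = span, iter = iter)
  }
  out
}

#' Collapse replicate probes to one value per mature miRNA
#'
#' Each miRNA is summarized per sample as the median of its unmasked
#' replicate probe values; a miRNA is masked in a sample only when all of
#' its replicates are masked there.
#'
#' @param x Probe-by-sample matrix.
#' @param probe_map Named character vector mapping probe id -> miRNA id
#'   (or a data.frame with columns `probe_id`, `feature_id`).
#' @return miRNA-by-sample matrix.
#' @export
collapse_replicates <- function(x, probe_map) {
  assert_expression_matrix(x)
  if (is.data.frame(probe_map)) {
    probe_map <- stats::setNames(as.character(probe_map$feature_id),
                                 probe_map$probe_id)
  }
  missing_probes <- setdiff(rownames(x), names(probe_map))
  if (length(missing_probes) > 0) {
    stop("probes absent from map: ",
         paste(utils::head(missing_probes, 5L), collapse = ", "),
         call. = FALSE)
  }
  mirna <- probe_map[rownames(x)]
  groups <- split(seq_len(nrow(x)), factor(mirna, levels = unique(mirna)))
  out <- matrix(NA_real_, length(groups), ncol(x),
                dimnames = list(names(groups), colnames(x)))
  for (g in seq_along(groups)) {
    sub <- x[groups[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else median(v)
    })
  }
  out
}

#' Drop heavily-masked features and impute remaining missing values
#'
#' Features masked in more than `max_missing` of samples are removed;
#' remaining masked entries are imputed with the feature median across
#' samples.
#'
#' @param x Feature-by-sample matrix.
#' @param max_missing Maximum tolerated masked fraction per feature.
#' @return Matrix with no missing values.
#' @export
filter_impute <- function(x, max_missing = 0.5) {
  assert_expression_matrix(x)
  frac <- rowMeans(is.na(x))
  x <- x[frac <= max_missing, , drop = FALSE]
  for (i in which(rowSums(is.na(x)) > 0L)) {
    med <- median(x[i, ], na.rm = TRUE)
    x[i, is.na(x[i, ])] <- med
  }
  x
}
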