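#' Per-feature two-sample t-test (pooled variance)
#'
#' Classical pooled-variance two-sample t statistics per feature, with
#' two-sided p-values, Benjamini-Hochberg FDR, and the geometric-mean
#' expression ratio `2^(mean_case - mean_control)` of the log2 values.
#' Features with zero pooled variance are flagged `excluded` and carry
#' `NA` statistics.
#'
#' @param x Feature-by-sample matrix of log2 values (`NA` = masked).
#' @param labels Character/factor class label per sample.
#' @param case,control The two class labels to compare; the ratio is
#'   case over control.
#' @return A `data.frame`: `feature_id`, `statistic`, `df`, `p`, `fdr`,
#'   `ratio`, `excluded`.
#' @export
t_test_per_feature <- function(x, labels, case = "cancer",
                               control = "normal") {
  assert_expression_matrix(x)
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) {
    stop("one label per sample required", call. = FALSE)
  }
  i1 <- labels == case
  i2 <- labels == control
  if (sum(i1) < 2L || sum(i2) < 2L) {
    stop("both classes need >= 2 samples", call. = FALSE)
  }
  x1 <- x[, i1, drop = FALSE]
  x2 <- x[, i2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1L, stats::var, na.rm = TRUE)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  usable <- n1 >= 2L & n2 >= 2L & !is.na(sp2)
  excluded <- !usable | sp2 <= 0
  tt <- rep(NA_real_, nrow(x))
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  ok <- !excluded
  tt[ok] <- (m1[ok] - m2[ok]) / se[ok]
  p <- rep(NA_real_, nrow(x))
  p[ok] <- 2 * pt(-abs(tt[ok]), df[ok])
  fdr <- rep(NA_real_, nrow(x))
  fdr[ok] <- bh_fdr(p[ok])
  data.frame(feature_id = rownames(x), statistic = tt, df = df, p = p,
             fdr = fdr, ratio = 2^(m1 - m2), excluded = excluded,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin validating wrapper
#' around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, monotone nondecreasing in `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

classifier_methods <- c("CCP", "DLDA", "1NN", "3NN", "NC", "SVM")

#' Train a two-class expression classifier
#'
#' Implements the six classifiers of the microarray class-prediction
#' protocol: compound covariate predictor (CCP), diagonal linear
#' discriminant analysis (DLDA), 1- and 3-nearest neighbors, nearest
#' centroid (NC), and a linear support vector machine (cost 1, features
#' standardized by training mean/SD). Feature selection (pooled t-test
#' `p < selection_alpha`) uses the training data only. If no feature
#' passes selection the classifier predicts the majority training class
#' with a warning.
#'
#' @param x Feature-by-sample training matrix (log2 values).
#' @param labels Class label per training sample (two classes).
#' @param method One of `"CCP"`, `"DLDA"`, `"1NN"`, `"3NN"`, `"NC"`,
#'   `"SVM"`.
#' @param selection_alpha Feature-selection p-value threshold.
#' @return An object of class `mirna_classifier` with a
#'   [predict.mirna_classifier()] method.
#' @export
train_classifier <- function(x, labels, method = classifier_methods,
                             selection_alpha = 0.05) {
  method <- match.arg(method)
  assert_expression_matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes required",
                                  call. = FALSE)
  stats <- t_test_per_feature(x, labels, case = classes[1L],
                              control = classes[2L])
  keep <- !stats$excluded & stats$p < selection_alpha
  obj <- list(method = method, classes = classes,
              selection_alpha = selection_alpha,
              features = stats$feature_id[keep], degenerate = FALSE)
  if (!any(keep)) {
    warning("no features passed selection; predicting majority class",
            call. = FALSE)
    obj$degenerate <- TRUE
    obj$majority <- names(which.max(table(labels)))
    class(obj) <- "mirna_classifier"
    return(obj)
  }
  xs <- x[keep, , drop = FALSE]
  m1 <- rowMeans(xs[, labels == classes[1L], drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(xs[, labels == classes[2L], drop = FALSE], na.rm = TRUE)
  obj$centroids <- cbind(m1, m2)
  colnames(obj$centroids) <- classes
  if (method == "CCP") {
    w <- stats$statistic[keep]
    cc <- drop(crossprod(xs, w))
    c1 <- mean(cc[labels == classes[1L]])
    c2 <- mean(cc[labels == classes[2L]])
    obj$weights <- w
    obj$threshold <- (c1 + c2) / 2
    obj$upper_class <- if (c1 >= c2) classes[1L] else classes[2L]
  } else if (method == "DLDA") {
    n1 <- sum(labels == classes[1L])
    n2 <- sum(labels == classes[2L])
    v1 <- apply(xs[, labels == classes[1L], drop = FALSE], 1L, stats::var)
    v2 <- apply(xs[, labels == classes[2L], drop = FALSE], 1L, stats::var)
    obj$pooled_var <- pmax(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2),
                           1e-12)
  } else if (method %in% c("1NN", "3NN")) {
    obj$k <- if (method == "1NN") 1L else 3L
    obj$train_x <- xs
    obj$train_labels <- labels
  } else if (method == "SVM") {
    mu <- rowMeans(xs)
    sdv <- apply(xs, 1L, sd)
    sdv[sdv == 0] <- 1
    obj$scale_center <- mu
    obj$scale_sd <- sdv
    zt <- t((xs - mu) / sdv)
    obj$svm_fit <- e1071::svm(zt, factor(labels, levels = classes),
                              kernel = "linear", cost = 1, scale = FALSE)
  }
  class(obj) <- "mirna_classifier"
  obj
}

# deterministic k-nearest-neighbour vote: neighbours ranked by distance
# then training order, majority of the k nearest
knn_predict <- function(train_x, train_labels, test_x, k) {
  apply(test_x, 2L, function(v) {
    d <- colSums((train_x - v)^2)
    nb <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else train_labels[nb[1L]]
  })
}

#' Predict class labels for new samples
#'
#' @param object A fitted [train_classifier()] object.
#' @param newdata Feature-by-sample matrix covering the selected
#'   features.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.mirna_classifier <- function(object, newdata, ...) {
  assert_expression_matrix(newdata)
  if (object$degenerate) {
    return(stats::setNames(rep(object$majority, ncol(newdata)),
                           colnames(newdata)))
  }
  missing <- setdiff(object$features, rownames(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks selected features: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  xs <- newdata[object$features, , drop = FALSE]
  cl <- object$classes
  out <- switch(
    object$method,
    CCP = {
      cc <- drop(crossprod(xs, object$weights))
      other <- setdiff(cl, object$upper_class)
      ifelse(cc > object$threshold, object$upper_class, other)
    },
    DLDA = {
      d1 <- colSums((xs - object$centroids[, 1L])^2 / object$pooled_var)
      d2 <- colSums((xs - object$centroids[, 2L])^2 / object$pooled_var)
      ifelse(d1 <= d2, cl[1L], cl[2L])
    },
    NC = {
      d1 <- colSums((xs - object$centroids[, 1L])^2)
      d2 <- colSums((xs - object$centroids[, 2L])^2)
      ifelse(d1 <= d2, cl[1L], cl[2L])
    },
    `1NN` = knn_predict(object$train_x, object$train_labels, xs, 1L),
    `3NN` = knn_predict(object$train_x, object$train_labels, xs, 3L),
    SVM = {
      zt <- t((xs - object$scale_center) / object$scale_sd)
      as.character(predict(object$svm_fit, zt))
    })
  stats::setNames(as.character(out), colnames(newdata))
}

#' Random-partition cross-validated prediction accuracy
#'
#' Repeats the full class-prediction protocol over `n_partitions`
#' class-stratified random 1:1 training/test splits: features are
#' re-selected on each training half, all classifiers are refitted, and
#' test-half accuracies are recorded. Degenerate training halves (a
#' class absent) are redrawn and counted.
#'
#' @inheritParams train_classifier
#' @param n_partitions Number of random splits.
#' @param methods Classifier names to evaluate.
#' @param seed Optional integer seed for the partition stream.
#' @return A list of class `partition_result`: `accuracy` (matrix
#'   `n_partitions` x classifiers), `median_accuracy` (named vector),
#'   `n_redrawn`.
#' @export
cross_partition_accuracy <- function(x, labels, n_partitions = 100L,
                                     selection_alpha = 0.05,
                                     methods = classifier_methods,
                                     seed = NULL) {
  assert_expression_matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes required",
                                  call. = FALSE)
  if (min(table(labels)) < 4L) stop(">= 4 samples per class required",
                                    call. = FALSE)
  local_seed(seed, {
    acc <- matrix(NA_real_, n_partitions, length(methods),
                  dimnames = list(NULL, methods))
    n_redrawn <- 0L
    for (b in seq_len(n_partitions)) {
      repeat {
        train_idx <- unlist(lapply(classes, function(cl) {
          idx <- which(labels == cl)
          sample(idx, floor(length(idx) / 2))
        }))
        if (length(unique(labels[train_idx])) == 2L &&
            length(train_idx) < length(labels)) break
        n_redrawn <- n_redrawn + 1L
      }
      test_idx <- setdiff(seq_along(labels), train_idx)
      xtr <- x[, train_idx, drop = FALSE]
      xte <- x[, test_idx, drop = FALSE]
      for (m in methods) {
        fit <- suppressWarnings(
          train_classifier(xtr, labels[train_idx], method = m,
                           selection_alpha = selection_alpha))
        pred <- predict(fit, xte)
        acc[b, m] <- mean(pred == labels[test_idx])
      }
    }
    structure(list(accuracy = acc,
                   median_accuracy = apply(acc, 2L, median),
                   n_redrawn = n_redrawn,
                   n_partitions = n_partitions,
                   selection_alpha = selection_alpha),
              class = "partition_result")
  })
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("class prediction over %d random 1:1 partitions (alpha = %g)\n",
              x$n_partitions, x$selection_alpha))
  cat("median test accuracy:\n")
  print(round(x$median_accuracy, 3))
  invisible(x)
}
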