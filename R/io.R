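#' Read a feature-by-sample expression table
#'
#' Reads a tab-separated expression table: first column feature (probe or
#' miRNA) identifiers, header row sample identifiers, remaining cells
#' numeric log-ratio values. Empty cells become `NA` (masked), never zero.
#'
#' @param path Path to a TSV file (UTF-8, tab-separated, '.' decimal).
#' @return A numeric matrix, rows = features, columns = samples.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                 bad, path, nf[bad], nf[1L]), call. = FALSE)
  }
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  if (ncol(df) < 2L) stop("expression table needs >= 1 sample column",
                          call. = FALSE)
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  feature_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  out <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(feature_ids, sample_ids))
  for (j in seq_len(ncol(vals))) {
    cell <- trimws(vals[, j])
    empty <- cell == "" | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric cell at row %d (feature '%s'), column '%s': '%s'",
                   i, feature_ids[i], sample_ids[j], vals[i, j]), call. = FALSE)
    }
    out[, j] <- ifelse(empty, NA_real_, num)
  }
  out
}

#' Write a feature-by-sample expression table
#'
#' Values are written with 6 significant digits; masked (`NA`) entries are
#' written as empty cells, so `write` then `read` round-trips to the
#' declared precision.
#'
#' @param x Numeric matrix, rows = features, columns = samples.
#' @param path Output path.
#' @param feature_col Name of the identifier column.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(x, path, feature_col = "feature_id") {
  assert_expression_matrix(x)
  chr <- matrix(sprintf("%.6g", x), nrow(x), ncol(x))
  chr[is.na(x)] <- ""
  df <- data.frame(rownames(x), chr, stringsAsFactors = FALSE,
                   check.names = FALSE)
  colnames(df) <- c(feature_col, colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical sample table
#'
#' Expected columns: `sample_id`, `class_label` (cancer/normal/none),
#' `ttp_months`, `event` (0/1), `pair_id`, `timepoint` (pre/post/none).
#' Missing optional columns are filled with `NA`/"none".
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`, one row per sample.
#' @export
read_clinical_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    stop("clinical table must have a 'sample_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in clinical table", call. = FALSE)
  }
  for (col in c("class_label", "timepoint")) {
    if (!col %in% colnames(df)) df[[col]] <- "none"
  }
  if (!"ttp_months" %in% colnames(df)) df$ttp_months <- NA_real_
  if (!"event" %in% colnames(df)) df$event <- NA_integer_
  if (!"pair_id" %in% colnames(df)) df$pair_id <- NA_character_
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  ok_tp <- df$timepoint %in% c("pre", "post", "none") | is.na(df$timepoint)
  if (!all(ok_tp)) stop("timepoint must be pre/post/none", call. = FALSE)
  has_pair <- !is.na(df$pair_id) & df$pair_id != ""
  if (any(has_pair & !(df$timepoint %in% c("pre", "post")))) {
    stop("samples with a pair_id must have timepoint pre or post",
         call. = FALSE)
  }
  for (pid in unique(df$pair_id[has_pair])) {
    tp <- sort(df$timepoint[has_pair & df$pair_id == pid])
    if (!identical(tp, c("post", "pre"))) {
      stop(sprintf("pair '%s' must occur exactly once as pre and once as post",
                   pid), call. = FALSE)
    }
  }
  tt <- df$ttp_months[!is.na(df$ttp_months)]
  if (any(tt < 0)) stop("ttp_months must be nonnegative", call. = FALSE)
  invisible(df)
}

#' Write a clinical sample table
#' @param df Clinical `data.frame` (see [read_clinical_tsv()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clinical_tsv <- function(df, path) {
  validate_clinical(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}
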