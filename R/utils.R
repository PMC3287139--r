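# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG state is restored afterwards. If `seed` is NULL the
# global RNG stream is used (and advanced).
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic child seeds for pipeline stages (kept < 2^31).
derive_seeds <- function(master_seed, n) {
  local_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric feature-by-sample matrix", arg),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must carry feature rownames and sample colnames", arg),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("`%s` has duplicated sample ids", arg), call. = FALSE)
  }
  invisible(x)
}

assert_survival <- function(ttp, event, n = NULL) {
  if (!is.numeric(ttp) || any(!is.finite(ttp)) || any(ttp < 0)) {
    stop("`ttp` must be finite nonnegative times (months)", call. = FALSE)
  }
  if (length(event) != length(ttp)) {
    stop("`ttp` and `event` lengths differ", call. = FALSE)
  }
  ev <- as.integer(event)
  if (any(is.na(ev)) || !all(ev %in% c(0L, 1L))) {
    stop("`event` must be 0/1 progression indicators", call. = FALSE)
  }
  if (!is.null(n) && length(ttp) != n) {
    stop("survival data length does not match number of samples", call. = FALSE)
  }
  ev
}
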