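test_that("log2_transform inverts exponentiation and flags nonpositives", {
  x <- named_matrix(c(1, 2, 0.5, 8), 2, 2)
  out <- log2_transform(x)
  expect_equal(as.vector(out), c(0, 1, -1, 3))
  set.seed(2)
  r <- named_matrix(rexp(30) + 0.01, 5, 6)
  expect_equal(2^log2_transform(r), r)
  r[3, 2] <- NA
  expect_true(is.na(log2_transform(r)[3, 2]))
  r[1, 1] <- -2
  expect_error(log2_transform(r), "nonpositive.*f01.*s01")
})

test_that("lowess normalization removes an intensity-dependent trend", {
  set.seed(3)
  n <- 500
  a <- runif(n, 4, 14)
  m <- 0.5 * sin(a) + rnorm(n, 0, 0.05)
  mn <- lowess_normalize(m, a, span = 0.2)
  # oracle: a freshly fitted smoother finds no material residual trend
  refit <- lowess(a, mn, f = 0.2, iter = 3)
  expect_lt(max(abs(refit$y)), 0.05)

  # constant offset is fully absorbed
  mc <- lowess_normalize(rep(1.7, 50), seq(4, 14, length.out = 50))
  expect_lt(max(abs(mc)), 1e-6)
  # zero in, zero out
  expect_equal(lowess_normalize(rep(0, 50), seq_len(50)), rep(0, 50))
})

test_that("a linear dye bias is removed within the smoother's resolution", {
  set.seed(4)
  a <- runif(200, 4, 14)
  m <- 0.3 * (a - 9) + rnorm(200, 0, 0.2)
  once <- lowess_normalize(m, a)
  refit <- lowess(a, once, f = 2/3, iter = 3)
  expect_lt(max(abs(refit$y)), 0.05 * sd(m))
  # a second application changes M far less than the first did
  twice <- lowess_normalize(once, a)
  expect_lt(max(abs(twice - once)), 0.1 * max(abs(once - m)))
  expect_error(lowess_normalize(rnorm(5), rnorm(5)), "fewer than 10")
  # masked probes stay masked and do not disturb the fit
  m2 <- m; m2[5] <- NA
  out <- lowess_normalize(m2, a)
  expect_true(is.na(out[5]))
})

test_that("replicate collapsing takes the median of unmasked probes", {
  x <- matrix(c(1, 1, 1, 1,
                1, 2, 3, 100,
                1, NA, 3, NA), 12, 1,
              dimnames = list(c(paste0("a_p", 1:4), paste0("b_p", 1:4),
                                paste0("c_p", 1:4)), "s1"))
  map <- stats::setNames(rep(c("a", "b", "c"), each = 4), rownames(x))
  out <- collapse_replicates(x, map)
  expect_equal(as.vector(out), c(1, 2.5, 2))
  # fully masked feature stays masked
  x[9:12, 1] <- NA
  expect_true(is.na(collapse_replicates(x, map)["c", 1]))
  expect_error(collapse_replicates(x, map[-1]), "absent from map")
})

test_that("collapsing commutes with sample subsetting", {
  co <- simulate_cancer_normal(
    sim_config(n_cancer = 6, n_normal = 4, n_features = 30,
               n_diff_features = 5, seed = 9))
  keep <- c(1, 3, 4, 8)
  a <- collapse_replicates(co$expression, co$probe_map)[, keep]
  b <- collapse_replicates(co$expression[, keep], co$probe_map)
  expect_equal(a, b)
})

test_that("filter_impute drops heavily masked features and fills the rest", {
  x <- named_matrix(as.numeric(1:20), 4, 5)
  x[1, 1:3] <- NA      # 60% masked -> dropped
  x[2, 2] <- NA        # 20% masked -> imputed with feature median
  out <- filter_impute(x, max_missing = 0.5)
  expect_false("f01" %in% rownames(out))
  expect_equal(out["f02", "s02"], median(x[2, ], na.rm = TRUE))
  expect_false(anyNA(out))
})
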