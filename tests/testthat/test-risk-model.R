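test_that("predictive index via weights equals the explicit two-PC route", {
  sc <- small_surv_cohort(seed = 51)
  m <- fit_risk_model(sc$x, sc$ttp, sc$event, selection_alpha = 0.1)
  xs <- sc$x[m$selected_features, , drop = FALSE]
  # two-step route: PC scores u_k = V_k . (x - mu), PI = b1 u1 + b2 u2
  u <- t(m$loadings) %*% (xs - m$means)
  pi_two_step <- drop(m$pc_betas %*% u)
  expect_equal(unname(predict_index(m, sc$x)), unname(pi_two_step),
               tolerance = 1e-10)
  expect_equal(unname(m$training_pi), unname(pi_two_step),
               tolerance = 1e-10)
  # loadings are orthonormal
  g <- crossprod(m$loadings)
  expect_lt(abs(g[1, 2]), 1e-10)
  expect_equal(diag(g), c(PC1 = 1, PC2 = 1), tolerance = 1e-10)
})

test_that("flipping a loading sign together with its Cox beta leaves PI unchanged", {
  sc <- small_surv_cohort(seed = 52)
  m <- fit_risk_model(sc$x, sc$ttp, sc$event, selection_alpha = 0.1)
  flipped <- m
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$pc_betas[1] <- -flipped$pc_betas[1]
  flipped$weights <- drop(flipped$loadings %*% flipped$pc_betas)
  expect_equal(predict_index(flipped, sc$x), predict_index(m, sc$x),
               tolerance = 1e-12)
})

test_that("a sample at the training means has PI exactly zero", {
  sc <- small_surv_cohort(seed = 53)
  m <- fit_risk_model(sc$x, sc$ttp, sc$event, selection_alpha = 0.1)
  x0 <- matrix(0, nrow(sc$x), 1, dimnames = list(rownames(sc$x), "mean"))
  x0[m$selected_features, 1] <- m$means
  expect_equal(unname(predict_index(m, x0)), 0, tolerance = 1e-12)
})

test_that("variance concentrated on one feature degenerates to a single-PC index", {
  # two informative, perfectly correlated features; the second carries
  # a thousandth of the variance, so PI is proportional to (x1 - m1)
  set.seed(54)
  n <- 40
  x1 <- rnorm(n)
  x <- rbind(f1 = x1, f2 = 0.2 * x1)
  colnames(x) <- sprintf("s%02d", seq_len(n))
  tt <- rexp(n, 0.2 * exp(x1))
  ev <- rep(1L, n)
  m <- fit_risk_model(x, tt, ev, selection_alpha = 0.05)
  pi <- predict_index(m, x)
  slope <- pi / (x1 - mean(x1))
  expect_lt(diff(range(slope)), 1e-6 * abs(mean(slope)))
})

test_that("percentiles follow the midrank counting rule", {
  m <- structure(list(training_pi = c(1, 2, 3, 4), cutoff_percentile = 67,
                      selected_features = "f", means = 0, weights = 1),
                 class = "risk_model")
  expect_equal(pi_percentile(m, 2.5), 50)
  expect_equal(pi_percentile(m, 0), 0)
  expect_equal(pi_percentile(m, 5), 100)
  expect_equal(pi_percentile(m, 2), 100 * 1.5 / 4)

  # training median (odd n) maps to exactly 50%
  m$training_pi <- c(-2, 0.5, 1, 3, 9)
  expect_equal(pi_percentile(m, 1), 50)
})

test_that("risk-group assignment uses a strict cutoff", {
  expect_identical(assign_risk_group(39), "low")
  expect_identical(assign_risk_group(67), "low")
  expect_identical(assign_risk_group(67.01), "high")
  expect_identical(assign_risk_group(100), "high")
  expect_error(assign_risk_group(105), "0, 100")
})

test_that("PI increases by c * ||w||^2 when a sample moves along the weights", {
  sc <- small_surv_cohort(seed = 55)
  m <- fit_risk_model(sc$x, sc$ttp, sc$event, selection_alpha = 0.1)
  x1 <- sc$x[, 3]
  x2 <- x1
  cc <- 0.7
  x2[m$selected_features] <- x2[m$selected_features] + cc * m$weights
  expect_equal(unname(predict_index(m, x2) - predict_index(m, x1)),
               cc * sum(m$weights^2), tolerance = 1e-10)
})

test_that("LOOCV returns one deterministic label per sample and matches an R refit", {
  sc <- small_surv_cohort(seed = 56)
  cv1 <- loocv_risk_groups(sc$x, sc$ttp, sc$event, selection_alpha = 0.1)
  cv2 <- loocv_risk_groups(sc$x, sc$ttp, sc$event, selection_alpha = 0.1)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1), ncol(sc$x))
  expect_true(all(cv1$group %in% c("low", "high")))

  # the compiled fold path equals refitting in R without sample i
  for (i in c(2, 17)) {
    m <- fit_risk_model(sc$x[, -i], sc$ttp[-i], sc$event[-i],
                        selection_alpha = 0.1)
    pi_i <- predict_index(m, sc$x[, i, drop = FALSE])
    expect_equal(cv1$predictive_index[i], unname(pi_i), tolerance = 1e-8)
    expect_equal(cv1$percentile[i], unname(pi_percentile(m, pi_i)),
                 tolerance = 1e-8)
  }
})

test_that("too few selected features is an informative error; LOOCV guards n", {
  set.seed(57)
  x <- named_matrix(rnorm(200), 10, 20)
  tt <- rexp(20, 0.3)
  ev <- rep(1L, 20)
  expect_error(fit_risk_model(x, tt, ev, selection_alpha = 1e-9),
               "increase selection_alpha")
  expect_error(loocv_risk_groups(x[, 1:8], tt[1:8], ev[1:8]), "n >= 10")
})

test_that("permutation significance is deterministic and order-invariant", {
  sc <- small_surv_cohort(n = 30, p = 30, seed = 58)
  p1 <- permutation_significance(sc$x, sc$ttp, sc$event, n_perm = 19,
                                 seed = 7, selection_alpha = 0.1)
  p2 <- permutation_significance(sc$x, sc$ttp, sc$event, n_perm = 19,
                                 seed = 7, selection_alpha = 0.1)
  expect_identical(p1$p, p2$p)
  expect_identical(p1$lr_perm, p2$lr_perm)
  # p follows the add-one tail formula
  expect_equal(p1$p, (1 + sum(p1$lr_perm >= p1$lr_obs)) / 20)

  # shuffling the sample order does not change the result
  ord <- sample(ncol(sc$x))
  p3 <- permutation_significance(sc$x[, ord], sc$ttp[ord], sc$event[ord],
                                 n_perm = 19, seed = 7,
                                 selection_alpha = 0.1)
  expect_identical(p1$p, p3$p)
  expect_identical(p1$lr_obs, p3$lr_obs)
  expect_identical(p1$groups, p3$groups[order(ord)])
  expect_error(permutation_significance(sc$x, sc$ttp, sc$event,
                                        n_perm = 5), ">= 19")
})
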