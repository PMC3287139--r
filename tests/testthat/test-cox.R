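test_that("single-feature Cox fit matches the analytic fixture", {
  f <- cox_fit_single(c(0, 1, 0), c(1, 2, 3), c(1, 1, 1))
  expect_equal(f$beta, log(sqrt(2)), tolerance = 1e-8)
  expect_equal(f$hazard_ratio, sqrt(2), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("Cox fit agrees with the brute-force partial-likelihood grid", {
  set.seed(31)
  for (r in 1:8) {
    n <- sample(4:8, 1)
    x <- rnorm(n)
    tt <- sample(1:4, n, replace = TRUE) # ties on purpose
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2 || max(x) == min(x)) next
    f <- cox_fit_single(x, tt, ev)
    if (!f$converged) next
    expect_lt(abs(f$beta - oracle_cox_beta(x, tt, ev)), 1e-4)
  }
})

test_that("Cox fit agrees with survival::coxph (Efron ties) on larger fixtures", {
  set.seed(32)
  n <- 50
  x <- rnorm(n)
  tt <- round(rexp(n, 0.3), 1) + 0.1
  ev <- rbinom(n, 1, 0.7)
  f <- cox_fit_single(x, tt, ev)
  m <- survival::coxph(survival::Surv(tt, ev) ~ x)
  expect_equal(f$beta, unname(coef(m)), tolerance = 1e-7)
  expect_equal(f$se, sqrt(vcov(m)[1, 1]), tolerance = 1e-7)
  sm <- summary(m)$coefficients
  expect_equal(f$p, sm[1, "Pr(>|z|)"], tolerance = 1e-6)
})

test_that("negating the covariate negates beta exactly", {
  set.seed(33)
  x <- rnorm(20)
  tt <- rexp(20, 0.3)
  ev <- rbinom(20, 1, 0.8)
  a <- cox_fit_single(x, tt, ev)
  b <- cox_fit_single(-x, tt, ev)
  expect_equal(a$beta, -b$beta, tolerance = 1e-10)
  expect_equal(a$hazard_ratio, 1 / b$hazard_ratio, tolerance = 1e-10)
})

test_that("degenerate inputs raise the documented errors and flags", {
  expect_error(cox_fit_single(rep(1, 5), 1:5, rep(1, 5)), "no variation")
  expect_error(cox_fit_single(rnorm(5), 1:5, rep(0, 5)), "no events")
  # monotone likelihood: the only x = 1 subject fails first
  f <- cox_fit_single(c(1, 0, 0), c(1, 2, 3), c(1, 1, 1))
  expect_false(f$converged)
  # the oracle confirms the likelihood increases along the beta grid
  grid <- seq(0, 10, by = 0.5)
  ll <- oracle_efron_loglik(grid, c(1, 0, 0), c(1, 2, 3), c(1, 1, 1))
  expect_true(all(diff(ll) > 0))
})

test_that("screening matches per-feature coxph and computes FDR over all features", {
  set.seed(34)
  n <- 40; p <- 25
  x <- named_matrix(rnorm(n * p), p, n)
  tt <- round(rexp(n, 0.3), 1) + 0.1
  ev <- rbinom(n, 1, 0.8)
  tab <- cox_screen(x, tt, ev)
  ref <- t(vapply(seq_len(p), function(j) {
    m <- survival::coxph(survival::Surv(tt, ev) ~ x[j, ])
    c(unname(coef(m)), summary(m)$coefficients[1, "Pr(>|z|)"])
  }, numeric(2)))
  expect_equal(tab$beta, ref[, 1], tolerance = 1e-6)
  expect_equal(tab$p, ref[, 2], tolerance = 1e-6)
  expect_equal(tab$fdr, bh_fdr(tab$p))
})

test_that("selection splits features by hazard direction, sorted by p", {
  sc <- small_surv_cohort(n = 82, p = 80, n_hazard = 4, seed = 35)
  sel <- select_survival_features(sc$x, sc$ttp, sc$event, alpha = 0.05)
  expect_true(all(sel$resistance$hazard_ratio > 1))
  expect_true(all(sel$sensitivity$hazard_ratio < 1))
  expect_false(is.unsorted(sel$resistance$p))
  expect_false(is.unsorted(sel$sensitivity$p))
  expect_error(select_survival_features(sc$x, sc$ttp, sc$event, alpha = 2),
               "alpha")
  # planted features dominate the selected lists in the right direction
  got <- rbind(sel$resistance, sel$sensitivity)
  truth <- sc$truth
  hit <- intersect(got$feature_id, truth$feature_id)
  expect_gte(length(hit), 3)
  for (f in hit) {
    expect_equal(got$hazard_ratio[got$feature_id == f] > 1,
                 truth$effect[truth$feature_id == f] > 0)
  }
})
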