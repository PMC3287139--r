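test_that("identical configs give bit-identical cohorts", {
  cfg <- sim_config(n_cancer = 8, n_normal = 6, n_features = 40,
                    n_diff_features = 6, seed = 42)
  a <- simulate_cancer_normal(cfg)
  b <- simulate_cancer_normal(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  s1 <- simulate_survival_cohort(cfg)
  s2 <- simulate_survival_cohort(cfg)
  expect_identical(s1$clinical$ttp_months, s2$clinical$ttp_months)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_diff_features = 10, n_features = 5),
               "n_diff_features")
  expect_error(sim_config(n_hazard_features = 10, n_features = 5),
               "n_hazard_features")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_cancer = -1), "n_cancer")
})

test_that("null cancer/normal cohort is calibrated at nominal alpha", {
  co <- simulate_cancer_normal(
    sim_config(n_cancer = 45, n_normal = 17, n_features = 1000,
               n_replicates_per_feature = 2, n_diff_features = 0,
               noise_sd = 0.5, seed = 5))
  x <- collapse_replicates(co$expression, co$probe_map)
  tab <- t_test_per_feature(x, co$clinical$class_label)
  rate <- mean(tab$p < 0.05, na.rm = TRUE)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), ci)
})

test_that("planted differential features are recovered with high power", {
  co <- simulate_cancer_normal(
    sim_config(n_cancer = 45, n_normal = 17, n_features = 1000,
               n_replicates_per_feature = 2, n_diff_features = 50,
               diff_log2_effect = 1, noise_sd = 0.5, seed = 6))
  x <- collapse_replicates(co$expression, co$probe_map)
  tab <- t_test_per_feature(x, co$clinical$class_label)
  planted <- tab$feature_id %in% co$truth$feature_id
  expect_gte(mean(tab$p[planted] < 0.005), 0.9)

  # empirical log2 fold change recovers the planted effect:
  # per-feature within 3 SE (SE from the feature's own t statistic)
  lfc <- log2(tab$ratio[planted])
  se_feat <- abs(lfc / tab$statistic[planted])
  expect_gt(mean(abs(abs(lfc) - 1) < 3 * se_feat), 0.95)
  expect_lt(abs(mean(abs(lfc)) - 1), 3 * mean(se_feat) / sqrt(50))
  # planted sign matches the truth table
  expect_equal(sign(lfc), sign(co$truth$effect))
})

test_that("survival generator matches exponential closed forms", {
  # beta = 0, no censoring: mean TTP -> 1 / baseline_hazard
  cfg <- sim_config(n_cancer = 5000, n_features = 2,
                    n_replicates_per_feature = 1, n_hazard_features = 0,
                    censor_rate = 0, seed = 8)
  co <- suppressWarnings(simulate_survival_cohort(cfg))
  lam0 <- cfg$baseline_hazard
  mu <- 1 / lam0
  expect_lt(abs(mean(co$clinical$ttp_months) - mu),
            4 * mu / sqrt(5000))
  expect_true(all(co$clinical$event == 1))

  # default rates: median TTP ~ 3.1 months with ~20% censoring
  cfg2 <- sim_config(n_cancer = 4000, n_features = 2,
                     n_replicates_per_feature = 1, n_hazard_features = 0,
                     seed = 9)
  co2 <- simulate_survival_cohort(cfg2)
  expect_lt(abs(median(co2$clinical$ttp_months) - 3.1), 0.25)
  expect_lt(abs(mean(1 - co2$clinical$event) - 0.2), 0.03)
})

test_that("null survival cohort yields nominal per-feature selection", {
  co <- simulate_survival_cohort(
    sim_config(n_cancer = 82, n_features = 500,
               n_replicates_per_feature = 1, n_hazard_features = 0,
               seed = 10))
  x <- collapse_replicates(co$expression, co$probe_map)
  sel <- select_survival_features(x, co$clinical$ttp_months,
                                  co$clinical$event, alpha = 0.05)
  rate <- (nrow(sel$resistance) + nrow(sel$sensitivity)) / 500
  ci <- 2.576 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(rate - 0.05), ci)
})

test_that("an over-censored cohort warns", {
  cfg <- sim_config(n_cancer = 30, n_features = 2,
                    n_replicates_per_feature = 1, n_hazard_features = 0,
                    baseline_hazard = 1e-6, censor_rate = 10, seed = 3)
  expect_warning(simulate_survival_cohort(cfg), "censored")
})

test_that("pair simulation shifts post samples along the direction", {
  sc <- small_surv_cohort(n = 40, p = 40, seed = 12)
  model <- fit_risk_model(sc$x, sc$ttp, sc$event, selection_alpha = 0.1)
  co <- sc$cohort

  # zero shift, zero technical noise: post identical to pre
  pc0 <- simulate_pairs(co, model$weights, pair_shift = 0, tech_sd = 0,
                        seed = 2)
  x0 <- collapse_replicates(pc0$expression, pc0$probe_map)
  pre <- grep("_pre$", colnames(x0), value = TRUE)
  post <- sub("_pre$", "_post", pre)
  expect_equal(predict_index(model, x0[, post]),
               predict_index(model, x0[, pre]),
               ignore_attr = TRUE)

  # positive shift along the model gradient, zero noise: PI strictly up
  pc2 <- simulate_pairs(co, model$weights, pair_shift = 2, tech_sd = 0,
                        seed = 2)
  x2 <- collapse_replicates(pc2$expression, pc2$probe_map)
  expect_true(all(predict_index(model, x2[, post]) >
                    predict_index(model, x2[, pre])))

  expect_error(simulate_pairs(co, c(mir0001 = 0)), "zero vector")
  expect_error(simulate_pairs(co, c(nope = 1)), "unknown")
})
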