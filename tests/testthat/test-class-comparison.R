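test_that("pooled t statistics match the hand formula and t.test", {
  x <- named_matrix(c(0, 2, 1, 3), 1, 4)
  tab <- t_test_per_feature(x, c("cancer", "cancer", "normal", "normal"))
  expect_equal(tab$statistic, -0.7071, tolerance = 1e-4)
  expect_equal(tab$df, 2)
  expect_equal(tab$p, 0.5528, tolerance = 1e-4)

  set.seed(21)
  y <- named_matrix(rnorm(80), 8, 10)
  labs <- rep(c("cancer", "normal"), c(6, 4))
  tab2 <- t_test_per_feature(y, labs)
  ref <- apply(y, 1, function(v) {
    r <- t.test(v[labs == "cancer"], v[labs == "normal"], var.equal = TRUE)
    c(unname(r$statistic), r$p.value)
  })
  expect_equal(tab2$statistic, unname(ref[1, ]), tolerance = 1e-12)
  expect_equal(tab2$p, unname(ref[2, ]), tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1, ratio = 1; zero-variance excluded", {
  x <- named_matrix(c(1, 1, 2, 2, 1, 1, 2, 2), 2, 4)
  tab <- t_test_per_feature(x, c("cancer", "cancer", "normal", "normal"))
  expect_equal(tab$statistic, c(0, 0))
  expect_equal(tab$p, c(1, 1))
  expect_equal(tab$ratio, c(1, 1))

  const <- named_matrix(rep(3, 4), 1, 4)
  tab3 <- t_test_per_feature(const, c("cancer", "cancer", "normal", "normal"))
  expect_true(tab3$excluded)
  expect_true(is.na(tab3$p))
})

test_that("the sign of the mean difference splits over/under-expressed lists", {
  set.seed(22)
  x <- rbind(up = c(rnorm(5, 1, .1), rnorm(5, 0.285, .1)),  # ratio ~ 1.64
             dn = c(rnorm(5, -1, .1), rnorm(5, 0.36, .1)))  # ratio ~ 0.39
  colnames(x) <- sprintf("s%02d", 1:10)
  labs <- rep(c("cancer", "normal"), each = 5)
  tab <- t_test_per_feature(x, labs)
  expect_gt(tab$ratio[tab$feature_id == "up"], 1)
  expect_lt(tab$ratio[tab$feature_id == "dn"], 1)
  expect_gt(tab$statistic[1], 0)
  expect_lt(tab$statistic[2], 0)
})

test_that("BH adjustment follows the step-up rule and is order-invariant", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(23)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # fdr >= p, monotone in p
  expect_true(all(bh_fdr(p) >= p))
})

test_that("all six classifiers separate a perfectly separating feature", {
  set.seed(24)
  x <- named_matrix(rnorm(8 * 12, 0, 0.3), 8, 12)
  labs <- rep(c("cancer", "normal"), each = 6)
  x[1, labs == "cancer"] <- x[1, labs == "cancer"] + 5
  xt <- named_matrix(rnorm(8 * 6, 0, 0.3), 8, 6, prefix_s = "t")
  labt <- rep(c("cancer", "normal"), each = 3)
  xt[1, labt == "cancer"] <- xt[1, labt == "cancer"] + 5
  for (m in c("CCP", "DLDA", "1NN", "3NN", "NC", "SVM")) {
    fit <- train_classifier(x, labs, method = m, selection_alpha = 0.01)
    expect_identical(unname(predict(fit, xt)), labt, label = m)
  }
})

test_that("DLDA matches the hand-computed diagonal discriminant", {
  # two features, clear separation so both pass selection
  x <- rbind(f1 = c(0.0, 0.2, 0.1, 2.0, 2.2, 2.1),
             f2 = c(1.0, 1.1, 0.9, 3.0, 3.1, 2.9))
  colnames(x) <- sprintf("s%d", 1:6)
  labs <- rep(c("a", "b"), each = 3)
  fit <- train_classifier(x, labs, method = "DLDA", selection_alpha = 0.05)
  test <- matrix(c(1.2, 1.8), 2, 1, dimnames = list(c("f1", "f2"), "q"))
  # hand rule: class minimizing sum_i (x_i - mu_gi)^2 / s_i^2
  mu_a <- rowMeans(x[, 1:3]); mu_b <- rowMeans(x[, 4:6])
  s2 <- (2 * apply(x[, 1:3], 1, var) + 2 * apply(x[, 4:6], 1, var)) / 4
  d_a <- sum((test[, 1] - mu_a)^2 / s2)
  d_b <- sum((test[, 1] - mu_b)^2 / s2)
  expect_identical(unname(predict(fit, test)),
                   if (d_a <= d_b) "a" else "b")
})

test_that("1NN predicts its own training set perfectly", {
  set.seed(25)
  x <- named_matrix(rnorm(60), 6, 10)
  labs <- rep(c("cancer", "normal"), each = 5)
  x[1, ] <- x[1, ] + ifelse(labs == "cancer", 3, 0)
  fit <- train_classifier(x, labs, method = "1NN", selection_alpha = 0.5)
  expect_identical(unname(predict(fit, x)), labs)
})

test_that("CCP and DLDA predictions survive a constant feature shift", {
  set.seed(26)
  x <- named_matrix(rnorm(200), 20, 10)
  labs <- rep(c("cancer", "normal"), each = 5)
  x[1:3, labs == "cancer"] <- x[1:3, labs == "cancer"] + 2
  xt <- named_matrix(rnorm(100), 20, 5, prefix_s = "t")
  for (m in c("CCP", "DLDA")) {
    fit <- train_classifier(x, labs, method = m)
    fit_sh <- train_classifier(x + 7, labs, method = m)
    expect_identical(predict(fit, xt), predict(fit_sh, xt + 7), label = m)
  }
})

test_that("degenerate selection falls back to the majority class", {
  set.seed(27)
  x <- named_matrix(rnorm(40), 4, 10)
  labs <- rep(c("cancer", "normal"), c(6, 4))
  expect_warning(
    fit <- train_classifier(x, labs, method = "NC", selection_alpha = 1e-12),
    "majority")
  expect_true(all(predict(fit, x) == "cancer"))
})

test_that("random partitions are deterministic under a seed and honest under shuffled labels", {
  set.seed(28)
  x <- named_matrix(rnorm(50 * 24), 50, 24)
  labs <- rep(c("cancer", "normal"), each = 12) # pure noise = shuffled labels
  r1 <- cross_partition_accuracy(x, labs, n_partitions = 25, seed = 99)
  r2 <- cross_partition_accuracy(x, labs, n_partitions = 25, seed = 99)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_true(all(r1$median_accuracy >= 0.35 & r1$median_accuracy <= 0.65))
})
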