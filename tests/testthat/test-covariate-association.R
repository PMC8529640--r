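test_that("classification-error matrix from degenerate and flat posteriors", {
  # one-hot posteriors give the identity
  g <- diag(3)[c(1, 2, 3, 2, 1), ]
  post <- structure(list(state_post = g), class = "mlmm_posterior")
  D <- classification_error_matrix(post)
  expect_equal(unclass(D), diag(3), ignore_attr = TRUE)

  # uniform posteriors over K = 2: modal ties break to state 1, and each
  # true state is assigned state 1 with certainty
  g2 <- matrix(0.5, 4, 2)
  post2 <- structure(list(state_post = g2), class = "mlmm_posterior")
  D2 <- classification_error_matrix(post2)
  expect_equal(unclass(D2), rbind(c(1, 0), c(1, 0)), ignore_attr = TRUE)

  # a state with zero posterior mass is an error
  g3 <- cbind(rep(1, 3), 0)
  post3 <- structure(list(state_post = g3), class = "mlmm_posterior")
  expect_error(classification_error_matrix(post3), "zero posterior mass")
})

test_that("the error matrix of a default-cohort fit is diagonally dominant", {
  pan <- simulate_panel(generator_config(n_patients = 400, seed = 25))
  fb <- forward_backward(strip_truth(pan), ground_truth_defaults())
  D <- classification_error_matrix(fb)
  expect_equal(rowSums(unclass(D)), rep(1, 4), tolerance = 1e-10)
  expect_true(all(diag(unclass(D)) > 0.5))
  expect_true(all(diag(unclass(D)) > apply(unclass(D) - diag(diag(unclass(D))),
                                           1, max)))
})

test_that("identity error matrix leaves the cross-tab unchanged", {
  modal <- c(1, 1, 2, 2, 2, 1)
  cov <- c("a", "b", "a", "b", "b", "a")
  ct <- corrected_crosstab(modal, cov, diag(2))
  expect_equal(unclass(ct$counts), unclass(ct$observed), ignore_attr = TRUE)
  expect_equal(rowSums(ct$proportions), c(1, 1), ignore_attr = TRUE)
  expect_error(corrected_crosstab(modal, cov, matrix(0.5, 2, 2)),
               "singular")
})

test_that("inverse-D correction moves estimates toward the truth", {
  # misclassification model: true state ~ occupancy, modal drawn via D,
  # covariate depends on the true state
  K <- 4
  D <- matrix(0.04, K, K); diag(D) <- 0.88
  occ <- c(0.16, 0.25, 0.21, 0.38)
  pcov <- c(0.75, 0.65, 0.50, 0.35)  # P(category "a" | true state)
  set.seed(31)
  tv_corr <- tv_raw <- numeric(50)
  for (r in 1:50) {
    n <- 4000
    s <- sample.int(K, n, TRUE, prob = occ)
    modal <- vapply(s, function(j) sample.int(K, 1, prob = D[j, ]), 0L)
    cov <- ifelse(runif(n) < pcov[s], "a", "b")
    truth_tab <- prop.table(table(factor(s, 1:K), cov), 1)
    ct <- suppressWarnings(corrected_crosstab(modal, cov, D))
    raw_tab <- prop.table(ct$observed, 1)
    tv_corr[r] <- sum(abs(ct$proportions - truth_tab)) / 2
    tv_raw[r] <- sum(abs(raw_tab - truth_tab)) / 2
  }
  expect_lt(mean(tv_corr), mean(tv_raw))
})

test_that("chi-squared tests match hand computation and Bonferroni logic", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2)
  res <- chisq_bonferroni(list(x = tab), alpha = 0.05, n_tests = 1)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$df, 1)

  # identical rows give a zero statistic
  flat <- rbind(c(30, 70), c(30, 70))
  res0 <- chisq_bonferroni(list(flat), n_tests = 1)
  expect_equal(res0$statistic, 0)
  expect_false(res0$significant)

  # Bonferroni threshold arithmetic at alpha = 0.01, six tests: the
  # family-wise threshold is 0.0016667, so p = 0.002 fails and p = 0.0009
  # passes
  res6 <- chisq_bonferroni(list(a = tab, b = flat), alpha = 0.01,
                           n_tests = 6)
  expect_equal(res6$threshold, rep(0.01 / 6, 2), tolerance = 1e-12)
  expect_identical(res6$significant, res6$p_value < 0.01 / 6)
  expect_false(0.002 < 0.01 / 6)
  expect_true(0.0009 < 0.01 / 6)

  # small expected cells warn but still report
  expect_warning(chisq_bonferroni(list(rbind(c(2, 3), c(4, 1))),
                                  n_tests = 1), "expected cell")
})

test_that("panel-level association flags state-linked covariates only", {
  pan <- simulate_panel(generator_config(n_patients = 600, seed = 33))
  fb <- forward_backward(strip_truth(pan), ground_truth_defaults())
  res <- suppressWarnings(associate_covariates(pan, fb))
  tests <- res$tests
  expect_equal(nrow(tests), 5L)
  expect_equal(unique(tests$threshold), 0.01 / 5, tolerance = 1e-12)
  # gender and illness duration are generated state-linked; age is flat
  expect_true(tests$significant[tests$covariate == "gender"])
  expect_false(tests$significant[tests$covariate == "age_band"])
  for (tb in res$tables) {
    expect_equal(rowSums(tb$proportions), rep(1, 4), ignore_attr = TRUE,
                 tolerance = 1e-6)
  }
})

test_that("group differences use unpooled Wald 95% intervals", {
  # identical groups: difference zero, interval straddles zero
  gd <- group_difference_ci(c(1, 2, 3), c(1, 2, 3), kind = "mean")
  expect_equal(gd$difference, 0)
  expect_true(gd$ci[1] <= 0 && gd$ci[2] >= 0)
  expect_false(gd$significant)

  # proportions 0.5 vs 0.5 at n = 100 each: CI half-width 1.96*sqrt(0.005)
  a <- rep(c(0, 1), 50)
  gd2 <- group_difference_ci(a, a, kind = "proportion")
  expect_equal(gd2$ci, c(-0.138593, 0.138593), tolerance = 1e-5)

  # large separated samples are flagged
  set.seed(8)
  gd3 <- group_difference_ci(rnorm(10000, 10), rnorm(10000, 8), kind = "mean")
  expect_true(gd3$significant)
  expect_true(gd3$ci[1] > 0)

  # zero variance in both mean groups degenerates to a point interval
  gd4 <- group_difference_ci(c(2, 2), c(1, 1), kind = "mean")
  expect_equal(gd4$ci, c(1, 1))
  expect_error(group_difference_ci(numeric(0), 1, kind = "mean"),
               "non-empty")
})
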