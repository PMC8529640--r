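test_that("ground-truth defaults satisfy the documented constraints", {
  p <- ground_truth_defaults()
  A <- p$A[, , 1]
  expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diag(A) >= 0.77 & diag(A) <= 0.89))
  expect_equal(A[1, 4], 0.0031)
  expect_equal(A[4, 1], 0.0049)
  expect_equal(A[2, 4], 0.10)
  expect_equal(A[3, 4], 0.10)
  expect_equal(p$mu, c(5.7, 6.7, 5.9, 7.1))
  # the initial distribution is (near-)stationary for the matrix
  pi0 <- p$pi[1, ]
  expect_lt(sum(abs(pi0 %*% A - pi0)), 0.01)
})

test_that("a degenerate generator emits constant, determined series", {
  B <- array(0, c(2, 3, 11))
  B[1, 1, ] <- 1; B[2, 3, ] <- 1
  p <- mlmm_parameters(1, c(0.5, 0.5), diag(2), B, c(2, 8), 1e-8)
  cfg <- generator_config(n_patients = 40, length_mean = 4, length_sd = 0,
                          length_range = c(4L, 4L),
                          obs_rates = c(PANSS = 1, FRT = 1, SIQ = 1),
                          params = p, covariate_model = NULL, seed = 26)
  pan <- simulate_panel(cfg)
  tt <- truth_table(pan)
  # identity transitions: every patient stays in the initial state
  first_state <- tt$true_state[tt$occasion == 0]
  expect_equal(tt$true_state,
               rep(first_state, each = 4))
  # one-hot emissions: category determined by the state
  frt <- pan$data$FRT_daily
  expect_true(all(frt[tt$true_state == 1] == 0))
  expect_true(all(frt[tt$true_state == 2] == 2))
  # near-zero sigma pins SIQ at the state mean
  expect_equal(pan$data$SIQ, c(2, 8)[tt$true_state], tolerance = 1e-6)
})

test_that("series lengths match the cohort's mean and dispersion", {
  cfg <- generator_config(n_patients = 50000, seed = 27,
                          covariate_model = NULL)
  set.seed(cfg$seed)
  lens <- pmin(pmax(round(rnorm(cfg$n_patients, cfg$length_mean,
                                cfg$length_sd)), 1), 11)
  expect_equal(mean(lens), 4.4, tolerance = 0.012)
  expect_equal(sd(lens), 2.4, tolerance = 0.012)
  expect_true(all(lens >= 1 & lens <= 11))
})

test_that("simulated transitions and rates converge to their targets", {
  pan <- simulate_panel(generator_config(n_patients = 50000, seed = 28))
  tt <- truth_table(pan)
  truth <- ground_truth_defaults()

  # empirical annual transition frequencies against the generating matrix
  from <- tt$true_state[tt$occasion < ave(tt$occasion, tt$patient_id,
                                          FUN = max)]
  keep <- tt$occasion > 0
  to <- tt$true_state[keep]
  emp <- prop.table(table(from, to), 1)
  expect_true(all(abs(emp - truth$A[, , 1]) < 0.005))

  # occupancy at the fifth visit stays near the initial distribution: it
  # matches the exact four-step propagation of the initial law tightly and
  # the initial law itself up to the matrix's small stationarity drift
  occ5 <- prop.table(table(factor(tt$true_state[tt$occasion == 4], 1:4)))
  exact5 <- truth$pi[1, ]
  for (s in 1:4) exact5 <- as.numeric(exact5 %*% truth$A[, , 1])
  expect_true(all(abs(occ5 - exact5) < 0.008))
  expect_true(all(abs(occ5 - truth$pi[1, ]) < 0.025))

  # observation rates converge to the configured block rates
  s <- panel_summary(pan)
  expect_equal(unname(s$obs_rates),
               c(0.911, 0.549, 0.630), tolerance = 0.012)
})

test_that("the generating parameters are a local likelihood optimum", {
  cfg <- generator_config(n_patients = 1500, seed = 29,
                          obs_rates = c(PANSS = 1, FRT = 1, SIQ = 1),
                          covariate_model = NULL)
  pan <- strip_truth(simulate_panel(cfg))
  truth <- ground_truth_defaults()
  ll0 <- forward_backward(pan, truth)$loglik
  set.seed(30)
  for (r in 1:5) {
    pert <- truth
    pert$mu <- truth$mu + runif(4, -0.05, 0.05)
    A <- truth$A[, , 1] + matrix(runif(16, 0, 0.05), 4, 4)
    pert$A <- array(A / rowSums(A), c(4, 4, 1))
    B <- truth$B
    for (v in 1:11) {
      Bv <- truth$B[, , v] + matrix(runif(12, 0, 0.05), 4, 3)
      B[, , v] <- Bv / rowSums(Bv)
    }
    pert$B <- B
    expect_lt(forward_backward(pan, pert)$loglik, ll0)
  }
})

test_that("truth attaches, strips and round-trips cleanly", {
  pan <- simulate_panel(generator_config(n_patients = 30, seed = 35))
  expect_false(is.null(pan$truth))
  bare <- strip_truth(pan)
  expect_null(bare$truth)
  # observables untouched by stripping
  expect_identical(bare$data, pan$data)
  expect_identical(bare$covariates, pan$covariates)
  back <- attach_truth(bare, pan$truth)
  expect_identical(back$truth, pan$truth)
  expect_identical(truth_table(back), truth_table(pan))
  expect_error(truth_table(bare), "no truth")
  # written panels never contain truth columns
  f <- tempfile(fileext = ".csv")
  write_panel(pan, f)
  expect_false(any(grepl("true_state|true_class", readLines(f)[1])))
  unlink(f)
})
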