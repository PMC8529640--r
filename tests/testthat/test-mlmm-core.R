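test_that("free-parameter count follows the model structure", {
  expect_identical(n_parameters(mlmm_spec(1, 1)), 24L)
  expect_identical(n_parameters(mlmm_spec(4, 1)), 108L)
  expect_identical(n_parameters(mlmm_spec(2, 2)), 54L)
})

test_that("emission log-likelihood sums observed items and skips missing", {
  p <- rand_params(K = 2, seed = 11)

  expect_equal(emission_loglik(blank_records(1), 1, p), 0)

  # single categorical indicator observed with emission probability 0.5
  p$B[1, , 3] <- c(0.5, 0.3, 0.2)   # indicator 3 = P3, category 0 has 0.5
  rec <- blank_records(1)
  rec$P3 <- 1                        # raw 1 -> category 0
  expect_equal(emission_loglik(rec, 1, p), log(0.5))

  # happiness alone at its state mean with unit variance
  p$mu[2] <- 6; p$sigma <- 1
  rec <- blank_records(1)
  rec$SIQ <- 6
  expect_equal(emission_loglik(rec, 2, p), -0.5 * log(2 * pi))
})

test_that("sequence likelihood equals brute-force path enumeration", {
  cases <- list(c(K = 2, M = 1, T = 3), c(K = 3, M = 1, T = 4),
                c(K = 2, M = 2, T = 3), c(K = 3, M = 2, T = 2),
                c(K = 1, M = 1, T = 3), c(K = 2, M = 1, T = 1))
  for (cs in cases) {
    p <- rand_params(cs["K"], cs["M"], seed = 20 + cs["T"])
    d <- rand_series(cs["T"], p_miss = 0.25, seed = 30 + cs["K"])
    expect_equal(sequence_loglik(d, p), oracle_enumerate(d, p)$loglik,
                 tolerance = 1e-10)
  }
})

test_that("degenerate one-state chain reduces to summed emissions", {
  p <- rand_params(1, 1, seed = 41)
  d <- rand_series(4, p_miss = 0.3, seed = 42)
  direct <- sum(vapply(seq_len(nrow(d)), function(t) {
    emission_loglik(d[t, ], 1, p)
  }, 0))
  expect_equal(sequence_loglik(d, p), direct, tolerance = 1e-10)
})

test_that("class mixture combines class-conditional likelihoods", {
  p <- rand_params(2, 2, seed = 43)
  d <- rand_series(3, p_miss = 0.2, seed = 44)
  pc <- function(c) {
    mlmm_parameters(1, p$pi[c, ], p$A[, , c, drop = FALSE], p$B, p$mu,
                    p$sigma)
  }
  L <- vapply(1:2, function(c) sequence_loglik(d, pc(c)), 0)
  expect_equal(sequence_loglik(d, p),
               log(p$omega[1] * exp(L[1]) + p$omega[2] * exp(L[2])),
               tolerance = 1e-12)
})

test_that("non-finite parameters are rejected", {
  p <- rand_params(2, 1, seed = 45)
  p$mu[1] <- NaN
  expect_error(sequence_loglik(rand_series(2, seed = 1), p), "non-finite")
})

test_that("smoothed posteriors equal brute-force enumeration", {
  for (cs in list(c(K = 2, M = 1, T = 3), c(K = 3, M = 2, T = 4),
                  c(K = 2, M = 2, T = 4))) {
    p <- rand_params(cs["K"], cs["M"], seed = 50 + cs["K"])
    d <- rand_series(cs["T"], p_miss = 0.25, seed = 60 + cs["T"])
    o <- oracle_enumerate(d, p)
    fb <- forward_backward(records_as_panel(d), p)
    expect_equal(fb$loglik, o$loglik, tolerance = 1e-10)
    expect_equal(unname(fb$state_post), unname(o$state_post),
                 tolerance = 1e-10)
    expect_equal(unname(as.numeric(fb$class_post)),
                 unname(o$class_post), tolerance = 1e-10)
    for (t in 2:cs["T"]) {
      expect_equal(fb$pairwise[, , t], o$pairwise[, , t], tolerance = 1e-10)
    }
    # every posterior normalizes
    expect_equal(rowSums(fb$state_post), rep(1, cs["T"]), tolerance = 1e-8)
    expect_equal(sum(fb$class_post), 1, tolerance = 1e-8)
  }
})

test_that("single-occasion posterior is the emission-weighted prior", {
  p <- rand_params(3, 2, seed = 70)
  d <- rand_series(1, p_miss = 0, seed = 71)
  fb <- forward_backward(records_as_panel(d), p)
  lik <- exp(vapply(1:3, function(k) emission_loglik(d[1, ], k, p), 0))
  prior_mix <- colSums(p$pi * p$omega)
  post <- prior_mix * lik
  expect_equal(as.numeric(fb$state_post), post / sum(post),
               tolerance = 1e-10)
})

test_that("all-missing series propagates the prior through the chain", {
  p <- rand_params(3, 1, seed = 72)
  d <- blank_records(4)
  fb <- forward_backward(records_as_panel(d), p)
  marg <- p$pi[1, ]
  for (t in 1:4) {
    expect_equal(as.numeric(fb$state_post[t, ]), as.numeric(marg),
                 tolerance = 1e-10)
    marg <- as.numeric(marg %*% p$A[, , 1])
  }
  expect_equal(fb$loglik, 0, tolerance = 1e-12)
})

test_that("likelihood is invariant under state relabelling", {
  p <- rand_params(3, 2, seed = 80)
  d <- rand_series(4, p_miss = 0.2, seed = 81)
  base <- sequence_loglik(d, p)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(3, 2, 1))) {
    expect_equal(sequence_loglik(d, permute_states(p, perm)), base,
                 tolerance = 1e-12)
  }
})

test_that("EM is monotone and deterministic under a fixed seed", {
  pan <- strip_truth(simulate_panel(generator_config(n_patients = 60,
                                                     seed = 9)))
  cfg <- fit_config(n_starts = 3, seed = 5, n_short = 15, max_iter = 200)
  fit <- em_fit(pan, mlmm_spec(2, 1), cfg)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))

  fit2 <- em_fit(pan, mlmm_spec(2, 1), cfg)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$params$B, fit2$params$B)
  expect_identical(fit$params$A, fit2$params$A)

  expect_equal(sum(fit$state_sizes), 1, tolerance = 1e-8)
  expect_equal(sum(fit$class_sizes), 1, tolerance = 1e-8)
})

test_that("one-state fit recovers pooled empirical moments", {
  pan <- strip_truth(simulate_panel(generator_config(n_patients = 80,
                                                     seed = 10)))
  fit <- em_fit(pan, mlmm_spec(1, 1), fit_config(n_starts = 1, seed = 1))
  d <- pan$data
  # pooled SIQ mean and (ML, denominator n) standard deviation
  siq <- d$SIQ[!is.na(d$SIQ)]
  expect_equal(fit$params$mu, mean(siq), tolerance = 1e-6)
  expect_equal(fit$params$sigma,
               sqrt(mean((siq - mean(siq))^2)), tolerance = 1e-6)
  # pooled category frequencies of one categorical indicator
  fr <- categorize_panss(d$P1[!is.na(d$P1)])
  expect_equal(as.numeric(fit$params$B[1, , 1]),
               as.numeric(table(factor(fr, levels = 0:2)) / length(fr)),
               tolerance = 1e-6)
})

test_that("EM recovers a well-separated two-state generating process", {
  truth <- sep_params_k2()
  cfg <- generator_config(n_patients = 1500, length_mean = 5, length_sd = 0,
                          length_range = c(5L, 5L),
                          obs_rates = c(PANSS = 1, FRT = 1, SIQ = 1),
                          params = truth, covariate_model = NULL, seed = 21)
  pan <- strip_truth(simulate_panel(cfg))
  fit <- em_fit(pan, mlmm_spec(2, 1), fit_config(n_starts = 6, seed = 3))
  est <- permute_states(fit$params, align_states(fit$params, truth))
  expect_true(all(abs(est$A[, , 1] - truth$A[, , 1]) < 0.03))
  expect_true(all(abs(est$mu - truth$mu) < 0.15))
})

test_that("fitted models serialize to JSON and back", {
  pan <- strip_truth(simulate_panel(generator_config(n_patients = 40,
                                                     seed = 12)))
  fit <- em_fit(pan, mlmm_spec(2, 2),
                fit_config(n_starts = 2, seed = 2, n_short = 10,
                           max_iter = 60))
  f <- tempfile(fileext = ".json")
  write_mlmm(fit, f)
  back <- read_mlmm(f)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(back$params$A, fit$params$A, tolerance = 1e-12)
  expect_equal(back$params$B, fit$params$B, tolerance = 1e-12)
  expect_equal(back$spec$K, 2L)
  expect_equal(back$spec$M, 2L)
  unlink(f)
})
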