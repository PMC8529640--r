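# Shared fixtures: random valid parameter sets, tiny record series, and a
# brute-force path-enumeration oracle for likelihood and posteriors.

rdir <- function(n, k) {
  x <- matrix(rexp(n * k), n, k)
  x / rowSums(x)
}

# random valid MLMM parameter set (independent of the package's own
# initialization code)
rand_params <- function(K, M = 1, seed = 1) {
  set.seed(seed)
  A <- array(0, c(K, K, M))
  for (c in seq_len(M)) A[, , c] <- rdir(K, K)
  B <- array(0, c(K, 3, 11))
  for (v in 1:11) B[, , v] <- rdir(K, 3)
  mlmm_parameters(omega = as.numeric(rdir(1, M)), pi = rdir(M, K), A = A,
                  B = B, mu = seq(3, 8, length.out = K),
                  sigma = runif(1, 0.8, 2))
}

# well-separated 2-state parameter set used for recovery tests
sep_params_k2 <- function() {
  B <- array(0, c(2, 3, 11))
  for (v in 1:11) B[, , v] <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))
  mlmm_parameters(omega = 1, pi = c(0.6, 0.4),
                  A = rbind(c(0.8, 0.2), c(0.3, 0.7)), B = B,
                  mu = c(4, 7), sigma = 1.2)
}

# empty record data.frame with the 12 indicator columns
blank_records <- function(T) {
  d <- as.data.frame(matrix(NA_real_, T, length(indicator_items())))
  names(d) <- indicator_items()
  d
}

# random series: categorical values drawn per item, raw PANSS set to a
# fixed representative of each category band; p_miss items set missing
rand_series <- function(T, p_miss = 0.2, seed = 1) {
  set.seed(seed)
  d <- blank_records(T)
  reps <- c(1, 3, 5)  # raw representative of categories 0, 1, 2
  for (it in panss_items()) {
    cat <- sample(0:2, T, replace = TRUE)
    v <- reps[cat + 1]
    v[runif(T) < p_miss] <- NA
    d[[it]] <- v
  }
  for (it in frt_items()) {
    v <- sample(0:2, T, replace = TRUE)
    v[runif(T) < p_miss] <- NA
    d[[it]] <- v
  }
  siq <- round(runif(T, 0, 10), 1)
  siq[runif(T) < p_miss] <- NA
  d$SIQ <- siq
  d
}

# categorical coding of a record data.frame (mirrors the documented item
# coding, written independently of the package internals)
series_cat <- function(d) {
  cat <- matrix(NA_integer_, nrow(d), 11)
  for (v in 1:8) {
    raw <- d[[panss_items()[v]]]
    cat[, v] <- ifelse(raw <= 2, 0L, ifelse(raw <= 4, 1L, 2L))
  }
  for (v in 1:3) cat[, 8 + v] <- as.integer(d[[frt_items()[v]]])
  cat
}

# Brute-force oracle: enumerate all K^T state paths under every class and
# sum path probabilities directly.
oracle_enumerate <- function(d, params) {
  cat <- series_cat(d)
  siq <- d$SIQ
  K <- params$K; M <- params$M; T <- nrow(d)
  lik <- matrix(1, T, K)
  for (t in 1:T) {
    for (k in 1:K) {
      for (v in 1:11) {
        if (!is.na(cat[t, v])) {
          lik[t, k] <- lik[t, k] * params$B[k, cat[t, v] + 1, v]
        }
      }
      if (!is.na(siq[t])) {
        lik[t, k] <- lik[t, k] * dnorm(siq[t], params$mu[k], params$sigma)
      }
    }
  }
  paths <- as.matrix(expand.grid(rep(list(1:K), T)))
  total <- 0
  marg <- matrix(0, T, K)
  classp <- numeric(M)
  pair <- array(0, c(K, K, T))
  for (c in 1:M) {
    for (r in seq_len(nrow(paths))) {
      s <- paths[r, ]
      p <- params$omega[c] * params$pi[c, s[1]] * prod(lik[cbind(1:T, s)])
      if (T > 1) for (t in 2:T) p <- p * params$A[s[t - 1], s[t], c]
      total <- total + p
      for (t in 1:T) marg[t, s[t]] <- marg[t, s[t]] + p
      classp[c] <- classp[c] + p
      if (T > 1) for (t in 2:T) {
        pair[s[t - 1], s[t], t] <- pair[s[t - 1], s[t], t] + p
      }
    }
  }
  list(loglik = log(total), state_post = marg / total,
       class_post = classp / total, pairwise = pair / total)
}

# small long-format panel data.frame around given record rows
records_as_panel <- function(d, patient_id = "p1", years = NULL) {
  if (is.null(years)) years <- 2006 + seq_len(nrow(d)) - 1
  cbind(data.frame(patient_id = patient_id, year = years), d)
}
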