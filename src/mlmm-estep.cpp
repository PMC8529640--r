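// Scaled forward-backward E-step for the mixture latent Markov model.
//
// Latent structure: each patient belongs to one of M classes (time-constant);
// given the class, states follow a first-order Markov chain with
// class-specific initial and transition probabilities. Emissions depend on
// the state only, so the per-record emission log-likelihoods are computed
// once in R and passed in as a dense matrix.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// logB:    N x K emission log-likelihoods (rows in patient blocks, occasions
//          consecutive; all-missing records have an all-zero row)
// first:   0-based offset of each patient's first record
// len:     series length per patient
// logomega: M log class weights
// logpi:  M x K log initial-state probabilities
// logA:   K x K x M log transition matrices (row = from, col = to)
// keep_pairwise: also return class-marginal joint posteriors of
//          (state at t-1, state at t), stored at the slice of occasion t
//
// Returns the sufficient statistics for the M-step plus posteriors.
// [[Rcpp::export]]
Rcpp::List mlmm_estep_cpp(const arma::mat& logB,
                          const arma::ivec& first,
                          const arma::ivec& len,
                          const arma::vec& logomega,
                          const arma::mat& logpi,
                          const arma::cube& logA,
                          const bool keep_pairwise) {
  const uword n = first.n_elem;
  const uword K = logB.n_cols;
  const uword M = logomega.n_elem;
  const uword N = logB.n_rows;

  mat gamma(N, K, fill::zeros);        // class-marginal smoothed posteriors
  mat classpost(n, M, fill::zeros);
  mat init_counts(M, K, fill::zeros);  // class-weighted t=0 posteriors
  cube trans_counts(K, K, M, fill::zeros);
  vec pat_ll(n);
  cube pairwise;
  if (keep_pairwise) {
    pairwise.set_size(K, K, N);
    pairwise.fill(datum::nan);
  }

  // transition matrices in probability space
  std::vector<mat> A(M);
  std::vector<rowvec> pi(M);
  for (uword c = 0; c < M; ++c) {
    A[c] = exp(logA.slice(c));
    pi[c] = exp(logpi.row(c));
  }

  for (uword i = 0; i < n; ++i) {
    const uword T = (uword)len(i);
    const uword f = (uword)first(i);

    // stabilized emission probabilities, per occasion
    mat b(T, K);
    vec rowshift(T);
    for (uword t = 0; t < T; ++t) {
      rowvec lb = logB.row(f + t);
      double m = lb.max();
      rowshift(t) = m;
      b.row(t) = exp(lb - m);
    }

    vec cls_ll(M);
    cube g_c(T, K, M);              // class-conditional gamma
    cube xi_c;                      // class-conditional summed xi (K x K x M)
    xi_c.set_size(K, K, M);
    xi_c.zeros();
    cube xi_full;                   // per-transition xi, class-weighted later
    if (keep_pairwise && T > 1) {
      xi_full.set_size(K, K, (T - 1) * M);
    }

    for (uword c = 0; c < M; ++c) {
      mat alpha(T, K);
      vec scale(T);
      rowvec a0 = pi[c] % b.row(0);
      scale(0) = accu(a0);
      alpha.row(0) = a0 / scale(0);
      for (uword t = 1; t < T; ++t) {
        rowvec at = (alpha.row(t - 1) * A[c]) % b.row(t);
        scale(t) = accu(at);
        alpha.row(t) = at / scale(t);
      }
      cls_ll(c) = accu(log(scale)) + accu(rowshift);

      mat beta(T, K);
      beta.row(T - 1).ones();
      for (uword t = T - 1; t > 0; --t) {
        rowvec bt = (beta.row(t) % b.row(t)) * A[c].t();
        beta.row(t - 1) = bt / scale(t);
      }

      for (uword t = 0; t < T; ++t) {
        rowvec g = alpha.row(t) % beta.row(t);
        g_c.slice(c).row(t) = g / accu(g);
      }
      for (uword t = 1; t < T; ++t) {
        // xi(j,k) prop alpha_{t-1}(j) A(j,k) b_t(k) beta_t(k)
        mat xi = (alpha.row(t - 1).t() * (b.row(t) % beta.row(t))) % A[c];
        xi /= accu(xi);
        xi_c.slice(c) += xi;
        if (keep_pairwise) xi_full.slice((t - 1) * M + c) = xi;
      }
    }

    // class posterior via log-sum-exp of logomega + class-conditional loglik
    vec lw = logomega + cls_ll;
    double mx = lw.max();
    vec w = exp(lw - mx);
    double sw = accu(w);
    pat_ll(i) = mx + std::log(sw);
    w /= sw;
    classpost.row(i) = w.t();

    for (uword c = 0; c < M; ++c) {
      gamma.rows(f, f + T - 1) += w(c) * g_c.slice(c);
      init_counts.row(c) += w(c) * g_c.slice(c).row(0);
      trans_counts.slice(c) += w(c) * xi_c.slice(c);
      if (keep_pairwise && T > 1) {
        for (uword t = 1; t < T; ++t) {
          if (c == 0) pairwise.slice(f + t).zeros();
          pairwise.slice(f + t) += w(c) * xi_full.slice((t - 1) * M + c);
        }
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loglik") = accu(pat_ll),
    Rcpp::Named("patient_loglik") = pat_ll,
    Rcpp::Named("gamma") = gamma,
    Rcpp::Named("classpost") = classpost,
    Rcpp::Named("init_counts") = init_counts,
    Rcpp::Named("trans_counts") = trans_counts);
  if (keep_pairwise) out["pairwise"] = pairwise;
  return out;
}
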