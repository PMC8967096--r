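// Gaussian HMM core for time-delay embedded LFP data.
//
// Emissions are zero-mean multivariate Gaussians (the embedded signal is
// z-normalized; spectral content lives in the autocovariance), so the M-step
// updates covariances only. All routines are multi-segment aware: the
// forward-backward recursions restart at every segment boundary and the
// sufficient statistics are pooled, so no state visit or transition ever
// spans a session boundary.
//
// The cohort-scale fits run over 10^5-10^6 embedded rows, so the per-state
// quadratic forms and scatter matrices are arranged as plain GEMMs on
// preallocated buffers and the forward-backward inner loops avoid
// temporaries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-state Gaussian log-densities for zero-mean emissions, written into
// logB (T x K). Z is a reusable T x d work buffer.
static void gauss_logdens_into(const mat& X, const cube& Sigma,
                               mat& logB, mat& Z) {
  const uword d = X.n_cols, K = Sigma.n_slices;
  const double c0 = -0.5 * (double)d * std::log(2.0 * M_PI);
  for (uword k = 0; k < K; ++k) {
    mat L;
    if (!chol(L, Sigma.slice(k), "lower"))
      Rcpp::stop("covariance matrix for state %d is not positive definite", (int)k + 1);
    double logdet = 2.0 * accu(log(L.diag()));
    // q_t = || L^-1 x_t ||^2 via Z = X * (L^-1)' (one GEMM, no transposes)
    mat Linv_t = inv(trimatl(L)).t();
    Z = X * Linv_t;
    logB.col(k) = c0 - 0.5 * logdet - 0.5 * sum(square(Z), 1);
  }
}

// [[Rcpp::export]]
arma::mat gauss_logdens_cpp(const arma::mat& X, const arma::cube& Sigma) {
  mat logB(X.n_rows, Sigma.n_slices);
  mat Z(X.n_rows, X.n_cols);
  gauss_logdens_into(X, Sigma, logB, Z);
  return logB;
}

// Scaled forward-backward on rows [a, b) of B (pre-exponentiated, rowwise
// max-shifted densities with shifts in msum). Writes posteriors into gamma,
// adds pairwise-posterior sums into xi_sum; returns the log-likelihood.
static double fb_block(const mat& B, double mshift_sum,
                       const mat& A, const rowvec& pi,
                       mat& gamma, mat& xi_sum) {
  const uword T = B.n_rows, K = B.n_cols;
  mat alpha(T, K);
  vec c(T);
  const double* Bp = B.memptr();
  double* ap = alpha.memptr();

  // forward pass (column-major: element (t,k) at [k*T + t])
  {
    double s = 0;
    for (uword k = 0; k < K; ++k) {
      double v = pi(k) * Bp[k * T];
      ap[k * T] = v;
      s += v;
    }
    c(0) = s;
    for (uword k = 0; k < K; ++k) ap[k * T] /= s;
  }
  for (uword t = 1; t < T; ++t) {
    double s = 0;
    for (uword j = 0; j < K; ++j) {
      double acc = 0;
      for (uword i = 0; i < K; ++i) acc += ap[i * T + t - 1] * A(i, j);
      double v = acc * Bp[j * T + t];
      ap[j * T + t] = v;
      s += v;
    }
    c(t) = s;
    for (uword j = 0; j < K; ++j) ap[j * T + t] /= s;
  }

  // backward pass, accumulating gamma and xi on the fly
  std::vector<double> beta(K, 1.0), beta_next(K), bb(K);
  double* gp = gamma.memptr();
  const uword Tg = gamma.n_rows;
  for (uword k = 0; k < K; ++k) gp[k * Tg + T - 1] = ap[k * T + T - 1];
  for (uword t = T - 1; t-- > 0;) {
    const double ct1 = c(t + 1);
    for (uword j = 0; j < K; ++j) bb[j] = Bp[j * T + t + 1] * beta[j];
    double gs = 0;
    for (uword i = 0; i < K; ++i) {
      double acc = 0;
      const double ai = ap[i * T + t];
      for (uword j = 0; j < K; ++j) {
        const double x = A(i, j) * bb[j];
        xi_sum(i, j) += ai * x / ct1;
        acc += x;
      }
      beta_next[i] = acc / ct1;
      const double g = ai * beta_next[i];
      gp[i * Tg + t] = g;
      gs += g;
    }
    for (uword i = 0; i < K; ++i) gp[i * Tg + t] /= gs;
    std::swap(beta, beta_next);
  }
  return accu(log(c)) + mshift_sum;
}

// Shift-exponentiate logB rows in place; returns the sum of shifts.
static double exp_shift(mat& B) {
  const uword T = B.n_rows, K = B.n_cols;
  double msum = 0;
  double* Bp = B.memptr();
  for (uword t = 0; t < T; ++t) {
    double m = Bp[t];
    for (uword k = 1; k < K; ++k) m = std::max(m, Bp[k * T + t]);
    msum += m;
    for (uword k = 0; k < K; ++k) Bp[k * T + t] = std::exp(Bp[k * T + t] - m);
  }
  return msum;
}

// Run forward-backward over all segments; B is destroyed (exponentiated).
static double fb_all(mat& B, const uvec& seg_start, const uvec& seg_end,
                     const mat& A, const rowvec& pi,
                     mat& gamma, mat& xi_sum, rowvec& pi_acc) {
  double ll = 0;
  for (uword s = 0; s < seg_start.n_elem; ++s) {
    const uword a = seg_start(s), b = seg_end(s);
    mat Bs = B.rows(a, b - 1);
    double msum = exp_shift(Bs);
    mat gs(b - a, gamma.n_cols);
    ll += fb_block(Bs, msum, A, pi, gs, xi_sum);
    gamma.rows(a, b - 1) = gs;
    pi_acc += gs.row(0);
  }
  return ll;
}

// [[Rcpp::export]]
Rcpp::List fb_cpp(const arma::mat& logB, const arma::mat& A, const arma::rowvec& pi) {
  mat B = logB;
  double msum = exp_shift(B);
  mat gamma(B.n_rows, B.n_cols);
  mat xi_sum(B.n_cols, B.n_cols, fill::zeros);
  double ll = fb_block(B, msum, A, pi, gamma, xi_sum);
  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("xi_sum") = xi_sum,
                            Rcpp::Named("loglik") = ll);
}

// E-step / decoding over multiple segments (0-based half-open row ranges).
// [[Rcpp::export]]
Rcpp::List hmm_estep_cpp(const arma::mat& X,
                         const arma::uvec& seg_start, const arma::uvec& seg_end,
                         const arma::mat& A, const arma::rowvec& pi,
                         const arma::cube& Sigma) {
  const uword K = A.n_rows;
  mat logB(X.n_rows, K);
  mat Z(X.n_rows, X.n_cols);
  gauss_logdens_into(X, Sigma, logB, Z);
  mat gamma(X.n_rows, K);
  mat xi_sum(K, K, fill::zeros);
  rowvec pi_acc(K, fill::zeros);
  double ll = fb_all(logB, seg_start, seg_end, A, pi, gamma, xi_sum, pi_acc);
  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("xi_sum") = xi_sum,
                            Rcpp::Named("loglik") = ll);
}

// Baum-Welch EM with zero-mean full-covariance Gaussian emissions.
// Returns parameters, posteriors from a final E-step under the converged
// parameters, the log-likelihood trace, and a convergence flag.
// [[Rcpp::export]]
Rcpp::List hmm_em_cpp(const arma::mat& X,
                      const arma::uvec& seg_start, const arma::uvec& seg_end,
                      arma::mat A, arma::rowvec pi, arma::cube Sigma,
                      int max_iter, double tol, double eps) {
  const uword K = A.n_rows, d = X.n_cols, S = seg_start.n_elem;
  std::vector<double> trace;
  double ll_prev = -datum::inf;
  bool converged = false;

  mat logB(X.n_rows, K), Z(X.n_rows, X.n_cols);
  mat gamma(X.n_rows, K);
  mat Xw(X.n_rows, d); // reusable weighted-data buffer

  for (int it = 0; it <= max_iter; ++it) {
    // E-step
    gauss_logdens_into(X, Sigma, logB, Z);
    mat xi_sum(K, K, fill::zeros);
    rowvec pi_acc(K, fill::zeros);
    double ll = fb_all(logB, seg_start, seg_end, A, pi, gamma, xi_sum, pi_acc);
    trace.push_back(ll);
    bool last = (it == max_iter);
    if (std::abs(ll - ll_prev) < tol * std::abs(ll)) { converged = true; last = true; }
    ll_prev = ll;
    if (last) break;

    // M-step
    pi = pi_acc / (double)S;
    vec rs = sum(xi_sum, 1);
    for (uword k = 0; k < K; ++k)
      if (rs(k) > 0) A.row(k) = xi_sum.row(k) / rs(k);
    rowvec occ = sum(gamma, 0);
    for (uword k = 0; k < K; ++k) {
      Xw = X;
      Xw.each_col() %= sqrt(gamma.col(k));
      mat Sk = (Xw.t() * Xw) / occ(k);
      Sk.diag() += eps;
      Sigma.slice(k) = symmatu(Sk);
    }
  }

  rowvec occ = sum(gamma, 0);
  return Rcpp::List::create(
      Rcpp::Named("A") = A, Rcpp::Named("pi") = pi, Rcpp::Named("Sigma") = Sigma,
      Rcpp::Named("gamma") = gamma, Rcpp::Named("loglik") = trace.back(),
      Rcpp::Named("loglik_trace") = trace,
      Rcpp::Named("occupancy") = occ,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("dim") = (int)d);
}

// Viterbi decoding per segment; returns 0-based state indices.
// [[Rcpp::export]]
arma::uvec viterbi_cpp(const arma::mat& logB,
                       const arma::uvec& seg_start, const arma::uvec& seg_end,
                       const arma::mat& A, const arma::rowvec& pi) {
  const uword K = A.n_rows;
  mat logA = log(A);
  rowvec logpi = log(pi);
  uvec path(logB.n_rows);
  for (uword s = 0; s < seg_start.n_elem; ++s) {
    const uword a = seg_start(s), b = seg_end(s), T = b - a;
    mat delta(T, K);
    umat psi(T, K);
    delta.row(0) = logpi + logB.row(a);
    for (uword t = 1; t < T; ++t) {
      for (uword j = 0; j < K; ++j) {
        vec cand = delta.row(t - 1).t() + logA.col(j);
        // ties prefer the self-transition, then the lower index, so the
        // prior-dominated limit yields a constant path
        uword arg = cand.index_max();
        if (cand(j) >= cand(arg)) arg = j;
        psi(t, j) = arg;
        delta(t, j) = cand(arg) + logB(a + t, j);
      }
    }
    // terminal ties resolve toward the state with the larger initial
    // weight (then the lower index), so a flat lattice follows the prior
    uword st = delta.row(T - 1).index_max();
    for (uword j = 0; j < K; ++j)
      if (delta(T - 1, j) == delta(T - 1, st) && delta(0, j) > delta(0, st))
        st = j;
    path(a + T - 1) = st;
    for (uword t = T - 1; t-- > 0;) {
      st = psi(t + 1, st);
      path(a + t) = st;
    }
  }
  return path;
}
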