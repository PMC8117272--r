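#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log N(x; mu, Sigma) for every row of X, given the lower Cholesky factor L
static vec mvn_logpdf(const mat& X, const rowvec& mu, const mat& L) {
  const double d = static_cast<double>(X.n_cols);
  mat Xc = X.each_row() - mu;
  mat Z = solve(trimatl(L), Xc.t());
  vec quad = sum(square(Z), 0).t();
  double logdet = 2.0 * accu(log(L.diag()));
  return -0.5 * (d * std::log(2.0 * datum::pi) + logdet + quad);
}

// Component-wise weighted log densities; columns whose covariance is not
// SPD even after extra regularization are filled with -Inf so the
// component receives no responsibility and is dropped.  The bivariate
// case (the spatiotemporal models) uses the explicit 2x2 inverse.
static double estep(const mat& X, const vec& w, const mat& mu, const cube& Sigma,
                    double reg, mat& logp, vec& lse) {
  const uword K = w.n_elem;
  const uword d = X.n_cols;
  logp.set_size(X.n_rows, K);
  for (uword k = 0; k < K; ++k) {
    if (d == 2) {
      double s11 = Sigma(0, 0, k), s12 = Sigma(0, 1, k), s22 = Sigma(1, 1, k);
      double det = s11 * s22 - s12 * s12;
      if (!(det > 0.0 && s11 > 0.0)) {
        s11 += 10.0 * reg; s22 += 10.0 * reg;
        det = s11 * s22 - s12 * s12;
        if (!(det > 0.0 && s11 > 0.0)) { logp.col(k).fill(-datum::inf); continue; }
      }
      vec dx = X.col(0) - mu(k, 0);
      vec dy = X.col(1) - mu(k, 1);
      vec quad = (s22 * square(dx) - 2.0 * s12 * (dx % dy) + s11 * square(dy)) / det;
      logp.col(k) = std::log(w(k)) -
        0.5 * (2.0 * std::log(2.0 * datum::pi) + std::log(det) + quad);
    } else {
      mat L;
      mat Sk = Sigma.slice(k);
      if (!chol(L, Sk, "lower")) {
        Sk.diag() += 10.0 * reg;
        if (!chol(L, Sk, "lower")) {
          logp.col(k).fill(-datum::inf);
          continue;
        }
      }
      logp.col(k) = std::log(w(k)) + mvn_logpdf(X, mu.row(k), L);
    }
  }
  vec m = max(logp, 1);
  lse = m + log(sum(exp(logp.each_col() - m), 1));
  return accu(lse);
}

// Full-covariance EM for a Gaussian mixture.  Components whose weight
// collapses (or whose covariance is not SPD despite regularization) are
// dropped and counted.  Returns the parameters, the log-likelihood trace
// of the visited iterates, and a final log-likelihood evaluated at the
// returned parameters.
// [[Rcpp::export]]
Rcpp::List em_gmm_cpp(const arma::mat& X, arma::vec w, arma::mat mu,
                      arma::cube Sigma, double tol, int max_iter, double reg) {
  const uword n = X.n_rows;
  const uword d = X.n_cols;
  std::vector<double> trace;
  double ll_old = -datum::inf;
  bool converged = false;
  int dropped = 0;
  int iter_done = 0;

  for (int iter = 0; iter < max_iter; ++iter) {
    mat logp;
    vec lse;
    double ll = estep(X, w, mu, Sigma, reg, logp, lse);
    trace.push_back(ll);
    iter_done = iter + 1;

    mat R = exp(logp.each_col() - lse);
    rowvec Nk = sum(R, 0);

    uvec keep = find(Nk.t() > 1e-8 * static_cast<double>(n));
    if (keep.n_elem == 0) break;
    if (keep.n_elem < w.n_elem) {
      dropped += static_cast<int>(w.n_elem - keep.n_elem);
      R = R.cols(keep);
      mu = mu.rows(keep);
      cube S2(d, d, keep.n_elem);
      for (uword j = 0; j < keep.n_elem; ++j) S2.slice(j) = Sigma.slice(keep(j));
      Sigma = S2;
      w = w(keep);
      Nk = sum(R, 0);
    }

    // M-step
    w = Nk.t() / static_cast<double>(n);
    w /= accu(w);
    for (uword k = 0; k < w.n_elem; ++k) {
      rowvec mk = (R.col(k).t() * X) / Nk(k);
      mu.row(k) = mk;
      mat Xc = X.each_row() - mk;
      mat Sk = (Xc.t() * (Xc.each_col() % R.col(k))) / Nk(k);
      Sk = 0.5 * (Sk + Sk.t());
      Sk.diag() += reg;
      Sigma.slice(k) = Sk;
    }

    if (iter > 0 && std::abs(ll - ll_old) < tol * (std::abs(ll_old) + 1e-10)) {
      converged = true;
      break;
    }
    ll_old = ll;
  }

  // log-likelihood at the returned (post M-step) parameters
  mat logp;
  vec lse;
  double ll_final = estep(X, w, mu, Sigma, reg, logp, lse);
  trace.push_back(ll_final);

  return Rcpp::List::create(
    Rcpp::Named("weights") = w,
    Rcpp::Named("means") = mu,
    Rcpp::Named("covariances") = Sigma,
    Rcpp::Named("log_likelihood") = ll_final,
    Rcpp::Named("loglik_trace") = trace,
    Rcpp::Named("iterations") = iter_done,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("dropped") = dropped);
}

// Direct-form II transposed IIR filter with explicit initial state,
// the building block of the zero-phase (forward-backward) filter.
// [[Rcpp::export]]
arma::vec iir_filter_cpp(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  const uword n = x.n_elem;
  const uword m = a.n_elem - 1;  // filter order (a[0] assumed 1)
  vec z = zi;
  vec y(n);
  for (uword i = 0; i < n; ++i) {
    double yi = b(0) * x(i) + (m > 0 ? z(0) : 0.0);
    for (uword j = 0; j + 1 < m; ++j) {
      z(j) = b(j + 1) * x(i) + z(j + 1) - a(j + 1) * yi;
    }
    if (m > 0) z(m - 1) = b(m) * x(i) - a(m) * yi;
    y(i) = yi;
  }
  return y;
}
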