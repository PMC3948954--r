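// Core numerics for the modified multivariate autoregressive (mMVAR) model:
// per-equation least squares with contemporaneous cross-regressors, plus the
// phase-randomized surrogate ensemble loop. Kept in C++ because surrogate
// inference refits the model thousands of times per subject.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Design matrix: [zero-lag X columns (optional) | lag 1..p blocks | intercept].
static arma::mat lag_design(const arma::mat& X, int p, bool include_a0) {
  const int T = X.n_rows, k = X.n_cols, Tp = T - p;
  const int ncol = (include_a0 ? k : 0) + p * k + 1;
  arma::mat Z(Tp, ncol);
  int c = 0;
  if (include_a0) {
    Z.cols(0, k - 1) = X.rows(p, T - 1);
    c = k;
  }
  for (int n = 1; n <= p; ++n) {
    Z.cols(c, c + k - 1) = X.rows(p - n, T - 1 - n);
    c += k;
  }
  Z.col(c).ones();
  return Z;
}

// Solve the k per-equation regressions. Equation i regresses x_i(t) on the
// zero-lag values of every OTHER series (self column dropped: the diagonal of
// A(0) is structurally zero) and on p lags of all series, plus an intercept.
// Returns the full coefficient matrix C (n_regressors x k) with a structural
// zero in each dropped position.
static arma::mat mmvar_solve(const arma::mat& Z, const arma::mat& Y,
                             int k, bool include_a0) {
  const int m = Z.n_cols;
  const arma::mat G = Z.t() * Z;
  const arma::mat B = Z.t() * Y;
  arma::mat C(m, k, arma::fill::zeros);
  for (int i = 0; i < k; ++i) {
    if (include_a0) {
      arma::uvec idx(m - 1);
      int c = 0;
      for (int j = 0; j < m; ++j)
        if (j != i) idx(c++) = j;
      arma::vec coef;
      const arma::mat Gs = G.submat(idx, idx);
      const arma::vec bs = B.submat(idx, arma::uvec{(arma::uword)i});
      if (!arma::solve(coef, Gs, bs, arma::solve_opts::no_approx))
        stop("mMVAR regressor matrix is rank-deficient (duplicated or collinear ROI series?)");
      for (int j = 0; j < m - 1; ++j) C(idx(j), i) = coef(j);
    } else {
      arma::vec coef;
      if (!arma::solve(coef, G, B.col(i), arma::solve_opts::no_approx))
        stop("VAR regressor matrix is rank-deficient (duplicated or collinear ROI series?)");
      C.col(i) = coef;
    }
  }
  return C;
}

// CPGC from the coefficient matrix: sum over lags of squared lagged
// coefficients, diagonal zero. C layout as produced by mmvar_solve.
static arma::mat cpgc_from_coef(const arma::mat& C, int k, int p,
                                bool include_a0) {
  const int off = include_a0 ? k : 0;
  arma::mat out(k, k, arma::fill::zeros);
  for (int i = 0; i < k; ++i) {      // target
    for (int j = 0; j < k; ++j) {    // source
      if (i == j) continue;
      double s = 0.0;
      for (int n = 0; n < p; ++n) {
        const double a = C(off + n * k + j, i);
        s += a * a;
      }
      out(i, j) = s;
    }
  }
  return out;
}

// [[Rcpp::export]]
List mmvar_fit_cpp(const arma::mat& X, int p, bool include_a0) {
  const int T = X.n_rows, k = X.n_cols, Tp = T - p;
  const arma::mat Y = X.rows(p, T - 1);
  const arma::mat Z = lag_design(X, p, include_a0);
  const arma::mat C = mmvar_solve(Z, Y, k, include_a0);
  const arma::mat resid = Y - Z * C;
  const arma::mat sigma = (resid.t() * resid) / (double)Tp;

  const int off = include_a0 ? k : 0;
  arma::mat A0(k, k, arma::fill::zeros);
  if (include_a0) {
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        if (i != j) A0(i, j) = C(j, i);
  }
  arma::cube Alags(k, k, p);
  for (int n = 0; n < p; ++n)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        Alags(i, j, n) = C(off + n * k + j, i);
  arma::vec intercept = C.row(C.n_rows - 1).t();

  return List::create(
    _["A0"] = A0, _["Alags"] = Alags, _["intercept"] = intercept,
    _["residuals"] = resid, _["sigma"] = sigma,
    _["cpgc"] = cpgc_from_coef(C, k, p, include_a0));
}

// Surrogate ensemble loop. A phase-randomized surrogate of a real series
// with spectrum F_q is
//   x_s(t) = F_0/T + (2/T) sum_{q=1}^{m} |F_q| cos(2 pi q t / T + psi_q)
//            [+ F_{T/2} (-1)^t / T for even T, phase untouched]
// with psi_q iid uniform on [0, 2 pi) (the original phase plus a uniform
// offset is again uniform). Writing cos(wt + psi) = cos(wt) cos(psi) -
// sin(wt) sin(psi) lets all surrogates share two precomputed T x m trig
// basis matrices, avoiding per-surrogate FFTs (the series length need not
// be FFT-friendly). The mMVAR coefficients come from the precision matrix
// of the full design: with H = (Z'Z)^{-1}, the least-squares regression of
// column i of Z on all remaining columns has coefficients -H[j,i]/H[i,i],
// which yields every equation of the instantaneous model from a single
// inversion per surrogate.
// [[Rcpp::export]]
arma::cube cpgc_null_cpp(const arma::mat& X, int p, int n_surr,
                         bool include_a0) {
  const int T = X.n_rows, k = X.n_cols;
  const int m = (T - 1) / 2;
  const bool even = (T % 2 == 0);

  // per-column spectra
  arma::mat amp(m, k);       // 2 |F_q| / T for q = 1..m
  arma::rowvec c0(k);        // F_0 / T (the mean)
  arma::vec nyq(k, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    arma::cx_vec F = arma::fft(arma::conv_to<arma::cx_vec>::from(X.col(j)));
    for (int q = 1; q <= m; ++q) amp(q - 1, j) = 2.0 * std::abs(F(q)) / T;
    c0(j) = std::real(F(0)) / T;
    if (even) nyq(j) = std::real(F(T / 2)) / T;
  }
  arma::mat Cb(T, m), Sb(T, m);
  for (int q = 1; q <= m; ++q) {
    const double w = 2.0 * M_PI * q / T;
    for (int t = 0; t < T; ++t) {
      Cb(t, q - 1) = std::cos(w * t);
      Sb(t, q - 1) = std::sin(w * t);
    }
  }
  arma::vec alt(T);
  for (int t = 0; t < T; ++t) alt(t) = (t % 2 == 0) ? 1.0 : -1.0;

  arma::cube out(k, k, n_surr);
  arma::mat psi(m, k), Xs(T, k);
  for (int s = 0; s < n_surr; ++s) {
    for (int j = 0; j < k; ++j)
      for (int q = 0; q < m; ++q)
        psi(q, j) = R::runif(0.0, 2.0 * M_PI);
    Xs = Cb * (amp % arma::cos(psi)) - Sb * (amp % arma::sin(psi));
    Xs.each_row() += c0;
    if (even) Xs += alt * nyq.t();
    for (int j = 0; j < k; ++j) {
      const double mu = arma::mean(Xs.col(j));
      const double sd = arma::stddev(Xs.col(j));  // denominator T-1
      Xs.col(j) = (Xs.col(j) - mu) / sd;
    }

    const arma::mat Z = lag_design(Xs, p, include_a0);
    const arma::mat G = Z.t() * Z;
    arma::mat C;
    if (include_a0) {
      arma::mat H;
      if (!arma::inv_sympd(H, G) && !arma::inv(H, G))
        stop("surrogate %d: rank-deficient regressor matrix", s + 1);
      C.zeros(G.n_rows, k);
      for (int i = 0; i < k; ++i) {
        C.col(i) = -H.col(i) / H(i, i);
        C(i, i) = 0.0;
      }
    } else {
      const arma::mat B = Z.t() * Xs.rows(p, T - 1);
      if (!arma::solve(C, G, B, arma::solve_opts::no_approx))
        stop("surrogate %d: rank-deficient regressor matrix", s + 1);
    }
    out.slice(s) = cpgc_from_coef(C, k, p, include_a0);
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
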