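// Recursive (Kalman) estimation of time-varying AR regression coefficients
// and surrogate MVAR iteration. Hot loops of the connectivity analysis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Shared recursion for the single-target time-varying regression
//   y(t) = x(t)' beta(t) + e(t),   beta(t) = beta(t-1) + w(t)
// with random-walk state (w ~ N(0, q I)), fixed observation noise r and
// diffuse initial covariance p0 I. errScale is the exponentially
// smoothed innovation SD (decay lambda). Rank-one covariance update
// keeps P symmetric without re-symmetrization; inner loops avoid
// temporaries.
static void kalman_core(const arma::mat& X, const arma::vec& y,
                        double q, double r, double p0, double lambda,
                        arma::vec& errScale, arma::vec& innov,
                        arma::mat* coeffs) {
  const arma::uword T = X.n_rows, d = X.n_cols;
  arma::vec beta(d, arma::fill::zeros), Px(d);
  arma::mat P(d, d, arma::fill::zeros);
  P.diag() += p0;
  // bias-corrected exponentially weighted variance of the innovations
  // (normalising by 1 - lambda^(t+1) removes the zero-start transient)
  double s2raw = 0.0, norm = 0.0;
  double* Pm = P.memptr();
  double* px = Px.memptr();
  for (arma::uword t = 0; t < T; ++t) {
    if (q > 0.0) P.diag() += q;
    const arma::rowvec xt = X.row(t);
    Px = P * xt.t();
    const double S = arma::dot(xt, Px) + r;
    const double e = y(t) - arma::dot(xt, beta);
    beta += (e / S) * Px;
    const double invS = 1.0 / S;
    for (arma::uword j = 0; j < d; ++j) {
      const double pj = px[j] * invS;
      double* col = Pm + j * d;
      for (arma::uword i = 0; i < d; ++i) col[i] -= px[i] * pj;
    }
    s2raw = lambda * s2raw + (1.0 - lambda) * e * e;
    norm = lambda * norm + (1.0 - lambda);
    double s2 = s2raw / norm;
    if (s2 < 1e-300) s2 = 1e-300;
    errScale(t) = std::sqrt(s2);
    innov(t) = e;
    if (coeffs) coeffs->row(t) = beta.t();
  }
}

// Full filter output: per-timepoint coefficients, innovations and
// prediction-error scale.
// [[Rcpp::export(name = ".kalman_ar_filter")]]
List kalman_ar_filter(const arma::mat& X, const arma::vec& y,
                      double q, double r, double p0, double lambda) {
  const arma::uword T = X.n_rows, d = X.n_cols;
  arma::mat coeffs(T, d);
  arma::vec innov(T), errScale(T);
  kalman_core(X, y, q, r, p0, lambda, errScale, innov, &coeffs);
  return List::create(_["coeffs"] = coeffs,
                      _["innovations"] = innov,
                      _["error_scale"] = errScale);
}

// Iterate an MVAR process x(t) = sum_k A_k(t) x(t-k) + eps(t).
// A: (n*n*p) x T matrix; column t holds the coefficient cube at time t,
//    vectorised as A[target, source, lag] in column-major order
//    (index = target + n*source + n*n*lag).
// eps: n x T innovation matrix (pre-drawn in R so all RNG stays in R).
// First p columns of the output are taken directly from eps.
// [[Rcpp::export(name = ".mvar_iterate")]]
arma::mat mvar_iterate(const arma::mat& A, const arma::mat& eps,
                       int n, int p) {
  const arma::uword T = eps.n_cols;
  arma::mat x(n, T);
  const arma::uword up = static_cast<arma::uword>(p);
  for (arma::uword t = 0; t < T; ++t) {
    if (t < up) { x.col(t) = eps.col(t); continue; }
    arma::vec v = eps.col(t);
    const double* a = A.colptr(t);
    for (int k = 0; k < p; ++k) {
      const arma::vec xl = x.col(t - k - 1);
      for (int j = 0; j < n; ++j) {
        const double xlj = xl(j);
        if (xlj == 0.0) continue;
        const double* col = a + static_cast<size_t>(n) * n * k +
                            static_cast<size_t>(n) * j;
        for (int i = 0; i < n; ++i) v(i) += col[i] * xlj;
      }
    }
    x.col(t) = v;
  }
  return x;
}

// Batch bootstrap: for each replicate, iterate the (already zeroed and
// smoothed) surrogate coefficient schedule with pool-resampled
// innovations, refit the full and counter models for the target, and
// return the GCi at the requested window rows.
// A: (n*n*p) x T schedule; pools: per-channel residual pools;
// idx: n x (T*B) 1-based resample indices; rows: 1-based indices into
// the model rows 1..T-p; tgt/src: 1-based channel positions.
// Replicates whose surrogate diverges get ok = false and NA gci.
// [[Rcpp::export(name = ".bootstrap_gci_batch")]]
List bootstrap_gci_batch(const arma::mat& A, const List& pools,
                         const arma::imat& idx, int n, int p,
                         const arma::uvec& rows, int tgt, int src,
                         double q, double r, double p0, double lambda) {
  const arma::uword T = A.n_cols;
  const int B = idx.n_cols / T;
  arma::mat out(B, rows.n_elem);
  out.fill(NA_REAL);
  LogicalVector ok(B);

  std::vector<arma::vec> pool(n);
  for (int j = 0; j < n; ++j) pool[j] = as<arma::vec>(pools[j]);

  const arma::uword Tm = T - p;           // model rows
  arma::uvec keep((n - 1) * p);           // counter-model columns
  arma::uword c = 0;
  for (int k = 0; k < p; ++k)
    for (int j = 0; j < n; ++j)
      if (j != src - 1) keep(c++) = k * n + j;

  arma::mat eps(n, T), Xf(Tm, n * p);
  arma::vec efull(Tm), ectr(Tm), innov(Tm);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < n; ++j)
      for (arma::uword t = 0; t < T; ++t)
        eps(j, t) = pool[j](idx(j, b * T + t) - 1);
    arma::mat x = mvar_iterate(A, eps, n, p);
    if (!x.is_finite() || arma::abs(x).max() > 1e6) { ok[b] = false; continue; }
    ok[b] = true;
    for (int k = 0; k < p; ++k)
      for (int j = 0; j < n; ++j)
        Xf.col(k * n + j) = x.row(j).subvec(p - k - 1, T - k - 2).t();
    arma::vec y = x.row(tgt - 1).subvec(p, T - 1).t();
    kalman_core(Xf, y, q, r, p0, lambda, efull, innov, nullptr);
    kalman_core(Xf.cols(keep), y, q, r, p0, lambda, ectr, innov, nullptr);
    for (arma::uword w = 0; w < rows.n_elem; ++w) {
      const arma::uword rw = rows(w) - 1;
      out(b, w) = std::log(ectr(rw) / efull(rw));
    }
  }
  return List::create(_["gci"] = out, _["ok"] = ok);
}
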