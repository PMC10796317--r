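#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sample-wise recursive least squares with an impulse-train reference.
//
// The regressor at sample t is u = [x[t], x[t-1], ..., x[t-M+1]]'; x is a
// unit-impulse train at the QRS instants, so u is sparse (at most a few
// ones: the impulses inside the last M samples). The tap vector w is the
// evolving per-beat response template; the a-priori output y[t] = w'u is
// the beat-locked circulatory estimate and e[t] = d[t] - y[t] the residual,
// so y + e == d exactly at every sample.
//
// Exact exponentially-weighted recursion, including P <- P/lambda on
// samples with an empty regressor (template information decays between
// beats). The rank-1 update P <- (P - pi pi'/(lambda + u'pi))/lambda (with
// pi = P u, and the RLS gain k = pi/(lambda + u'pi)) preserves symmetry
// exactly, and the inner loops are fused so each sample costs one pass
// over P.
// [[Rcpp::export]]
List rls_filter_cpp(NumericVector ref, NumericVector d, int M, double lam,
                    double delta) {
  const int n = d.size();
  if (ref.size() != n) stop("reference and signal lengths differ");
  if (M < 1) stop("n_taps must be >= 1");
  if (lam <= 0.0 || lam > 1.0) stop("lambda must be in (0, 1]");
  if (delta <= 0.0) stop("delta must be > 0");

  arma::vec w(M, arma::fill::zeros);
  arma::mat P(M, M, arma::fill::eye);
  P *= delta;
  arma::vec pi(M);
  NumericVector y(n), e(n);
  std::vector<int> active;  // sample indices (0-based) of impulses in window
  const double invl = 1.0 / lam;
  double* Pm = P.memptr();

  for (int t = 0; t < n; ++t) {
    if (ref[t] != 0.0) active.push_back(t);
    // retire impulses that slid out of the M-sample window
    std::size_t k0 = 0;
    while (k0 < active.size() && t - active[k0] >= M) ++k0;
    if (k0 > 0) active.erase(active.begin(), active.begin() + k0);

    if (active.empty()) {
      y[t] = 0.0;
      e[t] = d[t];
      if (lam < 1.0) P *= invl;
      continue;
    }

    double yhat = 0.0;
    pi.zeros();
    for (int s : active) {
      const int j = t - s;
      const double rv = ref[s];
      yhat += rv * w[j];
      const double* col = Pm + static_cast<std::size_t>(j) * M;
      for (int r2 = 0; r2 < M; ++r2) pi[r2] += rv * col[r2];
    }
    double upi = 0.0;
    for (int s : active) upi += ref[s] * pi[t - s];

    const double err = d[t] - yhat;
    const double denom = lam + upi;
    w += (err / denom) * pi;
    for (int c = 0; c < M; ++c) {
      const double pc = pi[c] / denom;
      double* col = Pm + static_cast<std::size_t>(c) * M;
      for (int r2 = 0; r2 < M; ++r2) col[r2] = (col[r2] - pi[r2] * pc) * invl;
    }
    y[t] = yhat;
    e[t] = err;
  }

  return List::create(_["cc"] = y, _["residual"] = e, _["taps"] = wrap(w));
}
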