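#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the elastic net, parameterized by the Gram
// matrix XtX = X'X, Xty = X'y and yty = y'y of a (standardized, centered)
// design.  Objective:
//   (1/2n) ||y - X b||^2 + lambda * (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
// Coordinate update: b_j <- S(rho_j, lambda*alpha) / (x_j'x_j/n + lambda*(1-alpha))
// with rho_j the partial residual correlation.  Lambdas are visited in the
// given (decreasing) order with warm starts.  When `trace` is true the
// objective value after every sweep is recorded per lambda.
// [[Rcpp::export]]
List enet_cd_gram(const NumericMatrix& XtX, const NumericVector& Xty,
                  double yty, int n, const NumericVector& lambda,
                  double alpha, NumericVector beta_init,
                  double tol, int max_sweeps, bool trace) {
  const int p = Xty.size(), L = lambda.size();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> g(p, 0.0);                    // XtX * beta
  for (int j = 0; j < p; ++j)
    if (beta[j] != 0.0)
      for (int i = 0; i < p; ++i) g[i] += XtX(i, j) * beta[j];

  NumericMatrix betas(p, L);
  IntegerVector sweeps(L);
  LogicalVector conv(L);
  List traces(L);

  std::vector<int> active;
  active.reserve(p);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    const double la = lam * alpha, lr = lam * (1.0 - alpha);
    std::vector<double> objs;
    int s = 0;
    bool done = (p == 0);

    // one cyclic pass over the given coordinate set
    auto sweep_over = [&](const std::vector<int>& idx) {
      double maxd = 0.0;
      for (int j : idx) {
        const double bj = beta[j];
        const double rho = (Xty[j] - g[j] + XtX(j, j) * bj) / n;
        const double denom = XtX(j, j) / n + lr;
        const double bn = denom > 0.0 ? soft(rho, la) / denom : 0.0;
        const double d = bn - bj;
        if (d != 0.0) {
          beta[j] = bn;
          for (int i = 0; i < p; ++i) g[i] += XtX(i, j) * d;
          const double ad = std::fabs(d);
          if (ad > maxd) maxd = ad;
        }
      }
      return maxd;
    };
    std::vector<int> all(p);
    for (int j = 0; j < p; ++j) all[j] = j;

    if (trace) {
      // plain cyclic sweeps with a per-sweep objective record
      while (s < max_sweeps && !done) {
        ++s;
        const double maxd = sweep_over(all);
        double quad = 0.0, l1 = 0.0, l2 = 0.0;
        for (int j = 0; j < p; ++j) {
          quad += beta[j] * (g[j] - 2.0 * Xty[j]);
          l1 += std::fabs(beta[j]);
          l2 += beta[j] * beta[j];
        }
        objs.push_back((yty + quad) / (2.0 * n) +
                       lam * (alpha * l1 + 0.5 * (1.0 - alpha) * l2));
        if (maxd < tol) done = true;
      }
    } else {
      // active-set strategy: iterate the current support to convergence,
      // then screen every inactive coordinate against its KKT condition
      // using the maintained gradient g (an O(p) check, no full sweep);
      // violators are updated once and join the active set
      while (s < max_sweeps && !done) {
        active.clear();
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
        while (s < max_sweeps) {
          ++s;
          if (sweep_over(active) < tol) break;
        }
        bool entered = false;
        for (int j = 0; j < p; ++j) {
          if (beta[j] != 0.0) continue;
          const double rho = (Xty[j] - g[j]) / n;
          if (std::fabs(rho) > la) {
            const double denom = XtX(j, j) / n + lr;
            if (denom <= 0.0) continue;
            const double bn = soft(rho, la) / denom;
            beta[j] = bn;
            for (int i = 0; i < p; ++i) g[i] += XtX(i, j) * bn;
            entered = true;
          }
        }
        if (!entered) done = true;
      }
    }
    sweeps[l] = s;
    conv[l] = done;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    if (trace) traces[l] = wrap(objs);
  }
  return List::create(_["beta"] = betas, _["sweeps"] = sweeps,
                      _["converged"] = conv, _["objective"] = traces);
}

// Fused preprocessing core: optional common average reference, segmentation
// into nsp-sample epochs with per-epoch per-lead linear detrending, and
// peak-amplitude epoch rejection, in one pass.  Input is leads x samples;
// output epochs are nsp x leads x n_kept plus the 1-based kept indices.
// Numerically identical to composing the step-wise operations.
// [[Rcpp::export]]
List preprocess_core(const NumericMatrix& x, int nsp, double threshold,
                     bool reref) {
  const int L = x.nrow(), S = x.ncol();
  const int K = S / nsp;
  std::vector<double> colmean(S, 0.0);
  if (reref) {
    for (int s = 0; s < S; ++s) {
      double m = 0.0;
      for (int l = 0; l < L; ++l) m += x(l, s);
      colmean[s] = m / L;
    }
  }
  const double tmid = (nsp + 1) / 2.0;
  double stt = 0.0;
  for (int t = 1; t <= nsp; ++t) stt += (t - tmid) * (t - tmid);

  NumericVector out(Dimension(nsp, L, K));
  std::vector<double> peak(K, 0.0);
  std::vector<double> buf(nsp);
  for (int e = 0; e < K; ++e) {
    double pk = 0.0;
    for (int l = 0; l < L; ++l) {
      double sum = 0.0, st = 0.0;
      const int off = e * nsp;
      for (int t = 0; t < nsp; ++t) {
        const double v = x(l, off + t) - colmean[off + t];
        buf[t] = v;
        sum += v;
        st += v * (t + 1 - tmid);
      }
      const double mu = sum / nsp, slope = st / stt;
      double* o = REAL(out) + ((R_xlen_t)e * L + l) * nsp;
      for (int t = 0; t < nsp; ++t) {
        const double v = buf[t] - mu - slope * (t + 1 - tmid);
        o[t] = v;
        const double av = std::fabs(v);
        if (av > pk) pk = av;
      }
    }
    peak[e] = pk;
  }
  std::vector<int> kept;
  for (int e = 0; e < K; ++e) if (peak[e] <= threshold) kept.push_back(e);
  if (kept.empty())
    stop("all epochs exceed the rejection threshold");
  NumericVector res(Dimension(nsp, L, (int)kept.size()));
  for (size_t i = 0; i < kept.size(); ++i)
    std::copy(REAL(out) + (R_xlen_t)kept[i] * L * nsp,
              REAL(out) + (R_xlen_t)(kept[i] + 1) * L * nsp,
              REAL(res) + (R_xlen_t)i * L * nsp);
  IntegerVector ki(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) ki[i] = kept[i] + 1;
  return List::create(_["data"] = res, _["kept"] = ki);
}
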