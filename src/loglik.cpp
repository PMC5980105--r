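#include <Rcpp.h>
using namespace Rcpp;

// exp(x) by the standard Cephes rational approximation (argument reduction
// x = n ln2 + r, Pade form on r), accurate to ~1 ulp. The likelihood spends
// most of its time in exp over [-60, 0]; the libm call dominates runtime on
// this hot path.
static inline double fexp(double x) {
  if (x < -708.0) return 0.0;
  if (x > 708.0) return std::exp(x);
  const double n = std::floor(1.4426950408889634 * x + 0.5);
  double r = x - n * 6.93145751953125e-1 - n * 1.42860682030941723212e-6;
  const double rr = r * r;
  const double p = r * (9.99999999999999999910e-1 +
                        rr * (3.02994407707441961300e-2 +
                              rr * 1.26177193074810590878e-4));
  const double q = 2.00000000000000000005e0 +
    rr * (2.27265548208155028766e-1 +
          rr * (2.52448340349684104192e-3 +
                rr * 3.00198505138664455042e-6));
  return std::ldexp(1.0 + 2.0 * p / (q - p), (int)n);
}

// log(1 - p) for p in [0, 1): Maclaurin series below 0.01 (error < 2e-15),
// libm log1p above.
static inline double flog1mp(double p) {
  if (p < 0.01) {
    const double p2 = p * p;
    return -p - p2 * (0.5 + p * (1.0 / 3.0 + p * (0.25 + p * (0.2 + p / 6.0))));
  }
  return std::log1p(-p);
}

// Half-normal Bernoulli detection kernel sums for the SECR likelihood.
//
// d2:   K x M matrix of squared detector-to-mask-point distances (km^2),
//       K = detector x occasion rows, M = mask points.
// g0:   per-row detection probability at distance zero.
// inv2s2: per-row 1 / (2 sigma^2).
// occ:  per-row occasion index (1..S).
// detcols: 1-based rows of d2 for which log(p) and log(1-p) are returned
//       (the detector-occasions where detections actually occurred).
//
// Returns logQ (S x M): per-occasion sums of log(1 - p), plus LP / L1P
// ((length(detcols)) x M): log p and log(1 - p) at the requested rows.
// [[Rcpp::export]]
List secr_kernel_cpp(NumericMatrix d2, NumericVector g0,
                     NumericVector inv2s2, IntegerVector occ, int S,
                     IntegerVector detcols) {
  const int K = d2.nrow(), M = d2.ncol(), nd = detcols.size();
  NumericMatrix logQ(S, M), LP(nd, M), L1P(nd, M);
  std::vector<int> pos(K, -1);
  for (int j = 0; j < nd; ++j) pos[detcols[j] - 1] = j;
  for (int m = 0; m < M; ++m) {
    for (int k = 0; k < K; ++k) {
      const double e = d2(k, m) * inv2s2[k];
      const int j = pos[k];
      // exponent > 30 => p < 1e-13: negligible in log(1-p) sums; still
      // evaluated exactly at detected columns, where log(p) matters
      if (e > 30.0 && j < 0) continue;
      double p = g0[k] * fexp(-e);
      if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
      const double l1p = flog1mp(p);
      logQ(occ[k] - 1, m) += l1p;
      if (j >= 0) {
        LP(j, m) = std::log(p > 1e-300 ? p : 1e-300);
        L1P(j, m) = l1p;
      }
    }
  }
  return List::create(_["logQ"] = logQ, _["LP"] = LP, _["L1P"] = L1P);
}

// Single-pass likelihood evaluation for the common model class (no
// behavioural response, no finite mixture): returns per-animal
// log sum_m exp(logPr(omega_i | x_m) + r_m) via streaming log-sum-exp,
// plus G = sum_m exp(r_m) * pdot(x_m), where r is the density linear
// predictor without its intercept.
//
// detcol/detanimal: one entry per detection record (1-based row of d2 /
// animal index).
// [[Rcpp::export]]
List secr_fast_cpp(NumericMatrix d2, NumericVector g0, NumericVector inv2s2,
                   IntegerVector detcol, IntegerVector detanimal, int n,
                   NumericVector r) {
  const int K = d2.nrow(), M = d2.ncol(), R = detcol.size();
  std::vector<int> pos(K, -1);
  std::vector<int> uniq;
  for (int t = 0; t < R; ++t) {
    const int k = detcol[t] - 1;
    if (pos[k] < 0) { pos[k] = (int)uniq.size(); uniq.push_back(k); }
  }
  std::vector<double> pw(uniq.size());
  std::vector<double> acc(n), mx(n, R_NegInf), sm(n, 0.0);
  double G = 0.0;
  for (int m = 0; m < M; ++m) {
    double totQ = 0.0;
    for (int k = 0; k < K; ++k) {
      const double e = d2(k, m) * inv2s2[k];
      const int j = pos[k];
      if (e > 30.0 && j < 0) continue;
      double p = g0[k] * fexp(-e);
      if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
      const double l1p = flog1mp(p);
      totQ += l1p;
      if (j >= 0) pw[j] = std::log(p > 1e-300 ? p : 1e-300) - l1p;
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int t = 0; t < R; ++t)
      acc[detanimal[t] - 1] += pw[pos[detcol[t] - 1]];
    const double base = totQ + r[m];
    for (int i = 0; i < n; ++i) {
      const double v = base + acc[i];
      if (v <= mx[i]) sm[i] += fexp(v - mx[i]);
      else { sm[i] = sm[i] * fexp(mx[i] - v) + 1.0; mx[i] = v; }
    }
    G += fexp(r[m]) * (1.0 - fexp(totQ));
  }
  NumericVector Li(n);
  for (int i = 0; i < n; ++i) Li[i] = mx[i] + std::log(sm[i]);
  return List::create(_["Li"] = Li, _["G"] = G);
}

// Squared Euclidean distances between detector rows and mask points.
// [[Rcpp::export]]
NumericMatrix dist2_cpp(NumericVector dx, NumericVector dy,
                        NumericVector mx, NumericVector my) {
  const int K = dx.size(), M = mx.size();
  NumericMatrix out(K, M);
  for (int m = 0; m < M; ++m) {
    const double x = mx[m], y = my[m];
    for (int k = 0; k < K; ++k) {
      const double ddx = dx[k] - x, ddy = dy[k] - y;
      out(k, m) = ddx * ddx + ddy * ddy;
    }
  }
  return out;
}
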