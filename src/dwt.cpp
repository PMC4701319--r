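#include <Rcpp.h>
using namespace Rcpp;

// Orthogonal two-channel filter-bank kernels.
//
// Conventions (fixed, shared with the R layer):
//   analysis  a[k] = sum_m lo[m] * x[2k + m]   (correlation form)
//   synthesis x[i] = sum_k a[k] * lo[i - 2k] + d[k] * hi[i - 2k]
// so the synthesis filters equal the analysis filters. Two boundary rules:
//   periodic  - indices taken modulo n (n even); the transform matrix is
//               orthonormal for any even n (filters alias modulo n), giving
//               exact Parseval and perfect reconstruction.
//   symmetric - half-point reflection, f-1 samples each side; coefficients
//               are the subset of the infinite-signal analysis needed to
//               reconstruct the interior exactly, length floor((n+f-1)/2).

static inline int imod(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// [[Rcpp::export]]
List cpp_dwt_per(NumericVector x, NumericVector lo, NumericVector hi) {
  const int n = x.size(), f = lo.size();
  if (n % 2 != 0) stop("periodic mode requires even signal length");
  const int m = n / 2;
  NumericVector a(m), d(m);
  for (int k = 0; k < m; ++k) {
    double sa = 0.0, sd = 0.0;
    for (int j = 0; j < f; ++j) {
      const double xv = x[imod(2 * k + j, n)];
      sa += lo[j] * xv;
      sd += hi[j] * xv;
    }
    a[k] = sa; d[k] = sd;
  }
  return List::create(_["a"] = a, _["d"] = d);
}

// [[Rcpp::export]]
NumericVector cpp_idwt_per(NumericVector a, NumericVector d,
                           NumericVector lo, NumericVector hi) {
  const int m = a.size(), f = lo.size(), n = 2 * m;
  if (d.size() != m) stop("approximation/detail length mismatch");
  NumericVector x(n);
  for (int k = 0; k < m; ++k) {
    for (int j = 0; j < f; ++j) {
      x[imod(2 * k + j, n)] += a[k] * lo[j] + d[k] * hi[j];
    }
  }
  return x;
}

// [[Rcpp::export]]
List cpp_dwt_sym(NumericVector x, NumericVector lo, NumericVector hi) {
  const int n = x.size(), f = lo.size();
  if (n < f) stop("signal shorter than filter");
  const int e = f - 1;                       // extension on each side
  const int m = (n + f - 1) / 2;             // coefficient length
  std::vector<double> ext(n + 2 * e);
  for (int i = 0; i < e; ++i) ext[i] = x[e - 1 - i];          // reflect left
  for (int i = 0; i < n; ++i) ext[e + i] = x[i];
  for (int i = 0; i < e; ++i) ext[e + n + i] = x[n - 1 - i];  // reflect right
  NumericVector a(m), d(m);
  for (int k = 0; k < m; ++k) {
    const int t = 2 * k + 1;
    double sa = 0.0, sd = 0.0;
    for (int j = 0; j < f; ++j) {
      const double xv = ext[t + j];
      sa += lo[j] * xv;
      sd += hi[j] * xv;
    }
    a[k] = sa; d[k] = sd;
  }
  return List::create(_["a"] = a, _["d"] = d);
}

// [[Rcpp::export]]
NumericVector cpp_idwt_sym(NumericVector a, NumericVector d,
                           NumericVector lo, NumericVector hi, int out_len) {
  const int m = a.size(), f = lo.size();
  if (d.size() != m) stop("approximation/detail length mismatch");
  if (out_len > 2 * m - f + 2) stop("requested output longer than reconstructable");
  // c[s] = sum_j a[j] lo[s-2j] + d[j] hi[s-2j]; x[i] = c[i + f - 2]
  NumericVector x(out_len);
  for (int j = 0; j < m; ++j) {
    const int base = 2 * j - (f - 2);        // c index s = base + f - 2 maps to x index
    for (int t = 0; t < f; ++t) {
      const int i = base + t;
      if (i >= 0 && i < out_len) x[i] += a[j] * lo[t] + d[j] * hi[t];
    }
  }
  return x;
}

// ---- fast denoising path (used by the scoring loop) -----------------------
// Mirrors the R reference implementation denoise_epoch(): level-dependent
// MAD noise scale, SURE (or hybrid) soft threshold per detail level,
// approximation untouched.

static double mad_sigma(const std::vector<double>& v) {
  std::vector<double> a(v.size());
  for (size_t i = 0; i < v.size(); ++i) a[i] = std::fabs(v[i]);
  std::sort(a.begin(), a.end());
  const size_t n = a.size();
  const double med = (n % 2) ? a[n / 2] : 0.5 * (a[n / 2 - 1] + a[n / 2]);
  return med / 0.6745;
}

static double sure_thresh(const std::vector<double>& c, double sigma, bool hybrid) {
  const int n = (int)c.size();
  std::vector<double> z2(n);
  for (int i = 0; i < n; ++i) { const double z = c[i] / sigma; z2[i] = z * z; }
  std::sort(z2.begin(), z2.end());
  double cum = 0.0, best = R_PosInf, best_z2 = 0.0;
  int k = 0;
  while (k < n) {
    int k2 = k;                          // count of values <= z2[k] (handle ties)
    while (k2 + 1 < n && z2[k2 + 1] <= z2[k]) ++k2;
    double cum_k = cum;
    for (int j = k; j <= k2; ++j) cum_k += z2[j];
    const double risk = n - 2.0 * (k2 + 1) + cum_k + (double)(n - k2 - 1) * z2[k];
    if (risk < best) { best = risk; best_z2 = z2[k]; }
    cum = cum_k;
    k = k2 + 1;
  }
  double t = sigma * std::sqrt(best_z2);
  if (hybrid) {
    const double t_univ = sigma * std::sqrt(2.0 * std::log((double)n));
    double sum_z2 = 0.0;
    for (int i = 0; i < n; ++i) sum_z2 += z2[i];
    const double eta = (sum_z2 - n) / n;
    const double crit = std::pow(std::log2((double)n), 1.5) / std::sqrt((double)n);
    t = (eta < crit) ? t_univ : std::min(t, t_univ);
  }
  return t;
}

static void soft_inplace(std::vector<double>& v, double t) {
  for (size_t i = 0; i < v.size(); ++i) {
    const double a = std::fabs(v[i]) - t;
    v[i] = (a > 0.0) ? ((v[i] > 0.0) ? a : -a) : 0.0;
  }
}

static void dwt_step_vec(const std::vector<double>& x, const NumericVector& lo,
                         const NumericVector& hi, bool periodic,
                         std::vector<double>& a, std::vector<double>& d) {
  const int n = (int)x.size(), f = lo.size();
  if (periodic) {
    const int m = n / 2;
    a.assign(m, 0.0); d.assign(m, 0.0);
    for (int k = 0; k < m; ++k) {
      double sa = 0.0, sd = 0.0;
      for (int j = 0; j < f; ++j) {
        const double xv = x[imod(2 * k + j, n)];
        sa += lo[j] * xv; sd += hi[j] * xv;
      }
      a[k] = sa; d[k] = sd;
    }
  } else {
    const int e = f - 1, m = (n + f - 1) / 2;
    std::vector<double> ext(n + 2 * e);
    for (int i = 0; i < e; ++i) ext[i] = x[e - 1 - i];
    for (int i = 0; i < n; ++i) ext[e + i] = x[i];
    for (int i = 0; i < e; ++i) ext[e + n + i] = x[n - 1 - i];
    a.assign(m, 0.0); d.assign(m, 0.0);
    for (int k = 0; k < m; ++k) {
      const int t = 2 * k + 1;
      double sa = 0.0, sd = 0.0;
      for (int j = 0; j < f; ++j) {
        const double xv = ext[t + j];
        sa += lo[j] * xv; sd += hi[j] * xv;
      }
      a[k] = sa; d[k] = sd;
    }
  }
}

static std::vector<double> idwt_step_vec(const std::vector<double>& a,
                                         const std::vector<double>& d,
                                         const NumericVector& lo,
                                         const NumericVector& hi,
                                         bool periodic, int out_len) {
  const int m = (int)a.size(), f = lo.size();
  std::vector<double> x(periodic ? 2 * m : out_len, 0.0);
  if (periodic) {
    const int n = 2 * m;
    for (int k = 0; k < m; ++k) {
      for (int j = 0; j < f; ++j) {
        x[imod(2 * k + j, n)] += a[k] * lo[j] + d[k] * hi[j];
      }
    }
    x.resize(out_len);
  } else {
    for (int j = 0; j < m; ++j) {
      const int base = 2 * j - (f - 2);
      for (int t = 0; t < f; ++t) {
        const int i = base + t;
        if (i >= 0 && i < out_len) x[i] += a[j] * lo[t] + d[j] * hi[t];
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_denoise_epoch(NumericVector x, NumericVector lo,
                                NumericVector hi, int levels, bool periodic,
                                bool zero_d1, bool hybrid) {
  std::vector<double> a(x.begin(), x.end());
  std::vector<std::vector<double> > dets(levels);
  std::vector<int> lens(levels);
  for (int k = 0; k < levels; ++k) {
    lens[k] = (int)a.size();
    std::vector<double> na, nd;
    dwt_step_vec(a, lo, hi, periodic, na, nd);
    dets[k] = nd;
    a = na;
  }
  for (int k = 0; k < levels; ++k) {
    const double s = mad_sigma(dets[k]);
    if (s > 0.0) soft_inplace(dets[k], sure_thresh(dets[k], s, hybrid));
  }
  if (zero_d1) std::fill(dets[0].begin(), dets[0].end(), 0.0);
  for (int k = levels - 1; k >= 0; --k) {
    a = idwt_step_vec(a, dets[k], lo, hi, periodic, lens[k]);
  }
  return NumericVector(a.begin(), a.end());
}
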