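#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fuzzy approximate entropy kernel.
//
// Template vectors of length m (delay d) are baseline-removed: each vector has
// its own mean subtracted before comparison. Similarity between two templates
// is a Gaussian membership exp(-dist^2 / (2 r^2)) of their Chebyshev distance,
// and phi^m(r) is the mean over templates of the log mean membership.
// fApEn(m, r) = phi^m(r) - phi^{m+1}(r), with r = k * sd(series) shared by
// both phi terms. Self-matches (j == i) are included by default, matching the
// printed sums; excluding them is an option.

namespace {

double sample_sd(const double* x, int n) {
  if (n < 2) return 0.0;
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - mu;
    ss += d * d;
  }
  return std::sqrt(ss / (n - 1));
}

double rms_raw(const double* x, int n) {
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += x[i] * x[i];
  return std::sqrt(ss / n);
}

// phi^m(r); returns NA if fewer than 2 template vectors fit.
double phi_raw(const double* x, int N, int m, double r, int delay,
               bool exclude_self) {
  int n = N - (m - 1) * delay;  // number of template vectors
  if (n < 2 || m < 1) return NA_REAL;
  std::vector<double> tmpl((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    double mu = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k * delay];
    mu /= m;
    for (int k = 0; k < m; ++k)
      tmpl[(size_t)i * m + k] = x[i + k * delay] - mu;
  }
  const double inv2r2 = 1.0 / (2.0 * r * r);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* ti = &tmpl[(size_t)i * m];
    double ci = 0.0;
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (exclude_self && j == i) continue;
      const double* tj = &tmpl[(size_t)j * m];
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(ti[k] - tj[k]);
        if (a > d) d = a;
      }
      ci += std::exp(-d * d * inv2r2);
      ++cnt;
    }
    acc += std::log(ci / cnt);
  }
  return acc / n;
}

double fapen_given_r(const double* x, int N, int m, double r, int delay,
                     bool exclude_self) {
  double p1 = phi_raw(x, N, m, r, delay, exclude_self);
  double p2 = phi_raw(x, N, m + 1, r, delay, exclude_self);
  if (ISNAN(p1) || ISNAN(p2)) return NA_REAL;
  return p1 - p2;
}

double tol_r(const double* x, int N, double k, double r_floor) {
  double r = k * sample_sd(x, N);
  if (r < r_floor) r = r_floor;
  return r;
}

// E_X and E_Y per scale; dims m*s and m*s + 1 respectively, shared r.
void scale_entropies_raw(const double* x, int N, int m,
                         const int* scales, int ns, double r, int delay,
                         bool exclude_self, double* EX, double* EY) {
  for (int s = 0; s < ns; ++s) {
    int dim = m * scales[s];
    double ex = fapen_given_r(x, N, dim, r, delay, exclude_self);
    double ey = fapen_given_r(x, N, dim + 1, r, delay, exclude_self);
    if (ISNAN(ex) || ISNAN(ey))
      stop("series too short (N = %d) for scale %d (needs N >= %d)", N,
           scales[s], dim + 3);
    EX[s] = ex;
    EY[s] = ey;
  }
}

double mfapen_raw(const double* x, int N, int m, const int* scales, int ns,
                  double k, double eps, int delay, double r_floor,
                  bool exclude_self, bool literal) {
  std::vector<double> EX(ns), EY(ns);
  double r = tol_r(x, N, k, r_floor);
  scale_entropies_raw(x, N, m, scales, ns, r, delay, exclude_self,
                      EX.data(), EY.data());
  double acc = 0.0;
  for (int s = 0; s < ns; ++s) {
    // entropy estimates are nonnegative in expectation; clamp the
    // occasional negative finite-sample estimate so the log stays defined
    double ey = EY[s] > 0 ? EY[s] : 0.0;
    double ex = EX[s] > 0 ? EX[s] : 0.0;
    double denom = literal ? (ey + eps) : (ex + eps);
    acc += ey * std::log((ey + eps) / denom);
  }
  return -acc / ns;
}

}  // namespace

// [[Rcpp::export]]
double cpp_phi(NumericVector x, int m, double r, int delay, bool exclude_self) {
  if (m < 1) stop("embedding dimension must be >= 1");
  if (r <= 0) stop("tolerance r must be > 0");
  if (delay < 1) stop("delay must be >= 1");
  double v = phi_raw(REAL(x), x.size(), m, r, delay, exclude_self);
  if (ISNAN(v))
    stop("fewer than 2 template vectors for dimension %d (series length %d)",
         m, (int)x.size());
  return v;
}

// [[Rcpp::export]]
double cpp_fapen(NumericVector x, int m, double k, int delay, double r_floor,
                 bool exclude_self) {
  if (m < 1) stop("embedding dimension must be >= 1");
  double r = tol_r(REAL(x), x.size(), k, r_floor);
  double v = fapen_given_r(REAL(x), x.size(), m, r, delay, exclude_self);
  if (ISNAN(v))
    stop("series length %d too short for dimension %d (needs >= %d)",
         (int)x.size(), m, m + 2);
  return v;
}

// [[Rcpp::export]]
List cpp_scale_entropies(NumericVector x, int m, IntegerVector scales,
                         double k, int delay, double r_floor,
                         bool exclude_self) {
  int ns = scales.size();
  NumericVector EX(ns), EY(ns);
  double r = tol_r(REAL(x), x.size(), k, r_floor);
  scale_entropies_raw(REAL(x), x.size(), m, INTEGER(scales), ns, r, delay,
                      exclude_self, REAL(EX), REAL(EY));
  return List::create(_["EX"] = EX, _["EY"] = EY, _["r"] = r);
}

// [[Rcpp::export]]
double cpp_mfapen(NumericVector x, int m, IntegerVector scales, double k,
                  double eps, int delay, double r_floor, bool exclude_self,
                  bool literal) {
  return mfapen_raw(REAL(x), x.size(), m, INTEGER(scales), scales.size(), k,
                    eps, delay, r_floor, exclude_self, literal);
}

// Windowed batch extraction: slide an inner window of w samples (stride
// `stride`) over each row of `seg` (channels x L) and emit
// MfApEn + RMS per position.  For L = 100, w = 10, stride = 1 this yields
// 91 values per channel.
// [[Rcpp::export]]
NumericMatrix cpp_mfaren_features(NumericMatrix seg, int w, int stride, int m,
                                  IntegerVector scales, double k, double eps,
                                  int delay, double r_floor, bool exclude_self,
                                  bool literal) {
  int nch = seg.nrow(), L = seg.ncol();
  if (w > L) stop("inner window (%d) longer than segment (%d)", w, L);
  if (stride < 1) stop("stride must be >= 1");
  int F = (L - w) / stride + 1;
  NumericMatrix out(nch, F);
  std::vector<double> buf(w);
  for (int c = 0; c < nch; ++c) {
    for (int f = 0; f < F; ++f) {
      int start = f * stride;
      for (int t = 0; t < w; ++t) buf[t] = seg(c, start + t);
      double mf = mfapen_raw(buf.data(), w, m, INTEGER(scales), scales.size(),
                             k, eps, delay, r_floor, exclude_self, literal);
      out(c, f) = mf + rms_raw(buf.data(), w);
    }
  }
  return out;
}
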