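#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Epoch cubes are trial x channel x sample arrays stored in R's column-major
// order: index = t + T*(c + C*s). Lags are in samples; a trial's component
// occurs at sample (reference + lag), so aligning a trial to the reference
// means reading the trial at (s + lag).

static inline double read_interp(const double *x, int t, int c, int T, int C,
                                 int S, double pos, bool &ok) {
  if (pos < 0.0 || pos > S - 1.0) { ok = false; return 0.0; }
  ok = true;
  int p0 = (int)std::floor(pos);
  double fr = pos - p0;
  double v0 = x[t + T * (c + C * p0)];
  if (fr == 0.0) return v0;
  double v1 = x[t + T * (c + C * (p0 + 1))];
  return v0 + fr * (v1 - v0);
}

// Pointwise median across trials after aligning each trial by its lag.
// Out-of-range samples are excluded from the median; all-missing points
// (and trials with use[t] == 0) give 0.
// [[Rcpp::export]]
NumericMatrix cpp_align_median(NumericVector data, NumericVector lags,
                               LogicalVector use) {
  IntegerVector dim = data.attr("dim");
  int T = dim[0], C = dim[1], S = dim[2];
  const double *x = REAL(data);
  NumericMatrix out(C, S);
  std::vector<double> buf(T);
  for (int s = 0; s < S; s++) {
    for (int c = 0; c < C; c++) {
      int k = 0;
      for (int t = 0; t < T; t++) {
        if (!use[t]) continue;
        bool ok;
        double v = read_interp(x, t, c, T, C, S, s + lags[t], ok);
        if (ok) buf[k++] = v;
      }
      double med = 0.0;
      if (k > 0) {
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        med = buf[k / 2];
        if (k % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
          med = 0.5 * (med + lo);
        }
      }
      out(c, s) = med;
    }
  }
  return out;
}

// Subtract a component waveform, placed at each trial's lag, from every
// trial: out[t,c,s] = data[t,c,s] - comp[c, s - lag_t] (zero outside).
// Trials with use[t] == 0 are left untouched.
// [[Rcpp::export]]
NumericVector cpp_subtract_aligned(NumericVector data, NumericMatrix comp,
                                   NumericVector lags, LogicalVector use) {
  IntegerVector dim = data.attr("dim");
  int T = dim[0], C = dim[1], S = dim[2];
  NumericVector out = clone(data);
  double *y = REAL(out);
  int CS = comp.nrow();
  int SS = comp.ncol();
  for (int t = 0; t < T; t++) {
    if (!use[t]) continue;
    double lag = lags[t];
    for (int s = 0; s < S; s++) {
      double pos = s - lag;
      if (pos < 0.0 || pos > SS - 1.0) continue;
      int p0 = (int)std::floor(pos);
      double fr = pos - p0;
      for (int c = 0; c < CS; c++) {
        double v0 = comp(c, p0);
        double v = (fr == 0.0) ? v0 : v0 + fr * (comp(c, p0 + 1) - v0);
        y[t + T * (c + C * s)] -= v;
      }
    }
  }
  return out;
}

// Mean over trials of the component placed at each trial's lag (zero
// outside its support); the single-subject model of what latency-varying
// components contribute to a conventional average.
// [[Rcpp::export]]
NumericMatrix cpp_place_mean(NumericMatrix comp, NumericVector lags,
                             int n_out) {
  int C = comp.nrow(), S = comp.ncol();
  int T = lags.size();
  NumericMatrix out(C, n_out);
  if (T == 0) return out;
  for (int t = 0; t < T; t++) {
    double lag = lags[t];
    for (int s = 0; s < n_out; s++) {
      double pos = s - lag;
      if (pos < 0.0 || pos > S - 1.0) continue;
      int p0 = (int)std::floor(pos);
      double fr = pos - p0;
      for (int c = 0; c < C; c++) {
        double v0 = comp(c, p0);
        double v = (fr == 0.0) ? v0 : v0 + fr * (comp(c, p0 + 1) - v0);
        out(c, s) += v;
      }
    }
  }
  for (int i = 0; i < C * n_out; i++) out[i] /= T;
  return out;
}

// Channel-summed cross-correlation latency search. For each trial the
// template (restricted to sample columns [lo, hi]) is slid over lags
// base_lag[t] + L, L in [lmin, lmax]; the lag curve is smoothed with a
// centered moving average of half-width smooth_hw samples and the argmax
// taken, ties broken toward the smallest |L|. Returns per-trial L (samples,
// relative to base_lag). Trials with use[t]==0 get 0.
//
// With prior_w > 0 the smoothed curve is standardized (divided by its SD)
// and a quadratic penalty prior_w * ((base+L-prior)/prior_scale)^2 is
// subtracted: a maximum-a-posteriori variant in which an informative peak
// overrides the penalty while a flat, noise-only curve yields an estimate
// near the prior latency.
// [[Rcpp::export]]
NumericVector cpp_best_lags(NumericVector data, NumericMatrix comp, int lo,
                            int hi, NumericVector base_lags, int lmin,
                            int lmax, int smooth_hw, LogicalVector use,
                            NumericVector prior_lags =
                                NumericVector::create(),
                            double prior_w = 0.0,
                            double prior_scale = 1.0) {
  IntegerVector dim = data.attr("dim");
  int T = dim[0], C = dim[1], S = dim[2];
  const double *x = REAL(data);
  int nl = lmax - lmin + 1;
  std::vector<double> r(nl), rs(nl);
  NumericVector best(T);
  for (int t = 0; t < T; t++) {
    if (!use[t]) { best[t] = 0.0; continue; }
    double base = base_lags[t];
    for (int li = 0; li < nl; li++) {
      double lag = base + (lmin + li);
      double acc = 0.0;
      for (int s = lo; s <= hi; s++) {
        double pos = s + lag;
        if (pos < 0.0 || pos > S - 1.0) continue;
        int p0 = (int)std::floor(pos);
        double fr = pos - p0;
        for (int c = 0; c < C; c++) {
          double v0 = x[t + T * (c + C * p0)];
          double v = (fr == 0.0)
                         ? v0
                         : v0 + fr * (x[t + T * (c + C * (p0 + 1))] - v0);
          acc += v * comp(c, s);
        }
      }
      r[li] = acc;
    }
    if (smooth_hw > 0) {
      for (int li = 0; li < nl; li++) {
        int a = std::max(0, li - smooth_hw);
        int b = std::min(nl - 1, li + smooth_hw);
        double s = 0.0;
        for (int j = a; j <= b; j++) s += r[j];
        rs[li] = s / (b - a + 1);
      }
    } else {
      rs = r;
    }
    if (prior_w > 0.0 && prior_lags.size() == T) {
      double mu = 0.0, s2 = 0.0;
      for (int li = 0; li < nl; li++) mu += rs[li];
      mu /= nl;
      for (int li = 0; li < nl; li++) s2 += (rs[li] - mu) * (rs[li] - mu);
      double sdv = std::sqrt(s2 / std::max(1, nl - 1));
      if (sdv > 0) {
        for (int li = 0; li < nl; li++) {
          double dev = (base + (lmin + li) - prior_lags[t]) / prior_scale;
          rs[li] = rs[li] / sdv - prior_w * dev * dev;
        }
      }
    }
    int bi = 0;
    for (int li = 1; li < nl; li++) {
      double d = rs[li] - rs[bi];
      if (d > 1e-12) {
        bi = li;
      } else if (d >= -1e-12 &&
                 std::abs(lmin + li) < std::abs(lmin + bi)) {
        bi = li;
      }
    }
    best[t] = lmin + bi;
  }
  return best;
}

// ---- zero-phase IIR filtering -------------------------------------------

static void filt_zero_state(const std::vector<double> &b,
                            const std::vector<double> &a,
                            std::vector<double> &x) {
  int n = (int)b.size();
  int m = n - 1;
  std::vector<double> z(m, 0.0);
  for (size_t i = 0; i < x.size(); i++) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int k = 0; k < m - 1; k++)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    if (m > 0) z[m - 1] = b[m] * xi - a[m] * yi;
    x[i] = yi;
  }
}

// Forward-backward filtering of each row of X (zero phase, squared
// magnitude): forward pass over the row extended with 2*(order+1) zeros,
// then a reverse pass, mirroring the classic two-pass recursive scheme.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_rows(NumericVector bv, NumericVector av,
                                NumericMatrix X) {
  std::vector<double> b(bv.begin(), bv.end()), a(av.begin(), av.end());
  if (a.size() < b.size()) a.resize(b.size(), 0.0);
  if (b.size() < a.size()) b.resize(a.size(), 0.0);
  if (a[0] != 1.0) {
    double a0 = a[0];
    for (size_t i = 0; i < a.size(); i++) a[i] /= a0;
    for (size_t i = 0; i < b.size(); i++) b[i] /= a0;
  }
  int n = X.ncol(), nr = X.nrow();
  int npad = 2 * (int)a.size();
  NumericMatrix out(nr, n);
  std::vector<double> ext(n + npad);
  for (int r = 0; r < nr; r++) {
    for (int i = 0; i < n; i++) ext[i] = X(r, i);
    for (int i = 0; i < npad; i++) ext[n + i] = 0.0;
    filt_zero_state(b, a, ext);
    std::reverse(ext.begin(), ext.end());
    filt_zero_state(b, a, ext);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < n; i++) out(r, i) = ext[i];
  }
  return out;
}

// Minimum peak-to-peak range over all sliding windows of w samples
// (stepped by one sample); the flat-line detector primitive.
// [[Rcpp::export]]
double cpp_min_window_range(NumericVector x, int w) {
  int n = x.size();
  if (w > n) w = n;
  double best = R_PosInf;
  for (int i = 0; i + w <= n; i++) {
    double mn = x[i], mx = x[i];
    for (int j = 1; j < w; j++) {
      double v = x[i + j];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    double rg = mx - mn;
    if (rg < best) best = rg;
  }
  return best;
}
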