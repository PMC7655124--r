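#include <Rcpp.h>
#include <fftw3.h>
#include <algorithm>
#include <complex>
#include <functional>
#include <map>
#include <vector>

using namespace Rcpp;

// Per-band suprathreshold interval extraction for the HFO detector.
//
// X:  FFT of the mirror-padded channel (length nfft); n: unpadded length.
// For each band: heterodyne the band's Gaussian spectral support to
// baseband, inverse-transform at a reduced length m (m divides nfft, so the
// decimated samples coincide with every (nfft/m)-th full-rate sample), take
// the analytic amplitude, z-score it in consecutive statistical windows
// (final partial window reuses the last full window's statistics), and emit
// maximal runs above the threshold with linearly interpolated crossing
// times. Mirrors the R reference path (band_envelope_dec + zscore_windows +
// supra_runs); equivalence is asserted in the test suite.

namespace {

struct PlanCache {
  std::map<int, fftw_plan> plans;
  std::map<int, fftw_complex*> bufs;
  fftw_complex* buffer(int m) {
    auto it = bufs.find(m);
    if (it != bufs.end()) return it->second;
    fftw_complex* b = fftw_alloc_complex(m);
    bufs[m] = b;
    return b;
  }
  fftw_plan plan(int m) {
    auto it = plans.find(m);
    if (it != plans.end()) return it->second;
    fftw_complex* b = buffer(m);
    // MEASURE planning amortizes across channels: fftw wisdom is retained
    // process-wide, so repeated sizes re-plan in microseconds
    fftw_plan p = fftw_plan_dft_1d(m, b, b, FFTW_BACKWARD, FFTW_MEASURE);
    plans[m] = p;
    return p;
  }
  ~PlanCache() {
    for (auto& kv : plans) fftw_destroy_plan(kv.second);
    for (auto& kv : bufs) fftw_free(kv.second);
  }
};

int smooth_divisor_of(int nfft, int bound) {
  int best = 1;
  long p2 = 1, p3 = 1, p5 = 1;
  while (nfft % (p2 * 2) == 0) p2 *= 2;
  while (nfft % (p3 * 3) == 0) p3 *= 3;
  while (nfft % (p5 * 5) == 0) p5 *= 5;
  for (long d2 = 1; d2 <= p2; d2 *= 2)
    for (long d3 = 1; d3 <= p3; d3 *= 3)
      for (long d5 = 1; d5 <= p5; d5 *= 5) {
        long d = d2 * d3 * d5;
        if (d <= bound && d > best) best = (int)d;
      }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".hfo_band_intervals")]]
DataFrame hfo_band_intervals(const ComplexVector& X, int nfft, double fs,
                             int n, const NumericVector& centers,
                             const NumericVector& sigmas,
                             double stat_window_s, double z_threshold,
                             double truncate_sd, double rate_mult) {
  PlanCache cache;
  std::vector<int> out_band;
  std::vector<double> out_ts, out_te, out_zmax, out_tpeak;
  const double df = fs / nfft;
  const double t_total = n / fs;
  std::vector<double> env;

  for (int b = 0; b < centers.size(); ++b) {
    const double fc = centers[b], sg = sigmas[b];
    int k1 = std::max(1, (int)std::floor((fc - truncate_sd * sg) / df));
    int k2 = std::min(nfft / 2 - 1,
                      (int)std::ceil((fc + truncate_sd * sg) / df));
    int need = std::max(k2 - k1 + 1,
                        std::max((int)std::ceil(rate_mult * sg / df), 64));
    int m = nfft / smooth_divisor_of(nfft, nfft / need);
    // plan BEFORE filling: FFTW_MEASURE planning overwrites the buffer
    fftw_plan pl = cache.plan(m);
    fftw_complex* y = cache.buffer(m);
    std::fill(&y[0][0], &y[0][0] + 2 * (size_t)m, 0.0);
    for (int k = k1; k <= k2; ++k) {
      double g = 2.0 * std::exp(-0.5 * std::pow((k * df - fc) / sg, 2));
      int p = k % m;
      y[p][0] += g * X[k].r;
      y[p][1] += g * X[k].i;
    }
    fftw_execute(pl);
    double fs_env = fs * (double)m / nfft;
    int n_env = std::min(m, (int)std::ceil(t_total * fs_env));
    env.resize(n_env);
    const double scale2 = 1.0 / ((double)nfft * nfft);
    for (int i = 0; i < n_env; ++i) {
      env[i] = std::sqrt(scale2 * (y[i][0] * y[i][0] + y[i][1] * y[i][1]));
    }

    // per-window mean/SD; threshold applied as env > mu + z_threshold * sd
    int w = std::max(2, (int)std::lround(stat_window_s * fs_env));
    int kwin = n_env / w;
    if (kwin < 1) stop("signal shorter than one statistical window");
    std::vector<double> mu(kwin), sdv(kwin);
    for (int j = 0; j < kwin; ++j) {
      double s1 = 0;
      for (int i = j * w; i < (j + 1) * w; ++i) s1 += env[i];
      mu[j] = s1 / w;
      double s2 = 0;
      for (int i = j * w; i < (j + 1) * w; ++i) {
        s2 += (env[i] - mu[j]) * (env[i] - mu[j]);
      }
      sdv[j] = std::sqrt(s2 / (w - 1));
      if (sdv[j] == 0) sdv[j] = R_PosInf;
    }
    auto zat = [&](int i) {
      int j = std::min(i / w, kwin - 1);
      return (env[i] - mu[j]) / sdv[j];
    };

    // maximal runs above threshold, boundaries refined by interpolation
    int i = 0;
    while (i < n_env) {
      int j = std::min(i / w, kwin - 1);
      double thr = mu[j] + z_threshold * sdv[j];
      if (env[i] > thr) {
        int s = i;
        while (i < n_env && zat(i) > z_threshold) ++i;
        int e = i - 1;  // inclusive
        double ts = (double)s / fs_env;
        if (s > 0) {
          double z0 = zat(s - 1), z1 = zat(s);
          ts = (s - 1 + (z_threshold - z0) / (z1 - z0)) / fs_env;
        }
        double te = (double)(e + 1) / fs_env;
        if (e < n_env - 1) {
          double z0 = zat(e), z1 = zat(e + 1);
          te = (e + (z0 - z_threshold) / (z0 - z1)) / fs_env;
        }
        double zm = zat(s); int jm = s;
        for (int jj = s + 1; jj <= e; ++jj) {
          double zj = zat(jj);
          if (zj > zm) { zm = zj; jm = jj; }
        }
        out_band.push_back(b + 1);
        out_ts.push_back(ts);
        out_te.push_back(te);
        out_zmax.push_back(zm);
        out_tpeak.push_back((double)jm / fs_env);
      } else {
        ++i;
      }
    }
  }
  return DataFrame::create(_["band"] = out_band, _["t_start"] = out_ts,
                           _["t_end"] = out_te, _["z_max"] = out_zmax,
                           _["t_peak"] = out_tpeak);
}

// Connected-component labels for (band, interval) nodes: edges connect
// temporally overlapping (half-open) intervals in adjacent bands. Same
// semantics as the R reference join; returns 1-based component ids in
// first-occurrence order over the input rows.
// [[Rcpp::export(name = ".join_interval_components")]]
IntegerVector join_interval_components(const IntegerVector& band,
                                       const NumericVector& t_start,
                                       const NumericVector& t_end) {
  const int n = band.size();
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (band[a] != band[b]) return band[a] < band[b];
    return t_start[a] < t_start[b];
  });
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  auto unite = [&](int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
  };
  // sweep adjacent band pairs
  int i = 0;
  while (i < n) {
    int b0 = band[ord[i]];
    int j = i;
    while (j < n && band[ord[j]] == b0) ++j;  // [i, j) = band b0
    int k = j;
    if (k < n && band[ord[k]] == b0 + 1) {
      int kEnd = k;
      while (kEnd < n && band[ord[kEnd]] == b0 + 1) ++kEnd;
      int a = i, c = k;
      while (a < j && c < kEnd) {
        int ia = ord[a], ic = ord[c];
        if (t_start[ia] < t_end[ic] && t_start[ic] < t_end[ia]) {
          unite(ia, ic);
        }
        if (t_end[ia] <= t_end[ic]) ++a; else ++c;
      }
    }
    i = j;
  }
  std::map<int, int> relabel;
  int next = 1;
  for (int r = 0; r < n; ++r) {
    int root = find(r);
    auto it = relabel.find(root);
    if (it == relabel.end()) {
      relabel[root] = next;
      out[r] = next;
      ++next;
    } else {
      out[r] = it->second;
    }
  }
  return out;
}
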