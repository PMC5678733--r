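#include <Rcpp.h>
using namespace Rcpp;

// Per-target-unit weighted sums ("projection drive").
//
// Units live on an nc x nc grid; the presynaptic activity `field` may be a
// larger sheet (retina/LGN) or the cortical sheet itself. Unit (ui, uj)
// (0-based) has its window centred at field coordinates
// (ui + offset, uj + offset) with half-width `half`. Weights W are K^2 x N
// with K = 2*half+1, entries ordered column-major over (di fastest, dj), and
// unit index u = uj*nc + ui (matching as.vector() of an nc x nc matrix).
// Field pixels outside the sheet contribute zero activity.
// [[Rcpp::export]]
NumericVector proj_drive(const NumericMatrix field, const NumericMatrix W,
                         const int nc, const int half, const int offset) {
  const int K = 2 * half + 1;
  const int fr = field.nrow(), fc = field.ncol();
  NumericVector out(nc * nc);
  for (int uj = 0; uj < nc; ++uj) {
    const int cj = uj + offset;
    const int dj_lo = std::max(-half, -cj);
    const int dj_hi = std::min(half, fc - 1 - cj);
    for (int ui = 0; ui < nc; ++ui) {
      const int ci = ui + offset;
      const int di_lo = std::max(-half, -ci);
      const int di_hi = std::min(half, fr - 1 - ci);
      const int len = di_hi - di_lo + 1;
      const double* w = &W(0, uj * nc + ui);
      double s = 0.0;
      for (int dj = dj_lo; dj <= dj_hi; ++dj) {
        const double* wc = w + (dj + half) * K + (di_lo + half);
        const double* fp = &field(ci + di_lo, cj + dj);
        double s0 = 0.0, s1 = 0.0;
        int t = 0;
        for (; t + 1 < len; t += 2) {
          s0 += wc[t] * fp[t];
          s1 += wc[t + 1] * fp[t + 1];
        }
        if (t < len) s0 += wc[t] * fp[t];
        s += s0 + s1;
      }
      out[uj * nc + ui] = s;
    }
  }
  return out;
}

// In-place normalized Hebbian update (divisive postsynaptic normalization)
// of one projection: w <- (w + eta * y * P) / sum(w + eta * y * P).
// `mask` marks the circular support; entries off the mask stay zero.
// Columns with zero postsynaptic rate are untouched (their sum is already
// 1); a column whose normalizer would be zero is left unchanged.
// Returns the number of columns skipped for a zero normalizer.
// [[Rcpp::export]]
int hebbian_window(NumericMatrix W, const LogicalVector mask,
                   const NumericVector post, const NumericMatrix field,
                   const int nc, const int half, const int offset,
                   const double eta) {
  const int K = 2 * half + 1;
  const int KK = K * K;
  const int fr = field.nrow(), fc = field.ncol();
  int skipped = 0;
  for (int uj = 0; uj < nc; ++uj) {
    const int cj = uj + offset;
    for (int ui = 0; ui < nc; ++ui) {
      const int u = uj * nc + ui;
      const double y = post[u];
      if (y <= 0.0) continue;
      const int ci = ui + offset;
      double* w = &W(0, u);
      double tot = 0.0;
      for (int dj = -half; dj <= half; ++dj) {
        const int fj = cj + dj;
        const bool okj = fj >= 0 && fj < fc;
        double* wc = w + (dj + half) * K;
        for (int di = -half; di <= half; ++di) {
          const int k = (dj + half) * K + di + half;
          if (!mask[k]) continue;
          const int fi = ci + di;
          if (okj && fi >= 0 && fi < fr) {
            const double p = field(fi, fj);
            if (p > 0.0) wc[di + half] += eta * y * p;
          }
          tot += wc[di + half];
        }
      }
      if (tot <= 0.0) { ++skipped; continue; }
      const double inv = 1.0 / tot;
      for (int k = 0; k < KK; ++k)
        if (mask[k]) w[k] *= inv;
    }
  }
  return skipped;
}

// Joint Hebbian update of the paired ON/OFF afferent projections with a
// single divisive normalization across both banks (standard LISSOM
// practice, so the ON/OFF balance is free to differentiate).
// [[Rcpp::export]]
int hebbian_window_pair(NumericMatrix Won, NumericMatrix Woff,
                        const LogicalVector mask, const NumericVector post,
                        const NumericMatrix fon, const NumericMatrix foff,
                        const int nc, const int half, const int offset,
                        const double eta) {
  const int K = 2 * half + 1;
  const int KK = K * K;
  const int fr = fon.nrow(), fc = fon.ncol();
  int skipped = 0;
  for (int uj = 0; uj < nc; ++uj) {
    const int cj = uj + offset;
    for (int ui = 0; ui < nc; ++ui) {
      const int u = uj * nc + ui;
      const double y = post[u];
      if (y <= 0.0) continue;
      const int ci = ui + offset;
      double* won = &Won(0, u);
      double* woff = &Woff(0, u);
      double tot = 0.0;
      for (int dj = -half; dj <= half; ++dj) {
        const int fj = cj + dj;
        const bool okj = fj >= 0 && fj < fc;
        for (int di = -half; di <= half; ++di) {
          const int k = (dj + half) * K + di + half;
          if (!mask[k]) continue;
          const int fi = ci + di;
          if (okj && fi >= 0 && fi < fr) {
            won[k]  += eta * y * fon(fi, fj);
            woff[k] += eta * y * foff(fi, fj);
          }
          tot += won[k] + woff[k];
        }
      }
      if (tot <= 0.0) { ++skipped; continue; }
      const double inv = 1.0 / tot;
      for (int k = 0; k < KK; ++k)
        if (mask[k]) { won[k] *= inv; woff[k] *= inv; }
    }
  }
  return skipped;
}

// In-place BCM update of the lateral excitatory projection with
// astrocyte-set thresholds: dE = eta * y_post * (y_post - theta) * y_pre,
// clipped to [0, emax]. Synapses whose presynaptic partner lies within
// `r2_near` (squared pixel distance) of the target sit inside the target's
// astrocyte domain and see theta = theta[u]; synapses from beyond it see
// theta = theta_far (1 = no astrocytic coverage: coactivity depresses and
// the connection is pruned). Passing r2_near = Inf recovers the node-global
// rule. No renormalization here (the trainer's mass ceiling bounds growth).
// [[Rcpp::export]]
void bcm_window(NumericMatrix E, const LogicalVector mask,
                const NumericVector post, const NumericVector theta,
                const NumericMatrix yfield, const int nc, const int half,
                const double eta, const double emax, const double r2_near,
                const double theta_far) {
  const int K = 2 * half + 1;
  const int fr = yfield.nrow(), fc = yfield.ncol();
  for (int uj = 0; uj < nc; ++uj) {
    for (int ui = 0; ui < nc; ++ui) {
      const int u = uj * nc + ui;
      const double y = post[u];
      if (y <= 0.0) continue;
      const double gain_near = eta * y * (y - theta[u]);
      const double gain_far = eta * y * (y - theta_far);
      if (gain_near == 0.0 && gain_far == 0.0) continue;
      double* e = &E(0, u);
      for (int dj = -half; dj <= half; ++dj) {
        const int fj = uj + dj;
        if (fj < 0 || fj >= fc) continue;
        for (int di = -half; di <= half; ++di) {
          const int k = (dj + half) * K + di + half;
          if (!mask[k]) continue;
          const int fi = ui + di;
          if (fi < 0 || fi >= fr) continue;
          const double p = yfield(fi, fj);
          if (p == 0.0) continue;
          const double g = ((double)(di * di + dj * dj) <= r2_near)
                             ? gain_near : gain_far;
          double v = e[k] + g * p;
          if (v < 0.0) v = 0.0; else if (v > emax) v = emax;
          e[k] = v;
        }
      }
    }
  }
}

// Disc pooling: out(i,j) = sum of field over all nodes within Euclidean
// pixel distance `radius_px` of (i,j). The centre node is always included,
// so sub-pixel radii degrade gracefully to identity pooling.
// [[Rcpp::export]]
NumericMatrix pool_disc(const NumericMatrix field, const double radius_px) {
  const int nr = field.nrow(), nc = field.ncol();
  const int h = (int)std::floor(radius_px);
  const double r2 = radius_px * radius_px;
  NumericMatrix out(nr, nc);
  std::vector<int> dis, djs;
  for (int dj = -h; dj <= h; ++dj)
    for (int di = -h; di <= h; ++di)
      if ((double)(di * di + dj * dj) <= r2) { dis.push_back(di); djs.push_back(dj); }
  if (dis.empty()) { dis.push_back(0); djs.push_back(0); }
  const int K = (int)dis.size();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const int fi = i + dis[k], fj = j + djs[k];
        if (fi < 0 || fi >= nr || fj < 0 || fj >= nc) continue;
        s += field(fi, fj);
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Mean (over units) of the weight mass lying at lags strictly greater than
// `radius_px` from the window centre. Diagnostic for excitatory pruning.
// [[Rcpp::export]]
double mass_beyond(const NumericMatrix W, const int half, const double radius_px) {
  const int N = W.ncol();
  const int K = 2 * half + 1;
  const double r2 = radius_px * radius_px;
  double acc = 0.0;
  for (int u = 0; u < N; ++u) {
    const double* w = &W(0, u);
    double s = 0.0;
    for (int dj = -half; dj <= half; ++dj)
      for (int di = -half; di <= half; ++di)
        if ((double)(di * di + dj * dj) > r2) s += w[(dj + half) * K + di + half];
    acc += s;
  }
  return acc / N;
}
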