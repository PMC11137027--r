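#include <Rcpp.h>
using namespace Rcpp;

// Core numerics for anchored nucleosome calling.
//
// Conventions shared with the R layer:
//  * profiles are dense vectors over anchor-relative offsets -W..W
//    (length 2W+1, element i holds offset i-W);
//  * the smoothing kernel vector has odd length 2h+1 and is indexed -h..h;
//  * out-of-range scores are zero-padded in the convolution;
//  * peaks are interior local maxima; window edges only act as boundaries
//    for prominence, they are never peaks themselves.

// [[Rcpp::export]]
NumericVector cpp_smooth(NumericVector s, NumericVector w) {
  const int n = s.size(), m = w.size();
  if (m % 2 == 0) stop("kernel length must be odd");
  const int h = (m - 1) / 2;
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double acc = 0.0;
    const int jlo = std::max(-h, -k), jhi = std::min(h, n - 1 - k);
    for (int j = jlo; j <= jhi; ++j) acc += s[k + j] * w[j + h];
    out[k] = acc;
  }
  return out;
}

// Histogram of integer offsets onto the dense grid -W..W; offsets outside
// the grid are dropped.
// [[Rcpp::export]]
IntegerVector cpp_hist_offsets(IntegerVector offs, int W) {
  IntegerVector out(2 * W + 1);
  for (int i = 0; i < offs.size(); ++i) {
    const int o = offs[i];
    if (o >= -W && o <= W) out[o + W]++;
  }
  return out;
}

// Interior local maxima (plateau runs collapse to their center; even runs
// break toward anchor_idx) with topographic prominence: height minus the
// higher of the two minimal valleys separating the peak from the nearest
// strictly higher point on each side, the window edge acting as a boundary
// when no higher point exists.
// [[Rcpp::export]]
List cpp_find_peaks(NumericVector y, double min_prom, int anchor_idx) {
  const int n = y.size();
  std::vector<int> idx;
  std::vector<double> hts, proms;
  int i = 1;
  while (i < n - 1) {
    // candidate plateau run [i, j] of equal values
    if (y[i] > y[i - 1]) {
      int j = i;
      while (j + 1 < n && y[j + 1] == y[i]) ++j;
      if (j < n - 1 && y[j + 1] < y[i]) {
        int c;
        if ((i + j) % 2 == 0) {
          c = (i + j) / 2;
        } else {
          const int c1 = (i + j) / 2, c2 = c1 + 1;
          c = (std::abs(c1 - anchor_idx) <= std::abs(c2 - anchor_idx)) ? c1 : c2;
        }
        const double v = y[i];
        // left side
        double lmin = R_PosInf;
        bool higher_l = false;
        for (int k = i - 1; k >= 0; --k) {
          if (y[k] > v) { higher_l = true; break; }
          if (y[k] < lmin) lmin = y[k];
        }
        (void)higher_l;  // edge acts as boundary: lmin already spans to edge
        double rmin = R_PosInf;
        for (int k = j + 1; k < n; ++k) {
          if (y[k] > v) break;
          if (y[k] < rmin) rmin = y[k];
        }
        const double prom = v - std::max(lmin, rmin);
        if (prom >= min_prom) {
          idx.push_back(c);
          hts.push_back(v);
          proms.push_back(prom);
        }
        i = j + 1;
        continue;
      }
      i = j + 1;
      continue;
    }
    ++i;
  }
  return List::create(_["index"] = wrap(idx), _["height"] = wrap(hts),
                      _["prominence"] = wrap(proms));
}

// Three-point parabolic apex refinement; returns the sub-bin correction in
// [-0.5, 0.5] or 0 when the apex is flat or at the window edge.
static double apex_delta(const NumericVector &y, int i) {
  if (i <= 0 || i >= y.size() - 1) return 0.0;
  const double d2 = y[i - 1] - 2.0 * y[i] + y[i + 1];
  if (d2 >= 0.0) return 0.0;
  double d = (y[i - 1] - y[i + 1]) / (2.0 * d2);
  if (d > 0.5) d = 0.5;
  if (d < -0.5) d = -0.5;
  return d;
}

// Call the -1/+1 pair from a smoothed profile over -W..W. The profile is
// restricted to the +/- search_hw window, rescaled to max 1 there, peaks
// are found at min_prom, and the highest peak strictly upstream (offset
// < 0) and strictly downstream (offset > 0) are returned; offset 0 counts
// for neither side. Ties in height break toward the anchor. Returns
// c(m1_off, m1_h, m1_prom, p1_off, p1_h, p1_prom), NAs when uncallable.
// [[Rcpp::export]]
NumericVector cpp_call_pair(NumericVector ysm, int W, int search_hw,
                            double min_prom, bool refine) {
  NumericVector out(6, NA_REAL);
  if (2 * W + 1 != ysm.size()) stop("profile length does not match W");
  if (search_hw > W) stop("search halfwidth exceeds profile halfwidth");
  const int lo = W - search_hw, m = 2 * search_hw + 1;
  NumericVector y(m);
  double ymax = 0.0;
  for (int k = 0; k < m; ++k) {
    y[k] = ysm[lo + k];
    if (y[k] > ymax) ymax = y[k];
  }
  if (!(ymax > 0.0)) return out;
  for (int k = 0; k < m; ++k) y[k] /= ymax;
  List pk = cpp_find_peaks(y, min_prom, search_hw);
  IntegerVector idx = pk["index"];
  NumericVector hts = pk["height"], proms = pk["prominence"];
  int best_m = -1, best_p = -1;
  for (int k = 0; k < idx.size(); ++k) {
    const int off = idx[k] - search_hw;
    if (off < 0) {
      if (best_m < 0 || hts[k] > hts[best_m] ||
          (hts[k] == hts[best_m] && off > idx[best_m] - search_hw))
        best_m = k;
    } else if (off > 0) {
      if (best_p < 0 || hts[k] > hts[best_p] ||
          (hts[k] == hts[best_p] && off < idx[best_p] - search_hw))
        best_p = k;
    }
  }
  if (best_m >= 0) {
    double off = idx[best_m] - search_hw;
    if (refine) off += apex_delta(y, idx[best_m]);
    out[0] = off; out[1] = hts[best_m]; out[2] = proms[best_m];
  }
  if (best_p >= 0) {
    double off = idx[best_p] - search_hw;
    if (refine) off += apex_delta(y, idx[best_p]);
    out[3] = off; out[4] = hts[best_p]; out[5] = proms[best_p];
  }
  return out;
}

// Full per-anchor call from raw midpoint offsets: histogram on a grid wide
// enough for the kernel margin, smooth, then call the pair.
// [[Rcpp::export]]
NumericVector cpp_call_from_midpoints(IntegerVector offs, NumericVector w,
                                      int search_hw, double min_prom,
                                      bool refine) {
  const int h = (w.size() - 1) / 2;
  const int W = search_hw + h;
  IntegerVector cnt = cpp_hist_offsets(offs, W);
  NumericVector s(cnt.size());
  for (int k = 0; k < cnt.size(); ++k) s[k] = cnt[k];
  NumericVector ysm = cpp_smooth(s, w);
  return cpp_call_pair(ysm, W, search_hw, min_prom, refine);
}

// Bootstrap standard errors of the called -1/+1 offsets. Fragments (midpoint
// offset + length) are resampled with replacement; the canonical length
// filter, smoothing and calling run inside the loop. Resamples where either
// side is uncallable are dropped and counted. Uses R's RNG stream.
// [[Rcpp::export]]
List cpp_bootstrap_se(IntegerVector offs, IntegerVector lens, int min_len,
                      int max_len, NumericVector w, int search_hw,
                      double min_prom, int B, bool refine) {
  const int n = offs.size();
  const int h = (w.size() - 1) / 2;
  const int W = search_hw + h;
  std::vector<double> m1s, p1s;
  m1s.reserve(B); p1s.reserve(B);
  IntegerVector cnt(2 * W + 1);
  NumericVector s(2 * W + 1);
  for (int b = 0; b < B; ++b) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int t = 0; t < n; ++t) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      if (lens[i] < min_len || lens[i] > max_len) continue;
      const int o = offs[i];
      if (o >= -W && o <= W) cnt[o + W]++;
    }
    for (int k = 0; k < 2 * W + 1; ++k) s[k] = cnt[k];
    NumericVector ysm = cpp_smooth(s, w);
    NumericVector call = cpp_call_pair(ysm, W, search_hw, min_prom, refine);
    if (!NumericVector::is_na(call[0]) && !NumericVector::is_na(call[3])) {
      m1s.push_back(call[0]);
      p1s.push_back(call[3]);
    }
  }
  const int ok = (int)m1s.size();
  double se_m = NA_REAL, se_p = NA_REAL;
  if (ok >= 2) {
    double mm = 0, mp = 0;
    for (int k = 0; k < ok; ++k) { mm += m1s[k]; mp += p1s[k]; }
    mm /= ok; mp /= ok;
    double vm = 0, vp = 0;
    for (int k = 0; k < ok; ++k) {
      vm += (m1s[k] - mm) * (m1s[k] - mm);
      vp += (p1s[k] - mp) * (p1s[k] - mp);
    }
    se_m = std::sqrt(vm / (ok - 1));
    se_p = std::sqrt(vp / (ok - 1));
  }
  return List::create(_["se_minus1"] = se_m, _["se_plus1"] = se_p,
                      _["n_ok"] = ok, _["B"] = B);
}

// Row-wise smoothing for profile matrices (anchors x offsets).
// [[Rcpp::export]]
NumericMatrix cpp_smooth_rows(NumericMatrix m, NumericVector w) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    NumericVector row(nc);
    for (int c = 0; c < nc; ++c) row[c] = m(r, c);
    NumericVector sm = cpp_smooth(row, w);
    for (int c = 0; c < nc; ++c) out(r, c) = sm[c];
  }
  return out;
}
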