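#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Relative extrema on uniform-grid spectra, column-wise.
// A point is a relative maximum iff its ordinate >= every ordinate within
// w bins; candidates within w bins of an already kept candidate (necessarily
// ties) are dropped, keeping the smallest abscissa. Top-n selected by
// ordinate (maxima: largest first; minima: smallest first), ties broken by
// smaller bin index. Returns 1-based bin positions, NA padded.
// [[Rcpp::export]]
List cpp_relative_extrema(NumericMatrix ord, int w, int n, bool maxima) {
  const int L = ord.nrow(), nc = ord.ncol();
  IntegerMatrix pos(n, nc);
  NumericMatrix val(n, nc);
  std::fill(pos.begin(), pos.end(), NA_INTEGER);
  std::fill(val.begin(), val.end(), NA_REAL);
  std::vector<int> cand;
  std::vector<int> kept;
  std::vector<double> nb(L);
  for (int c = 0; c < nc; ++c) {
    const double *col = &ord(0, c);
    bool has_na = false;
    for (int i = 0; i < L && !has_na; ++i)
      if (std::isnan(col[i])) has_na = true;
    if (has_na) continue;            // undefined spectrum: leave slots NA
    // neighborhood extreme via offset sweeps (branch-light, cache friendly)
    std::copy(col, col + L, nb.begin());
    for (int d = 1; d <= w; ++d) {
      if (maxima) {
        for (int i = 0; i < L - d; ++i) {
          const double a = col[i], b = col[i + d];
          if (b > nb[i]) nb[i] = b;
          if (a > nb[i + d]) nb[i + d] = a;
        }
      } else {
        for (int i = 0; i < L - d; ++i) {
          const double a = col[i], b = col[i + d];
          if (b < nb[i]) nb[i] = b;
          if (a < nb[i + d]) nb[i + d] = a;
        }
      }
    }
    cand.clear();
    for (int i = 0; i < L; ++i)
      if (col[i] == nb[i]) cand.push_back(i);
    kept.clear();
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      if (kept.empty() || cand[ci] - kept.back() > w) kept.push_back(cand[ci]);
    }
    // order kept by ordinate (desc for maxima, asc for minima), tie: index asc
    std::stable_sort(kept.begin(), kept.end(), [&](int a, int b) {
      const double va = ord(a, c), vb = ord(b, c);
      if (va != vb) return maxima ? (va > vb) : (va < vb);
      return a < b;
    });
    const int m = std::min<int>(n, kept.size());
    for (int s = 0; s < m; ++s) {
      pos(s, c) = kept[s] + 1;
      val(s, c) = ord(kept[s], c);
    }
  }
  return List::create(_["pos"] = pos, _["val"] = val);
}

// Moving-window sudden rise / drop detection, column-wise.
// Windows of k consecutive samples (stride 1); mean and population SD
// (denominator k) computed on the k observations including the candidate;
// a sample strictly above mean + c*SD in any window containing it is a rise
// candidate (below mean - c*SD: drop). Windows containing NA produce no
// flags. Each flagged sample is reported once with its first flagging
// window. Rises ranked by descending value, drops by ascending value, ties
// by earlier sample; top-n returned with 1-based sample indices, NA padded.
// [[Rcpp::export]]
List cpp_moving_window(NumericMatrix x, int k, int n, double cmult) {
  const int N = x.nrow(), nc = x.ncol();
  IntegerMatrix rise_t(n, nc), drop_t(n, nc);
  NumericMatrix rise_v(n, nc), drop_v(n, nc);
  IntegerMatrix rise_w(n, nc), drop_w(n, nc);   // first flagging window (1-based)
  IntegerVector rise_count(nc), drop_count(nc);
  std::fill(rise_t.begin(), rise_t.end(), NA_INTEGER);
  std::fill(drop_t.begin(), drop_t.end(), NA_INTEGER);
  std::fill(rise_w.begin(), rise_w.end(), NA_INTEGER);
  std::fill(drop_w.begin(), drop_w.end(), NA_INTEGER);
  std::fill(rise_v.begin(), rise_v.end(), NA_REAL);
  std::fill(drop_v.begin(), drop_v.end(), NA_REAL);

  std::vector<int> fw_rise(N), fw_drop(N);
  std::vector<int> idx;
  for (int c = 0; c < nc; ++c) {
    std::fill(fw_rise.begin(), fw_rise.end(), -1);
    std::fill(fw_drop.begin(), fw_drop.end(), -1);
    const int W = N - k + 1;
    for (int w = 0; w < W; ++w) {
      double s = 0.0, ss = 0.0;
      bool has_na = false;
      for (int j = 0; j < k; ++j) {
        const double v = x(w + j, c);
        if (NumericVector::is_na(v)) { has_na = true; break; }
        s += v; ss += v * v;
      }
      if (has_na) continue;
      const double m = s / k;
      double var = ss / k - m * m;
      if (var < 0) var = 0;
      const double sd = std::sqrt(var);
      const double hi = m + cmult * sd, lo = m - cmult * sd;
      for (int j = 0; j < k; ++j) {
        const double v = x(w + j, c);
        if (v > hi && fw_rise[w + j] < 0) fw_rise[w + j] = w;
        if (v < lo && fw_drop[w + j] < 0) fw_drop[w + j] = w;
      }
    }
    // rises
    idx.clear();
    for (int i = 0; i < N; ++i) if (fw_rise[i] >= 0) idx.push_back(i);
    rise_count[c] = idx.size();
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (x(a, c) != x(b, c)) return x(a, c) > x(b, c);
      return a < b;
    });
    for (int s2 = 0; s2 < std::min<int>(n, idx.size()); ++s2) {
      rise_t(s2, c) = idx[s2] + 1;
      rise_v(s2, c) = x(idx[s2], c);
      rise_w(s2, c) = fw_rise[idx[s2]] + 1;
    }
    // drops
    idx.clear();
    for (int i = 0; i < N; ++i) if (fw_drop[i] >= 0) idx.push_back(i);
    drop_count[c] = idx.size();
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (x(a, c) != x(b, c)) return x(a, c) < x(b, c);
      return a < b;
    });
    for (int s2 = 0; s2 < std::min<int>(n, idx.size()); ++s2) {
      drop_t(s2, c) = idx[s2] + 1;
      drop_v(s2, c) = x(idx[s2], c);
      drop_w(s2, c) = fw_drop[idx[s2]] + 1;
    }
  }
  return List::create(_["rise_t"] = rise_t, _["rise_v"] = rise_v,
                      _["rise_w"] = rise_w, _["drop_t"] = drop_t,
                      _["drop_v"] = drop_v, _["drop_w"] = drop_w,
                      _["rise_count"] = rise_count,
                      _["drop_count"] = drop_count);
}

// Column medians ignoring NA (NA for all-missing columns).
// [[Rcpp::export]]
NumericVector cpp_col_medians(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(p);
  std::vector<double> buf;
  buf.reserve(n);
  for (int j = 0; j < p; ++j) {
    buf.clear();
    for (int i = 0; i < n; ++i) {
      const double v = x(i, j);
      if (!std::isnan(v)) buf.push_back(v);
    }
    const size_t m = buf.size();
    if (m == 0) { out[j] = NA_REAL; continue; }
    const size_t h = m / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (m % 2 == 0) {
      const double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = (med + lo) / 2.0;
    }
    out[j] = med;
  }
  return out;
}
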