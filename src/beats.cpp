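#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Beat segmentation core: local maxima of x filtered by topographic
// prominence >= min_prom, minimum peak separation min_gap samples (higher
// peak wins), onset/end at the minima between retained peaks, partial
// edge-touching beats discarded. Mirrors the documented R semantics of
// detect_beats().
// [[Rcpp::export]]
List beat_segments_cpp(NumericVector x, double min_prom, int min_gap) {
  const int n = x.size();
  std::vector<int> cand;
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) cand.push_back(i);
  }
  // prominence
  std::vector<int> peaks;
  std::vector<double> proms;
  for (int p : cand) {
    double lv = x[p];
    double left = lv, right = lv;
    for (int i = p - 1; i >= 0; --i) {
      if (x[i] > lv) break;
      if (x[i] < left) left = x[i];
    }
    for (int i = p + 1; i < n; ++i) {
      if (x[i] > lv) break;
      if (x[i] < right) right = x[i];
    }
    double pr = lv - std::max(left, right);
    if (pr >= min_prom && pr > 0) {
      peaks.push_back(p);
      proms.push_back(pr);
    }
  }
  const int np = peaks.size();
  // separation: process by height, keep if no kept peak within min_gap
  std::vector<int> ord(np);
  for (int i = 0; i < np; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[peaks[a]] > x[peaks[b]]; });
  std::vector<bool> kept(np, false);
  for (int oi : ord) {
    bool clash = false;
    for (int j = 0; j < np; ++j)
      if (kept[j] && std::abs(peaks[j] - peaks[oi]) < min_gap) { clash = true; break; }
    if (!clash) kept[oi] = true;
  }
  std::vector<int> fin;
  for (int i = 0; i < np; ++i)
    if (kept[i]) fin.push_back(peaks[i]);
  std::sort(fin.begin(), fin.end());

  const int k = fin.size();
  std::vector<int> onset(k), endi(k);
  std::vector<double> promf(k);
  for (int i = 0; i < k; ++i) {
    int lo = (i == 0) ? 0 : fin[i - 1];
    int hi = (i == k - 1) ? n - 1 : fin[i + 1];
    int io = lo;
    for (int j = lo; j <= fin[i]; ++j) if (x[j] < x[io]) io = j;
    int ie = fin[i];
    for (int j = fin[i]; j <= hi; ++j) if (x[j] < x[ie]) ie = j;
    onset[i] = io; endi[i] = ie;
    promf[i] = x[fin[i]] - std::max(x[io], x[ie]);
  }
  // edge discards
  std::vector<int> o2, p2, e2;
  std::vector<double> pr2;
  for (int i = 0; i < k; ++i) {
    if (fin[i] == 0 || fin[i] == n - 1) continue;
    if (onset[i] == 0 && x[0] > x[endi[i]] + 0.25 * promf[i]) continue;
    if (endi[i] == n - 1 && x[n - 1] > x[onset[i]] + 0.25 * promf[i]) continue;
    if (promf[i] < min_prom) continue;
    o2.push_back(onset[i] + 1); // 1-based
    p2.push_back(fin[i] + 1);
    e2.push_back(endi[i] + 1);
    pr2.push_back(promf[i]);
  }
  return List::create(_["onset"] = wrap(o2), _["peak"] = wrap(p2),
                      _["end"] = wrap(e2), _["prominence"] = wrap(pr2));
}

// Per-beat metrics: D = d_s[peak] - d_s[onset], V/Acc = max of v/a over the
// contraction phase [onset, peak], clipped below at 0. Indices 1-based.
// [[Rcpp::export]]
List beat_metrics_cpp(NumericVector ds, NumericVector v, NumericVector a,
                      IntegerVector onset, IntegerVector peak) {
  const int k = onset.size();
  NumericVector D(k), V(k), A(k);
  bool degen = false;
  for (int i = 0; i < k; ++i) {
    int io = onset[i] - 1, ip = peak[i] - 1;
    if (io >= ip) { degen = true; D[i] = V[i] = A[i] = 0; continue; }
    D[i] = std::max(ds[ip] - ds[io], 0.0);
    double vm = v[io], am = a[io];
    for (int j = io; j <= ip; ++j) {
      if (v[j] > vm) vm = v[j];
      if (a[j] > am) am = a[j];
    }
    V[i] = std::max(vm, 0.0);
    A[i] = std::max(am, 0.0);
  }
  return List::create(_["D"] = D, _["V"] = V, _["Acc"] = A,
                      _["degenerate"] = degen);
}
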