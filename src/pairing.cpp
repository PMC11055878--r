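// Greedy nearest-neighbour one-to-one matching of localizations across
// odd -> consecutive even camera frames, capped at a maximum search radius.
// Ties in distance are broken by the lower odd record index, then the lower
// even record index, so the matching is a deterministic function of the
// record order.
#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix pair_frames_cpp(IntegerVector frame, NumericVector x,
                              NumericVector y, double rmax) {
  int n = frame.size();
  std::map<int, std::vector<int>> byframe;  // ordered: output follows frame order
  for (int i = 0; i < n; ++i) byframe[frame[i]].push_back(i);

  double r2max = rmax * rmax;
  std::vector<int> out_odd, out_even;

  struct Cand { double d2; int oi, ej; };
  for (auto &kv : byframe) {
    int f = kv.first;
    if (f % 2 == 0) continue;
    auto it = byframe.find(f + 1);
    if (it == byframe.end()) continue;
    std::vector<int> &odds = kv.second, &evens = it->second;
    std::vector<Cand> cands;
    for (size_t a = 0; a < odds.size(); ++a) {
      for (size_t b = 0; b < evens.size(); ++b) {
        double dx = x[odds[a]] - x[evens[b]];
        double dy = y[odds[a]] - y[evens[b]];
        double d2 = dx * dx + dy * dy;
        if (d2 <= r2max) cands.push_back({d2, (int)a, (int)b});
      }
    }
    std::sort(cands.begin(), cands.end(), [&](const Cand &p, const Cand &q) {
      if (p.d2 != q.d2) return p.d2 < q.d2;
      if (odds[p.oi] != odds[q.oi]) return odds[p.oi] < odds[q.oi];
      return evens[p.ej] < evens[q.ej];
    });
    std::vector<char> used_o(odds.size(), 0), used_e(evens.size(), 0);
    for (const Cand &c : cands) {
      if (used_o[c.oi] || used_e[c.ej]) continue;
      used_o[c.oi] = 1; used_e[c.ej] = 1;
      out_odd.push_back(odds[c.oi] + 1);
      out_even.push_back(evens[c.ej] + 1);
    }
  }

  IntegerMatrix res((int)out_odd.size(), 2);
  for (size_t i = 0; i < out_odd.size(); ++i) {
    res(i, 0) = out_odd[i];
    res(i, 1) = out_even[i];
  }
  return res;
}
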