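#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Greedy mass-ordered single-pass clustering of pooled, mass-sorted peaks.
// A peak joins the open cluster whose intensity-weighted centroid is
// nearest in mass among those with |dmass|/mass <= massRel and
// |dtime| <= timeAbs; otherwise it opens a new cluster. At most one peak
// per sample per cluster: the most intense wins, the loser is dropped
// (flagged kept = false).
//
// Inputs must be sorted by ascending mass.
// [[Rcpp::export(name = ".greedyCluster")]]
List greedyCluster(NumericVector mass, NumericVector time,
                   NumericVector intensity, IntegerVector sample,
                   double massRel, double timeAbs) {
  const int n = mass.size();
  IntegerVector clusterId(n);
  LogicalVector kept(n);
  std::vector<double> sumW, sumWM, sumWT, firstMass;
  std::vector<std::unordered_map<int, int> > members; // sample -> peak idx
  int conflicts = 0;

  for (int i = 0; i < n; ++i) {
    const double m = mass[i], t = time[i], w = intensity[i];
    const double lo = m * (1.0 - 3.0 * massRel);
    int best = -1;
    double bestD = R_PosInf;
    for (int c = (int)sumW.size() - 1; c >= 0; --c) {
      if (firstMass[c] < lo) break; // older clusters cannot qualify
      const double cm = sumWM[c] / sumW[c];
      const double ct = sumWT[c] / sumW[c];
      const double d = std::fabs(m - cm);
      if (d / cm <= massRel && std::fabs(t - ct) <= timeAbs && d < bestD) {
        best = c;
        bestD = d;
      }
    }
    if (best < 0) { // open a new cluster
      sumW.push_back(w);
      sumWM.push_back(w * m);
      sumWT.push_back(w * t);
      firstMass.push_back(m);
      members.push_back(std::unordered_map<int, int>());
      members.back()[sample[i]] = i;
      clusterId[i] = (int)sumW.size();
      kept[i] = true;
      continue;
    }
    std::unordered_map<int, int>& mem = members[best];
    std::unordered_map<int, int>::iterator it = mem.find(sample[i]);
    if (it == mem.end()) {
      mem[sample[i]] = i;
      sumW[best] += w;
      sumWM[best] += w * m;
      sumWT[best] += w * t;
      clusterId[i] = best + 1;
      kept[i] = true;
    } else {
      ++conflicts;
      const int j = it->second;
      if (w > intensity[j]) { // replace the weaker duplicate
        sumW[best] += w - intensity[j];
        sumWM[best] += w * m - intensity[j] * mass[j];
        sumWT[best] += w * t - intensity[j] * time[j];
        kept[j] = false;
        clusterId[i] = best + 1;
        kept[i] = true;
        it->second = i;
      } else {
        clusterId[i] = best + 1;
        kept[i] = false;
      }
    }
  }
  return List::create(_["clusterId"] = clusterId, _["kept"] = kept,
                      _["nClusters"] = (int)sumW.size(),
                      _["conflicts"] = conflicts);
}
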