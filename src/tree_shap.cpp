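#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Interventional Shapley attribution for an additive tree ensemble.
//
// For one explained sample x and one background row b, the ensemble output
// restricted to a coalition S is f(x_S, b_{\S}). Each leaf is reached by a
// path of split conditions; collapsing the conditions per feature, let A be
// the features satisfied by x but not b and D those satisfied by b but not
// x (a leaf with any feature satisfied by neither is unreachable for every
// coalition). The leaf's reachability indicator is the unanimity-veto game
// [A \subseteq S][D \cap S = 0], whose Shapley values have the closed form
//   i in A:  (|A|-1)! |D|! / (|A|+|D|)!
//   i in D: -|A|! (|D|-1)! / (|A|+|D|)!
// and zero elsewhere. Summing leaf_value * phi(game) over leaves and trees
// and averaging over background rows gives the exact Shapley values of the
// background-marginalised value function. Implemented as a single recursive
// descent per (sample, background, tree) that tracks, per feature, whether
// x resp. b still satisfy every condition seen on the current path.

struct TreeShap {
  const IntegerVector &feature, &yes, &no_;
  const NumericVector &split, &value;
  bool strict; // true: go yes iff v < split; false: left iff v <= split
  const NumericMatrix &X, &B;
  int nfeat;
  std::vector<int> path_feats;       // features constrained on current path
  std::vector<signed char> x_ok, b_ok, on_path;
  std::vector<double> phi_pair;     // per-feature accumulator for one pair
  double base_pair, fx_pair;
  int xi, bi;

  TreeShap(const IntegerVector &f, const NumericVector &s,
           const IntegerVector &y, const IntegerVector &n,
           const NumericVector &v, bool strict_,
           const NumericMatrix &X_, const NumericMatrix &B_)
      : feature(f), yes(y), no_(n), split(s), value(v), strict(strict_),
        X(X_), B(B_), nfeat(X_.ncol()),
        x_ok(nfeat, 1), b_ok(nfeat, 1), on_path(nfeat, 0),
        phi_pair(nfeat, 0.0), base_pair(0.0), fx_pair(0.0) {}

  bool goes_yes(double v, double s) const {
    return strict ? (v < s) : (v <= s);
  }

  void leaf(double val) {
    int a = 0, d = 0;
    for (int k = (int)path_feats.size() - 1; k >= 0; --k) {
      int f = path_feats[k];
      if (x_ok[f] && !b_ok[f]) ++a;
      else if (!x_ok[f] && b_ok[f]) ++d;
    }
    if (a == 0 && d == 0) { base_pair += val; fx_pair += val; return; }
    if (a == 0) { base_pair += val; }
    if (d == 0) { fx_pair += val; }
    // factorial weights; a+d <= path length, small by construction
    double wA = 0.0, wD = 0.0;
    if (a > 0) {
      wA = 1.0;
      for (int t = 2; t <= d; ++t) wA *= t;              // d!
      for (int t = 2; t <= a - 1; ++t) wA *= t;          // (a-1)!
      double denom = 1.0;
      for (int t = 2; t <= a + d; ++t) denom *= t;       // (a+d)!
      wA /= denom;
    }
    if (d > 0) {
      wD = 1.0;
      for (int t = 2; t <= a; ++t) wD *= t;              // a!
      for (int t = 2; t <= d - 1; ++t) wD *= t;          // (d-1)!
      double denom = 1.0;
      for (int t = 2; t <= a + d; ++t) denom *= t;       // (a+d)!
      wD /= denom;
    }
    for (int k = (int)path_feats.size() - 1; k >= 0; --k) {
      int f = path_feats[k];
      if (x_ok[f] && !b_ok[f]) phi_pair[f] += val * wA;
      else if (!x_ok[f] && b_ok[f]) phi_pair[f] -= val * wD;
    }
  }

  void descend(int node) {
    int f = feature[node];
    if (f < 0) { leaf(value[node]); return; }
    bool cx = goes_yes(X(xi, f), split[node]);
    bool cb = goes_yes(B(bi, f), split[node]);
    signed char sx = x_ok[f], sb = b_ok[f], sp = on_path[f];
    bool pushed = false;
    if (!sp) { on_path[f] = 1; path_feats.push_back(f); pushed = true; }
    // branch where the condition is "goes yes"
    {
      signed char nx = sx && cx, nb = sb && cb;
      if (nx || nb) {
        x_ok[f] = nx; b_ok[f] = nb;
        descend(yes[node]);
      }
    }
    // branch where the condition is "goes no"
    {
      signed char nx = sx && !cx, nb = sb && !cb;
      if (nx || nb) {
        x_ok[f] = nx; b_ok[f] = nb;
        descend(no_[node]);
      }
    }
    x_ok[f] = sx; b_ok[f] = sb;
    if (pushed) { on_path[f] = sp; path_feats.pop_back(); }
    on_path[f] = sp;
  }
};

// [[Rcpp::export]]
List cpp_tree_shap(IntegerVector feature, NumericVector split,
                   IntegerVector yes, IntegerVector no_,
                   NumericVector value, IntegerVector roots, bool strict,
                   NumericMatrix X, NumericMatrix B) {
  int ns = X.nrow(), nb = B.nrow(), nfeat = X.ncol();
  NumericMatrix phi(ns, nfeat);
  double base_total = 0.0;
  TreeShap ts(feature, split, yes, no_, value, strict, X, B);
  for (int s = 0; s < ns; ++s) {
    ts.xi = s;
    std::vector<double> acc(nfeat, 0.0);
    double base_s = 0.0;
    for (int b = 0; b < nb; ++b) {
      ts.bi = b;
      std::fill(ts.phi_pair.begin(), ts.phi_pair.end(), 0.0);
      ts.base_pair = 0.0;
      ts.fx_pair = 0.0;
      for (int r = 0; r < roots.size(); ++r) ts.descend(roots[r]);
      for (int f = 0; f < nfeat; ++f) acc[f] += ts.phi_pair[f];
      base_s += ts.base_pair;
    }
    for (int f = 0; f < nfeat; ++f) phi(s, f) = acc[f] / nb;
    if (s == 0) base_total = base_s / nb;
  }
  return List::create(Named("phi") = phi, Named("base") = base_total);
}
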