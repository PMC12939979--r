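#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Interventional TreeSHAP for ensembles of regression trees.
//
// For one explained sample x, one background row z and one tree, every leaf
// reachable by mixing x- and z-coordinates defines an indicator game over
// the distinct decision features on its path: the leaf is reached by
// coalition S iff the features where only x satisfies the path are all in S
// (set U) and the features where only z satisfies it are all outside S
// (set V). The Shapley value of that game is closed-form:
//   phi_i = w * (u-1)! v! / (u+v)!   for i in U
//   phi_j = -w * u! (v-1)! / (u+v)!  for j in V
// with w the leaf value, u = |U|, v = |V|; features satisfying the path for
// both x and z are dummies. Branches failing for both are pruned during the
// descent, so the walk touches only the leaves that can contribute.
// Attributions are averaged over the background rows; efficiency per pair
// (sum phi = f(x) - f(z)) makes base_value + sum phi = f(x) exactly when
// base_value is the mean background prediction.

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> split;
  std::vector<int> yes, no_;
  std::vector<double> value;  // leaf value
};

class Walker {
public:
  Walker(int nfeat, std::vector<double>& phi_out)
    : phi(phi_out), occ(nfeat, 0), xfail(nfeat, 0), zfail(nfeat, 0),
      seen(nfeat, 0), stamp(0) {
    fact.resize(171);
    fact[0] = 1.0;
    for (int i = 1; i <= 170; ++i) fact[i] = fact[i - 1] * i;
  }

  void run(const Tree& tr, const double* x_, const double* z_) {
    tree = &tr; x = x_; z = z_;
    path.clear();
    recurse(0);
  }

private:
  std::vector<double>& phi;
  std::vector<int> occ, xfail, zfail, seen;
  std::vector<int> path;          // features pushed, with repeats
  std::vector<double> fact;
  int stamp;
  const Tree* tree;
  const double* x;
  const double* z;

  void leaf(double w) {
    ++stamp;
    int u = 0, v = 0;
    for (size_t i = 0; i < path.size(); ++i) {
      int f = path[i];
      if (seen[f] == stamp) continue;
      seen[f] = stamp;
      if (xfail[f] == 0 && zfail[f] > 0) ++u;
      else if (xfail[f] > 0 && zfail[f] == 0) ++v;
    }
    int tot = u + v;
    if (tot == 0 || tot > 170) {
      if (tot > 170) Rcpp::stop("tree path too deep for factorial weights");
      return;
    }
    double wu = (u > 0) ? w * fact[u - 1] * fact[v] / fact[tot] : 0.0;
    double wv = (v > 0) ? w * fact[u] * fact[v - 1] / fact[tot] : 0.0;
    ++stamp;
    for (size_t i = 0; i < path.size(); ++i) {
      int f = path[i];
      if (seen[f] == stamp) continue;
      seen[f] = stamp;
      if (xfail[f] == 0 && zfail[f] > 0) phi[f] += wu;
      else if (xfail[f] > 0 && zfail[f] == 0) phi[f] -= wv;
    }
  }

  void recurse(int node) {
    int f = tree->feat[node];
    if (f < 0) { leaf(tree->value[node]); return; }
    // xgboost evaluates split conditions in single precision
    float sp = static_cast<float>(tree->split[node]);
    bool xyes = static_cast<float>(x[f]) < sp;
    bool zyes = static_cast<float>(z[f]) < sp;
    int children[2] = { tree->yes[node], tree->no_[node] };
    for (int c = 0; c < 2; ++c) {
      bool xfollow = (c == 0) ? xyes : !xyes;
      bool zfollow = (c == 0) ? zyes : !zyes;
      int nxf = xfail[f] + (xfollow ? 0 : 1);
      int nzf = zfail[f] + (zfollow ? 0 : 1);
      if (nxf > 0 && nzf > 0) continue;  // unreachable under any coalition
      ++occ[f];
      xfail[f] = nxf;
      zfail[f] = nzf;
      path.push_back(f);
      recurse(children[c]);
      path.pop_back();
      xfail[f] -= (xfollow ? 0 : 1);
      zfail[f] -= (zfollow ? 0 : 1);
      --occ[f];
    }
  }
};

// Double-precision ensemble evaluation of the parsed trees (xgboost's own
// predict accumulates in float32; attribution identities are checked in
// double). Split comparisons still use float32 to match the booster's
// routing.
// [[Rcpp::export]]
NumericVector ens_predict_cpp(List trees, NumericMatrix X) {
  int nx = X.nrow(), nt = trees.size();
  NumericVector out(nx);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    IntegerVector fe = tl["feature"];
    NumericVector sp = tl["split"];
    IntegerVector ye = tl["yes"], no_ = tl["no"];
    NumericVector va = tl["value"];
    for (int i = 0; i < nx; ++i) {
      int node = 0;
      while (fe[node] >= 0) {
        float s = static_cast<float>(sp[node]);
        node = (static_cast<float>(X(i, fe[node])) < s) ? ye[node] : no_[node];
      }
      out[i] += va[node];
    }
  }
  return out;
}

// trees: list of lists with elements feature (int, -1 = leaf), split (num),
// yes/no (int, 0-based child node index), value (num, leaf prediction).
// X: samples to explain; Z: background rows. Returns n_X x nfeat matrix.
// [[Rcpp::export]]
NumericMatrix interv_treeshap_cpp(List trees, NumericMatrix X,
                                  NumericMatrix Z) {
  int nfeat = X.ncol();
  if (Z.ncol() != nfeat) stop("background column count mismatch");
  int nx = X.nrow(), nz = Z.nrow(), nt = trees.size();
  std::vector<Tree> parsed(nt);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    IntegerVector fe = tl["feature"];
    NumericVector sp = tl["split"];
    IntegerVector ye = tl["yes"], no_ = tl["no"];
    NumericVector va = tl["value"];
    Tree& tr = parsed[t];
    tr.feat.assign(fe.begin(), fe.end());
    tr.split.assign(sp.begin(), sp.end());
    tr.yes.assign(ye.begin(), ye.end());
    tr.no_.assign(no_.begin(), no_.end());
    tr.value.assign(va.begin(), va.end());
    for (size_t k = 0; k < tr.feat.size(); ++k) {
      if (tr.feat[k] >= nfeat) stop("tree references unknown feature");
    }
  }
  NumericMatrix out(nx, nfeat);
  std::vector<double> phi(nfeat);
  std::vector<double> xrow(nfeat), zrow(nfeat);
  Walker walker(nfeat, phi);
  for (int i = 0; i < nx; ++i) {
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int j = 0; j < nfeat; ++j) xrow[j] = X(i, j);
    for (int zi = 0; zi < nz; ++zi) {
      for (int j = 0; j < nfeat; ++j) zrow[j] = Z(zi, j);
      for (int t = 0; t < nt; ++t) {
        walker.run(parsed[t], xrow.data(), zrow.data());
      }
    }
    for (int j = 0; j < nfeat; ++j) out(i, j) = phi[j] / nz;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
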