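#include <Rcpp.h>
using namespace Rcpp;

// Spatiotemporal connected components over a (channel x time) grid.
// Nodes are suprathreshold samples of one sign; edges connect a node to the
// same channel at adjacent time samples and to neighbouring channels at the
// same time sample (no diagonal connectivity).

static void flood(const int start, const double *t, const int nch,
                  const int ntime, const double thr, const int sign,
                  const std::vector<std::vector<int>> &adj,
                  std::vector<int> &label, const int id,
                  std::vector<int> &stack, double &mass) {
  stack.clear();
  stack.push_back(start);
  label[start] = id;
  while (!stack.empty()) {
    int node = stack.back();
    stack.pop_back();
    mass += t[node];
    int ch = node % nch, ti = node / nch;
    // temporal neighbours
    for (int dt = -1; dt <= 1; dt += 2) {
      int tj = ti + dt;
      if (tj < 0 || tj >= ntime) continue;
      int nb = ch + tj * nch;
      if (label[nb] == 0 && sign * t[nb] > thr) {
        label[nb] = id;
        stack.push_back(nb);
      }
    }
    // spatial neighbours
    for (size_t k = 0; k < adj[ch].size(); ++k) {
      int nb = adj[ch][k] + ti * nch;
      if (label[nb] == 0 && sign * t[nb] > thr) {
        label[nb] = id;
        stack.push_back(nb);
      }
    }
  }
}

static std::vector<std::vector<int>> adj_from_list(const List &adj_list) {
  int nch = adj_list.size();
  std::vector<std::vector<int>> adj(nch);
  for (int i = 0; i < nch; ++i) {
    IntegerVector v = adj_list[i];
    for (int k = 0; k < v.size(); ++k) adj[i].push_back(v[k] - 1);
  }
  return adj;
}

// Find all sign-separated clusters in a t-map. tmat is nch x ntime.
// Returns labels (nch x ntime; 0 = subthreshold), masses and signs.
// [[Rcpp::export]]
List find_clusters_cpp(NumericMatrix tmat, double thr, List adj_list) {
  int nch = tmat.nrow(), ntime = tmat.ncol();
  std::vector<std::vector<int>> adj = adj_from_list(adj_list);
  std::vector<int> label(nch * ntime, 0);
  std::vector<int> stack;
  std::vector<double> masses;
  std::vector<int> signs;
  int id = 0;
  const double *t = tmat.begin();
  for (int node = 0; node < nch * ntime; ++node) {
    if (label[node] != 0) continue;
    int sign = t[node] > thr ? 1 : (-t[node] > thr ? -1 : 0);
    if (sign == 0) continue;
    double mass = 0.0;
    flood(node, t, nch, ntime, thr, sign, adj, label, ++id, stack, mass);
    masses.push_back(mass);
    signs.push_back(sign);
  }
  IntegerMatrix lab(nch, ntime);
  for (int i = 0; i < nch * ntime; ++i) lab[i] = label[i];
  return List::create(_["labels"] = lab,
                      _["mass"] = NumericVector(masses.begin(), masses.end()),
                      _["sign"] = IntegerVector(signs.begin(), signs.end()));
}

// Per-tail permutation null of the maximal cluster mass.
// diffs: n_subj x (nch*ntime) matrix of paired condition differences
// (channel-major within each time sample). signs: n_perm x n_subj matrix of
// +/-1 sign flips. Returns an n_perm x 2 matrix: column 1 the max positive
// cluster mass, column 2 the max |negative cluster mass| (0 when none).
// [[Rcpp::export]]
NumericMatrix perm_null_cpp(NumericMatrix diffs, IntegerMatrix signs,
                            int nch, double thr, List adj_list) {
  int nsub = diffs.nrow(), nspace = diffs.ncol();
  int ntime = nspace / nch;
  int nperm = signs.nrow();
  std::vector<std::vector<int>> adj = adj_from_list(adj_list);
  NumericMatrix out(nperm, 2);
  std::vector<double> tmap(nspace);
  std::vector<int> label(nspace);
  std::vector<int> stack;
  double sqn = std::sqrt((double)nsub);
  for (int p = 0; p < nperm; ++p) {
    // paired t per sample under sign-flipped differences
    for (int j = 0; j < nspace; ++j) {
      double m = 0.0, m2 = 0.0;
      for (int s = 0; s < nsub; ++s) {
        double x = signs(p, s) * diffs(s, j);
        m += x;
        m2 += x * x;
      }
      m /= nsub;
      double var = (m2 - nsub * m * m) / (nsub - 1);
      tmap[j] = var > 0 ? m / std::sqrt(var) * sqn : 0.0;
    }
    std::fill(label.begin(), label.end(), 0);
    int id = 0;
    double best_pos = 0.0, best_neg = 0.0;
    for (int node = 0; node < nspace; ++node) {
      if (label[node] != 0) continue;
      int sign = tmap[node] > thr ? 1 : (-tmap[node] > thr ? -1 : 0);
      if (sign == 0) continue;
      double mass = 0.0;
      flood(node, tmap.data(), nch, ntime, thr, sign, adj, label, ++id,
            stack, mass);
      if (sign > 0 && mass > best_pos) best_pos = mass;
      if (sign < 0 && -mass > best_neg) best_neg = -mass;
    }
    out(p, 0) = best_pos;
    out(p, 1) = best_neg;
  }
  return out;
}
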