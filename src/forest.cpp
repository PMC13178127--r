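// Classification trees with surrogate splits.
//
// CART conventions throughout: Gini impurity, candidate thresholds at
// midpoints between consecutive distinct sorted values, ties broken by
// lowest variable index then lowest threshold. Surrogates are scanned over
// every non-primary variable in both orientations (direct / mirrored) and
// ranked by chance-corrected (adjusted) agreement with the primary
// partition. All randomness comes from a per-tree std::mt19937 seed passed
// in from R, so a fitted forest is reproducible bit for bit.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct SurrogateRec {
  int var;            // 0-based
  double threshold;
  bool mirrored;
  double agreement;   // raw fraction of matching routings, best orientation
  double adjusted;    // chance-corrected, clamped at 0
};

struct NodeRec {
  int id;             // 0-based, root = 0
  int depth;
  int size;
  bool is_leaf;
  int pred;           // majority class, 0-based
  int var;            // primary variable, -1 for leaf
  double threshold;
  double decrease;    // weighted Gini decrease
  double p_left;
  int left, right;    // child ids, -1 for leaf
  std::vector<SurrogateRec> surr;
};

inline double gini_from_counts(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : cnt) {
    double p = (double)c / (double)n;
    g -= p * p;
  }
  return g;
}

// Exhaustive midpoint scan for the best primary split on one variable.
// `ord` holds sample slots sorted ascending by x. Returns false when the
// variable is constant on the node.
bool scan_primary(const NumericMatrix &X, const IntegerVector &y, int nclass,
                  const std::vector<int> &rows, const int *ord, int n,
                  int var, double parent_gini,
                  double &best_dec, double &best_thr, double &best_pl) {
  std::vector<int> left_cnt(nclass, 0), tot_cnt(nclass, 0);
  for (int i = 0; i < n; ++i) tot_cnt[y[rows[ord[i]]]]++;
  bool found = false;
  int nl = 0;
  for (int i = 0; i + 1 < n; ++i) {
    int r = rows[ord[i]];
    left_cnt[y[r]]++;
    nl++;
    double x0 = X(r, var), x1 = X(rows[ord[i + 1]], var);
    if (x1 <= x0) continue;
    double mid = (x0 + x1) / 2.0;
    if (!(mid > x0 && mid < x1)) continue;  // float-degenerate midpoint
    int nr = n - nl;
    double gl = 0.0, gr = 0.0;
    {
      double sl = 0.0, sr = 0.0;
      for (int k = 0; k < nclass; ++k) {
        double pl = (double)left_cnt[k] / (double)nl;
        double pr = (double)(tot_cnt[k] - left_cnt[k]) / (double)nr;
        sl += pl * pl;
        sr += pr * pr;
      }
      gl = 1.0 - sl;
      gr = 1.0 - sr;
    }
    double dec = parent_gini - ((double)nl / n) * gl - ((double)nr / n) * gr;
    // a candidate must beat the incumbent by > 1e-12: genuine decrease
    // gaps are rationals with denominator <= n^3, far above this, while
    // mathematically tied (e.g. mirrored) splits may differ by one ulp
    if (!found || dec > best_dec + 1e-12) {  // first max kept
      found = true;
      best_dec = dec;
      best_thr = mid;
      best_pl = (double)nl / n;
    }
  }
  return found;
}

// Best surrogate on one variable against a fixed primary partition
// (go_left over the node's sample slots). Scans midpoints and both
// orientations; keeps the first maximizer (lowest threshold, direct
// orientation preferred on ties).
bool scan_surrogate(const NumericMatrix &X, const std::vector<int> &rows,
                    const int *ord, int n, int var,
                    const std::vector<char> &go_left, int n_left,
                    SurrogateRec &out) {
  int n_right = n - n_left;
  double p_maj = std::max((double)n_left / n, (double)n_right / n);
  bool found = false;
  int prefix_left = 0;  // primary-left among the first i sorted samples
  for (int i = 0; i + 1 < n; ++i) {
    int slot = ord[i];
    if (go_left[slot]) prefix_left++;
    double x0 = X(rows[slot], var), x1 = X(rows[ord[i + 1]], var);
    if (x1 <= x0) continue;
    double mid = (x0 + x1) / 2.0;
    if (!(mid > x0 && mid < x1)) continue;
    int ns_left = i + 1;  // surrogate-left count (direct orientation)
    // direct: surrogate-left <-> primary-left
    int match_direct = prefix_left + (n_right - (ns_left - prefix_left));
    int match_mirror = n - match_direct;
    for (int o = 0; o < 2; ++o) {
      int m = (o == 0) ? match_direct : match_mirror;
      double A = (double)m / n;
      double adj = (A - p_maj) / (1.0 - p_maj);
      if (adj < 0.0) adj = 0.0;
      if (!found || adj > out.adjusted + 1e-12) {
        found = true;
        out.var = var;
        out.threshold = mid;
        out.mirrored = (o == 1);
        out.agreement = A;
        out.adjusted = adj;
      }
    }
  }
  return found;
}

class TreeBuilder {
public:
  // prio: tie-break priority per variable (smaller wins); drawn per tree so
  // that agreement ties at small nodes do not favour low column indices
  TreeBuilder(const NumericMatrix &X, const IntegerVector &y, int nclass,
              int mtry, int s, int min_node_size, std::mt19937 &rng,
              const std::vector<int> &prio)
      : X_(X), y_(y), nclass_(nclass), mtry_(mtry), s_(s),
        min_node_(min_node_size), rng_(rng), prio_(prio) {}

  // rows: bootstrap-resolved sample row indices (may repeat)
  std::vector<NodeRec> build(const std::vector<int> &rows) {
    rows_ = rows;
    int n = rows_.size();
    int p = X_.ncol();
    // presort each variable once over the node's slots; per-node order is
    // maintained by stable partition so no further sorting is needed
    order_.assign(p, std::vector<int>(n));
    for (int v = 0; v < p; ++v) {
      std::vector<int> &o = order_[v];
      for (int i = 0; i < n; ++i) o[i] = i;
      const NumericMatrix &X = X_;
      const std::vector<int> &rw = rows_;
      std::stable_sort(o.begin(), o.end(), [&X, &rw, v](int a, int b) {
        return X(rw[a], v) < X(rw[b], v);
      });
    }
    nodes_.clear();
    grow(0, n, 0);
    return nodes_;
  }

private:
  int grow(int lo, int hi, int depth) {
    int n = hi - lo;
    int id = (int)nodes_.size();
    nodes_.push_back(NodeRec());
    NodeRec &stub = nodes_[id];
    stub.id = id;
    stub.depth = depth;
    stub.size = n;
    stub.is_leaf = true;
    stub.var = -1;
    stub.threshold = NA_REAL;
    stub.decrease = NA_REAL;
    stub.p_left = NA_REAL;
    stub.left = stub.right = -1;

    std::vector<int> cnt(nclass_, 0);
    for (int i = lo; i < hi; ++i) cnt[y_[rows_[order_[0][i]]]]++;
    int pred = 0;
    for (int k = 1; k < nclass_; ++k)
      if (cnt[k] > cnt[pred]) pred = k;
    nodes_[id].pred = pred;

    double g_parent = gini_from_counts(cnt, n);
    bool pure = false;
    for (int k = 0; k < nclass_; ++k)
      if (cnt[k] == n) pure = true;
    if (pure || n <= min_node_ || n < 2) return id;

    // draw mtry candidate variables, scanned in priority order so the
    // first-max rule breaks decrease ties toward the preferred variable
    int p = X_.ncol();
    std::vector<int> cand = sample_vars(p, mtry_);
    const std::vector<int> &prio = prio_;
    std::sort(cand.begin(), cand.end(),
              [&prio](int a, int b) { return prio[a] < prio[b]; });

    int best_var = -1;
    double best_dec = 0.0, best_thr = 0.0, best_pl = 0.0;
    for (int v : cand) {
      double dec, thr, pl;
      if (scan_primary(X_, y_, nclass_, rows_, order_[v].data() + lo, n, v,
                       g_parent, dec, thr, pl)) {
        if (best_var < 0 || dec > best_dec + 1e-12) {
          best_var = v;
          best_dec = dec;
          best_thr = thr;
          best_pl = pl;
        }
      }
    }
    if (best_var < 0 || best_dec <= 0.0) return id;

    // primary partition over node slots
    int n_left = 0;
    std::vector<char> go_left_slot;  // indexed by slot (position in rows_)
    go_left_slot.assign(rows_.size(), 0);
    for (int i = lo; i < hi; ++i) {
      int slot = order_[best_var][i];
      if (X_(rows_[slot], best_var) <= best_thr) {
        go_left_slot[slot] = 1;
        n_left++;
      }
    }
    if (n_left == 0 || n_left == n) return id;  // degenerate; keep leaf

    NodeRec &nd = nodes_[id];
    nd.is_leaf = false;
    nd.var = best_var;
    nd.threshold = best_thr;
    nd.decrease = best_dec;
    nd.p_left = (double)n_left / n;

    // surrogate search over every other variable
    if (s_ > 0) {
      std::vector<SurrogateRec> all;
      all.reserve(p > 0 ? p - 1 : 0);
      for (int v = 0; v < p; ++v) {
        if (v == best_var) continue;
        SurrogateRec rec;
        rec.adjusted = -1.0;
        if (scan_surrogate(X_, rows_, order_[v].data() + lo, n, v,
                           go_left_slot, n_left, rec) &&
            rec.adjusted > 0.0)
          all.push_back(rec);
      }
      std::stable_sort(all.begin(), all.end(),
                       [&prio](const SurrogateRec &a, const SurrogateRec &b) {
                         if (a.adjusted != b.adjusted)
                           return a.adjusted > b.adjusted;
                         return prio[a.var] < prio[b.var];
                       });
      if ((int)all.size() > s_) all.resize(s_);
      nodes_[id].surr = std::move(all);
    }

    // stable partition of every variable's order slice by the primary split
    std::vector<int> buf_l, buf_r;
    buf_l.reserve(n_left);
    buf_r.reserve(n - n_left);
    for (int v = 0; v < p; ++v) {
      buf_l.clear();
      buf_r.clear();
      std::vector<int> &o = order_[v];
      for (int i = lo; i < hi; ++i) {
        if (go_left_slot[o[i]])
          buf_l.push_back(o[i]);
        else
          buf_r.push_back(o[i]);
      }
      std::copy(buf_l.begin(), buf_l.end(), o.begin() + lo);
      std::copy(buf_r.begin(), buf_r.end(), o.begin() + lo + n_left);
    }

    int left_id = grow(lo, lo + n_left, depth + 1);
    nodes_[id].left = left_id;
    int right_id = grow(lo + n_left, hi, depth + 1);
    nodes_[id].right = right_id;
    return id;
  }

  std::vector<int> sample_vars(int p, int m) {
    if (m >= p) {
      std::vector<int> all(p);
      for (int i = 0; i < p; ++i) all[i] = i;
      return all;
    }
    // partial Fisher-Yates with plain modulo draws (deterministic given seed)
    std::vector<int> pool(p);
    for (int i = 0; i < p; ++i) pool[i] = i;
    std::vector<int> out(m);
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(rng_() % (unsigned)(p - i));
      std::swap(pool[i], pool[j]);
      out[i] = pool[i];
    }
    return out;
  }

  const NumericMatrix &X_;
  const IntegerVector &y_;
  int nclass_, mtry_, s_, min_node_;
  std::mt19937 &rng_;
  std::vector<int> prio_;
  std::vector<int> rows_;
  std::vector<std::vector<int>> order_;
  std::vector<NodeRec> nodes_;
};

List tree_to_list(const std::vector<NodeRec> &nodes,
                  const std::vector<int> &inbag,
                  const std::vector<int> &prio) {
  int m = nodes.size();
  IntegerVector id(m), depth(m), size(m), pred(m), var(m), left(m), right(m);
  LogicalVector is_leaf(m);
  NumericVector threshold(m), decrease(m), p_left(m);
  int nsurr = 0;
  for (const NodeRec &nd : nodes) nsurr += nd.surr.size();
  IntegerVector s_node(nsurr), s_var(nsurr);
  NumericVector s_thr(nsurr), s_agree(nsurr), s_adj(nsurr);
  LogicalVector s_mirror(nsurr);
  int k = 0;
  for (int i = 0; i < m; ++i) {
    const NodeRec &nd = nodes[i];
    id[i] = nd.id + 1;
    depth[i] = nd.depth;
    size[i] = nd.size;
    is_leaf[i] = nd.is_leaf;
    pred[i] = nd.pred + 1;
    var[i] = nd.is_leaf ? NA_INTEGER : nd.var + 1;
    threshold[i] = nd.threshold;
    decrease[i] = nd.decrease;
    p_left[i] = nd.p_left;
    left[i] = nd.left < 0 ? NA_INTEGER : nd.left + 1;
    right[i] = nd.right < 0 ? NA_INTEGER : nd.right + 1;
    for (const SurrogateRec &sr : nd.surr) {
      s_node[k] = nd.id + 1;
      s_var[k] = sr.var + 1;
      s_thr[k] = sr.threshold;
      s_mirror[k] = sr.mirrored;
      s_agree[k] = sr.agreement;
      s_adj[k] = sr.adjusted;
      ++k;
    }
  }
  IntegerVector ib(inbag.begin(), inbag.end());
  IntegerVector pr(prio.size());
  for (size_t i = 0; i < prio.size(); ++i) pr[i] = prio[i] + 1;
  return List::create(
      _["nodes"] = List::create(
          _["id"] = id, _["depth"] = depth, _["size"] = size,
          _["is_leaf"] = is_leaf, _["pred"] = pred, _["var"] = var,
          _["threshold"] = threshold, _["decrease"] = decrease,
          _["p_left"] = p_left, _["left"] = left, _["right"] = right),
      _["surrogates"] = List::create(
          _["node"] = s_node, _["var"] = s_var, _["threshold"] = s_thr,
          _["mirrored"] = s_mirror, _["agreement"] = s_agree,
          _["adjusted"] = s_adj),
      _["inbag"] = ib, _["tie_priority"] = pr);
}

}  // namespace

// [[Rcpp::export(name = ".fit_forest_cpp")]]
List fit_forest_cpp(NumericMatrix X, IntegerVector y, int nclass,
                    int num_trees, int mtry, int s, int min_node_size,
                    bool bootstrap, IntegerVector tree_seeds) {
  int n = X.nrow();
  int p = X.ncol();
  List trees(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    std::mt19937 rng((unsigned)tree_seeds[t]);
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) rows[i] = (int)(rng() % (unsigned)n);
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    std::vector<int> inbag(rows.size());
    for (size_t i = 0; i < rows.size(); ++i) inbag[i] = rows[i] + 1;
    // per-tree tie-break priorities: random permutation of the variables
    std::vector<int> perm(p), prio(p);
    for (int i = 0; i < p; ++i) perm[i] = i;
    for (int i = 0; i < p - 1; ++i) {
      int j = i + (int)(rng() % (unsigned)(p - i));
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < p; ++i) prio[perm[i]] = i;
    TreeBuilder tb(X, y, nclass, mtry, s, min_node_size, rng, prio);
    std::vector<NodeRec> nodes = tb.build(rows);
    trees[t] = tree_to_list(nodes, inbag, prio);
  }
  return trees;
}
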