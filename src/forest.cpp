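// Random-forest engine for case-control dosage data.
//
// Requirements that rule out off-the-shelf forests: full per-node tree
// structure must be returned to R (the epistasis statistics are computed on
// it), class balance is enforced through weighted bootstrap *sampling*, and
// corrected (shadow-debiased) impurity importance needs per-candidate
// bookkeeping inside the split search. All randomness comes from an
// own-rolled xoshiro256++ generator so results are byte-identical across
// platforms for a given seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG: splitmix64 seeding + xoshiro256++
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, n); n < 2^32
  inline int unif_int(int n) {
    uint32_t r = (uint32_t)(next() >> 32);
    return (int)(((uint64_t)r * (uint64_t)n) >> 32);
  }
  inline double unif_double() { return (next() >> 11) * 0x1.0p-53; }
};

// ---------------------------------------------------------------------------
// Tree containers
// ---------------------------------------------------------------------------

struct TreeNodes {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> split;  // NA for leaf
  std::vector<int> left, right;
  std::vector<int> n, ncase, nctrl;
  std::vector<int> pred;  // leaf prediction (majority in-bag class)
  int add(int nn, int ncs, int nct) {
    feature.push_back(-1);
    split.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    n.push_back(nn);
    ncase.push_back(ncs);
    nctrl.push_back(nct);
    pred.push_back(ncs >= nct ? 1 : 0);
    return (int)feature.size() - 1;
  }
};

// Gini "decrease in counts" for a parent split into (aL,bL) / (aR,bR)
// where a = controls, b = cases; equals n_p*g_p - nL*gL - nR*gR rearranged.
static inline double gini_dec_counts(double aL, double bL, double aR, double bR) {
  double nL = aL + bL, nR = aR + bR, np = nL + nR;
  if (nL <= 0.0 || nR <= 0.0) return -1.0;  // invalid split
  double a = aL + aR, b = bL + bR;
  return (aL * aL + bL * bL) / nL + (aR * aR + bR * bR) / nR -
         (a * a + b * b) / np;
}

// best split of a 3x2 dosage-class count table over thresholds 0.5, 1.5;
// returns decrease in counts (or -1 if none valid), sets thr.
static inline double best_split_table(const int cnt[3][2], double &thr) {
  double best = -1.0;
  // threshold 0.5: dosage {0} left
  double d1 = gini_dec_counts(cnt[0][0], cnt[0][1], cnt[1][0] + cnt[2][0],
                              cnt[1][1] + cnt[2][1]);
  if (d1 > best) { best = d1; thr = 0.5; }
  // threshold 1.5: dosage {0,1} left
  double d2 = gini_dec_counts(cnt[0][0] + cnt[1][0], cnt[0][1] + cnt[1][1],
                              cnt[2][0], cnt[2][1]);
  if (d2 > best) { best = d2; thr = 1.5; }
  return best;
}

struct BuildCtx {
  const int *x;  // n x p column-major dosages
  const int *y;  // 0/1
  int n, p;
  int mtry;
  int min_node_size;
  double inv_ninbag;
  const int *shadow_perm;  // per-tree subject permutation for shadow copies
  // importance accumulators (across forest)
  std::vector<double> gini_acc, corr_acc;
  std::vector<int> cand_nodes;
};

struct StackItem {
  int node_id, start, end;
};

// grow one tree; idx is the in-bag index buffer (length n_inbag, repeats ok)
static void grow_tree(BuildCtx &ctx, Xoshiro &rng, std::vector<int> &idx,
                      std::vector<int> &feat_pool, TreeNodes &tree,
                      std::vector<char> &feat_in_tree) {
  const int *x = ctx.x;
  const int *y = ctx.y;
  const int n = ctx.n;
  int n_inbag = (int)idx.size();

  // root
  int ncs = 0;
  for (int k = 0; k < n_inbag; ++k) ncs += y[idx[k]];
  int root = tree.add(n_inbag, ncs, n_inbag - ncs);

  std::vector<StackItem> stack;
  stack.push_back({root, 0, n_inbag});

  while (!stack.empty()) {
    StackItem it = stack.back();
    stack.pop_back();
    int sz = it.end - it.start;
    int node_cs = tree.ncase[it.node_id];
    int node_ct = tree.nctrl[it.node_id];
    if (sz <= ctx.min_node_size || node_cs == 0 || node_ct == 0) continue;

    // sample mtry candidate features (partial Fisher-Yates)
    for (int t = 0; t < ctx.mtry; ++t) {
      int j = t + rng.unif_int(ctx.p - t);
      std::swap(feat_pool[t], feat_pool[j]);
    }

    double best_dec = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    for (int t = 0; t < ctx.mtry; ++t) {
      int f = feat_pool[t];
      const int *xf = x + (size_t)f * (size_t)n;
      int cnt[3][2] = {{0, 0}, {0, 0}, {0, 0}};
      for (int k = it.start; k < it.end; ++k) {
        int s = idx[k];
        ++cnt[xf[s]][y[s]];
      }
      // constant-in-node candidates fall through: both thresholds are
      // invalid (-1 -> clipped to 0), keeping actual and shadow terms
      // exchangeable for every candidate evaluation
      double thr_a = 0.0;
      double dec_a = best_split_table(cnt, thr_a);
      double dec_a0 = dec_a > 0.0 ? dec_a : 0.0;

      // shadow: the tree's permuted copy of the same feature, i.e. the
      // feature indexed through the tree-level subject permutation; the
      // bootstrap duplication structure is preserved, so actual and
      // shadow tables are exchangeable under the null
      int sh[3][2] = {{0, 0}, {0, 0}, {0, 0}};
      for (int k = it.start; k < it.end; ++k) {
        int s = idx[k];
        ++sh[xf[ctx.shadow_perm[s]]][y[s]];
      }
      double thr_s = 0.0;
      double dec_s = best_split_table(sh, thr_s);
      double dec_s0 = dec_s > 0.0 ? dec_s : 0.0;

      ctx.corr_acc[f] += (dec_a0 - dec_s0) * ctx.inv_ninbag;
      ++ctx.cand_nodes[f];

      if (dec_a > best_dec) {
        best_dec = dec_a;
        best_f = f;
        best_thr = thr_a;
      }
    }

    if (best_f < 0) continue;  // no improving split -> leaf

    ctx.gini_acc[best_f] += best_dec * ctx.inv_ninbag;
    feat_in_tree[best_f] = 1;

    // partition idx[start, end) in place: dosage <= thr goes left
    const int *xf = x + (size_t)best_f * (size_t)n;
    int lo = it.start, hi = it.end - 1;
    while (lo <= hi) {
      if ((double)xf[idx[lo]] <= best_thr) {
        ++lo;
      } else {
        std::swap(idx[lo], idx[hi]);
        --hi;
      }
    }
    int mid = lo;
    int ncsL = 0;
    for (int k = it.start; k < mid; ++k) ncsL += y[idx[k]];
    int nL = mid - it.start, nR = it.end - mid;

    int lid = tree.add(nL, ncsL, nL - ncsL);
    int rid = tree.add(nR, node_cs - ncsL, nR - (node_cs - ncsL));
    tree.feature[it.node_id] = best_f;
    tree.split[it.node_id] = best_thr;
    tree.left[it.node_id] = lid;
    tree.right[it.node_id] = rid;
    // children pushed right-first so left is processed first (cosmetic)
    stack.push_back({rid, mid, it.end});
    stack.push_back({lid, it.start, mid});
  }
}

// predict one subject through a tree, optionally overriding feature
// `ovr_f`'s value with `ovr_val`
static inline int tree_predict(const TreeNodes &tr, const int *x, int n,
                               int s, int ovr_f, int ovr_val) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    int f = tr.feature[node];
    int v = (f == ovr_f) ? ovr_val : x[(size_t)f * (size_t)n + s];
    node = ((double)v <= tr.split[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(IntegerMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node_size, double seed_d,
                  bool compute_permutation, bool keep_inbag) {
  const int n = X.nrow(), p = X.ncol();
  const int *xp = INTEGER(X);
  std::vector<int> yv(n);
  int n_case = 0;
  for (int i = 0; i < n; ++i) {
    yv[i] = y[i];
    n_case += y[i];
  }
  int n_ctrl = n - n_case;
  if (n_case == 0 || n_ctrl == 0)
    stop("phenotype must contain both cases and controls");
  for (int i = 0; i < n * p; ++i)
    if (xp[i] < 0 || xp[i] > 2) stop("dosages must be 0, 1 or 2 (no missing)");

  std::vector<int> case_ids, ctrl_ids;
  case_ids.reserve(n_case);
  ctrl_ids.reserve(n_ctrl);
  for (int i = 0; i < n; ++i) (yv[i] ? case_ids : ctrl_ids).push_back(i);

  BuildCtx ctx;
  ctx.x = xp;
  ctx.y = yv.data();
  ctx.n = n;
  ctx.p = p;
  ctx.mtry = mtry;
  ctx.min_node_size = min_node_size;
  ctx.inv_ninbag = 1.0 / (double)n;
  ctx.gini_acc.assign(p, 0.0);
  ctx.corr_acc.assign(p, 0.0);
  ctx.cand_nodes.assign(p, 0);

  uint64_t forest_seed = (uint64_t)seed_d;
  List trees(n_trees);
  NumericVector case_frac(n_trees);
  IntegerMatrix inbag_mat = keep_inbag ? IntegerMatrix(n, n_trees)
                                       : IntegerMatrix(0, 0);

  std::vector<double> perm_acc(p, 0.0);
  int perm_trees_used = 0;

  // class-weighted accuracy weights (per-subject)
  double w_case = 0.5 / (double)n_case, w_ctrl = 0.5 / (double)n_ctrl;

  // forest-level OOB vote tallies
  std::vector<int> oob_votes1(n, 0), oob_times(n, 0);

  std::vector<int> idx(n), feat_pool(p), inbag_cnt(n), shadow_perm(n);
  std::vector<int> oob_ids, perm_ids;
  std::vector<char> feat_in_tree(p);

  for (int t = 0; t < n_trees; ++t) {
    uint64_t sm = forest_seed;
    uint64_t tseed = splitmix64(sm) ^ (0x9e3779b97f4a7c15ULL * (uint64_t)(t + 1));
    Xoshiro rng(tseed);

    // weighted bootstrap: draw class with prob 1/2, subject uniform in class
    std::fill(inbag_cnt.begin(), inbag_cnt.end(), 0);
    int draws_case = 0;
    for (int k = 0; k < n; ++k) {
      int s;
      if (rng.unif_double() < 0.5) {
        s = case_ids[rng.unif_int(n_case)];
        ++draws_case;
      } else {
        s = ctrl_ids[rng.unif_int(n_ctrl)];
      }
      idx[k] = s;
      ++inbag_cnt[s];
    }
    case_frac[t] = (double)draws_case / (double)n;
    if (keep_inbag)
      for (int i = 0; i < n; ++i) inbag_mat(i, t) = inbag_cnt[i];

    for (int f = 0; f < p; ++f) feat_pool[f] = f;
    std::fill(feat_in_tree.begin(), feat_in_tree.end(), 0);

    // tree-level subject permutation defining this tree's shadow copies
    for (int i = 0; i < n; ++i) shadow_perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = rng.unif_int(i + 1);
      std::swap(shadow_perm[i], shadow_perm[j]);
    }
    ctx.shadow_perm = shadow_perm.data();

    TreeNodes tr;
    grow_tree(ctx, rng, idx, feat_pool, tr, feat_in_tree);

    // OOB bookkeeping
    oob_ids.clear();
    for (int i = 0; i < n; ++i)
      if (inbag_cnt[i] == 0) oob_ids.push_back(i);

    if (!oob_ids.empty()) {
      double wsum = 0.0, acc_base = 0.0;
      std::vector<int> base_pred(oob_ids.size());
      for (size_t k = 0; k < oob_ids.size(); ++k) {
        int s = oob_ids[k];
        int pr = tree_predict(tr, xp, n, s, -1, 0);
        base_pred[k] = pr;
        double w = yv[s] ? w_case : w_ctrl;
        wsum += w;
        if (pr == yv[s]) acc_base += w;
        ++oob_times[s];
        if (pr == 1) ++oob_votes1[s];
      }
      acc_base /= wsum;

      if (compute_permutation) {
        ++perm_trees_used;
        size_t m = oob_ids.size();
        perm_ids.resize(m);
        for (int f = 0; f < p; ++f) {
          if (!feat_in_tree[f]) continue;  // difference is exactly 0
          // permute feature f's OOB values (permutation of subjects)
          for (size_t k = 0; k < m; ++k) perm_ids[k] = oob_ids[k];
          for (size_t k = m - 1; k > 0; --k) {
            int j = rng.unif_int((int)k + 1);
            std::swap(perm_ids[k], perm_ids[j]);
          }
          double acc_perm = 0.0;
          const int *xf = xp + (size_t)f * (size_t)n;
          for (size_t k = 0; k < m; ++k) {
            int s = oob_ids[k];
            int pr = tree_predict(tr, xp, n, s, f, xf[perm_ids[k]]);
            double w = yv[s] ? w_case : w_ctrl;
            if (pr == yv[s]) acc_perm += w;
          }
          acc_perm /= wsum;
          perm_acc[f] += acc_base - acc_perm;
        }
      }
    }

    int nn = (int)tr.feature.size();
    IntegerVector feature(nn), left(nn), right(nn), nnode(nn), ncs(nn),
        nct(nn), pred(nn);
    NumericVector split(nn);
    for (int k = 0; k < nn; ++k) {
      feature[k] = tr.feature[k] >= 0 ? tr.feature[k] + 1 : NA_INTEGER;
      split[k] = tr.split[k];
      left[k] = tr.left[k] >= 0 ? tr.left[k] + 1 : NA_INTEGER;
      right[k] = tr.right[k] >= 0 ? tr.right[k] + 1 : NA_INTEGER;
      nnode[k] = tr.n[k];
      ncs[k] = tr.ncase[k];
      nct[k] = tr.nctrl[k];
      pred[k] = tr.pred[k];
    }
    trees[t] = List::create(
        Named("feature") = feature, Named("split") = split,
        Named("left") = left, Named("right") = right, Named("n") = nnode,
        Named("n_case") = ncs, Named("n_ctrl") = nct, Named("pred") = pred);
  }

  // forest-level class-weighted OOB accuracy (majority vote)
  double acc_w = 0.0, acc_wsum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (oob_times[i] == 0) continue;
    int pr = (2 * oob_votes1[i] >= oob_times[i]) ? 1 : 0;
    double w = yv[i] ? w_case : w_ctrl;
    acc_wsum += w;
    if (pr == yv[i]) acc_w += w;
  }
  double oob_acc = acc_wsum > 0 ? acc_w / acc_wsum : NA_REAL;

  NumericVector perm_imp(p, NA_REAL);
  if (compute_permutation) {
    for (int f = 0; f < p; ++f)
      perm_imp[f] = perm_trees_used > 0 ? perm_acc[f] / perm_trees_used
                                        : 0.0;
  }

  return List::create(
      Named("trees") = trees,
      Named("importance_gini") = NumericVector(ctx.gini_acc.begin(),
                                               ctx.gini_acc.end()),
      Named("importance_corrected") = NumericVector(ctx.corr_acc.begin(),
                                                    ctx.corr_acc.end()),
      Named("candidate_nodes") = IntegerVector(ctx.cand_nodes.begin(),
                                               ctx.cand_nodes.end()),
      Named("importance_permutation") = perm_imp,
      Named("case_draw_fraction") = case_frac,
      Named("oob_balanced_accuracy") = oob_acc,
      Named("inbag") = inbag_mat);
}

// Recompute class-weighted permutation importance from a stored forest.
// Needs the per-tree in-bag multiplicities to recover OOB membership.
// [[Rcpp::export(name = ".rf_perm_cpp")]]
NumericVector rf_perm_cpp(List trees, IntegerMatrix X, IntegerVector y,
                          IntegerMatrix inbag, double seed_d) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  if (inbag.nrow() != n || inbag.ncol() != T)
    stop("inbag matrix does not match forest/data dimensions");
  const int *xp = INTEGER(X);
  int n_case = 0;
  for (int i = 0; i < n; ++i) n_case += y[i];
  int n_ctrl = n - n_case;
  double w_case = 0.5 / (double)n_case, w_ctrl = 0.5 / (double)n_ctrl;

  std::vector<double> acc(p, 0.0);
  int trees_used = 0;
  uint64_t base = (uint64_t)seed_d;

  for (int t = 0; t < T; ++t) {
    List trl = trees[t];
    IntegerVector feature = trl["feature"], left = trl["left"],
                  right = trl["right"], pred = trl["pred"];
    NumericVector split = trl["split"];
    int nn = feature.size();
    TreeNodes tr;
    tr.feature.resize(nn); tr.split.resize(nn);
    tr.left.resize(nn); tr.right.resize(nn); tr.pred.resize(nn);
    std::vector<char> in_tree(p, 0);
    for (int k = 0; k < nn; ++k) {
      tr.feature[k] = feature[k] == NA_INTEGER ? -1 : feature[k] - 1;
      tr.split[k] = split[k];
      tr.left[k] = left[k] == NA_INTEGER ? -1 : left[k] - 1;
      tr.right[k] = right[k] == NA_INTEGER ? -1 : right[k] - 1;
      tr.pred[k] = pred[k];
      if (tr.feature[k] >= 0) in_tree[tr.feature[k]] = 1;
    }
    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    if (oob.empty()) continue;
    ++trees_used;

    uint64_t sm = base;
    Xoshiro rng(splitmix64(sm) ^ (0x9e3779b97f4a7c15ULL * (uint64_t)(t + 1)));

    double wsum = 0.0, acc_base = 0.0;
    for (size_t k = 0; k < oob.size(); ++k) {
      int s = oob[k];
      int pr = tree_predict(tr, xp, n, s, -1, 0);
      double w = y[s] ? w_case : w_ctrl;
      wsum += w;
      if (pr == y[s]) acc_base += w;
    }
    acc_base /= wsum;

    size_t m = oob.size();
    std::vector<int> perm(m);
    for (int f = 0; f < p; ++f) {
      if (!in_tree[f]) continue;
      for (size_t k = 0; k < m; ++k) perm[k] = oob[k];
      for (size_t k = m - 1; k > 0; --k) {
        int j = rng.unif_int((int)k + 1);
        std::swap(perm[k], perm[j]);
      }
      const int *xf = xp + (size_t)f * (size_t)n;
      double acc_perm = 0.0;
      for (size_t k = 0; k < m; ++k) {
        int s = oob[k];
        int pr = tree_predict(tr, xp, n, s, f, xf[perm[k]]);
        double w = y[s] ? w_case : w_ctrl;
        if (pr == y[s]) acc_perm += w;
      }
      acc_perm /= wsum;
      acc[f] += acc_base - acc_perm;
    }
  }
  NumericVector out(p);
  for (int f = 0; f < p; ++f)
    out[f] = trees_used > 0 ? acc[f] / trees_used : 0.0;
  return out;
}

// Per-tree subtree feature membership + asymmetry bookkeeping for a
// feature set. For every internal node splitting on feature i, checks
// whether each other feature j occurs in the left / right daughter
// subtree. n_left / n_right count every occurrence (both daughters may
// count, matching the selection-asymmetry definition). For the calibrated
// test, every *exclusive* occurrence is recorded as a trial whose null
// probability is node-matched and empirical: the fraction of the OTHER
// selected features that, at this same node, landed in the left daughter
// among their exclusive occurrences. Co-features at the same node are
// perfectly matched controls for daughter size, depth and class purity;
// a pair-specific interaction is exactly a deviation from them.
// [[Rcpp::export(name = ".rf_asymmetry_cpp")]]
List rf_asymmetry_cpp(List trees, IntegerVector features) {
  int K = features.size();
  std::vector<int> fmap;  // feature id (1-based) -> index in features, else -1
  int maxf = 0;
  for (int k = 0; k < K; ++k) maxf = std::max(maxf, features[k]);
  fmap.assign(maxf + 1, -1);
  for (int k = 0; k < K; ++k) fmap[features[k]] = k;

  IntegerMatrix nL(K, K), nR(K, K);
  std::vector<double> tr_i, tr_j, tr_q, tr_x, tr_m;

  std::vector<int> ex_g; ex_g.reserve(K);
  std::vector<char> ex_o; ex_o.reserve(K);

  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    IntegerVector left = tr["left"], right = tr["right"];
    int nn = feature.size();
    int words = (K + 63) / 64;
    std::vector<uint64_t> sub((size_t)nn * words, 0ULL);
    // children are stored after parents: reverse order is a post-order
    for (int v = nn - 1; v >= 0; --v) {
      if (feature[v] == NA_INTEGER) continue;
      uint64_t *me = &sub[(size_t)v * words];
      int f = feature[v];
      if (f <= maxf && fmap[f] >= 0) {
        int k = fmap[f];
        me[k >> 6] |= (1ULL << (k & 63));
      }
      int l = left[v] - 1, r = right[v] - 1;
      const uint64_t *lv = &sub[(size_t)l * words];
      const uint64_t *rv = &sub[(size_t)r * words];
      for (int w = 0; w < words; ++w) me[w] |= lv[w] | rv[w];
    }
    for (int v = 0; v < nn; ++v) {
      if (feature[v] == NA_INTEGER) continue;
      int f = feature[v];
      if (f > maxf || fmap[f] < 0) continue;
      int ki = fmap[f];
      const uint64_t *lv = &sub[(size_t)(left[v] - 1) * words];
      const uint64_t *rv = &sub[(size_t)(right[v] - 1) * words];
      ex_g.clear();
      ex_o.clear();
      for (int kj = 0; kj < K; ++kj) {
        if (kj == ki) continue;
        bool inl = lv[kj >> 6] & (1ULL << (kj & 63));
        bool inr = rv[kj >> 6] & (1ULL << (kj & 63));
        if (inl) ++nL(ki, kj);
        if (inr) ++nR(ki, kj);
        if (inl != inr) {
          ex_g.push_back(kj);
          ex_o.push_back(inl ? 1 : 0);
        }
      }
      int m = (int)ex_g.size();
      if (m < 2) continue;  // no co-feature controls at this node
      int lefts = 0;
      for (int e = 0; e < m; ++e) lefts += ex_o[e];
      for (int e = 0; e < m; ++e) {
        // Jeffreys-smoothed leave-one-out control fraction: keeps the
        // estimated null probability off the degenerate 0/1 boundary
        double q = ((double)(lefts - ex_o[e]) + 0.5) / (double)(m - 1 + 1);
        tr_i.push_back(ki + 1);
        tr_j.push_back(ex_g[e] + 1);
        tr_q.push_back(q);
        tr_x.push_back(ex_o[e] ? 1.0 : 0.0);
        tr_m.push_back(m - 1);
      }
    }
  }
  NumericMatrix trials(tr_i.size(), 5);
  for (size_t r = 0; r < tr_i.size(); ++r) {
    trials(r, 0) = tr_i[r];
    trials(r, 1) = tr_j[r];
    trials(r, 2) = tr_q[r];
    trials(r, 3) = tr_x[r];
    trials(r, 4) = tr_m[r];
  }
  colnames(trials) = CharacterVector::create("i", "j", "q", "left", "m");
  return List::create(Named("n_left") = nL, Named("n_right") = nR,
                      Named("trials") = trials);
}
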