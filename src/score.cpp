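#include <Rcpp.h>
using namespace Rcpp;

// Parsimony scoring kernel.
//
// Trees arrive as postorder edge matrices (two columns: parent, child),
// node ids 1-based, tips 1..ntip, internal nodes > ntip.  Postorder means
// every edge inside a child's subtree appears before the edge joining the
// child to its parent, which is exactly what ape::reorder(phy, "postorder")
// produces.  The fold below is exact for binary trees rooted anywhere
// (including the basal trichotomy of an unrooted ape tree, which is
// equivalent to rooting along one of the three basal edges).

static const double INF = 1e12;
static const int FULL_MASK = (1 << 10) - 1; // states 0..9

// Fitch fold for one unordered character over one tree.
// tipmask: per-taxon state bitmask (FULL_MASK for missing).
static int fitch_steps(const IntegerMatrix &edge, int ntip, int maxnode,
                       const std::vector<int> &tipmask,
                       std::vector<int> &acc) {
  std::fill(acc.begin(), acc.end(), FULL_MASK);
  int steps = 0;
  const int ne = edge.nrow();
  for (int i = 0; i < ne; ++i) {
    int p = edge(i, 0), c = edge(i, 1);
    int sc = (c <= ntip) ? tipmask[c - 1] : acc[c - 1];
    int a = acc[p - 1] & sc;
    if (a == 0) {
      a = acc[p - 1] | sc;
      ++steps;
    }
    acc[p - 1] = a;
  }
  return steps;
}

// Sankoff fold with linear (ordered) or irreversible (increase-only) costs.
// mode: 1 ordered, 2 irreversible. For irreversible the tree is scored as
// rooted at the encoding root and the root state is fixed to root_state.
static double sankoff_steps(const IntegerMatrix &edge, int ntip, int maxnode,
                            const std::vector<int> &tipstate, int nst,
                            int mode, int root_state,
                            std::vector<double> &acc) {
  std::fill(acc.begin(), acc.end(), 0.0);
  const int ne = edge.nrow();
  std::vector<double> childvec(nst);
  for (int i = 0; i < ne; ++i) {
    int p = edge(i, 0), c = edge(i, 1);
    if (c <= ntip) {
      int st = tipstate[c - 1];
      for (int s = 0; s < nst; ++s)
        childvec[s] = (st < 0 || st == s) ? 0.0 : INF;
    } else {
      for (int s = 0; s < nst; ++s) childvec[s] = acc[(c - 1) * nst + s];
    }
    for (int s = 0; s < nst; ++s) {
      double best = INF;
      for (int t = 0; t < nst; ++t) {
        double w;
        if (mode == 1) w = std::abs(t - s);
        else w = (t >= s) ? (t - s) : INF;
        double v = childvec[t] + w;
        if (v < best) best = v;
      }
      acc[(p - 1) * nst + s] += best;
    }
  }
  int root = edge(ne - 1, 0);
  double res;
  if (mode == 2) {
    res = acc[(root - 1) * nst + root_state];
  } else {
    res = INF;
    for (int s = 0; s < nst; ++s)
      res = std::min(res, acc[(root - 1) * nst + s]);
  }
  return res;
}

// [[Rcpp::export]]
SEXP score_trees_cpp(List edges, int ntip, IntegerMatrix states,
                     IntegerVector modes, NumericVector weights,
                     IntegerVector root_states, bool per_char) {
  const int ntree = edges.size();
  const int nchar = states.ncol();
  if (states.nrow() != ntip) stop("states must have one row per tip");
  if (modes.size() != nchar || weights.size() != nchar ||
      root_states.size() != nchar)
    stop("modes/weights/root_states must have one entry per character");

  // per-character tip encodings
  std::vector<std::vector<int>> tipmask(nchar, std::vector<int>(ntip));
  std::vector<std::vector<int>> tipstate(nchar, std::vector<int>(ntip));
  std::vector<int> nst(nchar, 1);
  for (int j = 0; j < nchar; ++j) {
    int mx = 0;
    for (int i = 0; i < ntip; ++i) {
      int s = states(i, j);
      tipstate[j][i] = (s == NA_INTEGER) ? -1 : s;
      if (s != NA_INTEGER && s > mx) mx = s;
      tipmask[j][i] = (s == NA_INTEGER) ? FULL_MASK : (1 << s);
    }
    nst[j] = mx + 1;
  }

  NumericMatrix percol(per_char ? ntree : 0, per_char ? nchar : 0);
  NumericVector totals(ntree);

  std::vector<int> accI;
  std::vector<double> accD;
  for (int t = 0; t < ntree; ++t) {
    IntegerMatrix edge = edges[t];
    int maxnode = 0;
    for (int i = 0; i < edge.nrow(); ++i) {
      maxnode = std::max(maxnode, edge(i, 0));
      maxnode = std::max(maxnode, edge(i, 1));
    }
    if ((int)accI.size() < maxnode) accI.resize(maxnode);
    double tot = 0.0;
    for (int j = 0; j < nchar; ++j) {
      double s;
      if (modes[j] == 0) {
        s = fitch_steps(edge, ntip, maxnode, tipmask[j], accI);
      } else {
        if ((int)accD.size() < maxnode * nst[j]) accD.resize(maxnode * nst[j]);
        s = sankoff_steps(edge, ntip, maxnode, tipstate[j], nst[j], modes[j],
                          root_states[j], accD);
        if (s >= INF / 2) s = R_PosInf;
      }
      if (per_char) percol(t, j) = s;
      tot += s * weights[j];
    }
    totals[t] = (tot >= INF / 2) ? R_PosInf : tot;
  }
  if (per_char) return percol;
  return totals;
}
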