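#include <Rcpp.h>
using namespace Rcpp;

// Residue codes shared with the R side:
// 0 = gap ('-'/'.'), 1 = A, 2 = C, 3 = G, 4 = U, 5 = N.

// G-test of independence over the 4x4 joint residue counts of columns i, j
// (0-based here), on rows where both positions hold a definite residue.
// Terms with n_ab = 0 contribute 0. Returns 0 with fewer than 2 usable rows.
static double pair_g(const IntegerMatrix& m, int i, int j) {
  int n[4][4] = {{0}};
  int ra[4] = {0}, rb[4] = {0};
  int N = 0;
  const int nr = m.nrow();
  for (int r = 0; r < nr; ++r) {
    const int a = m(r, i), b = m(r, j);
    if (a >= 1 && a <= 4 && b >= 1 && b <= 4) {
      ++n[a - 1][b - 1];
      ++ra[a - 1];
      ++rb[b - 1];
      ++N;
    }
  }
  if (N < 2) return 0.0;
  double g = 0.0;
  for (int a = 0; a < 4; ++a) {
    if (!ra[a]) continue;
    for (int b = 0; b < 4; ++b) {
      if (n[a][b] > 0) {
        g += n[a][b] * std::log((double)n[a][b] * N / ((double)ra[a] * rb[b]));
      }
    }
  }
  g *= 2.0;
  return g > 0.0 ? g : 0.0;  // clamp -0.0 / rounding noise
}

// [[Rcpp::export]]
double cpp_pair_g(IntegerMatrix m, int i, int j) {
  return pair_g(m, i - 1, j - 1);
}

// All column pairs i < j; returns the flattened upper triangle in
// column-pair order (1,2),(1,3),(2,3),(1,4),... matching R's combn order
// would differ — we emit (i,j) ordered by i then j and also return the
// index columns, so the R side never re-derives the order.
// [[Rcpp::export]]
NumericMatrix cpp_all_pairs_g(IntegerMatrix m) {
  const int nc = m.ncol();
  const int np = nc * (nc - 1) / 2;
  NumericMatrix out(np, 3);
  int k = 0;
  for (int i = 0; i < nc - 1; ++i) {
    for (int j = i + 1; j < nc; ++j, ++k) {
      out(k, 0) = i + 1;
      out(k, 1) = j + 1;
      out(k, 2) = pair_g(m, i, j);
    }
  }
  colnames(out) = CharacterVector::create("i", "j", "stat");
  return out;
}

// Pooled null statistics: for each of n_null pre-shuffled alignments
// (stacked row-wise in `stack`, each `nr` rows), compute all pair stats.
// [[Rcpp::export]]
NumericVector cpp_pooled_null(IntegerMatrix stack, int nr, int n_null) {
  const int nc = stack.ncol();
  const int np = nc * (nc - 1) / 2;
  NumericVector out(np * n_null);
  int k = 0;
  for (int b = 0; b < n_null; ++b) {
    IntegerMatrix sub = stack(Range(b * nr, (b + 1) * nr - 1), Range(0, nc - 1));
    for (int i = 0; i < nc - 1; ++i) {
      for (int j = i + 1; j < nc; ++j) {
        out[k++] = pair_g(sub, i, j);
      }
    }
  }
  return out;
}

// ---- Weighted Nussinov / single-layer CYK fold -------------------------
//
// Maximizes the total weight of a nested set of base pairs. w(i,j) < 0
// marks an ineligible pair. Hairpin loops must span at least min_loop
// unpaired positions. Traceback is iterative (explicit stack) so long
// consensus sequences cannot overflow the C stack.

// [[Rcpp::export]]
List cpp_nussinov(NumericMatrix w, int min_loop) {
  const int L = w.nrow();
  NumericMatrix S(L + 1, L + 1);  // 1-based, S(i,j) for i..j
  for (int span = min_loop + 1; span < L; ++span) {
    for (int i = 1; i + span <= L; ++i) {
      const int j = i + span;
      double best = S(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (w(i - 1, k - 1) < 0) continue;
        double cand = w(i - 1, k - 1) + S(i + 1, k - 1);
        if (k < j) cand += S(k + 1, j);
        if (cand > best) best = cand;
      }
      S(i, j) = best;
    }
  }
  // traceback
  std::vector<int> pi, pj;
  std::vector<std::pair<int,int> > todo;
  if (L >= 2) todo.push_back(std::make_pair(1, L));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (i >= j) continue;
    if (S(i, j) == S(i + 1, j)) {
      todo.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (w(i - 1, k - 1) < 0) continue;
      double cand = w(i - 1, k - 1) + S(i + 1, k - 1);
      if (k < j) cand += S(k + 1, j);
      if (cand == S(i, j)) {
        pi.push_back(i);
        pj.push_back(k);
        todo.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) todo.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["score"] = (L >= 2 ? S(1, L) : 0.0),
                      _["pair_i"] = wrap(pi), _["pair_j"] = wrap(pj));
}

// ---- H/ACA guide-target scan -------------------------------------------

static inline bool is_pair(int a, int b) {
  // Watson-Crick + G:U wobble; N (5) and gap (0) never pair.
  return (a == 1 && b == 4) || (a == 4 && b == 1) ||
         (a == 3 && b == 2) || (a == 2 && b == 3) ||
         (a == 3 && b == 4) || (a == 4 && b == 3);
}

static inline bool is_wobble(int a, int b) {
  return (a == 3 && b == 4) || (a == 4 && b == 3);
}

// For every U in target (code 4), extend complementary runs outward from
// the pocket: upstream target[t-1], t-2, ... against guide3 5'->3', and
// downstream target[t+2], t+3, ... against guide5 read from its 3' end.
// Position t+1 stays unpaired (canonical pocket geometry). A hit needs
// both maximal runs >= min_bp with no internal mismatches.
// Columns: pos, left_bp, right_bp, n_wobble.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_guides(IntegerVector target, IntegerVector g5,
                              IntegerVector g3, int min_bp) {
  const int L = target.size(), L5 = g5.size(), L3 = g3.size();
  std::vector<int> pos, lbp, rbp, wob;
  for (int t = 1; t <= L; ++t) {
    if (target[t - 1] != 4) continue;
    int left = 0, wl = 0;
    for (int k = 1; k <= L3 && t - k >= 1; ++k) {
      const int a = target[t - k - 1 + 0], b = g3[k - 1];
      if (!is_pair(a, b)) break;
      ++left;
      if (is_wobble(a, b)) ++wl;
    }
    if (left < min_bp) continue;
    int right = 0, wr = 0;
    for (int k = 1; k <= L5 && t + 1 + k <= L; ++k) {
      const int a = target[t + k], b = g5[L5 - k];
      if (!is_pair(a, b)) break;
      ++right;
      if (is_wobble(a, b)) ++wr;
    }
    if (right < min_bp) continue;
    pos.push_back(t);
    lbp.push_back(left);
    rbp.push_back(right);
    wob.push_back(wl + wr);
  }
  IntegerMatrix out(pos.size(), 4);
  for (size_t r = 0; r < pos.size(); ++r) {
    out(r, 0) = pos[r];
    out(r, 1) = lbp[r];
    out(r, 2) = rbp[r];
    out(r, 3) = wob[r];
  }
  colnames(out) = CharacterVector::create("pos", "left_bp", "right_bp",
                                          "n_wobble");
  return out;
}
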