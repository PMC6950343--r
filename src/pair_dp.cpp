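#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Transition column layout shared with the R side:
// MM, MI, MD, IM, II, DM, DD (log2 probabilities; -Inf encodes probability 0).
static const int TMM = 0, TMI = 1, TMD = 2, TIM = 3, TII = 4, TDM = 5, TDD = 6;

// log2(2^a + 2^b), safe against -Inf.
static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double hi = a > b ? a : b, lo = a > b ? b : a;
  return hi + std::log1p(std::exp2(lo - hi)) / M_LN2;
}

// Pair-state dynamic program over {MM, MI, IM, DG, GD}.
//
// S      : L1 x L2 matrix of per-column co-emission scores (bits).
// ta, tb : (L+1) x 7 log2 transition matrices; row k holds the transitions
//          out of node k, row 0 is the BEGIN node, row L the exit row
//          (M->M there means M->E, D->M means D->E).
// local  : free entry/exit at any MM cell (no begin/end transition cost);
//          global anchors at the model ends through the BEGIN/exit rows.
// forward: log-sum-exp over all paths instead of max.
//
// State semantics at cell (i, j) (1-based match columns consumed):
//   MM: columns i and j aligned (co-emitted);
//   MI: model A advanced to match i while model B idles in insert after j;
//   IM: symmetric;
//   DG: model A passed match i through a delete state, B contributes no move;
//   GD: symmetric.
// A pair step's weight is the product (log-sum) of the component transitions
// of each model; insert states contribute transition weight only.
// [[Rcpp::export]]
List pair_dp_cpp(NumericMatrix S, NumericMatrix ta, NumericMatrix tb,
                 bool local, bool forward, bool want_trace) {
  const int L1 = S.nrow(), L2 = S.ncol();
  const int C = L2 + 1;
  const size_t n = (size_t)(L1 + 1) * C;
  std::vector<double> MM(n, R_NegInf), MI(n, R_NegInf), IM(n, R_NegInf),
      DG(n, R_NegInf), GD(n, R_NegInf);
  std::vector<signed char> bMM, bMI, bIM, bDG, bGD;
  const bool trace = want_trace && !forward;
  if (trace) {
    bMM.assign(n, -1); bMI.assign(n, -1); bIM.assign(n, -1);
    bDG.assign(n, -1); bGD.assign(n, -1);
  }
  auto at = [C](int i, int j) { return (size_t)i * C + j; };

  if (!local) MM[at(0, 0)] = 0.0;  // virtual global start

  for (int i = 0; i <= L1; ++i) {
    for (int j = 0; j <= L2; ++j) {
      const size_t c = at(i, j);
      // MM
      if (i >= 1 && j >= 1) {
        const size_t p = at(i - 1, j - 1);
        double cand[6];
        cand[1] = MM[p] + ta(i - 1, TMM) + tb(j - 1, TMM);
        cand[2] = MI[p] + ta(i - 1, TMM) + tb(j - 1, TIM);
        cand[3] = IM[p] + ta(i - 1, TIM) + tb(j - 1, TMM);
        cand[4] = DG[p] + ta(i - 1, TDM) + tb(j - 1, TMM);
        cand[5] = GD[p] + ta(i - 1, TMM) + tb(j - 1, TDM);
        cand[0] = local ? 0.0 : R_NegInf;  // fresh local entry
        double v; int who = 0;
        if (forward) {
          v = cand[0];
          for (int k = 1; k < 6; ++k) v = lse2(v, cand[k]);
        } else {
          v = cand[0]; who = 0;
          for (int k = 1; k < 6; ++k)
            if (cand[k] > v) { v = cand[k]; who = k; }
        }
        if (v > R_NegInf) MM[c] = S(i - 1, j - 1) + v;
        if (trace) bMM[c] = (signed char)who;
      }
      // MI: A advances a match, B sits in insert after column j
      if (i >= 1) {
        double c1 = MM[at(i - 1, j)] + ta(i - 1, TMM) + tb(j, TMI);
        double c2 = MI[at(i - 1, j)] + ta(i - 1, TMM) + tb(j, TII);
        MI[c] = forward ? lse2(c1, c2) : (c1 >= c2 ? c1 : c2);
        if (trace) bMI[c] = (signed char)(c1 >= c2 ? 1 : 2);
      }
      // IM
      if (j >= 1) {
        double c1 = MM[at(i, j - 1)] + ta(i, TMI) + tb(j - 1, TMM);
        double c2 = IM[at(i, j - 1)] + ta(i, TII) + tb(j - 1, TMM);
        IM[c] = forward ? lse2(c1, c2) : (c1 >= c2 ? c1 : c2);
        if (trace) bIM[c] = (signed char)(c1 >= c2 ? 1 : 3);
      }
      // DG: A deletes match i, B gapped
      if (i >= 1) {
        double c1 = MM[at(i - 1, j)] + ta(i - 1, TMD);
        double c2 = DG[at(i - 1, j)] + ta(i - 1, TDD);
        DG[c] = forward ? lse2(c1, c2) : (c1 >= c2 ? c1 : c2);
        if (trace) bDG[c] = (signed char)(c1 >= c2 ? 1 : 4);
      }
      // GD
      if (j >= 1) {
        double c1 = MM[at(i, j - 1)] + tb(j - 1, TMD);
        double c2 = GD[at(i, j - 1)] + tb(j - 1, TDD);
        GD[c] = forward ? lse2(c1, c2) : (c1 >= c2 ? c1 : c2);
        if (trace) bGD[c] = (signed char)(c1 >= c2 ? 1 : 5);
      }
    }
  }

  double score = R_NegInf;
  int end_i = -1, end_j = -1, end_state = 1;  // 1=MM, 4=DG, 5=GD
  if (local) {
    for (int i = 1; i <= L1; ++i)
      for (int j = 1; j <= L2; ++j) {
        double v = MM[at(i, j)];
        if (forward) score = lse2(score, v);
        else if (v > score) { score = v; end_i = i; end_j = j; }
      }
  } else {
    const size_t e = at(L1, L2);
    double cm = MM[e] + ta(L1, TMM) + tb(L2, TMM);
    double cd = DG[e] + ta(L1, TDM) + tb(L2, TMM);
    double cg = GD[e] + ta(L1, TMM) + tb(L2, TDM);
    if (forward) {
      score = lse2(lse2(cm, cd), cg);
    } else {
      score = cm; end_state = 1;
      if (cd > score) { score = cd; end_state = 4; }
      if (cg > score) { score = cg; end_state = 5; }
      end_i = L1; end_j = L2;
    }
  }

  List out = List::create(_["score"] = score);
  if (trace && score > R_NegInf) {
    // Walk backpointers from the recorded end cell.
    std::vector<int> ti, tj, ts;
    int i = end_i, j = end_j, st = end_state;
    while (i >= 0 && j >= 0) {
      ti.push_back(i); tj.push_back(j); ts.push_back(st);
      const size_t c = at(i, j);
      int prev;
      switch (st) {
        case 1: prev = bMM[c]; if (prev == 0) { i = -1; continue; }
                --i; --j; break;
        case 2: prev = bMI[c]; --i; break;
        case 3: prev = bIM[c]; --j; break;
        case 4: prev = bDG[c]; --i; break;
        case 5: prev = bGD[c]; --j; break;
        default: prev = -1;
      }
      if (prev <= 0) break;  // reached global start (MM(0,0)) or entry
      st = prev;
      if (!local && i == 0 && j == 0) break;
    }
    const int m = (int)ti.size();
    IntegerMatrix tr(m, 3);
    for (int k = 0; k < m; ++k) {  // reverse into forward order
      tr(k, 0) = ti[m - 1 - k];
      tr(k, 1) = tj[m - 1 - k];
      tr(k, 2) = ts[m - 1 - k];
    }
    out["trace"] = tr;
  }
  return out;
}
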