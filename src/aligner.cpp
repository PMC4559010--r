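// Dynamic-programming alignment of ordered label maps.
//
// States are label pairs (query i, reference j). Matching consecutive pairs
// scores a Gaussian sizing term on the gap difference; skipped reference
// labels pay a missed-label (FN) penalty, skipped query labels pay a
// spurious-label (FP) penalty. Alignment is local: any cell may start or end
// a chain, and unmatched labels outside the chained span are free.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct AlnParams {
  double s0sq;        // sizing variance scale: var = s0sq * gap + var0
  double var0;
  double match_bonus;
  double fp_pen;      // penalty per skipped query label
  double fn_pen;      // penalty per skipped reference label
  int    max_skip;    // max labels skipped between consecutive matches
};

struct Workspace {
  std::vector<double> S;
  std::vector<int> par;
  std::vector<int> qi, ri;
};

static AlnParams unpack_params(const List& par) {
  AlnParams p;
  double s0 = as<double>(par["s0"]);
  p.s0sq        = s0 * s0;
  p.var0        = as<double>(par["var0"]);
  p.match_bonus = as<double>(par["match_bonus"]);
  p.fp_pen      = as<double>(par["fp_pen"]);
  p.fn_pen      = as<double>(par["fn_pen"]);
  p.max_skip    = as<int>(par["max_skip"]);
  return p;
}

// Fill the DP table and trace back the best chain into ws.qi / ws.ri
// (0-based, ascending). Returns the best local score (0 for empty input).
static double dp_align(const double* q, int nq, const double* r, int nr,
                       const AlnParams& p, Workspace& ws) {
  ws.qi.clear(); ws.ri.clear();
  if (nq == 0 || nr == 0) return 0.0;

  ws.S.resize((size_t)nq * nr);
  ws.par.assign((size_t)nq * nr, -1);
  double* S = ws.S.data();
  int* par = ws.par.data();
  const int K = p.max_skip + 1;

  double bestsc = -1.0;
  int bestcell = -1;
  for (int i = 0; i < nq; ++i) {
    double* Srow = S + (size_t)i * nr;
    int* prow_par = par + (size_t)i * nr;
    const int dimax = std::min(K, i);
    for (int j = 0; j < nr; ++j) {
      double pbest = 0.0;   // fresh chain start at (i, j)
      int bp = -1;
      const double qi_pos = q[i];
      const double rj_pos = r[j];
      const int djmax = std::min(K, j);
      for (int di = 1; di <= dimax; ++di) {
        const double dq = qi_pos - q[i - di];
        const double fpcost = p.fp_pen * (di - 1);
        const double* Sprev = S + (size_t)(i - di) * nr;
        for (int dj = 1; dj <= djmax; ++dj) {
          const double dr = rj_pos - r[j - dj];
          const double diff = dr - dq;
          const double cand = Sprev[j - dj]
            - 0.5 * diff * diff / (p.s0sq * dr + p.var0)
            - fpcost - p.fn_pen * (dj - 1);
          if (cand > pbest + 1e-12) {
            pbest = cand;
            bp = (int)((i - di) * nr + (j - dj));
          }
        }
      }
      const double sc = p.match_bonus + pbest;
      Srow[j] = sc;
      prow_par[j] = bp;
      if (sc > bestsc + 1e-12) { bestsc = sc; bestcell = (int)(i * nr + j); }
    }
  }

  int cell = bestcell;
  while (cell >= 0) {
    ws.qi.push_back(cell / nr);
    ws.ri.push_back(cell % nr);
    cell = par[cell];
  }
  std::reverse(ws.qi.begin(), ws.qi.end());
  std::reverse(ws.ri.begin(), ws.ri.end());
  return bestsc;
}

// Align query to reference in one orientation frame.
// [[Rcpp::export]]
List cpp_align_one(NumericVector q, NumericVector r, List params) {
  AlnParams p = unpack_params(params);
  Workspace ws;
  double sc = dp_align(q.begin(), q.size(), r.begin(), r.size(), p, ws);
  IntegerVector qi(ws.qi.begin(), ws.qi.end()), ri(ws.ri.begin(), ws.ri.end());
  return List::create(_["score"] = sc,
                      _["qi"] = qi + 1,   // 1-based for R
                      _["ri"] = ri + 1);
}

// Align trying both orientations of the query. Reverse frame uses positions
// qlen - rev(q). Forward is preferred on ties (within 1e-9).
// [[Rcpp::export]]
List cpp_align_both(NumericVector q, NumericVector r, double qlen, List params) {
  AlnParams p = unpack_params(params);
  const int nq = q.size(), nr = r.size();
  std::vector<double> qr(nq);
  for (int k = 0; k < nq; ++k) qr[k] = qlen - q[nq - 1 - k];
  Workspace wf, wb;
  double sf = dp_align(q.begin(), nq, r.begin(), nr, p, wf);
  double sb = dp_align(qr.data(), nq, r.begin(), nr, p, wb);
  bool fwd = sf >= sb - 1e-9;
  Workspace& ws = fwd ? wf : wb;
  IntegerVector qi(ws.qi.begin(), ws.qi.end()), ri(ws.ri.begin(), ws.ri.end());
  return List::create(_["score"] = fwd ? sf : sb,
                      _["orientation"] = fwd ? "+" : "-",
                      _["qi"] = qi + 1,
                      _["ri"] = ri + 1,
                      _["score_fwd"] = sf,
                      _["score_rev"] = sb);
}

// Pairwise overlap graph. Distance is 1 - S / (match_bonus * min(n_i, n_j)),
// clamped to [0, 1]; pairs whose best chain has fewer than min_pairs matched
// sites (or a molecule with < 2 labels) get distance 1 and no transform.
// For qualifying pairs the placement transform of molecule i into molecule
// j's frame, x_j = a + b * x_i with b = +/-1, is returned (a = median offset
// over matched pairs).
// [[Rcpp::export]]
List cpp_overlap_graph(List labels, NumericVector lens, List params,
                       int min_pairs) {
  AlnParams p = unpack_params(params);
  const int n = labels.size();
  std::vector< std::vector<double> > fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    NumericVector v = labels[i];
    fwd[i].assign(v.begin(), v.end());
    rev[i].resize(v.size());
    for (size_t k = 0; k < fwd[i].size(); ++k)
      rev[i][k] = lens[i] - fwd[i][fwd[i].size() - 1 - k];
  }
  NumericMatrix D(n, n);
  NumericMatrix A(n, n), B(n, n);
  std::fill(A.begin(), A.end(), NA_REAL);
  std::fill(B.begin(), B.end(), NA_REAL);
  std::vector<double> offs;
  Workspace wf, wb;
  for (int i = 0; i < n; ++i) {
    const int ni = (int)fwd[i].size();
    for (int j = i + 1; j < n; ++j) {
      const int nj = (int)fwd[j].size();
      double d = 1.0;
      if (ni >= 2 && nj >= 2 && std::min(ni, nj) >= min_pairs) {
        double sa = dp_align(fwd[i].data(), ni, fwd[j].data(), nj, p, wf);
        double sb = dp_align(rev[i].data(), ni, fwd[j].data(), nj, p, wb);
        bool use_fwd = sa >= sb;
        Workspace& best = use_fwd ? wf : wb;
        double sc = use_fwd ? sa : sb;
        if ((int)best.qi.size() >= min_pairs) {
          double norm = p.match_bonus * std::min(ni, nj);
          d = std::max(0.0, std::min(1.0, 1.0 - sc / norm));
          const std::vector<double>& qv = use_fwd ? fwd[i] : rev[i];
          offs.clear();
          for (size_t k = 0; k < best.qi.size(); ++k)
            offs.push_back(fwd[j][best.ri[k]] - qv[best.qi[k]]);
          std::sort(offs.begin(), offs.end());
          size_t m = offs.size();
          double med = (m % 2) ? offs[m / 2]
                               : 0.5 * (offs[m / 2 - 1] + offs[m / 2]);
          // x_j = med + x_i' where x_i' = x_i (fwd) or len_i - x_i (rev)
          if (use_fwd) { A(i, j) = med;           B(i, j) = 1.0; }
          else         { A(i, j) = med + lens[i]; B(i, j) = -1.0; }
          if (use_fwd) { A(j, i) = -med;          B(j, i) = 1.0; }
          else         { A(j, i) = med + lens[i]; B(j, i) = -1.0; }
        }
      }
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return List::create(_["dist"] = D, _["a"] = A, _["b"] = B);
}

// Batch placement of molecules against a fixed reference label set (used
// when recruiting molecules to provisional consensus maps): returns per
// molecule the best score, orientation, matched-pair count and median
// offset in the reference frame.
// [[Rcpp::export]]
List cpp_place_batch(List labels, NumericVector lens, NumericVector ref,
                     List params, int min_pairs) {
  AlnParams p = unpack_params(params);
  const int n = labels.size();
  NumericVector score(n), offset(n, NA_REAL);
  IntegerVector npairs(n);
  CharacterVector orient(n);
  Workspace wf, wb;
  std::vector<double> qr, offs;
  for (int i = 0; i < n; ++i) {
    NumericVector q = labels[i];
    const int nq = q.size();
    qr.resize(nq);
    for (int k = 0; k < nq; ++k) qr[k] = lens[i] - q[nq - 1 - k];
    double sf = dp_align(q.begin(), nq, ref.begin(), ref.size(), p, wf);
    double sb = dp_align(qr.data(), nq, ref.begin(), ref.size(), p, wb);
    bool use_fwd = sf >= sb - 1e-9;
    Workspace& ws = use_fwd ? wf : wb;
    score[i] = use_fwd ? sf : sb;
    npairs[i] = (int)ws.qi.size();
    orient[i] = use_fwd ? "+" : "-";
    if (npairs[i] >= min_pairs) {
      offs.clear();
      for (size_t k = 0; k < ws.qi.size(); ++k) {
        double qp = use_fwd ? q[ws.qi[k]] : qr[ws.qi[k]];
        offs.push_back(ref[ws.ri[k]] - qp);
      }
      std::sort(offs.begin(), offs.end());
      size_t m = offs.size();
      offset[i] = (m % 2) ? offs[m / 2]
                          : 0.5 * (offs[m / 2 - 1] + offs[m / 2]);
    }
  }
  return List::create(_["score"] = score, _["orientation"] = orient,
                      _["n_pairs"] = npairs, _["offset"] = offset);
}
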