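#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Exact affine-gap local alignment (Smith-Waterman / Gotoh) with
// deterministic tie-breaking: among equal-score optima the alignment with
// the smallest query start wins, then the smallest subject start, then the
// smallest end cell. Ties among DP predecessors prefer the candidate whose
// path origin is lexicographically smallest, then the match state over the
// two gap states. A gap of length L costs gap_open + L * gap_extend.
//
// States: M = i,j aligned; X = gap in subject (query base consumed);
//         Y = gap in query (subject base consumed).
// Local alignments start and end in M; with positive gap penalties an
// optimal local alignment never starts or ends in a gap state.

namespace {

const double NEG_INF = -1e30;

struct Origin {
  int32_t oi;  // query start (0-based row index of first aligned base - 1)
  int32_t oj;  // subject start
};

inline bool origin_less(const Origin& a, const Origin& b) {
  return a.oi < b.oi || (a.oi == b.oi && a.oj < b.oj);
}

}  // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s, double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = static_cast<int>(q.size());
  const int m = static_cast<int>(s.size());

  // Flattened (n+1) x (m+1) matrices.
  const size_t ncell = static_cast<size_t>(n + 1) * static_cast<size_t>(m + 1);
  std::vector<double> M(ncell, 0.0), X(ncell, NEG_INF), Y(ncell, NEG_INF);
  std::vector<Origin> Mo(ncell), Xo(ncell), Yo(ncell);
  // Traceback: for M, 0 = fresh start, 1/2/3 = diag from M/X/Y.
  //            for X, 1 = open (from M above), 2 = extend (from X above).
  //            for Y, 1 = open (from M left), 2 = extend (from Y left).
  std::vector<uint8_t> Mt(ncell, 0), Xt(ncell, 0), Yt(ncell, 0);

  auto idx = [m](int i, int j) {
    return static_cast<size_t>(i) * static_cast<size_t>(m + 1) +
           static_cast<size_t>(j);
  };

  double best = 0.0;
  int best_i = -1, best_j = -1;
  Origin best_o = {0, 0};

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = idx(i, j);
      const size_t d = idx(i - 1, j - 1);
      const size_t u = idx(i - 1, j);
      const size_t l = idx(i, j - 1);

      // X: gap in subject, consume query base i.
      {
        double open_sc = M[u] - gap_open - gap_extend;
        double ext_sc = X[u] - gap_extend;
        if (open_sc >= ext_sc) {
          bool tie = (open_sc == ext_sc);
          if (tie && origin_less(Xo[u], Mo[u])) {
            X[c] = ext_sc; Xo[c] = Xo[u]; Xt[c] = 2;
          } else {
            X[c] = open_sc; Xo[c] = Mo[u]; Xt[c] = 1;
          }
        } else {
          X[c] = ext_sc; Xo[c] = Xo[u]; Xt[c] = 2;
        }
      }
      // Y: gap in query, consume subject base j.
      {
        double open_sc = M[l] - gap_open - gap_extend;
        double ext_sc = Y[l] - gap_extend;
        if (open_sc >= ext_sc) {
          bool tie = (open_sc == ext_sc);
          if (tie && origin_less(Yo[l], Mo[l])) {
            Y[c] = ext_sc; Yo[c] = Yo[l]; Yt[c] = 2;
          } else {
            Y[c] = open_sc; Yo[c] = Mo[l]; Yt[c] = 1;
          }
        } else {
          Y[c] = ext_sc; Yo[c] = Yo[l]; Yt[c] = 2;
        }
      }
      // M: align q[i-1] with s[j-1].
      {
        const double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
        double cand_sc[4];
        Origin cand_o[4];
        uint8_t cand_t[4];
        // Fresh local start.
        cand_sc[0] = sub;
        cand_o[0].oi = i - 1; cand_o[0].oj = j - 1;
        cand_t[0] = 0;
        cand_sc[1] = M[d] + sub; cand_o[1] = Mo[d]; cand_t[1] = 1;
        cand_sc[2] = X[d] + sub; cand_o[2] = Xo[d]; cand_t[2] = 2;
        cand_sc[3] = Y[d] + sub; cand_o[3] = Yo[d]; cand_t[3] = 3;
        // Continuing from a zero-score M cell duplicates the fresh start
        // (candidate 0); only strictly positive predecessors may extend.
        if (M[d] <= 0.0) cand_sc[1] = NEG_INF;

        int pick = 0;
        for (int k = 1; k < 4; ++k) {
          if (cand_sc[k] > cand_sc[pick] ||
              (cand_sc[k] == cand_sc[pick] &&
               origin_less(cand_o[k], cand_o[pick]))) {
            pick = k;
          }
        }
        double v = cand_sc[pick];
        if (v < 0.0) {
          M[c] = 0.0; Mo[c].oi = i; Mo[c].oj = j; Mt[c] = 0;
        } else {
          M[c] = v; Mo[c] = cand_o[pick]; Mt[c] = cand_t[pick];
          if (v > best ||
              (v == best && best_i >= 0 &&
               (origin_less(Mo[c], best_o)))) {
            best = v; best_i = i; best_j = j; best_o = Mo[c];
          } else if (v == best && best_i < 0) {
            best = v; best_i = i; best_j = j; best_o = Mo[c];
          }
        }
      }
    }
  }

  if (best <= 0.0 || best_i < 0) {
    return List::create(
        _["score"] = 0.0, _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
        _["s_start"] = NA_INTEGER, _["s_end"] = NA_INTEGER,
        _["n_matches"] = 0L, _["aln_length"] = 0L,
        _["identity"] = NA_REAL);
  }

  // Traceback from (best_i, best_j) in state M.
  int i = best_i, j = best_j, state = 0;  // 0 = M, 1 = X, 2 = Y
  long n_match = 0, n_col = 0;
  for (;;) {
    const size_t c = idx(i, j);
    if (state == 0) {
      ++n_col;
      if (q[i - 1] == s[j - 1]) ++n_match;
      uint8_t t = Mt[c];
      --i; --j;
      if (t == 0) break;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
    } else if (state == 1) {
      ++n_col;
      uint8_t t = Xt[c];
      --i;
      state = (t == 1) ? 0 : 1;
    } else {
      ++n_col;
      uint8_t t = Yt[c];
      --j;
      state = (t == 1) ? 0 : 2;
    }
  }

  // (i, j) is now the 0-based start of the alignment.
  return List::create(
      _["score"] = best,
      _["q_start"] = i, _["q_end"] = best_i,
      _["s_start"] = j, _["s_end"] = best_j,
      _["n_matches"] = static_cast<int>(n_match),
      _["aln_length"] = static_cast<int>(n_col),
      _["identity"] = 100.0 * static_cast<double>(n_match) /
                      static_cast<double>(n_col));
}
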