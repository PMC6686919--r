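#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Local Viterbi alignment of one encoded protein against a profile model.
//
// emlo:  match_length x 21 matrix of log2-odds match emissions; column 21
//        (index 20) is the ambiguity code and must be 0.
// trlo:  match_length x 7 matrix of log2 transition probabilities, columns
//        (mm, mi, md, im, ii, dm, dd); row j holds transitions OUT of state j.
// seq:   0-based residue codes (0..19, 20 = ambiguous).
//
// Path grammar: free entry Begin->M_j at any j and position, free exit from
// any M_j; inserts emit at background (log-odds 0); I<->D transitions are
// forbidden. Spans are 0-based half-open over match states / target positions.
// Rolling score rows + raw pointers keep the inner loop tight; full byte
// pointer matrices are retained for the traceback.

static void viterbi_one(const double *emlo /* 21 cols x M, col-major (M rows) */,
                        const double *tmm, const double *tmi, const double *tmd,
                        const double *tim, const double *tii,
                        const double *tdm, const double *tdd,
                        int M, const int *seq, int L,
                        std::vector<double> &Mprev, std::vector<double> &Mcur,
                        std::vector<double> &Iprev, std::vector<double> &Icur,
                        std::vector<double> &Dcur,
                        std::vector<unsigned char> &Mp,
                        std::vector<unsigned char> &Ip,
                        std::vector<unsigned char> &Dp,
                        double *out) {
  const double NEG = -1e300;

  Mprev.assign(M + 1, NEG);
  Mcur.assign(M + 1, NEG);
  Iprev.assign(M + 1, NEG);
  Icur.assign(M + 1, NEG);
  Dcur.assign(M + 1, NEG);
  // Dprev needed for M transition: keep a copy per row
  std::vector<double> Dprev(M + 1, NEG);

  Mp.assign((size_t)(L + 1) * (M + 1), 0);
  Ip.assign((size_t)(L + 1) * (M + 1), 0);
  Dp.assign((size_t)(L + 1) * (M + 1), 0);

  double best = NEG;
  int bi = 0, bj = 0;

  for (int i = 1; i <= L; ++i) {
    const double *em = emlo + (size_t)seq[i - 1] * M; // emissions for residue
    unsigned char *mp = Mp.data() + (size_t)i * (M + 1);
    unsigned char *ip = Ip.data() + (size_t)i * (M + 1);
    unsigned char *dp = Dp.data() + (size_t)i * (M + 1);
    Dcur[0] = NEG;
    for (int j = 1; j <= M; ++j) {
      // match: free entry (0) or from M/I/D at (i-1, j-1)
      double sc = 0.0;
      unsigned char ptr = 0;
      if (j > 1) {
        const double fm = Mprev[j - 1] + tmm[j - 2];
        const double fi = Iprev[j - 1] + tim[j - 2];
        const double fd = Dprev[j - 1] + tdm[j - 2];
        if (fm > sc) { sc = fm; ptr = 1; }
        if (fi > sc) { sc = fi; ptr = 2; }
        if (fd > sc) { sc = fd; ptr = 3; }
      }
      const double m = sc + em[j - 1];
      Mcur[j] = m;
      mp[j] = ptr;
      if (m > best) { best = m; bi = i; bj = j; }

      // insert (emits at background, log-odds 0)
      const double im = Mprev[j] + tmi[j - 1];
      const double ii = Iprev[j] + tii[j - 1];
      if (im >= ii) { Icur[j] = im; ip[j] = 1; }
      else          { Icur[j] = ii; ip[j] = 2; }

      // delete
      if (j > 1) {
        const double dm = Mcur[j - 1] + tmd[j - 2];
        const double dd = Dcur[j - 1] + tdd[j - 2];
        if (dm >= dd) { Dcur[j] = dm; dp[j] = 1; }
        else          { Dcur[j] = dd; dp[j] = 3; }
      } else {
        Dcur[j] = NEG;
      }
    }
    std::swap(Mprev, Mcur);
    std::swap(Iprev, Icur);
    std::swap(Dprev, Dcur);
  }

  if (bi == 0) { // no cell scored above NEG (cannot happen for L,M >= 1)
    out[0] = NEG; out[1] = out[2] = out[3] = out[4] = 0;
    return;
  }

  // traceback from (bi, bj, M) to the entry
  int i = bi, j = bj, state = 0; // 0 = M, 1 = I, 2 = D
  int jmin = bj, imin = bi;
  for (;;) {
    if (state == 0) {
      jmin = j < jmin ? j : jmin;
      imin = i < imin ? i : imin;
      const unsigned char p = Mp[(size_t)i * (M + 1) + j];
      if (p == 0) break;
      // every predecessor of M(i, j) sits at cell (i-1, j-1)
      state = (p == 1) ? 0 : (p == 2) ? 1 : 2;
      --i; --j;
    } else if (state == 1) {
      imin = i < imin ? i : imin;
      const unsigned char p = Ip[(size_t)i * (M + 1) + j];
      state = (p == 1) ? 0 : 1;
      --i; // insert consumed a residue; stays at state j
    } else {
      jmin = j < jmin ? j : jmin;
      const unsigned char p = Dp[(size_t)i * (M + 1) + j];
      state = (p == 1) ? 0 : 2;
      --j; // delete consumed a match state, no residue
    }
  }

  out[0] = best;
  out[1] = jmin - 1; // query start (0-based)
  out[2] = bj;       // query end (half-open)
  out[3] = imin - 1; // target start
  out[4] = bi;       // target end
}

// [[Rcpp::export]]
NumericMatrix cpp_score_proteins(NumericMatrix emlo, NumericMatrix trlo,
                                 List seqs) {
  const int n = seqs.size();
  const int M = emlo.nrow();
  NumericMatrix res(n, 5);
  colnames(res) = CharacterVector::create("bit_score", "query_start",
                                          "query_end", "target_start",
                                          "target_end");
  // contiguous transition columns (column-major: each column is contiguous)
  const double *tr = trlo.begin();
  const double *tmm = tr, *tmi = tr + M, *tmd = tr + 2 * M,
               *tim = tr + 3 * M, *tii = tr + 4 * M,
               *tdm = tr + 5 * M, *tdd = tr + 6 * M;
  std::vector<double> Mprev, Mcur, Iprev, Icur, Dcur;
  std::vector<unsigned char> Mp, Ip, Dp;
  double out[5];
  for (int k = 0; k < n; ++k) {
    IntegerVector s = seqs[k];
    std::vector<int> sv(s.begin(), s.end());
    viterbi_one(emlo.begin(), tmm, tmi, tmd, tim, tii, tdm, tdd, M,
                sv.data(), sv.size(), Mprev, Mcur, Iprev, Icur, Dcur,
                Mp, Ip, Dp, out);
    for (int c = 0; c < 5; ++c) res(k, c) = out[c];
  }
  return res;
}

// Global Needleman-Wunsch of an encoded sequence against a profile of
// per-column residue frequencies (ncol x 21; col 21 = gap fraction).
// Returns path codes from first to last alignment column:
//   0 = profile column paired with a residue
//   1 = profile column paired with a gap in the sequence
//   2 = residue inserted relative to the profile (new all-gap column)
// [[Rcpp::export]]
IntegerVector cpp_align_seq_profile(NumericMatrix prof, IntegerVector seq,
                                    double match, double mismatch, double gap) {
  const int C = prof.nrow();
  const int L = seq.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> S((C + 1) * (L + 1), NEG);
  std::vector<unsigned char> P((C + 1) * (L + 1), 0); // 0 diag, 1 up(colgap), 2 left(insert)
  auto idx = [L](int c, int l) { return c * (L + 1) + l; };

  S[0] = 0;
  for (int c = 1; c <= C; ++c) { S[idx(c, 0)] = S[idx(c - 1, 0)] + gap; P[idx(c, 0)] = 1; }
  for (int l = 1; l <= L; ++l) { S[idx(0, l)] = S[idx(0, l - 1)] + gap; P[idx(0, l)] = 2; }

  // expected substitution score of each residue against each column
  std::vector<double> colscore((size_t)C * 21);
  for (int c = 0; c < C; ++c) {
    double tot = 0.0;
    for (int b = 0; b < 20; ++b) tot += prof(c, b);
    const double gap_part = prof(c, 20) * gap;
    for (int a = 0; a < 20; ++a) {
      colscore[(size_t)c * 21 + a] =
          gap_part + prof(c, a) * match + (tot - prof(c, a)) * mismatch;
    }
    // ambiguity code: score as an average residue
    double amb = 0.0;
    for (int a = 0; a < 20; ++a) amb += colscore[(size_t)c * 21 + a];
    colscore[(size_t)c * 21 + 20] = amb / 20.0;
  }

  for (int c = 1; c <= C; ++c) {
    for (int l = 1; l <= L; ++l) {
      const int a = seq[l - 1];
      const double sub = colscore[(size_t)(c - 1) * 21 + a];
      const double d = S[idx(c - 1, l - 1)] + sub;
      const double u = S[idx(c - 1, l)] + gap;
      const double lf = S[idx(c, l - 1)] + gap;
      double bestv = d; unsigned char p = 0;
      if (u > bestv) { bestv = u; p = 1; }
      if (lf > bestv) { bestv = lf; p = 2; }
      S[idx(c, l)] = bestv; P[idx(c, l)] = p;
    }
  }

  std::vector<int> path;
  int c = C, l = L;
  while (c > 0 || l > 0) {
    const unsigned char p = P[idx(c, l)];
    if (p == 0) { path.push_back(0); --c; --l; }
    else if (p == 1) { path.push_back(1); --c; }
    else { path.push_back(2); --l; }
  }
  IntegerVector out(path.size());
  for (size_t k = 0; k < path.size(); ++k) out[k] = path[path.size() - 1 - k];
  return out;
}
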