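#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state
// recursion), scored by a substitution matrix passed from R (typically
// BLOSUM62). A gap of length k costs gap_open + k * gap_ext (the BLAST
// convention). Local alignments end in the match state: a trailing gap never
// improves the score. X<->Y (insertion<->deletion) transitions are omitted;
// with BLOSUM62 (min score -4) and these gap costs two adjacent opens are
// always worse than a substitution, so the three-state recursion is exact.

struct AlnRes {
  int score;      // best raw score (0 if no positive-scoring alignment)
  int qs, qe;     // 1-based inclusive query span
  int ss, se;     // 1-based inclusive subject span
  int alen;       // number of alignment columns (incl. gaps)
};

static const int NEG_INF = -1000000000;

enum { FROM_M = 1, FROM_X = 2, FROM_Y = 3 };

static AlnRes sw_full(const std::vector<int>& q, const std::vector<int>& s,
                      const std::vector<int>& S, int nalpha,
                      int gap_open, int gap_ext) {
  const int m = (int)q.size(), n = (int)s.size();
  AlnRes res = {0, 0, 0, 0, 0, 0};
  if (m == 0 || n == 0) return res;
  const int gfirst = gap_open + gap_ext;
  const size_t W = (size_t)n + 1;

  std::vector<int> M(W * (m + 1), 0), X(W * (m + 1), NEG_INF), Y(W * (m + 1), NEG_INF);
  std::vector<uint8_t> tbM(W * (m + 1), 0), tbX(W * (m + 1), 0), tbY(W * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int* Srow = S.data() + (size_t)q[i - 1] * nalpha;
    const size_t o = (size_t)i * W, op = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      int xm = M[op + j] - gfirst, xx = X[op + j] - gap_ext;
      if (xm >= xx) { X[o + j] = xm; tbX[o + j] = FROM_M; }
      else          { X[o + j] = xx; tbX[o + j] = FROM_X; }

      int ym = M[o + j - 1] - gfirst, yy = Y[o + j - 1] - gap_ext;
      if (ym >= yy) { Y[o + j] = ym; tbY[o + j] = FROM_M; }
      else          { Y[o + j] = yy; tbY[o + j] = FROM_Y; }

      int dM = M[op + j - 1], dX = X[op + j - 1], dY = Y[op + j - 1];
      int dbest = dM; uint8_t dtb = FROM_M;
      if (dX > dbest) { dbest = dX; dtb = FROM_X; }
      if (dY > dbest) { dbest = dY; dtb = FROM_Y; }
      int val = dbest + Srow[s[j - 1]];
      if (val <= 0) { M[o + j] = 0; tbM[o + j] = 0; }
      else          { M[o + j] = val; tbM[o + j] = dtb; }
      if (M[o + j] > best) { best = M[o + j]; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best <= 0) return res;

  // traceback from (bi, bj), state M, until the alignment's first column
  int i = bi, j = bj, state = 0, alen = 0;
  res.qe = bi; res.se = bj;
  while (true) {
    const size_t o = (size_t)i * W;
    if (state == 0) {
      ++alen;
      res.qs = i; res.ss = j;
      uint8_t src = tbM[o + j];
      --i; --j;
      if (src == FROM_M) {
        if (i == 0 || j == 0 || M[(size_t)i * W + j] == 0) break;
        state = 0;
      } else if (src == FROM_X) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in subject: consumed q[i]
      ++alen;
      uint8_t src = tbX[o + j];
      --i;
      state = (src == FROM_M) ? 0 : 1;
    } else {                 // gap in query: consumed s[j]
      ++alen;
      uint8_t src = tbY[o + j];
      --j;
      state = (src == FROM_M) ? 0 : 2;
    }
  }
  res.alen = alen;
  return res;
}

// score-only Smith-Waterman with rolling rows (no traceback); used as a fast
// first pass so the full matrices are only built for hits worth reporting
static int sw_score_only(const std::vector<int>& q, const std::vector<int>& s,
                         const std::vector<int>& S, int nalpha,
                         int gap_open, int gap_ext) {
  const int m = (int)q.size(), n = (int)s.size();
  if (m == 0 || n == 0) return 0;
  const int gfirst = gap_open + gap_ext;
  // M, X, Y hold the previous row right of the cursor, the current row left
  // of it; diag* carry the [i-1][j-1] values across the column step
  std::vector<int> M(n + 1, 0), X(n + 1, NEG_INF), Y(n + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int* Srow = S.data() + (size_t)q[i - 1] * nalpha;
    int diagM = 0, diagX = NEG_INF, diagY = NEG_INF;
    int Mleft = 0, Yleft = NEG_INF;  // current row, column j-1
    for (int j = 1; j <= n; ++j) {
      int Xij = std::max(M[j] - gfirst, X[j] - gap_ext);
      int Yij = std::max(Mleft - gfirst, Yleft - gap_ext);
      int dbest = diagM;
      if (diagX > dbest) dbest = diagX;
      if (diagY > dbest) dbest = diagY;
      int val = dbest + Srow[s[j - 1]];
      if (val < 0) val = 0;
      diagM = M[j]; diagX = X[j]; diagY = Y[j];
      M[j] = val; X[j] = Xij; Y[j] = Yij;
      Mleft = val; Yleft = Yij;
      if (val > best) best = val;
    }
  }
  return best;
}

// row-major copy of the (square) substitution matrix
static std::vector<int> rowmajor(const IntegerMatrix& S) {
  int nr = S.nrow(), nc = S.ncol();
  std::vector<int> out((size_t)nr * nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out[(size_t)r * nc + c] = S(r, c);
  return out;
}

static std::vector<int> build_lut(const CharacterVector& alphabet) {
  std::vector<int> lut(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    std::string a = as<std::string>(alphabet[k]);
    if (a.size() == 1) lut[(unsigned char)a[0]] = k;
  }
  return lut;
}

static int find_x_index(const CharacterVector& alphabet) {
  for (int k = 0; k < alphabet.size(); ++k)
    if (as<std::string>(alphabet[k]) == "X") return k;
  return 0;
}

static std::vector<int> encode_seq(const std::string& x, const std::vector<int>& lut,
                                   int x_index) {
  std::vector<int> out(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    int v = lut[(unsigned char)x[i]];
    out[i] = (v >= 0) ? v : x_index;
  }
  return out;
}

// sorted unique k-mer codes over the alphabet (for the word prefilter)
static std::vector<int> kmer_codes(const std::vector<int>& seq, int k, int base) {
  std::vector<int> out;
  if ((int)seq.size() < k) return out;
  out.reserve(seq.size() - k + 1);
  for (size_t i = 0; i + k <= seq.size(); ++i) {
    int code = 0;
    for (int j = 0; j < k; ++j) code = code * base + seq[i + j];
    out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static bool share_kmer(const std::vector<int>& a, const std::vector<int>& b) {
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) return true;
    if (a[i] < b[j]) ++i; else ++j;
  }
  return false;
}

// [[Rcpp::export(name = ".sw_pair_cpp")]]
List sw_pair_cpp(std::string query, std::string subject, IntegerMatrix score,
                 CharacterVector alphabet, int gap_open, int gap_ext) {
  std::vector<int> lut = build_lut(alphabet);
  int xi = find_x_index(alphabet);
  std::vector<int> S = rowmajor(score);
  std::vector<int> q = encode_seq(query, lut, xi);
  std::vector<int> s = encode_seq(subject, lut, xi);
  AlnRes r = sw_full(q, s, S, score.ncol(), gap_open, gap_ext);
  return List::create(_["raw_score"] = r.score,
                      _["q_start"] = r.qs, _["q_end"] = r.qe,
                      _["s_start"] = r.ss, _["s_end"] = r.se,
                      _["aln_len"] = r.alen);
}

// All-vs-all local alignments between two protein sets, with an optional
// exact shared-k-mer prefilter (BLAST-like word seeding). Returns one row per
// computed pair with score > 0; pairs skipped by the filter yield no row.
// [[Rcpp::export(name = ".sw_batch_cpp")]]
DataFrame sw_batch_cpp(CharacterVector qseqs, CharacterVector sseqs,
                       IntegerMatrix score, CharacterVector alphabet,
                       int gap_open, int gap_ext, bool kmer_filter, int kmer_k,
                       int min_score) {
  std::vector<int> lut = build_lut(alphabet);
  int xi = find_x_index(alphabet);
  int base = alphabet.size();
  std::vector<int> S = rowmajor(score);
  int nq = qseqs.size(), ns = sseqs.size();

  std::vector<std::vector<int>> Q(nq), Ss(ns), QK(nq), SK(ns);
  for (int i = 0; i < nq; ++i) {
    Q[i] = encode_seq(as<std::string>(qseqs[i]), lut, xi);
    if (kmer_filter) QK[i] = kmer_codes(Q[i], kmer_k, base);
  }
  for (int j = 0; j < ns; ++j) {
    Ss[j] = encode_seq(as<std::string>(sseqs[j]), lut, xi);
    if (kmer_filter) SK[j] = kmer_codes(Ss[j], kmer_k, base);
  }

  std::vector<int> vqi, vsi, vsc, vqs, vqe, vss, vse, val;
  for (int i = 0; i < nq; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < ns; ++j) {
      if (kmer_filter && !share_kmer(QK[i], SK[j])) continue;
      if (min_score > 0) {
        // cheap score-only pass; only hits that can reach min_score are
        // realigned with traceback for their spans
        int sc = sw_score_only(Q[i], Ss[j], S, score.ncol(), gap_open, gap_ext);
        if (sc < min_score) continue;
      }
      AlnRes r = sw_full(Q[i], Ss[j], S, score.ncol(), gap_open, gap_ext);
      if (r.score <= 0) continue;
      vqi.push_back(i + 1); vsi.push_back(j + 1); vsc.push_back(r.score);
      vqs.push_back(r.qs); vqe.push_back(r.qe);
      vss.push_back(r.ss); vse.push_back(r.se); val.push_back(r.alen);
    }
  }
  return DataFrame::create(_["q_idx"] = vqi, _["s_idx"] = vsi, _["raw_score"] = vsc,
                           _["q_start"] = vqs, _["q_end"] = vqe,
                           _["s_start"] = vss, _["s_end"] = vse,
                           _["aln_len"] = val);
}
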