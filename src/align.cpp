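#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh, three-state) with full traceback.
// Gap of length L costs open + extend * L (BLAST convention).
// Ties in the traceback are broken "high road": diagonal, then up (gap in
// the second sequence), then left — results are deterministic.

static const double NEG = -1e18;

struct AlnOut {
  double score;
  int matches;        // identical aligned residues, 'X'/'N' never count
  int aln_len;        // alignment columns including gaps
  int a_start, a_end; // 1-based inclusive, 0 when empty
  int b_start, b_end;
  std::string aln_a, aln_b;
};

// score lookup over raw chars
struct Scorer {
  std::vector<double> tab; // 256*256
  Scorer() : tab(256 * 256, NEG) {}
  inline double operator()(unsigned char x, unsigned char y) const {
    return tab[(size_t)x * 256 + y];
  }
};

static Scorer scorer_from_matrix(const NumericMatrix& m) {
  Scorer sc;
  List dn = m.attr("dimnames");
  if (dn.size() != 2) stop("substitution matrix must have dimnames");
  CharacterVector rn = dn[0], cn = dn[1];
  for (int i = 0; i < m.nrow(); ++i) {
    std::string ri = as<std::string>(rn[i]);
    for (int j = 0; j < m.ncol(); ++j) {
      std::string cj = as<std::string>(cn[j]);
      sc.tab[(size_t)(unsigned char)ri[0] * 256 + (unsigned char)cj[0]] =
          m(i, j);
    }
  }
  return sc;
}

static Scorer scorer_nt(double match, double mismatch) {
  Scorer sc;
  const std::string alpha = "ACGTN";
  for (char x : alpha)
    for (char y : alpha) {
      double s = (x == y && x != 'N') ? match : mismatch;
      if (x == 'N' || y == 'N') s = mismatch; // ambiguity never rewarded
      sc.tab[(size_t)(unsigned char)x * 256 + (unsigned char)y] = s;
    }
  return sc;
}

// residues that never count as an identity match, per alphabet:
// 'X'/'*' for protein, 'N' for nucleotide
static inline bool counts_as_match(char x, char y, const std::string& excl) {
  return x == y && excl.find(x) == std::string::npos;
}

// trace codes: predecessor state of each cell
enum { TM_M = 0, TM_IX = 1, TM_IY = 2, TM_START = 3 };

static AlnOut gotoh(const std::string& a, const std::string& b,
                    const Scorer& sc, double go, double ge, bool local,
                    const std::string& excl = "X*") {
  const int n = (int)a.size(), m = (int)b.size();
  const double oe = go + ge;
  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W), IX((size_t)(n + 1) * W),
      IY((size_t)(n + 1) * W);
  std::vector<uint8_t> tm((size_t)(n + 1) * W), tx((size_t)(n + 1) * W),
      ty((size_t)(n + 1) * W);
#define AT(v, i, j) v[(size_t)(i)*W + (j)]
  AT(M, 0, 0) = 0;
  AT(IX, 0, 0) = AT(IY, 0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    AT(M, i, 0) = local ? 0 : NEG;
    AT(IX, i, 0) = local ? NEG : -(go + ge * i);
    AT(IY, i, 0) = NEG;
    AT(tm, i, 0) = TM_START;
    AT(tx, i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    AT(M, 0, j) = local ? 0 : NEG;
    AT(IY, 0, j) = local ? NEG : -(go + ge * j);
    AT(IX, 0, j) = NEG;
    AT(tm, 0, j) = TM_START;
    AT(ty, 0, j) = 1;
  }
  double best = local ? 0 : NEG;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sc((unsigned char)a[i - 1], (unsigned char)b[j - 1]);
      if (s <= NEG / 2)
        stop("residue pair (%c,%c) not covered by the substitution matrix",
             a[i - 1], b[j - 1]);
      // M: diagonal extension; prefer M > IX > IY on ties
      double dm = AT(M, i - 1, j - 1), dx = AT(IX, i - 1, j - 1),
             dy = AT(IY, i - 1, j - 1);
      double v = dm;
      uint8_t t = TM_M;
      if (dx > v) { v = dx; t = TM_IX; }
      if (dy > v) { v = dy; t = TM_IY; }
      v += s;
      if (local && v < 0) { v = 0; t = TM_START; }
      AT(M, i, j) = v;
      AT(tm, i, j) = t;
      // IX: gap in b (consume a[i-1]); open from M preferred on ties
      double xo = AT(M, i - 1, j) - oe, xe = AT(IX, i - 1, j) - ge;
      if (xo >= xe) { AT(IX, i, j) = xo; AT(tx, i, j) = 0; }
      else          { AT(IX, i, j) = xe; AT(tx, i, j) = 1; }
      // IY: gap in a (consume b[j-1])
      double yo = AT(M, i, j - 1) - oe, ye = AT(IY, i, j - 1) - ge;
      if (yo >= ye) { AT(IY, i, j) = yo; AT(ty, i, j) = 0; }
      else          { AT(IY, i, j) = ye; AT(ty, i, j) = 1; }
      if (local && AT(M, i, j) > best) { best = AT(M, i, j); bi = i; bj = j; }
    }
  }
  AlnOut out;
  int i, j, state; // 0=M 1=IX 2=IY
  if (local) {
    out.score = best;
    i = bi; j = bj; state = 0;
    if (best <= 0) { // nothing aligns
      out.matches = 0; out.aln_len = 0;
      out.a_start = out.a_end = out.b_start = out.b_end = 0;
      return out;
    }
  } else {
    double em = AT(M, n, m), ex = AT(IX, n, m), ey = AT(IY, n, m);
    state = 0; out.score = em;
    if (ex > out.score) { out.score = ex; state = 1; }
    if (ey > out.score) { out.score = ey; state = 2; }
    i = n; j = m;
  }
  std::string ra, rb;
  int matches = 0;
  out.a_end = i; out.b_end = j;
  while (true) {
    if (!local && i == 0 && j == 0) break;
    if (state == 0) {
      uint8_t t = AT(tm, i, j);
      if (local && t == TM_START) break;
      if (i == 0 && j == 0) break;
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      if (counts_as_match(a[i - 1], b[j - 1], excl)) ++matches;
      --i; --j;
      state = (t == TM_M) ? 0 : (t == TM_IX ? 1 : 2);
      if (local && i == 0 && j == 0) break;
      if (local && state == 0 && AT(tm, i, j) == TM_START && AT(M, i, j) == 0 &&
          i == 0 && j == 0) break;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      uint8_t t = AT(tx, i, j);
      --i;
      state = (t == 0) ? 0 : 1;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      uint8_t t = AT(ty, i, j);
      --j;
      state = (t == 0) ? 0 : 2;
    }
    if (local && state == 0 && AT(M, i, j) == 0 && AT(tm, i, j) == TM_START)
      break;
  }
  out.a_start = i + 1;
  out.b_start = j + 1;
  if (ra.empty()) { out.a_start = out.a_end = out.b_start = out.b_end = 0; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  out.aln_a = ra;
  out.aln_b = rb;
  out.matches = matches;
  out.aln_len = (int)ra.size();
  return out;
#undef AT
}

static List aln_to_list(const AlnOut& o) {
  return List::create(
      _["score"] = o.score, _["matches"] = o.matches, _["aln_len"] = o.aln_len,
      _["a_start"] = o.a_start, _["a_end"] = o.a_end, _["b_start"] = o.b_start,
      _["b_end"] = o.b_end, _["aligned_a"] = o.aln_a, _["aligned_b"] = o.aln_b);
}

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, NumericMatrix submat,
                    double gap_open, double gap_extend, bool local) {
  Scorer sc = scorer_from_matrix(submat);
  return aln_to_list(gotoh(a, b, sc, gap_open, gap_extend, local, "X*"));
}

// [[Rcpp::export]]
List align_pair_nt_cpp(std::string a, std::string b, double match,
                       double mismatch, double gap_open, double gap_extend,
                       bool local) {
  Scorer sc = scorer_nt(match, mismatch);
  return aln_to_list(gotoh(a, b, sc, gap_open, gap_extend, local, "N"));
}

// number of k-mer start positions of the shorter sequence whose word occurs
// anywhere in the longer sequence (the clustering prefilter statistic)
// [[Rcpp::export]]
int shared_kmer_positions_cpp(std::string a, std::string b, int k) {
  const std::string& s = (a.size() <= b.size()) ? a : b;
  const std::string& l = (a.size() <= b.size()) ? b : a;
  if ((int)s.size() < k) return 0;
  std::unordered_set<std::string> words;
  for (size_t i = 0; i + k <= l.size(); ++i) words.insert(l.substr(i, k));
  int hits = 0;
  for (size_t i = 0; i + k <= s.size(); ++i)
    if (words.count(s.substr(i, k))) ++hits;
  return hits;
}

// ---- fragment-vs-genome mapping for ANIb ---------------------------------

static inline int base2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Map each query fragment onto the subject with exact k-mer seeds voting on
// (binned) diagonals, then run a local affine alignment of the fragment
// against the best-voted subject window on the best strand.  This is the
// seed-and-extend core a BLASTn-based ANI would delegate to the search tool.
// [[Rcpp::export]]
DataFrame anib_map_cpp(CharacterVector fragments, std::string subject, int k,
                       int pad, double match, double mismatch,
                       double gap_open, double gap_extend) {
  const int BIN = 32;
  if ((int)subject.size() < k) stop("subject shorter than seed length");
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve(subject.size());
  {
    uint64_t w = 0; int run = 0; const uint64_t mask = (1ULL << (2 * k)) - 1;
    for (size_t i = 0; i < subject.size(); ++i) {
      int c = base2(subject[i]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[w].push_back((int)(i + 1 - k));
    }
  }
  Scorer sc = scorer_nt(match, mismatch);
  int nf = fragments.size();
  NumericVector identity(nf), score(nf), frag_cov(nf);
  IntegerVector matches(nf), aln_len(nf);
  CharacterVector strand(nf);
  for (int f = 0; f < nf; ++f) {
    std::string q = as<std::string>(fragments[f]);
    int best_votes = 0, best_bin = 0;
    char best_strand = '+';
    std::string best_q;
    for (int ori = 0; ori < 2; ++ori) {
      std::string qq = ori ? revcomp(q) : q;
      std::unordered_map<int, int> votes;
      uint64_t w = 0; int run = 0; const uint64_t mask = (1ULL << (2 * k)) - 1;
      for (size_t i = 0; i < qq.size(); ++i) {
        int c = base2(qq[i]);
        if (c < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(w);
          if (it != index.end()) {
            int qpos = (int)(i + 1 - k);
            for (int spos : it->second) {
              int d = spos - qpos;
              // a hit near a bin edge supports both neighbouring bins
              votes[d / BIN - (d < 0 ? 1 : 0)]++;
            }
          }
        }
      }
      for (auto& kv : votes)
        if (kv.second > best_votes) {
          best_votes = kv.second; best_bin = kv.first;
          best_strand = ori ? '-' : '+'; best_q = qq;
        }
    }
    if (best_votes == 0) {
      identity[f] = NA_REAL; score[f] = NA_REAL; frag_cov[f] = NA_REAL;
      matches[f] = NA_INTEGER; aln_len[f] = NA_INTEGER; strand[f] = NA_STRING;
      continue;
    }
    int d0 = best_bin * BIN;
    int ws = d0 - pad, we = d0 + BIN + (int)best_q.size() + pad;
    if (ws < 0) ws = 0;
    if (we > (int)subject.size()) we = (int)subject.size();
    std::string window = subject.substr(ws, we - ws);
    AlnOut o = gotoh(best_q, window, sc, gap_open, gap_extend, true, "N");
    if (o.aln_len == 0) {
      identity[f] = NA_REAL; score[f] = NA_REAL; frag_cov[f] = NA_REAL;
      matches[f] = NA_INTEGER; aln_len[f] = NA_INTEGER; strand[f] = NA_STRING;
      continue;
    }
    identity[f] = 100.0 * o.matches / o.aln_len;
    score[f] = o.score;
    frag_cov[f] = 100.0 * (o.a_end - o.a_start + 1) / (double)q.size();
    matches[f] = o.matches;
    aln_len[f] = o.aln_len;
    strand[f] = std::string(1, best_strand);
  }
  return DataFrame::create(_["identity"] = identity, _["frag_cov"] = frag_cov,
                           _["matches"] = matches, _["aln_len"] = aln_len,
                           _["score"] = score, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
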