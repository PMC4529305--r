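#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small string kernels shared by read mapping, trimming and siRNA screening
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_mismatch_at(const std::vector<std::string>& subjects,
                              const IntegerVector& subj_idx,
                              const IntegerVector& start,
                              const std::vector<std::string>& query) {
  R_xlen_t n = query.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string& s = subjects[subj_idx[i] - 1];
    const std::string& q = query[i];
    long st = start[i];
    if (st < 0 || st + (long)q.size() > (long)s.size()) {
      out[i] = NA_INTEGER;
      continue;
    }
    int mm = 0;
    for (size_t j = 0; j < q.size(); ++j)
      if (s[st + j] != q[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// Windows of each transcript matching `cand` in >= min_match positions.
// Used by the off-target screen when the pigeonhole seed index does not
// apply, and exercised directly in oracle tests.
// [[Rcpp::export]]
DataFrame cpp_hamming_windows(const std::string& cand,
                              const std::vector<std::string>& txs,
                              int min_match) {
  std::vector<int> tx_out, off_out, match_out;
  int k = (int)cand.size();
  for (size_t t = 0; t < txs.size(); ++t) {
    const std::string& s = txs[t];
    if ((int)s.size() < k) continue;
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      int m = 0;
      for (int j = 0; j < k; ++j)
        if (s[p + j] == cand[j]) ++m;
      if (m >= min_match) {
        tx_out.push_back((int)t + 1);
        off_out.push_back(p);
        match_out.push_back(m);
      }
    }
  }
  return DataFrame::create(_["tx_idx"] = tx_out, _["offset"] = off_out,
                           _["matches"] = match_out);
}

// Longest run of consecutive matching positions between cand and the window
// of s starting at p (both same length as cand).
// [[Rcpp::export]]
IntegerVector cpp_max_match_run(const std::string& cand,
                                const std::vector<std::string>& txs,
                                const IntegerVector& tx_idx,
                                const IntegerVector& offset) {
  R_xlen_t n = tx_idx.size();
  IntegerVector out(n);
  int k = (int)cand.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string& s = txs[tx_idx[i] - 1];
    int p = offset[i], run = 0, best = 0;
    for (int j = 0; j < k; ++j) {
      if (s[p + j] == cand[j]) { if (++run > best) best = run; }
      else run = 0;
    }
    out[i] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// read trimming (adapter clip -> trailing Ns -> quality ends -> filters)
// ---------------------------------------------------------------------------

static int adapter_clip_pos(const std::string& seq, const std::string& adapter,
                            int min_overlap, double min_identity) {
  int n = (int)seq.size(), alen = (int)adapter.size();
  // leftmost start (= longest overlap) whose suffix/prefix overlap with the
  // adapter reaches the identity threshold
  for (int p = 0; p + min_overlap <= n; ++p) {
    int ov = std::min(n - p, alen);
    if (ov < min_overlap) break;
    int match = 0;
    for (int j = 0; j < ov; ++j)
      if (seq[p + j] == adapter[j]) ++match;
    if ((double)match / ov >= min_identity) return p;
  }
  return n;
}

// [[Rcpp::export]]
List cpp_trim_mates(const std::vector<std::string>& seqs,
                    const std::vector<std::string>& quals,
                    const std::string& adapter,
                    int qual_trim, double min_mean_qual, int min_len,
                    int trim_ns, int min_overlap, double min_identity) {
  R_xlen_t n = seqs.size();
  CharacterVector out_seq(n), out_qual(n), reason(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = seqs[i], q = quals[i];
    if (s.size() != q.size())
      stop("sequence/quality length mismatch in record %d", (int)(i + 1));
    // (1) adapter clip
    int clip = adapter_clip_pos(s, adapter, min_overlap, min_identity);
    s = s.substr(0, clip);
    q = q.substr(0, clip);
    // (2) up to trim_ns trailing Ns
    int dropped = 0;
    while (!s.empty() && dropped < trim_ns &&
           (s.back() == 'N' || s.back() == 'n')) {
      s.pop_back(); q.pop_back(); ++dropped;
    }
    // (3) quality-trim both ends
    size_t lo = 0, hi = s.size();
    while (lo < hi && (int)q[lo] - 33 < qual_trim) ++lo;
    while (hi > lo && (int)q[hi - 1] - 33 < qual_trim) --hi;
    s = s.substr(lo, hi - lo);
    q = q.substr(lo, hi - lo);
    // (4) filters
    double mean_q = 0.0;
    for (char c : q) mean_q += (int)c - 33;
    if (!q.empty()) mean_q /= q.size();
    if ((int)s.size() < min_len) {
      reason[i] = "min_len";
    } else if (mean_q < min_mean_qual) {
      reason[i] = "min_mean_qual";
    } else {
      reason[i] = NA_STRING;
    }
    out_seq[i] = s;
    out_qual[i] = q;
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["reason"] = reason);
}

// ---------------------------------------------------------------------------
// streaming median k-mer coverage normalization (canonical k-mers)
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static void canonical_kmers(const std::string& s, int k,
                            std::vector<std::string>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  for (int p = 0; p + k <= n; ++p) {
    std::string fwd = s.substr(p, k);
    std::string rev(k, 'N');
    for (int j = 0; j < k; ++j) rev[j] = comp_base(fwd[k - 1 - j]);
    out.push_back(fwd <= rev ? fwd : rev);
  }
}

static double median_count(const std::vector<std::string>& kmers,
                           std::unordered_map<std::string, int>& table) {
  if (kmers.empty()) return 0.0;
  std::vector<int> counts;
  counts.reserve(kmers.size());
  for (const auto& km : kmers) {
    auto it = table.find(km);
    counts.push_back(it == table.end() ? 0 : it->second);
  }
  std::sort(counts.begin(), counts.end());
  size_t n = counts.size();
  if (n % 2 == 1) return counts[n / 2];
  return (counts[n / 2 - 1] + counts[n / 2]) / 2.0;
}

// [[Rcpp::export]]
LogicalVector cpp_normalize_pairs(const std::vector<std::string>& mate1,
                                  const std::vector<std::string>& mate2,
                                  int k, double max_cov) {
  R_xlen_t n = mate1.size();
  LogicalVector keep(n);
  std::unordered_map<std::string, int> table;
  std::vector<std::string> km1, km2;
  for (R_xlen_t i = 0; i < n; ++i) {
    canonical_kmers(mate1[i], k, km1);
    canonical_kmers(mate2[i], k, km2);
    bool acc = median_count(km1, table) <= max_cov ||
               median_count(km2, table) <= max_cov;
    keep[i] = acc;
    if (acc) {
      for (const auto& km : km1) ++table[km];
      for (const auto& km : km2) ++table[km];
    }
  }
  return keep;
}

// ---------------------------------------------------------------------------
// pairwise alignment (Gotoh affine-gap DP): global and local
// gap of length L costs gap_open + L * gap_ext (matches the convention of
// Biostrings::pairwiseAlignment, used as an independent cross-check in tests)
// ---------------------------------------------------------------------------

static void build_lookup(const NumericMatrix& submat, double lut[128][128]) {
  CharacterVector rn = rownames(submat), cn = colnames(submat);
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) lut[i][j] = NA_REAL;
  for (int i = 0; i < submat.nrow(); ++i) {
    char a = CHAR(STRING_ELT(rn, i))[0];
    for (int j = 0; j < submat.ncol(); ++j) {
      char b = CHAR(STRING_ELT(cn, j))[0];
      lut[(int)a][(int)b] = submat(i, j);
    }
  }
}

static const double NEG_INF = -1e18;

// state codes: 0 = M (diagonal), 1 = Ix (gap in b, consumes a), 2 = Iy
// traceback byte: bits 0-1 best state, bit 2 Ix-from-Ix, bit 3 Iy-from-Iy

// [[Rcpp::export]]
List cpp_nw_align(const std::string& a, const std::string& b,
                  const NumericMatrix& submat,
                  double gap_open, double gap_ext) {
  double lut[128][128];
  build_lookup(submat, lut);
  size_t n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF),
      Ix((n + 1) * (m + 1), NEG_INF), Iy((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);
  auto at = [m](size_t i, size_t j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (size_t i = 1; i <= n; ++i) {
    Ix[at(i, 0)] = -(gap_open + i * gap_ext);
    tb[at(i, 0)] = 1 | (i > 1 ? 4 : 0);
  }
  for (size_t j = 1; j <= m; ++j) {
    Iy[at(0, j)] = -(gap_open + j * gap_ext);
    tb[at(0, j)] = 2 | (j > 1 ? 8 : 0);
  }
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      double sc = lut[(int)a[i - 1]][(int)b[j - 1]];
      if (ISNA(sc)) stop("character pair (%c,%c) not in substitution matrix",
                         a[i - 1], b[j - 1]);
      double prev = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             Iy[at(i - 1, j - 1)]);
      M[at(i, j)] = prev + sc;
      unsigned char flags = 0;
      double fromM = (M[at(i - 1, j)] > NEG_INF / 2)
                         ? M[at(i - 1, j)] - gap_open - gap_ext : NEG_INF;
      double fromIy_x = (Iy[at(i - 1, j)] > NEG_INF / 2)
                         ? Iy[at(i - 1, j)] - gap_open - gap_ext : NEG_INF;
      double open_x = std::max(fromM, fromIy_x);
      double ext_x = (Ix[at(i - 1, j)] > NEG_INF / 2)
                         ? Ix[at(i - 1, j)] - gap_ext : NEG_INF;
      if (ext_x > open_x) { Ix[at(i, j)] = ext_x; flags |= 4; }
      else Ix[at(i, j)] = open_x;
      double fromM_y = (M[at(i, j - 1)] > NEG_INF / 2)
                         ? M[at(i, j - 1)] - gap_open - gap_ext : NEG_INF;
      double fromIx_y = (Ix[at(i, j - 1)] > NEG_INF / 2)
                         ? Ix[at(i, j - 1)] - gap_open - gap_ext : NEG_INF;
      double open_y = std::max(fromM_y, fromIx_y);
      double ext_y = (Iy[at(i, j - 1)] > NEG_INF / 2)
                         ? Iy[at(i, j - 1)] - gap_ext : NEG_INF;
      if (ext_y > open_y) { Iy[at(i, j)] = ext_y; flags |= 8; }
      else Iy[at(i, j)] = open_y;
      // tie preference: diagonal, then gap-in-b, then gap-in-a
      unsigned char best = 0;
      double bs = M[at(i, j)];
      if (Ix[at(i, j)] > bs) { bs = Ix[at(i, j)]; best = 1; }
      if (Iy[at(i, j)] > bs) { bs = Iy[at(i, j)]; best = 2; }
      tb[at(i, j)] = flags | best;
    }
  }
  double score = M[at(n, m)];
  int state = 0;
  if (Ix[at(n, m)] > score) { score = Ix[at(n, m)]; state = 1; }
  if (Iy[at(n, m)] > score) { score = Iy[at(n, m)]; state = 2; }
  std::string al_a, al_b;
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      al_a.push_back(a[i - 1]);
      al_b.push_back(b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      double best = M[at(i, j)];
      state = 0;
      if (Ix[at(i, j)] > best) { best = Ix[at(i, j)]; state = 1; }
      if (Iy[at(i, j)] > best) { state = 2; }
    } else if (state == 1) {
      al_a.push_back(a[i - 1]);
      al_b.push_back('-');
      bool from_ix = tb[at(i, j)] & 4;
      --i;
      if (!from_ix) {
        state = (Iy[at(i, j)] > M[at(i, j)]) ? 2 : 0;
        if (i == 0 && j > 0) state = 2;
      }
    } else {
      al_a.push_back('-');
      al_b.push_back(b[j - 1]);
      bool from_iy = tb[at(i, j)] & 8;
      --j;
      if (!from_iy) {
        state = (Ix[at(i, j)] > M[at(i, j)]) ? 1 : 0;
        if (j == 0 && i > 0) state = 1;
      }
    }
  }
  std::reverse(al_a.begin(), al_a.end());
  std::reverse(al_b.begin(), al_b.end());
  return List::create(_["score"] = score, _["aligned_a"] = al_a,
                      _["aligned_b"] = al_b);
}

// [[Rcpp::export]]
List cpp_sw_align(const std::string& a, const std::string& b,
                  const NumericMatrix& submat,
                  double gap_open, double gap_ext) {
  double lut[128][128];
  build_lookup(submat, lut);
  size_t n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), 0.0),
      Ix((n + 1) * (m + 1), NEG_INF), Iy((n + 1) * (m + 1), NEG_INF);
  auto at = [m](size_t i, size_t j) { return i * (m + 1) + j; };
  double best_score = 0.0;
  size_t bi = 0, bj = 0;
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      double sc = lut[(int)a[i - 1]][(int)b[j - 1]];
      if (ISNA(sc)) stop("character pair (%c,%c) not in substitution matrix",
                         a[i - 1], b[j - 1]);
      double prev = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             Iy[at(i - 1, j - 1)]);
      M[at(i, j)] = std::max(0.0, prev + sc);
      Ix[at(i, j)] = std::max(
          std::max(M[at(i - 1, j)], Iy[at(i - 1, j)]) - gap_open - gap_ext,
          Ix[at(i - 1, j)] - gap_ext);
      Iy[at(i, j)] = std::max(
          std::max(M[at(i, j - 1)], Ix[at(i, j - 1)]) - gap_open - gap_ext,
          Iy[at(i, j - 1)] - gap_ext);
      if (M[at(i, j)] > best_score) {
        best_score = M[at(i, j)];
        bi = i; bj = j;
      }
    }
  }
  // traceback from the maximum M cell until the running score drops to 0
  std::string al_a, al_b;
  size_t i = bi, j = bj;
  int state = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (M[at(i, j)] <= 0.0) break;
      al_a.push_back(a[i - 1]);
      al_b.push_back(b[j - 1]);
      --i; --j;
      double bm = M[at(i, j)];
      state = 0;
      if (Ix[at(i, j)] > bm) { bm = Ix[at(i, j)]; state = 1; }
      if (Iy[at(i, j)] > bm) state = 2;
      if (std::max(std::max(M[at(i, j)], Ix[at(i, j)]), Iy[at(i, j)]) <= 0.0)
        break;
    } else if (state == 1) {
      al_a.push_back(a[i - 1]);
      al_b.push_back('-');
      double from_ext = Ix[at(i - 1, j)] - gap_ext;
      double from_open = std::max(M[at(i - 1, j)], Iy[at(i - 1, j)]) -
                         gap_open - gap_ext;
      --i;
      if (from_ext > from_open) state = 1;
      else state = (Iy[at(i, j)] > M[at(i, j)]) ? 2 : 0;
    } else {
      al_a.push_back('-');
      al_b.push_back(b[j - 1]);
      double from_ext = Iy[at(i, j - 1)] - gap_ext;
      double from_open = std::max(M[at(i, j - 1)], Ix[at(i, j - 1)]) -
                         gap_open - gap_ext;
      --j;
      if (from_ext > from_open) state = 2;
      else state = (Ix[at(i, j)] > M[at(i, j)]) ? 1 : 0;
    }
  }
  std::reverse(al_a.begin(), al_a.end());
  std::reverse(al_b.begin(), al_b.end());
  return List::create(_["score"] = best_score,
                      _["a_start"] = (double)i, _["a_end"] = (double)bi,
                      _["b_start"] = (double)j, _["b_end"] = (double)bj,
                      _["aligned_a"] = al_a, _["aligned_b"] = al_b);
}

// score-only Smith-Waterman (rolling rows); used to pre-filter candidate
// target proteins before the full traceback alignment
// [[Rcpp::export]]
double cpp_sw_score(const std::string& a, const std::string& b,
                    const NumericMatrix& submat,
                    double gap_open, double gap_ext) {
  double lut[128][128];
  build_lookup(submat, lut);
  size_t n = a.size(), m = b.size();
  std::vector<double> M_prev(m + 1, 0.0), M_cur(m + 1, 0.0),
      Ix_prev(m + 1, NEG_INF), Ix_cur(m + 1, NEG_INF),
      Iy_prev(m + 1, NEG_INF), Iy_cur(m + 1, NEG_INF);
  double best = 0.0;
  for (size_t i = 1; i <= n; ++i) {
    M_cur[0] = 0.0; Ix_cur[0] = NEG_INF; Iy_cur[0] = NEG_INF;
    for (size_t j = 1; j <= m; ++j) {
      double sc = lut[(int)a[i - 1]][(int)b[j - 1]];
      if (ISNA(sc)) stop("character pair (%c,%c) not in substitution matrix",
                         a[i - 1], b[j - 1]);
      double prev = std::max(std::max(M_prev[j - 1], Ix_prev[j - 1]),
                             Iy_prev[j - 1]);
      M_cur[j] = std::max(0.0, prev + sc);
      Ix_cur[j] = std::max(
          std::max(M_prev[j], Iy_prev[j]) - gap_open - gap_ext,
          Ix_prev[j] - gap_ext);
      Iy_cur[j] = std::max(
          std::max(M_cur[j - 1], Ix_cur[j - 1]) - gap_open - gap_ext,
          Iy_cur[j - 1] - gap_ext);
      if (M_cur[j] > best) best = M_cur[j];
    }
    std::swap(M_prev, M_cur);
    std::swap(Ix_prev, Ix_cur);
    std::swap(Iy_prev, Iy_cur);
  }
  return best;
}

// longest substring of each sequence whose reverse complement also occurs
// in the same sequence (self-complementarity potential of an siRNA)
// [[Rcpp::export]]
IntegerVector cpp_self_complement(const std::vector<std::string>& seqs) {
  R_xlen_t ns = seqs.size();
  IntegerVector out(ns);
  for (R_xlen_t s = 0; s < ns; ++s) {
    const std::string& a = seqs[s];
    int n = (int)a.size();
    std::string rc(n, 'N');
    for (int i = 0; i < n; ++i) rc[i] = comp_base(a[n - 1 - i]);
    // longest common substring of a and rc via suffix DP
    std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= n; ++j) {
        if (a[i - 1] == rc[j - 1]) {
          cur[j] = prev[j - 1] + 1;
          if (cur[j] > best) best = cur[j];
        } else cur[j] = 0;
      }
      std::swap(prev, cur);
    }
    out[s] = best;
  }
  return out;
}
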