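// Local alignment of read sequences against a retroelement consensus
// library. Scoring: match +1, mismatch -1, gap -2. Two modes:
//  * seed_k > 0: shared-k-mer seeding against a per-consensus k-mer index
//    (built once), diagonal voting, then a banded Smith-Waterman around
//    the best diagonal. Substitution-dominated reads stay on one
//    diagonal, so the band is exact for them.
//  * seed_k == 0: exhaustive full-matrix Smith-Waterman.
// The DP tracks start coordinates, match count and alignment length so
// identity and consensus span fall out of a single score-only pass.

#include <Rcpp.h>
#include <cstring>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

struct Cell {
  int score = 0;
  int nmatch = 0;
  int alen = 0;   // alignment columns (incl. gaps)
  int si = 0;     // start row (read, 0-based)
  int sj = 0;     // start col (subject, 0-based)
};

struct Best {
  int score = 0, nmatch = 0, alen = 0;
  int ri0 = 0, ri1 = 0, cj0 = 0, cj1 = 0; // read/subject spans, half-open
};

static inline void relax(const char* r, const char* s, int i, int j,
                         const Cell& diag, const Cell& up, const Cell& left,
                         bool up_valid, bool left_valid,
                         int match, int mismatch, int gap, Cell& c) {
  bool eq = (r[i - 1] == s[j - 1]) && r[i - 1] != 'N';
  int sub = diag.score + (eq ? match : mismatch);
  int del = up_valid ? up.score + gap : -1000000;
  int ins = left_valid ? left.score + gap : -1000000;
  c = Cell();
  if (sub >= del && sub >= ins && sub > 0) {
    c.score = sub;
    c.nmatch = diag.nmatch + (eq ? 1 : 0);
    c.alen = diag.alen + 1;
    if (diag.score == 0 && diag.alen == 0) { c.si = i - 1; c.sj = j - 1; }
    else { c.si = diag.si; c.sj = diag.sj; }
  } else if (del >= ins && del > 0) {
    c.score = del; c.nmatch = up.nmatch; c.alen = up.alen + 1;
    c.si = up.si; c.sj = up.sj;
  } else if (ins > 0) {
    c.score = ins; c.nmatch = left.nmatch; c.alen = left.alen + 1;
    c.si = left.si; c.sj = left.sj;
  }
}

static Best sw_full(const char* r, int n, const char* s, int m,
                    int match, int mismatch, int gap) {
  std::vector<Cell> prev(m + 1), cur(m + 1);
  Best best;
  for (int i = 1; i <= n; ++i) {
    cur[0] = Cell();
    for (int j = 1; j <= m; ++j) {
      relax(r, s, i, j, prev[j - 1], prev[j], cur[j - 1], true, true,
            match, mismatch, gap, cur[j]);
      const Cell& c = cur[j];
      if (c.score > best.score ||
          (c.score == best.score && c.alen > best.alen)) {
        best = {c.score, c.nmatch, c.alen, c.si, i, c.sj, j};
      }
    }
    std::swap(prev, cur);
  }
  return best;
}

// banded SW around diagonal d0 (j - i in [d0-band, d0+band])
static Best sw_banded(const char* r, int n, const char* s, int m,
                      int d0, int band, int match, int mismatch, int gap) {
  int W = 2 * band + 1;
  // row storage indexed by j - (i + d0 - band)
  std::vector<Cell> prev(W + 2), cur(W + 2);
  std::vector<char> pvalid(W + 2, 0), cvalid(W + 2, 0);
  Best best;
  for (int i = 1; i <= n; ++i) {
    int jlo = i + d0 - band, jhi = i + d0 + band;
    std::fill(cvalid.begin(), cvalid.end(), 0);
    for (int j = std::max(1, jlo); j <= std::min(m, jhi); ++j) {
      int k = j - jlo;          // 0..W-1 in current row
      int kp = k + 1;           // same j in previous row (jlo shifts by 1)
      Cell diag, up, left;
      bool upv = false, leftv = false;
      // prev row: j-1 -> index (j-1) - (jlo-1) = k ; j -> k+1
      if (i > 1) {
        if (k >= 0 && k < W && pvalid[k]) diag = prev[k];
        else diag = Cell();
        if (kp >= 0 && kp < W && pvalid[kp]) { up = prev[kp]; upv = true; }
      } else diag = Cell();
      if (k - 1 >= 0 && cvalid[k - 1]) { left = cur[k - 1]; leftv = true; }
      relax(r, s, i, j, diag, up, left, upv, leftv, match, mismatch, gap, cur[k]);
      cvalid[k] = 1;
      const Cell& c = cur[k];
      if (c.score > best.score ||
          (c.score == best.score && c.alen > best.alen)) {
        best = {c.score, c.nmatch, c.alen, c.si, i, c.sj, j};
      }
    }
    std::swap(prev, cur);
    std::swap(pvalid, cvalid);
  }
  return best;
}

struct KIndex {
  std::unordered_map<uint64_t, std::vector<int>> pos; // kmer -> subject starts
};

static inline int enc(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

static KIndex build_index(const std::string& s, int k, int cap) {
  KIndex idx;
  uint64_t key = 0, mask = (1ULL << (2 * k)) - 1ULL;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int e = enc(s[i]);
    if (e < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)e) & mask;
    if (++run >= k) {
      auto& v = idx.pos[key];
      if ((int)v.size() < cap) v.push_back((int)(i + 1 - k));
    }
  }
  return idx;
}

// best seed diagonal of read vs indexed subject; returns votes (0 = none)
static int seed_diag(const std::string& r, const KIndex& idx, int k,
                     int* best_diag) {
  std::unordered_map<int, int> votes;
  uint64_t key = 0, mask = (1ULL << (2 * k)) - 1ULL;
  int run = 0;
  for (size_t i = 0; i < r.size(); ++i) {
    int e = enc(r[i]);
    if (e < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)e) & mask;
    if (++run >= k) {
      auto it = idx.pos.find(key);
      if (it != idx.pos.end()) {
        int ri = (int)(i + 1 - k);
        for (int sj : it->second) votes[sj - ri]++;
      }
    }
  }
  int bv = 0, bd = 0;
  for (auto& kv : votes)
    if (kv.second > bv || (kv.second == bv && kv.first < bd)) {
      bv = kv.second; bd = kv.first;
    }
  *best_diag = bd;
  return bv;
}

// [[Rcpp::export(name = ".sw_classify")]]
DataFrame sw_classify(CharacterVector reads,
                      CharacterVector lib_seq_fwd,
                      CharacterVector lib_seq_rev,
                      double min_identity, int min_len,
                      int match, int mismatch, int gap,
                      int seed_k, int band = 16) {
  int nr = reads.size(), nl = lib_seq_fwd.size();
  std::vector<std::string> seqs(2 * nl);
  std::vector<KIndex> idx(2 * nl);
  for (int l = 0; l < nl; ++l) {
    seqs[2 * l] = as<std::string>(lib_seq_fwd[l]);
    seqs[2 * l + 1] = as<std::string>(lib_seq_rev[l]);
  }
  if (seed_k > 0)
    for (int t = 0; t < 2 * nl; ++t)
      idx[t] = build_index(seqs[t], seed_k, 16);

  IntegerVector lib_index(nr, NA_INTEGER);
  CharacterVector orient(nr, NA_STRING);
  NumericVector identity(nr, NA_REAL);
  IntegerVector cs(nr, NA_INTEGER), ce(nr, NA_INTEGER), alen(nr, NA_INTEGER);

  for (int i = 0; i < nr; ++i) {
    std::string r = as<std::string>(reads[i]);
    Best best; int best_t = -1;
    for (int t = 0; t < 2 * nl; ++t) {
      const std::string& s = seqs[t];
      Best b;
      if (seed_k > 0) {
        int d0 = 0;
        int votes = seed_diag(r, idx[t], seed_k, &d0);
        if (votes == 0) continue;
        b = sw_banded(r.c_str(), r.size(), s.c_str(), s.size(), d0, band,
                      match, mismatch, gap);
      } else {
        b = sw_full(r.c_str(), r.size(), s.c_str(), s.size(),
                    match, mismatch, gap);
      }
      // ties: longer alignment, then library order (earlier wins); forward
      // strand preferred within an entry
      if (b.score > best.score ||
          (b.score == best.score && b.alen > best.alen)) {
        best = b; best_t = t;
      }
    }
    if (best_t < 0) continue;
    double id = best.alen > 0 ? (double)best.nmatch / best.alen : 0.0;
    if (best.alen < min_len || id < min_identity) continue;
    int l = best_t / 2; bool fwds = best_t % 2 == 0;
    lib_index[i] = l + 1;
    orient[i] = fwds ? "+" : "-";
    identity[i] = id;
    int m = (int)seqs[2 * l].size();
    if (fwds) { cs[i] = best.cj0; ce[i] = best.cj1; }
    else { cs[i] = m - best.cj1; ce[i] = m - best.cj0; }
    alen[i] = best.alen;
  }
  return DataFrame::create(_["lib_index"] = lib_index, _["orientation"] = orient,
                           _["identity"] = identity, _["consensus_start"] = cs,
                           _["consensus_end"] = ce, _["aligned_len"] = alen,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".sw_local")]]
List sw_local(std::string a, std::string b, int match, int mismatch, int gap) {
  Best r = sw_full(a.c_str(), a.size(), b.c_str(), b.size(), match, mismatch, gap);
  return List::create(_["score"] = r.score, _["nmatch"] = r.nmatch,
                      _["alen"] = r.alen,
                      _["a_start"] = r.ri0, _["a_end"] = r.ri1,
                      _["b_start"] = r.cj0, _["b_end"] = r.cj1);
}
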