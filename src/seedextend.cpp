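// Greedy seed-and-extend local alignment core.
//
// Sequences arrive as plain character strings; lowercase letters mark
// soft-masked positions.  Masked and ambiguous positions never seed but are
// scored normally during extension (soft-mask semantics).  Gap costs are
// linear.  Extension in each direction is a banded dynamic program over the
// cells whose running score stays within `xdrop` of the running maximum,
// which is the classical X-drop termination rule.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Enc {
  std::vector<uint8_t> code;    // A=0 C=1 G=2 T=3 other=4
  std::vector<uint8_t> seedok;  // 1 iff uppercase ACGT
};

Enc encode_seq(const std::string& s) {
  Enc e;
  const size_t n = s.size();
  e.code.resize(n);
  e.seedok.resize(n);
  for (size_t i = 0; i < n; ++i) {
    const char c = s[i];
    const bool lower = (c >= 'a' && c <= 'z');
    const char u = lower ? static_cast<char>(c - 32) : c;
    uint8_t k;
    switch (u) {
      case 'A': k = 0; break;
      case 'C': k = 1; break;
      case 'G': k = 2; break;
      case 'T': k = 3; break;
      default:  k = 4; break;
    }
    e.code[i] = k;
    e.seedok[i] = (!lower && k < 4) ? 1 : 0;
  }
  return e;
}

struct Run { int a0; int b0; int len; };  // 0-based starts, exact-match run

// All maximal exact matches of length >= W between seedable positions.
std::vector<Run> seed_runs(const Enc& A, const Enc& B, int W) {
  std::vector<Run> runs;
  const int nA = static_cast<int>(A.code.size());
  const int nB = static_cast<int>(B.code.size());
  if (nA < W || nB < W) return runs;

  const uint64_t mask = (W >= 32) ? ~0ULL : ((1ULL << (2 * W)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(static_cast<size_t>(nA));

  uint64_t key = 0;
  int valid = 0;
  for (int i = 0; i < nA; ++i) {
    if (A.seedok[i]) { key = ((key << 2) | A.code[i]) & mask; ++valid; }
    else             { key = 0; valid = 0; }
    if (valid >= W) idx[key].push_back(i - W + 1);
  }

  std::vector<std::pair<int,int>> hits;  // (a0, b0) word matches
  key = 0; valid = 0;
  for (int j = 0; j < nB; ++j) {
    if (B.seedok[j]) { key = ((key << 2) | B.code[j]) & mask; ++valid; }
    else             { key = 0; valid = 0; }
    if (valid >= W) {
      auto it = idx.find(key);
      if (it != idx.end())
        for (int a0 : it->second) hits.push_back(std::make_pair(a0, j - W + 1));
    }
  }
  if (hits.empty()) return runs;

  std::sort(hits.begin(), hits.end(),
            [](const std::pair<int,int>& x, const std::pair<int,int>& y) {
              const int dx = x.second - x.first, dy = y.second - y.first;
              if (dx != dy) return dx < dy;
              return x.first < y.first;
            });

  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i;
    while (j + 1 < hits.size() &&
           (hits[j + 1].second - hits[j + 1].first) ==
               (hits[i].second - hits[i].first) &&
           hits[j + 1].first == hits[j].first + 1)
      ++j;
    Run r;
    r.a0 = hits[i].first;
    r.b0 = hits[i].second;
    r.len = static_cast<int>(j - i) + W;
    runs.push_back(r);
    i = j + 1;
  }
  return runs;
}

struct Ext {
  int score;         // best extension score (>= 0)
  int alen;          // A characters consumed to the best cell
  int blen;          // B characters consumed to the best cell
  std::string ops;   // outward-most character FIRST ('M' diag, 'D' consumes A, 'I' consumes B)
};

// Extend from (astart, bstart) (0-based index of the first character to
// consume) in direction dir (+1 right, -1 left).  Returns the maximal-score
// prefix of the extension under X-drop pruning.
Ext xdrop_extend(const Enc& A, const Enc& B, int astart, int bstart, int dir,
                 int match, int mismatch, int gap, int xdrop) {
  const int NEG = INT_MIN / 4;
  Ext out; out.score = 0; out.alen = 0; out.blen = 0; out.ops.clear();

  const int nA = static_cast<int>(A.code.size());
  const int nB = static_cast<int>(B.code.size());
  int UA = 0, UB = 0;
  if (astart >= 0 && astart < nA) UA = (dir > 0) ? nA - astart : astart + 1;
  if (bstart >= 0 && bstart < nB) UB = (dir > 0) ? nB - bstart : bstart + 1;
  if (UA <= 0 && UB <= 0) return out;

  int best = 0, bu = 0, bv = 0;

  // tb[u] holds traceback codes for row u starting at column lov[u]
  // codes: 0 dead, 1 diag, 2 up (consume A), 3 left (consume B)
  std::vector<std::vector<int8_t>> tb;
  std::vector<int> lov;

  std::vector<int> prev;
  int plo = 0, phi = -1;

  {  // row 0: leading gaps in A (consume B only)
    std::vector<int> row;
    std::vector<int8_t> t;
    for (int v = 0; v <= UB; ++v) {
      const int s = v * gap;
      if (s < best - xdrop) break;
      row.push_back(s);
      t.push_back(v == 0 ? 0 : 3);
    }
    prev = row;
    plo = 0;
    phi = static_cast<int>(row.size()) - 1;
    lov.push_back(0);
    tb.push_back(t);
  }

  const int MAX_ROWS = 400000;  // guard against runaway extensions
  for (int u = 1; u <= UA && u <= MAX_ROWS; ++u) {
    std::vector<int> cur;
    std::vector<int8_t> t;
    int curlo = -1;
    int localBest = NEG;

    for (int v = plo; v <= UB; ++v) {
      const int diag = (v - 1 >= plo && v - 1 <= phi) ? prev[v - 1 - plo] : NEG;
      const int up   = (v     >= plo && v     <= phi) ? prev[v - plo]     : NEG;
      const int left = (curlo >= 0 && v - 1 >= curlo &&
                        v - 1 <= curlo + static_cast<int>(cur.size()) - 1)
                           ? cur[v - 1 - curlo] : NEG;

      int cand = NEG;
      int8_t op = 0;
      if (diag > NEG) {
        const uint8_t ca = A.code[astart + dir * (u - 1)];
        const uint8_t cb = B.code[bstart + dir * (v - 1)];
        const int sij = (ca < 4 && ca == cb) ? match : mismatch;
        cand = diag + sij;
        op = 1;
      }
      if (up > NEG && up + gap > cand)   { cand = up + gap;   op = 2; }
      if (left > NEG && left + gap > cand) { cand = left + gap; op = 3; }
      if (cand < best - xdrop) { cand = NEG; op = 0; }

      if (curlo < 0) {
        if (cand == NEG) {
          if (v > phi + 1) break;  // nothing reachable further right
          continue;
        }
        curlo = v;
      }
      cur.push_back(cand);
      t.push_back(cand == NEG ? static_cast<int8_t>(0) : op);
      if (cand > NEG) {
        if (cand > localBest) localBest = cand;
        if (cand > best) { best = cand; bu = u; bv = v; }
      } else if (v > phi + 1) {
        break;  // past diag/up reach and the left chain just died
      }
    }

    if (curlo < 0 || localBest == NEG) break;  // row dead: X-drop termination
    while (!cur.empty() && cur.back() == NEG) { cur.pop_back(); t.pop_back(); }
    prev = cur;
    plo = curlo;
    phi = curlo + static_cast<int>(cur.size()) - 1;
    lov.push_back(curlo);
    tb.push_back(t);
  }

  // traceback from the best cell
  out.score = best;
  out.alen = bu;
  out.blen = bv;
  int u = bu, v = bv;
  std::string ops;
  while (u > 0 || v > 0) {
    const int8_t op = tb[u][v - lov[u]];
    if (op == 1)      { ops.push_back('M'); --u; --v; }
    else if (op == 2) { ops.push_back('D'); --u; }
    else if (op == 3) { ops.push_back('I'); --v; }
    else break;  // defensive; should not happen on an alive path
  }
  // ops currently runs from the best (outward-most) cell back to the seed
  // boundary, i.e. outward-most character first, which is what we return.
  out.ops = ops;
  return out;
}

struct Hit {
  int a_start, a_end, b_start, b_end;  // 0-based inclusive
  int score, cols, idents;
  std::string ops;                     // left-to-right on A
};

Hit assemble_hit(const Enc& A, const Enc& B, const Run& r,
                 int match, int mismatch, int gap, int xdrop) {
  Ext left  = xdrop_extend(A, B, r.a0 - 1, r.b0 - 1, -1,
                           match, mismatch, gap, xdrop);
  Ext right = xdrop_extend(A, B, r.a0 + r.len, r.b0 + r.len, +1,
                           match, mismatch, gap, xdrop);

  Hit h;
  h.a_start = r.a0 - left.alen;
  h.b_start = r.b0 - left.blen;
  h.a_end = r.a0 + r.len - 1 + right.alen;
  h.b_end = r.b0 + r.len - 1 + right.blen;
  h.score = r.len * match + left.score + right.score;

  std::string ops = left.ops;                 // leftmost-first already
  ops.append(static_cast<size_t>(r.len), 'M');
  std::string rops = right.ops;               // outward-most first: reverse
  std::reverse(rops.begin(), rops.end());
  ops += rops;
  h.ops = ops;

  // identities / columns from the operation string
  int ai = h.a_start, bi = h.b_start, id = 0;
  for (char c : ops) {
    if (c == 'M') {
      const uint8_t ca = A.code[ai], cb = B.code[bi];
      if (ca < 4 && ca == cb) ++id;
      ++ai; ++bi;
    } else if (c == 'D') {
      ++ai;
    } else {
      ++bi;
    }
  }
  h.cols = static_cast<int>(ops.size());
  h.idents = id;
  return h;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_find_seeds(std::string a, std::string b, int w) {
  Enc A = encode_seq(a), B = encode_seq(b);
  std::vector<Run> runs = seed_runs(A, B, w);
  const int n = static_cast<int>(runs.size());
  IntegerVector a_start(n), b_start(n), len(n);
  for (int i = 0; i < n; ++i) {
    a_start[i] = runs[i].a0 + 1;
    b_start[i] = runs[i].b0 + 1;
    len[i] = runs[i].len;
  }
  return DataFrame::create(_["a_start"] = a_start,
                           _["b_start"] = b_start,
                           _["length"] = len,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_extend_seed(std::string a, std::string b,
                     int a_start, int b_start, int seed_len,
                     int match, int mismatch, int gap, int xdrop) {
  Enc A = encode_seq(a), B = encode_seq(b);
  Run r; r.a0 = a_start - 1; r.b0 = b_start - 1; r.len = seed_len;
  Hit h = assemble_hit(A, B, r, match, mismatch, gap, xdrop);
  return List::create(_["a_start"] = h.a_start + 1,
                      _["a_end"] = h.a_end + 1,
                      _["b_start"] = h.b_start + 1,
                      _["b_end"] = h.b_end + 1,
                      _["score"] = h.score,
                      _["aligned_cols"] = h.cols,
                      _["identities"] = h.idents,
                      _["ops"] = h.ops);
}

// [[Rcpp::export]]
DataFrame cpp_align_pair(std::string a, std::string b, int w,
                         int match, int mismatch, int gap, int xdrop) {
  Enc A = encode_seq(a), B = encode_seq(b);
  std::vector<Run> runs = seed_runs(A, B, w);

  // extend the longest runs first so shorter seeds inside an already
  // recovered alignment can be skipped cheaply
  std::sort(runs.begin(), runs.end(), [](const Run& x, const Run& y) {
    if (x.len != y.len) return x.len > y.len;
    if (x.a0 != y.a0) return x.a0 < y.a0;
    return x.b0 < y.b0;
  });

  std::vector<Hit> hits;
  for (const Run& r : runs) {
    bool contained = false;
    for (const Hit& h : hits) {
      if (r.a0 >= h.a_start && r.a0 + r.len - 1 <= h.a_end &&
          r.b0 >= h.b_start && r.b0 + r.len - 1 <= h.b_end &&
          (r.b0 - r.a0) >= (h.b_start - h.a_end) &&
          (r.b0 - r.a0) <= (h.b_end - h.a_start)) {
        contained = true;
        break;
      }
    }
    if (contained) continue;
    hits.push_back(assemble_hit(A, B, r, match, mismatch, gap, xdrop));
  }

  const int n = static_cast<int>(hits.size());
  IntegerVector a_start(n), a_end(n), b_start(n), b_end(n),
      score(n), cols(n), idents(n);
  CharacterVector ops(n);
  for (int i = 0; i < n; ++i) {
    a_start[i] = hits[i].a_start + 1;
    a_end[i] = hits[i].a_end + 1;
    b_start[i] = hits[i].b_start + 1;
    b_end[i] = hits[i].b_end + 1;
    score[i] = hits[i].score;
    cols[i] = hits[i].cols;
    idents[i] = hits[i].idents;
    ops[i] = hits[i].ops;
  }
  return DataFrame::create(_["a_start"] = a_start, _["a_end"] = a_end,
                           _["b_start"] = b_start, _["b_end"] = b_end,
                           _["score"] = score, _["aligned_cols"] = cols,
                           _["identities"] = idents, _["ops"] = ops,
                           _["stringsAsFactors"] = false);
}
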