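#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend local alignment for one query strand against one
// reference, BLAST-style scoring: match/mismatch +1/-1, gap of length k
// costs gap_open + k * gap_extend. Two stages, as in classic seeded
// search: exact word seeds are extended ungapped with X-drop and only
// extensions reaching a trigger score are resolved by a full affine
// Smith-Waterman with traceback inside a padded window — so a reported
// score can never exceed the unrestricted Smith-Waterman score.

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N and friends: never seed, always mismatch
  }
}

struct Hsp {
  int q_start, q_end, r_start, r_end; // 0-based half-open
  int aln_len, mismatches, gap_opens, score;
};

struct Ungapped {
  int d, qs, qe, score; // diagonal r - q, query span, ungapped score
};

// local affine SW with traceback restricted to q[q0,q1) x r[r0,r1)
static bool window_sw(const std::string& q, const std::string& r,
                      int q0, int q1, int r0, int r1,
                      int gap_open, int gap_extend, Hsp& out) {
  const int nq = q1 - q0, nr = r1 - r0;
  if (nq <= 0 || nr <= 0) return false;
  const int NEG = -1000000000;
  const int go = gap_open + gap_extend; // cost of opening a 1-long gap
  std::vector<int> Hprev(nr + 1, 0), Hcur(nr + 1, 0);
  std::vector<int> Eprev(nr + 1, NEG), Ecur(nr + 1, NEG); // gap in reference
  std::vector<int> F(nr + 1, NEG);                        // gap in query
  std::vector<uint8_t> tbH((size_t)(nq + 1) * (nr + 1), 0);
  std::vector<uint8_t> tbE((size_t)(nq + 1) * (nr + 1), 0); // 1 = extend
  std::vector<uint8_t> tbF((size_t)(nq + 1) * (nr + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= nq; ++i) {
    int ci = base2code(q[q0 + i - 1]);
    F[0] = NEG;
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    Hcur[0] = 0;
    for (int j = 1; j <= nr; ++j) {
      size_t at = (size_t)i * (nr + 1) + j;
      int e_open = Hprev[j] - go, e_ext = Eprev[j] - gap_extend;
      Ecur[j] = std::max(e_open, e_ext);
      tbE[at] = e_ext > e_open ? 1 : 0;
      int f_open = Hcur[j - 1] - go, f_ext = F[j - 1] - gap_extend;
      F[j] = std::max(f_open, f_ext);
      tbF[at] = f_ext > f_open ? 1 : 0;
      int cj = base2code(r[r0 + j - 1]);
      int sub = (ci >= 0 && ci == cj) ? 1 : -1;
      int diag = Hprev[j - 1] + sub;
      int h = 0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; dir = 2; }
      if (F[j] > h) { h = F[j]; dir = 3; }
      Hcur[j] = h;
      tbH[at] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (best <= 0) return false;
  int i = bi, j = bj, state = 0;
  int aln = 0, mism = 0, gaps = 0;
  int qe = bi, re = bj;
  while (i > 0 && j > 0) {
    size_t at = (size_t)i * (nr + 1) + j;
    if (state == 0) {
      uint8_t dd = tbH[at];
      if (dd == 0) break;
      if (dd == 1) {
        int ci = base2code(q[q0 + i - 1]), cj = base2code(r[r0 + j - 1]);
        if (!(ci >= 0 && ci == cj)) ++mism;
        ++aln; --i; --j;
      } else if (dd == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) { // gap in reference, consume query
      ++aln;
      if (tbE[at] == 0) { ++gaps; state = 0; }
      --i;
    } else {                 // gap in query, consume reference
      ++aln;
      if (tbF[at] == 0) { ++gaps; state = 0; }
      --j;
    }
  }
  out.q_start = q0 + i; out.q_end = q0 + qe;
  out.r_start = r0 + j; out.r_end = r0 + re;
  out.aln_len = aln; out.mismatches = mism;
  out.gap_opens = gaps; out.score = best;
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, std::string reference,
                          int word_size, int gap_open, int gap_extend,
                          int pad, int diag_band, int trigger, int xdrop) {
  const int nq = (int)query.size(), nr = (int)reference.size();
  std::vector<Hsp> hsps;
  if (nq >= word_size && nr >= word_size) {
    // hash reference words
    std::unordered_map<uint32_t, std::vector<int>> index;
    uint32_t mask = (word_size >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word_size)) - 1);
    uint32_t w = 0; int run = 0;
    for (int j = 0; j < nr; ++j) {
      int c = base2code(reference[j]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & mask;
      if (++run >= word_size) index[w].push_back(j - word_size + 1);
    }
    // seeds as (diagonal, qpos)
    std::vector<std::pair<int, int>> seeds;
    w = 0; run = 0;
    for (int i = 0; i < nq; ++i) {
      int c = base2code(query[i]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & mask;
      if (++run >= word_size) {
        auto it = index.find(w);
        if (it != index.end()) {
          int qpos = i - word_size + 1;
          for (int rpos : it->second) seeds.emplace_back(rpos - qpos, qpos);
        }
      }
    }
    // stage 1: ungapped X-drop extension per seed; per-diagonal skip of
    // seeds already inside an extended segment
    std::vector<Ungapped> cands;
    if (!seeds.empty()) {
      std::sort(seeds.begin(), seeds.end());
      std::unordered_map<int, int> covered_to; // diagonal -> q end covered
      for (auto& s : seeds) {
        int d = s.first, qp = s.second;
        auto it = covered_to.find(d);
        if (it != covered_to.end() && qp + word_size <= it->second) continue;
        // extend right from the seed's start
        int score = 0, max_sc = 0;
        int qe = qp, best_qe = qp + word_size;
        for (int i = qp; i < nq && i + d < nr; ++i) {
          int ci = base2code(query[i]), cj = base2code(reference[i + d]);
          score += (ci >= 0 && ci == cj) ? 1 : -1;
          if (score > max_sc) { max_sc = score; best_qe = i + 1; }
          if (score < max_sc - xdrop) break;
          qe = i + 1;
        }
        // extend left
        int lscore = 0, lmax = 0, best_qs = qp;
        for (int i = qp - 1; i >= 0 && i + d >= 0; --i) {
          int ci = base2code(query[i]), cj = base2code(reference[i + d]);
          lscore += (ci >= 0 && ci == cj) ? 1 : -1;
          if (lscore > lmax) { lmax = lscore; best_qs = i; }
          if (lscore < lmax - xdrop) break;
        }
        covered_to[d] = std::max(it != covered_to.end() ? it->second : 0, qe);
        int total = max_sc + lmax;
        if (total >= trigger) {
          cands.push_back({d, best_qs, best_qe, total});
        }
      }
    }
    // stage 2: group candidates on nearby diagonals overlapping in
    // query, then resolve each group with windowed gapped DP
    std::sort(cands.begin(), cands.end(),
              [](const Ungapped& a, const Ungapped& b) {
                return a.d != b.d ? a.d < b.d : a.qs < b.qs;
              });
    std::vector<int> group(cands.size(), -1);
    int ngroups = 0;
    for (size_t a = 0; a < cands.size(); ++a) {
      if (group[a] >= 0) continue;
      group[a] = ngroups;
      for (size_t b = a + 1; b < cands.size(); ++b) {
        if (group[b] >= 0) continue;
        if (cands[b].d - cands[a].d > diag_band) break;
        if (cands[b].qs < cands[a].qe + 60 && cands[a].qs < cands[b].qe + 60) {
          group[b] = ngroups;
        }
      }
      ++ngroups;
    }
    for (int g = 0; g < ngroups; ++g) {
      int q0 = nq, q1 = 0, dlo = 0, dhi = 0; bool first = true;
      for (size_t a = 0; a < cands.size(); ++a) {
        if (group[a] != g) continue;
        q0 = std::min(q0, cands[a].qs);
        q1 = std::max(q1, cands[a].qe);
        if (first) { dlo = dhi = cands[a].d; first = false; }
        else { dlo = std::min(dlo, cands[a].d); dhi = std::max(dhi, cands[a].d); }
      }
      q0 = std::max(0, q0 - pad);
      q1 = std::min(nq, q1 + pad);
      int r0 = std::max(0, q0 + dlo - pad);
      int r1 = std::min(nr, q1 + dhi + pad);
      Hsp h;
      if (window_sw(query, reference, q0, q1, r0, r1,
                    gap_open, gap_extend, h) && h.score >= trigger) {
        hsps.push_back(h);
      }
    }
  }
  // drop HSPs that duplicate a higher-scoring overlapping HSP
  std::sort(hsps.begin(), hsps.end(),
            [](const Hsp& a, const Hsp& b) { return a.score > b.score; });
  std::vector<Hsp> kept;
  for (const Hsp& h : hsps) {
    bool dup = false;
    for (const Hsp& g : kept) {
      int qov = std::min(h.q_end, g.q_end) - std::max(h.q_start, g.q_start);
      int rov = std::min(h.r_end, g.r_end) - std::max(h.r_start, g.r_start);
      if (qov > 0 && rov > 0 &&
          qov * 2 > (h.q_end - h.q_start) && rov * 2 > (h.r_end - h.r_start)) {
        dup = true; break;
      }
    }
    if (!dup) kept.push_back(h);
  }
  int n = (int)kept.size();
  IntegerVector qs(n), qe(n), rs(n), re(n), al(n), mm(n), go_(n), sc(n);
  for (int t = 0; t < n; ++t) {
    qs[t] = kept[t].q_start; qe[t] = kept[t].q_end;
    rs[t] = kept[t].r_start; re[t] = kept[t].r_end;
    al[t] = kept[t].aln_len; mm[t] = kept[t].mismatches;
    go_[t] = kept[t].gap_opens; sc[t] = kept[t].score;
  }
  return DataFrame::create(
    Named("q_start") = qs, Named("q_end") = qe,
    Named("r_start") = rs, Named("r_end") = re,
    Named("aln_len") = al, Named("mismatches") = mm,
    Named("gap_opens") = go_, Named("score") = sc);
}
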