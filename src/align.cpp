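#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), full traceback,
// and iterative query masking for multiple HSPs. Genome-sized subjects are
// screened BLAST-style: exact word seeds, diagonal clustering, an x-drop
// ungapped extension filter, then banded-window DP around surviving
// clusters. Gap of length L costs gap_open + gap_ext * L (BLASTN
// convention).

static const int NEG = -1000000000;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct Hit {
  int qs, qe, ss, se;      // 0-based half-open
  int score, matches, mismatches, gap_opens, gap_bases, cols;
};

struct SwBuffers {
  std::vector<int> H, E, F;
  std::vector<uint8_t> tH, tE, tF;
  void resize(size_t sz) {
    H.assign(sz, 0); E.assign(sz, NEG); F.assign(sz, NEG);
    tH.assign(sz, 0); tE.assign(sz, 0); tF.assign(sz, 0);
  }
};

// One masked Smith-Waterman pass over q x s; returns false when no local
// alignment reaches min_score.
static bool sw_best(const std::string& q, const std::string& s,
                    int reward, int penalty, int gap_open, int gap_ext,
                    const std::vector<char>& qmask, int min_score,
                    SwBuffers& buf, Hit& hit) {
  int n = (int)q.size(), m = (int)s.size();
  size_t sz = (size_t)(n + 1) * (m + 1);
  buf.resize(sz);
  std::vector<int>& H = buf.H; std::vector<int>& E = buf.E;
  std::vector<int>& F = buf.F;
  std::vector<uint8_t>& tH = buf.tH; std::vector<uint8_t>& tE = buf.tE;
  std::vector<uint8_t>& tF = buf.tF;
  auto ix = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    if (qmask[i - 1]) continue;  // row stays at initialised H=0, E=F=-inf
    char qc = q[i - 1];
    size_t row = ix(i, 0), prev = ix(i - 1, 0);
    for (int j = 1; j <= m; ++j) {
      size_t c = row + j;
      int e_open = H[c - 1] - gap_open - gap_ext;
      int e_ext  = E[c - 1] == NEG ? NEG : E[c - 1] - gap_ext;
      E[c] = e_ext > e_open ? e_ext : e_open;
      tE[c] = e_ext > e_open ? 1 : 0;
      int f_open = H[prev + j] - gap_open - gap_ext;
      int f_ext  = F[prev + j] == NEG ? NEG : F[prev + j] - gap_ext;
      F[c] = f_ext > f_open ? f_ext : f_open;
      tF[c] = f_ext > f_open ? 1 : 0;
      bool match = is_acgt(qc) && qc == s[j - 1];
      int d = H[prev + j - 1] + (match ? reward : -penalty);
      int h = 0; uint8_t t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[c] > h) { h = E[c]; t = 2; }
      if (F[c] > h) { h = F[c]; t = 3; }
      H[c] = h; tH[c] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best < min_score || best <= 0) return false;

  hit = Hit{0, 0, 0, 0, best, 0, 0, 0, 0, 0};
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  hit.qe = bi; hit.se = bj;
  while (true) {
    size_t c = ix(i, j);
    if (state == 0) {
      uint8_t t = tH[c];
      if (t == 0) break;
      if (t == 1) {
        bool match = is_acgt(q[i - 1]) && q[i - 1] == s[j - 1];
        if (match) ++hit.matches; else ++hit.mismatches;
        ++hit.cols; --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {           // gap in query, consumes subject
      ++hit.gap_bases; ++hit.cols;
      uint8_t t = tE[c];
      --j;
      if (t == 0) { ++hit.gap_opens; state = 0; }
    } else {                           // gap in subject, consumes query
      ++hit.gap_bases; ++hit.cols;
      uint8_t t = tF[c];
      --i;
      if (t == 0) { ++hit.gap_opens; state = 0; }
    }
  }
  hit.qs = i; hit.ss = j;
  return true;
}

static void sw_iterate(const std::string& q, const std::string& s,
                       int reward, int penalty, int gap_open, int gap_ext,
                       int min_score, int max_hits, int s_offset,
                       SwBuffers& buf, std::vector<Hit>& out) {
  std::vector<char> qmask(q.size(), 0);
  for (int it = 0; it < max_hits; ++it) {
    Hit h;
    if (!sw_best(q, s, reward, penalty, gap_open, gap_ext, qmask, min_score,
                 buf, h))
      break;
    if (h.qe - h.qs == 0) break;  // safety: no progress
    for (int i = h.qs; i < h.qe; ++i) qmask[i] = 1;
    h.ss += s_offset; h.se += s_offset;
    out.push_back(h);
  }
}

struct Seed { int i, j; };  // query pos, subject pos

// Ungapped x-drop extension score of a seed along its diagonal.
static int xdrop_extend(const std::string& q, const std::string& s,
                        int i, int j, int w, int reward, int penalty,
                        int xdrop) {
  int n = (int)q.size(), m = (int)s.size();
  int score = w * reward, best = score;
  int qi = i + w, sj = j + w;
  int cur = score;
  while (qi < n && sj < m) {
    cur += (is_acgt(q[qi]) && q[qi] == s[sj]) ? reward : -penalty;
    if (cur > best) best = cur;
    if (cur < best - xdrop) break;
    ++qi; ++sj;
  }
  cur = best;
  qi = i - 1; sj = j - 1;
  int best2 = best;
  while (qi >= 0 && sj >= 0) {
    cur += (is_acgt(q[qi]) && q[qi] == s[sj]) ? reward : -penalty;
    if (cur > best2) best2 = cur;
    if (cur < best2 - xdrop) break;
    --qi; --sj;
  }
  return best2;
}

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string q, std::string s, int reward,
                          int penalty, int gap_open, int gap_ext,
                          int word_size, int min_score, int max_hits,
                          double dp_limit) {
  std::vector<Hit> hits;
  SwBuffers buf;
  int n = (int)q.size(), m = (int)s.size();
  double cells = (double)n * (double)m;
  if (cells <= dp_limit) {
    sw_iterate(q, s, reward, penalty, gap_open, gap_ext, min_score, max_hits,
               0, buf, hits);
  } else if (word_size <= n && word_size <= m && word_size <= 15) {
    // index subject words
    auto encode = [&](const std::string& str, int pos, uint64_t& code) {
      code = 0;
      for (int k = 0; k < word_size; ++k) {
        char c = str[pos + k];
        int b = c == 'A' ? 0 : c == 'C' ? 1 : c == 'G' ? 2 : c == 'T' ? 3 : -1;
        if (b < 0) return false;
        code = (code << 2) | (uint64_t)b;
      }
      return true;
    };
    std::unordered_map<uint64_t, std::vector<int>> index;
    uint64_t code;
    for (int j = 0; j + word_size <= m; ++j)
      if (encode(s, j, code)) index[code].push_back(j);
    std::vector<Seed> seeds;
    for (int i = 0; i + word_size <= n; ++i) {
      if (!encode(q, i, code)) continue;
      auto it = index.find(code);
      if (it == index.end()) continue;
      for (int j : it->second) seeds.push_back({i, j});
    }
    // cluster seeds by diagonal band
    const int band = 150;
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      int da = a.j - a.i, db = b.j - b.i;
      return da != db ? da < db : a.j < b.j;
    });
    struct Cluster { int dmin, dmax, jmin, jmax, best_seed; };
    std::vector<Cluster> clusters;
    for (auto& sd : seeds) {
      int d = sd.j - sd.i;
      if (!clusters.empty() && d - clusters.back().dmax <= band) {
        Cluster& c = clusters.back();
        c.dmax = d;
        c.jmin = std::min(c.jmin, sd.j);
        c.jmax = std::max(c.jmax, sd.j);
        c.best_seed = std::max(c.best_seed,
                               xdrop_extend(q, s, sd.i, sd.j, word_size,
                                            reward, penalty, 40));
      } else {
        clusters.push_back({d, d, sd.j, sd.j,
                            xdrop_extend(q, s, sd.i, sd.j, word_size,
                                         reward, penalty, 40)});
      }
    }
    // window DP around clusters passing the ungapped filter; windows are
    // merged when they overlap so no hit is reported twice
    const int pad = 400;
    int filter = std::max(min_score, 30);
    std::vector<std::pair<int, int>> windows;
    for (auto& c : clusters) {
      if (c.best_seed < filter) continue;
      int lo = std::max(0, c.jmin - (n - 1) - pad);
      int hi = std::min(m, c.jmax + word_size + (n - 1) + pad);
      windows.push_back({lo, hi});
    }
    std::sort(windows.begin(), windows.end());
    std::vector<std::pair<int, int>> merged;
    for (auto& w : windows) {
      if (!merged.empty() && w.first <= merged.back().second)
        merged.back().second = std::max(merged.back().second, w.second);
      else merged.push_back(w);
    }
    for (auto& w : merged) {
      std::string sub = s.substr(w.first, w.second - w.first);
      sw_iterate(q, sub, reward, penalty, gap_open, gap_ext, min_score,
                 max_hits, w.first, buf, hits);
    }
  }
  int nh = (int)hits.size();
  IntegerVector qs(nh), qe(nh), ss(nh), se(nh), sc(nh), ma(nh), mi(nh),
      go(nh), gb(nh), co(nh);
  for (int i = 0; i < nh; ++i) {
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se;
    sc[i] = hits[i].score; ma[i] = hits[i].matches;
    mi[i] = hits[i].mismatches; go[i] = hits[i].gap_opens;
    gb[i] = hits[i].gap_bases; co[i] = hits[i].cols;
  }
  return DataFrame::create(
      _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
      _["score"] = sc, _["matches"] = ma, _["mismatches"] = mi,
      _["gap_opens"] = go, _["gap_bases"] = gb, _["aln_cols"] = co);
}
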