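// Seed-and-extend local alignment core:
//  - exact k-mer seeding (optionally excluding soft-masked sequence),
//  - ungapped X-drop extension thresholded at K,
//  - gapped Y-drop extension (affine gaps, banded by the Y-drop pruning)
//    thresholded at L.
// Coordinates are 0-based offsets into the two fragments throughout.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <climits>

using namespace Rcpp;

typedef long long ll;
static const ll NEG = LLONG_MIN / 4;

// base codes: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// respect_mask: lowercase letters become code 4, so they can neither seed
// nor score better than the worst matrix entry (hard-masked regime).
static std::vector<uint8_t> encode_seq(const std::string& s, bool respect_mask) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[i];
    if (c >= 'a' && c <= 'z') {
      if (respect_mask) { v[i] = 4; continue; }
      c = (char)(c - 'a' + 'A');
    }
    switch (c) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'T': v[i] = 3; break;
      default:  v[i] = 4; break;
    }
  }
  return v;
}

struct SchemeC {
  int mat[25];
  ll gap_open, gap_ext, K, L, Y, xdrop;
};

static SchemeC make_scheme(const IntegerMatrix& mat, double gap_open, double gap_ext,
                           double K, double L, double Y, double xdrop) {
  SchemeC sc;
  if (mat.nrow() != 5 || mat.ncol() != 5)
    stop("substitution matrix must be 5x5 (A,C,G,T,N)");
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j)
      sc.mat[i * 5 + j] = mat(i, j);
  sc.gap_open = (ll)gap_open;
  sc.gap_ext  = (ll)gap_ext;
  sc.K = (ll)K; sc.L = (ll)L; sc.Y = (ll)Y; sc.xdrop = (ll)xdrop;
  return sc;
}

// ---------------------------------------------------------------- seeding

struct SeedHit { int t, q; };

static uint64_t xorshift64(uint64_t& s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return s;
}

static std::vector<SeedHit> find_seeds_core(const std::vector<uint8_t>& R,
                                            const std::vector<uint8_t>& Q,
                                            int k, int cap, uint64_t subseed,
                                            bool& capped, size_t& n_total) {
  std::vector<SeedHit> hits;
  capped = false; n_total = 0;
  int n = (int)R.size(), m = (int)Q.size();
  if (n < k || m < k) return hits;

  // index reference k-mers (2-bit packed); windows containing code 4 skipped
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve((size_t)n * 2);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int valid = 0;
  for (int i = 0; i < n; ++i) {
    if (R[i] > 3) { valid = 0; h = 0; continue; }
    h = ((h << 2) | R[i]) & mask;
    if (++valid >= k) idx[h].push_back(i - k + 1);
  }
  h = 0; valid = 0;
  for (int j = 0; j < m; ++j) {
    if (Q[j] > 3) { valid = 0; h = 0; continue; }
    h = ((h << 2) | Q[j]) & mask;
    if (++valid >= k) {
      auto it = idx.find(h);
      if (it != idx.end()) {
        int qpos = j - k + 1;
        for (int tpos : it->second) hits.push_back({tpos, qpos});
      }
    }
  }
  n_total = hits.size();
  std::sort(hits.begin(), hits.end(), [](const SeedHit& a, const SeedHit& b) {
    return a.t != b.t ? a.t < b.t : a.q < b.q;
  });
  if (cap > 0 && (int)hits.size() > cap) {
    capped = true;
    // deterministic uniform subsample: partial Fisher-Yates on the sorted list
    uint64_t s = subseed ? subseed : 0x9E3779B97F4A7C15ULL;
    size_t nh = hits.size();
    for (int i = 0; i < cap; ++i) {
      size_t j = i + (size_t)(xorshift64(s) % (nh - i));
      std::swap(hits[i], hits[j]);
    }
    hits.resize(cap);
    std::sort(hits.begin(), hits.end(), [](const SeedHit& a, const SeedHit& b) {
      return a.t != b.t ? a.t < b.t : a.q < b.q;
    });
  }
  return hits;
}

// ------------------------------------------------- ungapped X-drop stage

struct HspC {
  int ts, te, qs, qe;   // half-open bounds
  ll score;
  int at, aq;           // anchor column (max running-prefix point)
};

// Extend a seed (t,q,k) along its diagonal in both directions; the running
// score may drop at most xdrop below the running maximum before extension
// stops. Returns false when the best segment scores below K.
static bool extend_ungapped_core(const std::vector<uint8_t>& R,
                                 const std::vector<uint8_t>& Q,
                                 int t, int q, int k, const SchemeC& sc,
                                 HspC& out) {
  int n = (int)R.size(), m = (int)Q.size();
  ll s0 = 0;
  for (int i = 0; i < k; ++i) s0 += sc.mat[R[t + i] * 5 + Q[q + i]];

  ll run = 0, best = 0; int off = 0;
  for (int i = 1; i <= std::min(t, q); ++i) {
    run += sc.mat[R[t - i] * 5 + Q[q - i]];
    if (run > best) { best = run; off = i; }
    if (run < best - sc.xdrop) break;
  }
  ll best_left = best; int left_off = off;

  run = 0; best = 0; off = 0;
  int lim = std::min(n - (t + k), m - (q + k));
  for (int i = 1; i <= lim; ++i) {
    run += sc.mat[R[t + k - 1 + i] * 5 + Q[q + k - 1 + i]];
    if (run > best) { best = run; off = i; }
    if (run < best - sc.xdrop) break;
  }
  ll best_right = best; int right_off = off;

  out.ts = t - left_off;
  out.qs = q - left_off;
  out.te = t + k + right_off;
  out.qe = q + k + right_off;
  out.score = best_left + s0 + best_right;
  // anchor = first column attaining the maximal running prefix score
  ll pref = 0, pbest = NEG; int pa = 0;
  for (int i = 0; i < out.te - out.ts; ++i) {
    pref += sc.mat[R[out.ts + i] * 5 + Q[out.qs + i]];
    if (pref > pbest) { pbest = pref; pa = i; }
  }
  out.at = out.ts + pa;
  out.aq = out.qs + pa;
  return out.score >= sc.K;
}

// ------------------------------------------------- gapped Y-drop stage

struct SegC { int t, q, len; };

// One-sided Y-drop extension: align A[0..n) vs B[0..m) with the path forced
// to start at the (0,0) corner.  Affine gaps (first gap base costs
// gap_open + gap_ext).  Cells whose best state falls more than Y below the
// best score seen so far are abandoned.  Returns the best score (>= 0) and
// the matched columns of the best path, as (i,j) 0-based pairs in ascending
// order.  cell_budget bounds the stored traceback (bytes); extension stops
// early (keeping the best found so far) if it would be exceeded.
static ll ydrop_one_side(const uint8_t* A, int n, const uint8_t* B, int m,
                         const SchemeC& sc, int max_rows, size_t cell_budget,
                         std::vector<std::pair<int,int>>& cols) {
  cols.clear();
  if (n <= 0 || m <= 0) return 0;
  if (max_rows > 0 && n > max_rows) n = max_rows;

  const ll open1 = sc.gap_open + sc.gap_ext;
  int m_alloc = m + 1;

  std::vector<ll> Mp(m_alloc, NEG), Xp(m_alloc, NEG), Yp(m_alloc, NEG);
  std::vector<ll> Mc(m_alloc, NEG), Xc(m_alloc, NEG), Yc(m_alloc, NEG);

  // traceback codes per row (window lo..hi):
  //  bits 0-1: M diag source (0 invalid, 1 M, 2 Ix, 3 Iy)
  //  bit 2: Ix from Ix (1) / from M (0);  bit 3: Iy from Iy (1) / from M (0)
  std::vector<int> row_lo(1, 0), row_hi;
  std::vector<std::vector<uint8_t>> tb;
  size_t cells_used = 0;

  ll best = 0; int bi = 0, bj = 0;

  // row 0
  Mp[0] = 0;
  int hi0 = 0;
  {
    std::vector<uint8_t> t0;
    t0.push_back(0);
    for (int j = 1; j <= m; ++j) {
      ll v = (j == 1) ? Mp[0] - open1 : Yp[j - 1] - sc.gap_ext;
      if (v < best - sc.Y) break;
      Yp[j] = v;
      t0.push_back((uint8_t)((j == 1 ? 0 : 1) << 3));
      hi0 = j;
    }
    cells_used += t0.size();
    tb.push_back(std::move(t0));
    row_hi.push_back(hi0);
  }

  int lo = 0, hi = hi0;
  int last_row = 0;
  for (int i = 1; i <= n; ++i) {
    int new_lo = -1, new_hi = -1;
    std::vector<uint8_t> trow;
    trow.reserve((size_t)(hi - lo + 8));
    if (lo > 0) { Mc[lo - 1] = NEG; Xc[lo - 1] = NEG; Yc[lo - 1] = NEG; }

    for (int j = lo; j <= m; ++j) {
      uint8_t code = 0;
      ll Mv = NEG, Xv = NEG, Yv = NEG;
      // Ix: consumes a reference base (gap in query)
      if (j >= lo && j <= hi) {
        ll fromM = (Mp[j] <= NEG / 2) ? NEG : Mp[j] - open1;
        ll fromX = (Xp[j] <= NEG / 2) ? NEG : Xp[j] - sc.gap_ext;
        if (fromM >= fromX) { Xv = fromM; }
        else { Xv = fromX; code |= 4; }
      }
      // M: diagonal step aligning A[i-1] to B[j-1]
      if (j >= 1 && j - 1 >= lo && j - 1 <= hi) {
        ll d = Mp[j - 1]; uint8_t src = 1;
        if (Xp[j - 1] > d) { d = Xp[j - 1]; src = 2; }
        if (Yp[j - 1] > d) { d = Yp[j - 1]; src = 3; }
        if (d > NEG / 2) {
          Mv = d + sc.mat[A[i - 1] * 5 + B[j - 1]];
          code |= src;
        }
      }
      // Iy: consumes a query base (gap in reference); left neighbour, same row
      if (j >= 1) {
        ll fromM = (Mc[j - 1] <= NEG / 2) ? NEG : Mc[j - 1] - open1;
        ll fromY = (Yc[j - 1] <= NEG / 2) ? NEG : Yc[j - 1] - sc.gap_ext;
        if (fromM >= fromY) { Yv = fromM; }
        else { Yv = fromY; code |= 8; }
      }
      ll top = std::max(Mv, std::max(Xv, Yv));
      bool viable = (top > NEG / 2) && (top >= best - sc.Y);
      if (!viable) {
        Mc[j] = Xc[j] = Yc[j] = NEG;
        if (j > hi) break;  // nothing to the right can become viable
        if (new_lo >= 0) trow.push_back(0);
        continue;
      }
      Mc[j] = Mv; Xc[j] = Xv; Yc[j] = Yv;
      if (new_lo < 0) new_lo = j;
      new_hi = j;
      trow.push_back(code);
      if (Mv > best) { best = Mv; bi = i; bj = j; }
    }
    if (new_lo < 0) break;  // extension exhausted
    // trailing pruned cells may have been pushed; trim to the window
    trow.resize((size_t)(new_hi - new_lo + 1));
    row_lo.push_back(new_lo);
    row_hi.push_back(new_hi);
    cells_used += trow.size();
    tb.push_back(std::move(trow));
    lo = new_lo; hi = new_hi;
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    last_row = i;
    if (cells_used > cell_budget) break;
  }
  (void)last_row;

  if (best <= 0) return 0;

  // traceback from (bi,bj), state M
  int i = bi, j = bj, state = 0; // 0=M 1=Ix 2=Iy
  std::vector<std::pair<int,int>> rev;
  while (!(i == 0 && j == 0)) {
    const std::vector<uint8_t>& trow = tb[i];
    int lo_i = row_lo[i];
    uint8_t code = trow[j - lo_i];
    if (state == 0) {
      rev.push_back(std::make_pair(i - 1, j - 1));
      uint8_t src = code & 3;
      --i; --j;
      if (src == 1) state = 0;
      else if (src == 2) state = 1;
      else if (src == 3) state = 2;
      else break; // origin
    } else if (state == 1) {
      state = (code & 4) ? 1 : 0;
      --i;
    } else {
      state = (code & 8) ? 2 : 0;
      --j;
    }
  }
  cols.assign(rev.rbegin(), rev.rend());
  return best;
}

static void cols_to_segs(const std::vector<std::pair<int,int>>& cols,
                         std::vector<SegC>& segs) {
  for (size_t i = 0; i < cols.size(); ++i) {
    if (!segs.empty()) {
      SegC& s = segs.back();
      if (cols[i].first == s.t + s.len && cols[i].second == s.q + s.len) {
        ++s.len;
        continue;
      }
    }
    SegC s; s.t = cols[i].first; s.q = cols[i].second; s.len = 1;
    segs.push_back(s);
  }
}

struct AlnC {
  std::vector<SegC> segs;
  ll score;
  int tmin, tmax, qmin, qmax;
};

static const size_t CELL_BUDGET = (size_t)256 * 1024 * 1024;

// Gapped extension anchored at the HSP's maximum-scoring point: independent
// leftward and rightward Y-drop extensions whose scores add.
static bool extend_gapped_core(const std::vector<uint8_t>& R,
                               const std::vector<uint8_t>& Q,
                               int at, int aq, const SchemeC& sc,
                               int max_rows, AlnC& out) {
  int n = (int)R.size(), m = (int)Q.size();
  // right side includes the anchor column
  std::vector<std::pair<int,int>> colsR, colsL;
  ll sr = ydrop_one_side(R.data() + at, n - at, Q.data() + aq, m - aq,
                         sc, max_rows, CELL_BUDGET, colsR);
  // left side on reversed prefixes
  std::vector<uint8_t> Ar(at), Br(aq);
  for (int i = 0; i < at; ++i) Ar[i] = R[at - 1 - i];
  for (int j = 0; j < aq; ++j) Br[j] = Q[aq - 1 - j];
  ll sl = ydrop_one_side(Ar.data(), at, Br.data(), aq,
                         sc, max_rows, CELL_BUDGET, colsL);

  ll total = sl + sr;
  if (total < sc.L) return false;

  std::vector<std::pair<int,int>> cols;
  cols.reserve(colsL.size() + colsR.size());
  for (size_t i = colsL.size(); i-- > 0;)
    cols.push_back(std::make_pair(at - 1 - colsL[i].first,
                                  aq - 1 - colsL[i].second));
  for (size_t i = 0; i < colsR.size(); ++i)
    cols.push_back(std::make_pair(at + colsR[i].first,
                                  aq + colsR[i].second));
  if (cols.empty()) return false;

  out.segs.clear();
  cols_to_segs(cols, out.segs);
  out.score = total;
  out.tmin = cols.front().first;
  out.qmin = cols.front().second;
  out.tmax = cols.back().first + 1;
  out.qmax = cols.back().second + 1;
  return true;
}

// ---------------------------------------------------------- full pipeline

static List aln_to_list(const AlnC& a) {
  IntegerMatrix segs((int)a.segs.size(), 3);
  for (int i = 0; i < (int)a.segs.size(); ++i) {
    segs(i, 0) = a.segs[i].t;
    segs(i, 1) = a.segs[i].q;
    segs(i, 2) = a.segs[i].len;
  }
  colnames(segs) = CharacterVector::create("t_start", "q_start", "size");
  return List::create(_["score"] = (double)a.score, _["segments"] = segs);
}

// [[Rcpp::export]]
List cpp_find_seeds(std::string ref, std::string query, int k,
                    bool respect_mask, int cap, double subseed) {
  std::vector<uint8_t> R = encode_seq(ref, respect_mask);
  std::vector<uint8_t> Q = encode_seq(query, respect_mask);
  bool capped; size_t n_total;
  std::vector<SeedHit> hits =
      find_seeds_core(R, Q, k, cap, (uint64_t)subseed, capped, n_total);
  IntegerMatrix out((int)hits.size(), 2);
  for (int i = 0; i < (int)hits.size(); ++i) {
    out(i, 0) = hits[i].t;
    out(i, 1) = hits[i].q;
  }
  colnames(out) = CharacterVector::create("t_pos", "q_pos");
  return List::create(_["seeds"] = out, _["n_total"] = (double)n_total,
                      _["capped"] = capped);
}

// [[Rcpp::export]]
SEXP cpp_extend_ungapped(std::string ref, std::string query, int t_pos,
                         int q_pos, int k, IntegerMatrix mat, double gap_open,
                         double gap_ext, double K, double xdrop,
                         bool respect_mask) {
  SchemeC sc = make_scheme(mat, gap_open, gap_ext, K, 0, 0, xdrop);
  std::vector<uint8_t> R = encode_seq(ref, respect_mask);
  std::vector<uint8_t> Q = encode_seq(query, respect_mask);
  if (t_pos < 0 || q_pos < 0 || t_pos + k > (int)R.size() ||
      q_pos + k > (int)Q.size())
    stop("seed out of bounds");
  HspC h;
  if (!extend_ungapped_core(R, Q, t_pos, q_pos, k, sc, h)) return R_NilValue;
  return List::create(_["t_start"] = h.ts, _["t_end"] = h.te,
                      _["q_start"] = h.qs, _["q_end"] = h.qe,
                      _["score"] = (double)h.score,
                      _["anchor_t"] = h.at, _["anchor_q"] = h.aq);
}

// [[Rcpp::export]]
SEXP cpp_extend_gapped(std::string ref, std::string query, int anchor_t,
                       int anchor_q, IntegerMatrix mat, double gap_open,
                       double gap_ext, double L, double Y, int max_rows,
                       bool respect_mask) {
  SchemeC sc = make_scheme(mat, gap_open, gap_ext, 0, L, Y, 0);
  std::vector<uint8_t> R = encode_seq(ref, respect_mask);
  std::vector<uint8_t> Q = encode_seq(query, respect_mask);
  if (anchor_t < 0 || anchor_q < 0 || anchor_t >= (int)R.size() ||
      anchor_q >= (int)Q.size())
    stop("anchor out of bounds");
  AlnC a;
  if (!extend_gapped_core(R, Q, anchor_t, anchor_q, sc, max_rows, a))
    return R_NilValue;
  return aln_to_list(a);
}

// [[Rcpp::export]]
List cpp_align_region(std::string ref, std::string query, IntegerMatrix mat,
                      double gap_open, double gap_ext, double K, double L,
                      double Y, double xdrop, int k, bool respect_mask,
                      int cap, double subseed, int max_rows, bool dedup) {
  SchemeC sc = make_scheme(mat, gap_open, gap_ext, K, L, Y, xdrop);
  std::vector<uint8_t> R = encode_seq(ref, respect_mask);
  std::vector<uint8_t> Q = encode_seq(query, respect_mask);

  bool capped; size_t n_total;
  std::vector<SeedHit> hits =
      find_seeds_core(R, Q, k, cap, (uint64_t)subseed, capped, n_total);

  // ungapped stage: per-diagonal skip of seeds already inside an extension
  std::vector<SeedHit> by_diag = hits;
  std::sort(by_diag.begin(), by_diag.end(), [](const SeedHit& a, const SeedHit& b) {
    int da = a.t - a.q, db = b.t - b.q;
    return da != db ? da < db : a.t < b.t;
  });
  std::vector<HspC> hsps;
  int cur_diag = INT_MIN; int diag_end = -1;
  for (const SeedHit& s : by_diag) {
    int d = s.t - s.q;
    if (d != cur_diag) { cur_diag = d; diag_end = -1; }
    if (s.t < diag_end) continue;
    HspC h;
    bool ok = extend_ungapped_core(R, Q, s.t, s.q, k, sc, h);
    diag_end = std::max(diag_end, h.te);
    if (ok) hsps.push_back(h);
  }
  std::sort(hsps.begin(), hsps.end(), [](const HspC& a, const HspC& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ts != b.ts) return a.ts < b.ts;
    return a.qs < b.qs;
  });

  // gapped stage, skipping HSPs covered by an existing gapped alignment
  std::vector<AlnC> alns;
  for (const HspC& h : hsps) {
    if (dedup) {
      bool covered = false;
      for (const AlnC& a : alns) {
        if (h.ts >= a.tmin && h.te <= a.tmax &&
            h.qs >= a.qmin && h.qe <= a.qmax) { covered = true; break; }
      }
      if (covered) continue;
    }
    AlnC a;
    if (extend_gapped_core(R, Q, h.at, h.aq, sc, max_rows, a))
      alns.push_back(a);
  }
  std::stable_sort(alns.begin(), alns.end(), [](const AlnC& a, const AlnC& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.tmin != b.tmin) return a.tmin < b.tmin;
    return a.qmin < b.qmin;
  });

  List out((int)alns.size());
  for (int i = 0; i < (int)alns.size(); ++i) out[i] = aln_to_list(alns[i]);
  return List::create(_["alignments"] = out,
                      _["n_seeds"] = (double)n_total,
                      _["capped"] = capped,
                      _["n_hsps"] = (double)hsps.size());
}
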