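#include <Rcpp.h>
#include <cmath>
#include <deque>
#include <map>
#include <array>
#include <cstdint>
#include <memory>
using namespace Rcpp;

static const int ALN_INF = 1 << 28;

static inline int base2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// ---------------------------------------------------------------------------
// Homopolymer compression
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_hpc(std::string s) {
  std::string comp;
  std::vector<int> starts, ends;
  int n = (int)s.size();
  comp.reserve(n);
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && s[j] == s[i]) ++j;
    comp.push_back(s[i]);
    starts.push_back(i);
    ends.push_back(j);
    i = j;
  }
  return List::create(_["compressed"] = comp,
                      _["start"] = wrap(starts),
                      _["end"] = wrap(ends));
}

// ---------------------------------------------------------------------------
// Banded edit-distance alignment (unit costs) with traceback.
//
// The DP is restricted to diagonals d = j - i in [d_lo, d_hi] (query index i,
// target index j, both 0-based in the (m+1) x (n+1) matrix). With
// d_lo <= -B and d_hi >= (n - m) + B the result is the exact edit distance
// whenever dist < B (Ukkonen band argument); callers double the band until
// that holds or a cap is reached.
//
// free_t_start : leading target bases are free (alignment may start at any j)
// free_t_end   : trailing target bases are free (alignment may end at any j)
// free_q_end   : trailing query bases may be clipped (ends when j reaches n)
// ---------------------------------------------------------------------------

struct AlnResult {
  int dist = ALN_INF;
  int t_start = 0, t_end = 0, q_end = 0;
  int alnlen = 0;
  std::vector<int> cig_op;   // 0 '=' 1 'X' 2 'I' (query only) 3 'D' (target only)
  std::vector<int> cig_len;
  std::vector<int> calls;    // per query position: target base 0..3,
                             // 4 = deletion in target, -1 = unaligned/N
};

// saturated 16-bit copy of the DP rows kept for the traceback; real
// distances are bounded by m + n << VAL16_INF, so equality tests against
// reconstructed int arithmetic are exact
static const int VAL16_INF = 60000;

static AlnResult band_align_core(const std::string& q, const std::string& t,
                                 int d_lo, int d_hi,
                                 bool free_t_start, bool free_t_end,
                                 bool free_q_end,
                                 bool traceback, bool want_calls) {
  AlnResult res;
  int m = (int)q.size(), n = (int)t.size();
  if (d_hi < d_lo) return res;
  int W = d_hi - d_lo + 1;
  // rows carry a sentinel cell on each side: index w+1 holds diagonal w
  std::vector<int> prev((size_t)W + 2, ALN_INF), cur((size_t)W + 2, ALN_INF);
  bool tb = traceback || want_calls;
  // traceback re-derives moves from cell values (preference diagonal > up >
  // left, matching strict-improvement move selection), so only a compact
  // 16-bit value matrix is kept; row i starts at val[i * W]
  std::unique_ptr<uint16_t[]> val;
  if (tb) val.reset(new uint16_t[(size_t)(m + 1) * W]);

  for (int d = std::max(d_lo, 0); d <= d_hi && d <= n; ++d) {
    prev[(size_t)(d - d_lo) + 1] = free_t_start ? 0 : d;
  }
  if (tb) {
    for (int w = 0; w < W; ++w) {
      int v = prev[(size_t)w + 1];
      val[(size_t)w] = (uint16_t)(v >= VAL16_INF ? VAL16_INF : v);
    }
  }

  int best = ALN_INF, best_i = -1, best_j = -1;
  const char* tp = t.data();
  // row 0 can end the alignment only in degenerate cases; require i >= 1.
  for (int i = 1; i <= m; ++i) {
    int jmin = std::max(0, i + d_lo), jmax = std::min(n, i + d_hi);
    uint16_t* row16 = tb ? val.get() + (size_t)i * W : nullptr;
    if (jmin > jmax) {
      std::fill(cur.begin(), cur.end(), ALN_INF);
      if (row16) std::fill(row16, row16 + W, (uint16_t)VAL16_INF);
      prev.swap(cur);
      continue;
    }
    int w_begin = jmin - i - d_lo, w_end = jmax - i - d_lo;
    int* pv = prev.data() + 1;
    int* cv = cur.data() + 1;
    // invalidate the cells flanking this row's computed range
    cv[w_begin - 1] = ALN_INF;
    if (w_end + 1 <= W) cv[w_end + 1] = ALN_INF;
    const char qc = q[(size_t)(i - 1)];
    int w0 = w_begin;
    if (jmin == 0) {  // j == 0: only an up move is possible
      cv[w0] = pv[w0 + 1] + 1;
      ++w0;
    }
    // pass 1 (vectorizable): diagonal and up moves
    {
      const char* tj = tp + (i + d_lo + w0 - 1);
      for (int w = w0; w <= w_end; ++w) {
        int vd = pv[w] + (qc != tj[w - w0]);
        int vu = pv[w + 1] + 1;
        cv[w] = vd < vu ? vd : vu;
      }
    }
    // pass 2: left-move chain (running min with unit increments)
    {
      int run = cv[w_begin - 1];
      for (int w = w_begin; w <= w_end; ++w) {
        ++run;
        if (run < cv[w]) cv[w] = run; else run = cv[w];
      }
    }
    if (row16) {
      if (w_begin > 0)
        std::fill(row16, row16 + w_begin, (uint16_t)VAL16_INF);
      for (int w = w_begin; w <= w_end; ++w)
        row16[w] = (uint16_t)(cv[w] >= VAL16_INF ? VAL16_INF : cv[w]);
      if (w_end + 1 < W)
        std::fill(row16 + w_end + 1, row16 + W, (uint16_t)VAL16_INF);
    }
    if (free_q_end && i < m && n >= jmin && n <= jmax) {
      int v = cv[n - i - d_lo];
      if (v < best || (v == best && i > best_i)) { best = v; best_i = i; best_j = n; }
    }
    if (i == m) {
      if (free_t_end) {
        for (int jj = jmin; jj <= jmax; ++jj) {
          int v = cv[jj - i - d_lo];
          if (v < best || (v == best && jj > best_j)) { best = v; best_i = m; best_j = jj; }
        }
      } else if (n >= jmin && n <= jmax) {
        int v = cv[n - i - d_lo];
        if (v < best || (v == best && m >= best_i)) { best = v; best_i = m; best_j = n; }
      }
    }
    prev.swap(cur);
  }

  if (best >= ALN_INF || best_i < 0) return res;
  res.dist = best;
  res.q_end = best_i;
  res.t_end = best_j;

  if (tb) {
    if (want_calls) res.calls.assign((size_t)m, -1);
    int i = best_i, j = best_j;
    std::vector<int> ops;
    ops.reserve((size_t)(m + 8));
    // a cell (r, jj) was computed iff jj lies in row r's banded range
    auto cell = [&](int r, int jj) -> int {
      if (jj < std::max(0, r + d_lo) || jj > std::min(n, r + d_hi))
        return ALN_INF;
      uint16_t v = val[(size_t)r * W + (size_t)(jj - r - d_lo)];
      return v >= VAL16_INF ? ALN_INF : (int)v;
    };
    while (true) {
      if (i == 0) {
        // row 0: free leading target, or j left-moves from the origin
        if (!free_t_start) {
          while (j > 0) { ops.push_back(3); --j; }
        }
        break;
      }
      int v = cell(i, j);
      int dg = (j >= 1) ? cell(i - 1, j - 1) : ALN_INF;
      if (dg < ALN_INF &&
          dg + (q[(size_t)(i - 1)] == t[(size_t)(j - 1)] ? 0 : 1) == v) {
        bool match = q[(size_t)(i - 1)] == t[(size_t)(j - 1)];
        ops.push_back(match ? 0 : 1);
        if (want_calls) res.calls[(size_t)(i - 1)] = base2i(t[(size_t)(j - 1)]);
        --i; --j;
        continue;
      }
      int up = cell(i - 1, j);
      if (up < ALN_INF && up + 1 == v) {
        ops.push_back(2);
        if (want_calls) res.calls[(size_t)(i - 1)] = 4;
        --i;
        continue;
      }
      ops.push_back(3);
      --j;
    }
    res.t_start = j;
    res.alnlen = (int)ops.size();
    if (want_calls) {
      // leading/trailing runs of target-gap are unaligned ends, not deletions
      for (int p = 0; p < m && res.calls[(size_t)p] == 4; ++p)
        res.calls[(size_t)p] = -1;
      for (int p = m - 1; p >= 0 && res.calls[(size_t)p] == 4; --p)
        res.calls[(size_t)p] = -1;
    }
    // reverse + run-length encode
    for (int p = (int)ops.size() - 1; p >= 0;) {
      int op = ops[(size_t)p];
      int p2 = p;
      while (p2 >= 0 && ops[(size_t)p2] == op) --p2;
      res.cig_op.push_back(op);
      res.cig_len.push_back(p - p2);
      p = p2;
    }
  } else {
    res.t_start = NA_INTEGER;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_align(std::string q, std::string t, int d_lo, int d_hi,
               bool free_t_start, bool free_t_end, bool free_q_end,
               bool traceback, bool want_calls) {
  int m = (int)q.size();
  int W = d_hi - d_lo + 1;
  if ((double)(m + 1) * W > 6e8) stop("alignment band too large");
  AlnResult r = band_align_core(q, t, d_lo, d_hi, free_t_start, free_t_end,
                                free_q_end, traceback, want_calls);
  List out = List::create(
      _["dist"] = r.dist >= ALN_INF ? NA_INTEGER : r.dist,
      _["t_start"] = r.t_start, _["t_end"] = r.t_end, _["q_end"] = r.q_end,
      _["alnlen"] = r.alnlen,
      _["cig_op"] = wrap(r.cig_op), _["cig_len"] = wrap(r.cig_len));
  if (want_calls) out["calls"] = wrap(r.calls);
  return out;
}

// ---------------------------------------------------------------------------
// Minimizers (canonical k-mers, k <= 15, leftmost window minimum)
// ---------------------------------------------------------------------------

static inline uint32_t fmix32(uint32_t h) {
  h ^= h >> 16; h *= 0x85ebca6bU;
  h ^= h >> 13; h *= 0xc2b2ae35U;
  h ^= h >> 16;
  return h;
}

// [[Rcpp::export]]
List cpp_minimizers(std::string s, int k, int w) {
  int n = (int)s.size();
  std::vector<int> out_pos, out_hash, out_str;
  if (k < 2 || k > 15 || w < 1) stop("need 2 <= k <= 15 and w >= 1");
  if (n >= k) {
    uint32_t mask = (1U << (2 * k)) - 1U;
    uint32_t vf = 0, vr = 0;
    int run = 0;
    struct Km { int pos; uint32_t h; int str; };
    std::deque<Km> dq;
    int last_pos = -1;
    int nk = 0;  // number of valid kmer slots seen (incl. invalid ones counted)
    for (int i = 0; i < n; ++i) {
      int b = base2i(s[(size_t)i]);
      if (b < 0) { run = 0; vf = 0; vr = 0; }
      else {
        vf = ((vf << 2) | (uint32_t)b) & mask;
        vr = (vr >> 2) | ((uint32_t)(3 - b) << (2 * (k - 1)));
        ++run;
      }
      if (i >= k - 1) {
        ++nk;
        int p = i - k + 1;
        if (run >= k) {
          uint32_t val; int str;
          if (vf <= vr) { val = vf; str = 1; } else { val = vr; str = -1; }
          uint32_t h = fmix32(val) & 0x7fffffffU;
          while (!dq.empty() && dq.back().h > h) dq.pop_back();
          dq.push_back({p, h, str});
        }
        while (!dq.empty() && dq.front().pos < p - (w - 1)) dq.pop_front();
        if (nk >= w && !dq.empty() && dq.front().pos != last_pos) {
          out_pos.push_back(dq.front().pos);
          out_hash.push_back((int)dq.front().h);
          out_str.push_back(dq.front().str);
          last_pos = dq.front().pos;
        }
      }
    }
  }
  return List::create(_["pos"] = wrap(out_pos), _["hash"] = wrap(out_hash),
                      _["strand"] = wrap(out_str));
}

// ---------------------------------------------------------------------------
// Per-base read error simulation (uses the R RNG for reproducibility)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mutate_read(std::string s, double rate, double p_sub, double p_ins,
                     double p_del) {
  double tot = p_sub + p_ins + p_del;
  if (tot <= 0) stop("error composition must be positive");
  p_sub /= tot; p_ins /= tot;
  std::string out;
  out.reserve(s.size() + 16);
  int n_ops = 0;
  const char B[4] = {'A', 'C', 'G', 'T'};
  for (size_t i = 0; i < s.size(); ++i) {
    double u = unif_rand();
    if (u >= rate) { out.push_back(s[i]); continue; }
    ++n_ops;
    double v = unif_rand();
    if (v < p_sub) {
      int cur = base2i(s[i]);
      int off = 1 + (int)(unif_rand() * 3.0);
      if (off > 3) off = 3;
      out.push_back(cur < 0 ? B[(int)(unif_rand() * 4.0) & 3]
                            : B[(cur + off) & 3]);
    } else if (v < p_sub + p_ins) {
      int nb = (int)(unif_rand() * 4.0); if (nb > 3) nb = 3;
      out.push_back(B[nb]);
      out.push_back(s[i]);
    }  // else deletion: emit nothing
  }
  return List::create(_["seq"] = out, _["n_ops"] = n_ops);
}

// ---------------------------------------------------------------------------
// Pairwise genotype Hamming distances (normalized over shared loci)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pairwise_geno(IntegerMatrix g) {
  int n = g.nrow(), L = g.ncol();
  NumericMatrix dist(n, n);
  IntegerMatrix shared(n, n);
  for (int i = 0; i < n; ++i) {
    dist(i, i) = 0.0;
    shared(i, i) = 0;
    for (int j = i + 1; j < n; ++j) {
      int sh = 0, df = 0;
      for (int l = 0; l < L; ++l) {
        int a = g(i, l), b = g(j, l);
        if (a >= 0 && b >= 0) { ++sh; if (a != b) ++df; }
      }
      shared(i, j) = shared(j, i) = sh;
      double d = sh > 0 ? (double)df / sh : NA_REAL;
      dist(i, j) = dist(j, i) = d;
    }
  }
  return List::create(_["dist"] = dist, _["shared"] = shared);
}

// ---------------------------------------------------------------------------
// Randomized recursive partition of a block by cis-morphism loci
// ---------------------------------------------------------------------------

static void geno_consensus(const IntegerMatrix& g,
                           const std::vector<std::vector<int>>& clusters,
                           std::vector<std::vector<int>>& cons) {
  int L = g.ncol();
  cons.assign(clusters.size(), std::vector<int>((size_t)L, -1));
  for (size_t c = 0; c < clusters.size(); ++c) {
    for (int l = 0; l < L; ++l) {
      int cnt[5] = {0, 0, 0, 0, 0};
      for (int r : clusters[c]) {
        int b = g(r, l);
        if (b >= 0 && b < 5) ++cnt[b];
      }
      int bb = -1, bc = 0;
      for (int b = 0; b < 5; ++b)
        if (cnt[b] > bc) { bc = cnt[b]; bb = b; }
      cons[c][(size_t)l] = bb;
    }
  }
}

static int geno_dist(const IntegerMatrix& g, int r, const std::vector<int>& cons) {
  int L = g.ncol(), d = 0;
  for (int l = 0; l < L; ++l) {
    int a = g(r, l), b = cons[(size_t)l];
    if (a >= 0 && b >= 0 && a != b) ++d;
  }
  return d;
}

// [[Rcpp::export]]
List cpp_random_partition(IntegerMatrix g, double floor_, int n_sim,
                          double penalty, NumericVector state_rate,
                          double z_gate) {
  int n = g.nrow(), L = g.ncol();
  if (n < 1) stop("empty block");
  if (state_rate.size() != 5) stop("state_rate must have length 5");
  double rate[5];
  for (int s = 0; s < 5; ++s) rate[s] = state_rate[s];
  double bestScore = R_PosInf;
  int bestK = INT_MAX;
  std::vector<int> bestAssign;
  std::vector<std::vector<int>> bestCons;

  // pileup genotype calls miss a fraction of the reads that truly carry a
  // state (alignment wobble around homopolymer boundaries), so a locus is
  // worth trying once its visible groups reach this fraction of the floor;
  // the floor itself is enforced on the constructed clusters after
  // nearest-consensus assignment.
  const double VIS = 0.6;

  // the root node's candidate loci are identical across simulations
  std::vector<int> root_cand;
  bool root_cand_ready = false;

  for (int sim = 0; sim < n_sim; ++sim) {
    std::vector<std::vector<int>> clusters;
    std::vector<std::vector<int>> stack;
    {
      std::vector<int> all((size_t)n);
      for (int i = 0; i < n; ++i) all[(size_t)i] = i;
      stack.push_back(std::move(all));
    }
    bool at_root = true;
    while (!stack.empty()) {
      std::vector<int> node = std::move(stack.back());
      stack.pop_back();
      // cis-morphism states are re-tested within every node: as copies are
      // split off, a remaining copy's site frequency rises above the
      // per-state noise expected at the node's depth
      std::vector<int> cand;
      bool use_cache = at_root && root_cand_ready;
      at_root = false;
      if (use_cache) {
        cand = root_cand;
      } else if (L > 0 && (double)node.size() >= 2.0 * floor_) {
        for (int l = 0; l < L; ++l) {
          int cnt[5] = {0, 0, 0, 0, 0};
          int ncov = 0;
          for (int r : node) {
            int b = g(r, l);
            if (b >= 0) { ++cnt[b]; ++ncov; }
          }
          int ok = 0;
          for (int b = 0; b < 5; ++b) {
            double noise = ncov * rate[b] +
              z_gate * std::sqrt(ncov * rate[b] * (1.0 - rate[b]));
            if ((double)cnt[b] >= VIS * floor_ && (double)cnt[b] > noise) ++ok;
          }
          if (ok >= 2) cand.push_back(l);
        }
        if ((int)node.size() == n && !root_cand_ready) {
          root_cand = cand;
          root_cand_ready = true;
        }
      }
      bool split_done = false;
      int tries = 0;
      while (!cand.empty() && tries < 4 && !split_done) {
        ++tries;
        int pick = (int)(unif_rand() * (double)cand.size());
        if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
        int l = cand[(size_t)pick];
        cand.erase(cand.begin() + pick);
        int cnt[5] = {0, 0, 0, 0, 0};
        int ncov = 0;
        for (int r : node) { int b = g(r, l); if (b >= 0) { ++cnt[b]; ++ncov; } }
        bool branch[5];
        int maj = -1, majc = -1, nb = 0;
        for (int b = 0; b < 5; ++b) {
          double noise = ncov * rate[b] +
            z_gate * std::sqrt(ncov * rate[b] * (1.0 - rate[b]));
          branch[b] = (double)cnt[b] >= VIS * floor_ && (double)cnt[b] > noise;
          if (branch[b]) ++nb;
          if (branch[b] && cnt[b] > majc) { majc = cnt[b]; maj = b; }
        }
        if (nb < 2) continue;
        std::vector<std::vector<int>> kids;
        std::vector<int> branch_of(5, -1);
        for (int b = 0; b < 5; ++b)
          if (branch[b]) { branch_of[(size_t)b] = (int)kids.size(); kids.push_back({}); }
        for (int r : node) {
          int b = g(r, l);
          int k = (b >= 0 && branch[b]) ? branch_of[(size_t)b]
                                        : branch_of[(size_t)maj];
          kids[(size_t)k].push_back(r);
        }
        // reassign the node's reads to the nearest child consensus, then
        // enforce the cluster-size floor on the constructed children
        std::vector<std::vector<int>> kcons;
        geno_consensus(g, kids, kcons);
        std::vector<std::vector<int>> kids2(kids.size());
        for (int r : node) {
          int bc = 0, bd = geno_dist(g, r, kcons[0]);
          for (size_t c = 1; c < kcons.size(); ++c) {
            int d = geno_dist(g, r, kcons[c]);
            if (d < bd) { bd = d; bc = (int)c; }
          }
          kids2[(size_t)bc].push_back(r);
        }
        bool ok = true;
        for (auto& kd : kids2)
          if ((double)kd.size() < floor_) { ok = false; break; }
        if (!ok) continue;
        for (auto& kd : kids2) stack.push_back(std::move(kd));
        split_done = true;
      }
      if (!split_done) clusters.push_back(std::move(node));
    }

    // nearest-consensus reassignment, then rescore
    std::vector<std::vector<int>> cons;
    geno_consensus(g, clusters, cons);
    int k = (int)clusters.size();
    std::vector<int> assign((size_t)n, 0);
    for (int r = 0; r < n; ++r) {
      int bc = 0, bd = geno_dist(g, r, cons[0]);
      for (int c = 1; c < k; ++c) {
        int d = geno_dist(g, r, cons[(size_t)c]);
        if (d < bd) { bd = d; bc = c; }
      }
      assign[(size_t)r] = bc;
    }
    std::vector<std::vector<int>> clusters2((size_t)k);
    for (int r = 0; r < n; ++r) clusters2[(size_t)assign[(size_t)r]].push_back(r);
    // drop empties, renumber
    std::vector<std::vector<int>> clusters3;
    for (auto& c : clusters2)
      if (!c.empty()) clusters3.push_back(std::move(c));
    geno_consensus(g, clusters3, cons);
    k = (int)clusters3.size();
    double score = 0.0;
    std::vector<int> assign3((size_t)n, 0);
    for (int r = 0; r < n; ++r) {
      int bc = 0, bd = geno_dist(g, r, cons[0]);
      for (int c = 1; c < k; ++c) {
        int d = geno_dist(g, r, cons[(size_t)c]);
        if (d < bd) { bd = d; bc = c; }
      }
      score += bd;
      assign3[(size_t)r] = bc + 1;
    }
    // penalized comparison: an extra cluster must buy `penalty` distance
    double pscore = score + penalty * k;
    double pbest = bestScore + penalty * bestK;
    if (pscore < pbest || (pscore == pbest && k < bestK)) {
      bestScore = score;
      bestK = k;
      bestAssign = assign3;
      bestCons = cons;
    }
  }

  IntegerMatrix consM(bestK, L);
  for (int c = 0; c < bestK; ++c)
    for (int l = 0; l < L; ++l) consM(c, l) = bestCons[(size_t)c][(size_t)l];
  return List::create(_["assign"] = wrap(bestAssign), _["score"] = bestScore,
                      _["k"] = bestK, _["consensus"] = consM);
}

// ---------------------------------------------------------------------------
// Windowed consensus polishing: realign reads to the working template and
// take per-column majorities (bases, deletions, and voted insertions).
// Reads are expected to start near template coordinate `offset[i]`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_polish(std::string tmpl, std::vector<std::string> reads,
                IntegerVector offsets, int band, int max_rounds,
                double max_div) {
  int rounds = 0, used = 0;
  if ((int)reads.size() != offsets.size()) stop("offsets length mismatch");
  for (int round = 0; round < max_rounds; ++round) {
    int n = (int)tmpl.size();
    std::vector<std::array<int, 5>> cnt((size_t)n, {0, 0, 0, 0, 0});
    std::vector<int> cov((size_t)n, 0);
    std::map<int, std::map<std::string, int>> ins;
    used = 0;
    for (size_t ri = 0; ri < reads.size(); ++ri) {
      const std::string& rd = reads[ri];
      int m = (int)rd.size();
      if (m < 30) continue;
      int off = offsets[ri];
      int w0 = std::max(0, off - band);
      int w1 = std::min(n, off + m + band);
      if (w1 - w0 < 30) continue;
      std::string win = tmpl.substr((size_t)w0, (size_t)(w1 - w0));
      int exp_d = off - w0;  // expected start diagonal inside the window
      AlnResult a = band_align_core(rd, win, exp_d - band, exp_d + band,
                                    true, true, true, true, false);
      if (a.dist >= ALN_INF || a.alnlen <= 0) continue;
      if ((double)a.dist / (double)a.alnlen > max_div) continue;
      ++used;
      int i = 0, j = w0 + a.t_start;
      std::string buf;
      for (size_t c = 0; c < a.cig_op.size(); ++c) {
        int op = a.cig_op[c], len = a.cig_len[c];
        for (int s = 0; s < len; ++s) {
          if (op == 2) { buf.push_back(rd[(size_t)i]); ++i; continue; }
          if (!buf.empty()) {
            if (j < n) ++ins[j][buf];
            buf.clear();
          }
          if (op == 0 || op == 1) {
            int b = base2i(rd[(size_t)i]);
            if (b >= 0) ++cnt[(size_t)j][(size_t)b];
            ++cov[(size_t)j];
            ++i; ++j;
          } else {  // deletion in read
            ++cnt[(size_t)j][4];
            ++cov[(size_t)j];
            ++j;
          }
        }
      }
    }
    std::string out;
    out.reserve((size_t)n + 64);
    for (int j = 0; j < n; ++j) {
      auto it = ins.find(j);
      if (it != ins.end() && cov[(size_t)j] > 0) {
        // pool all insertion votes at this junction (read errors corrupt or
        // shift individual inserted strings, fragmenting exact-string votes),
        // then emit the plurality string when the pooled support is clear
        const std::string* bs = nullptr;
        int bc = 0, tot = 0;
        for (auto& kv : it->second) {
          tot += kv.second;
          if (kv.second > bc) { bc = kv.second; bs = &kv.first; }
        }
        if (bs && tot > 0.4 * cov[(size_t)j] && bc >= 2) out += *bs;
      }
      if (cov[(size_t)j] == 0) { out.push_back(tmpl[(size_t)j]); continue; }
      if (2 * cnt[(size_t)j][4] > cov[(size_t)j]) continue;  // delete column
      int bb = -1, bcnt = 0;
      for (int b = 0; b < 4; ++b)
        if (cnt[(size_t)j][(size_t)b] > bcnt) { bcnt = cnt[(size_t)j][(size_t)b]; bb = b; }
      if (bb < 0) { out.push_back(tmpl[(size_t)j]); continue; }
      out.push_back("ACGT"[bb]);
    }
    ++rounds;
    if (out == tmpl) break;
    tmpl = out;
  }
  return List::create(_["seq"] = tmpl, _["rounds"] = rounds,
                      _["n_used"] = used);
}
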