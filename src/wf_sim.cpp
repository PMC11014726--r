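#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Individual-based Wright-Fisher simulation with partial selfing,
// recombination and two mutation streams (neutral markers and focal
// mutations that are a mixture of neutral and selected classes).
//
// Haplotypes live in a shared pool: a gamete that experiences neither
// crossover nor mutation reuses its parental haplotype by id, so the
// per-generation cost is dominated by the (rare) modified gametes.
// Mutation ids index global arrays (position, origin, class, s).
//
// Mutation class codes: 0 = neutral marker, 1 = focal neutral,
// 2 = focal selected. Mutation status: 0 segregating, 1 fixed, 2 lost.

namespace {

// xoshiro256++ with splitmix64 seeding; seeded from R's RNG so runs are
// reproducible under set.seed() while avoiding per-draw R API overhead
struct FastRNG {
  uint64_t s[4];
  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int pois(double lambda) {  // inversion; lambda is small here
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

struct Pool {
  std::vector< std::vector<int> > muts;   // slot -> mut ids sorted by position
  std::vector< std::vector<int> > sel;    // slot -> selected mut ids, sorted by id
  std::vector<double> w_het;              // product of (1 + h s) over selected muts
  std::vector<double> w_hom;              // product of (1 + s)
  std::vector<int> freelist;

  int alloc() {
    if (!freelist.empty()) { int s = freelist.back(); freelist.pop_back(); return s; }
    muts.push_back(std::vector<int>());
    sel.push_back(std::vector<int>());
    w_het.push_back(1.0);
    w_hom.push_back(1.0);
    return (int)muts.size() - 1;
  }
};

} // namespace

// [[Rcpp::export(name = ".wf_sim_cpp")]]
List wf_sim_cpp(int N0, double L, double mu_neutral, double mu_focal,
                double rho, double selfing, double r_neutral, double s_sel,
                double h, int n_generations, int sample_size,
                IntegerMatrix demography, int fix_cutoff_gen) {
  if (N0 < 2) stop("population size must be >= 2");
  if (L < 1.0) stop("fragment length must be >= 1 bp");
  if (selfing < 0.0 || selfing > 1.0) stop("selfing rate must lie in [0, 1]");
  if (1.0 + s_sel <= 0.0) stop("per-generation selection coefficient implies non-positive fitness");

  RNGScope rngscope;
  FastRNG rng;
  {
    uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
    rng.seed((a << 32) ^ b ^ 0x5851F42D4C957F2DULL);
  }

  // no selected mutations can ever arise -> fitness is identically 1
  const bool neutral_run = (mu_focal <= 0.0) || (s_sel == 0.0) || (r_neutral >= 1.0);

  // global mutation tables
  std::vector<double> mpos;
  std::vector<int> morigin, mcls;
  std::vector<signed char> mstatus;       // 0 seg, 1 fixed, 2 lost
  std::vector<double> msel;               // per-mutation s

  Pool pool;
  int empty_slot = pool.alloc();

  int N = N0;
  std::vector<int> hapA(N, empty_slot), hapB(N, empty_slot);
  std::vector<int> nxtA, nxtB;

  std::vector<double> cum;
  std::vector<int> fix_gen_v, fix_origin_v, fix_cls_v;
  long intro[3] = {0, 0, 0}, intro_cut[3] = {0, 0, 0};
  long fixed_cut[3] = {0, 0, 0};

  const double mu_tot = (mu_neutral + mu_focal) * L;
  const double rho_tot = rho * L;
  const double p_neutral_marker =
    (mu_neutral + mu_focal) > 0 ? mu_neutral / (mu_neutral + mu_focal) : 0.0;
  // P(no crossover and no mutation): the overwhelmingly common case,
  // resolved with a single uniform draw instead of two Poisson draws
  const double p_quiet = std::exp(-(rho_tot + mu_tot));

  std::vector<int> gbuf, selbuf;
  std::vector<double> bp;
  gbuf.reserve(512);

  // binary search gbuf (sorted by position) for mutation id `mid`
  auto gbuf_contains = [&](int mid) -> bool {
    double p = mpos[mid];
    size_t lo = 0, hi = gbuf.size();
    while (lo < hi) {
      size_t m = (lo + hi) / 2;
      if (mpos[gbuf[m]] < p) lo = m + 1; else hi = m;
    }
    return lo < gbuf.size() && gbuf[lo] == mid;
  };

  // draw one gamete from parent p; returns a slot id (shared or new)
  auto gamete = [&](int pa, int pb, int gen) -> int {
    if (rng.unif() < p_quiet)
      return (rng.unif() < 0.5) ? pa : pb;
    // at least one event: (ncx, nmu) conditioned on ncx + nmu > 0
    int ncx, nmu;
    do {
      ncx = (rho_tot > 0) ? rng.pois(rho_tot) : 0;
      nmu = (mu_tot > 0) ? rng.pois(mu_tot) : 0;
    } while (ncx == 0 && nmu == 0);

    gbuf.clear();
    selbuf.clear();
    double gw_het, gw_hom;
    if (ncx == 0) {
      int src = (rng.unif() < 0.5) ? pa : pb;
      gbuf.assign(pool.muts[src].begin(), pool.muts[src].end());
      selbuf.assign(pool.sel[src].begin(), pool.sel[src].end());
      gw_het = pool.w_het[src];
      gw_hom = pool.w_hom[src];
    } else {
      bp.resize(ncx);
      for (int k = 0; k < ncx; ++k) bp[k] = rng.unif() * L;
      std::sort(bp.begin(), bp.end());
      const std::vector<int> *H[2] = {&pool.muts[pa], &pool.muts[pb]};
      size_t i[2] = {0, 0};
      int cur = (rng.unif() < 0.5) ? 0 : 1;
      size_t bi = 0;
      for (;;) {
        double seg_end = (bi < bp.size()) ? bp[bi] : L + 1.0;
        while (i[cur] < H[cur]->size() && mpos[(*H[cur])[i[cur]]] < seg_end) {
          gbuf.push_back((*H[cur])[i[cur]]);
          ++i[cur];
        }
        int oth = 1 - cur;
        while (i[oth] < H[oth]->size() && mpos[(*H[oth])[i[oth]]] < seg_end) ++i[oth];
        if (bi >= bp.size()) break;
        cur = 1 - cur;
        ++bi;
      }
      // selected mutations of the gamete are the subset of the parents'
      // selected mutations whose segment was transmitted
      gw_het = 1.0; gw_hom = 1.0;
      const std::vector<int> &sa = pool.sel[pa], &sb = pool.sel[pb];
      size_t ia = 0, ib = 0;
      while (ia < sa.size() || ib < sb.size()) {
        int mid;
        if (ib >= sb.size()) mid = sa[ia++];
        else if (ia >= sa.size()) mid = sb[ib++];
        else if (sa[ia] < sb[ib]) mid = sa[ia++];
        else if (sb[ib] < sa[ia]) mid = sb[ib++];
        else { mid = sa[ia]; ++ia; ++ib; }
        if (gbuf_contains(mid)) {
          selbuf.push_back(mid);
          gw_het *= 1.0 + h * msel[mid];
          gw_hom *= 1.0 + msel[mid];
        }
      }
    }

    for (int k = 0; k < nmu; ++k) {
      double p_bp = rng.unif() * L;
      int cls;
      double s;
      if (rng.unif() < p_neutral_marker) { cls = 0; s = 0.0; }
      else if (rng.unif() < r_neutral)   { cls = 1; s = 0.0; }
      else                               { cls = 2; s = s_sel; }
      int mid = (int)mpos.size();
      mpos.push_back(p_bp);
      morigin.push_back(gen);
      mcls.push_back(cls);
      mstatus.push_back(0);
      msel.push_back(s);
      ++intro[cls];
      if (gen <= fix_cutoff_gen) ++intro_cut[cls];
      // insert preserving position order
      size_t lo = 0, hi = gbuf.size();
      while (lo < hi) {
        size_t mide = (lo + hi) / 2;
        if (mpos[gbuf[mide]] < p_bp) lo = mide + 1; else hi = mide;
      }
      gbuf.insert(gbuf.begin() + lo, mid);
      if (s != 0.0) {
        selbuf.push_back(mid);
        gw_het *= 1.0 + h * s;
        gw_hom *= 1.0 + s;
      }
    }

    int slot = pool.alloc();
    pool.muts[slot].assign(gbuf.begin(), gbuf.end());
    std::sort(selbuf.begin(), selbuf.end());
    pool.sel[slot].assign(selbuf.begin(), selbuf.end());
    pool.w_het[slot] = gw_het;
    pool.w_hom[slot] = gw_hom;
    return slot;
  };

  // recompute selected-mutation summaries for one slot (used after fixation
  // stripping during garbage collection)
  auto refresh_sel = [&](int slot) {
    std::vector<int> &sl = pool.sel[slot];
    sl.clear();
    double wh = 1.0, wo = 1.0;
    for (int mid : pool.muts[slot]) {
      double s = msel[mid];
      if (s != 0.0) {
        sl.push_back(mid);
        wh *= 1.0 + h * s;
        wo *= 1.0 + s;
      }
    }
    std::sort(sl.begin(), sl.end());
    pool.w_het[slot] = wh;
    pool.w_hom[slot] = wo;
  };

  std::vector<int> use;         // slot usage counts (GC scratch)
  std::vector<int> cnt;         // per-mutation copy counts (GC scratch)
  std::vector<char> fixedflag;

  auto garbage_collect = [&](int gen) {
    size_t P = pool.muts.size();
    use.assign(P, 0);
    for (int s : hapA) ++use[s];
    for (int s : hapB) ++use[s];
    cnt.assign(mpos.size(), 0);
    for (size_t s = 0; s < P; ++s) {
      if (use[s] == 0) continue;
      for (int mid : pool.muts[s]) cnt[mid] += use[s];
    }
    const int total = 2 * N;
    std::vector<int> newly_fixed;
    for (size_t m = 0; m < mpos.size(); ++m) {
      if (mstatus[m] != 0) continue;
      if (cnt[m] == 0) { mstatus[m] = 2; }
      else if (cnt[m] == total) {
        mstatus[m] = 1;
        newly_fixed.push_back((int)m);
        fix_gen_v.push_back(gen);
        fix_origin_v.push_back(morigin[m]);
        fix_cls_v.push_back(mcls[m]);
        if (morigin[m] <= fix_cutoff_gen) ++fixed_cut[mcls[m]];
      }
    }
    if (!newly_fixed.empty()) {
      // strip fixed mutations from live haplotypes (relative fitness unchanged)
      if (fixedflag.size() < mpos.size()) fixedflag.resize(mpos.size(), 0);
      for (int m : newly_fixed) fixedflag[m] = 1;
      for (size_t s = 0; s < P; ++s) {
        if (use[s] == 0) continue;
        std::vector<int> &v = pool.muts[s];
        size_t w = 0;
        bool touched = false;
        for (size_t i2 = 0; i2 < v.size(); ++i2) {
          if (fixedflag[v[i2]]) { touched = true; continue; }
          v[w++] = v[i2];
        }
        if (touched) { v.resize(w); refresh_sel(s); }
      }
      for (int m : newly_fixed) fixedflag[m] = 0;
    }
    pool.freelist.clear();
    for (size_t s = 0; s < P; ++s) {
      if (use[s] == 0) {
        pool.muts[s].clear();  // keep capacity: freed slots are reused
        pool.sel[s].clear();
        pool.w_het[s] = 1.0;
        pool.w_hom[s] = 1.0;
        pool.freelist.push_back((int)s);
      }
    }
  };

  const int gc_every = 64;

  for (int gen = 1; gen <= n_generations; ++gen) {
    // scheduled population-size changes take effect in this generation's offspring
    int N_next = N;
    for (int r = 0; r < demography.nrow(); ++r)
      if (demography(r, 0) == gen) N_next = demography(r, 1);
    if (N_next < 2) stop("demography schedule drove N below 2 at generation %d", gen);

    double tot = 0.0, w_max = 0.0;
    if (!neutral_run) {
      cum.resize(N);
      for (int i = 0; i < N; ++i) {
        int a = hapA[i], b = hapB[i];
        double w;
        if (a == b) {
          w = pool.w_hom[a];
        } else {
          w = pool.w_het[a] * pool.w_het[b];
          const std::vector<int> &sa = pool.sel[a], &sb = pool.sel[b];
          if (!sa.empty() && !sb.empty()) {
            size_t ia = 0, ib = 0;
            while (ia < sa.size() && ib < sb.size()) {
              if (sa[ia] < sb[ib]) ++ia;
              else if (sb[ib] < sa[ia]) ++ib;
              else {
                double s = msel[sa[ia]];
                double het = 1.0 + h * s;
                w *= (1.0 + s) / (het * het);
                ++ia; ++ib;
              }
            }
          }
        }
        tot += w;
        if (w > w_max) w_max = w;
        cum[i] = w;  // individual fitness (rejection sampling below)
      }
      if (tot <= 0.0) stop("total fitness collapsed to zero at generation %d", gen);
    }

    // fitness-proportional parent sampling by rejection: fitnesses are
    // close to w_max for almost all individuals, so acceptance is ~1
    auto draw_parent = [&]() -> int {
      for (;;) {
        int i = (int)(rng.unif() * N);
        if (i >= N) i = N - 1;
        if (neutral_run || rng.unif() * w_max <= cum[i]) return i;
      }
    };

    nxtA.resize(N_next);
    nxtB.resize(N_next);
    for (int i = 0; i < N_next; ++i) {
      if (N == 1 || rng.unif() < selfing) {
        int p = draw_parent();
        nxtA[i] = gamete(hapA[p], hapB[p], gen);
        nxtB[i] = gamete(hapA[p], hapB[p], gen);
      } else {
        int p1 = draw_parent();
        int p2;
        do { p2 = draw_parent(); } while (p2 == p1);
        nxtA[i] = gamete(hapA[p1], hapB[p1], gen);
        nxtB[i] = gamete(hapA[p2], hapB[p2], gen);
      }
    }
    hapA.swap(nxtA);
    hapB.swap(nxtB);
    N = N_next;

    if (gen % gc_every == 0 || gen == n_generations) garbage_collect(gen);
    if (gen % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  // terminal sample of individuals without replacement
  int n_s = std::min(sample_size, N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_s; ++i) {
    int j = i + (int)(rng.unif() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(idx[i], idx[j]);
  }

  std::vector<int> scount(mpos.size(), 0), shet(mpos.size(), 0);
  for (int k = 0; k < n_s; ++k) {
    int a = hapA[idx[k]], b = hapB[idx[k]];
    if (a == b) {
      for (int mid : pool.muts[a]) scount[mid] += 2;
    } else {
      const std::vector<int> &va = pool.muts[a], &vb = pool.muts[b];
      size_t ia = 0, ib = 0;
      while (ia < va.size() || ib < vb.size()) {
        if (ib >= vb.size() || (ia < va.size() && mpos[va[ia]] < mpos[vb[ib]])) {
          scount[va[ia]] += 1; shet[va[ia]] += 1; ++ia;
        } else if (ia >= va.size() || mpos[vb[ib]] < mpos[va[ia]]) {
          scount[vb[ib]] += 1; shet[vb[ib]] += 1; ++ib;
        } else {  // same mutation on both haplotypes
          scount[va[ia]] += 2; ++ia; ++ib;
        }
      }
    }
  }

  std::vector<int> out_id, out_origin, out_cls, out_count, out_het;
  std::vector<double> out_pos, out_s;
  const int tot_chr = 2 * n_s;
  for (size_t m = 0; m < mpos.size(); ++m) {
    if (scount[m] > 0 && scount[m] < tot_chr) {
      out_id.push_back((int)m + 1);
      out_pos.push_back(mpos[m]);
      out_origin.push_back(morigin[m]);
      out_cls.push_back(mcls[m]);
      out_s.push_back(msel[m]);
      out_count.push_back(scount[m]);
      out_het.push_back(shet[m]);
    }
  }

  long unresolved_cut[3] = {0, 0, 0};
  for (size_t m = 0; m < mpos.size(); ++m)
    if (mstatus[m] == 0 && morigin[m] <= fix_cutoff_gen) ++unresolved_cut[mcls[m]];

  return List::create(
    _["sample"] = DataFrame::create(
      _["mut_id"] = out_id, _["position"] = out_pos,
      _["origin_generation"] = out_origin, _["class_code"] = out_cls,
      _["s"] = out_s, _["count"] = out_count, _["het_count"] = out_het),
    _["fixations"] = DataFrame::create(
      _["fixed_generation"] = fix_gen_v, _["origin_generation"] = fix_origin_v,
      _["class_code"] = fix_cls_v),
    _["introduced"] = IntegerVector::create(intro[0], intro[1], intro[2]),
    _["introduced_cohort"] = IntegerVector::create(intro_cut[0], intro_cut[1], intro_cut[2]),
    _["fixed_cohort"] = IntegerVector::create(fixed_cut[0], fixed_cut[1], fixed_cut[2]),
    _["unresolved_cohort"] = IntegerVector::create(unresolved_cut[0], unresolved_cut[1], unresolved_cut[2]),
    _["final_N"] = N,
    _["n_sampled"] = n_s,
    _["n_generations"] = n_generations);
}
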