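#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Forward Wright-Fisher machinery.
//
// Each haplotype is the sorted vector of positions (integer bp) at which it
// carries a derived allele; the ancestral state is 0 everywhere. Mutation
// follows the infinite-sites approximation with collision retry, and
// recombination is a single crossover per meiosis with probability
// min(rec * L, 1). Sites fixed across all populations are purged
// periodically (they are substitutions, invisible within the sample). All
// randomness goes through R's RNG so set.seed() on the R side makes every
// run reproducible.

typedef std::vector<int> Hap; // sorted derived-allele positions
typedef std::vector<Hap> Pop;

static inline int pick_uniform(int N) {
  int i = (int)(unif_rand() * N);
  return i >= N ? N - 1 : i;
}

static int pick_weighted(const std::vector<double> &cum) {
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

static inline bool carries(const Hap &h, int p) {
  return std::binary_search(h.begin(), h.end(), p);
}

static void gamete(const Hap &h1, const Hap &h2, double rec, double L,
                   Hap &child) {
  if (unif_rand() < rec * L) {
    int b = (int)(unif_rand() * L);
    const Hap &A = (unif_rand() < 0.5) ? h1 : h2;
    const Hap &B = (&A == &h1) ? h2 : h1;
    child.clear();
    Hap::const_iterator sa = std::lower_bound(A.begin(), A.end(), b);
    Hap::const_iterator sb = std::lower_bound(B.begin(), B.end(), b);
    child.reserve((sa - A.begin()) + (B.end() - sb));
    child.insert(child.end(), A.begin(), sa);
    child.insert(child.end(), sb, B.end());
  } else {
    child = (unif_rand() < 0.5) ? h1 : h2;
  }
}

// One generation of reproduction for a population of N diploids.
// sweep_pos >= 0 enables genic selection (fitness 1, 1+s, 1+2s) there.
static void next_generation(const Pop &cur, Pop &nxt, int N, double rec,
                            double L, int sweep_pos, double s) {
  std::vector<double> cum;
  bool sel = sweep_pos >= 0 && s > 0;
  if (sel) {
    cum.resize(N);
    double acc = 0;
    for (int i = 0; i < N; ++i) {
      int g = carries(cur[2 * i], sweep_pos) + carries(cur[2 * i + 1], sweep_pos);
      acc += 1.0 + s * g;
      cum[i] = acc;
    }
  }
  nxt.resize(2 * (size_t)N);
  for (int i = 0; i < N; ++i) {
    int m = sel ? pick_weighted(cum) : pick_uniform(N);
    int f = sel ? pick_weighted(cum) : pick_uniform(N);
    gamete(cur[2 * m], cur[2 * m + 1], rec, L, nxt[2 * i]);
    gamete(cur[2 * f], cur[2 * f + 1], rec, L, nxt[2 * i + 1]);
  }
}

// Poisson(mu*L) new mutations per haplotype; each insert touches one
// haplotype only.
static void mutate(std::vector<Pop *> &pops, std::unordered_set<int> &active,
                   double mu, double L) {
  for (Pop *p : pops)
    for (Hap &h : *p) {
      int cnt = (int)R::rpois(mu * L);
      for (int k = 0; k < cnt; ++k) {
        int b;
        do { b = (int)(unif_rand() * L); } while (active.count(b));
        active.insert(b);
        h.insert(std::lower_bound(h.begin(), h.end(), b), b);
      }
    }
}

// Remove substitutions (positions carried by every haplotype of every pop)
// and rebuild the active-position set from what actually segregates.
static void compact(std::vector<Pop *> &pops, std::unordered_set<int> &active,
                    int keep_pos) {
  std::unordered_map<int, long long> cnt;
  long long tot = 0;
  for (Pop *p : pops) {
    tot += (long long)p->size();
    for (const Hap &h : *p)
      for (int b : h) ++cnt[b];
  }
  std::unordered_set<int> fixed;
  active.clear();
  for (std::unordered_map<int, long long>::iterator it = cnt.begin();
       it != cnt.end(); ++it) {
    if (it->second >= tot && it->first != keep_pos) fixed.insert(it->first);
    else active.insert(it->first);
  }
  if (keep_pos >= 0) active.insert(keep_pos);
  if (fixed.empty()) return;
  for (Pop *p : pops)
    for (Hap &h : *p) {
      size_t w = 0;
      for (size_t j = 0; j < h.size(); ++j)
        if (!fixed.count(h[j])) h[w++] = h[j];
      h.resize(w);
    }
}

static void sample_individuals(int n, std::vector<int> &out,
                               std::vector<int> &pool) {
  // partial Fisher-Yates on a caller-provided pool of individual indices
  out.clear();
  for (int i = 0; i < n; ++i) {
    int j = i + pick_uniform((int)pool.size() - i);
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

// [[Rcpp::export]]
List wf_sim_cpp(int N_anc, int N_wild, int N_dom, double L, double mu, double rec,
                int burn_in, int T_split,
                double sweep_pos, double sweep_s, int sweep_start,
                double sweep_min_freq, int sweep_max_attempts,
                int n_sample_wild, int n_sample_dom) {
  const int CLEAN_EVERY = 16;
  std::unordered_set<int> active;
  int sweep_at = -1; // integer position of the sweep site once introduced
  bool want_sweep = sweep_pos >= 0;

  Pop anc(2 * (size_t)N_anc), buf;

  for (int g = 0; g < burn_in; ++g) {
    next_generation(anc, buf, N_anc, rec, L, -1, 0);
    anc.swap(buf);
    std::vector<Pop *> cur;
    cur.push_back(&anc);
    mutate(cur, active, mu, L);
    if (g % CLEAN_EVERY == 0) compact(cur, active, -1);
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  Pop wild, dom, wbuf, dbuf;
  int attempts = 0;
  double final_freq = NA_REAL;

  if (T_split == 0) {
    // no divergence requested: both samples come from the burned-in deme
    wild = anc;
    dom = anc;
  } else {
    next_generation(anc, wild, N_wild, rec, L, -1, 0);
    next_generation(anc, dom, N_dom, rec, L, -1, 0);
    anc.clear(); anc.shrink_to_fit();
    std::vector<Pop *> two;
    two.push_back(&wild);
    two.push_back(&dom);
    mutate(two, active, mu, L);

    // snapshot storage for sweep conditioning
    Pop snap_w, snap_d;
    std::unordered_set<int> snap_active;

    int g = 1;
    while (g <= T_split) {
      if (want_sweep && g == sweep_start && sweep_at < 0) {
        int b = (int)sweep_pos;
        while (active.count(b)) ++b;
        active.insert(b);
        sweep_at = b;
        Hap &h = dom[pick_uniform(2 * N_dom)];
        h.insert(std::lower_bound(h.begin(), h.end(), b), b);
        snap_w = wild; snap_d = dom; snap_active = active;
        attempts = 1;
      }
      int sw = (want_sweep && g >= sweep_start) ? sweep_at : -1;
      next_generation(wild, wbuf, N_wild, rec, L, -1, 0);
      wild.swap(wbuf);
      next_generation(dom, dbuf, N_dom, rec, L, sw, sweep_s);
      dom.swap(dbuf);
      mutate(two, active, mu, L);
      if (g % CLEAN_EVERY == 0) compact(two, active, sweep_at);
      if (g % 64 == 0) Rcpp::checkUserInterrupt();

      if (g == T_split && want_sweep) {
        long long c = 0;
        for (const Hap &h : dom) c += carries(h, sweep_at);
        final_freq = (double)c / (2.0 * N_dom);
        if (final_freq < sweep_min_freq) {
          if (attempts >= sweep_max_attempts)
            stop("sweep failed to reach frequency %f within %d attempts",
                 sweep_min_freq, sweep_max_attempts);
          ++attempts;
          wild = snap_w; dom = snap_d; active = snap_active;
          g = sweep_start; // state as of the introduction generation
          continue;        // redo generations sweep_start+1 .. T_split
        }
      }
      ++g;
    }
  }

  // sample individuals (disjoint when both pops alias the same deme)
  std::vector<int> sw_idx, sd_idx;
  if (T_split == 0) {
    if (n_sample_wild + n_sample_dom > N_anc)
      stop("T_split = 0 requires n_sample_wild + n_sample_dom <= N_anc");
    std::vector<int> pool(N_anc);
    for (int i = 0; i < N_anc; ++i) pool[i] = i;
    std::vector<int> both;
    sample_individuals(n_sample_wild + n_sample_dom, both, pool);
    sw_idx.assign(both.begin(), both.begin() + n_sample_wild);
    sd_idx.assign(both.begin() + n_sample_wild, both.end());
  } else {
    std::vector<int> pw(N_wild), pd(N_dom);
    for (int i = 0; i < N_wild; ++i) pw[i] = i;
    for (int i = 0; i < N_dom; ++i) pd[i] = i;
    sample_individuals(n_sample_wild, sw_idx, pw);
    sample_individuals(n_sample_dom, sd_idx, pd);
  }

  int nh = 2 * (n_sample_wild + n_sample_dom);
  std::vector<const Hap *> hsel;
  hsel.reserve(nh);
  for (int i : sw_idx) { hsel.push_back(&wild[2 * i]); hsel.push_back(&wild[2 * i + 1]); }
  for (int i : sd_idx) { hsel.push_back(&dom[2 * i]); hsel.push_back(&dom[2 * i + 1]); }

  // keep sites segregating within the sample
  std::unordered_map<int, int> scount;
  for (int h = 0; h < nh; ++h)
    for (int b : *hsel[h]) ++scount[b];
  std::vector<int> segpos;
  segpos.reserve(scount.size());
  for (std::unordered_map<int, int>::iterator it = scount.begin();
       it != scount.end(); ++it)
    if (it->second > 0 && it->second < nh) segpos.push_back(it->first);
  std::sort(segpos.begin(), segpos.end());

  std::unordered_map<int, int> colof;
  for (size_t k = 0; k < segpos.size(); ++k) colof[segpos[k]] = (int)k;
  IntegerMatrix G((int)segpos.size(), nh);
  for (int h = 0; h < nh; ++h)
    for (int b : *hsel[h]) {
      std::unordered_map<int, int>::iterator it = colof.find(b);
      if (it != colof.end()) G(it->second, h) = 1;
    }
  NumericVector outpos((int)segpos.size());
  for (size_t k = 0; k < segpos.size(); ++k) outpos[k] = (double)segpos[k];

  return List::create(
      _["pos"] = outpos, _["haps"] = G,
      _["sweep_pos"] = want_sweep ? (double)sweep_at : NA_REAL,
      _["sweep_attempts"] = attempts, _["sweep_final_freq"] = final_freq);
}

// ---------------------------------------------------------------------------
// EHH / iHH outward walk.
//
// Haplotype homozygosity among the carriers of the core allele is refined
// site by site moving away from the core; the trapezoid integral of EHH
// against genetic distance (cM) accumulates until EHH < cutoff, the physical
// extent exceeds max_extend, an inter-SNP gap exceeds max_gap, or the data
// end. The trapezoid into the first sub-cutoff point is included.

static double ehh_side(const IntegerMatrix &H, const NumericVector &pos_bp,
                       const NumericVector &pos_cm, int core,
                       const std::vector<int> &carriers, int dir,
                       double cutoff, double max_extend, double max_gap,
                       int *flag) {
  int nsites = H.nrow();
  int nc = (int)carriers.size();
  std::vector<int> g(nc, 0);
  int ngroups = 1;
  double ehh_prev = 1.0, cm_prev = pos_cm[core], bp_prev = pos_bp[core];
  double area = 0.0;
  int j = core;
  std::vector<int> remap, tab;
  while (true) {
    j += dir;
    if (j < 0 || j >= nsites) { *flag |= 1; break; }
    if (std::fabs(pos_bp[j] - bp_prev) > max_gap) { *flag |= 2; break; }
    if (std::fabs(pos_bp[j] - pos_bp[core]) > max_extend) { *flag |= 1; break; }
    remap.assign(2 * (size_t)ngroups, -1);
    int newn = 0;
    for (int c = 0; c < nc; ++c) {
      int key = g[c] * 2 + (H(j, carriers[c]) != 0 ? 1 : 0);
      if (remap[key] < 0) remap[key] = newn++;
      g[c] = remap[key];
    }
    ngroups = newn;
    tab.assign(ngroups, 0);
    for (int c = 0; c < nc; ++c) tab[g[c]]++;
    double num = 0;
    for (int t : tab) num += (double)t * (t - 1);
    double ehh = num / ((double)nc * (nc - 1));
    area += 0.5 * (ehh_prev + ehh) * std::fabs(pos_cm[j] - cm_prev);
    if (ehh < cutoff) break;
    ehh_prev = ehh; cm_prev = pos_cm[j]; bp_prev = pos_bp[j];
  }
  return area;
}

// [[Rcpp::export]]
List ihh_scan_cpp(IntegerMatrix H, NumericVector pos_bp, NumericVector pos_cm,
                  IntegerVector cores, double cutoff, double max_extend,
                  double max_gap, int min_carriers) {
  int ncores = cores.size();
  NumericMatrix ihh(ncores, 2); // columns: allele 0 carriers, allele 1 carriers
  IntegerVector flags(ncores);
  for (int ci = 0; ci < ncores; ++ci) {
    int core = cores[ci] - 1;
    std::vector<int> c0, c1;
    for (int h = 0; h < H.ncol(); ++h)
      (H(core, h) != 0 ? c1 : c0).push_back(h);
    if ((int)c0.size() < min_carriers || (int)c1.size() < min_carriers) {
      flags[ci] = 4;
      ihh(ci, 0) = NA_REAL;
      ihh(ci, 1) = NA_REAL;
      continue;
    }
    int flag = 0;
    ihh(ci, 0) = ehh_side(H, pos_bp, pos_cm, core, c0, -1, cutoff, max_extend, max_gap, &flag) +
                 ehh_side(H, pos_bp, pos_cm, core, c0, +1, cutoff, max_extend, max_gap, &flag);
    ihh(ci, 1) = ehh_side(H, pos_bp, pos_cm, core, c1, -1, cutoff, max_extend, max_gap, &flag) +
                 ehh_side(H, pos_bp, pos_cm, core, c1, +1, cutoff, max_extend, max_gap, &flag);
    flags[ci] = flag;
    if (ci % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["ihh"] = ihh, _["flags"] = flags);
}
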