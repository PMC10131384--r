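// Forward Wright-Fisher simulator with recombination, infinite-sites
// mutation, deme splits, migration and an optional hard selective sweep.
// Haplotypes are sparse sorted vectors of derived-allele positions; the
// founding population defines the ancestral state, so polarization of the
// emitted data is exact by construction.
#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

typedef std::vector<int> Hap;          // sorted derived positions (1-based bp)
typedef std::vector<Hap> Deme;         // 2N haplotypes

// --- self-contained RNG: streams are derived per (generation, deme, retry)
// from the master seed, so adding a deme does not perturb the others and a
// fixed seed gives bit-identical output on any platform.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() { // xorshift128+
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
  int poisson(double lambda) { // inversion; lambda is small here (<= ~1)
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

static inline uint64_t stream_seed(uint64_t master, int gen, int deme, int retry) {
  uint64_t x = master;
  x ^= 0x9E3779B97f4A7C15ULL * (uint64_t)(gen + 1);
  x ^= 0xC2B2AE3D27D4EB4FULL * (uint64_t)(deme + 1);
  x ^= 0x165667B19E3779F9ULL * (uint64_t)(retry + 1);
  return splitmix64(x);
}

// one gamete: recombine parent's two haplotypes, then add new mutations
static Hap make_gamete(const Hap &a, const Hap &b, double rec_lambda,
                       double mut_lambda, int L, Rng &rng,
                       std::unordered_set<int> &used) {
  const Hap *src[2] = { &a, &b };
  int cur = rng.unif_int(2);
  Hap g;
  int nx = rec_lambda > 0 ? rng.poisson(rec_lambda) : 0;
  if (nx == 0) {
    g = *src[cur];
  } else {
    static thread_local std::vector<int> bp;
    bp.resize(nx);
    for (int i = 0; i < nx; ++i) bp[i] = 1 + rng.unif_int(L); // crossover before this bp
    std::sort(bp.begin(), bp.end());
    g.reserve(std::max(a.size(), b.size()) + 4);
    size_t ia = 0, ib = 0;
    int seg_start = 0;
    for (int k = 0; k <= nx; ++k) {
      int seg_end = (k < nx) ? bp[k] : (L + 1); // half-open [seg_start, seg_end)
      const Hap &s = *src[cur];
      size_t &ip = (cur == 0) ? ia : ib;
      size_t &io = (cur == 0) ? ib : ia;
      const Hap &o = *src[1 - cur];
      while (ip < s.size() && s[ip] < seg_start) ++ip;
      while (ip < s.size() && s[ip] < seg_end) { g.push_back(s[ip]); ++ip; }
      while (io < o.size() && o[io] < seg_end) ++io;
      seg_start = seg_end;
      cur = 1 - cur;
    }
  }
  int nm = mut_lambda > 0 ? rng.poisson(mut_lambda) : 0;
  for (int i = 0; i < nm; ++i) {
    int p;
    int guard = 0;
    do {
      p = 1 + rng.unif_int(L);
    } while (used.count(p) && ++guard < 10000);
    if (used.count(p)) continue; // region saturated; skip (never at desk scale)
    used.insert(p);
    g.insert(std::lower_bound(g.begin(), g.end(), p), p);
  }
  return g;
}

static inline int hap_has(const Hap &h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos) ? 1 : 0;
}

// remove globally fixed mutations; rebuild the used-position set from the
// currently segregating + fixed positions (lost positions become reusable)
static void purge(std::vector<Deme> &demes, const std::vector<bool> &alive,
                  std::unordered_set<int> &used, std::unordered_set<int> &fixed,
                  int focal_pos) {
  std::unordered_map<int, long> cnt;
  long total = 0;
  for (size_t d = 0; d < demes.size(); ++d) {
    if (!alive[d]) continue;
    total += (long)demes[d].size();
    for (const Hap &h : demes[d])
      for (int p : h) ++cnt[p];
  }
  std::unordered_set<int> newly_fixed;
  for (auto &kv : cnt)
    if (kv.second == total && kv.first != focal_pos) newly_fixed.insert(kv.first);
  if (!newly_fixed.empty()) {
    for (size_t d = 0; d < demes.size(); ++d) {
      if (!alive[d]) continue;
      for (Hap &h : demes[d]) {
        Hap out;
        out.reserve(h.size());
        for (int p : h)
          if (!newly_fixed.count(p)) out.push_back(p);
        h.swap(out);
      }
    }
    for (int p : newly_fixed) fixed.insert(p);
  }
  used.clear();
  for (auto &kv : cnt)
    if (!newly_fixed.count(kv.first)) used.insert(kv.first);
  for (int p : fixed) used.insert(p);
}

// [[Rcpp::export(name = ".simulate_wf_cpp")]]
List simulate_wf_cpp(int n_demes, int deme_size, IntegerVector split_generations,
                     IntegerVector parent_deme, double migration_rate,
                     int seq_length, double mu, double rec_rate, int burn_in,
                     bool has_sweep, int sweep_deme, int sweep_pos,
                     double sweep_s, int sweep_onset, int max_retries,
                     IntegerVector sample_sizes, double seed_master) {
  const int N = deme_size, L = seq_length;
  const double mut_lambda = mu * L, rec_lambda = rec_rate * L;
  const uint64_t master = (uint64_t)seed_master;

  int max_split = 0;
  for (int d = 1; d < n_demes; ++d)
    if (split_generations[d] > max_split) max_split = split_generations[d];
  const int T = burn_in + max_split;
  if (has_sweep && sweep_onset > T)
    stop("sweep onset predates the start of the simulation");

  std::vector<Deme> demes(n_demes);
  std::vector<bool> alive(n_demes, false);
  demes[0].assign(2 * N, Hap());
  alive[0] = true;
  std::unordered_set<int> used, fixed;

  // snapshot taken at sweep onset so a lost sweep can be restarted
  std::vector<Deme> snap_demes;
  std::vector<bool> snap_alive;
  std::unordered_set<int> snap_used, snap_fixed;
  bool have_snapshot = false;

  std::vector<double> trajectory; // focal derived freq in sweep deme per gen
  int retry = 0;
  const int purge_every = 50;

  int gbp = T;
  while (gbp >= 1) {
    // deme splits: the new deme copies its parent and evolves from here on
    for (int d = 1; d < n_demes; ++d) {
      if (!alive[d] && split_generations[d] == gbp) {
        demes[d] = demes[parent_deme[d]];
        alive[d] = true;
      }
    }
    // sweep onset: snapshot state, then plant the focal mutation
    if (has_sweep && gbp == sweep_onset && !have_snapshot) {
      snap_demes = demes;
      snap_alive = alive;
      snap_used = used;
      snap_fixed = fixed;
      have_snapshot = true;
      trajectory.clear();
    }
    if (has_sweep && gbp == sweep_onset) {
      Rng rng(stream_seed(master, 0, sweep_deme, retry));
      // infinite sites: if the focal bp already mutated, take the nearest
      // unused position instead (reported back via focal_pos)
      int shift = 0;
      while (used.count(sweep_pos + shift) &&
             used.count(sweep_pos - shift) && shift < L)
        ++shift;
      if (!used.count(sweep_pos + shift)) sweep_pos += shift;
      else sweep_pos -= shift;
      used.insert(sweep_pos);
      Hap &h = demes[sweep_deme][rng.unif_int(2 * N)];
      h.insert(std::lower_bound(h.begin(), h.end(), sweep_pos), sweep_pos);
    }

    // synchronous reproduction over all living demes
    std::vector<int> living;
    for (int d = 0; d < n_demes; ++d)
      if (alive[d]) living.push_back(d);
    std::vector<Deme> next(n_demes);
    const bool selecting = has_sweep && gbp <= sweep_onset;
    // fitness cumulative weights per deme (only the sweep deme is non-uniform)
    std::vector<std::vector<double>> cum(n_demes);
    for (int d : living) {
      if (selecting && d == sweep_deme) {
        std::vector<double> w(N);
        double acc = 0;
        for (int i = 0; i < N; ++i) {
          int copies = hap_has(demes[d][2 * i], sweep_pos) +
                       hap_has(demes[d][2 * i + 1], sweep_pos);
          acc += 1.0 + sweep_s * copies;
          w[i] = acc;
        }
        cum[d] = w;
      }
    }
    for (int d : living) {
      Rng rng(stream_seed(master, gbp, d, retry));
      Deme kids(2 * N);
      for (int i = 0; i < N; ++i) {
        for (int par = 0; par < 2; ++par) {
          int src_deme = d;
          if (migration_rate > 0 && living.size() > 1 &&
              rng.unif() < migration_rate) {
            int k = rng.unif_int((int)living.size() - 1);
            int pick = 0;
            for (int dd : living) {
              if (dd == d) continue;
              if (pick == k) { src_deme = dd; break; }
              ++pick;
            }
          }
          int pi;
          if (src_deme == d && !cum[d].empty()) {
            double u = rng.unif() * cum[d].back();
            pi = (int)(std::lower_bound(cum[d].begin(), cum[d].end(), u) -
                       cum[d].begin());
            if (pi >= N) pi = N - 1;
          } else {
            pi = rng.unif_int(N);
          }
          kids[2 * i + par] = make_gamete(demes[src_deme][2 * pi],
                                          demes[src_deme][2 * pi + 1],
                                          rec_lambda, mut_lambda, L, rng, used);
        }
      }
      next[d] = std::move(kids);
    }
    for (int d : living) demes[d] = std::move(next[d]);

    if (has_sweep && gbp <= sweep_onset) {
      long c = 0;
      for (const Hap &h : demes[sweep_deme]) c += hap_has(h, sweep_pos);
      trajectory.push_back((double)c / (2.0 * N));
      if (c == 0) { // sweep lost: restart from the onset snapshot
        if (++retry > max_retries)
          stop("sweep allele lost in every retry (cap %d)", max_retries);
        demes = snap_demes;
        alive = snap_alive;
        used = snap_used;
        fixed = snap_fixed;
        trajectory.clear();
        gbp = sweep_onset;
        continue;
      }
    }
    if (gbp % purge_every == 0 || gbp == 1)
      purge(demes, alive, used, fixed, has_sweep ? sweep_pos : -1);
    --gbp;
  }

  // sample the first k haplotypes per deme (exchangeable by construction)
  std::unordered_map<int, long> cnt;
  long total_sampled = 0;
  for (int d = 0; d < n_demes; ++d) {
    int k = sample_sizes[d];
    total_sampled += k;
    for (int i = 0; i < k; ++i)
      for (int p : demes[d][i]) ++cnt[p];
  }
  std::vector<int> positions;
  positions.reserve(cnt.size());
  for (auto &kv : cnt)
    if (kv.second > 0 && kv.second < total_sampled) positions.push_back(kv.first);
  std::sort(positions.begin(), positions.end());
  std::unordered_map<int, int> colof;
  for (size_t j = 0; j < positions.size(); ++j) colof[positions[j]] = (int)j;

  List mats(n_demes);
  NumericVector focal_freq(n_demes), focal_freq_sample(n_demes);
  for (int d = 0; d < n_demes; ++d) {
    int k = sample_sizes[d];
    IntegerMatrix M(k, (int)positions.size());
    long cs = 0;
    for (int i = 0; i < k; ++i)
      for (int p : demes[d][i]) {
        auto it = colof.find(p);
        if (it != colof.end()) M(i, it->second) = 1;
        if (has_sweep && p == sweep_pos) ++cs;
      }
    mats[d] = M;
    if (has_sweep) {
      long c = 0;
      for (const Hap &h : demes[d]) c += hap_has(h, sweep_pos);
      focal_freq[d] = (double)c / (2.0 * N);
      focal_freq_sample[d] = (double)cs / (double)k;
    }
  }

  return List::create(
      _["matrices"] = mats, _["positions"] = wrap(positions),
      _["focal_pos"] = has_sweep ? sweep_pos : NA_INTEGER,
      _["focal_freq"] = focal_freq, _["focal_freq_sample"] = focal_freq_sample,
      _["retries"] = retry, _["trajectory"] = wrap(trajectory),
      _["n_fixed"] = (int)fixed.size());
}
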