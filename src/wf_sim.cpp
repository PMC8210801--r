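#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Forward Wright-Fisher engine for the synthetic-data generator.
//
// Haplotypes are stored site-major (one byte vector of length 2N per
// segregating site); sites are unlinked (each gamete draws every site's
// allele from a random parental haplotype).  Fitness is multiplicative
// across sites: 1, 1-hs, 1-s for genotypes 0/1/2 with s,h indexed by impact
// class code (0 MODIFIER, 1 HIGH, 2 MODERATE, 3 LOW).  Only the per-site
// transmission coins use a local xoshiro generator (seeded once from R's
// RNG stream so runs are reproducible under set.seed); every other draw
// goes through R's RNG.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {          // splitmix64 expansion
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
};

inline int sample_cum(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

} // namespace

// [[Rcpp::export(name = ".wf_evolve_cpp")]]
List wf_evolve_cpp(IntegerMatrix hap0,        // S0 x 2N_in binary
                   IntegerVector pos0,        // 0-based site positions
                   IntegerVector cls0,        // impact class codes
                   NumericVector f0,          // length N_in starting F
                   int n_dip,                 // diploid size of this epoch
                   double selfing,
                   int ngens,
                   double mu,                 // per mutable site per gen
                   IntegerVector mut_pos,     // candidate mutation positions
                   IntegerVector mut_codon,   // 0 noncoding, 1/2/3 codon offset+1
                   NumericVector class_probs, // P(high, moderate, low)
                   NumericVector s_class,     // s by class code 0..3
                   NumericVector h_class) {   // h by class code 0..3
  const int two_n = 2 * n_dip;
  const int n_in = hap0.ncol() / 2;
  if (ngens < 0) stop("ngens must be >= 0");
  if (ngens == 0 && n_in != n_dip)
    stop("population size cannot change without evolving");
  for (int c = 0; c < s_class.size(); ++c)
    if (s_class[c] > 1.0 || s_class[c] < 0.0 ||
        h_class[c] > 1.0 || h_class[c] < 0.0)
      stop("selection coefficients must be in [0,1] and dominance in [0,1]");

  std::vector<std::vector<uint8_t>> H, Hnext;
  std::vector<int> pos, cls, tot;
  std::unordered_set<int> seg;
  H.reserve(hap0.nrow() + 256);
  for (int s = 0; s < hap0.nrow(); ++s) {
    std::vector<uint8_t> row(hap0.ncol());
    int t = 0;
    for (int j = 0; j < hap0.ncol(); ++j) { row[j] = (uint8_t)hap0(s, j); t += row[j]; }
    H.push_back(std::move(row));
    pos.push_back(pos0[s]);
    cls.push_back(cls0[s]);
    tot.push_back(t);
    seg.insert(pos0[s]);
  }
  std::vector<double> F(f0.begin(), f0.end());
  std::vector<int> mother_of(n_dip, -2), father_of(n_dip, -2);
  std::vector<int> fixed_pos, fixed_cls;
  std::vector<double> Fnext(n_dip), cum;
  std::vector<int> sel_idx;

  Xoshiro coin((uint64_t)(unif_rand() * 9007199254740992.0));

  const int n_mutable = mut_pos.size();
  const double lam = 2.0 * n_dip * mu * n_mutable;
  const double p_h = class_probs[0], p_m = class_probs[1];

  for (int g = 0; g < ngens; ++g) {
    const int n_par = (g == 0) ? n_in : n_dip;
    const int par_cols = 2 * n_par;

    // fitness of parents over selected sites only
    cum.assign(n_par, 1.0);
    sel_idx.clear();
    for (size_t s = 0; s < H.size(); ++s)
      if (s_class[cls[s]] > 0.0) sel_idx.push_back((int)s);
    for (int si : sel_idx) {
      const double sv = s_class[cls[si]], hv = h_class[cls[si]];
      const double w1 = 1.0 - hv * sv, w2 = 1.0 - sv;
      const uint8_t* row = H[si].data();
      for (int i = 0; i < n_par; ++i) {
        int gt = row[2 * i] + row[2 * i + 1];
        if (gt == 1) cum[i] *= w1;
        else if (gt == 2) cum[i] *= w2;
      }
    }
    for (int i = 1; i < n_par; ++i) cum[i] += cum[i - 1];

    // parents and inbreeding recursion (selfing only; outcrossed F = 0)
    for (int o = 0; o < n_dip; ++o) {
      int m = sample_cum(cum);
      int f = (selfing > 0.0 && unif_rand() < selfing) ? m : sample_cum(cum);
      mother_of[o] = 2 * m; father_of[o] = 2 * f;
      Fnext[o] = (m == f) ? 0.5 * (1.0 + F[m]) : 0.0;
    }

    // transmit (fused with the allele-count pass)
    const size_t S = H.size();
    Hnext.resize(S);   // exact size: a longer scratch buffer would leak stale rows via swap
    for (size_t s = 0; s < S; ++s) {
      if ((int)Hnext[s].size() != two_n) Hnext[s].resize(two_n);
      const uint8_t* row = H[s].data();
      uint8_t* out = Hnext[s].data();
      uint64_t bits = 0; int nbits = 0;
      int t = 0;
      for (int o = 0; o < n_dip; ++o) {
        if (nbits < 2) { bits = coin.next(); nbits = 64; }
        uint8_t a = row[mother_of[o] + (int)(bits & 1)]; bits >>= 1;
        uint8_t b = row[father_of[o] + (int)(bits & 1)]; bits >>= 1;
        nbits -= 2;
        out[2 * o] = a; out[2 * o + 1] = b;
        t += a + b;
      }
      tot[s] = t;
    }
    H.swap(Hnext);
    F.assign(Fnext.begin(), Fnext.end());

    // new mutations (infinite-sites on the finite mutable set)
    if (lam > 0) {
      int nmut = (int)R::rpois(lam);
      for (int k = 0; k < nmut; ++k) {
        int idx = (int)(unif_rand() * n_mutable);
        if (idx >= n_mutable) idx = n_mutable - 1;
        int p = mut_pos[idx];
        if (seg.count(p)) continue;
        int code = 0;
        if (mut_codon[idx] > 0) {
          double u = unif_rand();
          if (mut_codon[idx] == 2) {  // mid-codon: synonymous impossible
            code = (u < p_h / (p_h + p_m)) ? 1 : 2;
          } else {
            if (u < p_h) code = 1;
            else if (u < p_h + p_m) code = 2;
            else code = 3;
          }
        }
        std::vector<uint8_t> row(two_n, 0);
        int carrier = (int)(unif_rand() * two_n);
        if (carrier >= two_n) carrier = two_n - 1;
        row[carrier] = 1;
        H.push_back(std::move(row));
        pos.push_back(p);
        cls.push_back(code);
        tot.push_back(1);
        seg.insert(p);
      }
    }

    // prune fixed / lost sites
    size_t keep = 0;
    for (size_t s = 0; s < H.size(); ++s) {
      if (tot[s] > 0 && tot[s] < two_n) {
        if (keep != s) {
          H[keep].swap(H[s]);
          pos[keep] = pos[s]; cls[keep] = cls[s]; tot[keep] = tot[s];
        }
        ++keep;
      } else if (tot[s] == 0) {
        seg.erase(pos[s]);              // lost: position free to mutate again
      } else {
        fixed_pos.push_back(pos[s]);    // fixed: record, keep blocked
        fixed_cls.push_back(cls[s]);
      }
    }
    H.resize(keep); pos.resize(keep); cls.resize(keep); tot.resize(keep);
    if (g % 128 == 0) Rcpp::checkUserInterrupt();
  }

  const int S = (int)H.size();
  IntegerMatrix hap_out(S, two_n);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < two_n; ++j) hap_out(s, j) = H[s][j];
  IntegerMatrix ped(n_dip, 2);
  for (int i = 0; i < n_dip; ++i) {
    ped(i, 0) = mother_of[i] / 2; ped(i, 1) = father_of[i] / 2;
  }
  return List::create(_["hap"] = hap_out,
                      _["pos"] = wrap(pos),
                      _["class"] = wrap(cls),
                      _["F"] = wrap(F),
                      _["pedigree"] = ped,
                      _["fixed_pos"] = wrap(fixed_pos),
                      _["fixed_class"] = wrap(fixed_cls));
  }
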