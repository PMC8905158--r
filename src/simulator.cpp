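#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Self-contained xoshiro256++ stream.  The 32-byte state travels inside the
// population state on the R side, so single-stepped and batched runs consume
// the identical stream and results are reproducible without touching R's
// global RNG.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double norm() {  // Marsaglia polar method
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    return u * std::sqrt(-2.0 * std::log(s2) / s2);
  }
};

static uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Seed a fresh 32-byte generator state from an integer seed.
// [[Rcpp::export(name = ".rng_init_cpp")]]
RawVector rng_init_cpp(int seed) {
  uint64_t x = (uint64_t)(int64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL;
  Xoshiro g;
  for (int i = 0; i < 4; ++i) g.s[i] = splitmix64(x);
  RawVector out(32);
  std::memcpy(RAW(out), g.s, 32);
  return out;
}

// One locus value after a possible Gaussian mutation step, reflected into
// [0, 1] (steps are small, one reflection suffices; clamp as a backstop).
static inline double mutate_locus(Xoshiro &g, double v, double prob, double sd) {
  if (prob > 0.0 && g.unif() < prob) {
    v += g.norm() * sd;
    if (v < 0.0) v = -v;
    if (v > 1.0) v = 2.0 - v;
    if (v < 0.0) v = 0.0;
    if (v > 1.0) v = 1.0;
  }
  return v;
}

// Advance the island-model life cycle `gens` generations:
//   reproduction (+ mutation) -> social survival -> density-dependent
//   dispersal (with transit mortality c) -> regulation to n breeders.
//
// The altruism locus is mutated at birth (it acts before survival); the
// dispersal loci and neutral marker of a juvenile are only realised if she
// survives the social stage — an equivalent reordering of the same
// per-locus mutation process that halves the work at s0 = 0.5.
// [[Rcpp::export(name = ".sim_steps_cpp")]]
List sim_steps_cpp(IntegerVector patch_of, NumericVector y_in,
                   NumericVector lo_in, NumericVector hi_in,
                   IntegerVector allele_in, int allele_next,
                   RawVector rng_state,
                   int num_patches, int n, int k, double cdisp,
                   double B, double C, double s0,
                   double mut_prob, double mut_sd, double neutral_mut,
                   double P_lo, double P_hi,
                   bool freeze_disp, bool freeze_alt,
                   int gens, int generation0, bool capture_juveniles) {
  Xoshiro g;
  if (rng_state.size() != 32) stop("corrupt RNG state");
  std::memcpy(g.s, RAW(rng_state), 32);

  const int cap = num_patches * n * k;
  int nb = patch_of.size();

  std::vector<int> bpatch(nb), ballele(nb);
  std::vector<double> by(nb), blo(nb), bhi(nb);
  for (int i = 0; i < nb; ++i) {
    bpatch[i] = patch_of[i];
    by[i] = y_in[i]; blo[i] = lo_in[i]; bhi[i] = hi_in[i];
    ballele[i] = allele_in[i];
  }

  // juvenile buffers; jy/jparent are filled at birth, the rest only for
  // survivors (prefix-compacted)
  std::vector<int> jparent(cap), jpatch(cap), jallele(cap), jdest(cap);
  std::vector<double> jy(cap), jlo(cap), jhi(cap);
  std::vector<double> msum(num_patches), Pd(num_patches), inv_m1(num_patches);
  std::vector<int> mcnt(num_patches), scnt(num_patches), ccnt(num_patches),
      coff(num_patches + 1), cidx(cap);

  const int NREC = 10;
  NumericMatrix rec(gens, NREC);
  colnames(rec) = CharacterVector::create(
      "generation", "mean_altruism", "mean_realized_dispersal",
      "mean_relative_density", "mean_norm_lo", "mean_norm_hi",
      "x_at_P1", "mu_hat", "n_breeders", "underfilled");

  IntegerVector cap_patch, cap_allele;
  bool extinct = false;
  int extinct_gen = -1, gens_done = 0;
  long underfilled_total = 0;
  const double norm_span = P_hi - P_lo;
  const double inv_span = 1.0 / norm_span;

  // lineage labels must be carried through every generation if they are
  // ever going to be read
  const bool track_neutral = neutral_mut > 0.0 || capture_juveniles;

  for (int gen = 0; gen < gens; ++gen) {
    // --- reproduction: altruism locus realised at birth ------------------
    std::fill(msum.begin(), msum.end(), 0.0);
    std::fill(mcnt.begin(), mcnt.end(), 0);
    int nj = 0;
    for (int i = 0; i < nb; ++i) {
      const int p = bpatch[i];
      const double py = by[i];
      for (int o = 0; o < k; ++o) {
        const double yy = freeze_alt ? py : mutate_locus(g, py, mut_prob, mut_sd);
        jparent[nj] = i;
        jy[nj] = yy;
        msum[p] += yy;
        ++nj;
      }
      mcnt[p] += k;
    }

    if (capture_juveniles && gen == gens - 1) {
      // neutral alleles of every juvenile born this generation (drawn
      // before viability selection, as the social neighbourhood is the
      // whole brood cohort)
      cap_patch = IntegerVector(nj);
      cap_allele = IntegerVector(nj);
      for (int j = 0; j < nj; ++j) {
        int al = ballele[jparent[j]];
        if (neutral_mut > 0.0 && g.unif() < neutral_mut) al = allele_next++;
        cap_patch[j] = bpatch[jparent[j]];
        cap_allele[j] = al;
      }
    }

    // --- social survival -------------------------------------------------
    const bool social = (B != 0.0) || (C != 0.0);
    if (social)
      for (int p = 0; p < num_patches; ++p)
        inv_m1[p] = mcnt[p] > 1 ? 1.0 / (mcnt[p] - 1) : 0.0;
    int ns = 0;
    std::fill(scnt.begin(), scnt.end(), 0);
    for (int j = 0; j < nj; ++j) {
      const int parent = jparent[j];
      const int p = bpatch[parent];
      double S = s0;
      if (social) {
        const double ybo = (msum[p] - jy[j]) * inv_m1[p];
        S = s0 - C * jy[j] + B * ybo;
        if (S < 0.0) S = 0.0;
        if (S > 1.0) S = 1.0;
      }
      if (g.unif() < S) {
        // survivor: realise the remaining heritable loci now
        double ll = mutate_locus(g, blo[parent], mut_prob, mut_sd);
        double hh = freeze_disp ? ll
                                : mutate_locus(g, bhi[parent], mut_prob, mut_sd);
        jpatch[ns] = p; jy[ns] = jy[j]; jlo[ns] = ll; jhi[ns] = hh;
        if (track_neutral) {
          int al = (capture_juveniles && gen == gens - 1)
                     ? cap_allele[j] : ballele[parent];
          if (!(capture_juveniles && gen == gens - 1) &&
              neutral_mut > 0.0 && g.unif() < neutral_mut)
            al = allele_next++;
          jallele[ns] = al;
        }
        ++scnt[p];
        ++ns;
      }
    }
    if (ns == 0) { extinct = true; extinct_gen = generation0 + gen + 1; break; }

    // --- relative density and dispersal ----------------------------------
    const double inv_mean_surv = (double)num_patches / ns;
    double sumP = 0.0;
    for (int p = 0; p < num_patches; ++p) Pd[p] = scnt[p] * inv_mean_surv;
    int attempts = 0, alive = 0;
    for (int j = 0; j < ns; ++j) {
      const int p = jpatch[j];
      sumP += Pd[p];
      double x = jlo[j] + (jhi[j] - jlo[j]) * (Pd[p] - P_lo) * inv_span;
      if (x < 0.0) x = 0.0;
      if (x > 1.0) x = 1.0;
      int dest = p;
      bool dead = false;
      if (g.unif() < x) {
        ++attempts;
        if (g.unif() < cdisp) {
          dead = true;
        } else {
          int d = (int)(g.unif() * (num_patches - 1));
          if (d >= num_patches - 1) d = num_patches - 2;
          if (d >= p) ++d;  // uniform over non-natal patches
          dest = d;
        }
      }
      if (!dead) {
        jdest[alive] = dest; jy[alive] = jy[j]; jlo[alive] = jlo[j];
        jhi[alive] = jhi[j];
        if (track_neutral) jallele[alive] = jallele[j];
        ++alive;
      }
    }
    if (alive == 0) { extinct = true; extinct_gen = generation0 + gen + 1; break; }

    // --- regulation: up to n random candidates breed per patch ------------
    std::fill(ccnt.begin(), ccnt.end(), 0);
    for (int j = 0; j < alive; ++j) ++ccnt[jdest[j]];
    coff[0] = 0;
    for (int p = 0; p < num_patches; ++p) coff[p + 1] = coff[p] + ccnt[p];
    {
      std::vector<int> fill(coff.begin(), coff.end() - 1);
      for (int j = 0; j < alive; ++j) cidx[fill[jdest[j]]++] = j;
    }
    int new_nb = 0, underfilled = 0;
    for (int p = 0; p < num_patches; ++p) {
      const int m = ccnt[p];
      if (m < n) ++underfilled;
      const int take = m < n ? m : n;
      int *ids = cidx.data() + coff[p];
      for (int t = 0; t < take; ++t) {
        int pick = t + (int)(g.unif() * (m - t));
        if (pick > m - 1) pick = m - 1;
        std::swap(ids[t], ids[pick]);
        const int j = ids[t];
        bpatch[new_nb] = p; by[new_nb] = jy[j]; blo[new_nb] = jlo[j];
        bhi[new_nb] = jhi[j];
        ballele[new_nb] = track_neutral ? jallele[j] : ballele[new_nb];
        ++new_nb;
      }
    }
    nb = new_nb;
    underfilled_total += underfilled;

    // --- per-generation record --------------------------------------------
    double sy = 0, slo = 0, shi = 0;
    for (int i = 0; i < nb; ++i) { sy += by[i]; slo += blo[i]; shi += bhi[i]; }
    const double mlo = slo / nb, mhi = shi / nb;
    rec(gen, 0) = generation0 + gen + 1;
    rec(gen, 1) = sy / nb;
    rec(gen, 2) = (double)attempts / ns;
    rec(gen, 3) = sumP / ns;
    rec(gen, 4) = mlo;
    rec(gen, 5) = mhi;
    rec(gen, 6) = mlo + (mhi - mlo) * (1.0 - P_lo) * inv_span;  // unclamped
    rec(gen, 7) = (mhi - mlo) * inv_span;
    rec(gen, 8) = nb;
    rec(gen, 9) = underfilled;
    gens_done = gen + 1;
  }

  IntegerVector out_patch(nb), out_allele(nb);
  NumericVector out_y(nb), out_lo(nb), out_hi(nb);
  for (int i = 0; i < nb; ++i) {
    out_patch[i] = bpatch[i]; out_y[i] = by[i]; out_lo[i] = blo[i];
    out_hi[i] = bhi[i]; out_allele[i] = ballele[i];
  }
  RawVector rng_out(32);
  std::memcpy(RAW(rng_out), g.s, 32);

  List out = List::create(
      _["records"] = rec, _["gens_done"] = gens_done,
      _["patch"] = out_patch, _["y"] = out_y, _["norm_lo"] = out_lo,
      _["norm_hi"] = out_hi, _["allele"] = out_allele,
      _["allele_next"] = allele_next, _["rng"] = rng_out,
      _["extinct"] = extinct, _["extinct_gen"] = extinct_gen,
      _["underfilled_total"] = (double)underfilled_total);
  if (capture_juveniles) {
    out["juvenile_patch"] = cap_patch;
    out["juvenile_allele"] = cap_allele;
  }
  return out;
}
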