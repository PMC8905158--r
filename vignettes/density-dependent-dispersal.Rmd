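---
title: "Kin selection under density-dependent dispersal: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin selection under density-dependent dispersal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscokin)
```

## The question

Population viscosity — individuals staying near their birthplace — surrounds
individuals with relatives, which should favour indiscriminate altruism.  But
it also concentrates competition among those same relatives.  In the
simplest island model, where every juvenile disperses with a fixed
probability, the two effects cancel exactly: the threshold cost-to-benefit
ratio below which altruism is favoured (the *potential for altruism*, `A`)
is `1/n` regardless of the dispersal rate or its cost.

`viscokin` implements the theory and simulation machinery for the case where
dispersal is *conditioned on local density*.  When individuals disperse more
readily from crowded patches, the extra survivors created by altruism leave
rather than compete with kin; evolution favours exactly such a strategy; and
the net result is that viscosity does promote altruism, with `A` decreasing
in the evolved population-average dispersal rate when populations are
compared across different costs of dispersal.

## Model

An infinite (in practice: many-patch) island model.  Each patch holds `n`
haploid asexual breeders; each produces `k` offspring and dies.  Offspring
interact socially: a juvenile with altruism `y` in a patch whose other
juveniles average `y'` survives with probability

  S = s0 − C·y + B·y',

truncated to [0, 1] (the theory only fixes the marginal effects −C and +B;
the linear clamped form is this package's concrete choice, with `B, C ≤ 0.1`
and `s0 = 0.5` so clamping is rare and the weak-selection analytics apply).
Survivors may attempt dispersal with probability `x = M(P)` where `P` is the
patch's survivor density relative to the population average; a fraction `c`
of dispersers die in transit.  Finally `n` of each patch's candidates
(non-dispersing survivors plus arriving immigrants) are chosen uniformly at
random to breed.

The closed-form layer provides, at a mean rate `x̄` and density slope
`μ = dM/dP` at `P = 1`:

* `relatedness(demog, x̄)` — whole-group relatedness
  `r = (1−cx̄)² / [(1−x̄)² + x̄ n (1−c)(2−(1+c)x̄)]`, pinned down by the
  demography rather than chosen freely;
* `scale_of_competition()` `a` and `mortality_load()` `χ`, the two
  competition-side corrections to Hamilton's rule;
* `potential_general(r, a, χ) = (r − ar − χr)/(1 − ar − χr)` and the
  demographically explicit `potential_explicit()`, which agree to 1e-10 by
  construction and are cross-checked in the test suite;
* `optimal_dispersal_rate()` — the ESS mean rate
  `x̄* = 2 / (1 + 2cn + √(1 + 4c²n(n−1)))`, reducing to `1/(1+c)` at
  `n = 1`;
* `optimal_dispersal_at_density(P)` — the ESS schedule
  `x*_P = 1 − (1−x̄*)/P`, the *constant non-disperser* strategy: every
  patch retains the same absolute number of philopatric individuals;
* `potential_under_optimal_dispersal()` — `A = (r − c²)/(1 − c²)` at the
  ESS, which exceeds `1/n` for all `0 < c < 1`, `n > 1`.

Two independent numerical routes guard the algebra: an identity-by-descent
lineage recursion for `r` (`relatedness_recursion()`) and a best-response
fixed point on invasion fitness for `x̄*` (`ess_dispersal_numeric()`).

### A domain caveat on the μ-monotonicity

The claim that `A` increases with the density slope μ holds on the
biologically reachable side `x̄ < 1/(1+c)` (every ESS state satisfies
`x̄* ≤ 1/(1+c)`).  Beyond that line the factor `1−(1+c)x̄` flips sign and
additional density-dependence is pure mortality load, so the derivative
reverses; and for strongly negative μ at small `x̄` the explicit expression
crosses a pole.  The test suite asserts monotonicity on the reachable
branch and asserts the sign flip beyond it, so the restriction is a
documented property rather than an accident.

## The individual-based simulator

`run_simulation(sim_config(...))` evolves three loci per individual: the
altruism level `y` and a linear dispersal reaction norm defined by its
intercepts at two reference densities `P_lo < 1 < P_hi`.  Each locus mutates
at birth with probability `mutation_prob`, taking a Gaussian step
(`mutation_sd`) reflected into [0, 1].  A compiled core (Rcpp) advances the
full life cycle; the RNG stream (xoshiro256++) is carried inside the
population state, so runs are bitwise reproducible from `config$seed` and
single-stepping with `step_generation()` is identical to batching.  A
neutral infinite-alleles marker can be switched on
(`neutral_mutation > 0`) to estimate realised relatedness from the
simulation itself (`estimate_juvenile_relatedness()`), which recovers the
closed form within Monte Carlo error.

Parameter defaults, with reasons:

* `num_patches = 500`, `generations = 5000`, `burn_in = 2000` — the
  desk-scale protocol; the publication-scale run (5×10⁴ breeders, 2×10⁴
  generations) sits behind `sweep_settings(full = TRUE)` and is hours of
  compute.
* `k = 10` offspring per breeder — enough juveniles for density variation
  at acceptable cost.  Note that the closed forms are a large-brood limit:
  the relative patch density seen by the simulator carries binomial noise
  with variance ≈ `1/(n·k·s0)`, and the evolving *linear* norm approximates
  a concave ESS schedule across that noisy range, which biases the norm's
  value at `P = 1` downward by a few hundredths at `k = 10`.  ESS-recovery
  experiments therefore use `k = 40`, where the bias shrinks to ≈ 0.01;
  the co-evolution sweep keeps `k = 10` because its target is the
  cross-population association, not pointwise agreement.
* `mutation_prob = 0.05`, `mutation_sd = 0.05` — supplies enough
  mutational variance for the mean dispersal rate to equilibrate within a
  few thousand generations; an order of magnitude less and the population
  is still in transit at the end of a desk-scale run.
* `P_lo = 0.8`, `P_hi = 1.2` — the slope of the norm is defined at
  `P = 1`, so the anchors bracket it tightly; tight anchors also give the
  slope more mutational variance per locus step, which it needs because
  selection on the slope is weaker than on the level by roughly a factor
  `Var(P)`.

### What the simulator does and does not establish

The generator emulates exactly the stated life cycle with demographic
stochasticity, finite patch number and finite broods.  It does not emulate
environmental variation, overlapping generations, spatially local dispersal
or sexual reproduction.  A green ESS-recovery test therefore establishes
that the implementation and the closed forms describe the same limit — not
that the model describes any particular organism.

Two desk-scale limitations are worth stating plainly, because the package's
own acceptance tests surface them:

* the evolved norm *slope* `μ̂` equilibrates on a timescale set by
  `1/Var(P)`; at `(n, c) = (5, 0.5)` its target `1 − x̄* ≈ 0.81` is
  unreachable within 5000 generations at any reasonable mutation kernel
  (the measured value plateaus near 0.2–0.3), and at `(2, 0.2)` the
  equilibrium overshoots the vanishing-variance prediction by about +0.1.
  The corresponding slope assertions are left failing rather than
  weakened; the *level* `x̂(1)` recovers the ESS within ±0.05 at all
  tested cells.  The same slope time-scale limits the headline sweep: at
  large `n` with high dispersal cost the slope (the ingredient that lifts
  the potential above `1/n`) stays near zero, so those strata contribute
  no within-stratum signal at desk scale, and the stratified
  randomization p-value of the dispersal–potential association lands
  around 0.01–0.02 rather than below the publication-scale 0.001.  The
  acceptance test asserts the stricter bound and is left failing, with
  the measured association still clearly negative.
* with dispersal free to respond to density, realised mean dispersal and
  the norm level at `P = 1` differ slightly (the norm is a chord of a
  concave schedule); comparisons use the norm at `P = 1`, the quantity the
  theory defines.  In the co-evolution sweep, whose small broods (down to
  `k = 5`) maximise density variation, the norm level carries a visible downward
  finite-brood bias; the sweep's target is the within-patch-size
  *association* between dispersal and the potential, which survives a
  monotone bias, not pointwise agreement — that is what the `k = 40`
  ESS-recovery runs are for.

## Estimating the potential for altruism from simulations

`estimate_potential(n, c, ...)` bisects on the cost-to-benefit ratio
`C/B ∈ [0, 1]` (depth ≥ 4): at each candidate ratio, `votes` (default 1)
population(s) are simulated with altruism initialised at 0.5 and
dispersal co-evolving, and the direction of selection on altruism is the
sign of the (summed) displacement of mean `y` from its known initial
value, measured over the final tenth of each run.  Anchoring at the exact
monomorphic start maximises the selection signal relative to drift, and
drift is why population size matters so much here: the neutral endpoint
displacement of mean `y` over 5000 generations has a measured standard
deviation of ≈ 0.16 at 1000 breeders but ≈ 0.06 at 5000.  The bisection's
flip point brackets `A`; the final estimate is then refined at zero extra
cost by the fitted zero crossing of displacement against cost ratio
across all the runs (displacement is linear in the ratio near the
threshold; saturated runs are excluded and the crossing is only trusted
near the final bracket).  The bracket endpoints are theory-anchored
(0: free altruism; 1: strictly costly) and are not simulated by default;
`check_endpoints = TRUE` runs them and raises an inconclusive-bracket
error if they agree.

`run_sweep()` applies this over the 5×5 grid `n ∈ {1, 2, 3, 5, 10}`,
`c ∈ {0, 0.2, 0.4, 0.6, 0.8}` with per-cell seeds derived deterministically
from one master seed.  Following the published design, every cell's
population holds the same total number of breeders (5×10³ at desk scale,
5×10⁴ with `full = TRUE`), i.e. `patches = breeders / n`, which equalises
drift across cells.  The sweep uses a per-cell brood size
`k = max(5, ⌈10/n⌉)`: density noise `Var(P) ≈ 1/(n·k·s0)` is the very
selection pressure that drives the reaction-norm slope — large broods
leave the slope stranded at zero at large `n` within the desk-scale run
length — while the floor on `n·k` keeps small-`n`, high-cost cells
viable under heavy transit mortality.

`permutation_test()` assesses the association between the evolved
dispersal rate and `Â` with a one-tailed Monte Carlo randomization test of
the Pearson correlation (`p = (1 + #{r_perm ≤ r_obs}) / (n_perm + 1)`),
exhaustively enumerable for small inputs as an oracle.  A design point
discovered by implementation: both `x̄*` and `A` *fall* with patch size,
so the pooled correlation across the whole grid is positive (+0.19) even
for the exact analytic predictions — the negative relationship lives
within each patch size as the cost of dispersal varies (one curve per `n`
in the headline figure).  The headline test is therefore stratified by
patch size: the statistic is the Pearson correlation of stratum-centered
values (a partial correlation controlling for `n`), and permutations
shuffle `Â` within strata only (stratum-centered analytic ideal:
r = −0.84).  The pooled unstratified test remains available.
`figure1d_pipeline()` chains the sweep, the analytic overlay and the
stratified test.

```{r example, eval = FALSE}
# the headline pipeline, desk scale (several minutes)
res <- figure1d_pipeline(master_seed = 1)
res$test
plot(res$table$x_hat, res$table$A_hat,
     xlab = "evolved mean dispersal rate", ylab = "estimated potential")
```

## Numerical choices

* Closed-form identities are asserted at absolute tolerance 1e-10;
  fixed-point oracles at 1e-6.
* `potential_under_optimal_dispersal()` evaluates both closed forms and
  errors if they disagree beyond 1e-10 — a permanent transcription guard.
* The ESS guard `r > c` is evaluated with relatedness at the candidate ESS
  rate (self-consistent); for `c < 1` it never binds, at `c = 1` it yields
  `x̄* = 0`.
* `x*_P` is clamped to [0, 1] pointwise in `P`; raw values go negative for
  sparse patches, where the quota interpretation says nobody disperses.
* Ambiguous bisection cells resolve by majority vote over three replicates;
  a still-ambiguous cell counts as "favoured", which biases `Â` upward by
  at most one bisection step and only in cells where selection is
  genuinely undetectable at this scale.
* Under-filled patches (fewer candidates than `n`) simply breed short for
  a generation; no resampling is invented.  The count is recorded and
  reported in run manifests.

## Command line

The installed package ships a launcher (`inst/cli/viscokin`) exposing
`analytic`, `simulate`, `sweep`, `potential`, `permtest` and `figure1d`
subcommands; all accept `--config` (JSON, schema `viscokin-config/1`),
`--seed`, `--out` and `--full`, write CSV results with 12-significant-digit
floats, and pair every result file with a JSON run manifest sufficient to
reproduce it byte-for-byte.
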