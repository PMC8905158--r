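#' Simulation configuration
#'
#' Assembles and validates every knob of the individual-based island-model
#' simulator.  Defaults give a desk-scale run: 500 patches, 5000
#' generations with a 2000-generation burn-in, per-locus mutation
#' probability 0.05 with Gaussian step sd 0.05 (reflected into \[0, 1\])
#' per locus — enough mutational variance for dispersal to equilibrate
#' within a few thousand generations — and a linear dispersal reaction
#' norm anchored at relative densities 0.8 and 1.2, tight around the
#' average patch so the norm's slope is a local quantity at P = 1.
#'
#' @param n Breeders per patch.
#' @param c Dispersal transit mortality in \[0, 1\].
#' @param k Offspring per breeder.
#' @param num_patches Number of patches (>= 2).
#' @param generations Generations to simulate (> `burn_in`).
#' @param burn_in Generations excluded from post-hoc summaries (>= 0).
#' @param benefit,cost,baseline Survival effects B, C and baseline s0 (see
#'   [survival_probability()]); `benefit = cost = 0` switches social
#'   selection off.
#' @param mutation_prob Per-locus mutation probability in \[0, 1\].
#' @param mutation_sd Gaussian mutational step standard deviation.
#' @param P_lo,P_hi Reference densities anchoring the reaction norm
#'   (`P_lo < 1 < P_hi`).
#' @param freeze_dispersal If `TRUE`, the two norm loci are pinned equal so
#'   dispersal evolves but is density-independent (control condition).
#' @param freeze_altruism If `TRUE`, the altruism locus never mutates.
#' @param init_altruism,init_norm Initial locus values for all founders.
#' @param neutral_mutation Infinite-alleles mutation probability of the
#'   neutral marker locus (0 disables marker turnover).
#' @param seed RNG seed used by [run_simulation()].
#'
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(n = 2, c = 0.2, num_patches = 50, generations = 100, burn_in = 20)
#' @export
sim_config <- function(n, c, k = 10L, num_patches = 500L,
                       generations = 5000L, burn_in = 2000L,
                       benefit = 0, cost = 0, baseline = 0.5,
                       mutation_prob = 0.05, mutation_sd = 0.05,
                       P_lo = 0.8, P_hi = 1.2,
                       freeze_dispersal = FALSE, freeze_altruism = FALSE,
                       init_altruism = 0.5, init_norm = 0.5,
                       neutral_mutation = 0, seed = 1L) {
  cfg <- list(n = n, c = c, k = k, num_patches = num_patches,
              generations = generations, burn_in = burn_in,
              benefit = benefit, cost = cost, baseline = baseline,
              mutation_prob = mutation_prob, mutation_sd = mutation_sd,
              P_lo = P_lo, P_hi = P_hi,
              freeze_dispersal = freeze_dispersal,
              freeze_altruism = freeze_altruism,
              init_altruism = init_altruism, init_norm = init_norm,
              neutral_mutation = neutral_mutation, seed = seed)
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A named list of configuration values.
#' @export
validate_sim_config <- function(cfg) {
  num1 <- function(key, lo = -Inf, hi = Inf, integer = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("config key `%s` must be a single number", key), call. = FALSE)
    if (integer && v != round(v))
      stop(sprintf("config key `%s` must be an integer", key), call. = FALSE)
    if (v < lo || v > hi)
      stop(sprintf("config key `%s` = %g is outside [%g, %g]", key, v, lo, hi),
           call. = FALSE)
    as.numeric(v)
  }
  flag <- function(key) {
    v <- cfg[[key]]
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      stop(sprintf("config key `%s` must be TRUE or FALSE", key), call. = FALSE)
    v
  }
  cfg$n <- as.integer(num1("n", 1, Inf, integer = TRUE))
  cfg$c <- num1("c", 0, 1)
  cfg$k <- as.integer(num1("k", 1, Inf, integer = TRUE))
  cfg$num_patches <- as.integer(num1("num_patches", 2, Inf, integer = TRUE))
  cfg$generations <- as.integer(num1("generations", 1, Inf, integer = TRUE))
  cfg$burn_in <- as.integer(num1("burn_in", 0, Inf, integer = TRUE))
  if (cfg$generations <= cfg$burn_in)
    stop("config key `generations` must exceed `burn_in`", call. = FALSE)
  cfg$benefit <- num1("benefit", 0, Inf)
  cfg$cost <- num1("cost", 0, Inf)
  cfg$baseline <- num1("baseline", 0, 1)
  if (cfg$baseline == 0)
    stop("config key `baseline` must be > 0", call. = FALSE)
  cfg$mutation_prob <- num1("mutation_prob", 0, 1)
  cfg$mutation_sd <- num1("mutation_sd", 0, Inf)
  cfg$P_lo <- num1("P_lo", 0, Inf)
  cfg$P_hi <- num1("P_hi", 0, Inf)
  if (!(cfg$P_lo < 1 && 1 < cfg$P_hi))
    stop("config keys `P_lo`, `P_hi` must bracket 1 (P_lo < 1 < P_hi)",
         call. = FALSE)
  cfg$freeze_dispersal <- flag("freeze_dispersal")
  cfg$freeze_altruism <- flag("freeze_altruism")
  cfg$init_altruism <- num1("init_altruism", 0, 1)
  cfg$init_norm <- num1("init_norm", 0, 1)
  cfg$neutral_mutation <- num1("neutral_mutation", 0, 1)
  cfg$seed <- as.integer(num1("seed", -2^31 + 1, 2^31 - 1, integer = TRUE))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> n = %d, c = %g, k = %d | %d patches x %d generations ",
    "(burn-in %d)\n  B = %g, C = %g, s0 = %g | mutation %g (sd %g) | ",
    "norm anchors [%g, %g]%s%s | seed %d\n"),
    x$n, x$c, x$k, x$num_patches, x$generations, x$burn_in,
    x$benefit, x$cost, x$baseline, x$mutation_prob, x$mutation_sd,
    x$P_lo, x$P_hi,
    if (x$freeze_dispersal) " | dispersal frozen flat" else "",
    if (x$freeze_altruism) " | altruism frozen" else "", x$seed))
  invisible(x)
}

#' Juvenile survival probability
#'
#' Linear clamped survival: `S = s0 - C*y + B*ybar_others`, truncated to
#' \[0, 1\].  Within the unclamped region the marginal effect of the
#' focal's altruism `y` is exactly `-C` and of the patch mates' (others
#' only) average `ybar_others` exactly `+B`.
#'
#' @param y Focal altruism in \[0, 1\] (vectorised).
#' @param ybar_others Average altruism of the other juveniles on the patch.
#' @param effects A [social_effects()] object.
#'
#' @return Survival probability/ies in \[0, 1\].
#' @export
survival_probability <- function(y, ybar_others, effects) {
  stopifnot(inherits(effects, "social_effects"))
  pmin(1, pmax(0, effects$baseline - effects$cost * y +
                 effects$benefit * ybar_others))
}

#' Dispersal probability from a reaction norm
#'
#' Evaluates a genome's linear dispersal reaction norm at relative patch
#' density `P`: a line through `(P_lo, norm_lo)` and `(P_hi, norm_hi)`,
#' clamped to \[0, 1\].
#'
#' @param genome A list (or data.frame row) with numeric `norm_lo` and
#'   `norm_hi` entries.
#' @param P Relative patch density (> 0; vectorised).
#' @param config A [sim_config()] supplying the anchors `P_lo`, `P_hi`.
#'
#' @return Dispersal probability/ies in \[0, 1\].
#' @export
dispersal_probability <- function(genome, P, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(!is.finite(P)) || any(P <= 0))
    stop("`P` must be > 0", call. = FALSE)
  lo <- genome$norm_lo; hi <- genome$norm_hi
  x <- lo + (hi - lo) * (P - config$P_lo) / (config$P_hi - config$P_lo)
  pmin(1, pmax(0, x))
}

#' Founding population state
#'
#' Creates a monomorphic founding population: every patch full with `n`
#' breeders carrying the configured initial locus values and a unique
#' neutral marker allele (so identity-by-descent starts at zero).
#'
#' @param config A [sim_config()].
#' @return An object of class `"population_state"`: parallel vectors
#'   `patch` (1-based), `y`, `norm_lo`, `norm_hi`, `allele`, plus the
#'   allele counter, generation number and the simulation's own RNG state
#'   (seeded from `config$seed`; R's global RNG is never touched).
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$num_patches * config$n
  structure(list(
    patch = rep(seq_len(config$num_patches), each = config$n),
    y = rep(config$init_altruism, N),
    norm_lo = rep(config$init_norm, N),
    norm_hi = rep(config$init_norm, N),
    allele = seq_len(N),
    allele_next = N + 1L,
    generation = 0L,
    underfilled_total = 0,
    rng = .rng_init_cpp(config$seed)
  ), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> generation %d, %d breeders on %d occupied patches\n",
              x$generation, length(x$patch), length(unique(x$patch))))
  invisible(x)
}

run_steps <- function(state, config, gens, capture_juveniles = FALSE) {
  res <- .sim_steps_cpp(
    as.integer(state$patch) - 1L, as.numeric(state$y),
    as.numeric(state$norm_lo), as.numeric(state$norm_hi),
    as.integer(state$allele), as.integer(state$allele_next),
    state$rng,
    config$num_patches, config$n, config$k, config$c,
    config$benefit, config$cost, config$baseline,
    config$mutation_prob, config$mutation_sd, config$neutral_mutation,
    config$P_lo, config$P_hi,
    config$freeze_dispersal, config$freeze_altruism,
    as.integer(gens), as.integer(state$generation), capture_juveniles)
  if (res$extinct)
    stop(structure(class = c("viscokin_extinction", "error", "condition"),
                   list(message = sprintf(
                          "population went extinct at generation %d",
                          res$extinct_gen),
                        call = NULL)))
  new_state <- structure(list(
    patch = res$patch + 1L, y = res$y, norm_lo = res$norm_lo,
    norm_hi = res$norm_hi, allele = res$allele,
    allele_next = res$allele_next, rng = res$rng,
    generation = state$generation + res$gens_done,
    underfilled_total = state$underfilled_total + res$underfilled_total
  ), class = "population_state")
  records <- as.data.frame(res$records)
  out <- list(state = new_state, records = records)
  if (capture_juveniles)
    out$juveniles <- data.frame(patch = res$juvenile_patch + 1L,
                                allele = res$juvenile_allele)
  out
}

#' Advance the population one generation
#'
#' Runs a single pass of the life cycle — reproduction with mutation,
#' social survival, density-dependent dispersal with transit mortality,
#' and regulation to at most `n` breeders per patch.  The RNG stream is
#' carried inside `state`, so stepping one generation at a time is
#' bitwise-identical to a batched [run_simulation()].
#'
#' @param state A [init_population()] state.
#' @param config A [sim_config()].
#'
#' @return A list with the advanced `state` and a one-row `record`
#'   data.frame (means of the evolving loci, realized dispersal fraction,
#'   relative density, reaction-norm summaries, breeder count and number
#'   of under-filled patches).
#' @export
step_generation <- function(state, config) {
  stopifnot(inherits(state, "population_state"), inherits(config, "sim_config"))
  res <- run_steps(state, config, gens = 1L)
  list(state = res$state, record = res$records)
}

#' Run a full simulation
#'
#' Founds a monomorphic population (with its own RNG stream seeded from
#' `config$seed`) and advances it `config$generations` generations.
#' Identical configurations (including seed) give bitwise-identical
#' outputs; R's global RNG is neither used nor disturbed.
#'
#' @param config A [sim_config()].
#' @param capture_juveniles If `TRUE`, also returns the patch and neutral
#'   allele of every juvenile born in the final generation (pre-survival),
#'   for relatedness estimation.
#'
#' @return An object of class `"island_sim"`: `records` (one row per
#'   generation), final `state`, the `config`, and `summary` — post-burn-in
#'   means of mean altruism, realized dispersal, the reaction norm at
#'   P = 1 (`x_at_P1`) and its slope (`mu_hat`).
#' @examples
#' sim <- run_simulation(sim_config(n = 2, c = 0.2, num_patches = 40,
#'                                  generations = 60, burn_in = 20, seed = 7))
#' sim$summary
#' @export
run_simulation <- function(config, capture_juveniles = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  state <- init_population(config)
  res <- run_steps(state, config, gens = config$generations,
                   capture_juveniles = capture_juveniles)
  records <- res$records
  post <- records[records$generation > config$burn_in, , drop = FALSE]
  summary <- list(
    mean_altruism = mean(post$mean_altruism),
    mean_realized_dispersal = mean(post$mean_realized_dispersal),
    x_at_P1 = mean(post$x_at_P1),
    mu_hat = mean(post$mu_hat),
    underfilled_total = res$state$underfilled_total
  )
  out <- list(records = records, state = res$state, config = config,
              summary = summary)
  if (capture_juveniles) out$juveniles <- res$juveniles
  structure(out, class = "island_sim")
}

#' @export
print.island_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "<island_sim> n = %d, c = %g, %d generations | post-burn-in means: ",
    "y = %.3f, x(1) = %.3f, mu = %.3f\n"),
    x$config$n, x$config$c, x$state$generation,
    x$summary$mean_altruism, x$summary$x_at_P1, x$summary$mu_hat))
  invisible(x)
}

#' Population-mean reaction norm summary
#'
#' Maps the population's mean reaction-norm loci to the coordinates of the
#' analytic theory: the mean norm evaluated at relative density P = 1
#' (before clamping) and the mean slope per unit density.
#'
#' @param state A `population_state`.
#' @param config A [sim_config()] supplying the anchors.
#'
#' @return Named numeric vector `c(x_at_P1 = ..., mu_hat = ...)`.
#' @export
summarize_reaction_norm <- function(state, config) {
  stopifnot(inherits(state, "population_state"), inherits(config, "sim_config"))
  if (length(state$patch) == 0L)
    stop("empty population", call. = FALSE)
  span <- config$P_hi - config$P_lo
  lo <- mean(state$norm_lo); hi <- mean(state$norm_hi)
  c(x_at_P1 = lo + (hi - lo) * (1 - config$P_lo) / span,
    mu_hat = (hi - lo) / span)
}

#' Estimate juvenile relatedness from the neutral marker
#'
#' F-statistic style estimator of whole-group juvenile relatedness from
#' the infinite-alleles neutral marker: with `Q_w` the probability that
#' two distinct juveniles of the same patch carry identical alleles and
#' `Q_b` the same probability for juveniles of different patches, the
#' estimator is \eqn{(Q_w - Q_b) / (1 - Q_b)}.  Requires a simulation run
#' with
#' `neutral_mutation > 0` and `capture_juveniles = TRUE`.
#'
#' @param sim An `"island_sim"` result carrying `juveniles`.
#' @return Estimated relatedness (real).
#' @export
estimate_juvenile_relatedness <- function(sim) {
  stopifnot(inherits(sim, "island_sim"))
  juv <- sim$juveniles
  if (is.null(juv))
    stop("run_simulation() must be called with capture_juveniles = TRUE",
         call. = FALSE)
  by_patch <- split(juv$allele, juv$patch)
  m_p <- as.numeric(lengths(by_patch))
  patch_tallies <- lapply(by_patch, function(a) as.numeric(table(a)))
  within_pairs <- sum(vapply(patch_tallies, function(cc) sum(cc * (cc - 1)), 0))
  within_sq <- sum(vapply(patch_tallies, function(cc) sum(cc^2), 0))
  C_a <- as.numeric(table(juv$allele))
  M <- sum(m_p)
  Qw <- within_pairs / sum(m_p * (m_p - 1))
  Qb <- (sum(C_a^2) - within_sq) / (M^2 - sum(m_p^2))
  (Qw - Qb) / (1 - Qb)
}
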