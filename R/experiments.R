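# Computational experiments: bisection estimation of the potential for
# altruism from evolving populations, the (n, c) sweep behind the headline
# figure, and the Monte Carlo randomization test of its trend.

#' Settings template for simulation experiments
#'
#' Desk-scale defaults: 500 patches, 5000 generations, 2000 burn-in,
#' benefit B = 0.1 with baseline survival 0.5 (selection weak enough for
#' the marginal analytics to apply, clamping rare).  `full = TRUE`
#' switches to the publication scale — 5e4 breeders and 2e4 generations
#' per run — which is hours of compute and not meant for routine use.
#'
#' @param full Use publication-scale population and run length.
#' @param freeze_dispersal Pin the reaction norm flat (density-independent
#'   control).
#' @param bisect_depth Number of bisection steps when estimating the
#'   potential for altruism (>= 4).
#' @param votes Replicate simulations per bisection midpoint; the
#'   selection direction is the sign of the summed altruism displacement
#'   across replicates (drift variance falls as 1/votes).
#' @param n_permutations Permutations for the randomization test.
#'
#' @return A named list of experiment settings consumed by
#'   [estimate_potential()], [run_sweep()] and [figure1d_pipeline()].
#' @export
sweep_settings <- function(full = FALSE, freeze_dispersal = FALSE,
                           bisect_depth = 4L, votes = 1L,
                           n_permutations = 1e5) {
  if (bisect_depth < 4L) stop("`bisect_depth` must be >= 4", call. = FALSE)
  list(
    # constant total breeders across cells (patches = breeders / n), the
    # published design scaled down 10x; every population then carries the
    # same drift level, so one run per bisection midpoint suffices
    num_patches = NA_integer_,
    total_breeders = if (full) 50000L else 5000L,
    generations = if (full) 20000L else 5000L,
    burn_in = if (full) 8000L else 2000L,
    # k = NA: per-cell brood size max(5, ceiling(10/n)) — keeps density
    # variation high (Var(P) ~ 1/(n k s0) is the selection pressure on the
    # norm slope) while giving each patch enough surviving juveniles that
    # small-n, high-cost cells do not go extinct
    k = NA_integer_, benefit = 0.1, baseline = 0.5,
    mutation_prob = 0.05, mutation_sd = 0.05,
    P_lo = 0.8, P_hi = 1.2,
    freeze_dispersal = freeze_dispersal,
    bisect_depth = as.integer(bisect_depth),
    votes = as.integer(votes),
    n_permutations = n_permutations,
    full = full
  )
}

# deterministic per-cell / per-run seed below 2^31, mixing a master seed
# with cell coordinates
cell_seed <- function(master, n, c, extra = 0L) {
  h <- (as.numeric(master) %% 2147483647) * 48271 +
    n * 69621 + round(c * 1000) * 16807 + extra * 30269
  as.integer(h %% 2147483563 + 1)
}

cell_config <- function(n, c, settings, seed, cost_ratio = NULL,
                        freeze_altruism = FALSE) {
  np <- settings$num_patches
  if (is.na(np)) np <- max(2L, as.integer(round(settings$total_breeders / n)))
  k <- settings$k
  if (is.na(k)) k <- max(5L, as.integer(ceiling(10 / n)))
  benefit <- settings$benefit
  cost <- if (is.null(cost_ratio)) 0 else cost_ratio * benefit
  if (is.null(cost_ratio)) benefit <- 0  # altruism neutral
  sim_config(
    n = n, c = c, k = k, num_patches = np,
    generations = settings$generations, burn_in = settings$burn_in,
    benefit = benefit, cost = cost, baseline = settings$baseline,
    mutation_prob = settings$mutation_prob, mutation_sd = settings$mutation_sd,
    P_lo = settings$P_lo, P_hi = settings$P_hi,
    freeze_dispersal = settings$freeze_dispersal,
    freeze_altruism = freeze_altruism, seed = seed)
}

# Displacement of mean altruism from its (known, monomorphic) starting
# value, measured over the final stretch of the run.  Starting from the
# exact initial value maximises the selection signal relative to drift.
altruism_displacement <- function(records, init = 0.5, tail_frac = 0.1) {
  ng <- nrow(records)
  tail_w <- records$mean_altruism[seq.int(ng - max(1L, round(ng * tail_frac)) + 1L, ng)]
  mean(tail_w) - init
}

# Direction of selection on altruism in one finished run: +1 favoured,
# -1 disfavoured, 0 ambiguous (displacement within the drift scale).
classify_direction <- function(records, init = 0.5, ambiguous_below = 0.02) {
  d <- altruism_displacement(records, init = init)
  if (abs(d) < ambiguous_below) 0L else as.integer(sign(d))
}

#' Estimate the potential for altruism from evolving populations
#'
#' Bisects on the cost-to-benefit ratio `C/B` in \[0, 1\]: at each
#' candidate ratio, `votes` replicate simulations are run with altruism
#' initialised at 0.5 and dispersal co-evolving, and the direction of
#' selection on altruism is the sign of the summed displacement of mean
#' altruism from its initial value (measured over the final tenth of each
#' run; the monomorphic start makes this the maximum-signal statistic
#' against drift).  The threshold ratio at which the direction flips is
#' the estimate `A_hat`.
#'
#' The bracket endpoints 0 (altruism free, always favoured by relatedness)
#' and 1 (altruism strictly costly to the actor with no net group gain)
#' are assumed rather than simulated by default; with
#' `check_endpoints = TRUE` they are simulated first and an
#' inconclusive-bracket error is raised if they agree.
#'
#' @param n,c Patch size and dispersal cost of the cell.
#' @param settings A [sweep_settings()] list (supplies `votes` and
#'   `bisect_depth`).
#' @param seed Master seed for the cell; all run seeds derive from it.
#' @param check_endpoints Simulate the bracket endpoints first.
#'
#' @return A list of class `"potential_estimate"`: `n`, `c`, `A_hat`,
#'   `resolution` (bisection half-width), `runs_used`, `seed`, plus
#'   `x_hat` and `mu_hat` — post-burn-in reaction-norm summaries averaged
#'   over the bisection runs.
#' @export
estimate_potential <- function(n, c, settings = sweep_settings(), seed = 1L,
                               check_endpoints = FALSE) {
  depth <- settings$bisect_depth
  votes <- if (is.null(settings$votes)) 3L else settings$votes
  runs_used <- 0L
  x_hats <- c(); mu_hats <- c()
  ratios <- c(); disps <- c()
  run_direction <- function(ratio) {
    extra_base <- as.integer(round(ratio * 10000))
    d_sum <- 0
    for (v in seq_len(votes)) {
      cfg <- cell_config(n, c, settings,
                         seed = cell_seed(seed, n, c, extra_base + v),
                         cost_ratio = ratio)
      sim <- run_simulation(cfg)
      runs_used <<- runs_used + 1L
      x_hats <<- c(x_hats, sim$summary$x_at_P1)
      mu_hats <<- c(mu_hats, sim$summary$mu_hat)
      d <- altruism_displacement(sim$records, init = cfg$init_altruism)
      ratios <<- c(ratios, ratio); disps <<- c(disps, d)
      d_sum <- d_sum + d
    }
    if (d_sum >= 0) 1L else -1L  # exact ties count as favoured
  }
  if (check_endpoints) {
    d0 <- run_direction(0); d1 <- run_direction(1)
    if (d0 == d1)
      stop("inconclusive bracket: selection direction identical at C/B = 0 and C/B = 1",
           call. = FALSE)
  }
  lo <- 0; hi <- 1
  for (i in seq_len(depth)) {
    mid <- (lo + hi) / 2
    if (run_direction(mid) > 0) lo <- mid else hi <- mid
  }
  A_hat <- (lo + hi) / 2
  # dose-response refinement at zero extra simulation cost: near the
  # threshold the displacement is linear in the cost ratio, so the fitted
  # zero crossing of d(ratio) uses the magnitudes the sign-only bisection
  # discards.  Saturated runs (|d| large) are excluded; the estimate is
  # trusted only inside the final bracket widened by one step.
  keep <- abs(disps) < 0.35
  if (sum(keep) >= 4 && length(unique(ratios[keep])) >= 2) {
    fit <- stats::lm(disps[keep] ~ ratios[keep])
    slope <- stats::coef(fit)[2]
    if (is.finite(slope) && slope < 0) {
      crossing <- -stats::coef(fit)[1] / slope
      step <- (hi - lo)
      if (is.finite(crossing) && crossing > lo - step && crossing < hi + step)
        A_hat <- min(1, max(0, crossing))
    }
  }
  structure(list(
    n = n, c = c, A_hat = as.numeric(A_hat), resolution = (hi - lo) / 2,
    runs_used = runs_used, seed = seed,
    x_hat = mean(x_hats), mu_hat = mean(mu_hats)
  ), class = "potential_estimate")
}

#' @export
print.potential_estimate <- function(x, ...) {
  cat(sprintf("<potential_estimate> n = %d, c = %g: A_hat = %.4f (+/- %.4f), %d runs\n",
              x$n, x$c, x$A_hat, x$resolution, x$runs_used))
  invisible(x)
}

#' Sweep the (patch size, dispersal cost) grid
#'
#' Runs [estimate_potential()] for every combination of `ns` and `cs`
#' (defaults give the 5 x 5 = 25-cell grid: n in 1, 2, 3, 5, 10 and c in
#' 0, 0.2, 0.4, 0.6, 0.8), with per-cell seeds derived deterministically
#' from `master_seed`.  Each record carries the evolved mean dispersal
#' rate and norm slope, the estimated potential, and the analytic ESS
#' dispersal rate and potential for reference.
#'
#' @param ns Integer vector of patch sizes.
#' @param cs Numeric vector of dispersal costs.
#' @param settings A [sweep_settings()] list.
#' @param master_seed Master seed.
#' @param progress Emit one message per finished cell.
#'
#' @return A `data.frame` with columns `n`, `c`, `x_hat`, `mu_hat`,
#'   `A_hat`, `resolution`, `xbar_star`, `A_analytic`, `seed`.
#' @export
run_sweep <- function(ns = c(1L, 2L, 3L, 5L, 10L),
                      cs = c(0, 0.2, 0.4, 0.6, 0.8),
                      settings = sweep_settings(), master_seed = 1L,
                      progress = FALSE) {
  if (!length(ns) || !length(cs)) stop("empty grid", call. = FALSE)
  grid <- expand.grid(n = as.integer(ns), c = as.numeric(cs))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n[i]; c <- grid$c[i]
    seed <- cell_seed(master_seed, n, c)
    est <- tryCatch(
      estimate_potential(n, c, settings, seed = seed),
      error = function(e) stop(sprintf("sweep cell (n = %d, c = %g) failed: %s",
                                       n, c, conditionMessage(e)), call. = FALSE))
    d <- demography(n, c)
    if (progress)
      message(sprintf("sweep cell n = %d, c = %.1f: x_hat = %.3f, A_hat = %.3f",
                      n, c, est$x_hat, est$A_hat))
    data.frame(n = n, c = c, x_hat = est$x_hat, mu_hat = est$mu_hat,
               A_hat = est$A_hat, resolution = est$resolution,
               xbar_star = optimal_dispersal_rate(d),
               A_analytic = potential_under_optimal_dispersal(d),
               seed = seed)
  })
  do.call(rbind, rows)
}

#' Monte Carlo randomization test for a negative association
#'
#' One-tailed permutation test of the Pearson correlation between paired
#' observations, against the null of no association: `A_values` is
#' randomly permuted against fixed `x_values` `n_permutations` times and
#' \deqn{p = \frac{1 + \#\{r_{perm} \le r_{obs}\}}{n_{perm} + 1}.}
#'
#' With `strata` (e.g. the patch size of each sweep cell), the statistic
#' is the Pearson correlation of the *stratum-centered* values — a partial
#' correlation controlling for stratum fixed effects — and permutations
#' shuffle `A_values` only within each stratum.  This is the relevant
#' design for the dispersal-altruism sweep: both the ESS dispersal rate
#' and the potential fall with patch size, so the pooled correlation
#' across patch sizes is positive even for the exact analytic
#' predictions; the negative relationship lives within each patch size as
#' the cost of dispersal varies.
#'
#' @param x_values,A_values Equal-length numeric vectors (length >= 3),
#'   neither constant (after stratum-centering, if `strata` is given).
#' @param n_permutations Number of random permutations.
#' @param seed RNG seed.
#' @param strata Optional vector (factor-like) of stratum labels, same
#'   length as the data.
#'
#' @return A list of class `"randomization_result"`: `statistic` (observed
#'   correlation), `p_value`, `n_permutations`, `seed`, `tail`
#'   (`"negative"`), `stratified`.
#' @export
permutation_test <- function(x_values, A_values, n_permutations = 1e5,
                             seed = 1L, strata = NULL) {
  cen <- center_perm_inputs(x_values, A_values, strata)
  set.seed(seed)
  xc <- cen$xc; ac <- cen$ac
  denom <- sqrt(sum(xc^2) * sum(ac^2))
  r_obs <- sum(xc * ac) / denom
  hits <- 0L
  if (is.null(strata)) {
    n <- length(xc)
    for (b in seq_len(n_permutations)) {
      r_b <- sum(xc * ac[sample.int(n)]) / denom
      if (r_b <= r_obs) hits <- hits + 1L
    }
  } else {
    idx <- split(seq_along(xc), cen$strata)
    perm <- seq_along(xc)
    for (b in seq_len(n_permutations)) {
      for (s in idx) perm[s] <- s[sample.int(length(s))]
      r_b <- sum(xc * ac[perm]) / denom
      if (r_b <= r_obs) hits <- hits + 1L
    }
  }
  structure(list(statistic = r_obs,
                 p_value = (1 + hits) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), tail = "negative",
                 stratified = !is.null(strata)),
            class = "randomization_result")
}

center_perm_inputs <- function(x_values, A_values, strata = NULL) {
  if (length(x_values) != length(A_values) || length(x_values) < 3L)
    stop("`x_values` and `A_values` must have equal length >= 3", call. = FALSE)
  if (!is.null(strata) && length(strata) != length(x_values))
    stop("`strata` must match the data length", call. = FALSE)
  if (is.null(strata)) {
    xc <- x_values - mean(x_values)
    ac <- A_values - mean(A_values)
  } else {
    strata <- as.factor(strata)
    xc <- x_values - stats::ave(x_values, strata)
    ac <- A_values - stats::ave(A_values, strata)
  }
  if (sum(xc^2) == 0 || sum(ac^2) == 0)
    stop("degenerate variance: a value list is constant", call. = FALSE)
  list(xc = xc, ac = ac, strata = strata)
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result> r = %.4f, one-tailed (negative) p = %.3g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Exact permutation test by full enumeration
#'
#' Enumerates every permutation (all `n!` without strata, the product of
#' per-stratum factorials with them; capped at 45000 permutations) and
#' returns the exact one-tailed (negative) p-value
#' `#\{r_perm <= r_obs\} / #perms`, the identity permutation included.
#'
#' @inheritParams permutation_test
#' @return A list with `statistic` and `p_value`.
#' @export
permutation_test_exact <- function(x_values, A_values, strata = NULL) {
  cen <- center_perm_inputs(x_values, A_values, strata)
  xc <- cen$xc; ac <- cen$ac
  denom <- sqrt(sum(xc^2) * sum(ac^2))
  r_obs <- sum(xc * ac) / denom
  idx <- if (is.null(strata)) list(seq_along(xc))
         else split(seq_along(xc), cen$strata)
  n_perm <- prod(factorial(lengths(idx)))
  if (n_perm > 45000)
    stop("exact enumeration limited to 45000 permutations (n <= 8 unstratified)",
         call. = FALSE)
  # cross the per-stratum permutation tables
  perms <- matrix(seq_along(xc), nrow = 1)
  for (s in idx) {
    sub <- all_permutations(length(s))
    expanded <- perms[rep(seq_len(nrow(perms)), each = nrow(sub)), ,
                      drop = FALSE]
    expanded[, s] <- matrix(s[sub], nrow = nrow(sub))[
      rep(seq_len(nrow(sub)), times = nrow(perms)), , drop = FALSE]
    perms <- expanded
  }
  r_all <- apply(perms, 1L, function(p) sum(xc * ac[p]) / denom)
  list(statistic = r_obs, p_value = mean(r_all <= r_obs + 1e-12))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Sweep, analytic overlay and randomization test in one call
#'
#' Runs the full pipeline behind the headline result: the (n, c) sweep,
#' the analytic ESS dispersal rate and potential for each cell, and the
#' one-tailed Monte Carlo randomization test — stratified by patch size
#' (see [permutation_test()]) — of the association between the evolved
#' dispersal rate and the estimated potential for altruism.
#'
#' @inheritParams run_sweep
#' @param out Optional output CSV path; a JSON run manifest is written
#'   alongside (see [write_results()]).
#'
#' @return A list with `table` (the sweep `data.frame`) and `test` (a
#'   `"randomization_result"`).
#' @export
figure1d_pipeline <- function(ns = c(1L, 2L, 3L, 5L, 10L),
                              cs = c(0, 0.2, 0.4, 0.6, 0.8),
                              settings = sweep_settings(), master_seed = 1L,
                              out = NULL, progress = FALSE) {
  table <- run_sweep(ns, cs, settings, master_seed, progress = progress)
  test <- permutation_test(table$x_hat, table$A_hat,
                           n_permutations = settings$n_permutations,
                           seed = cell_seed(master_seed, 97L, 0.97),
                           strata = table$n)
  if (!is.null(out)) {
    write_results(table, out, manifest = list(
      master_seed = master_seed, settings = settings,
      statistic = test$statistic, p_value = test$p_value,
      n_permutations = test$n_permutations, cell_seeds = table$seed))
  }
  list(table = table, test = test)
}
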