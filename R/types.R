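#' Island-model demography
#'
#' Structural parameters of the island model: patches of `n` haploid
#' asexual breeders, each producing `k` offspring before dying, with a
#' probability `c` that a dispersing juvenile dies in transit.
#'
#' @param n Integer, number of breeders per patch (>= 1).
#' @param c Real in \[0, 1\], probability that a disperser perishes in
#'   transit.
#' @param k Integer, offspring per breeder (>= 1); only used by the
#'   individual-based simulator, the closed-form theory takes the large-`k`
#'   limit.
#'
#' @return An object of class `"demography"`.
#' @examples
#' demography(n = 2, c = 0.2)
#' @export
demography <- function(n, c = 0, k = 10L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 1)
    stop("`c` must be a single real in [0, 1]", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("`k` must be a single integer >= 1", call. = FALSE)
  structure(list(n = as.integer(n), c = as.numeric(c), k = as.integer(k)),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("<demography> n = %d breeders/patch, c = %g dispersal cost, k = %d offspring/breeder\n",
              x$n, x$c, x$k))
  invisible(x)
}

#' Population-level dispersal regime
#'
#' Describes dispersal at the population level: the average dispersal
#' probability `mean_rate` (written x-bar in the theory) and the local
#' sensitivity of dispersal to relative patch density,
#' `density_slope` = dM/dP evaluated at P = 1.  A slope of zero is
#' density-independent dispersal; the evolutionarily stable schedule has
#' slope `1 - mean_rate`.
#'
#' @param mean_rate Real in \[0, 1\], population-average dispersal
#'   probability.
#' @param density_slope Real (may be negative), dependency of dispersal on
#'   relative patch density at the average density.
#'
#' @return An object of class `"dispersal_regime"`.
#' @examples
#' dispersal_regime(mean_rate = 0.5, density_slope = 0.3)
#' @export
dispersal_regime <- function(mean_rate, density_slope = 0) {
  if (!is.numeric(mean_rate) || length(mean_rate) != 1L || is.na(mean_rate) ||
      mean_rate < 0 || mean_rate > 1)
    stop("`mean_rate` must be a single real in [0, 1]", call. = FALSE)
  if (!is.numeric(density_slope) || length(density_slope) != 1L || is.na(density_slope))
    stop("`density_slope` must be a single finite real", call. = FALSE)
  structure(list(mean_rate = as.numeric(mean_rate),
                 density_slope = as.numeric(density_slope)),
            class = "dispersal_regime")
}

#' @export
print.dispersal_regime <- function(x, ...) {
  cat(sprintf("<dispersal_regime> mean rate x-bar = %g, density slope mu = %g\n",
              x$mean_rate, x$density_slope))
  invisible(x)
}

#' Social survival effects
#'
#' Marginal effects of altruism on juvenile survival: an actor investing
#' `y` pays a marginal survival cost `cost` (C) while conferring a marginal
#' survival benefit `benefit` (B) on each patch mate.  `baseline` is the
#' survival probability of a juvenile in a patch with no altruism
#' (simulator only; the analytics are marginal and do not need it).
#'
#' @param benefit Real > 0, marginal survival benefit B to patch mates.
#' @param cost Real > 0, marginal survival cost C to the actor.
#' @param baseline Real in (0, 1\], baseline juvenile survival s0.
#'
#' @return An object of class `"social_effects"`.
#' @examples
#' social_effects(benefit = 0.1, cost = 0.05)
#' @export
social_effects <- function(benefit, cost, baseline = 0.5) {
  if (!is.numeric(benefit) || length(benefit) != 1L || is.na(benefit) || benefit <= 0)
    stop("`benefit` must be a single real > 0", call. = FALSE)
  if (!is.numeric(cost) || length(cost) != 1L || is.na(cost) || cost <= 0)
    stop("`cost` must be a single real > 0", call. = FALSE)
  if (!is.numeric(baseline) || length(baseline) != 1L || is.na(baseline) ||
      baseline <= 0 || baseline > 1)
    stop("`baseline` must be a single real in (0, 1]", call. = FALSE)
  structure(list(benefit = as.numeric(benefit), cost = as.numeric(cost),
                 baseline = as.numeric(baseline)),
            class = "social_effects")
}

#' @export
print.social_effects <- function(x, ...) {
  cat(sprintf("<social_effects> benefit B = %g, cost C = %g, baseline s0 = %g\n",
              x$benefit, x$cost, x$baseline))
  invisible(x)
}

# internal: accept either a demography object or bare (n, c) for vectorised
# analytic work
as_demography <- function(x) {
  if (inherits(x, "demography")) return(x)
  stop("expected a `demography` object; see demography()", call. = FALSE)
}
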