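#' Whole-group relatedness in the island model
#'
#' Relatedness of a focal juvenile to the juveniles of her patch, relative
#' to the population at large, in an infinite island model with dispersal
#' cost.  Relatedness here is not a free parameter: it is pinned down by
#' the demography (`n`, `c`) and the population-average dispersal rate:
#'
#' \deqn{r = \frac{(1 - c\bar{x})^2}{(1-\bar{x})^2 +
#'   \bar{x}\, n (1-c)(2 - (1+c)\bar{x})}}
#'
#' It decreases with patch size and with the dispersal rate, and increases
#' with the cost of dispersal.
#'
#' @param demog A [demography()] object.
#' @param mean_rate Population-average dispersal probability, real in
#'   \[0, 1\] (may be a vector).
#'
#' @return Relatedness value(s) in \[0, 1\].
#' @seealso [relatedness_recursion()] for an independent lineage-recursion
#'   route to the same quantity.
#' @examples
#' relatedness(demography(n = 2, c = 0.2), mean_rate = 0.5)
#' @export
relatedness <- function(demog, mean_rate) {
  demog <- as_demography(demog)
  if (any(!is.finite(mean_rate)) || any(mean_rate < 0) || any(mean_rate > 1))
    stop("`mean_rate` must lie in [0, 1]", call. = FALSE)
  if (demog$c == 1 && any(mean_rate == 1))
    stop("relatedness is undefined at c = 1, mean_rate = 1 (degenerate denominator)",
         call. = FALSE)
  r_formula(demog$n, demog$c, mean_rate)
}

# vectorised kernel, no validation
r_formula <- function(n, c, xbar) {
  (1 - c * xbar)^2 /
    ((1 - xbar)^2 + xbar * n * (1 - c) * (2 - (1 + c) * xbar))
}

#' Scale of competition
#'
#' The extent to which a marginal increase in patch density caused by
#' altruism intensifies local competition for breeding spots:
#' \deqn{a = \frac{1-\bar{x}}{1-c\bar{x}} \cdot
#'           \frac{1-\bar{x}-\mu}{1-c\bar{x}}.}
#' It vanishes when the density slope satisfies \eqn{\mu = 1 - \bar{x}}
#' (the constant non-disperser schedule): every extra survivor disperses
#' away instead of competing with kin.
#'
#' @param regime A [dispersal_regime()] object.
#' @param c Dispersal cost in \[0, 1\].
#'
#' @return The scale of competition (real).
#' @examples
#' scale_of_competition(dispersal_regime(0.5, 0.5), c = 0.3)  # 0: annulled
#' @export
scale_of_competition <- function(regime, c) {
  stopifnot(inherits(regime, "dispersal_regime"))
  check_cxbar(c, regime$mean_rate)
  a_formula(regime$mean_rate, regime$density_slope, c)
}

a_formula <- function(xbar, mu, c) {
  ((1 - xbar) / (1 - c * xbar)) * ((1 - xbar - mu) / (1 - c * xbar))
}

#' Dispersal-mortality load
#'
#' The relative marginal increase in dispersal-related mortality caused by
#' altruism, \eqn{\chi = \mu c / (1 - c\bar{x})}: extra survivors induced
#' by altruism trigger \eqn{\mu} extra dispersal attempts, each fatal with
#' probability `c`.
#'
#' @inheritParams scale_of_competition
#' @return The load (real; zero when `c = 0` or the regime is
#'   density-independent).
#' @export
mortality_load <- function(regime, c) {
  stopifnot(inherits(regime, "dispersal_regime"))
  check_cxbar(c, regime$mean_rate)
  chi_formula(regime$mean_rate, regime$density_slope, c)
}

chi_formula <- function(xbar, mu, c) {
  mu * c / (1 - c * xbar)
}

check_cxbar <- function(c, xbar) {
  if (any(!is.finite(c)) || any(c < 0) || any(c > 1))
    stop("`c` must lie in [0, 1]", call. = FALSE)
  if (any(c * xbar >= 1))
    stop("degenerate denominator: need c * mean_rate < 1", call. = FALSE)
  invisible(TRUE)
}

#' Potential for altruism from relatedness, competition and load
#'
#' The threshold cost-to-benefit ratio `A` below which indiscriminate
#' altruism is favoured, expressed in terms of relatedness `r`, the scale
#' of competition `a` and the dispersal-mortality load `chi`:
#' \deqn{A = \frac{r - a r - \chi r}{1 - a r - \chi r}.}
#' With `chi = 0` this reduces to the classic competition-discounted form
#' \eqn{(r - ar)/(1 - ar)}.
#'
#' @param r Relatedness in \[0, 1\].
#' @param a Scale of competition.
#' @param chi Dispersal-mortality load.
#'
#' @return The potential for altruism (real).
#' @export
potential_general <- function(r, a, chi = 0) {
  den <- 1 - a * r - chi * r
  if (any(abs(den) < 1e-14))
    stop("singularity: 1 - r*(a + chi) = 0", call. = FALSE)
  (r - a * r - chi * r) / den
}

#' Potential for altruism, demographically explicit
#'
#' The potential for altruism written directly in terms of patch size,
#' dispersal cost, mean dispersal rate and density slope:
#' \deqn{A = \frac{1}{n} + \frac{n-1}{n}\,
#'   \frac{(1-(1+c)\bar{x})\,\mu}
#'        {n \bar{x}(2-(1+c)\bar{x}) + (1-(1+c)\bar{x})\,\mu}.}
#' For a density-independent regime (`density_slope = 0`) this is exactly
#' `1/n` for every dispersal rate and cost: the relatedness and
#' kin-competition consequences of viscosity cancel.  The potential
#' increases with the density slope.
#'
#' @param demog A [demography()] object.
#' @param regime A [dispersal_regime()] object (`mean_rate` and
#'   `density_slope` may be equal-length vectors).
#'
#' @return The potential for altruism (real).
#' @examples
#' potential_explicit(demography(2, 0.2), dispersal_regime(0.5, 0.3))
#' @export
potential_explicit <- function(demog, regime) {
  demog <- as_demography(demog)
  stopifnot(inherits(regime, "dispersal_regime"))
  A_explicit_formula(demog$n, demog$c, regime$mean_rate, regime$density_slope)
}

A_explicit_formula <- function(n, c, xbar, mu) {
  base <- 1 / n
  out <- rep_len(base, max(length(xbar), length(mu)))
  xbar <- rep_len(xbar, length(out))
  mu <- rep_len(mu, length(out))
  idx <- mu != 0
  if (any(idx)) {
    g <- 1 - (1 + c) * xbar[idx]
    den <- n * xbar[idx] * (2 - (1 + c) * xbar[idx]) + g * mu[idx]
    if (any(den == 0))
      stop("singularity in the demographically explicit potential (zero denominator)",
           call. = FALSE)
    out[idx] <- base + ((n - 1) / n) * g * mu[idx] / den
  }
  out
}

#' Signed Hamilton's-rule margin
#'
#' The signed left-hand side of the condition for altruism to be favoured,
#' \deqn{-C(1-c\bar{x}) + B(1-c\bar{x})r
#'  - (1-\bar{x}-\mu)\frac{1-\bar{x}}{1-c\bar{x}}(B-C)r - \mu c (B-C) r,}
#' with relatedness computed from the demography via [relatedness()].  The
#' margin is positive exactly when `cost/benefit` lies below the potential
#' for altruism [potential_explicit()].
#'
#' Its four terms are: the actor's direct survival cost, the benefit to
#' patch mates weighted by relatedness, the kin-competition consequence of
#' the extra surviving patch density, and the extra dispersal mortality
#' induced when dispersal responds to density.
#'
#' @param effects A [social_effects()] object.
#' @param demog A [demography()] object.
#' @param regime A [dispersal_regime()] object.
#'
#' @return The signed margin (real; positive when altruism is favoured).
#' @export
hamilton_margin <- function(effects, demog, regime) {
  stopifnot(inherits(effects, "social_effects"))
  demog <- as_demography(demog)
  stopifnot(inherits(regime, "dispersal_regime"))
  check_cxbar(demog$c, regime$mean_rate)
  B <- effects$benefit; C <- effects$cost
  xbar <- regime$mean_rate; mu <- regime$density_slope; c <- demog$c
  r <- relatedness(demog, xbar)
  -C * (1 - c * xbar) + B * (1 - c * xbar) * r -
    (1 - xbar - mu) * ((1 - xbar) / (1 - c * xbar)) * (B - C) * r -
    mu * c * (B - C) * r
}

#' Evolutionarily stable mean dispersal rate
#'
#' The population-average dispersal rate at the evolutionarily stable
#' density-dependent dispersal schedule:
#' \deqn{\bar{x}^* = \frac{2}{1 + 2cn + \sqrt{1 + 4c^2 n(n-1)}}}
#' provided relatedness exceeds the dispersal cost at that rate
#' (otherwise 0).  At `n = 1` this is the classic `1/(1+c)`; at `c = 0`
#' everyone disperses.  The rate decreases with both patch size and
#' dispersal cost.
#'
#' @param demog A [demography()] object.
#' @return The ESS mean dispersal rate in \[0, 1\].
#' @seealso [ess_dispersal_numeric()] for an independent numerical route.
#' @examples
#' optimal_dispersal_rate(demography(1, 0.5))  # 2/3
#' @export
optimal_dispersal_rate <- function(demog) {
  demog <- as_demography(demog)
  xstar_formula(demog$n, demog$c)
}

xstar_formula <- function(n, c) {
  x <- 2 / (1 + 2 * c * n + sqrt(1 + 4 * c^2 * n * (n - 1)))
  # guard: dispersal only pays while relatedness exceeds its cost; evaluate
  # relatedness self-consistently at the candidate ESS rate
  r <- ifelse(c == 1 & x == 1, 1, r_formula(n, c, x))
  ifelse(r > c, x, 0)
}

#' Optimal dispersal probability at a given patch density
#'
#' The ESS dispersal probability for an individual experiencing relative
#' patch density `P` is \eqn{x^*_P = 1 - (1 - \bar{x}^*)/P}, clamped to
#' \[0, 1\].  Where unclamped, the absolute number of philopatric
#' individuals \eqn{P (1 - x^*_P)} is the same on every patch — the
#' constant non-disperser principle: each patch keeps a fixed quota and
#' everyone in excess of it disperses.
#'
#' @param P Relative patch density (> 0; may be a vector).
#' @param demog A [demography()] object.
#'
#' @return Dispersal probability/ies in \[0, 1\].
#' @examples
#' optimal_dispersal_at_density(c(0.5, 1, 2), demography(2, 0.2))
#' @export
optimal_dispersal_at_density <- function(P, demog) {
  demog <- as_demography(demog)
  if (any(!is.finite(P)) || any(P <= 0))
    stop("`P` must be > 0", call. = FALSE)
  xs <- optimal_dispersal_rate(demog)
  pmin(1, pmax(0, 1 - (1 - xs) / P))
}

#' Potential for altruism under the ESS dispersal schedule
#'
#' When the dispersal reaction norm has evolved to its ESS (the constant
#' non-disperser schedule, with density slope \eqn{1 - \bar{x}^*}), kin
#' competition is abolished and the potential for altruism becomes
#' \deqn{A = \frac{1 - c \bar{x}^*}
#'            {1 + ((n-1)(2-(1+c)\bar{x}^*) - c)\,\bar{x}^*}
#'         = \frac{r - c^2}{1 - c^2},}
#' where `r` is relatedness at the ESS rate.  Both forms are evaluated and
#' must agree to 1e-10 (a transcription-error guard); for `c = 1` only the
#' first form is defined.  The result exceeds `1/n` for all `0 < c < 1`
#' and `n > 1`: under density-dependent dispersal, viscosity promotes
#' altruism.
#'
#' @param demog A [demography()] object.
#' @return The potential for altruism at the dispersal ESS.
#' @examples
#' potential_under_optimal_dispersal(demography(2, 0.2))
#' @export
potential_under_optimal_dispersal <- function(demog) {
  demog <- as_demography(demog)
  n <- demog$n; c <- demog$c
  xs <- xstar_formula(n, c)
  A_form1 <- (1 - c * xs) / (1 + ((n - 1) * (2 - (1 + c) * xs) - c) * xs)
  if (c >= 1) return(A_form1)
  r <- r_formula(n, c, xs)
  A_form2 <- (r - c^2) / (1 - c^2)
  if (abs(A_form1 - A_form2) > 1e-10)
    stop(sprintf(
      "internal inconsistency: the two closed forms for the potential under optimal dispersal disagree (%.3e)",
      abs(A_form1 - A_form2)), call. = FALSE)
  A_form1
}

#' Full analytic summary
#'
#' Evaluates every closed-form quantity at a given demography and
#' dispersal regime.  When `mean_rate` is omitted the ESS schedule is
#' used: `mean_rate = ` \eqn{\bar{x}^*} and
#' `density_slope = ` \eqn{1 - \bar{x}^*}.  When `mean_rate` is supplied
#' but `density_slope` is omitted, dispersal is taken as
#' density-independent (`density_slope = 0`).
#'
#' @param demog A [demography()] object.
#' @param mean_rate Optional mean dispersal rate(s).
#' @param density_slope Optional density slope(s).
#' @param P Relative density at which to evaluate the ESS schedule
#'   (default 1).
#'
#' @return A one-row (or vectorised) `data.frame` with columns `n`, `c`,
#'   `mean_rate`, `density_slope`, `relatedness`, `scale_of_competition`,
#'   `mortality_load`, `potential`, `optimal_mean_dispersal`,
#'   `optimal_dispersal_at_P`, `potential_at_optimum`, `P`.
#' @examples
#' analytic_summary(demography(2, 0.2))
#' @export
analytic_summary <- function(demog, mean_rate = NULL, density_slope = NULL, P = 1) {
  demog <- as_demography(demog)
  n <- demog$n; c <- demog$c
  xs <- xstar_formula(n, c)
  if (is.null(mean_rate)) {
    mean_rate <- xs
    if (is.null(density_slope)) density_slope <- 1 - xs
  } else if (is.null(density_slope)) {
    density_slope <- 0
  }
  len <- max(length(mean_rate), length(density_slope), length(P))
  mean_rate <- rep_len(mean_rate, len)
  density_slope <- rep_len(density_slope, len)
  P <- rep_len(P, len)
  check_cxbar(c, mean_rate)
  r <- r_formula(n, c, mean_rate)
  a <- a_formula(mean_rate, density_slope, c)
  chi <- chi_formula(mean_rate, density_slope, c)
  data.frame(
    n = n, c = c, mean_rate = mean_rate, density_slope = density_slope,
    relatedness = r, scale_of_competition = a, mortality_load = chi,
    potential = A_explicit_formula(n, c, mean_rate, density_slope),
    optimal_mean_dispersal = xs,
    P = P,
    optimal_dispersal_at_P = optimal_dispersal_at_density(P, demog),
    potential_at_optimum = potential_under_optimal_dispersal(demog)
  )
}
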