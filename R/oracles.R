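# Independent numerical routes to the headline closed forms.  These are
# deliberately derived from first principles (lineage probabilities and
# invasion fitness) rather than from the algebraic expressions in
# kin_analytics.R, so the two can cross-validate each other.

#' Relatedness by identity-by-descent lineage recursion
#'
#' Computes whole-group juvenile relatedness by iterating the
#' identity-by-descent recursion of the island model to its fixed point,
#' instead of evaluating the closed form.  A breeder is native to her
#' patch with probability
#' \eqn{\phi = (1-\bar{x}) / (1-c\bar{x})} (philopatric juveniles compete
#' against surviving immigrants).  Pairwise identity `G` between two
#' distinct breeders of a patch then obeys
#' \deqn{G' = \phi^2 \left(\tfrac{1}{n} + (1-\tfrac{1}{n}) G\right),}
#' and juvenile whole-group relatedness (large-`k` limit, where two random
#' patch-mate juveniles share a mother with probability `1/n`) is
#' \eqn{r = 1/n + (1 - 1/n) G}.
#'
#' @param n Breeders per patch.
#' @param c Dispersal cost in \[0, 1\].
#' @param xbar Mean dispersal rate in \[0, 1\].
#' @param tol Fixed-point convergence tolerance.
#'
#' @return Relatedness in \[0, 1\].
#' @seealso [relatedness()] for the closed form.
#' @export
relatedness_recursion <- function(n, c, xbar, tol = 1e-14) {
  stopifnot(n >= 1, c >= 0, c <= 1, xbar >= 0, xbar <= 1)
  if (c == 1 && xbar == 1)
    stop("undefined at c = 1, xbar = 1", call. = FALSE)
  phi <- (1 - xbar) / (1 - c * xbar)
  G <- 0
  repeat {
    G_new <- phi^2 * (1 / n + (1 - 1 / n) * G)
    if (abs(G_new - G) < tol) break
    G <- G_new
  }
  1 / n + (1 - 1 / n) * G_new
}

#' ESS dispersal rate by numerical best response
#'
#' Locates the evolutionarily stable mean dispersal rate as the fixed
#' point at which a rare mutant's inclusive-fitness gradient vanishes,
#' without using the closed form.  With resident rate `x`, a focal
#' juvenile playing `x_f` in a patch whose juveniles play `x_p` on average
#' has expected reproductive success
#' \deqn{W = \frac{1-x_f}{(1-x_p) + (1-c)x} + \frac{(1-c)\,x_f}{1-cx},}
#' (stay and compete against local stayers plus incoming immigrants, or
#' pay the transit cost and compete in an average patch).  The selection
#' gradient on dispersal, weighting the patch-average effect by
#' whole-group relatedness `r(x)` from [relatedness_recursion()], is
#' \deqn{D(x) = -\frac{c}{1-cx} + r(x)\,\frac{1-x}{(1-cx)^2}.}
#' The ESS solves `D(x) = 0` (interior) and is found by damped
#' best-response iteration with a bisection fallback.
#'
#' @param n Breeders per patch.
#' @param c Dispersal cost in \[0, 1\].
#' @param tol Convergence tolerance on the rate.
#' @param max_iter Iteration cap.
#'
#' @return The ESS mean dispersal rate in \[0, 1\].
#' @seealso [optimal_dispersal_rate()] for the closed form.
#' @export
ess_dispersal_numeric <- function(n, c, tol = 1e-10, max_iter = 10000L) {
  stopifnot(n >= 1, c >= 0, c <= 1)
  grad <- function(x) {
    r <- relatedness_recursion(n, c, x)
    -c / (1 - c * x) + r * (1 - x) / (1 - c * x)^2
  }
  eps <- 1e-12
  if (grad(1 - eps) >= 0) return(1)
  if (grad(eps) <= 0) return(0)
  # damped gradient-ascent iteration to the best-response fixed point
  x <- 0.5
  for (i in seq_len(max_iter)) {
    step <- 0.5 * grad(x)
    x_new <- min(1 - eps, max(eps, x + step))
    if (abs(x_new - x) < tol / 10) {
      x <- x_new
      break
    }
    x <- x_new
  }
  # polish with bisection on the gradient for guaranteed accuracy
  stats::uniroot(grad, lower = eps, upper = 1 - eps, tol = tol / 100)$root
}
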