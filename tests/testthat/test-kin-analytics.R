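# Closed-form layer: frozen example values, algebraic identities over the
# parameter grids, and equivalence with the independent numerical oracles.

test_that("relatedness matches frozen values and limits", {
  # well-mixed limit: whole-group relatedness 1/n
  expect_equal(relatedness(demography(2, 0), 1), 0.5)
  # no dispersal: clonal patch
  for (d in list(demography(1, 0.3), demography(7, 0.9), demography(3, 0)))
    expect_equal(relatedness(d, 0), 1)
  # single breeder per patch: relatedness is 1 at any dispersal rate
  expect_equal(relatedness(demography(1, 0.5), 2 / 3), 1)
  # frozen value, cross-checked against the lineage recursion oracle
  expect_equal(relatedness(demography(2, 0.2), 0.5), 0.5912409, tolerance = 1e-6)
  expect_error(relatedness(demography(2, 0.2), 1.2), "\\[0, 1\\]")
  expect_error(relatedness(demography(2, 1), 1), "degenerate")
})

test_that("relatedness closed form equals the lineage recursion oracle", {
  for (n in c(1, 2, 5, 10, 20)) for (c in c(0, 0.2, 0.5, 0.8)) {
    for (xbar in c(0.05, 0.3, 0.6, 0.95)) {
      expect_equal(relatedness(demography(n, c), xbar),
                   relatedness_recursion(n, c, xbar),
                   tolerance = 1e-12,
                   label = sprintf("r(n=%d, c=%g, xbar=%g)", n, c, xbar))
    }
  }
})

test_that("scale of competition and mortality load match frozen values", {
  expect_equal(scale_of_competition(dispersal_regime(0.5, 0.5), 0.3), 0)
  expect_equal(scale_of_competition(dispersal_regime(0.5, 0), 0), 0.25)
  expect_equal(scale_of_competition(dispersal_regime(0.5, 0.3), 0.2),
               (0.5 / 0.9) * (0.2 / 0.9), tolerance = 1e-12)
  expect_equal(mortality_load(dispersal_regime(0.7, 0), 0.4), 0)
  expect_equal(mortality_load(dispersal_regime(0.7, 0.3), 0), 0)
  expect_equal(mortality_load(dispersal_regime(0.5, 0.3), 0.2), 0.06 / 0.9,
               tolerance = 1e-12)
  expect_error(scale_of_competition(dispersal_regime(1, 0), 1), "degenerate")
})

test_that("the two routes to the potential agree and match frozen values", {
  expect_equal(potential_general(0.3, 0, 0), 0.3)
  expect_equal(potential_general(1, 0, 0.25), 1)
  d <- demography(2, 0.2)
  reg <- dispersal_regime(0.5, 0.3)
  A <- potential_explicit(d, reg)
  expect_equal(A, 0.5394737, tolerance = 1e-6)
  expect_equal(potential_general(relatedness(d, 0.5),
                                 scale_of_competition(reg, 0.2),
                                 mortality_load(reg, 0.2)),
               A, tolerance = 1e-12)
  # negative density-dependence inhibits altruism below the 1/n baseline
  expect_equal(potential_explicit(d, dispersal_regime(0.5, -0.3)), 0.453125,
               tolerance = 1e-9)
  expect_lt(potential_explicit(d, dispersal_regime(0.5, -0.3)), 1 / 2)
})

test_that("composition identity holds across the full parameter grid", {
  worst <- 0
  for (n in grid_n) {
    d <- demography(n, 0)  # c replaced in loop below via formula route
    for (c in grid_c) {
      dd <- demography(n, c)
      for (mu in grid_mu) {
        reg_A <- potential_explicit(dd, dispersal_regime(0, 0))  # warm check
        r <- relatedness(dd, grid_xbar)
        a <- sapply(grid_xbar, function(x)
          scale_of_competition(dispersal_regime(x, mu), c))
        chi <- sapply(grid_xbar, function(x)
          mortality_load(dispersal_regime(x, mu), c))
        A1 <- sapply(grid_xbar, function(x)
          potential_explicit(dd, dispersal_regime(x, mu)))
        A2 <- potential_general(r, a, chi)
        worst <- max(worst, max(abs(A1 - A2)))
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("density-independent dispersal gives A = 1/n exactly", {
  for (n in grid_n) {
    d <- demography(n, 0.4)
    A <- sapply(grid_xbar, function(x)
      potential_explicit(d, dispersal_regime(x, 0)))
    expect_true(all(A == 1 / n))
  }
  expect_identical(potential_explicit(demography(5, 0.4),
                                      dispersal_regime(0.6, 0)), 0.2)
})

test_that("potential is monotonically increasing in the density slope", {
  # the monotonic claim holds on the biologically reachable side
  # xbar < 1/(1+c); beyond it the sign of 1-(1+c)*xbar flips and extra
  # dispersal is pure mortality load.  All ESS states satisfy
  # xbar* <= 1/(1+c), with equality only at n = 1.
  for (n in c(1, 2, 5, 20)) for (c in c(0, 0.3, 0.8)) {
    d <- demography(n, c)
    for (xbar in c(0.05, 0.5, 0.8)) {
      if (xbar >= 1 / (1 + c)) next
      g <- 1 - (1 + c) * xbar
      # stay on the branch where the denominator of Eq for A is positive;
      # strongly negative mu can push it through a pole at small xbar
      mus <- grid_mu[n * xbar * (2 - (1 + c) * xbar) + g * grid_mu > 0]
      A <- sapply(mus, function(mu)
        potential_explicit(d, dispersal_regime(xbar, mu)))
      if (n == 1) expect_true(all(abs(A - 1) < 1e-12))
      else expect_true(all(diff(A) > 0),
                       label = sprintf("dA/dmu > 0 at n=%d c=%g x=%g", n, c, xbar))
    }
  }
  # above the line the derivative has the opposite sign (regression guard
  # so the domain restriction stays an informed choice, not an accident)
  d <- demography(2, 0.8)
  A_hi <- sapply(c(-0.25, 0.25), function(mu)
    potential_explicit(d, dispersal_regime(0.8, mu)))
  expect_lt(A_hi[2], A_hi[1])
})

test_that("relatedness monotonicities hold by finite differences", {
  for (c in c(0, 0.3, 0.6, 0.9)) {
    for (xbar in grid_xbar) {
      r_n <- sapply(grid_n, function(n) relatedness(demography(n, c), xbar))
      expect_true(all(diff(r_n) < 0))
    }
    for (n in c(2, 5, 20)) {
      r_x <- relatedness(demography(n, c), grid_xbar)
      expect_true(all(diff(r_x) < 0))
    }
  }
  for (n in c(1, 2, 5, 20)) for (xbar in c(0.05, 0.5, 0.95)) {
    r_c <- sapply(grid_c, function(c) relatedness(demography(n, c), xbar))
    if (n == 1) expect_true(all(abs(r_c - 1) < 1e-12))
    else expect_true(all(diff(r_c) > 0))
  }
})

test_that("hamilton margin changes sign exactly at the potential", {
  cases <- expand.grid(n = c(1, 2, 5, 10), c = c(0, 0.2, 0.6),
                       xbar = c(0.2, 0.5, 0.8), mu = c(-0.3, 0, 0.4))
  for (i in seq_len(nrow(cases))) {
    d <- demography(cases$n[i], cases$c[i])
    reg <- dispersal_regime(cases$xbar[i], cases$mu[i])
    A <- potential_explicit(d, reg)
    if (A <= 0.011 || A >= 1) next
    expect_gt(hamilton_margin(social_effects(1, max(1e-6, A - 0.01)), d, reg), 0)
    expect_lt(hamilton_margin(social_effects(1, A + 0.01), d, reg), 0)
    expect_equal(hamilton_margin(social_effects(1, A), d, reg), 0,
                 tolerance = 1e-10)
  }
  # well-mixed special case: margin reduces to -C + B/n
  expect_gt(hamilton_margin(social_effects(1, 0.4), demography(2, 0),
                            dispersal_regime(1, 0)), 0)
  expect_lt(hamilton_margin(social_effects(1, 0.6), demography(2, 0),
                            dispersal_regime(1, 0)), 0)
})

test_that("ESS dispersal rate: closed form, guard, limits, monotonicity", {
  expect_equal(optimal_dispersal_rate(demography(1, 0.5)), 2 / 3,
               tolerance = 1e-12)
  for (n in c(1, 3, 10)) expect_equal(optimal_dispersal_rate(demography(n, 0)), 1)
  expect_equal(optimal_dispersal_rate(demography(2, 0.2)), 0.6782161,
               tolerance = 1e-6)
  # Hamilton-May at n = 1 for every cost
  for (c in grid_c)
    expect_equal(optimal_dispersal_rate(demography(1, c)), 1 / (1 + c),
                 tolerance = 1e-12)
  # decreasing in n and c
  for (c in c(0.1, 0.5, 0.9)) {
    xs <- sapply(grid_n, function(n) optimal_dispersal_rate(demography(n, c)))
    expect_true(all(diff(xs) < 0))
  }
  for (n in c(1, 2, 5, 20)) {
    xs <- sapply(seq(0.05, 0.95, 0.05), function(c)
      optimal_dispersal_rate(demography(n, c)))
    expect_true(all(diff(xs) < 0))
  }
})

test_that("ESS identity (1-x*) r / (1-c x*) = c, equivalently chi*r = c^2", {
  for (n in grid_n) for (c in seq(0.05, 0.95, by = 0.05)) {
    d <- demography(n, c)
    xs <- optimal_dispersal_rate(d)
    r <- relatedness(d, xs)
    expect_equal((1 - xs) * r / (1 - c * xs), c, tolerance = 1e-10,
                 label = sprintf("ESS identity at n=%d c=%g", n, c))
    chi <- mortality_load(dispersal_regime(xs, 1 - xs), c)
    expect_equal(chi * r, c^2, tolerance = 1e-10)
  }
})

test_that("ESS schedule: increasing in P, constant non-disperser quota", {
  d <- demography(2, 0.2)
  xs <- optimal_dispersal_rate(d)
  expect_equal(optimal_dispersal_at_density(1, d), xs, tolerance = 1e-12)
  expect_equal(optimal_dispersal_at_density(2, d), 1 - (1 - xs) / 2,
               tolerance = 1e-12)
  expect_identical(optimal_dispersal_at_density(0.2, d), 0)
  expect_error(optimal_dispersal_at_density(-1, d), "> 0")
  P <- c(0.5, 1, 2, 4)
  for (n in c(1, 2, 5, 10)) for (c in c(0.1, 0.4, 0.7)) {
    dd <- demography(n, c)
    xP <- optimal_dispersal_at_density(P, dd)
    expect_true(all(diff(xP) >= 0))
    quota <- (P * (1 - xP))[xP > 0 & xP < 1]
    if (length(quota) > 1)
      expect_lt(max(abs(quota - quota[1])), 1e-12)
  }
})

test_that("potential at the dispersal ESS: both closed forms, frozen values", {
  expect_equal(potential_under_optimal_dispersal(demography(7, 0)), 1 / 7,
               tolerance = 1e-12)
  expect_equal(potential_under_optimal_dispersal(demography(1, 0.5)), 1,
               tolerance = 1e-12)
  expect_equal(potential_under_optimal_dispersal(demography(2, 0.2)),
               0.5179457, tolerance = 1e-6)
  expect_equal(potential_under_optimal_dispersal(demography(10, 0.8)),
               0.4738660, tolerance = 1e-6)
  # matches the general machinery with a annulled and chi*r = c^2
  for (n in c(2, 5, 10)) for (c in c(0.2, 0.5, 0.8)) {
    d <- demography(n, c)
    xs <- optimal_dispersal_rate(d)
    expect_equal(potential_under_optimal_dispersal(d),
                 potential_explicit(d, dispersal_regime(xs, 1 - xs)),
                 tolerance = 1e-10)
  }
})

test_that("viscosity premium and monotonicity along the optimal manifold", {
  cs <- seq(0.05, 0.95, by = 0.05)
  for (n in 2:20) {
    A <- sapply(cs, function(c) potential_under_optimal_dispersal(demography(n, c)))
    expect_true(all(A > 1 / n), label = sprintf("A > 1/n at n=%d", n))
    expect_true(all(diff(A) > 0), label = sprintf("dA/dc > 0 at n=%d", n))
  }
  for (c in cs) {
    A <- sapply(grid_n, function(n) potential_under_optimal_dispersal(demography(n, c)))
    expect_true(all(diff(A) < 0), label = sprintf("dA/dn < 0 at c=%g", c))
  }
})

test_that("ESS closed form agrees with the numerical best-response oracle", {
  for (n in c(2, 5, 10)) for (c in c(0.2, 0.5, 0.8)) {
    expect_equal(optimal_dispersal_rate(demography(n, c)),
                 ess_dispersal_numeric(n, c), tolerance = 1e-6,
                 label = sprintf("ESS oracle at n=%d c=%g", n, c))
  }
  expect_equal(ess_dispersal_numeric(3, 0), 1)
})

test_that("analytic summary assembles consistent columns", {
  d <- demography(2, 0.2)
  s <- analytic_summary(d)
  expect_equal(s$mean_rate, optimal_dispersal_rate(d))
  expect_equal(s$density_slope, 1 - s$mean_rate)
  expect_equal(s$scale_of_competition, 0, tolerance = 1e-14)
  expect_equal(s$potential, s$potential_at_optimum, tolerance = 1e-10)
  s2 <- analytic_summary(d, mean_rate = 0.5)
  expect_equal(s2$density_slope, 0)
  expect_equal(s2$potential, 0.5)
})
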