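test_that("offspring pmf container computes mean, variance and pgf", {
  pmf <- example_pmf()
  expect_equal(pmf$mean, 1.5)
  expect_equal(pmf$var, 0.45)
  expect_equal(pmf$pgf(1), 1)
  expect_equal(pmf$pgf(0), 0.1)
  expect_error(offspring_pmf(c(0.5, 0.4)), "sum to 1")
  expect_error(offspring_pmf(c(1.2, -0.2)), "nonnegative")
})

test_that("binomial thinning matches exhaustive enumeration and boundary cases", {
  pmf <- example_pmf()
  expect_equal(thinned_pmf(pmf, 0)$probs, pmf$probs)
  expect_equal(thinned_pmf(pmf, 1)$probs, c(1, 0, 0))
  expect_equal(thinned_pmf(pmf, 0.5)$probs, c(0.40, 0.45, 0.15))
  set.seed(101)
  for (i in 1:20) {
    p <- random_pmf()
    F <- runif(1)
    expect_equal(thinned_pmf(p, F)$probs, thinned_pmf_oracle(p$probs, F),
                 tolerance = 1e-12)
  }
  expect_error(thinned_pmf(pmf, 1.5), "\\[0, 1\\]")
})

test_that("thinned mean equals E[r] (1 - F) exactly (mean-thinning identity)", {
  set.seed(202)
  for (i in 1:100) {
    p <- random_pmf(8L)
    for (F in c(0, 0.25, 0.5, 0.9, 1)) {
      expect_equal(thinned_pmf(p, F)$mean, p$mean * (1 - F),
                   tolerance = 1e-12)
      expect_equal(mean_offspring(p, F), p$mean * (1 - F), tolerance = 1e-14)
    }
  }
  pmf <- example_pmf()
  expect_equal(mean_offspring(pmf, 0), 1.5)
  expect_equal(mean_offspring(pmf, 1 - 0.6647), 0.99705, tolerance = 1e-4)
  expect_equal(mean_offspring(pmf, 0.5), 0.75)
})

test_that("finite-horizon extinction recursion starts and converges correctly", {
  pmf <- example_pmf()
  expect_equal(extinction_by_generation(pmf, 0, 1), 0.1)
  expect_equal(extinction_by_generation(pmf, 0.5, 1), 0.4)  # = thinned p0
  d <- extinction_by_generation(pmf, 0, 400)
  expect_true(all(diff(d) >= 0))
  expect_equal(d[400], ultimate_extinction(pmf, 0), tolerance = 1e-10)
  # with loss the recursion converges to the modified fixed point
  d2 <- extinction_by_generation(pmf, 0.2, 600)
  expect_equal(d2[600], ultimate_extinction(pmf, 0.2), tolerance = 1e-8)
})

test_that("ultimate extinction: smallest pgf root, exact subcritical 1, monotone in F", {
  pmf <- example_pmf()
  expect_equal(ultimate_extinction(pmf, 0), 1 / 6, tolerance = 1e-10)
  # certain extinction exactly at and beyond the critical loss fraction
  expect_identical(ultimate_extinction(pmf, 1 / 3), 1)
  expect_identical(ultimate_extinction(pmf, 0.8), 1)
  # trivial case: one offspring with certainty never dies out
  expect_equal(ultimate_extinction(offspring_pmf(c(0, 1)), 0), 0)
  # independently solved quadratic root at F = 1 - S_hat(3)
  F <- 1 - modified_success(laplace_kernel(), 3.0)
  # oracle: with u = (1 - F) d + F, the fixed point d = f(u) becomes the
  # quadratic a u^2 + b u + cc = 0 in u; map the smaller root back to d
  a <- 0.6 * (1 - F); b <- 0.3 * (1 - F) - 1; cc <- 0.1 * (1 - F) + F
  u_oracle <- min((-b - sqrt(b^2 - 4 * a * cc)) / (2 * a),
                  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a))
  d_oracle <- (u_oracle - F) / (1 - F)
  expect_equal(ultimate_extinction(pmf, F), d_oracle, tolerance = 1e-9)
  expect_equal(ultimate_extinction(pmf, F), 0.856, tolerance = 2e-3)
  # monotone nondecreasing in F
  dF <- vapply(seq(0, 1, by = 0.1), function(F) ultimate_extinction(pmf, F), 0)
  expect_true(all(diff(dF) >= -1e-12))
})

test_that("modified-process extinction equals classical extinction of the thinned law", {
  set.seed(303)
  for (i in 1:15) {
    p <- random_pmf(6L)
    for (F in c(0, 0.1, 0.3, 0.6)) {
      expect_equal(ultimate_extinction(p, F),
                   ultimate_extinction(thinned_pmf(p, F), 0),
                   tolerance = 1e-10)
    }
  }
})

test_that("population extinction is d^z", {
  expect_equal(extinction_for_population(1, 50), 1)
  expect_equal(extinction_for_population(0.4, 1), 0.4)
  expect_equal(extinction_for_population(0.1^(1 / 1000), 1000), 0.1,
               tolerance = 1e-12)
  expect_error(extinction_for_population(0.5, 0), "positive integer")
})

test_that("critical retention and critical length follow the criticality condition", {
  pmf <- example_pmf()
  k <- laplace_kernel()
  expect_equal(critical_retention(pmf), 1 / 3, tolerance = 1e-12)
  expect_equal(critical_retention(offspring_pmf(c(0.5, 0.5))), 0)
  expect_equal(critical_retention(offspring_pmf(c(0.5, 0, 0, 0, 0.5))), 0.5,
               tolerance = 1e-12)  # E[r] = 2 arranged on a wider support
  L <- gw_critical_length(pmf, k)
  expect_equal(modified_success(k, L), 2 / 3, tolerance = 1e-10)
  expect_gt(L, laplace_critical_length(1.5))  # stochastic needs more habitat
  expect_error(gw_critical_length(offspring_pmf(c(0.5, 0.5)), k),
               "E\\[r\\] <= 1")
})

test_that("conservation-goal solver inverts the extinction requirement", {
  pmf <- example_pmf()
  k <- laplace_kernel()
  g <- domain_for_goal(pmf, k, z = 1000L, goal = 0.10)
  expect_equal(g$d_required, 0.1^(1 / 1000))
  expect_equal(g$F, 0.333, tolerance = 1e-3)
  expect_equal(g$L, 2.726, tolerance = 1e-3)
  # solution satisfies its defining equations
  # the ^1000 amplifies the fixed-point solver's relative error ~1000x
  expect_equal(ultimate_extinction(pmf, g$F)^1000, 0.10, tolerance = 1e-5)
  expect_equal(modified_success(k, g$L), 1 - g$F, tolerance = 1e-10)
  # independent quadratic oracle at z = 10, goal = 0.5
  d_req <- 0.5^(1 / 10)
  u <- (-0.3 + sqrt(0.09 - 2.4 * (0.1 - d_req))) / 1.2
  F_oracle <- (u - d_req) / (1 - d_req)
  g2 <- domain_for_goal(pmf, k, z = 10L, goal = 0.5)
  expect_equal(g2$F, F_oracle, tolerance = 1e-10)
  # goals below the non-spatial floor are impossible at any length
  expect_error(domain_for_goal(pmf, k, z = 2L, goal = (1 / 6)^2 * 0.9),
               "infeasible")
})

test_that("large domains recover the non-spatial branching process", {
  pmf <- example_pmf()
  k <- laplace_kernel()
  d_prev <- 1
  for (L in c(50, 200)) {
    F <- 1 - modified_success(k, L)
    d <- ultimate_extinction(pmf, F)
    expect_lt(abs(d - 1 / 6), F)   # first-order in the vanishing loss
    expect_lt(d, d_prev)           # approaches the non-spatial value from above
    d_prev <- d
  }
})
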