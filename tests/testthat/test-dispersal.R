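test_that("kernel densities are normalised, even, and have mean |u| = b", {
  for (b in c(0.5, 1, 2)) {
    k <- laplace_kernel(b)
    expect_equal(kernel_density(k, 0, 0), 1 / (2 * b))
    mass <- integrate(function(u) k$density(u), -Inf, Inf, rel.tol = 1e-10)
    expect_equal(mass$value, 1, tolerance = 1e-8)
    mad <- integrate(function(u) abs(u) * k$density(u), -Inf, Inf,
                     rel.tol = 1e-10)
    expect_equal(mad$value, b, tolerance = 1e-8)
    u <- seq(0.1, 5, by = 0.3)
    expect_equal(k$density(u), k$density(-u))
  }
  set.seed(42)
  expect_equal(mean(abs(kernel_sample(laplace_kernel(2), 2e5))), 2,
               tolerance = 0.03)
  expect_error(laplace_kernel(-1), "positive")
})

test_that("settlement probability matches its quadrature oracle and closed form", {
  k <- laplace_kernel()
  ku <- laplace_as_user_kernel()
  L <- 2.703
  # frozen oracle values (adaptive quadrature of the kernel over the domain)
  expect_equal(settlement_probability(k, L, 0), 1 - exp(-L / 2),
               tolerance = 1e-10)
  expect_equal(settlement_probability(k, L, 0), 0.7412, tolerance = 1e-4)
  expect_equal(settlement_probability(k, L, L / 2), 0.5 * (1 - exp(-L)),
               tolerance = 1e-10)
  expect_equal(settlement_probability(k, L, L / 2), 0.4665, tolerance = 1e-4)
  expect_equal(settlement_probability(k, 0, 0), 0)
  # closed form vs generic quadrature path, and evenness
  y <- seq(-L / 2, L / 2, length.out = 11)
  expect_equal(settlement_probability(k, L, y),
               settlement_probability(ku, L, y), tolerance = 1e-8)
  expect_equal(settlement_probability(k, L, y), rev(settlement_probability(k, L, -y)))
  expect_true(all(settlement_probability(k, L, y) >= 0 &
                  settlement_probability(k, L, y) <= 1))
})

test_that("S and S_hat match quadrature oracles and obey S <= S_hat, monotone in L", {
  k <- laplace_kernel()
  for (L in c(0.1, 1, 2.703, 5, 20)) {
    expect_equal(average_success(k, L), average_success_oracle(k, L),
                 tolerance = 1e-8)
    expect_equal(modified_success(k, L), modified_success_oracle(k, L),
                 tolerance = 1e-8)
    expect_lte(average_success(k, L), modified_success(k, L))
    expect_gt(average_success(k, L), 0)
    expect_lt(modified_success(k, L), 1)
  }
  Ls <- c(0.5, 1, 2, 4, 8, 16)
  S <- vapply(Ls, function(L) average_success(k, L), 0)
  Sh <- vapply(Ls, function(L) modified_success(k, L), 0)
  expect_true(all(diff(S) > 0))
  expect_true(all(diff(Sh) > 0))
  # limits: all mass retained on a huge domain, none on a vanishing one
  expect_equal(modified_success(k, 1e4), 1, tolerance = 1e-3)
  expect_lt(modified_success(k, 1e-4), 1e-3)
  expect_error(average_success(k, -1), "positive")
})

test_that("success variances are the defining integrals and are nonnegative", {
  k <- laplace_kernel()
  L <- 2.703
  v <- success_variances(k, L)
  expect_true(all(v >= 0))
  # defining integrals recomputed directly
  S <- average_success(k, L)
  Sh <- modified_success(k, L)
  s <- function(y) settlement_probability(k, L, y)
  expect_equal(unname(v["var_S"]),
               integrate(function(y) (s(y) - S)^2, -L / 2, L / 2,
                         rel.tol = 1e-10)$value, tolerance = 1e-8)
  expect_equal(unname(v["var_S_hat"]),
               integrate(function(y) (s(y)^2 / S - Sh)^2, -L / 2, L / 2,
                         rel.tol = 1e-10)$value, tolerance = 1e-8)
  expect_equal(unname(success_variances(k, L, normalized = TRUE)),
               unname(v) / L)
  # a near-uniform settlement profile has near-zero variance: a very
  # short-ranged kernel retains everything except within b of the edges
  ksh <- dispersal_kernel(function(u) dnorm(u, sd = 0.01),
                          function(n) rnorm(n, sd = 0.01), b = 0.01)
  expect_lt(success_variances(ksh, 2)[["var_S"]], 0.01)
})

test_that("the reference variance closed form is consistent with quadrature at desk precision", {
  # the reference b = 1 expression for N * Var(A-bar) tracks the
  # un-normalised integral of the variance of s(y)^2/S (not a 1/L-scaled
  # variance); it carries small typographical slips, so quadrature is
  # authoritative and the expression is checked only loosely here
  k <- laplace_kernel()
  L <- 2.703
  S <- average_success(k, L)
  reference <- 7 / 2 + (S^2 - 2 + S^-2 - exp(-L)) * L - 269 / (96 * S^2) -
    4 / exp(L) + 1 / (2 * exp(2 * L)) + 3 * L / (S^2 * exp(L)) +
    3 * L / (8 * S^2 * exp(2 * L)) + 5 / (4 * S^2 * exp(L)) +
    3 / (2 * S^2 * exp(2 * L)) + 1 / (12 * S^2 * exp(3 * L)) -
    1 / (32 * S^2 * exp(4 * L))
  expect_equal(success_variances(k, L)[["var_S_hat"]], reference,
               tolerance = 5e-3)
})

test_that("inverting the modified success recovers domain lengths", {
  k <- laplace_kernel()
  for (L in c(0.5, 2.722, 7)) {
    expect_equal(invert_modified_success(k, modified_success(k, L)), L,
                 tolerance = 1e-8)
  }
  expect_equal(invert_modified_success(k, 2 / 3), 2.722, tolerance = 1e-3)
  expect_equal(invert_modified_success(k, 0.667), 2.726, tolerance = 5e-3)
  expect_error(invert_modified_success(k, 1.2), "between 0 and 1")
  expect_error(invert_modified_success(k, 0), "between 0 and 1")
})

test_that("IDE eigenvalue critical length matches the Laplace dispersion relation", {
  k <- laplace_kernel()
  for (r in c(1.1, 1.5, 2, 5)) {
    expect_equal(ide_critical_length(k, r, nodes = 200),
                 laplace_critical_length(r), tolerance = 1e-4)
  }
  # r -> infinity: ever less habitat needed
  Lr <- vapply(c(1.5, 2, 5, 20), function(r) laplace_critical_length(r), 0)
  expect_true(all(diff(Lr) < 0))
  expect_error(ide_critical_length(k, 0.9), "r <= 1")
})

test_that("critical length is stable under grid refinement", {
  k <- laplace_kernel()
  L1 <- ide_critical_length(k, 1.5, nodes = 200, extrapolate = FALSE)
  L2 <- ide_critical_length(k, 1.5, nodes = 400, extrapolate = FALSE)
  expect_lt(abs(L2 - L1), 1e-3)
  L2b <- ide_critical_length(k, 1.5, nodes = 400, extrapolate = TRUE)
  expect_lt(abs(L2b - L2), 1e-3)
  # eigenvalue itself is increasing in L and crosses 1 at the critical point
  expect_lt(ide_dominant_eigenvalue(k, 1.5, 2.0), 1)
  expect_gt(ide_dominant_eigenvalue(k, 1.5, 3.5), 1)
})
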