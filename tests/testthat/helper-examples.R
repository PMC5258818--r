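# Shared fixtures: the demographic and environmental worked examples, and
# quadrature oracles that deliberately avoid the package's closed forms.

example_pmf <- function() offspring_pmf(c(0.1, 0.3, 0.6))

example_ensemble <- function() {
  environment_ensemble(
    h = c(0.4, 0.4, 0.2),
    pmfs = list(offspring_pmf(c(0.1, 0.2, 0.7)),
                offspring_pmf(c(0.1, 0.3, 0.6)),
                offspring_pmf(c(0.2, 0.3, 0.5))))
}

# a Laplace kernel registered as a user kernel, so that every dispersal
# computation on it goes through the generic quadrature path
laplace_as_user_kernel <- function(b = 1) {
  dispersal_kernel(
    density = function(u) exp(-abs(u) / b) / (2 * b),
    sampler = function(n) stats::rexp(n, 1 / b) * sample(c(-1, 1), n, TRUE),
    b = b, family = "user-laplace")
}

# independent settlement-probability oracle: direct quadrature of the
# kernel density over the domain, split at the source position where
# kernels like the Laplace have a derivative kink
settlement_oracle <- function(kernel, L, y) {
  vapply(y, function(yi) {
    stats::integrate(function(x) kernel$density(x - yi), -L / 2, yi,
                     rel.tol = 1e-12)$value +
      stats::integrate(function(x) kernel$density(x - yi), yi, L / 2,
                       rel.tol = 1e-12)$value
  }, 0)
}

# independent average-success oracles: the outer integral uses fixed
# Gauss-Legendre nodes (the integrand is smooth, so 200 nodes give ~1e-12)
# because adaptive integrate() trips its roundoff detector when fed an
# integrand that is itself an inner quadrature
gl_outer <- function(f, L) {
  gl <- pracma::gaussLegendre(200, -L / 2, L / 2)
  sum(gl$w * f(gl$x))
}

average_success_oracle <- function(kernel, L) {
  gl_outer(function(y) settlement_oracle(kernel, L, y), L) / L
}

modified_success_oracle <- function(kernel, L) {
  S <- average_success_oracle(kernel, L)
  gl_outer(function(y) settlement_oracle(kernel, L, y)^2, L) / (L * S)
}

# exhaustive-enumeration oracle for the dispersal-thinned offspring law:
# for each parental count v, enumerate all 2^v survival outcomes
thinned_pmf_oracle <- function(probs, F) {
  K <- length(probs) - 1L
  out <- numeric(K + 1L)
  for (v in 0:K) {
    if (probs[v + 1L] == 0) next
    if (v == 0L) { out[1L] <- out[1L] + probs[1L]; next }
    outcomes <- expand.grid(rep(list(c(0L, 1L)), v))  # 1 = survived
    for (i in seq_len(nrow(outcomes))) {
      surv <- sum(outcomes[i, ])
      w <- prod(ifelse(outcomes[i, ] == 1L, 1 - F, F))
      out[surv + 1L] <- out[surv + 1L] + probs[v + 1L] * w
    }
  }
  out
}

# random finite offspring pmf for property-style checks
random_pmf <- function(max_support = 5L) {
  k <- sample(2:max_support, 1L)
  p <- stats::runif(k)
  offspring_pmf(p / sum(p))
}
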