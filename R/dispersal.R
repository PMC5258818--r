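#' Settlement probability and dispersal success
#'
#' For an individual at position `y` inside the symmetric domain
#' `[-L/2, L/2]`, the settlement probability
#' `s(y) = integral of k(x, y) over the domain` is the chance that one
#' dispersal event ends inside the domain. Averaging `s(y)` over a uniform
#' population gives the average dispersal success
#' `S = (1/L) integral of s(y)`; reweighting by `s(y) / S` — the idea being
#' that the settled population itself concentrates where dispersal success
#' is high — gives the modified dispersal success
#' `S_hat = (1/(L S)) integral of s(y)^2`, which satisfies
#' `S <= S_hat` for symmetric kernels and is the retention approximation
#' used throughout the stochastic models in this package.
#'
#' For the Laplace kernel every quantity has a closed form;
#' user-supplied kernels are handled by adaptive quadrature. Closed forms
#' and quadrature agree to the quadrature tolerance (1e-10).
#'
#' @param kernel a [dispersal_kernel()].
#' @param L positive domain length, in units of the mean dispersal distance.
#' @param y position(s) in the domain (vectorised).
#' @return `settlement_probability`: `s(y)` in `[0, 1]`.
#'   `average_success` and `modified_success`: scalars in `[0, 1]`.
#' @examples
#' k <- laplace_kernel()
#' settlement_probability(k, L = 2.703, y = 0)
#' average_success(k, L = 2.703)
#' modified_success(k, L = 2.703)   # 0.6647
#' @export
settlement_probability <- function(kernel, L, y) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  check_length(L, allow_zero = TRUE)
  if (L == 0) return(rep(0, length(y)))
  if (kernel$family == "laplace") {
    b <- kernel$b
    return(1 - 0.5 * exp(-(L / 2 - y) / b) - 0.5 * exp(-(L / 2 + y) / b))
  }
  vapply(y, function(yi) {
    stats::integrate(function(x) kernel$density(x - yi), -L / 2, L / 2,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, 0)
}

#' @rdname settlement_probability
#' @export
average_success <- function(kernel, L) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  check_length(L)
  if (kernel$family == "laplace") {
    b <- kernel$b
    return(1 - (b / L) * (1 - exp(-L / b)))
  }
  stats::integrate(function(y) settlement_probability(kernel, L, y),
                   -L / 2, L / 2, rel.tol = 1e-10)$value / L
}

#' @rdname settlement_probability
#' @param closed_form for the Laplace family, use the analytic expression
#'   (default) rather than quadrature; ignored for other kernels.
#' @export
modified_success <- function(kernel, L, closed_form = TRUE) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  check_length(L)
  if (kernel$family == "laplace" && closed_form)
    return(shat_laplace(L, kernel$b))
  S <- average_success(kernel, L)
  if (S <= 0) stop("domain too small: average dispersal success is zero",
                   call. = FALSE)
  stats::integrate(function(y) settlement_probability(kernel, L, y)^2,
                   -L / 2, L / 2, rel.tol = 1e-10)$value / (L * S)
}

# Analytic modified dispersal success for the Laplace kernel. Written with
# exp(-L/b) factors so it is stable for large L (the textbook form with
# exp(+2L/b) overflows beyond L/b ~ 700).
shat_laplace <- function(L, b = 1) {
  E <- exp(-L / b)
  # numerator/denominator of the closed form, multiplied through by e^{-2L/b}
  num <- 2 * L * E - b * E^2 + 4 * L + 8 * b * E - 7 * b
  den <- 4 * (b * E + L - b)
  num / den
}

#' Variability of dispersal success over the domain
#'
#' The spread of the settlement probability `s(y)` (and of its
#' success-weighted counterpart `s(y)^2 / S`) over the domain drives the
#' generation-to-generation variance of the realised retained fraction in
#' the population-level model. Both quantities are returned as the plain
#' integrals `sigma_S^2 = integral (s(y) - S)^2 dy` and
#' `sigma_Shat^2 = integral (s(y)^2 / S - S_hat)^2 dy`; set
#' `normalized = TRUE` to divide each by `L`, which is the mean-square
#' deviation of a uniformly located individual.
#'
#' @inheritParams settlement_probability
#' @param normalized divide both integrals by `L`.
#' @return named numeric vector with elements `var_S` and `var_S_hat`.
#' @export
success_variances <- function(kernel, L, normalized = FALSE) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  check_length(L)
  S <- average_success(kernel, L)
  if (S <= 0) stop("domain too small: average dispersal success is zero",
                   call. = FALSE)
  Shat <- modified_success(kernel, L)
  s <- function(y) settlement_probability(kernel, L, y)
  vS <- stats::integrate(function(y) (s(y) - S)^2, -L / 2, L / 2,
                         rel.tol = 1e-10)$value
  vShat <- stats::integrate(function(y) (s(y)^2 / S - Shat)^2, -L / 2, L / 2,
                            rel.tol = 1e-10)$value
  out <- c(var_S = vS, var_S_hat = vShat)
  if (normalized) out <- out / L
  out
}

#' @rdname success_variances
#' @return `dispersal_success` bundles the whole per-domain summary:
#'   the settlement function, `S`, `S_hat` and both variances, as an object
#'   of class `"dispersal_success"`.
#' @export
dispersal_success <- function(kernel, L, normalized = FALSE) {
  v <- success_variances(kernel, L, normalized = normalized)
  structure(list(kernel = kernel, L = L,
                 settlement = function(y) settlement_probability(kernel, L, y),
                 S = average_success(kernel, L),
                 S_hat = modified_success(kernel, L),
                 var_S = unname(v["var_S"]),
                 var_S_hat = unname(v["var_S_hat"]),
                 normalized = normalized),
            class = "dispersal_success")
}

#' @export
print.dispersal_success <- function(x, ...) {
  cat(sprintf("Dispersal success on [-L/2, L/2], L = %g (%s kernel, b = %g)\n",
              x$L, x$kernel$family, x$kernel$b))
  cat(sprintf("  S = %.6f, S_hat = %.6f\n", x$S, x$S_hat))
  cat(sprintf("  var_S = %.6g, var_S_hat = %.6g%s\n", x$var_S, x$var_S_hat,
              if (x$normalized) " (per unit length)" else ""))
  invisible(x)
}

#' Invert the modified dispersal success for a domain length
#'
#' `S_hat(L)` is strictly increasing in `L` with limits 0 and 1, so for any
#' target retention in `(0, 1)` there is a unique domain length achieving
#' it. This inversion is the final step of every critical-domain-size
#' computation in the branching-process models: criticality fixes the
#' required retained fraction `1 - F`, and the domain must be long enough
#' that `S_hat(L)` reaches it.
#'
#' @inheritParams settlement_probability
#' @param target required modified dispersal success, strictly between 0
#'   and 1.
#' @param tol absolute tolerance on `S_hat(L) - target`.
#' @return the domain length `L` with `S_hat(L) = target`.
#' @examples
#' invert_modified_success(laplace_kernel(), 2 / 3)    # about 2.722
#' @export
invert_modified_success <- function(kernel, target, tol = 1e-12) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0 || target >= 1)
    stop("'target' retention must lie strictly between 0 and 1", call. = FALSE)
  f <- function(L) modified_success(kernel, L) - target
  lo <- 1e-6 * kernel$b
  hi <- 100 * kernel$b
  while (f(hi) < 0 && hi < 1e6 * kernel$b) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-14, f.lower = f(lo), f.upper = f(hi),
                 maxiter = 2000)$root
}

check_length <- function(L, allow_zero = FALSE) {
  ok <- is.numeric(L) && length(L) == 1L && is.finite(L) &&
    (L > 0 || (allow_zero && L == 0))
  if (!ok) stop("domain length 'L' must be a positive number", call. = FALSE)
  invisible(L)
}
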