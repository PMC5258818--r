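#' Dispersal-thinned offspring law
#'
#' In the spatially implicit branching process each offspring, after being
#' produced, independently leaves the domain (and dies) with probability
#' `F`. The offspring law of survivors is the binomial thinning
#' `p_tilde_q = sum over v >= q of C(v, q) p_v (1 - F)^q F^(v - q)`,
#' and its mean is exactly `E[r] (1 - F)`: thinning rescales the mean by
#' the retained fraction.
#'
#' @param pmf an [offspring_pmf()].
#' @param F probability in `[0, 1]` that an offspring settles outside the
#'   domain and is lost.
#' @return `thinned_pmf`: an [offspring_pmf()] for the post-dispersal
#'   offspring count. `mean_offspring`: the effective mean
#'   `xi = E[r] (1 - F)`.
#' @examples
#' thinned_pmf(offspring_pmf(c(0.1, 0.3, 0.6)), F = 0.5)$probs  # 0.40 0.45 0.15
#' mean_offspring(offspring_pmf(c(0.1, 0.3, 0.6)), F = 0)       # 1.5
#' @export
thinned_pmf <- function(pmf, F) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  check_F(F)
  K <- max(pmf$support)
  probs <- vapply(0:K, function(q) {
    v <- q:K
    sum(pmf$probs[v + 1L] * stats::dbinom(q, size = v, prob = 1 - F))
  }, 0)
  offspring_pmf(probs)
}

#' @rdname thinned_pmf
#' @export
mean_offspring <- function(pmf, F) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  check_F(F)
  pmf$mean * (1 - F)
}

#' Extinction probabilities of the modified Galton-Watson process
#'
#' A Galton-Watson process with offspring pgf `f` and post-reproduction
#' dispersal loss `F` has finite-horizon lineage extinction probabilities
#' given by the recursion `d_n = f((1 - F) d_{n-1} + F)` with `d_0 = 0`;
#' `F = 0` recovers the classical `d_n = f(d_{n-1})`. The ultimate
#' extinction probability `d` is the smallest root in `[0, 1]` of
#' `d = f((1 - F) d + F)`, reached monotonically by iterating from 0.
#' Since the effective mean is `xi = E[r] (1 - F)`, the process is
#' supercritical (`d < 1`) exactly when `E[r] (1 - F) > 1`; subcritical and
#' critical processes go extinct almost surely and `d = 1` is returned
#' exactly in that case rather than iterated toward.
#'
#' For an initial population of `z` independent lineages the probability
#' that all are extinct is `d^z` ([extinction_for_population()]).
#'
#' @inheritParams thinned_pmf
#' @param n horizon: number of generations.
#' @param tol convergence tolerance for the fixed-point iteration.
#' @return `extinction_by_generation`: numeric vector `d_1, ..., d_n`.
#'   `ultimate_extinction`: scalar `d` in `[0, 1]`.
#' @examples
#' pmf <- offspring_pmf(c(0.1, 0.3, 0.6))
#' ultimate_extinction(pmf, F = 0)        # 1/6
#' extinction_by_generation(pmf, F = 0.3, n = 5)
#' @export
extinction_by_generation <- function(pmf, F, n) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  check_F(F)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  d <- numeric(n)
  prev <- 0
  for (k in seq_len(n)) {
    prev <- pmf$pgf((1 - F) * prev + F)
    d[k] <- prev
  }
  d
}

#' @rdname extinction_by_generation
#' @export
ultimate_extinction <- function(pmf, F = 0, tol = 1e-12) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  check_F(F)
  if (mean_offspring(pmf, F) <= 1) {
    # the trivial case p_1 = 1 (after thinning) keeps the line alive forever
    if (F == 0 && isTRUE(all.equal(pmf$probs[2], 1)) &&
        length(pmf$probs) >= 2) return(0)
    return(1)
  }
  d <- 0
  for (i in seq_len(100000L)) {
    d_new <- pmf$pgf((1 - F) * d + F)
    if (abs(d_new - d) < tol) return(d_new)
    d <- d_new
  }
  d
}

#' @rdname extinction_by_generation
#' @param d lineage extinction probability in `[0, 1]`.
#' @param z initial population size (number of independent lineages).
#' @export
extinction_for_population <- function(d, z) {
  if (!is.numeric(d) || any(d < 0 | d > 1))
    stop("'d' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z))
    stop("'z' must be a positive integer", call. = FALSE)
  d^z
}

#' Criticality and critical domain size under demographic stochasticity
#'
#' The modified branching process is critical when
#' `E[r] (1 - F) = 1`, so the largest sustainable loss fraction is
#' `F* = 1 - 1 / E[r]` (zero if `E[r] <= 1`: such a population cannot
#' persist even without dispersal loss). Identifying the retained fraction
#' with the modified dispersal success, `1 - F = S_hat(L)`, turns the
#' criticality condition into a critical domain length: the `L` with
#' `S_hat(L) = 1 / E[r]`. Below that length ultimate extinction is certain;
#' above it the extinction probability drops below one.
#'
#' @inheritParams thinned_pmf
#' @param kernel a [dispersal_kernel()].
#' @return `critical_retention`: `F*` in `[0, 1]`.
#'   `gw_critical_length`: the critical domain length.
#' @examples
#' pmf <- offspring_pmf(c(0.1, 0.3, 0.6))
#' critical_retention(pmf)               # 1/3
#' gw_critical_length(pmf, laplace_kernel())  # about 2.722
#' @export
critical_retention <- function(pmf) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  max(0, 1 - 1 / pmf$mean)
}

#' @rdname critical_retention
#' @export
gw_critical_length <- function(pmf, kernel) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  if (pmf$mean <= 1)
    stop("no finite critical length: mean offspring number E[r] <= 1",
         call. = FALSE)
  invert_modified_success(kernel, 1 / pmf$mean)
}

#' Domain size for a conservation goal
#'
#' Rather than asking merely for persistence, fix an acceptable ultimate
#' extinction probability `goal` for an initial population of `z`
#' independent lineages. Each lineage must then satisfy
#' `d <= goal^(1/z)`; solving the fixed-point equation
#' `d = f((1 - F) d + F)` for the loss fraction `F` that makes this `d`
#' the ultimate extinction probability, and inverting the modified
#' dispersal success at retention `1 - F`, gives the required domain
#' length.
#'
#' The equation is solved for `u = (1 - F) d + F` as `f(u) = d` on
#' `[d, 1]` (where `f` is increasing), then `F = (u - d) / (1 - d)`. A goal
#' below `d0^z`, where `d0` is the loss-free extinction probability, is
#' infeasible at any domain length.
#'
#' @inheritParams critical_retention
#' @param z initial population size.
#' @param goal required ultimate extinction probability for the whole
#'   population, in `(0, 1)`.
#' @return list with `d_required` (per-lineage extinction probability),
#'   `F` (allowable loss fraction) and `L` (domain length with
#'   `S_hat(L) = 1 - F`).
#' @examples
#' domain_for_goal(offspring_pmf(c(0.1, 0.3, 0.6)), laplace_kernel(),
#'                 z = 1000, goal = 0.10)
#' @export
domain_for_goal <- function(pmf, kernel, z, goal) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  if (!is.numeric(goal) || length(goal) != 1L || goal <= 0 || goal >= 1)
    stop("'goal' must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z))
    stop("'z' must be a positive integer", call. = FALSE)
  d0 <- ultimate_extinction(pmf, F = 0)
  if (goal <= d0^z)
    stop(sprintf(paste0("goal %.4g is infeasible: even without dispersal ",
                        "loss the extinction probability is %.6g^%d = %.4g"),
                 goal, d0, z, d0^z), call. = FALSE)
  d_req <- goal^(1 / z)
  f <- pmf$pgf
  u <- stats::uniroot(function(u) f(u) - d_req, c(d_req, 1),
                      tol = 1e-15)$root
  F <- (u - d_req) / (1 - d_req)
  F <- min(max(F, 0), 1)
  list(d_required = d_req, F = F,
       L = invert_modified_success(kernel, 1 - F))
}

check_F <- function(F) {
  if (!is.numeric(F) || length(F) != 1L || !is.finite(F) || F < 0 || F > 1)
    stop("loss fraction 'F' must lie in [0, 1]", call. = FALSE)
  invisible(F)
}
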