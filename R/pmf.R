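#' Offspring probability mass functions
#'
#' The reproductive law of a single individual over one generation: `probs`
#' is the finite vector `p_0, p_1, ..., p_imax`, where `p_i` is the
#' probability of producing `i` (female) offspring. Parental survival is
#' folded into the offspring count, so `p_0` means no offspring and no
#' surviving parent. The support is finite by assumption (some maximum
#' biologically possible number of offspring).
#'
#' @param probs numeric vector of probabilities for 0, 1, ..., length(probs) - 1
#'   offspring; must be nonnegative and sum to one.
#' @return an object of class `"offspring_pmf"` with fields `probs`,
#'   `support` (0-based counts), `mean` (`xi = E[r]`), `var` (`sigma_r^2`)
#'   and `pgf`, the probability generating function
#'   `f(s) = sum_i p_i s^i` on `[0, 1]`.
#' @examples
#' pmf <- offspring_pmf(c(0.1, 0.3, 0.6))
#' pmf$mean    # 1.5
#' pmf$var     # 0.45
#' pmf$pgf(1)  # 1
#' @export
offspring_pmf <- function(probs) {
  if (!is.numeric(probs) || length(probs) < 1L || anyNA(probs))
    stop("'probs' must be a numeric vector", call. = FALSE)
  if (any(probs < 0))
    stop("offspring probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-8)
    stop("offspring probabilities must sum to 1", call. = FALSE)
  probs <- probs / sum(probs)   # remove rounding dust
  support <- seq_along(probs) - 1L
  xi <- sum(support * probs)
  sigma2 <- sum(support^2 * probs) - xi^2
  pgf <- function(s) vapply(s, function(si) sum(probs * si^support), 0)
  structure(list(probs = probs, support = support, mean = xi,
                 var = sigma2, pgf = pgf),
            class = "offspring_pmf")
}

#' @rdname offspring_pmf
#' @param pmf an `offspring_pmf`.
#' @param n number of offspring-count draws.
#' @export
pmf_sample <- function(pmf, n) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  sample(pmf$support, n, replace = TRUE, prob = pmf$probs)
}

#' @export
print.offspring_pmf <- function(x, ...) {
  cat("Offspring pmf on 0..", max(x$support), ": ",
      paste(signif(x$probs, 4), collapse = ", "), "\n", sep = "")
  cat(sprintf("  mean xi = %g, variance = %g\n", x$mean, x$var))
  invisible(x)
}

#' Ensembles of environmental states
#'
#' Environmental stochasticity is modelled by an iid sequence of
#' environmental states: each generation, state `j` occurs with probability
#' `h_j` and every individual then reproduces according to that state's
#' offspring pmf. The state drawn in a generation is shared by the whole
#' population, which is what distinguishes environmental from demographic
#' variability.
#'
#' @param h numeric vector of state probabilities, summing to one.
#' @param pmfs list of [offspring_pmf()] objects, one per state.
#' @param labels optional character labels for the states.
#' @return an object of class `"environment_ensemble"` with fields `h`,
#'   `pmfs`, `labels`, `means` (per-state `xi^j`) and `vars` (per-state
#'   offspring variances).
#' @examples
#' ens <- environment_ensemble(
#'   h = c(0.4, 0.4, 0.2),
#'   pmfs = list(offspring_pmf(c(0.1, 0.2, 0.7)),
#'               offspring_pmf(c(0.1, 0.3, 0.6)),
#'               offspring_pmf(c(0.2, 0.3, 0.5))))
#' ens$means   # 1.6 1.5 1.3
#' @export
environment_ensemble <- function(h, pmfs, labels = NULL) {
  if (!is.numeric(h) || length(h) < 1L || any(h < 0))
    stop("'h' must be a vector of nonnegative state probabilities", call. = FALSE)
  if (abs(sum(h) - 1) > 1e-8)
    stop("state probabilities 'h' must sum to 1", call. = FALSE)
  if (!is.list(pmfs) || length(pmfs) != length(h) ||
      !all(vapply(pmfs, inherits, TRUE, "offspring_pmf")))
    stop("'pmfs' must be a list of offspring_pmf objects, one per state",
         call. = FALSE)
  if (is.null(labels)) labels <- paste0("state", seq_along(h))
  structure(list(h = h / sum(h), pmfs = pmfs, labels = labels,
                 means = vapply(pmfs, `[[`, 0, "mean"),
                 vars = vapply(pmfs, `[[`, 0, "var")),
            class = "environment_ensemble")
}

#' @export
print.environment_ensemble <- function(x, ...) {
  cat("Environment ensemble with", length(x$h), "states\n")
  for (j in seq_along(x$h))
    cat(sprintf("  %s: h = %g, xi = %g, var = %g\n",
                x$labels[j], x$h[j], x$means[j], x$vars[j]))
  invisible(x)
}

#' @rdname environment_ensemble
#' @param ensemble an `environment_ensemble`.
#' @export
is_degenerate_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "environment_ensemble"))
  sum(ensemble$h > 0) == 1L
}
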