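#' Branching processes in iid random environments with dispersal loss
#'
#' Each generation an environmental state `j` is drawn with probability
#' `h_j` and every individual reproduces by that state's offspring pmf
#' (mean `xi^j`); offspring are then lost from the domain with probability
#' `F`, independent of the environment. The effective per-environment mean
#' is `xi^j (1 - F)`, so the long-run log growth rate is
#' `E[ln xi] = sum_j h_j ln(xi^j) + ln(1 - F)`.
#'
#' Following Smith-Wilkinson theory, the process is supercritical (ultimate
#' extinction probability strictly below one) iff `E[ln xi] > 0` and the
#' catastrophe condition `E|ln(1 - p_tilde_0)| < infinity` holds — for the
#' finite-support ensembles used here the latter reduces to requiring
#' `p_tilde_0 < 1` in every environment with positive probability (no
#' single-generation total collapse). `E[ln xi] <= 0` gives certain
#' extinction (critical at equality, else subcritical).
#'
#' @param ensemble an [environment_ensemble()].
#' @param F probability in `[0, 1]` that an offspring is lost outside the
#'   domain; assumed independent of the environmental state.
#' @return `ensemble_mean_offspring`: the environment-averaged mean
#'   `sum_j h_j xi^j`. `expected_log_growth`: `E[ln xi]` (possibly `-Inf`).
#' @examples
#' ens <- environmental_example()$ensemble
#' ensemble_mean_offspring(ens)       # 1.5
#' expected_log_growth(ens, F = 0)    # 0.4027
#' critical_retention_bpre(ens)       # 0.3315
#' @export
ensemble_mean_offspring <- function(ensemble) {
  stopifnot(inherits(ensemble, "environment_ensemble"))
  sum(ensemble$h * ensemble$means)
}

#' @rdname ensemble_mean_offspring
#' @export
expected_log_growth <- function(ensemble, F = 0) {
  stopifnot(inherits(ensemble, "environment_ensemble"))
  check_F(F)
  active <- ensemble$h > 0
  if (F == 1 || any(ensemble$means[active] == 0)) return(-Inf)
  sum(ensemble$h[active] * log(ensemble$means[active])) + log(1 - F)
}

#' @rdname ensemble_mean_offspring
#' @return `bpre_classify`: a list (class `"criticality_report"`) with
#'   `expected_log_growth`, the `classification`
#'   (`"subcritical"`, `"critical"` or `"supercritical"`),
#'   `catastrophe_condition_ok`, the critical loss fraction `F_star`, and
#'   the critical domain length `L_star` for the supplied kernel (`NA` if
#'   no kernel is given or growth is nonpositive at `F = 0`).
#' @param kernel optionally, a [dispersal_kernel()] used to convert
#'   `F_star` into a critical domain length.
#' @export
bpre_classify <- function(ensemble, F = 0, kernel = NULL) {
  stopifnot(inherits(ensemble, "environment_ensemble"))
  check_F(F)
  elg <- expected_log_growth(ensemble, F)
  active <- which(ensemble$h > 0)
  p0_tilde <- vapply(active, function(j) {
    thinned_pmf(ensemble$pmfs[[j]], F)$probs[1]
  }, 0)
  catastrophe_ok <- all(p0_tilde < 1)
  classification <- if (elg > 0 && catastrophe_ok) "supercritical"
    else if (elg == 0) "critical" else "subcritical"
  F_star <- critical_retention_bpre(ensemble)
  L_star <- if (!is.null(kernel) && expected_log_growth(ensemble, 0) > 0)
    critical_length_bpre(ensemble, kernel) else NA_real_
  structure(list(expected_log_growth = elg,
                 classification = classification,
                 catastrophe_condition_ok = catastrophe_ok,
                 F_star = F_star, L_star = L_star),
            class = "criticality_report")
}

#' @export
print.criticality_report <- function(x, ...) {
  cat(sprintf("BPRE criticality: %s (E[ln xi] = %.4f)\n",
              x$classification, x$expected_log_growth))
  cat(sprintf("  catastrophe condition satisfied: %s\n",
              x$catastrophe_condition_ok))
  cat(sprintf("  critical loss fraction F* = %.4f\n", x$F_star))
  if (!is.na(x$L_star))
    cat(sprintf("  critical domain length L* = %.4f\n", x$L_star))
  invisible(x)
}

#' Critical loss fraction and domain size under environmental stochasticity
#'
#' Setting `E[ln xi] = sum_j h_j ln(xi^j) + ln(1 - F) = 0` gives the
#' critical loss fraction `F* = 1 - exp(-sum_j h_j ln xi^j)`: any loss at
#' or beyond `F*` makes extinction certain. Identifying the retained
#' fraction with the modified dispersal success, `S_hat(L) = 1 - F*`
#' defines the critical domain length. For a degenerate (single-state)
#' ensemble both reduce to the demographic-only Galton-Watson results.
#'
#' @inheritParams ensemble_mean_offspring
#' @param kernel a [dispersal_kernel()].
#' @return `critical_retention_bpre`: `F*` in `[0, 1]` (0 when the
#'   loss-free process is already non-supercritical).
#'   `critical_length_bpre`: the critical domain length.
#' @export
critical_retention_bpre <- function(ensemble) {
  stopifnot(inherits(ensemble, "environment_ensemble"))
  elg0 <- expected_log_growth(ensemble, 0)
  if (elg0 <= 0) return(0)
  1 - exp(-elg0)
}

#' @rdname critical_retention_bpre
#' @export
critical_length_bpre <- function(ensemble, kernel) {
  stopifnot(inherits(ensemble, "environment_ensemble"))
  if (expected_log_growth(ensemble, 0) <= 0)
    stop(paste0("no positive-growth ensemble: E[ln xi] <= 0 at F = 0, ",
                "so extinction is certain at every domain length"),
         call. = FALSE)
  invert_modified_success(kernel, 1 - critical_retention_bpre(ensemble))
}

#' Monte-Carlo finite-horizon extinction probabilities for the BPRE
#'
#' No closed form exists for `Pr(Z_n = 0)` in random environments, so the
#' finite-horizon curve is estimated by averaging, over random environment
#' sequences, the conditional (time-inhomogeneous) Galton-Watson recursion
#' `d_k = f^{s_k}((1 - F) d_{k-1} + F)` with `d_0 = 0`, where `f^{s_k}` is
#' the pgf of the environment drawn in generation `k`. Because the
#' environments are iid, at every fixed horizon `k` this composition has
#' exactly the law of the true conditional extinction probability, so the
#' Monte-Carlo average over sequences is an unbiased estimate of
#' `Pr(Z_k = 0)`. For an initial population of `z` independent lineages the
#' conditional probability is raised to the `z` before averaging (lineages
#' share the environment, so they are only conditionally independent).
#'
#' @inheritParams ensemble_mean_offspring
#' @param n horizon (number of generations).
#' @param z initial population size.
#' @param sequences number of environment sequences to average over.
#' @return numeric vector of cumulative extinction probabilities
#'   `d_1, ..., d_n`.
#' @export
bpre_extinction_curve <- function(ensemble, F, n, z = 1, sequences = 10000) {
  stopifnot(inherits(ensemble, "environment_ensemble"))
  check_F(F)
  nstate <- length(ensemble$h)
  acc <- numeric(n)
  for (s in seq_len(sequences)) {
    env <- sample.int(nstate, n, replace = TRUE, prob = ensemble$h)
    d <- 0
    for (k in seq_len(n)) {
      d <- ensemble$pmfs[[env[k]]]$pgf((1 - F) * d + F)
      acc[k] <- acc[k] + d^z
    }
  }
  acc / sequences
}
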