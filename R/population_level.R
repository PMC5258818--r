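#' Population-level random growth and retention draws
#'
#' The spatially implicit population-level model replaces individuals by a
#' real-valued total `N_bar` and iterates
#' `N_bar_n = A_bar * r_bar * N_bar_{n-1}`. By the Central Limit Theorem,
#' for a population of size `N` the realised per-capita offspring number
#' `r_bar` is approximately `Normal(xi, sigma_r^2 / N)` and the realised
#' retained fraction `A_bar` approximately
#' `Normal(S_hat, sigma_Shat^2 / N)`. A per-capita offspring number cannot
#' be negative: by default negative draws are censored to zero (a point
#' mass at zero), with `negative = "truncate"` available to sample the
#' normal conditioned on nonnegativity instead. Retention draws are
#' clipped into `[0, 1]`, since a retained proportion outside that range
#' is meaningless.
#'
#' @param pmf an [offspring_pmf()] supplying `xi` and `sigma_r^2`.
#' @param N current population size (positive).
#' @param n number of draws.
#' @param negative treatment of negative growth draws: `"censor"` (map to
#'   zero, the default) or `"truncate"` (condition the normal on being
#'   nonnegative).
#' @return numeric vector of `n` draws.
#' @export
draw_per_capita_growth <- function(pmf, N, n = 1,
                                   negative = c("censor", "truncate")) {
  stopifnot(inherits(pmf, "offspring_pmf"))
  negative <- match.arg(negative)
  if (any(N <= 0)) stop("population size 'N' must be positive", call. = FALSE)
  sd <- sqrt(pmf$var / N)
  if (negative == "censor") {
    pmax(0, stats::rnorm(n, mean = pmf$mean, sd = sd))
  } else {
    lo <- stats::pnorm(0, mean = pmf$mean, sd = sd)
    stats::qnorm(lo + stats::runif(n) * (1 - lo), mean = pmf$mean, sd = sd)
  }
}

#' @rdname draw_per_capita_growth
#' @param success a [dispersal_success()] supplying `S_hat` and
#'   `sigma_Shat^2`.
#' @export
draw_retention <- function(success, N, n = 1) {
  stopifnot(inherits(success, "dispersal_success"))
  if (any(N <= 0)) stop("population size 'N' must be positive", call. = FALSE)
  pmin(1, pmax(0, stats::rnorm(n, mean = success$S_hat,
                               sd = sqrt(success$var_S_hat / N))))
}

#' Simulate the spatially implicit population-level model
#'
#' Iterates `N_bar_n = A_bar * r_bar * N_bar_{n-1}` with the CLT draws of
#' [draw_per_capita_growth()] and [draw_retention()] until the population
#' falls below the quasi-extinction threshold or the horizon is reached.
#' The population is real-valued and only tends to zero asymptotically, so
#' a quasi-extinction threshold (default 1: less than one whole
#' individual) stands in for true extinction. Under an
#' [environment_ensemble()] one environmental state is drawn per
#' generation and supplies that generation's `(xi^j, Var^j)`; retention is
#' unaffected by the environment.
#'
#' @param reproduction an [offspring_pmf()] or [environment_ensemble()].
#' @param success a [dispersal_success()].
#' @param N0 initial population size (real-valued).
#' @param max_generations horizon.
#' @param threshold quasi-extinction threshold (default 1).
#' @param negative treatment of negative growth draws, see
#'   [draw_per_capita_growth()].
#' @param demographic_variance if `FALSE`, the `1/N` CLT variances of both
#'   growth and retention are switched off (draws collapse to their means)
#'   so that only environmental variation remains; used to isolate
#'   environmental from demographic stochasticity.
#' @return an object of class `"pop_trajectory"`: list with `sizes`
#'   (`N_bar_0 ... N_bar_T`) and `extinction_generation` (first `n` with
#'   `N_bar_n < threshold`, or `NA`).
#' @examples
#' sc <- dispersal_success(laplace_kernel(), L = 2.7)
#' tr <- simulate_population_level(offspring_pmf(c(0.1, 0.3, 0.6)), sc,
#'                                 N0 = 10, max_generations = 50)
#' tr$extinction_generation
#' @export
simulate_population_level <- function(reproduction, success, N0,
                                      max_generations, threshold = 1,
                                      negative = c("censor", "truncate"),
                                      demographic_variance = TRUE) {
  stopifnot(inherits(success, "dispersal_success"))
  negative <- match.arg(negative)
  env_mode <- inherits(reproduction, "environment_ensemble")
  if (!env_mode && !inherits(reproduction, "offspring_pmf"))
    stop("'reproduction' must be an offspring_pmf or environment_ensemble",
         call. = FALSE)
  if (N0 < threshold)
    return(structure(list(sizes = N0, extinction_generation = 0L),
                     class = "pop_trajectory"))
  sizes <- numeric(max_generations + 1L)
  sizes[1] <- N <- N0
  ext <- NA_integer_
  for (g in seq_len(max_generations)) {
    pmf_g <- if (env_mode) {
      j <- sample.int(length(reproduction$h), 1L, prob = reproduction$h)
      reproduction$pmfs[[j]]
    } else reproduction
    r_bar <- if (demographic_variance)
      draw_per_capita_growth(pmf_g, N, 1L, negative = negative)
    else pmf_g$mean
    A_bar <- if (demographic_variance) draw_retention(success, N, 1L)
    else success$S_hat
    N <- A_bar * r_bar * N
    sizes[g + 1L] <- N
    if (N < threshold) { ext <- g; break }
  }
  structure(list(sizes = sizes[seq_len(if (is.na(ext)) max_generations + 1L
                                       else ext + 1L)],
                 extinction_generation = ext),
            class = "pop_trajectory")
}

#' @export
print.pop_trajectory <- function(x, ...) {
  T <- length(x$sizes) - 1L
  cat(sprintf("Population-level trajectory over %d generations; %s\n", T,
              if (is.na(x$extinction_generation)) "no quasi-extinction"
              else sprintf("quasi-extinct at generation %d",
                           x$extinction_generation)))
  invisible(x)
}

#' Composite growth-factor model and mean time to extinction
#'
#' Collapsing retention and reproduction into one random factor
#' `B = A r` with `E[B] = E[A] E[r]` and
#' `Var(B) = E[A]^2 sigma_r^2 + E[r]^2 sigma_A^2 + sigma_A^2 sigma_r^2`
#' gives the one-parameter-pair recursion `N_bar_{n+1} = B_bar N_bar_n`
#' with `B_bar ~ Normal(B_mean, B_var / N_bar_n)` (censored at zero). In
#' the deterministic limit (`B_var = 0`, `B_mean < 1`) the extinction time
#' is `-ln(N0) / ln(B_mean)`; with noise, the mean first-passage time
#' below the threshold remains close to linear in `ln(N0)`.
#'
#' @param B_mean mean composite growth factor `E[B]`.
#' @param B_var composite variance `sigma_B^2`; per-generation variance is
#'   `B_var / N_bar` when `scale_variance = TRUE` (default), or `B_var`
#'   unscaled otherwise.
#' @param N0 initial population size.
#' @param max_generations horizon.
#' @param threshold quasi-extinction threshold.
#' @param scale_variance divide the variance by the current population
#'   size (the CLT scaling).
#' @return `simulate_composite`: a `"pop_trajectory"`.
#' @examples
#' simulate_composite(0.8, 0, N0 = 100, max_generations = 50)  # extinct at 21
#' @export
simulate_composite <- function(B_mean, B_var, N0, max_generations,
                               threshold = 1, scale_variance = TRUE) {
  if (B_mean < 0 || B_var < 0)
    stop("'B_mean' and 'B_var' must be nonnegative", call. = FALSE)
  if (N0 < threshold)
    return(structure(list(sizes = N0, extinction_generation = 0L),
                     class = "pop_trajectory"))
  sizes <- numeric(max_generations + 1L)
  sizes[1] <- N <- N0
  ext <- NA_integer_
  for (g in seq_len(max_generations)) {
    v <- if (scale_variance) B_var / N else B_var
    B <- max(0, stats::rnorm(1L, B_mean, sqrt(v)))
    N <- B * N
    sizes[g + 1L] <- N
    if (N < threshold) { ext <- g; break }
  }
  structure(list(sizes = sizes[seq_len(if (is.na(ext)) max_generations + 1L
                                       else ext + 1L)],
                 extinction_generation = ext),
            class = "pop_trajectory")
}

#' @rdname simulate_composite
#' @param N0_grid vector of initial population sizes.
#' @param replicates Monte-Carlo replicates per initial size.
#' @param seed optional integer seed.
#' @return `mean_time_to_extinction`: data frame with columns `N0`,
#'   `mean_time`, `se` (Monte-Carlo standard error) and `replicates`.
#'   Replicates still alive at `max_generations` contribute the horizon as
#'   a (conservative) extinction time.
#' @export
mean_time_to_extinction <- function(B_mean, B_var, N0_grid,
                                    replicates = 10000, seed = NULL,
                                    max_generations = 10000, threshold = 1,
                                    scale_variance = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(N0_grid, function(N0) {
    N <- rep(as.numeric(N0), replicates)
    t_ext <- rep(NA_real_, replicates)
    alive <- N >= threshold
    t_ext[!alive] <- 0
    g <- 0L
    while (any(alive) && g < max_generations) {
      g <- g + 1L
      idx <- which(alive)
      v <- if (scale_variance) B_var / N[idx] else rep(B_var, length(idx))
      B <- pmax(0, stats::rnorm(length(idx), B_mean, sqrt(v)))
      N[idx] <- B * N[idx]
      died <- idx[N[idx] < threshold]
      t_ext[died] <- g
      alive[died] <- FALSE
    }
    t_ext[is.na(t_ext)] <- max_generations
    data.frame(N0 = N0, mean_time = mean(t_ext),
               se = stats::sd(t_ext) / sqrt(replicates),
               replicates = replicates)
  })
  do.call(rbind, out)
}

#' Monte-Carlo extinction curves from the population-level model
#'
#' Vectorised analogue of [extinction_curve_ibm()] for the spatially
#' implicit model: many replicate populations are iterated through
#' `N_bar_n = A_bar r_bar N_bar_{n-1}` in parallel, and the cumulative
#' fraction below the quasi-extinction threshold is recorded each
#' generation.
#'
#' @inheritParams simulate_population_level
#' @param z initial population size per replicate.
#' @param generations horizon of the curve.
#' @param replicates number of replicates.
#' @param seed optional integer seed.
#' @return an `"extinction_curve"` object (`model = "population_level"`).
#' @export
extinction_curve_population <- function(reproduction, success, z, generations,
                                        replicates, seed = NULL,
                                        threshold = 1,
                                        negative = c("censor", "truncate"),
                                        demographic_variance = TRUE) {
  stopifnot(inherits(success, "dispersal_success"))
  negative <- match.arg(negative)
  if (!is.null(seed)) set.seed(seed)
  env_mode <- inherits(reproduction, "environment_ensemble")
  if (!env_mode && !inherits(reproduction, "offspring_pmf"))
    stop("'reproduction' must be an offspring_pmf or environment_ensemble",
         call. = FALSE)
  N <- rep(as.numeric(z), replicates)
  alive <- N >= threshold
  curve <- numeric(generations)
  Shat <- success$S_hat
  vS <- success$var_S_hat
  for (g in seq_len(generations)) {
    idx <- which(alive)
    if (length(idx)) {
      if (env_mode) {
        env <- sample.int(length(reproduction$h), length(idx), replace = TRUE,
                          prob = reproduction$h)
        mu <- reproduction$means[env]
        v_r <- reproduction$vars[env]
      } else {
        mu <- rep(reproduction$mean, length(idx))
        v_r <- rep(reproduction$var, length(idx))
      }
      if (demographic_variance) {
        sd_r <- sqrt(v_r / N[idx])
        r_bar <- if (negative == "censor")
          pmax(0, stats::rnorm(length(idx), mu, sd_r))
        else {
          lo <- stats::pnorm(0, mu, sd_r)
          stats::qnorm(lo + stats::runif(length(idx)) * (1 - lo), mu, sd_r)
        }
        A_bar <- pmin(1, pmax(0, stats::rnorm(length(idx), Shat,
                                              sqrt(vS / N[idx]))))
      } else {
        r_bar <- mu
        A_bar <- Shat
      }
      N[idx] <- A_bar * r_bar * N[idx]
      alive[idx[N[idx] < threshold]] <- FALSE
    }
    curve[g] <- mean(!alive)
  }
  structure(list(generations = seq_len(generations),
                 cumulative_probability = curve,
                 replicates = replicates, seed = seed,
                 model = "population_level", L = success$L, z = z),
            class = "extinction_curve")
}
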