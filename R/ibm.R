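#' Spatially explicit individual-based model
#'
#' The individual-based model (IBM) is the ground truth that every
#' approximation in this package is judged against. Individuals live at
#' real-valued positions in the domain `[-L/2, L/2]`. Each generation,
#' every individual independently draws an offspring count from the
#' offspring pmf (parental survival is folded into the count); each
#' offspring then disperses from the parent's location by a kernel
#' displacement, and offspring settling outside the domain die. Settling
#' exactly on a boundary counts as inside (the domain is closed).
#'
#' `initialize_population` places `N0` founders at the centres of `N0`
#' equal subintervals ("evenly distributed"); `method = "uniform"` draws
#' positions uniformly at random instead.
#'
#' @param N0 initial population size (positive integer).
#' @param L domain length.
#' @param method `"even"` (deterministic subinterval centres, the default)
#'   or `"uniform"` (iid uniform positions).
#' @return an object of class `"ibm_state"`: a list with `generation`,
#'   `positions`, `L` and the flag `extinct`.
#' @examples
#' st <- initialize_population(10, L = 2.703)
#' st <- ibm_step(st, offspring_pmf(c(0.1, 0.3, 0.6)), laplace_kernel())
#' length(st$positions)
#' @export
initialize_population <- function(N0, L, method = c("even", "uniform")) {
  if (!is.numeric(N0) || length(N0) != 1L || N0 < 1 || N0 != round(N0))
    stop("'N0' must be a positive integer", call. = FALSE)
  check_length(L)
  method <- match.arg(method)
  pos <- if (method == "even")
    -L / 2 + L * (seq_len(N0) - 0.5) / N0
  else
    stats::runif(N0, -L / 2, L / 2)
  structure(list(generation = 0L, positions = pos, L = L, extinct = FALSE),
            class = "ibm_state")
}

#' @rdname initialize_population
#' @param state an `ibm_state`.
#' @param pmf an [offspring_pmf()] governing every individual's offspring
#'   count this generation.
#' @param kernel a [dispersal_kernel()].
#' @export
ibm_step <- function(state, pmf, kernel) {
  stopifnot(inherits(state, "ibm_state"), inherits(pmf, "offspring_pmf"),
            inherits(kernel, "dispersal_kernel"))
  n <- length(state$positions)
  if (n == 0L) {
    state$generation <- state$generation + 1L
    state$extinct <- TRUE
    return(state)
  }
  counts <- pmf_sample(pmf, n)
  total <- sum(counts)
  newpos <- rep.int(state$positions, counts) + kernel$sample(total)
  newpos <- newpos[abs(newpos) <= state$L / 2]
  state$generation <- state$generation + 1L
  state$positions <- newpos
  state$extinct <- length(newpos) == 0L
  state
}

#' @rdname initialize_population
#' @param ensemble an [environment_ensemble()]; one state is drawn for the
#'   whole generation and its pmf governs every individual's offspring
#'   draw.
#' @return `ibm_step_environment`: a list with the advanced `state` and the
#'   index `environment` of the state drawn this generation.
#' @export
ibm_step_environment <- function(state, ensemble, kernel) {
  stopifnot(inherits(ensemble, "environment_ensemble"))
  j <- sample.int(length(ensemble$h), 1L, prob = ensemble$h)
  list(state = ibm_step(state, ensemble$pmfs[[j]], kernel), environment = j)
}

#' @export
print.ibm_state <- function(x, ...) {
  cat(sprintf("IBM state: generation %d, %d individuals on [-%g, %g]%s\n",
              x$generation, length(x$positions), x$L / 2, x$L / 2,
              if (x$extinct) " (extinct)" else ""))
  invisible(x)
}

#' Monte-Carlo extinction curves from the individual-based model
#'
#' Runs many replicate IBM populations and records, for each generation,
#' the fraction of replicates whose population has hit zero. All
#' replicates are simulated in one pooled vector of individuals tagged
#' with replicate ids, so a run with thousands of replicates costs a
#' handful of vectorised draws per generation. Reproduction is either a
#' single [offspring_pmf()] (demographic stochasticity only) or an
#' [environment_ensemble()] (each replicate draws its own iid environment
#' sequence).
#'
#' A replicate whose population reaches `survival_ceiling` individuals is
#' frozen as surviving: its subsequent extinction probability is at most
#' `d^ceiling` for some lineage extinction probability `d < 1`, which is
#' astronomically small, and freezing keeps supercritical runs from
#' growing without bound.
#'
#' @param reproduction an [offspring_pmf()] or an [environment_ensemble()].
#' @param kernel a [dispersal_kernel()].
#' @param L domain length.
#' @param z initial population size per replicate.
#' @param generations horizon of the curve.
#' @param replicates number of independent replicates.
#' @param seed optional integer seed (set once for the whole run).
#' @param init initial placement, as in [initialize_population()].
#' @param survival_ceiling population size at which a replicate is frozen
#'   as surviving.
#' @return an object of class `"extinction_curve"`: list with
#'   `generations`, `cumulative_probability`, `replicates`, `seed`, and
#'   `model = "ibm"`. Coerce with `as.data.frame()`.
#' @examples
#' pmf <- offspring_pmf(c(0.1, 0.3, 0.6))
#' cv <- extinction_curve_ibm(pmf, laplace_kernel(), L = 2.8, z = 10,
#'                            generations = 10, replicates = 500, seed = 1)
#' as.data.frame(cv)
#' @export
extinction_curve_ibm <- function(reproduction, kernel, L, z, generations,
                                 replicates, seed = NULL,
                                 init = c("even", "uniform"),
                                 survival_ceiling = 1000) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  check_length(L)
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  env_mode <- inherits(reproduction, "environment_ensemble")
  if (!env_mode && !inherits(reproduction, "offspring_pmf"))
    stop("'reproduction' must be an offspring_pmf or environment_ensemble",
         call. = FALSE)

  init_pos <- if (init == "even") -L / 2 + L * (seq_len(z) - 0.5) / z
              else stats::runif(z, -L / 2, L / 2)
  pos <- rep(init_pos, times = replicates)
  id <- rep(seq_len(replicates), each = z)
  extinct_by <- rep(NA_integer_, replicates)   # generation of extinction
  frozen <- logical(replicates)                # reached the ceiling
  curve <- numeric(generations)

  for (g in seq_len(generations)) {
    if (length(pos) > 0L) {
      if (env_mode) {
        nstate <- length(reproduction$h)
        env_of_rep <- sample.int(nstate, replicates, replace = TRUE,
                                 prob = reproduction$h)
        env_ind <- env_of_rep[id]
        counts <- integer(length(pos))
        for (j in seq_len(nstate)) {
          sel <- env_ind == j
          if (any(sel))
            counts[sel] <- pmf_sample(reproduction$pmfs[[j]], sum(sel))
        }
      } else {
        counts <- pmf_sample(reproduction, length(pos))
      }
      newpos <- rep.int(pos, counts) + kernel$sample(sum(counts))
      newid <- rep.int(id, counts)
      keep <- abs(newpos) <= L / 2
      pos <- newpos[keep]
      id <- newid[keep]
      # replicates newly extinct this generation
      alive <- tabulate(id, nbins = replicates) > 0L
      died <- !alive & is.na(extinct_by) & !frozen
      extinct_by[died] <- g
      # freeze replicates that have outgrown any realistic extinction risk
      big <- which(tabulate(id, nbins = replicates) >= survival_ceiling)
      if (length(big)) {
        frozen[big] <- TRUE
        sel <- !(id %in% big)
        pos <- pos[sel]
        id <- id[sel]
      }
    }
    curve[g] <- mean(!is.na(extinct_by) & extinct_by <= g)
  }
  structure(list(generations = seq_len(generations),
                 cumulative_probability = curve,
                 replicates = replicates, seed = seed, model = "ibm",
                 L = L, z = z),
            class = "extinction_curve")
}

#' @export
as.data.frame.extinction_curve <- function(x, ...) {
  data.frame(generation = x$generations,
             cumulative_extinction = x$cumulative_probability,
             replicates = x$replicates,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed,
             model = x$model)
}

#' @export
print.extinction_curve <- function(x, ...) {
  cat(sprintf("Extinction curve (%s, %d replicates%s)\n", x$model,
              x$replicates,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  print(utils::head(as.data.frame(x)[, 1:2], 10))
  if (length(x$generations) > 10) cat("  ...\n")
  invisible(x)
}
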