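#' Worked-example presets
#'
#' Two parameter bundles used throughout the package's examples and tests.
#' `demographic_example()` is a population with offspring pmf
#' `{p0 = 0.1, p1 = 0.3, p2 = 0.6}` (mean 1.5, variance 0.45) dispersing
#' by a Laplace kernel with unit mean dispersal distance.
#' `environmental_example()` adds a three-state environment with
#' probabilities `h = {0.4, 0.4, 0.2}` and per-state offspring pmfs
#' `{0.1, 0.2, 0.7}`, `{0.1, 0.3, 0.6}` and `{0.2, 0.3, 0.5}` (means 1.6,
#' 1.5 and 1.3), the middle state being the demographic example.
#'
#' @return a list with elements `pmf` (or `ensemble`), `kernel`, `z`
#'   (default initial population 10), `domains` (domain lengths bracketing
#'   the deterministic critical length) and `L_deterministic`, the
#'   critical domain size 2.703 of the corresponding deterministic IDE
#'   with logistic growth at intrinsic rate 1.5 — the established
#'   benchmark against which the stochastic critical lengths are compared
#'   (the linearised eigenvalue solver [ide_critical_length()] reproduces
#'   it to about 1e-3).
#' @examples
#' demographic_example()$pmf$mean        # 1.5
#' environmental_example()$ensemble$means
#' @export
demographic_example <- function() {
  list(name = "demographic_example",
       pmf = offspring_pmf(c(0.1, 0.3, 0.6)),
       kernel = laplace_kernel(b = 1),
       z = 10L,
       domains = c(2.6, 2.7, 2.8),
       L_deterministic = 2.703)
}

#' @rdname demographic_example
#' @export
environmental_example <- function() {
  list(name = "environmental_example",
       ensemble = environment_ensemble(
         h = c(0.4, 0.4, 0.2),
         pmfs = list(offspring_pmf(c(0.1, 0.2, 0.7)),
                     offspring_pmf(c(0.1, 0.3, 0.6)),
                     offspring_pmf(c(0.2, 0.3, 0.5)))),
       kernel = laplace_kernel(b = 1),
       z = 10L,
       domains = c(2.6, 2.7, 2.8),
       L_deterministic = 2.703)
}

#' The full chain of headline quantities for the worked examples
#'
#' Computes, from scratch, every analytic quantity in the demographic and
#' environmental worked examples: the deterministic IDE critical length;
#' the modified dispersal success at that length and the resulting
#' effective mean offspring number; the branching-process critical length;
#' the non-spatial ultimate extinction probability; the conservation-goal
#' solution (10 % ultimate extinction for 1000 founders); and the
#' random-environments chain (expected log growth, critical loss fraction,
#' critical domain length).
#'
#' @return a data frame with columns `quantity`, `value` and `description`.
#' @examples
#' worked_numbers()
#' @export
worked_numbers <- function() {
  dem <- demographic_example()
  env <- environmental_example()
  pmf <- dem$pmf
  kern <- dem$kernel

  L_ide <- ide_critical_length(kern, r = pmf$mean)
  # the example chain is anchored at the benchmark deterministic critical
  # length (logistic growth), which the linear eigenvalue solver recovers
  Shat_det <- modified_success(kern, dem$L_deterministic)
  goal <- domain_for_goal(pmf, kern, z = 1000L, goal = 0.10)

  rows <- list(
    c("L_ide", L_ide,
      "critical domain length of the deterministic linear IDE, r = 1.5"),
    c("Shat_at_L_ide", Shat_det,
      "modified dispersal success at the deterministic critical length"),
    c("Er_Shat", pmf$mean * Shat_det,
      "effective mean offspring number E[r] * S_hat at the IDE length"),
    c("L_gw", gw_critical_length(pmf, kern),
      "critical length of the dispersal-modified Galton-Watson process"),
    c("d_nonspatial", ultimate_extinction(pmf, F = 0),
      "non-spatial ultimate extinction probability of one lineage"),
    c("F_goal", goal$F,
      "loss fraction for a 10% ultimate-extinction goal with z = 1000"),
    c("L_goal", goal$L,
      "domain length achieving the 10% conservation goal"),
    c("E_ln_xi", expected_log_growth(env$ensemble, F = 0),
      "expected log growth of the three-environment ensemble at F = 0"),
    c("F_bpre", critical_retention_bpre(env$ensemble),
      "critical loss fraction of the random-environments process"),
    c("L_bpre", critical_length_bpre(env$ensemble, env$kernel),
      "critical domain length under environmental stochasticity")
  )
  data.frame(quantity = vapply(rows, `[[`, "", 1),
             value = as.numeric(vapply(rows, `[[`, "", 2)),
             description = vapply(rows, `[[`, "", 3))
}

#' Reproduce the package's simulation experiments
#'
#' Re-runs the Monte-Carlo comparisons behind the package's worked
#' examples at a configurable replicate count and returns tidy data frames
#' suitable for plotting or CSV export.
#'
#' \describe{
#'   \item{`"fig1"`}{mean time to quasi-extinction of the composite model
#'     (`E[B] = 0.8`, `Var(B) = 0.3`) against `ln N0` for
#'     `N0 = 10, 100, 1000, 10000`.}
#'   \item{`"fig2"`}{IBM versus population-level extinction curves for the
#'     demographic example over `L = 2.6, 2.7, 2.8`.}
#'   \item{`"fig3"`}{IBM versus the modified branching recursion
#'     `d_n^z` with `F = 1 - S_hat(L)` over the same lengths.}
#'   \item{`"fig4"`}{ultimate extinction probability `d(L)^z` over a grid
#'     of domain lengths and initial sizes (analytic).}
#'   \item{`"fig5"`}{environmental IBM versus environmental
#'     population-level curves.}
#'   \item{`"fig6"`}{population-level curves at `L = 2.7` under
#'     demographic-only, environmental-only and combined stochasticity.}
#'   \item{`"fig7"`}{environmental IBM versus the Monte-Carlo BPRE
#'     recursion curves.}
#'   \item{`"table_worked"`}{the [worked_numbers()] table.}
#' }
#'
#' @param name experiment name, see Details.
#' @param replicates Monte-Carlo replicates (simulation experiments only).
#' @param seed integer seed.
#' @param generations horizon for extinction curves.
#' @return a data frame; columns depend on the experiment.
#' @examples
#' head(run_example("fig4"))
#' @export
run_example <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig5",
                                 "fig6", "fig7", "table_worked"),
                        replicates = 10000, seed = 1, generations = 20) {
  name <- match.arg(name)
  dem <- demographic_example()
  env <- environmental_example()

  curve_df <- function(cv, model, L) {
    data.frame(model = model, L = L, generation = cv$generations,
               cumulative_extinction = cv$cumulative_probability,
               replicates = cv$replicates)
  }

  switch(name,
    fig1 = {
      df <- mean_time_to_extinction(0.8, 0.3, N0_grid = 10^(1:4),
                                    replicates = replicates, seed = seed)
      df$ln_N0 <- log(df$N0)
      df
    },
    fig2 = do.call(rbind, lapply(dem$domains, function(L) {
      sc <- dispersal_success(dem$kernel, L)
      rbind(
        curve_df(extinction_curve_ibm(dem$pmf, dem$kernel, L, dem$z,
                                      generations, replicates,
                                      seed = seed), "ibm", L),
        curve_df(extinction_curve_population(dem$pmf, sc, dem$z, generations,
                                             replicates, seed = seed + 1L),
                 "population_level", L))
    })),
    fig3 = do.call(rbind, lapply(dem$domains, function(L) {
      F <- 1 - modified_success(dem$kernel, L)
      dn <- extinction_by_generation(dem$pmf, F, generations)
      rbind(
        curve_df(extinction_curve_ibm(dem$pmf, dem$kernel, L, dem$z,
                                      generations, replicates,
                                      seed = seed), "ibm", L),
        data.frame(model = "branching", L = L,
                   generation = seq_len(generations),
                   cumulative_extinction = dn^dem$z, replicates = NA))
    })),
    fig4 = {
      grid <- expand.grid(L = seq(2.5, 4, by = 0.05), z = c(1, 5, 10, 50))
      grid$d <- vapply(seq_len(nrow(grid)), function(i) {
        F <- 1 - modified_success(dem$kernel, grid$L[i])
        extinction_for_population(ultimate_extinction(dem$pmf, F), grid$z[i])
      }, 0)
      grid
    },
    fig5 = do.call(rbind, lapply(env$domains, function(L) {
      sc <- dispersal_success(env$kernel, L)
      rbind(
        curve_df(extinction_curve_ibm(env$ensemble, env$kernel, L, env$z,
                                      generations, replicates,
                                      seed = seed), "ibm", L),
        curve_df(extinction_curve_population(env$ensemble, sc, env$z,
                                             generations, replicates,
                                             seed = seed + 1L),
                 "population_level", L))
    })),
    fig6 = {
      L <- 2.7
      sc <- dispersal_success(env$kernel, L)
      demographic_only <- env$ensemble$pmfs[[2]]
      rbind(
        curve_df(extinction_curve_population(demographic_only, sc, env$z,
                                             generations, replicates,
                                             seed = seed),
                 "demographic", L),
        curve_df(extinction_curve_population(env$ensemble, sc, env$z,
                                             generations, replicates,
                                             seed = seed + 1L,
                                             demographic_variance = FALSE),
                 "environmental", L),
        curve_df(extinction_curve_population(env$ensemble, sc, env$z,
                                             generations, replicates,
                                             seed = seed + 2L), "both", L))
    },
    fig7 = do.call(rbind, lapply(env$domains, function(L) {
      F <- 1 - modified_success(env$kernel, L)
      set.seed(seed + 1L)
      dn <- bpre_extinction_curve(env$ensemble, F, generations, z = env$z,
                                  sequences = replicates)
      rbind(
        curve_df(extinction_curve_ibm(env$ensemble, env$kernel, L, env$z,
                                      generations, replicates,
                                      seed = seed), "ibm", L),
        data.frame(model = "bpre", L = L, generation = seq_len(generations),
                   cumulative_extinction = dn, replicates = replicates))
    })),
    table_worked = worked_numbers()
  )
}
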