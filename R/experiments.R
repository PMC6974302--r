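#' Named scenario presets
#'
#' Returns the exact published run configuration for each experimental
#' regime, or a reduced-scale variant suitable for desk runs: the reduced
#' variants keep every probability and ladder unchanged and scale down only
#' the grid (N = 10), the material (T_NPB = 2000), the step count (2e5,
#' recorded every 1e3) and the inoculation step (5e4).
#'
#' Available names (append `"_reduced"` or pass `reduced = TRUE`):
#' \describe{
#'   \item{fig2a_complete}{template-directed route only (P_TL = 0.01,
#'     P_RL = 0), complete chiral selection (F_CST = 0), 50 D 6-mers
#'     inoculated; regime: deviation.}
#'   \item{fig2a_partial}{as above with F_CST = 0.5.}
#'   \item{fig2a_noselect}{as above with F_CST = 1 (no chiral selection;
#'     cross-inhibition termination alone still breaks symmetry).}
#'   \item{fig2a_notermination}{neither chiral selection (F_CST = 1) nor
#'     cross-inhibition termination; control, regime: no_deviation.}
#'   \item{fig2b}{de novo appearance of RNA: P_RL = 1e-6, F_CST = 0.5,
#'     F_CSS = 0, P_TL = 0.01, no inoculation; which chirality prevails is
#'     seed-dependent.}
#'   \item{fig3_ladder1 / fig3_ladder50 / fig3_ladder100 / fig3_ladder200}{
#'     surface-mediated route only (P_AT = 0), P_RL = 1e-6, P_NDE = 1e-5,
#'     F_CSS = 0, with surface primer ladders R1:R2:R3 of 1:1:1 (uniform
#'     control, no deviation), 1:10:50 (too weak), 1:10:100 and 1:10:200
#'     (deviation).}
#'   \item{fig4a_nsr}{NSR emergence: default rates, P_NFR = 0.2, P_TLR = 0,
#'     surface ladder 1:10:20, template ladder 1:5:10.}
#'   \item{fig4b_rep}{REP emergence: as fig4a but P_NFR = 0, P_TLR = 0.9.}
#' }
#'
#' @param name scenario name.
#' @param reduced use the reduced scale regardless of the name suffix.
#' @param seed RNG seed stored in the configuration.
#' @return A `scenario`: list with `name`, `config` (a [sim_config()]) and
#'   `expected_regime` (`"no_deviation"`, `"deviation"` or
#'   `"deviation_then_ribozyme"`).
#' @examples
#' sc <- scenario("fig2a_complete", reduced = TRUE)
#' sc$config$params$P_TL
#' @export
scenario <- function(name, reduced = FALSE, seed = 1L) {
  full_name <- name
  if (grepl("_reduced$", name)) {
    reduced <- TRUE
    name <- sub("_reduced$", "", name)
  }
  uni <- primer_ladder()
  base <- list(params = list(), surface = uni, template = uni,
               inoculate = FALSE, no_term = FALSE,
               regime = "deviation")
  sc <- switch(name,
    fig2a_complete = modifyList(base, list(
      params = list(P_TL = 0.01, P_RL = 0, F_CST = 0), inoculate = TRUE)),
    fig2a_partial = modifyList(base, list(
      params = list(P_TL = 0.01, P_RL = 0, F_CST = 0.5), inoculate = TRUE)),
    fig2a_noselect = modifyList(base, list(
      params = list(P_TL = 0.01, P_RL = 0, F_CST = 1), inoculate = TRUE)),
    fig2a_notermination = modifyList(base, list(
      params = list(P_TL = 0.01, P_RL = 0, F_CST = 1), inoculate = TRUE,
      no_term = TRUE, regime = "no_deviation")),
    fig2b = modifyList(base, list(
      params = list(P_TL = 0.01, P_RL = 1e-6, F_CST = 0.5, F_CSS = 0))),
    fig3_ladder1 = modifyList(base, list(
      params = list(P_AT = 0, P_RL = 1e-6, P_NDE = 1e-5, F_CSS = 0),
      regime = "no_deviation")),
    fig3_ladder50 = modifyList(base, list(
      params = list(P_AT = 0, P_RL = 1e-6, P_NDE = 1e-5, F_CSS = 0),
      surface = primer_ladder(1, 10, 50), regime = "no_deviation")),
    fig3_ladder100 = modifyList(base, list(
      params = list(P_AT = 0, P_RL = 1e-6, P_NDE = 1e-5, F_CSS = 0),
      surface = primer_ladder(1, 10, 100))),
    fig3_ladder200 = modifyList(base, list(
      params = list(P_AT = 0, P_RL = 1e-6, P_NDE = 1e-5, F_CSS = 0),
      surface = primer_ladder(1, 10, 200))),
    fig4a_nsr = modifyList(base, list(
      params = list(P_NFR = 0.2, P_TLR = 0),
      surface = primer_ladder(1, 10, 20),
      template = primer_ladder(1, 5, 10),
      regime = "deviation_then_ribozyme")),
    fig4b_rep = modifyList(base, list(
      params = list(P_NFR = 0, P_TLR = 0.9),
      surface = primer_ladder(1, 10, 20),
      template = primer_ladder(1, 5, 10),
      regime = "deviation_then_ribozyme")),
    stop(sprintf("unknown scenario '%s'", name), call. = FALSE))

  scale <- if (reduced)
    list(N = 10, T_NPB = 2000, steps = 2e5, record_every = 1e3,
         inoc_step = 5e4)
  else
    list(N = 20, T_NPB = 50000, steps = if (grepl("^fig4", name)) 6e6
                                        else 3e6,
         record_every = 1e4, inoc_step = 1e6)
  params <- do.call(sim_params,
                    c(sc$params, list(N = scale$N, T_NPB = scale$T_NPB)))
  inocs <- if (sc$inoculate)
    list(inoculation(step = scale$inoc_step, count = 50, length = 6,
                     chirality = "D"))
  else list()
  cfg <- sim_config(params = params, surface_ladder = sc$surface,
                    template_ladder = sc$template, steps = scale$steps,
                    seed = seed, inoculations = inocs,
                    no_termination = sc$no_term,
                    record_every = scale$record_every)
  structure(list(name = if (reduced && !grepl("_reduced$", full_name))
                          paste0(name, "_reduced") else full_name,
                 config = cfg, expected_regime = sc$regime),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (expected regime: %s)\n", x$name,
              x$expected_regime))
  print(x$config)
  invisible(x)
}

#' Run a scenario over one or more replicate seeds
#'
#' @param sc a [scenario()] or a scenario name (string).
#' @param seeds integer vector of replicate seeds.
#' @param reduced passed to [scenario()] when `sc` is a name.
#' @return A list with `summary` (tibble: one row per seed with
#'   [ee_summary()] columns plus final ribozyme counts) and `trajectories`
#'   (list of `chiro_trajectory`).
#' @export
run_scenario <- function(sc, seeds = 1L, reduced = FALSE) {
  if (is.character(sc)) sc <- scenario(sc, reduced = reduced)
  stopifnot(inherits(sc, "scenario"))
  trajs <- lapply(seeds, function(s) {
    cfg <- sc$config
    cfg$seed <- as.integer(s)
    run_sim(cfg)
  })
  summ <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    tr <- trajs[[i]]
    n <- nrow(tr$records)
    cbind(tibble::tibble(scenario = sc$name, seed = seeds[i]),
          ee_summary(tr),
          tibble::tibble(nsr_final = tr$records$nsr_D[n] +
                           tr$records$nsr_L[n],
                         rep_final = tr$records$rep_D[n] +
                           tr$records$rep_L[n]))
  }))
  list(summary = tibble::as_tibble(summ), trajectories = trajs)
}

#' Parameter sweep over a scenario
#'
#' Runs a grid of configurations obtained by setting one parameter of a
#' base scenario to each of the given values, with replicate seeds, and
#' reports final / time-averaged ee per run (and its absolute value, which
#' is what matters when the prevailing chirality is itself seed-dependent).
#'
#' @param base_scenario a [scenario()] or scenario name.
#' @param parameter name of a [sim_params()] field, e.g. `"F_CST"`.
#' @param values values to sweep over.
#' @param replicates replicate runs per value.
#' @param seed base seed; replicate r of value v uses a distinct recorded
#'   seed derived from it.
#' @param reduced passed to [scenario()] when a name is given.
#' @return A tibble with one row per (value, replicate): the seed used,
#'   `final_ee`, `mean_ee_last`, `mean_abs_ee`, `max_abs_ee`.
#' @export
sweep_param <- function(base_scenario, parameter, values, replicates = 1L,
                        seed = 1L, reduced = TRUE) {
  if (is.character(base_scenario))
    base_scenario <- scenario(base_scenario, reduced = reduced)
  stopifnot(inherits(base_scenario, "scenario"))
  if (!parameter %in% names(unclass(base_scenario$config$params)))
    stop(sprintf("'%s' is not a simulation parameter", parameter),
         call. = FALSE)
  out <- list()
  for (vi in seq_along(values)) {
    for (r in seq_len(replicates)) {
      cfg <- base_scenario$config
      cfg$params[[parameter]] <- values[vi]
      validate_params(cfg$params)
      run_seed <- as.integer((seed + 7919L * (vi - 1L) + 104729L * (r - 1L)) %%
                               .Machine$integer.max)
      cfg$seed <- run_seed
      tr <- run_sim(cfg)
      out[[length(out) + 1L]] <-
        cbind(tibble::tibble(parameter = parameter, value = values[vi],
                             replicate = r, seed = run_seed),
              ee_summary(tr))
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}
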