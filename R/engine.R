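#' Inoculation event
#'
#' Scheduled injection of homochiral RNA molecules, scattered into uniformly
#' random rooms immediately before the given step executes.
#'
#' @param step Monte-Carlo step at which to inoculate.
#' @param count number of molecules.
#' @param length chain length; taken from `sequence` when one is given.
#' @param chirality `"D"` or `"L"`.
#' @param sequence explicit base string, or `"random"` to draw each
#'   molecule's bases uniformly.
#' @return An `inoculation` object.
#' @examples
#' inoculation(step = 1e6, count = 50, length = 6, chirality = "D")
#' @export
inoculation <- function(step, count, length = NULL, chirality = "D",
                        sequence = "random") {
  stopifnot(step >= 0, count >= 0, chirality %in% c("D", "L"))
  if (!identical(sequence, "random")) {
    sequence <- toupper(sequence)
    if (!grepl("^[AUCG]+$", sequence))
      stop("sequence must be 'random' or a string over A/U/C/G",
           call. = FALSE)
    if (is.null(length)) length <- nchar(sequence)
    if (length != nchar(sequence))
      stop("length must equal the sequence length", call. = FALSE)
  }
  if (is.null(length)) stop("length required for random sequences",
                            call. = FALSE)
  structure(list(step = as.numeric(step), count = as.integer(count),
                 length = as.integer(length), chirality = chirality,
                 sequence = sequence), class = "inoculation")
}

#' Run configuration
#'
#' Bundles everything that defines a reproducible run: the parameters, the
#' two primer-effect ladders (surface and template routes), the step count,
#' the RNG seed, the inoculation schedule, the no-termination control flag
#' (which disables cross-inhibition termination; used only for control
#' experiments), and the recording interval.
#'
#' @param params a [sim_params()].
#' @param surface_ladder,template_ladder [primer_ladder()]s for the two
#'   synthesis routes.
#' @param steps number of Monte-Carlo steps (>= 1).
#' @param seed integer RNG seed.
#' @param inoculations list of [inoculation()] events.
#' @param no_termination disable cross-inhibition termination everywhere.
#' @param record_every record observables every this many steps (>= 1).
#' @return A `sim_config`.
#' @export
sim_config <- function(params = sim_params(),
                       surface_ladder = primer_ladder(),
                       template_ladder = primer_ladder(),
                       steps = 1000, seed = 1L, inoculations = list(),
                       no_termination = FALSE, record_every = 1000) {
  validate_params(params)
  stopifnot(inherits(surface_ladder, "primer_ladder"),
            inherits(template_ladder, "primer_ladder"),
            steps >= 1, record_every >= 1)
  if (inherits(inoculations, "inoculation"))
    inoculations <- list(inoculations)
  for (ino in inoculations)
    if (!inherits(ino, "inoculation"))
      stop("inoculations must be a list of inoculation() events",
           call. = FALSE)
  structure(list(params = params, surface_ladder = surface_ladder,
                 template_ladder = template_ladder,
                 steps = as.numeric(steps), seed = as.integer(seed),
                 inoculations = inoculations,
                 no_termination = isTRUE(no_termination),
                 record_every = as.numeric(record_every)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d steps, seed %d, record every %d, %d inoculation(s)%s\n",
              x$steps, x$seed, x$record_every, length(x$inoculations),
              if (x$no_termination) ", no-termination control" else ""))
  print(x$params)
  invisible(x)
}

inoculations_df <- function(inoculations) {
  if (length(inoculations) == 0)
    return(data.frame(step = numeric(0), count = integer(0),
                      length = integer(0), chirality = character(0),
                      sequence = character(0)))
  do.call(rbind, lapply(inoculations, function(i)
    data.frame(step = i$step, count = i$count, length = i$length,
               chirality = i$chirality,
               sequence = if (identical(i$sequence, "random")) ""
                          else i$sequence)))
}

#' Advance a state by a number of Monte-Carlo steps
#'
#' Low-level driver: executes the fixed per-step phase order -- (1) ribozyme
#' census fixing per-room NSR/REP catalysis credits, (2) precursor
#' racemization and nucleotide formation, (3) free-nucleotide decay,
#' (4) `C_T` pairwise collision rounds (surface ligation or template
#' attraction), (5) template-directed ligation, (6) end decay and bond
#' breaking, (7) duplex separation, (8) movement. Uses the current R RNG
#' stream: call `set.seed()` first for reproducibility, or use [run_sim()].
#'
#' @param state a `chiro_state`.
#' @param config a [sim_config()]; its `steps` field is ignored in favour of
#'   `steps`.
#' @param steps number of steps to execute.
#' @param record_every record observables every this many steps (0 = none).
#' @param record_initial include a record of the incoming state.
#' @param verbose print a progress line (step, ee, molecule counts) every
#'   1e4 steps.
#' @return A list with `state` (the advanced `chiro_state`), `records`
#'   (tibble of trajectory records) and `clamped` (number of effective
#'   probabilities clamped into `[0, 1]`).
#' @export
advance_state <- function(state, config, steps = config$steps,
                          record_every = config$record_every,
                          record_initial = FALSE, verbose = FALSE) {
  stopifnot(inherits(state, "chiro_state"), inherits(config, "sim_config"))
  control <- list(
    steps = as.numeric(steps),
    record_every = as.numeric(record_every),
    record_initial = isTRUE(record_initial),
    verbose = isTRUE(verbose),
    no_termination = config$no_termination,
    surface_ladder = ladder_vec(config$surface_ladder),
    template_ladder = ladder_vec(config$template_ladder),
    inoculations = inoculations_df(config$inoculations))
  res <- cpp_run(unclass(state), unclass(config$params), control)
  if (res$clamped > 0)
    warning(sprintf("%d effective probabilities were clamped into [0, 1]",
                    res$clamped), call. = FALSE)
  list(state = new_state(res$state),
       records = tibble::as_tibble(res$records),
       clamped = res$clamped)
}

#' Run a complete simulation
#'
#' Seeds the RNG, initializes a racemic precursor pool, executes the
#' configured number of steps with the scheduled inoculations, and returns
#' the recorded trajectory.
#'
#' @param config a [sim_config()].
#' @param verbose print a progress line every 1e4 steps.
#' @return A `chiro_trajectory`: list with `records` (tibble, one row per
#'   recorded step, including the initial state), `final_state`, `config`
#'   and `seed`.
#' @examples
#' cfg <- sim_config(sim_params(N = 5, T_NPB = 200), steps = 200,
#'                   seed = 42, record_every = 100)
#' tr <- run_sim(cfg)
#' tr$records[, c("step", "ee", "D_total", "L_total")]
#' @export
run_sim <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- initialize_state(config$params, seed = NULL)
  res <- advance_state(state, config, steps = config$steps,
                       record_every = config$record_every,
                       record_initial = TRUE, verbose = verbose)
  structure(list(records = res$records, final_state = res$state,
                 config = config, seed = config$seed,
                 clamped = res$clamped),
            class = "chiro_trajectory")
}

#' @export
print.chiro_trajectory <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<chiro_trajectory> %d records over %g steps (seed %d); final ee = %.4f\n",
              n, x$records$step[n], x$seed, x$records$ee[n]))
  invisible(x)
}

#' Trajectory summary statistics
#'
#' @param traj a `chiro_trajectory`, or a records tibble.
#' @param last_frac fraction of the run (by recorded rows, from the end)
#'   over which the time-averaged ee is taken.
#' @return A one-row tibble with `final_ee`, `mean_ee_last` (time-averaged
#'   ee over the final `last_frac` of records), `mean_abs_ee`, and
#'   `max_abs_ee` over every recorded step.
#' @export
ee_summary <- function(traj, last_frac = 0.5) {
  rec <- if (inherits(traj, "chiro_trajectory")) traj$records else traj
  n <- nrow(rec)
  tail_idx <- seq.int(max(1L, n - ceiling(n * last_frac) + 1L), n)
  tibble::tibble(final_ee = rec$ee[n],
                 mean_ee_last = mean(rec$ee[tail_idx]),
                 mean_abs_ee = mean(abs(rec$ee)),
                 max_abs_ee = max(abs(rec$ee)))
}
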