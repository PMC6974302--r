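# Shared fixtures and oracles for the test suite.  All fixtures are built in
# code; Monte-Carlo frequency checks use a 3-sigma binomial band around the
# closed-form rate.

# parameter set with every event switched off; tests enable one rate at a time
zero_params <- function(...) {
  zeros <- as.list(setNames(rep(0, 14),
                            c("P_AT", "P_BB", "P_CIC", "P_FP", "P_MN",
                              "P_MPN", "P_ND", "P_NDE", "P_NF", "P_NFR",
                              "P_RL", "P_SP", "P_TL", "P_TLR")))
  do.call(sim_params, utils::modifyList(zeros, list(...)))
}

# advance a state one step under the given params (no recording)
step_once <- function(state, params, seed, C_T = NULL,
                      surface_ladder = primer_ladder(),
                      template_ladder = primer_ladder(),
                      no_termination = FALSE, steps = 1) {
  cfg <- sim_config(params, steps = steps, seed = seed, record_every = steps,
                    surface_ladder = surface_ladder,
                    template_ladder = template_ladder,
                    no_termination = no_termination)
  set.seed(seed)
  advance_state(state, cfg, steps = steps, record_every = 0)
}

# 3-sigma binomial band check: observed successes out of n trials at rate p
expect_binomial <- function(observed, n, p, label = "event") {
  mu <- n * p
  sig <- sqrt(n * p * (1 - p))
  expect_true(abs(observed - mu) <= 3 * sig + 1e-9,
              label = sprintf("%s frequency %d/%d vs expected %.1f +- %.1f",
                              label, observed, n, mu, 3 * sig))
}

# a grid-room data frame with one precursor per row
prec_df <- function(n, chirality = "D", row = 0, col = 0) {
  data.frame(row = row, col = col, chirality = rep(chirality, n))
}

chain_df <- function(seqs, chirs, row = 0, col = 0) {
  data.frame(row = row, col = col, seq = seqs, chir = chirs)
}

# a template complex occupying one room
complex_spec <- function(row, col, template_seq, template_chir, att_start,
                         att_seq, att_chir) {
  list(row = row, col = col, template_seq = template_seq,
       template_chir = template_chir, att_start = as.integer(att_start),
       att_seq = att_seq, att_chir = att_chir)
}

# number of D->L / L->D switches along a chirality string
n_switches <- function(chir) {
  v <- strsplit(chir, "")[[1]]
  sum(v[-1] != v[-length(v)])
}

is_homochiral <- function(chir) length(unique(strsplit(chir, "")[[1]])) == 1L

# all chain chirality strings in a state, including template complexes
all_chirs <- function(state) {
  out <- state$chains$chir
  for (cx in state$complexes)
    out <- c(out, cx$template_chir, cx$att_chir)
  out
}

# Reduced-scale scenario batches are expensive (tens of seconds per run), and
# several acceptance properties interrogate the same batch, so runs are
# cached per session.
.batch_cache <- new.env(parent = emptyenv())

regime_batch <- function(name, seeds = 1:10, T_NPB = NULL, steps = NULL,
                         record_every = NULL) {
  key <- paste(name, paste(seeds, collapse = ","), T_NPB, steps, sep = "|")
  if (!is.null(.batch_cache[[key]])) return(.batch_cache[[key]])
  sc <- scenario(name, reduced = TRUE)
  if (!is.null(T_NPB)) sc$config$params$T_NPB <- as.integer(T_NPB)
  if (!is.null(steps)) sc$config$steps <- steps
  if (!is.null(record_every)) sc$config$record_every <- record_every
  res <- run_scenario(sc, seeds = seeds)
  out <- list(summary = res$summary,
              ee_series = lapply(res$trajectories, function(t) t$records$ee))
  .batch_cache[[key]] <- out
  out
}
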