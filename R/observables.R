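#' Trajectory record of a system state
#'
#' Computes, in one pass over a state, the observables recorded along a
#' trajectory: the enantiomeric excess, enantiomer totals (precursors, free
#' nucleotides and every chain residue, including residues inside template
#' complexes), precursor and free-nucleotide counts per chirality, active
#' ribozyme counts, and chain-length histograms per chirality (lengths 1-20
#' with an overflow bin at 21+; templates and each attached substrate count
#' as chains of their own lengths; a heterochiral chain is classified by its
#' majority residue chirality, ties following its first residue).
#'
#' This is a pure R implementation, independent of the engine's internal
#' bookkeeping, so the two can be cross-checked.
#'
#' @param state a `chiro_state`.
#' @param params a [sim_params()] supplying the ribozyme domains.
#' @return A one-row tibble with the same columns as `run_sim()$records`.
#' @export
record_state <- function(state, params = sim_params()) {
  stopifnot(inherits(state, "chiro_state"))
  tot <- enantiomer_totals(state)
  if (sum(tot) == 0)
    stop("cannot record an empty system", call. = FALSE)
  nD <- function(s) sum(s == "D")
  prec_D <- nD(state$precursors$chirality)
  prec_L <- nrow(state$precursors) - prec_D

  all_chains <- character(0)
  all_chirs <- character(0)
  free_flag <- logical(0)
  if (nrow(state$chains)) {
    all_chains <- state$chains$seq
    all_chirs <- state$chains$chir
    free_flag <- rep(TRUE, nrow(state$chains))
  }
  for (cx in state$complexes) {
    all_chains <- c(all_chains, cx$template_seq, cx$att_seq)
    all_chirs <- c(all_chirs, cx$template_chir, cx$att_chir)
    free_flag <- c(free_flag, rep(FALSE, 1L + length(cx$att_seq)))
  }

  lens <- nchar(all_chains)
  nt_D <- sum(free_flag & lens == 1L & all_chirs == "D")
  nt_L <- sum(free_flag & lens == 1L & all_chirs == "L")

  hist_D <- integer(21)
  hist_L <- integer(21)
  nsr <- c(D = 0L, L = 0L)
  rep_ <- c(D = 0L, L = 0L)
  for (i in seq_along(all_chains)) {
    ch <- strsplit(all_chirs[i], "")[[1]]
    d <- sum(ch == "D")
    l <- length(ch) - d
    cls <- if (d > l) "D" else if (l > d) "L" else ch[1]
    bin <- min(lens[i], 21L)
    if (cls == "D") hist_D[bin] <- hist_D[bin] + 1L
    else hist_L[bin] <- hist_L[bin] + 1L
    if (free_flag[i]) {
      z <- detect_ribozyme(all_chains[i], params$CS_NSR, all_chirs[i])
      if (z$active) nsr[z$chirality] <- nsr[z$chirality] + 1L
      z <- detect_ribozyme(all_chains[i], params$CS_REP, all_chirs[i])
      if (z$active) rep_[z$chirality] <- rep_[z$chirality] + 1L
    }
  }
  out <- tibble::tibble(
    step = state$step,
    ee = unname((tot["D"] - tot["L"]) / sum(tot)),
    D_total = unname(tot["D"]), L_total = unname(tot["L"]),
    prec_D = prec_D, prec_L = prec_L, nt_D = nt_D, nt_L = nt_L,
    nsr_D = unname(nsr["D"]), nsr_L = unname(nsr["L"]),
    rep_D = unname(rep_["D"]), rep_L = unname(rep_["L"]))
  labs <- c(as.character(1:20), "21plus")
  for (j in 1:21) out[[paste0("len", labs[j], "_D")]] <- hist_D[j]
  for (j in 1:21) out[[paste0("len", labs[j], "_L")]] <- hist_L[j]
  out
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config$params)), collapse = "")
  s <- paste0(s, paste(deparse(config[c("surface_ladder", "template_ladder",
                                        "steps", "no_termination")]),
                       collapse = ""))
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

#' Write / read a trajectory as TSV
#'
#' One row per record; header comment lines carry the seed and a hash of the
#' configuration so runs can be told apart. The round trip is lossless.
#'
#' @param traj a `chiro_trajectory`, or a records tibble (then `seed` and
#'   `hash` may be given explicitly).
#' @param path file path.
#' @param seed,hash metadata when `traj` is a bare records table.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a list with `records`, `seed` and `hash`.
#' @export
write_trajectory <- function(traj, path, seed = NA_integer_,
                             hash = NA_character_) {
  if (inherits(traj, "chiro_trajectory")) {
    rec <- traj$records
    seed <- traj$seed
    hash <- config_hash(traj$config)
  } else {
    rec <- traj
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed=%s", seed), sprintf("# config_hash=%s", hash)),
             con)
  utils::write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(m) == 0) return(NA_character_)
    sub(sprintf("^# %s=", key), "", m[1])
  }
  rec <- tryCatch(
    utils::read.delim(path, comment.char = "#", check.names = FALSE),
    error = function(e)
      stop(sprintf("malformed trajectory file %s: %s", path,
                   conditionMessage(e)), call. = FALSE))
  if (nrow(rec) > 0 && !all(c("step", "ee") %in% names(rec)))
    stop(sprintf("malformed trajectory file %s: missing step/ee columns",
                 path), call. = FALSE)
  list(records = tibble::as_tibble(rec),
       seed = suppressWarnings(as.integer(get_meta("seed"))),
       hash = get_meta("config_hash"))
}
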