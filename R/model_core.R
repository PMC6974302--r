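#' Molecular species constructors
#'
#' Molecules carry a chirality (`"D"` or `"L"`) per residue. A free
#' nucleotide and a 1-residue RNA chain are the same species: `nucleotide()`
#' simply returns a 1-mer [rna_chain()], the canonical representation.
#'
#' @param chirality `"D"` or `"L"`.
#' @param seq base string over `A`, `U`, `C`, `G`.
#' @param chir chirality string over `D`/`L`, one character per residue; a
#'   single character is recycled to the chain length.
#' @param base a single base for `nucleotide()`.
#' @return `precursor()` returns a `chiro_precursor`; `rna_chain()` and
#'   `nucleotide()` return a `chiro_chain`.
#' @examples
#' rna_chain("ACUGGC", "D")          # homochiral D 6-mer
#' nucleotide("A", "L")              # 1-mer chain
#' @export
precursor <- function(chirality) {
  stopifnot(chirality %in% c("D", "L"))
  structure(list(chirality = chirality), class = "chiro_precursor")
}

#' @rdname precursor
#' @export
rna_chain <- function(seq, chir) {
  seq <- toupper(seq)
  if (!grepl("^[AUCG]+$", seq))
    stop("seq must be a non-empty string over A/U/C/G", call. = FALSE)
  if (nchar(chir) == 1L) chir <- strrep(chir, nchar(seq))
  if (nchar(chir) != nchar(seq) || !grepl("^[DL]+$", chir))
    stop("chir must be a D/L string matching seq in length", call. = FALSE)
  structure(list(seq = seq, chir = chir), class = "chiro_chain")
}

#' @rdname precursor
#' @export
nucleotide <- function(base, chirality) {
  stopifnot(nchar(base) == 1L)
  rna_chain(base, chirality)
}

#' Chain length (residue count, the relative mass m)
#' @param chain a `chiro_chain`.
#' @return Integer residue count.
#' @export
chain_length <- function(chain) {
  stopifnot(inherits(chain, "chiro_chain"))
  nchar(chain$seq)
}

#' Mirror a molecule or a whole system state
#'
#' Global D/L relabeling: every chirality is flipped, bases are untouched.
#' `mirror(mirror(x))` is the identity.
#'
#' @param x a `chiro_precursor`, `chiro_chain` or `chiro_state`.
#' @return The mirrored object of the same class.
#' @export
mirror <- function(x) UseMethod("mirror")

flip_chir <- function(s) chartr("DL", "LD", s)

#' @export
mirror.chiro_precursor <- function(x) precursor(flip_chir(x$chirality))

#' @export
mirror.chiro_chain <- function(x) rna_chain(x$seq, flip_chir(x$chir))

#' @export
mirror.chiro_state <- function(x) {
  x$precursors$chirality <- flip_chir(x$precursors$chirality)
  x$chains$chir <- flip_chir(x$chains$chir)
  x$complexes <- lapply(x$complexes, function(cx) {
    cx$template_chir <- flip_chir(cx$template_chir)
    cx$att_chir <- flip_chir(cx$att_chir)
    cx
  })
  x
}

#' Initialize a racemic system state
#'
#' Places `T_NPB/2` D-precursors and `T_NPB/2` L-precursors uniformly at
#' random over the N x N toroidal grid (an odd `T_NPB` assigns the leftover
#' molecule to either chirality with equal probability). The initial
#' enantiomeric excess is 0 for even `T_NPB`.
#'
#' @param params a [sim_params()].
#' @param seed integer RNG seed; the same seed reproduces the state exactly.
#' @return A `chiro_state`.
#' @examples
#' st <- initialize_state(sim_params(N = 5, T_NPB = 100), seed = 1)
#' ee_statistic(st)
#' @export
initialize_state <- function(params, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  st <- cpp_initialize(unclass(params), params$T_NPB)
  new_state(st)
}

new_state <- function(raw) {
  raw$precursors <- tibble::as_tibble(raw$precursors)
  raw$chains <- tibble::as_tibble(raw$chains)
  class(raw) <- "chiro_state"
  raw
}

#' Construct a system state explicitly (for experiments and tests)
#'
#' @param N grid side.
#' @param precursors data frame with columns `row`, `col` (0-based) and
#'   `chirality`.
#' @param chains data frame with columns `row`, `col`, `seq`, `chir`.
#' @param complexes list of template complexes, each a list with `row`,
#'   `col`, `template_seq`, `template_chir`, `att_start` (0-based template
#'   positions), `att_seq`, `att_chir`. Attachments must form one contiguous
#'   block.
#' @param step step counter.
#' @return A `chiro_state`.
#' @export
make_state <- function(N, precursors = NULL, chains = NULL,
                       complexes = list(), step = 0) {
  empty_prec <- data.frame(row = integer(0), col = integer(0),
                           chirality = character(0))
  empty_chain <- data.frame(row = integer(0), col = integer(0),
                            seq = character(0), chir = character(0))
  if (is.null(precursors)) precursors <- empty_prec
  if (is.null(chains)) chains <- empty_chain
  chains <- as.data.frame(chains)
  if (nrow(chains)) {
    short <- nchar(chains$chir) == 1L & nchar(chains$seq) > 1L
    chains$chir[short] <- strrep(chains$chir[short], nchar(chains$seq[short]))
  }
  st <- list(N = as.integer(N), step = as.numeric(step),
             precursors = as.data.frame(precursors), chains = chains,
             complexes = complexes)
  ok <- function(v, lim) all(v >= 0 & v < lim)
  if (!ok(st$precursors$row, N) || !ok(st$precursors$col, N) ||
      !ok(st$chains$row, N) || !ok(st$chains$col, N))
    stop("room coordinates must lie in [0, N)", call. = FALSE)
  st$precursors$row <- as.integer(st$precursors$row)
  st$precursors$col <- as.integer(st$precursors$col)
  st$chains$row <- as.integer(st$chains$row)
  st$chains$col <- as.integer(st$chains$col)
  st$complexes <- lapply(st$complexes, function(cx) {
    cx$row <- as.integer(cx$row); cx$col <- as.integer(cx$col)
    cx$att_start <- as.integer(cx$att_start)
    cx
  })
  new_state(st)
}

#' @export
print.chiro_state <- function(x, ...) {
  cat(sprintf("<chiro_state> %dx%d grid, step %g: %d precursors, %d chains, %d complexes (mass %d)\n",
              x$N, x$N, x$step, nrow(x$precursors), nrow(x$chains),
              length(x$complexes), state_mass(x)))
  invisible(x)
}

#' Nucleotide-equivalent mass and enantiomer totals of a state
#'
#' Every precursor, free nucleotide and chain residue (including residues
#' inside template complexes) counts one nucleotide-equivalent.
#'
#' @param state a `chiro_state`.
#' @return `state_mass()`: a single integer. `enantiomer_totals()`: named
#'   integer vector `c(D = ..., L = ...)`.
#' @export
state_mass <- function(state) {
  sum(enantiomer_totals(state))
}

#' @rdname state_mass
#' @export
enantiomer_totals <- function(state) {
  stopifnot(inherits(state, "chiro_state"))
  count_d <- function(s) if (length(s)) sum(nchar(gsub("L", "", s))) else 0L
  count_l <- function(s) if (length(s)) sum(nchar(gsub("D", "", s))) else 0L
  d <- count_d(state$precursors$chirality) + count_d(state$chains$chir)
  l <- count_l(state$precursors$chirality) + count_l(state$chains$chir)
  for (cx in state$complexes) {
    d <- d + count_d(cx$template_chir) + count_d(cx$att_chir)
    l <- l + count_l(cx$template_chir) + count_l(cx$att_chir)
  }
  c(D = as.integer(d), L = as.integer(l))
}

#' Enantiomeric excess of a system state
#'
#' `ee = (D - L) / (D + L)` where D and L sum every nucleotide precursor,
#' free nucleotide and nucleotide residue in RNA (including residues inside
#' template complexes) of the corresponding handedness.
#'
#' @param state a `chiro_state`.
#' @return A value in `[-1, 1]`.
#' @examples
#' st <- make_state(2, chains = data.frame(row = 0, col = 0,
#'                                         seq = "ACUGGC", chir = "D"))
#' ee_statistic(st) # 1: all material is D
#' @export
ee_statistic <- function(state) {
  tot <- enantiomer_totals(state)
  if (sum(tot) == 0)
    stop("ee is undefined for an empty system", call. = FALSE)
  unname((tot["D"] - tot["L"]) / (tot["D"] + tot["L"]))
}

#' Ribozyme recognition
#'
#' A single-stranded chain is an active ribozyme for a catalytic domain iff
#' (a) its length does not exceed twice the domain length, (b) it contains
#' the domain as a contiguous base subsequence (chains are directionless, so
#' both residue orders are checked), and (c) the matched residues all share
#' one chirality. If several matches exist, any uniform-handedness match
#' activates the ribozyme.
#'
#' @param chain a `chiro_chain`, or a base string (then `chir` must be
#'   given).
#' @param domain the catalytic domain base string, e.g. `"ACUGGC"` (NSR) or
#'   `"GUUCAG"` (REP).
#' @param chir optional chirality string when `chain` is given as a string.
#' @return A list with `active` (logical) and `chirality` (`"D"`, `"L"`, or
#'   `NA` when inactive).
#' @examples
#' detect_ribozyme(rna_chain("ACUGGC", "D"), "ACUGGC")
#' @export
detect_ribozyme <- function(chain, domain, chir = NULL) {
  if (inherits(chain, "chiro_chain")) {
    seq <- chain$seq
    chir <- chain$chir
  } else {
    seq <- toupper(chain)
    if (is.null(chir)) stop("chir required when chain is a string",
                            call. = FALSE)
    if (nchar(chir) == 1L) chir <- strrep(chir, nchar(seq))
  }
  res <- cpp_detect_ribozyme(seq, chir, toupper(domain))
  list(active = res$active, chirality = res$chirality)
}

#' Per-molecule snapshot table of a state
#'
#' One row per molecule: room coordinates (0-based), species (`precursor`,
#' `chain`, `template`, `substrate`), chirality (`D`, `L` or `mixed`),
#' length, sequence, and whether the molecule is an active NSR or REP.
#' Templates and their attached substrates share a `complex` id.
#'
#' @param state a `chiro_state`.
#' @param params a [sim_params()] supplying the ribozyme domains.
#' @return A tibble.
#' @export
state_molecules <- function(state, params = sim_params()) {
  stopifnot(inherits(state, "chiro_state"))
  rows <- list()
  add <- function(row, col, species, chir, seq, complex = NA_integer_,
                  nsr = FALSE, rep = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      row = row, col = col, species = species, chirality = chir,
      length = if (is.na(seq)) 1L else nchar(seq), seq = seq,
      complex = complex, nsr = nsr, rep = rep)
  }
  if (nrow(state$precursors))
    for (i in seq_len(nrow(state$precursors)))
      add(state$precursors$row[i], state$precursors$col[i], "precursor",
          state$precursors$chirality[i], NA_character_)
  chir_label <- function(ch) {
    u <- unique(strsplit(ch, "")[[1]])
    if (length(u) == 1L) u else "mixed"
  }
  if (nrow(state$chains))
    for (i in seq_len(nrow(state$chains))) {
      sq <- state$chains$seq[i]; ch <- state$chains$chir[i]
      add(state$chains$row[i], state$chains$col[i], "chain",
          chir_label(ch), sq,
          nsr = detect_ribozyme(sq, params$CS_NSR, ch)$active,
          rep = detect_ribozyme(sq, params$CS_REP, ch)$active)
    }
  for (k in seq_along(state$complexes)) {
    cx <- state$complexes[[k]]
    add(cx$row, cx$col, "template", chir_label(cx$template_chir),
        cx$template_seq, complex = k)
    for (j in seq_along(cx$att_seq))
      add(cx$row, cx$col, "substrate", chir_label(cx$att_chir[j]),
          cx$att_seq[j], complex = k)
  }
  if (length(rows) == 0)
    return(tibble::tibble(row = integer(0), col = integer(0),
                          species = character(0), chirality = character(0),
                          length = integer(0), seq = character(0),
                          complex = integer(0), nsr = logical(0),
                          rep = logical(0)))
  tibble::as_tibble(do.call(rbind, rows))
}

#' Write a spatial snapshot as TSV
#'
#' Emits the [state_molecules()] table, sufficient for external rendering of
#' per-room occupancy frames (dot diameter proportional to the square root
#' of chain length, etc.).
#'
#' @inheritParams state_molecules
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path, params = sim_params()) {
  tab <- state_molecules(state, params)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
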