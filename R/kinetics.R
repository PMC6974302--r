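#' Kinetic rate formulas
#'
#' Closed-form per-step event probabilities of the model. These are the
#' formulas the simulation engine applies; they are exposed so that rates
#' can be inspected and tested against empirical event frequencies.
#'
#' * `end_decay_probability()`: a chain-end residue decays at `P_NDE` when
#'   single-stranded; a duplex end loses both paired residues together at
#'   `P_NDE^(3/2)` (synergistic decay).
#' * `bond_break_probability()`: a phosphodiester bond breaks at `P_BB` in a
#'   single-stranded region; in a duplex region the two parallel bonds break
#'   together at `P_BB^(3/2)`.
#' * `separation_probability()`: a duplex of `r` base pairs separates at
#'   `P_SP^((r+1)/2)`, strictly decreasing in `r` for `P_SP` in (0, 1).
#' * `movement_probability()`: a precursor moves at `P_MPN`; an RNA of
#'   relative mass `m` residues (a template complex moves as one unit with
#'   the mass of all its residues) moves at `P_MN / sqrt(m)`.
#'
#' @param end_is_paired,site_in_duplex_region logical.
#' @param r base-pair count (>= 1).
#' @param mol a `chiro_precursor`, a `chiro_chain`, or a numeric relative
#'   mass.
#' @param params a [sim_params()].
#' @return A probability in `[0, 1]`.
#' @examples
#' p <- sim_params()
#' separation_probability(1, p)  # P_SP itself
#' movement_probability(rna_chain("ACGU", "D"), p)  # P_MN / 2
#' @name kinetics
NULL

#' @rdname kinetics
#' @export
end_decay_probability <- function(end_is_paired, params) {
  ifelse(end_is_paired, params$P_NDE^1.5, params$P_NDE)
}

#' @rdname kinetics
#' @export
bond_break_probability <- function(site_in_duplex_region, params) {
  ifelse(site_in_duplex_region, params$P_BB^1.5, params$P_BB)
}

#' @rdname kinetics
#' @export
separation_probability <- function(r, params) {
  if (any(r < 1)) stop("r must be >= 1", call. = FALSE)
  params$P_SP^((r + 1) / 2)
}

#' @rdname kinetics
#' @export
movement_probability <- function(mol, params) {
  if (inherits(mol, "chiro_precursor")) return(params$P_MPN)
  m <- if (inherits(mol, "chiro_chain")) chain_length(mol) else as.numeric(mol)
  if (any(m < 1)) stop("relative mass must be >= 1", call. = FALSE)
  clamp01(params$P_MN / sqrt(m))
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)

#' Single-molecule stochastic events
#'
#' Per-step Bernoulli events on individual molecules, returning an outcome
#' with the products replacing the input. All chemical events conserve
#' nucleotide-equivalent mass, and all conserve chirality except
#' `racemize()`, the only chirality-changing event in the model (only
#' precursors racemize; D- and L-nucleotides cannot interconvert directly).
#'
#' * `racemize()`: a precursor flips handedness with `P_CIC`.
#' * `form_nucleotide()`: a precursor becomes a nucleotide of the same
#'   handedness, its base drawn uniformly from A/U/C/G. When same-chirality
#'   NSR catalysis is available (`nsr_credit > 0`) the success probability
#'   is `P_NFR` and a credit is consumed on success; otherwise it is `P_NF`.
#' * `decay_nucleotide()`: a free nucleotide (1-mer chain) reverts to a
#'   precursor of the same handedness with `P_ND`; the base identity is
#'   lost.
#'
#' @param p a `chiro_precursor`.
#' @param n a 1-mer `chiro_chain`.
#' @param nsr_credit number of same-chirality NSR molecules still available
#'   for catalysis in the room this step.
#' @param params a [sim_params()].
#' @return A list with `occurred` (logical), `products` (list of molecules),
#'   and for `form_nucleotide()` also `credit_used`.
#' @examples
#' set.seed(1)
#' racemize(precursor("D"), sim_params())
#' @name events
NULL

#' @rdname events
#' @export
racemize <- function(p, params) {
  stopifnot(inherits(p, "chiro_precursor"))
  if (runif(1) < params$P_CIC)
    list(occurred = TRUE, products = list(mirror(p)))
  else
    list(occurred = FALSE, products = list(p))
}

#' @rdname events
#' @export
form_nucleotide <- function(p, nsr_credit = 0, params = sim_params()) {
  stopifnot(inherits(p, "chiro_precursor"), nsr_credit >= 0)
  rate <- if (nsr_credit > 0) params$P_NFR else params$P_NF
  if (runif(1) < rate) {
    base <- sample(c("A", "U", "C", "G"), 1)
    list(occurred = TRUE,
         products = list(nucleotide(base, p$chirality)),
         credit_used = nsr_credit > 0)
  } else {
    list(occurred = FALSE, products = list(p), credit_used = FALSE)
  }
}

#' @rdname events
#' @export
decay_nucleotide <- function(n, params) {
  stopifnot(inherits(n, "chiro_chain"), chain_length(n) == 1L)
  if (runif(1) < params$P_ND)
    list(occurred = TRUE, products = list(precursor(n$chir)))
  else
    list(occurred = FALSE, products = list(n))
}
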