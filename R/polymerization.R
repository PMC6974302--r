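#' Cross-inhibition: is a chain end blocked for further extension?
#'
#' Incorporation of an opposite-handed residue terminates elongation.
#' Termination is encoded structurally: an end is blocked iff the terminal
#' residue's chirality differs from its neighbour's (a heterochiral junction
#' at that end). Breaking a chain behind the junction therefore yields an
#' unblocked homochiral fragment, matching the chemistry of removing the
#' inhibiting residue. Length-1 chains are never blocked.
#'
#' @param chain a `chiro_chain`.
#' @param end `"front"` (residue 1) or `"back"` (last residue).
#' @return Logical.
#' @examples
#' end_blocked(rna_chain("AAAU", "DDDL"), "back")  # TRUE
#' @export
end_blocked <- function(chain, end = c("back", "front")) {
  stopifnot(inherits(chain, "chiro_chain"))
  end <- match.arg(end)
  n <- chain_length(chain)
  if (n < 2L) return(FALSE)
  ch <- strsplit(chain$chir, "")[[1]]
  if (end == "front") ch[1] != ch[2] else ch[n] != ch[n - 1]
}

#' Surface-mediated (de novo) ligation rate
#'
#' Rate at which an extending polymer incorporates an incoming molecule in
#' the surface-mediated route:
#' `P_RL * ladder(extender_length) * (1 if same chirality else F_CSS)`,
#' clamped to `[0, 1]`. The ladder multiplier implements the primer effect
#' (extension faster than initiation). Base identity does not constrain
#' surface-mediated ligation; only the template route uses base pairing.
#'
#' @param extender_chirality chirality (`"D"`/`"L"`) of the extender's
#'   joining-end residue.
#' @param incomer_chirality chirality of the incomer's joining-end residue.
#' @param extender_length residue count of the extender before
#'   incorporation.
#' @param params a [sim_params()].
#' @param ladder a [primer_ladder()] for the surface route.
#' @return A probability.
#' @export
surface_ligation_rate <- function(extender_chirality, incomer_chirality,
                                  extender_length, params,
                                  ladder = primer_ladder()) {
  factor <- ifelse(extender_chirality == incomer_chirality, 1, params$F_CSS)
  clamp01(params$P_RL * ladder_multiplier(ladder, extender_length) * factor)
}

#' Non-enzymatic template-directed ligation rate
#'
#' Rate at which a substrate aligned next to the growing chain on a template
#' is ligated:
#' `P_TL * ladder(growing_length) * (1 if the incomer matches both the
#' growing chain and the template in chirality, else F_CST)`, clamped to
#' `[0, 1]`. A blocked growing end (cross-inhibition) ligates at rate 0.
#'
#' @param incomer_chirality chirality of the incoming substrate's junction
#'   residue.
#' @param growing_chirality chirality of the growing chain's junction
#'   residue.
#' @param template_chirality chirality of the template residue paired with
#'   the incomer's junction residue.
#' @param growing_length residue count of the growing chain before
#'   incorporation.
#' @param params a [sim_params()].
#' @param ladder a [primer_ladder()] for the template route.
#' @param blocked is the growing end blocked (see [end_blocked()])?
#' @return A probability.
#' @export
template_ligation_rate <- function(incomer_chirality, growing_chirality,
                                   template_chirality, growing_length,
                                   params, ladder = primer_ladder(),
                                   blocked = FALSE) {
  match <- incomer_chirality == growing_chirality &
    incomer_chirality == template_chirality
  factor <- ifelse(match, 1, params$F_CST)
  rate <- clamp01(params$P_TL * ladder_multiplier(ladder, growing_length) *
                    factor)
  ifelse(blocked, 0, rate)
}

#' Substrate attraction probability onto a template
#'
#' A substrate no longer than the available single-stranded stretch of a
#' template may be attracted onto it, aligned by base pairing. The success
#' probability is `P_AT` times `P_FP` per non-Watson-Crick position
#' (A-U and C-G are the complementary pairs; no wobble). Attraction is
#' chirality-agnostic: all chiral discrimination happens at ligation.
#'
#' @param template_seq base string of the template stretch being paired.
#' @param substrate_seq base string of the substrate, aligned position by
#'   position with `template_seq`.
#' @param params a [sim_params()].
#' @return A probability.
#' @examples
#' attraction_probability("A", "U", sim_params())  # P_AT
#' attraction_probability("A", "A", sim_params())  # P_AT * P_FP
#' @export
attraction_probability <- function(template_seq, substrate_seq, params) {
  t <- strsplit(toupper(template_seq), "")[[1]]
  s <- strsplit(toupper(substrate_seq), "")[[1]]
  if (length(t) != length(s))
    stop("template stretch and substrate must have equal length",
         call. = FALSE)
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  mism <- sum(comp[t] != s)
  clamp01(params$P_AT * params$P_FP^mism)
}
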