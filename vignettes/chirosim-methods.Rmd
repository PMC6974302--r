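---
title: "chirosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chirosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

chirosim simulates the joint emergence of biological homochirality and RNA
on an `N x N` toroidal grid of "rooms". Three chiral species inhabit the
rooms: nucleotide precursors (raw material with a handedness, D or L, but no
base identity), free nucleotides, and RNA chains whose residues each carry a
base (A/U/C/G) and a handedness. A free nucleotide and a 1-residue chain are
the same species and share one canonical representation. Template complexes
— an RNA template with substrates aligned on it by base pairing — represent
replication intermediates.

Time advances in synchronous Monte-Carlo steps. Every eligible event fires
independently with a fixed per-step probability; there is no thermodynamics
and no secondary structure. Only molecules in the same room can interact
within a step, and molecules diffuse between 4-neighbor (von Neumann) rooms.
The grid wraps in both directions to avoid edge effects, and the
two-dimensional setting stands in for a mineral surface on which de novo
("surface-mediated") RNA synthesis can occur.

The chemistry comprises:

* **Racemization** (`P_CIC`): precursors interconvert between D and L.
  This is the *only* chirality-changing event; nucleotides and residues
  never racemize. Racemization continuously re-balances the precursor pool
  and is what lets one chirality's polymers drain material from the other.
* **Nucleotide formation / decay** (`P_NF`, `P_ND`): a precursor becomes a
  nucleotide of the same handedness with a uniformly random base; a free
  nucleotide decays back, losing its base.
* **Surface-mediated (random) ligation** (`P_RL`): co-located chains and
  nucleotides collide pairwise `C_T` times per step and may join end to
  end. The rate is multiplied by a primer-effect ladder (below) and, when
  the joining ends differ in handedness, by the chiral-selection factor
  `F_CSS`. Base identity does not constrain this route.
* **Template-directed synthesis**: a chain may attract a substrate not
  longer than its available single-stranded stretch (`P_AT`, with `P_FP`
  per mismatched base pair; A–U and C–G only, no wobble), and substrates
  aligned adjacently are ligated (`P_TL`, times the template-route ladder
  and, for an opposite-handed incomer, `F_CST`).
* **Cross-inhibition**: incorporating an opposite-handed residue terminates
  elongation at that end. chirosim encodes this structurally: an end is
  blocked iff its terminal residue differs in handedness from its
  neighbour. This survives fragmentation for free — breaking a chain behind
  the junction yields an unblocked homochiral fragment, which matches the
  chemistry of removing the inhibiting residue.
* **Degradation**: chain-end residues decay at `P_NDE` (both paired
  residues of a duplex end decay together at `P_NDE^(3/2)`), and backbone
  bonds break at `P_BB` (`P_BB^(3/2)` for the two parallel bonds of a
  duplex region, breaking both strands at once). Interior residues are
  protected.
* **Strand separation**: a duplex of `r` base pairs dissociates at
  `P_SP^((r+1)/2)`.
* **Movement**: precursors move at `P_MPN`; an RNA of mass `m` residues at
  `P_MN / sqrt(m)` (Zimm-type size scaling); a template complex moves as
  one unit with the mass of all its residues.
* **Ribozymes**: a single-stranded chain is an active NSR (nucleotide
  synthetase) or REP (replicase/ligase) if it contains the corresponding
  6-nt catalytic domain (`ACUGGC` / `GUUCAG`) as a contiguous base
  subsequence with uniform handedness in the match and is at most twice the
  domain length (too much flanking sequence is assumed to spoil folding).
  An NSR catalyses precursor-to-nucleotide conversion of its own
  handedness (`P_NFR`); a REP catalyses template-directed ligation when
  template, both substrates and the REP share one handedness (`P_TLR`).
  Each ribozyme molecule grants one catalysis credit per room per step.

Function is assigned by sequence lookup, not folding: the model's point is
evolutionary dynamics, and a sequence-function linkage is the minimal
requirement for that.

## Parameters

`sim_params()` holds the full parameter set; defaults are the published
table values. All probabilities are per step and dimensionless.

| symbol | meaning | default |
|---|---|---|
| `P_AT` | template attracts a substrate | 0.5 |
| `P_BB` | backbone bond breaks (single-strand site) | 1e-5 |
| `P_CIC` | precursor racemization | 0.5 |
| `P_FP` | false base pairing, per mismatched position | 0.001 |
| `P_MN` | movement of a nucleotide (mass 1) | 1e-4 |
| `P_MPN` | movement of a precursor | 0.002 |
| `P_ND` | nucleotide decays to precursor | 0.01 |
| `P_NDE` | chain-end residue decays | 1e-4 |
| `P_NF` | nucleotide forms, non-enzymatic | 0.001 |
| `P_NFR` | nucleotide forms, NSR-catalysed | 0 (0.2 when NSR modeled) |
| `P_RL` | surface-mediated ligation | 2e-6 |
| `P_SP` | separation of one base pair | 0.3 |
| `P_TL` | template-directed ligation, non-enzymatic | 0.002 |
| `P_TLR` | template-directed ligation, REP-catalysed | 0 (0.9 when REP modeled) |
| `N` | grid side | 20 |
| `T_NPB` | total precursors at start | 50000 |
| `C_T` | collision rounds per room per step | 8 |
| `F_CSS` | chiral selection, surface route (0 = complete) | 0.5 |
| `F_CST` | chiral selection, template route (0 = complete) | 0.5 |

`P_NFR` and `P_TLR` default to 0 because the ribozyme-catalysed rates are
meaningful only in scenarios that model the corresponding ribozyme; the
`fig4a_nsr` / `fig4b_rep` presets switch them to 0.2 / 0.9.

The exponent 3/2 (rather than 2) for the paired decay and double bond break
reflects a synergistic effect between the two single events; the `(r+1)/2`
exponent in separation reflects self-folding of the single strands aiding
dissociation.

**Primer ladders.** The primer effect — extension being faster than
initiation — is a `primer_ladder(R1, R2, R3, Rn)` of multipliers applied to
the ligation rate according to the extending polymer's current length (1, 2,
3, ≥4 residues; every published ladder has `Rn = R3`, the constructor's
default). Separate ladders configure the surface and template routes.

## The per-step schedule

Each step applies, over all rooms, a fixed phase order: (1) ribozyme census
fixing per-room NSR/REP credits; (2) precursor racemization and nucleotide
formation (consuming NSR credits); (3) free-nucleotide decay; (4) `C_T`
collision rounds — molecules (including template complexes) are grouped
into a uniform random pairwise matching, the odd molecule idling, and each
chain–chain pair attempts either surface ligation or template attraction
(one of the two, chosen uniformly, since both are always formally open
between two free chains), while a chain–complex pair attempts attraction
next to the complex's growing block; (5) template-directed ligation at
every adjacent substrate junction (consuming REP credits); (6) end decay
and bond breaking; (7) duplex separation; (8) movement.

The model defines no ordering, so chirosim fixes one — chemistry before
transport — for determinism, and verifies by a bit-exact mirror test that
no phase leaks a chirality preference: running the globally mirrored
initial state under the same seed yields the exactly negated ee series.
This invariant is the reason every random draw in the engine is made in an
order that never depends on which handedness a molecule carries.

## Design choices where the model is silent

* **Chain polarity.** Chains are directionless (no 3'/5'); ribozyme domain
  matching checks both residue orders, and a multi-residue substrate pairs
  onto a template in a uniformly random orientation.
* **Extender in polymer–polymer ligation.** The longer partner is the
  extender: its length selects the ladder multiplier and its joining-end
  residue defines same/opposite handedness (ties broken at random). The
  published description covers only monomer incorporation; this extends it
  monotonically.
* **Blocked ends.** Ligation (surface or template route) requires *both*
  joining ends unblocked. Gating only the growing chain's end would allow
  extension into an already-terminated junction, burying the inhibiting
  residue, which is exactly what cross-inhibition forbids.
* **Attraction is chirality-agnostic**; all chiral discrimination happens
  at ligation. An opposite-handed substrate can therefore occupy a
  template and never ligate — a structural realization of the inhibitory
  side of cross-inhibition in the template route.
* **First substrate placement** on a bare template is uniform over valid
  positions; subsequent substrates must sit contiguously next to the
  existing block (one growing region per complex; the complementary strand
  cannot itself recruit substrates).
* **Paired-end decay.** The duplex form of end decay applies where a
  template end is paired with the outer residue of the attachment block
  (both residues leave together). An attachment-block end paired to a
  template-*interior* residue is treated as protected: removing its
  partner would cut the template mid-chain, which end decay does not
  describe. Unpaired template ends decay at the single-strand rate.
* **Bond breaking inside complexes** enumerates template bonds: where a
  single attachment spans the bond, the two parallel bonds break together
  at `P_BB^(3/2)` and the complex severs into two complexes preserving
  local pairing; elsewhere (unpaired stretches, or the unligated seam
  between two adjacent attachments, where only one backbone bond exists)
  the template breaks alone at `P_BB`.
* **Ribozymes may simultaneously serve as substrates or templates** in the
  same step; the census is taken at the start of the step.
* **Inoculated molecules** are scattered into uniformly random rooms, with
  uniform random homochiral sequences unless an explicit sequence is given.

## Numerical and implementation notes

Effective rates (probability × multiplier) are clamped into [0, 1] before
sampling; `advance_state()` warns with a count when clamping occurred.
Per-molecule Bernoulli events are sampled as a binomial count of
occurrences plus a uniform choice of which molecules fire — the identical
distribution at a fraction of the RNG cost — and the engine consumes R's
RNG stream, so one `set.seed()` determines everything, bit-exactly, across
repeated runs. Separation probabilities for duplexes up to 64 bp are
precomputed once per run.

Degenerate inputs: an empty system has no defined ee (`ee_statistic()`
raises); an odd `T_NPB` assigns the leftover molecule to either chirality
with equal probability so no systematic bias enters; a 1-residue template's
single duplex end is tested once, not once per nominal end.

## Scenarios, scales and what the tests show

`scenario()` encodes the published experimental regimes: `fig2a_*`
(template route only, inoculated D 6-mers, chiral selection complete /
partial / absent / absent-with-no-termination), `fig2b` (de novo emergence,
either chirality may prevail), `fig3_ladder*` (surface route only under
increasingly strong primer ladders, with the uniform ladder as the
no-deviation control), and `fig4a_nsr` / `fig4b_rep` (ribozyme emergence).
Full-scale presets use the published `N = 20`, `T_NPB = 50000` and run for
3e6–6e6 steps; they are long-running batch jobs, not test material.

Reduced-scale variants keep **every probability and ladder unchanged** and
shrink only the arena: `N = 10`, `T_NPB = 2000`, 2e5 steps, inoculation at
step 5e4, recording every 1e3 steps. At this scale the template-route
symmetry breaking and its controls separate cleanly within minutes of CPU
time. The surface-route (fig3) amplification is intrinsically slower — the
deviation must first sequester a substantial mass fraction into long
homochiral chains — so its regime test runs denser and longer within the
same reduced family (`T_NPB = 4000`, 3e5 steps), a choice made once on the
basis of where the mass-in-polymer fraction becomes appreciable, and
documented here rather than tuned per seed.

The initialization emulates exactly the published starting condition — a
racemic pool of precursors, half D and half L, scattered uniformly — and
the inoculation schedule reproduces the published injections. What the
reduced-scale tests do *not* show is quantitative agreement with the
published trajectories: a stochastic lattice model at one-25th of the
material has larger fluctuations, earlier saturation and rarer ribozyme
emergence. The tests therefore check regime-level properties (control
nullity, strict boundedness of |ee| under degradation, regime separation,
conservation laws, exact mirror symmetry, and closed-form event rates
against empirical frequencies at ≥1e5 trials within binomial 3σ), not
point-by-point curves.

## Known limitations

* No energetics, folding, wobble pairing or strand displacement; fidelity
  is one lumped false-pair probability.
* Ribozyme function is a sequence lookup, so a 6-nt domain is the entire
  genotype–phenotype map; real replicases would be far longer, and
  emergence frequencies here cannot be read quantitatively.
* The synchronous per-step Bernoulli scheduler is the model; it is not an
  exact-stochastic (Gillespie) treatment of the same chemistry.
* Room occupancy does not slow diffusion or crowd out reactions.
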