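# chirosim

Agent-based Monte-Carlo simulation of how biological homochirality can
emerge *together with* RNA, rather than before it.

## The problem

Life's polymers are homochiral — RNA and DNA use D-sugars, proteins
L-amino-acids — yet prebiotic chemistry produces racemic mixtures. Most
work on the origin of homochirality has looked for mechanisms that bias the
*monomer* pool first. chirosim implements the alternative: a spatial
stochastic model of an RNA world in which the bias arises at the *polymer*
level, out of a perfectly racemic pool of nucleotide precursors.

The model places precursors, nucleotides and RNA chains of both
handednesses (D and L) on an N x N toroidal grid. Per Monte-Carlo step,
every event fires independently with a fixed probability: precursor
racemization (P_CIC), nucleotide formation/decay (P_NF, P_ND),
surface-mediated ligation (P_RL), template-directed replication
(attraction P_AT with base-pairing fidelity P_FP, ligation P_TL),
degradation (P_NDE, P_BB, with synergistic 3/2-power rates in duplex
regions), strand separation (P_SP^((r+1)/2) for r base pairs) and
diffusion (P_MN/sqrt(m) for mass m). Two mechanisms couple chirality to
polymerization:

* **chiral selection** — an extending chain or template prefers monomers of
  its own handedness (factors F_CSS, F_CST; 0 = complete selection), and
* **cross-inhibition** — incorporating an opposite-handed monomer
  *terminates* elongation at that end.

Both synthesis routes are autocatalytic with respect to chirality (via a
primer effect for the surface route), so a chance imbalance amplifies: the
majority handedness drains material from the minority through the
racemizing precursor pool. The headline observable is the enantiomeric
excess over all material,

    ee = (D - L) / (D + L),

0 for a racemic system, +-1 for pure chirality. Sequence-defined ribozymes
— a nucleotide synthetase (NSR, domain `ACUGGC`) and a replicase (REP,
domain `GUUCAG`) — can emerge in the deviated background and amplify it
further (rates P_NFR, P_TLR).

## Worked example

Template-directed symmetry breaking at reduced scale: a racemic pool of
2000 precursors on a 10 x 10 grid, complete chiral selection (F_CST = 0),
no de novo synthesis (P_RL = 0), 50 homochiral D 6-mers inoculated at step
20000:

```r
library(chirosim)
cfg <- sim_config(
  params = sim_params(N = 10, T_NPB = 2000, P_TL = 0.01, P_RL = 0,
                      F_CST = 0),
  steps = 1e5, seed = 42, record_every = 2e4,
  inoculations = list(inoculation(step = 2e4, count = 50, length = 6,
                                  chirality = "D")))
tr <- run_sim(cfg)
tr$records[, c("step", "ee", "D_total", "L_total", "nt_D", "nt_L")]
#> # A tibble: 6 x 6
#>     step    ee D_total L_total  nt_D  nt_L
#>    <dbl> <dbl>   <int>   <int> <int> <int>
#> 1      0 0        1000    1000     0     0
#> 2  20000 0.007    1007     993    87    89
#> 3  40000 0.463    1683     617    43    53
#> 4  60000 0.642    1888     412    22    38
#> 5  80000 0.7      1955     345    29    26
#> 6 100000 0.737    1997     303    19    27
```

Before the inoculation the system is racemic (ee fluctuates around 0; the
300 nucleotide-equivalents of inoculated D-RNA appear in the totals from
the next record). The D templates then replicate, consuming D nucleotides;
racemization converts L precursors to D to restore the precursor
equilibrium, and the whole system tips: ee climbs to ~0.74, with most
material now D. It cannot reach 1 — degradation keeps returning residues to
the racemizing pool. Records also carry precursor/nucleotide counts per
handedness, active NSR/REP counts and chain-length histograms (lengths
1–20 and 21+, per handedness).

Scenario presets reproduce each published regime, e.g.
`run_scenario("fig3_ladder200", seeds = 1:10, reduced = TRUE)` for
surface-mediated symmetry breaking under a strong primer ladder, and
`sweep_param()` drives one-parameter sweeps. A thin CLI lives at
`inst/cli/chirosim` (`chirosim run --config FILE`, `chirosim scenario NAME
--reduced`). Configurations round-trip through plain-text key=value files
(`write_config()` / `read_config()`), trajectories and spatial snapshots
through TSV (`write_trajectory()`, `write_snapshot()`).

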