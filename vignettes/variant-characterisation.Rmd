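---
title: "Characterising active-site variants of an mRNA 2'O-methyltransferase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising active-site variants of an mRNA 2'O-methyltransferase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varsite)
```

## The problem

Viral cap-0 2'O-mRNA methyltransferases such as Vaccinia VP39 transfer a
methyl group from s-adenosylmethionine (SAM) onto the 2' oxygen of the first
transcribed nucleotide of capped mRNA. Engineering such enzymes means
measuring, for each active-site variant, three largely independent fitness
axes — whether the protein folds, how thermostable the fold is, and how much
transferase activity survives — and then connecting those phenotypes to the
structural context of the mutated positions: their distance shell around
the catalytic lysine (K175 in VP39), the residues tolerated at the
homologous positions across the protein family, and the hydrogen-bond
architecture of the active site in molecular-dynamics simulations.

`varsite` implements that analysis pipeline end to end, with synthetic-data
generators that carry machine-readable ground truth so every stage is
testable without any external download.

## Distance shells around the catalytic lysine

`assign_shells()` classifies residues by distance from the focal lysine:

* **Shell 1**: residues with at least one side-chain heavy atom within 4 Å
  of the focal residue's side chain.
* **Shell 3**: residues whose nearest side-chain heavy atom lies more than
  6 Å from the focal reference atom (the terminal amine Nζ for a lysine).
* **Shell 2**: not defined by a single published criterion. The default is
  the distance band between the two cutoffs; an alternative graph-expansion
  definition (side-chain contacts of shell-1 residues) is available via
  `second = "graph"`, and the variant used is recorded on the result.
  Neither is asserted to be *the* original convention — that is why both
  are provided and labelled.

Two conventions deliberately coexist for "within 4 Å of residue X": any
side-chain heavy atom of the focal residue (the default, which reproduces
the published first shell of K175: D138, E207, R209), or a single named
atom (`focal_atom = "NZ"`, the convention that reproduces the published
4 Å neighbours of K41's Nζ: L42, E207, Q198, A201). Hydrogens are ignored
(crystal structures rarely carry them), waters and non-"A" altlocs are
dropped, and sequence-adjacent residues are *not* excluded.

```{r shells}
toy <- gen_toy_structure(c(0, 3, 7))
assign_shells(toy$structure, 1)
```

## Family context: sequence-similarity networks

The family analysis follows the standard SSN recipe: every pair of family
sequences is aligned, and an edge connects two sequences when their
alignment scores an E-value *strictly* below 1e-30 (strict, because the
published convention is "lower than"). `pairwise_similarity()` provides a
desk-scale stand-in for an external all-versus-all BLAST run —
Smith–Waterman under BLOSUM62 with affine gaps (open 11, extend 1) and the
Karlin–Altschul E-value `E = K m n exp(-λS)` with the gapped BLOSUM62
constants (λ = 0.267, K = 0.041) — while `parse_blast_tabular()` accepts a
real BLAST tabular file as the faithful route. Reciprocal hits keep the
lower E-value. `map_reference_position()` and `annotate_nodes()` translate
a reference residue number (e.g. position 41) into an MSA column and report
the residue each family member carries there; `column_probabilities()`
yields the per-column frequencies behind a sequence logo, normalised over
non-gap rows with the gap fraction reported separately (logo conventions
differ on gap handling, so both numbers are exposed).

A caution on regression targets: summary statistics such as a family's
median pairwise identity are properties of a particular sequence-database
snapshot and are not reproducible without that exact sequence set; the
package therefore asserts network *construction* properties (brute-force
equality, threshold strictness, monotone edge density), not snapshot
statistics.

## Thermal unfolding from barycentric-mean melt curves

Each emission spectrum collapses to its barycentric mean
$\lambda_{bcm} = \sum_\lambda \lambda I(\lambda) / \sum_\lambda I(\lambda)$,
the intensity-weighted mean emission wavelength. Melt curves are fitted
with either a single transition,

$$I(T) = I_N + \frac{I_D - I_N}{1 + e^{(T_{m1}-T)/a}},$$

or two transitions,

$$I(T) = I_N + \frac{I_2 - I_N}{1 + e^{(T_{m1}-T)/a}}
             + \frac{I_D - I_2}{1 + e^{(T_{m2}-T)/b}},$$

where $I_N, I_2, I_D$ are the native / intermediate / denatured baselines
(nm), $T_{m1} < T_{m2}$ are the transition midpoints (°C) and $a, b > 0$
are cooperativity factors (°C). $T_{m1}$ is always the first (or only)
transition. Model choice uses the small-sample-corrected AICc with ties
going to the single-transition model. The unfolding red-shift is the fitted
baseline difference $I_D - I_N$; a model-free alternative from raw end
averages is available (`red_shift_raw()`) because either reading of the
published analysis is defensible.

Numerical choices: baselines initialise from the first and last 10% of
points, transition candidates sit at the steepest-slope temperature and
±5, ±10 °C, cooperativity starts at 2 °C, and the best residual sum of
squares over all starts wins (`minpack.lm::nlsLM`, bounded so $T_m$ stays
inside the observed range and $a, b \ge 10^{-3}$). A curve whose total
barycentric-mean range is under 0.05 nm is flagged as transition-free
rather than fitted. If the fitted $T_{m2} < T_{m1}$ the transitions are
relabelled (the intermediate baseline maps to $I_N + I_D - I_2$, which
leaves the model values unchanged). Replicates are fitted independently
and summarised by median and range.

```{r melt}
g <- gen_melt_spectra(tm1 = 55, a = 2, bcm_n = 352.2, bcm_d = 360,
                      noise_sd = 0.1, seed = 1)
fit_single_transition(build_melt_curve(g$spectra))
```

## Coupled-assay activity

Activity comes from resorufin fluorescence traces of a four-enzyme coupled
assay read over 30 minutes. `initial_rate()` takes the slope of the longest
initial window whose linear fit reaches R² ≥ 0.98 (minimum 5 points), then
trims trailing points whose residuals are strongly negative relative to the
window scatter — the signature of a developing plateau, which R² alone
detects poorly. Rates are normalised by protein concentration when given.

`activity_ratio()` references everything to the controls: with knock-out
subtraction (the default),
`ratio = (median(variant) − median(ko)) / (median(wt) − median(ko))`,
so the wild type maps to exactly 1 and the knock-out to exactly 0, and the
ratio is invariant under any common detector-gain rescaling. A variant is
flagged **below detection** when its median rate does not exceed the
knock-out median by more than `k` knock-out interquartile ranges (`k = 1`
by default, configurable). A no-subtraction mode and the alternative
median-of-ratios aggregation are both computed, since the published
normalisation does not pin either choice down. Note that with triplicate
controls the `k·IQR` detection margin is itself a noisy quantity, so the
below-detection flag for a variant sitting exactly at the knock-out level
is correct in most but not all noise realisations — a property of the rule,
not of its implementation. `saturation_check()` flags reactions whose rate
reaches the full-conversion positive control.

## Melting-temperature epistasis

For variant tables carrying `tm1`, `single_effects()` computes per-mutation
$\Delta T_m = T_{m1}(\text{mutant}) - T_{m1}(\text{WT})$, and `epistasis()`
compares each multi-mutant's observed $\Delta T_m$ with the additive
expectation (sum of its constituent single-mutant effects; for triples,
the sum of the three singles). The deviation `observed − expected` is the
epistasis score: negative means the combination is worse than additive.
Deviations are exactly 0 for single mutants and invariant under a uniform
shift of all $T_m$ values. For activity ratios a multiplicative
(log-additive) null is reported alongside, the natural analogue on a
strictly positive ratio scale; it is left `NA` when a constituent activity
is censored at zero, where a point expectation would be meaningless.

## Trajectory metrics

Three observables are computed from MD trajectories (read from multi-model
PDB or DCD files against a PDB topology; coordinates are converted to
nanometres internally):

* **Hydrogen-bond occurrence networks** (`occurrence_network()`): per
  residue pair, the number of frames — pooled over replicates — containing
  at least one side-chain-to-side-chain hydrogen bond in either direction,
  plus the occupancy (count / frames). Per-replicate counts are emitted
  alongside the pooled ones, since either may be wanted for edge weights.
* **Catalytic distance series** (`atom_distance_series()`), e.g. the
  Nζ(K175)–2'O distance, whose ~0.3 nm regime marks a catalytically
  competent geometry.
* **Side-chain rigidity** (`sidechain_rmsd_series()`): each frame is
  superposed on the reference over the whole-protein backbone (the default;
  a local fit over the measured residues is available), then the RMSD of
  the side-chain heavy atoms of the chosen residues is taken. The backbone
  fit is deliberate: it retains internal side-chain motion, so a low median
  RMSD reads as an intrinsically rigid active site. Medians and
  interquartile ranges are reported per replicate and pooled.

Hydrogen bonds use the common MD geometric criterion: donor–acceptor
distance ≤ 0.35 nm and hydrogen–donor–acceptor angle ≤ 30°, both
configurable. Hydrogens are attached to their nearest heavy atom within
0.12 nm; donors are N/O atoms carrying a hydrogen, acceptors are N/O atoms.
For hydrogen-free topologies a heavy-atom-only proxy (distance plus a
donor–acceptor–antecedent angle ≥ 90°) is applied and flagged — it is not
equivalent to the hydrogen-resolved criterion. Side chains are heavy atoms
from Cβ outward; glycine in a measured set is an error, not a silent zero.

Equilibration handling: by default the analysis discards frames before the
running mean of the all-atom RMSD (to the first frame, after superposition)
changes by less than 5% across a 1 ns window; an explicit cut time in ps
(including 0, keep everything) can be given instead, and short stable
trajectories are kept whole.

## Fitness classification

`classify()` reproduces the three-axis grouping with strict inequalities
at the published boundaries (defaults: red-shift < 6 nm ⇒ misfolded;
$T_{m1}$ more than 5 °C below WT ⇒ stability penalty; activity < 60% of
WT ⇒ activity penalty). Decision order matters and is fixed: a
sub-threshold red-shift dominates everything (a misfolded protein is
inactive for reasons upstream of active-site chemistry); below-detection
activity then splits into inactive-stable versus inactive-unstable by the
stability criterion; the remaining variants take activity and/or stability
penalty labels or `wt_like`. Missing measurements give an explicit
`unclassifiable` with the reason — never a silent default. The finer
narrative sub-grouping of active variants is annotation, not a threshold
class, and is intentionally out of scope.

## What the generators emulate — and what they do not

* `gen_melt_spectra()` builds each spectrum as a Gaussian mixture (folded /
  optional intermediate / unfolded components, width 20 nm) whose mixing
  weights follow the same sigmoids the fits assume, so the analytic
  barycentric mean equals the model curve; component centres are corrected
  for grid truncation so the discrete barycentric mean matches the nominal
  value to < 0.01 nm. Intensity noise is shot-noise-like and calibrated so
  the induced barycentric-mean scatter has the requested standard
  deviation in nm. Real spectra have asymmetric band shapes and correlated
  baseline drift; none of that is modelled, so passing tests demonstrate
  correct curve algebra and fit behaviour, not instrument realism.
* `gen_kinetic_traces()` produces linear-then-plateau traces with
  replicate-level multiplicative rate noise (default study conditions:
  triplicates, 5% coefficient of variation, 30 min at 1 min sampling).
  The four-enzyme cascade's lag phase is not modelled.
* `gen_toy_structure()` and `gen_toy_trajectory()` place side-chain anchors
  at analytically known distances, schedule ideal hydrogen-bond geometry
  (0.29 nm, 10°) in chosen frames, and add isotropic Gaussian side-chain
  fluctuation about a fixed backbone — sufficient to give shell membership,
  occupancy and RMSD closed-form ground truth, and deliberately *not*
  physical dynamics.
* `gen_sequence_family()` mutates an exact number of positions per member,
  so identity to the root is controlled exactly; substitutions at the
  planted column avoid the planted letter so its count stays as designed.
  There are no indels and no phylogenetic correlation structure.

All generators are byte-deterministic under a fixed seed.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run entirely on synthetic
data sized for a single CPU: 100-replicate melt recovery at 0.1 nm noise,
1000 random 50-atom frames for the hydrogen-bond oracle comparison,
3 × 100-frame toy trajectories for occupancy, 200-frame trajectories per
fluctuation level for RMSD scaling, 200 random hit sets for the network
oracle, and a 9-variant end-to-end bundle in triplicate. Recovery
tolerances asserted on generator data: $T_{m1}$ within 0.05 °C noiseless /
0.5 °C at 0.1 nm noise; red-shift within 0.3 nm; activity ratios within
0.05 (median over 50 seeds); planted occupancies and epistasis terms exact.

## Known limitations

* The internal aligner is a desk-scale stand-in; for publication-grade
  networks, run an external all-versus-all BLAST and import the tabular
  hits.
* XTC trajectories are not supported (no reader available to the package);
  convert to DCD or multi-model PDB.
* mmCIF structures, homology modelling of missing loops, pKa estimation
  and electrostatic-surface analysis are out of scope.
* Activity epistasis on censored (below-detection) variants is reported as
  a bound/NA rather than a point estimate.
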