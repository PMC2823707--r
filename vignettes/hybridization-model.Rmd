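---
title: "A multi-state thermodynamic model of microarray hybridization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-state thermodynamic model of microarray hybridization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

On a tiling microarray, probes are placed along a reference at a fixed
step with no selection for hybridization behaviour.  Probes reading the
same transcript routinely differ in fluorescence by one to two orders of
magnitude, and this variation is sequence driven.  `hybtherm` models the
signal of a perfect-match probe as the outcome of a competition: the
probe-target duplex forms only to the extent that the probe is not
folded on itself, the binding site in the target is not sequestered in
target structure, and the probe is not dimerised with its neighbours on
the feature.

## The model

For each probe the package assembles an energy profile:

$$\Delta G \;=\; \Delta G_h - \Delta G_p - \Delta G_t - \Delta G_{pp},$$

where every term is a non-positive free energy (kcal/mol) and unstable
structures contribute zero:

* $\Delta G_h$: nearest-neighbor free energy of the probe against its
  exact antiparallel complement — dinucleotide stack terms plus a duplex
  initiation term.  cDNA targets use the DNA/DNA table; RNA targets use
  the RNA/DNA hybrid table, which is keyed by the RNA strand and is
  *not* symmetric under reverse-complement.  The value is clamped at 0
  for (hypothetical) unstable duplexes.
* $\Delta G_p$: the ensemble free energy $-RT\ln Z$ of the whole probe.
  The whole probe must unfold to hybridize, so the full ensemble, not
  just the mfe structure, is used.  Because the open chain contributes
  weight 1 to $Z$, this term is $\le 0$ by construction.
* $\Delta G_t$: minus the opening energy
  $-RT\ln P(\text{site unpaired})$ of the binding site inside a target
  fragment.  The fragment is the site plus up to 200 nt of flanking
  sequence on each side: nearly all base pairs form within a couple of
  hundred bases, so the flanked fragment captures the structures that
  matter at a fraction of the cost of folding the full transcript.
* $\Delta G_{pp}$: the ensemble free energy of intermolecular-only
  probe-probe pairings (stacks between adjacent intermolecular pairs,
  bulge/internal penalties between separated ones, one initiation term
  per structure, unbound state at weight 1).

The profile also carries the corrected two-state melting temperature
(helix initiation factor $A = -10.8$ cal/(K·mol), $R\ln(C_t/4)$
concentration term, $16.6\log_{10}[\mathrm{Na^+}]$ salt term, and a
formamide depression of exactly 0.63 °C per percent) and the probe mfe.
Melting temperatures always use the DNA/DNA table — the probe is a DNA
oligonucleotide and the Tm is a probe property in this analysis —
while $\Delta G_h$ switches to the hybrid table for RNA targets.

## The folding engine

Single-strand ensembles are computed by a McCaskill-style dynamic
program over a Turner-style loop decomposition: nearest-neighbor stacks,
length-dependent hairpin, bulge and internal-loop penalties, and linear
multiloops ($a + b\cdot\text{branches} + c\cdot\text{unpaired}$, with
the closing pair counted as a branch).  Deliberate simplifications, all
shared with the verification oracle:

* Watson-Crick pairs only (no G·U/G·T wobble).  This keeps one stack
  table per chemistry; wobble pairs would mildly enrich RNA ensembles
  but do not change any qualitative behaviour the package asserts.
* No dangling ends or coaxial stacking.
* Minimum hairpin loop of 3 unpaired bases; no lonely-pair prohibition.
* Interior loops capped at 15 unpaired bases in total (configurable via
  `maxloop`).  A 15-base interior loop already costs ≈ 6.7 kcal/mol, so
  larger loops contribute negligible ensemble weight.
* Loop penalties are tabulated as free energies at 310.15 K, treated as
  purely entropic (scaled by $T/310.15$), with Jacobson-Stockmayer
  extrapolation ($1.75\,RT\ln(n/n_{max})$) beyond the tables.  Stack
  terms carry their own $\Delta H/\Delta S$ split.

Opening energies are two partition-function runs (free and with the
site's bases forbidden to pair); the identity
$\text{opening}(whole\ strand) = -\Delta G_{ensemble}$ holds to
$10^{-9}$ and is asserted in the tests.

Every dynamic program is validated against `enumerate_structures()`, a
pure-R exhaustive enumerator that lists all pseudoknot-free structures
of strands up to 20 nt and scores them by walking the loops — an
implementation fully independent of the C++ recursions.  Partition
function, mfe, opening and dimer energies agree with enumeration to a
relative $10^{-6}$ over hundreds of random strands per chemistry.

## Parameter tables

The stack tables ship as plain text under `inst/extdata/params/`: the
unified DNA/DNA oligonucleotide set, the Watson-Crick RNA/RNA set, and
the RNA/DNA hybrid set keyed by the RNA strand 5'→3'.  The loop tables
are a single curated set applied to every chemistry; published loop
parameters differ somewhat between DNA and RNA, but every quantitative
claim the package makes is about self-consistency of the model (engine
vs oracle, identities, recovery), not about literature transcription,
so one shared table keeps the model small and auditable.

## The importance ranking

`guide_tree()` follows the GUIDE recipe rather than CART: the split
*variable* at a node is selected by unbiased chi-square tests, and only
the split *point* is found by exhaustive search (minimising the summed
children sum-of-squares of constant models, ties toward the smaller
threshold).  Two selection tests are computed from the signs of the
node-model residuals:

* curvature: independence of the residual sign and the predictor
  discretized into quartile bins (2×4 table);
* interaction: for each predictor pair, residual sign against the 2×2
  grid of median halves.

If an interaction beats every curvature statistic, the pair member with
the larger curvature is split on.  Node models are least-squares linear
fits on all predictors ("piecewise least-squares regression"), with a
constant fallback for tiny or rank-deficient nodes; `node_model =
"constant"` switches the residual definition to the piecewise-constant
convention.  Growth stops at `min_node_size` (default 50) or
`max_depth`; pruning is cost-complexity with 10-fold cross-validation,
keeping the smallest tree within one standard error of the minimal
prediction error.

Importance is $\sum \chi^2 \sqrt{n_{node}}$ over split nodes.  By
default only the winning variable accrues score at a node
(`credit = "winner"`); whether losing variables should also accrue
their selection statistics is genuinely ambiguous in the GUIDE
literature, so `credit = "all"` is available.  `bootstrap_importance()`
refits on 100 replicates (90 % subsamples, or resamples with
replacement for large tables), reports means and SDs, and scales by the
top mean so the best predictor reads 1.0.  Replicate trees are grown
unpruned by default: pruning guards *prediction error*, which the
ranking does not consume, and cross-validated pruning inside every
replicate would multiply the cost elevenfold without changing the
ranking in the synthetic benchmark.

`spearman_cor()` reports the rank correlation with average ties, with
exact permutation p-values up to $n = 8$ and the t-approximation above.

## The synthetic benchmark

The generator emulates the statistical structure the analysis assumes,
not any particular organism: i.i.d. random targets at a configured GC
content, tiling probes (reverse complements of target windows) at the
preset's step, and intensities from a saturating isotherm on the chosen
energy driver with multiplicative lognormal noise.  Two presets mirror
the two regimes the model addresses: `cdna` (45–75-mers, 22 nt step,
DNA targets) and `rrna` (25-mers, 1 nt step, nine RNA targets).

Choices worth recording:

* **Isotherm midpoint and slope.** Occupancy is
  $\theta = 1/(1+e^{\beta(\Delta G - \Delta G_{1/2})})$.  Target
  concentration — unknown in the motivating experiments — shifts the
  midpoint, so $\Delta G_{1/2}$ is placed at the preset's typical
  effective energy (−65 kcal/mol for `cdna` 45–75-mers, −20 for `rrna`
  25-mers), putting typical probes mid-isotherm where signal is
  informative.  The slope $\beta$ is an *effective* inverse temperature
  (0.15/kcal for `cdna`): the equilibrium value $1/RT \approx 1.6$/kcal
  would saturate the isotherm within a fraction of the observed energy
  spread, whereas real arrays show a far flatter response after
  washing, labelling and scanner compression.
* **Noise.** Lognormal with $\sigma = 0.4$ (natural-log scale), set so
  the per-target `log2(max/min)` variation on the `cdna` preset matches
  the ≈ 4.2 bits (18-fold) typical of real tiling data.
* **Non-expressed targets** receive background-only signal, enabling
  the expression-filter recovery test.
* What the generator does **not** emulate: cross-hybridization,
  target-target interactions, fragmentation/labelling chemistry,
  spatial artifacts, and probe-sequence correlation along the genome.
  Passing tests therefore demonstrate internal consistency and
  recoverability under the model's own assumptions, not performance on
  real arrays.

## The steric truncation scan

`cli_truncate_scan()` recomputes ΔG after removing 5/10/20 bases from
the solution (5') or tethered (3') probe end, shrinking the binding
site correspondingly (the probe 5' end pairs the site's 3' end).  The
steric simulation generates signal from the ΔG of the 3':5-truncated
probe — the 5 surface-proximal bases carry zero weight, emulating
steric inaccessibility at the feature surface.  Under this generator
the 3':5 variant is by construction at least as predictive as the full
probe, so the acceptance check asserts "not significantly worse"
(paired-bootstrap SE), and that removing the same 5 bases from the
*solution* end degrades the correlation significantly.  The scan uses
fixed-length 60-mers: with mixed 45–75-mers the probe-length term
dominates the energy variance and washes out the few-kcal/mol
end-truncation effects this comparison is about.

## Numerical choices and degenerate inputs

* Energies in kcal/mol, temperatures in °C at the interface and K
  internally, $R = 1.987$ cal/(K·mol) throughout; coordinates 0-based
  half-open everywhere.
* The partition function works on linear scale (double); the largest
  fragments folded (~500 nt) stay ≈ $10^{100}$, far below overflow.
* Strands shorter than 5 nt, or without complementary pairs, return
  $Z = 1$, mfe 0, opening 0 — the open chain, not an error.
* A constant response yields a flagged root-only tree with zero
  importance for every predictor; tied split-search optima resolve to
  the smaller threshold, tied variable selection to column order.
* `melting_temperature()` refuses non-negative denominators (reporting
  the inputs) rather than returning a nonsensical Tm.
* The Tm concentration convention ($C_t/4$ vs $C_t$) is a documented
  switch, default $C_t/4$ (non-self-complementary probes).

## Problem sizes

The shipped tests exercise: enumeration-oracle agreement on 200 random
strands of 8–14 nt per chemistry (plus 100 dimer pairs each); model
identities on a benchmark of ≈ 10,000 tiling probes on 150–300 nt
targets; parameter recovery with 100 bootstrap replicates on the same
benchmark; and a steric scan on ≈ 2,000 fixed-length probes.  These
sizes give stable rankings and tight identity checks while keeping a
full test run in the minutes range on one CPU.

## Known limitations

* Perfect-match probes only: no mismatch, dangling-end or coaxial
  parameters, no cross-hybridization of near-matches.
* $\Delta G_t$ opens the single contiguous binding site; an
  accessibility average over partial interaction sites would be the
  natural refinement.
* $\Delta G_h$ is the perfect-helix nearest-neighbor sum, not an
  interaction ensemble over partial pairings.
* No magnesium/divalent salt model; salt enters only the Tm.
* $\Delta G_{pp}$ ignores strand concentration on the feature.
* The GUIDE implementation covers numeric predictors and the published
  test constructions; categorical predictors and missing-value handling
  are out of scope.
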