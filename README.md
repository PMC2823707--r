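# hybtherm

Thermodynamic modelling of oligonucleotide microarray hybridization.

Probes tiling the same transcript can differ in signal by orders of
magnitude, and the variation is sequence driven: the probe-target duplex
competes with secondary structure in the probe, with structure around the
binding site in the target, and with probe-probe dimers on the feature.
`hybtherm` implements a multi-state thermodynamic model of this
competition for people analysing or designing tiling arrays, together
with the statistical machinery to ask *which* energetic contribution
actually explains observed signal.

## The model

For a probe `p` bound to its perfect-match site in a target, the package
computes the **effective interaction energy**

```
ΔG = ΔG_h − ΔG_p − ΔG_t − ΔG_pp        (all terms ≤ 0, kcal/mol)
```

* `ΔG_h` — free energy of the probe-target duplex, from nearest-neighbor
  stack tables (DNA/DNA for cDNA targets, the orientation-specific
  RNA/DNA hybrid table for RNA targets);
* `ΔG_p` — ensemble free energy of probe secondary structure,
  `−RT ln Z` over all pseudoknot-free structures (McCaskill-style
  partition function);
* `ΔG_t` — minus the *opening energy* of the binding site within a
  target fragment that includes 200 nt of flanking sequence on each
  side: `−RT ln P(site unpaired)`;
* `ΔG_pp` — ensemble free energy of intermolecular probe-probe dimers.

Unstable competitor structures contribute zero; the competitor terms can
only weaken, never strengthen, the effective binding.  Alongside ΔG the
package computes the corrected two-state melting temperature

```
Tm = 1000·ΔH / (ΔS + A + R·ln(C_t/4)) − 273.15 + 16.6·log10[Na+] − 0.63·F
```

with the helix-initiation factor `A = −10.8 cal/(K·mol)`, strand
concentration `C_t`, sodium and formamide (`F`, percent) corrections,
and the probe-structure minimum free energy (mfe).

Predictor importance for observed (or simulated) intensities is ranked
with a GUIDE-style regression tree: split variables chosen by unbiased
chi-square curvature/interaction tests, piecewise least-squares leaf
models, cost-complexity pruning under the 1-SE rule, and importance
scores `Σ χ²·√(node size)` over split nodes, bootstrapped for error
bars.  A synthetic-data module (random targets, tiling probes, Langmuir
intensity simulation) makes the whole chain testable end to end.

## Worked example

Simulate a small cDNA-style tiling experiment, profile every probe and
rank the predictors:

```r
library(hybtherm)

cfg      <- sim_config("cdna", seed = 42, n_targets = 150,
                       target_length = c(150, 300))
targets  <- random_targets(cfg)
probes   <- tile_probes(targets, cfg)              # 1191 probes
profiles <- profile_probes(probes[, c("probe_id", "seq")], targets,
                           target_chemistry = "DNA",
                           conditions = cfg$conditions)
head(profiles[, c("probe_id", "dG_h", "dG_p", "dG_t", "dG_pp", "dG", "Tm")], 3)
#>            probe_id   dG_h    dG_p   dG_t   dG_pp     dG    Tm
#> 1 target_001_p00000 -88.78 -0.3720 -1.707 -11.741 -74.96 57.79
#> 2 target_001_p00022 -86.15 -0.2556 -1.828 -11.833 -72.23 59.07
#> 3 target_001_p00044 -74.94 -0.2486 -3.095  -7.359 -64.24 52.80
```

Each row decomposes one probe's binding: e.g. the first probe gains
−88.8 kcal/mol from duplex formation but pays 11.7 kcal/mol to unfold
probe-probe dimers, leaving ΔG = −75.0 kcal/mol.  Simulated intensities
driven by ΔG are then traced back to it by the ranking:

```r
intens <- simulate_intensities(profiles, cfg)
imp <- bootstrap_importance(intensity ~ dG + Tm + dG_h + dG_p + dG_t + dG_pp,
                            feature_table(profiles, intens),
                            n_rep = 25, seed = 7)
imp
#> Predictor importance (relative to top):
#>   predictor   mean    sd relative
#> 1        dG 1983.2 238.3   1.0000
#> 2      dG_p  487.9 165.1   0.2460
#> 3        Tm  457.9 241.9   0.2309
#> 4      dG_t  386.3 219.6   0.1948
#> 5     dG_pp  352.2 153.8   0.1776
#> 6      dG_h  321.9 201.7   0.1623
```

The effective interaction energy is recovered as the dominant predictor
(relative score 1.0); the individual terms and the melting temperature
trail far behind — the behaviour expected for specific hybridization.
`variation_stats()` summarises the per-target probe variation
(`log2(max/min)`), and `cli_truncate_scan()` repeats the analysis after
removing 5/10/20 bases from the solution or tethered probe end.

A command-line front-end over the same steps lives in
`inst/cli/hybtherm.R` (`simulate`, `profile`, `rank`, `truncate-scan`,
each driven by a YAML run configuration).

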