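# Loop penalty tables shared by all chemistries, free energies in kcal/mol at
# the 310.15 K reference temperature.  Treated as purely entropic: at
# temperature T the penalty is G37 * T_K / 310.15.  Lengths beyond the last
# tabulated value are extrapolated with the Jacobson-Stockmayer term
# G(n) = G(n_max) + 1.75 * R * 310.15 * ln(n / n_max).
# Grammar: <loop_type> <length-or-coefficient> <G37>; '#' = comment.
# multiloop coefficients: closing offset 'a', per-branch 'b' (the closing
# pair counts as a branch), per-unpaired-base 'c'.
hairpin	3	5.4
hairpin	4	5.6
hairpin	5	5.7
hairpin	6	5.4
hairpin	7	6.0
hairpin	8	5.5
hairpin	9	6.4
hairpin	10	6.5
bulge	1	3.8
bulge	2	2.8
bulge	3	3.2
bulge	4	3.6
bulge	5	4.0
bulge	6	4.4
internal	2	4.1
internal	3	5.1
internal	4	4.9
internal	5	5.3
internal	6	5.7
multiloop	a	3.4
multiloop	b	0.4
multiloop	c	0.0
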