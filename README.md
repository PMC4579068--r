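# aridiv

Diversification-rate and ancestral-range analysis for dated phylogenies of
incompletely sampled clades, built for the kind of question asked of
arid-zone plant radiations: *did this clade diversify at a constant rate, or
did its speciation rate shift when new habitat opened up — and where did it
come from?*

`aridiv` takes a rooted ultrametric chronogram (node ages in Ma), the total
number of described species, and optionally a posterior sample of dated
trees plus a tip-to-area table, and runs:

1. **Whole-clade and per-node speciation rates.** The Baldwin–Sanderson
   crown estimator `r = (ln N − ln N0)/T` with the crown convention
   `N0 = 2`, and the Magallón–Sanderson estimator
   `r = ln(N(1−ε) + ε)/T` at relative extinction fractions ε = μ/λ
   (defaults 0, 0.5, 0.9), profiled over every internal node.
2. **LTT null-envelope test.** Lineage-through-time curves compared, on a
   pointwise age grid, against an envelope of pure-birth (Yule) trees
   simulated at the whole-clade rate with the full species count and then
   randomly pruned to the sampled tip count — isolating the footprint of
   incomplete sampling from genuine rate variation.
3. **Birth–death-shift detection.** A piecewise-constant reconstructed
   birth–death likelihood with a present-day sampling probability ρ,
   conditioned on survival of both crown lineages. Shift times are searched
   exhaustively over a regular age grid (default 0.1 Myr); nested models
   are compared with likelihood-ratio tests (`α = 0.05`), adding shifts
   until the first non-significant addition.
4. **DIVA / S-DIVA ancestral ranges.** Exact dispersal–vicariance
   optimization by dynamic programming over area subsets (vicariance and
   duplication free; each unit-area dispersal or extinction costs 1),
   returning *all* cost-optimal ranges per node, and S-DIVA frequency pies
   pooled over a posterior tree sample by exact clade matching.
5. **Synthetic studies with recorded truth.** Yule / birth–death /
   rate-shift simulators conditioned on tip count, random tip pruning, and
   an anagenetic area-evolution process, so every stage above can be
   validated against known truth without any external data.

## Worked example

A synthetic 51-species clade whose speciation rate jumps from 0.03 to
0.32 /Myr at 10 Ma (crown anchored at 19.56 Ma), run through the full
pipeline:

```r
library(aridiv)

whole_clade_rate(51, 19.56)
#> baldwin_sanderson rate: 0.166 species/Myr (N = 51, N0 = 2, T = 19.56 Myr, eps = 0)

study <- generate_study(zygophyllum_preset("shift", seed = 42))
path <- tempfile(fileext = ".nwk")
write_newick(study$full_tree, path)
cfg <- analysis_config(path, total_species = 51, rho = 1,
                       envelope_reps = 200, max_shifts = 2, seed = 42)
run_analysis(cfg)
#> == diversification / biogeography analysis report ==
#> tree: 51 tips, crown 19.560 Ma; sampling rho = 1.000
#> whole-clade rate: 0.166 species/Myr
#> LTT envelope: 6 interval(s) below, 0 interval(s) above the envelope
#> shift detection: 1 shift(s) at alpha = 0.05 (8.6 Ma)
#>  k_null k_alt     chi2 df          p
#>       0     1 6.998640  2 0.03021792
#>       1     2 3.424796  2 0.18043264
#> biogeography: skipped: no areas
```

Reading the report: the whole-clade rate of a 51-species clade with a
19.56 Ma crown is 0.166 species/Myr; the empirical LTT curve falls *below*
every simulated constant-rate curve over parts of its history (the
flat-then-steep signature); the 0-vs-1-shift likelihood-ratio test is
significant (χ² = 7.0, df = 2, p = 0.030) and places the shift at 8.6 Ma
(truth: 10 Ma — with only ~1 expected branching before the shift, the
placement is limited by the data, not the optimizer); adding a second
shift is not supported (p = 0.18), so the verdict is one shift.

With a tree sample and an area table (`tree_sample_path`,
`area_table_path`), the report additionally carries S-DIVA ancestral-range
frequencies and clade coverages per node of the representative tree.

## Command line

A launcher is installed under `inst/cli/`:

```sh
Rscript inst/cli/aridiv.R synth --variant shift --seed 42 --out study/
Rscript inst/cli/aridiv.R shiftfit --tree study/full.nwk --max-shifts 2 --out fits.json
Rscript inst/cli/aridiv.R diva --tree study/pruned.nwk --areas study/areas.tsv
```

Subcommands: `simulate`, `ltt-test`, `rates`, `shiftfit`, `diva`, `synth`,
`run`.

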