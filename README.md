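# apmshits

Hit identification for AP-MS protein-interaction screens that use a
**double negative-control** design.

In an affinity purification–mass spectrometry (AP-MS) screen, a tagged
bait protein is purified together with everything bound to it, and the
co-purified proteins are identified and quantified (MaxQuant-style
protein lists, one raw-intensity column per LC-MS/MS run). The raw lists
are contaminated by proteins that bind the chromatography resins and by
proteins that bind the affinity tag itself. Two negative controls
separate these backgrounds: an untagged strain (control 1, resin
binders) and a strain expressing an unrelated tagged protein (control 2,
tag binders), each purified in triplicate alongside every bait × growth
condition triplicate.

`apmshits` implements the two complementary hit-calling strategies for
this design, a synthetic screen generator with planted ground truth, and
condition-resolved interaction-network reporting:

- **Qualitative** (presence/absence): a hit is a protein detected in all
  three experimental replicates (the triplicate core) and in *no*
  replicate of either control:
  `hits = ∩ᵢ Eᵢ \ (∪ⱼ C1ⱼ ∪ ∪ⱼ C2ⱼ)`.
- **Quantitative** (intensity-based): per run, intensities are divided
  by the median of the run's nonzero intensities and log10-transformed
  (raw 0 ↦ transformed 0); a condition-wide global SD `σ` is pooled over
  all transformed values; replicate triplicates are averaged. Against
  each control, a protein is significant if the control average is 0
  (absent), or if `(av_exp − av_ctrl)/log10 2 ≥ 1.5` and the one-sided
  z-test `z = (av_exp − av_ctrl)/σ` survives Benjamini–Hochberg
  correction at adjusted p ≤ 0.01. A final hit must additionally be
  detected in all three experimental replicates.
- **Reporting**: bait–prey edge lists with evidence type (absent in both
  controls vs enriched) and log2 fold enrichment vs control 2 as edge
  weight; SIF/GraphML/TSV export for Cytoscape; replicate-overlap
  fractions, three-condition Venn region counts, pairwise
  bait-similarity matrices, and volcano tables/plots.

The packaged default experimental design (`default_design()`) encodes a
screen of eight SPA-tagged *E. coli* replication baits (DnaA, DnaB, Hda,
SeqA, DiaA, DnaG, HolD, NrdB) under three growth conditions with both
controls, 90 runs in total.

## Worked example

```r
library(apmshits)
library(dplyr)

ds <- generate_dataset(sim_params(n_proteins = 120, n_baits = 2,
                                  preys_per_bait = 5, seed = 11))
res <- process_all(filter_flagged(ds$table), ds$design)
res
#> <apms_result> strategy: both
#>   quantitative: 36 hits / 690 records
#>   qualitative:  30 hits

tidy(res) |>
  filter(final_hit, bait == "BAIT1", condition == "LB_log") |>
  select(accession, av_exp, av_c2, log2fc_c2, padj_c2, verdict_c2)
#> # A tibble: 6 × 6
#>   accession av_exp  av_c2 log2fc_c2  padj_c2 verdict_c2
#>   <chr>      <dbl>  <dbl>     <dbl>    <dbl> <chr>
#> 1 SIM0001     2.85 -0.473      11.0  5.53e-9 enriched
#> 2 SIM0003     1.49  0          NA   NA       absent_in_control
#> 3 SIM0004     1.47  0          NA   NA       absent_in_control
#> 4 SIM0005     2.60  0          NA   NA       absent_in_control
#> 5 SIM0006     1.54  0          NA   NA       absent_in_control
#> 6 SIM0007     2.74  0          NA   NA       absent_in_control
```

The 36 quantitative hits are the 2 baits × 3 conditions × 5 planted
preys (30) plus each bait in its own pull-down (6): `SIM0001` is BAIT1
itself — present in the controls but ~11 log2 units enriched in its own
purification — while the planted preys never appear in any control run
and are called through the absence rule (`verdict_c2 =
absent_in_control`, no p-value fabricated). The qualitative strategy
recovers exactly the 30 exclusive-presence preys and, by design, cannot
call the baits, which the controls also contain.

`plot_volcano(tidy(res))`, `plot_bait_similarity()`,
`plot_condition_overlap()` and `autoplot(res)` draw the standard
figures; `build_network()` + `export_network()` produce Cytoscape-ready
files.

A thin command-line wrapper with `simulate` / `process` / `report`
subcommands is installed at
`system.file("cli", "apms-pipeline.R", package = "apmshits")`.

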