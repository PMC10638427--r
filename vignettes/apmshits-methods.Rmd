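---
title: "Hit identification in double-control AP-MS screens: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hit identification in double-control AP-MS screens: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmshits)
library(dplyr)
```

## The problem

Affinity purification coupled with mass spectrometry (AP-MS) pulls a
tagged bait protein out of a lysate together with its binding partners and
identifies everything that co-purifies. The raw protein list is dominated
by two classes of false positives: proteins that stick to the
chromatography resins and proteins that bind the affinity tag itself. A
double negative-control design separates them: control 1 is the untagged
parental strain (anything it yields is a resin binder) and control 2 is a
strain expressing an unrelated tagged protein, here SPA-tagged mVenus
(anything extra it yields binds the tag). Each bait, in each growth
condition, is measured in biological triplicate alongside triplicates of
both controls.

`apmshits` implements the two complementary hit-calling strategies for
this design.

## The qualitative (presence/absence) strategy

A protein group counts as detected in a run when its raw MaxQuant
intensity is strictly positive; 0 means not detected. For each pull-down:

1. intersect the detections of the three experimental replicates (the
   *triplicate core*);
2. reject any core protein detected in **any** replicate of either
   control.

We subtract the *union* of the six control replicates' detections, not the
controls' own triplicate cores. The instruction "absent in all replicates
of both controls" is strictly the union reading, and it is also the
conservative one: a single control sighting disqualifies a protein. This
strategy can only find preys that are entirely absent from the controls;
intensity never enters the decision.

## The quantitative strategy

Raw intensities vary across runs for technical reasons, so the pipeline
works on median-normalized logarithms:

1. **Normalization.** Each intensity is divided by the median of the
   run's *nonzero* intensities (zeros would otherwise drag the median
   toward the dropout rate rather than the signal level).
2. **Transform.** Values are log10-transformed; a raw 0 is replaced so
   that its transformed value is 0 (the 0 → 1 → log10 rule). Missing
   cells and explicit zeros are treated identically.
3. **Global dispersion.** The variance and standard deviation are pooled
   over *every* transformed value of *every* run of one growth condition,
   experimental and control runs alike, zero placeholders included. This
   condition-wide SD is the denominator of the test statistic below. The
   default uses the sample (n−1) estimator; a population mode is
   available.
4. **Averaging.** Each protein's three replicate values are averaged into
   `av_intensity`, per sample.
5. **Absence rule.** If a control's average is 0 the protein is treated
   as significant relative to that control with no test performed — there
   is nothing to compare against, and absence from a control is itself
   the strongest evidence.
6. **Fold filter.** Otherwise the enrichment is the difference of log10
   averages rescaled to log2 units, `(av_exp − av_ctrl)/log10(2)`, and
   must be at least 1.5 (boundary inclusive). The averages are already
   logarithms, so a literal ratio of logs would be dimensionless
   nonsense; rescaling the log10 difference to the log2 scale is the only
   coherent reading of a "log2 ratio" of intensities. Because the
   arithmetic is a defensible choice rather than a mathematical
   necessity, an alternative mode applies the threshold directly to the
   log10 difference (`fold_scale = "log10"`).
7. **Test.** Enrichment is assessed with a one-sided upper-tail z-score
   using the global SD: `z = (av_exp − av_ctrl)/global_sd` by default.
   Because the compared quantities are means of three replicates, an
   optional `zscore_scale = "mean_of_three"` multiplies the denominator
   by `sqrt(2/3)` (the SD of a difference of two three-replicate means
   under equal variance). p-values are Benjamini–Hochberg adjusted and
   must be ≤ 0.01.
8. Both controls are processed this way; the BH family is the set of
   proteins that actually received a p-value for that control (control
   average > 0 and fold filter passed) within one (bait, condition) —
   adjusting proteins that were never tested would dilute the correction
   with ghosts. A pooled per-sample family would be the alternative
   reading; per-control is the default because the two tests answer
   different questions.
9. **Final rule.** A protein is a hit only if it is detected in all
   three experimental replicates (raw > 0 in each) and is, for *each*
   control, either absent from it or significantly enriched over it.

Records are emitted for every protein detected in at least one
experimental replicate — not only hits — so the full calculation trail
(averages, fold changes, z, p, adjusted p, verdicts) can be exported and
re-sorted, with `final_hit` flagging the calls.

### Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `fold_threshold_log2` | 1.5 | log2 units | minimum enrichment over a detected control |
| `alpha_adjusted` | 0.01 | probability | BH-adjusted significance threshold |
| `sd_mode` | `"sample"` | — | n−1 vs n denominator of the global SD |
| `zscore_scale` | `"raw"` | — | optional `sqrt(2/3)` scaling of the z denominator |
| `fold_scale` | `"log2"` | — | scale on which the fold threshold is applied |

The two thresholds are deliberately conservative defaults; relaxing
`alpha_adjusted` to 0.05 or lowering the fold threshold are the natural
first knobs for a more permissive screen, and hit sets are provably
nested across `alpha_adjusted`.

### Numerical choices

Comparisons use exact `>=`/`<=` on doubles with no epsilon fuzzing:
reproducibility is worth more than cosmetic tolerance at the boundary,
and the inclusive threshold means a fold change of exactly 1.5 passes.
Replicate averages are computed as the plain two-pass `mean()` of three
values. If a whole run is empty the transform returns all zeros with a
warning; if the global SD is 0 (degenerate, constant data) tested
proteins get p = 0 with a warning rather than NaN. Row order never
affects any result.

## The synthetic screen

`generate_dataset()` emulates the screen's structure so both strategies
are testable without any MS download: per condition, one triplicate per
bait plus both control triplicates; protein abundances are lognormal
(`10^(baseline + offset + noise)`), with protein baselines
`Normal(7, 0.5)` on the log10 scale (typical magnitudes for label-free
MS intensities), replicate noise SD 0.15 log10 units, and per-cell
dropout applied after the fact. Five planted classes encode the
double-control rationale: resin binders and bystanders everywhere at
baseline, tag binders everywhere except control 1, specific preys either
exclusively present in their bait's pull-downs (default) or present
everywhere and enriched by `effect_log10` in them, and the bait itself
present everywhere with a +3 log10 boost in its own pull-down — baits
dominate their own purifications, which is also what the volcano plots
of the real screen show. The two prey modes exist because the
qualitative strategy can only detect exclusive presence, while the
quantitative strategy also detects enrichment over a nonzero background
— the reason a quantitative variant is worth its complexity.

Defaults (300 proteins, 3 baits, 10 preys per bait, effect 2.0 log10
units, dropout 0, seed 42) are the package's reference conditions for
recovery checks. A single RNG seeding per dataset with a documented draw
order — baselines, then the full noise matrix in design run order, then
the dropout matrix — keeps outputs byte-stable; noise is drawn for every
cell including structurally absent ones, so realized values do not shift
when class layouts change.

What the generator does *not* emulate: peptide-level effects (shared
peptides, protein-group ambiguity), intensity-dependent missingness
(dropout here is uniform, whereas real nondetection is biased toward
low-abundance proteins), correlated replicate noise, and
condition-dependent interactomes (planted preys bind in all three
conditions). Passing recovery tests therefore demonstrates the
*decision logic* is right, not that real screens will reach sensitivity
1.0 — real data add ambiguity these simulations deliberately omit.

## Network reporting

Final hits become bait–prey edges attributed by condition and evidence
type: preys absent in both controls versus significantly enriched ones
(the distinction drawn by node shape in the original visualizations),
with the log2 fold enrichment versus control 2 as the edge weight where
it exists. Prey functional categories are *input data* — a user-supplied
mapping validated against the packaged ten-label vocabulary — because
such classifications are curated manually, not computed. Volcano tables
exclude absent-in-control proteins from the p-value axis instead of
imputing a pseudo-p: no test was performed for them.

The pairwise bait-similarity matrix is underspecified in prose form
("percent of shared interactants, weighted-averaged to the number of all
interactants"), so two labelled modes are provided: the default weights
the pairwise Jaccard percentage by the pair's share of the screen-wide
interactant union, `100 · |Si∩Sj|/|Si∪Sj| · |Si∪Sj|/|U|`; the
`"jaccard"` mode reports the unweighted percentage. The mode travels
with the result as an attribute.

## Problem sizes used in the checks

The test suite runs the set-algebra oracle comparison on 200 random
instances of up to 50 proteins, the step-by-step quantitative oracle on
100 instances of 50 proteins, the BH oracle on 1,000 random p-vectors,
and recovery on the 300-protein default simulation — sizes chosen so the
whole suite completes in well under a minute while still exercising
every branch of the decision rules.

## Known limitations

- Protein groups are opaque accession keys; multi-accession groups are
  never split, so the same protein in two groups is two keys.
- The quantitative model assumes a shared, condition-wide dispersion;
  proteins with unusually variable intensities are tested against an
  average SD, not their own.
- No imputation beyond the 0 → transformed-0 rule; heavy dropout
  therefore deflates averages toward 0 rather than being modelled.
- Empirical-Bayes or spectral-count interaction scorers (SAINT,
  CompPASS) answer the same question with different models and are out
  of scope here.

## Worked example

```{r example}
ds <- generate_dataset(sim_params(n_proteins = 120, n_baits = 2,
                                  preys_per_bait = 5, seed = 11))
res <- process_all(filter_flagged(ds$table), ds$design)
res
glance(res)
tidy(res) |>
  filter(final_hit, bait == "BAIT1", condition == "LB_log") |>
  select(accession, av_exp, av_c2, log2fc_c2, padj_c2, verdict_c2)
```
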