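# eventshift

Analysis toolkit for relating **event boundary strength** — how strongly
independent observers agree that "one event ended and another began" at a
moment of a movie — to **multi-voxel pattern shifts** across a cortical
hierarchy of processing timescales in naturalistic movie-viewing fMRI,
with boundary-locked hippocampal responses on top.

It is aimed at cognitive-neuroimaging researchers who have (a) observer
segmentation logs and (b) preprocessed voxel time series, or who want to
prototype and validate this class of analysis end-to-end on synthetic
data with known ground truth (the package ships a seeded generator for
exactly that purpose).

## The analysis in brief

* **Agreement series.** Each observer's boundary marks (0.1 s
  resolution) are rasterized with a 1 s inclusion window on each side,
  averaged across observers into an agreement series *a(t)*, smoothed
  with a 2 s Gaussian window, and concatenated across movies. Peaks
  above the 65th percentile are event boundaries; they are sorted by
  agreement and split into *weak / moderate / strong* terciles, then
  boundary pairs closer than 6 s, boundaries at movie-title onsets and
  the last boundary of each run are excluded, and times are shifted by
  3 TRs for the hemodynamic response.
* **Cortical hierarchy.** Voxels are labelled short/medium/long
  timescale from inter-subject correlation (ISC > 0.2) under intact,
  fine-scrambled and coarse-scrambled stimulation; parcels with at
  least half their voxels labelled are assigned by majority to level 1
  (early auditory / early visual), 2, 3 or 4.
* **Pattern shifts.** At TR *t* the shift value is the Pearson
  correlation between the mean multi-voxel pattern over TRs
  *t*−3..*t*−1 and over *t*+1..*t*+3; series are z-scored across runs
  and averaged within levels. The **cross-boundary correlation (CBC)**
  is the series mean over boundary ± 1 TR; a CBC below zero marks a
  pattern shift at that level.
* **Alignment scores.** Per boundary, the level-wise shift indicators
  are scored by *strict nesting* (bottom-up prefix over levels 1–4,
  0–4, undefined if non-nested), *nesting* (levels 2–4, 0–3) and
  *summation* (count over levels 2–4).
* **Statistics.** Kruskal–Wallis + Dunn post hocs across strength bins,
  Spearman correlations against continuous agreement, between-subject
  CBC variance with a JZS Bayesian one-way ANOVA (BF01, Cauchy scale
  0.5), Hartigan's dip test with seeded bootstrap p-values (graded vs.
  binary response profiles), repeated-measures ANOVA with generalized
  eta squared, and baseline-corrected hippocampal responses grouped by
  alignment score or strength.

## Worked example (synthetic study)

```r
library(eventshift)

study <- simulate_study(seed = 7)   # 17 subjects, 16 observers, ~130 boundaries
#> <simulated_study> 17 subjects, 16 observers, 130 planted boundaries (graded)

seg <- segment_boundaries(study$observer_logs, study$layout)
b <- seg$boundaries
table(b$category, excluded = b$excluded)
#>           excluded
#>            FALSE TRUE
#>   weak        43    0
#>   moderate    42    1
#>   strong      42    1

rl     <- run_lengths(study$layout)
series <- level_shift_series(group_level_data(study$subject_data), rl)
kept   <- b[!b$excluded, ]
cbc    <- cbc_table(series, b, rl)

aud <- cbc[cbc$level == "1_AUD" & !is.na(cbc$cbc), ]
kruskal_wallis(aud$cbc, kept$category[aud$boundary_id])
#> <stat_report> kruskal-wallis: stat = 90.76, df = (2), p = 1.961e-20, eta2 = 0.7158

at <- alignment_table(cbc)
alignment_vs_agreement(at$nesting, kept$agreement[at$boundary_id])
#> <stat_report> spearman: stat = 0.6205, df = (121), p = 1.939e-14
```

Reading the output: 127 of the 130 planted boundaries survive the
exclusion rules and fall into near-equal strength terciles. In the
auditory level-1 stream the cross-boundary correlation differs strongly
across strength bins (H(2) = 90.8, rank η² = 0.72) with strong < moderate
< weak means, i.e. larger pattern shifts at stronger boundaries; and the
nesting alignment score rises with boundary agreement (Spearman ρ = 0.62
over the 123 boundaries with a defined score). Both recover the planted
graded ground truth.

The same stages run from the command line:

```sh
Rscript inst/cli/eventshift simulate --out demo --seed 3
Rscript inst/cli/eventshift segment --logs demo/observer_logs.tsv \
        --layout demo/layout.json --out demo_seg
```

## Layout

* `R/` — layout/timing, synthetic generators, segmentation, hierarchy,
  pattern shift, statistics (incl. native dip test and JZS Bayes
  factor), alignment + hippocampus, I/O and pipeline/CLI.
* `tests/testthat/` — unit, property and oracle-equivalence tests plus
  `test-acceptance.R` (recovery and calibration criteria).
* `vignettes/eventshift-methods.Rmd` — the model, parameter and
  design-decision write-up.
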