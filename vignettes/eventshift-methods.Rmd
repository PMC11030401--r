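---
title: "Methods: event boundary strength and cortical pattern shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event boundary strength and cortical pattern shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During naturalistic movie-viewing, people spontaneously segment
continuous experience into events, and the transitions between events
(*event boundaries*) vary in how salient they feel. `eventshift`
implements an analysis pipeline that relates that behavioural variation
to brain activity at several scales:

1. **Boundary strength from observer agreement.** Independent observers
   mark boundaries with 0.1 s resolution; the fraction of observers
   marking near a moment, smoothed, is the boundary-agreement series
   $a(t)$, and its peaks define boundaries binned into *weak*,
   *moderate* and *strong* terciles.
2. **Cortical hierarchy of timescales.** Voxels are labelled short-,
   medium- or long-timescale from their inter-subject correlation (ISC)
   under three levels of temporal scrambling of a localizer stimulus,
   and parcels are assigned to four hierarchy levels (level 1: early
   auditory/visual sensory cortex; level 2: other short-timescale
   cortex; level 3: medium; level 4: long-timescale cortex, largely the
   default mode network).
3. **Multi-voxel pattern shifts.** At every TR $t$, the correlation
   between the mean pattern over TRs $t-3..t-1$ and over $t+1..t+3$
   (the focal TR excluded) forms a pattern-shift series; z-scored and
   averaged within hierarchy levels. The *cross-boundary correlation*
   (CBC) is the mean of that series over boundary TR $\pm 1$; lower or
   negative values mean a larger pattern shift.
4. **Alignment across the hierarchy.** Per boundary, each level gets a
   shift indicator (CBC strictly below 0). Three scores summarize the
   bottom-up structure: *strict nesting* (prefix length over levels
   1–4; undefined when a shift sits above a non-shifting level),
   *nesting* (same over levels 2–4), and *summation* (count over
   levels 2–4).
5. **Hippocampal boundary-locked responses.** ROI activity from −2 to
   +10 TRs around each boundary, baseline-corrected by the 2 (or 10)
   preceding TRs, summarized as the 0–4 TR mean, and compared across
   alignment-score or strength groups.

Because the underlying study's data are not deposited, the package
ships a first-class synthetic-study generator with planted ground
truth, so every stage is exercisable and testable.

## Statistical machinery

* **Kruskal–Wallis** with tie correction; effect size
  $\eta^2 = (H - k + 1)/(N - k)$ (the spec's convention; the source
  analysis names but does not define its effect size).
* **Dunn's pairwise tests** with the tie-corrected pooled variance
  $Z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}$
  and Bonferroni correction (corrected $p$ capped at 1).
* **Spearman correlations** with average ranks for ties and the
  $t$-approximation for $p$.
* **One-way repeated-measures ANOVA** computed from sums of squares on
  a complete subject × condition table, with generalized eta squared
  $\eta_G^2 = SS_{cond}/(SS_{cond} + SS_{subj} + SS_{err})$; validated
  against an independent reference implementation to $10^{-8}$.
* **Hartigan's dip test.** The dip statistic is implemented from the
  greatest-convex-minorant / least-concave-majorant construction in
  observation-count units, one index per observation so ties are
  handled naturally (a unimodal CDF may carry an atom at its mode, so
  ties never force a dip above the one-observation tube; an all-equal
  sample returns the floor $1/(2n)$). The implementation reproduces the
  reference implementation of the published algorithm exactly on
  thousands of randomized cases; three frozen reference values are
  asserted in the tests. $p$-values come from a seeded uniform
  bootstrap (`dip_null_dist()`), which is reproducible across platforms
  and can be shared across repeated tests at the same $n$.
* **Bayesian one-way ANOVA (BF01).** Default JZS priors: flat prior on
  the grand mean, Jeffreys on $\sigma^2$, and on the sum-to-zero
  projected group effects $\theta \mid g \sim N(0, g\sigma^2 I)$ with
  $g \sim \text{InvGamma}(1/2, r^2/2)$, fixed-effect scale $r = 0.5$.
  The Bayes factor is a one-dimensional numerical integral over
  $\log g$; the "prior 0.5" of the source analysis is read as equal
  model prior odds, which cancel from the BF. Posterior group means and
  95% credible intervals are reported via importance sampling on a $g$
  grid (Monte Carlo, seedable; the BF itself is deterministic).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `grid_step` | 0.1 | s | observer response resolution |
| `window` | 1 | s | inclusion window on each side of a mark |
| `smooth_window` | 2 | s | Gaussian smoothing width; $\sigma$ = width/5 = 0.4 s, truncated and renormalized at edges |
| `percentile` | 65 | — | threshold on the concatenated smoothed series (type-7 quantile, zeros included) |
| `min_peak_sep` | 1 | s | minimum peak separation before the pair rule |
| `min_sep` | 6 | s | pair exclusion distance (both members dropped) |
| `hrf_shift` | 3 | TR | hemodynamic delay applied to boundary times |
| `halfwin` | 3 | TR | pattern window half-width (focal TR excluded) |
| `win` | 1 | TR | CBC window half-width (−1..+1 TRs) |
| `isc_thr` | 0.2 | r | voxel timescale-labelling threshold |
| `retino_thr` | 0.25 | prob | early-visual probabilistic-atlas threshold |
| `level1_mode` | either | — | level-1 indicator combines AUD/VIS streams by OR (configurable to AND) |
| `baseline` | 2 | TR | hippocampal baseline span (10 available for comparison) |
| `tr` | 1.5 | s | repetition time |

Strength binning sorts by agreement ascending and splits into three
equal-count bins with remainders assigned to the *stronger* bins (10
boundaries split 3/3/4); this is deterministic and consistent with the
strongest bin being the largest after exclusions in the source
analysis. Categories are assigned *before* the exclusion rules, so
exclusion removes members from bins rather than re-binning.

## What the synthetic generator emulates

Defaults mirror the analysed study's scale: 17 subjects, 16 observers,
~130 planted boundaries, ten movies (2.15–7.75 min) in two runs of
five, TR 1.5 s, 4 s title windows (title length is not stated by the
source; 4 s is our fixed choice). Observer jitter defaults to 0.3 s —
well inside the 1 s inclusion window, so agreement recovery is not
jitter-limited. Planted boundaries keep ≥ 8 s pairwise gaps so they
survive the 6 s pair-exclusion rule.

* **Observers** mark boundary $i$ with probability equal to its
  strength (optionally transformed), with truncated Gaussian jitter; a
  `false_alarm_rate` (marks/minute) is exposed but defaults to 0, as no
  empirical false-alarm level is available.
* **Cortex.** Within an event a parcel's voxel pattern is a fixed
  latent unit vector (scaled to unit per-voxel amplitude) plus i.i.d.
  Gaussian noise (`noise_sd`, default 0.1 — a deliberately clean
  regime; recovery under heavier noise is exercised at 0.3 in the
  binary tests). In **graded** mode the latent vector rotates at each
  boundary by the fraction `shift_gain * w_level * strength` toward a
  fresh random direction (slerp; fraction 1 lands on an
  orthogonal-in-expectation direction). The per-level weights
  (1, 1, 0.8, 0.6, 0.4) make sensory levels track strength tightly
  while higher levels rotate less at weak boundaries — so their shift
  indicators fire progressively less often, producing the bottom-up
  nested alignment structure and score variability. We deliberately
  rejected a strength-independent baseline shift at high levels: it
  saturates every nesting score at 3. In **binary** mode the pattern
  is fully replaced with probability `detection_curve(strength)`,
  drawn independently per subject and boundary — which is exactly what
  makes between-subject CBC variance peak at detection probability
  0.5. Latent sequences restart at run onsets.
* **Hippocampus** is an additive model: amplitude × kernel at each
  (HRF-shifted) boundary plus Gaussian noise; the default kernel peaks
  2 TRs after the boundary, inside the 0–4 TR summary window.

What it does **not** emulate: hemodynamic convolution shape, spatially
smooth noise, motion artifacts, inter-subject anatomical variability,
or observer false-alarm structure. A green recovery test therefore
establishes that the *pipeline* recovers planted structure under the
stated statistical model — not that the model captures every property
of real fMRI data.

## Numerical choices and degenerate inputs

* Undefined values propagate: the first/last 3 TRs of each run, any
  window touching them, and any mean over an undefined sample are `NA`;
  alignment scoring drops boundaries with undefined CBC (reasons
  recorded) rather than imputing 0, which shrinks correlations' df as
  in the source analysis.
* Peak plateaus resolve to their earliest sample; peak thinning keeps
  the higher peak (earlier on exact ties).
* Constant voxels z-score to zeros with a warning; constant shift
  series and constant rank inputs are errors.
* The shift indicator is *strictly* below zero: a CBC of exactly 0 is
  "no shift".
* TR indexing is 0-based everywhere; seconds→TR conversion happens in
  exactly one place (`to_tr_indices()` / `time_to_tr()`).
* The dip bootstrap p uses a +1 continuity correction,
  $(\#\{d_0 \ge d\} + 1)/(B + 1)$.

## Design choices where the design was open

* **Peak detection specifics** (local maxima above a percentile
  threshold, plateau → earliest sample, 1 s minimum separation) are the
  simplest rules consistent with the later 6 s pair exclusion.
* **ISC** is leave-one-out correlation-with-the-mean-of-others
  (pairwise mean available as `method = "pairwise"`).
* **Majority-label ties** in parcel assignment go to the longer
  timescale; inconsistent ISC patterns (e.g. fine above threshold but
  intact below) are `unlabeled`.
* **Auditory parcels are an input list** (hand-selected anatomically in
  the source); the fixture ships placeholder ids.
* **Non-boundary control points** are additionally required to stay 6 s
  away from retained boundaries (the source only says "non-boundary
  periods"); controlled by `exclude_near_boundaries`.
* **Title-onset exclusion window** is
  `[title_onset, title_onset + title_duration + 1 s]`.

## Known limitations

* No NIfTI reader is bundled: imaging-shaped inputs are R arrays /
  headered TSV. The ROI and parcel interfaces accept 4D arrays, so a
  NIfTI front-end would only need to hand over arrays.
* The Bayesian ANOVA's posterior summaries (not the BF) are Monte
  Carlo; exact numeric parity with any particular GUI tool's posterior
  output is not guaranteed and is not asserted.
* The miniature fixture is 3-level and skips alignment scoring; the
  full 4-level path is exercised by the simulated-study tests.
* Group-level and subject-level pipelines share all code paths except
  the averaging step, as intended, but no mixed-effects extensions are
  provided.
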