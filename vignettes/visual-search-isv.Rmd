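---
title: "Analysing visual-search eye movements: performance, intra-subject variability and scanpath structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing visual-search eye movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visearch)
library(dplyr)
```

## The problem this package addresses

In cued visual search a participant first reads a cue (here: a foreign
word in a box on the left of the screen), then searches a grid of twelve
word-pair cells for the matching pair and presses the corresponding field
on a response pad.  Each trial starts with a fixation cross shown for 2 s,
followed by cue and grid for 7 s; a block has 30 trials, with six target
cells used twice and six used three times, so that trials sharing a target
cell can later be compared with each other.

Two families of questions are asked of such data:

* **Performance** -- how quickly does gaze reach the cue, how long is the
  cue encoded, how many and how long are the search fixations, how fast is
  the button response?  These are summarised per participant as the
  *mean* over their valid trials.
* **Intra-subject variability (ISV)** -- how much do those same quantities
  fluctuate from trial to trial within one participant?  ISV is
  summarised as the *standard deviation* over valid trials (for manual
  responses this is the classic RTSD).  Elevated ISV is a robust correlate
  of ADHD symptomatology, which makes trial-to-trial SDs first-class
  outcome variables here, not nuisance terms.

Beyond scalar variables, the *structure* of the search scanpath is
quantified in two complementary ways: categorical Recurrence
Quantification Analysis (RQA) of the AOI sequence, and MultiMatch
similarity between pairs of scanpaths from same-target trials.

The package implements the full chain -- raw gaze samples to group
statistics -- together with a synthetic generator that produces gaze
recordings with known ground truth, so every stage is testable without
clinical recordings.

## Pipeline stages and their contracts

1. **I-DT fixation detection** (`detect_fixations()`).  A window of
   consecutive samples is a fixation when its dispersion stays at or below
   2 degrees for at least 60 ms (both configurable).  Dispersion is the
   Salvucci-Goldberg sum of the x- and y-ranges; a max-of-ranges variant
   is available via `dispersion_metric = "max"` because the convention
   behind any given vendor's event detector is rarely documented.
   Degrees are converted to pixels with the small-angle formula from the
   configured screen geometry (default: 1920 px / 47.4 cm wide display at
   70 cm, about 49.5 px per degree) -- never hard-coded, because the
   physical screen size is an apparatus property.  Track-loss samples are
   removed and the stream is split wherever the resulting gap exceeds
   75 ms; shorter gaps are bridged.  The 75 ms default sits above the
   60 ms minimum duration, so bridging can never stitch two sub-threshold
   stretches into a spuriously valid fixation.

2. **AOI labelling and segmentation** (`label_fixations()`,
   `segment_trials()`).  Fixations are labelled by the AOI containing
   their centroid (cue box, one of 12 grid cells, or `outside`).  Each
   trial is then either rejected or split into two phases:
   *encoding-and-initiation* (from the first cue fixation to the first
   grid fixation after it) and *search* (from there to the last fixation
   on the target cell before the final correct press).  The rejection
   rules run in a fixed order -- outcome filter, cue-entry window of
   1700--3300 ms from trial onset (closed on both ends; the fixation
   qualifies by its onset alone), at most one pre-cue grid fixation of at
   most 300 ms, and existence of a search end -- so each rejected trial
   carries exactly one primary reason and the accounting of valid,
   incorrect, missing and rule-rejected trials is auditable
   (`tabulate_validity()`).  Interval conventions are half-open
   `[start, end)`: a fixation starting exactly on a boundary belongs to
   the later phase, and a fixation starting exactly at the button press
   no longer belongs to the search.  Trials whose first press was wrong
   but corrected by a later press on the target count as correct, and the
   *final* press defines the search end.

3. **Per-trial variables and participant summaries**
   (`trial_features()`, `summarize_participants()`).  Search fixation
   duration is the per-fixation mean within a trial, so the participant
   level is a mean of trial means; cue fixation duration is the per-trial
   *total* dwell within encoding (the two conventions differ by roughly
   the fixation count, and the total is what ~600 ms magnitudes with
   ~1.5 fixations per encoding imply).  SDs use the n-1 denominator.
   With one valid trial an SD is undefined and reported `NA`, never 0.
   Participants need `min_trials` (default 10) valid trials to enter
   group statistics; the floor is explicit configuration, replacing an
   unstated "poor data quality" judgement with a reproducible rule.
   Entry times are reported from trial onset (cross onset = 0); the
   cue-onset convention differs by exactly the 2000 ms cross duration.

4. **RQA** (`rqa_measures()`, `rqa_trials()`, `rqa_isv()`).  Two
   fixations recur when they share an AOI label.  With `R` recurrent
   pairs among `N` search fixations:
   recurrence `= 100·2R/(N(N-1))`; determinism = percentage of recurrent
   points on diagonal lines of length >= L (repeated sub-scanpaths);
   laminarity `= 100(|H|+|V|)/(2R)` over horizontal/vertical line
   structures (prolonged dwelling); CORM
   `= 100·Σ(j-i)r_ij /((N-1)R)` (low values: revisits close in time).
   `L = 2` by default.  Note a consequence of the line-length floor that
   is easy to miss: in a fully recurrent 4-fixation path the corner point
   `(1,4)` sits alone on a length-1 diagonal, so determinism is 5/6, not
   1 -- the implementation follows the formulas, and an independent
   brute-force full-matrix line scan in the test suite agrees.
   `outside` fixations stay in the sequence but never recur; dropping
   them would distort the lag structure that CORM measures.  The
   subtracted ISV variant averages absolute pairwise differences of each
   measure over all same-target-cell trial pairs; absolute differences
   with an unweighted mean are the symmetric reading of "subtracted from
   each other", and the aggregation is deliberately simple so that a zero
   means literally "identical recurrence structure whenever the target
   repeated".

5. **MultiMatch** (`simplify_scanpath()`, `align_scanpaths()`,
   `similarity_dimensions()`, `multimatch_isv()`).  Paths are simplified
   by iteratively merging consecutive saccades that are both small
   (amplitude < 10% of the screen diagonal with an intervening fixation
   < 300 ms) or nearly collinear (direction difference < 45 degrees);
   the merged vector is the vector sum and the absorbed fixation's
   duration is added to its predecessor (configurable).  Simplification
   is idempotent.  The two vector sequences are then aligned by the
   minimum-total-cost monotone path through the matrix of vector-difference
   norms (dynamic programming; ties prefer the diagonal so that
   self-alignment is exactly the diagonal).  Five dimensions score the
   aligned pairs -- vector, length, direction, position, duration -- each
   normalised to [0, 1] and aggregated by the median (mean available).
   Comparisons are computed on the search segment, consistent with the
   RQA scope, and restricted to same-target-cell trial pairs; all pairs
   are weighted equally because no session-order weighting is defensible
   without further assumptions.  Note that the vector, length, direction
   and duration dimensions are invariant under translating one path
   (saccade vectors are differences); only position responds to it.

6. **Group statistics** (`oneway_anova()`, `tukey_posthoc()`,
   `ancova()`, `group_stats()`).  One-way between-subject ANOVA per
   variable with eta squared = SS_between/SS_total; Tukey HSD post hoc
   contrasts reported for *all* pairs regardless of the omnibus result,
   with t from the pooled error mean square and Cohen's d from the pooled
   two-group SD; optional single-covariate ANCOVA (homogeneity of slopes
   assumed) with missing-covariate rows dropped and logged.  The 3-SD
   within-group outlier rule is single-pass and applied only to variables
   an analysis plan names, mirroring selective use in practice.  Both the
   nominal and the post-removal error df are reported, because published
   tables are often ambiguous about which was used.  A caveat worth
   knowing: the plain 3-SD rule is self-masking in small groups -- in a
   group of n the largest possible z is `(n-1)/sqrt(n)`, which is below 3
   for n <= 10, so such groups can never lose a member.

## The synthetic generator: what it emulates, and what it does not

`simulate_participant()` draws, per subject, a mean and a trial-to-trial
SD for each base variable (entry to cue, total cue dwell, cue fixation
count, search fixation duration) and renders each trial as a fixation
sequence: cross fixation, optional premature grid glance, cue fixations,
then a scan over grid cells until the target cell is fixated, a button
press one motor delay later, and a rest fixation.  Group profiles follow
a three-level hierarchy: population mean, between-subject SD, and a
Gamma-distributed subject-level ISV (mean `isv`, SD `isv_spread`), so
that groups can differ in level and in variability independently.  The
default four-group set places entry-to-cue at ~2493 ms (TD-like) to
~2662 ms (comorbid-like) with trial-to-trial SDs of ~129 to ~169 ms --
magnitudes typical for 10--13-year-olds in this task class -- and the
groups with ADHD-type profiles carry the larger ISV.

Design choices a user should know about:

* **Entry-to-grid is emergent, not drawn.**  The generator draws entry
  time and cue dwell and lets entry-to-grid be their sum plus saccade
  time.  Published descriptive tables for tasks of this type are not
  always internally consistent here (mean entry + mean dwell can exceed
  mean grid entry, which is impossible if the dwell lives inside the
  encoding phase); a generator must pick a self-consistent convention,
  and this one preserves the two laws that drive the ISV analyses.
* **Scan policy.**  Unvisited cells are scanned in random (or,
  for degenerate scenarios, sequential) order with 1--2 fixations per
  cell; after each new cell the scan may revisit an old cell
  (`revisit_probability`) or glance back at the cue
  (`cue_recheck_probability`).  This is the minimal policy that spans the
  range of the RQA statistics; it makes no claim about lexical
  processing, and it produces recurrence rates somewhat below and
  reaction times somewhat faster than typical empirical values.  No
  conclusion drawn from this package's tests depends on those two
  magnitudes.
* **Censoring.**  Entry-time draws are truncated to
  `[cue onset - 300, trial end]` so both valid and rule-rejected trials
  occur; searches still running near the stimulus offset become missing
  trials on top of the profile's explicit miss probability.
* **Rendering.**  Samples are rendered at 120 Hz (60 Hz supported) with
  isotropic Gaussian within-fixation jitter (default 0.12 degrees, well
  below the 2-degree dispersion threshold) and linear sweeps between
  fixation centres.  In-flight samples carry `valid = FALSE`, as video
  trackers report degraded confidence during fast motion; the detector's
  gap bridging absorbs them.  With this convention the I-DT stage
  recovers the generated fixations with exact counts and boundaries
  within one inter-sample interval, which is the property the test suite
  asserts.  Rendering every in-flight sample as valid
  (`flag_saccades = FALSE`) is supported, but boundary recovery then
  degrades to a few samples around each saccade, as it does for any
  dispersion-based detector on real data.
* **What is not modelled.**  Word identity and lexical difficulty,
  smooth pursuit, blinks, saccade kinematics beyond a duration-amplitude
  rule, drift and calibration error, and between-subject heterogeneity
  beyond the normal/Gamma hierarchy.  Passing tests therefore show that
  the *analysis* is correct and well-calibrated on data whose generative
  structure matches its assumptions -- not that real recordings meet
  those assumptions.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; a study is reproduced bit-identically
from (configuration, seed), and each participant has an independent
stream seeded from the study seed and the participant index.
`run_study()` writes all stage tables as TSV plus a manifest with the
configuration and its hash; doubles are serialised at 17 significant
digits so a write/read cycle is exact.

The test suite sizes its Monte-Carlo checks as follows: RQA brute-force
equivalence on 1000 random AOI strings (N <= 30, 13-symbol alphabet plus
`outside`); alignment against exhaustive path enumeration on instances up
to 8x8 vectors; detector recovery on full 30-trial participants rendered
at 120 Hz; ISV parameter recovery over 200 replicate two-group studies
(29 + 18 participants, 30 trials each), where the group effect on
entry-time ISV must be detected at alpha = 0.05 in a majority of studies
and the recovered per-group mean ISV must sit within Monte-Carlo error of
the configured law after the `c4(n)` small-sample correction for the
expectation of a sample SD; and ANOVA type-I error within [0.04, 0.06]
over 10,000 null replicates.

## Known limitations

* The generator's search-stage timing approximates, but does not match,
  empirical reaction-time magnitudes (see above).
* ANCOVA assumes homogeneous slopes and a single covariate; no
  trial-level (mixed-effects) models are provided, matching the
  participant-summary design of the analysis.
* No correction for multiple testing across outcome variables is applied
  by `group_stats()`; variables are analysed as pre-specified outcomes.
* The pre-scan rule reads "fixation on the grid" as "fixation inside any
  grid-cell AOI"; fixations in the gaps between cells (there are none in
  the default layout, which tiles the grid area exactly) would not
  trigger it.

## A short worked example

```{r example, eval = FALSE}
cfg <- default_config(seed = 1, n_per_group = c(8, 8, 8, 8))
res <- run_study(cfg, out_dir = "run1")
res$group_stats |> filter(variable == "sd_entry_to_cue")
res$posthoc |> filter(variable == "sd_entry_to_cue")
```

The README shows a complete run with the numbers it prints.
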