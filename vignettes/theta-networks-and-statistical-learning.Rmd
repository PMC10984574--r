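---
title: "Statistical learning scores and small-world EEG coherence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical learning scores and small-world EEG coherence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrtnet)
```

# What the package computes

`asrtnet` implements a two-track analysis used to study probabilistic
sequence learning and its neurophysiological substrate:

1. **Behaviour.** In the cued Alternating Serial Reaction Time (ASRT) task,
   pattern and random stimuli alternate (`1-r-2-r-3-r-4-r`). Some runs of
   three consecutive trials ("triplets") therefore occur more often than
   others. The *statistical learning score* is the accuracy (or RT)
   difference between random trials that complete high-probability triplets
   and random trials that complete low-probability triplets — both are
   random by construction, so the contrast isolates sensitivity to the
   probabilistic structure.
2. **Networks.** Multichannel recordings are segmented, band-limited
   imaginary coherency is estimated for every electrode pair, each
   segment's coherence matrix is binarized at the 85th percentile, and the
   resulting graph is summarized by its mean degree (`2k`), characteristic
   path length (`L`), clustering coefficient (`C`) and the small-world
   coefficient

   $$\omega = \frac{L_{rand}}{L} - \frac{C}{C_{latt}},$$

   where `L_rand` and `C_latt` are ensemble means over 2000 random and
   2000 ring-lattice reference graphs with the same number of nodes and
   edges. `omega < 0` indicates a lattice-like network, `omega > 0` a
   random-like network, and values near zero a small-world balance of
   local segregation and global integration.

A synthetic-data generator plants known learning effects and known
connectivity graphs so every stage can be checked against ground truth
without access to participant data.

# The behavioural model

## Trial categorization and exclusions

Each trial is labelled as the terminal element of the triplet formed with
the two preceding trials of the same block (moving window). A triplet
`(d1, d2, d3)` is high-probability when `d3` is the alternating sequence's
successor of `d1`; pattern trials are high-probability by construction of
the task. Scoring then excludes, in this order: the first seven trials of
each block (five practice trials plus the first two triplet elements),
terminal trials with `d1 == d3` (this single rule covers both trills
`a-b-a` and repetitions `a-a-a`; the source procedure gives examples
rather than a formula, and `d1 == d3` is the minimal rule that covers
both), and unresponded trials. Accuracy uses responded trials as the
denominator — no-response trials are excluded from all analyses rather
than counted as errors. RT summaries (medians) additionally use correct
responses only.

Scores are computed per five-block unit; the overall score is the
unweighted mean of unit scores. Pooling trials task-wide instead of
averaging unit scores is the other defensible reading of an "overall"
score; unit averaging was chosen because the unit is the task's analysis
quantum everywhere else (ANOVA cells, learning trajectories).

## The response simulator

`simulate_responses()` draws, per trial: a response flag
(`1 - lapse_rate`), correctness `Bernoulli(p)` with
`p = base_accuracy + ramp_b * acc_learning_pp / 100` on high-probability
trials, and `RT = base_rt_ms - ramp_b * rt_learning_ms + N(0, sd)`
truncated to the 500-ms response window (late responses become
unresponded, mirroring the task's deadline). `ramp_b = min(1, ramp *
block)` models gradual acquisition. The planted advantage applies to
*all* high-probability trials (pattern and random): the learning contrast
uses random trials only, so restricting the advantage to one structure
would bias the contrast.

Defaults (chosen once, as plausible values for adult ASRT performance):
`base_accuracy = 0.95`, `base_rt_ms = 350`, `rt_noise_sd_ms = 80`,
`lapse_rate = 0.02`, `learning_ramp = 0.25` (asymptote by block 4). The
default cohort plants asymptotic accuracy advantages of 2.0 (patient
group) vs 0.7 (control group) percentage points, and 13 of 25 patients
carry a medication flag with one-to-one control matching.

With the 0.25/block ramp the expected overall learning score is the
asymptote times the mean ramp over 20 blocks (0.925), i.e. 1.85 and 0.65
points. Because correctness is Bernoulli at the trial level, a subject's
overall score carries an irreducible sampling SD of about 1.5 points;
the implied power of the Probability x Group interaction at n = 25 + 25 is
about 0.5 at this gap — the acceptance suite reports the detection rate it
actually measures, and the type-I error of the same test is calibrated at
the nominal 5% under a null cohort.

# The synthetic recordings

Each node of a planted graph carries an independent Gaussian latent
oscillation band-limited to the coupling band (theta, 4–7 Hz, by
default). For every edge one endpoint is randomly designated the sender;
the receiver's channel adds the sender's latent delayed by `lag_ms`
(default 20 ms). A channel contains its own latent only if it sends on at
least one edge, so an isolated planted pair approaches `|Im C| = 1` at
high SNR. Two receivers of the same sender share that latent at *zero
relative lag*, so indirect leakage is confined to the real part of
coherency — exactly the property that motivates using the imaginary part.
Independent `1/f` background noise is added per channel at the requested
signal-to-noise variance ratio (pink noise approximates resting
electrophysiological spectra without modelling artifacts; preprocessing
is out of scope). Segments are statistically independent and concatenated
with an `R0` event at each onset.

What the generator does *not* emulate: volume conduction and a forward
model, non-stationarity, artifacts (blinks, muscle), and any
tic-related activity. Passing recovery tests therefore demonstrates the
correctness of the estimator chain, not robustness to real-world
contamination.

# Spectral estimation choices

Coherency from a *single* segment with a *single* taper is degenerate
(`|C| = 1` at every bin), so per-segment estimates use three discrete
prolate spheroidal (Slepian) tapers with time-bandwidth product 2,
computed from the standard symmetric tridiagonal eigenproblem and cached.
Resting segments of 2000 ms at 500 Hz give 0.5-Hz resolution (the theta
band averages 7 bins); task epochs span −500..1000 ms (0.667-Hz
resolution). The band edges printed as 8–10 and 10–13 Hz are resolved
half-open (`[8,10)`, `[10,13)`) so the shared edge is not counted twice;
theta and beta are closed intervals.

The unsigned magnitude `|Im C|` is used for thresholding so that "strong"
coherence does not depend on the direction of the phase lag. Per-segment
matrices feed the per-segment thresholding procedure; a pooled estimator
(cross-spectra averaged over all segments before normalization,
`coherence_matrices(..., pooled = TRUE)`) is provided for analyses that
need low-variance pair estimates, such as recovering a planted graph —
single-segment estimates carry sampling noise of the same order as
realistic effect sizes, which per-segment thresholding tolerates (it only
needs within-segment ranks) but edge-level recovery does not.

# Graph-analysis choices

- **Percentile rule.** The 85th percentile is computed over the
  `n(n-1)/2` upper-triangle values of one segment's matrix with the
  `h = np + 0.5` linear-interpolation convention (`quantile type 5`,
  MATLAB's `prctile`), and edges require *strictly greater* values. With
  60 channels and distinct values this keeps 265 edges (15.0% density).
  R's default convention (type 7) keeps 266; both are exposed because the
  choice shifts edge counts by one.
- **Null references.** The random reference is the uniform distribution
  over graphs with exactly the observed edge count ("completely random"
  networks with matched `n` and mean degree `2k`), not degree-preserving
  rewiring; degree-preserving rewiring is available as an option. The
  lattice reference fills complete nearest-neighbour rings and places the
  leftover edges uniformly at random on next-ring positions, so the
  2000-replicate ensemble meaningfully averages both references. Ensembles
  depend only on `(n, edges, reps, seed)` and are memoized.
- **Disconnected graphs.** `L` is the mean over ordered pairs with finite
  distance, identically inside the null ensembles; at 15% density and
  n = 60 disconnection is rare, and this rule keeps `L` defined when it
  happens. Edgeless graphs are flagged as undefined rather than scored.
- **Per-segment omega.** Thresholding, metrics and omega are computed per
  segment (nulls matched to that segment's edge count) and averaged —
  the reading forced by per-segment thresholding; thresholding a
  segment-averaged matrix instead is available via `average_first = TRUE`
  for sensitivity analyses.

# Group statistics

`mixed_anova()` fits split-plot designs (one between-subjects factor,
fully crossed within-subjects factors) with Type-III sums of squares and
the univariate sphericity-assumed tables, the convention under which the
reference analyses report plain degrees of freedom such as `F(3,144)`; no
sphericity correction is applied by default (Greenhouse–Geisser-corrected
inference would alter the printed dfs). Partial eta squared is
`SS_effect / (SS_effect + SS_error)`. Post hoc contrasts are uncorrected
pairwise t-tests (Fisher-LSD convention; a `p.adjust` method can be
supplied), paired within subjects and independent between groups.
Spearman correlations report the t-approximation P value with
`df = n - 2`. The medication-free sensitivity rerun excludes flagged
patients and their matched controls and reports which effects changed
significance class.

The packaged clinical table transcribes 25 patients' characteristics; one
disease-duration entry is approximate in the source ("ca. 40") and is
stored as missing, and the Rush score is available for 20 of 25 patients.
Column means ignore missing entries.

# Numerical and degenerate-input conventions

- All randomness flows from one integer seed; cohort sub-seeds are
  derived deterministically per subject and component (sequence,
  responses, network, noise).
- Zero-variance channels yield zero coherencies with a warning; an
  all-constant coherence matrix thresholds to the empty graph (strict
  inequality) with a warning; an all-constant dependent variable yields
  `F = 0, P = 1` rather than `0/0`.
- `omega` requires `L_real > 0` and `C_latt > 0`; degenerate densities
  are rejected.
- Edge counts are `round(density * n(n-1)/2)` with round-half-even, so
  tests can assert exact counts.

# Problem sizes used in the validation suites

The packaged test-suite and the acceptance script run entirely from
synthetic data at the study's native scale where that scale is what is
being validated — 60-channel graphs at 15% density with 2000-replicate
null ensembles, 60 two-second segments per recording, 25 + 25-subject
cohorts — and at reduced sizes (6–20 nodes, a few segments or blocks)
where only correctness of the arithmetic is at stake. Monte-Carlo rates
(detection rate of the planted group gap, type-I error of the interaction
test) use 50 and 400 cohort replicates respectively.

# Known limitations

- No volume-conduction or source model: recovery results speak to the
  estimator chain, not to sensor-space leakage in real data.
- The response model has no between-subject parameter heterogeneity by
  default; group-level variance is purely trial-level sampling noise,
  which is the optimistic lower bound for power analyses.
- Graphs are unweighted and undirected; no hub/centrality or
  minimum-spanning-tree analyses.
- BrainVision support covers the float32 multiplexed dialect this package
  writes; the raw binary + JSON sidecar format is the bit-exact
  round-trip.

# A small worked run

```{r, eval = FALSE}
cc <- cohort_config(n_per_group = 4, design = asrt_design(n_blocks = 10),
                    n_medicated = 2)
pc <- pipeline_config(overrides = list(seed = 7, null_reps = 200))
out <- run_pipeline(cc, pc)
out$behavior_anova
```
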