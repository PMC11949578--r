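---
title: "A two-state model of dynamic functional connectivity and its reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-state model of dynamic functional connectivity and its reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Resting-state fMRI connectivity is not stationary: the correlation
structure between brain regions drifts over minutes. `dfcstates`
implements the most common way of resolving that drift, sliding-window
analysis (SWA), together with a deliberately minimal *two-state* model of
the resulting dynamics.

For one subject-session the pipeline is:

1. **Windowed connectivity.** From an ROI time-series matrix (frames x
   regions), Pearson correlations of every region pair are computed inside
   a rectangular window of fixed length (default 40 frames) slid one TR at
   a time, then Fisher-transformed, `z = atanh(r)`. Each window yields one
   *state instance*: the upper triangle of its connectivity matrix,
   vectorized in a fixed row-major order. A series of `F` frames yields
   `F - w + 1` instances (961 instances for 1,000 frames with a 40-frame
   window).
2. **State clustering.** All session-A instances of the cohort are pooled
   and partitioned into `k = 2` clusters by k-means under the cosine
   distance `CD = 1 - cos(angle)` between edge vectors (`CD` in [0, 2]).
   The centroid of a state is the mean of its members after each member is
   divided by the root of its sum of squares; the cluster whose centroid
   has the larger mean edge value is the *integrated* state I, the other
   the *segregated* state S.
3. **Back-projection.** Session-B instances are not re-clustered; each is
   assigned to the session-A centroid with the smaller cosine distance.
   This keeps the state definition fixed across sessions so that
   between-session differences reflect the subject, not the clustering.
4. **State dynamics.** From each subject-session's window-label sequence:
   mean dwell time (MDT, seconds) of each state over *interior* dwell
   segments only — the first and last dwell of a run are censored because
   their true onset/offset is unobserved; prevalence (Prev, the fraction
   of windows per state, with `Prev_I = 1 - Prev_S`); the intertransition
   interval `ITI = (MDT_I + MDT_S)/2`; and state variability (Var), the
   mean Euclidean distance of a subject's within-state instances to their
   plain within-state mean. MDT requires at least two transitions, ITI at
   least three; when the requirement fails the value is missing, never
   zero.
5. **Reliability.** Test-retest reliability of every parameter is the
   one-way random-effects intraclass correlation
   `ICC = (MSbs - MSws) / (MSbs + (k - 1) MSws)` with `k = 2`
   measurements, which estimates the between-subject share of total
   variance and can be negative. Spearman correlations accompany it, and
   95% confidence intervals come from a percentile bootstrap over
   subjects. Centroid reliability treats edges as the paired units.
6. **Graph characterization.** Each centroid, thresholded at Fisher
   `z = 0` (only strictly positive connections kept), becomes a weighted
   graph scored by Newman modularity `Q = sum_i e_ii - sum_i (sum_j e_ij)^2`
   and by global efficiency, the mean inverse shortest-path distance with
   edge length `1/weight`. The integrated state should show high
   efficiency and low modularity, the segregated state the opposite;
   bootstrap clouds of (Q, E) over subjects visualize the stability of
   that contrast.

## Worked example

```{r, eval = FALSE}
library(dfcstates)

coh <- generate_cohort(cohort_config(seed = 1))
dfc <- lapply(coh$timeseries, sliding_window_fc, window_length_frames = 40)

keys_A <- grep("_A$", names(dfc), value = TRUE)
inst_A <- do.call(rbind, lapply(dfc[keys_A], `[[`, "instances"))
km     <- kmeans_cosine(inst_A, k = 2, seed = 1)
model  <- label_states(state_model(km$centroids))

sq <- back_project(dfc[["sub001_B"]], model)
dfc_parameters(dfc[["sub001_B"]], sq)
```

The full grid (scan length x atlas size x centering, optionally x GSR and
x k) is orchestrated by `run_study(study_config(...))`, and
`write_report()` emits the reliability, cross-correlation, graph and
silhouette tables as CSV plus a JSON manifest of every seed and decision
flag.

## What the synthetic cohort emulates

There is no public ground truth for window-level brain states, so the
package ships a generator whose truth is known by construction. Each
subject alternates, frame by frame, between two multivariate-Gaussian
regimes under a first-order Markov chain:

* an **integrated** regime with uniform positive correlation
  (`r_integrated = 0.55`), and
* a **segregated** regime with block-modular correlation (5 modules,
  `r_within_module = 0.55`, `r_between_module = 0.05`).

Three subject-stable signals make test-retest reliability a meaningful
target:

* an **occupancy trait** `t ~ N(0, 0.5)` on the logit scale, applied
  antisymmetrically (`+t` to the segregated stay probability, `-t` to the
  integrated one), so each subject has a stable preferred state;
* a **static-connectivity offset**, a symmetric rank-1 perturbation of
  both regime correlation matrices (scale 0.1) projected back to a valid
  correlation matrix, emulating stable between-subject differences in
  static FC;
* both sessions of a subject reuse the trait and the offset; sessions
  differ only in their RNG draws (an optional `session_offset_sd` can
  degrade this).

Defaults are 40 subjects x 2 sessions, 30 ROIs, 400 frames at TR = 1 s,
and additive white observation noise with `noise_sd = 0.5` (0.2 in the
package's low-noise validation runs). Stay probabilities default to
0.995 per frame, i.e. a mean dwell time around 200 frames. The dwell time
must be long relative to the 40-frame window: a window mixes all frames it
covers, so switching much faster than the window makes window-level state
labels ill-defined regardless of noise. Ground-truth window labels are
defined by majority vote of the frame labels inside the window, with
exact ties resolved to the window's center frame.

What the generator does **not** emulate: hemodynamic smoothing and its
autocorrelation, physiological noise spectra, motion artifacts, scanner
drift, spatial structure beyond the block-modular pattern, and any
systematic session effect by default. Passing tests on this cohort
therefore validate the *pipeline machinery* — that the estimators recover
a truth of exactly the assumed form — not the biological adequacy of a
two-state description of real fMRI.

## Numerical and design choices

* **Window**: rectangular (untapered), length in frames with the
  seconds value (`frames x TR`) carried in metadata; no within-window
  detrending.
* **Edge vectorization**: diagonal excluded (self-connectivity is never
  used and `atanh(1)` is infinite); fixed row-major upper-triangle order
  shared by every module.
* **Clipping**: correlations are clipped to `±(1 - 1e-7)` before the
  Fisher transform so every instance is finite even for collinear
  windows.
* **k-means**: spherical variant — the update step averages the
  unit-normalized members, so the in-loop objective and the reported
  normalized-mean centroid definition coincide. 20 seeded restarts,
  300-iteration cap; an emptied cluster is reseeded at the instance
  farthest from that cluster's previous centroid; assignment ties break
  to the lowest centroid index and are counted. On small problems the
  solution is verified in the test suite against exhaustive bipartition
  enumeration.
* **Centering**: within-subject-within-session mean removal happens in
  edge space before clustering; the removed mean is retained. Because
  centered centroids no longer reflect connectivity strength, the
  session-level mean is added back before I/S labeling and before graph
  thresholding.
* **Centroid-mean removal**: uncentered centroids of *different* states
  are highly similar (both are dominated by mean connectivity), so
  centroid reliability is also reported after subtracting, from each
  session's centroids, the mean of that session's centroid pair. The two
  mean-removed centroids of one session are exactly antipodal.
* **ICC**: one-way random-effects mean squares (not the two-way
  ICC(2,1)/ICC(3,1) variants); p-values come from an F-test on
  `MSbs/MSws` and are reported unadjusted. Undefined parameter values are
  deleted pairwise per parameter, and the n actually used is always
  reported.
* **Bootstrap**: percentile intervals (not BCa), resampling subjects with
  replacement; degenerate resamples are redrawn up to a cap and counted,
  and more than 50% degenerate draws is an error.
* **State matching across clusterings**: minimum-total-CD one-to-one
  assignment, solved exactly by permutation enumeration (k <= 8), with a
  flag when a greedy per-row argmin would have conflicted.
* **ITI with an odd number of dwell segments**: the same
  `(MDT_I + MDT_S)/2` formula is applied; the definition is only exact
  for alternating even runs, and this choice is recorded here rather than
  hidden.
* **Graph metrics**: weighted modularity by default (binary optional);
  the partition comes from igraph's leading-eigenvector implementation of
  Newman's algorithm, while Q itself is evaluated by this package's
  e-matrix formula; shortest-path lengths use the `1/weight` convention
  and unreachable pairs contribute zero to efficiency.

## Problem sizes used in validation

The shipped validation runs use the default cohort (40 subjects, 30 ROIs,
400 frames, 361 windows per session; about 14,400 clustered instances of
435 edges), silhouette curves on a seeded 600-instance subsample over
`k = 2..6`, bootstrap calibration on 200 simulated 100-subject cohorts
with 500 resamples each, and 20 seeded replicates for the directional
pipeline comparisons (uncentered vs. centered, full vs. half scan). These
sizes were chosen as the smallest at which the targeted effects are
well-resolved statistically.

## Limitations

* Hard state assignment only: no mixed or overlapping states, no HMM
  smoothing, no coactivation-pattern analysis.
* The two-state description is a modeling choice, not a claim about the
  true number of brain states; with `k > 2` the I/S labeling and the
  prevalence complement identity no longer apply.
* Reliability estimates on the synthetic cohort depend on generator
  settings (trait spread, dwell times, noise); they characterize the
  estimators, and are not calibrated to reproduce any particular
  empirical cohort's values.
* Sliding-window correlation itself has known biases (window-length
  trade-off, mixing across transitions); windows straddling a true
  transition are genuinely ambiguous and dominate the residual
  label-recovery error even at low noise.
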