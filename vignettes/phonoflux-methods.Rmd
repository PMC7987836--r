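---
title: "Methods: directed cortical dynamics of phonotactic repair"
author: "phonoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed cortical dynamics of phonotactic repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonoflux)
```

## The scientific problem

Listeners of English tend to "repair" phonotactically illegal onset
clusters: a spoken /sr-/ is frequently reported as the legal /ʃr-/.
Learning new words that contain an illegal cluster can weaken this bias.
phonoflux implements the analysis chain for a combined behavioral and
MEG/EEG study of that phenomenon:

1. **Behavior.** Subjects learn nonwords whose onsets are illegal
   (/sr-/ for one training group, /ʃl-/ for the other), then categorize
   fricatives from a five-step [s]–[ʃ] continuum spliced onto /_r/ and
   /_l/ contexts. A continuum is *Trained* for a subject when its
   potential cluster occurred in that subject's training words, *Naive*
   otherwise. A response is *unrepaired* when it reports the illegal
   cluster ("S" in the /_r/ context, "SH" in /_l/). The question is
   whether training raises the unrepaired-response rate.
2. **Neural dynamics.** From source-localized activation maps, regions
   of interest (ROIs) are identified by a data-driven algorithm, and
   directed influences between ROI time courses are estimated with a
   Kalman-filter time-varying MVAR model and the Granger Causality
   Index (GCi), separately per condition. Conditions are compared
   edge-by-edge by the number of significantly causal timepoints.

Raw recordings of such studies are rarely redistributable, so the
package ships a synthetic-data module that generates all three kinds of
input — activation maps with planted spatial clusters, multichannel
series from networks with known directed edges, and trial tables with a
planted learning effect — and every statistical claim in the test suite
is validated against that known ground truth.

## Behavioral model

Trial bookkeeping is deterministic: condition from (group, context) and
unrepaired coding from (context, response), as in the design table.
Analyses keep continuum steps 2–5 by default (step 1 sits at the floor
of the psychometric function; the step filter is configurable through
`stepsIncluded` rather than hard-coded). With 27 trials per cell this
yields 108 analyzed trials per participant per condition.

The condition test is a fixed-effects logistic regression of the
unrepaired indicator with a likelihood-ratio test of the Condition
term. The reference analysis for this design is a by-subject
random-slopes mixed model; the package deliberately uses the
fixed-effects form: the scientific claim under test — a positive shift
in unrepaired-response log-odds after training — is preserved, the
1-df likelihood-ratio test is exactly calibrated at the simulated
study scale (type-I error 0.05 ± 0.02 across 200 replicates in the
acceptance suite), and the fit has no convergence failure modes on
small synthetic samples. Subject can be added as a fixed covariate
(`includeSubject = TRUE`). The default "full" model contains main
effects of Condition, Context and Step (categorical); setting
`interactions = TRUE` tests Condition together with all its
interactions against a Context × Step null, for users who want the
factorial structure. Under complete separation both models are refit
with symmetric half-weight pseudo-observations per design cell (a weak
data-augmentation prior) and the result is flagged.

The synthetic generator draws responses from a logistic psychometric
function of step with a context-specific midpoint (defaults: slope 1.2
per step, midpoints 3.2 and 3.6 for the /_l/ and /_r/ contexts),
rising from near-floor at step 1 — the qualitative shape of the
observed repair-rate curves. The planted learning effect is an additive
log-odds shift (default +1.0) applied in the Trained condition only.
What the generator does **not** emulate: by-subject heterogeneity in
slopes or midpoints, lapses, sequential effects, or reaction times.
Passing tests therefore show correctness and calibration of the
estimator under the stated design, not robustness to individual
differences.

## ROI identification

The algorithm consumes a vertex-level activation map (vertex
coordinates in mm plus a per-vertex time course) and has three steps,
all operating on the analysis window (default 100–500 ms):

1. **Centroids** — vertices whose mean activation exceeds the 95th
   percentile (linear-interpolation definition) of all vertex means;
   scanning in descending strength, candidates within 5 mm (Euclidean)
   of an accepted stronger candidate are removed, leaving one centroid
   per local maximum. Ties in strength break lexicographically by
   vertex id, making the step fully deterministic.
2. **Growth** — each vertex's windowed course is z-scored (mean 0,
   SD 1), so Euclidean distance between courses measures shape, not
   amplitude ("non-normalized" strength is used everywhere amplitude is
   intended). A vertex joins a centroid's ROI when its distance to the
   centroid is below 0.5 SD of the distances from the supra-threshold
   candidate set to that centroid, **and** it is reachable from the
   centroid through the spatial adjacency graph (vertices within 2 mm
   are adjacent; growth is breadth-first), so ROIs are contiguous.
3. **Pruning** — ROIs whose normalized mean course lies within 0.9 SD
   (of the pairwise ROI-course distance distribution) of a stronger
   ROI's course are discarded, because the Granger model assumes each
   signal carries unique predictive information. With fewer than three
   ROIs that distribution has no SD; the degenerate rule prunes exact
   duplicates only.

Two readings of the published procedure are genuinely open and are
resolved here as configuration: which distribution's SD the 0.5/0.9
factors scale (chosen: centroid-distance distribution over
supra-threshold candidates for growth; pairwise ROI-course distances
for pruning), and whether the 5 mm exclusion is geodesic or Euclidean
(chosen: Euclidean — the synthetic patch is planar, where they agree).
Overlapping memberships after growth are resolved in favor of the
stronger ROI, and per-subject representative vertices are the members
best correlated with the group-level ROI mean course.

The synthetic maps place vertices on a jittered planar grid (spacing
1.5 mm, the density of a reasonably fine source space), with planted
clusters receiving a shared latent course scaled by a Gaussian spatial
falloff. Latent courses are unimodal bumps staggered across the central
part of the analysis window, so that every planted signal actually lies
in the window the algorithm inspects; cluster `amplitude / noiseSd`
defines the per-sample SNR. A folded cortical mesh, geodesic distance,
inter-subject morphing error, and spatially correlated noise are all
outside the generator's scope.

## Time-varying MVAR estimation

For each target channel the package runs a Kalman filter whose state is
the vector of AR coefficients of all channels at lags 1..p (default
p = 5, the study's model order; order selection is out of scope since
information criteria were inconclusive for this class of data). The
observation equation is the one-step regression of the target on the
p preceding samples of every channel; the state follows a random walk.
Counter-models re-run the same filter with the candidate source
channel's lags removed from the regressor.

Filter constants (all in `kalmanSettings()`):

* `processNoiseScale` (default 1e-4): random-walk variance per
  coefficient per sample. As it approaches 0 the filter reduces to
  recursive least squares, and on stationary data the post-warm-up mean
  coefficients agree with the OLS solution (the acceptance suite
  verifies RMSE < 0.05 on a 4-channel MVAR(2) with n = 2000). Larger
  values track changes faster: with 1e-3 the filter crosses half of a
  step change in a coupling coefficient within 300 samples.
* `observationNoiseScale` (default 1): fixed observation noise
  variance; with unit-variance innovations this is the natural scale.
* `initialCovarianceScale` (default 100): diffuse prior on the
  coefficients.
* `errorSmoothing` (default 0.95): decay of the exponentially weighted
  innovation variance whose square root is the per-timepoint
  prediction-error scale. The estimate is bias-corrected (normalized
  by 1 − λ^t), so it is unbiased from the first samples. The default
  corresponds to an effective averaging window of ~20 ms at 1000 Hz.
  This constant trades temporal resolution against variance: much
  slower decays make the error-scale trajectories of data and
  surrogates so smooth that the significant-timepoint count saturates
  at the window ceiling and loses all discrimination (in development
  runs, edge-recovery sensitivity collapsed to zero at λ = 0.99),
  while instantaneous |residual| is far too noisy.
* `warmupMs` (default 100): the filter converges within roughly the
  first 100 ms; the model is computed from 0 ms onward but consumed
  only from 100 ms, so the warm-up never overlaps the analysis window.

## GCi, bootstrap null and condition comparison

The Granger Causality Index for a directed pair at time t is
`ln(errReduced(t) / errFull(t))` — positive when omitting the source
worsens prediction of the target, i.e., when the source carries unique
predictive information.

Significance is assessed against a residual-resampling bootstrap null:
surrogate data are iterated from the fitted time-varying full model
with the tested source→target coefficient block set to zero and
innovations resampled with replacement from the per-channel residual
pools; each surrogate then passes through the identical full +
counter-model analysis. One construction detail matters and is a
deliberate design choice: the fitted coefficient trajectories carry
estimation noise at the filter's own adaptation timescale, and
re-iterating that noise as if it were signal biases the null GCi
downward (the re-fit full model tracks the wiggle worse than the
smaller counter-model). The surrogate schedule is therefore smoothed
with a centered moving average spanning the warm-up period (101
samples at 1000 Hz) before iteration; task-related coefficient changes
are slower than the filter's adaptation scale and survive the
smoothing. With this construction the null matches the sampling
distribution of the GCi under a truly absent edge, and the pointwise
p-values are approximately uniform (Kolmogorov–Smirnov distance < 0.1
in the acceptance suite).

Pointwise p-values are the plain one-sided empirical fraction of null
GCi values at or above the observed value (upper tail only — negative
GCi has no causal reading). Per edge, the summary statistic is the
count of window timepoints with p below α. Because neighboring
timepoints are strongly dependent, a Binomial(nWindow, α) reference
for that count would be badly anti-conservative; the count's null
distribution is instead taken from the bootstrap itself (each
replicate scored against the remaining replicates exactly as the
observed series is scored against all of them), and Benjamini–Hochberg
FDR control across the edge family is applied to those count-level
p-values when detecting edges within one condition.

Between conditions, edges are compared by the difference in
significant-timepoint counts with a conditional exact binomial test
(given k = countA + countB, countA ~ Binomial(k, ½) under exchange of
conditions; two-sided p = twice the smaller tail, capped at 1; k = 0
gives p = 1), again followed by FDR control across edges. The same
caveat about timepoint autocorrelation applies to the nominal level of
this comparison; it is the field's convention and is reported as such.
Surrogate series that diverge (|x| > 1e6) are redrawn and counted.

Bootstrap nulls are built at the level at which the GCi is computed —
per series (per subject and condition) — and `nBootstrap` defaults to
2000 to match the study design; the test suite and worked examples use
200, which the edge-recovery experiments show is already sufficient for
stable detection at these problem sizes.

## Problem sizes and numerical choices

Validation experiments run at the study's natural scale: series of 501
samples (0–500 ms at 1000 Hz) with the 100–500 ms window (401
timepoints), 200 bootstrap replicates for recovery/calibration suites,
100 seeded maps for ROI recovery, 20 seeded runs for 6-channel edge
recovery, and 200/100 replicates for the behavioral calibration/power
checks. All randomness flows through explicit integer seeds; per-stage
seeds derive from the top-level seed by a fixed affine counter scheme.
Windows in milliseconds convert to samples by rounding toward the
interior, so a closed 100–500 ms window at 1000 Hz is exactly 401
samples. The time-series text container serializes doubles with 17
significant digits, making write→read round trips bit-exact and
write→read→write byte-identical.

## Known limitations

* The generator's innovations are Gaussian and spatially independent;
  real source-space noise is neither. Calibration results transfer to
  real data only to the extent that trial-averaged residuals are
  well-behaved.
* The per-timepoint GCi count comparison inherits the autocorrelation
  caveat above; its nominal level between conditions is approximate.
* The fixed-effects behavioral model ignores by-subject slope
  variance; with strong subject heterogeneity its type-I error for the
  Condition effect would be optimistic relative to the mixed model.
* ROI identification is validated on planar patches with Euclidean
  distances; folded-mesh geodesics and atlas labeling are out of scope.
* Estimated edge counts, like any Granger-type measure, reflect
  predictive — not interventional — causality, conditional on the
  observed channel set.
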