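---
title: "Disentangling object size and depth with decoding RDMs and partial RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling object size and depth with decoding RDMs and partial RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An object's perceived real-world size, its retinal (displayed) size, and its
inferred egocentric depth are tightly coupled in natural images: under
perspective projection at a fixed viewing distance, depth is proportional to
real-world size divided by retinal size. Any neural signal that correlates
with one of the three therefore tends to correlate with the others, and a
time-resolved analysis that wants to say *when* the brain represents
real-world size — as opposed to the lower-level quantities it covaries
with — has to remove that shared variance explicitly.

`decodersa` implements a complete pipeline for this question:

1. **Neural RDMs by pairwise decoding.** For every unordered pair of
   conditions and every timepoint, a linear support-vector classifier is
   trained and tested on the channel vector at that timepoint with repeated,
   stratified cross-validation (default five-times fivefold). The held-out
   accuracy is the pairwise dissimilarity, giving one condition-by-condition
   RDM per timepoint per subject.
2. **Hypothesis RDMs.** Absolute pairwise differences of the real-world size
   rating, the retinal size in pixels, and the depth index (size/retinal).
3. **Model RDMs.** 1 − Pearson correlation between per-condition feature
   vectors supplied from outside (network-layer activations, word
   embeddings) or simulated by the package's recipes.
4. **Partial Spearman RSA.** Each hypothesis RDM is correlated with the
   neural RDM at each timepoint while the other two are partialled out:
   all vectors are rank-transformed (average ranks), both sides are
   residualized on the controls by least squares, and the residuals are
   correlated. This equals the precision-matrix partial correlation, which
   the test suite asserts to 1e-10.
5. **Inference.** Sign-flip cluster-based permutation tests over
   timecourses; bootstrap peak-latency estimation by resampling RDM cells;
   paired t-tests on subject-level bootstrap-mean latencies; a shuffle-null
   test for model RDMs; commonality-analysis variance partitioning; and
   leave-one-subject-out noise ceilings.

All user-facing results are tibbles (or carry `tidy()`/`glance()` methods),
and `autoplot()`/`plot_*()` give ggplot2 graphics.

## The synthetic-data generator

Real recordings of this kind are large and external; the package instead
ships a generator whose geometry is exactly the one the hypothesis RDMs
assume, so that the whole pipeline can be validated by parameter recovery.

The noiseless signal for condition $c$ at time $t$ is

$$ s_c(t) \;=\; \sum_f a_f\, g_f(t)\, \mathbf{u}_f\, z_f(c), $$

where $g_f$ is a unit-peak Gaussian bump (center and width in ms), $\mathbf
u_f$ a fixed random unit channel direction, and $z_f(c)$ the standardized
latent feature value. Because each feature occupies a single direction
scaled by its value, the noiseless pattern distance between two conditions
at the bump center is proportional to $|z_f(c_i) - z_f(c_j)|$ — precisely
the cell of an absolute-difference hypothesis RDM — so injected geometry is
recoverable by decoding + RSA. Trials add i.i.d. Gaussian noise.

Defaults and why:

* **Geometry** (17 channels, 40 samples spanning −100..300 ms at 100 Hz, 80
  trials per condition) mirrors the posterior-channel, epoch and
  trial-count layout of the public recordings this analysis style targets.
  Sample $k$ maps to $-100 + 10k$ ms; stimulus onset falls on sample 10.
* **Latent features.** Real-world size is drawn log-uniform on 100–423
  rating units (the span of the published behavioral ratings); retinal size
  independently log-uniform on 50–600 px; the depth index is exactly
  size/retinal. Size and depth RDMs are therefore positively intercorrelated
  by construction, as in the real feature set.
* **Feature windows** default to 87, 138 and 206 ms for depth, retinal size
  and real-world size — the processing order the method is designed to
  resolve — with a 15 ms Gaussian SD (a ≈35 ms FWHM transient, typical of
  early evoked components). These are config values, not constants.
* **Noise SD 1, amplitude 1 per feature.** This puts peak pairwise decoding
  accuracy near 0.65 at 80 trials/condition — comfortably above chance but
  far from saturation, which matters because at zero noise decoding
  saturates at 1 for every pair and the RDM flattens.
* **Pseudo-subjects** are independent noise realizations sharing the
  condition set (subject $s$ uses seed $\mathrm{seed}+s$).

What the generator does **not** emulate: 1/f spectra, channel covariance,
autocorrelated noise, eye or muscle artifacts, per-exemplar identity
structure beyond an optional toggle, or inter-subject variability in the
latency and topography of the injected features. Passing tests therefore
show that the *statistical machinery* is correct and calibrated, not that
any particular real dataset will behave this way.

Model-feature recipes prescribe the representational geometry directly: the
target model RDM is the weighted *rank* mixture of the named hypothesis
RDMs, and per-condition vectors realizing it are drawn from a Gaussian
factor model whose correlation matrix is 1 minus that mixture (made
positive definite, when needed, by a uniform ridge shrink of the
off-diagonal, which is linear in the mixture and so preserves its rank
structure exactly). Because the carried structure is rank-*linear* in the
hypothesis RDMs, partialling the named controls removes it, which is what
lets an "early layer" recipe (retinal size + depth) leave real-world size
unflagged — a property no concatenation-of-features embedding can deliver
here, since size = depth × retinal makes any nonlinear carrier of the
other two a partial carrier of size. Finite embeddings leave
$O(1/\sqrt{D})$ sampling noise, so the tests assert rank agreement ≥ 0.99
for a noiseless single-feature recipe rather than exactly 1. One caveat is
inherited by the shuffle-null test: the sampling error of a
correlation-distance RDM is dependent across cells sharing a condition,
while the shuffle null treats cells as exchangeable, so flag rates for
features a recipe does not carry run somewhat above the nominal 5% (of
order 10–20% at the default sizes); the shipped checks bound them well
below the carried-feature rate instead of at the nominal level.

## Numerical and design choices

* **Pair order.** All vectorizations use row-major $(i, j)$, $i < j$ —
  (1,2), (1,3), …, (2,3), … — so bootstrap resampling indices align across
  neural, target and control vectors. For 200 conditions this is the
  familiar 19,900-cell vector.
* **Classifier.** The solver is a dual coordinate-descent linear SVM
  (L2-regularized hinge loss, cost 1, bias as an augmented regularized
  feature), with features z-scored using training-fold statistics only.
  The default solver budget caps at 20 epochs with the standard
  projected-gradient stopping rule (0.1), warm-starting the dual variables
  across the 25 cross-validation fits that share a (pair, timepoint);
  relative to full convergence this changes held-out accuracies by well
  under 0.01 on average and leaves the RDM geometry intact (stack
  correlation ≈ 0.998), while cutting runtime several-fold. `max_epochs`
  raises it. The test suite cross-checks predictions against an independent
  SVM implementation (libsvm via e1071), which agrees on ≈99% of test
  points; the residual discrepancy comes from libsvm's unregularized bias.
* **Folds.** Stratified within condition; fold draws are made once per
  condition per repeat (repeat $r$ uses seed $\mathrm{seed}+r$), so results
  do not depend on which pairs are decoded or in what order. Trials are
  first put in a canonical order (blocked by sorted condition label,
  preserving within-condition sequence), making results invariant to any
  trial permutation that preserves within-condition order.
* **Degenerate decoding inputs.** A condition with fewer than
  $2 \times n_\mathrm{folds}$ trials is an error with the offending counts;
  a zero-variance training channel gets unit scale instead of NaN.
* **Cluster test.** The cluster-forming threshold is a one-tailed
  $p < 0.05$ t-threshold ($\mathrm{df} = n-1$), exposed in the config
  because the procedure it reimplements does not state one. The null
  sign-flips each subject's whole timecourse with probability ½ — the
  standard exchangeability argument for one-sample tests — and p-values use
  the $(1+\#\{\mathrm{null} \ge \mathrm{obs}\})/(1+N)$ estimator, so no
  cluster can report $p = 0$. Timepoints with zero across-subject variance
  are excluded with a warning.
* **Peak latencies.** The search window is the union of significant
  clusters of the matching partial timecourse (`run_rsa_pipeline()` falls
  back, with a notice, to the post-onset epoch when no cluster reaches
  significance). Ties break to the earliest sample. Subject latency is the
  bootstrap mean; group summaries are mean ± SEM over subjects.
* **Shuffle-null model test.** Shuffling the model vector's cell order and
  then ranking equals permuting its rank vector, which the implementation
  exploits; the one-sided criterion is "observed above the null's 95th
  percentile".
* **Variance partitioning** solves the inclusion–exclusion system relating
  subset $R^2$s to unique/shared components on rank-transformed vectors.
  Components sum to the full-model $R^2$ by construction; negative
  commonalities (suppressor structure) are reported, not clipped.
* **Noise ceiling.** Upper bound correlates each subject with the
  all-subject mean (which keeps an own-subject bias of roughly $1/\sqrt k$
  under pure noise — worth remembering when reading low-SNR ceilings);
  lower bound uses the leave-one-subject-out mean.
* **Multiple comparisons** across the three hypothesis timecourses: none
  beyond cluster-level correction, matching per-feature reporting; stated
  here deliberately.
* **Partial-correlation edge cases.** A vector fully explained by the
  controls (residual variance at numerical-noise level, relative tolerance
  1e-8) yields coefficient 0 with a warning rather than an undefined value;
  collinear controls are an error naming the offending pair.

## Replication sizes used by the shipped checks

The packaged tests and `scripts/acceptance.R` validate, end to end:
latency-order recovery (depth < retinal < size, and each group-mean latency
within ±20 ms of its injected center) across 10 and 8 independent seeds
respectively at the full default study conditions; cluster-test and
shuffle-null type-I rates at their nominal 5% (hundreds of pure-noise
replicates); decoding calibration (chance 0.50, ≥0.95 on strongly separated
pairs, monotone in injected amplitude); and the early/late recipe
dissociation across 50–100 seeds. These sizes are the package's own
replication choices and are stated here so they can be scaled up freely.

## Worked example

```{r, eval = FALSE}
library(decodersa)

res <- run_rsa_pipeline(pipeline_config(seed = 42))
res
#> <rsa_pipeline_result>
#>   20 conditions, 3 subject(s), 40 timepoints
#>   real_world_size    peak 203.1 ms +/- 1.1 (SEM)
#>   retinal_size       peak 136.2 ms +/- 2.5 (SEM)
#>   real_world_depth   peak 84.9 ms +/- 2.1 (SEM)

res$latency_tests       # paired two-tailed t-tests between features
tidy(res$cluster_tests$real_world_size)
autoplot(res$timecourses$real_world_size)
plot_peak_latencies(res$latencies)
```

The injected windows sit at 87, 138 and 206 ms; the recovered group-mean
latencies above come from an actual run with seed 42.

## Known limitations

* The depth index is a proxy: a ratio of a behavioral rating to a pixel
  measurement, meaningful only through the ranks of its pairwise
  differences.
* Decoding-accuracy RDMs are bounded, so strong effects compress near 1;
  the generator's default noise level deliberately avoids that regime.
* With few subjects (the default demo uses 3) the cluster-forming t
  threshold is coarse (df = 2) and the paired latency tests have little
  power; they are demonstrations of the machinery, not of a minimum
  sample size.
* The noise ceiling's upper bound is biased upward at low SNR, as noted
  above.
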