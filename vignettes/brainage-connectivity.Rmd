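---
title: "Functional brain age from static and dynamic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional brain age from static and dynamic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`connage` implements a functional brain-age analysis chain for
independent-component (IC) resting-state time courses. The scientific object
at its core is the *brain-age gap* (BAG): a regression model is trained to
predict chronological age from functional network connectivity (FNC) in a
healthy reference population; applied to a new individual, the difference

$$\mathrm{BAG} = \hat a - a$$

between predicted ($\hat a$) and chronological age ($a$) indexes accelerated
(positive) or resilient (negative) brain aging. The package supports two
connectivity representations:

* **Static FNC (sFNC)** — the Pearson correlation
  $R = \frac{\sum_n (x_1-\bar x_1)(x_2-\bar x_2)}
  {\sqrt{\sum_n (x_1-\bar x_1)^2\sum_n (x_2-\bar x_2)^2}}$
  between every pair of IC time courses over the whole scan, a $C \times C$
  matrix ($C = 53$ in the bundled atlas) vectorized into
  $\binom{C}{2}$ features (1378 for 53 components).
* **Dynamic FNC (dFNC)** — the same correlations computed inside a tapered
  sliding window (a 20-TR rectangle convolved with a Gaussian of
  $\sigma = 3$ TR, support 38 frames), producing a $C \times C \times T$
  array over window placements. Within each window the taper weights the
  moments (weighted Pearson correlation), which reduces exactly to the plain
  correlation under a uniform taper.

Three regression families are provided: a closed-form **ridge** baseline; a
**graph-convolutional network** on the sFNC matrix (row-normalized $|FNC|$
as propagation operator, FNC rows as node features, two ReLU graph layers,
global mean pooling, linear readout); and a **bidirectional stacked LSTM**
over the dFNC window sequence (last hidden states of both directions,
linear readout). The neural families are trained with Adam on mean absolute
error (learning rate $10^{-3}$, batch 64) under grouped $K=5$-fold
cross-validation; the refit epoch count is the median of the per-fold best
epochs by validation MAE. The graph-convolution layer structure is an
interpretation of brain-connectivity GCNs in the literature (the propagation
operator is not uniquely pinned down by any single convention), not a
reproduction of a specific published network.

Downstream, BAGs are tested against cognition scores (attention vigilance,
working memory) with an ordinary least-squares GLM adjusting for age, sex,
site, age², age×sex and diagnosis, with Benjamini–Hochberg FDR within each
declared family of tests: the wide-brain family (2 modalities) and the
sub-network family (7 networks × 2 modalities = 14 tests), per outcome. The
reported *r* is the partial correlation of BAG with the outcome given the
covariates, computed from the $t$ statistic as $t/\sqrt{t^2 + \nu}$ — the
only definition consistent with one GLM producing both $\beta$ and $r$.

## The synthetic cohort generator

Because the cohorts such models are normally trained on are
access-controlled, the package ships a generator whose defaults define the
study conditions for every test:

* **Aging signal** — linear in effective age on a random 15% of edges
  (drawn once per cohort from the seed), slope 0.003 correlation units per
  year by default; the perturbed matrix is projected to the nearest PSD
  correlation matrix by eigenvalue clipping with the unit diagonal restored.
* **Connectivity states** — a first-order Markov chain (self-transition
  $1 - 1/\text{dwell}$, mean dwell 40 frames) switches between states that
  share the aging mask but perturb the masked base correlations by ±0.2.
* **Site and diagnosis** — per-site component mean shifts (SD 0.1);
  diagnosed subjects carry a +7-year effective-age acceleration, consistent
  with the 6–8-year spread reported for schizophrenia in the brain-age
  literature; sex carries no planted signal.
* **Individual aging** — every subject additionally receives an
  idiosyncratic acceleration with SD 5 years (`bag_noise_sd`). This term is
  essential: if the true BAG were a deterministic function of diagnosis,
  the covariate-adjusted BAG–cognition association would be identically
  null once diagnosis is in the model, and no pipeline could recover it.
  A 5-year spread matches the within-group BAG dispersion reported across
  brain-age studies.
* **Cognition** — attention and working-memory scores are unit-free
  (intercept 0), equal to `cognition_slope` (−0.5/year) times the true BAG
  plus independent Gaussian noise (SD 4).

What the generator deliberately does **not** emulate: hemodynamics, spatial
maps, head motion, scanner drift, non-Gaussian noise, or any nonlinearity
of aging. Passing tests therefore demonstrate that the machinery recovers a
known linear-Gaussian ground truth, not that it would perform identically
on real scans.

On this design the state structure is age-independent, so the dynamic
representation carries no age information beyond the static one; the
package makes no claim that the LSTM family must outperform the static
families here, only that each family recovers the planted signal.

## Numerical choices

* **Denoising chain** (fixed order: detrend → nuisance → outlier → filter).
  Polynomial detrending projects out a constant plus orders {1,2,3} of
  normalized time. Nuisance regression (optional; synthetic scans have no
  realignment parameters) residualizes on the regressors and, if requested,
  their backward-difference derivatives (first row zero), refusing
  rank-deficient designs by name. Outlier handling is despiking-style
  clipping at 3.5 scaled MADs per component — deterministic and
  shape-preserving, chosen because frame censoring would break window
  bookkeeping. The low-pass is a 5th-order Butterworth below 0.15 Hz
  applied forward–backward (zero phase) with odd-symmetric padding of
  3×order and steady-state initial conditions, so a constant signal passes
  through unchanged.
* **Approximate idempotence.** Re-running the chain necessarily attenuates
  the filter's transition band a second time; for a 5th-order Butterworth
  this changes the RMS of white-noise input by roughly 3%, which is the
  floor for any test of chain idempotence at these settings.
* **Duration harmonization** is tail truncation in native sampling to the
  shortest scan duration (no resampling across TRs): windows are specified
  in TR units, so connectivity is TR-agnostic once the window is fixed.
  Note the tapered-window literature quotes both 20-TR and 40-TR widths in
  closely related settings; the default here is 20 TR and the width is
  fully configurable.
* **Windows** use only fully supported placements (no partial edge windows
  that would need asymmetric weight renormalization), stride 1 TR by
  default (configurable). No Fisher z-transform is applied by default.
* **PSD repair** clips negative eigenvalues at zero and renormalizes the
  diagonal; repair failure (a diagonal entry collapsing to zero) raises an
  error advising a smaller aging slope rather than silently producing an
  invalid correlation matrix.
* **Target scaling.** Neural families train on z-scored ages and invert the
  scaling at prediction; at desk-scale step counts Adam could not traverse
  the ~60-year offset on the raw scale within the configured epochs.
* **Bias correction** (optional, off by default): predicted age is
  regressed on age in a reference group and rescaled as
  $a + (\hat a - \alpha - \beta a)/\beta$, undoing regression-to-the-mean
  shrinkage before group comparisons of BAG.

## Study sizes used by the tests

All empirical claims in the test suite and the acceptance script are
computed at documented desk-scale sizes, chosen once: the
parameter-recovery study uses 400 subjects × 16 components × 200 frames at
TR 0.72 s with aging slope 0.004 (sampling error of a correlation from
~200 frames ≈ 0.07, against a planted across-subject signal of
0.004 × 22.5 years ≈ 0.09 per affected edge — the same signal-to-noise
regime in which full-scale functional brain-age models reach validation
r ≈ 0.87). At this scale the ridge baseline reaches r ≈ 0.9; the graph
network trains for 150 epochs and the LSTM (24 hidden units, one layer,
top-30 edges of stride-4 windows) for 50, both clearing r ≥ 0.8. GLM
calibration studies use n = 150 with 100–400 replicates; the end-to-end
pipeline property runs four seeded replicates at 300 + 300 subjects.

## Known limitations

* The neural families are small, pure-R implementations intended for
  correctness and desk-scale experiments, not GPU-scale cohorts.
* Sub-network models use within-network edges only; edges *touching* a
  network are attributed to no single network.
* The generator's linear-Gaussian ground truth cannot probe model behavior
  under realistic artifacts (motion, scanner effects beyond mean shifts).
* No k-means state clustering, meta-state statistics, site harmonization
  (e.g. ComBat) or mediation analysis; the association suite is
  cross-sectional OLS only.
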