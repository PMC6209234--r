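---
title: "Methods: personalized autism diagnosis from resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized autism diagnosis from resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`asdcad` implements a computer-aided diagnosis (CAD) pipeline for autism
spectrum disorder built on resting-state BOLD fMRI. The pipeline assumes the
measured signal at voxel $i$ is a noisy linear mixture of spatially fixed
sources with independent activation time courses,

$$x_i(t) = A\, s_i(t) + \eta_i(t), \qquad \eta_i \sim N(0, \sigma^2 I),$$

where the rows of $s$ are non-Gaussian spatial sources, $A$ is the mixing
matrix of time courses and $\sigma^2$ is an isotropic noise variance. The
stages, in order:

1. **Group probabilistic ICA** (`fit_group_pica()`): subjects are temporally
   concatenated (per-voxel variance normalization within subject), reduced by
   PCA to the model order $K$, whitened with the probabilistic-PCA gain
   $(\lambda_k - \sigma^2)^{-1/2}$, and rotated by a fixed-point
   negentropy-maximizing iteration (symmetric orthogonalization, `tanh`
   contrast). The noise variance is initialized from the mean of the
   discarded eigenvalues and re-estimated from the residuals of the
   reconstruction $\hat A \hat s$, iterating until it stabilizes. The model
   order is fixed at the atlas size (34 by default) rather than estimated.
2. **Dual regression** (`dual_regression()`): two least-squares stages map
   the group maps to subject-specific time courses, then the time courses to
   subject-specific maps. On data lying exactly in the span of the group
   maps this reproduces the data (projection idempotence), which the tests
   assert to numerical precision.
3. **Atlas matching** (`match_components()`): every atlas component selects
   the spatial map with the largest magnitude of the Pearson correlation
   between the component's binary mask and the map, both z-scored over
   in-brain voxels. Magnitude is used because ICA fixes neither sign nor
   scale of a source; the recorded correlation keeps its sign. The same map
   may serve several components, and ties break toward the lowest map index.
4. **PSD features** (`compute_psd()`, `extract_features()`): each matched
   time course is summarized by its power spectral density on a common
   frequency grid. The default estimator is the full-length periodogram with
   mean removal, which is *exactly* invariant under circular time shifts —
   the property that motivates PSD features in the first place — and
   satisfies Parseval's identity. Welch averaging is available as an option
   (`method = "welch"`) but breaks exact shift invariance.
5. **Per-area encoding and scoring** (`cad_fit()`): one sparse autoencoder
   per area encodes the standardized PSD bins; a probabilistic RBF-SVM on the
   encodings produces an autism-class membership score
   $m(x) = 1 / (1 + e^{-d(x)})$, the logistic transform of the signed
   decision value oriented toward the autism class.
6. **Screening and fusion** (`select_significant_areas()`,
   `global_diagnosis()`): areas whose stand-alone sensitivity *and*
   specificity exceed 0.65 (strictly) are "significant"; the global
   diagnosis averages the significant areas' scores per subject and calls
   autism when the mean exceeds 0.5 (winner-takes-all; an exact tie resolves
   to the no-diagnosis class TD).
7. **Evaluation** (`run_cv()`, `permutation_test()`, `predictive_values()`,
   `behavioral_correlation()`): stratified 2/4/10-fold and
   leave-one-subject-out cross-validation, repeated-CV summaries, 99-shuffle
   label-permutation significance, trapezoid ROC/AUC, prevalence-adjusted
   predictive values and per-area Pearson correlation with behavioural
   scores.

## Tunable parameters

| Parameter | Default | Range searched | Meaning |
|---|---|---|---|
| `model_order` | 34 | fixed | spatial sources extracted by group ICA |
| `hidden_size` | 10 | 10–100 | autoencoder hidden units |
| `sparsity_target` ($\rho$) | 0.3 | 0.05–0.9 | target mean hidden activation |
| `sparsity_weight` ($\beta$) | 1 | 1–20 | weight of the KL sparsity penalty |
| `weight_decay` ($\lambda$) | 1e-4 | 1e-6–1e-3 | L2 penalty on the weights |
| `kernel_scale` | 5 | 1–20 | RBF width: $K(x,y)=\exp(-\lVert x-y\rVert^2/s^2)$ |
| `box_constraint` | 12 | 1–100 | soft-margin cost $C$ |
| `screen_threshold` | 0.65 | — | significance screen on sens & spec |
| `n_bins` | 32 | — | common PSD grid size |
| prevalences | 1/68, 0.187 | — | general / high-risk autism prevalence |

The SVM defaults (5, 12) are the selected values of the reference pipeline;
the autoencoder defaults are a single choice from inside the search ranges
(a mild sparsity pressure — $\beta$ at the bottom of its range, $\rho=0.3$ —
keeps the encodings informative for downstream classification; heavier
sparsity measurably compresses away between-subject power differences).
`grid_search_sae()` and `grid_search_svm()` expose the full searches; inside
`cad_fit()` they operate per area on training data only.

## The sparse autoencoder

One hidden layer of sigmoid units with linear reconstruction, trained by
batch L-BFGS on the analytic gradient of

$$L = \frac{1}{2n}\sum_i \lVert \hat x_i - x_i \rVert^2
      + \beta \sum_j \mathrm{KL}(\rho \,\Vert\, \hat\rho_j)
      + \frac{\lambda}{2}\left(\lVert W_1\rVert^2 + \lVert W_2\rVert^2\right),$$

with $\hat\rho_j$ the mean activation of hidden unit $j$ and
$\mathrm{KL}(\rho\Vert q) = \rho\log(\rho/q) + (1-\rho)\log((1-\rho)/(1-q))$.
Mean activations are clamped to $(10^{-8}, 1-10^{-8})$ before the KL term.
Initialization is symmetric uniform scaled by fan-in/fan-out and seeded, so
training is bit-reproducible. The analytic gradient is verified against
central finite differences to a relative error below $10^{-5}$ in the test
suite. The architecture depth is one hidden layer; deeper stacks are out of
scope.

## Design choices where the design was open

- **Common-grid resampling by band averaging.** Raw periodogram ordinates
  are high-variance estimates (asymptotically exponential, i.e. a relative
  standard deviation near 1). Interpolating them onto the common grid would
  preserve that noise bin for bin; instead each grid point averages the raw
  ordinates in its band, the standard variance-reduction step behind
  band-power features. Circular-shift invariance is untouched because the
  averaged quantities are functions of Fourier magnitudes only. Grids finer
  than the raw spectrum fall back to linear interpolation.
- **Screening on out-of-fold scores.** Per-area sensitivity/specificity are
  computed from membership scores of an internal stratified CV on the
  training set (the autoencoder is trained once per area — it is
  unsupervised — and only the SVM is refit per internal fold).
  Resubstitution scores of a $C=12$ RBF-SVM would memorize the training set
  and admit uninformative areas; out-of-fold scores keep the screen honest
  while still never touching test labels.
- **Class-weighted SVM.** libsvm is fit with inverse-frequency class
  weights. For balanced folds this is a no-op; for leave-one-subject-out
  folds it removes the systematic tilt toward the majority class that
  otherwise drives null accuracy well below chance.
- **Label-independent permutation folds.** `permutation_test()` holds one
  plain (unstratified) seeded fold partition fixed across the observed
  labeling and all shuffles. Stratifying by the observed labels would
  privilege the observed labeling and make null p-values anti-conservative;
  with label-independent folds, observed and shuffled labelings are
  exchangeable under the null and the add-one p-value,
  $p = (1 + \#\{\text{shuffled} \ge \text{observed}\})/(1 + n_\text{shuffles})$,
  is exactly valid. Because the autoencoder stage ignores labels, its
  per-fold encoders are trained once and reused across all 99 shuffles —
  an exact reuse, not an approximation.
- **Tie rules**, all deterministic: fusion tie at mean 0.5 goes to TD; SAE
  grid ties go to the first combination in lexicographic order; SVM grid
  ties go to the smallest kernel scale, then the smallest box constraint;
  matching ties go to the lowest map index.
- **Group-difference statistic.** `group_difference_test()` summarizes each
  subject's component map by its mean value (optionally within a mask) and
  permutes group labels with the add-one two-sided convention, Bonferroni
  across components.

## The synthetic phantom

`simulate_cohort()` generates cohorts with exactly the statistical structure
the decomposition stage assumes: disjoint contiguous label regions
(`make_label_volume()`), one smooth positive source map per area, band-limited
area time courses synthesized in the frequency domain (random amplitudes and
phases inside 0.01–0.08 Hz, rescaled so total in-band power is exact), and
i.i.d. Gaussian voxel noise. Defaults mirror a common acquisition: TR 2 s,
180 frames (≈ 6 min), 20 + 20 matched subjects, noise σ = 0.5 against unit
source power.

The group difference is injected where the classifier looks: autism-group
subjects carry a multiplicative in-band power shift
$1 + \text{effect\_size} \times u_i$ in the affected areas, with a
per-subject severity $u_i \sim U(0.5, 1.5)$. A log-normal power jitter
(σ = 0.15) gives both groups natural within-group heterogeneity, so null
contrasts are non-degenerate. Behavioural (ADOS-like) scores are
$6 + 2\,\text{effect\_size}\,u_i + N(0,1)$ for autism-group subjects only,
so a positive score–severity relation is recoverable by
`behavioral_correlation()`. With `effect_size = 0` the two groups are
exchangeable by construction.

What the phantom does *not* emulate: head motion, slice-timing offsets,
scanner drift, physiological (cardiac/respiratory) noise, spatially
correlated noise, hemodynamic response shape, or anatomical variability —
preprocessing that handles such effects is upstream of this package's
contract (inputs are assumed skull-stripped, motion-corrected and
co-registered). Passing tests on phantoms therefore demonstrates correctness
of the algorithms under the model's own assumptions, not robustness to real
acquisition artifacts.

## Numerical choices

- Whitening gains floor eigenvalue gaps at $10^{-12} \lambda_{\max}$;
  ICA rotations stop when every diagonal of $R_{t+1} R_t^\top$ is within
  `tol` of ±1; non-convergence is flagged with a warning, never silent.
- The noise-variance loop uses the degrees-of-freedom-adjusted estimate
  $\hat\sigma^2 = \mathrm{RSS} / ((T - K) V)$ and stops on a relative change
  below `tol` (default $10^{-6}$, at most 10 cycles).
- L-BFGS uses `pgtol = 1e-6` and at most 500 iterations (200 inside
  `cad_fit`, where per-area feature dimensionality is small and convergence
  is fast); a final loss above the initial loss raises an error carrying the
  trace tail.
- Gaussian smoothing kernels use $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$,
  truncate at $4\sigma$ and renormalize rows, so constant volumes pass
  through exactly.
- Seeds: every stochastic routine takes a seed and restores the caller's RNG
  state; multi-run procedures derive child seeds as
  $(s \cdot 1000003 + 7919\,k) \bmod (2^{31}-1)$.

## Problem sizes used by the test and acceptance suites

Simulation studies run at reduced sizes chosen to finish comfortably on one
CPU while keeping the tested contrasts far from their decision boundaries:
classifier-level studies use 40-subject cohorts with 10 areas, 160 frames
and 8 PSD bins on ground-truth time courses; the full volumetric pipeline
runs on 14×14×7 to 16×16×8 grids with 60–120 frames; screening recovery uses
50 seeded replicates; null calibrations use 10–60 replicates. The acceptance
script re-runs the complete volumetric pipeline (simulation → concatenation →
group PICA → dual regression → matching → PSD features → per-area SAE + SVM →
fusion → 99-shuffle permutation) at these sizes.

## Known limitations

- The PICA noise model is isotropic ($\Sigma_i = I$); voxel-specific noise
  covariances are not estimated.
- Model order is fixed, not selected (no Laplace-approximation order
  estimation), and component maps are not mixture-model thresholded.
- The membership sigmoid has unit slope (no Platt scaling), so scores are
  calibrated only up to that choice.
- Leave-one-subject-out estimates retain the usual small-sample fold bias;
  class weighting removes the imbalance tilt but not fold-to-fold variance.
- The phantom's spatial sources are disjoint smooth blobs; overlapping or
  anti-correlated networks are not simulated.
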