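---
title: "Boosted common-vectors LDA for small-sample spectral classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted common-vectors LDA for small-sample spectral classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldaboost)
```

## The problem

Near-infrared authentication data sit in an awkward statistical corner:
each spectrum has hundreds of correlated absorbance channels, but a
study rarely affords more than a few dozen samples per class. With $C$
classes, $M$ training spectra and $d$ channels, classical Fisher LDA
requires the within-class scatter
$S_W = \sum_{i=1}^{C}\sum_{m}(x_m^i-\mu_i)(x_m^i-\mu_i)^\top$
to be invertible; when $d > M - C$ it is singular and the
Fisher criterion is undefined. This package implements two answers and
the scaffolding to compare them:

* **PCA + LDA** (`fit_pca_lda()`): compress until $S_W$ is invertible,
  then run Fisher LDA in the score space. Simple, but the compression
  is unsupervised — discriminative detail riding on low-variance
  directions is truncated, and when nuisance variation (scatter)
  dominates total variance the retained components can be mostly
  nuisance.
* **Common-vectors LDA** (`clda()`): use the singularity. The null
  space of $S_W$ contains, for each class, a single *common vector*
  $x_{com}^i = x - QQ^\top x$ (any sample $x$ of the class gives the
  same result, since class-mates differ only inside
  $\mathrm{range}(S_W)$, spanned by the orthonormal basis $Q$). The
  eigenvectors $W$ of the scatter of the centred common vectors — at
  most $C-1$ with nonzero eigenvalue — define the projection, and the
  class templates $\Omega_i = W^\top x_{com}^i$ (the *discriminative
  common vectors*) classify a test spectrum by nearest Euclidean
  distance. Training samples project exactly onto their class template,
  so training classes collapse to $C$ points.
* **AdaBoost-CLDA** (`adaboost_clda()`): the boosted ensemble described
  below, which addresses the main weakness of a single CLDA subspace —
  its variance under noise.

## Why boosting helps CLDA

The common vectors are estimated from the orthogonal complement of a
subspace spanned by $M - C$ noisy difference vectors. Under channel
noise the estimated null space wobbles, and test spectra of confusable
classes land on the wrong side of templates. AdaBoost.M1 treats one
CLDA-plus-nearest-neighbour rule as a weak learner and averages many of
them, each fitted on a different weighted bootstrap resample:

1. normalise weights to a distribution $P_t$ (initially uniform);
2. draw $n$ samples with replacement from $P_t$; fit CLDA on the draw;
3. the weak hypothesis $h_t$ is nearest-neighbour in that round's
   subspace (equivalently nearest $\Omega$, by the exact-projection
   identity);
4. $\varepsilon_t = \sum_i P_t(i)\,[y_i \ne h_t(x_i)]$ over **all** $n$
   training samples;
5. stop if $\varepsilon_t = 0$ or $\varepsilon_t \ge \tfrac12$;
   otherwise $\alpha_t = \tfrac12\ln\frac{1-\varepsilon_t}{\varepsilon_t}$,
   multiply misclassified weights by $e^{\alpha_t}$ and correct ones by
   $e^{-\alpha_t}$;
6. classify by $H(x) = \arg\max_y \sum_t \alpha_t [h_t(x) = y]$.

Two design points deserve justification because the classical recipe
leaves them open:

* **Resampling rather than weighting.** CLDA has no per-sample-weight
  formulation, so the weight distribution enters through bootstrap
  resampling — the standard resampling variant of AdaBoost. Resampling
  has a second, structural benefit here: CLDA fitted on the *full*
  training set classifies every training sample perfectly (the
  exact-projection identity), which would make $\varepsilon_t = 0$ in
  round one, every time, and boosting would degenerate. Fitting on a
  bootstrap draw and evaluating on the full set keeps the weak learner
  genuinely weak. A weighted-scatter CLDA is a possible extension
  point, not implemented.
* **$\varepsilon_t$ on the full weighted set.** The weight update must
  touch every $P_t(i)$, so the error is evaluated over all training
  samples, not only the drawn subset.

Edge policies: a subset must contain every class (up to 10 redraws,
then each missing class's heaviest sample is swapped in for the
lightest draws); $\varepsilon_t = 0$ retains the perfect round with
$\alpha$ capped at the value an error of $1/(2n)$ would give — throwing
away a perfect classifier would be pathological, but an infinite vote
must be avoided — and stops; $\varepsilon_t = \tfrac12$ exactly stops
*without* retaining the round, since its vote weight would be zero.
After each update the renormalised weight of the misclassified samples
is exactly $\tfrac12$, and the ensemble training error obeys the
AdaBoost.M1 bound $\prod_t 2\sqrt{\varepsilon_t(1-\varepsilon_t)}$;
both identities are asserted by the test suite on every fitted model.

The default of `T_rounds = 10` reflects the iteration count at which
boosted-CLDA ensembles of this size stop improving appreciably; the
staged-accuracy curve (`staged_accuracy()`, `autoplot()`) makes the
choice inspectable per fit.

## Numerical choices

* **Gram-matrix route.** Eigen-structure of $S_W$ (and of the
  common-vector scatter) is always obtained from the $M \times M$ (or
  $C \times C$) Gram matrix, never the $d \times d$ scatter; `Q` is
  recovered as $A V \Lambda^{-1/2}$.
* **Rank tolerance.** Gram eigenvalues below
  $m\,\varepsilon_{mach}\lambda_{max}$ are treated as zero,
  with a structural cap on top: $\mathrm{rank}(S_W) \le M - C$ and
  $\mathrm{rank}(S_{com}) \le C - 1$ hold by construction, so at most
  that many eigenpairs are ever retained. The cap matters on tiny
  instances where a round-off eigenvalue can straddle any relative
  tolerance.
* **Sign convention.** Each column of $W$ (and of the LDA directions)
  is flipped so its largest-magnitude entry is positive, making
  templates and plots reproducible across platforms.
* **Representative sample.** The common vector is computed from the
  first sample of each class; the theorem that any choice is equivalent
  is *asserted* (to $10^{-8}$) rather than assumed.
* **Tie-breaks.** Nearest-template and naive-Bayes ties go to the
  lowest class index; KNN vote ties go to the larger summed inverse
  distance, then the lowest class index. All deterministic.
* **Degenerate inputs.** Fitting refuses loudly when $d \le M - C$ (use
  the PCA + LDA baseline there), when two classes' common vectors
  coincide within $10^{-8}\,\max\|x_{com}\|$ (classes not separable in
  the null space), when an MSC reference is constant, or when an SNV
  input row is constant.
* **Naive-Bayes variance floor.** Within-class variances are floored at
  $10^{-9}$ times the largest observed per-class variance: CLDA
  training features are exactly constant within class, and a zero
  variance would break the Gaussian likelihood.
* **PCA retention.** `k = "auto"` keeps the smallest $k$ explaining
  99 % of training variance, capped at $M - C$ so the within-class
  scatter in score space stays invertible; a ridge of
  $10^{-10}\,\mathrm{tr}(S_W)/k$ is added if it is numerically singular
  anyway. No published retention rule exists for this baseline, so the
  choice is the package's own and is exposed as a parameter.
* **Savitzky–Golay defaults.** Window 11, order 2, derivative 0 —
  common NIR smoothing practice; smoothing (not differentiation) is the
  intended default role. Filtering is delegated to
  `signal::sgolayfilt`, whose edge handling evaluates the first/last
  window's fitted polynomial so the channel count is preserved; the
  filter is exact on polynomials up to its order, including at the
  edges.
* **Preprocessing chains.** "MSC + SG" is applied left to right. Any
  data-derived statistic (the MSC mean reference) is computed on the
  training set only and frozen for the test transform; SNV uses the
  sample ($d-1$) standard deviation.

## The synthetic generator

Real study spectra of this kind are typically not deposited, so
`generate_spectra()` provides the test bed: class-dependent Gaussian
absorption bands on a tilted baseline, per-spectrum multiplicative gain
$a_s \sim N(1,\sigma_a^2)$ and offset $b_s \sim N(0,\sigma_b^2)$
(mimicking particle-size scatter), and i.i.d. channel noise. The
default design is 4 classes × 60 samples × 228 channels over
5894.5–11111 cm⁻¹ with shared bands near 6993 and 8475 cm⁻¹ (the
water/carbohydrate O–H and C–H overtone regions that dominate fruit NIR
spectra) whose amplitudes differ by origin; the axis is gridded
uniformly in wavenumber as a simplification. Class identity enters
through band *amplitudes* only — the composition-driven signature that
origin differences produce — never band positions.

Three frozen presets define the regimes the test suite exercises, each
calibrated once to realise its defining behaviour and not revisited:

* `separable` (separation 2.5, noise 0.002, scatter 0.02/0.008):
  nearest-common-vector CLDA classifies held-out spectra perfectly.
* `overlapping` (separation 0.35, noise 0.012, scatter 0.18/0.08): a
  single CLDA subspace misclassifies confusable class pairs while the
  boosted ensemble recovers most of the gap. The scatter level is
  deliberately comparable to raw diffuse-reflectance variation, which
  also handicaps the unsupervised compression of PCA + LDA — the
  regime in which benchmark tables of this kind show boosted CLDA
  dominating both competitors.
* `scatter_heavy` (scatter 0.20/0.10): for exercising MSC/SNV, whose
  correction shrinks within-class variance severalfold.

What the generator does **not** emulate: real overtone band shapes and
baselines, wavelength-correlated instrument noise, class-dependent
scatter, batch effects, or any physical radiative transfer. Passing
tests therefore demonstrate algorithmic correctness and the *relative*
behaviour of the methods under controlled structure — not field
performance on any particular instrument or commodity.

## Problem sizes and runtime

The test suite and acceptance checks run at the study-design scale they
describe: 240-spectrum datasets (160 training), 10-round ensembles,
20-seed replications for the stochastic comparisons and 50 seeds for
the chance-floor calibration; the Gram-versus-direct eigendecomposition
cross-checks use 20 random instances small enough ($d \le 20$,
$M \le 12$) to form the dense scatter. The whole suite completes in
well under a minute on one core because every eigenproblem is at most
$M \times M$.

## Known limitations

* CLDA requires $d > M - C$; it is not a general-purpose classifier for
  tall data.
* Two classes with identical band signatures have coinciding common
  vectors; the fit detects and refuses this rather than guessing.
* The CLI's `predict` subcommand re-derives MSC references from the
  prediction file when a preprocessing chain is baked into a model
  archive; for strict train-frozen correction, preprocess train and
  test together in R via `apply_preprocess()`.
* No kernelised, regularised or weighted-scatter CLDA variants, no
  SAMME-style multiclass boosting, and no validation-based early
  stopping; `T_effective` is governed solely by the classical
  termination rule.
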