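---
title: "Methods: discriminant classification and kernel regression of FOCM/TS metabolite panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminant classification and kernel regression of FOCM/TS metabolite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Children with autism spectrum disorder (ASD) show systematic differences in
folate-dependent one-carbon metabolism (FOCM) and transsulfuration (TS) —
the pathways supplying methyl groups for DNA methylation and maintaining
intracellular redox state via glutathione. No single metabolite separates
affected from neurotypical (NEU) children, but a multivariate combination of
a 24-variable blood panel can. This package implements the complete analysis
chain for such data:

1. **Fisher discriminant analysis (FDA)** of two cohorts, with leave-one-out
   (LOO) cross-validated scoring;
2. **Gaussian kernel density estimation (KDE)** of the cohort score
   distributions, bandwidth chosen by least-squares cross-validation (LSCV);
3. **ROC / C-statistic** computation *from the fitted densities*, a
   density-crossing decision threshold, and the confusion-matrix rates;
4. **exhaustive and greedy metabolite subset selection** by cross-validated
   C-statistic, including a sibling (SIB) separability augmentation step;
5. **Gaussian-kernel partial least squares (KPLS)** regression of the
   Vineland Adaptive Behavior Composite on metabolite subsets, scored by
   LOO cross-validated R² (Q²);
6. a **synthetic cohort generator** with planted structure so the entire
   chain is testable without clinical data.

# Models and estimators

## Fisher discriminant analysis

For classes $i = 1..k$ with class means $\bar x_i$, grand mean $\bar x$ and
class sizes $n_i$:

$$S_B = \sum_i n_i (\bar x_i - \bar x)(\bar x_i - \bar x)^\top,\qquad
  S_W = \sum_i \sum_{j \in i} (x_j - \bar x_i)(x_j - \bar x_i)^\top,$$

and FDA maximizes $J(w) = (w^\top S_B w)/(w^\top S_W w)$. For $k = 2$ the
maximizer is $w \propto S_W^{-1}(\bar x_1 - \bar x_2)$ (`fit_fda()` also
exposes the generalized eigenvalues of $S_W^{-1} S_B$; for two classes
exactly one is nonzero).

Numerical choices:

* **Standardization.** Each variable is z-scored with center/scale computed
  from the *training* samples only, and recomputed inside every LOO fold.
  Metabolite concentrations span orders of magnitude; $J$ is
  scale-invariant but $w$ is not, so a fixed convention is needed. A
  zero-variance training column gets scale 1 (it standardizes to zero and
  cannot influence $w$).
* **Near-singular $S_W$.** Four panel variables are ratios of other panel
  members and nearly collinear with them. The direction solve falls back to
  a Moore–Penrose pseudo-inverse (relative singular-value cutoff $10^{-10}$)
  when LAPACK reports singularity.
* **Orientation and normalization.** $\|w\|_2 = 1$ and the sign is fixed so
  the mean projected ASD score exceeds the mean NEU score; "higher score =
  more ASD-like" holds everywhere downstream.
* **LOO implementation.** `loo_scores()` updates per-class sufficient
  statistics (sums, cross-products) by exact rank-one downdates per fold.
  This is algebraically identical to refitting from scratch (asserted in
  the tests to ~1e-13) and roughly two orders of magnitude faster, which is
  what makes exhaustive subset searches feasible in pure R.

## Kernel density estimation and bandwidth

Scores of a cohort are smoothed with the Gaussian kernel estimate
$\hat f(x) = \frac{1}{n\sigma}\sum_i K\!\left(\frac{x - x_i}{\sigma}\right)$.
The bandwidth minimizes the LSCV criterion

$$\mathrm{LSCV}(\sigma) = \int \hat f^2
  - \frac{2}{n}\sum_i \hat f_{-i}(x_i),$$

the canonical unbiased surrogate for mean integrated squared error (MISE)
risk. Both terms have exact pairwise closed forms for the Gaussian kernel;
the implementation evaluates one exponential per point pair per candidate
(the second term is the square of the first's exponential). Candidates are
51 log-spaced values spanning $[0.05, 5]\times$ the Silverman reference
bandwidth $1.06\,\mathrm{sd}\,n^{-1/5}$; ties break toward the larger
(smoother) bandwidth because LSCV objectives are often piecewise flat.
Bandwidths are selected per cohort independently (a recorded assumption —
a shared bandwidth is equally defensible and switchable by passing `sigma`
to `estimate_pdf()` directly).

Densities are tabulated on a fixed grid ($[\min - 6\sigma, \max + 6\sigma]$,
1024 points) so downstream ROC integrals are bit-for-bit reproducible;
`reevaluate_pdf()` re-evaluates the kernel sum exactly on any new grid (no
interpolation).

## ROC, C-statistic, threshold and confusion

The ROC curve is built from the two *fitted densities*, not from empirical
ranks: for each threshold on a merged grid, the true/false positive rates
are the trapezoidal tail masses of the positive/negative densities, and the
C-statistic is the trapezoidal area under tpr(fpr). The empirical
Mann–Whitney statistic is kept as an independent test oracle only (the two
agree within 0.02 on pipeline scores; the KDE version is slightly shrunk
toward 0.5 by smoothing).

The published analysis asserts a linear classifier on the FDA scores
without stating its cutoff. The default rule here is the **equal-density
crossing**: the score where the two fitted PDFs intersect between the two
cohort score means (nearest the mean midpoint if there are several
crossings), with a flagged midpoint fallback when no crossing exists. The
threshold is frozen once from the full-data PDFs and applied to all LOO
scores. Ties at the threshold classify negative. Rates with zero
denominators are reported as `NA` and named in an `undefined` field, never
coerced to 0.

## Subset selection

All variable combinations up to size $k_{\max}$ (6 in the study; the
per-combination cost makes the full 190,050-combination sweep a batch job,
not a test) are scored by the composed pipeline LOO-FDA → per-cohort
LSCV-KDE → density ROC. Ties break toward the smaller, canonically earlier
combination, making results independent of evaluation order and
parallel chunking. `greedy_extend()` continues from the best subset; with
`criterion = "sib_separability"` it adds the variable maximizing the
ASD-vs-SIB C-statistic under the same pipeline, subject to not lowering the
ASD-vs-NEU C-statistic by more than 0.002 — the package's operationalization
of the study's "improve sibling separability" step (the published analysis
gives no formula; reusing its own separability measure is the most
parsimonious reading). Near-ties between variable subsets are expected on
real data and the tests treat them as such.

## Kernel PLS regression

Predictors are z-scored, mapped through the Gaussian kernel
$k(a,b) = \exp(-\|a-b\|^2 / 2\sigma_k^2)$, and the response is regressed on
the feature space by dual NIPALS: latent scores $t_a$ are extracted from
the double-centered kernel with deflation of kernel and response, and
predictions use the dual form
$\hat y = K^{c}_{\text{new}} U (T^\top K U)^{-1} T^\top y + \bar y$.
With a linear kernel this reproduces ordinary linear PLS exactly (a test
asserts equality to 1e-8 against an independent textbook NIPALS
implementation).

Unstated hyperparameters were fixed as: kernel width $\sigma_k$ = median
pairwise distance of the standardized training predictors (the median
heuristic), recomputed inside every cross-validation fold; 4 latent
components by default; and an optional `hyper_policy = "nested"` that
selects both by an inner LOO grid ($\{0.25, 0.5, 1, 2, 4\}\times$ median,
components $1..\min(10, n-2)$). Q² uses the full-sample response mean in
its denominator, the dominant convention for cross-validated R² in the PLS
literature.

One algebraic subtlety: with training-feature-mean centering, a point far
from all training inputs predicts the model *constant*
$\bar y - \alpha^\top(\overline{K}_{\cdot} - \overline{K})$ (dual
coefficients applied to the centered kernel column means), which is close
to but not exactly $\bar y$. The tests assert the exact limit.

# The synthetic world

`synthetic_config()` describes the generator; its defaults are fixed once
and mirror the study design rather than any test outcome:

* cohort sizes 83 (ASD) / 47 (SIB) / 76 (NEU); Vineland scores for ~66% of
  ASD samples, clipped to [46, 106] — the study's census;
* latent Gaussian profiles with exchangeable within-block correlation
  $\rho = 0.3$ over five pathway blocks (methylation cycle, DNA
  oxidation markers, glutathione panel, tyrosine derivatives, cystine
  pair), exponentiated to lognormal marginals with coefficient of
  variation 0.3 — metabolite concentrations are positive and skewed, and
  the real covariance is unpublished, so these are stated assumptions;
* five planted classification variables ({% DNA methylation, 8-OHG,
  Glu.-Cys., Chlorotyrosine, % oxidized glutathione}) with standardized
  latent shift 1.75 each, giving a near-saturated joint C-statistic of the
  same order as the published panel; shifts are planted on the *latent*
  scale so monotone-transform-invariant oracles like
  $C = \Phi(\delta/\sqrt 2)$ remain exact;
* SIB means at $\lambda = 0.15$ of the ASD shift — siblings intermediate
  but NEU-like, reproducing the published sibling projection geometry;
* ratio variables recomputed exactly from their components, never sampled,
  so the collinearity that stresses $S_W$ inversion is present in tests;
* a behavior-score link: logistic of a linear index of five planted
  regression variables ({8-OHG, GSSG, Nitrotyrosine, Tyrosine, fCysteine} —
  8-OHG overlaps the classification set) plus one pairwise interaction,
  higher dysfunction mapping to lower scores, Gaussian noise of 4 score
  points. Only base (non-ratio) variables can carry planted structure,
  because ratios are derived quantities.

What a green synthetic test does **not** establish: agreement with the
study's printed numbers (that requires the study's supplementary CSV, see
`tests/testthat/test-acceptance.R`), realism of the assumed correlation
structure, batch/age/sex effects (not simulated), or the behavior of the
pipeline under missing data (missingness is rejected or dropped, never
imputed).

Planted-recovery benchmarks run on a reduced 8-variable canonical panel
(3 planted + 5 correlated noise variables) at n = 200 per cohort; the full
24-variable, 20-seed sweep is outside a reasonable test budget in pure R
and adds nothing to the property being asserted.

# Degenerate inputs and determinism

All-identical samples ("degenerate scatter"), empty classes, zero-variance
scores or responses, nonpositive bandwidths/kernel widths and out-of-range
component counts are rejected with named errors. Every stage is
deterministic given its inputs; the only randomness in the package is the
synthetic generator's seeded RNG (cohort draw and score-assignment use
distinct derived streams). Reduction orders are fixed; reruns reproduce
tables byte-for-byte.

# Known limitations

* The study's exact threshold rule, KDE bandwidth grid and KPLS
  hyperparameters are unpublished; the defaults here are principled
  choices, and the real-data acceptance tests carry explicit tolerances to
  absorb that freedom.
* Multi-class FDA beyond the two-class closed form is limited to the
  eigen-decomposition diagnostics; all study analyses are two-class.
* Kernel FDA is intentionally out of scope.
* The exhaustive search is single-threaded; it is order-independent by
  construction, so coarse-grained parallelism over combination chunks is
  safe if needed.
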