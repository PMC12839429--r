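---
title: "Methods: hierarchical feature selection and optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical feature selection and optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`hfsof` implements a three-phase pipeline for multi-class classification of
high-dimensional, nonlinear, imbalanced feature vectors — the regime of
flattened grayscale ultrasound images. The pipeline's assumptions are worth
stating explicitly:

* class structure is nonlinear in the raw features but approximately linear
  in a kernel feature space (hence kernel PCA, not PCA);
* univariate relevance signals (mutual information, chi-square, symmetrical
  uncertainty, class-scatter difference) are informative enough to prune the
  embedding, but feature *interactions* matter for the final subset (hence a
  wrapper stage on top of filters);
* macro-averaged F1 is the right objective under class imbalance, because it
  weights every class equally regardless of support.

### Phase 1: kernel PCA

Standardized features (zero mean, unit population variance, fitted on the
training split only) enter an RBF kernel with width `γ = 1/d`. The kernel is
double-centered, eigendecomposed, and only eigenvalues above
`1e-10 × λ_max` are retained; scores are `Z = K̃ U Λ^{-1/2}`, which satisfies
the spectral identity `ZᵀZ = Λ` (tested). Requesting more components than
the centered kernel's rank silently caps `p` — with the default `p = 1000`
this cap is active in every desk-scale run, since `p ≤ N − 1`.

**Out-of-sample projection.** Whether the original procedure embedded the
full dataset transductively or train-only is not decidable from its
description. We fit on the training split only and project held-out samples
through the centered cross-kernel using stored training statistics. This is
standard kernel-PCA practice and the only leakage-free option; it is also
the choice that makes the null-data safety test meaningful.

Numerical conventions: eigenvector columns are sign-fixed (largest-magnitude
entry positive) for run-to-run reproducibility; a linear-kernel variant
(`kernel = "linear"`) exists purely as an oracle hook, since linear kernel
PCA equals classical PCA up to column sign.

### Phase 2: filter ensemble and scatter-difference threshold

All three filters score the *same* discretization — 10 equal-width bins per
feature, fitted on training values, out-of-range values clamped — so they
see identical contingency tables. Mutual information uses the natural log
(the base cancels in symmetrical uncertainty). Scores become ranks
(descending score → rank 1; ties average), and the fused rank is the
per-feature **median** of the three — robust to one filter disagreeing.
Mean fusion and single-filter modes exist as ablation switches.

The top `m = ⌈p/2⌉` fused ranks form the candidate pool (the procedure we
follow never states `m`; half keeps the stage a genuine prune while leaving
the scatter threshold enough material). Pool features are then scored by
`MS_j = SB(j) − SW(j)` with `SB = Σ_c n_c (μ_jc − μ_j)²` and
`SW = Σ_c Σ_{i∈c} (x_ij − μ_jc)²`, implemented literally (support-weighted
between-class scatter, unnormalized within-class sum). Features at or above
the `(1−α)` quantile survive. The quantile uses linear interpolation on the
order statistics (R type 7) — conventions differ by ±1 feature, so the
threshold `τ_α` is recorded in every run artifact.

The two sub-stages compose **sequentially** (pool → threshold): the quantile
is taken over the filter-selected pool, not all `p` features. The composition
is not pinned down by the source procedure; sequential composition is the
reading under which each stage actually prunes.

### Phase 3: wrapper optimization

Masks are `b = 1(p > 1/2)` over positions in `[0,1]^d`; masks with fewer
than two features are repaired by forcing the two largest positions on
(ties to the lower index). Fitness is the mean over three *fixed* stratified
folds of the macro-F1 of an RBF SVM (`C = 100`, `γ = 0.01`) on the masked
columns, memoized by mask bits.

The Whale Migration Algorithm is implemented synchronously: leader/follower
assignment, the leader mean `m(t)` and the best individual `p*(t)` are
frozen at the start of each iteration, so the update order of individuals
cannot change the result. `p_prev` — named but never defined in the source
equations — is the individual's position one iteration earlier (initially
its starting position, making the follower's first `r1` term vanish).
Greedy acceptance is *strict* (ties keep the old position) to minimize
drift. The PSO baseline is canonical global-best PSO (inertia 0.729,
cognitive = social = 1.49445, velocity clamp 0.5) over the same space with
the same binarization and fitness.

### The SVM

The runtime ships no SVM, so the package implements a one-vs-rest C-SVC with
an SMO dual solver (maximal-violating-pair working-set selection, KKT gap
tolerance `1e-3`) in compiled code. One-vs-rest was chosen over pairwise
voting so that predicted labels are the row-wise argmax of the *same*
decision-score matrix the one-vs-rest AUC consumes. The solver was checked
against scikit-learn's SVC on a fixture during development; the frozen
decision values live in the test suite.

### Metrics

Per-class precision/recall/F1 use the 0/0 → 0 convention (a class never
predicted must not crash aggregation — imbalanced test sets make this a
real case, not an edge case). Weighted recall equals accuracy exactly, an
algebraic identity (`Σ_c n_c R_c = Σ_c TP_c`) the suite verifies on 1000
random confusion matrices. AUC is the tie-aware Mann–Whitney statistic on
decision scores (not calibrated probabilities); classes absent from the
test labels are excluded from AUC aggregates with a warning.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `split$test_fraction` | 0.3 | 70/30 stratified protocol |
| `kpca$p` | 1000 | stated component budget; capped at rank |
| `kpca$gamma` | `1/d` | stated kernel width |
| `filters$bins` | 10 | shared plug-in estimator; coarse enough for desk-scale N |
| `filters$pool_size` | `⌈p/2⌉` | unstated upstream; prune without starving MSDLDA |
| `msdlda$alpha` | 0.05 | stated optimum; 0.01 / 0.1 as ablations |
| `optimizer` | WMA, 45 × 100 | stated population and budget |
| `svm` | C = 100, γ = 0.01 | stated, fixed everywhere (fitness and final fit) |
| `fitness$k_fold` | 3 | stated CV depth |

One master seed fans out to split/fold/optimizer seeds by fixed offsets, so
stages can be re-run independently yet reproducibly.

## The synthetic world

**Phantoms** emulate what the pipeline assumes about B-mode ultrasound:
class-dependent mean intensity, an echo band, 0–3 elliptical lesions with
class-specific polarity, multiplicative unit-mean Rayleigh speckle (the
first-order speckle surrogate; scale `1/√(π/2)`) and additive Gaussian
noise; default supports scale the 238–3464 clinical imbalance profile by
×0.1 (≈ 767 images). They do **not** model point-spread convolution,
attenuation, probe geometry, or inter-device variation — a green phantom
test establishes that the pipeline recovers planted class structure under
speckle-like noise and imbalance, not clinical performance.

**Planted features**: `k` informative columns are `Normal(μ_c, 1)` with
class means evenly spaced over a **total spread of δ** standard deviations
(random class order per column); the rest are label-independent noise. The
total-spread reading of δ (rather than per-adjacent-class spacing) is a
deliberate design choice: under the per-gap reading at δ = 3, a single
column nearly separates all classes, the cross-validated fitness saturates
at exactly 1.0 with two or three columns, and *no* optimizer of the stated
objective can be forced to retain the remaining planted columns — the
recovery invariant would be unattainable by construction. Under the
total-spread reading each column is informative but insufficient, so
recovering all classes genuinely requires most planted columns, and the
recovery test measures what it claims to.

For the desk-scale recovery test (`d = 50`, pool 25) the MSDLDA stage runs
at `α = 0.3`: the surviving count is ≈ `α ×` pool by construction, so any
`α` with `α × 25 < 5` caps the recoverable planted features below `k`
regardless of implementation quality. The default `α = 0.05` is tuned to
the `p = 1000` production geometry (|S0| ≈ 25–50), not to 50-feature test
tables.

## Known limitations

* The SMO solver targets desk-scale kernels (thousands of samples); there is
  no shrinking or kernel caching across masks beyond the fitness memoizer.
* Image ingestion reads portable anymaps natively and PNG/JPEG only through
  optional decoders; BMP and DICOM are out of scope.
* The wrapper's fitness is in-sample CV; its value overestimates held-out
  performance by construction. All reported metrics therefore come from a
  test split touched exactly once, after selection is frozen — the null-data
  test exists precisely to verify that wrapper optimism does not leak.
* Scores for AUC are uncalibrated decision values; AUC is invariant to
  monotone transforms, but the scores are not probabilities.
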