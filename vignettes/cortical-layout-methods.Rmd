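---
title: "Methods: from prewhitened voxel series to a compact cortical layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from prewhitened voxel series to a compact cortical layout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`cortexlayout` derives a functional layout of 52 cortical areas (26 per
hemisphere) from resting-state voxel time series and asks whether that
layout is *compact* in the sense of Cherniak's component-placement theory.
The pipeline is:

1. **Prewhitening.** Each voxel's raw BOLD series is trimmed (first 3
   volumes), filtered by coefficient of variation (CV = sd/mean ≤ 5%), and
   reduced to ARIMA(15, 1, 1) innovations. Raw series are nonstationary
   and autocorrelated; correlating them directly violates the independence
   assumptions of correlation inference and produces spurious
   associations. Innovations are practically white noise, verified per
   voxel by the Ljung–Box portmanteau test and the Durbin–Watson
   statistic.
2. **Connectivity.** For every area pair, every voxel innovation series in
   one area is correlated with every voxel innovation series in the other
   (zero-lag Pearson). Coefficients are Fisher z-transformed, averaged,
   back-transformed, shifted by +2 into a positive proximity, and averaged
   across subjects into a 52 × 52 proximity matrix.
3. **Clustering.** Areas are compared by the squared Euclidean distance
   between their proximity profiles (self-columns excluded) and clustered
   by UPGMA (unweighted average linkage). The dendrogram's serial leaf
   order is made deterministic by a recorded policy (below).
4. **Layout regression.** The serial order is regressed on the signed
   Talairach coordinates, `order = a + b·LR + c·PA + d·IS`. A spatially
   faithful tree gives a dominant negative PA coefficient (anterior at the
   top) and a non-significant LR coefficient (homotopic pairs interleave).
5. **Compactness.** With `M = n − 1` successive Euclidean distances along
   the tree order (M = 51 bilateral after rectifying LR; M = 25 per
   hemisphere with signed LR), the observed mean `D_tree` is compared with
   uniformly permuted placements: the *adjacency rule* predicts no
   permutation is more compact; the *size law* predicts the compactness
   index `c = mean(D_perm)/D_tree` grows with subset size; *metamodule
   grouping* predicts contiguous subsets are themselves never beaten by
   their permutations.

# The synthetic generator

No raw fMRI is distributed, so a generator provides multi-subject,
multi-voxel datasets with known ground truth. It emulates four properties
of the real data: nonstationary autocorrelated raw series; latent
inter-area correlation decaying with distance; strong homotopic coupling;
and strongest within-area coupling.

**Latent correlation model.** Area signals are drawn from
`corr(a, b) = exp(−distance_decay · d(a, b))` with `d` computed on
LR-rectified centroids, contralateral non-homotopic entries scaled by
`contralateral_attenuation`, and homotopic entries lifted toward 1 by
`c + homotopic_boost · (1 − c)`. Two modelling choices deserve comment:

- *Why a rectified kernel plus attenuation rather than a signed-distance
  kernel?* With a signed-LR kernel, homotopic partners receive
  mirror-image connectivity profiles (strong ipsilateral columns on
  opposite sides), and no amount of homotopic boosting lets profile-based
  clustering pair them — contrary to the pervasive homotopic doublets seen
  in real dendrograms. Real inter-area connectivity is approximately
  left-right symmetric with a mild ipsilateral excess; the rectified
  kernel gives the symmetry, and the attenuation factor (default 0.8)
  gives ipsilateral > contralateral.
- *Positive semi-definiteness.* Boosting individual entries can push the
  matrix outside the correlation cone. This is checked, never silently
  repaired: the default is an error suggesting a parameter change, and
  `psd_repair = TRUE` opts into projection onto the nearest correlation
  matrix (`Matrix::nearPD`), which in practice preserves the tier
  structure and the distance gradient almost exactly (element-wise r ≈
  0.99 on the packaged atlas).

**Voxels and coloring.** Each voxel is
`within_area_weight · latent + N(0, noise_sd)` (defaults 0.9 and 0.3, so
within-area innovation correlation is 0.9 and cross-area correlations are
scaled by 0.81), then colored by a zero-initialized ARMA filter (defaults
AR = 0.5, 0.2; MA = 0.3), integrated once (cumulative sum), and offset by
a 1000-unit baseline plus a subject-specific linear drift
(slope SD 0.05 units/volume). The single integration makes
ARIMA(p, 1, q) prewhitening well specified, and the baseline makes the CV
filter meaningful (typical CV ≈ 2–4%, so the 5% filter retains most
voxels, as with real gray-matter data). Defaults: 18 subjects, 203
volumes, 20 voxels per area, uniform allocation (a volume-proportional
option exists).

**What the generator does not emulate** — volumetric geometry (no images,
no spatial smoothing or partial-volume effects), physiological noise
(cardiac/respiratory), inter-subject anatomical variability, and
session-level nonstationarities beyond a linear drift. Passing recovery
tests therefore demonstrates the *pipeline's* correctness under the
assumed correlation structure, not the empirical truth of that structure
in any given dataset.

# Numerical and procedural choices

**ARIMA estimation.** `fit_innovations()` defaults to conditional sum of
squares (`method = "CSS"`); full maximum likelihood (`"ML"`, `"CSS-ML"`)
is available. With p = 15 AR terms on 200-point series, CSS is roughly
40× faster and, on generator output, its innovations are indistinguishable
in whiteness (Ljung–Box pass rates at 100% either way); the estimation
criterion is recorded in every result. Non-convergence falls back to
(5,1,1), then (1,1,1); a voxel failing all orders is excluded and logged —
a policy the analysis needs even if failures are rare. The first `d`
residuals (diffuse initialization) are dropped, so a 203-volume series
yields 199 innovations after trimming 3 volumes and differencing once.

**Ljung–Box degrees of freedom.** The fitted-parameter correction
(subtract p + q) is off by default and switchable (`fitdf`); with
20 lags and p + q = 16 the corrected reference has 4 df, which is
unusually aggressive, and the uncorrected test is the stricter whiteness
screen in this direction.

**Fisher pooling.** Correlations are clipped at |r| = 1 − 1e−7 before
`atanh` so degenerate perfect correlations stay finite. The +2 proximity
constant is added per subject before averaging; adding it after averaging
is algebraically identical and both code paths are tested. Within-area
(diagonal) proximities use all unordered distinct voxel pairs; the
diagonal never enters profile distances, which exclude the self-columns of
the two areas compared so that an area's self-proximity cannot dominate.

**Leaf ordering.** A dendrogram fixes the tree but not the left-right
orientation of its `n − 1` internal nodes. The default policy is exact
optimal leaf ordering ("olo"): the dynamic program that, among all
`2^(n-1)` compatible orientations, minimizes the total dissimilarity
between successive leaves. Simple conventions ("min-index",
"tighter-first", both available) can place whole blocks at the wrong end
of the sequence even when the clustering is perfect — on noiseless
ground-truth proximities they leave the frontal block detached from the
anterior end and the serial order uncorrelated with PA, while the optimal
order recovers the anterior→posterior progression. Since an order and its
reverse are equivalent, `orient_anterior()` applies the reading
convention that rank 1 is the anterior end (mean PA of the first versus
last quarter of leaves).

**Permutation streams.** All permutation tests take one root seed; window
`w` of a subset analysis always draws from child stream
`child_seed(seed, w)` and the whole-set adjacency test from
`child_seed(seed, 1)`, so results are reproducible, independent of
execution order, and a full-length single window reproduces the whole-set
test exactly. The identity permutation, if drawn, ties (`D = D_tree`) and
does not count as a violation, consistent with the strict inequality.
Subset windows are contiguous, with start positions sampled uniformly
*with replacement* over the full inclusive range `1..(n − L + 1)`.
Compactness indices are ratios, so per-window values are averaged on the
log scale and reported as geometric means. Degenerate sequences (all
coordinates identical, or an all-identical window) raise errors rather
than produce infinite indices.

**Per-hemisphere analyses** re-cluster each hemisphere from its 26 × 26
submatrix of the bilateral proximity matrix (rather than pruning the
bilateral tree) and use signed LR; the bilateral analysis rectifies LR so
homotopic partners coincide on the left-right axis.

# Problem sizes and reproducibility

The validation suite runs the full pipeline on the packaged 52-area atlas
with a strong-structure configuration of 6 subjects × 10 voxels/area ×
203 volumes (3,120 ARIMA(15,1,1) fits), which recovers the generator's
correlation matrix at element-wise r ≈ 0.98, pairs 100% of homotopic
partners as dendrogram siblings, and reproduces the anterior→posterior
regression with a dominant negative PA coefficient. Permutation analyses
use N = 1000 permutations (whole set) and up to 1000 subsets × 1000
permutations per subset size in `scripts/acceptance.R`; oracle tests
compare Monte-Carlo results with exhaustive enumeration at n ≤ 7.
Everything is seeded: identical configurations give bit-identical
datasets, manifests, and permutation results.

# Known limitations

- The homotopic boost plus attenuation model needs `psd_repair = TRUE`
  for realistic strong-coupling settings on the packaged atlas; the
  repaired matrix, not the raw formula, is the ground truth reported.
- The regression treats serial order as an interval scale, as the original
  analysis does; residual df is `n − 4` (reported as such even though
  serial ranks are exchangeable only under the null).
- Compactness is evaluated on area centroids; within-area extent and
  cortical folding are ignored.
- UPGMA tie-breaking follows the underlying `stats::hclust`
  implementation; ties are measure-zero for continuous proximities but
  can occur in constructed examples.
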