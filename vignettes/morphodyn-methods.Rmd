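---
title: "Morphodynamic phenotyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphodynamic phenotyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodyn)
```

## The problem

Suspended cells held in a microwell array and rotated magnetically at
~0.1 Hz expose their full 3-D shape to a camera over minutes of
observation. A cell's *morphodynamics* — the trajectory of its shape
over time, rather than a single adherent-state snapshot — carries
phenotype information: epithelial-like and mesenchymal-like cells, or
motile and non-motile fractions of one line, differ in lobedness,
protrusive activity, and texture. `morphodyn` implements the full
computational arm of such an assay:

1. **simulate** microwell time-lapse stacks with known per-well ground
   truth (no public imaging data exists for this assay, so a calibrated
   simulator is the test bed),
2. **segment** wells and delineate single live cells,
3. **extract** a fixed 169-column morphology feature vector per cell and
   timepoint,
4. **classify** phenotypes with a repeated-holdout normalise / project /
   boost pipeline, including extreme class-imbalance experiments,
5. **cluster** cells into sub-phenotypes with homogeneity-constrained
   k-means.

## The synthetic scene model

Cell shape is a star-convex boundary,

$$ r(\theta, t) = r_0\Big(1 + \sum_{k=2}^{6} a_k \cos\big(k(\theta - \omega t) - \varphi_k(t)\big)\Big) + \text{protrusions}, $$

with rotation $\omega = 2\pi f \cdot 60$ rad/min ($f$ = 0.1 Hz by
default), per-cell harmonic amplitudes $a_k$ drawn once per cell
($a_k < 0.5$ keeps the boundary star-convex and simple), slowly drifting
phases $\varphi_k$ (Gaussian random walk, SD `lobe_drift_rate` rad/min),
and transient protrusions (Poisson events per minute with a sinusoidal
temporal envelope, a Gaussian angular profile riding on the rotating
frame, and amplitude a fraction of $r_0$). This is the simplest
parametrization whose knobs map onto the morphologies the assay
discriminates — smooth versus lobed outlines, blebbing and protrusive
activity — while guaranteeing a simple polygon at every timepoint. The
render is a 2-D fluorescent silhouette: all downstream features are 2-D,
so well depth (35 µm) is carried as metadata only.

Scenes are a grid of triangular wells (side 40 µm, pitch 80 µm, pixel
0.5 µm so one well spans 160 px — resolvable but small on disk), with
per-well occupancy drawn from (`p_empty`, `p_single`, `p_multi`)
(defaults 0.25 / 0.65 / 0.10, matching the >60% single-cell loading the
real trapping protocol reaches) and a `dead_fraction` (default 0.10).
The camera model is Poisson shot noise on the signal plus Gaussian read
noise (SD 20 counts) over a constant background (200 counts) — the
standard fluorescence camera model; setting the read-noise SD to 0
disables all noise and makes renders deterministic, which the
truth-recovery tests exploit. Dead cells fluoresce in the main channel
like any cell but do not rotate or deform; only dead cells appear in the
end-of-run viability frame (the propidium-iodide analog). No deformation
magnitudes or timescales are published for this assay, so the dynamic
defaults are stipulated as plausible rather than fitted; every
experiment that depends on them states them explicitly.

## The feature-table generator

The machine-learning stages are tested against `simulate_feature_table()`,
which bypasses rendering: each cell draws a class and a sub-phenotype
component, and each timepoint emits the 169 columns as the component
centre plus AR(1) noise (coefficient 0.6, stationary marginal SD 1, so
every shift is in pooled within-class SD units). The reference
population, used by the acceptance experiments and analysis scripts:

* class separation: +6 SD on 10 fixed columns (class B vs class A);
* sub-phenotypes: 4 components in class A, 3 in class B; component
  $s > 1$ of a class adds an offset of Euclidean length 8 SD spread
  evenly over its own block of 10 columns, so all 7 component centres
  are mutually ≥ 8 SD apart.

Spreading each sub-phenotype mode over a block of columns (rather than a
single column) mirrors how a real morphological mode co-varies across
many measured features, and is what keeps the mode visible after
per-column standardization: a 1-column offset contributes exactly one
unit-variance column and is indistinguishable from noise to a
variance-based projection, whereas a 10-column mode carries an
eigenvalue well above the noise bulk and survives the 169 → 14
reduction. The population is constructed to be at least as separable as
two distinct cell lines; recovery results on it bound what the pipeline
can do, they do not measure real-data performance. In particular, real
cells violate the generator in ways the tests do not probe: features are
mutually correlated within a timepoint, class differences are not
axis-aligned, noise is heteroscedastic, and segmentation errors leak
into the features.

## Segmentation

Well positions come from grid geometry (stage positions are programmed
in the instrument), so cropping is arithmetic rather than registration.
Delineation is Gaussian smoothing (σ = 1 px) → Otsu threshold over the
patch's own range (hence invariance to constant offsets) → 3×3 opening
and closing → hole filling → largest connected component (ties to the
first in scan order). Since the upstream pipeline in the emulated assay
is a CellProfiler configuration whose settings are not published, this
stage is a defined, testable stand-in, not a reimplementation. Two
guards make it robust at desk scale: a patch whose robust intensity
range (0.1–99.9% quantiles) is below `min_contrast` (250 counts) is
declared empty — this is what stops the faint triangular well walls and
background noise from ever counting as objects — and occupancy is
classified on the pre-cleanup labelling (`empty` / `single` / `multi`
by components ≥ 30 px). A well that is multi-occupied in more than 20%
of frames is disqualified outright, the conservative reading of
"single cells only"; the viability filter then drops wells whose
viability-channel score (mean of the brightest 5% of pixels) clears an
automatic threshold derived from the frame's median and MAD.

## The 169-feature manifest

The assay's published pipeline exports "over 100" CellProfiler
measurements spanning basic shape, Zernike moments and Haralick
features, with 169 columns entering the learning stage; the exact member
list is not recoverable. The manifest here is therefore a fixed,
versioned reconstruction totalling exactly 169: 26 shape descriptors,
30 Zernike magnitudes ($n \le 9$, $m \ge 0$, $n-m$ even), 104 Haralick
statistics (13 classics × distances {1, 2} × angles {0°, 45°, 90°,
135°}), and 9 intensity summaries. Numerical conventions worth noting:

* perimeter uses the Vossepoel–Smeulders chain-code weights (0.948
  axial, 1.340 diagonal), the standard correction for digital-boundary
  overestimation; the convex hull uses exact polygon geometry, so
  `boundary_roughness` can dip ~1% below 1 for near-convex masks;
* the Zernike unit disk is centred on the mask centroid with radius the
  maximum centroid-to-pixel distance (object fully inside the disk); the
  equivalent-radius alternative was rejected because it clips pixels for
  elongated masks;
* GLCMs quantize in-mask intensities to 8 equal-width bins over the
  mask's own min–max range, are symmetrized, and use natural logs;
  correlation is defined as 0 at zero variance, and an offset with
  fewer than 2 in-mask pairs contributes 13 zeros rather than NaN, so
  the learning stage never sees missing values;
* undefined-at-empty features are errors, not imputations — callers
  filter empty masks first.

## Classification protocol

The supervised analysis is a repeated shuffled holdout, exactly as the
emulated study describes its cross-validation: per repeat, cells (never
rows) are shuffled and split 70/30 stratified by class; an optional time
limit keeps rows with `time_min` strictly below T; the minority class
may be subsampled to a target/general *row* ratio (whole cells removed
first); per-feature z-scoring and a 14-component PCA are fitted on the
training rows only and applied verbatim to the test rows; a discrete
AdaBoost of depth-1 stumps (100 rounds, $\alpha_t = \tfrac12
\ln((1-\epsilon_t)/\epsilon_t)$, stopping at $\epsilon_t \ge 0.5$ or
$\epsilon_t = 0$) is trained on labels coded 0/1; test cells get labels
by majority vote over their rows (ties to the general class), and
per-class precision, recall and f1 = 2PR/(P+R) are averaged over 30
repeats. Design choices that were genuinely open:

* **cell-level, stratified splitting** — prevents temporal self-leakage
  and keeps minority test cells present at extreme imbalance;
* **stumps, 100 rounds** — the study names the boosting algorithm but
  not the base learner or round count; depth-1 stumps are the classical
  choice and 100 rounds saturates on these problems;
* **the published split sizes** ("1100 training / 400 test cells") are
  inconsistent with 70% of 1500; exact 70% is implemented;
* **per-cell aggregation** is unspecified in the source; majority vote
  is the default, with `mean_score` and `per_row` modes provided;
* the f1 is computed from the harmonic-mean formula as printed, even
  though the surrounding prose calls it a geometric mean;
* stump ties break toward the lowest feature index, then the lowest
  threshold, then the polarity predicting 1 above the threshold —
  stated so runs are bit-reproducible.

## Sub-phenotype clustering

Clustering operates on per-cell mean vectors in the same standardized
14-component space as classification (a per-row mode exists). k-means
is plain Lloyd — assign to the nearest mean by squared Euclidean
distance, recompute means, repeat to a fixed point — with 10 random
restarts (initial means are k distinct data points), empty clusters
reseeded at the point farthest from its centroid, and WCSS asserted
non-increasing at every iteration. k is chosen from 2..15 under the
strict constraint that **every cluster's purity** (majority-class
fraction) exceeds 0.95, maximizing the global homogeneity score; ties
go to the smallest k, and an infeasible constraint returns the best
available clustering flagged `constraint_unmet`.

The homogeneity score is $1 - E(A|C)/E(A)$ with
$E(A|C) = -\sum_{m,k} \frac{n_{mk}}{N}\log\frac{n_{mk}}{c_k}$ and
$E(A)$ the class entropy (natural logs; the base cancels in the ratio;
$0\log(\cdot) = 0$; a single true class scores 1). The variant that
normalizes $n_{mk}$ by the class size $a_m$ instead of the cluster size
$c_k$ is exposed as `mode = "printed"` for comparison, but it assigns
the degenerate one-cluster labelling a score of 1, which contradicts the
defining property of a homogeneity measure (0 for that labelling); the
conditional-entropy form is therefore the default and is what the
selection procedure uses.

For the recovery experiments the truth labels supplied to `select_k()`
are the planted sub-phenotype component ids (7 of them), not the 2-way
class labels: recovery means finding the planted component count, and
under class labels any class-pure merge of components would tie at
homogeneity 1, letting the smallest-k tie-break collapse the answer to
k = 2. With component labels the procedure selects k = 7 with purity
and homogeneity 1 on the reference mixture, across seeds.

## Problem sizes and determinism

The shipped experiments use 550 cells/class × 10 timepoints (balanced
classification), 1500 + 200 cells × 20 timepoints (1/1500 imbalance,
keeping ≥ 50 held-out minority cells), and 100 cells per component × 30
seeds (k selection) — sizes at which every reported quantity is stable
to the third digit while a full run stays in the minutes range on one
core. All randomness flows from a single seed through named substreams
(`substream_seed`), so stages re-run in isolation reproduce exactly and
two runs with the same seed are bit-identical, TIFF bytes included.

## Known limitations

* The simulator renders 2-D silhouettes of a parametric shape family;
  it does not model 3-D deformation, optical blur, illumination fields,
  or cell–cell interactions, and its dynamics parameters are stipulated.
* The feature manifest is a reconstruction: totals and families match
  the emulated pipeline, the member list is this package's own.
* The segmentation stand-in is tuned for high-contrast fluorescent
  silhouettes; low-SNR or phase-contrast data would need a different
  delineation stage behind the same interface.
* Recovery rates on the synthetic populations are upper bounds, not
  estimates of real-data performance.
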