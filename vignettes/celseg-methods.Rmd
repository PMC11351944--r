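---
title: "Methods: patch-based contrast-enhancing lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based contrast-enhancing lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(celseg)
```

## The problem

Gadolinium contrast-enhancing lesions (CELs) mark active blood-brain-barrier
breakdown in multiple sclerosis. They appear hyperintense on post-contrast
T1-weighted MRI, are often tiny (down to 3 voxels at 1 mm isotropic), and are
easily confused with physiological post-contrast hyperintensities such as
veins. Because CELs are by definition the acute inflammatory component
*within* white matter lesions (WMLs), a FLAIR-derived WML mask is a powerful
spatial prior: it constrains where training patches are sampled, where
inference looks, and which predicted components can be real.

`celseg` implements this pipeline end to end: a synthetic multi-contrast
phantom generator (so every stage is testable without patient data),
WML-guided patch sampling and augmentation, a 3D encoder-decoder network
with dice and focal losses including an imbalance-weighted variant,
patch-reconstruction inference, rule-based lesion filtering, and
lesion-level evaluation.

## Sampling strategy

Inputs are co-registered, skull-stripped, 1 mm isotropic volumes: T1 pre- and
post-gadolinium plus FLAIR, with a binary WML mask and (for training) a
binary CEL ground truth. Each channel is z-score normalized over its brain
mask only — skull-stripped images are mostly zeros, and including background
would corrupt the statistics; statistics are per volume, never pooled across
scans.

Training crops follow a two-stage scheme: `patches_per_scan` (default 32)
initial crops of 64 voxels per edge, then a random sub-crop to 48. On
CEL-positive scans one third of the initial crops are centred on CEL voxels
and the rest on WML voxels; CEL-free scans sample all crops on WML voxels.
Since one third of 32 is not an integer we use `round(32/3) = 11` CEL-centred
crops; the count is configurable. Centres are drawn uniformly over mask
voxels, so larger lesions are sampled proportionally more often — the
simplest reading of random mask-centred cropping. Crop windows are clamped at
grid boundaries rather than padded (phantom grids always exceed the window).

Augmentation is applied after the sub-crop: per-axis random flips, one random
axis-pair rotation by a multiple of 90 degrees, a small random affine
(rotation up to 10 degrees, per-axis scale 0.9-1.1, no shear — kept small to
preserve the topology of few-voxel lesions), and an additive intensity shift
drawn uniformly from [-0.25, 0.25] applied to the image channels only.
Spatial transforms act voxel-identically on channels, ground truth and WML
mask; masks are resampled nearest-neighbour so they stay binary.

## Network

The segmentation network is a 3D U-Net-style encoder-decoder with encoder
widths (32, 64, 128, 256, 512), mirrored decoder widths, spatial
downsampling by stride 2 per level, and PReLU activations. The literature
leaves the block composition open; we use two 3x3x3 convolutions per level
with instance normalization, channel-concatenation skip connections,
nearest-neighbour upsampling in the decoder, and a terminal 1x1x1
convolution with a sigmoid producing one probability channel, so output
shape always equals input shape (input edges must be divisible by
`stride^(levels-1)`).

No deep-learning framework is assumed: convolutions are compiled
im2col + GEMM primitives (RcppArmadillo), and the backward pass is written
out layer by layer. The full network gradient is validated against central
finite differences in the test suite.

## Losses

Let $p$ be the per-voxel prediction and $g$ the binary ground truth of one
patch. The soft dice loss is

$$L_{Dice} = 1 - \frac{2\sum p g + \varepsilon}{\sum p + \sum g + \varepsilon},
\qquad \varepsilon = 10^{-5},$$

and the focal loss with $\gamma = 2$ is the voxel mean of
$-(1-p_t)^\gamma \log p_t$, with $p_t = p$ on lesion voxels and $1-p$
elsewhere. The baseline training objective combines them as
$0.5\,\overline{L_{Dice}} + \overline{L_{focal}}$ (per-patch means over the
batch).

A patch is *negative* when its ground-truth crop contains no lesion voxel —
classification is by content, not by sampling centre, because a WML-centred
crop can incidentally contain a CEL. On a negative patch the dice loss
saturates at 1 as soon as any false-positive mass appears, and negative
patches vastly outnumber positive ones, so the dice term is dominated by
lesion-free patches. The weighted loss therefore rescales each negative
patch's dice loss by the negative:positive patch ratio (`rate_imbalance`)
before averaging:

$$L = \operatorname{mean}_i\!\big(w_i\, L_{Dice,i}\big) +
      \operatorname{mean}_i\, L_{focal,i}, \qquad
  w_i = \begin{cases} 1 & \text{positive patch} \\
                      1/r & \text{negative patch.} \end{cases}$$

Dividing by the rate is the reading consistent with the stated purpose of
concentrating dice gradient on lesion-bearing patches; the opposite
direction (multiplying by $r$, which *up*-weights negative patches) is
available as `loss_config(multiply_negative = TRUE)` for comparison, and
both are covered by tests. At $r = 1$ the weighted loss coincides with the
baseline at dice weight 1.

The clinical-cohort value $r = 29$ is the default of `loss_config()`. The
ratio is a property of the data and the sampling scheme, so
`train_config(rate_mode = "auto")` recomputes it from the first epoch's
patch labels; the phantom profiles use this mode because the phantom's
patch imbalance (roughly 1-3) is far below 29, and an overstated rate
under-penalizes false-positive mass.

## Inference and reconstruction

Validation and test scans are segmented with the same spatial logic as
training: cubic windows at the network's input edge are tiled over the WML
bounding box with 50% overlap, clamped to the grid, and kept when they
intersect the mask — every WML voxel is covered by at least one window, and
nothing outside the windows can be predicted. Each window is predicted,
binarized at threshold 0.5 (the literature states no threshold; 0.5 is the
natural choice for a sigmoid output), and mapped back to its origin.
Overlapping predictions are summed and clipped to 1, which for binarized
patches is exactly a voxel-wise union and hence independent of patch order;
this is the default (`mode = "union"`). A probability-averaging mode
(`mode = "average"`) instead accumulates raw probabilities over the
overlapping windows and thresholds the per-voxel mean. With 50% overlap
every voxel receives up to eight votes; under the union rule a single
dissenting window can seed a spurious 3-voxel component inside WML that the
postprocessing rules cannot remove, so the union rule's false-positive
count grows with window overlap. The averaging mode suppresses exactly this
speckle (in our diagnostic runs it removed ~95% of false-positive
components at identical lesion sensitivity), and the desk-scale profiles
therefore use it; the union rule remains the default and is what the
reconstruction oracle tests exercise. Deterministic tiling was chosen over
random sampling for reproducible inference. An empty WML mask yields an
all-zero prediction with a warning (a CEL cannot exist outside WML by
definition).

## Postprocessing

Predicted components (26-connectivity by default, the common choice in MS
lesion tooling; 6 and 18 available) are filtered by two conjunctive rules:
components smaller than 3 voxels are removed, and components whose fraction
of voxels inside the WML mask is strictly below 10% are removed — a
component at exactly 10% is kept. The overlap fraction is computed on the
*predicted* component (share of its voxels inside WML), not on the WML mask;
the alternative reading would delete nearly all small CELs. The 0%-overlap
case ("outside the WML") is subsumed by the 10% rule. Within validation
*patches* the volume rule is deliberately not applied, because a patch may
contain only a fragment of a lesion; only the WML-overlap rule acts there.

## Evaluation

Detection is scored at the lesion level: with $TP$, $FP$, $FN$ counted over
connected components,

$$\mathrm{TPR} = \frac{TP}{TP+FN}, \qquad
  \mathrm{FPR} = \frac{FP}{TP+FP},$$

and segmentation by the hard dice score $2TP_v/(2TP_v+FN_v+FP_v)$ over
voxels. A ground-truth component counts as detected when at least one
predicted voxel overlaps it — the weakest criterion consistent with
lesion-count reporting, chosen because no stricter rule is stated in the
source literature; an IoU-threshold mode is provided. A predicted component
overlapping several ground-truth lesions yields one TP per lesion and no FP;
several predicted components hitting one lesion yield a single TP, and the
per-lesion dice uses the union of matched predictions. Whole-image dice is
computed only for images with at least one TP lesion (a miss excludes the
image from the mean rather than contributing 0). Volume-stratified reports
bin TP/FN lesions by ground-truth volume and FP lesions by their own volume
over bins 3-10, 10-20, ..., >300 mm^3, with an aggregate row.

## The synthetic phantom

The generator emulates the *statistical contract* of a clinical MS cohort,
not its anatomy. One scan is a large ellipsoidal "brain" with
piecewise-constant tissue intensities plus Gaussian noise (sigma 5 at tissue
mean 100), zero outside the brain as after skull-stripping. Per scan:

* WML components (default 6, 150-1500 mm^3) are carved as random ellipsoids
  in the brain interior; they are hyperintense on FLAIR and slightly
  hypointense on T1.
* With probability `p_scan_has_cels` (default 0.56) the scan is CEL-positive
  and receives $1 + \mathrm{Poisson}(\mu - 1)$ CELs (default mean 3).
  Volumes are lognormal (meanlog 4.07, sdlog 1.3; mean about 136 mm^3)
  truncated below at 3 mm^3, matching a right-skewed distribution dominated
  by small lesions. CELs are carved strictly inside WML components (the WML
  rim is extended by one voxel around each lesion), are bright on
  post-contrast T1 only, and a configurable fraction of larger lesions can
  be hollow shells mimicking ring enhancement (nodular is the default).
* Vessel-like confounder tubes (default 2, radius about 2 voxels, length
  20-35) are bright on post-contrast T1, FLAIR-isointense, and never
  intersect the WML mask — by construction only the WML-overlap filter can
  reject them, which is exactly what the postprocessing tests verify.

What the phantom does **not** model: real anatomy, partial-volume borders,
bias fields (optional hooks exist but default off), scanner/site effects,
open-ring enhancement near cortex, or WML segmentation errors (the
ground-truth CELs are exact subsets of exact WML masks). Passing the
end-to-end tests therefore demonstrates that the pipeline's machinery —
sampling, optimization, reconstruction, filtering, scoring — recovers
lesions under the stated statistical conditions; it does not certify
clinical performance, which the source cohort results address at GPU scale.

## Numerical choices and desk-scale profile

* Dice smoothing $\varepsilon = 10^{-5}$; focal predictions clamped to
  $[10^{-7}, 1-10^{-7}]$ before logs.
* He-style Gaussian initialization scaled by fan-in; PReLU slopes start at
  0.25; Adam with $\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$.
* Full-scale defaults: learning rate 5e-5, 48-voxel patches, widths
  32-512, 11 patient-level folds, model selection by whole-image validation
  dice, early stopping after 20 stale validations.
* The demo/test profile runs on one CPU in minutes: 20 scans at 96^3 from
  a 14/3/3 patient-disjoint split, encoder widths (8, 16), 24-to-16-voxel
  patch stages, 16 patches per scan, batch 8, 30 epochs, learning rate 3e-3,
  validation every 5 epochs, `rate_mode = "auto"`, probability-averaging
  reconstruction. These sizes are the
  package's choice of a minimal configuration that still exercises every
  pipeline stage; all full-scale settings remain reachable through the
  config objects.
* Reproducibility: every stochastic stage takes a seed (phantom, cohort,
  fold split, initialization, sampling); seeded runs are bit-identical.

## What the loss comparison shows at desk scale

The weighted loss was designed for a heavily imbalanced patch stream under
a long, conservatively tuned optimization. At desk scale its measurable
advantage is *robustness*: under a constrained step budget and realistic
learning rates, the unweighted objective — whose dice term is dominated by
lesion-free patches — sometimes fails to learn positive patches at all,
while the weighted objective still converges. When both objectives converge
fully on the easy phantom task their final positive-patch dice differ by
only a few hundredths, in either direction. The package's directional test
is therefore run in the constrained-budget, high-imbalance regime where the
mechanism is active, and should be read as evidence for the mechanism, not
as a claim that the weighting helps in every regime.

## Known limitations

The R-native network favours clarity and testability over speed: full-width
training at 48^3 is feasible but slow on CPU, so the package targets
reduced-width studies and treats the full-scale configuration as an
interface contract. Instance normalization carries no learned affine
parameters. The lesion-matching criterion (one-voxel overlap) is permissive;
use the IoU mode for stricter studies. The phantom's idealized WML masks
mean the 10% overlap filter is never stressed by boundary-inaccurate masks.
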