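---
title: "Identifying silkworm pupa species and sex from images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying silkworm pupa species and sex from images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sericulture breeding requires pairing male and female silkworm (*Bombyx
mori*) moths of the correct strains. Sorting happens at the pupal stage,
where species and sex must be read from subtle external morphology: body
size, the taper of the abdomen toward the tail, cuticle color and texture.
pupaevision implements a complete image-based identification pipeline —
segmentation, shape/texture/color description, CNN-style features, fusion,
shallow classification, and macro-averaged evaluation — for three tasks:
species (5 classes), sex (2 classes), and joint species+sex (10 classes).
All posture views (back, abdomen, side) are pooled into one "global" model,
so identification does not depend on how the pupa lands on the belt.

Because curated pupa image sets are generally not public, the package ships
a synthetic generator with known ground truth; every downstream stage is
developed and tested against it.

## The synthetic generator

A pupa body is modeled as a super-ellipse (exponent 2.5, so the ends are
blunter than an ellipse) of half-length $a$ and half-width $b = a/\mathrm{AR}$,
with a longitudinal taper applied to the posterior half:
$w(t) = b\,(1-|t|^{p})^{1/p}\,(1 - \tau\,\max(t, 0))$, $t \in [-1, 1]$.
The head ($t<0$) stays blunt while the tail thins — this asymmetry is what
makes head/tail disambiguation testable. The taper $\tau$ defaults to 0.30
for females and 0.55 for males (`sex_effect(tail_taper_delta = 0.25)`),
males are 5% shorter, and the per-pupa weight is lognormal around a species
mean with an additive $-0.22$ g male shift — weights of roughly 0.7–1.4 g,
in the range reported for commercial strains, with females heavier. Posture
modulates silhouette width (side views are ~16% narrower) and adds a
dorsal/ventral centerline bulge. Species differ in body length (185–255 px
at the default scale), aspect ratio (1.9–3.0), HSV cuticle color and a
multiplicative brightness grain; none of these profiles is calibrated to a
real strain — no per-strain morphometric statistics were available — so
they are plausible settings chosen once.

Three profile presets control separability: `"realistic"` (moderate
within-class spread), `"high"` (near-zero spread, wide between-class gaps;
used for end-to-end recovery checks), and `"none"` (all species identical;
any classifier should fall to chance). Rendering is deterministic: one
master seed derives a per-pupa seed (body shape and weight, shared by the
three posture images) and a per-image seed (pose, background and texture
noise), so a dataset is a pure function of its seed. `add_debris()`
scatters small dark fragments, each below a configurable area fraction and
never touching the body, to exercise the segmentation's area filter.

What the generator does *not* emulate: specular highlights, shadows, the
gonadal tail markings used by human sorters, appendage outlines, and
touching pupae. Passing tests therefore demonstrate internal correctness
and recoverability of planted signal, not field performance on photographs.

At full study scale (120 pupae per class) the generator emits 3600 images;
structural checks use the manifest-only mode (`render = FALSE`) since
class counts, identities and weights do not require pixels.

## Segmentation and cropping

`segment_pupa()` runs: Rec. 601 luminance grayscale, global Otsu threshold,
inversion (the pupa is darker than the light background), one pass of
morphological opening with a 5 px elliptical element (removes molt
filaments without eroding the body), connected components, an area filter
(default 2% of the image) that discards debris, and an outer-boundary trace
of the largest survivor. Otsu was chosen because the pupa/background
histogram is strongly bimodal and it is parameter-free; both the opening
size and area fraction are exposed. Degenerate images (near-constant
intensity, or a "foreground" covering most of the frame) raise a
"no pupa found" error rather than returning nonsense.

`crop_centered()` produces the standard 320×320 crop centered on the filled
contour's centroid, padding out-of-frame regions with the background's
median color, and carries the filled mask and the translated contour.
Coordinates are 0-based (row, col) with half-open crop windows.

## The 37-dimensional pupal shape feature

The shape descriptor (SD-PSF) concatenates 14 global contour statistics and
a 23-point curvature-width profile (KMM):

* perimeter (measured on a lightly smoothed boundary — a raw 8-connected
  chain overestimates smooth perimeters by several percent, which would
  bias circularity), filled area, dispersity, min/mean/max centroid radius,
  radius ratio (min/max), fitted-ellipse major/minor axis and their ratio,
  rectangularity (area over the minimum-area rotated rectangle),
  circularity $4\pi A/P^2$, compactness $P^2/A$, and eccentricity.
* KMM: after rotating the contour so the moment-fitted ellipse's major axis
  is horizontal, the vertical chord of the filled silhouette is sampled at
  $K/24$ of the bounding-box width, $K = 1..23$.

Design points that were genuinely open:

* **Dispersity** is defined as the coefficient of variation of the centroid
  radii — a dispersion measure not redundant with circularity.
* **The 37th entry.** Thirteen named global statistics plus 23 KMM values
  are 36; the fitted-ellipse eccentricity (computed during alignment
  anyway) completes the vector.
* **Head/tail canonicalization.** TL1 is the summed width of the anterior
  half-profile ($K \le 11$), TL2 of the posterior half ($K \ge 13$). Since
  a pupa tapers toward the tail, TL2 > TL1 means the tail is leftmost, and
  the silhouette is mirrored and re-measured. This makes the whole vector
  invariant to 180° rotations of the input for any shape with
  distinguishable ends; on exactly symmetric shapes TL1 = TL2 up to
  rasterization and the orientation is left as-is.
* **Scale is deliberately not normalized** — absolute size carries
  species/sex signal, mirroring the weight differences that motivate
  weight-stratified splitting.
* Chords are read from a single rasterized pixel column (no neighborhood
  averaging); ellipse-fit orientation ties (perfect circles) resolve to
  angle 0.

Rasterization uses an even-odd scanline fill of the boundary polygon plus
the boundary pixels themselves; chords agree with analytic ellipse chords
to within ±2 px and exactly match an independent per-column scan of the
same mask.

## Classical descriptors

Output dimensions are fixed contracts: HOG 1296, Hu 7, uniform LBP 59,
GLCM 20, HSV histogram 768.

* **HOG**: the crop is resized to 210×210 — the geometry at which 30 px
  cells, 2×2-cell blocks and single-cell stride yield exactly
  6·6·2·2·9 = 1296 features — with unsigned gradients, 9 orientation bins,
  and L2-Hys block normalization (clip 0.2).
* **Hu moments** are computed on the binary silhouette rather than
  grayscale, making them a pure shape complement to SD-PSF, and are
  signed-log transformed ($-\operatorname{sign}(h)\log_{10}(|h|+10^{-30})$).
* **Uniform LBP**: radius-1, 8 neighbors, 58 uniform patterns plus a
  catch-all bin; histogram over mask pixels, normalized to sum 1.
* **GLCM**: 64 gray levels, distance 1 (the conventional choice), four angles, five statistics
  per angle (angular second moment, contrast, entropy, correlation with a
  zero-variance guard, inverse difference moment), angle-major order.
* **Color histogram**: HSV, 256 bins per channel, each channel normalized
  independently. LBP, GLCM and color are restricted to the pupa mask so the
  background cannot leak class signal.

## CNN features and training protocol

All backbones share one contract: normalized 224×224 RGB in, the
1000-dimensional classification-head activations out, used as a feature
vector. The named large architectures (VGG16 … ConvNeXt-S) are declared
but require an externally supplied weight loader; the always-available
`tiny-test` backbone is a seeded, randomly initialized two-layer
convolutional network with the same output contract, keeping every test
download-free. Fine-tuning freezes the trunk and trains a softmax head
with SGD (momentum 0.9), cross-entropy, batch size 64, initial learning
rate $10^{-4}$ decayed ×0.8 every 5 epochs, and two-phase early stopping:
training is "converging" once the training loss fluctuates (max − min) by
< 0.001 over 5 epochs, and stops when the validation loss then shifts by
< 0.005 over 5 further epochs; the checkpoint with peak validation accuracy
is kept. The epoch cap defaults to 200. Augmentation applies a seeded
random subset of horizontal flips, translations, rotations and brightness
scaling with bounded magnitudes.

## Partitioning, fusion and classifiers

**Weight-stratified splitting.** Within each (species, sex) class, pupae
are ordered by weight and assigned systematically: every 5th pupa
(mid-stratum offset, rank ≡ 3 mod 5) to test for 8:2, and ranks ≡ 3 / ≡ 8
mod 10 to calibration/test for 8:1:1. Mid-stratum offsets avoid the bias of
always taking the heaviest rank in each stratum of a skewed weight
distribution. All three posture images of a pupa stay in one split — the
grouping is a deliberate strengthening against identity leakage.

**Fusion.** Each descriptor block is z-scored with training statistics
(necessary because SD-PSF mixes pixel units with dimensionless ratios) and
blocks wider than 500 columns are compressed to exactly 500 by
principal-component loadings fitted on the training split only; when the
training sample supports fewer than 500 components the projection is
completed to an orthonormal 500-frame so the output width is an invariant
contract. Narrower blocks pass through. Test data reuse the train-fitted
projection without refitting.

**Classifiers.** Three shallow classifiers with fixed random state 9:

* an MLP with ReLU activations and an L-BFGS optimizer (implemented on
  analytic gradients; one or two hidden layers per the grid
  25…150, (25,25)…(100,100) × alpha $10^{-1}..10^{-6}$),
* an SVM (RBF grid $C \in 2^{-5..5}$, $\gamma \in 2^{-15,-13,..,5}$; the
  linear $C=1$ variant for CNN features). Training uses libsvm's pairwise
  multiclass decomposition with Platt-calibrated per-class probability
  scores — the same semantics as the common "one-vs-rest decision shape"
  configuration of sklearn's SVC, which also trains pairwise and only
  shapes its outputs one-vs-rest,
* a random forest (Gini, minimum split 2 / leaf 1, 200–800 trees in steps
  of 10; 500 fixed for CNN features).

Hyperparameters are chosen by exhaustive grid search scored by stratified
5-fold cross-validated accuracy on the training split (ties: first grid
point), then refit on the full training split.

## Evaluation

The report contains the confusion matrix, per-class one-vs-rest counts, and
four macro metrics: macro binary accuracy (mean over classes of
$(TP+TN)/n$), macro precision, macro recall, and F1 computed from the macro
precision and recall as $2PR/(P+R)$ (per-class F1 is also emitted). Plain
multiclass accuracy (trace over total) is always reported alongside, since
"accuracy" in this literature can denote either quantity; note the macro
binary form is inflated by true negatives for more than two classes.
One-vs-rest ROC curves use trapezoidal areas; PR areas use step-wise
average precision, avoiding the optimistic bias of trapezoidal PR
interpolation. Classes absent from the truth are flagged undefined and
excluded from macro averages. A precision denominator of zero (class never
predicted) is defined as 0.

## Problem sizes and verification scale

End-to-end checks run at a reduced scale chosen to keep the full suite
desk-sized: the separable-recovery experiment uses 20 pupae per class
(600 images; {SD-PSF + color histogram + SVM} with the full 121-point grid)
and must reach ≥ 0.95 ten-class test accuracy; the null experiment
(identical profiles) uses 15 pupae per class and must stay within 3
binomial standard deviations of chance, with $n$ the number of held-out
*pupae* — postures of one pupa are correlated, so the pupa, not the image,
is the independent unit. Structural checks at the full 3600-image scale use
the manifest-only generator mode.

## Known limitations

* The generator's realism gap (above) bounds what green tests can claim
  about photographs; the preprocessing assumes a single dark pupa on a
  light background.
* Named CNN backbones run only with user-supplied pretrained weights; the
  shipped `tiny-test` network verifies contracts and training mechanics,
  not representation quality.
* Hyperparameter grids at full scale are CPU-intensive; grid overrides are
  provided for exploration.
* Scale non-normalization means features are resolution-dependent: images
  must share an acquisition geometry, as they do on a sorting line.
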