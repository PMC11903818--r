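---
title: "Weakly-supervised plaque segmentation in infrared microscopy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised plaque segmentation in infrared microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(irplaque)
```

# The problem

Anti-amyloid immunohistochemistry (IHC) is the gold standard for locating
Aβ plaques in brain sections, but the staining chemistry washes soluble
proteins out of the tissue. Quantum-cascade-laser infrared (QCL-IR)
microscopy measures a mid-infrared absorbance spectrum at every pixel of an
*unstained* section — 427 samples on the inclusive 1800→948 cm⁻¹ grid at
2 cm⁻¹, with 4.25 µm pixels — and plaques differ from surrounding tissue in
subtle, spatially localized ways: a β-sheet contribution near the Amide I
band, and changes around the lipid ester band (~1740 cm⁻¹), the C–H
deformation bands (1480–1430 cm⁻¹) and the congested 1320–1200 cm⁻¹ region.
`irplaque` trains a convolutional segmenter to find plaques in such cubes
using only image-level labels derived from registered IHC, then takes the
result all the way to laser-microdissection (LMD) shape export.

Pixel-accurate plaque annotation is impractical, so supervision is *weak*:
each 64 × 64-pixel region of interest (ROI) carries a binary label (contains
Aβ / Aβ-free) and a coarse binary stain mask. Everything pixel-level must be
inferred by the network during training.

# The mask preprocessing chain

IHC images registered to the cube grid are converted to masks by: taking the
blue channel (DAB brown absorbs blue strongly), windowing intensities from
[0.3, 0.9] onto [0, 1] with clipping, inverting, thresholding with Otsu's
method (256 bins), filling holes, removing connected components below 30
pixels (≈ 542 µm² at 4.25 µm/px), smoothing with a morphological opening
(disc of radius 1 by default — the element is unspecified in the source
chain, so the smallest disc was chosen), and finally dilating four times
with a 3 × 3 ones kernel so that pixels *surrounding* stained structures are
included. The inversion polarity is our inference: thresholding the raw blue
channel would make the unstained background the foreground.

ROI labels follow the positive-fraction rule: a window whose mask covers at
least 5 % is positive and keeps its mask; a window with no stain at all is
negative and receives an all-ones mask (this fallback keeps the pooled mean
defined and the gradient alive); windows strictly between 0 and 5 % belong
to neither published class and are excluded from training — manual ROI
selection never produced them — though they can still be scored at
inference. Otsu is computed per ROI by default (per slide is available); the
original chain does not say which was used.

# The network and its loss

The segmenter is a depth-reduced U-Net: three encoder levels of two 3 × 3
convolutions (ReLU) and 2 × 2 max-pooling, a two-convolution bottleneck
(spatial size input/8; 8 × 8 × 512 at the full scale of 64 input channels),
transposed-convolution upsampling with skip connections, and a 1 × 1
convolution squashed by a sigmoid into a bounded activation map. The first
convolution also collapses the spectral channels. The input layer applies a
fixed per-channel standardization computed from the training split:
absorbance images are dominated by the common tissue spectrum, and without
centering, the first layer's gradients are spent re-learning the mean
spectrum instead of the ~1 %-variance differences that matter.

Weak supervision enters through three pieces:

* **Pooling neuron.** `q = Σ(a·m)/Σ(m)` — the fraction of the mask-weighted
  area that is activated. The all-ones fallback guarantees `Σ(m) > 0`.
* **Transfer function.** `T(q) = clip((q−α)/r, 0, 1) − clip((q−(α+β))/r, 0, 1)`
  with α = 0.05, α + β = 0.8 and ramp width r = 0.1. `T` is continuous,
  piecewise linear, zero outside [α, α+β+r], and 1 on the plateau
  [α + r, α + β]. The source characterizes the transfer function only by its
  bounds and purpose (maximize activation within [α, α+β], minimize it
  elsewhere; the upper bound prevents overdetection); the trapezoid is the
  simplest shape satisfying every stated property while remaining
  subgradient-friendly. Note a corollary that is easy to miss: activating an
  *entire* positive mask is overdetection (`q = 1 ⇒ T = 0`), because the mask
  is dilated and only part of it is truly plaque.
* **Two-term loss.** A class-weighted binary cross-entropy on `T(q)` vs the
  ROI label (weights `N_total / (2·N_y)` from the training composition,
  weighted mean over the batch), plus `λ · mean(−log(1 − a + ε))` over the
  background pixel pool — masked-out pixels of positive ROIs and all pixels
  of negative ROIs — with ε = 1e-7. λ defaults to 1; the source states the
  term's form but not its scale.

Classification for model selection uses the interval rule — positive iff
α ≤ q ≤ α + β, endpoints inclusive — and the selected epoch maximizes
validation specificity, ties broken by F1 and then by the earlier epoch.
Degenerate single-class epochs (sensitivity or specificity exactly 0) are
excluded whenever an alternative exists: an untrained model that predicts
everything negative scores specificity 1 while detecting nothing, and
"highest specificity" is only meaningful among models that actually
classify. AUC-ROC uses `q` itself as the score: the natural monotone
surrogate below the upper bound.

# Training dynamics at reduced scale

The full-scale recipe (RMSprop, lr 5e-4 decaying ×0.9 every 50 of 500
epochs, batch 20) implies on the order of 10⁵ parameter updates. The
package's test-scale studies have a budget around 10³ updates, and a naive
transplant of the recipe stalls in a characteristic plateau: the class term
pulls the *whole* dilated mask up while the background term pushes
everything down, and the freely-trained global output bias absorbs the
balance, pinning background activation just above α — high AUC, zero
specificity. Three design choices, all in parameters the method leaves
open, resolve this (the full-scale defaults are unchanged):

* **Frozen low output bias.** The output bias is initialized at
  `qlogis(0.02)` and excluded from training. The background level can then
  only move through spectral features, where the up-pull on mask *ring*
  pixels and the down-push on identical-spectra background pixels cancel,
  while genuinely plaque-like directions receive uncontested gradient.
* **Leaky rescue subgradient.** The trapezoid's gradient is zero at and
  below α; a positive sample whose `q` falls there would be permanently
  dead. During training only, positive samples receive a small rescue slope
  (0.3 of the ramp slope) below α; the forward values of `T` are untouched.
  The pooled-gradient coefficient is also clamped (at 5/r) because the
  clipped cross-entropy derivative diverges like 1/ε at the transfer's ends.
* **Adam with proportional scaling.** The reduced studies use Adam
  (optimizer choice is configurable; RMSprop remains the default), lr 5e-3
  decayed ×0.9 every 4 epochs (the 50/500 proportion), batch 5 — more
  update steps at identical compute — λ = 5, and at most 40 epochs.

Even so, a short-budget run is sensitive to its optimization trajectory:
occasionally a training seed settles with the background activation on the
wrong side of α and no later epoch recovers. `run_phantom_study` therefore
allows a bounded number of training restarts (default 2) with derived
seeds, gated purely on validation metrics: restarting stops once the
selected epoch reaches specificity ≥ 0.9 and sensitivity ≥ 0.8 on the
validation cases, and otherwise the restart with the best validation
specificity (then F1) is kept. Held-out test cases play no role in any of
these choices.

# The phantom

The synthetic module generates everything needed to validate the pipeline
without tissue:

* **Spectra.** Both endmembers are sums of Gaussian bands; background:
  Amide I 1655/28/1.0, Amide II 1545/25/0.55, ester 1740/18/0.10, C–H
  1455/20/0.15, and 1240/30/0.12 (center/σ/amplitude). The plaque endmember
  adds a β-sheet shoulder at 1630/15 with amplitude 0.5·`contrast_scale` and
  perturbs the ester (×(1−c)), C–H and 1240 (×(1+0.8c)) amplitudes.
  `contrast_scale` defaults to 0.15 — differences are subtle but learnable.
  Setting it to 0 makes plaque and background pixels identically
  distributed, which the test suite verifies with two-sample KS tests. The
  mixing rule is `cube = bg + density·jitter·(plaque − bg) + baseline +
  noise`: contrast enters once, through the endmember construction.
* **Morphologies.** Cored plaques (density-1 core, 0.45 corona), compact
  disks (0.85), and diffuse blobs (ragged star-shaped outline, low density
  0.05–0.45 with multiplicative texture). Per-plaque amplitude jitter
  (±50 %) emulates plaque-to-plaque spectral heterogeneity. Placement is
  rejection-sampled without overlap; failure after bounded retries reports
  the achieved count.
* **Nuisances.** Per-voxel i.i.d. Gaussian noise (sd 0.01 absorbance), a
  per-pixel linear baseline (intercept U(0.01, 0.04), slope N(0, 2e-5)
  clamped so absorbance stays non-negative), fold artifacts (×1.6 spectral
  scaling along a line) and holes (×0.08 in a disc). No Mie scattering,
  detector-array tiling or water-vapor lines — conclusions about robustness
  to *those* effects cannot be drawn from phantom results.
* **Pseudo-IHC.** Brown DAB where density > 0 (blue channel
  `bg_blue − density·(bg_blue − dab_blue_min)`, defaults 0.95/0.1), violet
  counterstain speckle of bounded size (~2000 dots/mm²; rendered with the
  blue channel kept ≥ 0.9 so the stain chain keys on DAB alone), and faint
  gray artifacts. The full mask chain applied to a rendering recovers dense
  plaque components; faint diffuse plaques can drop below whole-slide Otsu
  sensitivity, mirroring how lightly stained diffuse deposits behave.

The default cohort for the weak-label recovery study is 8 cases of
256 × 256 pixels with 19 plaques each on a 16-channel compressed band set
(1800→948 cm⁻¹ at 56.8 cm⁻¹), giving ≈150 positive plus ≈150 negative ROIs
under a strict 4/2/2 case-level split. These sizes keep a full
generate–train–select–segment–score cycle around ten minutes on one CPU
while leaving the task statistically nontrivial. Passing this study shows
that the training machinery can recover pixel-level structure from weak
labels under the phantom's noise model; it does not certify performance on
real tissue, whose artifacts and spectral variability are richer.

# Whole-slide inference and evaluation

Tiling uses 64-pixel windows with 16-pixel overlap (stride 48); the final
origin per axis is clamped so every pixel is covered without padding —
clamping merely increases local overlap, which the max-merge stitching
tolerates by construction (the merge is associative and commutative, so tile
order is irrelevant). Pixel-level evaluation against the stain truth uses
PPV (precision), prevalence, and the purification factor PF = PPV/PR, which
obeys PF·PR = PPV identically and is reported both per sample (averaged) and
pooled — the two generally differ. The evaluation binarization threshold
defaults to 0.5 (unstated in the source; 0.9 is reserved for LMD export,
where it is stated).

# LMD export

Activation maps are binarized at 0.9 and filtered in the printed order:
drop components < 100 µm², dilate 15 µm, fill holes, erode 10 µm (net +5 µm
margin compensating cutting loss; µm radii are rounded to whole pixels),
drop components < 300 µm², then shape filters. The printed exclusion rule
"eccentricity < 0.97, or solidity > 0.7" would discard exactly the round,
solid objects that look like plaques, so the default excludes
eccentricity > 0.97 **or** solidity < 0.7 (removing elongated folds and
stringy artifacts); `literal_printed_rule = TRUE` restores the verbatim
polarity. Because the net margin strictly grows components, any object that
clears the first area filter also clears the second: in practice the second
filter acts only through its shape terms.

Polygons are traced along pixel boundaries, so a region's polygon area is
exactly its pixel count times the pixel area. Rings are traced per
4-connected region with a right-turn preference at checkerboard corners —
the only convention that guarantees simple (non-self-intersecting) rings; an
8-connected component touching only at a corner cannot have one. Stage
registration uses the closed-form least-squares 4-parameter Helmert
similarity (scale, rotation, translation) fitted from ≥ 2 noncoincident
reference-point pairs; the fit is exact (to numerical precision) whenever
the pairs are related by a true similarity, which the test suite checks on
1000 random transforms. Damaged-region exclusion is supported as an optional
mask input rather than an interactive tool.

# Conventions and degenerate inputs

All indices and origins are 1-based, matrices are row (y) by column (x), and
masks are rasters aligned to the cube grid; pixel (i, j) occupies
[(j−1)·s, j·s] × [(i−1)·s, i·s] µm. Connected components use
8-connectivity (the convention of the common image-processing toolboxes)
except polygon tracing, above. Degenerate cases are contracts, not
accidents: a constant image has no Otsu threshold and yields an empty mask
with a warning; an all-zero effective mask is rejected as a preprocessing
bug; a single-class truth makes AUC undefined (reported missing); zero
prevalence makes PF undefined; an empty background pixel pool zeroes the
background loss term; coincident Helmert source points are rejected.

Cube files are multi-page 32-bit TIFFs with a JSON sidecar carrying the
wavenumber grid, pixel size, seed and the affine offset/scale that maps
absorbance into the TIFF's unit interval; masks, activation maps and
renderings are plain TIFFs; configurations are YAML; every pipeline command
writes a manifest with the config hash and seed.

# Known limitations

* The reduced-scale training configuration is tuned for the phantom's
  16-channel cubes; full-scale 427-channel training is computationally out
  of scope for this implementation (pure R, CPU).
* Diffuse plaques with weak contrast are detected less reliably than cored
  and compact ones — the same bias the stain-guided method itself exhibits —
  so plaque extracts are expected to over-represent dense morphologies.
* The phantom's nuisance model is deliberately minimal; robustness to
  scattering artifacts, registration error between IHC and IR grids, and
  inter-case chemistry shifts is untested here.
* AUC for an interval classifier is computed with `q` as the score, which
  penalizes overdetection (q above the upper bound scores *high*). In
  practice trained models rarely overdetect, but the metric choice matters
  near that regime.
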