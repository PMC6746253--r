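---
title: "Detecting starch granules by negative autofluorescence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting starch granules by negative autofluorescence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Leaf starch granules are semi-crystalline glucan particles inside
chloroplasts. In a wild-type *Arabidopsis* leaf a chloroplast typically
holds five to seven granules of 0.8–1 µm; the *ss4* mutant (no starch
synthase 4) holds far fewer, larger and more irregular granules. Chlorophyll
and carotenoids make the chloroplast stroma brightly autofluorescent in the
red and green channels of an ordinary confocal acquisition, while the
granules themselves fluoresce almost not at all. Granules are therefore
visible *in situ*, without staining, as dark voids inside bright plastids —
negative contrast. `starchseg` turns that contrast into per-granule
morphometry:

1. **Enhance** — median filter + CLAHE per channel;
2. **Feature bank** — >300 per-pixel filter responses over two channels;
3. **Classify** — a 200-tree random forest over four classes
   (starch / plastid / membrane-cytosol / background), trained from sparse
   manual pixel labels, yielding per-class probability maps;
4. **Segment** — threshold both the starch and plastid maps at 80%
   confidence, keep only starch components embedded in plastids, split
   touching granules by watershed, drop tiny and edge-touching particles;
5. **Measure** — area, perimeter, fitted-ellipse axes, equivalent diameter
   in µm, with population summaries (mean ± standard error, histograms,
   Welch comparisons).

Because no public image set accompanies this problem, the package ships a
synthetic scene generator with dense class labels and instance-level ground
truth, so the entire pipeline is trainable and testable end to end.

## Preprocessing

The enhancement step reproduces the standard recipe for this kind of
imaging: a radius-1 (3×3) median filter — the smallest window that kills
shot-noise outliers — followed by contrast-limited adaptive histogram
equalization with block size 20 px, 50 histogram bins and maximum slope 2.5.
Channels are min–max scaled to [0, 1] first so 8-bit, 16-bit and float
inputs behave identically.

Two dialect notes. CLAHE implementations parameterize the clip limit
differently: we use the Zuiderveld/ImageJ convention where the parameter
*is* the maximum slope of the tile's cumulative-histogram mapping
(EBImage's `limit`), rather than converting to a scikit-image-style clip
fraction; this matches the parameterization the defaults were stated in.
Convolution borders are handled by nearest-pixel replication everywhere
(EBImage's `replicate` boundary; the same rule the median filter uses), and
tile grids that do not divide the image are handled by replicate-padding and
cropping. We make no claim of bit-parity with any particular ImageJ plugin —
tests assert the properties that matter (contrast increase on low-contrast
input, constants unchanged, determinism, [0, 1] range).

## The feature bank

Fourteen filter families over the power-of-two scale ladder
σ ∈ {1, 2, 4, 8, 16} px, computed per channel independently (no
cross-channel features): Gaussian blur; Sobel gradient magnitude of the
smoothed image; six Hessian planes (module, trace, determinant, both
eigenvalues, orientation) per scale; all pairwise differences of Gaussians;
membrane projections (a 19-px line kernel rotated 30× over 180°, projected
per pixel as sum/mean/sd/median/max/min); local mean and variance in a disk
per scale; Perona–Malik anisotropic diffusion snapshots at 1/5/10/20
iterations; bilateral filtering at spatial sd {3, 5} × range sd
{0.1, 0.25}; the L1-cone lower-envelope (Lipschitz cover) at slopes
{0.005, 0.01, 0.02, 0.04} per px; Kuwahara quadrant-mean filtering at
window sizes {9, 13, 17}; Gabor magnitudes at 8 orientations × frequencies
{0.1, 0.2, 0.4} cycles/px; local Shannon entropy (10 bins) in a disk per
scale; and the 8 neighbor intensities at offsets scaled by each σ. With the
raw intensity plane that is 151 features per channel — 302 on a two-channel
image, matching the ">300 parameters per pixel" regime these trainable
classifiers operate in.

Only the family list is canonical; per-family settings (diffusion
iterations, bilateral radii, Lipschitz slopes, Kuwahara windows) follow the
common conventions of trainable-segmentation banks and are recorded inside
`feature_config()`, which is embedded in every saved model so a model is
self-describing. Feature names are positional (`ch1_…`, `ch2_…`), so a
model applies to any image with the right channel count.

## Classification

A probability random forest (`ranger`) with 200 trees, √p features per
split, unlimited depth, fixed seed, single-threaded for bit-reproducibility.
Training uses the feature vectors of labeled pixels only (code 0 =
unlabeled is ignored); each of the four classes must be labeled somewhere in
the training set, and the error message names any class that is not.
Per-pixel class probabilities are the forest's vote fractions and sum to 1
by construction. No class reweighting is applied by default; an optional
`balanced_subsample` flag downsamples majority classes when labeling is
very skewed.

Object-level evaluation: a true granule counts as detected when one
predicted instance covers ≥50% of its pixels, matched greedily one-to-one
by largest pixel overlap; unmatched predictions are false positives. The
50% rule is a documented operationalization — any object-level criterion
needs an overlap convention, and this is the standard one.

## Segmentation

Both the starch and the plastid probability maps are thresholded at 0.80
(inclusive). The embedding constraint then formalizes "granules live inside
plastids": a starch component is kept iff ≥80% of its outer boundary pixels
(one-pixel dilation minus the component) lie on plastid-or-starch support.
Before that test the plastid support is closed with a small structuring
element (radius 2 px) and hole-filled: the classifier systematically leaves
a thin low-confidence annulus around each granule rim, and closing bridges
it so granule voids become true holes. The starch mask itself is never
hole-filled or dilated — every reported granule pixel was above the
confidence threshold, and each pipeline stage's granule pixel set is a
subset of the previous stage's.

Touching granules are split by watershed on the negated distance transform,
seeded from regional maxima (2-px neighborhood, depth tolerance 1 px);
splitting repartitions but never adds or removes pixels. Finally particles
smaller than 4 px and particles touching the image border are removed
(inclusive comparisons at every threshold). Out-of-focus granules carry no
explicit detector: they fail the 80% confidence threshold and/or the
embedding test, which, together with the edge rule, is how they are
excluded from statistics. All removals are tallied in an exclusion log.

## Morphometry

Area is the pixel count × pixel-size². Perimeter is the weighted
chain-code length of the traced 8-connected boundary (0.948 per orthogonal
step, 1.340 per diagonal — the classical corner-corrected weights; a
digitized r = 20 px disk comes out within ~1% of 2πr). Ellipse axes come
from the second central moments of the pixel set with each pixel treated as
a unit square (+1/12 moment correction), so even a single-pixel object has
positive axes; major/minor = 4√λ of the covariance eigenvalues. Equivalent
diameter is 2√(area/π) — exactly, as an identity, which makes it the right
quantity to compare against Coulter-type spherical diameters. Summary
standard errors are sd/√n — a descriptor of granule-size diversity, not of
measurement error — with the n = 1 standard error reported as 0 by
convention. Population contrasts use Welch's unequal-variance *t*-test,
since granule-size variance differs strongly between phenotypes.

## The synthetic scene generator

The generator's job is to emulate the *geometry and contrast regime* of
leaf fields, not their optics. All geometry is sampled in µm and rasterized
through the pixel size. Per scene: Voronoi cell borders of random seed
points become thin bright membrane lines; 4–6 non-overlapping plastid
ellipses (4–7 µm, mild eccentricity) get a smooth bright stroma texture;
granule ellipses are placed fully inside plastids without mutual overlap.
Wild-type granules follow the documented biology — 5–7 per plastid,
diameter Gaussian (mean 0.9 µm, sd 0.05, truncated to 0.8–1.0 µm), aspect
≤1.3; the ss4 preset has 0–2 per plastid, mean 1.8 µm (sd 0.3), aspect up
to 1.8. Granules are rendered at 0.15× the local stroma intensity — the
negative-contrast premise — and a 10% out-of-focus fraction is rendered
with extra blur and reduced contrast (0.55×) and flagged in the truth
table; those granules are excluded from detection-rate denominators. A
Gaussian PSF (σ 1.2 px), additive read noise (sd 0.04) and an
intensity-scaled Poisson surrogate (0.05·√I) finish the render. Class
labels and instance truth are taken before blur and noise.

Numbers worth justifying:

* **Pixel size 0.1 µm** (image side 256 px ≈ 25.6 µm). This is the Nyquist
  sampling of a 1.4-NA objective at ~500 nm and typical of a 60× confocal
  acquisition; it renders a wild-type granule ~9 px across, large enough
  for watershed splitting and moment-based ellipse fits.
* **Placement clearances** (0.2 µm granule-to-plastid-boundary, 0.05 µm
  granule-to-granule) keep ground truth unambiguous while still producing
  near-touching granule pairs that genuinely exercise the watershed.
* A granule that cannot be placed after 200 rejection attempts is dropped
  (the truth reflects what was rendered); a plastid that cannot be placed
  is an error, since that indicates an impossible configuration.
* At 0.1 µm/px a ~9 px granule quantizes with up to ~10% per-granule area
  scatter (unbiased; the mean recovers within ~3%), which is what the
  generator/measurer cross-check tests assert.

What the generator does *not* model: real emission spectra (the two
channels share geometry and differ only in levels and independent noise),
3-D chloroplast structure, depth-dependent defocus, chromatic aberration,
or the texture statistics of real stroma. Passing the shipped benchmark
therefore demonstrates that the pipeline machinery — training from sparse
labels, probability mapping, embedding-constrained segmentation,
morphometry — works end to end under realistic geometry and noise; it does
not certify performance on any particular microscope's images, for which
the classifier must be retrained on labeled real data (the intended
workflow).

## The shipped benchmark and experiment sizes

The detection benchmark trains on 6 scenes (sparse labels: per class, 2% of
that class's pixels, at least 50 where available — mimicking partial manual
labeling) and evaluates on 4 held-out scenes, all wild type, at one fixed
seed with default configuration throughout; ~100 in-focus granules end up
in the denominator. The phenotype-contrast experiment trains one classifier
on a mixed set (3 wild-type + 3 ss4 scenes) — training on both phenotypes
guards against overfitting the classifier to a single granule size — then
measures ≥100 granules per arm through the full pipeline and compares areas
with Welch's test. These sizes give the detection rate a standard error of
a few percent and the area contrast overwhelming power (the true effect is
roughly four-fold), while keeping a full run in minutes on one CPU.

## Known limitations

* 2-D only; no 3-D stacks, time series or proprietary microscope formats.
* Plastids are supported as a mask, not as instances; per-plastid granule
  counts are out of scope.
* The perimeter estimator is tolerance-grade (a few percent on smooth
  convex shapes), not a sub-pixel contour integral.
* The R TIFF writer has no float sample format, so intensities are stored
  on integer grids: images 16-bit, probability maps 32-bit (quantization
  ~2e-10; per-pixel sums stay within 1e-6 of 1 after a round trip).
* The embedding rule assumes granules are strictly interior; a granule
  genuinely protruding from a plastid section would be rejected.
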