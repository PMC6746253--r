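# starchseg

Starch granule detection and morphometry in leaf autofluorescence images.

## What problem this solves

Quantifying starch granule number and size in leaves normally requires
electron microscopy or granule purification. But granules give themselves
away in an ordinary two-channel confocal acquisition: chlorophyll (red) and
carotenoid (green) autofluorescence make the chloroplast stroma bright,
while the granules are nearly non-fluorescent — they appear as dark voids
*inside* bright plastids. `starchseg` is a trainable pixel-classification
pipeline that exploits this negative contrast to detect granules in situ
and measure them, aimed at plant biologists screening starch-morphology
phenotypes (e.g. wild type vs the *ss4* mutant, which has fewer, larger
granules).

## The method

For each pixel **x** of a median-filtered, CLAHE-enhanced two-channel image,
a filter bank computes a feature vector **f**(x) ∈ R^302 (14 families —
Gaussian, Sobel, Hessian, DoG, membrane projections, mean/variance,
anisotropic diffusion, bilateral, Lipschitz, Kuwahara, Gabor, entropy,
neighbors — over scales σ ∈ {1, 2, 4, 8, 16} px, per channel). A random
forest with T = 200 trees, trained on sparsely hand-labeled pixels, outputs
class probabilities

> p(c | x) = (1/T) Σ_t 1[tree_t(**f**(x)) = c],  c ∈ {starch, plastid, membrane, background}

Segmentation thresholds p(starch|x) ≥ 0.8 and p(plastid|x) ≥ 0.8, keeps a
starch component iff ≥80% of its outer boundary lies on (hole-filled)
plastid support — granules must be embedded in plastids, which kills dark
background mimics — splits touching granules by watershed on the negated
distance transform, and drops particles <4 px or touching the image edge.
Each granule is then measured: area A = n·s² (s = pixel size), perimeter
(weighted chain code), ellipse axes from second central moments
(major = 4√λ₁·s), and equivalent diameter d = 2√(A/π). Populations are
summarized as mean ± s.e. (sd/√n, describing granule-size diversity) and
compared with Welch's t-test.

A synthetic leaf-scene generator (plastid/granule geometry sampled in µm
from documented phenotype presets, rendered with texture, PSF blur and
noise, with dense labels and instance ground truth) makes the whole
pipeline trainable and testable without microscope data.

## Worked example

End-to-end on synthetic data — simulate a benchmark, train, analyze the
held-out scenes, evaluate detection against ground truth:

```r
library(starchseg)
run <- detection_benchmark(seed = 1)   # 6 train + 4 test wild-type scenes
#> wrote 10 scenes; manifest: .../manifest.json
#> trained on 6 image(s); OOB accuracy 0.984; model: .../model.rds
#> test_01: 35 granule(s)
#> test_02: 26 granule(s)
#> test_03: 20 granule(s)
#> test_04: 22 granule(s)
#> aggregate detection rate: 0.943 (100/106 true granules)
```

94.3% of the 106 in-focus ground-truth granules in the four held-out scenes
were recovered by the trained classifier + segmentation (a predicted
instance covering ≥50% of the granule's pixels; out-of-focus granules are
excluded from the denominator, as they are from all statistics).
Morphometry of a scene's ground truth recovers the generating phenotype —
wild-type granules are drawn at 0.9 µm mean diameter:

```r
sc <- generate_scene("wildtype", render_params(), seed = 11)
summarize_granules(measure_granules(sc$granule_truth, 0.1))
#>           parameter      mean standard_error  n
#>            area_um2 0.6244828    0.010487927 29
#>        perimeter_um 2.5388552    0.025031698 29
#>            major_um 0.9700680    0.009330813 29
#>            minor_um 0.8309255    0.008989440 29
#>   equiv_diameter_um 0.8908051    0.007517684 29
```

Single images are analyzed with `enhance()` → `predict_probabilities()` →
`segment_granules()` → `measure_granules()`, or from the shell via the
wrapper in `inst/cli/starchseg.R` (`simulate`, `train`, `analyze`,
`evaluate` subcommands). For real data: label a few images sparsely
(codes 1–4; 0 = unlabeled), train with `cmd_train()`, then `cmd_analyze()`
a directory of TIFFs.

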