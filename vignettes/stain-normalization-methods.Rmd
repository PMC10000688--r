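---
title: "Stain normalization of H&E slides: model, pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain normalization of H&E slides: model, pipeline and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hematoxylin and eosin (H&E) staining varies between laboratories, between
staining batches, and over time as reagents fade. On digitized slides this
shows up as reddish, greyish or washed-out ("weak") color casts that make
visual assessment harder and quantitative image analysis unstable. Stain
normalization remaps a *source* image so that its stain appearance matches a
single *target* image chosen by a pathologist for its optimal staining, while
leaving the tissue morphology untouched.

`stainnorm` implements a fully automated four-stage normalization pipeline
for flat images and tiled pyramidal whole-slide images (WSIs), plus the
synthetic ground-truth material and reader-study statistics needed to
validate it without any clinical data.

## The optical model

Light transmitted through a stained section follows the Beer–Lambert law.
For channel $c$ with incident intensity $I_{0,c}$ and transmitted intensity
$I_c$, the optical density (absorbance) is

$$\mathrm{OD}_c = -\log_{10}\!\left(\frac{\max(I_c, 1)}{I_{0,c}}\right),$$

clipped below at zero. Intensities are clamped to $\ge 1$ before the
logarithm so a fully black pixel maps to the finite value
$\log_{10} I_{0,c}$ rather than infinity; the clamp operates at the
quantization scale and is monotone. Base 10 is the absorbance convention;
any fixed base would do as long as it is used consistently. Because the
forward and inverse maps are exact inverses composed with half-up rounding,
the round trip is bit-exact on any 8-bit image whose intensities are all
$\ge 1$ — a property the test suite asserts on $10^6$ random pixels.

Stains mix additively in OD space. With unit absorbance directions
$\mathbf{h}, \mathbf{e} \in \mathbb{R}^3_{\ge 0}$ (the *stain vectors*,
rows of the stain matrix $S$) and per-pixel amounts $c_H, c_E \ge 0$,

$$\mathbf{od} = c_H \mathbf{h} + c_E \mathbf{e} + \varepsilon.$$

Separation solves this per pixel by least squares through the pseudoinverse
of the $2 \times 3$ matrix $S$, clipping negative amounts to zero. The
clipped pseudoinverse is fast and deterministic; an exact two-variable
non-negative least-squares solver is available via
`compute_concentrations(..., method = "nnls")` for pixels that fall outside
the stain wedge (the tests check it is never worse in residual).

## The pipeline

`normalize_image(source, profile)` runs four stages:

1. **Tissue detection.** A pixel is provisionally tissue when its OD
   Euclidean norm (against a provisional pure-white illuminant) exceeds
   `od_tissue_threshold` (default 0.10). A $3\times3$ morphological opening
   and closing removes speckle, and connected components below
   `min_component_px` (default 64 px at 200×, i.e. roughly a
   $3.7\,\mu m$ square) are dropped. An all-background mask is valid and
   triggers a warning, not an error.
2. **Illuminant correction.** The scanner white point is the per-channel
   median of background pixels — robust to the occasional tissue pixel that
   leaks into the background set. When background covers less than
   `background_fraction_floor` (default 1%) of the image, the per-channel
   99th percentile of all pixels substitutes. White balancing rescales each
   channel so this white point maps to (255, 255, 255).
3. **Stain separation.** Stain vectors are estimated by the Macenko
   singular-direction method: tissue OD pixels with norm $\ge \beta$
   (default 0.15) are projected onto their two principal directions, and
   the $\alpha$ / $100{-}\alpha$ angular percentile directions
   (default $\alpha = 1$) are taken as the stain extremes, clipped to the
   non-negative octant and renormalized. The vector with the larger
   red-channel absorbance is labeled hematoxylin — H absorbs red more
   strongly than E, as in the classical reference vectors
   (0.65, 0.70, 0.29) and (0.07, 0.99, 0.11). Estimation requires at least
   100 qualifying pixels (insufficient-tissue error otherwise) and a rank-2
   OD cloud (degenerate-stain error for single-stain material).
4. **Chromatic matching.** The *profile* of the target
   (`stain_profile(target)`) records the target's stain matrix, its
   estimated illuminant, and the 99th percentile of each stain's
   concentration over tissue — a robust scale that, unlike mean/sd
   matching, can never produce negative concentrations. Each source
   concentration channel is rescaled by
   `scale_target / scale_source`, and pixels are reconstructed in the
   *target's* stain basis against a neutral white illuminant.

Because stage 4 is a positive per-stain linear rescale, the rank order of
stain amounts across pixels is preserved exactly: normalization changes
chromatic appearance, never local structure. Background pixels ride the
same reconstruction path; their near-zero concentrations reconstruct to
near-white, which is what produces the clean tissue/background contrast of
the output (the tests require a median background intensity $\ge 250$ per
channel after normalizing any degraded phantom).

`stain_profile()` is deliberately shaped like a model fit: it returns a
classed object with `print()`, `coef()` and `predict()` methods
(`predict(profile, image)` normalizes), and persists to a deterministic
plain-text key-value file.

### Whole-slide processing

`normalize_wsi()` estimates *all* slide parameters once — mask, illuminant,
stain matrix, scales — from a stride-decimated composite of the
200×-equivalent plane (stride 1 up to 2048 px, so small slides use every
pixel), then applies the resulting fixed per-pixel transform tile by tile.
Global estimation with per-tile application is what guarantees seam-free
output: the test suite asserts that the tiled mosaic equals the whole-image
result exactly (max difference 0 on a 2048² slide, before any compression).
Tiles containing no pixel above the tissue OD threshold are counted as
skipped; they pass through the same transform (reconstructing to
near-white) rather than being replaced by constant white, precisely so that
the tiled and flat paths remain identical.

Input finer than 0.35 µm/px (400×-class scans at ~0.233 µm/px) is brought
to 200×-equivalent resolution by 2×2 average pooling, doubling the pixel
size; 200×-class input (~0.467 µm/px) passes through. The 0.35 cutoff is
the midpoint between the two scanner classes. Missing pixel-size metadata
is a hard error: resolution cannot be guessed.

### Tiled pyramidal TIFF output

Output is a classic little-endian tiled pyramidal TIFF: level 0 plus
successive 2×2-mean-pooled levels until both dimensions fit one tile
(256 px default), resolution tags in pixels-per-centimeter plus an exact
µm/px record in the image description, and either uncompressed tiles
(bit-exact) or per-tile JPEG at quality 80 (default). JPEG tiles are
written planar (PlanarConfiguration 2): one full-resolution grayscale
JFIF stream per channel, which avoids chroma subsampling entirely — stain
color is the signal being preserved, and subsampled chroma measurably
blurs nuclear boundaries (phantom round-trip error drops from ~4.1 to
~2.1 intensity levels at quality 80). Files are plain standard TIFF:
libtiff and Python's tifffile decode them to identical pixels.

The writer/reader pair is implemented in this package; coordinates are
0-based, top-left origin, half-open throughout.

## Synthetic ground truth

`generate_phantom()` renders prostate-like H&E phantoms through the exact
forward model above: elliptical gland rings carrying eosin, scattered
nuclear discs carrying hematoxylin, empty lumina, known stain matrix,
per-pixel concentration ground truth, additive Gaussian OD noise, and
8-bit quantization. Everything is a pure function of the seed.

Choices worth knowing:

* **Noise default** `noise_od_sigma = 0.005` corresponds to about one gray
  level of sensor noise at mid intensity on an 8-bit scanner
  ($\Delta \mathrm{OD} \approx 0.004$ at $I = 128$).
* **Tissue coverage** lands in 20–80% for default specs (asserted).
* **Degradations** are parametric stand-ins for three familiar suboptimal
  staining classes, with ground truth updated consistently: *reddish*
  rotates the eosin vector toward the red absorbance axis and boosts eosin
  amounts by $1 + s$; *greyish* blends both vectors toward the neutral gray
  axis by $0.7s$ (capped below collinearity); *weak* multiplies both
  concentration channels by $1 - 0.7s$. They emulate the visual classes,
  not the chemistry that causes them.
* **What phantoms do not contain:** realistic gland morphology (nothing
  here is gradeable), spatially varying illumination, tissue folds, pen
  marks, or scanner-specific noise spectra. Passing phantom tests
  demonstrates the estimators recover a Beer–Lambert world exactly as
  designed; it does not certify behavior on artifact-laden clinical
  material, which the upstream workflow is assumed to have filtered.

One measurement subtlety is documented here because it shapes a test: with
any appreciable OD noise, normalization *removes* the noise component
orthogonal to the stain plane (for the classical vectors, the plane normal
is ≈ (−0.33, −0.08, 0.94), so mostly blue-channel noise), while a merely
white-balanced image retains it. The self-normalization fixed-point check —
normalizing a target against its own profile should reproduce the
white-balanced target — is therefore run on a noise-free phantom, where it
isolates what it is meant to measure: estimation error plus 8-bit rounding
(99.6% of tissue pixels within 3 intensity levels; a second normalization
pass changes nothing beyond 2 levels). With noise present the deviation is
real denoising, not a pipeline defect.

## Reader-study statistics and simulator

The evaluation side mirrors how such a tool is assessed clinically: two
pathologists rate original and normalized versions of every slide for
perceived color quality (1–10), Gleason Grade Group (0 = no tumor, 1–5),
diagnostic confidence (1–10) and time to diagnosis (seconds).

`run_study()` computes quadratic weighted Cohen's kappa
($w_{ij} = (i-j)^2/(k-1)^2$ on the fixed 6-category GG scale, so ordinal
distances keep their meaning even when grades are unobserved), paired
t-tests per pathologist and metric (two-sided by default; one-sided
available), quartile summaries with linear interpolation between order
statistics, Tukey 1.5×IQR outliers, the fraction of diagnoses above 90 s,
and 6×6 confusion matrices. Degenerate inputs fail loudly: zero-variance
paired differences and agreement tables with no marginal variability raise
classed errors instead of returning numbers. No multiple-testing correction
is applied across the six tests, and the report says so.

`simulate_reader_study()` generates complete paired rating tables. Ratings
come from a discretized latent-Gaussian rater whose noise is calibrated to
a target intra-rater kappa — the kappa-vs-noise curve is computed in closed
form from the discretized-Gaussian confusion model and inverted with 1-D
root finding, so calibration is deterministic. Times are log-normal with a
per-(slide, pathologist) difficulty effect shared across arms, which is
what makes the paired design informative. Defaults encode a plausible
93-slide study (quality medians 6/5 rising by 2; time medians 72/39.6 s
shrinking by a factor 0.85; confidence means 7.0/6.2 rising by 1 with a
thinner lower tail). The true Grade-Group case mix of such studies is not
public; the uniform default is a placeholder, not an estimate. Setting all
shift parameters to their null values (including the confidence sd scale,
which would otherwise move the post-clipping mean) yields an exchangeable
null under which the type-I error of the full analysis is verified at
~5% per test.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale by design:
phantoms of 320–768 px for estimation checks, one 2048² slide for the
tiled-equals-flat check, 10 seeds for stain-vector recovery, 1000 null
replicates for t-test calibration, and 100 simulated studies each for the
effect-detection and null-calibration checks. Kappa is verified against an
exhaustive brute-force computation over all 7380 pairs of rating vectors of
length ≤ 4 on 3 categories.

Conventions fixed throughout: half-up rounding for all intensity
quantization (never banker's rounding); type-7 quantiles; sample (n−1)
standard deviations; 0-based half-open pixel coordinates; stain matrix rows
unit-norm with H in row 1.

## Known limitations

* Illumination is modeled as a single global white point; spatially varying
  illuminant fields are out of scope.
* Two stains only; no third-dye or spectral unmixing path.
* The Macenko estimator needs both stains present in reasonable proportion;
  near-monochrome material (e.g. a slide that is almost pure eosin) raises
  a degenerate-stain error rather than returning an unreliable matrix.
* Percentile matching aligns one robust scale per stain; it does not match
  full concentration histograms, and it assumes the target and source carry
  comparable dynamic range of staining.
* The simulator's rater model is intentionally simple (no slide-by-rater
  interaction in the ordinal ratings, no learning or fatigue effects).
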