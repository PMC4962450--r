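---
title: "Methods: virtual H&E staining and Raman spectral histopathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual H&E staining and Raman spectral histopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `spectropath`, the parameters
that matter, the numerical choices, and what the synthetic-data generators
do and do not emulate. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The screening problem

Histopathology of frozen sections is fast but less reliable than embedded
sections. Label-free nonlinear microscopy offers an alternative: CARS
(tuned to the CH2 stretch; lipids bright), TPEF (endogenous fluorophores;
cytoplasm) and SHG (fibrillar collagen) can be acquired as large tile
mosaics in minutes and carry much of the morphological information of an
H&E stain — but in a false-colour space pathologists do not read. The
package's first stage translates such images into *pseudo-HE* renderings
for red-flag screening. Suspicious regions are then measured by Raman
microspectroscopy and diagnosed by a supervised classifier trained on
cluster-annotated spectra — *spectral histopathology* (SHP). Both stages
are non-invasive, so the same section remains available for conventional
staining.

## 2. Pseudo-HE generation

### 2.1 Preprocessing

The fixed order is median filter → block-mean downsampling (factor 4) →
flat-field correction → percentile contrast adjustment.

* **Median filter** (radius 1, i.e. 3×3, reflection edges). Exact sliding
  median, implemented as a vectorised odd–even sorting network over the
  window stack so results match a brute-force median to the bit.
* **Downsampling**: each output pixel is the mean of a 4×4 block; the
  global mean is preserved exactly when the shape divides evenly,
  otherwise the image is cropped to the largest divisible extent.
* **Illumination correction.** Tile mosaics show within-tile vignetting
  and tile-to-tile gain steps. Two retrospective estimators are provided.
  The default, `method = "mosaic"`, exploits the fact that every tile is
  imaged through the same optics: the field is the per-pixel median over
  all median-normalised tiles (tiles whose median falls below half the
  global level — background-dominated tiles — are excluded), lightly
  smoothed; tile gains are then equalised through tile medians, which
  keeps genuinely dark (background) tiles dark and makes two tiles with
  identical content but different gains correct to the same output. The
  single-tile `method = "tile"` (Gaussian-blur division) is kept as an
  option; it needs no second tile but confounds specimen structure with
  the vignette and flattens background-only tiles, which in our
  experiments destroyed the downstream background segmentation — the
  reason "mosaic" is the default.
* **Contrast adjustment.** The bracketed per-channel settings CARS
  (0.05, 0.015), TPEF (0.05, 0.04), SHG (0.001, 0.001) are read as
  (low, high) tail saturation fractions — values far below 1 and
  asymmetric, consistent with percentile-clipping conventions; both tails
  are configurable. Degenerate (constant) channels map to zero with a
  warning.

### 2.2 Colour model

A single multivariate PLS2 (NIPALS, X-deflation) regression maps the three
channel intensities to H&E RGB; with the default 3 components on full-rank
input the predictor coincides with ordinary least squares (an equivalence
the tests verify against a normal-equations oracle and against an
independent PLS implementation). One joint model is used rather than three
univariate fits so the response covariance informs the latent directions.
Training pixels default to pure foreground (no background, no nuclei), as
the background is replaced by white and nuclei by the overlay anyway.
Rank-deficient input reduces the component count with a warning.

### 2.3 Nuclei overlay

Nuclei are *negative contrast* in all three channels, so the colour
regression cannot render them; a two-class LDA on the raw intensity
triplet (pooled covariance, explicit discriminant w'x + b, ridge
regularisation `eps * trace(S)/3` if S is singular) supplies a posterior
nucleus probability. The default decision threshold is 0.5; because mask
*overlap* rather than pixel error is the quantity of interest, an optional
calibration step scans posterior quantiles on the training pixels and
keeps the threshold maximising training IoU. Connected components below
`min_area` (default 5 px at the downsampled grid) are removed — a cheap
stand-in for region-level prediction. The overlay is restricted to tissue
(background weight < 0.5) since the dark background aliases with the
nuclei's darkness. Texture features are deliberately excluded: the model
is a fingerprint of the three intensities only.

### 2.4 Background weighting

k-means with k = 6 (k-means++ seeding, 10 restarts under a fixed seed,
best within-SS kept; stats::kmeans supplies the Lloyd iterations) segments
the pixel vectors; the cluster with minimal ‖centre‖² is background. The
binary mask is median filtered (disc 2), the *foreground* is
morphologically closed (disc 5, filling gaps), the background opened
(disc 5, removing specks and smoothing the contour), and a mean filter
(disc 7) turns the mask into weights in [0, 1] for smooth background
removal. Radii are in post-downsampling pixels and were chosen to remove
speckle while preserving gland-scale gaps; with `mean_radius = 0` the
weight stays binary. Compositing is convex per pixel:
`bg·white + (1 − bg)·(nuclei ? violet : colour)`, with dark violet
defaulting to RGB (0.29, 0.13, 0.37) — the named colour, with the triplet
itself configurable since no numeric value is canonical.

## 3. Spectral histopathology

### 3.1 Spectral pre-treatment

Spectra are cropped to 600–1800 cm⁻¹ (the fingerprint window shown in the
classification context; limits configurable), SNIP baseline-corrected and
vector normalised. SNIP runs in the LLS-compressed domain
v = log(log(√(y+1)+1)+1) by default and uses the decreasing-window
variant, which erodes peaks less. The window half-width m is a channel
count: clipping removes features narrower than the window while leaving
slower curvature as baseline, so m should sit just above the band width.
With 2 cm⁻¹ channels and ~19 cm⁻¹ FWHM bands the default is **m = 15**
(±30 cm⁻¹). Much larger windows are counterproductive: the iterated
midpoint clipping depresses concave baseline stretches by roughly
m³·|f″|/6, which for m ≈ 60 exceeds the band amplitudes themselves.
Points the clipping never touches return the input exactly, so a constant
spectrum yields a strictly zero corrected signal. Zero-norm corrected
spectra are flagged invalid and excluded downstream with a log entry in
the map's QC record. An optional cosmic-ray clamp exists in concept only:
spikes are handled by annotation-level exclusion, mirroring practice.

### 3.2 PCA compression

Mean-centred PCA via SVD; loadings orthonormal with the sign convention
that each loading's largest-magnitude element is positive. The feature
count for classification is the smallest number of components reaching
99 % cumulative explained variance, capped at 20 — a cap that keeps the
1-NN distance computations tractable without measurable loss on separated
cohorts.

### 3.3 Annotation transfer and the simulated pathologist

Each scan is clustered with k-means (default k = 9, range 9–15 per
subject configurable) on the PC scores; every cluster is mapped to a
diagnosis (normal / adenoma / carcinoma) or to an excluded class (muscle,
connective tissue, background, spikes, hyperplasia), and each spectrum
inherits its cluster's class. Per-scan clustering was chosen over pooled
per-individual clustering since the annotation is made scan by scan. For
synthetic cohorts the blinded pathologist is emulated by assigning each
cluster the majority truth class of its pixels.

### 3.4 Weighted kNN and cross-validation

The classifier stores the training scores and labels with k = 1 neighbour,
Minkowski order p = 2 and the "optimal" kernel: distances are
rank-normalised by the (k+1)-th neighbour distance and weighted with the
asymptotically optimal Epanechnikov form; with k = 1 — the default — all
kernels coincide with plain nearest-neighbour, which is the path the
package exercises. Ties break deterministically (earlier training row;
vote ties to the smallest class index). The k = 1 / p = 2 fast path
maximises the linear score 2q·t − ‖t‖² via BLAS without materialising a
distance matrix.

Evaluation is **individual-out cross-validation**: one fold per subject,
so the estimate includes between-subject variance — resubstitution-style
estimates cannot be lower, and a property test asserts exactly that.
Scoring defaults to the *region* level (majority vote of spectrum
predictions within each annotated scan×class region), matching the
magnitudes of a per-region diagnosis table; spectrum-level scoring is
available. Mean sensitivity is the unweighted macro-average over classes;
a class never annotated yields NA and is omitted. Merging adenoma and
carcinoma into "tumor" gives the tumour-vs-normal statistics.

### 3.5 Wilcoxon screening

`wilcoxon_screen()` applies the two-sided Mann–Whitney/Wilcoxon rank-sum
test per principal component (default components 3–5), exact for small
tie-free samples, normal approximation with tie correction otherwise; a
fully tied comparison returns p = 1.

## 4. Synthetic data: what is emulated, what is not

**Image scenes.** Tiles (default 128 px, standing in for 450 µm × 450 µm
mosaic tiles) carry diffuse TPEF cytoplasm, CARS lipid blobs, SHG fibre
segments, nuclei as multiplicative darkening (factor 0.2–0.5 — the
negative-contrast signature), a background region beyond a wavy specimen
contour anchored to one image side (thresholded at the exact requested
area fraction), per-tile radial vignetting with random tile gains,
and additive Gaussian noise. The HE reference is an exact affine map of
the clean channels (coefficients chosen to stay inside (0, 1), so the map
truly is affine), overwritten with violet nuclei and white background —
which is what makes an end-to-end colour-fidelity oracle possible. Not
emulated: real photophysics, resonance backgrounds, registration error,
dye chemistry. Passing the fidelity tests therefore shows the pipeline
recovers a recoverable map, not that real tissue obeys one.

**Raman cohorts.** Spectra are sums of four Gaussian marker bands — 785
(DNA phosphate backbone; stepping 0.5/1.0/1.5 across normal/adenoma/
carcinoma), 1003 (phenylalanine), 1449 (CH2), 1657 cm⁻¹ (amide I) — plus
a scan-specific fluorescence baseline (gentle low-order polynomial plus a
broad Gaussian hump, amplitude ≈ 3× band height, per-pixel gain
0.9–1.1) and Gaussian noise (default SD 0.1, i.e. band contrasts ≥ 5× the
noise). Baseline curvature is kept an order of magnitude broader than the
bands: that scale separation is what makes baseline removal well-posed at
all, and it matches tissue autofluorescence, which varies slowly across
the fingerprint window. Per-individual additive band-amplitude offsets
(SD 0.05) create the mild biological variance that separates IO-CV from
resubstitution. Class regions are contiguous blocks per scan (background
corner, occasional muscle strip, one diagnosis filling the rest),
matching annotation granularity; scans cycle through the three diagnoses
so every class occurs in every subject. Lorentzian line shapes, cosmic
rays, detector etaloning and wavenumber miscalibration are not modelled.

## 5. Problem sizes and seeds

The test suite runs scenes of 128–512 px (1024 px in the acceptance
checks, the native mosaic tile resolution) and cohorts of 3–6 individuals;
the acceptance checks use 6 individuals × 4 scans of 34×40 pixels — about
two thirds of a full 34-map study — and five independent seeds, with a
region-label permutation as negative control. All randomness flows from
explicit seeds through a fixed counter scheme (`derive_seed`), so every
artifact is bit-reproducible; k-means uses k-means++ with 10 restarts
under the derived seed.

## 6. Known limitations

* The flat-field estimate assumes several tiles share the vignette; single
  -tile images fall back to the structure-confounded per-tile method.
* The nuclei model is pixel-wise on three intensities; heavily textured
  tissue or stain-like artefacts would need richer features.
* Region scoring assumes one annotated region per scan and class.
* The "optimal"-kernel weighting is exercised only at k > 1; the default
  configuration (k = 1) is plain nearest-neighbour by construction.
* Synthetic cohorts are easier than real ones: band positions are exact,
  baselines smooth, labels noise-free at the region level.
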