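---
title: "Detecting stranded whales in VHR imagery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stranded whales in VHR imagery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandscan)
```

## The problem

Mass mortality events of large baleen whales on remote coastlines are easy
to miss: carcasses strand along fjord-indented shores that boats and planes
reach weeks or months later. Very high resolution (VHR) satellites image
such coastlines on demand, with a sub-meter panchromatic band and eight
2 m multispectral bands, and a decomposing carcass — 7–20 m long,
cigar-shaped, discolored pink/orange by decay — is large and bright enough
to be visible in that imagery. `strandscan` implements a complete,
testable pipeline for finding such carcasses: restrict the search to a
narrow coastal strip, score every pixel against reference carcass spectra
with the Spectral Angle Mapper, group flagged pixels into objects, grade
the objects by carcass-like morphometry, and score the result against
survey or ground-truth locations. Because the archival commercial imagery
behind the original analyses cannot be redistributed, the package ships a
synthetic scene generator that reproduces the statistical structure the
detector relies on; everything the tests and the acceptance script report
is computed on those synthetic scenes or on published count tables.

## The detector

### Spectral Angle Mapper

Each pixel spectrum $\mathbf{x} \in \mathbb{R}^8_{\ge 0}$ is compared with
a target end member $\mathbf{t}$ (the per-band mean spectrum over manually
chosen carcass pixels) through the spectral angle

$$\theta(\mathbf{x}, \mathbf{t}) =
  \arccos \frac{\langle \mathbf{x}, \mathbf{t}\rangle}
               {\lVert\mathbf{x}\rVert \, \lVert\mathbf{t}\rVert},$$

which depends only on spectral *shape*: scaling either spectrum by a
positive constant leaves it unchanged, so overall illumination differences
(sun angle, exposure) do not affect the score. A pixel is a candidate when
its minimum angle over all target signatures is at most `theta_max`
*and* that angle beats its angle to every *exclusion* signature (spectra
of features to reject — e.g. cloud — are supplied the same way and veto
pixels that match them better than any target). With several targets the
best-matching label is kept. Nodata pixels are never candidates.

Two pieces of the published procedure are not recoverable from its
description and are therefore explicit configuration:

* **`theta_max`** (default 0.10 rad). The original tool was driven by an
  uninterpretable "5% threshold"; the angle cutoff here is a required,
  logged parameter rather than a guess at that value.
* **The 1–100 "likelihood"**. The commercial implementation reports one
  without defining it. `strandscan` uses the simplest monotone map,
  $L = 100\,(1 - \theta/\theta_{\max})$ clipped to $[0, 100]$, documented
  as non-canonical. Analyses that only use likelihood *rankings and
  thresholds* (as the error tables do) are insensitive to the exact map so
  long as it is strictly decreasing in $\theta$.

Classification uses only the signature's per-band mean. Min/max/sd per
band are retained on the signature object because they describe how
heterogeneous the training carcass was, but they play no role in the
angle — this matches the end-member formulation of SAM.

### Water mask and coastal buffer

Carcasses strand at the waterline, so the search is restricted to a
metric buffer around the land–water boundary. The boundary comes from the
Normalized Difference Water Index,
$\mathrm{NDWI} = (G - N)/(G + N)$ with $G$ the green band (3) and $N$ the
NIR1 band (7); water is `NDWI > 0` by default (the index's standard zero
crossing — threshold configurable). Boundary pixels are land pixels with a
water pixel in their 4-neighborhood, and a pixel is in the buffer when the
Euclidean distance between pixel centers to the nearest boundary pixel is
at most `buffer_m` (default 5 m). The distance field is an exact Euclidean
distance transform, so the buffer equals a brute-force all-pairs
computation (the test suite checks this literally on small grids).

The buffer keeps **both** sides of the coastline by default: carcasses
sit beached or partially afloat, so land-only or water-only buffers each
lose real targets. Both the distance and the side are configuration
because a fixed 5 m strip is known to miss carcasses stranded high on
beaches; widening the buffer trades recall against commission errors from
spectrally similar beach sand.

### Objects, morphometrics, confidence classes

Candidate pixels are grouped into connected components, by 8-neighbor
adjacency by default — at 2 m pixels a diagonally oriented carcass is a
diagonal chain of pixels, and 4-connectivity would split it. Object length
is the extent of member pixel centers along the principal axis of their
scatter plus one pixel (so a single pixel has length = pixel size and a
straight run of $k$ pixels has length $k$ · pixel size); width is the
orthogonal extent plus one pixel; elongation is length/width.

The three-level manual confidence grading (1 obvious / 2 probable /
3 possible whale) is codified as nested numeric rules: class 1 requires
length in 7–20 m and elongation ≥ 2.5; class 2 relaxes to 5–25 m and
elongation ≥ 1.5; everything else is class 3. The length bounds come from
adult carcass size; the elongation cutoffs are the package's own defaults,
because the original grading was done by an experienced analyst's eye and
included a criterion (visible fluke) that pixel footprints cannot express.
Touching or overlapping carcasses merge into a single object by design; no
splitting heuristic is attempted, so crowded strandings are undercounted,
matching the original protocol's own caveat.

### Evaluation

`detection_report()` reproduces the published error-table layout: at each
likelihood threshold it counts flagged pixels, *whale pixels* (within one
pixel, Chebyshev, of a truth footprint — the tolerance absorbs
georeferencing jitter and is configurable), *errors of commission* (the
rest), *whales identified* (truth whales hit by at least one flagged
pixel; a whale claimed by two pixel groups counts once) and *errors of
omission*. Counts are conserved by construction (whale + commission =
total; identified + omitted = truth) and thresholds nest. Percentages are
rounded half-up to one decimal in table fields and to the nearest integer
in narrative-style summaries (`within_distance_summary()`,
`count_comparison()`), mirroring the mixed precision such reports use.
`count_comparison()` validates that per-class counts sum to the satellite
total and flags, rather than repairs, inconsistent inputs.

## Pan-sharpening

`pansharpen_gram_schmidt()` is the component-substitution form of
Gram-Schmidt sharpening: simulate a low-resolution pan as the band-weighted
sum of the (bilinearly upsampled) MS bands, match the real pan to it in
mean and standard deviation, and inject the matched detail into band $b$
with gain $g_b = \mathrm{cov}(b, \mathrm{pan_{sim}})/\mathrm{var}
(\mathrm{pan_{sim}})$ — the standard equivalence of the GS forward/inverse
transform pair. The default band weights follow the overlap of each band
with the pan passband (bands 2–6 dominate; NIR2 contributes nothing).

Global injection gains cannot reproduce band-specific contrast at sharp
land–water edges, which leaves a low-frequency radiometric residual of a
few percent of the band mean on coastal scenes. Since downstream spectral
analysis depends on the sharpened product preserving the MS radiometry,
the implementation finishes with a per-block residual correction
(`enforce_consistency = TRUE`): each band is shifted within every MS-sized
block so that block-averaging the output reproduces the input band
exactly (to machine precision; blocks containing nodata are excluded).
A constant image is an exact fixed point (no variance, nothing to
inject), scaling all inputs by $c>0$ scales the output by $c$, and nodata
in either input propagates to the output.

Whether SAM should run on the 2 m MS grid or the sharpened 0.5 m grid is
left as configuration; the default is the MS grid, the grid reference
spectral profiles are drawn from, because sharpening manufactures
sub-pixel spectra that were never observed.

## The synthetic scene generator

`generate_scene()` emulates one WorldView2-like coastal acquisition:

* **Bands and grids.** Eight bands centered at 427/478/546/608/659/724/
  833/949 nm, 2 m MS pixels, 0.5 m pan pixels (ratio 4). NIR1 sits at
  833 nm, carrying the near-infrared reflectance peak of decomposing
  carcasses. Values are dimensionless top-of-atmosphere radiance on a
  0–80 scale.
* **Geography.** Open water west of a sinuous coastline (three
  incommensurate sine harmonics — enough boundary length to host the
  configured object counts), a 3-pixel sandy beach strip, vegetated land
  with rock patches.
* **Whales.** Rotated ellipses (aspect 3:1–6:1) centered on boundary
  pixels and oriented along the local coast tangent, so each carcass lies
  beached/partially afloat inside the 5 m buffer. Target lengths are drawn
  uniformly from 7–20 m and footprints are re-measured after
  rasterization; a footprint whose principal-axis length falls outside the
  configured range is redrawn, so truth lengths always satisfy the range
  *as measured*. Each whale draws a decay state from a mixture
  (dark 0.15 / pink 0.35 / orange 0.30 / bleached 0.20); all states share
  the diagnostic shape — radiance rising from blue through red into NIR,
  peaking in NIR1 — at very different brightness.
* **Heterogeneity and noise.** Within-carcass patchiness is per-band
  multiplicative noise with sd = `within_cv` × band mean (default 5%),
  plus additive sensor noise (sd 0.5 radiance units, also applied to the
  pan band). The multiplicative form matters: decay mottling scales with
  brightness, and an additive sd large enough to look heterogeneous on a
  bright carcass would swamp the spectral shape of a dark one (the angle
  perturbation of additive noise grows as sd/‖x‖). Under these defaults
  the angle perturbation of a carcass pixel is ≈ 0.045 rad (sd ≈ 0.015),
  comfortably below `theta_max` = 0.10, while the closest confounder
  (sand vs a bleached carcass) sits at 0.21 rad — the
  whale-vs-background separation exceeds three times the noise-induced
  angle spread, which is the regime the detector is designed for.
* **Confounders.** Stranded logs (thin dark ellipses on the coast), wave/
  foam streaks (bright visible, very low NIR, in open water) and optional
  cloud patches. Logs and waves share carcass-like *shape* but have low
  red/NIR radiance relative to carcasses — the separability the detector
  exploits — while sand is the spectrally *closest* confounder, mirroring
  where commission errors arose in practice. Cloud defaults to zero and,
  when present, is handled by an exclusion signature.
* **Pan band.** Band-weighted MS brightness, bilinearly upsampled, plus
  sensor noise; block-averaging it back correlates > 0.9 with the
  weighted MS brightness.
* **Determinism.** One integer seed drives every stochastic step;
  identical configuration and seed give bit-identical rasters and truth.
  If the requested objects cannot be placed (extent too small, too much
  separation) generation aborts with an explicit placement-failure error
  rather than silently truncating.

What the generator does **not** emulate: atmospheric and radiative
transfer, sun-angle/shadow geometry (a shadowed carcass is approximated
only by the dark decay state), tides, sensor PSF/MTF, and the real
spatial texture of vegetation and surf. Passing tests on these scenes
therefore demonstrate that the pipeline's logic is correct and that the
procedure works *when carcass spectra are separable from the background
at the configured noise level* — they do not certify field performance on
real imagery, where carcass heterogeneity demonstrably breaks pure
spectral detection (errors of commission on sand and cloud, omission of
shadowed or bleached-out carcasses).

## Numerical choices and degenerate inputs

* Angle ties between targets resolve to the first signature in the list;
  the exclusion rule uses a strict inequality, so a pixel exactly
  equidistant between a target and an exclusion is rejected.
* `acos` arguments are clamped to [−1, 1]; zero-norm spectra are an error
  in `spectral_angle()` and never candidates in `sam_classify()`.
* Percentages round half-up (an epsilon guards against binary
  representation artifacts like 66.65 stored just below the midpoint).
* An all-water or all-land mask yields an empty buffer with a warning,
  not an error; NDWI 0/0 cells are nodata; a single-pixel object has
  length = width = pixel size; empty candidate sets group to an empty
  object list; a truth set with no whales makes `run_pipeline()` fall
  back to the built-in library spectra as targets and report zero counts.
* The principal axis of a pixel scatter comes from the eigen-decomposition
  of its 2×2 covariance; for collinear footprints the second eigenvalue is
  0 and width degrades cleanly to one pixel.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every code path while keeping a full run
in tens of seconds: 256×256 MS pixels (1024×1024 pan) with 20 whales for
detection-performance runs (10 seeds), 50–96 pixel grids for the
exhaustive per-pixel SAM and buffer oracles (where brute force is
feasible), and 64×64 scenes for pan-sharpening consistency. Worked
error-table percentages are reproduced from published counts directly, as
the original imagery is commercial and cannot be shipped or re-analyzed.

## Known limitations

* Spectral-only detection: no shape templates, object-based segmentation
  or learned classifiers; morphometric grading happens only *after*
  pixel-level detection, so a carcass with no spectrally matching pixel is
  unrecoverable downstream.
* The likelihood scale is package-defined; absolute values are not
  comparable with other SAM implementations (rankings are).
* Merged objects for touching carcasses; no abundance correction for
  carcass drift between acquisition dates.
* The ASCII-grid raster interface (one file per band) suits the pipeline
  and standard GIS import, but carries no CRS metadata beyond the
  geotransform; coordinates are assumed projected, in meters.
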