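# strandscan

Detection of stranded whale carcasses in very high resolution (VHR)
multispectral satellite imagery.

Mass strandings of large baleen whales often happen on coastlines too
remote for timely boat or aerial surveys. In sub-meter satellite imagery a
decomposing carcass — 7–20 m long, cigar-shaped, discolored pink/orange,
with elevated red and near-infrared radiance — is a detectable target.
`strandscan` implements the full detection workflow for such imagery and,
because the underlying commercial scenes cannot be redistributed, a
synthetic coastal scene generator with ground truth so the whole pipeline
can be exercised, validated and benchmarked end to end.

The pipeline:

1. **Scene** — `generate_scene()` renders an 8-band WorldView2-like
   multispectral raster (2 m), a panchromatic raster (0.5 m) and truth
   annotations: whales as rotated ellipses on the land–water boundary with
   a decay-state spectral mixture, plus log / wave / cloud confounders.
2. **Preprocess** — `to_toa_radiance()` (per-band affine calibration) and
   `pansharpen_gram_schmidt()` (Gram-Schmidt component substitution with a
   spectral-consistency correction).
3. **Coast** — `compute_ndwi()`, `extract_water_mask()`,
   `build_coastal_buffer()`: water from NDWI = (G − N)/(G + N), then an
   exact Euclidean buffer (default 5 m, both sides of the waterline) that
   restricts the search to the coastal strip.
4. **Detect** — `sam_classify()`: Spectral Angle Mapper. Pixel spectrum
   **x** matches target end member **t** when
   θ = arccos(⟨x,t⟩ / (‖x‖‖t‖)) ≤ θ_max (default 0.10 rad); exclusion
   signatures (e.g. cloud) veto pixels that match them better. Each
   candidate gets a likelihood L = 100·(1 − θ/θ_max).
5. **Objects** — `group_pixels()` (connected components, 8-adjacency),
   `measure_object()` (principal-axis length/width), and
   `classify_confidence()` (the 3-level obvious/probable/possible whale
   grading, codified as nested length/elongation rules).
6. **Evaluate** — `detection_report()` (whale pixels, errors of commission
   and omission, stratified by likelihood threshold),
   `nearest_match()` / `within_distance_summary()` (distance to survey
   points), `count_comparison()` (satellite vs ground counts).

`run_pipeline()` chains all stages from one configuration and writes every
product (ASCII-grid rasters, GeoJSON/CSV points, polygons and tables, a
JSON manifest) to an output directory. A command-line wrapper lives at
`inst/cli/strandscan.R`.

## Worked example

```r
library(strandscan)

run <- run_pipeline(run_config(scene = scene_config(seed = 42)), "run42")
print(run)
#> <strandscan_run> seed 42 -> run42
#>   20 truth whales, 190 candidate pixels, 21 objects
#> <detection_report>
#>   likelihood >= 0: 190 pixels (100% whale, 0% commission); 20 of 20 whales identified (100%), 0 omitted (0%)
#>   likelihood >= 40: 164 pixels (100% whale, 0% commission); 20 of 20 whales identified (100%), 0 omitted (0%)
#>   likelihood >= 65: 47 pixels (100% whale, 0% commission); 17 of 20 whales identified (85%), 3 omitted (15%)

print(run$comparison)
#> <count_comparison> satellite 21 vs ground 20: excess +1 (5%)
#>   classes 1/2/3: 16/3/2
```

Reading: on a default synthetic scene (256×256 MS pixels, 20 whales at
moderate noise) the detector flags 190 coastal pixels, all of them on true
carcasses (0% commission), and every carcass is hit by at least one pixel
(0% omission). Raising the likelihood threshold to 65 keeps only the
closest spectral matches: still zero commission, but three whales drop out
— the commission/omission trade the error tables quantify. Grouping gives
21 objects for 20 whales (one carcass split across the buffer), 16 graded
class 1 (obvious: whale-like length *and* elongation), and the
satellite-vs-ground comparison reports the +5% excess.

The evaluation module also reproduces published error-table arithmetic
directly from counts:

```r
detection_counts(39, 26, 14, 21)[c("whale_pixels_pct", "commission_pct")]
#>   whale_pixels_pct commission_pct
#> 1             66.7           33.3
```

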