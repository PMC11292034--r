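# panicletraits

Non-destructive extraction of rice panicle traits — grain number, grain
length and width, and panicle length — from photographs of *intact*
panicles, for phenotyping and breeding work where threshing and manual
shaping are too slow or destroy the sample.

A panicle is photographed on a uniform board next to a red circular
calibrator of known radius (25 mm). From that one image the package
computes:

* **Calibrated grain count.** Grains occlude each other, so any detector
  undercounts. The panicle morphology index
  `PMI = 1 − |N_actual − N_forecast| / N_actual` (clamped to [0, 1])
  quantifies the occlusion, and the final count divides the raw detector
  count by it: `N_grain = round(N_predict / PMI)`. When the detector only
  misses grains, this recovery is exact.
* **Grain length / width / aspect ratio.** Detections are screened for
  un-occluded grains (NMS IoU 0.8, confidence 0.7), cropped, segmented,
  and measured by the minimum-area rotated bounding rectangle; pixel sizes
  convert to mm via the calibrator's "pel density"
  (`mm_per_pixel = 25 / pixel_radius`). Panicle values are means over
  measured grains.
* **Panicle length.** The panicle is segmented on the HSV saturation
  channel, cleaned, and thinned to a skeleton; A* search from the bottom
  endpoint to the top-20 candidate endpoints picks the path with the most
  pixels (the main path), whose pixel count × pel density is the length.
* **Evaluation metrics.** MAPE, MAE, RMSE, R², accuracy, and single-class
  mAP₅₀ for detector quality.

A ground-truthed synthetic scene generator (board, calibrator, curved
branched stem, elliptical grains at controllable overlap, simulated
detector) makes every stage testable without field images. External
detections (CSV / COCO-style JSON) and external per-image PMI values can
be plugged in to replace the built-in baselines.

## Worked example

```r
library(panicletraits)

# a synthetic panicle scene with full ground truth
sc  <- generate_scene(pipeline_scene_spec(seed = 3))

cfg <- pipeline_config(detect_params = detect_params(method = "rgb_range"),
                       segment_method = "rgb_range")
analyze_panicles(list(scene_3 = sc$image), cfg)
#> # A tibble: 1 x 12
#>   image_id mm_per_pixel n_predict   pmi n_grain n_measured mean_length_mm
#>   <chr>           <dbl>     <int> <dbl>   <int>      <int>          <dbl>
#> 1 scene_3         0.352        22 0.919      24         17           13.7
#> # i 5 more variables: mean_width_mm <dbl>, mean_aspect <dbl>,
#> #   panicle_length_px <dbl>, panicle_length_mm <dbl>, reason <chr>
```

Reading the row: the calibrator gave 0.352 mm/px; the classical baseline
detector found 22 grain blobs in this heavily clustered panicle (the truth
is 150 — a trained detector would be plugged in here); the box-overlap PMI
heuristic estimated 0.919, calibrating the count to 24; 17 screened grains
were measured (their means inflated by clustering); and the skeleton main
path measured 725 px = 255 mm. On scenes with separated grains the same
call recovers counts exactly and grain dimensions to within a few percent:

```r
sc  <- generate_scene(scene_spec(seed = 42))       # 30 disjoint grains, 9.0 x 3.0 mm
pel <- pel_density(detect_calibrator(sc$image))
det <- baseline_detect(sc$image, detect_params(method = "rgb_range"))
nrow(det)                                          # 30 (count = truth)
panicle_grain_stats(measure_grains(sc$image, det, screening_config(), pel))
#> # A tibble: 1 x 4
#>   n_measured mean_length_mm mean_width_mm mean_aspect
#> 1         30           9.06          3.12        2.92
```

(true means for this scene: 8.97 mm and 3.00 mm).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/panicletraits.R simulate --n 3 --dir scenes --seed 1
Rscript inst/cli/panicletraits.R analyze  --images scenes --out traits.csv
Rscript inst/cli/panicletraits.R eval     --pred traits.csv --truth scenes/scenes.csv --column n_grains
```

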