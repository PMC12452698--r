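# matt

Transillumination-based tracking of bony landmark motion under intact
soft tissue.

## What this package is for

When a bone such as the lateral femoral epicondyle (LFE) is lit from
within by an arthroscopic light source, a bright "light hollow" shines
through the overlying fascia and can be filmed while a continuous
passive motion (CPM) device flexes the joint at constant angular
velocity. This package turns such recordings into displacement
measurements for anatomists and biomechanists studying how deep bony
landmarks move relative to myofascial structures (e.g. the iliotibial
band, ITB):

* **detection** — per-frame intensity thresholding, 8-connected
  components with contour/area/circularity descriptors, and an
  intensity-weighted subpixel centroid of the spot;
* **tracking** — nearest-to-prior temporal association with an explicit
  per-frame jump bound; detection gaps are recorded, never interpolated;
* **calibration** — mm/px from an in-frame millimetric ruler:
  `s = L_mm / ||p1 - p2||`;
* **kinematics** — with the spot centroid `x(θ)` at flexion angle θ and
  an anterior unit axis `a`, the signed distance to an annotated border
  line ℓ is `d(θ) = ((Q - x) · a) s`, where `Q` is the intersection of ℓ
  with the line through `x` along `a` (positive while the border lies
  anterior, negative after crossing). The landmark-relative anterior
  displacement is the subtraction rule `Δ = d(0°) - d(30°)`; absolute
  displacement is `||x(30°) - x(0°)|| s`; cohorts are summarized by
  median and IQR with type-7 quantiles, `h = (n-1)p`;
* **validation** — a synthetic-scene generator (blurred spot over
  fibrous texture, drawn ruler, sensor noise, known ground truth) and a
  layered-tissue Monte Carlo photon transport model (Henyey–Greenstein
  scattering, Fresnel boundaries, Russian roulette) for studying how
  tissue spreads and biases the transilluminated spot.

## Worked example

Simulate a recording with a commanded 9 mm displacement at 0.05 mm/px,
then measure it back with the full pipeline:

```r
library(matt)

scene <- render_scene(scene_spec(fps = 10, seed = 1))
dir <- tempfile(); write_scene(scene, dir)

res <- run_measure(file.path(dir, "frames"),
                   file.path(dir, "annotations.json"),
                   out_dir = file.path(dir, "run"), fps = 10)
res$scale
#> <matt_scale> 0.05 mm/px
glance(res$trajectory)
#> # A tibble: 1 × 5
#>   n_frames n_detected n_gaps   fps path_length_px
#> 1      101        100      1    10           181.
tidy(res$record)
#> # A tibble: 10 × 2
#>    measure           value_mm
#>  1 absolute_AB_mm        9.02
#>  2 d_ant_0              11.7
#>  3 d_ant_30              2.64
#>  4 d_post_0              2.83
#>  5 d_post_30            -6.19
#>  6 delta_ant_border      9.02
#>  7 delta_post_border     9.02
#>  8 titb_0                6.73
#>  9 titb_30               5.39
#> 10 delta_titb           -1.35
```

The spot was commanded to travel 9 mm along the anterior axis; the
pipeline recovers 9.02 mm from the noisy frames, with one detection gap
out of 101 frames. `d_post_0 > 0` and `d_post_30 < 0` show the spot
crossing the posterior border line (the negative-on-crossing
convention), and both border-relative displacements equal the absolute
one because the scene's motion is purely anterior. The subtraction rule
itself: `anterior_displacement(2.72, -6.23)` gives `8.95` mm and
`anterior_displacement(13.24, 9.29)` gives `3.95` mm.

Photon transport through a fascia-like slab:

```r
prof <- simulate_photons(
  tissue_stack(tissue_layer(mu_a = 0.5, mu_s = 10, g = 0.9,
                            n = 1.4, thickness = 2)),
  n_photons = 1e5, seed = 1)
prof
#> <matt_profile> 100000 photons: R = 0.0992, T = 0.0545, A = 0.8463 (residual 2.58e-12)
```

A command-line front end wraps the same functions
(`inst/cli/matt.R`; after installation, locate it with
`system.file("cli/matt.R", package = "matt")`):

```sh
matt.R simulate  --seed 5 --out scene/
matt.R measure   --video scene/frames --annotations scene/annotations.json --out run/ --fps 30
matt.R score     --run run/ --truth scene/truth.json
matt.R photon    --stack stack.json --n 100000 --seed 1 --out photon/
matt.R summarize --reports run/report.json --out summary.csv
```

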