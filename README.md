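# leapscan

Scan-pattern engineering and image quality control for secondary-electron SEM
imaging of charge-prone specimens — above all vitrified (cryo) biological
samples imaged in serial FIB/SEM volume workflows.

## The problem and the idea

Insulating specimens accumulate charge under the electron probe faster than
they can drain it. The result is the familiar artefact taxonomy of cryo-SEM:
dark streaks along the fast scanning direction when the fluence is delivered
line by line, blotchy dark patches under frame integration, and halos around
lipid droplets, myelin stacks and degradative compartments. Because these
artefacts depend on *when* each pixel's neighbourhood was last irradiated,
the scan pattern is itself an instrument parameter.

An interleaved ("leapfrog") scan visits a sub-lattice of the pixel grid —
skipping `s` pixels in x, returning to the starting x coordinate while
skipping `s` in y — and then repeats for the remaining sub-lattice offsets
until every pixel has been visited. With stride `s + 1` the minimum time
between visits of any two neighbouring pixels grows from the dwell time (a
raster scan's x-interval) to a large fraction of the sub-lattice pass period,
giving deposited charge time to dissipate isotropically before a neighbour is
probed.

`leapscan` implements the full desk-scale toolchain:

* **Timed scan patterns** (`make_raster_pattern()`,
  `make_interleaved_pattern()`, `min_neighbour_interval()`,
  `export_pattern_text()`) — validated visit sequences exported as the `x y`
  coordinate text files consumed by programmable scan engines, with
  line/frame integration semantics and electron-fluence arithmetic
  (`compute_fluence()`; the schedules 100 ns × 100, 500 ns × 20 and
  1000 ns × 10 at 6.3 pA and 6.34 nm pixels all deliver ≈ 0.1 e⁻/Å²).
* **Synthetic specimen phantoms** (`make_phantom()`) — lipid-droplet discs,
  myelin annulus stacks, thin membranes and an electrically heterogeneous
  background, with per-pixel secondary-electron yield, charge-leak time
  constant and ground-truth labels.
* **A charge simulator** (`simulate_acquisition()`) — per-visit deposition,
  isotropic diffusion + exponential leak (`dC/dt = D ∇²C − C/τ(x,y)`), and
  charge-attenuated detection
  (`gain · yield · exp(−α·C̃) + offset + noise`), producing 16-bit subframe
  stacks under any pattern.
* **Subframe processing** (`convert_to_uint8()`, `crop_flyback()`,
  `center_crop()`, `align_frames()`, `integrate_frames()`, `mean_filter()`)
  — the standard preparation pipeline including 5 × 5-patch, 20 %-overlap
  cross-correlation drift correction.
* **Quality metrics** (`histogram_mean()`, `estimate_flyback_extent()`,
  `segment_simple()`, `complexity_score()`, `anisotropy_index()`,
  `normalize_to_reference()`) — the mid-range-127 histogram charging metric,
  Gaussian + Sobel flyback-extent estimation, object counting and
  perimeter²/area shape complexity, and a streak-anisotropy index.
* **Statistics** (`quadrant_count_ratio()`, `compare_conditions()`) and the
  orchestrated **strategy comparison** (`run_strategy_comparison()`).

## Worked example

```r
library(leapscan)

# a 7x7 interleaved pattern, skip 2 — the schematic case
p <- make_interleaved_pattern(7, 7, skip_x = 2, skip_y = 2, dwell_ns = 100)
head(p$visits, 4)
#> # A tibble: 4 × 3
#>       x     y t_start_ns
#>   <int> <int>      <dbl>
#> 1     0     0          0
#> 2     3     0        100
#> 3     6     0        200
#> 4     0     3        300

# neighbouring pixels are revisited 4x later than in a raster scan
min_neighbour_interval(make_raster_pattern(7, 7, 100), 1)   # 100 ns
min_neighbour_interval(p, 1)                                 # 400 ns

# matched-fluence schedules
compute_fluence(6.3, 100, 100, 6.34)
#> [1] 0.0978254

# simulate one interleaved acquisition on a cell-like phantom and score it
ph  <- make_phantom("cell", 256, 256, seed = 1)
pat <- make_interleaved_pattern(256, 256, 2, 2, dwell_ns = 100, reps = 20)
stk <- simulate_acquisition(ph, pat, sim_params(), seed = 1)
img <- integrate_frames(align_frames(convert_to_uint8(stk))$aligned)
qc_report(img, condition = "interleaved_fi")
```

The histogram mean of a clean acquisition sits near 127 (the 8-bit
mid-range); `charging_deviation` is its distance from 127, and
`anisotropy_index` is ~1 for isotropic texture and rises with horizontal
streaking. The full in-silico comparison

```r
res <- run_strategy_comparison(experiment_config(
  schedules = data.frame(dwell_ns = 100, reps = 100L), seeds = 1:5))
res$verdicts
```

reports, per seed, which strategy's histogram mean lands closest to 127
(interleaved frame integration, in ≥ 4 of 5 seeds at the calibrated
defaults) and which is most anisotropic (raster line integration).

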