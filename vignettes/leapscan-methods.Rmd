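---
title: "Interleaved scanning, charge dissipation and image QC: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interleaved scanning, charge dissipation and image QC: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(leapscan)
```

## The problem

Secondary-electron SEM imaging of insulating specimens — vitrified cells and
tissue above all — deposits charge faster than the specimen can drain it.
Accumulated charge distorts the detected signal: dark streaks along the fast
scan direction, dark or bright patches around lipid droplets, myelin stacks
and degradative compartments, and a general loss of interpretable contrast.
Because the artefacts depend on *when* each pixel's neighbourhood was last
irradiated, the scan pattern itself is a control knob: an interleaved
("leapfrog") pattern that skips pixels and returns to them much later gives
deposited charge time to dissipate before a neighbour is visited.

`leapscan` provides the full desk-scale toolchain around this idea:

1. **scan patterns** — timed raster (line/frame integration) and interleaved
   visit sequences, validated, exported as the coordinate text files consumed
   by programmable scan engines;
2. **phantoms** — synthetic specimen maps with the structures that act as
   charging centres;
3. **charge simulation** — deposition, isotropic dissipation, and
   charge-attenuated detection under any pattern;
4. **frame processing** — 8-bit conversion, flyback cropping, patch-based
   alignment, integration, mean filtering;
5. **quality metrics** — histogram charging metric, flyback-extent
   estimation, object counting and shape complexity, streak anisotropy;
6. **statistics** — quadrant count ratio and condition comparisons;
7. **orchestration** — the in-silico strategy-comparison experiment.

## Scan patterns and timing

All patterns are tables of visits `(x, y, t_start_ns)` with 0-based
coordinates, origin top-left, x the fast axis. The raster scan proceeds
row-major; within a row the interval between visits is the dwell time, and
between rows it is `nx * dwell`. Line integration repeats each line `R` times
consecutively (with a settling "flyback" delay before every pass — the
instrument's built-in line mode does not allow disabling it), frame
integration repeats whole frames with no flyback delay.

The interleaved pattern visits the sub-lattice of stride `skip + 1`
(skipping `skip` pixels), then the remaining sub-lattice offsets until every
pixel has been visited once per repetition. A skip of 2 in both axes is the
default. Two open choices were fixed here:

* **Offset order.** After the `(0,0)` pass the remaining offsets are
  enumerated x-major: `(1,0), (2,0), (0,1), …`. The temporal order of the
  nine passes is not uniquely determined by the published schematic (a
  colour ramp); x-major was chosen for symmetry with the raster convention.
  Any fixed order gives the same minimum-neighbour-interval guarantee.
* **Coordinate base.** Exported coordinate files are 0-based, one `x y` pair
  per line, one frame only; repetitions and dwell travel in an optional `#`
  header, since some scan engines reject comment lines (`header = FALSE`
  drops it).

The quantity the pattern engineering targets is
`min_neighbour_interval()`: the minimal time between visits of any two
pixels at Chebyshev distance ≤ r. For a raster frame scan with r = 1 it is
exactly the dwell time; skip-2 interleaving raises it by orders of magnitude
(neighbours always land in different sub-lattice passes).

Electron fluence is `current · dwell · reps / (e · pixel_area)`. At 6.3 pA,
6.34 nm pixels, the three canonical schedules — 100 ns × 100, 500 ns × 20,
1000 ns × 10 — each deliver ≈ 0.1 e⁻/Å², and `compute_fluence()` multiplies
`dwell * reps` before anything else so the three give bit-identical values.

## The charge model

The dissipation hypothesis — charge spreads uniformly in all directions from
the point of deposition and drains to ground at a material-dependent rate —
is formalised as linear isotropic diffusion plus a per-pixel exponential
leak:

$$\frac{\partial C}{\partial t} = D \,\nabla^2 C \;-\; \frac{C}{\tau(x,y)},$$

integrated with explicit 5-point-stencil sub-steps (`D·dt ≤ 0.25 px²`,
zero-flux boundaries) interleaved with the exact proportional leak. With
`tau = Inf` total charge is conserved to machine precision, which the test
suite asserts.

Each visit deposits `q0 = current · dwell / e` electrons at the visited
pixel — point deposition, because the 2 nm FWHM probe is much narrower than
the 6.34 nm pixel. Detection returns

$$s = \mathrm{gain}\cdot \mathrm{yield}(x,y)\cdot e^{-\alpha \tilde C(x,y)}
      + \mathrm{offset} + \varepsilon,$$

where \(\tilde C\) is the charge field smoothed with a Gaussian of width
`sigma_local_px`: accumulated charge *darkens* the image (the dark-streak
sign convention; bright artefacts are available through an optional
discharge model, off by default, which emits a spike and resets local charge
when \(\tilde C\) crosses a threshold).

Dissipation is applied in batches of `batch_visits` visits (default: one
scan line) with exact elapsed-time accounting. This is purely a numerical
economy; the suite checks that per-visit updates (`batch_visits = 1`) and
per-line updates change the downstream charging metric by less than 5 %.

### Calibration constants and what they mean

The source material specifies *which* structures charge and *that*
dissipation is isotropic, but no material constants. The defaults were
chosen once, on physical-timescale arguments, so that the simulator
reproduces the qualitative artefact taxonomy at the package's desk scale
(256 × 256 px, 100 ns dwell, 100 repetitions; frame time 6.6 ms, line-pass
time 25.6 µs, sub-lattice pass period 0.73 ms):

* `tau_background_ns = 1e5` (median), with **log-normal heterogeneity**
  (`tau_grain_sdlog = 1`, correlation 12 px). A vitrified cytoplasmic matrix
  is not electrically uniform; patches whose leak time rivals the raster
  *window-crossing* time (~0.5 ms) are what produce the blotchy dark
  mottling of raster frame integration, because a raster delivers a patch's
  whole dose while the patch still holds its charge, whereas interleaving
  spreads that dose across the frame and lets most of it drain between
  passes.
* `disc_tau_factor = 100` (lipid droplets ≈ 10 ms) — droplets hold charge
  across frames under every strategy; they are the persistent charging
  centres with halos.
* `membrane_tau_factor = 10` (≈ 1 ms) — membranes shadow locally under
  raster, much less under interleaving.
* `D_px2_per_ns = 5e-6` — lateral spread of a few pixels over a sub-lattice
  pass period, negligible within a raster line; dissipation between
  neighbour revisits is dominated by the leak at these scales.
* `alpha = 0.5` per electron scales how strongly local charge attenuates
  signal; at this value the worst line-integration accumulation darkens
  without fully saturating to black (saturation makes the histogram
  bimodal and the mean uninformative).
* `sigma_local_px = 8` — the radius over which accumulated charge influences
  detection (surface-potential reach). Line integration concentrates charge
  into a ridge along the current line; a window wider than the ridge is what
  renders that ridge as line-correlated darkening, i.e. the characteristic
  streaks in the fast scanning direction.
* `noise_std = 150`, `detector_gain = 12000`, `detector_offset = 2000` — a
  mid-range SNR mapping into the signed 16-bit counts used by the
  acquisition format.

These are calibration constants of the simulator, not measured material
properties; the package treats them as the fixed study conditions of its
in-silico experiment.

## The processing pipeline

`convert_to_uint8()` shifts and rescales with the minimum and maximum taken
over the **whole stack** — per-frame ranges would destroy the inter-frame
comparability the histogram metric relies on; constant input maps to 0.
`crop_flyback()` removes the distorted left margin (default 64 px, the
estimated extent when no settling delay is applied); `center_crop()` takes
the centred analysis region (ties toward top-left), reproducing the
2048 → crop 64 → centred 1920 acquisition pipeline.

`align_frames()` reimplements the standard patch-based drift-correction
contract (5 × 5 patches, 20 % overlap): per-patch translation by
cross-correlation against the first frame (running-mean reference by flag),
subpixel refinement by upsampled cross-correlation (factor 10), bilinear
interpolation of patch shifts to a per-pixel field, reflective resampling.
The reference frame is never altered; integer planted shifts are recovered
exactly in the noise-free case, and `patch_grid = c(1, 1)` degenerates to
whole-frame rigid alignment.

## Quality metrics

* **Histogram charging metric.** An artefact-free 8-bit acquisition has a
  histogram centred near the mid-range grey level 127; charge-induced
  extremes skew it. `histogram_mean()` reports the mean and
  `|mean − 127|`.
* **Flyback extent.** Per frame: Gaussian blur (σ = 7 px), 3 × 3 Sobel
  magnitude, binarisation (automatic bimodal/Otsu threshold by default — the
  threshold value itself is not specified by the method's description, so an
  automatic one was chosen with a fixed-value override), rightmost
  foreground column inside a left-edge ROI. Frames are aggregated by the
  **median** rather than a fitted-normal mean: the estimator's known failure
  mode is frames whose edge detection finds nothing or fires on noise, and
  the median shrugs these off (a mean option exists). The σ = 7 smoothing
  systematically extends the detected edge a few pixels to the right, which
  is why recovery of a planted band of width w is asserted within
  `[w − 2, w + 14]`.
* **Complexity score.** Per segmented component, perimeter² / area, summed
  over components. Perimeter is the *crack-edge* length (count of
  foreground/background pixel edges, image border included), which makes the
  score exactly 16 for any axis-aligned square and hence analytically
  testable; components are 8-connected.
* **Anisotropy index.** Mean |vertical neighbour difference| over mean
  |horizontal neighbour difference|: ≈ 1 for isotropic texture, > 1 for
  horizontal streaking. This quantifies "streaks in the fast scanning
  direction" without any segmentation.

## The in-silico strategy comparison

`run_strategy_comparison()` crosses strategies (raster-LI, raster-FI,
interleaved-FI skip 2) with fluence-matched schedules and seeds on a cell
phantom; each condition is simulated, converted, cropped, aligned (frame
integration only), integrated and scored. Object counts and complexity are
normalised to the interleaved-FI condition of the same schedule and seed;
the per-seed verdict records which strategy's histogram mean lands closest
to 127 and which is most anisotropic.

At the calibrated defaults the experiment reproduces the qualitative
ordering: interleaved frame integration has the smallest charging deviation,
raster line integration the largest anisotropy index, in at least 4 of 5
seeds at 256 × 256. The problem size was chosen as the package's desk-scale
default: large enough for ~20 px structures and 5 × 5 patch alignment,
small enough that the full 15-condition experiment runs on a single CPU in
minutes. Schedules are scaled to small grids by preserving dwell and
repetitions (per-pixel fluence unchanged); only the field of view shrinks.

### What the phantom does and does not emulate

The `cell` preset reproduces the *statistical* features that drive charging
contrast — high-yield poorly-draining discs, thin membranes, textured yield,
electrically heterogeneous background — with reproducible placement from a
seed. It does not model 3-D structure, FIB curtaining, energy-dependent
yield, detector physics, or real material constants. A green strategy
ordering on the phantom therefore demonstrates that the *mechanism* (revisit
delay vs. dissipation time) produces the documented artefact taxonomy, not
that any particular real specimen will show a given numeric improvement.

## Numerical choices and degenerate inputs

* Charge evolution sub-steps keep `D·dt_sub ≤ 0.25 px²` (explicit-stencil
  stability); leak factors are cached per distinct `dt`.
* 8-bit conversion of a constant stack returns 0 (the rescale is undefined;
  0 is the conventional choice).
* `center_crop` ties break toward the top-left.
* On-median points are excluded from the quadrant count ratio (the standard
  definition; medians rather than means make the statistic invariant under
  monotone axis transforms). Pooled-variance t-tests are the default with
  Welch by flag.
* Pattern text import reports the first malformed or out-of-bounds line by
  number.
* `estimate_flyback_extent` returns 0 with a warning flag when no frame
  yields a detectable edge.

## Known limitations

* The charge model is two-dimensional and linear; real charging includes
  depth-dependent deposition, field-assisted drift and nonlinear breakdown.
  The discharge spike model is one plausible mechanism for bright artefacts
  and is off by default.
* Drift is integer-pixel and per-frame; continuous intra-frame drift is not
  modelled.
* The simulator's 16-bit pipeline does not model detector saturation beyond
  clipping (flagged).
* `peak_charge_trace()` smooths the full field at every batch update and is
  intended for desk-scale grids.
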