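---
title: "Simulating and quantifying osteoclastic resorption traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying osteoclastic resorption traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteotrace)
```

## The biological picture

Osteoclasts are multinucleated cells that resorb mineralized matrix. On a
substrate slice they leave two kinds of traces: **pits** — round or elliptical
cavities from a stationary cell whose actin ring seals a closed, roughly
circular region — and **trails** — elongated cavities left by a cell that
resorbs while advancing across the surface. Confocal imaging of
trail-forming cells shows a *crescent-shaped* actin ring: one side attaches
to intact surface just ahead of the trail margin, the other to the wall
inside the trail, sealing a narrow band of 3–21 µm. The cell degrades that
band as a thin layer from the surface down to its working depth, then steps
forward and repeats. A trail is therefore not a furrow ploughed horizontally
but the concatenation of many vertical, layer-by-layer excavation cycles.

Two further observations anchor the quantitative model:

* **Donor-specific depth plateau.** For every donor, pit depth grows with
  event size only up to a maximum `D_max` (32–68 µm across donors and
  replicate experiments); beyond it, events grow in area alone.
* **Material-dependent initiation, material-independent execution.** Dentin
  carries roughly 7× more resorption events per cm² and ~11× more resorbed
  area than bone, while per-event geometry (mean area, length, width and
  their histogram shapes) is comparable on both materials.

`osteotrace` turns this into a generative, testable artifact: a seeded
agent-based simulator writing resorption traces into digital height maps,
plus the histomorphometric pipeline that measures them back, so the printed
summary statistics can be reproduced as round-trip parameter-recovery
experiments on synthetic surfaces.

## Substrate surfaces

A surface is a `height_map`: a rectangular grid of heights in µm (0 =
pristine plane, negative = resorbed), isotropic `pixel_size`. Roughness
texture is synthesized by smoothing white Gaussian noise with an isotropic
Gaussian kernel (`correlation_length`, default 20 µm) and rescaling so the
mean row-wise Ra matches the profilometry target of the chosen substrate
condition (bone 6.27 / 1.05 µm, dentin 15.14 / 3.75 µm for rough/smooth).
One scale factor can pin only one moment; Ra is matched exactly and Rq is
emergent, with `Rq >= Ra` guaranteed on any profile. The published values
give no spatial correlation structure, so `correlation_length` is a free
parameter; 20 µm puts the texture wavelength between the pixel scale and the
event scale, which is what machined/polished mineralized slices look like
under a profilometer at these Ra values.

```{r}
map <- make_flat_map(400, 400, pixel_size = 1)
rough <- synthesize_roughness(map, ra_target = 6.27, seed = 1)
surface_roughness(rough)
```

Because event detection works on the *pristine-minus-final difference*, not
on absolute height, the texture never creates false events and never hides
true ones; it matters for realism of the surfaces, not for the measurement.

## The resorption simulator

Events arrive as a homogeneous Poisson process with the preset intensity
(449/cm² rough bone, 3,134/cm² rough dentin — the printed counts), uniform
positions, and Bernoulli pit/trail types. The published analyses pooled pits
and trails, so only pooled moments constrain the generator; the trail
fraction is a free parameter, default 0.5.

**Pits** are stamped as rotated ellipses with vertical walls, excavated to
the event's target depth below the local pristine surface.

**Trails** are decomposed into cycles. The drawn overall length `L` (caps
included) leaves a centerline of `L − W`; it is split into equal steps
aimed at ~12 µm and clamped to the mechanistic 3–21 µm bound — step lengths
outside that range are rejected as arguments, since they correspond to no
observable actin-ring configuration. Each cycle excavates its sealed band
and the rear cap to full depth (completing the previous cycle's in-progress
layer, which keeps the floor continuous) and leaves a linearly ramped front
cap — the layer still being resorbed. For an isolated cycle the removed
volume is `s·w·d·f` with the declared shape factor `f(s, w) = 1 + πw/(6s)`,
validated against a voxel-sum oracle in the tests.

Cycle headings follow a persistent random walk with wrapped-normal
increments of sd 5°. Turning statistics are unpublished and explicitly free;
we chose a gently curved walk because (a) that is what trail micrographs
look like, and (b) the width of a strongly curved trail, as read off a
minimum-area rotated rectangle, is no longer the excavation width — at 15°
per cycle the readout exceeds the true transverse width by ~30%, which would
make any width calibration meaningless.

**Depth.** Each event's target depth follows a saturating depth–area law,

`depth = ceiling · (1 − exp(−area / a0))`,

with the ceiling equal to the donor's `D_max` (optionally jittered downward
via `D_max_sd`, default 0) and `a0 = 150 µm²`. This replaces an
area-independent truncated-normal draw deliberately: the published
depth/area diagrams show depth *rising with area* and then plateauing at the
donor ceiling, and an area-independent depth cannot reproduce that
relationship (nor its plateau estimator). `a0` is a free parameter set so
that events of typical size (hundreds of µm²) already resorb near the
plateau, as observed. Overlapping events take the pointwise minimum height —
material is only ever removed — and merging into single measured events is
left to the quantifier, as in real image analysis.

```{r}
run <- run_simulation(
  substrate_preset("bone_rough"), donor_profile("donor1_expt1", D_max = 35),
  area_cm2 = 0.005, seed = 7
)
run
tidy(run)[1:3, c("event_id", "type", "length_um", "width_um", "depth_um")]
```

## Calibrating per-event geometry

Per-event planform geometry (length `L`, width `W`) uses correlated
log-normal marginals: strictly positive, right-skewed, with a long length
tail reaching beyond 300 µm as in the published histograms. Published
moments are means with SEM across donors only, so the coefficients of
variation are free (default 0.6). Marginal means are matched in closed form;
the remaining degree of freedom, the log-scale correlation ρ, is solved
analytically so the pooled mean *area* matches its target:
for pits (ellipses) `E[A] = (π/4)·E[LW]`, for trails (stadium bands)
`E[A] = E[LW] − (1 − π/4)·E[W²]`, and `E[LW] = E[L]E[W]·exp(ρ σ_L σ_W)`.
A positive L–W correlation is exactly what reconciles a mean area (580 µm²
on bone) that exceeds shape-factor × mean L × mean W (~440 µm²). A
Monte-Carlo check (n = 10⁵) verifies all three pooled moments to 2%, and an
infeasible target triple (one that would need |ρ| ≥ 1) raises a calibration
error with a diagnostic.

```{r}
calibrate_geometry(580, 53, 9.5, n_mc = 1e4)
```

## The histomorphometric pipeline

Quantification mirrors the published measurement procedure on cleaned,
imaged slices:

1. **Detection** — a pixel is resorbed when excavation exceeds
   `depth_threshold` (default 0.5 µm: far above numerical noise, far below
   event depths). Connected components (8-connectivity by default) are
   events — "an area of resorption surrounded by a margin of unresorbed
   material"; components under `min_event_area` (20 µm²) are discarded.
2. **Per-event measurement** — area from pixel counts; length and width as
   the longer/shorter side of the minimum-area rotated bounding rectangle
   (one pixel is added to each side so pixel footprints, not centers, are
   covered; the axis-aligned 10 µm square then measures exactly 10 µm).
   Width-by-rectangle was chosen over Feret diameters because trail "width"
   is clearly the transverse dimension. Maximum depth is read directly and
   also quantized as `z_step × ceiling(depth / z_step)` (default 1 µm),
   emulating depth-by-slice-count from confocal z-stacks.
3. **Summaries** — resorbed area (%), events/cm², and mean ± SEM of event
   area, length and width. Edge-touching events are flagged and included by
   default (whole-slice imaging); `include_edge = FALSE` drops them.

Cohort statistics follow the published reporting: per-donor summaries first,
then mean and SEM across donors (`summarize_cohort()`); Welch's t-test for
substrate comparisons (donor variances differ visibly); histogram bins fixed
to the published layout, half-open with the final bin open-ended; the
overlapping "300–330, >300" caption bins are resolved as [300, 330) and
[330, ∞). The plateau estimator reads the donor ceiling as the mean maximum
depth of events above the 0.75 area quantile — exactly the "large events
have saturated" observation.

## Numerical choices

* **Pixel size** defaults to 1 µm/px; trail widths of ~9–11 µm then span
  ~10 px. For geometry-recovery experiments the package uses 1/3 µm/px:
  the rectangle readout of a ~10 µm width carries an irreducible ±1 px
  discretization term, which at 1 µm/px is already the size of the
  recovery tolerance. Geometry-recovery runs also skip the roughness
  texture — it cancels identically in difference-based detection, so it
  cannot affect any measured quantity, and skipping the 10⁸-point random
  field frees most of the runtime.
* **Determinism** — every stochastic function takes a seed and restores the
  RNG state; identical (preset, donor, seed) gives bit-identical maps.
* **Degenerate inputs** — empty profiles, zero-area maps, zero-depth
  requests, footprints outside the map and sub-minimum components are
  rejected or no-ops with warnings, as documented per function.

## What the synthetic world does and does not establish

The generator emulates: Poisson event placement at printed intensities,
pooled pit/trail geometry calibrated to printed moments, donor depth
plateaus spanning the printed 32–68 µm, substrate roughness at printed Ra,
and the 16-donor cohort structure with inter-donor variability. It does not
emulate optical imaging, cell biology (fusion, vesicle traffic, actin
dynamics), time resolution, or any spatial interaction between events —
placement is independent by specification.

That last simplification has one measurable consequence worth knowing. At
dentin's printed intensity (3,134 events/cm², ~2% coverage), a few percent
of *measured* events are composites of independently placed trails that
cross; the minimum-area rectangle width of such an X-shaped composite is
several times the trail width, so the pooled mean width at full dentin
density reads high relative to the calibrated per-event width. At bone
density (449/cm²) the effect is negligible. A green geometry round-trip
therefore establishes quantifier fidelity per event and at moderate
densities; it does not establish that independently placed events reproduce
every pooled moment at arbitrary density — real osteoclasts, which do not
re-resorb excavated trails, are not independent placers.

## Known limitations

* Trail turning, trail:pit ratio, cycle dwell time and within-donor
  event-size spread are unpublished; all are free parameters with documented
  defaults.
* Smooth-surface intensities were not printed (only "no significant
  difference … a trend to higher levels on rough"); smooth presets use
  0.75× the rough intensity of the same material and feed no acceptance
  comparison.
* Substrate thickness is not modeled; surfaces are effectively semi-infinite
  (maximum simulated depth ≪ 300 µm slice thickness).
* The 300 µm-scale correlation structure of real surface roughness, and
  profilometer optics, are out of scope.
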