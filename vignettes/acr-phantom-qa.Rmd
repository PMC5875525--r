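---
title: "Phantom-based image QA for CT and CBCT: models, metrics and tolerance derivation"
author: "acrqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based image QA for CT and CBCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrqa)
```

## The problem

Image-guided radiotherapy relies on on-board cone-beam CT for patient
setup, and treatment planning on a fan-beam CT simulator. Both imaging
chains drift: tube aging, recalibration and mechanical changes shift
Hounsfield units, raise noise, and degrade uniformity and resolution.
Absolute accreditation limits are deliberately loose, so a machine can
deteriorate substantially while still "passing". The programme this
package implements instead tracks every image-quality metric against a
baseline and flags statistically surprising excursions — an early-warning
system rather than a pass/fail gate.

One phantom serves both machine types: the ACR CT accreditation phantom,
a 20 cm diameter cylinder of four 4 cm modules. Module 1 carries five
density plugs (air, polyethylene, water, acrylic, bone) and two wire
ramps; module 2 a 25 mm low-contrast cylinder and four 6 mm rods at 0.6 %
contrast; module 3 a uniform section with two distance BBs at a nominal
100.0 mm separation; module 4 bar patterns from 4 to 12 lp/cm. Four
peripheral alignment BBs mark the module-1 and module-4 centre planes.

## Phantom model and coordinate conventions

`acr_geometry()` is the single description shared by the analyzer and the
synthetic renderer. In-plane coordinates are mm relative to the phantom
axis with y towards 12 o'clock; z runs along the axis with the module-1
centre plane at 0, so module centre planes sit at 0, 40, 80, 120 mm.

The published phantom description fixes the diameter, module lengths, the
100.0 mm BB separation and the ROI areas (≈200 mm² for HU accuracy,
≈100 mm² for low contrast, ≈400 mm² for uniformity), but not the exact
in-plane coordinates of plugs, rods and BBs. Those are configuration with
defaults that place the plugs at 12/3/6/9 o'clock plus the centre, the
alignment BBs at radius 90 mm, and the rods on a 50 mm circle — the
metrics only require that renderer and analyzer agree, which a shared
geometry object guarantees. Accepted per-plug HU ranges default to values
per ACR CT Accreditation Program documentation and are plain,
documented configuration (`inst/extdata/acr_limits.yaml` holds the
absolute limits; the geometry serializes to YAML/JSON via
`write_geometry()`).

Two placements deserve a note:

* **Uniformity edge ROIs.** The edge ROIs sit at the four cardinal
  positions with their *outer boundary* 1 cm inside the phantom edge,
  i.e. centres at `phantom_radius − 10 − roi_radius ≈ 78.7 mm`. Placing
  the centres themselves 1 cm inside the edge would push a 400 mm² ROI
  outside the phantom.
* **Bar-pattern ROIs** are kept at 0.3 × the pattern size, well inside
  each pattern square, so PSF bleed across the pattern boundary cannot
  masquerade as modulation.

Pixel membership in an ROI uses the pixel-centre-in-circle rule: simple,
deterministic, and convergent — the rasterized area is within 5 % of
nominal at spacings ≤ 1 mm and converges as spacing → 0 (tested at 1.0,
0.5, 0.25 mm against a brute-force pixel count).

## Localization

Clinical practice aligns the phantom with room lasers and re-acquires if
it looks misaligned, and commercial analysis tools are known to fail at
exactly one step on noisy CBCT images: detecting the BBs. This package
automates localization with deliberately simple, absolute-HU rules and
explicit failure modes:

* **Body finding:** largest connected region above −300 HU per slice
  (holes such as the air plug are filled before the centroid is taken —
  an unfilled air plug biases the centre by ~1 mm). The −300/+800
  thresholds are configuration; their defaults sit in the wide margins
  between air (≈−1000), water (≈0), bone (<≈1000) and metal.
* **BB detection:** connected components above +800 HU with area below a
  small-object cap, matched to expected positions within a 5 mm gate.
  Centroids are refined to sub-pixel over a 3 mm window using the
  below-threshold skirt of the blurred BB; the thresholded component
  alone quantizes the position to the pixel grid (~0.2 mm bias at
  typical spacings), while the refined estimate is unbiased to
  <0.1 mm under 20 HU noise.
* **Roll:** the mean angular offset of matched alignment BBs from their
  nominal clock positions. ROI templates are rotated accordingly; rolls
  beyond a 5° guard are flagged as probable setup errors rather than
  silently corrected. Pitch/yaw are not corrected (the clinical response
  is re-setup, not software warping); they surface as flags.
* **Slice assignment:** modules 1/4 take the slices with the most visible
  alignment BBs, module 3 the slice containing both distance BBs, module
  2 the slice nearest its mid-plane. "Visible" means detected above
  threshold — a manual window/level judgement has no automated
  equivalent, so detection is the documented surrogate. If BBs are missing entirely (a documented CBCT
  failure mode), assignment falls back to nominal 40 mm offsets from the
  detected longitudinal mid-plane and the session is flagged, not
  aborted. Coverage shorter than ~3.5 module lengths is an error:
  no defensible panel can be measured.

Localization is invariant to global HU offsets that leave the threshold
ordering intact (tested at ±100 HU), because all thresholds are absolute.

## The measurement panel

* **HU accuracy** — one ≈200 mm² ROI per plug on the module-1 slice; each
  mean is checked against its accepted range and, in evaluation, against
  baseline.
* **CNR** — `|ROI_mean − BKG_mean| / BKG_SD`, with the water plug of the
  same slice as background for the polyethylene and acrylic plugs (these
  two sit ~95–120 HU from water, a reproducible "low-contrast" pair that
  still works on CBCT where the true low-contrast rods vanish). A zero
  background SD (only possible on noiseless synthetic input) is reported
  not-evaluable rather than infinite.
* **Noise** — `100 × ROI_SD / (ROI_mean + 1000)`, in percent. The +1000
  rescale avoids near-zero denominators for water-like plugs; it also
  makes the statistic deliberately *not* offset-invariant, which the test
  suite pins explicitly so the formula cannot regress to the unshifted
  variant.
* **Uniformity** — centre ROI mean and four ≈400 mm² edge ROI means; the
  reported value is `max |edge − centre|`. The centre mean is checked
  separately against its absolute limit. There is no universally printed
  formula for a scalar uniformity "value"; this package adopts the
  maximum edge-centre difference, the quantity the accreditation
  criterion ("<5 HU for all four edge positions") actually constrains.
  The centre-region limit is configurable as ±7 HU (default) or ±5 HU,
  both of which appear in accreditation material.
* **In-plane distance** — the Euclidean distance between the two sub-pixel
  BB centroids, against nominal 100.0 mm.
* **Slice thickness** — the wire-ramp count method: a wire is visible
  when its integrated contrast over a 1.4 mm capture disc exceeds half
  the maximum wire contrast; thickness = pitch × mean visible count over
  both ramps (pitch default 0.5 mm z per wire; the pitch is a geometry
  entry because it varies between phantom revisions). Integrated mass is
  used
  rather than a peak sample because mass is conserved under both the PSF
  and pixel discretization, while peak heights fluctuate by tens of
  percent at coarse spacings.
* **Low contrast** — CNR of the 25 mm cylinder against adjacent
  background, and rod visibility: a rod is visible when its ROI mean
  exceeds the local background (two flanking ROIs at the same radius) by
  more than `k ×` background SD, `k = 1` by default, mirroring the
  CNR ≥ 1.0 criterion. The SD comes from the larger adjacent-background
  ROI — the noise field is stationary, and the larger sample roughly
  halves the threshold's estimator variance. A count of 0 is a valid
  result and is exactly what CBCT-like noise produces.
* **High contrast** — the modulation statistic of each bar pattern is the
  HU standard deviation in its ROI; scanning coarse → fine, a pattern
  resolves while its statistic exceeds `f = 0.4` of the coarsest
  pattern's, and the scan stops at the first failure, making the score
  monotone by construction. If the coarsest pattern's noise-corrected
  modulation is below 20 HU the score is not-evaluable (a PSF much wider
  than the 4 lp/cm bars). These numeric surrogates replace a human
  window/level reading; both constants are configurable.
* **Artifact avoidance** — manual practice places ROIs away from CBCT
  artifacts by eye. Here an optional artifact mask excludes pixels;
  if >30 % of an ROI is masked, the ROI is re-seated by searching ±30° of
  angular offset about the phantom axis for the placement minimizing the
  masked fraction, and the result is flagged.

`run_session()` runs localization and the full panel, never aborting on a
single failed metric: each metric is a value or an explicit
not-evaluable with a reason, and a localization failure yields a session
with every metric not-evaluable.

## Baselines, tolerances, trending

The statistical layer assumes quarter-to-quarter fluctuation of each
metric is characterized by its standard deviation. Tolerances are

> 2 × the maximum SD over all machines, protocols and baseline segments,

so a single result outside the band is ~5 % likely under normality.
Normality is assumed, not tested — a documented simplification, not an
enforced check. Design choices:

* **Sample SD** (n−1): the standard choice for the small samples of a
  quarterly programme, fixed here as a convention.
* **Rounding, half away from zero:** plug-HU bands to the nearest HU
  (2 × 3.1 = 6.2 → 6, 2 × 7.9 = 15.8 → 16), CNR to one decimal, noise to
  two decimals, uniformity to one decimal (its CT band, 2 × 0.7 = 1.4 HU,
  is quoted at sub-HU precision).
* **Boundary rule:** a deviation exactly equal to the band passes; only
  results *outside* warrant action.
* **Baselines:** first session of a segment by default, or the mean of
  the first k sessions (the "preliminary" mode used for a programme's
  opening quarters). Baselines are reset — a new segment begins —
  at major maintenance, recalibration or tube replacement, and SD groups
  never straddle a reset.
* **Degenerate histories** (all values identical) produce a tolerance of
  0 with an explicit flag rather than silently passing everything;
  groups with fewer than two records are skipped with a reason.

The package ships reference summaries from a two-year quarterly programme
(one CT simulator, five protocols; three CBCT systems, five protocols
each) as plain CSV, and `tolerances_ct()` / `tolerances_cbct()` run the
derivation on them at load time — the bands are computed, not stored.
One band is deliberately not derived: applying the rule to the bone
plug's recorded maximum SD of 29.1 HU would give a ±58 HU band, far
wider than any band a monitoring programme would run with (the bone plug
is the most sensitive to beam-energy drift, and its spread in the
reference data reflects recalibration history rather than stable
variation). The package therefore ships no bone default;
`tolerances_cbct(bone_bound = ...)` makes that choice explicit
configuration.

`trend_report()` and its `plot()` method render the classic
metric-over-time chart: per-segment means, ±1 SD bands, and vertical
markers at baseline resets.

## The synthetic phantom

`render_phantom()` draws the ideal HU map (plugs, rods, ramps, BBs, bar
patterns at their geometric positions, with phantom offset and roll),
convolves with a Gaussian PSF, adds artifact fields, then adds i.i.d.
Gaussian noise in HU, seeded and bit-reproducible. Specific modelling
choices:

* **Noise after blur.** The stated preset noise levels are then exactly
  the measured ROI SDs: the CT-like preset (σ = 4 HU) yields plug noise
  ≈ 0.44 % and polyethylene CNR ≈ 24; the CBCT-like preset (σ = 30 HU,
  cupping 20 HU) yields ≈ 3.3 % and CNR ≈ 3 — the magnitude scales of
  real fan-beam and cone-beam systems.
* **Cupping** is a radial parabola whose amplitude is defined as the
  depression at the axis *relative to the uniformity edge-ROI radius*
  (the parabola crosses zero there). With that normalization the
  measured uniformity equals the injected amplitude up to ROI-averaging
  terms of ~1 %, which is what makes "uniformity tracks cupping within
  15 %" a meaningful recovery test.
* **Crescent** is a localized annular arc of configurable amplitude and
  position — enough structure to exercise the mask/re-seat machinery.
* **Wire ramps:** wires on a 0.5 mm z-pitch grid offset half a pitch from
  the module-1 centre plane; a wire renders in a slice iff its z falls in
  the slice's half-open thickness window, so the visible count is exactly
  thickness/pitch for thicknesses that are grid multiples (2.5 mm → 5,
  3.0 mm → 6).
* **Sub-pixel features** (BBs, wires) are rendered with 4 × 4
  supersampled area weighting so their mass — and hence blurred peak —
  does not depend on where the centre falls within a pixel.
* **Bar patterns** are square waves synthesized from their Fourier
  harmonics with everything above the pixel-grid Nyquist dropped, as a
  reconstruction kernel would. Naive point sampling aliases fine
  patterns into low-frequency moiré that survives blurring and scores as
  spurious resolution; bandlimited synthesis makes under-sampled patterns
  flatten to their mean instead. The test oracle for the high-contrast
  score is an independent 1-D convolution of the continuous square wave
  with the PSF.

What the simulator does **not** model: correlated/streak noise, scatter
and beam-hardening physics, bowtie/kVp effects, projection-domain
reconstruction, non-axial acquisitions. Passing tests therefore
demonstrate that the analysis pipeline is correct and self-consistent
under a controlled image model — not that any particular scanner meets
tolerance. Protocol parameters (kVp, mAs, fan type) are session metadata
labels, never simulated physics.

`simulate_longitudinal()` applies per-session drift, step events
(optionally triggering a baseline reset) and truth jitter to the plug
HUs, renders one series per session, and logs every injected truth so
recovery can be scored end-to-end: a +25 HU acrylic step against the
derived ±12 HU band is flagged at exactly the step session, and a
drift-free eight-session programme produces no flags.

## Numerical choices and problem sizes

Default rendering is a 384 × 384 matrix over a 250 mm field of view
(≈0.65 mm pixels), 2.5 mm slices, the matrix size typical of linac CBCT.
The test suite and acceptance script run most property checks at 256²
(and 512² where bar patterns beyond 7 lp/cm must be representable),
20 noise realizations per recovery statistic, and single-module
z-coverage where only one module's metric is under test — sizes chosen to
keep the full suite in the low minutes while leaving every estimator's
error an order of magnitude inside its asserted bound. Degenerate inputs
are contracts, not crashes: noiseless input makes CNR not-evaluable
(zero background SD), an all-air volume raises "phantom not found", a
short volume raises "incomplete phantom coverage", and heavy blur makes
the high-contrast score not-evaluable.

## Known limitations

* The DICOM layer supports exactly what the package writes: uncompressed
  explicit-VR little-endian axial CT series. Compressed transfer
  syntaxes and non-axial reformats are rejected by design.
* Rod visibility and bar resolvability are numeric surrogates for a
  human reading; their constants (k = 1.0, f = 0.4) were fixed once so
  the simulator reproduces the qualitative CT-vs-CBCT behaviour, and are
  configuration, not truth.
* The SPC layer implements the 2 × max-SD band, not full
  individual/moving-range control charts, and applies no
  multiple-testing correction across the panel; with ~15 bands per
  session, occasional isolated flags are expected behaviour.
* HU values measured here must not be converted to electron density for
  dose calculation: one phantom orientation, one slice, and a
  head-sized cylinder are inadequate for that purpose.
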