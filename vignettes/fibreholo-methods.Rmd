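---
title: "Methods: de-pixelation, multi-source resolution enhancement and numerical refocusing for fiber-bundle inline holography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiber-bundle inline holography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The imaging problem

A coherent fiber imaging bundle relays an intensity pattern from its distal
facet to a camera through tens of thousands of individual cores (roughly
30,000 cores in a 600 µm active area at ~3 µm core-to-core spacing for the
high-density bundles this package targets). Illuminating a semi-transparent
sample with a partially coherent source a short distance (0.1–0.65 mm) in
front of the facet forms an inline hologram on the facet: the interference
of light scattered by the sample with the unscattered beam. The bundle
transmits the intensity of that hologram — pixelated by the core mosaic —
and numerical refocusing can then recover an image at the sample plane.

Two artefacts dominate. First, the core mosaic superimposes a honeycomb
pattern and limits resolution to roughly twice the core spacing. Second,
inline holography's twin image: without phase retrieval the refocused
amplitude always contains an out-of-focus conjugate haze. This package
removes the mosaic, pushes the sampling limit back by a factor of
approximately two using holograms shifted between laterally offset
illumination fibers, and refocuses; the twin image is out of scope and
remains visible in refocused output, as it does in any non-iterative
inline-holography pipeline.

## Core detection

`find_cores()` locates every core in a blank calibration frame by a
morphological recipe: Gaussian smoothing (sigma = 1/5 of the estimated core
spacing, suppressing residual intra-core structure), grayscale dilation with
a 3 px disc, subtraction (local maxima now sit at exactly zero because
dilation never changes the value of a maximum), thresholding to keep the
(near-)maxima, an optional merge dilation with a disc 1/3 of the core
spacing in diameter, unweighted centroids of the connected regions, and a
radius cut at the bundle boundary.

Two numerical choices matter at the ~5 camera-pixels-per-spacing sampling
this geometry produces:

* **Structuring elements** are discrete discs with diameters rounded to the
  *nearest* odd pixel count, and any dilation whose element would be smaller
  than 3 px is skipped. At 5 px spacing the merge element computes to
  ~1.7 px; forcing it up to 3 px fuses the maxima of adjacent cores on
  jittered mosaics and badly degrades recall, so the no-op is the correct
  discretisation (the test suite holds recall above 99% on a synthetic
  mosaic at this sampling).
* **The step-4 threshold** keeps pixels within `eps_frac` (default 2%) of
  their local maximum *and* above an intensity level. The level defaults to
  Otsu's threshold over the smoothed pixels inside the bundle disc, which
  separates core peaks from inter-core gaps; without it, sensor noise
  creates spurious plateau "maxima" in the gaps and the detected count
  becomes noise-dependent.

The radius cut uses the bundle geometry from `estimate_bundle_geometry()`
(Otsu threshold, largest connected component, equivalent-area circle). The
equivalent-area radius sits slightly inside the outermost core ring, so when
the geometry is estimated automatically the cut radius is padded by one core
spacing.

## De-pixelation by precomputed barycentric interpolation

The mosaic is removed by triangular linear interpolation between core
intensities. All geometry is computed once per bundle (`calibrate_single()`):
a Delaunay triangulation over the core centres, and, for every pixel of a
square reconstruction grid spanning the bundle, the enclosing triangle and
its barycentric coordinates. Reconstructing a frame (`reconstruct()`) is
then one sparse weighted sum per pixel — no triangulation or search at frame
time, so per-frame cost is linear in grid pixels.

The triangulation is built by incremental Bowyer–Watson insertion in Morton
(z-order) spatial order. The insertion order is a pure function of the point
set, so calibration is bit-reproducible; exactly co-circular quadruples are
resolved deterministically by that order. The triangulation is stored in the
calibration container, so a calibration re-loaded from disk reproduces its
reconstructions exactly. Grid pixels are assigned to triangles by
rasterisation with a barycentric tolerance of 1e−12; pixels outside the
convex hull are set to zero (the cosine window removes the rim anyway — see
below). Correctness is checked in the test suite against the defining
empty-circumcircle property by brute force, against a triangle set frozen
from an independent computational-geometry implementation, and by the
analytic facts that barycentric weights partition unity and reproduce affine
fields exactly.

Before interpolation, core intensities are contrast-normalized against the
blank calibration frame, `c' = (b − c) / b`: background subtraction and
flat-fielding in one step. A blank field maps to zero everywhere, full
absorption to one; contrast is inverted, so absorbing features are bright.
Core values are read at the nearest integer pixel (the sampling convention
of the upstream acquisition software this mirrors); bilinear sampling is
available behind a flag.

## Multi-source resolution enhancement

Each illumination fiber, laterally offset by `s` from the reference fiber at
distance `h` from the sample, projects the hologram of an object at depth
`d` translated by

  s′ = s · d / (d + h).

Because `h/d ≥ 50`, the change in illumination angle is far below a degree
and the shifted holograms are pure translations of each other. A core at
position `p` in a hologram translated by `s′` samples the *reference*
hologram at `p − s′`; merging the shift-corrected core sets of all sources
therefore yields a denser sampling mesh of the same hologram, and the same
barycentric machinery over that merged mesh (`calibrate_enhancement()`,
`reconstruct_enhanced()`) produces a resolution-enhanced hologram.

Details that matter:

* **Shift estimation** (`estimate_shift()`) uses normalized
  cross-correlation between a central square template (one quarter of the
  bundle diameter, cut from the target) and a central square search region
  (one half of the diameter, cut from the reference), so the bundle rim is
  visible in neither. The peak is refined to sub-pixel by a separable
  quadratic fit. Registration runs on the *contrast* holograms — background
  structure would bias the peak — and both images are Gaussian smoothed with
  sigma of one core spacing first: content at and above the Nyquist limit of
  the single-frame mesh does not translate faithfully under resampling, and
  correlating it drags the peak towards integer multiples of the core
  lattice, systematically under-estimating sub-core shifts. The test suite
  asserts registration of imposed translations to better than 0.2 px.
* **Per-source normalization.** Each LED has its own power and illumination
  profile, and each source therefore gets its own blank frame: contrast
  normalization is per-source. In addition, each source's raw core vector is
  rescaled to its own blank's mean before the contrast normalization
  (`c_s ← c_s · mean(b_s)/mean(c_s)`). This one rescaling cancels any
  per-source global gain exactly (an LED power drift between calibration and
  acquisition leaves the output bit-identical) and maps blank input to
  exactly zero; rescaling *after* contrast normalization would do neither,
  because the contrast transform is affine, not linear, in the raw
  intensity.
* **De-duplication.** Merged points closer than 0.05 of the median core
  spacing collapse to the first occurrence, protecting the triangulation
  from degenerate slivers when two sources' shifts nearly coincide.

With one source the enhanced path reduces exactly to the single-frame path
(identical tables, identical output), which the test suite asserts.

## Numerical refocusing

`refocus()` implements the angular spectrum method: Fourier transform of the
(contrast) hologram, multiplication of each plane-wave component by the
defocus phase

  Δφ(u, v) = (2π z / λ) · sqrt(1 − (λu)² − (λv)²),

and inverse transform. Evanescent components ((λu)² + (λv)² > 1) are masked
to zero — the standard stability-preserving choice. Positive `z` with this
kernel back-propagates a bundle-plane hologram to the object plane; the
simulator uses the conjugate kernel for forward propagation, so the two are
consistent by construction and `refocus(z) ∘ refocus(−z)` is the identity on
band-limited input (asserted to 1e−9). At `z = 0` the operation is the exact
identity, evanescent content included. Frequencies come from the standard
DFT layout for the grid's pixel pitch, so results are bit-reproducible.

The step in intensity at the bundle rim rings under refocusing; a circular
cosine window (`cosine_window()`) with a 5 px taper (1 inside `R`, 0 beyond
`R + w`, cos² in between) is applied first. The tests assert the taper's
analytic values and that the window strictly reduces rim-annulus ringing.

`focus_metric()` supports manual depth finding by sharpness scan. It is the
normalized variance of the refocused *amplitude* over the bundle interior.
The amplitude, not the intensity, is deliberate: on sparse absorbing objects
the defocused twin's fringe energy keeps the intensity variance growing
well past the object plane, while the amplitude variance peaks at the true
depth — the test suite asserts the peak within one 10 µm scan step on a
simulated 10 µm disc.

## Depth-parameterized shifts and the calibration look-up table

The inter-source shifts depend only on the object depth once the illuminator
is fixed, and s′(d) is linear through the origin in the regime `h ≫ d`.
`fit_depth_model()` fits, per source, the shift magnitude against depth by
least squares through the origin (the shift at zero depth is exactly zero,
so the fit is forced through it) and averages the shift direction circularly
across depths (resultant-vector mean — arithmetic averaging of wrapped
angles would be wrong across ±π). The fitted `depth_shift_model` is a
standard S3 model object with `print`, `coef` and `predict` methods;
`predict(model, d)` returns the per-source 2D shifts at any depth.
Measurement noise across depths is not re-weighted in the fit (unweighted
least squares).

Because an enhancement calibration is only valid near the depth whose shifts
it used, and building one takes the bulk of the processing time (the
triangulation over the merged mesh), `build_lut()` pre-generates calibrations
on a uniform depth grid using predicted shifts — no registration needed per
depth — and `lut_lookup()` serves the nearest entry (ties toward the smaller
depth), reporting the depth error. A 20 µm grid step gives a worst-case
10 µm depth error, well inside the tolerance the depth-error study measures
(correlation with the correct-calibration image stays above 0.9 at 20 µm
error and degrades monotonically beyond). LUT keys are the intended refocus
depths, since the enhancement should always be calibrated for the refocus
depth in use.

## The synthetic forward model

Everything above is testable without instrument data through the simulator:

* `make_bundle_layout()` — hexagonal lattice (one lattice vector along +x)
  clipped to the circular aperture, each node jittered uniformly in a disc
  of radius `jitter × spacing` (default 0.15 — quasi-hexagonal order with no
  long-range perfection), per-core transmission from a Gamma distribution
  with unit mean and CV 0.1. Jitter up to 0.25 preserves the half-spacing
  minimum separation invariant.
* `make_usaf_target()` — standard 1951 three-bar elements (bar width = half
  the line-pair period, 5:1 bar length, both orientations), rendered opaque
  on a unit background, with per-element geometry recorded for objective
  contrast measurement. Spatial frequency of group g element e is
  2^(g + (e−1)/6) lp/mm; resolution is quoted as the full line-pair period
  in µm.
* `simulate_hologram()` — angular spectrum propagation of the amplitude
  object over depth `d`, intensity at the bundle plane, per-source lateral
  translation by s′ = s·d/(d+h) applied via the Fourier shift theorem (the
  pure-translation approximation justified above).
* `sample_through_bundle()` — per-core Gaussian-weighted collection
  (default sigma spacing/6, the second-moment equivalent of a top-hat core
  aperture two thirds of the spacing in diameter, i.e. a ~2 µm core at 3 µm
  pitch), multiplication by the core's transmission, additive Gaussian noise
  (default SD 0.01 on order-1 intensities), and rendering of the camera
  frame as Gaussian spots at the proximal magnification (default
  3.7 µm / 6 ≈ 0.62 µm per camera pixel, ~970 px across a 600 µm bundle,
  ~5 px per 3 µm spacing).
* `make_source_geometry()` — seven sources by default: a reference fiber on
  axis and six on a 225 µm ring, 30 mm from the sample, λ = 0.45 µm. The
  wavelength is a configurable default: "royal blue" LEDs centre near
  450 nm, and every kernel takes λ explicitly.
* Per-source LED gain spread (CV 0.15, emulating a 27–43 µW power range
  around 37 µW) exercises the per-source normalization path; the same gain
  applies to a source's blank and raw frames, as for a real LED.

What the simulator deliberately does **not** model: modal speckle inside
cores, inter-core cross-coupling, the source's finite spectral bandwidth and
spatial coherence, and detector saturation. Consequences: simulated
single-frame reconstruction is a few percent *better* than a real
instrument's relative to the core spacing (nothing degrades it besides
sampling), and the resolution gain measured here at long working distances
would not show the coherence-induced roll-off a real system exhibits beyond
~0.6 mm. Passing the resolution studies therefore demonstrates the sampling
physics and the correctness of the mesh machinery, not the full optical
error budget of an instrument.

## Objective resolution scoring

The studies score a chart element by sampling the refocused amplitude along
the three bar centres and two gap centres (central 60% of bar length) and
computing the Michelson modulation `(bar − gap)/(bar + gap)` at each
position along the bars. An element's contrast is the lower quartile of that
per-position modulation, orientations averaged: bars must be separated along
(most of) their length to count, which is what a visual "all three bars
distinct" judgement requires. Lane-averaged contrast alone would credit the
broken, wavy pseudo-bars that sub-Nyquist aliasing produces in single-frame
mode. The limiting period is where the isotonic (pool-adjacent-violators)
fit of contrast versus period crosses 0.2 — the fixed printed criterion that
stands in for visual assessment; the isotonic fit is needed because the twin
image modulates bar contrast non-monotonically with period. The
element-walk report (`limiting_element()`) is also available and is what the
CLI `report` subcommand prints.

Scene layout matters at these working distances: the defocused twin of one
element spreads over a halo of radius ≈ sqrt(2 λ d) ≈ 13 µm at d = 180 µm,
so study scenes separate elements by 12 µm. The studies use a 200 µm bundle
(at fixed core spacing the resolution limits are set by the spacing, not the
aperture; the smaller field keeps a full study inside a few minutes on one
CPU) with a 512-px reconstruction grid (~0.4 µm/px), seven elements spanning
6.2–2.5 µm, replicated over three independently seeded layouts/acquisitions
in the two-mode study.

## Known limitations

* No twin-image suppression or phase retrieval; quantitative amplitude
  values under the twin haze are biased accordingly.
* Nearest-pixel core sampling assumes the proximal optics oversample each
  core (~5 camera px per spacing); at coarser magnifications bilinear
  sampling should be enabled.
* The NCC search range is fixed by the template/search geometry
  (one-eighth of the bundle diameter in each direction); shifts beyond it
  are flagged by a border warning rather than recovered.
* The depth-shift model assumes a rigid illuminator; refitting is needed if
  the fiber geometry changes.
* Calibration containers are serialized R objects tagged with a format
  version; they are an on-disk cache, not an interchange format.
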