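# fibreholo

Inline holographic microscopy through coherent fiber imaging bundles:
core-mosaic removal, multi-source resolution enhancement, and angular
spectrum refocusing, with a full synthetic forward model for validation.

## Who this is for

A fiber imaging bundle (~30,000 cores, 600 µm active area, ~3 µm core
spacing) can relay an inline hologram from a remote or confined sample to a
camera, turning a lensless holographic microscope into a thin passive probe.
The cost is the core mosaic: the image is sampled on a quasi-hexagonal grid,
which superimposes a honeycomb pattern and limits resolution to roughly
twice the core spacing. This package is for optics / biomedical-imaging
researchers who want to process such bundle holograms:

1. **De-pixelation** — locate every core in a blank calibration frame,
   build a one-time Delaunay/barycentric interpolation calibration, and
   reconstruct each subsequent frame with a single sparse weighted sum
   (see the interpolation equation below).
2. **Resolution enhancement** — combine holograms acquired under several
   laterally offset illumination fibers. An illuminator fiber offset by `s`
   at distance `h` from the sample shifts the hologram of an object at
   depth `d` by `s' = s·d/(d+h)`; shifting each source's core positions
   back by its measured `-s'` merges all sources into one denser sampling
   mesh, roughly doubling the resolvable spatial frequency.
3. **Numerical refocusing** — angular spectrum propagation
   `I = F⁻¹[F{H}·exp(iΔφ)]` with
   `Δφ(u,v) = (2πz/λ)·sqrt(1−(λu)²−(λv)²)`, behind a circular cosine
   window that suppresses rim ringing.
4. **Depth-parameterized calibration** — per-source shift magnitude is
   linear in depth through the origin; a fitted `depth_shift_model`
   predicts shifts at any depth, and a look-up table of pre-built
   enhancement calibrations (e.g. 100–500 µm in 20 µm steps) makes live
   refocusing possible.

The interpolation itself is

    p_j = Σ_{k=1..3} c'_k · b_{j,k},   c' = (b − c)/b,

where `b_{j,k}` are the precomputed barycentric coordinates of
reconstruction pixel `j` in its enclosing triangle of cores, `c` the raw
core intensities and `b` the per-core blank (calibration) intensities — so
background subtraction, flat-fielding and de-pixelation happen in one pass.

A synthetic module (`make_bundle_layout`, `make_usaf_target`,
`simulate_hologram`, `sample_through_bundle`, `simulate_source_stack`)
generates bundle-sampled holograms of USAF 1951 resolution targets with
known ground truth, so every stage is testable without instrument data.

## Worked example

Simulate a 7-source acquisition of a USAF target 180 µm from a 200 µm test
bundle, then compare single-frame and enhanced processing:

```r
library(fibreholo)

layout <- make_bundle_layout(spacing = 3, diameter = 200, seed = 11)
geom   <- make_source_geometry()          # 7 fibers, h = 30 mm, 450 nm
target <- make_usaf_target(list(c(7, 3), c(7, 5), c(7, 6), c(8, 1),
                                c(8, 3), c(8, 4), c(8, 5)),
                           pixel_pitch = 0.25, canvas_um = 230, gap_um = 12)

stack <- simulate_source_stack(target, geom, layout, d = 180, seed = 3)
cores <- find_cores(stack$blanks[[1]], est_spacing = 3 / stack$cam_pitch)
nrow(cores)
#> [1] 3863

rep <- resolution_report(target, layout, geom, d = 180,
                         stack = stack, cores = cores)
rep$limits$single$period_um    # finest element resolved, one frame
rep$limits$enhanced$period_um  # finest element resolved, 7 merged frames
```

On this scene the single-frame mode resolves elements down to roughly
4.4–4.9 µm line-pair period while the enhanced mode reaches roughly
2.5–2.8 µm — the two-fold sampling gain the merged mesh provides (exact
values depend on the seed; `resolution_study()` averages replicates and
prints the limiting-period ratio). `run_single()` / `run_enhanced()` wrap
the same steps for TIFF stacks on disk, and

```r
amp <- run_enhanced(list(raws = stack$raws, blanks = stack$blanks,
                         cores = cores, cam_pitch_um = stack$cam_pitch,
                         refocus_z_um = 180))
plot(amp)
```

returns the windowed, refocused amplitude image.

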