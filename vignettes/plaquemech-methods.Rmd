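---
title: "Estimating plaque stiffness from ultrasound inflation tests: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating plaque stiffness from ultrasound inflation tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`plaquemech` implements a hybrid experimental–numerical workflow for the
local mechanical characterization of atherosclerotic plaques: an excised
artery is pressurized quasi-statically from 10 to 120 mmHg, imaged with a
high-frequency (40 MHz) linear-array ultrasound transducer, tissue motion
is estimated from the radiofrequency (RF) echo data by coarse-to-fine
cross-correlation, and the shear moduli of the vessel wall
(media + adventitia) and of the diseased intima are recovered by an
inverse finite-element (FE) grid search that matches computed to measured
displacements. Because no public RF recordings of such experiments exist,
the package also contains a synthetic-data generator — a geometric plaque
phantom, a ground-truth forward model, and an RF speckle simulator — so
that every stage of the chain can be validated against a known truth.

This vignette explains the models, the main tunable parameters, and the
numerical choices, in the order the pipeline runs them.

## The plaque phantom

`make_vessel_geometry()` builds a layered cross-section from closed
polyline contours in mm: lumen, intima–media interface (IMA), and outer
wall, optionally with a calcified inclusion adjacent to the IMA (where
calcifications are typically found). Contours are explicit polylines, not
parametric shapes, so traced contours from real images and synthetic ones
share one code path. Intima thickening follows a cosine-modulated radial
profile interpolating between concentric (`eccentricity = 0`) and fully
one-sided (`eccentricity = 1`) plaques; the thick pole faces the
transducer, as specimens were positioned experimentally.

Default dimensions (lumen radius 1.5 mm, wall 0.5 mm, maximum intima
1.6 mm at eccentricity 0.6, thick side facing the transducer) describe an
advanced but non-stenotic iliac plaque, positioned the way specimens were
in the experiments — thickest section in the beam. They are chosen so
that the default measurement grid (below) contains 30–50 cells of
100 µm — the element count regime of the original experiments.
Eccentricity is not cosmetic: in a perfectly concentric incompressible
vessel the displacement of every cell in the central measurement column
is kinematically tied to the lumen expansion alone, so wall and intima
stiffness are separable only through the weak nonlinearity of the
pressure–expansion curve; an eccentric plaque puts thick intima on one
side of the column and thin intima plus wall on the other, and the two
cell populations constrain the two moduli separately. The default
ground-truth moduli (`C_wall` 150 kPa, `C_intima` 30 kPa) sit in the
mid-range of published wall and intima estimates; a single Neo-Hookean
truth much softer than this would more than double the lumen radius at
120 mmHg, unlike anything inflation tests show. The coordinate convention
everywhere is x = lateral, y = axial (beam direction, increasing away
from the transducer face at y = 0).

`make_scatterers()` draws a Poisson number of point scatterers uniformly
over the cross-section with i.i.d. standard normal reflectivities. The
default density (2500 mm⁻²) puts ≥ 10 scatterers in each ultrasound
resolution cell, the classical condition for fully developed (Rayleigh)
speckle, which the tests verify with a Kolmogorov–Smirnov check.

## Forward finite-element model

The forward problem is plane-strain, quasi-static inflation of the layered
cross-section. All tissue components share the incompressible Neo-Hookean
strain energy `W = C (I1 − 3)` — `C` is the shear modulus parameter (the
classical shear modulus is `µ = 2C`, hence the reporting convention
`E = 6C`). Calcium uses the same law with `C = 1e5` kPa, i.e. quasi-rigid.
Rigid-body motion is suppressed, as in the original models, by a very soft
compressible buffer ring (Neo-Hookean with zero Poisson ratio) surrounding
the vessel, with zero displacement on its outer border. Pressure acts as a
follower load on the deformed lumen boundary; at 120 mmHg deformations are
large and a dead load would be wrong.

Numerical choices:

* **Elements.** Taylor–Hood triangles: quadratic displacement with linear
  continuous pressure on the corner nodes of incompressible regions. This
  is an inf-sup stable mixed formulation — the package's equivalent of the
  "hybrid" elements used to avoid volumetric locking in the original
  ABAQUS models. One subtlety matters for layered vessels: the stress is
  written `P = µ(F − J F⁻ᵀ) − p J F⁻ᵀ`, so the multiplier `p` is the
  hydrostatic *perturbation* — zero at rest and continuous across material
  interfaces. (With the naive `P = µF − pJF⁻ᵀ` the rest state needs
  `p = µ`, which jumps at the intima–wall interface; a continuous pressure
  interpolation cannot represent that jump and pollutes nearby
  displacements by tens of microns at any load.) A near-incompressible
  displacement-only penalty formulation (bulk modulus `1e4 × C`, full
  Newton steps, element-wise mean-dilatation volumetric treatment) is
  provided as a fallback; the two agree within 1% on homogeneous tubes.
  On layered tubes a two-layer analytic oracle shows the penalty path
  accurate to ~0.1% while the mixed element carries a ~2% bias from
  smearing the load-scale interface pressure jump over one element layer —
  a documented trade-off (the bias cancels identically in the
  self-consistent inverse workflow). Quadrilaterals are not implemented;
  triangulation covers arbitrary contours.
* **Meshing.** A structured radial–angular mesh conforming to all layer
  interfaces, with the calcium boundary conformed by snapping interior
  radial nodes onto it along each crossing ray. Contours must be
  star-shaped about the lumen center (every generated phantom is; meshing
  fails loudly otherwise). Default target edge 0.3 mm gives ≈ 1000
  quadratic triangles; the tests verify that lumen displacements change by
  < 1% when the edge is halved, and that the FE solution matches the
  closed-form incompressible tube solution (`analytic_tube_inflation()`,
  a 1D radial-quadrature oracle) within 1% on inner-radius expansion
  across C ∈ {20, 100, 400} kPa and P ∈ {2, 6, 10, 16} kPa. Element
  counts are deliberately two orders of magnitude below the original
  models (which ran one forward solve per candidate on a cluster-scale
  budget); the convergence and oracle tests document that this suffices
  for the displacement accuracy the inverse problem needs.
* **Solver.** Newton–Raphson with a backtracking line search on the
  residual norm and adaptive load stepping (bisection on divergence, depth
  8). The sparse LU factorization of the tangent is reused across
  iterations and load steps while the residual contracts, and refreshed on
  stall; since convergence is judged on the true residual (relative
  tolerance 1e-8), the converged states are those of a full Newton solve.
* **Buffer sensitivity.** The buffer modulus only needs to be "very soft";
  the tests verify that lumen displacements move by < 0.5% when it varies
  over [0.001, 0.1] kPa. Inside the inverse loop it is specified relative
  to the wall candidate (`1e-4 × C_wall`), which keeps it in this
  insensitivity band for every candidate.
* **Reference state.** The geometry is the configuration imaged at
  10 mmHg and is treated as stress-free; loads are gauge pressures above
  it (1 mmHg = 0.133322 kPa). All displacement bookkeeping — tracking
  accumulation and FE comparison alike — is Lagrangian with respect to
  this reference.

## RF simulation

`simulate_rf()` uses a separable convolutional point-spread-function
model: each RF line is a sum over scatterers of amplitude × lateral
Gaussian beam weight × Gaussian-modulated cosine pulse at the scatterer's
depth. Defaults: 40 MHz center frequency, 160 MHz axial sampling (4
samples per carrier period; depth convention `y = k·c/(2 fs)`, 4.8125 µm
per sample), 20 µm line pitch, 50% fractional bandwidth, 50 µm lateral
beam sigma. These are declared, configurable stand-ins — the true
acquisition parameters of the commercial scanner are not published — and
are chosen so the fine tracking kernels (60 µm axial) contain 12 RF
samples. The model deliberately omits beamforming, attenuation and
nonlinear propagation: what the tracking validation needs is speckle that
decorrelates realistically under deformation, which a PSF model provides.
Consequences for interpretation: simulated frames have
depth-independent resolution and noise, so tracking accuracy results
transfer to real data only where those assumptions roughly hold (the
focal region).

## Displacement tracking

`estimate_displacement()` is a three-iteration coarse-to-fine 2D
normalized cross-correlation estimator on RF frame pairs:

1. template 3850 × 715 µm (axial × lateral), search 7700 × 935 µm,
   overlaps 50% / 92% — a coarse integer-lag map;
2. template 60 × 715 µm, search 120 × 935 µm, overlaps 75% / 92%,
   with the coarse map offsetting the search windows;
3. same kernels, but with local alignment of the data and parabolic
   interpolation of the correlation peak for subsample estimates.

A 5 × 5 median filter is applied to the displacement field after each
iteration (reflect padding at the edges; in the last iteration it is
applied after the subsample refinement, configurable). Zero-mean
normalization makes the correlation robust to amplitude drift. Physical
kernel sizes are converted to even sample counts by flooring; the
final axial grid step is 60 µm × (1 − 0.75) = 15 µm (14.4375 µm once
quantized to whole samples at 160 MHz), and the lateral step computed
from the printed 92% overlap is 57.2 µm against the published rounded
55 µm.

Two details matter for accuracy at a carrier of a quarter of the sampling
rate. First, parabolic peak interpolation on RF correlation is biased by
up to ~0.05 samples when the residual lag is large; the package therefore
implements "local aligning" as an iterated warp–correlate cycle (at most
three passes), so the parabola is evaluated at near-zero residual where it
is unbiased. Second, the warp resamples the post frame with a Lanczos-3
kernel along the axial axis: linear or cubic interpolation distorts the
carrier phase by ~0.04 samples, which would defeat the alignment.
Tie-breaks between equal correlation maxima go to the smallest-magnitude
lag, and a numerically perfect integer match (peak correlation 1 to within
rounding) skips the subsample refinement, whose edge-term asymmetry would
otherwise add ~0.01-sample noise to an exact result. With these choices
the tests hold integer-shift recovery to 0.1 µm RMSE and a 0.3-sample
subsample shift to 0.05 samples RMSE at 30 dB SNR.

`track_sequence()` composes consecutive-pair estimates into cumulative
fields in the reference frame: `U[k+1](X) = U[k](X) + u_k(X + U[k](X))`.
Tracking frame pairs at 10 mmHg increments keeps inter-frame strains at a
few percent, which the 60 µm kernels tolerate; the 10→80 mmHg step is far
too large to track in one pair.

## Registration

Where plaque-component contours come from histology, `register_geometry()`
maps them onto the ultrasound frame with a thin-plate spline fitted to
landmarks placed by matched arc-length parameterization on the lumen and
outer-wall contours of both images. Rotation is fixed by anchoring at the
thickened side of the wall — specifically the thickness-weighted circular
mean of the region thicker than the mid-range, which is far more stable
than the bare thickness argmax when the profile has a plateau (strongly
anisotropic image scalings can still shift a blunt maximum by several
degrees; this is the method's main failure mode). This is a contour-driven
substitute for intensity-based registration, which needs image pairs a
synthetic workflow does not have; the substitution is exercised by
deforming a known geometry with a smooth synthetic warp and checking
recovery. Affine maps are reproduced exactly by the spline with zero
regularization.

## Inverse estimation

The measurement region is a vertical band through the vessel center —
where the beam direction coincides with the radial direction, so axial
displacement is radial displacement — tiled with 100 µm square cells
clipped to the tissue between lumen and outer wall, above and below the
lumen. The default band half-width (0.05 mm) yields a single column of
cells tracing the two tissue lines of the cross-section's midline, 30–50
cells for default phantoms. Only axial displacements enter the objective;
lateral estimates are far noisier and are retained for reporting only.

Per cell, measured displacements are the arithmetic mean of the map
samples in the cell; computed displacements are a fixed 4 × 4 Gauss
quadrature of the interpolated FE field, and the two averaging routes
agree to quadrature tolerance on smooth fields. For each incremental
pressure step — 10→80, 80→100, 100→120 mmHg, fitted independently — the
objective is

F = Σⱼ (uⱼᶜᵒᵐᵖ − uⱼᵐᵉᵃˢ)²,

minimized by exhaustive search over `(C_wall, C_intima)` in 1–400 kPa,
ties broken toward the smaller moduli. Each candidate's pre-deformation to
the step's start pressure is recomputed with that candidate's own moduli.
Goodness of fit is

Δu_rel = (√F / n) · (u_meanᵐᵉᵃˢ)⁻¹ × 100%,

with `u_mean` the mean absolute measured displacement of the step; this is
the published normalization (a per-cell RMS variant exists behind
`method = "rms"` but is never the default). Estimates are reported as
Young's moduli `E = 6C`.

Design choices in the search:

* **Lattice.** The published search used a constant step over 1–400 kPa of
  unstated size. The default here is two-stage: a 20 × 20 log-spaced
  coarse lattice followed by 9 × 9 refinements spanning the neighbour
  rectangles of the best two well-separated coarse candidates (the
  objective forms a shallow valley along a wall–intima compensation
  ridge, so refining only the single winner can miss the basin); a
  literal single-stage linear lattice is available by configuration.
  Refinement windows are parameterized in `(C_wall, C_intima/C_wall)`
  with the ratio range covering the full neighbour rectangle. Recovery
  statements are made relative to the final (refinement) lattice spacing.
* **Scaling cache.** The incompressible model obeys an exact scaling law:
  multiplying all moduli and the pressure by one factor leaves
  displacements unchanged. A candidate therefore only depends on
  `C_intima/C_wall` and `P/C_wall`, and `make_fe_forward()` serves an
  entire ratio family of lattice points — and all three pressure steps,
  and every noise replicate — from one pressure continuation. This is an
  exact property (covered by a test), not an approximation; a calcified
  geometry breaks the collapse and falls back to per-candidate paths.
* **Triage stage.** The exhaustive coarse scan only has to locate
  candidate basins, so it runs on a 2× coarser mesh with each ratio
  family solved once along a fixed 14-knot normalized-pressure grid and
  interpolated in pressure (`pressure_grid_n`); the refinement stage and
  all reported numbers use the accurate mesh and exact step pressures.
* **Feasibility cap.** Wall candidates with `P/C_wall > 1` at the top
  pressure imply strains far beyond anything inflation tests exhibit
  (the softest published wall responses sit near 0.8); they are excluded
  as non-converged rather than bisected into absurd strain states.
  Extremely soft-intima corner candidates can also fail to converge and
  are excluded with a warning; both exclusions are far from any plausible
  optimum.
* **Identifiability.** When the intima is thin (fewer than ~3 measurement
  cells through its thickness), area conservation makes the displacement
  field almost independent of how stiffness is distributed between the
  layers, and the objective becomes flat along `C_intima`. The acceptance
  test quantifies this as the range of F along the intima axis being
  < 1% of its range along the wall axis — a relative normalization,
  since the absolute value of F is set by the arbitrary measurement noise
  floor.

## What the synthetic loop does and does not show

The end-to-end test generates a phantom, inflates it with known moduli,
displaces scatterers with the FE field, simulates noisy RF at every
pressure level, tracks, averages, and searches; it requires the truth to
be recovered within one refinement-lattice step with Δu_rel < 2% for all
three steps — the success threshold of the original experiments, met
there by 14 of 18 cases. Passing it shows the chain is self-consistent
and that tracking noise at 30 dB SNR does not break identifiability. It
does not show that the Neo-Hookean model fits real tissue (the synthetic
truth is itself Neo-Hookean), nor does it exercise out-of-plane motion,
attenuation, reverberation, or histology-processing artifacts beyond a
smooth warp. Problem sizes throughout (mesh ≈ 1000 quadratic elements,
single-column measurement grid, 10 mmHg tracking increments) are the
package's desk-scale defaults, validated by the convergence and oracle
tests above.
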