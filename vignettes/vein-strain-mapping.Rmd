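---
title: "Mapping vessel-wall strain from volumetric photoacoustic image series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping vessel-wall strain from volumetric photoacoustic image series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(veinstrain)
```

## The measurement problem

Aqueous veins in the perilimbal sclera deform as intraocular pressure (IOP)
varies, and the strain of their walls is a direct mechanical readout of the
tissue. Optical-resolution photoacoustic microscopy of a perfused contrast
agent produces volumetric images in which the stained inner vein wall
appears as bright speckle on a dark background, with strongly anisotropic
resolution (about 4 µm laterally and about 37 µm axially). `veinstrain`
turns a series of such volumes, acquired at increasing IOP, into
three-dimensional strain fields:

1. **Detection.** Voxels with at least 55% intensity contrast over one of
   their 26 neighbours in the lowest-pressure (near-zero strain) reference
   frame are candidate features.
2. **Multi-window correlation tracking.** Each candidate is followed
   frame-to-frame by zero-normalized cross-correlation (ZNCC) of sliding
   windows of three sizes (21/31/41 voxels laterally; axial extents scaled
   to the axial resolution) over a 61-voxel-wide lateral search region. If
   the three window sizes disagree on the new location by more than 2
   voxels on any axis, the point is discarded (consensus rule); otherwise
   the mean location, rounded to the nearest voxel, is kept.
3. **Meshing.** Points tracked through all frames are decimated so that no
   two retained points are closer than a chosen radius (30–300 µm,
   depending on the image size), converted to physical coordinates
   (index × spacing — this is where the anisotropic voxel spacing enters),
   and joined by Delaunay triangulation into constant-strain simplex
   elements.
4. **Strain.** Each element's deformation gradient is
   `F = D_def %*% solve(D_ref)` where the `D` matrices stack edge vectors;
   the default strain measure is the true (logarithmic) strain
   `eps = ln U` with `F = R U` the polar decomposition, computed from the
   eigendecomposition of `F'F`. The region average `eps_bar` weights
   element strains by their initial area or volume; nodal averages of
   incident elements support interpolated visualisation and VTK export.
5. **Pressure dependence.** `eps_bar` components are fitted against IOP by
   `eps_bar = a*ln(IOP) + b` with `R^2` reported on the strain scale, the
   stiffening law soft tissue commonly follows.

## Why a synthetic phantom

No public volumetric data set accompanies the imaging protocol this
package implements, so validation rests on a speckle phantom with
analytically known deformation. `generate_phantom()` renders bright
Gaussian blobs (the imaging point-spread applied to point absorbers) on
the wall shell of a tube of radius 87.5 µm — the 150–200 µm diameter
range of the vessels of interest — over a near-zero noisy background.
`deform_volume()` warps a volume by any invertible smooth mapping with
backward (inverse) resampling, and `generate_series()` builds whole
pressure series whose ground-truth strain follows a prescribed
logarithmic law.

The phantom emulates the *image statistics relevant to tracking* —
speckle scale, amplitude variability (uniform in 0.5–1 of the peak; the
amplitude distribution of real stained veins is not characterised, so
this is a free choice exposed in `phantom_spec()`), anisotropic blur, and
sensor noise. It does not simulate acoustic propagation, optical fluence,
staining heterogeneity, motion artefacts, or out-of-focus geometry, so
passing the synthetic validation demonstrates correctness of the
*algorithmic chain*, not performance on degraded real acquisitions.

A density note: the acquisitions this emulates report at least 100
*trackable pixels* per 100 × 100 µm² region. One rendered speckle feature
spreads over tens of supra-threshold pixels after blurring, so the
default `speckle_density` of 6 features per 100 × 100 µm² of wall area
reproduces that pixel density; pushing the *feature* density to 100 per
patch would merge the speckle into unresolvable texture.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `contrast_threshold` | 0.55 | – | candidate detection; contrast over any neighbour |
| `lateral_windows` | 21, 31, 41 | voxels | correlation window sizes, smaller than the vessel, larger than the per-step motion |
| `axial_windows` | 71, 101, 133 | voxels | same physical proportions at the fine axial sampling these defaults assume; scale them with your axial pitch |
| `search_lateral` | 61 | voxels | search extent; must exceed the largest per-step displacement |
| `agreement_tol` | 2 | voxels | per-axis consensus range across window sizes |
| `dedup_radius` | 0 (pipeline: 12–40) | µm | one tracked point per blurred feature |
| `decimate_radius` | 30 (validation: 60) | µm | element-size uniformity |
| `quality_floor` | 0.05 (validation: 0.25) | – | sliver-element pruning (normalized inradius/circumradius) |
| `measure` | `"log"` | – | `ln U` (rotation-invariant) or linearised small strain |

Two defaults deserve their rationale spelled out.

**Window policy.** The tracker always *extracts* correlation windows from
the original reference frame at the original candidate location and only
advances the search centre (`window_policy = "reference"`). The
alternative — re-extracting windows from the previous frame each step —
accumulates the per-step voxel-rounding error like a random walk
(standard deviation growing with the square root of the step count),
whereas the reference policy estimates each frame's total displacement in
a single correlation, keeping the error at one rounding. Appearance drift
across the series (about 10% stretch end-to-end in the validation) lowers
the correlation peak slightly but does not move it at these deformations.
The incremental policy remains available for acquisitions with strong
appearance change.

**Decimation radius and element quality in the validation.** Tracked
locations are integers, so nodal positions carry up to half a voxel of
quantization. A constant-strain element converts nodal error into strain
error as (position error)/(element extent); with 4 µm lateral voxels,
60 µm elements keep per-element noise near 5% strain, and the sliver
floor of 0.25 removes the thin tetrahedra (inevitable when nodes sit on a
tubular shell) whose small altitudes would amplify that noise by another
order of magnitude. The logarithmic measure is nonlinear, so element
noise does not cancel exactly in the weighted average — a second-order
bias of roughly minus half the elemental variance — which is why element
extent, not element count, controls the accuracy of `eps_bar`.

## The induced-strain validation and its floor

`run_validation()` reproduces the accuracy protocol of the source method:
a reference phantom (240 × 240 × 80 voxels at 4 × 4 × 13 µm) is warped by
a uniaxial stretch of `exp(0.0953)` — i.e. a true strain of exactly
9.53% — applied in four equal increments; the full pipeline runs and the
volume-weighted average longitudinal strain is compared with the induced
value, together with per-element error statistics.
`displacement_source = "ground_truth"` bypasses the tracker and
prescribes exact displacements at the same nodes; the recovery is then
exact to machine precision, demonstrating that all observable error
originates in tracking quantization, not in the finite-element stage.

The achievable accuracy of the tracked validation is bounded by geometry:
locations are rounded to the voxel grid, so the average strain over a
span of `L` voxels cannot be recovered more accurately than roughly
`0.5/L` even with perfect correlation peaks. At the phantom's 240-voxel
(960 µm) span that floor is a few parts in a thousand of strain — about
one order of magnitude above the published 0.31% relative error, which
was obtained on a considerably larger pixel span. The acceptance suite
asserts the published bounds as stated and reports the measured values;
on this desk-scale phantom the average-strain recovery lands near 0.4–1.3%
relative error depending on the seed (about 0.9% on average over five
seeds), and the per-element statistics sit near `2e-2`, both consistent
with the quantization analysis above.

The axial window extents used by `validation_tracker_config()` (17/23/31
voxels with a 25-voxel axial search) cover the same physical distances as
the 71/101/133-voxel windows do at the fine axial sampling the published
numbers assume; the published voxel counts cannot even be extracted from
an 80-voxel-deep volume.

## Numerical choices

- **Interpolation for phantom warping** is Catmull-Rom cubic (linear
  selectable): sub-voxel texture fidelity ensures tracker errors reflect
  the tracker, not the phantom. Voxels mapping outside the source are
  zero-filled and excluded by the exported validity mask (with a 1-voxel
  guard band for the interpolation support). Negative interpolation
  overshoot is clamped to zero, matching non-negative image amplitudes.
- **ZNCC** is computed exactly (not an approximation): the correlation
  numerator via FFT cross-correlation, the per-position window variance
  via summed-area tables; both windows constant is defined as correlation
  0 with a degeneracy flag. Ties in the argmax break towards the smallest
  displacement magnitude, then lexicographically — deterministic and
  bias-free under symmetry.
- **Rounding** of consensus locations is half-away-from-zero (pixel-grid
  semantics), not banker's rounding. Sub-voxel parabolic peak refinement
  exists behind `subvoxel = TRUE` but is off by default, matching the
  published protocol's nearest-pixel rule.
- **Delaunay** uses incremental insertion with circumsphere tests in
  double precision after centring and a deterministic 1e-6 µm symbolic
  jitter (fixed seed), making co-spherical grids reproducible. Element
  orientation is normalised positive; the triangulation conserves the
  convex-hull measure to 1e-9 relative in the test suite.
- **Degenerate inputs** error early and specifically: folding deformation
  models (det F ≤ 0), collinear/coplanar node sets (with the advice to
  use 2-D mode), inverted elements (listing them), empty candidate sets,
  and meshes emptied by pruning.

## Problem sizes

The shipped experiments are sized for a single CPU: the 3-D validation
tracks roughly 350–400 accepted trajectories through 5 frames of a
240 × 240 × 80 volume in about a minute and a half per seed (five seeds
in the acceptance run); unit fixtures use 48–96-voxel grids and planar
phantoms.
These sizes are the package's own choices and scale linearly in voxels
and candidates.

## Known limitations

- Tracked locations are voxel-quantized end to end; on small images this,
  not the correlation, limits strain accuracy (see the floor analysis
  above).
- The tracker matches rigid windows; it tolerates the ~2% per-step
  stretches of the intended acquisitions but will lose lock under large
  rotations or shears within a window.
- The inter-structure (between-vein) strain assumes the bounding walls
  deform negligibly relative to the tissue between them.
- 2-D mode treats the image plane as material — out-of-plane motion
  aliases into in-plane strain, as in any planar speckle method.
- The phantom's affine and smooth deformation families do not exercise
  strain concentrations sharper than the element size.
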