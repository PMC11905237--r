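---
title: "Secondary dose/MU verification for a high-field MR-linac: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary dose/MU verification for a high-field MR-linac: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seccheck)
```

## Why a secondary calculation

An independent dose/MU check recomputes, with a deliberately simpler and
fully auditable model, the dose the treatment planning system predicts, and
flags disagreement beyond tolerance before the beam turns on. On an MR-linac
this check carries extra weight: adaptive plans are created with the patient
on the couch, so no measurement-based QA is possible and the secondary
calculation is the only independent barrier. It also carries extra physics:
the 1.5 T field sweeps secondary electrons laterally (Lorentz force), the
beam traverses the imaging cryostat whose attenuation varies with gantry
angle, and the source-axis distance (143.5 cm) differs from conventional
machines.

## The dose model

`point_dose()` evaluates a TG-71-style chain anchored exactly at the
absolute calibration (1 cGy/MU, 10 × 10 cm, source-to-plane 1385 mm, depth
50 mm). Every factor is relative to that geometry, so the calibration
identity holds to machine precision by construction — a deliberate design
choice that makes the chain self-normalizing and each factor separately
auditable:

* **Output factor** `S_c,p(s)`: linear in the Sterling equivalent square
  `s = 2XY/(X+Y)` of the effective aperture. When an MLC aperture is
  present, each leaf-pair opening is widened by half the dosimetric leaf
  gap (DLG) per leaf end, clipped by the jaws, and the equivalent square is
  formed from the total open width and the area-weighted mean opening.
* **Depth dose**: bilinear lookup (linear in side and depth, exact at
  nodes) in the commissioned PDD grid at SSD 1335 mm, converted to the
  field's SSD by the Mayneord F factor. Depth is the radiological depth
  along the ray (Siddon traversal of the electron-density grid;
  water-equivalent slant depth when no phantom is given). Extrapolation
  past the deepest node (130 mm) uses the log-linear slope of the last two
  nodes and is opt-in.
* **Inverse square**: the ratio of dmax-plane distances,
  `[(STD_cal + d_max)/(SSD + d_max)]^2`, with `d_max = 13` mm by default
  (shallow, as expected for a 7 MV FFF beam whose surface dose is raised
  by the magnetic field; configurable).
* **Off-axis ratio**: per-axis erf penumbra over the aperture edges times
  a linear FFF envelope `max(1 − h·|u|, 0.5)`, the cross-plane component
  translated by the Lorentz shift (2 mm default). The product is
  renormalized to exactly 1 on the central axis whenever the axis is open,
  and floored at the MLC transmission; a point under closed leaves
  receives the transmission directly.
* **Cryostat correction** `CF(θ)`: periodic linear interpolation of the
  normalized gantry-angle table; the unmeasured 8°–18° span (skipped to
  avoid the cryostat pipe) is bridged linearly between its neighbours.

`mu_for_dose()` inverts the chain; because dose is exactly linear in MU
the round trip is the identity.

### The pencil-beam aperture integrator

For modulated segments `pencil_beam_dose()` replaces the aperture
indicator with a fluence term: beamlets tile the DLG-widened opening at
the isocenter plane (each leaf pair tiled exactly, so areas are
preserved), each contributing a radially double-exponential kernel weight
`w1 e^{−r/r1} + w2 e^{−r/r2}` (defaults 0.92/2.2 mm and 0.08/6 mm),
laterally translated by the Lorentz shift and scaled by the beamlet's
radiological path relative to the evaluation point's. The sum is
normalized by the same kernel sum over the jaw rectangle evaluated at its
center — the open-collimator reference whose dosimetry the factor chain
already carries. Consequences: a fully open aperture reproduces
`point_dose()` to well under 1% at in-field calculation points, a fully
blocked one falls to the transmission floor, and translation of the
aperture translates the fluence exactly. Near the penumbra the kernel and
erf models differ by a few percent — expected, since a secondary check's
calculation points are chosen away from field edges.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `dmax` | 13 | mm | depth of maximum dose used in SSD conversion |
| `dosimetric_leaf_gap` | 0.010 | cm | aperture widening per leaf pair (commissioned value) |
| `transmission` | 0.0055 | — | closed-leaf transmission (commissioned value) |
| `asymmetry_shift` | 2 | mm | Lorentz translation of the cross-plane profile |
| `penumbra_width` | 5–8 | mm | 80–20 width at dmax, by field size |
| `horn_slope` | 0.002 | /mm | linear FFF off-axis envelope slope |
| `beamlet_mm` | 1 | mm | pencil-beam discretization (must resolve the smallest opening) |
| kernel `w/r` | 0.92/2.2, 0.08/6 | —/mm | double-exponential kernel components |

Tolerances follow clinical practice: a field passes if the MU difference
is within 5% **or** 5 MU (inclusive), the plan point dose within 5% or
5 cGy; percent differences use the TPS value as denominator — documented
prominently because the choice moves borderline verdicts. Automatic point
selection requires > 3 mm from tissue interfaces (voxels whose 6-neighbour
density differs by more than 0.1), > 10 mm from every field edge, and dose
at or above 90% of prescription (loosened once to 70% before giving up);
the fallback search maximizes MU-weighted open-field exposure with ties
broken toward the lowest linear voxel index, making selection
deterministic.

## The packaged beam model and what is synthetic

`unity_beam_model()` carries the commissioned scalar settings verbatim
(calibration, MLC transmission 0.0055, DLG 0.010 cm) and the published
depth-dose nodes bit-exactly at depths 50/100/130 mm for sides
20/30/50/100/220 mm. Everything the commissioning report does not print is
**synthetic but anchored**: shallow-depth PDD nodes follow an FFF-like
buildup with dmax at 13 mm; output factors are a monotone curve fixed at
1.000 for the 100 mm side; the cryostat curve is a smooth shape with
CF(0°) = 1 and range [−1.1%, +0.3%]; profile parameters (penumbra, horn
slope, Lorentz shift) were chosen once so that the engine reproduces the
packaged 27-point ion-chamber validation set. The equivalent-square field
sizes quoted with area-like units in the source data are treated as side
lengths in cm.

Against that validation set the engine agrees with measurement within 5%
at the two on-axis 10 × 10 cm points whose inputs are fully printed
(0.15% and 0.50%), with a median absolute difference below 5% across all
27 geometries and a worst case of about 12% at the 15–16.5 cm off-axis
points of asymmetric fields — the linear FFF envelope cannot reproduce the
true nonlinear cone shape at both 12.5 cm and 16 cm off axis, and we chose
to fit the conventional large-field region. The test suite asserts exactly
these bounds; nothing tighter is claimed.

## Synthetic data generators

`make_slab_phantom()` emulates heterogeneous-phantom commissioning: a
water body with a lung slab (relative electron density 0.25, depths 30–70
mm, x < 0) and a bone slab (1.6, depths 100–130 mm, x > 0) in separate
lateral halves, with labeled probe points per heterogeneity class.
Densities 0.25 and 1.6 are conventional surrogates.
`make_step_and_shoot_plan()` produces segments with randomized contiguous
MLC openings inside a 10 × 10 cm jaw setting; segment 1 is always fully
open so the plan touches the calibration identity.
`make_cryostat_readings()` produces 2°-spaced charge readings (skipping
10°–16°) with a configurable dip (default 1.4%) and noise.
`make_dlg_trials()` draws per-plan dose differences around a V-shaped
response centred on a known DLG with per-plan noise of 0.05% — the
reproducibility level of a TPS recalculation, and small enough that the
0.07% spacing of the clinical candidate grid is resolvable, as it
evidently was in practice. All generators are seed-deterministic.

What passing these tests does **not** show: generators contain no
electron-return-effect dose spikes at interfaces, no organ motion, and no
realistic modulation complexity, so agreement here bounds arithmetic and
geometry correctness, not clinical accuracy at tissue interfaces.

## Numerical choices and degenerate inputs

* Lookups are bit-exact at grid nodes (node match before interpolation).
* A point exactly on an aperture edge counts as inside (open).
* Gamma analysis normalizes globally to the reference maximum, excludes
  points below the low-dose threshold from the denominator, interpolates
  the evaluated curve at `dta/10` steps over a ±3·dta window (1-D) or
  disk (2-D); suite tests hold it to within 0.5 percentage points of a
  dense brute-force evaluation.
* DLG optimization uses unrounded weighted means; ties break toward the
  smaller DLG. The published mean column is reproduced by the
  plan-count-weighted mean (12 primary, 10 adaptive) to rounding for
  every row but one, where the printed value derives from unrounded
  source data; that row is not asserted.
* PDD comparison uses the measured value as denominator; printed
  difference columns derived from unrounded data are documented, not
  asserted.
* Plans with zero TPS MU get an undefined percent difference; the
  absolute criterion still applies. Fields whose geometry cannot be
  resolved are annotated unverifiable and fail the overall verdict.
* A multi-field plan point dose sums transmission-attenuated
  contributions from fields whose aperture excludes the point — a
  documented choice, not an assertion about any vendor's behaviour.
* DICOM I/O supports explicit-VR little-endian RT Plans with static
  step-and-shoot beams only; dynamic beams and rotating-gantry control
  points are rejected by name rather than approximated.

## Problem sizes used by the suite

The suite runs entirely from code-built fixtures: profiles of 200
samples for gamma oracles, phantoms up to 12³–20³ voxels for the POI
brute-force equivalence, 100 draws for DLG recovery, and 11-segment
step-and-shoot plans — sizes chosen so every oracle can be exhaustive
while the whole suite stays in the seconds range.

## Known limitations

* No electron-return-effect modelling at interfaces; heterogeneity acts
  only through radiological depth. Differences of several percent at
  lung/bone interfaces are expected and are why clinical tolerances are
  5%, not 2%.
* The linear FFF envelope underestimates far-off-axis falloff curvature
  (documented above).
* Gantry angle enters only through the cryostat correction; phantom
  grids are defined in beam coordinates (no couch/coil modelling beyond
  the density grid itself).
* No 3-D dose grids, wedges, electrons, or local-normalization gamma.
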