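---
title: "Processing MicroED tilt series: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing MicroED tilt series: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microed)
```

## The measurement being modelled

MicroED collects electron-diffraction still frames from a single sub-micron
3D protein crystal held in a cryo-microscope, tilting the goniometer by a
fixed increment (typically 1°) between exposures so that a 40–90° wedge of
reciprocal space is swept with a total electron dose small enough
(≲9 e⁻/Å²) to leave the crystal diffracting throughout. At 200 kV the
electron wavelength is λ = h/√(2m₀eV(1+eV/2m₀c²)) ≈ 0.0251 Å, so the Ewald
sphere of radius 1/λ is nearly flat on the scale of a protein lattice: at
2 Å resolution the sphere deviates from the zero-tilt reciprocal plane by
only `ewald_offset(2, 0.025)` ≈ 0.003 Å⁻¹. This package implements the
reduction of such data to a merged structure-factor set, together with a
forward simulator so every stage can be validated against ground truth.

The chain is: spot picking → difference-vector autoindexing
(`index_tilt_series()`) → zone-normal reflection prediction and
square/circle-mask integration (`process_frames()`) → Laue-symmetry
merging by the maximum-intensity rule (`merge_max()`) → text export
(`write_sf_file()`), with dose and dynamic-scattering diagnostics
(`critical_dose()`, `absence_ratio()`, `max_resolution_per_frame()`).

## Geometry and conventions

* Pixels are 0-based, `(x, y) = (column, row)`, origin at the image
  corner; images are plain matrices indexed `[y + 1, x + 1]`.
* Angles are degrees at every interface and radians internally.
* Reciprocal vectors are in Å⁻¹ with the crystallographic convention
  `a · a* = 1`; a Miller index maps to `r = h a* + k b* + l c*`.
* The default mapping between detector and reciprocal space is the
  flat-Ewald approximation `(gx, gy) = (Δx, Δy)·p/(Lλ)`; the exact
  spherical mapping is available via `mode = "exact"`. The error of the
  flat form is exactly the sagitta `ewald_offset()` quantifies, under
  0.5% of a pixel at the resolutions treated here.
* The effective camera length is not a measured constant of this
  artifact; the default (2000 mm) places ≈1.6 Å at the edge of a 4096-px,
  15.6 µm detector, consistent with frames whose best reflections reach
  ≈1.7 Å. Beam centre and tilt-axis azimuth are calibration inputs in the
  geometry block, defaulting to the image centre and the +x axis.

## The forward simulator

`simulate_tilt_series()` renders what the instrument records, from known
ground truth:

* **Cell and symmetry.** The reference cell (`reference_cell()`) is
  tetragonal lysozyme, a = b = 77 Å, c = 37 Å, P4₃2₁2. Its 2₁ screw axes
  make (2n+1, 0, 0) and (0, 2n+1, 0) systematically absent and the 4₃
  screw restricts (0, 0, l) to l = 4n.
* **Intensities.** One value per symmetry-unique reflection, drawn from an
  exponential (Wilson acentric) distribution whose mean falls off as
  `exp(-B/2d²)` with B = 15 Å² — a realistic contrast range for a
  room-dose protein data set. Equivalents and Friedel mates share the
  value. Absent classes get `leak_fraction` × the local mean (0 by
  default; a positive value emulates dynamic-scattering leakage).
* **Excitation and partiality.** A reflection appears on a frame when its
  rotated lattice point sits within the rocking half-width ρ of the flat
  Ewald plane (|ζ| ≤ ρ). The default ρ = 5×10⁻⁴ Å⁻¹ matches observed
  reflection extents of ~1/1000 Å. Recorded intensity is scaled by a
  triangular partiality 1 − |ζ|/ρ — the simplest symmetric profile that
  makes "keep the maximum observation" a consistent estimator of the full
  intensity.
* **Rendering.** Spots are isotropic Gaussians of σ = 1.5 px (FWHM
  ≈ 3.5 px, inside the 3–5 px range such detectors record) on a constant
  20-count background with Poisson noise; rendering is per-frame seeded
  and bit-reproducible. Dose decay multiplies frame k by g(Dₖ), a plateau
  of 1 up to the critical dose and a linear decline (default rate 0.1 per
  e⁻/Å²) beyond it; the plateau-then-linear form is a parsimonious stand-in
  for the empirically observed "flat, then falling" behaviour.

What the simulator deliberately does **not** model: dynamical (multi-beam)
scattering, mosaic-block or crystal-bending disorder, inelastic background
structure, and detector distortions. Tests passing on simulated data
therefore validate the *reduction algorithms* — geometry, indexing,
prediction, integration, merging and the diagnostics — not the physics the
simulator omits.

## Autoindexing: difference vectors and orthogonal triplets

Spot vectors from frames across the wedge (each mapped to the crystal-fixed
zero-tilt frame using the known tilt) are differenced pairwise; on a
lattice the differences are themselves lattice vectors, so short
differences pile up at ±a*, ±b*, ±c* and their small sums. The stages, and
the design choices inside them:

1. **Length estimates** come from peak picking the density of short
   difference lengths (`estimate_basis_lengths()`), replacing a manual
   measurement on zone images. The *shortest* significant peaks are used,
   not the tallest: sums and harmonics of basis vectors are always more
   numerous than the basis vectors themselves.
2. **Candidates** (`candidate_basis_vectors()`): differences matching an
   estimate within `length_tol` (default 10%) are folded antiparallel and
   clustered by direction (6° cone); cluster means are candidate basis
   vectors weighted by population.
3. **Orthogonal triplets** (`orthogonal_triplets()`): all candidate
   triples with pairwise angles within `angle_tol` (default 5°) of 90°.
   Only right angles are searched — the method as implemented is for
   lattices known to be orthogonal; anything else fails with a clear
   error. Among valid triplets the winner is the one that indexes the
   largest fraction of all spot vectors to near-integers
   (`residual_tol` = 0.2), with total length as tie-break, and all
   triplets compatible with the winner are averaged per axis. The
   consistency score is computed after a least-squares polish of each
   triplet, because raw cluster means carry a few percent of length noise
   that destroys integer agreement at high Miller order.
4. **Degeneracy guards.** Two classes of wrong-but-self-consistent answers
   exist and are handled explicitly. *Harmonics*: an axis may be an
   integer multiple of the true vector; integer division is tried and kept
   only on a substantial (>0.1) jump in indexed fraction, because dividing
   a *correct* axis can never reduce the score. *Centred superlattices*:
   a basis like {(a*+b*)/2, (a*−b*)/2, c*} indexes every spot yet doubles
   the cell; it betrays itself through a parity rule on the indexed
   Miller indices (h+k even for ≥95% of spots, against ≈50% for a true
   cell) and is undone by the corresponding integer transformation.
5. **Refinement** (`refine_basis()`): difference vectors parallel to an
   axis with length ≈ m× the axis length are rescaled by 1/m and
   averaged, then an integer-indexed least-squares polish is applied;
   each step is accepted only if the median fractional residual does not
   increase, so refinement can only help.
6. **Escalation.** `index_tilt_series()` starts from 13 frames × 25 spots
   (the conventional 100–350 spots in total). If the indexed fraction
   stays below 0.9 the spot budget is raised (21×40, then 31×60) — the
   programmatic analogue of choosing more spots from more images when a
   first attempt fails. On the reference simulation, 10/10 random
   orientations recover the cell within 0.1%.

Axis labels follow length: the two most similar lengths become a* and b*,
the remaining one c*; handedness is fixed by a*×b*·c* > 0. The absolute
orientation of the crystal about the beam is not observable from a single
wedge, nor needed: the basis is reported in the crystal-fixed frame.

## Prediction and integration

For each frame, the two strongest indexed spots subtending more than 30°
define the zone normal n = r₁×r₂; every enumerated reflection with
|n̂·r|/|r| below threshold is predicted on the frame. The default threshold
is the per-reflection rocking bound 2ρ/|r| rather than a constant: the
rocking slab has constant *thickness*, so its angular width shrinks with
|r|. Integration draws a square of side 2w+1 (w = 5 px default) with the
inscribed circle of equal diameter; the mean of square-minus-circle pixels
estimates the local background, subtracted from each in-circle pixel before
summing. Both masks are point-symmetric, so linear background gradients
cancel exactly. Negative integrated intensities are retained and flagged —
they are legitimate noise outcomes resolved at merging. An optional ±2 px
centroid refinement absorbs small basis error; it is off by default so the
measured value is strictly the model prediction's.

## Merging and export

Observations are grouped by their canonical representative under Laue
class 4/mmm — point group 422 plus Friedel inversion, the natural merging
class for P4₃2₁2 data without anomalous signal (asymmetric unit
h ≥ k ≥ 0, l ≥ 0). Within each group only the **maximum** intensity is
kept; all other observations are treated as partial recordings and
discarded. This estimator is deliberately crude — it is consistent only
insofar as some frame catches each reflection near the centre of its
rocking profile, which the simulator's convergence test demonstrates
(merged/true intensity rises monotonically as the tilt step shrinks
through 2°, 1°, 0.5°). No inter-crystal scaling is applied before the
maximum; the rule implicitly assumes a common scale, and multi-crystal
merges here inherit that assumption. Since each merged intensity stems
from a single observation, SigI = √I, F = √max(I, 0), SigF = √F; negative
merged intensities clamp to F = 0 and stay flagged in the I column.

`completeness_stats()` compares observed uniques with a brute-force
enumeration of the resolution range mapped to canonical indices, in
equal-reciprocal-volume shells; with the space-group label the absent
classes are excluded from the denominator (observed data cannot contain
them). Multiplicity is total observations over unique count. The exchange
format is a commented plain-text table with columns
`h k l F SIGF I SIGI` that round-trips through `read_sf_file()` at full
precision.

`perturb_dataset()` generates the four control datasets used to probe
model bias in downstream structure solution: uniform-random intensities
within the observed range, permuted intensities, donor intensities from an
unrelated structure, and ±35% multiplicative jitter.

## Diagnostics

* `cumulative_dose()` is the plain product rate × exposure × frames: the
  default protocol (0.01 e⁻/Å²/s, 10 s, ≤90 frames) stays at ≤9 e⁻/Å².
* `critical_dose()` fits normalized intensity vs cumulative dose with a
  plateau-then-linear model by least squares over a changepoint grid and
  keeps the decay only when BIC prefers it over a constant; pooled fitting
  over the tracked reflections is used (per-spot fits would be noisier at
  no benefit for a single changepoint). Tracked intensities are normalized
  to the mean of the first 10 frames. On injected decays at 3% noise the
  changepoint is recovered within ±1 e⁻/Å² and the false-positive rate on
  pure plateaus stays within the BIC's nominal few percent.
* `absence_ratio()` measures intensity leaked into the screw-axis-forbidden
  axial positions, as a percentage of the summed intensity of the four
  comparison reflections (2n+2, ±1, 0) and (2n−2, ±1, 0) — the comparison
  quadruple is kept exactly as conventionally printed, even though other
  "adjacent" definitions exist. Cases with an incomplete quadruple are
  skipped and the count n reported. The ratio is scale-invariant.
* `max_resolution_per_frame()` reports the best d-spacing among detected
  spots per frame; flat for thin well-ordered crystals, degrading with
  |tilt| when high-angle intensities are attenuated (an effectively
  thicker specimen path).

## Numerical and engineering choices

* Tolerances (`length_tol` 10%, `angle_tol` 5°, `residual_tol` 0.2,
  `zone_threshold` 2ρ/|r|) are engineering defaults, all configurable;
  nothing in the method prescribes them.
* Spot picking uses median/MAD background statistics, 8-neighbour local
  maxima, a 3×3 background-subtracted significance test (rejects
  single-pixel Poisson spikes, whose tails are heavier than a Gaussian
  threshold suggests), a beam-centre exclusion disc and an edge margin,
  then a 3×3 centroid refinement (~0.1 px accuracy on rendered spots).
* Degenerate inputs: a box crossing the image edge drops that observation
  with a count; a flat profile yields an FWHM flag, a spot at the beam
  centre an undefined-resolution error; an empty rocking condition warns
  and returns an empty series; fewer than 10 dose points is an error.
* All randomness is seeded explicitly (intensity seed, per-frame noise
  seeds, orientation seeds); identical configurations give byte-identical
  outputs, which `run_microed()` exploits for its determinism contract.

## Problem sizes used in tests and examples

Simulations in the test suite and the worked examples run on a 4×-binned
detector (1024 px, 62.4 µm effective pixels — identical angular coverage
to the full 4096 px frame) and render only the frames each stage needs
(13–31 frames for indexing, wedges of 17–31 frames for end-to-end runs).
These sizes were chosen so the whole suite exercises every stage on a
laptop-class budget; the algorithms are size-agnostic and accept the
full-frame geometry unchanged via `detector_geometry()`.

## Known limitations

* No partiality correction, inter-crystal scaling, Ewald-curvature
  correction or post-refinement: the merge is the plain maximum rule.
* Autoindexing assumes an orthogonal (here tetragonal) lattice; general
  triclinic autoindexing is out of scope.
* The dose model is phenomenological (plateau + linear), not a physical
  damage model; the absence diagnostics quantify dynamic-scattering
  leakage but no correction is attempted.
* The simulator's Gaussian-spot, flat-background world is kinder than real
  detectors; quantitative agreement on real frames will be limited by the
  physics listed above, not by the reduction code paths tested here.
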