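---
title: "Field modelling and susceptometry for printed NMR microcells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field modelling and susceptometry for printed NMR microcells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcell)
```

## The physical model

For every material relevant to solution NMR the induced magnetization
is linear in the applied field, M = χH0, with the volume
susceptibility χ quoted in ppm (negative for diamagnetic water, glass
and resin). A spatial distribution χ(r) perturbs the resonance
frequency; what an NMR line reports is the *nuclear* offset — the
macroscopic flux density corrected by the Lorentz sphere term, because
the nucleus does not feel the field of its own immediate spherical
neighbourhood. In this convention:

* a long cylinder parallel to B0 with interior contrast Δχ shifts its
  interior by Δχ/3 relative to far outside;
* a sphere produces **no** interior shift whatever the mismatch;
* an ellipsoid with semi-axes (a, b, c), long axis c parallel to B0,
  shifts its interior uniformly by (1/3 − N_c)Δχ, with N_c its
  demagnetizing factor (N_a + N_b + N_c = 1).

The third fact is the design principle of the ellipsoidal microcell:
mismatch moves the line but does not broaden it. The package computes
N by the closed elliptic forms for spheroids and by the standard
elliptic-integral quadrature for triaxial shapes
(`demagnetizing_factors()`).

At a flat interface orthogonal to B0 between media χ₁ (below) and χ₂
(above), flux conservation makes the field at the interface the
average of the two bulk values. The on-axis offset at height h above
the interface of a tube of radius R, relative to bulk solvent, is the
semi-infinite-solenoid expression

δ(h) = ((χ₁ − χ₂)/2) (1 − h/√(h² + R²)),

implemented in `interface_offset_on_axis()`. Half the susceptibility
difference is therefore directly readable as the frequency gap between
a thin slice at the interface and a slice in the bulk — the basis of
the susceptometry calculus (`chi_from_interface_shift()`: χ_solid =
χ_solvent + 2Δδ). Because χ is of order 1e-5, all (1 + χ) products are
linearized; the neglected χ² terms are ~1e-11 of the field.

## The forward solver and its discretization

`forward_field_fft()` convolves the susceptibility contrast (χ minus
the map's background) with the z-oriented unit dipole response. Two
kernel constructions are provided:

* **spatial** (default): the point-dipole kernel
  (3cos²θ − 1)·V/(4πr³) sampled at inter-voxel offsets, transformed
  with the map. With the default padding factor 2 per axis the
  circular convolution is an *exact* linear convolution over the
  source support, so the solver agrees with the brute-force summation
  oracle `forward_field_direct()` to machine precision, and the
  physics checks above hold to discretization accuracy.
* **spectral**: the continuum k-space form 1/3 − k_z²/|k|², sampled on
  the discrete frequency grid with the k = 0 term zeroed. This is the
  common quantitative-susceptibility-mapping form; it agrees with the
  spatial kernel for smooth fields but differs at the single-voxel
  scale (and shows mild ringing from the kernel's discontinuity at
  k = 0), which is why the spatial form is the default and the one
  the summation oracle certifies.

The self-voxel convention follows the Lorentz (spherical-cavity)
correction: the voxel containing the evaluation point contributes
nothing. On cubic lattices this is also the spectral kernel's implicit
convention (the k-grid average of k_z²/|k|² is exactly 1/3, so its
r = 0 weight vanishes), and it is what makes the sphere's interior
offset vanish. Offsets are defined up to a global constant; the
constant is pinned so the offset far from all contrast tends to zero.
Non-cubic voxels are rejected unless `anisotropic = TRUE`, purely as a
guard against accidental anisotropy — the kernels themselves are
evaluated at physical coordinates and handle anisotropic spacing
exactly.

## Scenes, presets and the shimming convention

Geometries are painted last-wins onto a uniform background
(`scene()`, `paint()`, `voxelize()`); voxel values are supersampled
means (default 3³ samples per voxel) so material boundaries are
anti-aliased. The background defaults to air, χ = +0.36 ppm. Interface
measurements depend only on same-medium frequency *differences* and
are insensitive to this choice.

The measurement presets (`preset_scene()`) reproduce the geometries
the calculus is calibrated for: a solvent column above
susceptibility-matched glass in a 4.2 mm ID tube ("shigemi"); a
printed 4.0 mm OD, 20 mm resin plug below solvent, including the thin
solvent annulus around the plug ("plug_in_tube"); and the ellipsoidal
microcell, default interior 1.65 × 1.65 × 11.5 mm with a 0.3 mm wall
and a 1.3 mm × 8.5 mm access channel ("microcell").

In the real experiment the magnet is shimmed on a solid-free tube of
the same solvent before the solid-containing sample is inserted, which
removes the tube-end gradients common to both samples. The interface
presets therefore carry a matched-reference scene (solid replaced by
solvent); `simulate_field(..., shimmed = TRUE)` subtracts the two
voxelizations before a single solve (the field is linear in χ). On a
compact simulation domain this matters: without the subtraction, the
solvent–air interface at the top of a short simulated column
contributes spurious gradients of the same order as the glass–solvent
signal being measured.

## Line shapes and diagnostics

`simulate_spectrum()` histograms solvent-voxel offsets — solvent
voxels are those whose supersampled χ matches the solvent value within
a tight tolerance, which deliberately excludes mixed boundary voxels —
weighted by a coil-sensitivity window and an optional slice profile,
then convolves with a Lorentzian. Defaults: 1 Hz full width at half
maximum (a typical non-spinning 1H linewidth), 600.13 MHz spectrometer
frequency for Hz/ppm conversion, histogram bins of a quarter
linewidth. The Lorentzian kernel is renormalized to unit sum and the
small tail mass falling outside the frequency window is folded back by
a uniform rescale, so the spectrum integral equals the total voxel
weight exactly.

The coil profile is a flat 16 mm window with 2 mm raised-cosine
roll-offs, centered 5 mm above the interface by default. No probe
datasheet profile is modelled; the window exists to represent a finite
sensitive region, and all quantitative claims are made on peak
*positions* and widths, which are insensitive to its exact shape.
Slice selection is ideal (rectangular) by default, with a Gaussian
option; radio-frequency pulse shapes are out of scope. A slab-edge
tolerance of 1e-9 of the slice scale keeps voxel centers that land
exactly on the slab boundary inside it regardless of floating-point
representation.

Diagnostics: `peak_position()` returns the intensity maximum, ties
broken toward downfield (positive ppm); `base_width()` returns the
stick-histogram support above a threshold fraction of the maximum
stick. The default threshold is 0.55% of the maximum, the convention
used for quoting residual solvent-line quality at the base. The
threshold interacts with the bin width: with quarter-linewidth bins
the bulk-solvent plateau concentrates into a few tall bins while
interface-shifted spins spread thinly across many, so thresholds much
above ~1% read only the plateau and under-report the physical base.
At 0.55% the measured base width of the simulated matched-tube line
converges to |χ_glass − χ_solvent|/2 as the solvent column grows, the
behaviour the diagnostic exists to capture.

Sign conventions throughout: positive ppm offset = higher frequency =
downfield; a solid more diamagnetic than the solvent (χ_solid <
χ_solvent) produces an upfield (negative) interface shoulder and a
negative Δδ.

## Calibrations and synthetic series

The NaCl model is the calibrated line χ = 0.2·[NaCl] − 9.01 ppm for
D2O (intercept −9.05 ppm for H2O), valid over 0–2 M; evaluation
outside that range warns. The isotope correction Δχ = 2Δδ/s treats the
printed 100/94 factor as the protonation-fraction span between a 97%
D2O and a 97% H2O sample (s = 0.97 − 0.03 = 0.94); whether the
underlying fractions are mole or volume fractions is numerically
immaterial at this precision, and the H2O literature anchor −9.05 ppm
fixes the absolute scale of everything derived from it. Doping
calibrations are ordinary least squares over all supplied
(concentration, shift) points (`fit_linear()`, backed by `stats::lm`),
with the matching concentration read off as the fitted zero crossing
(`doping_zero_crossing()`); a crossing outside the observed sign range
is flagged as an extrapolation. Reported χ values are rounded to two
decimals, the precision the measurement supports; unrounded values are
kept alongside.

`generate_synthetic_series()` draws y = a + bx + N(0, σ) under a fixed
seed. It emulates one feature of the real calibration experiments —
independent Gaussian read-off noise on each measured shift — and
nothing else: no lateral slice gradients, no concentration errors, no
drift. Recovery tests built on it (e.g. the salt slope 0.2 ppm/M
recovered within 0.03 at σ = 0.01 ppm in ≥95% of seeds) therefore
certify the fitting chain, not the spectrometer.

## Numerical choices and problem sizes

Grids used by the shipped tests: the matched-tube simulation runs at
64 × 64 × 256 voxels (0.1 mm transverse, 0.2 mm axial), chosen so the
first solvent layer sits 0.1 mm above the interface, where the closed
form predicts 95% of the h → 0 value — the dominant term in the ~9%
shortfall the tests allow for. The microcell homogeneity check runs at
0.15 mm isotropic with the interior mask eroded by two voxels
(a shrunken ellipsoid), excluding partial-volume wall voxels from the
spread statistic; the quoted result is that the interior standard
deviation stays below 2% of the uniform shift (1/3 − N_c)Δχ, and that
enabling the access channel strictly increases it. The
oracle-equivalence check uses 32³ white-noise maps. These sizes are
the package's accuracy/turnaround compromise; halving the spacing
quarters the discretization error of interface reads at 8× the memory.

Mesh export (`design_mesh()`, `export_stl()`) builds the printed solid
as polar-zone ellipsoid surfaces whose opening rings coincide exactly
with the channel-neck cylinder rings, guaranteeing a closed,
consistently oriented 2-manifold; export refuses non-watertight
meshes. Mesh volume converges to the analytic solid volume as the
facet budget grows (0.4% at 10⁴ facets for the default cell).

## Known limitations

* The field inside the solid below an interface is not modelled (the
  measurement never reads it).
* Shim-coil fields beyond the matched-reference subtraction, radiation
  damping, relaxation weighting and the temperature dependence of χ
  are out of scope.
* The ~0.15 mm cured-surface growth of printed parts is not modelled
  beyond adjusting design dimensions by hand; printed cells are best
  characterized by the measured channel diameter (1.3 mm rather than
  the drawn 1.6 mm), which the defaults adopt.
* Whether the quoted 23 × 3.3 mm ellipsoid describes the interior or
  the exterior of the printed cell is ambiguous at the 0.3 mm wall
  scale; the package takes 1.65 × 1.65 × 11.5 mm as the *interior*
  default, which reproduces the ~131 µL fill volume, and leaves the
  small discrepancy with the 130 µL gravimetric total (which includes
  part of the channel) unreconciled rather than tuning dimensions to
  match it.
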