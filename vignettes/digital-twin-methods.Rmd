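---
title: "Methods: a desk-scale digital twin for cryo-electron tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale digital twin for cryo-electron tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cryotwin)
```

# What the package models

`cryotwin` closes the loop of a cryo-electron tomography (cryo-ET)
experiment entirely in software: it builds a virtual frozen-hydrated
specimen with known ground truth, simulates a transmission electron
microscope (TEM) tilt series with physically motivated image formation,
reconstructs the data with the field's standard algorithms, and scores the
reconstruction against the ground truth. Because every stage is
parameterised, acquisition choices — tilt range, tilt increment, sample
geometry, dose scheduling — can be compared quantitatively before any
beam time is spent.

The pipeline is: declarative YAML configuration → virtual sample
(geometry + particles + amorphous ice) → per-tilt multislice image
simulation (beam damage → projected potential → wave propagation → optics →
detector) → contrast-transfer correction and weighted back projection →
wedge-masked subtomogram averaging → Fourier shell correlation (FSC)
against the rendered ground-truth density.

# The virtual specimen

Two geometries are supported, both centred on the origin with the tilt axis
along +y and the beam antiparallel to +z at zero tilt (all lengths in
Angstroms):

* **Planar lamella** — a slab of thickness `z_depth`. When tilted by
  $\alpha$ its beam path grows as $D/D_0 = 1/\cos\alpha$, the geometric root
  of the missing-wedge economics studied here.
* **Cylinder** — axis along the tilt axis, so the beam path is independent
  of tilt. The radius (and in-plane centre offset) is parameterised along
  the axis by natural cubic splines, which lets "natural", non-ideal shapes
  be described with a handful of knots; constant knots reproduce an exact
  cylinder to rounding error.

Particles are atomic models: read from PDB/mmCIF via bio3d, or produced by
`make_phantom_particle()` — a deterministic pseudo-protein (uniform atoms in
a ball, protein-like C/N/O/S composition, centroid exactly at the origin,
no accidental point symmetry) so tests and experiments need no downloads.
Placement guarantees non-overlap of bounding spheres (rejection sampling,
at most 10^4 attempts per particle, loud failure reporting the achieved
count) and containment with a bounding-radius margin. A single particle
defaults to the centre of the sample volume. `mill()` cuts the assembled
atomic model to an arbitrary signed region.

Amorphous ice comes in two flavours, as in practice:

* **Random water** — rigid H2O molecules at uniform random positions and
  orientations, `round(density * volume)` molecules (0.031 molecules/A^3
  reproduces vitreous ice at 0.94 g/cm^3). No minimum intermolecular
  distance is enforced; relaxing the water would need molecular dynamics,
  which is out of scope.
* **Gaussian random field (GRF)** — a continuum potential: Fourier-filtered
  white noise with amplitude spectrum $\exp(-q^2\ell^2/4)$ (variance
  spectrum Gaussian with correlation length $\ell$), rescaled analytically
  so the expected voxel variance equals the request. The spectrum family is
  a documented stand-in — the physically correct ice spectrum would be
  calibrated against scattering data — and is pluggable through the
  `spectrum` argument. Defaults: zero mean (potentials are measured
  relative to the uniform solvent background, which produces no contrast
  for a slab), variance 1 V^2, correlation length 8 A. For comparison, a
  random-water model at 0.031 molecules/A^3 would give ~2 V of potential
  fluctuation at the 8 A scale, so 1 V is conservative.

# Image formation

**Atomic potential.** Each atom deposits an integrated projected potential
of `atom_amplitude` (default 30) V·A^3 per unit atomic number, shaped as a
Gaussian of width `atom_sigma` (default 1.0 A). This single-Gaussian
parameterisation is a deliberate simplification: tabulated multi-Gaussian
electron scattering factors (Kirkland- or Lobato-style) give integrated
potentials of roughly 15–25 V·A^3 per unit Z for light elements with
element-specific shapes. The approximation affects absolute contrast
scales, not the comparative questions the package answers; the amplitude
and width are configurable, and a coefficient-table parameterisation can be
slotted in at `project_potential()` without touching the rest of the chain.

**Beam damage.** Radiation damage is an isotropic Gaussian blur of the
specimen potential with $B = 8\pi^2 D_E S_E$ (accumulated dose $D_E$,
sensitivity $S_E$ = 0.022 A^2/e^- by default; calibrated values run
0.020–0.090). In Fourier space the filter is $\exp(-q^2B/4)$. Because both
the filter and the atom profile are Gaussian, `project_potential()` folds
the damage into the deposited atom width analytically
($\sigma_\mathrm{eff}^2 = \sigma_a^2 + B/8\pi^2$), which is exactly the
composition with `apply_beam_damage()` for the atomic potential; the
lateral 2D filtering per slice equals isotropic 3D filtering for projected
slices because the axial blur is integrated out within each slice. The GRF
ice is treated as already-damaged background (its correlation length is a
phenomenological input), so it is not re-filtered per image. The
accumulated dose of the k-th acquired image is $k \times$ flux $\times$
exposure, so dose-symmetric ordering gives low tilts the least damage.

**Multislice.** The beam path is divided into 5 A slices (1 A pixels in the
full-scale configuration; the desk-scale sweeps use 2 A). Each slice is an
infinitesimally thin phase object $t(x) = \exp(i\sigma V_\mathrm{proj})$
with $\sigma$ the relativistic interaction constant, alternated with
Fresnel propagation $P(q)=\exp(-i\pi\lambda t_s q^2)$. An anti-alias
aperture at 2/3 of the Nyquist frequency suppresses wrap-around scattering.
Runs of empty slices are propagated in a single Fresnel step (the
propagator is a pure Fourier multiplier, so this is exact). With the
inelastic mean free path $\Lambda_{in}$ finite, each slice also applies
Beer–Lambert amplitude attenuation $\exp(-t_s \cdot \mathrm{interior} /
2\Lambda_{in})$ using the sample-interior mask. This term is what carries
the planar sample's $1/\cos\alpha$ intensity loss
($I/I_0 = \exp((1 - 1/\cos\alpha) D_0/\Lambda_{in})$, the closed form in
`relative_intensity()`); explicit inelastic scattering and energy filtering
are not simulated. With $\Lambda_{in} = \infty$ the chain is a pure phase
object and conserves total intensity to rounding.

**Optics.** The exit wave is multiplied in Fourier space by
$H(q) = E_t E_s \exp(-i(\chi + \phi_{pp}))$ with
$\chi = \pi\lambda\Delta f q^2 - \tfrac{\pi}{2} C_s \lambda^3 q^4$
(underfocus positive), a temporal envelope from the chromatic defocus
spread $\delta F = C_c\sqrt{(\Delta E/E^*)^2 + (\Delta V/V)^2 + (2\Delta
I/I)^2}$ treated as an rms spread ($E_t = \exp(-\pi^2\lambda^2\delta F^2
q^4/2)$; $E^*$ relativistically corrected), and a spatial envelope from the
source spread and the gradient of $\chi$
($E_s = \exp(-(\pi\theta_c/\lambda)^2 (C_s\lambda^3q^3 - \Delta f \lambda
q)^2)$). The phase-plate shift applies to scattered beams only (H(0) = 1).
In the weak-phase limit the image contrast spectrum is
$2\sigma \sin(\chi + \phi_{pp}) E_t E_s \hat V(q)$; the test suite verifies
the full chain against this analytic form to better than 2%.

**Detector.** Expected counts are intensity × dose × pixel area; the DQE
$\mathrm{DQE}(q) = \mathrm{DQE}_0 (1 - a (q/q_N)^2)$ (clipped at zero;
parametric because no standard functional form exists) filters the expected
counts in Fourier space; Poisson noise is drawn per pixel. Negative
filtered expectations are clipped to zero and counted.

# Reconstruction and scoring

Counts are converted to zero-mean fractional contrast per image, which
removes dose and attenuation scales. CTF correction is **phase flipping**
(multiplying by the sign of $\sin(\chi+\phi_{pp})$), which corrects
contrast inversions only — the choice made for robustness since a Wiener
filter amplifies noise near the CTF zeros. For per-particle work each
projection is flipped at the particle-centre defocus: nominal defocus plus
the particle's beam-frame z offset at that tilt. This is the
subtomogram-averaging route to approximate 3D CTF correction without
extending the reconstruction core.

**Weighted back projection** filters each projection with a 1D ramp
perpendicular to the tilt axis, scaled by the projection's local angular
gap (mean of its two neighbouring tilt increments, in radians; uniform
spacing reduces exactly to the classical $\pi/N$ ramp normalisation), then
back-projects with bilinear interpolation (sparse-matrix formulation).
Per-particle boxes are reconstructed directly in particle-centred
coordinates; a particle is skipped (and counted) when the box's inscribed
sphere would leave the image field of view at some tilt.

**Subtomogram averaging** rotates each box (and its missing-wedge mask) to
the reference orientation, sums the masked Fourier transforms and divides
by the summed mask with a Wiener-style floor of $10^{-3}\times$ the maximum
summed mask; never-covered regions are zero-filled and reported. The wedge
mask marks directions with $\mathrm{atan2}(|q_z|,|q_x|) \le$ max tilt
(invariant along the rotation axis).

**FSC.** Shells are one Fourier voxel wide; the summary score is the
element-count-weighted average $\sum N_i \mathrm{FSC}_i / \sum N_i$.
Anisotropy is probed by restricting the correlation to elements within 15
degrees of a named reciprocal plane (an angular-slab convention, declared
here because great-circle alternatives exist); resolution bins split at
half the Nyquist frequency. Before scoring, reconstructions and ground
truth are multiplied by a soft spherical mask (particle radius + 10 A, 6 A
cosine edge) — standard subtomogram practice, since solvent voxels carry no
particle signal. Sweep summaries restrict shells to the transferred band
(q at most 2/3 of the detector Nyquist frequency, the simulator's
anti-alias aperture): beyond it there is no signal by construction, only
noise dilution.

# The desk-scale study conditions

The missing-wedge experiments (`run_missing_wedge_sweep()`,
`quality_vs_projections()`, `projections_required()`) reproduce
comparative, ordinal results at desk scale, not absolute full-scale values.
The conditions were fixed once, from the following reasoning, and are the
package defaults:

* **Geometry at 1:10 scale.** Thickness/diameter 150 A with inelastic mean
  free path 314 A — the same dimensionless ratio $D_0/\Lambda_{in}$ as the
  150 nm lamella with 314 nm mean free path used in the closed-form tilt
  model, so relative intensity vs tilt is preserved exactly. The slab is
  20/3 times wider than thick, mirroring a 1000 nm x 150 nm lamella. At
  this thickness the cylinder's rim lies outside the 128 A field of view at
  every tilt, as it does (relatively) at full scale.
* **Phantom.** 12000 atoms in a 40 A-radius ball (protein-like heavy-atom
  density), one fixed orientation for all copies — the layout used when
  probing direction-dependent wedge artefacts — at the sample centre.
* **Scan.** 35 projections (fixed-count mode) or a 180/34 ~ 5.3 degree
  increment (fixed-increment mode), dose-symmetric ordering, total
  per-particle dose 120 e^-/A^2 divided equally among the projections.
  N = 35 keeps the Crowther-limited band $q \le N/(\pi D_\mathrm{mask})$
  above the transferred band at full tilt range, so angular sampling is not
  the binding constraint — the regime of the full-scale studies, which used
  90 projections.
* **Ensemble statistics.** Full-scale studies average maps over thousands
  of particles, which makes the average signal-dominated: quality trends
  then reflect Fourier coverage, damage and attenuation rather than shot
  noise. A desk-scale run that averaged a handful of particles at the same
  dose would be shot-noise-limited — and in that regime the coverage gain
  of a wider tilt range is cancelled almost exactly by the thinner angular
  sampling per Fourier element, hiding the effects under study. Each
  simulated copy therefore stands in for an ensemble of 100 particles:
  `dose_scale` multiplies the dose entering the detector's counting
  statistics (the Poisson statistics of an M-fold dose equal those of an
  M-particle average), while beam damage follows the true per-particle
  accumulated dose. Two explicit copies, each in its own ice patch and
  noise realisation, are averaged per cell, giving the statistics of a
  200-particle average.

What the sweeps do **not** emulate: molecular crowding (one particle per
field of view), orientation diversity, tilt-series misalignment (poses and
angles are taken as known), defocus gradients within one image, energy
filtering, and detector MTF distinct from DQE. Passing sweeps therefore
demonstrate the comparative physics of coverage, attenuation and dose
scheduling — not absolute attainable resolutions on real data.

# Numerical choices and degenerate inputs

* Angles are degrees at every interface, radians internally.
* FFT convention: forward kernel $e^{-2\pi i qx}$; frequency grids in 1/A,
  native FFT order.
* Dose-symmetric tie rule: the positive member of each $\pm$ pair first.
* Even fixed-count scans include both endpoints (and therefore skip exact
  zero tilt); the paper-style 90-projection full-range scan spans -90..+90.
* Phase-flip sign at exact CTF zeros (including DC without a phase plate)
  is +1, so double flipping is the identity.
* `wbp_reconstruct()` refuses fewer than two projections; zero-power FSC
  shells are recorded as NA, not dropped; an empty FSC selection is an
  error; placement failures report the achieved count.
* Rejection sampling bound: 10^4 attempts per particle.
* The Wiener floor in averaging is 1e-3 of the maximum summed mask.
* Seeds: every stochastic stage (placement, orientations, ice, detector)
  is reproducible given the configured seeds; sweep tables are
  bit-identical for identical specs.

# Known limitations

* The single-Gaussian atomic potential under-resolves true atomic form
  factors; absolute contrast is approximate.
* Intensity loss is geometric (Beer–Lambert through the interior mask);
  chromatic blurring of inelastically scattered electrons is not modelled,
  so the high-tilt penalty for thick planar samples is, if anything,
  understated — consistent with treating holder shadowing as out of scope.
* The GRF ice spectrum is a stand-in family, not a calibrated ice model.
* Local (per-voxel) FSC maps are not implemented; global, banded and
  plane-restricted FSC only.
* The sample archive is an RDS container with a schema version; it is
  lossless and self-describing within R but not a cross-language format.
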