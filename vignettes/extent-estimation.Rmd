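---
title: "Estimating cortical source extent with extended-source beamformers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cortical source extent with extended-source beamformers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamext)
```

## The problem

MEG source reconstruction almost always models neural activity as point
dipoles, yet real cortical activations occupy patches of tissue. `beamext`
asks and answers a concrete methodological question: if the source model of
a minimum-variance beamformer is made *extended* — a disc of elemental
dipoles, or a patch that follows the folded cortical sheet — can the spatial
extent of the generating activity be recovered from the data, and under what
conditions does the estimate break down?

Everything happens in simulation. The package generates its own cortical
geometry, sensor arrays, and noisy epochs, so the study is fully
reproducible from a seed.

## Model and procedure

**Forward model.** Sources live inside a homogeneous conducting sphere
(radius 90 mm by default); the magnetic field of each elemental dipole is
the Sarvas closed form, projected on radially oriented magnetometers (or
axial gradiometers) packed quasi-uniformly on a 120° spherical cap of radius
110 mm. A single sphere is used deliberately: conductor refinement shifts
absolute field values but not the structure of the extent-estimation
problem. Units are fixed throughout: geometry in mm, moments in nAm,
fields in fT.

**Extended sources.** A *disc* patch is a square grid (1 mm spacing) in the
plane perpendicular to a reference orientation, masked to the requested
radius; every element shares that orientation. A *cortical* patch is the
set of mesh vertices within a geodesic (along-mesh) distance of a target
vertex, each element oriented along its local vertex normal. In both cases
the elements share one time course — a coherent 40 Hz sinusoid — and a
uniform current density: a total moment Q is split equally over elements.
A constant-current-density mode (moment = density × element area, default
50 pAm/mm²) is available for studying how sensor-level SNR grows with
active area. Element areas use barycentric lumping (one third of incident
triangle area) on meshes and spacing² on disc grids.

**Beamformer.** Per analysis window (100 epochs × 120 samples at 600 Hz)
the sample covariance `C` is pooled over all epochs and samples, with no
regularisation — a singular covariance is an error, not something to be
papered over, because the scan statistic is meaningful only for the
unregularised minimum-variance solution. The weights are the unit-gain
solution `w = C⁻¹l/(lᵀC⁻¹l)` and the output is the pseudo-Z,
`wᵀCw / (σ² wᵀw)`, with `σ²` the known simulated white-noise variance (an
option estimates it from the zero-strength window instead). On hot paths the
algebraically identical closed form `(lᵀC⁻¹l)/(σ² lᵀC⁻²l)` is used; a test
asserts the equivalence.

**Orientation.** Disc models need an orientation per candidate location.
The fast solver treats the lead field as linear in orientation, `l(u) = Lu`
with `L` the three canonical-orientation disc lead fields, and maximises the
pseudo-Z as a 3×3 generalized eigenproblem. Two numerical guards matter in
a spherical conductor: (i) basis directions whose lead field is below 1e-3
of the dominant singular value are projected out — the pseudo-Z is
scale-invariant, so without the guard the solver can lock onto the
numerically tiny residual pattern of a magnetically silent direction; (ii)
the sign is fixed to a positive leading component (u and −u are physically
identical). The linearity assumption is exact for points but ignores that
rotating an extended disc also moves its elements; the exhaustive
"spinning" search (200 quasi-uniform hemisphere directions plus a local
simplex refinement, ~5° resolution) re-grows the disc per direction and is
the reference at large extents and high SNR, where the linearised solver
underestimates extent.

**The scan.** Model radius sweeps 0–20 mm (2 mm steps at desk scale). The
estimated extent is the radius of maximum pseudo-Z; exact ties resolve to
the smallest radius (parsimony), and a curve flat to within 5% is flagged
low-confidence rather than trusted. Three position strategies mirror the
practical options: fixed at the target, simplex-optimised from the target
(≤200 evaluations, boundary-clipped candidates penalised and flagged), or —
for cortical models — an exhaustive scan over all candidate vertices within
25 mm of the target, with ties going to the nearest candidate. The
orientation solver is re-run at every candidate position; cheaper variants
are configuration options.

## The synthetic cortex

The generator emulates the two properties of a real pial surface that drive
extent estimation: ~1 mm vertex spacing (mean edge length is rescaled to
within a few percent of the request) and the coexistence of strongly folded
and nearly flat regions. A triangular lattice is folded by a product
sinusoid (default amplitude 3 mm, wavelength 25 mm) whose amplitude ramps
across the sheet — one end stays smooth like a gyral crown, the other is
fully folded — and the sheet is bent onto a 200 mm spherical cap centred
65 mm above the conductor centre, below the helmet. With these defaults a
median split of 10 mm patches by curvature (mean angular deviation of
element normals from the patch mean normal) gives curved patches of about
20 ± 4° and flat ones of about 6 ± 4°, i.e. two clearly separated regimes.
A small seeded in-plane jitter removes lattice symmetry artefacts.

What the generator does *not* emulate: cortical thickness and the
white/pial distinction, long-range folding patterns, inter-subject
variability, and realistic conductor geometry. Passing tests therefore show
that the estimator behaves as designed on a folded sheet with known truth;
they do not certify accuracy on any individual anatomy.

The curvature statistic deserves a note: "average change in orientation
across a patch" admits several formalisations (mean pairwise angle, mean
deviation from the mean normal, discrete curvature tensors). We use the
mean angular deviation from the renormalised mean normal — the simplest
statistic that is 0 for flat patches, monotone in fold amplitude, and has a
closed form on a spherical cap (used as a test oracle). A patch whose
normals cancel entirely is flagged maximally curved (90°).

## Noise model and SNR

White sensor noise is generated directly as discrete-time Gaussian samples
with per-channel standard deviation `density × √bandwidth` (default
10 fT/√Hz × √80 Hz ≈ 89 fT rms); the noise is not band-limited, which keeps
the quoted rms exact and leaves the 35–45 Hz band statistics unchanged.
Spatially coloured noise is the summed field of 100 randomly chosen
cortical dipoles (1 nAm each) with independent Gaussian time courses; its
channel covariance has rank ≤ 100, which is exactly why a minimum-variance
beamformer suppresses it well at moderate levels.

SNR is defined as the ratio of 35–45 Hz band power (periodogram with a
rectangular window, bins whose centre lies in the closed band, averaged
over epochs and channels) between the analysis window and the
zero-strength reference window, minus 1 — so a null window scores 0 by
construction and SNR grows as Q². The 200 ms window at 600 Hz gives 5 Hz
bin spacing, placing the 40 Hz activation exactly on a bin.

## Design choices that were genuinely open

* **Geodesic distance** is graph shortest-path along mesh edges (igraph),
  not exact polyhedral geodesics: patches are defined by distance "along
  grid vertices", and the ~10–20% metric inflation of a lattice graph
  affects truth and model identically, so matched recovery is unaffected.
* **Epoch phase** of the 40 Hz activation is coherent across epochs: the
  beamformer consumes only the covariance, which is phase-insensitive here.
* **Surface shifts** (co-registration error emulation: 2, 5, 10 mm in a
  seeded random direction) are pure translations applied to the *model*
  surface while data come from the unshifted truth. Rotation errors are not
  modelled, matching the rigid-shift formulation.
* **Sampling rate** 600 Hz follows from 120 samples per 200 ms window.
* **Per-source regressions** of estimated on true extent pool noise
  realisations (a flag could aggregate per-seed means instead); group
  contrasts between flat and curved sources use a pooled two-sample t on
  the per-source gradients, and the count of sources with positive gradient
  is tested against chance with an exact one-tailed binomial test.
* **Q/N moment splitting** on meshes assumes near-uniform vertex spacing
  (true by construction here); the constant-current-density mode uses the
  actual lumped areas instead.
* An optional Gaussian distance taper on patch activation exists
  (`assign_moments` operates on any weighting) but is off by default; the
  uniform profile is the reference condition.

## Problem sizes and runtime

The package's study defaults are desk-scale: 120 channels, an 80 mm sheet
at 1 mm spacing (~12,700 vertices), radii 0–20 mm in 2 mm steps, 10 target
sources, 3 noise realisations. The full surface-recovery experiment at
these sizes takes ~5 minutes on one core; per-radius candidate patch lead
fields are precomputed per source, which is what makes the 25 mm
constrained vertex scan (≈1,900 candidate centres) cheap per window. A
full-scale configuration (275 channels, 1 mm radius steps, 10 seeds) is a
matter of changing `experiment_config()` arguments and is proportionally
slower.

## Known limitations

* The spherical conductor and idealised helmet mean *absolute* quantities
  that depend on lead-field similarity are geometry-specific. The clearest
  case is the shallowness of the pseudo-Z-vs-radius curve: with this
  geometry a dipolar model retains ≈80% of the matched 10 mm disc model's
  output at a window SNR of 12, and we verified across source depths,
  channel counts and sensor kinds that this ratio stays well below the
  mid-90s seen with a real multisphere/anatomy setup. Qualitative
  behaviour (shallow curves at low SNR, sharpening with SNR) is
  geometry-independent.
* Sources near the sheet's smooth end have near-radial normals and hence
  weak fields; this is physically faithful (gyral crowns are MEG-quiet) but
  means "flat" sources are also low-SNR sources, which couples the
  curvature and SNR effects just as it does on a real cortex.
* Only concentric patches are modelled; line sources and arbitrarily shaped
  patches are out of scope.
* No vector beamformers, eigenspace variants, or between-patch correlation
  modelling.
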