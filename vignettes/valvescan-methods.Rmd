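---
title: "Multi-scale valve-strip analysis: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale valve-strip analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvescan)
```

## The problem

Mitral (MV) and tricuspid (TV) valve assemblies are not one material: a
strip dissected from papillary muscle (PM) through chordae tendinae (CT) to
leaflet (LL) crosses two diffuse tissue transitions, PM–CT (muscle to dense
fibrillar collagen) and CT–LL (one collagen architecture to another). These
transition regions, not the pure tissues, are where mechanical failure
concentrates. Characterising them requires observing two scales at once:

* **molecular** — scanning fiber X-ray diffraction along the strip gives,
  per scan point, the collagen D-period (axial repeat, ~67 nm, measured
  from its 5th meridional order), the muscle equatorial (1,1) d-spacing,
  the relative muscle/collagen composition from the two reflections'
  intensities, and the azimuthal spread of diffraction (fiber alignment);
* **tissue** — video extensometry of fiducial dots drawn on the strip,
  combined with the pull rig's load log and regional cross-sections, gives
  per-region engineering strain, stress–strain curves, toe and linear
  moduli, ultimate stress and the tear location.

`valvescan` implements both analysis chains and a synthetic phantom that
generates all three raw data products with known ground truth, so the full
pipeline can be validated end to end on a desk.

## The phantom

`make_phantom()` builds a 30 mm strip segmented as PM (0–8 mm), PM–CT
(8–11 mm), CT (11–19 mm), CT–LL (19–22 mm), LL (22–30 mm). All of the
following are overridable fields of the preset configuration.

**Composition.** The relative muscle fraction $f_m(x)$ sits at a plateau
(default 0.85) in the PM, falls linearly across the PM–CT segment — the
transition is diffuse, spanning a few millimetres, with a near-linear
decrease of muscle relative to collagen — and is exactly 0 from pure CT
onward ("no muscle detected" in chordae). Rendered reflection amplitudes
are proportional to $f_m$ (muscle (1,0)/(1,1)) and $1-f_m$ (collagen
orders), with the (1,1) and the collagen 5th order sharing one weight so
that composition analysis with calibration weight $w = 1$ recovers
$f_m$ directly.

**Molecular strain coupling.** The local molecular strain is modelled as
$\varepsilon_{mol}(x) = c(x)\,\varepsilon_{eng}$ with $c(x)$ a Gaussian
bump (amplitude 0.05, width 1.2 mm) centred on the PM–CT junction atop a
baseline of 0.02. The experiments report the phenomenon — molecular strain
localises at the PM–CT transition — but no functional form; the Gaussian
bump is the simplest shape with a controllable locus and width. The
rendered D-period is $D(x) = D_0 (1 + c(x)\varepsilon_{eng})$ with
$D_0 = 67.0$ nm.

**Muscle lattice.** The resting (1,1) d-spacing defaults to 24.5 nm
(within the physiological myofilament-lattice range) and shrinks linearly
with strain (gain 0.3), standing in for lattice compression as sarcomeres
lengthen. The value is deliberately treated as a *relative* measure
throughout — its absolute relation to sarcomere length is loose — and the
default was chosen so the (1,1) stays radially clear of the 3rd order of
the 90°-rotated collagen population near the CT–LL junction: reflections
that are physically separate must stay separate on the detector.

**Orientation.** Azimuthal arc spread $\sigma_\chi(x, \varepsilon)$ starts
from a per-position profile (CT most aligned at ~10°, LL broadest at ~25°)
and contracts with strain, $\sigma_\chi \propto \max(0.5,\,
1 - 2\varepsilon_{eng})$ — fibers align as the sample is stretched, never
the reverse. Near the CT–LL junction a second collagen population rotated
by 90° is rendered (weight up to 1.5× the axial one, Gaussian footprint of
0.8 mm); this is the orientation signature used to call the CT–LL boundary,
which carries no composition contrast.

**Constitutive model and Table-derived presets.** Each region follows a
C¹-continuous toe/linear/failure law: an exponential toe
$\sigma = (E_t/k)(e^{k\varepsilon} - 1)$ up to $\varepsilon_{toe}$
(40% of the strain at capacity, carrying 15% of the capacity stress), a
linear branch with modulus $E$ up to $(\varepsilon_{ult}, \sigma_{ult})$,
then a linear drop over a strain width of 0.6 to a residual plateau at
50% — the shape of published soft-tissue failure pulls, with the softening
width chosen wide enough that the tear develops over many video frames
rather than in one.

The preset per-region ultimate stresses are the published microscopy-derived
values for bisected MV and TV pulls. A key modelling decision: in a series
pull one force runs through the whole strip, so the per-region "ultimate
stress" table from such an experiment is the common tear force divided by
each region's cross-section, and only the tear site actually reaches its
material limit. The phantom therefore chooses areas
$A_i = F_{tear}/\sigma_{table,i}$ (a thick PM of ~27 mm² against a thin
CT chord of ~0.2 mm² for the MV — anatomically sensible), designates the
PM–CT transition as the weak link (it is where tears are observed), and
gives every other region a 1.25× capacity margin. Every region's peak
recorded stress in a simulated pull then equals its preset value, while
only PM–CT fails — exactly the structure of the source data.

**Mechanical solver.** `solve_series_pull()` enforces equal force
($\sigma_i A_i = F$) and displacement conservation
($\sum \varepsilon_i L_{0,i} = D$) by bracketed root finding on $F$; the
ascending inverse strain-at-stress is closed-form, so equilibria are exact
to ~1e-13. Past capacity the weak region follows its softening branch while
the others unload; if the intact regions' elastic recovery outruns the
softening extension (snap-back), no softening equilibrium exists at the
imposed displacement and the state jumps to the residual plateau — a sudden
tear. Pull simulations always ramp through the force peak.

## Rendering

Diffraction frames are phenomenological, not physical optics: arcs are
radial Gaussians (σ = 2 px) at the exact geometric radius
$r = (L/p)\tan(2\arcsin(\lambda/2d))$, with azimuthal Gaussian lobes,
a smooth power-law background, a central beamstop disc, and optional
Poisson noise (the only noise model — photon counting; a seed is mandatory
for any stochastic render). The default geometry (λ = 1.033 Å, 2500 mm,
0.172 mm pixels, 512², beam center on the half-pixel symmetry point) puts
collagen orders 1–9 on the detector; no structure factors, polarization,
solid-angle or flat-field effects are modelled, so the reduction deliberately
omits those corrections too. The default peak amplitude (450 counts) sets
the 5th-order signal-to-noise near 20 under Poisson sampling.

Video frames are dark Gaussian dots (σ = 3 px) at 12 px/mm on a light
background, one dot at every region boundary and one mid-region, advected
by the solver's per-region strain truth; 5 fps matches the frame-extraction
convention of the source experiments.

## Reduction and fitting conventions

* Fiber axis vertical; meridional = vertical sector, equatorial =
  horizontal, ±15° half-angle by default (the upstream analysis suite never
  states its sector widths; 15° is a declared convention).
* Radial binning is 1 px with pixel-center assignment. Each bin's q value
  is evaluated at the bin's *pixel-centroid radius*: in a narrow sector the
  pixels cluster off the nominal bin center and the naive labelling biases
  d-spacings by ~0.2 px.
* Background: morphological opening (rolling minimum then maximum, window
  41 bins, ends padded by linear extrapolation) follows any monotone
  background exactly and removes peaks narrower than the window; an
  iterated lower-envelope line fit is available as `linear_local`.
* Peaks are Gaussian-plus-linear-baseline least squares (pseudo-Voigt
  optional), windows seeded from the expected spacing ±5% and refined by
  local-maximum search; a fit whose center leaves the search band is
  rejected (a neighbouring reflection must not masquerade as the target).
  Areas are analytic from the fitted parameters. Non-convergence returns a
  flagged null fit, never a silent zero.
* The D-period uses the 5th order only, `D = 5 * d5`; other orders feed a
  consistency diagnostic (`n * d_n` constant to ~0.05% on synthetic
  frames, with orders hugging the beamstop excluded).
* Orientation: two-lobed circular Gaussian fit to the 1°-binned azimuthal
  profile of the 5th-order band. Isotropy is declared when the modulation
  depth of the circularly smoothed profile falls below 0.1 (the smoothing
  matters: raw 1° bins at moderate radii hold a handful of pixels and are
  dominated by radial sampling noise). The plot ellipse has minor axis
  `b = min(1, 5°/spread)` — inversely proportional to the angular spread,
  with the 5° scale saturating at b = a; isotropic points are drawn as
  dots with b = 0.1 a.
* Composition: `pct_muscle = 100 * I11/(I11 + w*I5)` with `w = 1` by
  default; the upstream normalization is inherited and unspecified, so `w`
  is exposed as a calibration. These are relative percentages of the two
  load-bearing components, never absolute mass fractions.
* Transition calls: PM–CT spans the interpolated crossings of 80% down to
  5% muscle (thresholds are declared conventions; the source drew
  boundaries by eye). CT–LL requires the orientation signature (fiber
  direction rotated > 45° from the chordae axis); without orientation data
  no CT–LL call is made and a warning is raised.

## Mechanics conventions

Strain references the first video frame; stress is
`load_g * 9.80665e-3 / area` MPa. Failure on a stress series is a drop
below 90% of the running maximum sustained for 3 consecutive samples
(declared convention; the experiments identified failure visually). The
linear modulus is the steepest sustained sliding-window slope (window 20%
of the pre-failure series), the toe modulus the first window's slope, and
multiple low-slope plateaus before the linear rise are reported as multiple
toe intervals, a pattern seen in leaflet curves where fiber re-arrangement
delays loading.

**Failure localisation.** Under a series pull every region's stress series
is the one recorded force rescaled, so the stress-drop frame ties across
regions and cannot localise the tear by itself. `failure_locus()` breaks
frame ties by the post-drop strain direction — the torn region keeps
extending while intact regions unload and their strain recedes — and only
then by lower ultimate stress. This mirrors what the video shows in a real
pull: the tear gapes while the rest of the strip relaxes.

## What the tests do and do not show

The test suite and the validation runs exercise, end to end: Table-preset
recovery of all per-region ultimate stresses within 2% through the full
render→detect→track→stress→features chain; D-period recovery (0.2%
noise-free, 0.5% under Poisson noise in ≥95% of seeds); composition within
5 points of $100 f_m(x)$ with pure CT reading exactly 0%; strain-per-
thickness argmax inside the PM–CT interval and tear locus PM–CT in ≥95% of
50 jittered, Poisson-noised runs; orientation angle/spread within 2° up to
30° spreads; and force balance to 1e-6 with closed-form two-spring checks.

Problem sizes were chosen as the smallest that still exercise every code
path honestly: full 512² frames wherever a criterion speaks about the
default geometry, a half-distance 256² detector (identical physics, arcs at
half radius) for the 50-replicate localisation study, and solver-truth
strain series (bypassing video rendering) for that study's failure-locus
side — the video chain is itself validated by the Table-recovery runs.

Passing these tests shows the pipeline is *internally* correct: it
recovers what the phantom encodes. It does not show that real detector
images (with structure factors, disorder, beam polarization, detector
point-spread), real Sharpie dots (irregular, smearing), or real tissue
heterogeneity are handled; the phantom's diffuse transitions, Gaussian
arcs and clean dots are idealisations. The (1,1)-to-sarcomere relation in
particular is only ever treated as relative.

## Known limitations

* No multi-peak deconvolution: overlapping reflections are out of scope by
  design; the generator keeps them radially separated as they are
  physically.
* The constitutive model is elastic-with-failure; no viscoelasticity,
  preconditioning or hysteresis, and no fitting of the model back to
  measured curves.
* Beam geometry defaults are stand-ins: the source defers its apparatus
  description, so the defaults were chosen for coverage of orders 1–9,
  not to match a beamline.
* The AV preset is synthetic end to end (no published values exist) and
  carries no validation targets.

## A short worked example

```{r example, eval = FALSE}
ph <- make_phantom("MV")

# molecular side: scan, composition, strain map, failure predictor
tab  <- run_xrd_scan(ph, levels = c(0, 10))
comp <- composition_profile(tab[tab$eng_strain_pct == 0, ])
map  <- molecular_strain_map(tab)
spt  <- strain_per_thickness(map, ph$thickness_knots)
attr(spt, "argmax_mm")       # predicted failure locus, mm (inside 8-11)

# tissue side: full video-extensometry pipeline
mech <- run_mechanics_pipeline(ph)
vapply(mech$features, `[[`, numeric(1), "ultimate_stress")
mech$failure_locus           # "PM-CT"
```
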