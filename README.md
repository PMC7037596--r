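# valvescan

Multi-scale analysis of heart-valve strips: scanning fiber X-ray
diffraction reduction coupled with video-extensometry mechanics.

## The problem

Strips dissected from mitral (MV) and tricuspid (TV) valves run from
papillary muscle (PM) through chordae tendinae (CT) to leaflet (LL), and
cross two *diffuse* tissue transitions — PM–CT (muscle into dense fibrillar
collagen) and CT–LL (one collagen architecture into another). Failure
concentrates in these transitions rather than in the pure tissues.
Characterising them needs simultaneous observation at two scales:

* **molecular** — per scan point along the strip, 2D diffraction frames
  yield the collagen D-period $D = 5\,d_5$ (from the 5th meridional order,
  $d = 2\pi/q$), the muscle (1,1) equatorial d-spacing, the relative
  composition $\mathrm{pct}_{muscle} = 100\,I_{11}/(I_{11} + w I_5)$, and
  fiber orientation from the azimuthal intensity spread. Molecular strain
  is the percent D-period change from the resting (minimum-load) state;
  dividing the 10%-strain series by the local thickness gives a
  strain-per-thickness profile whose maximum predicts the failure locus.
* **tissue** — fiducial dots tracked at 5 fps give regional engineering
  strain $\varepsilon = 100\,(\lVert p_a - p_b\rVert - L_0)/L_0$; with the
  logged load and regional cross-sections,
  $\sigma = m\,g_0 / A$ (MPa), per-region stress–strain curves yield toe
  and linear moduli, ultimate stress and the tear location.

No public beamline data exist for this experiment, so the package includes
a first-class synthetic phantom: a parameterised PM→CT→LL strip (diffuse
composition ramp, thickness profile, molecular-strain coupling peaking at
the PM–CT junction, per-region toe/linear/failure constitutive laws with
ultimate stresses from the published bisected-pull table) that renders the
three raw data products — diffraction TIFFs, load–displacement CSVs,
marker video frames — with known ground truth. Every analysis stage is
validated against that truth.

## Worked example

```r
library(valvescan)
ph <- make_phantom("MV")
ph
#> tissue_phantom: MV strip, 30 mm (preset ultimate stresses from bisected-pull data)
#>   weak link: PM-CT | tear force 0.3 N | D0 = 67.0 nm
#>  region x_lo x_hi   area_mm2 sigma_table eps_ult
#>      PM    0    8 27.2727273       0.011    0.40
#>   PM-CT    8   11  2.0833333       0.144    0.25
#>      CT   11   19  0.2012072       1.491    0.06
#>   CT-LL   19   22 12.5000000       0.024    0.18
#>      LL   22   30 12.0000000       0.025    0.22
```

Molecular side — scan ten tracked points at 0% and 10% engineering strain,
then form composition, the molecular-strain map and the failure predictor:

```r
tab  <- run_xrd_scan(ph, levels = c(0, 10))
comp <- composition_profile(tab[tab$eng_strain_pct == 0, ])
round(comp$pct_muscle, 1)
#>  [1] 85.1 85.1 85.1 13.9  0.0  0.0  0.0  0.0  0.0  0.0
```

The muscle plateau (85%), the diffuse ramp entering the PM–CT transition
(13.9% at 10.5 mm) and the muscle-free chordae/leaflet (0%) reproduce the
generator's composition truth. Molecular strain at the 10% level localises
at the junction:

```r
map <- molecular_strain_map(tab)
round(map$strain[, "10"], 3)
#>     1     2     3     4     5     6     7     8     9    10
#> 0.193 0.193 0.316 0.532 0.180 0.180 0.186 0.195 0.195 0.195
spt <- strain_per_thickness(map, ph$thickness_knots)
attr(spt, "argmax_mm")
#> [1] 10.5
```

Point 4 (10.5 mm, inside the 8–11 mm PM–CT transition) carries the highest
molecular strain (0.53% at 10% engineering strain) and, normalised by the
thinning tissue, is the predicted point of breakage.

Tissue side — simulate the pull, render and track the marker video,
extract features:

```r
mech <- run_mechanics_pipeline(ph)
round(vapply(mech$features, `[[`, numeric(1), "ultimate_stress"), 4)
#>     PM  PM-CT     CT  CT-LL     LL
#> 0.0110 0.1438 1.4888 0.0240 0.0250
mech$failure_locus
#> [1] "PM-CT"
```

The recovered ultimate stresses match the preset table (0.011, 0.144,
1.491, 0.024, 0.025 MPa) to within 0.15%, and the tear localises to the
PM–CT junction — the same region the molecular predictor flagged.

A thin command-line front end over these functions is included at
`inst/cli/valvescan.R` (`simulate | reduce | fit | map | mech | all`).

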