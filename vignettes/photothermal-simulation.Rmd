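---
title: "Simulating photothermal therapy of a skin tumor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating photothermal therapy of a skin tumor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Photothermal therapy kills tumor tissue by laser heating, usually assisted
by a plasmonic agent (here rod-shaped gold nanoparticles) that raises the
absorption coefficient of the tumor at the laser wavelength (1064 nm).
Treatment quality is a balance: tumor tissue should be held in the
apoptosis band (43-50 degC), where cells self-destruct without spilling
their contents, while the surrounding normal tissue should be damaged as
little as possible. `photoheat` simulates this treatment for a squamous
cell carcinoma embedded in a four-layer skin model and scores it with
three banded damage metrics, then sweeps the laser profile, radius, power
and nanoparticle loading to locate favourable irradiation conditions.

## Model components

**Geometry.** A tissue cylinder (radius 15 mm, depth 20 mm) is embedded in
a Cartesian voxel grid; voxels outside the cylinder are void. The four
skin layers (epidermis 0.08 mm, papillary dermis 0.5 mm, reticular dermis
0.6 mm, subcutaneous fat 18.82 mm) stack from the surface; the tumor is a
disc of radius 5 mm and depth 2 mm whose top face sits 0.1 mm below the
surface and which overrides the layers it intersects. Material assignment
is by voxel centre. Two open choices are resolved explicitly: the 0.1 mm
offset is read as the depth of the tumor's *top face* (not its centre),
and the tumor's shape is taken as a flat cylindrical disc; both are
configurable in `domain_spec()`.

**Nanoparticle optics.** The particle ensemble contributes
`mu = 0.75 f_v Q / r_eff` to the absorption and scattering coefficients of
the tumor medium, linear in the volume fraction `f_v`. The optical
efficiencies `Q_a`, `Q_s` of the reference nanorod (aspect ratio 6.67,
effective radius 20 nm) would normally come from a discrete-dipole
computation; the package instead calibrates them once from the densest
published loading (`f_v = 1e-3`) and the bare-tumor baseline, which makes
the pipeline self-contained and exactly consistent with the published
coefficient table (the remaining columns are reproduced to printed
precision; this is asserted by the test suite). Anisotropy `g` is kept at
the base-tissue value: the mixing rule addresses only the coefficient
magnitudes.

**Photon transport.** Monte Carlo photon packets are launched at the
surface travelling straight down, with the radial position sampled from
the beam's energy density: `r = (R/sqrt(2)) sqrt(-ln xi)` for a Gaussian
beam of 1/e^2 radius `R`, `r = R sqrt(xi)` for a top-hat. Free paths are
exponential in the local total attenuation `mu_tot = mu_a + mu_s`; a
sampled optical depth is walked voxel by voxel, carrying the residual
across material boundaries. Each interaction deposits `W mu_a / mu_tot`
of the packet weight in the local voxel and redirects the packet by
Henyey-Greenstein inverse-CDF sampling of the deflection cosine with a
uniform azimuth. Details worth knowing:

* Boundaries are refractive-index matched — no Fresnel reflection or
  refraction. Packets crossing the surface upward, the cylinder wall or
  the bottom escape and are tallied. The source material lists no
  refractive indices, so this is the minimal consistent choice; its
  consequences are discussed under *Limitations*.
* Russian roulette terminates packets below weight `1e-4` with survival
  probability 0.1 and weight boost 10. The bookkeeping is exact per run:
  deposited + escaped + residual = launched to rounding, which the tests
  assert at `1e-9`.
* The printed form of the direction-update equation in the source
  material ends in a term that breaks unit-norm preservation; the
  standard update (as in MCML-style codes) is used instead, and unit norm
  is asserted over long scatter chains.
* The absorption map is stored per launched unit power, so one transport
  run serves every laser power.

**Heat diffusion.** Temperature obeys the thermal-diffusion equation with
the absorbed power density as source, integrated by forward Euler on the
same voxel grid. Face conductances use the harmonic mean
`2 k1 k2 / (k1 + k2)` of the adjacent conductivities, which preserves
flux continuity across layer interfaces (the discrete steady state of a
1-D bilayer is exact at the nodes). The time step respects the explicit
3-D stability bound `dt <= rho cv / (2 k_max (1/dx^2 + 1/dy^2 + 1/dz^2))`
per material with a default safety factor of 0.9, then is shortened so an
integer number of steps lands exactly on each snapshot. The model has no
blood perfusion, metabolic heat, surface convection or phase-change
physics (temperatures above 100 degC are only scored, never modelled),
matching the source model exactly. Initial condition: uniform 37 degC.
Boundaries: adiabatic at the skin-air surface, Dirichlet 37 degC
(far-field body temperature) on the cylinder wall and bottom. Neither the
initial nor the boundary temperatures are stated by the source material;
these are this package's choices and are configurable in `sim_config()`.

**Damage metrics.** For each stored snapshot, `theta_A` is the tumor
volume fraction in the apoptosis band [43, 50) degC, and `theta_H` is the
volume-weighted mean hazard weight over all normal (non-tumor) tissue in
the cylinder, using the 10-band weight table (normothermia 1 up to rapid
ablation 8). Band membership is lower-closed/upper-open everywhere, which
aligns the "43-50 degC" apoptosis range with the band edges of the weight
table; whether 50.0 degC itself counts is immaterial on continuous
temperature fields. Starred metrics are trapezoidal time averages over
the 600 s treatment (including the initial unheated snapshot), and
`theta_eff* = theta_A*/theta_H*`. The normal-tissue reference volume is
the *entire* non-tumor cylinder across all four layers — the source
material gives no radius limit for "surrounding normal tissue". This
normalization matters: it makes `theta_H*` deviate from 1 by only a few
percent at therapeutic powers, so `theta_eff*` is dominated by
`theta_A*`.

**Sweep driver.** One transport run plus one unit-power heat run per
(profile, radius ratio, volume fraction) cell; the temperature *rise* is
linear in power, so all 51 powers are scored from the same rise field by
converting band edges into rise thresholds `e/P` and counting voxels by
binary search at each snapshot. This turns the 2448-condition grid into
48 simulations. Cell seeds derive from the master seed as
`master_seed + 1000 * cell_index`, and seeded reruns are bit-identical.

## Numerical working points

The scaled preset (`preset_scaled()`) — 0.25 mm voxels, 1e5 packets per
transport run, 2 s snapshots, 600 s treatment — is the package's
verification working point: a full single-profile sweep (24 cells,
121 x 121 x 80 voxels, about 8700 explicit steps per cell) runs in
minutes. At this voxel size the 0.08 mm epidermis is thinner than one
axial voxel and is absorbed into its neighbours (the domain builder warns
about this). The paper preset (`preset_paper()`) resolves it with a
0.04 mm axial grid over the top 2.6 mm and 1e6 packets. The sweep kernel
integrates the rise field in single precision with precomputed per-voxel
face weights; the general-purpose solver (`simulate_heat()`) is double
precision. The two routes agree to about `1e-4` in the starred metrics,
far below the Monte Carlo noise at 1e5 packets.

## What the tests do and do not show

The test suite verifies the machinery against independent oracles:
Beer-Lambert attenuation of a pure absorber (total and depth-resolved),
the sampled mean scattering cosine, exact energy bookkeeping, adiabatic
energy conservation, the discrete maximum principle, the 3-D heat kernel
for a point release, the bilayer series-resistance steady state, and
brute-force per-voxel recomputation of all damage metrics. Passing these
shows the *solver* is right, not that the *model* captures real skin:
tissue properties are single-valued literature constants, the skin is
flat and layered, particle loading is uniform, and perfusion is absent.

## Limitations

* **Optimal powers are resolution-sensitive at the scaled preset.** The
  strongly scattering 0.08 mm epidermis is unresolved at 0.25 mm axial
  voxels, which lets more beam energy reach the shallow tumor and shifts
  the power at which each condition's `theta_A*` peaks downward by
  roughly two power-grid steps relative to an epidermis-resolving axial
  grid. A single condition can be re-run on the fine axial grid by
  passing a preset with `dz = NULL` to `run_condition()` (minutes per
  condition rather than seconds).
* **The effective-ratio landscape is nearly flat in the radius ratio.**
  With the full-cylinder normal-tissue normalization, `theta_H*` differs
  across radius ratios by only a few percent — less than the `theta_A*`
  gains from wider, more uniform tumor coverage — so the sweep's
  Gaussian `theta_eff*` optimum tends to the largest radius ratio
  rather than an intermediate one; see the acceptance script's output
  for the exact recovered optimum. A more local definition of
  "surrounding normal tissue" would sharpen the collateral-damage
  penalty, but no such radius is published.
* **Index-matched boundaries.** Real skin reflects part of the diffuse
  upward flux back into the tissue; with the highly scattering layer
  stack only a few percent of the launched energy escapes, so this is a
  secondary effect here. Interface physics is out of scope by design.
* Temperatures above 100 degC are scored by the hazard table but the
  underlying physics (vaporization, charring) is not modelled; at the
  powers the optimizer prefers this band is rarely reached.
* The cross-study validation fixture reproduces the published *geometry*
  (30 mm homogeneous cylinder, 5 mm central spherical tumor, 1.7 W,
  800 s) but the prior study's tissue properties and temperature curves
  are not available, so the fixture checks internal properties (monotone
  heating, beam-radius ordering) and exports the trace for manual
  comparison.
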