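---
title: "Monte Carlo TG-43 dosimetry of encapsulated cobalt-60 HDR sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo TG-43 dosimetry of encapsulated cobalt-60 HDR sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`tg43co` derives and applies the AAPM TG-43 / TG-43U1 dosimetric
parameters of encapsulated cylindrical ⁶⁰Co high-dose-rate (HDR)
brachytherapy sources — specifically the two source designs used by the
three-channel GZP3 afterloading system (channels 1/2: 1 mm active core;
channel 3: 2 mm active core; both 0.5 mm core radius inside a 2.1 mm ×
5.8 mm stainless-steel capsule). It contains five cooperating parts:

1. **Source models** (`builtin_source()`, `path_lengths()`): nested-cylinder
   geometry with Table-driven materials and exact ray tracing.
2. **Kerma Monte Carlo** (`run_water_simulation()`, `run_air_simulation()`):
   an analog photon transport with a collision-kerma track-length estimator,
   standing in for general-purpose codes (Geant4/EGSnrc) at desk scale.
3. **Parameter extraction** (`dose_rate_constant()`,
   `radial_dose_function()`, `anisotropy_2d()`, `anisotropy_1d()`,
   `uncertainty_budget()`).
4. **Radial dose function fitting** (`fit_radial()`, `eval_gr_model()`).
5. **Forward TG-43 engine and reference tables** (`dose_rate_2d()`,
   `along_away_table()`, `load_fixtures()`).

## The dose model

TG-43 factorizes the dose rate around a cylindrically symmetric source as

$$\dot D(r,\theta) = S_K\,\Lambda\,
  \frac{G(r,\theta)}{G(r_0,\theta_0)}\,g(r)\,F(r,\theta),$$

with reference point \(r_0 = 1\) cm, \(\theta_0 = 90^\circ\), air-kerma
strength \(S_K\) (1 U = 1 µGy·m²·h⁻¹ = 1 cGy·cm²·h⁻¹), dose-rate constant
\(\Lambda = \dot D(r_0,\theta_0)/S_K\) in cGy·h⁻¹·U⁻¹, line-source
geometry factor \(G(r,\theta) = \beta/(L\,r\sin\theta)\), radial dose
function \(g(r)\) (normalized to \(g(1\,\mathrm{cm})=1\)) and 2D
anisotropy function \(F(r,\theta)\) (normalized to
\(F(r,90^\circ)=1\)). The 1D variant replaces \(F\) by the
solid-angle-weighted anisotropy
\(\phi_{an}(r) = \int_0^\pi \dot D(r,\theta)\sin\theta\,
  \mathrm d\theta / (2\dot D(r,\theta_0))\).

The subtended angle \(\beta\) is evaluated as
\(\mathrm{atan2}(yL,\ r^2 - L^2/4)\), an exact angle-addition form that
stays stable at small \(\theta\) and large \(r\); on the long axis the
degenerate limit \((r^2-L^2/4)^{-1}\) applies, and \(L=0\) recovers the
point source \(1/r^2\).

## What the Monte Carlo does — and does not

The transport kernel emulates the simulation design used when such
sources are characterized:

* **Emission.** Each decay emits the two γ lines (1.17, 1.33 MeV) from a
  position sampled uniformly in the active core; the β spectrum is not
  transported (it is absorbed in the capsule in reality; its omission is
  standard for these sources).
* **Physics.** Compton scattering on free stationary electrons sampled
  from the Klein–Nishina distribution by composition–rejection;
  photoelectric absorption; pair production above 1.022 MeV with the two
  0.511 MeV annihilation photons re-emitted isotropically at the
  interaction site. Rayleigh scattering is not simulated: the attenuation
  tables are total (with-coherent) coefficients, so the small coherent
  part of the non-Compton remainder is treated as local absorption
  (sub-percent at the primary energies, where >99% of interactions are
  Compton). Photons are terminated below 10 keV or on leaving the
  phantom.
* **Phantoms.** A 30-cm-radius liquid water sphere for dose parameters
  (effectively unbounded for the 0.25–10 cm region of interest) and a
  3 × 3 × 3 m cube of dry air (the tabulated C/N/O/Ar composition,
  ρ = 0.001205 g/cm³) for air-kerma strength.
* **Scoring.** Collision kerma by the track-length estimator: each flight
  segment through a ring cell contributes
  (length × E × μ_en/ρ(E)) / volume. Ring cells follow the three-zone
  scheme (0.025 × 0.005 cm for r ≤ 1 cm, 0.05 × 0.05 cm to 3 cm,
  0.1 × 0.1 cm to 10 cm); air-kerma strength uses a 0.1 × 0.1 cm ring at
  100 cm on the transverse axis with d² scaling. Type-A uncertainties
  come from the variance over 100 history batches. Collision kerma
  equals absorbed dose only under charged-particle equilibrium
  (established ≈1 cm from a ⁶⁰Co source); cells with r < 0.7 cm are
  flagged `kerma_approx` and small-radius validation should use the
  packaged reference tables, not this simulator.
* **Cross sections.** Element-level μ/ρ and μ_en/ρ tables (10 keV–1.5 MeV,
  log-log interpolated) compiled from the standard published
  photon-coefficient compilations are shipped as package data; materials
  are built by mass-fraction additivity. The Compton share of the total
  is computed from the analytic Klein–Nishina cross section and the
  material's electrons per gram. The water and air rows reproduce the
  published material coefficients to better than 0.5% across the grid
  (asserted in the tests); the mid-Z metal rows matter only through the
  capsule's total attenuation, where a few-percent error moves the
  extracted parameters by well under 0.1%.
* **Reproducibility.** All sampling uses R's RNG; a run is a pure
  function of (`spec`, `grid`, `n_histories`, `seed`). An energy ledger
  (emitted = absorbed + escaped, to ≤1e-9 relative) is carried in every
  result.

What it does not do: condensed-history electron transport (hence kerma,
not dose, near the source), Doppler broadening or electron binding in
Compton scattering, bremsstrahlung, and any variance reduction beyond the
track-length estimator.

### Source geometry choices

Only the core and capsule dimensions are published for these sources. The
core is centered in the capsule by default (`core_axial_offset = 0`),
since the published anisotropy tables are nearly mirror-symmetric and no
offset is stated. The drive cable is modeled as a 2-cm stub of the
wire-rope steel on the proximal (−z) side with a 0.05 cm radius — a
typical drive-wire gauge; it only shades the θ → 180° region. The
capsule uses the spring-cover steel alloy; the cobalt density follows the
materials table (8.85 g/cm³). All of these are overridable through
`source_spec()`.

## Numerical choices

* **g(r) fit.** The field-standard parameterization
  \(g(r) = (a_0 r^{-2} + a_1 r^{-1} + a_2 + a_3 r + a_4 r^2)
  e^{-a_5 r}\) is fitted by profiled least squares: the single nonlinear
  parameter \(a_5\) is scanned on a 0.005 cm⁻¹ grid over [0, 1] cm⁻¹
  with an exact linear solve for \(a_0\ldots a_4\) at each value, then
  refined by bounded 1-D minimization (tolerance 1e-12 on the SSE). This
  is deterministic and immune to local minima and starting values.
  Unweighted residuals are used. Published coefficient sets for these
  sources are not reproduced — the printed coefficients evaluate to
  ≈0.746 at r = 1 cm, inconsistent with g(1) = 1 — so fit quality
  (R², maximum relative deviation) is the meaningful surface, not
  coefficient equality. Note also that fit-quality numbers quoted for
  unrounded simulation output are not generally attainable from
  3-decimal rounded tables: the best possible (minimax) deviation of
  this model family over the printed channel-1/2 values is 0.53%.
* **φ_an integration.** The 2D anisotropy is taken piecewise linear in θ
  between tabulated samples, clamped to its edge values beyond the
  first/last tabulated angle (the sin θ weight makes those tails
  sub-0.3%), and each interval is integrated with 5-point Gauss–Legendre
  quadrature with G and sin θ evaluated exactly. A plain trapezoid on
  the coarse tabulated grid would bias the integral low by 0.2–0.6%
  purely through the curvature of sin θ — with exact per-interval
  quadrature, a constant F with L = 0 integrates to exactly 1, as it
  must.
* **θ = 0 samples.** The ring cell tabulated at θ = 0 has zero radius,
  so geometry factors for that sample are evaluated at 0.5°
  (configurable) while G itself retains its finite on-axis formula.
* **Interpolation.** g linearly in r; F bilinearly in (r, θ) with θ
  clamped outside the tabulated range and missing entries filled from
  the nearest tabulated angle at the same radius; exact at table nodes.
  Outside the tabulated radial range the engine errors by default
  (`extrapolate = TRUE` clamps; the QA table generator marks such cells
  missing).
* **Units.** Internally Gy per decay; conversions (1 Bq = 3600 decays/h,
  1 Gy = 100 cGy, U = cGy·cm²·h⁻¹) are applied only at reporting
  boundaries.

## Problem sizes and what passing tests show

The packaged study conditions mirror the published simulation design
(30 cm water sphere, two-line spectrum, 10 keV cutoff, three-zone ring
grids, 3 m air cube, 100 cm scoring ring). History counts are
configurable; the characterization-grade counts (5 × 10⁹) are not needed
to exercise the pipeline, and the validation suite runs 10⁷ decays per
simulation (≈2 minutes each), giving ≈0.4% type-A uncertainty on the
reference water cell and ≈1% on the air ring. At that scale the
simulated dose-rate constants land within ±2% of the published
Geant4/EGSnrc values (≈1.09–1.10 vs 1.115/1.116 cGy·h⁻¹·U⁻¹) — the
residual ≈1.5% deficit is the documented cost of the simplified physics
(collision kerma in place of electron-transported dose, free-electron
Compton, compiled coefficient tables) plus sampling error, with the
transport itself verified against closed-form primary attenuation,
quadrature of the Klein–Nishina distribution, and an independent
single-scatter quadrature oracle.

A passing suite therefore shows that the extraction pipeline is exact on
noise-free fields (engine → extraction round-trips to 1e-9), that the
Monte Carlo obeys its analytic limits, and that fixture-derived
statistics reproduce the published comparisons; it does not certify the
simulator as a replacement for a full-physics code near the source
(r < 0.7 cm) or for absolute dosimetry beyond the stated ±2%.

## A worked example

```{r, eval = FALSE}
library(tg43co)

src <- builtin_source("1_2")
grid <- build_scoring_grid(r = 1, theta = 90)
water <- run_water_simulation(src, grid, n_histories = 1e6, seed = 1)
air <- run_air_simulation(src, n_histories = 1e6, seed = 2)
dose_rate_constant(water, air)

fx <- load_fixtures()
fit_radial(data.frame(r = fx$radial_dose$r_cm,
                      g = fx$radial_dose$ch12_geant4))

params <- tg43_parameters(
  channel = "1_2", L = 0.1, lambda = 1.115,
  g = data.frame(r = fx$radial_dose$r_cm, g = fx$radial_dose$ch12_geant4),
  F_table = fx$anisotropy$ch12$F, phi_an = fx$anisotropy$ch12$phi_an)
along_away_table(params, y = c(0.5, 1, 2), z = c(-2, 0, 2))
```

## Known limitations

* Collision kerma only: no electron transport, so absolute values within
  0.7 cm of the source are approximations and flagged as such.
* Free-electron Klein–Nishina scattering and with-coherent attenuation
  tables introduce a sub-percent to ≈1% systematic on scattered dose;
  together with the coefficient compilation this bounds the accuracy of
  the absolute Λ and S_K near the 1–2% level at desk-scale statistics.
* The along–away reference tables are stored verbatim from the print,
  including cells that fail a ±25% neighbor-consistency check (flagged,
  never corrected), and the printed along–away absolute scale is not
  consistent with a TG-43 reconstruction at Ḋ(1 cm, 90°) = Λ; the
  tables are fixtures for regression, not ground truth.
* Single-source, homogeneous water only: no multi-dwell superposition,
  no heterogeneity corrections, no DICOM-RT I/O.
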