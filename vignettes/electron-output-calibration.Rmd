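---
title: "Electron beam output calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron beam output calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebcal)
```

## The calibration problem

Output calibration of a clinical electron beam asks: how much absorbed dose
to water, in cGy, does one monitor unit (MU) of the linac deliver at the
depth of maximum dose? The chain runs from a raw electrometer reading in a
water phantom to that single number, and every link has a convention
attached:

1. **Reading corrections.** The raw charge $M_{raw}$ is corrected
   multiplicatively,
   $$M = M_{raw}\,P_{TP}\,P_{ion}\,P_{pol}\,P_{elec}\,P_{leak}\,P_{rp},$$
   for air density (temperature/pressure), ion recombination, polarity,
   electrometer calibration, leakage and radial beam profile.
2. **Beam quality.** Electron beams are indexed by $R_{50}$, the depth at
   which the depth-dose curve falls to half its maximum, and measured at the
   reference depth $z_{ref} = 0.6\,R_{50} - 0.1$ cm.
3. **Dose conversion.** A chamber calibrated in a Co-60 beam
   ($N_{D,w}^{Co\text{-}60}$, Gy/nC) needs a beam-quality conversion factor
   to be used in an electron beam.
4. **Reporting.** The dose at $z_{ref}$ is moved to the depth of maximum via
   the measured depth-dose curve,
   $D_w(z_{max}) = 100\,D_w(z_{ref})/PDD(z_{ref})$, and divided by the MU
   delivered.

The package implements two variants of step 3 and compares them.

### Standard protocol

$$D_{w,Q_o} = M\,N_{D,w}^{Co\text{-}60}\,k_{Q,Q_o},$$
with $k_{Q,Q_o}$ interpolated linearly in $R_{50}$ from a tabulated grid
(`kq_trs398()`). Cylindrical chambers are physically placed with their axis
$0.5\,r_{cyl}$ deeper than $z_{ref}$ — this positions the effective point of
measurement at the reference depth — and parallel-plate chambers with their
front reference plane at $z_{ref}$. Tabulated grids for cylindrical chambers
do not extend to low-energy beams (roughly $R_{50} < 4$ cm), so at 6 and
8 MeV the factor is *not determinable*: the package raises a per-record
error rather than extrapolating.

### Modified calibration

$$D_{w,Q}(z_{ref}) = M\,k_Q'\,k_{Q,ecal}\,N_{D,w}^{Co\text{-}60},$$
where $k_Q'$ comes from chamber-specific fits to Monte Carlo calculated
factors,
$$k_Q' = a + b\,R_{50}^{-c} \quad\text{(cylindrical)},\qquad
  k_Q' = a + b\,e^{-R_{50}/c} \quad\text{(parallel-plate)},$$
and $k_{Q,ecal}$ is a fixed chamber constant referring the calibration to
the reference electron quality ($R_{50} = 7.5$ cm). Because the fitted
factors absorb gradient effects by construction, cylindrical chambers sit
with their axis directly at $z_{ref}$ (no $0.5\,r_{cyl}$ shift and no
explicit gradient correction), and parallel-plate chambers are shifted so
their effective point of measurement (EPOM) is at $z_{ref}$. The fits are
defined at all clinical $R_{50}$, which is the practical attraction: one
cylindrical chamber can calibrate every energy.

The built-in registry (`builtin_registry()`) carries the four chambers' fit
coefficients, fit RMSDs (0.10–0.15%), calibration factors and operating
voltages. Two constants are deliberately *not* bundled as data of record:

* **Cavity radii** are not part of the published calibration data set; they
  ship in `inst/extdata/chamber_geometry_defaults.json`, flagged as vendor
  data-sheet values, and can be overridden.
* **$k_{Q,ecal}$** values are chamber-specific numbers the user must take
  from their own reference. `dose_modified()` errors if it is unset; the
  package never assumes 1.0, because a silent unity factor would bias every
  modified-protocol dose.

### Comparison

Both protocols are normalized at $z_{max}$ (dose per MU), and the modified
result is divided by the standard one: ratio $D_w$, discrepancy
$(D_w - 1)\times 100\%$, verdict at the ±2% tolerance used for clinical
dose delivery. With identical corrected readings the ratio reduces
algebraically to $k_Q' k_{Q,ecal} / k_{Q,Q_o}$ — a property the test suite
checks exactly, since it isolates the protocols' only substantive
difference once positioning is fixed.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ref_temperature_c`, `ref_pressure_kpa` | 20.0, 101.325 | °C, kPa | Code-of-practice reference conditions; configurable for 22 °C standards. |
| `voltage_ratio` | — (user data) | — | $V_H/V_L$ of the two-voltage recombination measurement; must be > 1. |
| `p_leak`, `p_rp` | exactly 1 | — | Their contributions (≤ 0.05% and ≤ 0.15%) are conventionally neglected; explicit overrides are accepted. |
| `monitor_units` | 100 | MU | The usual output-calibration irradiation. |
| `tolerance_pct` | 2 | % | Clinical dose-tolerance band. |

$P_{ion}$ uses the pulsed-beam two-voltage closed form
$(1 - V_H/V_L)/(M_H/M_L - V_H/V_L)$ — clinical linacs are pulsed, and the
closed form is exactly oracle-checkable. A hook accepts user-supplied
quadratic coefficients for laboratories that prefer the tabulated quadratic
variant. All charges are handled as magnitudes once the operating polarity
is recorded, sidestepping electrometer sign conventions.

## The synthetic-session generator

`synth_pdd()` emulates an institutional electron depth-dose curve with the
analytic shape
$$n(z) = \left(1 - e^{-z/s}\right)\,\sigma\!\left(\frac{R_{50}' - z}{w}\right) + t,$$
a saturating build-up (scale $s$, default $R_{50}/6$) times a logistic
falloff (width $w$, default $R_{50}/12$) plus a flat bremsstrahlung-like
tail ($t$, default 2% — typical of clinical electron beams). The internal
$R_{50}'$ is calibrated by bisection until the sampled, normalized curve's
interpolated 50% crossing matches the requested $R_{50}$ within 0.01 cm, so
consumers can rely on the contract (max = 100, calibrated $R_{50}$) without
caring about the shape. The defaults give $PDD(z_{ref})$ in the high 90s,
matching commissioning data for clinical beams.

`simulate_readings()` inverts the calibration chain: from a true dose per
MU it computes the corrected reading the chamber must deliver, divides out
$P_{TP}$ for the simulated environment (default 22 °C / 100.5 kPa, so
$P_{TP} \neq 1$) and the configured $P_{pol}$ (1.002), $P_{ion}$ (1.004) and
$P_{elec}$, then synthesizes the opposite-polarity and reduced-voltage
companion readings from the raw reading so the pipeline recovers exactly the
configured correction factors. Noise is a single multiplicative Gaussian
factor per reading set — shot-to-shot output variation common to the
companion readings, the dominant repeatability term in practice — so a
noiseless simulation is inverted to machine precision and the recovered dose
under noise is truth × the noise factor, making Central Limit Theorem bounds
on replicate means exact rather than approximate. Every simulation is
reproducible from its integer seed.

What the generator does **not** emulate: energy-dependent chamber
perturbations beyond the beam-quality factors, depth-ionization vs
depth-dose differences, positioning uncertainty, electrometer
nonlinearity, or drift between the companion readings. Passing
synthetic-session tests therefore demonstrates that the arithmetic chain is
self-consistent and invertible — not that any physical chamber behaves as
modelled.

## Numerical choices

* **Interpolation** of depth-dose curves and $k_{Q,Q_o}$ grids is piecewise
  linear: it matches the granularity of water-tank exports and printed
  tables, is exact at grid points, and is checkable against an independent
  oracle. The $k_{Q,Q_o}$ scheme is intentionally isolated in
  `kq_trs398()` so another scheme could be plugged in.
* **$R_{50}$ extraction** searches only the distal falloff (beyond the
  global maximum), because build-up regions also cross 50%.
* **Out-of-range queries error** rather than extrapolate: depth-dose
  evaluation outside the sampled range, and $k_{Q,Q_o}$ outside the
  tabulated $R_{50}$ range, both refuse — the latter mirrors the genuine
  "not determinable" state of cylindrical chambers in low-energy beams.
* **Full-precision pipeline.** All quantities are carried at double
  precision; rounding (half-to-even, 3 decimals for beam-quality factors
  and reference depths) happens only in display and reports, and rounded
  values never feed back into computation.
* **Reference-depth rounding caveat.** For $R_{50} = 2.37$ cm the formula
  gives $z_{ref} = 1.322$ cm exactly, while commissioning tables in
  circulation print 1.320 for that beam — consistent with an underlying
  unrounded $R_{50}$ slightly below 2.37. The package always computes from
  the formula and documents the 2 µm-scale discrepancy in its tests.
* **Session robustness.** `run_session()` isolates each record in
  `tryCatch`; one bad record yields an error entry keyed by its
  `record_id` and the rest of the session still processes.

## Problem sizes used in validation

The test suite validates the correction stack on 100 randomized reading
sets, the fitted beam-quality factors on the full 4-chamber × 10-beam grid,
inversion of noiseless synthetic sessions for all chambers and both
protocols, and statistical recovery from 200 replicate sessions at 0.5%
relative reading noise against the 3σ bound
$3 \times 0.005/\sqrt{200}$. Synthetic depth-dose curves are sampled at
0.02 cm steps, comfortably finer than clinical water-tank exports.

## Known limitations

* No conversion from depth-ionization $I_{50}$ to $R_{50}$; the beam-quality
  index must already be a depth-dose quantity.
* No humidity correction, continuous-beam recombination, or electrometer
  linearity modelling.
* No uncertainty budget beyond carrying the fit RMSD as metadata; the
  comparison verdict is a point estimate against the ±2% band.
* The bundled $k_{Q,Q_o}$ example grid exists to exercise the machinery and
  covers only the four built-in chambers over clinical $R_{50}$; users
  performing actual reference dosimetry must load their own transcription
  of the code-of-practice table (the package does not redistribute it).
* Cross-calibration procedures and photon-beam factors are out of scope.
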