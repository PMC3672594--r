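---
title: "Oscillatory mechanics for PEEP titration: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory mechanics for PEEP titration: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillung)
```

This vignette is the package's own account of the science it implements:
the measurement model, the simulator that stands in for animal data, the
estimators, and the places where the design was genuinely open and a choice
had to be made.

## 1. The measurement model

A small sinusoidal pressure oscillation (default 1.5 cm H2O peak-to-peak at
5 Hz) rides on the ventilator waveform. Writing tracheal pressure and
airway-opening flow as phasors at the oscillation frequency
(`s(t) = Re(S e^{+jwt})`), the respiratory input impedance is

```
Zrs = P / Q = Rrs + j Xrs .
```

Below resonance a passive respiratory system is compliance-dominated, so
`Xrs < 0`, and the oscillatory elastance

```
E_X5 = -2 pi f Xrs ,   f = 5 Hz
```

is positive and equals `1/C` for a single linear compartment of compliance
`C`. Because the oscillation probes the lung at whatever volume and
recruitment state it is in *right now*, `E_X5` read during an expiratory
hold reflects the end-expiratory state and during an inspiratory hold the
end-inspiratory state — which is what makes it usable for separating
derecruitment (raises `E_X5` at end-expiration: fewer units share the
oscillated gas) from overdistension (raises `E_X5` at end-inspiration:
strain stiffening).

The titration logic follows from this: on the decremental limb of the PEEP
trial, the PEEP minimising end-expiratory `E_X5` is the open-lung PEEP
(`PEEPol`); below it the end-expiratory and end-inspiratory curves diverge
and the CT shows intra-tidal recruitment.

## 2. The synthetic ventilated lung

No data are deposited for this protocol, so the study conditions are
reproduced by a mechanistic simulator that is itself first-class, tested
code. It makes the following assumptions.

**Unit population.** The lung is `n_units` (default 300) parallel alveolar
units behind one shared airway resistance (`Raw`, default
0.012 cm H2O·s/ml). Each open unit follows a Salazar–Knowles exponential
pressure–volume curve `v = vmax (1 - e^{-kP})` with common curvature
`k = 0.06 /cm H2O` and capacity `vmax` scaled to 45 ml/kg of body weight
(27 kg default, i.e. ~1.2 L total capacity, ~360 ml of gas at mid-PEEP —
a realistic FRC). Each unit carries a fixed tissue volume (16.7 ml/kg in
total). The exponential form is the minimal standard curve giving the
strain stiffening that produces the right (high-PEEP) arm of the U-shaped
elastance–PEEP relationship.

**Hysteretic recruitment.** A closed unit opens when local pressure reaches
its opening pressure `Po` and an open unit closes when pressure falls to
its closing pressure `Pc < Po`; between the two it is bistable. Closing
pressures are a two-component mixture: a "healthy" fraction
(`1 - 0.7·severity`) with `Pc ~ N(-4, 2)` truncated below -0.5 cm H2O
(these units never derecruit at ZEEP — at `severity = 0` the whole lung is
like this), and an "injured" fraction with
`Pc ~ N(11.25·severity - 0.5, 0.5 + 0.625·severity)`. Opening pressures
sit `Po = Pc + delta` with `delta ~ N(9, 3)` truncated above 2 cm H2O.
The mixture weight and means were calibrated analytically, before any
end-to-end run, so that at the default severity 0.8 the closing-pressure
CDF has its knee between PEEP 8 and 12: the marginal recruitment loss per
decremental step crosses the marginal strain-stiffening gain (`~2k` per
2 cm H2O) there, which places the end-expiratory `E_X5` minimum — and the
ground-truth open-lung PEEP — at 10–12 cm H2O, in the range the method is
meant to resolve. The wide `delta` spread matters: units with small
offsets reopen within a breath below `PEEPol` (tidal recruitment seen by
CT), units with large offsets stay closed through the incremental limb's
plateaus (limb hysteresis).

**Ventilation.** Volume control at 6 ml/kg with constant inspiratory flow
(duty cycle 1/3, 30 breaths/min), passive single-exponential expiration to
PEEP through the expiratory resistance (defaults to `Raw`; the ventilator's
expiratory valve behaviour is not otherwise specified, so one configurable
time constant is assumed). The PEEP protocol is 0→24 cm H2O by 4 then
24→0 by 2, each step 13 breaths with a 10 s inspiratory hold at breath 9
and a 10 s expiratory hold after breath 11 (ventilatory flow clamped to
zero; the oscillation continues). Ten-second holds match the duration of a
spiral CT acquisition; the original steps lasted 8 minutes and the
protocol can be configured back to that, but the desk-scale default keeps a
full 20-step trial near 15 minutes of simulated signal. Per-sample state
updates solve gas volume and pressure jointly with the hysteresis rule
(safeguarded Newton plus an opening avalanche, in compiled code).

**Oscillation source.** The oscillator is modelled as a flow source at the
tube tip whose amplitude is servo-regulated each sample to hold the
tracheal pressure oscillation at the configured peak-to-peak value, using
the current input impedance. The measured `Ptr`/`V'ao` relation at the
oscillation frequency is identical to that of a tracheal pressure source,
and the servo reproduces the "approximately 1.5 cm H2O" amplitude of a
real loudspeaker system without modelling its source impedance (which is
not documented). The oscillatory flow starts in cosine phase so that the
oscillatory gas volume `(A/w) sin(wt)` is zero-mean; a sine start would
park a permanent quarter-cycle of gas (~2.4 ml) in the lung and bias every
mean pressure by ~0.12 cm H2O.

**Noise.** Zero-mean Gaussian measurement noise, SD 0.05 cm H2O on
pressure and 2 ml/s on flow — a high-SNR tracheal measurement; at these
defaults the 5 Hz pressure SNR is ~20 dB.

**What the simulator does not emulate.** Units are quasi-static (no
per-unit time constants), so the frequency dependence of resistance and
elastance that distinguishes `Edyn` from `E_X5` and `Rdyn` from `Rrs` in
heterogeneous lungs is out of scope by design: a 5 Hz single-frequency
analysis cannot identify distributed time constants, and here `E_X5` and
`Edyn` agree up to the volume at which they are read (their correlation is
a tested property). There is no gas exchange, no hemodynamics, no
spontaneous breathing (the animals were paralyzed), no chest-wall
compartment (the simulator contract is
`Ptr = Raw·V'ao + recoil of open units + PEEP`; adding a series chest wall
would break the closed-form link between PEEP and unit state used for the
ground truth — the consequence is that absolute elastances sit at the
compliant end of the physiological range, while every relative feature the
method relies on is preserved), and `Raw` is pressure-independent, so the
simulated `Rrs`-vs-PEEP curve is flat rather than gently falling. Passing
tests therefore demonstrate correctness of the estimators and of the
titration logic under the stated mechanism, not fidelity to every feature
of real pig data.

## 3. Estimators and numerical choices

**Impedance.** Each analysis window (default 5 oscillation periods = 1 s,
hop 0.2 s) spans an integer number of periods, which makes the quadrature
regressors orthogonal and kills leakage from the oscillation itself; the
window is regressed on `{cos, sin, polynomial trend}` (order 2 by default,
absorbing the ventilatory waveform). On any noiseless stationary window
the phasors agree with a DFT cross-spectral estimate to numerical
precision — that equivalence, and the 1% agreement at 20 dB SNR, are
tested against an independently coded DFT oracle. Windows with
oscillatory-flow magnitude below 1e-9 are flagged degenerate rather than
silently dropped. The residual-power fraction is reported per window.

**Hold extraction.** Per hold, windows lying wholly inside it whose
centers fall in the first third (`initial_fraction = 1/3`; "initial parts"
is otherwise unquantified) are averaged. Windows straddling hold
boundaries are excluded, preserving the integer-period precondition. At
the default noise the per-window reactance SE is several percent — the
price of a 1.5 cm H2O oscillation — so hold length directly controls the
step-to-step scatter of the `E_X5` curves; 10 s holds give ~3 s of usable
initial part and ~4% SE per value.

**De-oscillation before tidal fits.** The oscillation must be removed
before fitting the equation of motion, or it inflates `Rdyn`. A zero-phase
2 Hz low-pass was considered first, but at 30 breaths/min the inspiration
lasts only ~3 filter time constants: the smeared flow corners biased onset
times, tidal volume, `EEP` and the edge volume-slices. The package instead
fits, per breath, a sinusoid at the oscillation frequency with linearly
varying amplitude and phase (the elastic/resistive split drifts as tangent
compliance changes over the breath), using a one-period trapezoidal moving
average as the trend and skipping samples within 0.15 s of the flow
corners, and subtracts it from the raw signals. This keeps the waveform
edges intact; the residual oscillation is ~1% of the component. Onset
detection still uses the moving-average trace: onsets are the half-rise
crossings (for a symmetric smoother, the 50% level of a step sits exactly
at the edge), with a hysteresis band of 5% of peak flow so noise cannot
trigger crossings.

**Volume.** Trapezoidal integration, zeroed against the pre-onset baseline
sample, with a per-breath linear drift correction forcing end-expiratory
volume back to zero (the removed volume is logged and stays below 2% of
VT on simulator data). The simulator accumulates gas trapezoidally too, so
generated signals and re-integrated volumes agree sample by sample.

**Equation of motion.** Ordinary least squares of pressure on
`{volume, flow, 1}` pooled over the breaths preceding the inspiratory hold
(default 8; breaths overlapping holds are excluded, and breaths starting
within 4 s of a PEEP change are dropped because their end-expiratory
volume is still equilibrating — pooling them shifts the per-step fits).
Rank deficiency (e.g. constant flow with volume proportional to time)
raises a typed conditioning error.

**SLICE.** Inspiratory samples are restricted per breath to 10–90% of its
inspired volume and pooled into six equal-width volume bins. Under
constant-flow ventilation the flow barely varies inside one bin, so a
per-slice resistance is not identifiable (attempting it produced wild
per-slice resistances and non-monotone elastances even on noiseless
stiffening lungs); the resistance is therefore estimated once from the
pooled restricted inspiration and each slice fits elastance plus offset on
the resistive-corrected pressure. Equal-volume (not equal-sample) bins and
per-slice offsets were chosen where the original method description is
silent. A subtlety worth knowing: if the breath period is an exact
multiple of the oscillation period (RR 30 at 5 Hz is), any residual
oscillation has the same phase in every breath and aliases into the
sub-period bins; the slice-accuracy checks therefore ventilate at
17 breaths/min, where the phase rotates across breaths and the residual
averages out.

**Titration.** `PEEPol` is the argmin of end-expiratory `E_X5` on the
decremental limb, ties broken toward the lower PEEP (the lowest pressure
achieving the minimum is the clinically preferred one); the analogous
argmins of the end-inspiratory curve and of the EI-EE difference are
reported alongside. No smoothing is applied before the argmin. `NaN`
values are excluded; an all-`NaN` curve is an error.

**CT accounting.** Compartment intervals are half-open at the upper edge
(the sources do not state edge handling); voxels outside [-1000, 100] HU
are excluded with a logged count; the gas fraction is `-HU/1000` with HU
clamped to [-1000, 0] (the "standard equations" are not printed in the
sources; this is the canonical form). Partition identities
(compartments sum to whole-lung volumes exactly) are tested against a
per-voxel brute-force loop.

## 4. Ground truth and the cohort checks

The simulator emits, per step and phase, the exact unit states, alveolar
pressure and gas volume, plus a matched CT phantom (one voxel per unit,
`HU = -1000 · gas fraction`, so a closed unit reads 0 HU). The true
open-lung PEEP is defined as the lowest decremental PEEP whose
end-expiratory open fraction is at least 0.97 — an explicit, testable
stand-in for "keeps the lung open" (configurable).

The cohort-level acceptance checks run six animals (300 units each, fixed
seeds, severity 0.8, the default shortened protocol) and assert: recovery
of the true open-lung PEEP within one decremental step in at least 5 of 6;
an interior minimum of the decremental end-expiratory (and end-inspiratory)
curve; end-inspiratory at or above end-expiratory elastance at every
decremental step; limb hysteresis; intra-tidal `ΔVtissNA%` below one
percentage point at the estimated `PEEPol` and above two percentage points
four cm H2O below it; and divergence of the EI/EE curves below the
open-lung pressure. One operationalization deserves a note: incremental
end-expiratory elastance is asserted above decremental strictly at the
overlap levels within 2 cm H2O of the per-animal `PEEPol` plus a positive
mean gap across all overlap levels, because at levels far above the
open-lung pressure both limbs are fully recruited, the true difference is
zero, and a strict per-level inequality would be decided by measurement
noise alone.

Problem sizes were chosen to keep the full test suite near a minute of
compute: 300-unit lungs, 13-breath steps, 10 s holds, six animals; the
estimator-oracle checks use 50-200 noise replicates on 1-5 s records. All
of these are configurable upward to the original protocol's scale.

## 5. Known limitations

* Absolute elastance magnitudes are at the compliant end of the reported
  physiological range (no chest wall; capacity chosen so the tidal volume
  remains deliverable at PEEP 24 under a purely exponential PV curve).
* `Rrs` is constant by construction; findings that hinge on
  frequency-dependent or PEEP-dependent resistance are out of scope.
* The hysteresis rule is binary per unit; graded opening/closing or
  time-dependent recruitment dynamics are not modelled, so hold-length
  effects on CT (dynamic phenomena during the ~10 s scan) do not arise.
* The titration is only as stable as the `E_X5` hold averages; at the
  default oscillation amplitude and noise the per-value SE is ~4%, which
  is why per-animal `PEEPol` estimates can move by one grid step.
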