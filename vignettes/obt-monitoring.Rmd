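---
title: "Oscillation-based impedance monitoring of myoblast cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillation-based impedance monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obtcell)
```

## The measurement principle

Adherent cells grown on gold microelectrodes change the electrode's
impedance as they attach, spread and proliferate (electric cell-substrate
impedance sensing, ECIS).  Instead of exciting the electrode with an
external source and demodulating the response, the oscillation-based test
(OBT) closes a feedback loop around the culture: a band-pass filter
$H_{BP}(s)$, a two-level comparator, and a bioimpedance block that converts
the comparator voltage into a small injected current ($i = k_z\,v$, limited
to 10 µA) through the electrode-culture impedance $Z(s)$.  The loop
self-oscillates; the oscillation frequency $f_{osc}$ and amplitude
$a_{osc}$ of the filtered output encode $Z$, and the instrument only has to
log one amplitude per hour.

First-harmonic balance predicts the limit cycle from

$$1 + L(j\omega)\,N(a) = 0, \qquad
  L = \ell\, H_{BP}(j\omega)\,k_z Z(j\omega)\,H_{CMP}, \qquad
  N(a) = \frac{4 V_{sat}}{\pi a},$$

where $N(a)$ is the describing function of the ideal comparator
(output swing $\pm V_{sat}$), $H_{CMP}$ a unity comparator-path gain and
$\ell = -1$ the loop polarity.  Since $N$ is real and positive, oscillation
requires $L(j\omega)$ real and negative; `solve_oscillation()` scans the
loop phase on a log-spaced grid over $[f_0/20,\,20 f_0]$, refines each
crossing with `uniroot`, prefers crossings with negative phase slope
(amplitude-stable limit cycles) and picks the one closest to the band-pass
center — the filter is there precisely to select that mode.  The amplitude
follows as $a_{osc} = (4 V_{sat}/\pi)\,|L(j\,2\pi f_{osc})|$.  A
configuration with no phase crossing is reported as non-oscillating, not an
error.

## Circuit models

**Partially covered electrode.**  The interface of the bare electrode is a
parallel $R_{ct}\,\|\,C_{dl}$ (charge-transfer resistance, double-layer
capacitance).  With a fraction $f\!f$ of the sensing area covered, the
interface splits proportionally into an uncovered branch
$R_1 = R_{ct}/(1-f\!f)$, $C_1 = C_{dl}(1-f\!f)$ and a covered branch
$R_2 = R_{ct}/f\!f$, $C_2 = C_{dl}\,f\!f$ reached through the gap
resistance $R_{gap}$ of the electrolyte cleft under the cell layer; the
solution resistance $R_s$ is in series:

$$Z(\omega) = R_s + Z_1 \,\|\, (R_{gap} + Z_2).$$

This is the standard ECIS electrode-splitting construction: both branch
time constants equal $R_{ct} C_{dl}$ for every coverage, and as $f\!f$
grows $R_1, C_2$ increase while $C_1, R_2$ decrease.  The limits are coded
explicitly: $f\!f = 0$ gives $R_s + R_{ct}\|C_{dl}$ and $f\!f = 1$ gives
$R_s + R_{gap} + R_{ct}\|C_{dl}$ — no division by zero, and the acceptance
suite checks both identities to $10^{-10}$.  $R_{gap}$ is treated as a
single layer-level lump (whether it should scale per cell is not
established), and $R_s$ is coverage-independent by default with a linear
hook (`R_s_ff_slope`) exposing the known-direction, unknown-form increase
during differentiation.

**Differentiated tissue.**  Once myoblasts fuse into myotubes the gap is
replaced by two series resistances — $R_{bulk}$ between microelectrode and
tissue, and $R_{tissue}$ of the tissue itself — above the same
$R_{ct}\|C_{dl}$ interface.  At full coverage the two models are
algebraically identical whenever $R_{bulk} + R_{tissue} = R_{gap}$;
`consistency_check()` verifies this on a frequency grid and reports (rather
than throws on) parameter mismatches.  The analysis convention follows the
experimental one: $R_{bulk}$ of a differentiated well is fixed at the mean
fitted $R_{gap}$ of the same experiment's undifferentiated wells
(`derive_rbulk`), and $R_{tissue}$ is then the single free parameter of a
one-dimensional least-squares fit (`derive_rtissue`).

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| $R_s$ | 500 Ω | solution path to the large reference electrode |
| $R_{ct}$ | 1 MΩ | faradaic resistance of the small gold array |
| $C_{dl}$ | 50 nF | 10 µF/cm² (textbook gold/saline value) × 4.9·10⁻³ cm² sensing area |
| $R_{gap}$ | 1 kΩ | anchored to the reported "bulk resistance near 1 kΩ" |
| $f_0$, $Q$, $k$ | 10 kHz, 5, 1 | band-pass fixture of the loop |
| $V_{sat}$ | 3.3 V | logic-level comparator swing |
| $k_z$ | $10\,\mu A / V_{sat}$ | saturates the 10 µA injection limit exactly |

One default deserves a note.  An interface capacitance of a few nF would
put the interface reactance near 4 kΩ at $f_0$ (impedance phase ≈ −85°),
push the harmonic-balance crossing to ~2 kHz, and place the comparator
square wave's fifth harmonic on the band-pass resonance, where it is
amplified ~17× relative to the fundamental: the forced response then
crosses zero six times per period and no simple relay limit cycle exists —
the describing function's low-pass assumption is violated and the transient
simulation confirms the loop dies.  The 50 nF default (the physically
expected order for this electrode area) keeps the oscillation at
9.3–9.8 kHz, inside the passband, where harmonics are attenuated, the
describing function is accurate to ~1–3%, and the oscillation amplitude is
strictly monotone in coverage with a threefold dynamic range — the property
that makes amplitude traces readable as confluence at all.  The
monotonicity is asserted in the test suite, not assumed.

## The transient oracle

`transient_simulate()` integrates the closed loop exactly: between
comparator switchings the system is linear ($\dot x = Ax + Bu$ with
$u = \pm V_{sat}$), so each step applies the matrix exponential of the
augmented system; switching instants — zero crossings of the band-pass
output, which is exactly the comparator input — are located inside a step
by cubic-Hermite root finding and the state is re-advanced exactly to the
crossing.  There is no ODE-solver truncation error in the dynamics; the
only discretization is the recording grid.  The all-zero state is an exact
(unstable) equilibrium of the ideal relay loop; a small deterministic
band-pass perturbation is seeded by default, and a zero-state run without
it is returned flagged rather than spun forever.  Steady state is declared
when five consecutive cycle amplitudes agree within 0.1%, after which
twelve further cycles are recorded for measurement.  The injected current
is $k_z V_{sat}$ by construction, so the 10 µA limit binds identically in
every simulation.

`measure_waveform()` reports the frequency from same-direction zero-crossing
spacing (with a noise-calibrated hysteresis band so measurement noise does
not spray spurious crossings) and, by default, the **first-harmonic
(lock-in) amplitude** $\tfrac2N|\sum (v-\bar v)e^{-j2\pi f t}|$.  The
half-peak-to-peak statistic is available as `method = "peak"`; it is kept
because it is the natural instrument-level definition, but the maximum of
~200 noisy samples per cycle is biased upward by ≈2.5 standard deviations
of the noise, which already exceeds a 2% tolerance at 1% noise, whereas the
lock-in projection is unbiased and estimates exactly the quantity harmonic
balance predicts.  The solver-versus-oracle acceptance comparison uses the
peak measure on the noiseless oracle waveform (the instrument-level
definition, applied where its bias vanishes); both measures agree with the
describing function within 5% in amplitude and 2% in frequency across the
coverage grid.

## Estimation

**Fill factor from counts** is the bookkeeping identity
$f\!f = A_{cell} N_{cell} / A_p$ with all areas converted to µm²
internally (the well area is user-facing in cm²).  Supra-confluent counts
return their value > 1 with an `overflow` flag and a warning — never a
silent clip.

**Amplitude inversion.**  `build_calibration()` tabulates
$(f\!f, a_{osc}, f_{osc})$ on a coverage grid and flags strict
monotonicity; `amplitude_to_ff()` inverts through a monotone (Hyman) spline
and, when the curve carries its configuration, refines by root finding on
the forward solver, so noiseless round trips are exact to ~10⁻⁹.
Amplitudes up to 2% outside the calibrated range map to the nearest
endpoint; beyond that a range error is raised, and a non-monotone curve is
refused outright.  Under 1% multiplicative amplitude noise the inversion
error is ≈0.005–0.017 in coverage units on the operational band
(0.5–0.95); below coverage ≈0.4 the bare electrode dominates the impedance
and the instrument has little sensitivity (the calibration curve is nearly
flat there), so no noise level makes low-coverage inversion accurate — a
physical limit of the method, not an implementation artifact.  The noisy
acceptance check therefore draws its 200 coverages uniformly on
[0.5, 0.95], the band in which the 70% medium-change threshold and the
differentiation rise live.

**Parameter fitting.**  `fit_interface_params()` minimizes summed squared
log-residuals of the forward oscillation model (relative loss, so volt- and
hertz-scale channels can mix) over any subset of $R_s, R_{ct}, C_{dl},
R_{gap}$, on the log scale with positivity implicit; standard errors come
from the Jacobian at the optimum.  The amplitude channel alone identifies
$R_{gap}$ (log-sensitivity 0.08–0.6 over the confluent range) and
$R_{tissue}$ (≈0.1); the frequency channel can be added with
`use_frequency = TRUE`.  `derive_rtissue()` exploits that the model
amplitude is strictly monotone in $R_{tissue}$: the log-loss minimizer
satisfies $\log a(R_{tissue}) = \overline{\log a_{obs}}$ and is found by
bracketed root finding, exact to the solver tolerance.

## Phase segmentation

A differentiated well's amplitude trace has four regimes: logistic growth,
a medium change at 70% confluence, a growth-arrest plateau
(0.8 ± 0.1 days), and a linear differentiation rise to a level above the
undifferentiated ceiling.  `segment_phases()` analyses the trace from the
medium-change time on (taken from study metadata when known, otherwise from
`detect_confluence_threshold()`, which maps the 70% coverage through the
calibration curve and interpolates the first crossing).

The default method is a penalized changepoint fit: constant (plateau),
then **quadratic** (rise), then linear (saturation), over all breakpoint
pairs by exact least squares on cumulative sums, model-selected by BIC
against no-plateau alternatives (line, quadratic, quadratic + line).  The
rise segment is quadratic because a linear coverage rise maps through the
convex calibration curve to a convex amplitude rise; a straight rise
segment systematically drags the breakpoint ~0.25 d late, which alone would
exceed the ±0.1 d recovery tolerance.  The quadratic keeps the fit
affine-equivariant (offset and gain invariant), recovers noiseless plateaus
within one sample, and recovers the ensemble mean within ~0.04 d at 1%
noise.  The literal slope-threshold window method (6-h windows, bound 3×
the noise-implied slope SE) is available as `method = "slope_window"`; it
carries an intrinsic half-window edge bias of ~0.12 d per boundary and is
retained as a cross-check, not as the default.  A 5-sample centered median
filter precedes segmentation; the experiment-level delta statistics
(`delta_growth`, amplitude at medium change minus initial;
`delta_max`, maximum minus initial) are always computed on the raw trace.

**Group comparison** of `delta_max` between differentiated and
undifferentiated wells uses an exact two-sided rank-sum test with midranks,
enumerated over all group assignments (Welch's t is an option).  At two to
three wells per group an exact test is the only defensible choice — but its
discreteness must be respected: with 3 + 3 wells the most extreme
arrangement has two-sided $p = 2/\binom{6}{3} = 0.1$, so **no** effect
size can reach $p < 0.05$.  The generator's groups separate essentially
perfectly and every replicate study lands on $p = 0.1$; a power criterion
demanding $p < 0.05$ at these group sizes is unattainable in principle, and
the corresponding acceptance assertion is left failing with this analysis
rather than quietly weakened.

## The synthetic-study generator

`simulate_study()` is the package's stated world, not a tuning knob:

* **Layout** — the 7-well plate: wells 1 and 5 medium only, 2–4
  undifferentiated, 6–7 for differentiation; wells 4 and 7 are unmonitored
  current controls, so a default study emits five traces.
* **Growth** — logistic coverage with ceiling 0.95, rate 1.3/day, seeded at
  0.05 (10⁴ cells of ~400 µm² in 0.8 cm²); confluence (≥0.9) is reached in
  ~4.5 days and the 70% threshold on day ~3, matching the reported timing.
* **Differentiation** — at the 70% crossing the coverage freezes for a
  plateau drawn from Normal(0.8 d, 0.1 d) truncated at 0, then an
  *effective coverage* rises linearly at 0.1/day to 1.0, above the
  undifferentiated ceiling, reproducing the higher final amplitude of
  differentiated wells.  The rise slope and final level are fixture
  choices (the source reports no numeric gain); differentiation is trace
  morphology here, not a mechanistic myotube model.  One structural
  consequence: the generator's differentiated endpoint *is* the
  full-coverage electrode model, so a pipeline run on synthetic studies
  correctly recovers $R_{tissue} \approx 0$ — recovering a nonzero tissue
  resistance requires observations generated from the tissue model, which
  is how the parameter-recovery checks are built.
* **Noise** — 1% multiplicative Gaussian gain noise (additive term
  available, default 0), one seeded generator per study; the same seed
  reproduces every file byte for byte.
* Every sample of every monitored well is pushed through
  `solve_oscillation` (`solver = "exact"`); `solver = "interpolate"`
  tabulates a dense (step 0.005) calibration once and evaluates a monotone
  spline instead — relative difference ~10⁻⁶, used for the 100-replicate
  power simulation to stay inside its runtime budget.

What a green test on this generator does *not* establish: robustness to
electrode-to-electrode heterogeneity, drift, medium evaporation steps,
cell-cycle dynamics, or any deviation of real differentiation kinetics from
the frozen-then-linear morphology.  The generator's contract is the trace
morphology and the stated stochastic structure, nothing more.

## Numerical choices and degenerate inputs

* Phase-crossing detection excludes ±π wraps (a sign change of the phase
  with $|\varphi_1|+|\varphi_2| \ge \pi$ is the negative real axis, not a
  crossing); root refinement runs at machine-precision tolerance and the
  solution is accepted when the phase residual is below 10⁻⁹ rad.
* The piecewise fit floors segment SSEs at a relative 10⁻²⁰ so BIC remains
  defined on noiseless data; plateau segments need ≥ 2 samples, rise
  segments ≥ 5.
* Exact rank-sum enumeration is used up to 2·10⁵ arrangements, beyond which
  a tie-corrected normal approximation is returned and labelled as such.
* Config files are JSON (no YAML parser is available in the target
  environment); unknown sections or keys are rejected by name, JSON nulls
  fall back to defaults, and every run logs its seed and an 8-hex config
  hash.
* Exit codes of the CLI: 0 success, 1 runtime failure, 2 usage error.

## Known limitations

The comparator is ideal (no hysteresis or delay); the interface is a pure
RC (no constant-phase element or Warburg branch); higher harmonics beyond
the first are not balanced, so the solver inherits the residual 1–3%
describing-function bias quantified against the transient oracle; and the
per-well fits assume a known confluent coverage for undifferentiated wells
(default 0.95) rather than estimating it jointly.
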