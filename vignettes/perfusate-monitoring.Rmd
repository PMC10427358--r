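---
title: "Real-time perfusate biomarker monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time perfusate biomarker monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusense)
```

## Scope

`perfusense` implements a software counterpart of a real-time
spectrofluorometric biomarker monitor for ex situ organ machine perfusion.
During hypothermic oxygenated perfusion (HOPE) of a donor liver, flavin
mononucleotide (FMN) leaks from mitochondrial complex I into the perfusate
in proportion to mitochondrial injury; NADH accumulates during ischemia.
Both are natively fluorescent, so a flow cell, an LED and a compact
spectrometer can track their perfusate concentrations continuously.
Creatinine is not fluorescent; it is measured through a flow-injection
colorimetric assay on waste dialysate drawn from a blood circuit.

Since the package contains no hardware drivers, a synthetic instrument
stands in for the optics and the organ: it generates emission-spectrum
frames with realistic noise, driven by mass-balance models of the perfusion
loop and of a dialysed blood compartment. Everything downstream of frame
acquisition — calibration, streaming quantification, assay inversion,
graft-assessment analytics — is the same code that would run against real
frames.

## Optical and quantification model

A measurement channel pairs an excitation LED with an emission readout
band: FMN is excited at 405 nm and read at 530 nm, NADH at 385/460 nm, and
the creatinine reaction product at 405/475 nm. The detector model is a
uniform wavelength grid (300–800 nm at 1 nm by default).

Quantification is strictly linear:

1. **Dark correction.** Every light frame is paired with the most recent
   dark frame (LED off) of the same LED; the dark spectrum is subtracted
   pointwise. Because ambient light and dark current enter both frames
   identically, any common-mode disturbance cancels — this is the property
   that makes the method usable in an operating room with changing light.
2. **Band readout.** The net spectrum is averaged over the closed band
   `emission ± 10 nm` (configurable half-width) and normalised per second
   of integration time. Averaging over a band rather than a single pixel
   suppresses pixel noise and reduces to the single-pixel reading as the
   half-width shrinks to the grid step; per-second normalisation lets one
   calibration serve any integration time.
3. **Inverse calibration.** Concentration is `(net − intercept)/slope`,
   minus the run's blank offset. Negative results are clipped to zero and
   flagged `NEGATIVE_CLIPPED` (concentrations are physical quantities);
   results under the limit of detection are flagged `BELOW_LOD`; frames
   touching the detector's full well are flagged `SATURATED` rather than
   fitted nonlinearly.

The acquisition schedule visits channels in order with a dark frame before
every light frame. Each frame occupies the integration time (2 s default)
plus a per-frame overhead (0.75 s default, covering LED switching and
readout), so a two-channel dark-interleaved cycle takes
`2 × 2 × (2 + 0.75) = 11` s — the cadence a two-LED design achieves. The
overhead is a configuration value, not a hardware claim. The concentration
stream is optionally smoothed with a trailing median of 5 (robust to the
single-frame glitches dark pairing can produce; the first `k − 1` records
are flagged `WARMUP`).

## Calibration, blank offset and limit of detection

Standards of known concentration are circulated until steady (the trailing
5-min window's regression slope is statistically indistinguishable from
zero), averaged, and fitted by ordinary least squares of intensity on
concentration. The model is strictly linear; the blank intensity noise
`sigma_blank` comes from blank replicates when at least three are present,
else from the RMS residual. The limit of detection uses the universal
3-sigma convention, `LOD = 3 sigma_blank / slope`. Before a run, the blank
offset is the mean of ten quantifications of pure carrier solution; it is
stored on the curve and subtracted from every subsequent estimate, and in a
well-behaved system stays below 0.02 µg/mL.

In `calibrate_simulated()`, `sigma_blank` is taken from the individual
blank frames rather than the 5-min averages: the LOD characterises a single
quantification, and averaged replicates would understate it by the square
root of the frames averaged.

Two orthogonal validation helpers close the loop: `expected_adduct_mz()`
computes the nominal `[M+H]+` mass from a molecular formula with integer
nominal atomic masses (FMN `C17H21N4O9P` → 457 Da, creatinine `C4H7N3O` →
114 Da), the sanity check applied to LC-MS confirmation peaks; and
`validate_against_reference()` regresses sensor estimates on a reference
series (plain OLS with Pearson r and mean bias — Deming regression would be
a drop-in replacement but the comparison here is a scatter agreement, not
an errors-in-variables calibration).

## The synthetic instrument

Emission spectra are idealised Gaussians: FMN centred at 530 nm (sd 25),
NADH at 460 nm (sd 30), the creatinine product at 475 nm (sd 25), and
bilirubin at 520 nm as a negative control. Cross-channel selectivity lives
in the LED excitation-efficiency map: NADH responds at 0.002 relative
efficiency under the 405 nm LED, and the bilirubin brightness is set so
that 100 µM bilirubin contributes well under 1% of the FMN-channel signal —
the two negative controls a real deployment must demonstrate. The default
FMN brightness (2 × 10⁴ counts s⁻¹ per µg/mL at the peak) keeps the whole
clinically relevant concentration range inside the 16-bit detector's linear
range.

Noise has three components: Gaussian dark/read noise, shot noise with
variance proportional to expected counts, and a slow sinusoidal ambient
drift (period 600 s) common to dark and light frames. The Gaussian term's
magnitude is not free: `anchored_noise_model()` solves for the dark-noise
rate such that the 3-sigma concentration equivalent of a single blank
quantification on the FMN channel equals 4.4 nM — the one printed
instrument-noise figure — so the simulator's noise floor is tied to the
instrument it emulates.

Biology enters only through release profiles. The perfusion loop is a
closed, well-mixed volume (3 L default) in which the graft releases analyte
at rate r(t), so the concentration is the integral of release over volume:

* *plateau* (good organ): `r(t) = r0 · exp(−t/τ)`, concentration
  `r0 τ (1 − e^(−t/τ)) / V` — concave, flattening;
* *progressive* (advancing ischemic damage): `r(t) = r0 + a·t`,
  concentration `(r0 t + a t²/2) / V` — convex, accelerating.

The dialysis scenario is a one-compartment clearance model
`dc/dt = (G − CL·c)/V_b`, integrated with fixed-step RK4 (1 s steps behind
a 1-min output grid); the closed-form exponential is used as an independent
oracle in the tests, never as the implementation under test. Waste
dialysate equals blood times an equilibration factor (default 1, exposed
because complete equilibration at 200 mL/h dialysate against 0.2 L/min
blood is asserted rather than measured).

The creatinine assay train is the printed 20:5:5 mL/h flow split (dialysate
: NaOH : reagent), giving a mixing dilution of 2/3, followed by a plug-flow
delay of 30 min to the cuvette. The delay is ideal — no axial dispersion —
because the tubing was sized for reaction completeness, not characterised
for dispersion; a dispersion kernel is a documented extension point.
Reaction yield is assumed complete (any constant shortfall is absorbed by
the calibration slope).

## Cohort generation and the study conditions

`make_graft_cohort()` generates labelled trajectories for the assessment
analytics. Good grafts follow plateau profiles with `r0 = 3` µg/min,
`τ = 6` min and 15% log-normal jitter on both parameters; poor grafts
follow progressive profiles constructed so their 60-min concentration is
3× the good-cohort mean (with 10% jitter, floored at 2×). Every trajectory
carries pointwise Gaussian measurement noise of sd 0.003 µg/mL, emulating
sensor scatter at the anchored noise floor plus matrix variability. No
quantitative release rates for good versus poor organs are printed
anywhere, so these are free parameters chosen once to land the 60-min
concentrations (≈ 0.006 µg/mL for good grafts) in the same order as the
device's calibration range, with the 3× separation the deviation analytics
are specified against. The plateau constant τ = 6 min makes good grafts
genuinely flat over the 30–60 min slope window (true slope ≈ 4 × 10⁻⁶
µg/mL/min, an order below the slope test's detectability at the default
noise), which is what "plateau indicates good quality" means operationally.

What the generator does *not* emulate: organ-to-organ matrix effects,
temperature and flow dependence (reported negligible over 2–25 °C and
across flows, carried as metadata only), optical drift beyond the sinusoid,
bile/oxygenation chemistry, and any real biological coupling between FMN
release and patient outcomes. Passing tests therefore demonstrate the
pipeline's internal correctness and noise behaviour, not clinical validity.

## Assessment analytics

* **AUC** — trapezoidal, with integration limits between samples resolved
  by linear interpolation and extrapolation refused. A constant INR of 1
  over the first 24 h gives AUC 24, the printed reference case.
* **Reference band** — trajectories are resampled onto a common grid
  (linear interpolation, no extrapolation) and pooled pointwise as
  `mean ± 1.96·SD` at the default 95% level, lower bound clipped at zero.
  This is a tolerance band describing the cohort spread (an SEM mode is a
  config option); its Monte-Carlo coverage of a held-out graft is checked
  at 200 grafts.
* **Classification** — a trajectory is `DEVIATING` if more than 20% of
  covered grid points exceed the band's upper envelope, or if its OLS slope
  over 30–60 min is positive with one-sided p < 0.05; under 50% band
  coverage the result is an explicit `INSUFFICIENT_DATA`. The thresholds
  are calibrated on the synthetic cohort and exposed as arguments — the
  clinical rules they encode are qualitative.
* **Discrete protocol** — plate-reader readings at 5/10/15/30/60 min; a
  reading at or past 30 min reaching the 3000–4000 A.U. damage window
  (lower edge) yields `DISCARD_CANDIDATE`. The A.U.-to-µg/mL mapping
  between plate reader and device is never defined, so the rule stays in
  A.U.
* **Decay fits** — post-transplant transaminase series are fitted with
  `y = A·exp(−k·t) + b` (A > 0, k ≥ 0, b ≥ 0) by bounded
  Levenberg–Marquardt, initialised from a log-linear fit of the
  above-baseline part, starting at the series peak. Constant series and
  non-convergent fits return a flagged degenerate result with a log-linear
  fallback rather than an error.
* **Correlations** — Spearman by default (robust to the skewed biomarker
  distributions such cohorts show), Pearson on request, via `cor.test`.

`graft_report()` bundles FMN at 30 and 60 min, AUC over 0–60 min, the band
classification and the discrete verdict into one JSON document; fields with
missing inputs are absent, never fabricated, and a run shorter than 30 min
produces an `INSUFFICIENT_DATA` report (a non-result, not an error).

## Numerical choices and degenerate inputs

Closed forms are preferred over numerics wherever they exist (loop mass
balance, dialysis steady state); the RK4 integrator is reserved for the
simulated compartment. Steadiness and slope tests use two-sided and
one-sided t-tests at α = 0.05. Ties and degenerate designs fail loudly:
identical standard concentrations, non-positive fitted slopes, even filter
windows, non-monotone timestamps and Stokes-shift violations are all
rejected with named errors at construction or load time. Band lower
envelopes clip at zero, which slightly inflates empirical coverage where
the mean approaches zero — visible in the first grid points of a cohort
starting at concentration 0.

Problem sizes in the test suite are chosen to keep the full run near ten
seconds on one core while leaving the statistical checks meaningful:
200-graft bands with 100 held-out grafts for coverage, 100 seeds for decay
recovery and blank-offset bounds, 300-cycle streams for RMSE, 15–45 min
simulated runs for end-to-end identities.

## Reproducibility

Every stochastic routine takes an integer seed and is bit-reproducible
under it; simulated frame streams, cohort draws and record CSVs are
byte-identical across repeats. Run directories carry a manifest (config
digest, seed, schedule, curve identifiers, software version) from which the
run can be regenerated exactly.

## Known limitations

The fluorescence model is affine with Gaussian spectra — no inner-filter
effects, photobleaching, or spectral overlap beyond the Gaussian tails. The
plug-flow delay ignores dispersion, so step changes arrive unrealistically
sharp at the cuvette. The reference band is pointwise, not simultaneous:
its 95% is per grid point, and a whole-trajectory coverage statement would
need a multiplicity adjustment. The cohort separation results say nothing
about real organs; they verify the analytics against the generator's own
assumptions.
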