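# perfusense

Real-time spectrofluorometric biomarker monitoring for organ machine
perfusion, as software.

During hypothermic oxygenated machine perfusion (HOPE) of a donor liver,
flavin mononucleotide (FMN) released from mitochondrial complex I
accumulates in the perfusate in proportion to mitochondrial injury, and its
native fluorescence makes it measurable in-line: a flow cell, an excitation
LED and a compact spectrometer yield a concentration reading every few
seconds, early enough to inform the transplant decision while the organ is
still on the pump. `perfusense` implements that measurement chain and its
clinical analytics for people who study or prototype such monitors:
instrumentation developers, perfusion researchers, and methodologists who
need a controllable, fully synthetic testbed — the hardware and the organ
are replaced by a simulator, everything downstream is the real pipeline.

The core quantitative machinery:

* **Quantification** — per-cycle dark-frame subtraction (common-mode
  rejection of ambient light), band-mean readout at the emission wavelength
  (λ_em ± 10 nm, per-second normalised), and inversion of a linear
  calibration `I = a·c + b` with a pre-run blank offset, giving
  `ĉ = (I − b)/a − c₀`.
* **Calibration** — OLS fits of steady-state standard intensities, blank
  offset as the mean of ten blank quantifications, limit of detection by
  the 3σ convention `LOD = 3σ_blank/a` (the simulator's noise floor is
  anchored so the FMN LOD equals 4.4 nM), cross-talk matrices, and nominal
  [M+H]⁺ adduct masses for LC-MS confirmation.
* **Flow chemistry** — the creatinine assay train: mixing dilution
  `Q_d/(Q_d+Q_NaOH+Q_r)` (2/3 at the default 20:5:5 mL/h), a 30-min
  plug-flow delay line, and the inverse map from cuvette signal back to
  dialysate and blood concentrations.
* **Simulation** — Gaussian emission spectra with dark current, shot noise
  and ambient drift; closed-loop perfusate mass balance
  `c(t) = (1/V)∫₀ᵗ r(s)ds` under plateau (`r₀e^{−t/τ}`) or progressive
  (`r₀+at`) release; one-compartment dialysis clearance
  `dc/dt = (G − CL·c)/V_b`; labelled graft cohorts.
* **Assessment** — trapezoidal AUC, pointwise cohort reference bands
  (mean ± 1.96·SD), deviation classification (band exceedance or a
  significant rising slope over 30–60 min), the discrete 3000–4000 A.U.
  discard rule, bounded exponential decay fits `y = A·e^{−kt} + b` for
  post-transplant transaminases, and Spearman/Pearson outcome correlations.

See `vignettes/perfusate-monitoring.Rmd` for the models, parameter
defaults and their rationale.

## Worked example

Calibrate the simulated FMN channel, monitor a simulated 62-minute
perfusion of a good-quality graft, and assess it against a reference band
built from ten good grafts:

```r
library(perfusense)

cv  <- calibrate_simulated("FMN", seed = 7)
scn <- hope_scenario(release_profile = "plateau", r0 = 3, tau_min = 6,
                     duration_min = 62)
sch <- led_schedule(default_channels("FMN"))
sim <- simulate_hope_run(scn, sch, seed = 7)
df  <- run_monitor(sim$frames, list(FMN = cv), sch, "run7", seed = 7)

traj <- trajectory("demo", df$timestamp_s / 60,
                   pmax(df$concentration_ug_per_ml, 0))
band <- reference_band(make_graft_cohort(10, 0, seed = 2))
rep  <- graft_report(traj, band)
```

Printing the pieces gives:

```
<calibration_curve> FMN: slope 1.941e+04, intercept 2.305, R2 1.00000, LOD 0.002011 ug/mL
LOD in nM: 4.41        # the instrument's stated detection limit
blank offset: 0.00024  # well under the 0.02 ug/mL acceptance bound
records: 676           # one per 5.5 s single-channel cycle
FMN @ 30 min: 0.00475 ug/mL   (ground truth 0.00596)
FMN @ 60 min: 0.00618 ug/mL   (ground truth 0.00600)
AUC 0-60 min: 0.3060 ug/mL·min (ground truth 0.3240)
classification: WITHIN
```

The 30-min and 60-min readings and the 0–60 min AUC are the quantities a
transplant team would read off; `WITHIN` means the trajectory stays inside
the good-graft cohort's 95% band and shows no significant rising slope in
the 30–60 min window — the pattern of a flattening, good-quality release.
Single readings scatter by about one LOD around truth (the 30-min reading
above is ~1.7σ low); the smoothed stream in `records_filtered.csv` is the
display quantity.

The same chain is scriptable from a shell via the thin CLI wrapper:

```sh
inst/scripts/perfusense simulate-hope --seed 1 --scenario good --out runA
inst/scripts/perfusense calibrate --seed 1 --analyte FMN --out cal
inst/scripts/perfusense monitor --curves cal/curves.json \
    --simulate runA/scenario.json --seed 1 --out mon
inst/scripts/perfusense report --records mon/records.csv --out rep
```

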