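# ---------------------------------------------------------------------------
# Synthetic instrument + perfusion biology. Replaces the spectrometer/LED
# hardware and the graft: Gaussian emission spectra with dark current, shot
# noise and slow ambient drift; a closed recirculating perfusion loop
# accumulating released FMN/NADH; a dialysed blood compartment for creatinine.
# ---------------------------------------------------------------------------

#' Idealised fluorophore emission model
#'
#' Emission spectra are idealised as Gaussians; `brightness` is the expected
#' net count rate per unit concentration at the emission peak under a fully
#' efficient excitation source. `excitation_response` maps LED identifiers to
#' relative excitation efficiencies in \[0, 1\], which is what confines each
#' fluorophore's signal to its own channel.
#'
#' @param analyte Analyte name.
#' @param emission_center_nm Gaussian emission peak (nm).
#' @param emission_sd_nm Gaussian width (nm, > 0).
#' @param brightness Counts s-1 per (ug mL-1) at the peak, per unit LED
#'   efficiency; must be >= 0.
#' @param excitation_response Named numeric vector, led_id -> efficiency in
#'   \[0, 1\].
#' @return An object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(analyte, emission_center_nm, emission_sd_nm,
                              brightness, excitation_response) {
  if (emission_sd_nm <= 0) stop("fluorophore_model: emission_sd_nm must be > 0",
                                call. = FALSE)
  if (brightness < 0) stop("fluorophore_model: brightness must be >= 0",
                           call. = FALSE)
  if (any(excitation_response < 0 | excitation_response > 1)) {
    stop("fluorophore_model: excitation efficiencies must lie in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(
      analyte = analyte, emission_center_nm = emission_center_nm,
      emission_sd_nm = emission_sd_nm, brightness = brightness,
      excitation_response = excitation_response
    ),
    class = "fluorophore_model"
  )
}

#' Default fluorophore library
#'
#' FMN (peak 530 nm, sd 25), NADH (peak 460 nm, sd 30), the creatinine
#' reaction product (peak 475 nm, sd 25) and bilirubin as a negative control.
#' Excitation efficiencies and the bilirubin brightness are set so that
#' cross-channel contamination is negligible: NADH contributes well under 1%
#' of the FMN-channel signal even at 50 uM, and bilirubin at 100 uM is
#' insignificant at 530 nm, mirroring the measured negative controls.
#'
#' @return Named list of [fluorophore_model()] objects.
#' @export
default_fluorophores <- function() {
  list(
    FMN = fluorophore_model("FMN", 530, 25, 2e4,
                            c(LED405 = 1.0, LED385 = 0.05)),
    NADH = fluorophore_model("NADH", 460, 30, 8e3,
                             c(LED405 = 0.002, LED385 = 1.0)),
    CREATININE_PRODUCT = fluorophore_model("CREATININE_PRODUCT", 475, 25, 500,
                                           c(LED405 = 1.0, LED385 = 0.01)),
    BILIRUBIN = fluorophore_model("BILIRUBIN", 520, 25, 5,
                                  c(LED405 = 0.5, LED385 = 0.3))
  )
}

#' Detector noise model
#'
#' Dark current with Gaussian read noise, shot noise with variance
#' proportional to expected counts, and a slow sinusoidal ambient drift that
#' is common to dark and light frames (and therefore cancelled by dark
#' subtraction).
#'
#' @param dark_mean Dark count rate (counts s-1).
#' @param dark_sd Gaussian dark/read noise rate (counts s-1, >= 0); the
#'   per-frame count noise standard deviation is `dark_sd * integration_time`.
#' @param shot_factor Shot-noise variance per expected count (>= 0).
#' @param ambient_drift_amplitude Amplitude of the ambient drift (counts s-1).
#' @param ambient_drift_period_s Drift period (s).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(dark_mean = 200, dark_sd = 100, shot_factor = 1,
                        ambient_drift_amplitude = 50,
                        ambient_drift_period_s = 600) {
  if (dark_sd < 0) stop("noise_model: dark_sd must be >= 0", call. = FALSE)
  if (shot_factor < 0) stop("noise_model: shot_factor must be >= 0", call. = FALSE)
  structure(
    list(
      dark_mean = dark_mean, dark_sd = dark_sd, shot_factor = shot_factor,
      ambient_drift_amplitude = ambient_drift_amplitude,
      ambient_drift_period_s = ambient_drift_period_s
    ),
    class = "noise_model"
  )
}

#' A noiseless noise model (for identity checks)
#' @return A [noise_model()] with all stochastic and drift terms zero.
#' @export
noiseless_model <- function() {
  noise_model(dark_mean = 200, dark_sd = 0, shot_factor = 0,
              ambient_drift_amplitude = 0)
}

#' Mean Gaussian band shape of a fluorophore over a channel's readout band
#'
#' The mean, over the in-band grid pixels, of the fluorophore's normalised
#' emission profile. Multiplied by brightness and excitation efficiency this
#' is the expected net band intensity per unit concentration.
#'
#' @param fluor A [fluorophore_model()].
#' @param channel An [analyte_channel()].
#' @param grid A [wavelength_grid()].
#' @return Dimensionless mean shape factor in \[0, 1\].
#' @export
band_shape_factor <- function(fluor, channel, grid) {
  wl <- grid_wavelengths(grid)
  inside <- wl >= channel$emission_nm - channel$band_halfwidth_nm &
    wl <= channel$emission_nm + channel$band_halfwidth_nm
  if (!any(inside)) stop("band_shape_factor: band outside grid", call. = FALSE)
  mean(exp(-(wl[inside] - fluor$emission_center_nm)^2 /
             (2 * fluor$emission_sd_nm^2)))
}

#' Expected net band intensity per unit concentration
#'
#' The effective calibration slope implied by the simulator's optics:
#' `brightness * excitation_efficiency(led) * band_shape_factor`.
#'
#' @inheritParams band_shape_factor
#' @return Counts s-1 per (ug mL-1).
#' @export
expected_band_response <- function(fluor, channel, grid) {
  eff <- fluor$excitation_response[[channel$led_id]]
  if (is.null(eff)) eff <- 0
  fluor$brightness * eff * band_shape_factor(fluor, channel, grid)
}

#' Noise model anchored to a stated limit of detection
#'
#' Chooses the Gaussian dark-noise rate so that the 3-sigma
#' concentration-equivalent of a blank quantification on the given channel
#' equals `lod_nM`. The blank concentration noise comes from the net
#' (light minus dark) band mean: per-pixel variance
#' `2 (dark_sd T)^2 + 2 shot dark_mean T` averaged over the in-band pixels
#' and divided by the integration time squared.
#'
#' @param channel The anchoring [analyte_channel()] (default FMN).
#' @param fluor Matching [fluorophore_model()].
#' @param grid Detector [wavelength_grid()].
#' @param lod_nM Target limit of detection in nM (default 4.4).
#' @param integration_time_s Integration time assumed for the anchor (s).
#' @param base Base [noise_model()] supplying dark mean, shot factor and
#'   drift; only `dark_sd` is replaced.
#' @return A [noise_model()] whose `dark_sd` realises the anchor.
#' @export
anchored_noise_model <- function(channel = default_channels("FMN")[[1]],
                                 fluor = default_fluorophores()$FMN,
                                 grid = wavelength_grid(),
                                 lod_nM = 4.4,
                                 integration_time_s = 2,
                                 base = noise_model()) {
  lod_conc <- convert_units(lod_nM, "nM_to_ug_per_ml", channel)
  slope <- expected_band_response(fluor, channel, grid)
  wl <- grid_wavelengths(grid)
  m <- sum(wl >= channel$emission_nm - channel$band_halfwidth_nm &
             wl <= channel$emission_nm + channel$band_halfwidth_nm)
  target_band_sd <- slope * lod_conc / 3
  T <- integration_time_s
  var_needed <- (target_band_sd * T)^2 * m - 2 * base$shot_factor * base$dark_mean * T
  if (var_needed <= 0) {
    stop("anchored_noise_model: shot noise alone exceeds the LOD anchor; ",
         "reduce shot_factor or dark_mean", call. = FALSE)
  }
  dark_sd <- sqrt(var_needed / 2) / T
  noise_model(
    dark_mean = base$dark_mean, dark_sd = dark_sd,
    shot_factor = base$shot_factor,
    ambient_drift_amplitude = base$ambient_drift_amplitude,
    ambient_drift_period_s = base$ambient_drift_period_s
  )
}

# ---------------------------------------------------------------------------
# Perfusion-loop and dialysis scenarios
# ---------------------------------------------------------------------------

#' Hypothermic machine-perfusion scenario
#'
#' A closed recirculating loop of `perfusate_volume_L` in which the graft
#' releases analyte at rate r(t) (ug min-1). Two release shapes:
#' `"plateau"`, r(t) = r0 exp(-t / tau), a release that dies away (good
#' organ quality), and `"progressive"`, r(t) = r0 + a t, accelerating
#' release (progressive ischemic damage).
#'
#' @param perfusate_volume_L Loop volume in litres (default 3, the standard
#'   cold-perfusion charge).
#' @param release_profile `"plateau"` or `"progressive"`.
#' @param r0 Initial release rate (ug min-1, >= 0).
#' @param tau_min Plateau decay constant (min); plateau profile only.
#' @param accel Release acceleration `a` (ug min-2); progressive only.
#' @param duration_min Run length (min).
#' @param analytes Analytes released (default `"FMN"`).
#' @param flow_rate_mL_min Loop flow rate, metadata only (default 250, the
#'   maximum used clinically).
#' @return An object of class `hope_scenario`.
#' @export
hope_scenario <- function(perfusate_volume_L = 3,
                          release_profile = c("plateau", "progressive"),
                          r0 = 3, tau_min = 20, accel = 0.05,
                          duration_min = 60, analytes = "FMN",
                          flow_rate_mL_min = 250) {
  release_profile <- match.arg(release_profile)
  if (perfusate_volume_L <= 0) stop("hope_scenario: volume must be > 0", call. = FALSE)
  if (duration_min <= 0) stop("hope_scenario: duration must be > 0", call. = FALSE)
  if (r0 < 0) stop("hope_scenario: r0 must be >= 0", call. = FALSE)
  if (release_profile == "plateau" && tau_min <= 0) {
    stop("hope_scenario: tau_min must be > 0", call. = FALSE)
  }
  if (release_profile == "progressive" && r0 + accel * duration_min < 0) {
    stop("hope_scenario: release rate becomes negative within the run", call. = FALSE)
  }
  structure(
    list(
      perfusate_volume_L = perfusate_volume_L, release_profile = release_profile,
      r0 = r0, tau_min = tau_min, accel = accel, duration_min = duration_min,
      analytes = analytes, flow_rate_mL_min = flow_rate_mL_min
    ),
    class = "hope_scenario"
  )
}

#' True perfusate concentration under a perfusion scenario
#'
#' Mass balance of the closed loop: c(t) = (1/V) * integral of r(s) ds from 0
#' to t. Closed forms: plateau `r0 tau (1 - exp(-t/tau)) / V`; progressive
#' `(r0 t + a t^2 / 2) / V`. Volume is converted to mL so the result is in
#' ug mL-1.
#'
#' @param scn A [hope_scenario()].
#' @param t_min Time(s) in minutes within `[0, duration_min]`.
#' @return Concentration(s) in ug mL-1.
#' @export
true_hope_concentration <- function(scn, t_min) {
  stopifnot(inherits(scn, "hope_scenario"))
  if (any(t_min < 0 | t_min > scn$duration_min)) {
    stop("true_hope_concentration: t outside the run", call. = FALSE)
  }
  v_ml <- scn$perfusate_volume_L * 1000
  switch(scn$release_profile,
    plateau = scn$r0 * scn$tau_min * (1 - exp(-t_min / scn$tau_min)) / v_ml,
    progressive = (scn$r0 * t_min + scn$accel * t_min^2 / 2) / v_ml
  )
}

#' Hemodialysis monitoring scenario
#'
#' A well-mixed blood compartment of volume `V_b` with endogenous creatinine
#' generation `G` and dialyser clearance `CL`:
#' `dc/dt = (G - CL c) / V_b`. Waste dialysate equilibrates with blood up to
#' `equilibration_factor`.
#'
#' @param blood_volume_L Blood/perfusate compartment volume (L).
#' @param initial_creatinine_mg_dL Starting creatinine (mg dL-1).
#' @param generation_rate_mg_min Creatinine generation G (mg min-1).
#' @param dialyzer_clearance_mL_min Clearance CL (mL min-1).
#' @param blood_bypass_flow_L_min Bypass blood flow (L min-1, default 0.2).
#' @param dialysate_flow_mL_h Dialysate flow (mL h-1, default 200).
#' @param duration_h Run length (h, default 24).
#' @param equilibration_factor Dialysate/blood equilibration in (0, 1].
#' @return An object of class `dialysis_scenario`.
#' @export
dialysis_scenario <- function(blood_volume_L = 5, initial_creatinine_mg_dL = 2,
                              generation_rate_mg_min = 1,
                              dialyzer_clearance_mL_min = 100,
                              blood_bypass_flow_L_min = 0.2,
                              dialysate_flow_mL_h = 200, duration_h = 24,
                              equilibration_factor = 1) {
  if (blood_volume_L <= 0 || blood_bypass_flow_L_min <= 0 ||
      dialysate_flow_mL_h <= 0 || duration_h <= 0) {
    stop("dialysis_scenario: volumes, flows and duration must be > 0", call. = FALSE)
  }
  if (dialyzer_clearance_mL_min < 0) {
    stop("dialysis_scenario: clearance must be >= 0", call. = FALSE)
  }
  if (dialyzer_clearance_mL_min > blood_bypass_flow_L_min * 1000) {
    stop("dialysis_scenario: clearance cannot exceed the bypass blood flow",
         call. = FALSE)
  }
  if (equilibration_factor <= 0 || equilibration_factor > 1) {
    stop("dialysis_scenario: equilibration_factor must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      blood_volume_L = blood_volume_L,
      initial_creatinine_mg_dL = initial_creatinine_mg_dL,
      generation_rate_mg_min = generation_rate_mg_min,
      dialyzer_clearance_mL_min = dialyzer_clearance_mL_min,
      blood_bypass_flow_L_min = blood_bypass_flow_L_min,
      dialysate_flow_mL_h = dialysate_flow_mL_h, duration_h = duration_h,
      equilibration_factor = equilibration_factor
    ),
    class = "dialysis_scenario"
  )
}

# ---------------------------------------------------------------------------
# Frame synthesis
# ---------------------------------------------------------------------------

ambient_drift <- function(noise, t_s) {
  if (noise$ambient_drift_amplitude == 0) return(0)
  noise$ambient_drift_amplitude * sin(2 * pi * t_s / noise$ambient_drift_period_s)
}

#' Synthesise one detector frame
#'
#' Light frames carry the summed Gaussian emission of every fluorophore
#' present, scaled by LED excitation efficiency, plus dark current, ambient
#' drift and noise. Dark frames omit the fluorophore term but keep dark
#' current, drift and noise, which is exactly what dark subtraction removes.
#'
#' @param concs Named numeric vector, analyte -> concentration (ug mL-1).
#' @param channel The [analyte_channel()] whose LED is active.
#' @param fluors Named list of [fluorophore_model()] (default library).
#' @param noise A [noise_model()].
#' @param t_s Frame timestamp (s since run start).
#' @param dark Synthesise a dark frame (LED off)?
#' @param grid Detector [wavelength_grid()].
#' @param integration_time_s Integration time (s, default 2).
#' @param full_well Saturation level in counts (clipped, default 2^16 - 1).
#' @return A raw [spectrum_frame()]. Counts are clipped to
#'   `[0, full_well]`.
#' @export
emit_frame <- function(concs, channel, fluors = default_fluorophores(),
                       noise = noise_model(), t_s = 0, dark = FALSE,
                       grid = wavelength_grid(), integration_time_s = 2,
                       full_well = 65535) {
  unknown <- setdiff(names(concs), names(fluors))
  if (length(unknown)) {
    stop("emit_frame: no fluorophore model for analyte(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  wl <- grid_wavelengths(grid)
  T <- integration_time_s
  rate <- rep(noise$dark_mean + ambient_drift(noise, t_s), length(wl))
  if (!dark && length(concs)) {
    for (a in names(concs)) {
      f <- fluors[[a]]
      eff <- f$excitation_response[[channel$led_id]]
      if (is.null(eff)) eff <- 0
      shape <- exp(-(wl - f$emission_center_nm)^2 / (2 * f$emission_sd_nm^2))
      rate <- rate + f$brightness * eff * concs[[a]] * shape
    }
  }
  expected <- rate * T
  counts <- expected
  if (noise$dark_sd > 0) {
    counts <- counts + stats::rnorm(length(wl), 0, noise$dark_sd * T)
  }
  if (noise$shot_factor > 0) {
    counts <- counts +
      stats::rnorm(length(wl), 0, sqrt(noise$shot_factor * pmax(expected, 0)))
  }
  counts <- pmin(pmax(counts, 0), full_well)
  spectrum_frame(grid, counts, channel$led_id, is_dark = dark,
                 integration_time_s = T, timestamp_s = t_s)
}

#' Simulate a machine-perfusion monitoring run
#'
#' Produces the interleaved (dark, light) frame stream a monitoring device
#' would acquire under an LED schedule, together with the ground-truth
#' concentration trajectory on the light-frame timestamps. Fully
#' deterministic for a given seed.
#'
#' @param scn A [hope_scenario()].
#' @param schedule A [led_schedule()]; its channels determine which analytes
#'   are acquired.
#' @param fluors Fluorophore library.
#' @param noise A [noise_model()].
#' @param grid Detector [wavelength_grid()].
#' @param seed Integer RNG seed.
#' @return List with `frames` (list of [spectrum_frame()], in acquisition
#'   order) and `truth` (data frame `timestamp_s`, `analyte`,
#'   `concentration`).
#' @export
simulate_hope_run <- function(scn, schedule = default_schedule(),
                              fluors = default_fluorophores(),
                              noise = anchored_noise_model(), grid = wavelength_grid(),
                              seed = 1) {
  stopifnot(inherits(scn, "hope_scenario"), inherits(schedule, "led_schedule"))
  set.seed(as.integer(seed))
  slot_s <- schedule$integration_time_s + schedule$per_frame_overhead_s
  duration_s <- scn$duration_min * 60
  frames <- list()
  truth <- list()
  t <- 0
  while (t + cycle_period(schedule) <= duration_s) {
    for (ch in schedule$channels) {
      if (schedule$dark_every_frame) {
        frames[[length(frames) + 1L]] <- emit_frame(
          numeric(), ch, fluors, noise, t_s = t, dark = TRUE, grid = grid,
          integration_time_s = schedule$integration_time_s
        )
        t <- t + slot_s
      }
      t_min <- t / 60
      concs <- stats::setNames(
        rep(true_hope_concentration(scn, min(t_min, scn$duration_min)),
            length(scn$analytes)),
        scn$analytes
      )
      frames[[length(frames) + 1L]] <- emit_frame(
        concs, ch, fluors, noise, t_s = t, dark = FALSE, grid = grid,
        integration_time_s = schedule$integration_time_s
      )
      if (ch$analyte %in% names(concs)) {
        truth[[length(truth) + 1L]] <- data.frame(
          timestamp_s = t, analyte = ch$analyte,
          concentration = concs[[ch$analyte]]
        )
      }
      t <- t + slot_s
    }
  }
  list(
    frames = frames,
    truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(timestamp_s = numeric(), analyte = character(),
                 concentration = numeric())
  )
}

#' Simulate a dialysis clearance run
#'
#' Integrates the one-compartment clearance ODE
#' `dc/dt = (G - CL c) / V_b` with fixed-step fourth-order Runge-Kutta
#' (1-minute output grid, `rk4` steps at `step_s` resolution) and derives the
#' waste-dialysate series as `blood * equilibration_factor`.
#'
#' @param scn A [dialysis_scenario()].
#' @param output_dt_min Output grid spacing (min, default 1).
#' @param step_s Integrator step (s, default 1).
#' @return Data frame `timestamp_min`, `blood_mg_dL`, `dialysate_mg_dL`.
#' @export
simulate_dialysis_run <- function(scn, output_dt_min = 1, step_s = 1) {
  stopifnot(inherits(scn, "dialysis_scenario"))
  v_ml <- scn$blood_volume_L * 1000
  g_mg_dl_min <- scn$generation_rate_mg_min / v_ml * 100  # mg min-1 -> mg dL-1 min-1
  k <- scn$dialyzer_clearance_mL_min / v_ml               # min-1
  duration_min <- scn$duration_h * 60
  times <- seq(0, duration_min, by = output_dt_min)
  deriv <- function(t, y, parms) list(parms$g - parms$k * y)
  sol <- deSolve::ode(
    y = scn$initial_creatinine_mg_dL, times = times, func = deriv,
    parms = list(g = g_mg_dl_min, k = k), method = "rk4", hini = step_s / 60
  )
  blood <- sol[, 2]
  data.frame(
    timestamp_min = times,
    blood_mg_dL = blood,
    dialysate_mg_dL = blood * scn$equilibration_factor
  )
}

#' Closed-form solution of the dialysis clearance ODE
#'
#' `c(t) = c* + (c0 - c*) exp(-k t)` with `k = CL / V_b` and steady state
#' `c* = G / CL` (or linear growth `c0 + G t / V_b` when `CL = 0`).
#'
#' @param scn A [dialysis_scenario()].
#' @param t_min Times in minutes.
#' @return Blood concentrations (mg dL-1).
#' @export
dialysis_closed_form <- function(scn, t_min) {
  v_ml <- scn$blood_volume_L * 1000
  g <- scn$generation_rate_mg_min / v_ml * 100
  k <- scn$dialyzer_clearance_mL_min / v_ml
  c0 <- scn$initial_creatinine_mg_dL
  if (k == 0) return(c0 + g * t_min)
  cstar <- g / k
  cstar + (c0 - cstar) * exp(-k * t_min)
}

# ---------------------------------------------------------------------------
# Cohort generation for assessment analytics
# ---------------------------------------------------------------------------

#' Generate a labelled synthetic graft cohort
#'
#' Good grafts follow plateau release profiles with multiplicative parameter
#' jitter; poor grafts follow progressive profiles constructed so that their
#' 60-minute perfusate concentration exceeds the good-cohort mean by
#' `bad_factor` (jittered). Pointwise measurement noise emulating sensor
#' scatter is added to every trajectory.
#'
#' @param n_good Number of good grafts (>= 2).
#' @param n_bad Number of poor grafts.
#' @param seed Integer RNG seed.
#' @param grid_min Common sampling grid (min, default 0..60 by 2).
#' @param r0 Mean initial release rate of good grafts (ug min-1).
#' @param tau_min Mean plateau constant of good grafts (min).
#' @param jitter_cv Coefficient of variation of the good-graft parameter
#'   jitter (default 0.15).
#' @param bad_factor Ratio of the poor grafts' 60-min concentration to the
#'   good-cohort mean (default 3).
#' @param noise_sd Pointwise measurement noise (ug mL-1, default 0.003).
#' @param volume_L Perfusate volume (L, default 3).
#' @return List of trajectories (see [trajectory()]), each labelled
#'   `TRANSPLANTED_OK` or `DISCARDED`, with attribute `"labels"`.
#' @export
make_graft_cohort <- function(n_good, n_bad = 0, seed = 1,
                              grid_min = seq(0, 60, by = 2),
                              r0 = 3, tau_min = 6, jitter_cv = 0.15,
                              bad_factor = 3, noise_sd = 0.003,
                              volume_L = 3) {
  if (n_good < 2) {
    stop("make_graft_cohort: need n_good >= 2 to support a reference band",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  v_ml <- volume_L * 1000
  t_end <- max(grid_min)
  mean_c_end <- r0 * tau_min * (1 - exp(-t_end / tau_min)) / v_ml
  out <- vector("list", n_good + n_bad)
  for (i in seq_len(n_good)) {
    ri <- r0 * exp(stats::rnorm(1, 0, jitter_cv))
    ti <- tau_min * exp(stats::rnorm(1, 0, jitter_cv))
    c_t <- ri * ti * (1 - exp(-grid_min / ti)) / v_ml
    c_t <- pmax(c_t + stats::rnorm(length(grid_min), 0, noise_sd), 0)
    out[[i]] <- trajectory(sprintf("good_%02d", i), grid_min, c_t,
                           label = "TRANSPLANTED_OK")
  }
  for (j in seq_len(n_bad)) {
    f <- max(bad_factor * exp(stats::rnorm(1, 0, 0.1)), 2)
    r0_b <- r0 / 3
    # solve the release acceleration so c(t_end) hits f x good mean
    accel <- (f * mean_c_end * v_ml - r0_b * t_end) / (t_end^2 / 2)
    c_t <- (r0_b * grid_min + accel * grid_min^2 / 2) / v_ml
    c_t <- pmax(c_t + stats::rnorm(length(grid_min), 0, noise_sd), 0)
    out[[n_good + j]] <- trajectory(sprintf("bad_%02d", j), grid_min, c_t,
                                    label = "DISCARDED")
  }
  attr(out, "labels") <- vapply(out, `[[`, character(1), "label")
  out
}
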