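# Shared fixtures and independent oracles used across the suite.

fix_grid <- function() wavelength_grid(300, 1, 501)

fix_channel_fmn <- function() default_channels("FMN")[[1]]

# a flat spectrum frame with given constant counts
flat_frame <- function(value, dark = FALSE, grid = fix_grid(), led = "LED405",
                       integration = 2, t = 0, corrected = FALSE) {
  spectrum_frame(grid, rep(value, grid$n_points), led, is_dark = dark,
                 integration_time_s = integration, timestamp_s = t,
                 dark_corrected = corrected)
}

# independent normal-equations OLS oracle (no lm)
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# brute-force trapezoid over the exact sample knots
oracle_trapz <- function(time, value) {
  s <- 0
  for (i in seq_len(length(time) - 1)) {
    s <- s + (time[i + 1] - time[i]) * (value[i] + value[i + 1]) / 2
  }
  s
}

# brute-force trailing sliding median
oracle_sliding_median <- function(x, k) {
  out <- x
  for (i in seq_along(x)) {
    if (i >= k) out[i] <- median(x[(i - k + 1):i])
  }
  out
}

# brute-force piecewise-linear evaluation
oracle_pwlinear <- function(time, value, t) {
  if (t <= time[1]) return(value[1])
  for (i in seq_len(length(time) - 1)) {
    if (t <= time[i + 1]) {
      w <- (t - time[i]) / (time[i + 1] - time[i])
      return(value[i] * (1 - w) + value[i + 1] * w)
    }
  }
  value[length(value)]
}

# analytic calibration curve implied by the simulator optics (no fitting)
analytic_curve <- function(analyte = "FMN", channel = fix_channel_fmn(),
                           fluor = default_fluorophores()[[analyte]],
                           grid = fix_grid(), lod = NA_real_) {
  calibration_curve(analyte, expected_band_response(fluor, channel, grid), 0,
                    r_squared = 1, lod = lod)
}
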