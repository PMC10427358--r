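# ---------------------------------------------------------------------------
# Domain types: wavelength grid, spectrum, analyte channel, measurement record
# ---------------------------------------------------------------------------

#' Detector wavelength axis
#'
#' A uniformly spaced wavelength grid describing the detector pixel axis.
#'
#' @param start_nm First wavelength (nm).
#' @param step_nm Wavelength increment (nm), must be positive.
#' @param n_points Number of grid points, at least 2.
#' @return An object of class `wavelength_grid`.
#' @export
wavelength_grid <- function(start_nm = 300, step_nm = 1, n_points = 501) {
  if (!is.numeric(step_nm) || step_nm <= 0) {
    stop("wavelength_grid: step_nm must be > 0", call. = FALSE)
  }
  if (n_points < 2) {
    stop("wavelength_grid: n_points must be >= 2", call. = FALSE)
  }
  structure(
    list(start_nm = start_nm, step_nm = step_nm, n_points = as.integer(n_points)),
    class = "wavelength_grid"
  )
}

#' Wavelengths of a grid
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of wavelengths (nm), strictly increasing.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + grid$step_nm * (seq_len(grid$n_points) - 1)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(a$start_nm, b$start_nm)) &&
    isTRUE(all.equal(a$step_nm, b$step_nm)) &&
    a$n_points == b$n_points
}

#' One detector frame
#'
#' A single spectrometer acquisition: intensity counts on a wavelength grid
#' plus acquisition metadata. Raw frames carry non-negative counts; frames
#' that have been dark-corrected may contain negative values.
#'
#' @param grid A [wavelength_grid()].
#' @param counts Numeric vector of detector counts, one per grid point.
#' @param led_id Identifier of the excitation source active (or switched off,
#'   for a dark frame) during acquisition.
#' @param is_dark Logical; `TRUE` for a dark frame (LED off).
#' @param integration_time_s Detector integration time in seconds (> 0).
#' @param timestamp_s Seconds since run start.
#' @param dark_corrected Logical; `TRUE` once a dark frame has been subtracted.
#' @return An object of class `spectrum_frame`.
#' @export
spectrum_frame <- function(grid, counts, led_id, is_dark = FALSE,
                           integration_time_s = 2, timestamp_s = 0,
                           dark_corrected = FALSE) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(counts) != grid$n_points) {
    stop("spectrum_frame: counts length must equal grid n_points", call. = FALSE)
  }
  if (integration_time_s <= 0) {
    stop("spectrum_frame: integration_time_s must be > 0", call. = FALSE)
  }
  structure(
    list(
      grid = grid, counts = as.numeric(counts), led_id = led_id,
      is_dark = isTRUE(is_dark), integration_time_s = integration_time_s,
      timestamp_s = timestamp_s, dark_corrected = isTRUE(dark_corrected)
    ),
    class = "spectrum_frame"
  )
}

#' @export
print.spectrum_frame <- function(x, ...) {
  cat(sprintf(
    "<spectrum_frame> %s%s t=%.2fs, %d px [%g..%g nm], %gs integration\n",
    x$led_id, if (x$is_dark) " (dark)" else "", x$timestamp_s,
    x$grid$n_points, x$grid$start_nm,
    x$grid$start_nm + x$grid$step_nm * (x$grid$n_points - 1),
    x$integration_time_s
  ))
  invisible(x)
}

#' Analyte measurement channel
#'
#' Pairs an excitation source with an emission readout band for one analyte.
#' The Stokes shift requires excitation below emission.
#'
#' @param analyte Analyte name (e.g. `"FMN"`, `"NADH"`, `"CREATININE_PRODUCT"`).
#' @param excitation_nm Excitation wavelength (nm).
#' @param emission_nm Emission readout wavelength (nm); must exceed excitation.
#' @param band_halfwidth_nm Half-width of the emission readout band (nm, > 0).
#' @param led_id Identifier of the excitation source.
#' @param molar_mass_g_per_mol Molar mass used for nM / ug mL-1 conversion.
#' @return An object of class `analyte_channel`.
#' @export
analyte_channel <- function(analyte, excitation_nm, emission_nm,
                            band_halfwidth_nm = 10, led_id,
                            molar_mass_g_per_mol = NA_real_) {
  if (excitation_nm >= emission_nm) {
    stop("analyte_channel: excitation_nm must be < emission_nm (Stokes shift)",
         call. = FALSE)
  }
  if (band_halfwidth_nm <= 0) {
    stop("analyte_channel: band_halfwidth_nm must be > 0", call. = FALSE)
  }
  structure(
    list(
      analyte = analyte, excitation_nm = excitation_nm, emission_nm = emission_nm,
      band_halfwidth_nm = band_halfwidth_nm, led_id = led_id,
      molar_mass_g_per_mol = molar_mass_g_per_mol
    ),
    class = "analyte_channel"
  )
}

#' Default analyte channels
#'
#' FMN is excited at 405 nm and read out at 530 nm; NADH is excited at 385 nm
#' and read out at 460 nm; the creatinine reaction product is excited at
#' 405 nm and read out at 475 nm. Molar masses: FMN 456.34, NADH 709.40,
#' creatinine 113.12 g mol-1.
#'
#' @param analytes Character vector of channels to return.
#' @return Named list of [analyte_channel()] objects.
#' @export
default_channels <- function(analytes = c("FMN", "NADH", "CREATININE_PRODUCT")) {
  all <- list(
    FMN = analyte_channel("FMN", 405, 530, 10, "LED405", 456.34),
    NADH = analyte_channel("NADH", 385, 460, 10, "LED385", 709.40),
    CREATININE_PRODUCT = analyte_channel("CREATININE_PRODUCT", 405, 475, 10,
                                         "LED405", 113.12)
  )
  unknown <- setdiff(analytes, names(all))
  if (length(unknown)) {
    stop("default_channels: unknown analyte(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  all[analytes]
}

#' One timestamped quantification
#'
#' @param timestamp_s Seconds since run start.
#' @param analyte Analyte name.
#' @param raw_intensity Band intensity of the light frame (counts s-1).
#' @param dark_intensity Band intensity of the paired dark frame (counts s-1).
#' @param concentration Estimated concentration (ug mL-1).
#' @param flags Character vector drawn from
#'   `BELOW_LOD`, `SATURATED`, `NEGATIVE_CLIPPED`, `WARMUP`.
#' @return An object of class `measurement_record`. `net_intensity` is always
#'   `raw_intensity - dark_intensity`.
#' @export
measurement_record <- function(timestamp_s, analyte, raw_intensity,
                               dark_intensity, concentration,
                               flags = character()) {
  structure(
    list(
      timestamp_s = timestamp_s, analyte = analyte,
      raw_intensity = raw_intensity, dark_intensity = dark_intensity,
      net_intensity = raw_intensity - dark_intensity,
      concentration = concentration, flags = flags
    ),
    class = "measurement_record"
  )
}

#' Convert a list of measurement records to a data frame
#' @param records List of [measurement_record()] objects.
#' @return A data frame with one row per record; flags semicolon-joined.
#' @export
records_to_df <- function(records) {
  if (!length(records)) {
    return(data.frame(
      timestamp_s = numeric(), analyte = character(),
      raw_intensity = numeric(), dark_intensity = numeric(),
      net_intensity = numeric(), concentration_ug_per_ml = numeric(),
      flags = character(), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    timestamp_s = vapply(records, `[[`, numeric(1), "timestamp_s"),
    analyte = vapply(records, `[[`, character(1), "analyte"),
    raw_intensity = vapply(records, `[[`, numeric(1), "raw_intensity"),
    dark_intensity = vapply(records, `[[`, numeric(1), "dark_intensity"),
    net_intensity = vapply(records, `[[`, numeric(1), "net_intensity"),
    concentration_ug_per_ml = vapply(records, `[[`, numeric(1), "concentration"),
    flags = vapply(records, function(r) paste(r$flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Elementary spectral operations
# ---------------------------------------------------------------------------

#' Subtract a dark frame from a light frame
#'
#' A dark acquisition (LED off) captures ambient light and detector dark
#' current; subtracting it from the subsequent light frame makes the net
#' signal robust to changing light conditions.
#'
#' @param raw A light [spectrum_frame()] (`is_dark = FALSE`).
#' @param dark The paired dark frame (`is_dark = TRUE`), same grid and LED.
#' @return A dark-corrected `spectrum_frame` with `counts = raw - dark`
#'   pointwise and metadata copied from `raw`.
#' @export
dark_subtract <- function(raw, dark) {
  stopifnot(inherits(raw, "spectrum_frame"), inherits(dark, "spectrum_frame"))
  if (!grids_equal(raw$grid, dark$grid)) {
    stop("dark_subtract: wavelength grids do not match", call. = FALSE)
  }
  if (raw$is_dark || !dark$is_dark) {
    stop("dark_subtract: expected a light frame and a dark frame (frame-role error)",
         call. = FALSE)
  }
  if (!identical(raw$led_id, dark$led_id)) {
    stop("dark_subtract: frames come from different LEDs", call. = FALSE)
  }
  out <- raw
  out$counts <- raw$counts - dark$counts
  out$dark_corrected <- TRUE
  out
}

#' Band intensity of a spectrum
#'
#' Mean counts over the grid points inside the closed emission band
#' `emission_nm +/- band_halfwidth_nm`, normalised per second of integration
#' time so that readings transfer across integration settings.
#'
#' @param spec A dark-corrected [spectrum_frame()].
#' @param channel An [analyte_channel()] defining the readout band.
#' @param require_dark_corrected Refuse raw frames (default `TRUE`).
#' @return Band intensity in counts s-1.
#' @export
band_intensity <- function(spec, channel, require_dark_corrected = TRUE) {
  stopifnot(inherits(spec, "spectrum_frame"), inherits(channel, "analyte_channel"))
  if (require_dark_corrected && !spec$dark_corrected) {
    stop("band_intensity: spectrum has not been dark-corrected", call. = FALSE)
  }
  wl <- grid_wavelengths(spec$grid)
  inside <- wl >= channel$emission_nm - channel$band_halfwidth_nm &
    wl <= channel$emission_nm + channel$band_halfwidth_nm
  if (!any(inside)) {
    stop("band_intensity: readout band lies outside the wavelength grid",
         call. = FALSE)
  }
  mean(spec$counts[inside]) / spec$integration_time_s
}

#' Invert a calibration curve
#'
#' Maps a net band intensity to a concentration through the inverse of the
#' linear calibration, subtracts the run's blank offset if one is stored on
#' the curve, and flags sub-zero and sub-LOD results.
#'
#' @param net Net band intensity (counts s-1).
#' @param curve A [calibration_curve()].
#' @param apply_blank_offset Subtract the curve's stored blank offset
#'   (default `TRUE`).
#' @param clip_negative Clip negative concentrations to zero with a
#'   `NEGATIVE_CLIPPED` flag (default `TRUE`).
#' @return List with `concentration` (ug mL-1) and `flags`.
#' @export
concentration_from_intensity <- function(net, curve, apply_blank_offset = TRUE,
                                         clip_negative = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) {
    stop("concentration_from_intensity: invalid calibration (slope <= 0)",
         call. = FALSE)
  }
  conc <- (net - curve$intercept) / curve$slope
  if (apply_blank_offset && is.finite(curve$blank_offset)) {
    conc <- conc - curve$blank_offset
  }
  flags <- character()
  if (conc < 0 && clip_negative) {
    conc <- 0
    flags <- c(flags, "NEGATIVE_CLIPPED")
  }
  if (is.finite(curve$lod) && conc < curve$lod) {
    flags <- c(flags, "BELOW_LOD")
  }
  list(concentration = conc, flags = flags)
}

#' Convert between nM and ug mL-1
#'
#' `nM * molar_mass / 1e6 = ug mL-1`, and the inverse.
#'
#' @param value Concentration to convert.
#' @param direction One of `"nM_to_ug_per_ml"` or `"ug_per_ml_to_nM"`.
#' @param channel An [analyte_channel()] carrying the molar mass, or a bare
#'   molar mass in g mol-1.
#' @return Converted concentration.
#' @export
convert_units <- function(value,
                          direction = c("nM_to_ug_per_ml", "ug_per_ml_to_nM"),
                          channel) {
  direction <- match.arg(direction)
  mm <- if (inherits(channel, "analyte_channel")) channel$molar_mass_g_per_mol else channel
  if (!is.numeric(mm) || !is.finite(mm) || mm <= 0) {
    stop("convert_units: molar mass must be a positive number", call. = FALSE)
  }
  switch(direction,
    nM_to_ug_per_ml = value * mm / 1e6,
    ug_per_ml_to_nM = value * 1e6 / mm
  )
}

# ---------------------------------------------------------------------------
# Serialization: spectrum frames and measurement record streams
# ---------------------------------------------------------------------------

#' Write a spectrum frame to CSV
#'
#' Format: `#`-prefixed header block (led_id, is_dark, integration_time_s,
#' timestamp_s, dark_corrected) followed by `wavelength_nm,counts` rows.
#'
#' @param spec A [spectrum_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_frame"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# led_id: %s", spec$led_id),
    sprintf("# is_dark: %s", tolower(as.character(spec$is_dark))),
    sprintf("# integration_time_s: %.17g", spec$integration_time_s),
    sprintf("# timestamp_s: %.17g", spec$timestamp_s),
    sprintf("# dark_corrected: %s", tolower(as.character(spec$dark_corrected))),
    "wavelength_nm,counts"
  ), con)
  wl <- grid_wavelengths(spec$grid)
  writeLines(sprintf("%.17g,%.17g", wl, spec$counts), con)
  invisible(path)
}

#' Read a spectrum frame from CSV
#' @param path File written by [write_spectrum()].
#' @return A [spectrum_frame()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("read_spectrum: missing header key ", key, call. = FALSE)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  wl <- df$wavelength_nm
  if (length(wl) < 2) stop("read_spectrum: too few grid points", call. = FALSE)
  step <- wl[2] - wl[1]
  grid <- wavelength_grid(wl[1], step, length(wl))
  spectrum_frame(
    grid, df$counts, get("led_id"),
    is_dark = identical(get("is_dark"), "true"),
    integration_time_s = as.numeric(get("integration_time_s")),
    timestamp_s = as.numeric(get("timestamp_s")),
    dark_corrected = identical(get("dark_corrected"), "true")
  )
}

#' Write a measurement-record stream to CSV
#' @param records List of [measurement_record()] or a data frame from
#'   [records_to_df()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  df <- if (is.data.frame(records)) records else records_to_df(records)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement-record stream from CSV
#' @param path File written by [write_records()].
#' @return A data frame in the layout of [records_to_df()].
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(flags = "character"))
  df$flags[is.na(df$flags)] <- ""
  df
}
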