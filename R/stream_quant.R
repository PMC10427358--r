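# ---------------------------------------------------------------------------
# Real-time acquisition pipeline: LED/dark scheduling, per-cycle
# quantification, rolling median filter, timestamped persistence.
# ---------------------------------------------------------------------------

#' LED acquisition schedule
#'
#' Channels are visited in order each cycle; with `dark_every_frame` a dark
#' frame (LED off) precedes every light frame. Each frame occupies
#' `integration_time_s + per_frame_overhead_s` of wall time. With two
#' channels, dark interleaving, 2 s integration and 0.75 s overhead the cycle
#' takes 11 s, the cadence achievable with a two-LED design.
#'
#' @param channels List of [analyte_channel()], in acquisition order.
#' @param integration_time_s Detector integration time (s, default 2).
#' @param per_frame_overhead_s LED switching / readout overhead per frame
#'   (s, default 0.75).
#' @param dark_every_frame Acquire a dark frame before every light frame
#'   (default `TRUE`).
#' @return An object of class `led_schedule`.
#' @export
led_schedule <- function(channels, integration_time_s = 2,
                         per_frame_overhead_s = 0.75,
                         dark_every_frame = TRUE) {
  if (!length(channels) || !all(vapply(channels, inherits, logical(1), "analyte_channel"))) {
    stop("led_schedule: channels must be a non-empty list of analyte_channel",
         call. = FALSE)
  }
  if (integration_time_s <= 0) stop("led_schedule: integration_time_s must be > 0",
                                    call. = FALSE)
  if (per_frame_overhead_s < 0) stop("led_schedule: overhead must be >= 0",
                                     call. = FALSE)
  structure(
    list(
      channels = channels, integration_time_s = integration_time_s,
      per_frame_overhead_s = per_frame_overhead_s,
      dark_every_frame = isTRUE(dark_every_frame)
    ),
    class = "led_schedule"
  )
}

#' Default two-channel schedule (FMN + NADH)
#' @return A [led_schedule()] with the default FMN and NADH channels.
#' @export
default_schedule <- function() {
  led_schedule(default_channels(c("FMN", "NADH")))
}

#' Cycle period of a schedule
#'
#' `n_channels * frames_per_channel * (integration + overhead)` where
#' frames_per_channel is 2 with dark interleaving, else 1.
#'
#' @param schedule A [led_schedule()].
#' @return Seconds per full acquisition cycle.
#' @export
cycle_period <- function(schedule) {
  stopifnot(inherits(schedule, "led_schedule"))
  frames <- length(schedule$channels) * (1L + as.integer(schedule$dark_every_frame))
  frames * (schedule$integration_time_s + schedule$per_frame_overhead_s)
}

#' Create an empty stream state
#'
#' Holds the most recent dark frame per LED, the append-only record log and
#' the rolling-filter buffers.
#'
#' @return An environment of class `stream_state`.
#' @export
new_stream_state <- function() {
  st <- new.env(parent = emptyenv())
  st$last_dark <- list()
  st$records <- list()
  st$filter_buffer <- list()
  st$events <- character()
  class(st) <- c("stream_state", "environment")
  st
}

log_event <- function(state, msg) {
  state$events <- c(state$events, msg)
  invisible(state)
}

#' Quantify one acquisition cycle
#'
#' Consumes the cycle's frames in order: dark frames update the per-LED dark
#' store; each light frame is paired with the most recent dark frame of its
#' LED, dark-subtracted, integrated over its channel's readout band and
#' inverted through the analyte's calibration curve. A light frame with no
#' available dark frame is skipped with a logged `MISSING_DARK` event rather
#' than crashing the stream.
#'
#' @param frames List of [spectrum_frame()] for the cycle.
#' @param curves Named list of [calibration_curve()], one per analyte.
#' @param state A [new_stream_state()]; updated in place.
#' @param schedule The [led_schedule()] mapping LEDs to channels.
#' @param full_well Saturation threshold in counts.
#' @return List of [measurement_record()] produced by the cycle (also
#'   appended to `state$records`).
#' @export
process_cycle <- function(frames, curves, state, schedule = default_schedule(),
                          full_well = 65535) {
  stopifnot(inherits(state, "stream_state"))
  chan_by_led <- stats::setNames(schedule$channels,
                                 vapply(schedule$channels, `[[`, character(1), "led_id"))
  out <- list()
  for (fr in frames) {
    if (fr$is_dark) {
      state$last_dark[[fr$led_id]] <- fr
      next
    }
    ch <- chan_by_led[[fr$led_id]]
    if (is.null(ch)) {
      log_event(state, sprintf("t=%.2f UNSCHEDULED_LED %s", fr$timestamp_s, fr$led_id))
      next
    }
    dark <- state$last_dark[[fr$led_id]]
    if (is.null(dark)) {
      log_event(state, sprintf("t=%.2f MISSING_DARK %s", fr$timestamp_s, fr$led_id))
      next
    }
    curve <- curves[[ch$analyte]]
    if (is.null(curve)) {
      log_event(state, sprintf("t=%.2f MISSING_CALIBRATION %s", fr$timestamp_s,
                               ch$analyte))
      next
    }
    net_spec <- dark_subtract(fr, dark)
    raw_i <- band_intensity(fr, ch, require_dark_corrected = FALSE)
    dark_i <- band_intensity(dark, ch, require_dark_corrected = FALSE)
    net_i <- band_intensity(net_spec, ch)
    est <- concentration_from_intensity(net_i, curve)
    flags <- est$flags
    if (max(fr$counts) >= full_well) flags <- unique(c(flags, "SATURATED"))
    rec <- measurement_record(fr$timestamp_s, ch$analyte, raw_i, dark_i,
                              est$concentration, flags)
    state$records[[length(state$records) + 1L]] <- rec
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' Trailing rolling-median filter
#'
#' Smooths a concentration stream with a trailing median of `k` values. The
#' first `k - 1` entries have no full window; they pass through unchanged and
#' are flagged `WARMUP`.
#'
#' @param x Numeric concentration stream.
#' @param k Odd window size >= 1 (default 5).
#' @return Data frame `value` (smoothed stream) and `warmup` (logical).
#' @export
rolling_filter <- function(x, k = 5) {
  if (k %% 2 == 0 || k < 1) {
    stop("rolling_filter: window size k must be odd and >= 1", call. = FALSE)
  }
  n <- length(x)
  out <- x
  if (n >= k && k > 1) {
    for (i in k:n) out[i] <- stats::median(x[(i - k + 1):i])
  }
  data.frame(value = out, warmup = seq_len(n) < k)
}

#' Run the monitoring pipeline over a frame stream
#'
#' Consumes frames cycle by cycle, quantifies each channel, and persists the
#' record stream incrementally (flushed after every cycle, so a crash loses
#' at most one cycle). Writes `records.csv`, `manifest.json` and
#' `events.log` to the output directory.
#'
#' @param frames List of [spectrum_frame()] in acquisition order (e.g. from
#'   [simulate_hope_run()]).
#' @param curves Named list of [calibration_curve()] covering every scheduled
#'   analyte.
#' @param schedule The [led_schedule()] used for acquisition.
#' @param out_dir Output run directory (created if missing).
#' @param filter_k Rolling-median window for the smoothed column (odd,
#'   default 5); `1` disables smoothing.
#' @param seed Seed recorded in the manifest when the source is simulated.
#' @return Invisibly, the record data frame (with smoothed concentrations).
#' @export
run_monitor <- function(frames, curves, schedule = default_schedule(),
                        out_dir, filter_k = 5, seed = NULL) {
  missing_cal <- setdiff(
    vapply(schedule$channels, `[[`, character(1), "analyte"), names(curves)
  )
  if (length(missing_cal)) {
    stop("run_monitor: no calibration curve for scheduled analyte(s): ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec_path <- file.path(out_dir, "records.csv")
  state <- new_stream_state()
  header <- paste(c("timestamp_s", "analyte", "raw_intensity", "dark_intensity",
                    "net_intensity", "concentration_ug_per_ml", "flags"),
                  collapse = ",")
  con <- file(rec_path, "w")
  writeLines(header, con)
  frames_per_cycle <- length(schedule$channels) *
    (1L + as.integer(schedule$dark_every_frame))
  n_cycles <- length(frames) %/% frames_per_cycle
  for (cyc in seq_len(n_cycles)) {
    idx <- ((cyc - 1) * frames_per_cycle + 1):(cyc * frames_per_cycle)
    recs <- process_cycle(frames[idx], curves, state, schedule)
    for (r in recs) {
      writeLines(sprintf("%.17g,%s,%.17g,%.17g,%.17g,%.17g,%s",
                         r$timestamp_s, r$analyte, r$raw_intensity,
                         r$dark_intensity, r$net_intensity, r$concentration,
                         paste(r$flags, collapse = ";")), con)
    }
    flush(con)
  }
  close(con)
  df <- records_to_df(state$records)
  # smoothed stream per analyte
  df$concentration_smoothed <- df$concentration_ug_per_ml
  for (a in unique(df$analyte)) {
    sel <- df$analyte == a
    sm <- rolling_filter(df$concentration_ug_per_ml[sel], k = filter_k)
    df$concentration_smoothed[sel] <- sm$value
    warm <- which(sel)[sm$warmup]
    df$flags[warm] <- ifelse(df$flags[warm] == "", "WARMUP",
                             paste(df$flags[warm], "WARMUP", sep = ";"))
  }
  utils::write.csv(df, file.path(out_dir, "records_filtered.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- run_manifest(
    config = list(
      schedule = list(
        analytes = vapply(schedule$channels, `[[`, character(1), "analyte"),
        integration_time_s = schedule$integration_time_s,
        per_frame_overhead_s = schedule$per_frame_overhead_s,
        dark_every_frame = schedule$dark_every_frame,
        cycle_period_s = cycle_period(schedule)
      ),
      curves = lapply(curves, function(cv) cv[c("analyte", "slope", "intercept", "lod")]),
      filter_k = filter_k
    ),
    seed = seed
  )
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  writeLines(state$events, file.path(out_dir, "events.log"))
  invisible(df)
}
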