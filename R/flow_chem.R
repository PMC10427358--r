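# ---------------------------------------------------------------------------
# Creatinine wet-chemistry transform: reagent mixing dilution, plug-flow
# delay line, and back-calculation from the cuvette signal to dialysate and
# blood concentrations.
# ---------------------------------------------------------------------------

#' Flow-injection assay train
#'
#' Waste dialysate is drawn off in a bypass and merged with an NaOH stream
#' and a colorimetric reagent stream; the combined flow transits a delay
#' line long enough for the reaction to complete before reaching the
#' cuvette. Defaults follow the 20:5:5 mL h-1 flow split with a 30 min
#' transit.
#'
#' @param dialysate_flow_mL_h Dialysate bypass flow (mL h-1, default 20).
#' @param naoh_flow_mL_h NaOH stream flow (mL h-1, default 5).
#' @param reagent_flow_mL_h Reagent stream flow (mL h-1, default 5).
#' @param transit_delay_min Plug-flow transit time to the cuvette (min,
#'   default 30).
#' @param equilibration_factor Dialysate/blood equilibration in (0, 1]
#'   (default 1).
#' @return An object of class `assay_train`.
#' @export
assay_train <- function(dialysate_flow_mL_h = 20, naoh_flow_mL_h = 5,
                        reagent_flow_mL_h = 5, transit_delay_min = 30,
                        equilibration_factor = 1) {
  if (dialysate_flow_mL_h <= 0) {
    stop("assay_train: dialysate flow must be > 0", call. = FALSE)
  }
  if (naoh_flow_mL_h < 0 || reagent_flow_mL_h < 0) {
    stop("assay_train: reagent flows must be >= 0", call. = FALSE)
  }
  if (transit_delay_min < 0) stop("assay_train: delay must be >= 0", call. = FALSE)
  if (equilibration_factor <= 0 || equilibration_factor > 1) {
    stop("assay_train: equilibration_factor must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      dialysate_flow_mL_h = dialysate_flow_mL_h,
      naoh_flow_mL_h = naoh_flow_mL_h,
      reagent_flow_mL_h = reagent_flow_mL_h,
      transit_delay_min = transit_delay_min,
      equilibration_factor = equilibration_factor
    ),
    class = "assay_train"
  )
}

#' Mixing dilution of the assay train
#'
#' The fraction of the combined stream that is dialysate:
#' `dialysate / (dialysate + naoh + reagent)`. With the default 20:5:5 split
#' this is 2/3.
#'
#' @param train An [assay_train()].
#' @return Dimensionless dilution factor in (0, 1].
#' @export
mixing_dilution <- function(train) {
  stopifnot(inherits(train, "assay_train"))
  total <- train$dialysate_flow_mL_h + train$naoh_flow_mL_h + train$reagent_flow_mL_h
  if (total <= 0) stop("mixing_dilution: total flow must be > 0", call. = FALSE)
  train$dialysate_flow_mL_h / total
}

#' Plug-flow delay line
#'
#' A pure time shift: `output(t) = input(t - delay)`, evaluated on the
#' input's own time grid. Values are carried through unchanged (linear
#' interpolation only where the delay does not align with the sampling
#' grid). Output times before the delayed stream first arrives are flagged
#' `no_signal`.
#'
#' @param series Data frame with columns `timestamp_min`, `value`.
#' @param delay_min Delay in minutes (>= 0).
#' @return Data frame `timestamp_min`, `value`, `no_signal` (logical; value
#'   is `NA` where `no_signal`).
#' @export
delay_line <- function(series, delay_min) {
  stopifnot(is.data.frame(series),
            all(c("timestamp_min", "value") %in% names(series)))
  if (delay_min < 0) stop("delay_line: delay must be >= 0", call. = FALSE)
  tt <- series$timestamp_min
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("delay_line: timestamps must be strictly increasing", call. = FALSE)
  }
  no_signal <- tt - delay_min < tt[1] - 1e-9
  value <- rep(NA_real_, length(tt))
  if (any(!no_signal)) {
    value[!no_signal] <- stats::approx(tt, series$value,
                                       xout = tt[!no_signal] - delay_min)$y
  }
  data.frame(timestamp_min = tt, value = value, no_signal = no_signal)
}

#' Forward assay model: dialysate series to cuvette series
#'
#' Applies the mixing dilution and the transit delay, mapping
#' dialysate-collection time to cuvette-arrival time.
#'
#' @param series Dialysate series (`timestamp_min`, `value`).
#' @param train An [assay_train()].
#' @return Cuvette series (`timestamp_min`, `value`).
#' @export
dialysate_to_cuvette <- function(series, train) {
  shifted <- delay_line(series, train$transit_delay_min)
  shifted <- shifted[!shifted$no_signal, ]
  data.frame(
    timestamp_min = shifted$timestamp_min,
    value = shifted$value * mixing_dilution(train)
  )
}

#' Invert the assay train: cuvette signal to dialysate concentration
#'
#' Divides out the mixing dilution and re-indexes timestamps by
#' dialysate-collection time (advances them by the transit delay).
#'
#' @param series Cuvette concentration series (`timestamp_min`, `value`).
#' @param train An [assay_train()].
#' @return Dialysate series (`timestamp_min`, `value`).
#' @export
cuvette_to_dialysate <- function(series, train) {
  stopifnot(inherits(train, "assay_train"))
  dil <- mixing_dilution(train)
  if (dil <= 0) stop("cuvette_to_dialysate: dilution must be > 0", call. = FALSE)
  data.frame(
    timestamp_min = series$timestamp_min - train$transit_delay_min,
    value = series$value / dil
  )
}

#' Dialysate concentration to blood concentration
#'
#' Waste dialysate reflects blood concentrations up to the equilibration
#' factor; dividing by it recovers the blood series.
#'
#' @param series Dialysate series (`timestamp_min`, `value`).
#' @param train An [assay_train()].
#' @return Blood series (`timestamp_min`, `value`).
#' @export
dialysate_to_blood <- function(series, train) {
  stopifnot(inherits(train, "assay_train"))
  if (train$equilibration_factor <= 0) {
    stop("dialysate_to_blood: equilibration factor must be > 0", call. = FALSE)
  }
  data.frame(
    timestamp_min = series$timestamp_min,
    value = series$value / train$equilibration_factor
  )
}
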