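#' Construct a sampled physiological time series
#'
#' A minimal container for a regularly or irregularly sampled measurement
#' series (rectal temperature in degrees C, heart rate in bpm). Times are in
#' minutes from exercise start.
#'
#' @param times Numeric vector of sampling times (min), strictly increasing.
#' @param values Numeric vector of measurements, same length as `times`.
#' @param max_gap Largest tolerated sampling gap (min). Measured sessions are
#'   validated with `max_gap = 10`: larger gaps are rejected, while gaps
#'   above the nominal 5-min cadence are linearly bridged with a warning.
#'   The default (`Inf`) accepts any grid, for analytically defined series.
#' @return An object of class `htt_ts`: a list with elements `times` and
#'   `values`.
#' @examples
#' ts <- time_series(seq(0, 120, 5), 37 + seq(0, 1.2, length.out = 25))
#' value_at(ts, 60)
#' @export
time_series <- function(times, values, max_gap = Inf) {
  if (!is.numeric(times) || !is.numeric(values)) {
    stop("`times` and `values` must be numeric", call. = FALSE)
  }
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a time series needs at least two samples", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values)) {
    stop("missing values are not allowed in a time series", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (is.finite(max_gap)) {
    gaps <- diff(times)
    if (any(gaps > max_gap)) {
      stop(sprintf("sampling gap exceeds %g min; series rejected", max_gap),
           call. = FALSE)
    }
    if (any(gaps > 5 + 1e-9)) {
      warning("sampling gap > 5 min; values are linearly bridged",
              call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "htt_ts")
}

#' Value of a series at an arbitrary time
#'
#' Returns the stored sample when `t` falls on the sampling grid and the
#' linear interpolant between the two neighbouring samples otherwise.
#'
#' @param series An `htt_ts` object (see [time_series()]).
#' @param t Time in minutes; must lie within the sampled range.
#' @return Interpolated value (scalar, or vector if `t` is a vector).
#' @export
value_at <- function(series, t) {
  stopifnot(inherits(series, "htt_ts"))
  if (any(t < min(series$times) - 1e-9) || any(t > max(series$times) + 1e-9)) {
    stop(sprintf("time %s outside sampled range [%g, %g]",
                 paste(t[t < min(series$times) | t > max(series$times)],
                       collapse = ", "),
                 min(series$times), max(series$times)), call. = FALSE)
  }
  stats::approx(series$times, series$values, xout = t, rule = 1)$y
}

# Insert exact threshold-crossing times into a sampling grid so that the
# trapezoid rule integrates the clamped excess max(v - threshold, 0) exactly
# for a piecewise-linear series.
augment_crossings <- function(times, values, threshold) {
  n <- length(times)
  v1 <- values[-n] - threshold
  v2 <- values[-1L] - threshold
  idx <- which(v1 * v2 < 0)
  if (length(idx)) {
    tc <- times[idx] + (0 - v1[idx]) * (times[idx + 1L] - times[idx]) /
      (v2[idx] - v1[idx])
    ord <- order(c(times, tc))
    all_t <- c(times, tc)[ord]
    all_v <- c(values, rep(threshold, length(tc)))[ord]
    list(times = all_t, values = all_v)
  } else {
    list(times = times, values = values)
  }
}

#' Area under a series above a threshold
#'
#' Trapezoidal area of `max(value - threshold, 0)` over the sampled range,
#' with threshold-crossing times interpolated linearly between samples so the
#' result is exact for a piecewise-linear series. Used for the thermal-strain
#' areas above 37, 38 and 38.5 degrees C and for baseline-adjusted areas.
#'
#' @param series An `htt_ts` object.
#' @param threshold Threshold in the units of the series.
#' @return Non-negative area in value-units times minutes.
#' @seealso [auc_baseline()]
#' @export
auc_above <- function(series, threshold) {
  stopifnot(inherits(series, "htt_ts"), is.numeric(threshold),
            length(threshold) == 1L)
  aug <- augment_crossings(series$times, series$values, threshold)
  pracma::trapz(aug$times, pmax(aug$values - threshold, 0))
}

#' Baseline-adjusted area under a series
#'
#' Identical to [auc_above()] with the threshold set to the participant's
#' pre-exercise baseline, quantifying strain relative to individual starting
#' values.
#'
#' @inheritParams auc_above
#' @param baseline Pre-exercise baseline value.
#' @return Non-negative area in value-units times minutes.
#' @export
auc_baseline <- function(series, baseline) {
  auc_above(series, baseline)
}

#' Thermal-circulatory ratio
#'
#' The ratio of rectal temperature to heart rate at a given time. Low values
#' indicate heart-rate-dominated strain; published tolerance cut-offs are
#' 0.32 degC/bpm at 60 min and 0.279 degC/bpm at 120 min.
#'
#' @param trec Rectal temperature (degrees C).
#' @param hr Heart rate (bpm), strictly positive.
#' @return Ratio in degrees C per bpm.
#' @examples
#' tcr(38.0, 100) # 0.38
#' @export
tcr <- function(trec, hr) {
  if (any(hr <= 0)) stop("heart rate must be > 0", call. = FALSE)
  trec / hr
}

#' Rate of rise
#'
#' Change from a start value to an end value divided by the exercise
#' duration. For rectal temperature the start is the pre-exercise baseline;
#' for heart rate it is the value at exercise start (T0).
#'
#' @param start_value Starting value.
#' @param end_value End-exercise value.
#' @param duration Exercise duration in minutes, > 0.
#' @return Rate in value-units per minute.
#' @export
rate_of_rise <- function(start_value, end_value, duration) {
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  (end_value - start_value) / duration
}

#' Plateau statistic: temperature change over the final hour
#'
#' `value_at(series, 120) - value_at(series, 60)`. Small values indicate a
#' thermoregulatory plateau; the published intolerance cut-off is a rise of
#' at least 0.45 degrees C. Negative values (cooling) are preserved.
#'
#' @param trec_series An `htt_ts` covering at least \[60, 120\] min.
#' @return Change in degrees C (may be negative).
#' @export
plateau_delta <- function(trec_series) {
  stopifnot(inherits(trec_series, "htt_ts"))
  if (min(trec_series$times) > 60 || max(trec_series$times) < 120) {
    stop("series does not cover [60, 120] min; plateau undefined",
         call. = FALSE)
  }
  value_at(trec_series, 120) - value_at(trec_series, 60)
}

# Time-weighted trapezoidal mean over the sampled range.
trapz_mean <- function(series) {
  rng <- range(series$times)
  pracma::trapz(series$times, series$values) / diff(rng)
}

#' Per-session derived metrics
#'
#' Computes every per-session quantity used downstream: temperature and heart
#' rate at exercise start (T0), 60 and 120 min, session peaks (sample maxima)
#' and time-weighted trapezoidal means, deltas and rates of rise, trapezoidal
#' areas above the pre-exercise baseline and above 37 / 38 / 38.5 degrees C,
#' the heart-rate area above its T0 value, and the thermal-circulatory ratio
#' at 60 and 120 min.
#'
#' @param session A session list with elements `trec_series` and `hr_series`
#'   (class `htt_ts`), `baseline_trec` (degrees C, pre-exercise seated) and
#'   `duration` (min; defaults to the span of the temperature series).
#' @return A one-row `data.frame` with columns `trec_t0`, `trec_t60`,
#'   `trec_t120`, `trec_peak`, `trec_mean`, `hr_t0`, `hr_t60`, `hr_t120`,
#'   `hr_peak`, `hr_mean`, `delta_trec`, `delta_hr`, `plateau_delta`,
#'   `trec_ror`, `hr_ror`, `trec_auc_baseline`, `trec_auc_37`, `trec_auc_38`,
#'   `trec_auc_385`, `hr_auc`, `tcr_t60`, `tcr_t120`.
#' @export
session_metrics <- function(session) {
  trec <- session$trec_series
  hr <- session$hr_series
  stopifnot(inherits(trec, "htt_ts"), inherits(hr, "htt_ts"))
  baseline <- session$baseline_trec
  if (is.null(baseline) || !is.finite(baseline)) {
    stop("session is missing `baseline_trec`", call. = FALSE)
  }
  duration <- session$duration
  if (is.null(duration)) duration <- diff(range(trec$times))
  t_end <- max(trec$times)
  h_end <- max(hr$times)

  trec_t0 <- value_at(trec, min(trec$times))
  hr_t0 <- value_at(hr, min(hr$times))
  trec_end <- value_at(trec, t_end)
  hr_end <- value_at(hr, h_end)

  data.frame(
    trec_t0 = trec_t0,
    trec_t60 = value_at(trec, 60),
    trec_t120 = value_at(trec, 120),
    trec_peak = max(trec$values),
    trec_mean = trapz_mean(trec),
    hr_t0 = hr_t0,
    hr_t60 = value_at(hr, 60),
    hr_t120 = value_at(hr, 120),
    hr_peak = max(hr$values),
    hr_mean = trapz_mean(hr),
    delta_trec = trec_end - trec_t0,
    delta_hr = hr_end - hr_t0,
    plateau_delta = plateau_delta(trec),
    trec_ror = rate_of_rise(baseline, trec_end, duration),
    hr_ror = rate_of_rise(hr_t0, hr_end, duration),
    trec_auc_baseline = auc_baseline(trec, baseline),
    trec_auc_37 = auc_above(trec, 37),
    trec_auc_38 = auc_above(trec, 38),
    trec_auc_385 = auc_above(trec, 38.5),
    hr_auc = auc_baseline(hr, hr_t0),
    tcr_t60 = tcr(value_at(trec, 60), value_at(hr, 60)),
    tcr_t120 = tcr(value_at(trec, 120), value_at(hr, 120))
  )
}
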