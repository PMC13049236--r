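#' Raw capnography trace
#'
#' A uniformly sampled recording of expired CO2 partial pressure (mmHg).
#'
#' @param values CO2 partial pressure per sample, mmHg.
#' @param sampling_interval seconds between samples (> 0).
#' @param acquisition_delay transit delay of the gas sampling line, seconds;
#'   subtracted when aligning the trace to scanner time.
#' @return object of class `raw_capno` with fields `values`,
#'   `sampling_interval`, `acquisition_delay` and derived `time` stamps.
#' @export
raw_capno <- function(values, sampling_interval, acquisition_delay = 0) {
  stopifnot_scalar(sampling_interval, "sampling_interval")
  values <- as.numeric(values)
  if (length(values) < 2L) stop("capnography trace is empty", call. = FALSE)
  if (!all(is.finite(values)))
    stop("capnography trace contains non-finite values", call. = FALSE)
  structure(list(values = values,
                 sampling_interval = sampling_interval,
                 acquisition_delay = acquisition_delay,
                 time = (seq_along(values) - 1) * sampling_interval),
            class = "raw_capno")
}

#' @export
print.raw_capno <- function(x, ...) {
  cat(sprintf("raw capnography trace: %d samples at %.3g Hz (%.1f s), %.1f-%.1f mmHg\n",
              length(x$values), 1 / x$sampling_interval,
              max(x$time), min(x$values), max(x$values)))
  invisible(x)
}

# Topographic prominence of a local maximum: height above the higher of the
# two minima separating it from the nearest higher samples (or trace edges).
peak_prominence <- function(v, i) {
  n <- length(v)
  left <- if (i > 1) {
    hi <- which(v[seq_len(i - 1L)] > v[i])
    lo <- if (length(hi)) max(hi) + 1L else 1L
    min(v[lo:(i - 1L)])
  } else v[i]
  right <- if (i < n) {
    hi <- which(v[(i + 1L):n] > v[i])
    hi <- if (length(hi)) i + min(hi) else n + 1L
    min(v[(i + 1L):(hi - 1L)])
  } else v[i]
  v[i] - max(left, right)
}

#' Detect expiratory peaks in a raw CO2 trace
#'
#' Finds the local maxima of the capnography waveform that correspond to
#' end-expiration: one peak per expiration, none during apnea. Candidate
#' strict local maxima are screened by topographic prominence, then a minimum
#' temporal separation is enforced greedily in order of descending height.
#'
#' @param raw a [raw_capno()].
#' @param min_prominence minimum peak prominence, mmHg (default 5).
#' @param min_separation minimum time between accepted peaks, seconds
#'   (default 2); must be at least two sampling intervals.
#' @return data.frame with columns `time` (s, strictly increasing), `value`
#'   (mmHg) and `index` (sample index); zero rows if no peak qualifies.
#' @export
#' @examples
#' tr <- raw_capno(35 * sin(pi * seq(0, 10, 0.05) / 5)^2, 0.05)
#' detect_expiratory_peaks(tr)
detect_expiratory_peaks <- function(raw, min_prominence = 5,
                                    min_separation = 2) {
  stopifnot(inherits(raw, "raw_capno"))
  if (min_separation < 2 * raw$sampling_interval)
    stop("min_separation must be at least two sampling intervals", call. = FALSE)
  v <- raw$values
  n <- length(v)
  if (n < 3L) return(data.frame(time = numeric(0), value = numeric(0),
                                index = integer(0)))
  cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
  # cheap prescreen: prominence can never exceed height above the global min
  cand <- cand[v[cand] - min(v) >= min_prominence]
  cand <- cand[vapply(cand, function(i) peak_prominence(v, i),
                      numeric(1)) >= min_prominence]
  if (!length(cand)) return(data.frame(time = numeric(0), value = numeric(0),
                                       index = integer(0)))
  # separation: accept by descending height, drop neighbours that crowd in
  ord <- cand[order(-v[cand], cand)]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all(abs(i - keep) * raw$sampling_interval >= min_separation))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  data.frame(time = raw$time[keep], value = v[keep], index = keep)
}

#' Interpolate expiratory peaks into a continuous end-tidal trace
#'
#' Piecewise-linear interpolation through the (time, value) pairs of the
#' expiratory peaks, on the raw sampling grid. Before the first and after the
#' last peak the nearest peak value is held constant, so the output never
#' leaves the range of the peak values.
#'
#' @param raw a [raw_capno()].
#' @param peaks peak table from [detect_expiratory_peaks()] (>= 2 rows).
#' @return object of class `end_tidal_series`: list with `time` (s) and
#'   `values` (mmHg) on the raw grid.
#' @export
build_end_tidal_trace <- function(raw, peaks) {
  stopifnot(inherits(raw, "raw_capno"))
  if (is.null(peaks) || nrow(peaks) < 2L)
    stop("insufficient respiratory events: need at least 2 expiratory peaks",
         call. = FALSE)
  out <- stats::approx(peaks$time, peaks$value, xout = raw$time,
                       method = "linear", rule = 2)$y
  structure(list(time = raw$time, values = out), class = "end_tidal_series")
}

#' Resample an end-tidal trace at the fMRI frame grid
#'
#' Samples the end-tidal series at `frame_time_i = (i - 1) * tr + shift` by
#' linear interpolation. `shift` re-aligns the recording to scanner time,
#' compensating the transit delay of the gas sampling line.
#'
#' @param end_tidal an `end_tidal_series` from [build_end_tidal_trace()].
#' @param tr fMRI repetition time, seconds.
#' @param n_frames number of fMRI frames.
#' @param shift time shift, seconds (default 0); typically the sampling-line
#'   delay.
#' @param baseline_duration seconds of pre-task baseline used for
#'   `rest_level` (default 60).
#' @return object of class `petco2_trace`: `frame_times`, `values` (mmHg),
#'   `is_filtered = FALSE`, `rest_level` (mean over the pre-task baseline),
#'   `tr`.
#' @export
resample_to_frames <- function(end_tidal, tr, n_frames, shift = 0,
                               baseline_duration = 60) {
  stopifnot(inherits(end_tidal, "end_tidal_series"))
  stopifnot_scalar(tr, "tr")
  ft <- frame_times(n_frames, tr)
  want <- ft + shift
  if (min(want) < min(end_tidal$time) - 1e-9 ||
      max(want) > max(end_tidal$time) + 1e-9)
    stop(sprintf(
      "trace does not cover scan: need [%.1f, %.1f] s, recording spans [%.1f, %.1f] s",
      min(want), max(want), min(end_tidal$time), max(end_tidal$time)),
      call. = FALSE)
  vals <- stats::approx(end_tidal$time, end_tidal$values, xout = want,
                        method = "linear", rule = 2)$y
  structure(list(frame_times = ft, values = vals, tr = tr,
                 is_filtered = FALSE,
                 rest_level = mean(vals[ft < baseline_duration])),
            class = "petco2_trace")
}

#' @export
print.petco2_trace <- function(x, ...) {
  cat(sprintf("PetCO2 trace: %d frames at TR %.3g s, %s, rest level %.1f mmHg\n",
              length(x$values), x$tr,
              if (x$is_filtered) "filtered" else "unfiltered", x$rest_level))
  invisible(x)
}

butter_coeffs <- function(spec, sampling_interval) {
  nyq_period <- 2 * sampling_interval
  if (spec$high_cutoff_period < nyq_period - 1e-12)
    stop(sprintf(
      "cutoff exceeds Nyquist: high cutoff period %.3g s is below the Nyquist time %.3g s",
      spec$high_cutoff_period, nyq_period), call. = FALSE)
  w <- c(nyq_period / spec$low_cutoff_period,
         min(nyq_period / spec$high_cutoff_period, 1 - 1e-6))
  signal::butter(spec$order, w, type = "pass")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass between 1/low_cutoff_period and 1/high_cutoff_period using a
#' digital IIR Butterworth filter of the spec's design order, applied forward
#' and then reverse for zero phase (doubling the effective magnitude order).
#' Edge transients are suppressed by odd-reflection padding of three times
#' the filter polynomial order. The high-pass edge removes DC, so the output
#' mean is approximately zero.
#'
#' @param series numeric vector, uniformly sampled.
#' @param spec a [filter_spec()].
#' @param sampling_interval seconds between samples.
#' @return filtered numeric vector of the same length.
#' @export
bandpass_filter <- function(series, spec = filter_spec(), sampling_interval) {
  stopifnot(inherits(spec, "filter_spec"))
  series <- as.numeric(series)
  n <- length(series)
  if (n <= 3 * spec$order)
    stop("series too short for the requested filter order", call. = FALSE)
  bt <- butter_coeffs(spec, sampling_interval)
  # the pass band excludes DC, so remove the mean first: this kills the
  # step-response startup transient of the IIR recursion on offset data
  series <- series - mean(series)
  if (!spec$zero_phase)
    return(as.numeric(signal::filter(bt, series)))
  np <- min(3L * (length(bt$a) - 1L), n - 1L)
  left <- 2 * series[1] - series[(np + 1L):2L]
  right <- 2 * series[n] - series[(n - 1L):(n - np)]
  x <- c(left, series, right)
  y <- as.numeric(signal::filter(bt, x))
  y <- rev(as.numeric(signal::filter(bt, rev(y))))
  y[(np + 1L):(np + n)]
}

#' Band-pass filter a PetCO2 trace
#'
#' Applies [bandpass_filter()] to the resampled PetCO2 values at the TR grid
#' and marks the trace as filtered (the regressor is filtered after
#' resampling and shifting).
#'
#' @param trace a [resample_to_frames()] output.
#' @param spec a [filter_spec()].
#' @return the trace with filtered, approximately zero-mean `values` and
#'   `is_filtered = TRUE`; `rest_level` is kept from the unfiltered trace.
#' @export
filter_petco2 <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "petco2_trace"))
  trace$values <- bandpass_filter(trace$values, spec, trace$tr)
  trace$is_filtered <- TRUE
  trace
}

#' Modulation range of a signal
#'
#' The difference between the 95th and the 5th percentiles of a (typically
#' filtered) signal; the summary used to quantify PetCO2 and fMRI signal
#' modulation during the breath-hold task. Percentiles use the linear
#' interpolation convention (`stats::quantile` type 7).
#'
#' @param series numeric vector (mmHg for PetCO2, percent for fMRI signals),
#'   or a `petco2_trace`.
#' @return non-negative scalar in the units of the input.
#' @export
modulation_range <- function(series) {
  if (inherits(series, "petco2_trace")) series <- series$values
  if (!length(series)) stop("empty series", call. = FALSE)
  q <- stats::quantile(series, c(0.05, 0.95), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Extract a filtered PetCO2 regressor from raw capnography
#'
#' Convenience chain: peak detection, end-tidal interpolation, resampling at
#' the frame grid with the sampling-line shift, then zero-phase band-pass
#' filtering at the TR grid.
#'
#' @param raw a [raw_capno()].
#' @param tr,n_frames fMRI frame grid.
#' @param shift alignment shift in seconds; default the trace's
#'   `acquisition_delay`.
#' @param fspec a [filter_spec()].
#' @param min_prominence,min_separation peak-detection parameters.
#' @param baseline_duration pre-task baseline window for `rest_level`.
#' @return a filtered `petco2_trace`; attributes `n_peaks` and
#'   `modulation_range` record the peak count and the filtered-trace
#'   95th-5th percentile range.
#' @export
extract_petco2 <- function(raw, tr, n_frames, shift = raw$acquisition_delay,
                           fspec = filter_spec(), min_prominence = 5,
                           min_separation = 2, baseline_duration = 60) {
  peaks <- detect_expiratory_peaks(raw, min_prominence, min_separation)
  et <- build_end_tidal_trace(raw, peaks)
  trace <- resample_to_frames(et, tr, n_frames, shift = shift,
                              baseline_duration = baseline_duration)
  trace <- filter_petco2(trace, fspec)
  attr(trace, "n_peaks") <- nrow(peaks)
  attr(trace, "modulation_range") <- modulation_range(trace$values)
  trace
}
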