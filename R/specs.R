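#' Band-pass filter specification
#'
#' Describes the zero-phase Butterworth band-pass applied to the PetCO2
#' regressor and to every fMRI voxel time series. Cutoffs are given as
#' periods (seconds): the defaults, 150 s and 10.1 s, correspond to a
#' 6.7-99 mHz pass band at a Nyquist time of 10 s (TR = 5 s).
#'
#' @param low_cutoff_period high-pass edge, seconds (default 150).
#' @param high_cutoff_period low-pass edge, seconds (default 10.1).
#' @param order design order of the one-way Butterworth filter (default 4).
#'   The forward-reverse pass doubles the effective magnitude order.
#' @param zero_phase apply the filter forward and reverse (default TRUE).
#' @return an object of class `filter_spec`.
#' @export
#' @examples
#' fs <- filter_spec()
#' band_edges_mhz(fs) # 6.7 99
filter_spec <- function(low_cutoff_period = 150, high_cutoff_period = 10.1,
                        order = 4, zero_phase = TRUE) {
  stopifnot_scalar(low_cutoff_period, "low_cutoff_period")
  stopifnot_scalar(high_cutoff_period, "high_cutoff_period")
  if (!(low_cutoff_period > high_cutoff_period))
    stop("low_cutoff_period must exceed high_cutoff_period", call. = FALSE)
  if (order < 1 || order != round(order))
    stop("order must be an integer >= 1", call. = FALSE)
  structure(list(low_cutoff_period = low_cutoff_period,
                 high_cutoff_period = high_cutoff_period,
                 order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Pass-band edges in millihertz
#'
#' Converts the cutoff periods of a [filter_spec()] to frequencies in mHz,
#' rounded to two significant digits as conventionally printed
#' (150 s, 10.1 s -> 6.7, 99 mHz).
#'
#' @param spec a [filter_spec()].
#' @return numeric length 2: c(low_edge_mhz, high_edge_mhz).
#' @export
band_edges_mhz <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  signif(1000 / c(spec$low_cutoff_period, spec$high_cutoff_period), 2)
}

#' Hemodynamic lag search specification
#'
#' The PetCO2 regressor is allowed to shift by up to `max_lag` seconds in
#' steps of `step` to absorb hemodynamic delays. The default grid is integer
#' multiples of the TR (+/- 2 frames = +/- 10 s at TR = 5 s); finer steps use
#' linear interpolation of the regressor.
#'
#' @param max_lag maximum absolute shift, seconds (default 10).
#' @param step grid step, seconds (default 5 = one TR).
#' @return an object of class `lag_search_spec`.
#' @export
lag_search_spec <- function(max_lag = 10, step = 5) {
  stopifnot_scalar(max_lag, "max_lag", positive = FALSE)
  stopifnot_scalar(step, "step", positive = FALSE)
  if (max_lag < 0) stop("max_lag must be >= 0", call. = FALSE)
  if (step < 0 || step > max(max_lag, .Machine$double.eps))
    if (!(max_lag == 0 && step >= 0))
      stop("need 0 <= step <= max_lag", call. = FALSE)
  structure(list(max_lag = max_lag, step = step), class = "lag_search_spec")
}

lag_grid <- function(spec) {
  if (spec$max_lag == 0 || spec$step == 0) return(0)
  sort(unique(c(seq(-spec$max_lag, spec$max_lag, by = spec$step), 0)))
}

#' Breath-hold protocol specification
#'
#' Timing of the breath-hold (BH) task and of the acquisition: an initial
#' free-breathing baseline followed by repeated cycles of post-expiratory
#' breath-hold plus free-breathing recovery. Defaults: 60 s baseline and 10
#' cycles of 20 s BH + 40 s recovery, TR 5 s, 12 breaths/min, capnograph
#' sampled at 20 Hz. The default number of frames (138, 11.5 min) slightly
#' exceeds the 660 s task so the scan ends on free breathing.
#'
#' @param baseline_duration seconds of initial free breathing (default 60).
#' @param n_cycles number of BH cycles (default 10).
#' @param bh_duration breath-hold duration, seconds (default 20).
#' @param recovery_duration recovery breathing, seconds (default 40).
#' @param tr fMRI repetition time, seconds (default 5).
#' @param breathing_rate breaths per minute (default 12).
#' @param capno_sampling_rate capnograph sampling rate, Hz (default 20).
#' @param n_frames number of fMRI frames (default 138).
#' @return an object of class `protocol_spec` with derived fields
#'   `task_duration` and `scan_duration`.
#' @export
protocol_spec <- function(baseline_duration = 60, n_cycles = 10,
                          bh_duration = 20, recovery_duration = 40,
                          tr = 5, breathing_rate = 12,
                          capno_sampling_rate = 20, n_frames = 138) {
  for (nm in c("baseline_duration", "bh_duration", "recovery_duration",
               "tr", "breathing_rate", "capno_sampling_rate"))
    stopifnot_scalar(get(nm), nm)
  if (n_cycles < 1 || n_cycles != round(n_cycles))
    stop("n_cycles must be an integer >= 1", call. = FALSE)
  task <- baseline_duration + n_cycles * (bh_duration + recovery_duration)
  if (n_frames * tr < task)
    stop("n_frames * tr must cover the task duration", call. = FALSE)
  structure(list(baseline_duration = baseline_duration,
                 n_cycles = as.integer(n_cycles),
                 bh_duration = bh_duration,
                 recovery_duration = recovery_duration,
                 tr = tr, breathing_rate = breathing_rate,
                 capno_sampling_rate = capno_sampling_rate,
                 n_frames = as.integer(n_frames),
                 task_duration = task,
                 scan_duration = n_frames * tr),
            class = "protocol_spec")
}
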