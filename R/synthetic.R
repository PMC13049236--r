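#' Population and noise parameters for the synthetic cohort generator
#'
#' Ground-truth distributions and noise settings used by [gen_cohort()] and
#' the single-subject generators. The population CVR distributions default to
#' the group statistics of healthy adults during breath-hold hypercapnia:
#' gray-matter CVR_ASL 5.3 +/- 1.8 %CBF/mmHg, CVR_GE 0.18 +/- 0.05 and
#' CVR_SE 0.09 +/- 0.03 %BOLD/mmHg; resting PetCO2 35.0 +/- 1.4 mmHg with a
#' breath-hold end-tidal modulation calibrated so the filtered-trace
#' 95th-5th percentile range is about 6.7 mmHg.
#'
#' Noise SDs (scanner units, S0 = 1000) are set so that voxelwise GM
#' confidence follows the empirical ordering of the three weightings
#' (ASL z about 2.5 < SE about 3.2 < GE about 6.4).
#'
#' @param asl_mean,asl_sd population mean/SD of true GM CVR_ASL (%CBF/mmHg).
#' @param ge_mean,ge_sd population mean/SD of true GM CVR_GE (%BOLD/mmHg).
#' @param se_mean,se_sd population mean/SD of true GM CVR_SE (%BOLD/mmHg).
#' @param petco2_rest,petco2_rest_sd resting end-tidal CO2, mmHg.
#' @param petco2_modulation programmed end-tidal rise per breath-hold, mmHg
#'   (see above); per-subject values vary with `petco2_modulation_sd`.
#' @param petco2_modulation_sd between-subject SD of the programmed rise.
#' @param capno_noise_sd measurement noise on the raw CO2 trace, mmHg.
#' @param sampling_line_delay gas transit delay of the capnograph, seconds.
#' @param decay_tau exponential recovery time constant of the post-BH
#'   end-tidal excess, seconds.
#' @param perfusion_fraction baseline (control - tag)/control of the ASL
#'   series.
#' @param s0 baseline scanner signal.
#' @param noise_sd_asl,noise_sd_ge,noise_sd_se additive white noise SD per
#'   frame (scanner units).
#' @param drift_amplitude SD of the order-2 Legendre drift coefficients, as
#'   a fraction of S0.
#' @param asl_bold_mode fractional BOLD-like common mode on the ASL readout
#'   per unit fractional CBF change.
#' @param bold_contamination perfusion contamination amplitude on the BOLD
#'   series, as a fraction of `perfusion_fraction`.
#' @param macro_frac_ge,macro_frac_se macrovascular share of the GE / SE
#'   BOLD coupling (SE close to zero: the refocusing pulse suppresses static
#'   macrovascular dephasing).
#' @param load_asl_ge,load_venous_ge factor loadings of the GE population
#'   draw on the shared vascular factor and on the GE-specific venous
#'   factor; `load_asl_se` likewise for SE.
#' @param load_asl_se SE loading on the shared vascular factor.
#' @param venous_contamination SD of the per-subject, per-ROI multiplicative
#'   perturbation of the GE macrovascular coupling (spatially concentrated
#'   in high venous-density ROIs).
#' @param pattern_sd SD of the shared spatial CVR pattern (%CBF/mmHg).
#' @param voxel_sd SD of the subject-specific spatial variation.
#' @param lag_values,lag_probs support and probabilities of the true voxel
#'   lag (seconds, on the lag search grid).
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(asl_mean = 5.3, asl_sd = 1.8,
                          ge_mean = 0.18, ge_sd = 0.05,
                          se_mean = 0.09, se_sd = 0.03,
                          petco2_rest = 35.0, petco2_rest_sd = 1.4,
                          petco2_modulation = 8.4,
                          petco2_modulation_sd = 2.6,
                          capno_noise_sd = 0.3,
                          sampling_line_delay = 4,
                          decay_tau = 15,
                          perfusion_fraction = 0.01,
                          s0 = 1000,
                          noise_sd_asl = 4.7, noise_sd_ge = 11.7,
                          noise_sd_se = 11.7,
                          drift_amplitude = 0.005,
                          asl_bold_mode = 0.008,
                          bold_contamination = 0.2,
                          macro_frac_ge = 0.5, macro_frac_se = 0.05,
                          load_asl_ge = 0.55, load_venous_ge = 0.6,
                          load_asl_se = 0.7,
                          venous_contamination = 0.4,
                          pattern_sd = 1.0, voxel_sd = 0.8,
                          lag_values = c(-5, 0, 5),
                          lag_probs = c(0.1, 0.6, 0.3)) {
  out <- as.list(environment())
  if (abs(sum(out$lag_probs) - 1) > 1e-9)
    stop("lag_probs must sum to 1", call. = FALSE)
  if (out$load_asl_ge^2 + out$load_venous_ge^2 > 1)
    stop("GE factor loadings imply negative idiosyncratic variance",
         call. = FALSE)
  structure(out, class = "cohort_params")
}

#' Voxel grid, gray-matter mask and ROI parcellation of the simulator
#'
#' Desk-scale spatial layout: a 12 x 12 x 8 voxel grid whose interior
#' 10 x 10 x 6 block is gray matter, parcellated into 48 bilateral-style
#' ROIs of 12-13 voxels each.
#'
#' @param dims grid dimensions (default c(12, 12, 8)).
#' @param n_rois number of ROIs (default 48).
#' @return list with `dims`, `gm_mask` (3D logical), `roi_labels` (3D
#'   integer, 0 outside GM).
#' @export
synthetic_geometry <- function(dims = c(12, 12, 8), n_rois = 48) {
  gm <- array(FALSE, dims)
  gm[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)] <- TRUE
  gm_idx <- which(gm)
  sizes <- rep(length(gm_idx) %/% n_rois, n_rois)
  extra <- length(gm_idx) %% n_rois
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- array(0L, dims)
  labels[gm_idx] <- rep(seq_len(n_rois), times = sizes)
  list(dims = dims, gm_mask = gm, roi_labels = labels)
}

#' Synthetic per-ROI macrovascular venous-density table
#'
#' A deterministic stand-in for an atlas-derived per-ROI venous-density
#' table (the real values come from susceptibility-weighted imaging
#' atlases). Densities are lognormal draws under a fixed internal seed, in
#' arbitrary units; the same table ships as
#' `inst/extdata/venous_density_synthetic.tsv`.
#'
#' @param n_rois number of ROIs (default 48).
#' @return data.frame with `roi_id`, `name`, `venous_density`.
#' @export
synthetic_venous_density <- function(n_rois = 48) {
  dens <- with_seed(48123, round(exp(stats::rnorm(n_rois, 0, 0.5)), 3))
  data.frame(roi_id = seq_len(n_rois),
             name = sprintf("ROI_%02d", seq_len(n_rois)),
             venous_density = dens)
}

#' True end-tidal CO2 envelope of the breath-hold protocol
#'
#' Closed-form programmed envelope: resting PetCO2 during baseline; during
#' each breath-hold a linear rise from the last pre-BH expiratory value to
#' `rest + modulation` at the first post-BH expiratory peak (the subject
#' fully breathes out at the end of the hold, carrying the accumulated CO2);
#' during recovery an exponential decay back toward rest with time constant
#' `decay_tau`.
#'
#' @param protocol a [protocol_spec()].
#' @param rest resting PetCO2, mmHg.
#' @param modulation end-tidal rise per breath-hold, mmHg.
#' @param decay_tau recovery time constant, seconds (default 15).
#' @return a vectorized function of time (seconds) returning mmHg.
#' @export
petco2_envelope <- function(protocol, rest, modulation, decay_tau = 15) {
  bp <- 60 / protocol$breathing_rate
  tpk <- 0.35 * bp                      # expiratory peak offset within a breath
  cyc <- protocol$bh_duration + protocol$recovery_duration
  k <- seq_len(protocol$n_cycles)
  bh_start <- protocol$baseline_duration + (k - 1) * cyc
  ramp_start <- bh_start - bp + tpk     # last scheduled pre-BH peak
  peak_t <- bh_start + protocol$bh_duration + tpk  # first post-BH peak
  v_start <- rest + c(0, modulation *
                        exp(-(ramp_start[-1] - peak_t[-length(peak_t)]) /
                              decay_tau))
  force(rest); force(modulation); force(decay_tau)
  function(t) {
    i <- findInterval(t, ramp_start)
    out <- rep(rest, length(t))
    on <- i >= 1
    ii <- pmin(i[on], length(ramp_start))
    tt <- t[on]
    ramping <- tt <= peak_t[ii]
    frac <- (tt - ramp_start[ii]) / (peak_t[ii] - ramp_start[ii])
    out[on] <- ifelse(ramping,
                      v_start[ii] + (rest + modulation - v_start[ii]) * frac,
                      rest + modulation * exp(-(tt - peak_t[ii]) / decay_tau))
    out
  }
}

breath_starts <- function(protocol, total_duration) {
  bp <- 60 / protocol$breathing_rate
  cyc <- protocol$bh_duration + protocol$recovery_duration
  starts <- seq(0, protocol$baseline_duration - bp, by = bp)
  for (k in seq_len(protocol$n_cycles)) {
    rec0 <- protocol$baseline_duration + (k - 1) * cyc + protocol$bh_duration
    starts <- c(starts, seq(rec0, rec0 + protocol$recovery_duration - bp,
                            by = bp))
  }
  tail0 <- protocol$baseline_duration + protocol$n_cycles * cyc
  if (total_duration - bp > tail0)
    starts <- c(starts, seq(tail0, total_duration - bp, by = bp))
  starts
}

#' Generate a raw breath-hold capnography trace
#'
#' Breathing-shaped expired-CO2 waveform: each breath rises to an
#' expiratory peak sampling the programmed end-tidal envelope and falls to
#' ~0 mmHg on inspiration; during breath-holds the trace stays near zero (no
#' expiration); the first expiration after each hold carries the elevated
#' end-tidal value. Additive Gaussian measurement noise and an optional
#' sampling-line delay are applied.
#'
#' @param protocol a [protocol_spec()].
#' @param rest resting PetCO2, mmHg (default 35).
#' @param modulation end-tidal rise per BH, mmHg (default 8.4).
#' @param noise_sd measurement noise SD, mmHg (default 0.3).
#' @param delay sampling-line delay, seconds (default 0); stored as the
#'   trace's `acquisition_delay`.
#' @param decay_tau recovery time constant, seconds.
#' @param seed RNG seed (default NULL).
#' @return a [raw_capno()] covering the scan plus margin; attribute
#'   `envelope` holds the programmed end-tidal envelope function and
#'   `n_breaths` the number of generated expirations.
#' @export
gen_capnography <- function(protocol = protocol_spec(), rest = 35,
                            modulation = 8.4, noise_sd = 0.3, delay = 0,
                            decay_tau = 15, seed = NULL) {
  dt <- 1 / protocol$capno_sampling_rate
  bp <- 60 / protocol$breathing_rate
  dur <- protocol$scan_duration + delay + 2 * bp
  tt <- seq(0, dur, by = dt)
  env <- petco2_envelope(protocol, rest, modulation, decay_tau)
  starts <- breath_starts(protocol, dur)
  tpk <- 0.35 * bp
  clean <- numeric(length(tt))
  for (s in starts) {
    idx <- which(tt >= s & tt < s + 0.7 * bp)
    clean[idx] <- env(s + tpk) * sin(pi * (tt[idx] - s) / (0.7 * bp))^2
  }
  if (delay > 0)
    clean <- stats::approx(tt + delay, clean, xout = tt, rule = 2)$y
  vals <- with_seed(seed,
                    clean + if (noise_sd > 0)
                      stats::rnorm(length(tt), 0, noise_sd) else 0)
  out <- raw_capno(vals, dt, acquisition_delay = delay)
  attr(out, "envelope") <- env
  attr(out, "n_breaths") <- length(starts)
  out
}

#' Fractional CBF response to the PetCO2 stimulus
#'
#' Linear vasodilatory response: `f(t) = 1 + cvr/100 * dPetCO2(t - lag)`,
#' optionally smoothed with a first-order exponential kernel. `f = 1` at
#' baseline.
#'
#' @param dpet function of time returning the end-tidal CO2 excess over
#'   rest, mmHg (e.g. the envelope minus rest), or a numeric vector already
#'   on the frame grid (then `lag` must be 0).
#' @param cvr_true true CVR, %CBF/mmHg (scalar or per-voxel vector).
#' @param lag_true hemodynamic lag, seconds (scalar or per-voxel).
#' @param times frame times, seconds.
#' @param smoothing_tau exponential smoothing constant, seconds (default 0:
#'   none, keeping parameter recovery exact).
#' @return matrix (voxels x frames) of fractional CBF, or a vector when
#'   `cvr_true` is scalar.
#' @export
gen_cbf_response <- function(dpet, cvr_true, lag_true = 0, times,
                             smoothing_tau = 0) {
  if (!is.function(dpet)) {
    v <- dpet
    if (any(lag_true != 0)) stop("vector dpet supports lag 0 only", call. = FALSE)
    dpet <- function(t) stats::approx(times, v, xout = t, rule = 2)$y
  }
  nv <- length(cvr_true)
  lag_true <- rep_len(lag_true, nv)
  f <- matrix(1, nv, length(times))
  for (l in unique(lag_true)) {
    d <- dpet(times - l)
    if (smoothing_tau > 0) {
      a <- exp(-diff(times[1:2]) / smoothing_tau)
      d <- as.numeric(stats::filter(d * (1 - a), a, method = "recursive"))
    }
    rows <- which(lag_true == l)
    f[rows, ] <- 1 + outer(cvr_true[rows] / 100, d)
  }
  if (nv == 1L) drop(f) else f
}

series_noise <- function(nv, nt, sd) {
  if (sd > 0) matrix(stats::rnorm(nv * nt, 0, sd), nv, nt) else matrix(0, nv, nt)
}

series_drift <- function(nv, nt, amplitude, s0) {
  if (amplitude <= 0) return(matrix(0, nv, nt))
  L <- legendre_basis(nt)
  coef <- matrix(stats::rnorm(nv * 2, 0, amplitude * s0), nv, 2)
  coef %*% t(L)
}

#' Generate an interleaved ASL series from a fractional CBF time course
#'
#' Forward model of the tag/control perfusion contrast: control frames carry
#' the baseline signal plus a small BOLD-like common mode; tag frames are
#' reduced by `S0 * perfusion_fraction * f(t)`. Slow polynomial drift
#' (shared by tag and control, cancelled by surround subtraction) and white
#' noise are added.
#'
#' @param f fractional CBF matrix (voxels x frames) from
#'   [gen_cbf_response()].
#' @param params a [cohort_params()].
#' @param dims3 spatial grid dimensions; `f` must have `prod(dims3)` rows.
#' @param tr repetition time, seconds.
#' @param seed RNG seed (default NULL).
#' @return an [interleaved_series()] with weighting "asl", tag-first.
#' @export
gen_interleaved_asl <- function(f, params = cohort_params(), dims3, tr = 5,
                                seed = NULL) {
  if (is.null(dim(f))) f <- matrix(f, 1)
  nv <- nrow(f); nt <- ncol(f)
  stopifnot(nv == prod(dims3))
  with_seed(seed, {
    base <- params$s0 * (1 + params$asl_bold_mode * (f - 1)) +
      series_drift(nv, nt, params$drift_amplitude, params$s0)
    tag_mask <- rep_len(c(TRUE, FALSE), nt)   # tag-first
    s <- base
    s[, tag_mask] <- s[, tag_mask] -
      params$s0 * params$perfusion_fraction * f[, tag_mask, drop = FALSE]
    s <- s + series_noise(nv, nt, params$noise_sd_asl)
    interleaved_series(as_volume4d(s, dims3), tr, "asl", "tag_first")
  })
}

#' Generate an interleaved BOLD series (GE or SE weighting)
#'
#' Linearized isometabolic BOLD coupling: the fractional BOLD response is
#' `K(v) * (f(t) - 1)` where `K(v) = c_micro * v_micro(v) + c_macro *
#' v_macro(v)` sums micro- and macrovascular contributions (percent BOLD per
#' percent CBF, as a fraction). A parity-alternating perfusion contamination
#' (removed by surround averaging), drift and noise are added.
#'
#' @param f fractional CBF matrix (voxels x frames).
#' @param coupling per-voxel vector `K(v)` (fractional BOLD per fractional
#'   CBF change).
#' @param weighting "ge" or "se".
#' @param params a [cohort_params()].
#' @param dims3 spatial grid dimensions.
#' @param tr repetition time, seconds.
#' @param seed RNG seed.
#' @return an [interleaved_series()] of the requested weighting, tag-first.
#' @export
gen_bold <- function(f, coupling, weighting = c("ge", "se"),
                     params = cohort_params(), dims3, tr = 5, seed = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(dim(f))) f <- matrix(f, 1)
  nv <- nrow(f); nt <- ncol(f)
  stopifnot(nv == prod(dims3), length(coupling) == nv)
  noise_sd <- if (weighting == "ge") params$noise_sd_ge else params$noise_sd_se
  with_seed(seed, {
    b <- coupling * (f - 1)
    s <- params$s0 * (1 + b) +
      series_drift(nv, nt, params$drift_amplitude, params$s0)
    eps <- params$bold_contamination * params$perfusion_fraction * params$s0
    parity <- rep_len(c(-0.5, 0.5), nt)  # tag-first: tag lower, control higher
    s <- s + sweep(f * eps, 2L, parity, `*`)
    s <- s + series_noise(nv, nt, noise_sd)
    interleaved_series(as_volume4d(s, dims3), tr, weighting, "tag_first")
  })
}

# Smooth zero-mean spatial pattern shared by all subjects of a cohort:
# three random low-frequency cosine modes over the grid coordinates.
shared_pattern <- function(geom, sd_target) {
  dims <- geom$dims
  co <- which(array(TRUE, dims), arr.ind = TRUE)
  p <- numeric(nrow(co))
  for (m in 1:3) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    freq <- stats::runif(1, 0.5, 1.5) * pi / max(dims)
    phase <- stats::runif(1, 0, 2 * pi)
    p <- p + cos(freq * (co %*% dir) * 2 + phase)
  }
  gmv <- geom$gm_mask
  p <- p - mean(p[gmv])
  p * sd_target / stats::sd(p[gmv])
}

# Fixed focal vein anatomy: per-voxel macrovascular volume weights whose
# within-ROI distribution is spiky (a few vein-containing voxels carry most
# of the macrovascular volume) while the ROI mean equals the scaled atlas
# density. Deterministic: the vein map is anatomy shared by all subjects.
vein_map <- function(geom, v_macro_roi, cap = 0.85) {
  gm_idx <- which(geom$gm_mask)
  roi_of <- geom$roi_labels[gm_idx]
  with_seed(771203, {
    mult <- stats::rexp(length(gm_idx))^2
    v <- numeric(prod(geom$dims))
    for (id in seq_along(v_macro_roi)) {
      sel <- roi_of == id
      m <- mult[sel] / mean(mult[sel])
      v[gm_idx[sel]] <- pmin(v_macro_roi[id] * m, cap)
      # renormalize after capping so the ROI mean is preserved
      sc <- v_macro_roi[id] / mean(v[gm_idx[sel]])
      v[gm_idx[sel]] <- pmin(v[gm_idx[sel]] * sc, cap)
    }
    v
  })
}

draw_subject_truth <- function(params, geom, v_macro_roi) {
  gm_idx <- which(geom$gm_mask)
  nv <- prod(geom$dims)
  # subject-level GM means with a shared vascular factor plus a GE-specific
  # venous factor (ASL-independent between-subject variance)
  u <- stats::rnorm(1)
  venous <- stats::rnorm(1)
  mu_asl <- max(params$asl_mean + params$asl_sd * u, 0.5)
  lg <- params$load_asl_ge; lv <- params$load_venous_ge
  mu_ge <- params$ge_mean + params$ge_sd *
    (lg * u + lv * venous + sqrt(max(1 - lg^2 - lv^2, 0)) * stats::rnorm(1))
  ls <- params$load_asl_se
  mu_se <- params$se_mean + params$se_sd *
    (ls * u + sqrt(1 - ls^2) * stats::rnorm(1))
  mu_ge <- max(mu_ge, 0.02)
  mu_se <- max(mu_se, 0.01)
  # spatial CVR_ASL field: shared pattern + subject noise, recentred so the
  # GM mean equals the subject draw exactly
  field <- numeric(nv)
  field[gm_idx] <- mu_asl + geom$pattern[gm_idx] +
    stats::rnorm(length(gm_idx), 0, params$voxel_sd)
  for (it in 1:5) {
    field[gm_idx] <- pmax(field[gm_idx], 0.2)
    field[gm_idx] <- field[gm_idx] + (mu_asl - mean(field[gm_idx]))
  }
  field[gm_idx] <- pmax(field[gm_idx], 0.1)
  lag <- numeric(nv)
  lag[gm_idx] <- sample(params$lag_values, length(gm_idx), replace = TRUE,
                        prob = params$lag_probs)
  # vascular volume weights per voxel: focal vein anatomy with ROI means
  # given by the scaled venous-density table
  roi_of <- geom$roi_labels
  v_macro <- if (!is.null(geom$vein_map)) geom$vein_map
             else vein_map(geom, v_macro_roi)
  # capillary density is nearly uniform across GM; macrovascular volume adds
  # on top of it (sum bounded by the voxel volume)
  v_micro <- ifelse(as.logical(geom$gm_mask), pmin(0.06, 1 - v_macro), 0)
  # per-subject, per-ROI multiplicative venous perturbation on the GE
  # macrovascular coupling
  gamma_roi <- stats::rnorm(length(v_macro_roi), 0, params$venous_contamination)
  macro_pert <- numeric(nv)
  macro_pert[gm_idx] <- pmax(1 + gamma_roi[roi_of[gm_idx]], 0)
  # couplings calibrated so the realized GM-mean BOLD CVRs equal the draws
  a_micro <- mean(v_micro[gm_idx] * field[gm_idx])
  a_macro_ge <- mean(v_macro[gm_idx] * macro_pert[gm_idx] * field[gm_idx])
  a_macro_se <- mean(v_macro[gm_idx] * field[gm_idx])
  c_micro_ge <- (1 - params$macro_frac_ge) * mu_ge / a_micro
  c_macro_ge <- params$macro_frac_ge * mu_ge / a_macro_ge
  c_micro_se <- (1 - params$macro_frac_se) * mu_se / a_micro
  c_macro_se <- params$macro_frac_se * mu_se / a_macro_se
  # K(v) = CVR_bold(v) / CVR_asl(v): fractional BOLD per fractional CBF change
  k_ge <- c_micro_ge * v_micro + c_macro_ge * v_macro * macro_pert
  k_se <- c_micro_se * v_micro + c_macro_se * v_macro
  rest <- params$petco2_rest + params$petco2_rest_sd * stats::rnorm(1)
  modulation <- max(params$petco2_modulation +
                      params$petco2_modulation_sd * stats::rnorm(1), 2)
  list(gm_mean_asl = mu_asl, gm_mean_ge = mu_ge, gm_mean_se = mu_se,
       cvr_asl = field, lag = lag,
       v_micro = v_micro, v_macro = v_macro,
       coupling_ge = k_ge, coupling_se = k_se,
       c_micro_ge = c_micro_ge, c_macro_ge = c_macro_ge,
       c_micro_se = c_micro_se, c_macro_se = c_macro_se,
       rest = rest, modulation = modulation)
}

#' Generate one synthetic breath-hold subject
#'
#' Raw capnography plus the three interleaved series (ASL, GE, SE) for one
#' subject whose ground truth is given (or drawn by [gen_cohort()]).
#'
#' @param protocol a [protocol_spec()].
#' @param params a [cohort_params()].
#' @param truth a subject truth list as produced internally by
#'   [gen_cohort()]; when NULL a single subject is drawn at the population
#'   means.
#' @param geom a [synthetic_geometry()].
#' @param seed RNG seed.
#' @return object of class `synthetic_subject`: `raw_capno`, `series`
#'   (named list of [interleaved_series()]), `truth`.
#' @export
gen_subject <- function(protocol = protocol_spec(), params = cohort_params(),
                        truth = NULL, geom = synthetic_geometry(),
                        seed = NULL) {
  with_seed(seed, {
    if (is.null(truth)) {
      if (is.null(geom$pattern)) geom$pattern <- shared_pattern(geom, params$pattern_sd)
      vd <- synthetic_venous_density(max(geom$roi_labels))
      v_macro_roi <- scale_to_vmacro(vd$venous_density)
      truth <- draw_subject_truth(params, geom, v_macro_roi)
    }
    ft <- frame_times(protocol$n_frames, protocol$tr)
    raw <- gen_capnography(protocol, rest = truth$rest,
                           modulation = truth$modulation,
                           noise_sd = params$capno_noise_sd,
                           delay = params$sampling_line_delay,
                           decay_tau = params$decay_tau)
    env <- attr(raw, "envelope")
    dpet <- function(t) env(t) - truth$rest
    f <- gen_cbf_response(dpet, truth$cvr_asl, truth$lag, ft)
    series <- list(
      asl = gen_interleaved_asl(f, params, geom$dims, protocol$tr),
      ge = gen_bold(f, truth$coupling_ge, "ge", params, geom$dims, protocol$tr),
      se = gen_bold(f, truth$coupling_se, "se", params, geom$dims, protocol$tr))
    structure(list(raw_capno = raw, series = series, truth = truth),
              class = "synthetic_subject")
  })
}

scale_to_vmacro <- function(density, lo = 0.02, hi = 0.5) {
  r <- range(density)
  if (diff(r) == 0) return(rep((lo + hi) / 2, length(density)))
  lo + (density - r[1]) / diff(r) * (hi - lo)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n_subjects` subjects whose true GM-mean CVRs come from the
#' population distributions of [cohort_params()]: subject-level ASL, GE and
#' SE means follow a shared-vascular-factor structure (plus a GE-specific
#' venous factor), spatial CVR fields share a smooth cohort pattern plus
#' subject noise, per-ROI macrovascular volume comes from the venous-density
#' table, and each subject gets a full raw capnography trace and three
#' interleaved series. Everything is reproducible from `seed` and the truth
#' is stored losslessly alongside the data.
#'
#' @param n_subjects number of subjects (default 20).
#' @param protocol a [protocol_spec()].
#' @param params a [cohort_params()].
#' @param venous_density per-ROI density table (default
#'   [synthetic_venous_density()]).
#' @param seed RNG seed (default 1).
#' @return object of class `synthetic_cohort`: `subjects` (list of
#'   [gen_subject()] outputs), `gm_mask`, `roi_labels`, `venous_density`,
#'   `truth` (data.frame of per-subject true GM means), `protocol`,
#'   `params`, `seed`.
#' @export
gen_cohort <- function(n_subjects = 20, protocol = protocol_spec(),
                       params = cohort_params(),
                       venous_density = synthetic_venous_density(),
                       seed = 1) {
  geom <- synthetic_geometry()
  check_roi_table(geom$roi_labels, venous_density)
  v_macro_roi <- scale_to_vmacro(venous_density$venous_density)
  geom$vein_map <- vein_map(geom, v_macro_roi)
  with_seed(seed, {
    geom$pattern <- shared_pattern(geom, params$pattern_sd)
    subjects <- lapply(seq_len(n_subjects), function(i) {
      truth <- draw_subject_truth(params, geom, v_macro_roi)
      gen_subject(protocol, params, truth, geom)
    })
    truth_tab <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      tr <- subjects[[i]]$truth
      data.frame(subject = i, gm_mean_asl = tr$gm_mean_asl,
                 gm_mean_ge = tr$gm_mean_ge, gm_mean_se = tr$gm_mean_se,
                 petco2_rest = tr$rest, petco2_modulation = tr$modulation)
    }))
    structure(list(subjects = subjects, gm_mask = geom$gm_mask,
                   roi_labels = geom$roi_labels,
                   venous_density = venous_density,
                   truth = truth_tab, protocol = protocol, params = params,
                   seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic breath-hold cohort: %d subjects, %s grid, %d GM voxels, seed %s\n",
              length(x$subjects), paste(dim(x$gm_mask), collapse = "x"),
              sum(x$gm_mask), x$seed))
  invisible(x)
}

#' Run the full single-subject pipeline
#'
#' Capnography extraction (peaks, interpolation, resampling with the known
#' sampling-line shift, filtering), surround subtraction/averaging, percent
#' change from baseline, voxelwise filtering and lagged GLM mapping for all
#' three weightings.
#'
#' @param subject a `synthetic_subject` (or any list with `raw_capno` and
#'   `series`).
#' @param protocol a [protocol_spec()].
#' @param fspec a [filter_spec()].
#' @param lspec a [lag_search_spec()].
#' @param mask 3D mask of voxels to map (typically the GM mask).
#' @param baseline_window baseline seconds for percent change (default 50).
#' @return list of [map_cvr()] outputs named `asl`, `ge`, `se`; attribute
#'   `petco2` holds the extracted regressor.
#' @export
run_subject_pipeline <- function(subject, protocol = protocol_spec(),
                                 fspec = filter_spec(),
                                 lspec = lag_search_spec(), mask,
                                 baseline_window = 50) {
  pet <- extract_petco2(subject$raw_capno, tr = protocol$tr,
                        n_frames = protocol$n_frames, fspec = fspec,
                        baseline_duration = protocol$baseline_duration)
  prep <- function(series) {
    vs <- if (series$weighting == "asl") surround_subtract(series)
          else surround_average(series)
    fc <- to_fractional_change(vs, baseline_window)
    filter_series(fc, fspec)
  }
  maps <- lapply(subject$series, function(s)
    map_cvr(prep(s), pet, lspec, mask))
  attr(maps, "petco2") <- pet
  maps
}

#' Run the pipeline over a synthetic cohort
#'
#' @param cohort a [gen_cohort()] output.
#' @param fspec,lspec filter and lag-search specifications.
#' @return a [subject_cvr_set()] with the cohort's GM mask, ROI labels and
#'   venous-density table.
#' @export
run_cohort_pipeline <- function(cohort, fspec = filter_spec(),
                                lspec = lag_search_spec()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  maps <- lapply(cohort$subjects, run_subject_pipeline,
                 protocol = cohort$protocol, fspec = fspec, lspec = lspec,
                 mask = cohort$gm_mask)
  subject_cvr_set(maps, cohort$gm_mask, cohort$roi_labels,
                  cohort$venous_density)
}
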