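test_that("capnography generator respects the protocol and its ground truth", {
  pr <- protocol_spec()
  raw <- gen_capnography(pr, rest = 35, modulation = 0, noise_sd = 0, delay = 0)
  pk <- detect_expiratory_peaks(raw)
  expect_true(all(abs(pk$value - 35) < 1e-9)) # zero modulation: flat peaks
  raw2 <- gen_capnography(pr, rest = 35, modulation = 8.4, noise_sd = 0,
                          delay = 0)
  pk2 <- detect_expiratory_peaks(raw2)
  # exactly 10 elevated post-BH peaks, one per cycle
  elevated <- pk2$value > 35 + 8.4 * 0.9
  expect_equal(sum(elevated), 10)
  # the envelope attribute evaluates to rest before the task starts
  env <- attr(raw2, "envelope")
  expect_true(all(env(c(0, 20, 50)) == 35))
  expect_equal(env(60 + 20 + 0.35 * 5), 43.4)
})

test_that("cbf response is the linearized vasodilatory model", {
  times <- (0:40) * 5
  step <- function(t) ifelse(t >= 50, 6.7, 0)
  expect_true(all(gen_cbf_response(step, 0, 0, times) == 1))
  f <- gen_cbf_response(step, 5.3, 0, times)
  expect_equal(max(f), 1 + 5.3 / 100 * 6.7) # plateau 1.355
  # a lag moves the response peak alignment
  f10 <- gen_cbf_response(step, 5.3, 10, times)
  expect_equal(f10[times >= 60], f[times >= 60 - 10][1:sum(times >= 60)])
})

test_that("interleaved ASL series inverts to the programmed perfusion", {
  pa <- cohort_params(noise_sd_asl = 0, drift_amplitude = 0, asl_bold_mode = 0)
  f <- matrix(1, 1, 20)
  ser <- gen_interleaved_asl(f, pa, c(1, 1, 1), tr = 5)
  d <- surround_subtract(ser)
  expect_equal(as.numeric(d$volumes), rep(pa$s0 * pa$perfusion_fraction, 20),
               tolerance = 1e-12)
  expect_equal(ser$frame_labels[1:2], c("tag", "control"))
})

test_that("bold generator exposes the micro/macro coupling arithmetic", {
  pa <- cohort_params(noise_sd_ge = 0, noise_sd_se = 0, drift_amplitude = 0,
                      bold_contamination = 0)
  times <- (0:29) * 5
  step <- function(t) ifelse(t >= 50, 5, 0)
  f <- gen_cbf_response(step, rep(6, 2), 0, times)
  # two voxels identical except the coupling (e.g. v_macro 0 vs 0.5)
  k_ge <- c(0.03, 0.03 + 0.5 * 0.04)
  k_se <- c(0.017, 0.017 + 0.5 * 0.001)
  ge <- gen_bold(f, k_ge, "ge", pa, c(2, 1, 1), tr = 5)
  se <- gen_bold(f, k_se, "se", pa, c(2, 1, 1), tr = 5)
  plateau <- function(ser, v) (ser$volumes[v, 1, 1, 30] - pa$s0) / pa$s0
  expect_equal(plateau(ge, 1), 0.03 * 0.30, tolerance = 1e-12)
  expect_equal(plateau(ge, 2) - plateau(ge, 1), 0.02 * 0.30, tolerance = 1e-12)
  expect_lt(abs(plateau(se, 2) - plateau(se, 1)), 0.001 * 0.31)
  # zero couplings: flat series
  flat <- gen_bold(f, c(0, 0), "ge", pa, c(2, 1, 1), tr = 5)
  expect_true(all(flat$volumes == pa$s0))
})

test_that("noiseless single-voxel pipeline recovers beta and lag to the stencil tolerance", {
  pr <- protocol_spec()
  pa <- cohort_params(noise_sd_asl = 0, noise_sd_ge = 0, noise_sd_se = 0,
                      capno_noise_sd = 0, drift_amplitude = 0,
                      asl_bold_mode = 0, bold_contamination = 0)
  raw <- gen_capnography(pr, rest = 35, modulation = 8.4, noise_sd = 0,
                         delay = 0)
  env <- attr(raw, "envelope")
  ft <- (0:137) * 5
  pet <- extract_petco2(raw, 5, 138)
  for (lag in c(0, 5)) {
    f <- gen_cbf_response(function(t) env(t) - 35, 5.3, lag, ft)
    ser <- gen_interleaved_asl(matrix(f, 1), pa, c(1, 1, 1), tr = 5)
    fc <- filter_series(to_fractional_change(surround_subtract(ser)))
    fit <- fit_lagged_glm(fc$volumes[1, 1, 1, ], pet)
    expect_equal(fit$lag, lag)
    # surround interpolation low-passes the modulated perfusion component:
    # recovery is exact only up to the stencil's smoothing (here ~9%)
    expect_equal(fit$beta, 5.3, tolerance = 0.12)
    expect_gt(fit$beta, 5.3 * 0.85)
    ge <- gen_bold(matrix(f, 1), 0.18 / 5.3, "ge", pa, c(1, 1, 1), tr = 5)
    fcg <- filter_series(to_fractional_change(surround_average(ge)))
    fitg <- fit_lagged_glm(fcg$volumes[1, 1, 1, ], pet)
    expect_equal(fitg$lag, lag)
    expect_equal(fitg$beta, 0.18, tolerance = 0.12)
  }
})

test_that("cohorts are deterministic under a seed and carry lossless truth", {
  pr <- short_protocol()
  co1 <- gen_cohort(2, protocol = pr, seed = 9)
  co2 <- gen_cohort(2, protocol = pr, seed = 9)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$subjects[[2]]$raw_capno$values,
                   co2$subjects[[2]]$raw_capno$values)
  expect_identical(co1$subjects[[1]]$series$ge$volumes,
                   co2$subjects[[1]]$series$ge$volumes)
  co3 <- gen_cohort(2, protocol = pr, seed = 10)
  expect_false(identical(co1$subjects[[1]]$series$ge$volumes,
                         co3$subjects[[1]]$series$ge$volumes))
  # truth is self-consistent: stored GM means equal the field means
  gm <- which(co1$gm_mask)
  tr1 <- co1$subjects[[1]]$truth
  expect_equal(mean(tr1$cvr_asl[gm]), tr1$gm_mean_asl, tolerance = 1e-9)
  expect_equal(mean(tr1$coupling_ge[gm] * tr1$cvr_asl[gm]), tr1$gm_mean_ge,
               tolerance = 1e-9)
  expect_equal(mean(tr1$coupling_se[gm] * tr1$cvr_asl[gm]), tr1$gm_mean_se,
               tolerance = 1e-9)
  expect_true(all(tr1$lag[gm] %in% c(-5, 0, 5)))
  vm <- tr1$v_macro[gm] + tr1$v_micro[gm]
  expect_true(all(vm > 0 & vm <= 1))
})

test_that("deterministic single subject at population means when SDs vanish", {
  pr <- short_protocol()
  pa <- cohort_params(asl_sd = 0, ge_sd = 0, se_sd = 0, petco2_rest_sd = 0,
                      petco2_modulation_sd = 0, voxel_sd = 0, pattern_sd = 0,
                      venous_contamination = 0)
  co <- gen_cohort(1, protocol = pr, params = pa, seed = 3)
  expect_equal(co$truth$gm_mean_asl, 5.3)
  expect_equal(co$truth$gm_mean_ge, 0.18)
  expect_equal(co$truth$gm_mean_se, 0.09)
  expect_equal(co$truth$petco2_rest, 35)
})

test_that("doubling the noise doubles the residual SD of the GLM fit", {
  pr <- protocol_spec()
  pet <- default_petco2()
  resid_sd <- function(nsd, seed) {
    pa <- cohort_params(noise_sd_asl = nsd, drift_amplitude = 0,
                        asl_bold_mode = 0)
    env <- attr(gen_capnography(pr, noise_sd = 0, delay = 0), "envelope")
    f <- gen_cbf_response(function(t) env(t) - 35, 5.3, 0, (0:137) * 5)
    mean(replicate(25, {
      ser <- gen_interleaved_asl(matrix(f, 1), pa, c(1, 1, 1), tr = 5,
                                 seed = NULL)
      fc <- filter_series(to_fractional_change(surround_subtract(ser)))
      y <- fc$volumes[1, 1, 1, ]
      fit <- fit_lagged_glm(y, pet, lag_search_spec(0, 0))
      sd(y - fit$beta * pet$values)
    }))
  }
  set.seed(64)
  r1 <- resid_sd(2, 1)
  r2 <- resid_sd(4, 2)
  expect_equal(r2 / r1, 2, tolerance = 0.25)
})

test_that("default cohort reproduces the confidence ordering of the weightings", {
  co <- gen_cohort(4, seed = 31)
  set <- suppressMessages(run_cohort_pipeline(co))
  gm <- co$gm_mask
  zm <- sapply(c("asl", "ge", "se"), function(w)
    mean(sapply(set$subjects, function(s) mean(s[[w]]$z[gm], na.rm = TRUE))))
  expect_lt(zm["asl"], zm["se"]) # ASL least confident
  expect_lt(zm["se"], zm["ge"])  # GE most confident
})

test_that("venous contamination concentrates the correlation difference in high-density ROIs", {
  # build noise-free maps from the generator truth so the ROI analysis sees
  # exactly the injected GE-specific macrovascular contamination
  truth_set <- function(vc, sd) {
    co <- gen_cohort(20, params = cohort_params(venous_contamination = vc),
                     seed = sd)
    dims <- dim(co$gm_mask)
    subs <- lapply(co$subjects, function(su) {
      mk <- function(beta) structure(list(beta = array(beta, dims),
                                          z = array(10, dims),
                                          lag = array(0, dims), se = NULL,
                                          weighting = "x",
                                          n_lag_boundary = 0L),
                                     class = "cvr_map")
      list(asl = mk(su$truth$cvr_asl),
           ge = mk(su$truth$coupling_ge * su$truth$cvr_asl),
           se = mk(su$truth$coupling_se * su$truth$cvr_asl))
    })
    subject_cvr_set(subs, co$gm_mask, co$roi_labels, co$venous_density)
  }
  contrast <- function(rf)
    mean(rf$dz[rf$high_density], na.rm = TRUE) -
      mean(rf$dz[!rf$high_density], na.rm = TRUE)
  # Fisher-z(SE vs ASL) - Fisher-z(GE vs ASL) concentrates in high-density
  # ROIs when the contamination is on, and shows no such structure when off
  on <- sapply(61:62, function(sd) contrast(roi_fisher_maps(truth_set(1.5, sd))))
  off <- sapply(61:62, function(sd) contrast(roi_fisher_maps(truth_set(0, sd))))
  expect_true(all(on > 0.03))
  expect_gt(mean(on), mean(off) + 0.05)
})

test_that("z-thresholding inflates the recovered mean ASL CVR (selection bias)", {
  curves <- sapply(1:2, function(sd) {
    co <- gen_cohort(20, seed = 50 + sd)
    set <- suppressMessages(run_cohort_pipeline(co))
    threshold_curves(set, z_grid = seq(-2, 4, 1))$mean_asl
  })
  ens <- rowMeans(curves)
  expect_true(all(diff(ens) > -1e-6)) # non-decreasing ensemble average
  expect_gt(ens[length(ens)], ens[1])
})
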