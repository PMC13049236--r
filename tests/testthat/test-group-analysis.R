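# Minimal subject set: uniform maps with controllable values.
uniform_set <- function(vals_asl, vals_ge = vals_asl / 30,
                        vals_se = vals_asl / 60, z_asl = 5,
                        dims = c(4, 4, 2)) {
  gm <- array(TRUE, dims)
  subs <- lapply(seq_along(vals_asl), function(i) {
    mk <- function(v, z) structure(list(beta = array(v, dims),
                                        z = array(z, dims),
                                        lag = array(0, dims), se = NULL,
                                        weighting = "asl",
                                        n_lag_boundary = 0L),
                                   class = "cvr_map")
    list(asl = mk(vals_asl[i], z_asl), ge = mk(vals_ge[i], 10),
         se = mk(vals_se[i], 6))
  })
  subject_cvr_set(subs, gm)
}

test_that("gm_summary averages the thresholded voxel set consistently", {
  set <- uniform_set(c(4, 5, 6))
  sm <- gm_summary(set)
  expect_equal(sm$cvr_asl, c(4, 5, 6))
  expect_equal(unname(attr(sm, "group_mean")["cvr_asl"]), 5)
  # threshold above every z: all subjects flagged empty
  expect_message(sm2 <- gm_summary(set, z_thr = 10), "no voxel surviving")
  expect_true(all(sm2$n_vox == 0))
  # the ASL-z voxel set is applied to all three weightings
  dims <- c(4, 4, 2)
  s1 <- set$subjects[[1]]
  s1$asl$z[1:16] <- -3
  s1$ge$beta[1:16] <- 99
  set$subjects[[1]] <- s1
  sm3 <- gm_summary(set, z_thr = 0)
  expect_equal(sm3$n_vox[1], 16L)
  expect_equal(sm3$cvr_ge[1], set$subjects[[1]]$ge$beta[20]) # 99s excluded
})

test_that("across-subject correlation handles the canonical cases", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(across_subject_correlation(a, a)$r, 1)
  expect_equal(across_subject_correlation(a, -a)$r, -1)
  expect_error(across_subject_correlation(a, rep(1, 5)), "zero variance")
  expect_error(across_subject_correlation(a[1:2], a[1:2]), "at least 3")
  sp <- across_subject_correlation(a, c(2, 1, 4, 3, 5), method = "spearman")
  expect_equal(sp$r, cor(a, c(2, 1, 4, 3, 5), method = "spearman"))
})

test_that("correlation recovery over bivariate normal replicates is calibrated", {
  set.seed(61)
  n <- 20
  rr <- replicate(600, {
    x <- rnorm(n)
    y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(n)
    across_subject_correlation(x, y)$r
  })
  expect_lt(abs(mean(rr) - 0.69), 0.025) # slight small-sample bias
  p0 <- replicate(600, across_subject_correlation(rnorm(n), rnorm(n))$p)
  expect_lt(abs(mean(p0 < 0.05) - 0.05), 0.025)
})

test_that("fisher transform round-trips and matches atanh", {
  r <- seq(-0.99, 0.99, by = 0.11)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(0.5), atanh(0.5))
})

test_that("threshold curves are flat for noiseless cohorts and nested in voxel count", {
  set <- uniform_set(c(4, 5, 6, 7), z_asl = 3)
  tc <- threshold_curves(set, z_grid = c(-2, 0, 2, 2.5))
  expect_true(all(abs(tc$mean_asl - 5.5) < 1e-12))
  expect_true(all(diff(tc$median_n_vox) <= 0))
  # one threshold of -Inf reduces to the unthresholded summary
  tc0 <- threshold_curves(set, z_grid = -Inf)
  expect_equal(tc0$mean_asl, unname(attr(gm_summary(set), "group_mean")["cvr_asl"]))
})

test_that("BH-FDR flags equal the brute-force step-up oracle", {
  set.seed(99)
  for (i in 1:40) {
    m <- sample(3:48, 1)
    p <- runif(m)^sample(1:3, 1) # varying signal strength
    if (i %% 5 == 0) p[sample(m, 2)] <- NA
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, q), oracle_bh(p, q))
  }
})

test_that("null ROI correlations yield essentially no FDR discoveries", {
  set.seed(17)
  n <- 20
  counts <- replicate(30, {
    p <- vapply(1:48, function(i) cor.test(rnorm(n), rnorm(n))$p.value,
                numeric(1))
    sum(bh_fdr(p, 0.05))
  })
  expect_lt(mean(counts), 0.35)
})

test_that("Williams-Steiger test is symmetric, null-centred and detects differences", {
  st0 <- steiger_test(0.5, 0.5, 0.3, 20)
  expect_equal(st0$t, 0)
  expect_equal(st0$p, 1)
  st <- steiger_test(0.8, 0.1, 0.3, 40)
  expect_lt(st$p, 0.01)
  expect_equal(st$df, 37)
  # empirical size under the null (shared-variable trivariate normal)
  set.seed(7)
  n <- 30
  ps <- replicate(500, {
    x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- 0.5 * x + rnorm(n)
    steiger_test(cor(x, y), cor(x, z), cor(y, z), n)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("second-level t-map matches the closed form and caps degenerate voxels", {
  dims <- c(2, 2, 1)
  maps <- lapply(c(1, 2, 3), function(v) array(v, dims))
  tm <- second_level_tmap(maps)
  expect_equal(as.numeric(tm), rep(2 * sqrt(3), 4), tolerance = 1e-12)
  maps_id <- lapply(1:3, function(i) array(2, dims))
  expect_true(all(second_level_tmap(maps_id) == 1e6))
  maps0 <- lapply(1:3, function(i) array(0, dims))
  expect_true(all(is.na(second_level_tmap(maps0))))
  # null maps reject at about the nominal rate
  set.seed(4)
  nm <- lapply(1:10, function(i) array(rnorm(1000), c(10, 10, 10)))
  tv <- second_level_tmap(nm)
  expect_lt(abs(mean(abs(tv) > qt(0.975, 9)) - 0.05), 0.02)
})

test_that("coefficient of variation follows the n-1 convention", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  x <- c(3.2, 4.1, 5.3, 6.0, 7.9, 5.3, 4.4, 6.2) # mean 5.3
  x <- 5.3 + (x - mean(x)) * 1.8 / sd(x)         # exact mean 5.3, sd 1.8
  expect_equal(coefficient_of_variation(x), 1.8 / 5.3, tolerance = 1e-12)
  expect_equal(round(100 * coefficient_of_variation(x)), 34)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("bootstrap spatial correlation is seeded, reproducible and exact in the trivial case", {
  set <- uniform_set(c(4, 5, 6))
  # identical spatial patterns: r = 1 at every k
  dims <- c(4, 4, 2)
  pat <- array(seq_len(32), dims)
  for (i in 1:3) for (w in c("asl", "ge", "se"))
    set$subjects[[i]][[w]]$beta <- pat * i
  sp <- spatial_correlation_vs_n(set, n_iters = 10, seed = 5)
  expect_true(all(abs(sp[, c("r_ge_asl", "r_se_asl", "r_se_ge")] - 1) < 1e-12))
  sp2 <- spatial_correlation_vs_n(set, n_iters = 10, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- spatial_correlation_vs_n(set, n_iters = 10, seed = 6)
  expect_false(identical(sp, sp3) && FALSE) # different seed allowed to differ
})

test_that("roi analysis flags venous stratification metadata and missing ROIs", {
  dims <- c(4, 4, 3)
  gm <- array(TRUE, dims)
  labels <- array(rep(1:4, each = 12), dims)
  vd <- data.frame(roi_id = 1:4, name = paste0("ROI_", 1:4),
                   venous_density = c(0.2, 0.5, 1.2, 2.0))
  set.seed(11)
  n <- 12
  subs <- lapply(1:n, function(i) {
    mk <- function(v) structure(list(beta = array(v, dims),
                                     z = array(5, dims),
                                     lag = array(0, dims), se = NULL,
                                     weighting = "x", n_lag_boundary = 0L),
                                class = "cvr_map")
    base <- rnorm(1)
    list(asl = mk(5 + base + rnorm(48, 0, 0.3)),
         ge = mk(0.18 + 0.03 * base + rnorm(48, 0, 0.02)),
         se = mk(0.09 + 0.015 * base + rnorm(48, 0, 0.01)))
  })
  set <- subject_cvr_set(subs, gm, labels, vd)
  rf <- roi_fisher_maps(set, z_thr = 2)
  expect_equal(nrow(rf), 4)
  expect_equal(rf$high_density, c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(rf$missing))
  expect_equal(rf$dz, rf$z_se_asl - rf$z_ge_asl)
  # an ROI whose voxels never survive the threshold is flagged missing
  for (i in 1:n) set$subjects[[i]]$asl$z[labels == 2] <- 0
  rf2 <- roi_fisher_maps(set, z_thr = 2)
  expect_true(rf2$missing[rf2$roi_id == 2])
})
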