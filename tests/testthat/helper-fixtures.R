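# Shared fixtures and independent brute-force oracles.

# Short breath-hold protocol for fast property tests (3 cycles, 220 s).
short_protocol <- function() {
  protocol_spec(baseline_duration = 30, n_cycles = 3, bh_duration = 20,
                recovery_duration = 40, tr = 5, n_frames = 44)
}

# Cached noiseless default-protocol PetCO2 regressor.
default_petco2 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      raw <- gen_capnography(protocol_spec(), noise_sd = 0, delay = 0)
      cache <<- extract_petco2(raw, tr = 5, n_frames = 138)
    }
    cache
  }
})

# Exhaustive local-maximum oracle for expiratory peak detection: scans every
# sample, computes topographic prominence by walking left/right, and enforces
# the separation greedily by descending height. Plain loops, independent of
# the package implementation.
oracle_peaks <- function(values, dt, min_prominence, min_separation) {
  n <- length(values)
  cand <- integer(0)
  for (i in 2:(n - 1))
    if (values[i] > values[i - 1] && values[i] > values[i + 1])
      cand <- c(cand, i)
  prom <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    lmin <- values[i]; k <- i - 1
    while (k >= 1 && values[k] <= values[i]) {
      lmin <- min(lmin, values[k]); k <- k - 1
    }
    if (k < 1) lmin <- min(values[1:i])
    rmin <- values[i]; k <- i + 1
    while (k <= n && values[k] <= values[i]) {
      rmin <- min(rmin, values[k]); k <- k + 1
    }
    if (k > n) rmin <- min(values[i:n])
    prom[j] <- values[i] - max(lmin, rmin)
  }
  cand <- cand[prom >= min_prominence]
  ord <- cand[order(-values[cand], cand)]
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in keep) if (abs(i - k) * dt < min_separation) ok <- FALSE
    if (ok) keep <- c(keep, i)
  }
  sort(keep)
}

# Brute-force Benjamini-Hochberg step-up oracle.
oracle_bh <- function(p, q) {
  m <- sum(!is.na(p))
  ord <- order(p, na.last = NA)
  k_max <- 0
  for (k in seq_along(ord))
    if (p[ord[k]] <= k / m * q) k_max <- k
  rej <- rep(FALSE, length(p))
  if (k_max > 0) rej[ord[seq_len(k_max)]] <- TRUE
  rej
}

# Squared-magnitude response of the zero-phase Butterworth band-pass at a
# given period, from the filter's frequency response (independent of the
# padding/filtfilt code path).
analytic_gain <- function(spec, sampling_interval, period) {
  bt <- bhcvr:::butter_coeffs(spec, sampling_interval)
  w <- 2 * pi * sampling_interval / period
  h <- sum(bt$b * exp(-1i * w * (seq_along(bt$b) - 1))) /
    sum(bt$a * exp(-1i * w * (seq_along(bt$a) - 1)))
  Mod(h)^2  # forward + reverse pass
}

# 3-voxel grid helpers for map-level tests.
tiny_grid_series <- function(mat, tr = 5, weighting = "asl") {
  dims <- c(nrow(mat), 1, 1)
  interleaved_series(array(mat, c(dims, ncol(mat))), tr, weighting)
}
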