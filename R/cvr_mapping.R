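# Shift a regressor in time: shifted[i] = x(t_i - lag). Positive lag delays
# the regressor (hemodynamic response lags the stimulus). Integer-frame
# shifts move indices with edge replication; fractional shifts interpolate.
shift_regressor <- function(x, lag, tr) {
  n <- length(x)
  k <- lag / tr
  if (abs(k - round(k)) < 1e-9) {
    k <- as.integer(round(k))
    if (k == 0L) return(x)
    if (abs(k) >= n) stop("lag exceeds series duration", call. = FALSE)
    if (k > 0) c(rep(x[1], k), x[seq_len(n - k)])
    else c(x[(1 - k):n], rep(x[n], -k))
  } else {
    t <- frame_times(n, tr)
    stats::approx(t, x, xout = t - lag, rule = 2)$y
  }
}

Z_CAP <- 1e6

#' Lagged GLM fit of one voxel time course on the PetCO2 regressor
#'
#' Regresses a (band-pass filtered) percent-change voxel time course on the
#' (band-pass filtered) PetCO2 trace shifted over a grid of candidate lags,
#' by ordinary least squares with an intercept. The lag maximizing explained
#' variance (R^2, equivalently |t| of the slope for a single regressor) is
#' selected; ties go to the smaller |lag|, then to the negative lag. The
#' slope has units percent signal change per mmHg.
#'
#' @param y numeric voxel time course, percent signal change.
#' @param x a `petco2_trace` (mmHg) or numeric vector of the same length.
#' @param spec a [lag_search_spec()].
#' @param tr repetition time in seconds; taken from `x` when it is a
#'   `petco2_trace`.
#' @param z_mode "se" (default): z = beta / SE(beta); "ci": beta divided by
#'   the 95% confidence-interval half-width (z / 1.96).
#' @return list with `beta` (%/mmHg), `se`, `z` (capped at 1e6 for perfect
#'   fits), `lag` (s), `r2`. An all-zero `y` returns beta = 0, z = 0,
#'   lag = 0.
#' @export
fit_lagged_glm <- function(y, x, spec = lag_search_spec(), tr = NULL,
                           z_mode = c("se", "ci")) {
  z_mode <- match.arg(z_mode)
  if (inherits(x, "petco2_trace")) {
    tr <- x$tr
    x <- x$values
  }
  if (is.null(tr)) stop("tr is required when x is a plain vector", call. = FALSE)
  n <- length(y)
  if (length(x) != n) stop("y and x must have the same length", call. = FALSE)
  if (n < 10L) stop("need at least 10 frames", call. = FALSE)
  if (all(y == 0))
    return(list(beta = 0, se = 0, z = 0, lag = 0, r2 = 0))
  lags <- lag_grid(spec)
  lags <- lags[order(abs(lags), lags)] # tie priority: small |lag|, then negative
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  best <- NULL
  for (l in lags) {
    xs <- shift_regressor(x, l, tr)
    xc <- xs - mean(xs)
    sxx <- sum(xc^2)
    if (sxx <= 0)
      stop("degenerate regressor: shifted PetCO2 trace has zero variance",
           call. = FALSE)
    sxy <- sum(yc * xc)
    r2 <- (sxy^2 / sxx) / ssy
    if (is.null(best) || r2 > best$r2 + 1e-12)
      best <- list(lag = l, r2 = r2, sxy = sxy, sxx = sxx)
  }
  beta <- best$sxy / best$sxx
  rss <- max(ssy - best$sxy^2 / best$sxx, 0)
  se <- sqrt(rss / (n - 2) / best$sxx)
  z <- if (se > 0) beta / se else sign(beta) * Z_CAP
  z <- pmin(pmax(z, -Z_CAP), Z_CAP)
  if (z_mode == "ci") z <- z / stats::qnorm(0.975)
  list(beta = beta, se = se, z = z, lag = best$lag, r2 = best$r2)
}

#' Voxelwise CVR, z-score and lag maps
#'
#' Applies the lagged GLM of [fit_lagged_glm()] to every voxel inside the
#' mask of a filtered fractional-change series. The lag is evaluated
#' independently per weighting. Voxels outside the mask (or with undefined
#' fractional change) are set to NA.
#'
#' @param fc a filtered `fractional_change_series` (percent units).
#' @param x the filtered `petco2_trace`.
#' @param spec a [lag_search_spec()].
#' @param mask 3D logical (or 0/1) array on the series grid.
#' @param z_mode see [fit_lagged_glm()].
#' @return object of class `cvr_map`: 3D arrays `beta` (%/mmHg), `z`, `lag`
#'   (s), `se`, plus `weighting` and `n_lag_boundary` (count of voxels whose
#'   selected lag sits at +/- max_lag, a fit-quality warning).
#' @export
map_cvr <- function(fc, x, spec = lag_search_spec(), mask,
                    z_mode = c("se", "ci")) {
  z_mode <- match.arg(z_mode)
  stopifnot(inherits(fc, "fractional_change_series"))
  stopifnot(inherits(x, "petco2_trace"))
  dims3 <- dim(fc$volumes)[1:3]
  if (!identical(as.integer(dim(mask)), as.integer(dims3)))
    stop(sprintf("grid mismatch: series %s vs mask %s",
                 paste(dims3, collapse = "x"),
                 paste(dim(mask), collapse = "x")), call. = FALSE)
  vox <- which(as.logical(mask))
  if (!length(vox)) stop("empty mask", call. = FALSE)
  m <- as_voxel_matrix(fc$volumes)[vox, , drop = FALSE]
  n <- ncol(m)
  ok <- stats::complete.cases(m)
  lags <- lag_grid(spec)
  lags <- lags[order(abs(lags), lags)]
  yc <- m - rowMeans(m)
  ssy <- rowSums(yc^2)
  nv <- nrow(m)
  best_r2 <- rep(-Inf, nv)
  best_lag <- best_sxy <- best_sxx <- rep(NA_real_, nv)
  for (l in lags) {
    xs <- shift_regressor(x$values, l, x$tr)
    xc <- xs - mean(xs)
    sxx <- sum(xc^2)
    if (sxx <= 0)
      stop("degenerate regressor: shifted PetCO2 trace has zero variance",
           call. = FALSE)
    sxy <- as.numeric(yc %*% xc)
    r2 <- ifelse(ssy > 0, (sxy^2 / sxx) / ssy, 0)
    upd <- r2 > best_r2 + 1e-12
    upd[is.na(upd)] <- FALSE
    best_r2[upd] <- r2[upd]
    best_lag[upd] <- l
    best_sxy[upd] <- sxy[upd]
    best_sxx[upd] <- sxx
  }
  beta <- best_sxy / best_sxx
  rss <- pmax(ssy - best_sxy^2 / best_sxx, 0)
  se <- sqrt(rss / (n - 2) / best_sxx)
  z <- ifelse(se > 0, beta / se, sign(beta) * Z_CAP)
  z <- pmin(pmax(z, -Z_CAP), Z_CAP)
  if (z_mode == "ci") z <- z / stats::qnorm(0.975)
  # all-zero voxels: defined as beta = 0, z = 0, lag = 0
  zero <- ok & ssy == 0
  beta[zero] <- 0; z[zero] <- 0; best_lag[zero] <- 0; se[zero] <- 0
  beta[!ok] <- z[!ok] <- se[!ok] <- best_lag[!ok] <- NA_real_
  put <- function(v) {
    a <- array(NA_real_, dims3)
    a[vox] <- v
    a
  }
  structure(list(beta = put(beta), z = put(z), lag = put(best_lag),
                 se = put(se), weighting = fc$weighting,
                 n_lag_boundary = sum(abs(best_lag[ok]) >= spec$max_lag &
                                        spec$max_lag > 0, na.rm = TRUE)),
            class = "cvr_map")
}

#' @export
print.cvr_map <- function(x, ...) {
  b <- x$beta[is.finite(x$beta)]
  cat(sprintf("CVR map (%s): %s grid, %d voxels mapped, median beta %.3g %%/mmHg, median z %.2f\n",
              toupper(x$weighting), paste(dim(x$beta), collapse = "x"),
              length(b), stats::median(b),
              stats::median(x$z[is.finite(x$z)])))
  invisible(x)
}
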