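#' Interleaved tag/control volume series
#'
#' A 4D fMRI volume series for one weighting, with frames alternating
#' between ASL tag and control conditions.
#'
#' @param volumes 4D numeric array (x, y, z, frame).
#' @param tr repetition time, seconds.
#' @param weighting one of "asl", "ge", "se".
#' @param frame_order "tag_first" (default) or "control_first".
#' @return object of class `interleaved_series` with fields `volumes`, `tr`,
#'   `weighting`, `frame_labels` (character vector "tag"/"control").
#' @export
interleaved_series <- function(volumes, tr, weighting = c("asl", "ge", "se"),
                               frame_order = c("tag_first", "control_first")) {
  weighting <- match.arg(weighting)
  frame_order <- match.arg(frame_order)
  if (length(dim(volumes)) != 4L)
    stop("volumes must be a 4D array (x, y, z, frame)", call. = FALSE)
  stopifnot_scalar(tr, "tr")
  nt <- dim(volumes)[4]
  labels <- if (frame_order == "tag_first") rep_len(c("tag", "control"), nt)
            else rep_len(c("control", "tag"), nt)
  structure(list(volumes = volumes, tr = tr, weighting = weighting,
                 frame_labels = labels),
            class = "interleaved_series")
}

#' @export
print.interleaved_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("interleaved %s series: %dx%dx%d voxels, %d frames (TR %.3g s), %s\n",
              toupper(x$weighting), d[1], d[2], d[3], d[4],
              x$tr, x$frame_labels[1]))
  invisible(x)
}

check_alternating <- function(labels) {
  if (any(labels[-1] == labels[-length(labels)]))
    stop("label order violation: tag/control frames must strictly alternate",
         call. = FALSE)
  invisible(TRUE)
}

# flatten (x,y,z,t) to voxels x frames without copying semantics surprises
as_voxel_matrix <- function(vol4d) {
  d <- dim(vol4d)
  dim(vol4d) <- c(prod(d[1:3]), d[4])
  vol4d
}

as_volume4d <- function(mat, dims3) {
  dim(mat) <- c(dims3, ncol(mat))
  mat
}

# mean of the two temporal neighbours; edge frames use the single neighbour
neighbour_mean <- function(m) {
  nt <- ncol(m)
  nb <- m
  if (nt >= 3L) nb[, 2:(nt - 1L)] <- (m[, 1:(nt - 2L), drop = FALSE] +
                                        m[, 3:nt, drop = FALSE]) / 2
  nb[, 1L] <- m[, 2L]
  nb[, nt] <- m[, nt - 1L]
  nb
}

#' Surround subtraction of an interleaved ASL series
#'
#' Extracts the perfusion-weighted difference signal, proportional to CBF:
#' for each frame the difference between the frame and the mean of its two
#' opposite-label neighbours, signed so that control minus tag is positive.
#' The second-order stencil cancels common-mode linear trends; edge frames
#' fall back to the single available neighbour. Output keeps one value per
#' input frame (full TR grid).
#'
#' @param series an [interleaved_series()] with weighting "asl".
#' @return object of class `volume_series`: `volumes` (4D perfusion-weighted
#'   difference, scanner units), `tr`, `weighting`, `kind = "perfusion"`.
#' @export
surround_subtract <- function(series) {
  stopifnot(inherits(series, "interleaved_series"))
  if (series$weighting != "asl")
    stop("surround subtraction applies to the ASL weighting", call. = FALSE)
  check_alternating(series$frame_labels)
  m <- as_voxel_matrix(series$volumes)
  sgn <- ifelse(series$frame_labels == "control", 1, -1)
  d <- sweep(m - neighbour_mean(m), 2L, sgn, `*`)
  structure(list(volumes = as_volume4d(d, dim(series$volumes)[1:3]),
                 tr = series$tr, weighting = "asl", kind = "perfusion"),
            class = "volume_series")
}

#' Surround averaging of an interleaved BOLD series
#'
#' Removes perfusion contamination from a BOLD series: each frame is
#' replaced by the average of the frame and the mean of its opposite-label
#' neighbours, which cancels any additive component that alternates with
#' tag/control parity (exactly so at interior frames for a constant
#' alternation). Edge frames use the single neighbour.
#'
#' @param series an [interleaved_series()] with weighting "ge" or "se".
#' @return object of class `volume_series` with `kind = "bold"`.
#' @export
surround_average <- function(series) {
  stopifnot(inherits(series, "interleaved_series"))
  if (!series$weighting %in% c("ge", "se"))
    stop("surround averaging applies to the BOLD weightings (ge, se)",
         call. = FALSE)
  check_alternating(series$frame_labels)
  m <- as_voxel_matrix(series$volumes)
  a <- (m + neighbour_mean(m)) / 2
  structure(list(volumes = as_volume4d(a, dim(series$volumes)[1:3]),
                 tr = series$tr, weighting = series$weighting, kind = "bold"),
            class = "volume_series")
}

#' Express a volume series as percent change from baseline
#'
#' Voxelwise `(s(t) - m) / m * 100` with `m` the mean over frames acquired
#' before `baseline_window` seconds. For the perfusion difference series the
#' baseline is the mean perfusion-weighted difference, so the output is the
#' fractional CBF change; voxels whose baseline is not positive carry no
#' defined fractional change and are set to NA (their count is reported via
#' the `n_masked` attribute).
#'
#' @param series a `volume_series` (from [surround_subtract()] or
#'   [surround_average()]) or an [interleaved_series()].
#' @param baseline_window seconds of initial recording averaged as baseline
#'   (default 50).
#' @return object of class `fractional_change_series`: `volumes` (4D percent
#'   change), `frame_times`, `tr`, `weighting`, `baseline_map` (3D).
#' @export
to_fractional_change <- function(series, baseline_window = 50) {
  stopifnot(inherits(series, c("volume_series", "interleaved_series")))
  m <- as_voxel_matrix(series$volumes)
  ft <- frame_times(ncol(m), series$tr)
  base_idx <- which(ft < baseline_window)
  if (!length(base_idx))
    stop("series does not cover the baseline window", call. = FALSE)
  base <- rowMeans(m[, base_idx, drop = FALSE])
  bad <- !(base > 0)
  pct <- 100 * (m - base) / base
  pct[bad, ] <- NA_real_
  dims3 <- dim(series$volumes)[1:3]
  out <- structure(list(volumes = as_volume4d(pct, dims3),
                        frame_times = ft, tr = series$tr,
                        weighting = series$weighting,
                        baseline_map = array(base, dims3)),
                   class = "fractional_change_series")
  attr(out, "n_masked") <- sum(bad)
  out
}

# Zero-phase band-pass as a linear operator on a fixed frame grid, cached so
# that voxelwise filtering is a single matrix product.
.filter_ops <- new.env(parent = emptyenv())

filter_operator <- function(n, sampling_interval, spec) {
  key <- paste(n, sampling_interval, spec$low_cutoff_period,
               spec$high_cutoff_period, spec$order, spec$zero_phase,
               sep = "|")
  op <- get0(key, envir = .filter_ops)
  if (is.null(op)) {
    op <- vapply(seq_len(n), function(j) {
      e <- numeric(n); e[j] <- 1
      bandpass_filter(e, spec, sampling_interval)
    }, numeric(n))
    assign(key, op, envir = .filter_ops)
  }
  op
}

#' Band-pass filter a fractional-change series voxelwise
#'
#' Applies the zero-phase Butterworth band-pass of [bandpass_filter()] to
#' every voxel time course. Filtering is linear and time-invariant on the
#' fixed frame grid, so it is applied as a cached matrix operator.
#'
#' @param fc a `fractional_change_series`.
#' @param spec a [filter_spec()].
#' @return the series with filtered `volumes` (approximately zero-mean per
#'   voxel); NA voxels stay NA.
#' @export
filter_series <- function(fc, spec = filter_spec()) {
  stopifnot(inherits(fc, "fractional_change_series"))
  m <- as_voxel_matrix(fc$volumes)
  op <- filter_operator(ncol(m), fc$tr, spec)
  out <- m %*% t(op)
  fc$volumes <- as_volume4d(out, dim(fc$volumes)[1:3])
  attr(fc, "filtered") <- TRUE
  fc
}
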