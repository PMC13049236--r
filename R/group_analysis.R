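#' Bundle of subject-level CVR maps on a common grid
#'
#' @param subjects list; each element a list with `cvr_map`s named `asl`,
#'   `ge`, `se`.
#' @param gm_mask 3D logical gray-matter mask.
#' @param roi_labels 3D integer label image (0 = outside all ROIs).
#' @param venous_density data.frame with columns `roi_id`, `name`,
#'   `venous_density`; every nonzero label must have an entry.
#' @return object of class `subject_cvr_set`.
#' @export
subject_cvr_set <- function(subjects, gm_mask, roi_labels = NULL,
                            venous_density = NULL) {
  stopifnot(length(subjects) >= 1)
  ref <- dim(subjects[[1]]$asl$beta)
  for (s in subjects)
    for (w in c("asl", "ge", "se"))
      if (!identical(dim(s[[w]]$beta), ref))
        stop("grid mismatch across subject maps", call. = FALSE)
  if (!identical(as.integer(dim(gm_mask)), as.integer(ref)))
    stop(sprintf("grid mismatch: maps %s vs gm_mask %s",
                 paste(ref, collapse = "x"),
                 paste(dim(gm_mask), collapse = "x")), call. = FALSE)
  if (!is.null(roi_labels)) {
    if (!identical(as.integer(dim(roi_labels)), as.integer(ref)))
      stop("grid mismatch between maps and roi_labels", call. = FALSE)
    if (!is.null(venous_density)) check_roi_table(roi_labels, venous_density)
  }
  structure(list(subjects = subjects, gm_mask = array(as.logical(gm_mask), ref),
                 roi_labels = roi_labels, venous_density = venous_density),
            class = "subject_cvr_set")
}

#' Per-subject gray-matter mean CVR under ASL-confidence thresholding
#'
#' For each subject, averages the three CVR maps over the gray-matter voxels
#' whose ASL z-score exceeds `z_thr`; the same surviving voxel set is applied
#' to all three weightings. `z_thr = -Inf` gives the unthresholded GM means.
#'
#' @param set a [subject_cvr_set()].
#' @param z_thr lower bound on the ASL z-score (default -Inf).
#' @return data.frame with one row per subject: `subject`, `n_vox`,
#'   `cvr_asl`, `cvr_ge`, `cvr_se` (NA and zero `n_vox` when no voxel
#'   survives, in which case the subject is excluded from the group summary);
#'   attributes `group_mean` and `group_sd` hold the across-subject summary.
#' @export
gm_summary <- function(set, z_thr = -Inf) {
  stopifnot(inherits(set, "subject_cvr_set"))
  gm <- which(set$gm_mask)
  rows <- lapply(seq_along(set$subjects), function(i) {
    s <- set$subjects[[i]]
    zi <- s$asl$z[gm]
    keep <- gm[!is.na(zi) & zi > z_thr]
    if (!length(keep))
      return(data.frame(subject = i, n_vox = 0L, cvr_asl = NA_real_,
                        cvr_ge = NA_real_, cvr_se = NA_real_))
    data.frame(subject = i, n_vox = length(keep),
               cvr_asl = mean(s$asl$beta[keep], na.rm = TRUE),
               cvr_ge = mean(s$ge$beta[keep], na.rm = TRUE),
               cvr_se = mean(s$se$beta[keep], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  if (any(out$n_vox == 0L))
    message(sum(out$n_vox == 0L),
            " subject(s) had no voxel surviving z > ", z_thr,
            " and are excluded from the group summary")
  ok <- out$n_vox > 0L
  attr(out, "group_mean") <- colMeans(out[ok, c("cvr_asl", "cvr_ge", "cvr_se")])
  attr(out, "group_sd") <- vapply(out[ok, c("cvr_asl", "cvr_ge", "cvr_se")],
                                  stats::sd, numeric(1))
  out
}

#' Across-subject correlation between two CVR summaries
#'
#' @param a,b numeric vectors of per-subject values (length >= 3).
#' @param method "pearson" (default) or "spearman".
#' @return list with `r`, `p` (two-sided), `n`, `fisher_z = atanh(r)`.
#' @export
across_subject_correlation <- function(a, b,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need at least 3 paired finite values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: an input has zero variance", call. = FALSE)
  ct <- stats::cor.test(a, b, method = method, exact = FALSE)
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, n = length(a), fisher_z = atanh(r))
}

#' Group CVR summaries and correlations across an ASL z-threshold grid
#'
#' Re-evaluates [gm_summary()] and the pairwise across-subject Pearson
#' correlations at each ASL z-score threshold. Because the surviving voxel
#' sets are nested (higher threshold, fewer voxels), the curves expose the
#' selection bias by which the mean ASL CVR inflates with the threshold.
#'
#' @param set a [subject_cvr_set()].
#' @param z_grid ascending thresholds (default seq(-2, 6, 0.5)).
#' @return data.frame with one row per threshold: group means and SDs per
#'   weighting, pairwise correlations `r_ge_asl`, `r_se_asl`, `r_se_ge`,
#'   number of contributing subjects and median surviving voxel count.
#' @export
threshold_curves <- function(set, z_grid = seq(-2, 6, by = 0.5)) {
  stopifnot(!is.unsorted(z_grid))
  rows <- lapply(z_grid, function(zt) {
    sm <- suppressMessages(gm_summary(set, z_thr = zt))
    ok <- sm$n_vox > 0L
    gmn <- attr(sm, "group_mean"); gsd <- attr(sm, "group_sd")
    corr <- function(x, y) {
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(NA_real_)
      stats::cor(x[ok], y[ok])
    }
    data.frame(z_thr = zt, n_subjects = sum(ok),
               median_n_vox = stats::median(sm$n_vox[ok]),
               mean_asl = gmn[["cvr_asl"]], sd_asl = gsd[["cvr_asl"]],
               mean_ge = gmn[["cvr_ge"]], sd_ge = gsd[["cvr_ge"]],
               mean_se = gmn[["cvr_se"]], sd_se = gsd[["cvr_se"]],
               r_ge_asl = corr(sm$cvr_ge, sm$cvr_asl),
               r_se_asl = corr(sm$cvr_se, sm$cvr_asl),
               r_se_ge = corr(sm$cvr_se, sm$cvr_ge))
  })
  do.call(rbind, rows)
}

#' Williams-Steiger test for two dependent overlapping correlations
#'
#' Tests whether cor(x1, x2) differs from cor(x1, x3) when both share x1,
#' given the correlation of x2 with x3 (Williams' t with n - 3 degrees of
#' freedom).
#'
#' @param r12,r13 the two correlations sharing a variable.
#' @param r23 correlation between the non-shared variables.
#' @param n sample size (>= 4).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
steiger_test <- function(r12, r13, r23, n) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3
  tval <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  list(t = tval, df = n - 3,
       p = 2 * stats::pt(-abs(tval), df = n - 3))
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up FDR control: flags the hypotheses rejected at level `q`.
#'
#' @param p vector of p-values (NA allowed, never flagged).
#' @param q FDR level (default 0.05).
#' @return logical vector of rejections.
#' @export
bh_fdr <- function(p, q = 0.05) {
  adj <- stats::p.adjust(p, method = "BH")
  out <- !is.na(adj) & adj <= q
  out
}

#' Per-ROI Fisher-z correlation maps with venous-density stratification
#'
#' For every atlas ROI: the per-subject ROI-mean CVRs (GM voxels surviving
#' the ASL z-threshold), the across-subject Pearson correlations of the GE
#' and SE CVR with the ASL CVR, their Fisher transforms, the difference
#' (SE-vs-ASL minus GE-vs-ASL), a Williams-Steiger dependent-correlation test
#' for the difference, and Benjamini-Hochberg FDR flags (q = 0.05) computed
#' across ROIs separately for each of the three families. ROIs are
#' stratified into high/low macrovascular venous density at the 50th
#' percentile of the supplied per-ROI density table.
#'
#' @param set a [subject_cvr_set()] with `roi_labels` and `venous_density`.
#' @param z_thr ASL z-score threshold (default 2).
#' @param q FDR level (default 0.05).
#' @return data.frame with one row per ROI: correlations, Fisher z, `dz`
#'   (z_se_asl - z_ge_asl), p-values, FDR flags, `venous_density`,
#'   `high_density`, `n_subjects`; ROIs with < 3 contributing subjects are
#'   flagged `missing = TRUE`.
#' @export
roi_fisher_maps <- function(set, z_thr = 2, q = 0.05) {
  stopifnot(inherits(set, "subject_cvr_set"))
  if (is.null(set$roi_labels) || is.null(set$venous_density))
    stop("roi_labels and venous_density are required", call. = FALSE)
  vd <- set$venous_density
  ids <- sort(unique(as.integer(set$roi_labels[set$roi_labels > 0])))
  gm <- set$gm_mask
  per_roi <- lapply(ids, function(id) {
    roi_vox <- which(set$roi_labels == id & gm)
    vals <- t(vapply(set$subjects, function(s) {
      zi <- s$asl$z[roi_vox]
      keep <- roi_vox[!is.na(zi) & zi > z_thr]
      if (!length(keep)) return(c(NA_real_, NA_real_, NA_real_))
      c(mean(s$asl$beta[keep], na.rm = TRUE),
        mean(s$ge$beta[keep], na.rm = TRUE),
        mean(s$se$beta[keep], na.rm = TRUE))
    }, numeric(3)))
    colnames(vals) <- c("asl", "ge", "se")
    vals
  })
  rows <- lapply(seq_along(ids), function(k) {
    vals <- per_roi[[k]]
    ok <- stats::complete.cases(vals)
    n <- sum(ok)
    base <- data.frame(roi_id = ids[k], n_subjects = n,
                       r_ge_asl = NA_real_, r_se_asl = NA_real_,
                       r_ge_se = NA_real_, z_ge_asl = NA_real_,
                       z_se_asl = NA_real_, dz = NA_real_,
                       p_ge_asl = NA_real_, p_se_asl = NA_real_,
                       p_diff = NA_real_, missing = TRUE)
    if (n < 3) return(base)
    v <- vals[ok, , drop = FALSE]
    if (any(apply(v, 2, stats::sd) == 0)) return(base)
    r_ge <- stats::cor(v[, "ge"], v[, "asl"])
    r_se <- stats::cor(v[, "se"], v[, "asl"])
    r_gs <- stats::cor(v[, "ge"], v[, "se"])
    ct_ge <- stats::cor.test(v[, "ge"], v[, "asl"])
    ct_se <- stats::cor.test(v[, "se"], v[, "asl"])
    st <- if (n >= 4) steiger_test(r_se, r_ge, r_gs, n) else list(p = NA_real_)
    base$r_ge_asl <- r_ge; base$r_se_asl <- r_se; base$r_ge_se <- r_gs
    base$z_ge_asl <- atanh(r_ge); base$z_se_asl <- atanh(r_se)
    base$dz <- atanh(r_se) - atanh(r_ge)
    base$p_ge_asl <- ct_ge$p.value; base$p_se_asl <- ct_se$p.value
    base$p_diff <- st$p
    base$missing <- FALSE
    base
  })
  out <- do.call(rbind, rows)
  out$sig_ge_asl <- bh_fdr(out$p_ge_asl, q)
  out$sig_se_asl <- bh_fdr(out$p_se_asl, q)
  out$sig_diff <- bh_fdr(out$p_diff, q)
  dens <- vd$venous_density[match(out$roi_id, vd$roi_id)]
  out$venous_density <- dens
  out$high_density <- dens > stats::median(vd$venous_density)
  out
}

#' Spatial correlation of group-average maps versus number of subjects
#'
#' Bootstrap estimate of how the spatial (across GM voxels) Pearson
#' correlation between group-average CVR maps grows with the number of
#' averaged subjects: for each k = 1..N, `n_iters` bootstrap draws of k
#' subjects (with replacement) are averaged and the GM-voxel correlation is
#' computed for each weighting pair.
#'
#' @param set a [subject_cvr_set()].
#' @param n_iters bootstrap iterations per k (default 100).
#' @param seed RNG seed for reproducibility (default NULL: use current
#'   stream).
#' @return data.frame with one row per k: mean and SD over iterations of
#'   `r_ge_asl`, `r_se_asl`, `r_se_ge`.
#' @export
spatial_correlation_vs_n <- function(set, n_iters = 100, seed = NULL) {
  stopifnot(inherits(set, "subject_cvr_set"), n_iters >= 1)
  gm <- which(set$gm_mask)
  nsub <- length(set$subjects)
  mats <- lapply(c("asl", "ge", "se"), function(w)
    vapply(set$subjects, function(s) s[[w]]$beta[gm], numeric(length(gm))))
  names(mats) <- c("asl", "ge", "se")
  pair_r <- function(idx) {
    avg <- lapply(mats, function(m) rowMeans(m[, idx, drop = FALSE]))
    keep <- is.finite(avg$asl) & is.finite(avg$ge) & is.finite(avg$se)
    c(r_ge_asl = stats::cor(avg$ge[keep], avg$asl[keep]),
      r_se_asl = stats::cor(avg$se[keep], avg$asl[keep]),
      r_se_ge = stats::cor(avg$se[keep], avg$ge[keep]))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nsub), function(k) {
      rs <- t(vapply(seq_len(n_iters), function(it)
        pair_r(sample.int(nsub, k, replace = TRUE)), numeric(3)))
      data.frame(k = k,
                 r_ge_asl = mean(rs[, 1]), sd_ge_asl = stats::sd(rs[, 1]),
                 r_se_asl = mean(rs[, 2]), sd_se_asl = stats::sd(rs[, 2]),
                 r_se_ge = mean(rs[, 3]), sd_se_ge = stats::sd(rs[, 3]))
    })
    do.call(rbind, rows)
  })
}

#' Second-level one-sample t-map across subjects
#'
#' Voxelwise one-sample t statistic of the subject CVR values against zero.
#' Voxels with zero across-subject variance get a capped t (sign of the
#' mean, magnitude 1e6) when the mean is nonzero and NA otherwise.
#'
#' @param maps list of 3D beta arrays (one per subject, >= 2) or a
#'   [subject_cvr_set()] plus `weighting`.
#' @param weighting when `maps` is a `subject_cvr_set`: which weighting.
#' @return 3D array of t-scores.
#' @export
second_level_tmap <- function(maps, weighting = "asl") {
  if (inherits(maps, "subject_cvr_set"))
    maps <- lapply(maps$subjects, function(s) s[[weighting]]$beta)
  n <- length(maps)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  dims <- dim(maps[[1]])
  m <- vapply(maps, as.numeric, numeric(prod(dims)))
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  tval <- mu / (sdv / sqrt(n))
  flat <- sdv == 0
  tval[flat & mu != 0] <- sign(mu[flat & mu != 0]) * Z_CAP
  tval[flat & mu == 0] <- NA_real_
  array(tval, dims)
}

#' Coefficient of variation
#'
#' SD divided by mean (sample SD, n - 1 denominator). Returned as a
#' unitless fraction; multiply by 100 for percent.
#'
#' @param values numeric vector with nonzero mean.
#' @return sd(values) / mean(values).
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean",
                   call. = FALSE)
  stats::sd(values) / m
}
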