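#' Read a raw capnography trace from delimited text
#'
#' Accepts two-column text (time in seconds, CO2 in mmHg; uniform sampling
#' required) or single-column text with the sampling interval supplied.
#'
#' @param path file path; whitespace-, comma- or tab-delimited, optional
#'   header.
#' @param sampling_interval seconds between samples; required for
#'   single-column files, checked against the time column otherwise.
#' @param acquisition_delay sampling-line delay, seconds.
#' @return a [raw_capno()].
#' @export
read_capno <- function(path, sampling_interval = NULL, acquisition_delay = 0) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#", fill = TRUE)
  if (!is.numeric(tab[1, 1])) tab <- tab[-1, , drop = FALSE]
  tab[] <- lapply(tab, function(c) as.numeric(as.character(c)))
  if (ncol(tab) >= 2) {
    dt <- diff(tab[[1]])
    if (diff(range(dt)) > 1e-6 * mean(dt))
      stop("capnography time stamps are not uniformly sampled", call. = FALSE)
    si <- mean(dt)
    if (!is.null(sampling_interval) && !is.na(sampling_interval) &&
        abs(si - sampling_interval) > 1e-6 * si)
      stop("stated sampling interval disagrees with the time column",
           call. = FALSE)
    raw_capno(tab[[2]], si, acquisition_delay)
  } else {
    if (is.null(sampling_interval))
      stop("single-column capnography requires sampling_interval",
           call. = FALSE)
    raw_capno(tab[[1]], sampling_interval, acquisition_delay)
  }
}

#' Write a PetCO2 trace with its JSON sidecar
#'
#' One value per fMRI frame in plain text, plus `<path>.json` holding
#' `rest_level`, `modulation_range`, `tr`, `is_filtered` and the frame count.
#'
#' @param trace a `petco2_trace`.
#' @param path output text file.
#' @return invisibly, the sidecar path.
#' @export
write_petco2 <- function(trace, path) {
  stopifnot(inherits(trace, "petco2_trace"))
  writeLines(format(trace$values, digits = 10), path)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(rest_level = trace$rest_level,
                            modulation_range = modulation_range(trace$values),
                            tr = trace$tr, n_frames = length(trace$values),
                            is_filtered = trace$is_filtered),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read an interleaved tag/control series from NIfTI
#'
#' @param path 4D NIfTI file (.nii or .nii.gz).
#' @param weighting "asl", "ge" or "se".
#' @param sidecar JSON sidecar path (default `<path>.json` if present)
#'   carrying `frame_order` ("tag_first"/"control_first") and optionally
#'   `tr`; TR falls back to the NIfTI header.
#' @return an [interleaved_series()].
#' @export
read_series <- function(path, weighting = c("asl", "ge", "se"),
                        sidecar = NULL) {
  weighting <- match.arg(weighting)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D NIfTI series", call. = FALSE)
  side <- sidecar %||% paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  tr <- meta$tr %||% RNifti::pixdim(img)[4]
  if (!is.numeric(tr) || tr <= 0)
    stop("TR not available from header or sidecar", call. = FALSE)
  interleaved_series(array(as.numeric(img), dim(img)), tr, weighting,
                     frame_order = meta$frame_order %||% "tag_first")
}

#' Write an interleaved series to NIfTI with a JSON sidecar
#'
#' @param series an [interleaved_series()].
#' @param path output .nii or .nii.gz path.
#' @return invisibly, `path`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "interleaved_series"))
  img <- RNifti::asNifti(series$volumes)
  RNifti::pixdim(img) <- c(1, 1, 1, series$tr)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(tr = series$tr, weighting = series$weighting,
                            frame_order = if (series$frame_labels[1] == "tag")
                              "tag_first" else "control_first"),
                       paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a CVR map triplet to NIfTI
#'
#' Writes `cvr_<w>.nii.gz` (beta, % signal/mmHg), `z_<w>.nii.gz` and
#' `lag_<w>.nii.gz` (seconds) under the given directory; NA is the
#' missing-value sentinel.
#'
#' @param map a `cvr_map`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths.
#' @export
write_map <- function(map, dir) {
  stopifnot(inherits(map, "cvr_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- map$weighting
  paths <- file.path(dir, sprintf(c("cvr_%s.nii.gz", "z_%s.nii.gz",
                                    "lag_%s.nii.gz"), w))
  for (i in seq_along(paths))
    RNifti::writeNifti(RNifti::asNifti(map[[c("beta", "z", "lag")[i]]]),
                       paths[i])
  invisible(paths)
}

#' Read a CVR map triplet written by [write_map()]
#'
#' @param dir directory holding `cvr_<w>`, `z_<w>`, `lag_<w>` NIfTI files.
#' @param weighting "asl", "ge" or "se".
#' @return a `cvr_map`.
#' @export
read_map <- function(dir, weighting = c("asl", "ge", "se")) {
  weighting <- match.arg(weighting)
  rd <- function(stem) {
    arr <- RNifti::readNifti(file.path(dir, sprintf("%s_%s.nii.gz", stem,
                                                    weighting)))
    array(as.numeric(arr), dim(arr))
  }
  structure(list(beta = rd("cvr"), z = rd("z"), lag = rd("lag"), se = NULL,
                 weighting = weighting, n_lag_boundary = NA_integer_),
            class = "cvr_map")
}

#' Read a per-ROI venous-density table
#'
#' Tab-separated table with columns `roi_id`, `name`, `venous_density`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_roi_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("roi_id", "name", "venous_density")
  if (!all(need %in% names(tab)))
    stop("ROI table must have columns roi_id, name, venous_density",
         call. = FALSE)
  tab
}

#' Check that every ROI label has a venous-density entry
#'
#' @param roi_labels 3D integer label image.
#' @param table a venous-density data.frame.
#' @return TRUE invisibly; errors listing the missing ids otherwise.
#' @export
check_roi_table <- function(roi_labels, table) {
  ids <- sort(unique(as.integer(roi_labels[roi_labels > 0])))
  missing <- setdiff(ids, table$roi_id)
  if (length(missing))
    stop("venous-density table is missing ROI id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Load and validate a run configuration from YAML
#'
#' Recognized top-level keys: `protocol`, `filter`, `lag_search`, `seed`,
#' `z_threshold`, `frame_order`, `paths`. Unknown keys are rejected; the
#' sub-specs are passed through their constructors so invariants are
#' enforced on load.
#'
#' @param path YAML file.
#' @return list with validated `protocol` ([protocol_spec()]), `filter`
#'   ([filter_spec()]), `lag_search` ([lag_search_spec()]) and the scalar
#'   settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("protocol", "filter", "lag_search", "seed", "z_threshold",
             "frame_order", "paths")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  list(protocol = do.call(protocol_spec, cfg$protocol %||% list()),
       filter = do.call(filter_spec, cfg$filter %||% list()),
       lag_search = do.call(lag_search_spec, cfg$lag_search %||% list()),
       seed = cfg$seed %||% 1L,
       z_threshold = cfg$z_threshold %||% 2,
       frame_order = cfg$frame_order %||% "tag_first",
       paths = cfg$paths %||% list())
}
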