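# Plain-text serialisation of the pipeline's inputs and outputs. Images are
# CSV matrices (one file per channel or z-plane), tables are CSV with a
# header row, and metadata travels in JSON sidecars. These are the portable
# stand-ins for multi-page TIFF in this build.

#' Write / read a single-channel image as a CSV matrix
#'
#' @param img a [channel_image()].
#' @param path file path.
#' @return `read_image_csv` returns a [channel_image()].
#' @export
#' @rdname image_io
write_image_csv <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  utils::write.table(img$pixels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @param pixel_size_um,channel_label image metadata (not stored in the CSV).
#' @export
#' @rdname image_io
read_image_csv <- function(path, pixel_size_um, channel_label = "pre") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  channel_image(matrix(as.integer(m), nrow(m)), pixel_size_um, channel_label)
}

#' Write / read ROI fluorescence traces as CSV
#'
#' One `time_s` column plus one column per ROI.
#'
#' @param traces named list of [fluor_trace()]s with a common frame rate.
#' @param path file path.
#' @export
#' @rdname trace_io
write_traces_csv <- function(traces, path) {
  stopifnot(length(traces) >= 1L)
  fr <- traces[[1]]$frame_rate_hz
  n <- length(traces[[1]]$values)
  df <- data.frame(time_s = (seq_len(n) - 1) / fr)
  nm <- names(traces)
  if (is.null(nm)) nm <- paste0("roi", seq_along(traces))
  for (k in seq_along(traces)) df[[nm[k]]] <- traces[[k]]$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param is_dff whether the stored values are dF/F.
#' @return `read_traces_csv` returns a named list of [fluor_trace()]s.
#' @export
#' @rdname trace_io
read_traces_csv <- function(path, is_dff = TRUE) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("trace CSV must have a time_s column")
  fr <- 1 / mean(diff(df$time_s))
  cols <- setdiff(names(df), "time_s")
  setNames(lapply(cols, function(cn) fluor_trace(df[[cn]], fr, is_dff)),
           cols)
}

#' Write / read a cell-and-bead scene as a plain-text directory
#'
#' `masks.csv` holds the non-zero mask voxels in long form (`y`, `x`, `z`,
#' `label`), `beads.csv` the bead table, and `meta.json` the geometry.
#'
#' @param scene a `cell_bead_scene`.
#' @param dir output directory (created if needed).
#' @export
#' @rdname scene_io
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "cell_bead_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(scene$masks > 0L)
  d <- dim(scene$masks)
  vox <- data.frame(
    y = ((nz - 1L) %% d[1]) + 1L,
    x = (((nz - 1L) %/% d[1]) %% d[2]) + 1L,
    z = ((nz - 1L) %/% (d[1] * d[2])) + 1L,
    label = scene$masks[nz])
  utils::write.csv(vox, file.path(dir, "masks.csv"), row.names = FALSE)
  utils::write.csv(scene$beads, file.path(dir, "beads.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(dim = d, pixel_size_um = scene$pixel_size_um,
         z_step_um = scene$z_step_um, fov_um = scene$fov_um,
         n_cells = scene$n_cells),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @return `read_scene` returns a `cell_bead_scene`.
#' @export
#' @rdname scene_io
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  vox <- utils::read.csv(file.path(dir, "masks.csv"))
  masks <- array(0L, dim = meta$dim)
  masks[cbind(vox$y, vox$x, vox$z)] <- vox$label
  beads <- utils::read.csv(file.path(dir, "beads.csv"))
  structure(list(masks = masks, beads = beads,
                 pixel_size_um = meta$pixel_size_um,
                 z_step_um = meta$z_step_um, fov_um = meta$fov_um,
                 n_cells = meta$n_cells),
            class = "cell_bead_scene")
}

#' Write / read a point pattern as CSV
#'
#' @param pattern a [point_pattern()].
#' @param path file path; the FOV is stored in a `meta.json` next to it when
#'   writing and must be supplied when reading a bare CSV.
#' @export
#' @rdname pattern_io
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  utils::write.csv(data.frame(x_um = pattern$x, y_um = pattern$y), path,
                   row.names = FALSE)
  jsonlite::write_json(list(width = pattern$width, height = pattern$height),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param width,height field dimensions (um); read from the sidecar when
#'   `NULL`.
#' @export
#' @rdname pattern_io
read_pattern_csv <- function(path, width = NULL, height = NULL) {
  df <- utils::read.csv(path)
  if (is.null(width)) {
    meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                                simplifyVector = TRUE)
    width <- meta$width; height <- meta$height
  }
  if (is.null(height)) height <- width
  point_pattern(df$x_um, df$y_um, width, height)
}

#' Write / read a current trace as CSV
#'
#' Columns `time_s`, `current_pA`; markers live in the run config.
#'
#' @param trace a [current_trace()].
#' @param path file path.
#' @export
#' @rdname current_io
write_current_csv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  n <- length(trace$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / trace$sample_rate_hz,
               current_pA = trace$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' @param ttx_onset_s,agonist_onset_s,polarity trace metadata.
#' @export
#' @rdname current_io
read_current_csv <- function(path, ttx_onset_s = NA_real_,
                             agonist_onset_s = NA_real_,
                             polarity = "inward") {
  df <- utils::read.csv(path)
  fs <- 1 / mean(diff(df$time_s))
  current_trace(df$current_pA, fs, ttx_onset_s, agonist_onset_s,
                polarity = polarity)
}
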