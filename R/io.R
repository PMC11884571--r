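# I/O: multi-page TIFF stacks with JSON sidecars carrying calibration,
# per-frame time/state/mode and generator parameters; CSV export of
# gridded strain data, summary series and cell tracks.

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' @param stack list of numeric matrices (gray levels).
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param calibration µm/px recorded in the sidecar.
#' @param schedule optional [actuation_schedule()]; per-frame time, state
#'   and mode go into the sidecar.
#' @param bit_depth gray-level range of the data (values are stored
#'   normalized; the bit depth allows exact round-trip).
#' @param extra named list of additional sidecar entries (e.g. seed,
#'   ground-truth parameters).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, calibration = 1, schedule = NULL,
                        bit_depth = 8, extra = list()) {
  if (!is.list(stack)) stack <- list(stack)
  maxval <- 2^bit_depth - 1
  pages <- lapply(stack, function(m) pmin(pmax(m / maxval, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(list(calibration_um_per_px = calibration,
                 bit_depth = bit_depth, n_frames = length(stack)),
            extra)
  if (!is.null(schedule))
    meta$frames <- data.frame(time = schedule$time, state = schedule$state,
                              mode = schedule$mode)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @return List with `stack` (list of matrices in gray levels),
#'   `calibration`, and `meta` (full sidecar contents, or `NULL` when no
#'   sidecar exists).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  bit_depth <- if (!is.null(meta$bit_depth)) meta$bit_depth else 8
  stack <- lapply(pages, function(p) p * (2^bit_depth - 1))
  list(stack = stack,
       calibration = if (!is.null(meta$calibration_um_per_px))
         meta$calibration_um_per_px else 1,
       meta = meta)
}

#' Export a strain field as tidy CSV
#'
#' One row per grid point with columns `x_um`, `y_um`, `Exx`, `Eyy`,
#' `Exy` (text layout of gridded vector data; `NA` marks excluded
#' points).
#'
#' @param strain a [green_lagrange()] strain field.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_strain_csv <- function(strain, path) {
  stopifnot(inherits(strain, "strain_field"))
  grid <- expand.grid(y_um = strain$y_um, x_um = strain$x_um)
  df <- data.frame(x_um = grid$x_um, y_um = grid$y_um,
                   Exx = as.vector(strain$Exx),
                   Eyy = as.vector(strain$Eyy),
                   Exy = as.vector(strain$Exy))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a time series (strain, speed, fluorescence) or cell tracks as CSV
#'
#' @param x a data-frame-like package object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Export a pressure trace as two-column CSV (`t_s`, `p_bar`)
#'
#' @param trace a [pressure_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  utils::write.csv(data.frame(t_s = trace$time, p_bar = trace$pressure),
                   path, row.names = FALSE)
  invisible(path)
}
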