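# Synthetic epithelial-monolayer image sequences with ground truth.
# Cells are a seeded Voronoi tessellation of drifting seed points; the
# phase channel carries nucleus-like blobs and dark junction lines (enough
# texture for window correlation), the fluorescence channel carries a
# junction-localized signal whose global amplitude follows a per-frame
# schedule, and the label channel is the exact tessellation. Stretched
# frames are the relaxed rendering warped by the frame's deformation spec,
# exactly as the real membrane deforms under actuation.

#' Specification of a synthetic monolayer sequence
#'
#' @param n_cells number of cells (Voronoi seeds) in the field of view.
#' @param image_size `c(width, height)` in pixels.
#' @param calibration micrometres per pixel.
#' @param drift_speed collective drift speed of the monolayer in µm/h
#'   (applied along `drift_direction`); emulates slow collective motion of
#'   a confluent epithelium.
#' @param drift_direction unit-free direction `c(dx, dy)` of the drift.
#' @param junction_amplitude_schedule numeric vector, one junction
#'   fluorescence amplitude scale per frame (recycled); emulates e.g. a
#'   ramp of junctional adhesion-protein recruitment.
#' @param junction_halfwidth half-width of the junction fluorescence band
#'   around cell boundaries, in pixels.
#' @param noise_sd additive Gaussian noise, gray levels.
#' @param bit_depth clip range of rendered images.
#' @param seed integer seed (bit-identical sequences for identical specs).
#' @return Object of class `monolayer_spec`.
#' @export
monolayer_spec <- function(n_cells = 60, image_size = c(400, 400),
                           calibration = 0.55, drift_speed = 0,
                           drift_direction = c(1, 0),
                           junction_amplitude_schedule = 1,
                           junction_halfwidth = 2.5,
                           noise_sd = 2, bit_depth = 8, seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  stop_if_not_scalar_num(calibration, "calibration", positive = TRUE)
  stop_if_not_scalar_num(drift_speed, "drift_speed", nonneg = TRUE)
  stop_if_not_scalar_num(junction_halfwidth, "junction_halfwidth",
                         positive = TRUE)
  stop_if_not_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (!is.numeric(junction_amplitude_schedule) ||
      any(junction_amplitude_schedule < 0))
    stop("`junction_amplitude_schedule` must be nonnegative", call. = FALSE)
  structure(list(
    n_cells = as.integer(n_cells),
    image_size = as.integer(round(image_size)),
    calibration = calibration,
    drift_speed = drift_speed,
    drift_direction = drift_direction / sqrt(sum(drift_direction^2)),
    junction_amplitude_schedule = junction_amplitude_schedule,
    junction_halfwidth = junction_halfwidth,
    noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  ), class = "monolayer_spec")
}

# Seed points with blue-noise spacing (dart throwing) so cells have
# comparable sizes, as in a confluent epithelium.
.monolayer_seeds <- function(n, w, h) {
  target_r <- 0.6 * sqrt(w * h / n)
  px <- numeric(0); py <- numeric(0)
  tries <- 0L
  while (length(px) < n && tries < 200L * n) {
    x <- stats::runif(1, 1, w); y <- stats::runif(1, 1, h)
    if (!length(px) || min((px - x)^2 + (py - y)^2) > target_r^2) {
      px <- c(px, x); py <- c(py, y)
    }
    tries <- tries + 1L
  }
  while (length(px) < n) {  # fill up regardless if dart throwing stalls
    px <- c(px, stats::runif(1, 1, w)); py <- c(py, stats::runif(1, 1, h))
  }
  cbind(px, py)
}

# Distance-to-seed fields: label (nearest seed), d1, d2 (first and second
# nearest distances). Vectorized over pixels, looped over cells.
.voronoi_fields <- function(seeds, w, h) {
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  d1 <- matrix(Inf, h, w); d2 <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  for (k in seq_len(nrow(seeds))) {
    d <- (X - seeds[k, 1])^2 + (Y - seeds[k, 2])^2
    closer <- d < d1
    d2[closer] <- d1[closer]
    d2[!closer] <- pmin(d2[!closer], d[!closer])
    d1[closer] <- d[closer]
    lab[closer] <- k
  }
  list(label = lab, d1 = sqrt(d1), d2 = sqrt(d2))
}

# Render relaxed-state phase/fluorescence/label images from seed points.
# `granules` are material-attached bright/dark cytoplasmic speckles
# (positions in the same drifting frame as the seeds): phase-contrast
# images of epithelia carry this granularity, and window correlation
# needs texture with a correlation length well below the window size.
.render_monolayer <- function(seeds, spec, cell_shade, amp, granules = NULL) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  vf <- .voronoi_fields(seeds, w, h)
  # distance of a pixel to the Voronoi boundary is (d2 - d1) / 2
  bdist <- (vf$d2 - vf$d1) / 2
  hw <- spec$junction_halfwidth
  junction <- exp(-bdist^2 / (2 * (hw / 2)^2))
  junction[bdist > hw] <- 0  # fluorescence strictly confined to the band
  nucleus_r <- 0.22 * sqrt(w * h / spec$n_cells)
  nucleus <- exp(-vf$d1^2 / (2 * nucleus_r^2))
  phase <- matrix(cell_shade[vf$label], h, w) +
    60 * nucleus - 45 * junction
  if (!is.null(granules))
    phase <- render_spots(phase, granules[, 1], granules[, 2], 1.2,
                          granules[, 3])
  fluor <- amp * 150 * junction
  list(phase = phase, fluor = fluor, label = vf$label)
}

#' Generate a synthetic monolayer time-lapse
#'
#' Produces phase-contrast-like, junction-fluorescence and label-mask
#' stacks following an [actuation_schedule()]. Relaxed frames are rendered
#' from the drifted tessellation; stretched frames are the corresponding
#' relaxed rendering warped by the frame's deformation spec (bicubic for
#' intensities, nearest-neighbor for labels, label 0 / background fill for
#' out-of-frame content). Cell labels persist across frames.
#'
#' @param spec a [monolayer_spec()].
#' @param schedule an [actuation_schedule()]; times in seconds.
#' @return A list of class `monolayer_sequence` with elements `phase`,
#'   `fluor`, `label` (each a list of matrices, one per frame), `schedule`,
#'   `spec`, and `seeds0` (the reference seed positions).
#' @examples
#' sp <- monolayer_spec(n_cells = 20, image_size = c(120, 120), seed = 3)
#' sched <- actuation_schedule(c(0, 10), c("relaxed", "relaxed"))
#' seqs <- generate_monolayer_sequence(sp, sched)
#' @export
generate_monolayer_sequence <- function(spec, schedule) {
  stopifnot(inherits(spec, "monolayer_spec"))
  stopifnot(inherits(schedule, "actuation_schedule"))
  if (nrow(schedule) < 1L)
    stop("schedule must contain at least one frame", call. = FALSE)
  w <- spec$image_size[1]; h <- spec$image_size[2]
  nT <- nrow(schedule)
  amps <- rep_len(spec$junction_amplitude_schedule, nT)

  with_seed(spec$seed, {
    seeds0 <- .monolayer_seeds(spec$n_cells, w, h)
    cell_shade <- stats::runif(spec$n_cells, 90, 150)
    # cytoplasmic granularity, attached to the drifting material frame
    n_gran <- stats::rpois(1L, 0.012 * w * h)
    granules0 <- cbind(stats::runif(n_gran, 0.5, w + 0.5),
                       stats::runif(n_gran, 0.5, h + 0.5),
                       stats::runif(n_gran, -30, 30))
    noise <- if (spec$noise_sd > 0)
      lapply(seq_len(nT), function(i)
        matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w))
    else NULL

    drift_px_per_s <- spec$drift_speed / 3600 / spec$calibration
    phase <- fluor <- label <- vector("list", nT)
    last_key <- NULL; last_render <- NULL
    for (i in seq_len(nT)) {
      t_i <- schedule$time[i]
      shift <- t_i * drift_px_per_s * spec$drift_direction
      seeds <- seeds0 + matrix(shift, nrow(seeds0), 2, byrow = TRUE)
      granules <- granules0
      granules[, 1] <- granules[, 1] + shift[1]
      granules[, 2] <- granules[, 2] + shift[2]
      key <- c(t_i * drift_px_per_s, amps[i])
      if (is.null(last_key) || !isTRUE(all.equal(key, last_key))) {
        last_render <- .render_monolayer(seeds, spec, cell_shade, amps[i],
                                         granules)
        last_key <- key
      }
      rend <- last_render
      if (schedule$state[i] == "stretched") {
        dspec <- schedule$deformation[[i]]
        ph <- apply_deformation(rend$phase, dspec,
                                fill = stats::median(rend$phase))$warped
        fl <- apply_deformation(rend$fluor, dspec, fill = 0)$warped
        lb <- apply_deformation(rend$label, dspec, interp = "nearest",
                                fill = 0)$warped
      } else {
        ph <- rend$phase; fl <- rend$fluor; lb <- rend$label
      }
      if (!is.null(noise)) {
        ph <- ph + noise[[i]]
        fl <- fl + noise[[i]]
      }
      phase[[i]] <- clip_gray(ph, spec$bit_depth)
      fluor[[i]] <- clip_gray(fl, spec$bit_depth)
      label[[i]] <- matrix(as.integer(lb), h, w)
    }
    structure(list(phase = phase, fluor = fluor, label = label,
                   schedule = schedule, spec = spec, seeds0 = seeds0),
              class = "monolayer_sequence")
  })
}
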