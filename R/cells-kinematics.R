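# Monolayer kinematics: mean cell speed from consecutive unstretched
# phase-contrast frames by single-pass windowed correlation (PIV-style).
# Only unstretched-to-unstretched comparisons are meaningful for motility
# -- stretch displacement must never contaminate the speed estimate.

#' Mean cell speed from a phase-contrast time-lapse
#'
#' Consecutive unstretched frames are compared by single-pass windowed
#' FFT cross-correlation (default 32 px windows with 16 px overlap); the
#' mean displacement magnitude over the field of view divided by the
#' frame interval gives the mean cell speed.
#'
#' @param stack list of phase-contrast matrices, all unstretched frames at
#'   a constant interval.
#' @param dt frame interval in minutes (> 0).
#' @param calibration micrometres per pixel.
#' @param window interrogation window size in px.
#' @param overlap window overlap in px (grid step is `window - overlap`).
#' @param peak_ratio_min validity threshold on the correlation peak ratio;
#'   windows without usable texture are excluded from the average.
#' @param highpass_sigma Gaussian sigma (px) of the high-pass (unsharp)
#'   prefilter. Phase-contrast frames carry intensity structure much
#'   larger than the interrogation window (cell bodies, illumination);
#'   removing it before correlating suppresses the zero-lag envelope bias
#'   on subpixel displacements. `0` disables the prefilter.
#' @return Data frame of class `speed_series` with columns `time`
#'   (hours, time of the first frame of each pair), `mean_speed` (µm/h)
#'   and `normalized` (ratio to the first time point).
#' @examples
#' frames <- replicate(3, matrix(runif(64^2), 64, 64), simplify = FALSE)
#' mean_cell_speed(frames, dt = 2, calibration = 0.55)
#' @export
mean_cell_speed <- function(stack, dt = 2, calibration = 0.55,
                            window = 32, overlap = 16,
                            peak_ratio_min = 1.3,
                            highpass_sigma = window / 4) {
  if (!is.list(stack) || length(stack) < 2)
    stop("`stack` must be a list of at least two frames", call. = FALSE)
  stop_if_not_scalar_num(dt, "dt", positive = TRUE)
  stop_if_not_scalar_num(calibration, "calibration", positive = TRUE)
  step <- window - overlap
  if (step < 1) stop("`overlap` must be smaller than `window`", call. = FALSE)
  if (highpass_sigma > 0)
    stack <- lapply(stack, function(m)
      m - as.matrix(EBImage::gblur(m, sigma = highpass_sigma)))
  n <- length(stack) - 1L
  speeds <- numeric(n)
  for (k in seq_len(n)) {
    a <- stack[[k]]; b <- stack[[k + 1L]]
    if (!all(dim(a) == dim(b)))
      stop("all frames must share dimensions", call. = FALSE)
    h <- nrow(a); w <- ncol(a)
    starts_x <- seq(1L, w - window + 1L, by = step)
    starts_y <- seq(1L, h - window + 1L, by = step)
    mags <- ratios <- c()
    for (sy in starts_y) for (sx in starts_x) {
      rows <- sy:(sy + window - 1L); cols <- sx:(sx + window - 1L)
      r <- .correlate_window(a[rows, cols], b[rows, cols], window / 3,
                             apodize = TRUE)
      if (!is.na(r[1])) {
        mags <- c(mags, sqrt(r[1]^2 + r[2]^2))
        ratios <- c(ratios, r[4])
      }
    }
    usable <- is.finite(ratios) & ratios >= peak_ratio_min
    if (!any(usable)) usable <- rep(TRUE, length(mags))
    # displacement [um] over dt [min] -> speed [um/h]
    speeds[k] <- mean(mags[usable]) * calibration / dt * 60
  }
  out <- data.frame(time = (seq_len(n) - 1) * dt / 60,
                    mean_speed = speeds,
                    normalized = if (speeds[1] > 0) speeds / speeds[1]
                                 else rep(NA_real_, n))
  class(out) <- c("speed_series", "data.frame")
  out
}
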