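# Digital image correlation: displacement fields between relaxed and
# stretched image pairs by multi-pass windowed FFT cross-correlation with
# window deformation. Each stretched frame is referred to the relaxed
# frame of its own stretch period ("A+B, C+D" pairing), images are
# contrast-normalized by CLAHE, and correlation runs through a coarse-to-
# fine pass schedule (default 320/160/80 px windows with 50% overlap).

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit, used to normalize
#' speckle or phase-contrast texture before correlation. A thin wrapper
#' around [EBImage::clahe()] operating on plain matrices in native gray
#' levels.
#'
#' @param image numeric matrix.
#' @param window tile size in pixels (>= 2); a window larger than the
#'   image falls back to a single-tile equalization with a warning.
#' @param limit contrast clip limit (multiples of the uniform bin height).
#' @return Matrix of the same dimensions, rescaled to the input range.
#' @export
clahe <- function(image, window = 64, limit = 4) {
  check_image(image)
  if (window < 2) stop("`window` must be >= 2", call. = FALSE)
  rng <- range(image)
  if (diff(rng) == 0) return(image)  # constant image: nothing to equalize
  nx <- floor(ncol(image) / window)
  ny <- floor(nrow(image) / window)
  if (nx < 2 || ny < 2) {
    if (window > min(dim(image)))
      warning("CLAHE window exceeds image size; using single-tile equalization")
    nx <- max(nx, 2L); ny <- max(ny, 2L)
  }
  x01 <- (image - rng[1]) / diff(rng)
  # EBImage tiles must divide the image evenly; pad by edge replication
  h <- nrow(x01); w <- ncol(x01)
  wp <- ceiling(w / nx) * nx; hp <- ceiling(h / ny) * ny
  if (wp > w) x01 <- x01[, c(seq_len(w), rep(w, wp - w))]
  if (hp > h) x01 <- x01[c(seq_len(h), rep(h, hp - h)), ]
  eq <- as.matrix(EBImage::clahe(x01, nx = nx, ny = ny, limit = limit))
  eq <- eq[seq_len(h), seq_len(w)]
  rng[1] + eq * diff(rng)
}

#' Interrogation-window pass schedule
#'
#' @param windows strictly decreasing window sizes in pixels.
#' @param steps grid step per pass; defaults to 50% overlap
#'   (`windows / 2`). Each step must not exceed its window.
#' @return Object of class `pass_schedule`.
#' @examples
#' pass_schedule()                 # 320/160, 160/80, 80/40 px
#' pass_schedule(c(64, 32))        # a lighter two-pass schedule
#' @export
pass_schedule <- function(windows = c(320, 160, 80), steps = windows / 2) {
  if (length(windows) < 1L || any(diff(windows) >= 0))
    stop("`windows` must be strictly decreasing", call. = FALSE)
  if (length(steps) != length(windows) || any(steps > windows) ||
      any(steps < 1))
    stop("`steps` must satisfy 1 <= step <= window per pass", call. = FALSE)
  structure(list(windows = as.integer(windows), steps = as.integer(steps)),
            class = "pass_schedule")
}

#' Relaxed/stretched image pair
#'
#' @param reference relaxed-state image (matrix).
#' @param deformed stretched-state image of equal dimensions.
#' @param calibration micrometres per pixel (> 0).
#' @param pair_time acquisition time of the pair in seconds.
#' @return Object of class `image_pair`.
#' @export
image_pair <- function(reference, deformed, calibration = 1, pair_time = 0) {
  check_image(reference, "reference"); check_image(deformed, "deformed")
  if (!all(dim(reference) == dim(deformed)))
    stop("reference and deformed images must have equal dimensions",
         call. = FALSE)
  stop_if_not_scalar_num(calibration, "calibration", positive = TRUE)
  structure(list(reference = reference, deformed = deformed,
                 calibration = calibration, pair_time = pair_time),
            class = "image_pair")
}

#' Pair stretched frames with the relaxed frame of their own period
#'
#' Implements period-wise pairwise sequencing: every stretched frame is
#' referred to the most recent relaxed frame, and the relaxed reference is
#' updated each period (pattern "A+B, C+D"). A stretched frame with no
#' unconsumed relaxed frame before it is skipped with a warning.
#'
#' @param states character vector of frame states (`"relaxed"` /
#'   `"stretched"`), or an [actuation_schedule()].
#' @return Data frame with columns `ref` and `def` (frame indices) and,
#'   when a schedule is given, `time` (time of the stretched frame) and
#'   `mode`.
#' @examples
#' pair_frames(c("relaxed", "stretched", "relaxed", "stretched"))
#' @export
pair_frames <- function(states) {
  sched <- NULL
  if (inherits(states, "actuation_schedule")) {
    sched <- states
    states <- sched$state
  }
  if (!all(states %in% c("relaxed", "stretched")))
    stop('states must be "relaxed" or "stretched"', call. = FALSE)
  ref <- def <- integer(0)
  last_relaxed <- NA_integer_
  for (i in seq_along(states)) {
    if (states[i] == "relaxed") {
      last_relaxed <- i
    } else {
      if (is.na(last_relaxed)) {
        warning(sprintf(
          "stretched frame %d has no relaxed frame in its period; skipped", i))
      } else {
        ref <- c(ref, last_relaxed); def <- c(def, i)
        last_relaxed <- NA_integer_  # reference consumed, updated next period
      }
    }
  }
  out <- data.frame(ref = ref, def = def)
  if (!is.null(sched) && nrow(out)) {
    out$time <- sched$time[def]
    out$mode <- sched$mode[def]
  }
  out
}

# --- correlation engine -----------------------------------------------------

# Cross-correlate two equally sized zero-meaned windows via FFT and locate
# the displacement of `b` relative to `a` with subpixel refinement.
# Returns c(u, v, peak, ratio) or NA's when no usable peak exists.
.correlate_window <- function(a, b, max_shift, subpixel = "gaussian",
                              apodize = FALSE) {
  a <- a - mean(a); b <- b - mean(b)
  if (apodize) {
    # Hann apodization: features fade at the window edge instead of being
    # truncated; hard truncation correlates at zero lag and biases small
    # displacements toward zero. Used for single-pass measurements; the
    # multi-pass chain converges to near-zero residual where the bias
    # vanishes.
    wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nrow(a)) - 0.5) / nrow(a)))
    wc <- 0.5 * (1 - cos(2 * pi * (seq_len(ncol(a)) - 0.5) / ncol(a)))
    W <- outer(wr, wc)
    a <- a * W; b <- b * W
  }
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0) return(c(NA, NA, NA, NA))
  n <- nrow(a)
  C <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    (length(a) * sa * sb)
  C <- fftshift2(C)
  c0 <- floor(n / 2) + 1L
  # restrict the admissible shift to avoid circular-wrap aliases
  lag <- seq_len(n) - c0
  ok <- abs(lag) <= max_shift
  Cm <- C
  Cm[!ok, ] <- -Inf
  Cm[, !ok] <- -Inf
  imax <- arrayInd(which.max(Cm), dim(Cm))
  peak <- Cm[imax]
  if (!is.finite(peak) || peak <= 0) return(c(NA, NA, NA, NA))
  # second-highest peak outside a 3 px exclusion zone around the first
  Cm2 <- Cm
  r0 <- max(1L, imax[1] - 3L):min(n, imax[1] + 3L)
  c0s <- max(1L, imax[2] - 3L):min(n, imax[2] + 3L)
  Cm2[r0, c0s] <- -Inf
  second <- max(Cm2)
  ratio <- if (is.finite(second) && second > 0) peak / second else Inf
  # 3-point subpixel fit per axis (Gaussian; parabolic fallback when a
  # neighbor is non-positive), skipped on the plane border
  sub_fit <- function(cm, c0v, cp) {
    if (subpixel == "gaussian" && cm > 0 && cp > 0 && c0v > 0) {
      d <- (log(cm) - log(cp)) / (2 * log(cm) - 4 * log(c0v) + 2 * log(cp))
      if (is.finite(d) && abs(d) <= 1) return(d)
    }
    den <- 2 * (cm - 2 * c0v + cp)
    if (den == 0) return(0)
    d <- (cm - cp) / den
    if (!is.finite(d) || abs(d) > 1) 0 else d
  }
  dx <- dy <- 0
  if (imax[2] > 1 && imax[2] < n)
    dx <- sub_fit(C[imax[1], imax[2] - 1], peak, C[imax[1], imax[2] + 1])
  if (imax[1] > 1 && imax[1] < n)
    dy <- sub_fit(C[imax[1] - 1, imax[2]], peak, C[imax[1] + 1, imax[2]])
  c(imax[2] - c0 + dx, imax[1] - c0 + dy, peak, ratio)
}

# Normalized median test (universal outlier detection) on a gridded
# vector field. Returns a logical matrix of outliers.
.median_outliers <- function(u, v, threshold = 2, eps = 0.1) {
  nr <- nrow(u); nc <- ncol(u)
  out <- matrix(FALSE, nr, nc)
  if (nr * nc < 4) return(out)  # too few neighbors to judge
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    # full 3x3 block clamped inside the grid: border points are judged
    # against 8 neighbors too, otherwise the deviation of a corner point
    # on a smooth gradient field divides by a vanishing MAD
    i0 <- min(max(i - 1L, 1L), max(nr - 2L, 1L))
    j0 <- min(max(j - 1L, 1L), max(nc - 2L, 1L))
    ri <- i0:min(i0 + 2L, nr); ci <- j0:min(j0 + 2L, nc)
    nu <- u[ri, ci, drop = FALSE]; nv <- v[ri, ci, drop = FALSE]
    nu[which(ri == i), which(ci == j)] <- NA  # drop the center vector
    sel <- !is.na(nu) & !is.na(nv)
    nu <- nu[sel]; nv <- nv[sel]
    if (length(nu) < 2) next
    if (is.na(u[i, j]) || is.na(v[i, j])) { out[i, j] <- TRUE; next }
    mu <- stats::median(nu); mv <- stats::median(nv)
    ru <- abs(u[i, j] - mu) / (stats::median(abs(nu - mu)) + eps)
    rv <- abs(v[i, j] - mv) / (stats::median(abs(nv - mv)) + eps)
    if (sqrt(ru^2 + rv^2) > threshold) out[i, j] <- TRUE
  }
  out
}

# 3x3 moving-average smoothing of a gridded field (edge-truncated).
# Applied to the predictor between passes: window-averaged correlation
# cannot see grid-scale error modes, which would otherwise persist
# through the passes; mild smoothing damps them.
.smooth33 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    # truncate rather than replicate at edges: skip shifted-out cells
    rsel <- seq_len(nr) + di >= 1 & seq_len(nr) + di <= nr
    csel <- seq_len(nc) + dj >= 1 & seq_len(nc) + dj <= nc
    acc[rsel, csel] <- acc[rsel, csel] + m[ri[rsel], cj[csel]]
    cnt[rsel, csel] <- cnt[rsel, csel] + 1
  }
  acc / cnt
}

# Replace NA vectors by the median of their valid 3x3 neighbors (0 if none).
.fill_median <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  bad <- which(is.na(u), arr.ind = TRUE)
  if (!nrow(bad)) return(u)
  filled <- u
  for (k in seq_len(nrow(bad))) {
    i <- bad[k, 1]; j <- bad[k, 2]
    nb <- u[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    nb <- nb[!is.na(nb)]
    filled[i, j] <- if (length(nb)) stats::median(nb) else 0
  }
  filled
}

#' Estimate a displacement field between an image pair
#'
#' Multi-pass windowed FFT cross-correlation ("window deformation" PIV/DIC).
#' Per pass, zero-mean normalized cross-correlation is computed per
#' interrogation window, the correlation peak is refined to subpixel
#' precision by a 3-point Gaussian fit (parabolic fallback), vectors
#' failing the peak-ratio criterion or the normalized median test are
#' invalidated and replaced by the local median, and the deformed image is
#' warped by the current field before the next (finer) pass. Boundary
#' windows extending outside the image are dropped, not padded.
#'
#' @param pair an [image_pair()] (images must exceed the first-pass window).
#' @param schedule a [pass_schedule()]; the final-pass step sets the output
#'   grid spacing.
#' @param preprocess apply [clahe()] to both images first.
#' @param clahe_window CLAHE tile size in pixels.
#' @param peak_ratio_min minimum first/second correlation-peak ratio for a
#'   vector to count as valid.
#' @param outlier_threshold normalized median-test threshold.
#' @param final_refinements extra correlation iterations at the final pass
#'   after window deformation has converged coarsely.
#' @return Object of class `displacement_field`: grid coordinates in px
#'   (`grid_x`, `grid_y`) and µm (`x_um`, `y_um`), displacement components
#'   `u`, `v` in px and `u_um`, `v_um` in µm (matrices `[y-grid, x-grid]`),
#'   a logical `valid` mask (replaced/low-confidence vectors are flagged
#'   `FALSE`, never silently passed off as measurements), and the
#'   calibration.
#' @examples
#' img <- generate_speckle(speckle_spec(image_size = c(192, 192), seed = 5))
#' shifted <- apply_deformation(img, deformation_spec(F = diag(2),
#'   center = c(96, 96)))  # identity: zero field
#' fld <- estimate_displacement(image_pair(img, shifted$warped),
#'   pass_schedule(c(64, 32)))
#' @export
estimate_displacement <- function(pair, schedule = pass_schedule(),
                                  preprocess = TRUE, clahe_window = 64,
                                  peak_ratio_min = 1.3,
                                  outlier_threshold = 2,
                                  final_refinements = 1) {
  stopifnot(inherits(pair, "image_pair"), inherits(schedule, "pass_schedule"))
  ref <- pair$reference; def <- pair$deformed
  if (min(dim(ref)) < schedule$windows[1])
    stop("images must be larger than the first-pass window", call. = FALSE)
  if (preprocess) {
    ref <- clahe(ref, clahe_window)
    def <- clahe(def, clahe_window)
  }
  h <- nrow(ref); w <- ncol(ref)
  fill_val <- mean(def)
  px_X <- matrix(rep(seq_len(w), each = h), h, w)
  px_Y <- matrix(rep(seq_len(h), times = w), h, w)

  n_pass <- length(schedule$windows)
  passes <- c(seq_len(n_pass), rep(n_pass, max(0L, final_refinements)))

  u <- v <- NULL; gx <- gy <- NULL
  valid <- NULL
  for (p in passes) {
    win <- schedule$windows[p]; step <- schedule$steps[p]
    starts_x <- seq(1L, w - win + 1L, by = step)
    starts_y <- seq(1L, h - win + 1L, by = step)
    cx <- starts_x + (win - 1) / 2
    cy <- starts_y + (win - 1) / 2
    # predictor field: previous pass, lightly smoothed, interpolated
    coverage <- NULL
    if (!is.null(u)) {
      us <- .smooth33(u); vs <- .smooth33(v)
      Upx <- grid_bilinear(gx, gy, us, px_X, px_Y)
      Vpx <- grid_bilinear(gx, gy, vs, px_X, px_Y)
      map_x <- px_X + Upx; map_y <- px_Y + Vpx
      inside <- map_x >= 1 & map_x <= w & map_y >= 1 & map_y <= h
      defw <- warp_by_map(def, map_x, map_y, fill = fill_val)
      cxm <- outer(cy, cx, function(a, b) b)
      cym <- outer(cy, cx, function(a, b) a)
      u0 <- grid_bilinear(gx, gy, us, cxm, cym)
      v0 <- grid_bilinear(gx, gy, vs, cxm, cym)
      coverage <- matrix(NA_real_, length(cy), length(cx))
    } else {
      defw <- def
      inside <- NULL
      u0 <- v0 <- matrix(0, length(cy), length(cx))
    }
    du <- dv <- matrix(NA_real_, length(cy), length(cx))
    ratio <- matrix(NA_real_, length(cy), length(cx))
    max_shift <- win / 3
    for (iy in seq_along(starts_y)) {
      rows <- starts_y[iy]:(starts_y[iy] + win - 1L)
      for (ix in seq_along(starts_x)) {
        cols <- starts_x[ix]:(starts_x[ix] + win - 1L)
        if (!is.null(inside)) {
          cov <- mean(inside[rows, cols])
          coverage[iy, ix] <- cov
          if (cov < 0.6) next  # window material mostly left the frame
        }
        res <- .correlate_window(ref[rows, cols], defw[rows, cols], max_shift)
        du[iy, ix] <- res[1]; dv[iy, ix] <- res[2]; ratio[iy, ix] <- res[4]
      }
    }
    # The peak-ratio criterion gates validity only at the final pass: in
    # coarse passes the peak is legitimately smeared by in-window strain,
    # so the best peak is kept as predictor and cleaned by the median test.
    confident <- if (p == n_pass)
      !is.na(du) & !is.na(ratio) & ratio >= peak_ratio_min
    else !is.na(du)
    out <- .median_outliers(du, dv, outlier_threshold)
    ok <- confident & !out
    du[!ok] <- NA; dv[!ok] <- NA
    du <- .fill_median(du); dv <- .fill_median(dv)
    u <- u0 + du; v <- v0 + dv
    gx <- cx; gy <- cy
    valid <- ok
  }
  cal <- pair$calibration
  structure(list(
    grid_x = gx, grid_y = gy,
    x_um = gx * cal, y_um = gy * cal,
    u = u, v = v, u_um = u * cal, v_um = v * cal,
    valid = valid, calibration = cal,
    pair_time = pair$pair_time,
    step = schedule$steps[length(schedule$steps)]
  ), class = "displacement_field")
}

#' Convert a displacement field to a velocity field
#'
#' With a (pseudo-)time step of 1 s the velocity field is numerically equal
#' to the displacement field, the convention used when correlation is run
#' purely to measure displacements.
#'
#' @param field a `displacement_field`.
#' @param dt time step in seconds (> 0).
#' @return The field with `u`, `v`, `u_um`, `v_um` divided by `dt` and a
#'   `velocity = TRUE` marker.
#' @export
displacement_to_velocity <- function(field, dt = 1) {
  stopifnot(inherits(field, "displacement_field"))
  stop_if_not_scalar_num(dt, "dt", positive = TRUE)
  for (f in c("u", "v", "u_um", "v_um")) field[[f]] <- field[[f]] / dt
  field$velocity <- TRUE
  field$dt <- dt
  field
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d vectors (grid step %d px, %.3g um/px)\n",
              ncol(x$u), nrow(x$u), x$step, x$calibration))
  cat(sprintf("  u: [%.3f, %.3f] px   v: [%.3f, %.3f] px   valid: %.1f%%\n",
              min(x$u, na.rm = TRUE), max(x$u, na.rm = TRUE),
              min(x$v, na.rm = TRUE), max(x$v, na.rm = TRUE),
              100 * mean(x$valid)))
  invisible(x)
}

#' Quiver plot of a displacement field
#'
#' @param x a `displacement_field`.
#' @param scale arrow scale factor (px of plot per px of displacement).
#' @param ... passed to [graphics::image()].
#' @export
plot.displacement_field <- function(x, scale = 5, ...) {
  mag <- sqrt(x$u^2 + x$v^2) * x$calibration
  graphics::image(x$x_um, x$y_um, t(mag), col = grDevices::hcl.colors(64),
                  xlab = "x [um]", ylab = "y [um]",
                  main = "displacement magnitude [um]", ...)
  sel <- which(x$valid, arr.ind = TRUE)
  if (nrow(sel)) {
    x0 <- x$x_um[sel[, 2]]; y0 <- x$y_um[sel[, 1]]
    graphics::arrows(x0, y0,
                     x0 + scale * x$u_um[sel], y0 + scale * x$v_um[sel],
                     length = 0.03)
  }
  invisible(x)
}
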