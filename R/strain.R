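# Green-Lagrange strain analysis of displacement fields, spatial
# averaging over a region of interest, baseline-normalized time series,
# long-term stability metrics, and the closed-form Poisson membrane
# deflection.

#' Green–Lagrange strain field from a displacement field
#'
#' Displacement gradients are taken by central differences on the
#' calibrated (µm) grid, one-sided at the grid edges, and assembled into
#' the finite-deformation Green–Lagrange tensor
#' `E = 1/2 (grad U + grad U^T + grad U^T grad U)`, equivalently
#' `1/2 (F^T F - I)` with `F = I + grad U`. Strain is dimensionless
#' regardless of the pixel calibration because gradients are formed in
#' physical units. Grid points carrying invalid displacement vectors are
#' returned as `NA`, and a border margin of grid points is cropped to
#' ignore boundary artifacts inherent to windowed correlation.
#'
#' @param field a `displacement_field` with at least 3x3 valid vectors.
#' @param crop_margin border grid points removed from every side.
#' @param exclude a logical matrix (same grid as `field`) of additional
#'   points to drop, e.g. defocused regions; `NULL` for none.
#' @return Object of class `strain_field`: matrices `Exx`, `Eyy`, `Exy`,
#'   coordinates `x_um`, `y_um`, and the applied `crop_margin`.
#' @examples
#' # a pure 12%/-4% homogeneous stretch has Exx = 0.1272, Eyy = -0.0392
#' @export
green_lagrange <- function(field, crop_margin = 1, exclude = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  valid <- field$valid
  if (!is.null(exclude)) valid <- valid & !exclude
  if (sum(valid) < 9 || nrow(field$u) < 3 || ncol(field$u) < 3)
    stop("displacement field must contain at least 3x3 valid vectors",
         call. = FALSE)
  u <- field$u_um; v <- field$v_um
  gx <- field$x_um; gy <- field$y_um

  ux <- .ddx(u, gx); uy <- .ddy(u, gy)
  vx <- .ddx(v, gx); vy <- .ddy(v, gy)
  Exx <- ux + 0.5 * (ux^2 + vx^2)
  Eyy <- vy + 0.5 * (uy^2 + vy^2)
  Exy <- 0.5 * (uy + vx) + 0.5 * (ux * uy + vx * vy)
  Exx[!valid] <- NA; Eyy[!valid] <- NA; Exy[!valid] <- NA

  m <- as.integer(crop_margin)
  if (m > 0) {
    ri <- seq_len(nrow(Exx)); ci <- seq_len(ncol(Exx))
    if (length(ri) <= 2 * m || length(ci) <= 2 * m)
      stop("crop_margin leaves no grid points", call. = FALSE)
    ri <- ri[(m + 1):(length(ri) - m)]; ci <- ci[(m + 1):(length(ci) - m)]
    Exx <- Exx[ri, ci]; Eyy <- Eyy[ri, ci]; Exy <- Exy[ri, ci]
    gx <- gx[ci]; gy <- gy[ri]
  }
  structure(list(Exx = Exx, Eyy = Eyy, Exy = Exy,
                 x_um = gx, y_um = gy, crop_margin = m),
            class = "strain_field")
}

# d/dx along columns (x = grid columns), central interior, one-sided ends.
.ddx <- function(Z, x) {
  nc <- ncol(Z)
  D <- matrix(NA_real_, nrow(Z), nc)
  if (nc >= 3)
    D[, 2:(nc - 1)] <- (Z[, 3:nc] - Z[, 1:(nc - 2)]) /
      rep(x[3:nc] - x[1:(nc - 2)], each = nrow(Z))
  D[, 1] <- (Z[, 2] - Z[, 1]) / (x[2] - x[1])
  D[, nc] <- (Z[, nc] - Z[, nc - 1]) / (x[nc] - x[nc - 1])
  D
}

.ddy <- function(Z, y) {
  nr <- nrow(Z)
  D <- matrix(NA_real_, nr, ncol(Z))
  if (nr >= 3)
    D[2:(nr - 1), ] <- (Z[3:nr, ] - Z[1:(nr - 2), ]) /
      (y[3:nr] - y[1:(nr - 2)])
  D[1, ] <- (Z[2, ] - Z[1, ]) / (y[2] - y[1])
  D[nr, ] <- (Z[nr, ] - Z[nr - 1, ]) / (y[nr] - y[nr - 1])
  D
}

#' Spatially average a strain field over a region of interest
#'
#' Averages each strain component over the grid points falling inside a
#' rectangular region of interest (µm), excluding `NA` entries (invalid
#' vectors and cropped borders are already `NA`/removed in the
#' `strain_field`).
#'
#' @param strain a [green_lagrange()] strain field.
#' @param roi region `c(xmin, xmax, ymin, ymax)` in µm, or `NULL` for the
#'   whole (already border-cropped) field.
#' @return List with `avg_Exx`, `avg_Eyy`, `avg_Exy` and `n_points`, the
#'   number of contributing grid points per component (`n_points` counts
#'   in-ROI grid positions).
#' @export
crop_and_average <- function(strain, roi = NULL) {
  stopifnot(inherits(strain, "strain_field"))
  selx <- rep(TRUE, length(strain$x_um)); sely <- rep(TRUE, length(strain$y_um))
  if (!is.null(roi)) {
    if (length(roi) != 4) stop("`roi` must be c(xmin, xmax, ymin, ymax)",
                               call. = FALSE)
    selx <- strain$x_um >= roi[1] & strain$x_um <= roi[2]
    sely <- strain$y_um >= roi[3] & strain$y_um <= roi[4]
  }
  if (!any(selx) || !any(sely))
    stop("region of interest contains no grid points", call. = FALSE)
  sub <- function(M) M[sely, selx, drop = FALSE]
  Exx <- sub(strain$Exx); Eyy <- sub(strain$Eyy); Exy <- sub(strain$Exy)
  if (all(is.na(Exx)))
    stop("no valid strain data inside the region of interest", call. = FALSE)
  list(avg_Exx = mean(Exx, na.rm = TRUE),
       avg_Eyy = mean(Eyy, na.rm = TRUE),
       avg_Exy = mean(Exy, na.rm = TRUE),
       n_points = length(Exx))
}

#' Strain time series
#'
#' @param times times in seconds.
#' @param avg_Exx,avg_Eyy,avg_Exy spatially averaged strain components per
#'   time point (`avg_Exy` optional, defaults to 0).
#' @return Data frame of class `strain_series`.
#' @export
strain_series <- function(times, avg_Exx, avg_Eyy, avg_Exy = 0) {
  n <- length(times)
  if (length(avg_Exx) != n || length(avg_Eyy) != n)
    stop("series components must match `times` in length", call. = FALSE)
  s <- data.frame(time = as.numeric(times), avg_Exx = avg_Exx,
                  avg_Eyy = avg_Eyy, avg_Exy = rep_len(avg_Exy, n))
  class(s) <- c("strain_series", "data.frame")
  s
}

#' Normalize a strain series to its first time point
#'
#' Divides the averaged xx and yy strains of every time frame by their
#' value at the first frame (the t = 0 baseline), so the normalized series
#' starts at exactly 1 and drifts express relative change.
#'
#' @param series a [strain_series()].
#' @return The series with `norm_Exx` and `norm_Eyy` columns added.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "strain_series"))
  if (nrow(series) < 1) stop("empty series", call. = FALSE)
  if (series$avg_Exx[1] == 0 || series$avg_Eyy[1] == 0)
    stop("cannot normalize: strain at t = 0 is zero", call. = FALSE)
  series$norm_Exx <- series$avg_Exx / series$avg_Exx[1]
  series$norm_Eyy <- series$avg_Eyy / series$avg_Eyy[1]
  series
}

#' Long-term strain stability metrics
#'
#' Quantifies how stable a cyclically applied strain stays over a long
#' recording: the maximum relative fluctuation of the normalized series
#' with respect to the first stretch cycle (`max |norm(t) - 1|`, per
#' component) and the maximum absolute change of the averaged strains
#' from their initial values, over all components.
#'
#' @param series a [strain_series()] with at least two time points.
#' @return List with `max_rel_Exx`, `max_rel_Eyy` and `max_abs_change`.
#' @export
stability_metrics <- function(series) {
  stopifnot(inherits(series, "strain_series"))
  if (nrow(series) < 2)
    stop("stability metrics require at least two time points", call. = FALSE)
  if (is.null(series$norm_Exx)) series <- normalize_series(series)
  list(
    max_rel_Exx = max(abs(series$norm_Exx - 1)),
    max_rel_Eyy = max(abs(series$norm_Eyy - 1)),
    max_abs_change = max(abs(series$avg_Exx - series$avg_Exx[1]),
                         abs(series$avg_Eyy - series$avg_Eyy[1]),
                         abs(series$avg_Exy - series$avg_Exy[1]))
  )
}

#' Poisson-effect membrane deflection
#'
#' Out-of-plane motion of the top surface of a stretched elastomeric
#' membrane due to Poisson thinning: `dz = 1/2 * nu * eps * h`. For a
#' nearly incompressible elastomer (`nu = 0.5`), 10% equibiaxial strain
#' and a 100 µm membrane this is 2.5 µm.
#'
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @param eps in-plane strain (dimensionless, e.g. 0.10 for 10%).
#' @param h membrane thickness in µm (> 0).
#' @return Deflection in µm.
#' @examples
#' poisson_deflection(0.5, 0.10, 100)  # 2.5
#' @export
poisson_deflection <- function(nu, eps, h) {
  if (!is.numeric(nu) || any(nu < 0 | nu > 0.5))
    stop("`nu` must be within [0, 0.5]", call. = FALSE)
  if (!is.numeric(h) || any(h <= 0))
    stop("`h` must be positive", call. = FALSE)
  0.5 * nu * eps * h
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d x %d points (crop margin %d)\n",
              ncol(x$Exx), nrow(x$Exx), x$crop_margin))
  cat(sprintf("  Exx: mean %.4f   Eyy: mean %.4f   Exy: mean %.4f\n",
              mean(x$Exx, na.rm = TRUE), mean(x$Eyy, na.rm = TRUE),
              mean(x$Exy, na.rm = TRUE)))
  invisible(x)
}

#' Heatmap of a strain component
#'
#' @param x a `strain_field`.
#' @param component `"Exx"`, `"Eyy"` or `"Exy"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.strain_field <- function(x, component = "Exx", ...) {
  graphics::image(x$x_um, x$y_um, t(x[[component]]),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "x [um]", ylab = "y [um]", main = component, ...)
  invisible(x)
}

#' @export
plot.strain_series <- function(x, normalized = FALSE, ...) {
  if (normalized && is.null(x$norm_Exx)) x <- normalize_series(x)
  ys <- if (normalized) cbind(x$norm_Exx, x$norm_Eyy)
        else cbind(x$avg_Exx, x$avg_Eyy)
  graphics::plot.default(range(x$time), range(ys), type = "n",
                         xlab = "time [s]",
                         ylab = if (normalized) "normalized strain" else "strain", ...)
  graphics::lines(x$time, ys[, 1], col = "firebrick")
  graphics::lines(x$time, ys[, 2], col = "navy")
  graphics::legend("topright", c("Exx", "Eyy"), lty = 1,
                   col = c("firebrick", "navy"), bty = "n")
  invisible(x)
}
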