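# Internal numeric plumbing shared across modules: seeded evaluation,
# image interpolation/warping and small validators. Images are matrices
# indexed [y, x]; pixel centers at integer coordinates (see package doc).

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed` and restores
#' the previous RNG state afterwards, so generators are reproducible without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

check_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` must have positive dimensions", name), call. = FALSE)
  invisible(img)
}

# Swap quadrants of a correlation plane so that zero lag (index 1) lands
# at (floor(nr/2)+1, floor(nc/2)+1) for both parities.
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nr - floor(nr / 2); kc <- nc - floor(nc / 2)
  m[c((kr + 1):nr, 1:kr), c((kc + 1):nc, 1:kc)]
}

# Catmull-Rom weights for fractional offset f (vectorized): 4 taps at
# floor(x)-1 .. floor(x)+2.
.cubic_w <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  list(
    (-f3 + 2 * f2 - f) / 2,
    (3 * f3 - 5 * f2 + 2) / 2,
    (-3 * f3 + 4 * f2 + f) / 2,
    (f3 - f2) / 2
  )
}

#' Sample an image at arbitrary (possibly fractional) pixel coordinates
#'
#' @param img numeric matrix `[y, x]`.
#' @param xq,yq numeric vectors of query coordinates (1-based pixel centers).
#' @param method "bicubic" (Catmull-Rom), "bilinear" or "nearest".
#' @param fill value returned for queries outside the image support.
#' @return numeric vector of samples, same length as `xq`.
#' @keywords internal
#' @noRd
interp2 <- function(img, xq, yq, method = c("bicubic", "bilinear", "nearest"),
                    fill = 0) {
  method <- match.arg(method)
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(xq))
  inside <- xq >= 1 & xq <= nc & yq >= 1 & yq <= nr & is.finite(xq) & is.finite(yq)
  if (!any(inside)) return(out)
  x <- xq[inside]; y <- yq[inside]

  if (method == "nearest") {
    out[inside] <- img[cbind(pmin(pmax(round(y), 1), nr),
                             pmin(pmax(round(x), 1), nc))]
    return(out)
  }

  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0

  if (method == "bilinear") {
    x1 <- pmin(x0 + 1, nc); y1 <- pmin(y0 + 1, nr)
    x0 <- pmax(x0, 1); y0 <- pmax(y0, 1)
    v <- (1 - fx) * (1 - fy) * img[cbind(y0, x0)] +
      fx * (1 - fy) * img[cbind(y0, x1)] +
      (1 - fx) * fy * img[cbind(y1, x0)] +
      fx * fy * img[cbind(y1, x1)]
    out[inside] <- v
    return(out)
  }

  wx <- .cubic_w(fx); wy <- .cubic_w(fy)
  acc <- numeric(length(x))
  for (j in 1:4) {
    yi <- pmin(pmax(y0 + (j - 2L), 1), nr)
    rowacc <- numeric(length(x))
    for (i in 1:4) {
      xi <- pmin(pmax(x0 + (i - 2L), 1), nc)
      rowacc <- rowacc + wx[[i]] * img[cbind(yi, xi)]
    }
    acc <- acc + wy[[j]] * rowacc
  }
  out[inside] <- acc
  out
}

# Warp an image by an inverse map: out[y, x] = img(map_x[y, x], map_y[y, x]).
warp_by_map <- function(img, map_x, map_y, method = "bicubic", fill = 0) {
  out <- interp2(img, as.vector(map_x), as.vector(map_y), method = method,
                 fill = fill)
  matrix(out, nrow = nrow(map_x), ncol = ncol(map_x))
}

# Bilinear interpolation of values Z defined on a rectilinear grid
# (gx: ascending x/column coords, gy: ascending y/row coords, Z[y, x]),
# with linear extrapolation beyond the grid (edge-cell gradients extended).
# xq, yq any shape; returns same shape as xq.
grid_bilinear <- function(gx, gy, Z, xq, yq) {
  nx <- length(gx); ny <- length(gy)
  if (nx == 1L && ny == 1L) return(array(Z[1, 1], dim = dim(as.array(xq))))
  ix <- if (nx > 1L) pmin(pmax(findInterval(xq, gx), 1L), nx - 1L) else rep(1L, length(xq))
  iy <- if (ny > 1L) pmin(pmax(findInterval(yq, gy), 1L), ny - 1L) else rep(1L, length(yq))
  if (nx > 1L) {
    tx <- (xq - gx[ix]) / (gx[ix + 1L] - gx[ix])
  } else tx <- rep(0, length(xq))
  if (ny > 1L) {
    ty <- (yq - gy[iy]) / (gy[iy + 1L] - gy[iy])
  } else ty <- rep(0, length(yq))
  ix1 <- if (nx > 1L) ix + 1L else ix
  iy1 <- if (ny > 1L) iy + 1L else iy
  v <- (1 - tx) * (1 - ty) * Z[cbind(iy, ix)] +
    tx * (1 - ty) * Z[cbind(iy, ix1)] +
    (1 - tx) * ty * Z[cbind(iy1, ix)] +
    tx * ty * Z[cbind(iy1, ix1)]
  if (!is.null(dim(xq))) dim(v) <- dim(xq)
  v
}

# Standard error of the mean; 0 for a single observation.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) <= 1L) return(0)
  stats::sd(x) / sqrt(length(x))
}
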