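# Shared in-code fixtures. Everything is generated at test time from
# seeded generators; nothing is read from disk.

# Subpixel translation of an image by inverse bicubic mapping (content
# moves by +dx, +dy).
shift_image <- function(img, dx, dy, fill = mean(img)) {
  h <- nrow(img); w <- ncol(img)
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  out <- stretchfield:::warp_by_map(img, X - dx, Y - dy, fill = fill)
  out
}

# Rasterized disk mask of radius r centered in an (2r + pad) square.
raster_disk <- function(r, pad = 21) {
  n <- 2 * r + pad
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- t(X)
  (X - (n + 1) / 2)^2 + (Y - (n + 1) / 2)^2 <= r^2
}

# A moderate-size speckle fixture for correlation tests.
small_speckle <- function(size = 256, seed = 21, noise_sd = 3) {
  generate_speckle(speckle_spec(image_size = c(size, size),
                                noise_sd = noise_sd, seed = seed))
}

# Displacement field constructed analytically (no DIC) on a regular grid,
# for exercising the strain module against closed forms.
analytic_field <- function(ufun, vfun, nx = 12, ny = 12, spacing_px = 40,
                           calibration = 1) {
  gx <- seq(spacing_px, by = spacing_px, length.out = nx)
  gy <- seq(spacing_px, by = spacing_px, length.out = ny)
  X <- outer(gy, gx, function(a, b) b)
  Y <- outer(gy, gx, function(a, b) a)
  u <- ufun(X, Y); v <- vfun(X, Y)
  structure(list(
    grid_x = gx, grid_y = gy,
    x_um = gx * calibration, y_um = gy * calibration,
    u = u, v = v, u_um = u * calibration, v_um = v * calibration,
    valid = matrix(TRUE, ny, nx), calibration = calibration,
    pair_time = 0, step = spacing_px
  ), class = "displacement_field")
}

# One full synthgen -> DIC chain on a 512 px fixture, memoized per session
# because several tests inspect the same field.
.fixture_cache <- new.env(parent = emptyenv())
dic_fixture <- function(Fm = diag(c(1.08, 1.08)), key = "radial8") {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  img <- generate_speckle(speckle_spec(image_size = c(512, 512), seed = 31))
  d <- apply_deformation(img, deformation_spec(F = Fm), fill = 10)
  fld <- estimate_displacement(image_pair(img, d$warped, calibration = 2),
                               pass_schedule(c(128, 64, 32)))
  res <- list(img = img, warped = d$warped, displacement = d$displacement,
              field = fld, F = Fm)
  .fixture_cache[[key]] <- res
  res
}

# Seeded Gaussian-noise matrix without touching the global RNG stream.
with_seed_matrix <- function(seed, dims, sd) {
  stretchfield:::with_seed(seed, matrix(stats::rnorm(prod(dims), sd = sd),
                                        dims[1], dims[2]))
}
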