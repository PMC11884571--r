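# Synthetic speckle patterns emulating fluorescent tracer particles
# covalently attached to an elastomeric culture membrane. Particles are
# rendered as Gaussian spots at continuous (subpixel) positions so that
# warped copies carry exact, analytically known displacement fields.

#' Specification of a synthetic tracer-particle speckle image
#'
#' @param image_size integer vector `c(width, height)` in pixels.
#' @param particle_density expected particles per square pixel. The
#'   default 5e-3 px^-2 (several tens of particles per 80 px interrogation
#'   window) is chosen for robust window correlation rather than to match
#'   any particular bead dilution.
#' @param particle_sigma Gaussian spot standard deviation in pixels.
#' @param peak_intensity spot peak amplitude in gray levels.
#' @param background_level constant background in gray levels.
#' @param noise_sd standard deviation of additive Gaussian read noise in
#'   gray levels.
#' @param bit_depth image bit depth; rendered values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param seed integer seed; the same spec and seed reproduce the image
#'   bit-identically.
#' @return An object of class `speckle_spec`.
#' @seealso [generate_speckle()]
#' @export
speckle_spec <- function(image_size = c(1000, 1000), particle_density = 5e-3,
                         particle_sigma = 1.5, peak_intensity = 180,
                         background_level = 10, noise_sd = 3,
                         bit_depth = 8, seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  if (length(image_size) != 2L || any(!is.finite(image_size)) ||
      any(image_size < 1))
    stop("`image_size` must be two positive pixel dimensions", call. = FALSE)
  stop_if_not_scalar_num(particle_density, "particle_density", nonneg = TRUE)
  stop_if_not_scalar_num(particle_sigma, "particle_sigma", positive = TRUE)
  stop_if_not_scalar_num(peak_intensity, "peak_intensity", nonneg = TRUE)
  stop_if_not_scalar_num(background_level, "background_level", nonneg = TRUE)
  stop_if_not_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(
    image_size = as.integer(round(image_size)),
    particle_density = particle_density,
    particle_sigma = particle_sigma,
    peak_intensity = peak_intensity,
    background_level = background_level,
    noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  ), class = "speckle_spec")
}

#' Render a synthetic speckle image
#'
#' Draws a Poisson number of particles (expectation `density * area`),
#' places them uniformly at continuous positions, renders each as an
#' isotropic Gaussian spot, adds Gaussian noise and clips to the bit depth.
#'
#' @param spec a [speckle_spec()].
#' @return Numeric matrix `[y, x]` of gray levels (height x width).
#' @examples
#' img <- generate_speckle(speckle_spec(image_size = c(128, 128), seed = 7))
#' @export
generate_speckle <- function(spec) {
  stopifnot(inherits(spec, "speckle_spec"))
  w <- spec$image_size[1]; h <- spec$image_size[2]
  with_seed(spec$seed, {
    n <- stats::rpois(1L, spec$particle_density * w * h)
    img <- matrix(spec$background_level, nrow = h, ncol = w)
    if (n > 0) {
      px <- stats::runif(n, 0.5, w + 0.5)
      py <- stats::runif(n, 0.5, h + 0.5)
      img <- render_spots(img, px, py, spec$particle_sigma,
                          spec$peak_intensity)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
    clip_gray(img, spec$bit_depth)
  })
}

# Add Gaussian spots at continuous positions; `amp` may be a vector of
# per-spot (possibly signed) amplitudes.
render_spots <- function(img, px, py, sigma, amp) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  amp <- rep_len(amp, length(px))
  for (k in seq_along(px)) {
    x0 <- px[k]; y0 <- py[k]
    x_lo <- max(1L, floor(x0) - r); x_hi <- min(w, floor(x0) + r + 1L)
    y_lo <- max(1L, floor(y0) - r); y_hi <- min(h, floor(y0) + r + 1L)
    if (x_lo > x_hi || y_lo > y_hi) next
    xs <- x_lo:x_hi; ys <- y_lo:y_hi
    gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
    gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + amp[k] * outer(gy, gx)
  }
  img
}

clip_gray <- function(img, bit_depth) {
  pmax(pmin(img, 2^bit_depth - 1), 0)
}
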