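# Prescribed homogeneous membrane deformations with exact ground truth.
# A deformation maps a material point x (reference/relaxed configuration)
# to x' = center + F (x - center), so the displacement is
# U(x) = (F - I)(x - center) and vanishes at the stretching center, as it
# does at the center of a pneumatically stretched membrane. Radial
# (equibiaxial) stretch is the special case F = (1 + eps_r) I.

#' Specification of a homogeneous membrane deformation
#'
#' @param kind `"affine"` or `"radial"`.
#' @param F 2x2 deformation gradient (affine kind); must have positive
#'   determinant. Rows/columns follow (x, y) order.
#' @param radial_strain scalar engineering strain of an equibiaxial
#'   (radial) stretch; used when `kind = "radial"`.
#' @param center stretching center `c(x, y)` in pixel coordinates, or
#'   `NULL` to use the image center at warp time.
#' @return An object of class `deformation_spec` with the effective 2x2
#'   deformation gradient in `$F`.
#' @examples
#' uniax <- deformation_spec(F = diag(c(1.12, 0.96)))
#' radial <- deformation_spec(kind = "radial", radial_strain = 0.08)
#' @export
deformation_spec <- function(kind = c("affine", "radial"), F = diag(2),
                             radial_strain = 0, center = NULL) {
  kind <- match.arg(kind)
  if (kind == "radial") {
    stop_if_not_scalar_num(radial_strain, "radial_strain")
    if (radial_strain <= -1)
      stop("`radial_strain` must be > -1", call. = FALSE)
    F <- diag(2) * (1 + radial_strain)
  } else {
    if (!is.matrix(F) || any(dim(F) != 2L) || !is.numeric(F))
      stop("`F` must be a numeric 2x2 matrix", call. = FALSE)
    if (det(F) <= 0)
      stop("deformation gradient must have det(F) > 0", call. = FALSE)
  }
  if (!is.null(center)) {
    if (length(center) != 2L || any(!is.finite(center)))
      stop("`center` must be c(x, y)", call. = FALSE)
    center <- as.numeric(center)
  }
  structure(list(kind = kind, F = F, radial_strain = radial_strain,
                 center = center),
            class = "deformation_spec")
}

# Effective center for an image (defaults to the image center).
deformation_center <- function(spec, dim_img) {
  if (!is.null(spec$center)) return(spec$center)
  c((ncol_or(dim_img, 2) + 1) / 2, (dim_img[1] + 1) / 2)
}

ncol_or <- function(dim_img, i) dim_img[i]

#' Ground-truth displacement of a homogeneous deformation
#'
#' Evaluates `U(x) = (F - I)(x - center)` at arbitrary reference
#' coordinates.
#'
#' @param spec a [deformation_spec()].
#' @param x,y reference coordinates in pixels (vectors of equal length).
#' @param dim_img image dimensions `dim(img)` used to resolve a default
#'   center; required when the spec carries no explicit center.
#' @return A list with components `u` and `v` (pixel displacements in x
#'   and y).
#' @export
ground_truth_displacement <- function(spec, x, y, dim_img = NULL) {
  stopifnot(inherits(spec, "deformation_spec"))
  if (is.null(spec$center) && is.null(dim_img))
    stop("spec has no center; supply `dim_img`", call. = FALSE)
  ctr <- if (is.null(spec$center)) deformation_center(spec, dim_img) else spec$center
  A <- spec$F - diag(2)
  dx <- x - ctr[1]; dy <- y - ctr[2]
  list(u = A[1, 1] * dx + A[1, 2] * dy,
       v = A[2, 1] * dx + A[2, 2] * dy)
}

#' Warp an image by a homogeneous deformation
#'
#' Produces the stretched-state image of a relaxed-state input by inverse
#' mapping: each output pixel at deformed position `x'` samples the input
#' at `center + F^-1 (x' - center)`. Intensities are interpolated
#' bicubically (nearest-neighbor for integer label masks so labels stay
#' integral); content mapped from outside the input is filled with `fill`.
#'
#' @param image numeric matrix `[y, x]`.
#' @param spec a [deformation_spec()].
#' @param interp `"bicubic"` for intensity images or `"nearest"` for label
#'   masks.
#' @param fill fill value for out-of-frame content (background level for
#'   speckle, 0 for label masks).
#' @return A list of class `deformed_image` with elements:
#'   \describe{
#'     \item{warped}{the warped image matrix;}
#'     \item{displacement}{`function(x, y)` returning the exact analytic
#'       displacement `U(x)` at any reference coordinates;}
#'     \item{spec, center}{the deformation spec and the center used.}
#'   }
#' @examples
#' img <- generate_speckle(speckle_spec(image_size = c(64, 64), seed = 2))
#' def <- apply_deformation(img, deformation_spec(F = diag(c(1.05, 1.05))))
#' def$displacement(33.5, 32.5)  # exactly (F - I) (x - center)
#' @export
apply_deformation <- function(image, spec, interp = c("bicubic", "nearest"),
                              fill = 0) {
  check_image(image)
  stopifnot(inherits(spec, "deformation_spec"))
  interp <- match.arg(interp)
  ctr <- deformation_center(spec, dim(image))
  Finv <- solve(spec$F)
  h <- nrow(image); w <- ncol(image)
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  dx <- X - ctr[1]; dy <- Y - ctr[2]
  map_x <- ctr[1] + Finv[1, 1] * dx + Finv[1, 2] * dy
  map_y <- ctr[2] + Finv[2, 1] * dx + Finv[2, 2] * dy
  warped <- warp_by_map(image, map_x, map_y, method = interp, fill = fill)
  disp <- function(x, y) ground_truth_displacement(
    structure(list(kind = spec$kind, F = spec$F,
                   radial_strain = spec$radial_strain, center = ctr),
              class = "deformation_spec"), x, y)
  structure(list(warped = warped, displacement = disp, spec = spec,
                 center = ctr),
            class = "deformed_image")
}
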