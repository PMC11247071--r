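#' Analytic shape primitives for phantom regions and VOIs
#'
#' Shapes are described analytically (mm coordinates, origin at the grid
#' centre) and only voxelized when a mask is requested, so that phantom
#' regions and evaluation VOIs share one volume-preserving voxelization
#' rule.
#'
#' @param centre_mm Numeric length-3 centre of the shape (mm).
#' @param radius_mm Radius in mm (sphere, cylinder).
#' @param volume_mL Alternative to `radius_mm` for spheres: target volume.
#' @param length_mm Cylinder length along the z axis (mm).
#' @param semiaxes_mm Ellipsoid semi-axes `(a, b, c)` in mm.
#' @return A `spect_shape` list with an analytic volume in mL.
#' @examples
#' shape_sphere(c(0, 0, 0), volume_mL = 26.9)$volume_mL
#' @export
shape_sphere <- function(centre_mm, radius_mm = NULL, volume_mL = NULL) {
  if (is.null(radius_mm)) {
    if (is.null(volume_mL)) stop("give `radius_mm` or `volume_mL`", call. = FALSE)
    radius_mm <- (3 * volume_mL * 1000 / (4 * pi))^(1 / 3)
  }
  if (radius_mm <= 0) stop("sphere radius must be positive", call. = FALSE)
  structure(
    list(
      type = "sphere", centre = as.numeric(centre_mm), radius = radius_mm,
      volume_mL = 4 / 3 * pi * radius_mm^3 / 1000
    ),
    class = "spect_shape"
  )
}

#' @rdname shape_sphere
#' @export
shape_cylinder <- function(centre_mm, radius_mm, length_mm) {
  if (radius_mm <= 0 || length_mm <= 0) {
    stop("cylinder radius and length must be positive", call. = FALSE)
  }
  structure(
    list(
      type = "cylinder", centre = as.numeric(centre_mm), radius = radius_mm,
      length = length_mm, volume_mL = pi * radius_mm^2 * length_mm / 1000
    ),
    class = "spect_shape"
  )
}

#' @rdname shape_sphere
#' @export
shape_ellipsoid <- function(centre_mm, semiaxes_mm) {
  if (any(semiaxes_mm <= 0)) stop("semi-axes must be positive", call. = FALSE)
  structure(
    list(
      type = "ellipsoid", centre = as.numeric(centre_mm),
      semiaxes = as.numeric(semiaxes_mm),
      volume_mL = 4 / 3 * pi * prod(semiaxes_mm) / 1000
    ),
    class = "spect_shape"
  )
}

# Elliptical cylinder (axis along z): transaxial semi-axes (a, b), length L.
shape_elliptical_cylinder <- function(centre_mm, semiaxes_mm, length_mm) {
  structure(
    list(
      type = "elliptical_cylinder", centre = as.numeric(centre_mm),
      semiaxes = as.numeric(semiaxes_mm), length = length_mm,
      volume_mL = pi * prod(semiaxes_mm) * length_mm / 1000
    ),
    class = "spect_shape"
  )
}

# Vectorized point-membership test in mm coordinates.
shape_contains <- function(shape, x, y, z) {
  cx <- shape$centre[1]; cy <- shape$centre[2]; cz <- shape$centre[3]
  switch(shape$type,
    sphere = (x - cx)^2 + (y - cy)^2 + (z - cz)^2 <= shape$radius^2,
    cylinder = ((x - cx)^2 + (y - cy)^2 <= shape$radius^2) &
      (abs(z - cz) <= shape$length / 2),
    ellipsoid = ((x - cx) / shape$semiaxes[1])^2 +
      ((y - cy) / shape$semiaxes[2])^2 +
      ((z - cz) / shape$semiaxes[3])^2 <= 1,
    elliptical_cylinder = (((x - cx) / shape$semiaxes[1])^2 +
      ((y - cy) / shape$semiaxes[2])^2 <= 1) &
      (abs(z - cz) <= shape$length / 2),
    stop("unknown shape type: ", shape$type, call. = FALSE)
  )
}

# Bounding half-widths (mm) along each axis, for voxelization windows.
shape_halfwidths <- function(shape) {
  switch(shape$type,
    sphere = rep(shape$radius, 3),
    cylinder = c(shape$radius, shape$radius, shape$length / 2),
    ellipsoid = shape$semiaxes,
    elliptical_cylinder = c(shape$semiaxes, shape$length / 2)
  )
}
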