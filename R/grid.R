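#' Define a reconstruction/phantom voxel grid
#'
#' A regular isotropic 3-D grid with its origin at the grid centre, used
#' for activity maps, attenuation maps and reconstructed volumes. The
#' default 4.42 mm voxel matches the clinical acquisition matrix the
#' pipeline emulates; `shape` is freely scalable for desk-scale runs.
#'
#' @param shape Integer vector `(nx, ny, nz)`, each component at least 8.
#' @param voxel_mm Isotropic voxel size in mm (> 0).
#' @return An object of class `spect_grid`.
#' @examples
#' g <- spect_grid(c(32, 32, 24), voxel_mm = 8)
#' voxel_volume_mL(g)
#' @export
spect_grid <- function(shape = c(64, 64, 48), voxel_mm = 4.42) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(is.na(shape))) {
    stop("`shape` must be three integers (nx, ny, nz)", call. = FALSE)
  }
  if (any(shape < 8)) {
    stop("all grid dimensions must be at least 8 voxels", call. = FALSE)
  }
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1 || voxel_mm <= 0) {
    stop("`voxel_mm` must be a single positive number", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_mm = as.numeric(voxel_mm)),
    class = "spect_grid"
  )
}

#' @export
print.spect_grid <- function(x, ...) {
  cat(sprintf(
    "<spect_grid> %d x %d x %d voxels, %.3g mm isotropic (%.4g mL/voxel)\n",
    x$shape[1], x$shape[2], x$shape[3], x$voxel_mm, voxel_volume_mL(x)
  ))
  invisible(x)
}

#' Voxel volume in millilitres
#' @param grid A [spect_grid()].
#' @return Voxel volume in mL.
#' @export
voxel_volume_mL <- function(grid) {
  stopifnot(inherits(grid, "spect_grid"))
  (grid$voxel_mm / 10)^3
}

# Centre-of-voxel coordinates (mm) along each axis, origin at grid centre.
grid_axes <- function(grid) {
  lapply(grid$shape, function(n) {
    (seq_len(n) - (n + 1) / 2) * grid$voxel_mm
  })
}

# Zero-filled volume on a grid.
new_volume <- function(grid, value = 0) {
  array(value, dim = grid$shape)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s are defined on different grids", what), call. = FALSE)
  }
  invisible(TRUE)
}
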