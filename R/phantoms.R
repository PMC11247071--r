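# Printed phantom constants: NEMA-like sphere volumes (mL), tumour volumes
# (mL), and the Lu-177 half-life (days) used for decay correction.
NEMA_SPHERE_VOLUMES_ML <- c(0.52, 1.15, 2.72, 5.61, 11.7, 26.9)
TUMOUR_VOLUMES_ML <- c(2.8, 8.9, 40.0)
LU177_HALF_LIFE_D <- 6.647

# Default narrow-beam linear attenuation of water at 208 keV (cm^-1).
MU_WATER_208KEV <- 0.136

# Organ and tumour concentrations (MBq/mL) at the two imaging time points.
ANTHRO_CONCENTRATIONS <- list(
  `24` = c(liver = 0.14, spleen = 0.51, kidney_left = 0.34,
           kidney_right = 0.45, tumour = 1.9),
  `168` = c(liver = 0.040, spleen = 0.12, kidney_left = 0.051,
            kidney_right = 0.068, tumour = 0.75)
)

#' Radioactive decay factor for Lu-177
#'
#' @param delta_t_days Elapsed time in days (finite; may be negative for
#'   decay correction back in time).
#' @return `2^(-delta_t_days / 6.647)`.
#' @examples
#' decay_factor(6.647) # 0.5
#' @export
decay_factor <- function(delta_t_days) {
  if (any(!is.finite(delta_t_days))) {
    stop("`delta_t_days` must be finite", call. = FALSE)
  }
  2^(-delta_t_days / LU177_HALF_LIFE_D)
}

# Voxelize a shape by voxel-centre membership (used for large body
# support, where the one-voxel volume tolerance of the overlap rule is
# irrelevant).
centre_mask <- function(shape, grid) {
  axes <- grid_axes(grid)
  pts <- expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  array(shape_contains(shape, pts$x, pts$y, pts$z), dim = grid$shape)
}

new_phantom <- function(kind, grid, activity, mu, masks, regions) {
  structure(
    list(kind = kind, grid = grid, activity = activity, mu = mu,
         masks = masks, regions = regions),
    class = "spect_phantom"
  )
}

#' @export
print.spect_phantom <- function(x, ...) {
  cat(sprintf("<spect_phantom> kind '%s', %d regions, total %.3f MBq\n",
              x$kind, nrow(x$regions), total_activity_MBq(x)))
  invisible(x)
}

#' Total activity of a phantom or activity map
#' @param x A `spect_phantom` or a concentration volume (MBq/mL) with an
#'   accompanying `grid`.
#' @param grid Required when `x` is a bare array.
#' @return Total activity in MBq.
#' @export
total_activity_MBq <- function(x, grid = NULL) {
  if (inherits(x, "spect_phantom")) {
    sum(x$activity) * voxel_volume_mL(x$grid)
  } else {
    stopifnot(inherits(grid, "spect_grid"))
    sum(x) * voxel_volume_mL(grid)
  }
}

#' Sphere phantom: six hot spheres in a cold water-filled body
#'
#' Builds a NEMA-IEC-like phantom with six spheres (0.52, 1.15, 2.72,
#' 5.61, 11.7, 26.9 mL) at a uniform activity concentration in a
#' non-radioactive elliptical-cylinder body. Sphere regions are voxelized
#' with the volume-preserving overlap rule of [make_voi_mask()], so each
#' region's voxel volume matches its nominal volume within one voxel.
#'
#' @param grid A [spect_grid()]. Must be large enough to hold the body;
#'   with the default 4.42 mm voxels this means roughly a 64^2 transaxial
#'   matrix (use coarser voxels for smaller test grids).
#' @param concentration_MBq_mL Sphere activity concentration
#'   (default 5.80 MBq/mL, the acquisition-start value emulated here).
#' @param mu_water Body linear attenuation at 208 keV (cm^-1).
#' @param ring_radius_mm Radius of the circle the sphere centres sit on.
#' @param body_semiaxes_mm Transaxial semi-axes of the body.
#' @param body_length_mm Axial body length.
#' @return A `spect_phantom` with activity map (MBq/mL), attenuation map
#'   (cm^-1), named region masks (`sphere1` ... `sphere6`), and a region
#'   table carrying the reference concentrations.
#' @export
make_sphere_phantom <- function(grid, concentration_MBq_mL = 5.80,
                                mu_water = MU_WATER_208KEV,
                                ring_radius_mm = 57.2,
                                body_semiaxes_mm = c(120, 90),
                                body_length_mm = 170) {
  stopifnot(inherits(grid, "spect_grid"))
  if (concentration_MBq_mL < 0) stop("concentration must be >= 0", call. = FALSE)
  extent <- grid$shape * grid$voxel_mm / 2
  body <- shape_elliptical_cylinder(c(0, 0, 0), body_semiaxes_mm,
                                    body_length_mm)
  if (any(c(body_semiaxes_mm, body_length_mm / 2) > extent + 1e-9)) {
    stop("grid too small to contain the phantom body", call. = FALSE)
  }

  angles <- (seq_along(NEMA_SPHERE_VOLUMES_ML) - 1) * 60
  masks <- list()
  for (i in seq_along(NEMA_SPHERE_VOLUMES_ML)) {
    v <- NEMA_SPHERE_VOLUMES_ML[i]
    centre <- c(ring_radius_mm * cos(angles[i] * pi / 180),
                ring_radius_mm * sin(angles[i] * pi / 180), 0)
    sph <- shape_sphere(centre, volume_mL = v)
    # sphere must sit fully inside the body and the grid
    u <- centre[1:2] / body_semiaxes_mm
    edge <- sqrt(sum(u^2)) + sph$radius / min(body_semiaxes_mm)
    if (edge > 1 || any(abs(centre) + sph$radius > extent)) {
      stop(sprintf("sphere %d (%.2f mL) does not fit in the body/grid", i, v),
           call. = FALSE)
    }
    masks[[paste0("sphere", i)]] <- make_voi_mask(sph, grid,
                                                  target_volume_mL = v)
  }

  activity <- new_volume(grid)
  for (m in masks) activity[m] <- concentration_MBq_mL
  mu <- new_volume(grid)
  mu[centre_mask(body, grid)] <- mu_water

  regions <- tibble::tibble(
    label = names(masks),
    volume_mL = NEMA_SPHERE_VOLUMES_ML,
    concentration_MBq_mL = concentration_MBq_mL
  )
  new_phantom("spheres", grid, activity, mu, masks, regions)
}

#' Uniform cylinder phantom for calibration
#'
#' A cylinder of uniform activity concentration in water, matching the
#' calibration phantoms: by default the simulated calibration cylinder
#' (radius 10.8 cm, length 18.6 cm) at the measured Jaszczak
#' concentration of 22.8 kBq/mL.
#'
#' @inheritParams make_sphere_phantom
#' @param radius_mm Cylinder radius (default 108 mm).
#' @param length_mm Cylinder length (default 186 mm).
#' @param concentration_MBq_mL Uniform concentration (default 0.0228).
#' @return A `spect_phantom` with a single `cylinder` region.
#' @export
make_cylinder_phantom <- function(grid, radius_mm = 108, length_mm = 186,
                                  concentration_MBq_mL = 0.0228,
                                  mu_water = MU_WATER_208KEV) {
  stopifnot(inherits(grid, "spect_grid"))
  cyl <- shape_cylinder(c(0, 0, 0), radius_mm, length_mm)
  extent <- grid$shape * grid$voxel_mm / 2
  if (radius_mm > min(extent[1:2]) || length_mm / 2 > extent[3]) {
    stop("cylinder exceeds the grid", call. = FALSE)
  }
  mask <- make_voi_mask(cyl, grid)
  activity <- new_volume(grid)
  activity[mask] <- concentration_MBq_mL
  mu <- new_volume(grid)
  mu[mask] <- mu_water
  regions <- tibble::tibble(
    label = "cylinder", volume_mL = cyl$volume_mL,
    concentration_MBq_mL = concentration_MBq_mL
  )
  new_phantom("cylinder", grid, activity, mu, list(cylinder = mask), regions)
}

# Fixed anthropomorphic geometry (mm): a large ellipsoidal body with
# ellipsoidal organs and three spherical tumours at documented, pairwise
# disjoint positions. Locations are stand-ins (not printed anywhere); only
# volumes and concentrations are anchored.
anthro_geometry <- function() {
  list(
    body = shape_ellipsoid(c(0, 0, 0), c(130, 95, 100)),
    liver = shape_ellipsoid(c(45, 25, 25), c(55, 40, 35)),
    spleen = shape_ellipsoid(c(-75, 30, 20), c(22, 18, 16)),
    kidney_left = shape_ellipsoid(c(-45, -45, -35), c(30, 16, 16)),
    kidney_right = shape_ellipsoid(c(45, -45, -35), c(30, 16, 16)),
    tumour1 = shape_sphere(c(-20, 70, -40), volume_mL = TUMOUR_VOLUMES_ML[1]),
    tumour2 = shape_sphere(c(85, 20, -45), volume_mL = TUMOUR_VOLUMES_ML[2]),
    tumour3 = shape_sphere(c(-70, -20, 45), volume_mL = TUMOUR_VOLUMES_ML[3])
  )
}

#' Anthropomorphic stand-in phantom
#'
#' Ellipsoidal liver, spleen and kidneys plus three spherical tumours
#' (2.8, 8.9, 40.0 mL) in a water-equivalent ellipsoidal body, with the
#' organ and tumour activity concentrations of a Lu-177-DOTA-TATE
#' distribution at 24 h or 168 h post injection. Organ/tumour positions
#' are documented stand-ins; volumes and concentrations are the anchored
#' quantities.
#'
#' @inheritParams make_sphere_phantom
#' @param timepoint_h Imaging time point: 24 or 168 (hours post injection).
#' @param background_MBq_mL Uniform remainder-body concentration
#'   (default 0).
#' @return A `spect_phantom`; the region table carries per-region
#'   reference concentrations for the requested time point.
#' @export
make_anthro_phantom <- function(grid, timepoint_h = 24,
                                background_MBq_mL = 0,
                                mu_water = MU_WATER_208KEV) {
  stopifnot(inherits(grid, "spect_grid"))
  key <- as.character(timepoint_h)
  if (!key %in% names(ANTHRO_CONCENTRATIONS)) {
    stop("`timepoint_h` must be 24 or 168", call. = FALSE)
  }
  conc <- ANTHRO_CONCENTRATIONS[[key]]
  geo <- anthro_geometry()
  extent <- grid$shape * grid$voxel_mm / 2
  if (any(geo$body$semiaxes > extent + 1e-9)) {
    stop("grid too small to contain the body", call. = FALSE)
  }

  region_names <- setdiff(names(geo), "body")
  masks <- lapply(region_names, function(nm) make_voi_mask(geo[[nm]], grid))
  names(masks) <- region_names

  region_conc <- vapply(region_names, function(nm) {
    if (grepl("^tumour", nm)) conc[["tumour"]] else conc[[nm]]
  }, numeric(1))

  body_mask <- centre_mask(geo$body, grid)
  activity <- new_volume(grid)
  if (background_MBq_mL > 0) activity[body_mask] <- background_MBq_mL
  for (nm in region_names) activity[masks[[nm]]] <- region_conc[[nm]]
  mu <- new_volume(grid)
  mu[body_mask] <- mu_water

  regions <- tibble::tibble(
    label = region_names,
    volume_mL = vapply(region_names, function(nm) geo[[nm]]$volume_mL,
                       numeric(1)),
    concentration_MBq_mL = unname(region_conc),
    timepoint_h = as.numeric(timepoint_h)
  )
  new_phantom("anthro", grid, activity, mu, masks, regions)
}
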