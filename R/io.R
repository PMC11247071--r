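# Minimal NIfTI-1 I/O (single-file .nii, float32, mm units). No NIfTI
# package ships with the supported R stack, so the 348-byte header is
# written directly; only the fields this pipeline needs are populated
# (dims, pixdim in mm, an axis-aligned sform centred on the volume).

#' Write a volume as NIfTI-1
#'
#' @param vol 3-D numeric array.
#' @param grid A [spect_grid()] supplying the voxel size.
#' @param path Output path (`.nii`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, grid, path) {
  stopifnot(is.array(vol), length(dim(vol)) == 3,
            inherits(grid, "spect_grid"))
  d <- dim(vol)
  vs <- grid$voxel_mm
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1) # extents, session_error, regular, dim_info
  wi(c(3, d, 1, 1, 1, 1), 2)       # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)         # intent_p1-3, intent_code
  wi(16, 2); wi(32, 2); wi(0, 2)   # datatype float32, bitpix, slice_start
  wf(c(1, vs, vs, vs, 0, 0, 0, 0)) # pixdim[8]
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0, 2); wc("", 1); writeBin(as.raw(2), con) # slice_end, slice_code, xyzt_units = mm
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                   # glmax, glmin
  wc("spectpareto volume", 80); wc("", 24)
  wi(0, 2); wi(1, 2)               # qform_code, sform_code
  wf(c(0, 0, 0))                   # quatern b,c,d
  orig <- -vs * (d - 1) / 2
  wf(orig)                         # qoffset x,y,z
  wf(c(vs, 0, 0, orig[1]))         # srow_x
  wf(c(0, vs, 0, orig[2]))         # srow_y
  wf(c(0, 0, vs, orig[3]))         # srow_z
  wc("", 16); wc("n+1", 4)
  writeBin(raw(4), con)            # no extensions
  writeBin(as.numeric(vol), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package
#'
#' Supports single-file little-endian float32 `.nii` with an isotropic
#' pixdim.
#'
#' @param path Input path.
#' @return List with `volume` (array) and `voxel_mm`.
#' @export
read_volume_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348) stop("not a NIfTI-1 file", call. = FALSE)
  dim8 <- ri(40, 2, 8)
  d <- dim8[2:4]
  if (ri(70, 2) != 16) stop("only float32 NIfTI is supported", call. = FALSE)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  n <- prod(d)
  seek(con, vox_offset)
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  list(volume = array(vals, dim = d), voxel_mm = pixdim[2])
}

#' Write a projection set as NIfTI plus JSON sidecar
#'
#' The count array goes to `<prefix>.nii`; angles, time per projection,
#' provenance and seed go to `<prefix>.json`.
#'
#' @param ps A `projection_set`.
#' @param prefix Output path prefix.
#' @param pixel_mm Detector pixel size recorded in the NIfTI header.
#' @return The two paths, invisibly.
#' @export
write_projection_set <- function(ps, prefix, pixel_mm = 4.42) {
  stopifnot(inherits(ps, "projection_set"))
  nii <- paste0(prefix, ".nii")
  json <- paste0(prefix, ".json")
  fake_grid <- structure(list(shape = dim(ps$counts), voxel_mm = pixel_mm),
                         class = "spect_grid")
  write_volume_nifti(ps$counts, fake_grid, nii)
  jsonlite::write_json(
    list(
      angles_deg = ps$angles_deg,
      time_per_projection_s = ps$time_per_projection_s,
      provenance = ps$provenance,
      seed = if (is.null(ps$seed)) NA else ps$seed
    ),
    json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(nii, json))
}

#' Read a projection set written by [write_projection_set()]
#' @param prefix Path prefix used when writing.
#' @return A `projection_set`.
#' @export
read_projection_set <- function(prefix) {
  vol <- read_volume_nifti(paste0(prefix, ".nii"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new_projection_set(
    vol$volume, meta$angles_deg, meta$time_per_projection_s,
    provenance = meta$provenance,
    seed = if (is.na(meta$seed)) NULL else meta$seed
  )
}

#' Serialize / restore a study configuration as YAML
#' @param config Named list.
#' @param path File path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}

#' Serialize a phantom to disk
#'
#' Writes the activity map (`<prefix>_activity.nii`), attenuation map
#' (`<prefix>_mu.nii`), region masks as one integer label volume
#' (`<prefix>_labels.nii`, 0 = background, regions numbered in mask
#' order) with a JSON label table (`<prefix>_labels.json`), and the
#' region table as YAML (`<prefix>_spec.yaml`).
#'
#' @param phantom A `spect_phantom`.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "spect_phantom"))
  g <- phantom$grid
  labels <- new_volume(g)
  for (i in seq_along(phantom$masks)) labels[phantom$masks[[i]]] <- i
  paths <- c(
    activity = paste0(prefix, "_activity.nii"),
    mu = paste0(prefix, "_mu.nii"),
    labels = paste0(prefix, "_labels.nii"),
    table = paste0(prefix, "_labels.json"),
    spec = paste0(prefix, "_spec.yaml")
  )
  write_volume_nifti(phantom$activity, g, paths[["activity"]])
  write_volume_nifti(phantom$mu, g, paths[["mu"]])
  write_volume_nifti(labels, g, paths[["labels"]])
  jsonlite::write_json(
    data.frame(label = seq_along(phantom$masks), name = names(phantom$masks)),
    paths[["table"]]
  )
  yaml::write_yaml(
    c(list(kind = phantom$kind, voxel_mm = g$voxel_mm,
           shape = as.integer(g$shape)),
      list(regions = lapply(seq_len(nrow(phantom$regions)), function(i) {
        as.list(phantom$regions[i, ])
      }))),
    paths[["spec"]]
  )
  invisible(paths)
}
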