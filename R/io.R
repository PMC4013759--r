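#' Aligned multimodal volume set
#'
#' Container for the 3D volumes of one imaging session, keyed by
#' modality/condition (e.g. `t2`, `dwi_dir1_b125`, `mt_on`, `mt_off`,
#' `gd_pre`, `gd_post`, `t2star`). All volumes must share shape; they are
#' assumed spatially aligned (single-session acquisition), so no
#' registration is performed anywhere downstream.
#'
#' @param volumes Named list of 3D numeric arrays with identical dimensions.
#' @param voxel_size Voxel edge lengths in mm (length 3).
#' @param orientation Axis label record; default `c("R", "A", "S")`.
#' @return An object of class `volume_set`.
#' @export
volume_set <- function(volumes, voxel_size, orientation = c("R", "A", "S")) {
  if (!length(volumes) || is.null(names(volumes)) || any(names(volumes) == ""))
    stop_bsq("volumes must be a non-empty named list")
  if (anyDuplicated(names(volumes)))
    stop_bsq("condition keys must be unique")
  dims <- lapply(volumes, dim)
  if (any(vapply(dims, length, 0L) != 3))
    stop_bsq("all volumes must be 3D arrays")
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop_bsq("all volumes must share the same shape")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop_bsq("voxel_size must be 3 positive values (mm)")
  structure(list(volumes = volumes, voxel_size = as.numeric(voxel_size),
                 orientation = orientation),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat("Multimodal volume set:", length(x$volumes), "volumes,",
      paste(d, collapse = " x "), "voxels @",
      paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  cat("  conditions:", paste(names(x$volumes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[[.volume_set` <- function(x, key) {
  v <- x$volumes[[key]]
  if (is.null(v) && is.character(key))
    stop_bsq("unknown condition key '", key, "'")
  v
}

nifti_with_geometry <- function(arr, voxel_size) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- voxel_size
  im
}

#' Write a volume set to NIfTI-1 files
#'
#' Writes one `.nii.gz` per condition plus a JSON manifest mapping condition
#' keys to file names and recording the voxel size. Volumes are stored as
#' double precision so round-trips are lossless (NaN included).
#'
#' @param vs A [volume_set()].
#' @param dir Output directory (created if needed).
#' @param manifest File name of the manifest within `dir`.
#' @return Invisibly, the manifest path.
#' @export
write_volume_set <- function(vs, dir, manifest = "volumes.json") {
  stopifnot(inherits(vs, "volume_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- setNames(paste0(names(vs$volumes), ".nii.gz"), names(vs$volumes))
  for (key in names(vs$volumes)) {
    im <- nifti_with_geometry(vs$volumes[[key]], vs$voxel_size)
    RNifti::writeNifti(im, file.path(dir, files[[key]]), datatype = "double")
  }
  man <- list(voxel_size = vs$voxel_size, orientation = vs$orientation,
              volumes = as.list(files))
  path <- file.path(dir, manifest)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a volume set from a manifest
#'
#' @param manifest Path to a JSON manifest as written by
#'   [write_volume_set()]: `voxel_size`, optional `orientation`, and a
#'   `volumes` map from condition key to NIfTI file (relative to the
#'   manifest's directory).
#' @param keys Optional condition keys to load; all keys must be present in
#'   the manifest.
#' @return A [volume_set()]. Errors if any file is missing or if the
#'   volumes disagree in shape or voxel size.
#' @export
read_volume_set <- function(manifest, keys = NULL) {
  if (!file.exists(manifest)) stop_bsq("manifest not found: ", manifest)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (is.null(man$volumes) || !length(man$volumes))
    stop_bsq("manifest has no volumes map")
  files <- unlist(man$volumes)
  if (!is.null(keys)) {
    missing <- setdiff(keys, names(files))
    if (length(missing))
      stop_bsq("manifest is missing condition keys: ",
               paste(missing, collapse = ", "))
    files <- files[keys]
  }
  base <- dirname(manifest)
  vols <- list(); vsz <- NULL
  for (key in names(files)) {
    p <- file.path(base, files[[key]])
    if (!file.exists(p)) stop_bsq("volume file not found: ", p)
    im <- RNifti::readNifti(p)
    pd <- RNifti::pixdim(im)[seq_len(3)]
    if (is.null(vsz)) vsz <- pd
    else if (max(abs(pd - vsz)) > 1e-6)
      stop_bsq("voxel-size mismatch between conditions (", key, ")")
    arr <- as.array(im)
    attributes(arr) <- list(dim = dim(arr))
    vols[[key]] <- arr
  }
  dims <- lapply(vols, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop_bsq("shape mismatch between conditions")
  man_vsz <- man$voxel_size %||% vsz
  volume_set(vols, voxel_size = man_vsz,
             orientation = man$orientation %||% c("R", "A", "S"))
}

#' Define a circular/spherical region of interest
#'
#' ROIs follow the study convention: a circular ROI on one slice over each
#' motor nucleus, paired with a control region on the same slices within
#' the brainstem but outside the nuclei. Centres are in mm from the volume
#' origin; a voxel belongs to the ROI iff its centre lies within the circle
#' (centre-of-voxel inclusion), which makes rasterisation deterministic and
#' resolution-independent.
#'
#' The printed ROI sizes in the source protocol carry ambiguous units
#' ("diameters ... mm^2"); `size_unit` selects whether `size` is read as a
#' diameter in mm (default) or as an area in mm^2 (converted to the
#' equivalent-diameter circle).
#'
#' @param label ROI label, e.g. `"V"`, `"VII"`, `"XII"`, `"control"`.
#' @param center Centre in mm (length 2 for in-plane + `slice_index`, or
#'   length 3 for a spherical ROI).
#' @param size Diameter in mm, or area in mm^2 (see `size_unit`).
#' @param slice_index 1-based slice index for a 2D circular ROI, or `NULL`
#'   for a 3D spherical ROI with a length-3 `center`.
#' @param control_link Label of the paired control ROI (required downstream
#'   for nucleus ROIs).
#' @param size_unit `"diameter_mm"` or `"area_mm2"`.
#' @return An object of class `roi_definition`.
#' @export
roi_definition <- function(label, center, size, slice_index = NULL,
                           control_link = NULL,
                           size_unit = c("diameter_mm", "area_mm2")) {
  size_unit <- match.arg(size_unit)
  if (size <= 0) stop_bsq("ROI size must be positive")
  diameter <- if (size_unit == "area_mm2") 2 * sqrt(size / pi) else size
  if (is.null(slice_index) && length(center) != 3)
    stop_bsq("3D ROI needs a length-3 center")
  if (!is.null(slice_index) && length(center) < 2)
    stop_bsq("2D ROI needs an in-plane center (length 2)")
  structure(list(label = label, center = as.numeric(center),
                 diameter = diameter, slice_index = slice_index,
                 control_link = control_link, size_unit = size_unit),
            class = "roi_definition")
}

#' Rasterise an ROI to voxel indices
#'
#' @param roi A [roi_definition()].
#' @param dim Volume dimensions (length 3).
#' @param voxel_size Voxel size in mm (length 3).
#' @return Integer vector of linear voxel indices whose centres lie within
#'   the ROI circle (2D, on `roi$slice_index`) or sphere (3D).
#' @export
rasterize_roi <- function(roi, dim, voxel_size) {
  stopifnot(inherits(roi, "roi_definition"))
  r <- roi$diameter / 2
  xs <- vox_centers(dim[1], voxel_size[1])
  ys <- vox_centers(dim[2], voxel_size[2])
  if (is.null(roi$slice_index)) {
    zs <- vox_centers(dim[3], voxel_size[3])
    d2 <- outer(outer((xs - roi$center[1])^2, (ys - roi$center[2])^2, "+"),
                (zs - roi$center[3])^2, "+")
    idx <- which(d2 <= r^2)
  } else {
    k <- roi$slice_index
    if (k < 1 || k > dim[3]) stop_bsq("slice_index outside volume")
    d2 <- outer((xs - roi$center[1])^2, (ys - roi$center[2])^2, "+")
    inplane <- which(d2 <= r^2)
    idx <- inplane + (k - 1L) * dim[1] * dim[2]
  }
  if (!length(idx)) stop_bsq("ROI '", roi$label, "' rasterises to 0 voxels")
  as.integer(idx)
}

#' Write run outputs to disk
#'
#' Writes result tables as CSV, parametric maps as NIfTI, and a metadata
#' JSON (configuration, seed, package and R versions) plus a plain-text log.
#' Output is deterministic for a fixed configuration: no timestamps are
#' written into the data files.
#'
#' @param tables Named list of data.frames (may be empty or contain
#'   zero-row tables, written as header-only CSVs).
#' @param maps Named list of [parametric_map] objects or 3D arrays.
#' @param out_dir Output directory.
#' @param config Optional configuration object echoed into metadata.
#' @param seed Optional seed echoed into metadata.
#' @param voxel_size Voxel size for maps given as bare arrays.
#' @param overwrite Allow overwriting existing files (default `FALSE`).
#' @return Invisibly, a character vector of the files written.
#' @export
write_results <- function(tables = list(), maps = list(), out_dir,
                          config = NULL, seed = NULL, voxel_size = c(1, 1, 1),
                          overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) {
    if (file.exists(path) && !overwrite)
      stop_bsq("refusing to overwrite ", path, " (set overwrite = TRUE)")
    written <<- c(written, path)
    path
  }
  for (nm in names(tables)) {
    p <- emit(file.path(out_dir, paste0(nm, ".csv")))
    write.csv(tables[[nm]], p, row.names = FALSE)
  }
  for (nm in names(maps)) {
    m <- maps[[nm]]
    arr <- if (inherits(m, "parametric_map")) m$values else m
    vs <- if (inherits(m, "parametric_map")) m$voxel_size %||% voxel_size else voxel_size
    p <- emit(file.path(out_dir, paste0(nm, ".nii.gz")))
    RNifti::writeNifti(nifti_with_geometry(arr, vs), p, datatype = "double")
  }
  meta <- list(config = config, seed = seed,
               package = as.character(packageVersion("brainstemq")),
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  mp <- emit(file.path(out_dir, "run_metadata.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  log <- c(paste("tables:", length(tables)), paste("maps:", length(maps)),
           paste("files:", length(written)))
  lp <- emit(file.path(out_dir, "run.log"))
  writeLines(log, lp)
  invisible(written)
}
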