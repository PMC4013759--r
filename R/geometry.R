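#' Describe an MRI acquisition geometry
#'
#' Bundles the sequence parameters needed to derive reconstructed voxel
#' resolution and scan duration: field of view, acquired and zero-filled
#' matrix sizes, repetition time and averaging.
#'
#' @param fov Field of view in mm, one value per spatial axis.
#' @param matrix_size Acquired k-space points per axis (same length as `fov`).
#' @param zerofill Reconstructed points per axis after zero-filling. Defaults
#'   to `matrix_size` (no zero-filling). Must be `>= matrix_size` axis-wise.
#' @param tr Repetition time in seconds.
#' @param n_phase_encodes Number of phase-encode steps per repetition loop.
#' @param n_averages Number of signal averages. Default 1.
#' @param b_values Optional diffusion weightings in s/mm^2.
#' @param n_directions Optional number of diffusion gradient directions.
#'
#' @return An object of class `acquisition_geometry`.
#' @examples
#' g <- acquisition_geometry(fov = c(22.5, 22.5, 11.25),
#'                           matrix_size = c(256, 192, 96),
#'                           zerofill = c(256, 256, 128),
#'                           tr = 0.065, n_phase_encodes = 192)
#' voxel_resolution(g)
#' @export
acquisition_geometry <- function(fov, matrix_size, zerofill = matrix_size,
                                 tr, n_phase_encodes, n_averages = 1,
                                 b_values = NULL, n_directions = NULL) {
  if (length(fov) != length(matrix_size) || length(fov) != length(zerofill))
    stop_bsq("fov, matrix_size and zerofill must have the same length")
  if (any(fov <= 0) || any(matrix_size <= 0) || any(zerofill <= 0))
    stop_bsq("fov, matrix_size and zerofill must be positive")
  if (any(zerofill < matrix_size))
    stop_bsq("zerofill must be >= matrix_size on every axis")
  if (tr <= 0) stop_bsq("tr must be positive")
  if (n_phase_encodes < 1) stop_bsq("n_phase_encodes must be >= 1")
  if (n_averages < 1) stop_bsq("n_averages must be >= 1")
  if (!is.null(b_values) && any(b_values < 0)) stop_bsq("b_values must be >= 0")
  structure(list(fov = as.numeric(fov), matrix_size = as.integer(matrix_size),
                 zerofill = as.integer(zerofill), tr = as.numeric(tr),
                 n_phase_encodes = as.integer(n_phase_encodes),
                 n_averages = as.integer(n_averages),
                 b_values = b_values, n_directions = n_directions),
            class = "acquisition_geometry")
}

#' Reconstructed voxel resolution after zero-filling
#'
#' Zero-filling pads k-space before Fourier reconstruction, so the
#' reconstructed grid spacing on each axis is `fov / zerofill` rather than
#' `fov / matrix_size`.
#'
#' @param geom An [acquisition_geometry()].
#' @return Numeric vector of voxel sizes in mm, one per axis.
#' @export
voxel_resolution <- function(geom) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  geom$fov / geom$zerofill
}

#' Nominal scan duration of a spin-echo acquisition
#'
#' For a conventional (non-echo-train) spin-echo loop the duration is
#' `TR x n_phase_encodes x n_averages x n_repeats`, where `n_repeats`
#' counts outer repetitions such as the number of b-values in a
#' diffusion-weighted series.
#'
#' @param geom An [acquisition_geometry()].
#' @param n_repeats Outer repetitions (e.g. b-values). Default 1.
#' @return Duration in seconds.
#' @export
scan_duration <- function(geom, n_repeats = 1) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  if (n_repeats < 1) stop_bsq("n_repeats must be >= 1")
  geom$tr * geom$n_phase_encodes * geom$n_averages * n_repeats
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("MRI acquisition geometry\n")
  cat("  fov (mm):       ", paste(x$fov, collapse = " x "), "\n")
  cat("  matrix:         ", paste(x$matrix_size, collapse = " x "), "\n")
  cat("  zero-filled to: ", paste(x$zerofill, collapse = " x "), "\n")
  cat("  resolution (mm):", paste(signif(voxel_resolution(x), 4), collapse = " x "), "\n")
  cat("  TR (s):         ", x$tr, "\n")
  if (!is.null(x$b_values))
    cat("  b-values (s/mm2):", paste(x$b_values, collapse = ", "), "\n")
  invisible(x)
}
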