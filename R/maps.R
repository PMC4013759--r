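#' Construct a parametric map
#'
#' A voxelwise derived map (ADC, MTR, enhancement) with a validity mask:
#' voxels where the computation was undefined (non-positive signal, negative
#' diffusivity fit, ...) are `NA` in `values` and `FALSE` in `mask`, and
#' their counts are kept in `provenance` rather than silently dropped.
#'
#' @param values 3D numeric array.
#' @param kind One of `"adc_trace"`, `"adc_dir"`, `"mtr"`, `"enhancement"`.
#' @param units `"mm^2/s"` or `"fraction"`.
#' @param mask Logical array of valid voxels.
#' @param provenance List of source conditions, parameters and invalid-voxel
#'   counts.
#' @param voxel_size Optional voxel size (mm) carried for writing.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, kind, units, mask, provenance = list(),
                           voxel_size = NULL) {
  stopifnot(is.array(values), identical(dim(values), dim(mask)))
  structure(list(values = values, kind = kind, units = units, mask = mask,
                 provenance = provenance, voxel_size = voxel_size),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat("Parametric map:", x$kind, "(", x$units, ")\n")
  cat("  dims:", paste(dim(x$values), collapse = " x "),
      " valid voxels:", sum(x$mask), "\n")
  inv <- x$provenance$n_invalid
  if (!is.null(inv)) cat("  invalidated voxels:", inv, "\n")
  rng <- range(x$values[x$mask])
  cat("  range (valid):", signif(rng[1], 4), "to", signif(rng[2], 4), "\n")
  invisible(x)
}

# slope of y on b by least squares, vectorised over voxels (rows of y);
# centring y makes the slope exactly zero for constant rows
lsq_slope <- function(y, b) {
  bc <- b - mean(b)
  ((y - rowMeans(y)) %*% bc) / sum(bc^2)
}

#' Fit apparent diffusion coefficient maps
#'
#' Fits, per gradient direction and voxel, an ordinary least-squares line to
#' `ln S` versus `b` (with intercept, since no b = 0 image is acquired);
#' the directional diffusivity is minus the slope. The trace map is the
#' unweighted arithmetic mean of the directional maps. The fit is exact for
#' noiseless mono-exponential decay `S(b) = S0 exp(-b D)`.
#'
#' Voxels with any non-positive or non-finite signal, and voxels whose
#' fitted diffusivity is negative, are flagged invalid (`NA`) rather than
#' clipped; counts are reported in the map's provenance. Set
#' `clip_negative = TRUE` to clip negative fits to zero instead.
#'
#' @param dwi List over gradient directions; each element a list of 3D
#'   volumes, one per b-value, in the order of `b_values`.
#' @param b_values Diffusion weightings in s/mm^2 (>= 2 distinct values).
#' @param mask Optional logical array restricting the fit.
#' @param clip_negative Clip negative fitted diffusivities to 0 instead of
#'   invalidating them.
#' @param voxel_size Optional voxel size carried into the maps.
#' @return A list with `trace` (a [parametric_map] of kind `adc_trace`) and
#'   `directions` (list of `adc_dir` maps).
#' @export
fit_adc <- function(dwi, b_values, mask = NULL, clip_negative = FALSE,
                    voxel_size = NULL) {
  if (length(unique(b_values)) < 2)
    stop_bsq("need at least 2 distinct b-values")
  for (d in seq_along(dwi))
    if (length(dwi[[d]]) != length(b_values))
      stop_bsq("direction ", d, " has ", length(dwi[[d]]),
               " volumes for ", length(b_values), " b-values")
  dims <- dim(dwi[[1]][[1]])
  if (is.null(mask)) mask <- array(TRUE, dims)
  nvox <- sum(mask)
  dir_maps <- list()
  n_nonpos <- 0L; n_negative <- 0L
  D <- matrix(NA_real_, nvox, length(dwi))
  ok_all <- rep(TRUE, nvox)
  for (d in seq_along(dwi)) {
    S <- vapply(dwi[[d]], function(v) v[mask], numeric(nvox))
    ok <- rowSums(!is.finite(S) | S <= 0) == 0
    n_nonpos <- n_nonpos + sum(!ok)
    Dd <- rep(NA_real_, nvox)
    if (any(ok))
      Dd[ok] <- -as.numeric(lsq_slope(log(S[ok, , drop = FALSE]), b_values))
    neg <- !is.na(Dd) & Dd < 0
    n_negative <- n_negative + sum(neg)
    if (clip_negative) Dd[neg] <- 0
    else {
      Dd[neg] <- NA_real_
      ok <- ok & !neg
    }
    D[, d] <- Dd
    vm <- array(FALSE, dims); vm[mask] <- ok
    vals <- array(NA_real_, dims); vals[mask] <- Dd
    dir_maps[[d]] <- parametric_map(vals, "adc_dir", "mm^2/s", vm,
                                    provenance = list(direction = d,
                                                      b_values = b_values,
                                                      n_invalid = sum(!ok)),
                                    voxel_size = voxel_size)
    ok_all <- ok_all & ok
  }
  # trace needs every direction valid at the voxel
  trace_vals <- rowMeans(D)
  ok_tr <- ok_all & is.finite(trace_vals)
  trace_vals[!ok_tr] <- NA_real_
  vals <- array(NA_real_, dims); vals[mask] <- trace_vals
  vm <- array(FALSE, dims); vm[mask] <- ok_tr
  trace <- parametric_map(vals, "adc_trace", "mm^2/s", vm,
                          provenance = list(b_values = b_values,
                                            n_directions = length(dwi),
                                            n_invalid = sum(mask) - sum(vm),
                                            n_nonpositive_signal = n_nonpos,
                                            n_negative_fit = n_negative,
                                            clip_negative = clip_negative),
                          voxel_size = voxel_size)
  list(trace = trace, directions = dir_maps)
}

ratio_map <- function(num, den_ref, kind, mask, provenance, voxel_size) {
  dims <- dim(num)
  if (is.null(mask)) mask <- array(TRUE, dims)
  ok <- mask & is.finite(den_ref) & den_ref > 0 & is.finite(num)
  vals <- array(NA_real_, dims)
  vals[ok] <- num[ok] / den_ref[ok]
  provenance$n_invalid <- sum(mask) - sum(ok)
  parametric_map(vals, kind, "fraction", ok, provenance, voxel_size)
}

#' Compute a magnetization transfer ratio map
#'
#' `MTR = (S_off - S_on) / S_off` per voxel, as a fraction (multiply by 100
#' for percent units in reports). Voxels with non-positive `s_off` inside
#' the mask are invalidated and counted.
#'
#' @param s_off,s_on Aligned 3D volumes without and with the MT saturation
#'   pulse.
#' @param mask Optional logical array.
#' @param voxel_size Optional voxel size carried into the map.
#' @return A [parametric_map] of kind `mtr`.
#' @export
compute_mtr <- function(s_off, s_on, mask = NULL, voxel_size = NULL) {
  stopifnot(identical(dim(s_off), dim(s_on)))
  ratio_map(s_off - s_on, s_off, "mtr", mask,
            list(conditions = c("mt_off", "mt_on")), voxel_size)
}

#' Compute a fractional gadolinium enhancement map
#'
#' The pre-contrast image is subtracted from the post-contrast image and
#' expressed relative to the pre-contrast image: `E = (post - pre) / pre`.
#' Voxels with non-positive pre-contrast signal are invalidated and counted.
#'
#' @param pre,post Aligned pre- and post-contrast 3D volumes.
#' @param mask Optional logical array.
#' @param voxel_size Optional voxel size carried into the map.
#' @return A [parametric_map] of kind `enhancement`.
#' @export
compute_enhancement <- function(pre, post, mask = NULL, voxel_size = NULL) {
  stopifnot(identical(dim(pre), dim(post)))
  ratio_map(post - pre, pre, "enhancement", mask,
            list(conditions = c("gd_pre", "gd_post")), voxel_size)
}
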