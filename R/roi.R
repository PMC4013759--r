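#' Measure ROI-normalised contrast
#'
#' Computes the study's normalised intensity measure
#' `(ROI - control) / control` from the mean signal in a nucleus ROI and
#' its paired control region. For modalities in which pathology lowers the
#' value (ADC, MTR), `invert = TRUE` negates the contrast so that disease
#' effects carry the same sign across modalities.
#'
#' Invalid voxels (`NA` in a plain array, or masked-out voxels of a
#' [parametric_map]) are excluded from the means and counted; they are
#' never imputed.
#'
#' @param x A 3D array or a [parametric_map].
#' @param roi,control [roi_definition()]s for the nucleus and its paired
#'   control region.
#' @param voxel_size Voxel size in mm; taken from the map if available.
#' @param invert Negate the contrast (ADC/MTR convention).
#' @param modality Label recorded in the result.
#' @return An object of class `roi_measurement` with fields `roi_label`,
#'   `modality`, `mean_roi`, `mean_control`, `contrast`, `inverted`,
#'   `n_voxels_roi`, `n_voxels_control`, `n_invalid_roi`,
#'   `n_invalid_control`.
#' @export
measure_roi <- function(x, roi, control, voxel_size = NULL, invert = FALSE,
                        modality = NULL) {
  if (inherits(x, "parametric_map")) {
    vals <- x$values
    vals[!x$mask] <- NA_real_
    voxel_size <- voxel_size %||% x$voxel_size
    modality <- modality %||% x$kind
  } else {
    vals <- x
    modality <- modality %||% "image"
  }
  if (is.null(voxel_size)) stop_bsq("voxel_size required for a bare array")
  ri <- rasterize_roi(roi, dim(vals), voxel_size)
  ci <- rasterize_roi(control, dim(vals), voxel_size)
  rv <- vals[ri]; cv <- vals[ci]
  n_inv_r <- sum(is.na(rv)); n_inv_c <- sum(is.na(cv))
  rv <- rv[!is.na(rv)]; cv <- cv[!is.na(cv)]
  if (!length(rv)) stop_bsq("ROI '", roi$label, "' has no valid voxels")
  if (!length(cv)) stop_bsq("control region has no valid voxels")
  mr <- mean(rv); mc <- mean(cv)
  if (mc == 0) stop_bsq("control-region mean is zero; contrast undefined")
  contrast <- (mr - mc) / mc
  if (invert) contrast <- -contrast
  structure(list(roi_label = roi$label, modality = modality,
                 mean_roi = mr, mean_control = mc, contrast = contrast,
                 inverted = invert,
                 n_voxels_roi = length(rv), n_voxels_control = length(cv),
                 n_invalid_roi = n_inv_r, n_invalid_control = n_inv_c),
            class = "roi_measurement")
}

#' @export
print.roi_measurement <- function(x, ...) {
  cat(sprintf("ROI %s [%s]: mean %.6g vs control %.6g -> contrast %.6g%s\n",
              x$roi_label, x$modality, x$mean_roi, x$mean_control,
              x$contrast, if (x$inverted) " (inverted)" else ""))
  invisible(x)
}

#' @export
as.data.frame.roi_measurement <- function(x, ...) {
  data.frame(roi_label = x$roi_label, modality = x$modality,
             mean_roi = x$mean_roi, mean_control = x$mean_control,
             contrast = x$contrast, inverted = x$inverted,
             n_voxels_roi = x$n_voxels_roi,
             n_voxels_control = x$n_voxels_control,
             n_invalid_roi = x$n_invalid_roi,
             n_invalid_control = x$n_invalid_control,
             stringsAsFactors = FALSE)
}

#' Fold change of cell means against a reference
#'
#' For a long-format measurement table, computes per-cell fold change
#' `cell mean / reference mean` where the reference is either the
#' age-matched mean of a reference group (default, reference group `"WT"`)
#' or the group's own earliest-age baseline. The reference choice is
#' recorded in the output's `"reference"` attribute.
#'
#' @param table Data.frame with columns `group`, `age`, `value` and
#'   optionally `region` (cells are `group x age x region`).
#' @param reference `"group_age_matched"` or `"baseline_age"`.
#' @param reference_group Reference group label for age-matched
#'   normalisation (default `"WT"`).
#' @param baseline_age Baseline age; default the youngest age present.
#' @return Data.frame of cells with `mean`, `reference_mean` and `fold`.
#' @export
fold_change_series <- function(table,
                               reference = c("group_age_matched", "baseline_age"),
                               reference_group = "WT", baseline_age = NULL) {
  reference <- match.arg(reference)
  req <- c("group", "age", "value")
  if (!all(req %in% names(table)))
    stop_bsq("table needs columns ", paste(req, collapse = ", "))
  if (!"region" %in% names(table)) table$region <- "pooled"
  cells <- aggregate(value ~ group + age + region, table, mean)
  names(cells)[names(cells) == "value"] <- "mean"
  ref_mean <- numeric(nrow(cells))
  if (reference == "group_age_matched") {
    if (!any(cells$group == reference_group))
      stop_bsq("reference group '", reference_group, "' absent from table")
    for (i in seq_len(nrow(cells))) {
      j <- cells$group == reference_group & cells$age == cells$age[i] &
        cells$region == cells$region[i]
      if (!any(j))
        stop_bsq("no reference cell for age ", cells$age[i],
                 ", region ", cells$region[i])
      ref_mean[i] <- cells$mean[j][1]
    }
  } else {
    baseline_age <- baseline_age %||% min(cells$age)
    for (i in seq_len(nrow(cells))) {
      j <- cells$group == cells$group[i] & cells$age == baseline_age &
        cells$region == cells$region[i]
      if (!any(j))
        stop_bsq("no baseline cell at age ", baseline_age,
                 " for group ", cells$group[i], ", region ", cells$region[i])
      ref_mean[i] <- cells$mean[j][1]
    }
  }
  if (any(ref_mean == 0)) stop_bsq("reference mean is zero; fold undefined")
  cells$reference_mean <- ref_mean
  cells$fold <- cells$mean / ref_mean
  attr(cells, "reference") <- list(type = reference,
                                   reference_group = reference_group,
                                   baseline_age = baseline_age)
  cells
}
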