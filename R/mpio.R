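# neighbourhood offsets for 6-, 18- or 26-connectivity in 3D
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop_bsq("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  g
}

# label connected components of a logical 3D array by building the voxel
# adjacency graph and taking its connected components
label_components <- function(sub, connectivity = 26) {
  dims <- dim(sub)
  idx <- which(sub)
  if (!length(idx))
    return(list(labels = integer(0), index = integer(0), n = 0L))
  ar <- arrayInd(idx, dims)
  pos <- array(0L, dims); pos[idx] <- seq_along(idx)
  off <- connectivity_offsets(connectivity)
  # half neighbourhood: each undirected edge counted once
  keep <- (off[, 3] > 0) | (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off <- off[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- sweep(ar, 2, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    ni <- pos[nb[ok, , drop = FALSE]]
    sel <- ni > 0L
    from <- c(from, which(ok)[sel]); to <- c(to, ni[sel])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)
  list(labels = comp$membership, index = idx, n = comp$no)
}

#' Detect MPIO-induced hypointensities
#'
#' Applies the study's detection rule to a T2*-weighted volume: voxels
#' strictly below `fraction` (default 65%) of the mean signal intensity of
#' all voxels in the tissue mask are hypointense; contiguous hypointense
#' voxels are grouped into connected components; components larger than
#' `size_cutoff` voxels (default 20) are excluded to omit larger structures
#' such as sinuses. The percentage of hypointense voxels is reported over
#' the mask, with excluded-cluster voxels absent from the numerator but
#' still in the denominator.
#'
#' The mask mean includes sub-threshold voxels (no iterative
#' re-estimation), and ties at exactly the threshold are not hypointense.
#'
#' @param volume 3D numeric array.
#' @param mask Logical array of tissue voxels (non-empty; volume must be
#'   finite within it).
#' @param fraction Threshold as a fraction of the in-mask mean signal.
#' @param size_cutoff Maximum retained component size in voxels.
#' @param connectivity 3D neighbourhood: 6, 18 or 26 (default).
#' @param size_rule `"gt"` (default) excludes components with size strictly
#'   greater than `size_cutoff`; `"ge"` also excludes components of exactly
#'   the cutoff size.
#' @return An object of class `hypointensity_result` with the threshold,
#'   retained and excluded cluster tables (size + centroid), voxel counts
#'   and `percent_hypointense`.
#' @export
detect_hypointensities <- function(volume, mask, fraction = 0.65,
                                   size_cutoff = 20, connectivity = 26,
                                   size_rule = c("gt", "ge")) {
  size_rule <- match.arg(size_rule)
  stopifnot(identical(dim(volume), dim(mask)))
  if (!any(mask)) stop_bsq("mask is empty")
  if (any(!is.finite(volume[mask])))
    stop_bsq("volume contains non-finite values inside the mask")
  if (fraction <= 0) stop_bsq("fraction must be positive")
  thr <- fraction * mean(volume[mask])
  sub <- mask & volume < thr
  lab <- label_components(sub, connectivity)
  cluster_table <- function(ids) {
    if (!length(ids))
      return(data.frame(size = integer(0), cx = numeric(0), cy = numeric(0),
                        cz = numeric(0)))
    do.call(rbind, lapply(ids, function(i) {
      vox <- arrayInd(lab$index[lab$labels == i], dim(volume))
      data.frame(size = nrow(vox), cx = mean(vox[, 1]), cy = mean(vox[, 2]),
                 cz = mean(vox[, 3]))
    }))
  }
  if (lab$n) {
    sizes <- tabulate(lab$labels, lab$n)
    excluded_ids <- which(if (size_rule == "gt") sizes > size_cutoff
                          else sizes >= size_cutoff)
    retained_ids <- setdiff(seq_len(lab$n), excluded_ids)
  } else {
    sizes <- integer(0); excluded_ids <- integer(0); retained_ids <- integer(0)
  }
  retained <- cluster_table(retained_ids)
  excluded <- cluster_table(excluded_ids)
  n_ret <- sum(retained$size); n_mask <- sum(mask)
  structure(list(threshold_value = thr, fraction = fraction,
                 size_cutoff = size_cutoff, size_rule = size_rule,
                 connectivity = connectivity,
                 clusters_retained = retained, clusters_excluded = excluded,
                 n_hypo_voxels_retained = n_ret,
                 n_hypo_voxels_excluded = sum(excluded$size),
                 n_subthreshold_voxels = sum(sub),
                 n_mask_voxels = n_mask,
                 percent_hypointense = 100 * n_ret / n_mask),
            class = "hypointensity_result")
}

#' @export
print.hypointensity_result <- function(x, ...) {
  cat(sprintf("Hypointensity detection (< %.0f%% of mask mean, cutoff %d, %d-connectivity)\n",
              100 * x$fraction, x$size_cutoff, x$connectivity))
  cat(sprintf("  threshold %.6g | %d sub-threshold voxels in %d mask voxels\n",
              x$threshold_value, x$n_subthreshold_voxels, x$n_mask_voxels))
  cat(sprintf("  retained clusters: %d (%d voxels) | excluded: %d (%d voxels)\n",
              nrow(x$clusters_retained), x$n_hypo_voxels_retained,
              nrow(x$clusters_excluded), x$n_hypo_voxels_excluded))
  cat(sprintf("  percent hypointense: %.4g%%\n", x$percent_hypointense))
  invisible(x)
}

#' Per-region hypointensity report
#'
#' Runs [detect_hypointensities()] independently under each mask (e.g.
#' whole brain, cortex, brainstem), with the threshold recomputed per mask.
#'
#' @param volume 3D numeric array.
#' @param masks Named list of logical arrays. Overlapping masks are allowed
#'   but flagged in the `overlapping` attribute.
#' @param ... Passed to [detect_hypointensities()].
#' @return Data.frame with one row per mask: threshold, cluster and voxel
#'   counts, percent hypointense.
#' @export
per_region_report <- function(volume, masks, ...) {
  if (!length(masks) || is.null(names(masks)))
    stop_bsq("masks must be a non-empty named list")
  overlap <- FALSE
  nm <- names(masks)
  if (length(masks) > 1)
    for (i in seq_along(masks)[-1])
      for (j in seq_len(i - 1))
        if (any(masks[[i]] & masks[[j]])) overlap <- TRUE
  rows <- lapply(nm, function(n) {
    r <- detect_hypointensities(volume, masks[[n]], ...)
    data.frame(region = n, threshold = r$threshold_value,
               n_mask_voxels = r$n_mask_voxels,
               n_subthreshold = r$n_subthreshold_voxels,
               n_retained_clusters = nrow(r$clusters_retained),
               n_excluded_clusters = nrow(r$clusters_excluded),
               n_hypo_voxels_retained = r$n_hypo_voxels_retained,
               percent_hypointense = r$percent_hypointense,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overlapping") <- overlap
  out
}
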