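# Independent reference implementations used to cross-check the package.
# These are deliberately written with different algorithms from the package
# code paths (flood fill instead of graph components, per-voxel normal
# equations instead of vectorised slopes, explicit loops instead of
# vectorised masks).

oracle_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  g
}

# flood-fill component labelling, expanding one frontier level at a time
oracle_label_flood <- function(sub, connectivity) {
  dims <- dim(sub)
  idx <- which(sub)
  n <- length(idx)
  if (!n) return(list(labels = integer(0), index = integer(0)))
  ar <- arrayInd(idx, dims)
  pos <- array(0L, dims); pos[idx] <- seq_len(n)
  off <- oracle_offsets(connectivity); noff <- nrow(off)
  lab <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L; lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      a <- ar[frontier, , drop = FALSE]
      m <- nrow(a)
      nx <- rep(a[, 1], times = noff) + rep(off[, 1], each = m)
      ny <- rep(a[, 2], times = noff) + rep(off[, 2], each = m)
      nz <- rep(a[, 3], times = noff) + rep(off[, 3], each = m)
      ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
        nz >= 1 & nz <= dims[3]
      ni <- pos[cbind(nx[ok], ny[ok], nz[ok])]
      ni <- unique(ni[ni > 0L])
      frontier <- ni[lab[ni] == 0L]
      lab[frontier] <- cur
    }
  }
  list(labels = lab, index = idx)
}

# full detection rule applied literally: threshold, flood fill, size cutoff
oracle_detect <- function(volume, mask, fraction = 0.65, size_cutoff = 20,
                          connectivity = 26) {
  thr <- fraction * mean(volume[mask])
  sub <- mask & volume < thr
  lab <- oracle_label_flood(sub, connectivity)
  if (!length(lab$index))
    return(list(threshold = thr, retained_sizes = integer(0),
                excluded_sizes = integer(0), percent = 0))
  sizes <- as.integer(table(lab$labels))
  retained <- sizes[sizes <= size_cutoff]
  excluded <- sizes[sizes > size_cutoff]
  list(threshold = thr,
       retained_sizes = sort(retained), excluded_sizes = sort(excluded),
       percent = 100 * sum(retained) / sum(mask))
}

# per-voxel ADC via explicit normal equations solve(t(X) X) t(X) y
oracle_adc_voxel <- function(S, b) {
  if (any(S <= 0)) return(NA_real_)
  X <- cbind(1, b)
  beta <- solve(t(X) %*% X, t(X) %*% log(S))
  -beta[2]
}

# ROI contrast by explicit loops over every voxel
oracle_roi_contrast <- function(vals, roi, control, voxel_size) {
  in_circle <- function(i, j, k, def) {
    x <- (i - 0.5) * voxel_size[1]; y <- (j - 0.5) * voxel_size[2]
    if (!is.null(def$slice_index)) {
      if (k != def$slice_index) return(FALSE)
      (x - def$center[1])^2 + (y - def$center[2])^2 <= (def$diameter / 2)^2
    } else {
      z <- (k - 0.5) * voxel_size[3]
      (x - def$center[1])^2 + (y - def$center[2])^2 +
        (z - def$center[3])^2 <= (def$diameter / 2)^2
    }
  }
  acc <- function(def) {
    s <- 0; n <- 0L
    d <- dim(vals)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      if (in_circle(i, j, k, def) && !is.na(vals[i, j, k])) {
        s <- s + vals[i, j, k]; n <- n + 1L
      }
    s / n
  }
  (acc(roi) - acc(control)) / acc(control)
}

# small phantom spec used across tests (noise-free unless overridden)
tiny_phantom_spec <- function(...) {
  args <- list(grid_shape = c(32, 32, 16),
               voxel_size = c(0.2, 0.2, 0.2),
               brainstem = list(center = NULL, semiaxes = c(2.6, 2.2, 1.3)),
               nuclei = list(
                 list(label = "V",   center = c(1.9, 3.2, 1.6), diameter = 1.4),
                 list(label = "VII", center = c(4.5, 3.2, 1.6), diameter = 1.2),
                 list(label = "XII", center = c(3.2, 4.6, 1.6), diameter = 1.1)),
               noise_model = list(type = "none"))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}
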