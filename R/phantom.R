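#' Specify a multimodal brainstem MRI phantom
#'
#' Describes a synthetic brainstem volume containing the three cranial motor
#' nuclei (trigeminal V, facial VII, hypoglossal XII) as spheres inside an
#' ellipsoidal brainstem mask, together with the ground-truth tissue
#' parameters from which every modality is synthesised: T2 signal fold
#' change per nucleus relative to surrounding brainstem, per-direction
#' diffusivity, magnetization transfer ratio, fractional gadolinium
#' enhancement, and an inventory of MPIO-like hypointense clusters for the
#' T2*-weighted volume.
#'
#' Geometry is deliberately schematic (spheres in an ellipsoid): the point of
#' the phantom is that every downstream quantification can be checked against
#' exact truth, not anatomical realism.
#'
#' @param grid_shape Voxels per axis (length 3).
#' @param voxel_size Voxel edge length in mm per axis (length 3).
#' @param brainstem List with `center` (mm; default grid centre) and
#'   `semiaxes` (mm) of the ellipsoidal brainstem mask.
#' @param nuclei List of nuclei, each `list(label, center, diameter)` with
#'   `center` in mm and `diameter` in mm.
#' @param s0 Baseline signal intensity inside the brainstem (arbitrary units).
#' @param t2_fold_change Named multiplicative T2 contrast per nucleus versus
#'   surrounding brainstem (>= 1 for disease regions). The default is an
#'   end-stage preset with the largest effect in the facial nucleus.
#' @param adc_truth Named list (regions `brainstem`, nucleus labels) of
#'   per-direction diffusivities in mm^2/s, each length 3. Values must lie in
#'   (0, 4e-3).
#' @param mtr_truth Named vector of MTR fractions in `[0, 1)` per region.
#' @param enhancement_truth Named vector of fractional gadolinium enhancement
#'   per region.
#' @param b_values Diffusion weightings in s/mm^2 used to synthesise the
#'   diffusion-weighted series.
#' @param mpio_clusters List of hypointense clusters for the T2* volume, each
#'   `list(center, size, depth)`: `center` in mm, `size` in voxels, `depth`
#'   the cluster intensity as a fraction of the in-mask mean signal.
#' @param noise_model `list(type, sigma)` with `type` one of `"none"`,
#'   `"gaussian"`, `"rician"`. Rician is the default for magnitude MRI.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_mri_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 24),
                         voxel_size = c(0.15, 0.15, 0.15),
                         brainstem = list(center = NULL,
                                          semiaxes = c(3.0, 2.6, 1.5)),
                         nuclei = list(
                           list(label = "V",   center = c(2.2, 3.6, 1.8), diameter = 1.4),
                           list(label = "VII", center = c(5.0, 3.6, 1.8), diameter = 1.2),
                           list(label = "XII", center = c(3.6, 5.2, 1.8), diameter = 1.1)),
                         s0 = 100,
                         t2_fold_change = c(V = 10, VII = 15, XII = 8),
                         adc_truth = list(brainstem = rep(7e-4, 3),
                                          V = rep(5.5e-4, 3),
                                          VII = rep(5.5e-4, 3),
                                          XII = rep(5.5e-4, 3)),
                         mtr_truth = c(brainstem = 0.35, V = 0.30,
                                       VII = 0.30, XII = 0.30),
                         enhancement_truth = c(brainstem = 0, V = 0,
                                               VII = 0, XII = 0),
                         b_values = c(125, 500, 1000),
                         mpio_clusters = list(),
                         noise_model = list(type = "rician", sigma = 5),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, length(voxel_size) == 3)
  if (any(grid_shape < 2) || any(voxel_size <= 0))
    stop_bsq("grid_shape must be >= 2 and voxel_size positive on every axis")
  if (is.null(brainstem$center))
    brainstem$center <- grid_shape * voxel_size / 2
  labels <- vapply(nuclei, function(n) n$label, character(1))
  if (anyDuplicated(labels)) stop_bsq("nucleus labels must be unique")
  for (n in nuclei)
    if (n$diameter <= 0) stop_bsq("nucleus diameters must be > 0")
  regions <- c("brainstem", labels)
  for (r in regions) {
    a <- adc_truth[[r]]
    if (is.null(a) || length(a) != 3 || any(a <= 0) || any(a >= 4e-3))
      stop_bsq("adc_truth for region '", r,
               "' must be 3 per-direction values in (0, 4e-3) mm^2/s")
    m <- mtr_truth[[r]]
    if (is.null(m) || m < 0 || m >= 1)
      stop_bsq("mtr_truth for region '", r, "' must lie in [0, 1)")
    if (is.null(enhancement_truth[[r]]) || !is.finite(enhancement_truth[[r]]))
      stop_bsq("enhancement_truth missing or non-finite for region '", r, "'")
  }
  for (lab in labels)
    if (is.null(t2_fold_change[[lab]]) || t2_fold_change[[lab]] < 1)
      stop_bsq("t2_fold_change must be >= 1 for every nucleus")
  if (length(b_values) < 2) stop_bsq("need at least 2 b-values")
  if (!noise_model$type %in% c("none", "gaussian", "rician"))
    stop_bsq("noise_model$type must be none, gaussian or rician")
  if (noise_model$type != "none" && (is.null(noise_model$sigma) || noise_model$sigma < 0))
    stop_bsq("noise sigma must be >= 0")
  for (cl in mpio_clusters) {
    if (is.null(cl$center) || is.null(cl$size) || is.null(cl$depth))
      stop_bsq("each mpio cluster needs center, size and depth")
    if (cl$size < 1 || cl$depth < 0)
      stop_bsq("mpio cluster size must be >= 1 and depth >= 0")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 brainstem = brainstem, nuclei = nuclei, s0 = s0,
                 t2_fold_change = t2_fold_change, adc_truth = adc_truth,
                 mtr_truth = mtr_truth, enhancement_truth = enhancement_truth,
                 b_values = b_values, mpio_clusters = mpio_clusters,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Brainstem MRI phantom spec\n")
  cat("  grid:", paste(x$grid_shape, collapse = " x "),
      "voxels @", paste(x$voxel_size, collapse = " x "), "mm\n")
  cat("  nuclei:", paste(vapply(x$nuclei, `[[`, "", "label"), collapse = ", "), "\n")
  cat("  T2 fold change:", paste(names(x$t2_fold_change), signif(x$t2_fold_change, 3),
                                 sep = "=", collapse = ", "), "\n")
  cat("  noise:", x$noise_model$type,
      if (x$noise_model$type != "none") paste0("(sigma=", x$noise_model$sigma, ")"), "\n")
  cat("  MPIO clusters:", length(x$mpio_clusters), " seed:", x$seed, "\n")
  invisible(x)
}

# voxel-centre coordinates (mm) along one axis
vox_centers <- function(n, size) (seq_len(n) - 0.5) * size

# integer label map: 0 outside, 1 brainstem, 1 + k for the k-th nucleus
phantom_label_map <- function(spec) {
  d <- spec$grid_shape; vs <- spec$voxel_size
  xs <- vox_centers(d[1], vs[1]); ys <- vox_centers(d[2], vs[2])
  zs <- vox_centers(d[3], vs[3])
  bc <- spec$brainstem$center; ba <- spec$brainstem$semiaxes
  e2 <- outer(outer(((xs - bc[1]) / ba[1])^2, ((ys - bc[2]) / ba[2])^2, "+"),
              ((zs - bc[3]) / ba[3])^2, "+")
  lab <- array(0L, d)
  lab[e2 <= 1] <- 1L
  for (k in seq_along(spec$nuclei)) {
    nu <- spec$nuclei[[k]]
    r2 <- (nu$diameter / 2)^2
    d2 <- outer(outer((xs - nu$center[1])^2, (ys - nu$center[2])^2, "+"),
                (zs - nu$center[3])^2, "+")
    inside <- d2 <= r2
    if (!any(inside)) stop_bsq("nucleus ", nu$label, " rasterises to 0 voxels")
    if (any(lab[inside] == 0L))
      stop_bsq("nucleus ", nu$label, " extends outside the brainstem mask")
    lab[inside] <- 1L + k
  }
  lab
}

# map per-region values onto the grid; values named by region, index 1 is
# brainstem, 1 + k the k-th nucleus; outside voxels get `outside`
region_fill <- function(lab, values, outside = 0) {
  lut <- c(outside, values)
  array(lut[lab + 1L], dim(lab))
}

apply_noise <- function(vol, model) {
  switch(model$type,
    none = vol,
    gaussian = vol + array(rnorm(length(vol), 0, model$sigma), dim(vol)),
    rician = {
      re <- vol + array(rnorm(length(vol), 0, model$sigma), dim(vol))
      im <- array(rnorm(length(vol), 0, model$sigma), dim(vol))
      sqrt(re^2 + im^2)
    })
}

# the `size` grid voxels nearest to `center` (mm), ties broken by linear index
cluster_voxels <- function(spec, center, size) {
  d <- spec$grid_shape; vs <- spec$voxel_size
  xs <- vox_centers(d[1], vs[1]); ys <- vox_centers(d[2], vs[2])
  zs <- vox_centers(d[3], vs[3])
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  order(d2)[seq_len(size)]
}

#' Generate a multimodal MRI phantom with ground truth
#'
#' Synthesises the full acquisition set of a multimodal brainstem session
#' from a [phantom_spec()]: a T2-weighted volume with per-nucleus fold
#' change; a diffusion-weighted volume per (direction, b-value) following
#' mono-exponential decay `S(b) = S0 * exp(-b * D_dir)`; an MT-off/MT-on
#' pair with `S_on = S_off * (1 - MTR)`; a pre/post-gadolinium pair with
#' `post = pre * (1 + enhancement)`; and a T2*-weighted volume with injected
#' hypointense clusters rendered at `depth x` the in-mask mean signal.
#' Noise is applied last, per the spec's noise model.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volumes` (a [volume_set()]) and `truth`
#'   (class `phantom_truth`: label map, per-region truth table, cluster
#'   inventory with retained/excluded status under the default detection
#'   rule, and masks).
#' @export
generate_mri_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_label_map(spec)
  mask <- lab > 0L
  nlab <- vapply(spec$nuclei, `[[`, "", "label")
  regions <- c("brainstem", nlab)
  nreg <- length(regions)

  fold <- c(1, vapply(nlab, function(l) spec$t2_fold_change[[l]], 0))
  mtr <- vapply(regions, function(r) spec$mtr_truth[[r]], 0)
  enh <- vapply(regions, function(r) spec$enhancement_truth[[r]], 0)
  adc <- t(vapply(regions, function(r) spec$adc_truth[[r]], numeric(3)))

  vols <- list()
  vols$t2 <- spec$s0 * region_fill(lab, fold)
  for (dir in 1:3) {
    dmap <- region_fill(lab, adc[, dir])
    for (b in spec$b_values) {
      key <- sprintf("dwi_dir%d_b%g", dir, b)
      vols[[key]] <- spec$s0 * exp(-b * dmap) * mask
    }
  }
  vols$mt_off <- spec$s0 * mask
  vols$mt_on <- vols$mt_off * (1 - region_fill(lab, mtr))
  vols$gd_pre <- spec$s0 * mask
  vols$gd_post <- vols$gd_pre * (1 + region_fill(lab, enh))

  t2star <- spec$s0 * mask
  local_mean <- mean(t2star[mask])
  ncl <- length(spec$mpio_clusters)
  cl_idx <- vector("list", ncl)
  taken <- integer(0)
  for (k in seq_len(ncl)) {
    cl <- spec$mpio_clusters[[k]]
    idx <- cluster_voxels(spec, cl$center, cl$size)
    if (any(!mask[idx]))
      stop_bsq("mpio cluster ", k, " (size ", cl$size,
               ") exceeds the brainstem mask")
    if (any(idx %in% taken))
      stop_bsq("mpio cluster ", k, " overlaps an earlier cluster")
    t2star[idx] <- cl$depth * local_mean
    cl_idx[[k]] <- idx
    taken <- c(taken, idx)
  }
  vols$t2star <- t2star

  # retained/excluded status under the default detection rule, judged on the
  # noise-free volume (threshold from the post-injection in-mask mean)
  fraction <- 0.65; size_cutoff <- 20L
  thr <- fraction * mean(t2star[mask])
  clusters <- data.frame(
    cluster = seq_len(ncl),
    size = vapply(spec$mpio_clusters, function(c) as.integer(c$size), 0L),
    depth = vapply(spec$mpio_clusters, function(c) c$depth, 0),
    stringsAsFactors = FALSE)
  if (ncl) {
    clusters$subthreshold <- clusters$depth * local_mean < thr
    clusters$retained <- clusters$subthreshold & clusters$size <= size_cutoff
  } else {
    clusters$subthreshold <- logical(0); clusters$retained <- logical(0)
  }

  vols <- with_seed(spec$seed,
                    lapply(vols, apply_noise, model = spec$noise_model))

  region_table <- data.frame(
    region = regions, label = seq_len(nreg),
    t2_fold = fold, mtr = mtr, enhancement = enh,
    adc_dir1 = adc[, 1], adc_dir2 = adc[, 2], adc_dir3 = adc[, 3],
    adc_trace = rowMeans(adc), row.names = NULL, stringsAsFactors = FALSE)

  truth <- structure(list(
    label_map = lab, regions = region_table, clusters = clusters,
    cluster_voxels = cl_idx, mask = mask,
    n_mask_voxels = sum(mask), s0 = spec$s0, b_values = spec$b_values,
    voxel_size = spec$voxel_size, noise_model = spec$noise_model,
    detection_rule = list(fraction = fraction, size_cutoff = size_cutoff),
    t2star_local_mean = local_mean), class = "phantom_truth")

  list(volumes = volume_set(vols, voxel_size = spec$voxel_size),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("Phantom ground truth:", x$n_mask_voxels, "in-mask voxels\n")
  print(x$regions)
  if (nrow(x$clusters)) {
    cat("MPIO clusters:\n"); print(x$clusters)
  }
  invisible(x)
}

#' Published H-DAB stain vectors
#'
#' Unit absorption vectors (RGB optical-density space) for hematoxylin and
#' DAB as published by Ruifrok and Johnston for colour deconvolution of
#' H-DAB stained sections.
#'
#' @return A 2 x 3 matrix with rows `hematoxylin` and `dab`, each unit norm.
#' @export
hdab_stain_vectors <- function() {
  m <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             dab = c(0.269, 0.568, 0.778))
  m / sqrt(rowSums(m^2))
}

#' Specify a synthetic brightfield histology field
#'
#' Describes an RGB brightfield image synthesised by the Beer-Lambert law
#' from two stain density fields (hematoxylin counterstain and DAB reaction
#' product): `I_c = I0_c * 10^(-sum_s density_s * v_s,c)`. Elliptical
#' vacuoles render at background (white) intensity inside the tissue.
#'
#' @param image_shape Pixels per axis (rows, cols).
#' @param i0 White level per RGB channel (the intensity of light through
#'   empty glass). Images are generated on the `[0, i0]` scale; the default
#'   `c(1, 1, 1)` suits PNG round-trips.
#' @param stain_vectors 2 x 3 matrix of unit absorption vectors (rows:
#'   hematoxylin, DAB); default [hdab_stain_vectors()].
#' @param hematoxylin_density,dab_density Scalar or `image_shape` matrix of
#'   stain amount (optical-density units). The defaults emulate a uniformly
#'   counterstained section with a central disc of DAB-positive tissue.
#' @param vacuoles List of ellipses `list(center, axes, angle)` in pixel
#'   units (row/col centre, semi-axes, rotation in radians).
#' @param noise_sigma Gaussian intensity noise SD (same units as `i0`),
#'   applied last and clipped to `[0, i0]`.
#' @param seed Integer seed.
#' @return An object of class `histology_spec`.
#' @export
histology_spec <- function(image_shape = c(128, 128),
                           i0 = c(1, 1, 1),
                           stain_vectors = hdab_stain_vectors(),
                           hematoxylin_density = 0.5,
                           dab_density = NULL,
                           vacuoles = list(),
                           noise_sigma = 0,
                           seed = 1L) {
  stopifnot(length(image_shape) == 2, length(i0) == 3)
  if (any(image_shape < 1)) stop_bsq("image_shape must be positive")
  if (any(i0 <= 0)) stop_bsq("i0 must be positive in every channel")
  if (!is.matrix(stain_vectors) || ncol(stain_vectors) != 3 ||
      !nrow(stain_vectors) %in% c(2, 3))
    stop_bsq("stain_vectors must be a 2x3 or 3x3 matrix")
  if (any(stain_vectors < 0)) stop_bsq("stain vectors must be non-negative")
  stain_vectors <- stain_vectors / sqrt(rowSums(stain_vectors^2))
  if (qr(stain_vectors)$rank < nrow(stain_vectors))
    stop_bsq("stain vectors are collinear")
  if (is.null(dab_density)) {
    # central DAB-positive disc: immunopositive nucleus on counterstain
    rr <- row(matrix(0, image_shape[1], image_shape[2]))
    cc <- col(matrix(0, image_shape[1], image_shape[2]))
    ctr <- image_shape / 2
    dab_density <- 0.8 * ((rr - ctr[1])^2 + (cc - ctr[2])^2 <=
                            (min(image_shape) / 4)^2)
  }
  expand <- function(x)
    if (is.matrix(x)) {
      if (!all(dim(x) == image_shape)) stop_bsq("density field shape mismatch")
      x
    } else matrix(x, image_shape[1], image_shape[2])
  if (noise_sigma < 0) stop_bsq("noise_sigma must be >= 0")
  for (v in vacuoles)
    if (any(v$axes <= 0)) stop_bsq("vacuole semi-axes must be positive")
  structure(list(image_shape = as.integer(image_shape), i0 = as.numeric(i0),
                 stain_vectors = stain_vectors,
                 hematoxylin_density = expand(hematoxylin_density),
                 dab_density = expand(dab_density),
                 vacuoles = vacuoles, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "histology_spec")
}

# logical mask of pixels whose centres fall inside any ellipse
ellipse_mask <- function(shape, ellipses) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (!length(ellipses)) return(m)
  rr <- row(m); cc <- col(m)
  for (e in ellipses) {
    ang <- e$angle %||% 0
    dr <- rr - e$center[1]; dc <- cc - e$center[2]
    u <- dr * cos(ang) + dc * sin(ang)
    v <- -dr * sin(ang) + dc * cos(ang)
    m <- m | (u / e$axes[1])^2 + (v / e$axes[2])^2 <= 1
  }
  m
}

#' Generate a brightfield histology image with ground truth
#'
#' @param spec A [histology_spec()].
#' @return A list with `image` (rows x cols x 3 array on the `[0, i0]`
#'   scale) and `truth` (per-pixel stain density fields after vacuole
#'   clearing, the vacuole mask, stain vectors and white level).
#' @export
generate_histology_image <- function(spec) {
  stopifnot(inherits(spec, "histology_spec"))
  hem <- spec$hematoxylin_density
  dab <- spec$dab_density
  vac <- ellipse_mask(spec$image_shape, spec$vacuoles)
  hem[vac] <- 0; dab[vac] <- 0   # vacuoles are unstained holes
  img <- array(0, c(spec$image_shape, 3))
  for (ch in 1:3) {
    od <- hem * spec$stain_vectors[1, ch] + dab * spec$stain_vectors[2, ch]
    img[, , ch] <- spec$i0[ch] * 10^(-od)
  }
  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed,
                     img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img)))
    for (ch in 1:3)
      img[, , ch] <- pmin(pmax(img[, , ch], 0), spec$i0[ch])
  }
  truth <- structure(list(hematoxylin_density = hem, dab_density = dab,
                          vacuole_mask = vac, n_vacuole_px = sum(vac),
                          stain_vectors = spec$stain_vectors, i0 = spec$i0),
                     class = "histology_truth")
  list(image = img, truth = truth)
}

#' Default cohort effect design
#'
#' Per-cell means and SDs of the ROI-normalised T2 contrast for a
#' cross-sectional SOD1-G93A versus wild-type design (ages 40-120 days,
#' nuclei V/VII/XII). Wild-type contrast is centred on zero at all ages;
#' transgenic contrast rises earliest and furthest in the facial nucleus,
#' reaching the ~15-fold end-stage T2 signal increase (contrast 14) at 120
#' days. SDs scale with the mean, reflecting the multiplicative nature of
#' the pathology; the floor keeps null cells realistically noisy.
#'
#' @return A data.frame with columns `group`, `age`, `region`, `mean`, `sd`.
#' @export
default_cohort_design <- function() {
  ages <- c(40, 60, 80, 100, 120)
  sod1 <- list(V   = c(0, 0.2, 1.5, 4, 9),
               VII = c(0, 0.5, 2.0, 6, 14),
               XII = c(0, 0.1, 1.0, 3, 7))
  rows <- list()
  for (region in names(sod1)) {
    rows[[length(rows) + 1]] <- data.frame(
      group = "SOD1", age = ages, region = region, mean = sod1[[region]])
    rows[[length(rows) + 1]] <- data.frame(
      group = "WT", age = ages, region = region, mean = 0)
  }
  d <- do.call(rbind, rows)
  d$sd <- pmax(0.15, 0.25 * d$mean)
  d
}

#' Simulate a per-animal measurement cohort
#'
#' Draws independent normal per-animal ROI measurements for each design
#' cell, emulating a cross-sectional design in which each animal is scanned
#' once at one age.
#'
#' @param design Data.frame with columns `group`, `age`, `mean`, `sd` and
#'   optionally `region` and `modality`; default [default_cohort_design()].
#' @param n Animals per cell (>= 2).
#' @param seed Integer seed.
#' @return A long-format data.frame (`animal`, `group`, `age`, `region`,
#'   `modality`, `value`) of class `cohort_table`, with the design attached
#'   as attribute `"truth"`.
#' @export
generate_cohort <- function(design = default_cohort_design(), n = 4, seed = 1L) {
  req <- c("group", "age", "mean", "sd")
  if (!all(req %in% names(design)))
    stop_bsq("design needs columns ", paste(req, collapse = ", "))
  if (n < 2) stop_bsq("need n >= 2 animals per cell")
  if (any(design$sd <= 0))
    stop_bsq("cell SDs must be positive (degenerate cells cannot be simulated)")
  region <- design$region %||% rep("pooled", nrow(design))
  modality <- design$modality %||% rep("t2_contrast", nrow(design))
  out <- with_seed(seed, {
    vals <- lapply(seq_len(nrow(design)), function(i)
      rnorm(n, design$mean[i], design$sd[i]))
    data.frame(
      animal = paste0(rep(design$group, each = n), "_",
                      rep(design$age, each = n), "_",
                      rep(region, each = n), "_", seq_len(n)),
      group = rep(design$group, each = n),
      age = rep(design$age, each = n),
      region = rep(region, each = n),
      modality = rep(modality, each = n),
      value = unlist(vals), stringsAsFactors = FALSE)
  })
  attr(out, "truth") <- design
  class(out) <- c("cohort_table", "data.frame")
  out
}
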