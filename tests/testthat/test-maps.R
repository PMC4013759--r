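make_dwi <- function(S0, D_dirs, b, dims = c(4, 4, 3)) {
  lapply(D_dirs, function(D)
    lapply(b, function(bb) array(S0 * exp(-bb * D), dims)))
}

test_that("adc fit is exact on noiseless mono-exponential decay", {
  b <- c(125, 500, 1000)
  dwi <- make_dwi(100, c(7e-4, 7e-4, 7e-4), b)
  fit <- fit_adc(dwi, b)
  expect_lt(max(abs(fit$trace$values - 7e-4)), 1e-12)
  expect_true(all(fit$trace$mask))
  # constant signal across b -> zero diffusivity
  flat <- make_dwi(100, c(0, 0, 0), b)
  # D = 0 means S constant; build directly to avoid exp(0) subtlety
  flat <- lapply(1:3, function(d) lapply(b, function(bb) array(100, c(4, 4, 3))))
  fit0 <- fit_adc(flat, b)
  expect_lt(max(abs(fit0$trace$values)), 1e-15)
})

test_that("trace is the unweighted mean of directional fits", {
  b <- c(125, 500, 1000)
  fit <- fit_adc(make_dwi(100, c(1.0e-3, 0.5e-3, 0.3e-3), b), b)
  expect_equal(unique(as.vector(fit$trace$values)), 0.6e-3, tolerance = 1e-12)
  for (d in 1:3)
    expect_equal(unique(as.vector(fit$directions[[d]]$values)),
                 c(1.0e-3, 0.5e-3, 0.3e-3)[d], tolerance = 1e-12)
})

test_that("adc fit equals the per-voxel normal-equations oracle", {
  set.seed(42)
  b <- c(125, 500, 1000)
  dims <- c(5, 4, 3)
  dwi <- lapply(1:3, function(d)
    lapply(b, function(bb) array(exp(rnorm(prod(dims), log(80), 0.3)), dims)))
  fit <- fit_adc(dwi, b)
  for (v in seq_len(prod(dims))) {
    ijk <- arrayInd(v, dims)
    for (d in 1:3) {
      S <- vapply(seq_along(b), function(i)
        dwi[[d]][[i]][ijk[1], ijk[2], ijk[3]], numeric(1))
      expected <- oracle_adc_voxel(S, b)
      got <- fit$directions[[d]]$values[v]
      if (!is.na(expected) && expected < 0) {
        expect_true(is.na(got))  # negative fits are invalidated
      } else {
        expect_equal(got, expected, tolerance = 1e-10)
      }
    }
  }
  # with clipping disabled invalidation, the raw fit must match everywhere
  clip <- fit_adc(dwi, b, clip_negative = TRUE)
  for (v in sample(prod(dims), 20)) {
    ijk <- arrayInd(v, dims)
    S <- vapply(seq_along(b), function(i)
      dwi[[1]][[i]][ijk[1], ijk[2], ijk[3]], numeric(1))
    expect_equal(clip$directions[[1]]$values[v],
                 max(0, oracle_adc_voxel(S, b)), tolerance = 1e-10)
  }
})

test_that("non-positive signal and negative fits are flagged, not clipped", {
  b <- c(125, 500, 1000)
  dwi <- make_dwi(100, c(7e-4, 7e-4, 7e-4), b, dims = c(3, 3, 2))
  dwi[[2]][[3]][1, 1, 1] <- 0            # dead voxel in one direction
  dwi[[1]][[3]][2, 1, 1] <- 200          # rising signal -> negative D
  fit <- fit_adc(dwi, b)
  expect_false(fit$trace$mask[1, 1, 1])
  expect_true(is.na(fit$trace$values[1, 1, 1]))
  expect_false(fit$directions[[1]]$mask[2, 1, 1])
  expect_false(fit$trace$mask[2, 1, 1])
  expect_gte(fit$trace$provenance$n_nonpositive_signal, 1)
  expect_gte(fit$trace$provenance$n_negative_fit, 1)
  # counts conserved: valid + invalid = all voxels
  expect_identical(sum(fit$trace$mask) + fit$trace$provenance$n_invalid,
                   18L)
  # clipping zeroes the offending direction, so the trace is the mean of
  # the clipped directional fits
  clip <- fit_adc(dwi, b, clip_negative = TRUE)
  expect_identical(clip$directions[[1]]$values[2, 1, 1], 0)
  expect_equal(clip$trace$values[2, 1, 1], mean(c(0, 7e-4, 7e-4)),
               tolerance = 1e-12)
  expect_error(fit_adc(dwi, c(500, 500)), "distinct")
})

test_that("mtr and enhancement follow their defining ratios exactly", {
  off <- array(100, c(3, 3, 2)); on <- array(60, c(3, 3, 2))
  m <- compute_mtr(off, on)
  expect_true(all(m$values == 0.40))
  expect_true(all(compute_mtr(off, off)$values == 0))
  expect_true(all(compute_mtr(off, array(0, dim(off)))$values == 1))
  pre <- array(100, c(3, 3, 2)); post <- array(150, c(3, 3, 2))
  e <- compute_enhancement(pre, post)
  expect_true(all(e$values == 0.5))
  expect_true(all(compute_enhancement(pre, pre)$values == 0))
  # invalid voxels counted
  off[1, 1, 1] <- 0
  m2 <- compute_mtr(off, on)
  expect_false(m2$mask[1, 1, 1])
  expect_identical(m2$provenance$n_invalid, 1L)
})

test_that("phantom truth is recovered exactly at noise zero", {
  spec <- tiny_phantom_spec()
  p <- generate_mri_phantom(spec)
  mask <- p$truth$mask
  b <- spec$b_values
  dwi <- lapply(1:3, function(d)
    lapply(b, function(bb) p$volumes[[sprintf("dwi_dir%d_b%g", d, bb)]]))
  fit <- fit_adc(dwi, b, mask = mask)
  truth_trace <- region_truth <- p$truth$regions$adc_trace[p$truth$label_map[mask]]
  expect_lt(max(abs(fit$trace$values[mask] - truth_trace)), 1e-12)
  mtr <- compute_mtr(p$volumes[["mt_off"]], p$volumes[["mt_on"]], mask)
  expect_lt(max(abs(mtr$values[mask] -
                      p$truth$regions$mtr[p$truth$label_map[mask]])), 1e-15)
  enh <- compute_enhancement(p$volumes[["gd_pre"]], p$volumes[["gd_post"]], mask)
  expect_lt(max(abs(enh$values[mask] -
                      p$truth$regions$enhancement[p$truth$label_map[mask]])), 1e-15)
})

test_that("zero-fill resolution and scan durations match the printed protocol", {
  g3d <- acquisition_geometry(fov = c(22.5, 22.5, 11.25),
                              matrix_size = c(256, 192, 96),
                              zerofill = c(256, 256, 128),
                              tr = 0.065, n_phase_encodes = 192, n_averages = 2)
  res <- voxel_resolution(g3d)
  expect_equal(round(res * 1000), c(88, 88, 88))
  expect_equal(res[1], 22.5 / 256)
  t1 <- acquisition_geometry(fov = c(25, 25), matrix_size = c(256, 256),
                             tr = 0.5, n_phase_encodes = 256, n_averages = 2)
  expect_identical(scan_duration(t1), 256)          # 4 min 16 s
  dwi <- acquisition_geometry(fov = c(25, 25), matrix_size = c(128, 128),
                              tr = 2.0, n_phase_encodes = 128, n_averages = 1,
                              b_values = c(125, 500, 1000))
  expect_identical(scan_duration(dwi, n_repeats = 3), 768)  # 12 min 48 s
  expect_identical(scan_duration(acquisition_geometry(
    fov = 25, matrix_size = 1, tr = 1, n_phase_encodes = 1)), 1)
  expect_error(acquisition_geometry(fov = c(25, 25), matrix_size = c(256, 256),
                                    zerofill = c(128, 128), tr = 1,
                                    n_phase_encodes = 1), "zerofill")
})
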