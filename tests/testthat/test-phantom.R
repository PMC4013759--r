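test_that("phantom generation is deterministic for identical spec and seed", {
  spec <- tiny_phantom_spec(noise_model = list(type = "rician", sigma = 5),
                            seed = 7L)
  a <- generate_mri_phantom(spec)
  b <- generate_mri_phantom(spec)
  expect_identical(a$volumes$volumes, b$volumes$volumes)
  expect_identical(a$truth$label_map, b$truth$label_map)
  c <- generate_mri_phantom(tiny_phantom_spec(
    noise_model = list(type = "rician", sigma = 5), seed = 8L))
  expect_false(identical(a$volumes$volumes$t2, c$volumes$volumes$t2))
})

test_that("noise-free volumes are exactly consistent with the generating formulas", {
  spec <- tiny_phantom_spec()
  p <- generate_mri_phantom(spec)
  lab <- p$truth$label_map
  mask <- p$truth$mask
  # T2: s0 x fold per region
  for (k in seq_len(nrow(p$truth$regions))) {
    reg <- p$truth$regions[k, ]
    vox <- lab == reg$label
    expect_equal(unique(p$volumes[["t2"]][vox]), spec$s0 * reg$t2_fold)
    expect_equal(unique(p$volumes[["mt_off"]][vox]), spec$s0)
    expect_equal(unique(p$volumes[["mt_on"]][vox]), spec$s0 * (1 - reg$mtr))
    expect_equal(unique(p$volumes[["gd_post"]][vox]),
                 spec$s0 * (1 + reg$enhancement))
    for (b in spec$b_values)
      expect_equal(unique(p$volumes[[sprintf("dwi_dir1_b%g", b)]][vox]),
                   spec$s0 * exp(-b * reg$adc_dir1))
  }
  expect_true(all(p$volumes[["t2"]][!mask] == 0))
})

test_that("uniform fold change of 1 gives zero T2 ROI contrast", {
  spec <- tiny_phantom_spec(t2_fold_change = c(V = 1, VII = 1, XII = 1))
  p <- generate_mri_phantom(spec)
  roi <- roi_definition("VII", c(4.5, 3.2), 1.2, slice_index = 8)
  ctl <- roi_definition("control", c(3.2, 2.2), 1.0, slice_index = 8)
  m <- measure_roi(p$volumes[["t2"]], roi, ctl, voxel_size = spec$voxel_size)
  expect_identical(m$contrast, 0)
})

test_that("spec invariants are enforced", {
  expect_error(tiny_phantom_spec(adc_truth = list(
    brainstem = rep(5e-3, 3), V = rep(7e-4, 3), VII = rep(7e-4, 3),
    XII = rep(7e-4, 3))), "4e-03|adc")
  expect_error(tiny_phantom_spec(mtr_truth = c(brainstem = 1, V = 0.3,
                                               VII = 0.3, XII = 0.3)), "mtr")
  expect_error(tiny_phantom_spec(t2_fold_change = c(V = 0.5, VII = 2, XII = 2)),
               "fold")
  expect_error(tiny_phantom_spec(noise_model = list(type = "rician",
                                                    sigma = -1)), "sigma")
  # nucleus poking out of the brainstem mask
  expect_error(generate_mri_phantom(phantom_spec(
    grid_shape = c(32, 32, 16), voxel_size = c(0.2, 0.2, 0.2),
    brainstem = list(center = NULL, semiaxes = c(2.6, 2.2, 1.3)),
    nuclei = list(list(label = "V", center = c(0.8, 3.2, 1.6), diameter = 1.4)),
    t2_fold_change = c(V = 2),
    adc_truth = list(brainstem = rep(7e-4, 3), V = rep(7e-4, 3)),
    mtr_truth = c(brainstem = 0.3, V = 0.3),
    enhancement_truth = c(brainstem = 0, V = 0),
    noise_model = list(type = "none"))), "outside the brainstem")
})

test_that("mpio clusters render at depth x mask mean and fill the inventory", {
  spec <- tiny_phantom_spec(mpio_clusters = list(
    list(center = c(3.2, 3.2, 1.6), size = 8, depth = 0.4),
    list(center = c(2.0, 2.4, 1.6), size = 30, depth = 0.4)))
  p <- generate_mri_phantom(spec)
  v <- p$volumes[["t2star"]]
  lm <- p$truth$t2star_local_mean
  for (k in 1:2) {
    idx <- p$truth$cluster_voxels[[k]]
    expect_equal(length(idx), p$truth$clusters$size[k])
    expect_true(all(v[idx] == 0.4 * lm))
  }
  expect_equal(sum(p$truth$clusters$size), length(unlist(p$truth$cluster_voxels)))
  expect_equal(p$truth$clusters$retained, c(TRUE, FALSE))
  # a cluster bigger than the mask must be rejected with a diagnostic
  expect_error(generate_mri_phantom(tiny_phantom_spec(mpio_clusters = list(
    list(center = c(0.4, 0.4, 0.4), size = 10, depth = 0.4)))),
    "exceeds the brainstem mask")
})

test_that("rician background magnitude approaches sigma * sqrt(pi/2)", {
  sigma <- 5
  spec <- phantom_spec(grid_shape = c(72, 72, 32),
                       voxel_size = c(0.1, 0.1, 0.1),
                       noise_model = list(type = "rician", sigma = sigma),
                       seed = 11L)
  p <- generate_mri_phantom(spec)
  bg <- p$volumes[["t2"]][!p$truth$mask]
  expect_gt(length(bg), 1e5)
  expect_lt(abs(mean(bg) / (sigma * sqrt(pi / 2)) - 1), 0.02)
})

test_that("every voxel has exactly one label", {
  p <- generate_mri_phantom(tiny_phantom_spec())
  lab <- p$truth$label_map
  expect_true(all(lab %in% 0:4))
  expect_identical(sum(lab > 0), p$truth$n_mask_voxels)
})

test_that("cohort simulation recovers the design and rejects bad cells", {
  des <- data.frame(group = c("SOD1", "WT"), age = 120, region = "VII",
                    mean = c(2, 0), sd = 1)
  co <- generate_cohort(des, n = 500, seed = 3L)
  expect_equal(nrow(co), 1000)
  m <- tapply(co$value, co$group, mean)
  expect_lt(abs(m[["SOD1"]] - 2), 0.15)
  expect_lt(abs(m[["WT"]] - 0), 0.15)
  expect_identical(generate_cohort(des, n = 4, seed = 5L),
                   generate_cohort(des, n = 4, seed = 5L))
  des0 <- des; des0$sd <- 0
  expect_error(generate_cohort(des0, n = 4), "SD")
  expect_error(generate_cohort(des, n = 1), "n >= 2")
})

test_that("cohort effect-size simulation is consistent at true d = 2", {
  # mean sample d over replicates; small upward small-sample bias is
  # bounded by the Hedges factor 1 + 3/(4 df - 1) ~ 1.008 at n = 50
  des <- data.frame(group = c("SOD1", "WT"), age = 120, mean = c(2, 0), sd = 1)
  d <- vapply(1:300, function(r) {
    co <- generate_cohort(des, n = 50, seed = 1000L + r)
    cohens_d(co$value[co$group == "SOD1"], co$value[co$group == "WT"])$d
  }, numeric(1))
  expect_lt(abs(mean(d) - 2), 0.06)
})

test_that("null cohorts produce near-nominal two-group type-I error", {
  des <- data.frame(group = c("SOD1", "WT"), age = 120, mean = 0, sd = 1)
  p <- vapply(1:400, function(r) {
    co <- generate_cohort(des, n = 4, seed = 2000L + r)
    t.test(co$value[co$group == "SOD1"], co$value[co$group == "WT"],
           var.equal = TRUE)$p.value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / 400))
})
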