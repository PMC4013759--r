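test_that("optical density follows the decade absorbance definition", {
  img <- array(1, c(2, 2, 3))
  img[1, 1, ] <- 1        # white -> OD 0
  img[1, 2, ] <- 0.1      # one decade -> OD 1
  img[2, 1, ] <- 0.01     # two decades -> OD 2
  od <- rgb_to_od(img, i0 = c(1, 1, 1))
  expect_equal(od[1, 1, ], c(0, 0, 0))
  expect_equal(od[1, 2, ], c(1, 1, 1))
  expect_equal(od[2, 1, ], c(2, 2, 2))
  expect_true(all(od >= 0))
  expect_error(rgb_to_od(img, i0 = 0), "positive")
  # clip floor is recorded
  expect_equal(attr(od, "eps"), rep(1e-6, 3))
})

test_that("beer-lambert synthesis honours single-stain examples", {
  # single pixel with DAB density 1 and DAB vector (0,0,1): blue = I0/10
  spec <- histology_spec(image_shape = c(1, 1),
                         stain_vectors = rbind(hematoxylin = c(1, 0, 0),
                                               dab = c(0, 0, 1)),
                         hematoxylin_density = 0,
                         dab_density = 1)
  img <- generate_histology_image(spec)$image
  expect_equal(as.vector(img), c(1, 1, 0.1))
  # all densities zero -> image uniformly at I0
  spec0 <- histology_spec(image_shape = c(4, 4), hematoxylin_density = 0,
                          dab_density = 0)
  expect_true(all(generate_histology_image(spec0)$image == 1))
})

test_that("deconvolution inverts synthesis to machine precision", {
  set.seed(5)
  shape <- c(32, 32)
  spec <- histology_spec(
    image_shape = shape,
    hematoxylin_density = matrix(runif(prod(shape), 0, 1), shape[1]),
    dab_density = matrix(runif(prod(shape), 0, 1.5), shape[1]))
  h <- generate_histology_image(spec)
  dec <- color_deconvolve(rgb_to_od(h$image, spec$i0), spec$stain_vectors)
  expect_lt(max(abs(dec$densities$dab - h$truth$dab_density)), 1e-6)
  expect_lt(max(abs(dec$densities$hematoxylin - h$truth$hematoxylin_density)),
            1e-6)
  # residual channel is empty for a two-stain image
  expect_lt(max(abs(dec$densities$residual)), 1e-6)
})

test_that("pure hematoxylin pixels carry zero DAB density", {
  spec <- histology_spec(image_shape = c(8, 8), hematoxylin_density = 0.7,
                         dab_density = 0)
  h <- generate_histology_image(spec)
  dec <- color_deconvolve(rgb_to_od(h$image), spec$stain_vectors)
  expect_lt(max(abs(dec$densities$dab)), 1e-9)
  expect_lt(max(abs(dec$densities$hematoxylin - 0.7)), 1e-9)
  # zero OD image gives zero densities
  z <- color_deconvolve(array(0, c(4, 4, 3)))
  expect_true(all(vapply(z$densities, function(d) all(d == 0), TRUE)))
  expect_error(color_deconvolve(array(0, c(4, 4, 3)),
                                rbind(c(1, 0, 0), c(1, 0, 0))), "collinear")
})

test_that("vacuoles render white and are recovered in truth", {
  spec <- histology_spec(image_shape = c(64, 64), hematoxylin_density = 0.6,
                         dab_density = 0,
                         vacuoles = list(list(center = c(32, 32),
                                              axes = c(8, 5), angle = 0.4)))
  h <- generate_histology_image(spec)
  expect_gt(h$truth$n_vacuole_px, 0)
  for (ch in 1:3)
    expect_true(all(h$image[, , ch][h$truth$vacuole_mask] == spec$i0[ch]))
  expect_true(all(h$truth$dab_density[h$truth$vacuole_mask] == 0))
})

test_that("mean dab od averages within the circle and across sections", {
  mk <- function(d) {
    spec <- histology_spec(image_shape = c(40, 40), hematoxylin_density = 0.2,
                           dab_density = d)
    h <- generate_histology_image(spec)
    color_deconvolve(rgb_to_od(h$image), spec$stain_vectors)
  }
  secs <- lapply(c(0.1, 0.2, 0.3), mk)
  res <- mean_dab_od(secs, center = c(20, 20), diameter_px = 16)
  expect_equal(res$per_section, c(0.1, 0.2, 0.3), tolerance = 1e-9)
  expect_equal(res$mean, 0.2, tolerance = 1e-9)
  # uniform density d: mean = d for any circle
  one <- mean_dab_od(secs[[2]], center = c(13.3, 24.1), diameter_px = 9)
  expect_equal(one$mean, 0.2, tolerance = 1e-9)
  expect_error(mean_dab_od(secs, center = c(2, 2), diameter_px = 16),
               "outside")
  # pixels outside the circle are irrelevant
  half <- mk(0.5)
  half$densities$dab[, 31:40] <- 99
  res2 <- mean_dab_od(half, center = c(20, 15), diameter_px = 10)
  expect_equal(res2$mean, 0.5, tolerance = 1e-9)
})

test_that("half-disc density converges to 0.5 with resolution", {
  mean_half <- function(n) {
    d <- matrix(0, n, n); d[, seq_len(n / 2)] <- 1
    dm <- structure(list(densities = list(dab = d)),
                    class = "stain_density_map")
    mean_dab_od(dm, center = c(n / 2 + 0.5, n / 2 + 0.5),
                diameter_px = n - 2)$mean
  }
  expect_lt(abs(mean_half(64) - 0.5), 0.02)
  expect_lt(abs(mean_half(256) - 0.5), abs(mean_half(32) - 0.5) + 1e-12)
})

test_that("vacuolation score equals the brute-force positive-pixel count", {
  spec <- histology_spec(image_shape = c(100, 100), hematoxylin_density = 0.6,
                         dab_density = 0,
                         vacuoles = list(
                           list(center = c(40, 40), axes = c(9, 5), angle = 0.3),
                           list(center = c(66, 58), axes = c(6, 6), angle = 0)))
  h <- generate_histology_image(spec)
  roi <- list(center = c(50, 50), diameter = 80)
  sc <- score_vacuolation(h$image, roi, binarization = "otsu")
  rr <- row(h$truth$vacuole_mask); cc <- col(h$truth$vacuole_mask)
  circ <- (rr - 50)^2 + (cc - 50)^2 <= 40^2
  brute <- sum(h$truth$vacuole_mask & circ)
  expect_identical(sc$total_vacuolation, as.numeric(brute))
  expect_equal(sc$roi_area, sum(circ))
  expect_equal(sc$mean_binary, brute / sum(circ))
  # fixed threshold route agrees on the same clean image
  sc2 <- score_vacuolation(h$image, roi, binarization = "fixed",
                           threshold = 0.8)
  expect_identical(sc2$total_vacuolation, as.numeric(brute))
})

test_that("vacuolation bounds and degenerate inputs behave", {
  spec <- histology_spec(image_shape = c(60, 60), hematoxylin_density = 0.6,
                         dab_density = 0,
                         vacuoles = list(list(center = c(30, 30),
                                              axes = c(20, 20), angle = 0)))
  h <- generate_histology_image(spec)
  # ROI entirely inside one vacuole: fraction 1, total = area
  sc <- score_vacuolation(h$image, list(center = c(30, 30), diameter = 16),
                          binarization = "fixed", threshold = 0.8)
  expect_identical(sc$mean_binary, 1)
  expect_identical(sc$total_vacuolation, as.numeric(sc$roi_area))
  # no vacuoles -> total 0
  clean <- generate_histology_image(histology_spec(
    image_shape = c(60, 60), hematoxylin_density = 0.6, dab_density = 0))
  sc0 <- score_vacuolation(clean$image, list(center = c(30, 30), diameter = 30),
                           binarization = "fixed", threshold = 0.8)
  expect_identical(sc0$total_vacuolation, 0)
  # degenerate single-intensity image falls back with a warning under otsu
  flat <- array(0.5, c(20, 20, 3))
  expect_warning(score_vacuolation(flat, list(center = c(10, 10), diameter = 10),
                                   binarization = "otsu"), "degenerate")
  # polygon ROI: unit square in the vacuole centre
  poly <- cbind(c(25, 35, 35, 25), c(25, 25, 35, 35))
  scp <- score_vacuolation(h$image, poly, binarization = "fixed",
                           threshold = 0.8)
  expect_identical(scp$mean_binary, 1)
})
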