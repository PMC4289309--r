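mk_img <- function(mat, px = 0.1, units = "delta_R", pol = "ratio")
  spr_image(mat, px, 620, pol, units)

test_that("p/s normalization divides out shared structure", {
  p <- spr_image(matrix(runif(100, 0.3, 0.6), 10), 0.1, 620, "p", "counts")
  s_same <- spr_image(p$pixels, 0.1, 620, "s", "counts")
  expect_equal(normalize_ps(p, s_same)$pixels, matrix(1, 10, 10))
  s_half <- spr_image(p$pixels / 2, 0.1, 620, "s", "counts")
  expect_equal(normalize_ps(p, s_half)$pixels, matrix(2, 10, 10))
  bad <- spr_image(matrix(1, 5, 5), 0.1, 620, "s", "counts")
  expect_error(normalize_ps(p, bad), "shape")
  # a synthetic scene's illumination field cancels away from the bead
  cfg <- imaging_config(pixel_size_um = 0.1, image_shape = c(201L, 201L))
  scene <- render_bead_scene(bead_spec(2.85, 1.48), spr_stack(620), cfg,
                             illumination_seed = 21)
  imgs <- bead_scene_with_noise(scene, noise_sigma = 0, seed = 1)
  ratio <- normalize_ps(imgs$p, imgs$s)
  far <- ratio$pixels[, 1:30]          # margin far from the bead footprint
  expect_lt(max(abs(far / (scene$Rbg / scene$Rs) - 1)), 0.005)
})

test_that("delta-R conversion zeroes the background ROI mean", {
  img <- mk_img(matrix(0.105, 20, 20), units = "counts")
  roi <- matrix(FALSE, 20, 20); roi[1:5, 1:5] <- TRUE
  dR <- to_delta_R(img, roi)
  expect_equal(dR$pixels, matrix(0, 20, 20))
  img2 <- img; img2$pixels[10, 10] <- 0.180
  dR2 <- to_delta_R(img2, roi)
  expect_equal(dR2$pixels[10, 10], 0.075, tolerance = 1e-12)
  expect_equal(mean(dR2$pixels[roi]), 0, tolerance = 1e-15)
  expect_error(to_delta_R(img, matrix(FALSE, 20, 20)), "empty")
})

test_that("annulus sigma estimates the injected noise level", {
  px <- 0.1
  img0 <- mk_img(matrix(0, 301, 301), px)
  roi <- roi_circle(15, 15, 5)
  expect_equal(as.numeric(background_sigma_annulus(img0, roi)), 0)
  # area of the annulus matches the analytic ring area within 1%
  sig0 <- background_sigma_annulus(mk_img(matrix(rnorm(301^2), 301), px), roi)
  area_px <- attr(sig0, "n_pixels") * px^2
  expect_equal(area_px, pi * (10^2 - 5^2), tolerance = 0.01)
  expect_gt(attr(sig0, "n_pixels"), 1e4)
  # seeded noise of known sd recovered within 3%
  set.seed(11)
  imgn <- mk_img(matrix(rnorm(301^2, sd = 0.002), 301), px)
  expect_equal(as.numeric(background_sigma_annulus(imgn, roi)), 0.002,
               tolerance = 0.03)
  # clipping errors name the side
  expect_error(background_sigma_annulus(img0, roi_circle(2, 15, 5)), "left")
  expect_error(background_sigma_annulus(img0, roi_circle(15, 29, 5)),
               "bottom")
})

test_that("threshold radius recovers a painted disc and degrades sanely", {
  px <- 0.1
  mat <- matrix(0, 301, 301)
  mask <- sprcal:::circle_mask(c(301, 301), px, 15, 15, 5)  # 50 px radius
  mat[mask] <- 1
  img <- mk_img(mat, px)
  roi <- roi_circle(15, 15, 8)
  r2 <- bead_radius_from_threshold(img, roi, sigma = 0.01, k = 3)
  expect_equal(as.numeric(r2), 5, tolerance = 0.05 / 5)
  # flat image: nothing above threshold
  expect_warning(r0 <- bead_radius_from_threshold(mk_img(matrix(0, 301, 301),
                                                         px), roi, 0.01),
                 "no pixels")
  expect_equal(as.numeric(r0), 0)
  # threshold above the disc amplitude
  expect_warning(rk <- bead_radius_from_threshold(img, roi, sigma = 0.5,
                                                  k = 3))
  expect_equal(as.numeric(rk), 0)
  # monotone non-increasing in k
  set.seed(4)
  imgn <- mk_img(mat + matrix(rnorm(301^2, sd = 0.3), 301), px)
  radii <- vapply(c(0.5, 1, 2, 3, 4), function(k)
    as.numeric(bead_radius_from_threshold(imgn, roi, sigma = 0.3, k = k)), 0)
  expect_true(all(diff(radii) <= 0))
})

test_that("depth inversion matches the forward chord geometry", {
  expect_equal(depth_from_radii(3, 0), 0)
  expect_equal(depth_from_radii(3, 3), 3000)
  expect_equal(depth_from_radii(30, 3.458), 200, tolerance = 0.01)
  expect_error(depth_from_radii(3, 3.1), "r2 <= r1")
  set.seed(8)
  r1 <- runif(1000, 0.5, 50)
  d <- runif(1000) * r1 * 1000
  back <- depth_from_radii(r1, chord_radius(r1, d))
  expect_lt(max(abs(back - d) / pmax(d, 1)), 1e-12)
})

test_that("FWHM from profiles: Gaussian, triangle, error cases", {
  px <- 0.01
  x <- (0:400 - 200) * px
  g <- exp(-x^2 / (2 * 0.127^2))
  expect_equal(fwhm_from_profile(g, px), 2.3548 * 0.127, tolerance = 0.01)
  tri <- pmax(0, 1 - abs(x) / 0.8)      # half-width at half height = 0.4
  expect_equal(fwhm_from_profile(tri, px), 0.8, tolerance = 0.01)
  expect_error(fwhm_from_profile(rep(1, 10), px))
  # baseline offset does not disturb the width
  expect_equal(fwhm_from_profile(g + 5, px), 2.3548 * 0.127,
               tolerance = 0.01)
})

test_that("penetration-depth aggregation groups and flags correctly", {
  theory <- penetration_depth_curve(c(550, 620))
  m <- data.frame(wavelength_nm = c(620, 620, 620, 550),
                  material = c("PMMA", "PMMA", "PMMA", "silica"),
                  d_nm = c(160, 170, 165, 95))
  tab <- aggregate_penetration_depths(m, theory)
  pmma <- tab[tab$material == "PMMA", ]
  expect_equal(pmma$mean_d_nm, 165)
  expect_equal(pmma$n, 3L)
  expect_false(pmma$single_measurement)
  sil <- tab[tab$material == "silica", ]
  expect_equal(sil$sd_d_nm, 0)
  expect_true(sil$single_measurement)
  expect_equal(tab$Lp_theory_nm,
               theory$Lp_nm[match(tab$wavelength_nm,
                                  theory$wavelength_nm)])
  # replication leaves the mean unchanged and the sd zero
  dup <- data.frame(wavelength_nm = 620, material = "PS",
                    d_nm = rep(150, 4))
  expect_equal(aggregate_penetration_depths(dup, theory)$sd_d_nm, 0)
})

test_that("linescan classification labels intervals and runs", {
  cls <- linescan_classes(c(0.01, 0.05, 0.12))
  low <- classify_linescan(rep(0.001, 8), cls)
  expect_true(all(low == "substrate"))
  stair <- classify_linescan(c(0, 0, 0.03, 0.03, 0.08, 0.08, 0.2, 0.2), cls)
  runs <- attr(stair, "runs")
  expect_equal(as.character(runs$label),
               c("substrate", "ECM", "basal cell", "focal adhesion"))
  expect_equal(runs$length, rep(2L, 4))
  # tercile thresholds reproduce constructed proportions
  set.seed(2)
  v <- runif(3000)
  cls2 <- linescan_classes(as.numeric(quantile(v, c(0.25, 0.5, 0.75))))
  prop <- table(classify_linescan(v, cls2)) / 3000
  expect_true(all(abs(prop - 0.25) < 0.02))
})
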