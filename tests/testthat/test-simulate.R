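cfg_small <- function(...) imaging_config(wavelength_nm = 620,
                                          pixel_size_um = 0.05,
                                          image_shape = c(301L, 301L), ...)

test_that("bead height map follows the resting-sphere geometry", {
  cfg <- cfg_small()
  bead <- bead_spec(3, 1.48)
  z <- bead_height_map(bead, cfg)
  ctr <- (301 - 1) / 2 + 1
  expect_equal(z[ctr, ctr], 0)                      # contact point
  expect_true(is.na(z[ctr, 1]))                     # beyond the footprint
  # edge of footprint reaches the equator height r1
  edge_col <- ctr + 3 / 0.05
  expect_equal(z[ctr, edge_col], 3000, tolerance = 1e-9)
  # forward chord: the gap equals d at rho = sqrt(d (2 r1 - d))
  big <- imaging_config(pixel_size_um = 0.1, image_shape = c(701L, 701L))
  zb <- bead_height_map(bead_spec(30, 1.48), big)
  rho <- sqrt(0.2 * (2 * 30 - 0.2))                 # d = 0.2 um
  row <- zb[351, ]
  x <- (seq_len(701) - 351) * 0.1
  expect_equal(approx(x[x >= 0], row[x >= 0], rho)$y, 200, tolerance = 1)
})

test_that("index-matched beads are invisible and background is exact", {
  cfg <- cfg_small()
  stack <- spr_stack(620)
  img <- render_spr_bead_image(bead_spec(3, 1.333, material = "matched"),
                               stack, cfg)
  Rbg <- attr(img, "background_reflectance")
  expect_equal(Rbg, stack_reflectance(stack, attr(img, "incident_angle_deg"),
                                      "p"), tolerance = 1e-12)
  expect_lt(max(abs(img$pixels - Rbg)), 1e-12)
})

test_that("contact-point reflectance equals the stand-alone four-layer oracle", {
  cfg <- cfg_small(psf = NULL)          # no blur: per-pixel optics exposed
  stack <- spr_stack(620)
  img <- render_spr_bead_image(bead_spec(3, 1.48), stack, cfg)
  ang <- attr(img, "incident_angle_deg")
  ctr <- (301 - 1) / 2 + 1
  eps4 <- c(stack$eps[1:3], complex(real = 1.48^2))
  expect_equal(img$pixels[ctr, ctr],
               oracle_reflectance(eps4, c(NA, 45, 0, NA), ang, 620, "p"),
               tolerance = 1e-9)
})

test_that("apparent bead footprint shrinks at shorter wavelength (shorter Lp)", {
  # contrast-normalized footprint: radius where delta-R falls to half its
  # contact-point value, on the noise-free unblurred optical response
  half_radius <- function(wl) {
    cfg <- imaging_config(wavelength_nm = wl, pixel_size_um = 0.05,
                          image_shape = c(301L, 301L), psf = NULL)
    img <- render_spr_bead_image(bead_spec(3, 1.48), spr_stack(wl), cfg)
    dR <- img$pixels - attr(img, "background_reflectance")
    prof <- radial_profile(dR, c(7.5, 7.5), 0.05)
    sprcal:::profile_crossing_radius(prof$r_um, prof$value,
                                     max(prof$value) / 2)
  }
  r670 <- half_radius(670); r620 <- half_radius(620); r550 <- half_radius(550)
  expect_gt(r670, r620)
  expect_gt(r620, r550)
})

test_that("bright-field ring radius is recovered within half a pixel", {
  bead <- bead_spec(3, 1.48)
  for (px in c(0.05, 0.1)) {
    side <- round(15 / px) + 1L
    cfg <- imaging_config(pixel_size_um = px,
                          image_shape = c(side, side))
    bf <- render_brightfield_bead_image(bead, cfg)
    ctr <- (side - 1) / 2 * px
    expect_equal(brightfield_radius(bf, c(ctr, ctr), px), 3,
                 tolerance = px / 2 / 3)
  }
  # empty scene is uniform
  cfg <- cfg_small()
  expect_equal(render_brightfield_bead_image(list(), cfg),
               matrix(1, 301, 301))
})

test_that("point-source rendering: isotropy limit, anisotropy ratio, flux", {
  px <- 0.02
  cfg_iso <- imaging_config(pixel_size_um = px, image_shape = c(257L, 257L),
                            psf = psf_model(0.30, 0))
  img <- render_point_source(cfg_iso, amplitude = 1)
  ctr <- 129
  fx <- fwhm_from_profile(img$pixels[ctr, ], px)
  fy <- fwhm_from_profile(img$pixels[, ctr], px)
  expect_equal(fx, fy, tolerance = 0.02)
  expect_equal(fx, 0.30, tolerance = 0.01 / 0.30)
  expect_equal(sum(img$pixels), 1, tolerance = 1e-3)   # blur conserves flux
  # default PSF: y-FWHM about twice the x-FWHM
  cfg_def <- imaging_config(pixel_size_um = px, image_shape = c(257L, 257L))
  img2 <- render_point_source(cfg_def, amplitude = 1)
  pk <- which(img2$pixels == max(img2$pixels), arr.ind = TRUE)[1, ]
  fx2 <- fwhm_from_profile(img2$pixels[pk[1], ], px)
  fy2 <- fwhm_from_profile(img2$pixels[, pk[2]], px)
  expect_equal(fx2, 0.30, tolerance = 0.01 / 0.30)
  expect_equal(fy2 / fx2, 2, tolerance = 0.05)
})

test_that("rendering is bit-reproducible under a fixed seed", {
  cfg <- cfg_small(noise_sigma = 0.01, seed = 99L)
  stack <- spr_stack(620)
  a <- render_spr_bead_image(bead_spec(3, 1.48), stack, cfg)
  b <- render_spr_bead_image(bead_spec(3, 1.48), stack, cfg)
  expect_identical(a$pixels, b$pixels)
  cfg2 <- cfg_small(noise_sigma = 0.01, seed = 100L)
  c <- render_spr_bead_image(bead_spec(3, 1.48), stack, cfg2)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("small index perturbations decay as the squared evanescent field", {
  # first-order response to a semi-infinite index step at gap z follows the
  # local field intensity: delta-R proportional to exp(-2 z / Lp), with Lp
  # the 1/e length of the closed-form profile I(z)
  stack <- spr_stack(620)
  Lp <- penetration_depth(620, stack$eps[2], Re(stack$eps[3]))
  ang <- operating_angle(stack, 0.1)$angle_deg
  Rbg <- stack_reflectance(stack, ang, "p")
  z <- seq(0, 2 * Lp, length.out = 9)
  dev_at <- function(dn) {
    dR <- bead_gap_reflectance(stack, 1.333 + dn, z, ang) - Rbg
    max(abs((dR / dR[1]) / exp(-2 * z / Lp) - 1))
  }
  expect_lt(dev_at(0.010), 0.10)
  # deviations grow with the perturbation (onset of response saturation)
  devs <- vapply(c(0.005, 0.010, 0.020), dev_at, 0)
  expect_true(all(diff(devs) > 0))
})

test_that("non-overlapping beads are measured independently", {
  px <- 0.1
  shape <- c(221L, 421L)
  beads <- list(bead_spec(3, 1.48, center_um = c(11, 11)),
                bead_spec(3, 1.42, center_um = c(31, 11)))
  stack <- spr_stack(620)
  cfg <- imaging_config(pixel_size_um = px, image_shape = shape)
  Lp <- penetration_depth(620, stack$eps[2], Re(stack$eps[3]))
  pair_scene <- render_bead_scene(beads, stack, cfg)
  sig <- as.numeric(calibrate_noise_sigma(pair_scene, Lp))
  rois <- lapply(beads, function(b)
    roi_circle(b$center_um[1], b$center_um[2], chord_radius(3, Lp) + 3))
  measure_with <- function(scene) {
    imgs <- bead_scene_with_noise(scene, noise_sigma = sig, seed = 5)
    vapply(rois, function(roi)
      measure_bead(imgs$p, imgs$s, imgs$brightfield, roi)$d_nm, 0)
  }
  d_pair <- measure_with(pair_scene)
  d_solo <- c(measure_with(render_bead_scene(beads[1], stack, cfg))[1],
              measure_with(render_bead_scene(beads[2], stack, cfg))[2])
  expect_lt(max(abs(d_pair / d_solo - 1)), 0.01)
})

test_that("dataset truth tables are consistent with the scene geometry", {
  cfg <- imaging_config(pixel_size_um = 0.05, image_shape = c(301L, 301L),
                        noise_sigma = 0)
  ds <- make_bead_dataset(bead_spec(3, 1.48), 620, cfg, seed = 3)
  expect_length(ds, 1L)
  truth <- ds[[1]]$truth
  expect_equal(nrow(truth), 1L)
  expect_equal(truth$r1_um, 3)
  expect_true(is.na(truth$expected_r2_um))      # noise-free: no threshold
  # with noise calibrated at Lp the expected r2 is the chord at Lp
  Lp <- truth$Lp_nm
  scene <- ds[[1]]$scene
  sig <- as.numeric(calibrate_noise_sigma(scene, Lp))
  cfg2 <- cfg; cfg2$noise_sigma <- sig
  ds2 <- make_bead_dataset(bead_spec(3, 1.48), 620, cfg2, seed = 3)
  expect_equal(ds2[[1]]$truth$expected_r2_um, chord_radius(3, Lp),
               tolerance = 0.05)
})
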