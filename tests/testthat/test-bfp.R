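geom <- bfp_geometry(radius_px = 100, center_px = c(110, 110),
                     max_angle_deg = 60)

test_that("angle-radius mapping: endpoints, hand value, exact round trip", {
  expect_equal(angle_to_bfp_radius(0, geom), 0)
  expect_equal(angle_to_bfp_radius(60, geom), 1)
  expect_equal(angle_to_bfp_radius(54, geom), sin(54 * pi / 180) /
                 sin(60 * pi / 180), tolerance = 1e-12)
  th <- seq(0, 60, by = 0.5)
  r <- angle_to_bfp_radius(th, geom)
  expect_true(all(diff(r) > 0))
  expect_lt(max(abs(bfp_radius_to_angle(r, geom) - th)), 1e-12)
  expect_error(angle_to_bfp_radius(61, geom), "max_angle")
})

test_that("crescent masks have the expected areas and monotonicity", {
  # full disc: radial band 0..max over 360 degrees
  disc <- make_crescent_mask(crescent_spec(30, 60, 360), geom)
  expect_equal(sum(disc), pi * geom$radius_px^2, tolerance = 0.01)
  # a 40-degree arc of an annulus occupies 40/360 of the annulus area
  ring <- make_crescent_mask(crescent_spec(54, 4, 360), geom)
  arc <- make_crescent_mask(crescent_spec(54, 4, 40), geom)
  expect_equal(sum(arc) / sum(ring), 40 / 360, tolerance = 0.03)
  # monotone in radial width and azimuthal span
  wider <- make_crescent_mask(crescent_spec(54, 8, 40), geom)
  longer <- make_crescent_mask(crescent_spec(54, 4, 80), geom)
  expect_gt(sum(wider), sum(arc))
  expect_gt(sum(longer), sum(arc))
  # degenerate arc and out-of-aperture band
  expect_error(crescent_spec(54, 4, 0))
  expect_error(make_crescent_mask(crescent_spec(59, 4, 40), geom),
               "outside the aperture")
})

test_that("angle scans extracted from a rendered BFP recover the model curve", {
  stack <- spr_stack(620)
  img <- render_bfp_image(stack, geom)
  # uniform image gives a flat scan
  flat <- extract_angle_scan(matrix(0.7, 221, 221), geom)
  expect_lt(diff(range(flat$reflectance)), 1e-12)
  # render-then-extract round trip along the polarization (x) axis
  scan <- extract_angle_scan(img, geom, azimuth_deg = 0)
  model <- stack_reflectance(stack, scan$angle_deg, "p")
  expect_lt(sqrt(mean((scan$reflectance - model)^2)), 0.01)
  # x-scan shows the plasmon dip, y-scan (s-polarized) does not
  scan_y <- extract_angle_scan(img, geom, azimuth_deg = 90)
  sel <- scan$angle_deg > 50
  expect_lt(min(scan$reflectance[sel]), 0.05)
  expect_gt(min(scan_y$reflectance[sel]), 0.5)
  # ray leaving the image errors
  small <- matrix(0, 50, 50)
  expect_error(extract_angle_scan(small, geom), "outside image")
})

test_that("self-fit recovers the generating stack exactly", {
  stack <- spr_stack(620, gold_thickness_nm = 45)
  scan <- spr_angle_scan(stack, seq(45, 65, by = 0.2), "p")
  fit <- fit_fresnel_scan(scan, spr_stack(620, gold_thickness_nm = 40))
  expect_true(fit$converged)
  expect_equal(fit$thickness_nm, 45, tolerance = 1e-4)
  expect_lt(fit$residual_rms, 1e-8)
  # normalization round trip: the normalized scan reproduces reflectance
  expect_true(all(fit$normalized$reflectance >= 0 &
                    fit$normalized$reflectance <= 1))
  expect_equal(min(fit$normalized$reflectance),
               min(stack_reflectance(fit$stack, scan$angle_deg, "p")),
               tolerance = 1e-6)
})

test_that("fit is invariant to intensity rescaling", {
  stack <- spr_stack(620)
  angles <- seq(45, 65, by = 0.25)
  set.seed(7)
  counts <- 1350 * (stack_reflectance(stack, angles, "p") +
                      rnorm(length(angles), sd = 0.01))
  scan1 <- structure(data.frame(angle_deg = angles, reflectance = counts),
                     class = c("angle_scan", "data.frame"))
  scan2 <- scan1; scan2$reflectance <- counts * 57.3
  f1 <- fit_fresnel_scan(scan1, spr_stack(620, gold_thickness_nm = 40))
  f2 <- fit_fresnel_scan(scan2, spr_stack(620, gold_thickness_nm = 40))
  expect_equal(f1$thickness_nm, f2$thickness_nm, tolerance = 1e-6)
  expect_equal(f2$scale / f1$scale, 57.3, tolerance = 1e-6)
})
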