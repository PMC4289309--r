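glass_water <- function(wl = 620) optical_stack(list(
  optical_layer("glass", index = 1.78),
  optical_layer("water", index = 1.333)), wl)

test_that("two-medium closed forms: normal incidence and total internal reflection", {
  gw <- glass_water()
  R0 <- ((1.78 - 1.333) / (1.78 + 1.333))^2
  expect_equal(stack_reflectance(gw, 0, "p"), R0, tolerance = 1e-12)
  expect_equal(stack_reflectance(gw, 0, "s"), R0, tolerance = 1e-12)
  # critical angle ~48.5 deg; beyond it the lossless interface reflects all
  expect_equal(stack_reflectance(gw, 60, "p"), 1, tolerance = 1e-12)
  expect_equal(stack_reflectance(gw, 60, "s"), 1, tolerance = 1e-12)
})

test_that("all-dielectric scans match the two-interface closed form per angle", {
  gw <- glass_water()
  angles <- seq(0, 80, by = 2.5)
  scan <- spr_angle_scan(gw, angles, "s")
  n1 <- 1.78; n2 <- 1.333
  closed <- vapply(angles, function(a) {
    th <- a * pi / 180
    s2 <- (n1 / n2) * sin(th)
    if (s2 >= 1) return(1)
    c1 <- cos(th); c2 <- sqrt(1 - s2^2)
    ((n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2))^2
  }, 0)
  expect_equal(scan$reflectance, closed, tolerance = 1e-10)
  # single-angle scan is consistent with stack_reflectance
  one <- spr_angle_scan(gw, 37, "p")
  expect_equal(nrow(one), 1L)
  expect_equal(one$reflectance, stack_reflectance(gw, 37, "p"))
})

test_that("gold stack minimum agrees with the recursive-Fresnel oracle", {
  stack <- spr_stack(620)
  angles <- seq(40, 70, by = 0.05)
  ours <- stack_reflectance(stack, angles, "p")
  theirs <- oracle_stack_reflectance(stack, angles, "p")
  expect_lt(max(abs(ours - theirs)), 1e-10)
  expect_equal(angles[which.min(ours)], angles[which.min(theirs)])
})

test_that("p-polarized scan has the SPR dip beyond the critical angle; s does not", {
  stack <- spr_stack(620)
  thc <- 48.5
  angles <- seq(thc + 0.5, 70, by = 0.1)
  Rp <- stack_reflectance(stack, angles, "p")
  Rs <- stack_reflectance(stack, angles, "s")
  expect_lt(min(Rp), 0.05)
  expect_gt(min(Rs), 0.5)
})

test_that("reflectance stays in [0,1] and p equals s at normal incidence (random stacks)", {
  for (seed in 1:25) {
    st <- random_stack(seed)
    angles <- seq(0, 89, by = 4.45)
    for (pol in c("p", "s")) {
      R <- stack_reflectance(st, angles, pol)
      expect_true(all(R >= -1e-12 & R <= 1 + 1e-12))
    }
    expect_lt(abs(stack_reflectance(st, 0, "p") -
                    stack_reflectance(st, 0, "s")), 1e-12)
  }
})

test_that("energy is conserved for lossless stacks (R + T = 1)", {
  for (seed in 1:10) {
    st <- random_stack(seed, lossless = TRUE)
    angles <- seq(0, 85, by = 5)
    for (pol in c("p", "s")) {
      R <- stack_reflectance(st, angles, pol)
      T <- stack_transmittance(st, angles, pol)
      expect_lt(max(abs(R + T - 1)), 1e-10)
    }
  }
})

test_that("transfer matrix matches the independent oracle on random multilayers", {
  for (seed in 1:20) {
    st <- random_stack(seed + 100)
    angles <- seq(1, 88, by = 3)
    for (pol in c("p", "s"))
      expect_lt(max(abs(stack_reflectance(st, angles, pol) -
                          oracle_stack_reflectance(st, angles, pol))), 1e-10)
  }
})

test_that("four-layer bead gap reflectance converges to the three-layer background", {
  stack <- spr_stack(620)
  Lp <- penetration_depth(620, stack$eps[2], Re(stack$eps[3]))
  Rbg <- stack_reflectance(stack, 54.4, "p")
  R_far <- bead_gap_reflectance(stack, 1.48, 20 * Lp, 54.4)
  expect_lt(abs(R_far - Rbg), 1e-6)
  # and with zero gap it equals an independent 4-layer oracle evaluation
  eps4 <- c(stack$eps[1:3], complex(real = 1.48^2))
  expect_equal(bead_gap_reflectance(stack, 1.48, 0, 54.4),
               oracle_reflectance(eps4, c(NA, 45, 0, NA), 54.4, 620, "p"),
               tolerance = 1e-10)
})
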