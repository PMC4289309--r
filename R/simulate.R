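# Synthetic-scene generator: SPR and bright-field images of reference
# microspheres on the gold sensor, and point sources under the anisotropic
# SPR point spread function. Serves as the fixture generator for the
# measurement pipeline.

#' Anisotropic SPR point spread function
#'
#' The lateral response is a Gaussian of width `fwhm_x_um` along x
#' (perpendicular to plasmon propagation) and, along y (the propagation
#' direction), the same Gaussian convolved with a one-sided exponential of
#' length `decay_y_um` representing plasmon leakage-radiation blur. The
#' default `decay_y_um` is the value at which a 0.30 um x-FWHM point source
#' measures 0.60 um FWHM along y (see [solve_psf_decay()]).
#'
#' @param fwhm_x_um Gaussian FWHM along x, micrometers, `> 0`.
#' @param decay_y_um one-sided exponential tail length along y, micrometers,
#'   `>= 0` (0 disables the tail, giving an isotropic spot).
#' @return object of class `psf_model`.
#' @export
psf_model <- function(fwhm_x_um = 0.30, decay_y_um = 0.4539) {
  stopifnot(fwhm_x_um > 0, decay_y_um >= 0)
  structure(list(fwhm_x_um = fwhm_x_um, decay_y_um = decay_y_um),
            class = "psf_model")
}

#' Solve for the propagation-tail length giving a target y-FWHM
#'
#' Finds `decay_y_um` such that the y-profile of [psf_model()] (Gaussian of
#' `fwhm_x_um` convolved with the one-sided exponential) has the requested
#' full width at half maximum.
#'
#' @param fwhm_x_um Gaussian FWHM, micrometers.
#' @param fwhm_y_um target y FWHM, micrometers, `> fwhm_x_um`.
#' @return tail length in micrometers.
#' @export
#' @examples
#' solve_psf_decay(0.30, 0.60)
solve_psf_decay <- function(fwhm_x_um = 0.30, fwhm_y_um = 0.60) {
  stopifnot(fwhm_y_um > fwhm_x_um)
  sg <- fwhm_x_um / (2 * sqrt(2 * log(2)))
  h <- fwhm_x_um / 200
  n <- 8192
  y <- (seq_len(n) - n / 2) * h
  fwhm_of <- function(l) {
    g <- stats::dnorm(y, sd = sg)
    e <- ifelse(y >= 0, exp(-y / l), 0)
    k <- Re(stats::fft(stats::fft(g) * stats::fft(e), inverse = TRUE))
    k <- k / max(k)
    sum(k >= 0.5) * h
  }
  stats::uniroot(function(l) fwhm_of(l) - fwhm_y_um,
                 c(h, 20 * fwhm_y_um), tol = 1e-6)$root
}

#' Imaging configuration for the synthetic scene generator
#'
#' @param wavelength_nm excitation wavelength, nm.
#' @param pixel_size_um pixel size, micrometers, `> 0`.
#' @param image_shape image dimensions `c(rows, cols)` in pixels.
#' @param incident_angle_deg incidence angle; `NULL` (default) lets the
#'   renderer place the operating point on the shallow flank of the SPR dip
#'   via [operating_angle()].
#' @param noise_sigma additive Gaussian noise sd per acquired frame, in
#'   reflectance units, `>= 0`.
#' @param frames_to_average number of averaged frames; the effective noise
#'   sd is `noise_sigma / sqrt(frames_to_average)`.
#' @param psf a [psf_model()], or `NULL` to disable blurring.
#' @param operating_reflectance target background reflectance when the
#'   operating angle is computed, default 0.1.
#' @param seed integer seed making renders bit-reproducible; `NULL` leaves
#'   the RNG state alone.
#' @return object of class `imaging_config`.
#' @export
imaging_config <- function(wavelength_nm = 620, pixel_size_um = 0.1,
                           image_shape = c(256L, 256L),
                           incident_angle_deg = NULL,
                           noise_sigma = 0, frames_to_average = 1L,
                           psf = psf_model(), operating_reflectance = 0.1,
                           seed = NULL) {
  stopifnot(pixel_size_um > 0, length(image_shape) == 2L,
            noise_sigma >= 0, frames_to_average >= 1)
  if (!is.null(psf) && !inherits(psf, "psf_model"))
    stop("psf must be a psf_model or NULL")
  if (!is.null(incident_angle_deg) &&
      (incident_angle_deg <= 0 || incident_angle_deg >= 90))
    stop("operating angle outside (0, 90) degrees")
  structure(list(wavelength_nm = wavelength_nm,
                 pixel_size_um = pixel_size_um,
                 image_shape = as.integer(image_shape),
                 incident_angle_deg = incident_angle_deg,
                 noise_sigma = noise_sigma,
                 frames_to_average = as.integer(frames_to_average),
                 psf = psf, operating_reflectance = operating_reflectance,
                 seed = seed),
            class = "imaging_config")
}

#' Reference microsphere specification
#'
#' Polymer beads of known radius and refractive index resting on the sensor
#' surface; the calibration reference materials (Sephacryl n = 1.345,
#' silica n = 1.42, PMMA n = 1.48, polystyrene n = 1.59).
#'
#' @param radius_um bead radius r1 in micrometers, `> 0`.
#' @param index real refractive index, in the supported 1.33-1.60 range.
#' @param center_um bead center `(x, y)` in micrometers; `NULL` places the
#'   bead at the image center.
#' @param material text label.
#' @return object of class `bead_spec`.
#' @export
bead_spec <- function(radius_um, index, center_um = NULL,
                      material = sprintf("n=%.3f", index)) {
  stopifnot(radius_um > 0)
  if (index < 1.33 || index > 1.60)
    stop("bead index outside supported range [1.33, 1.60]")
  structure(list(radius_um = radius_um, index = index,
                 center_um = center_um, material = material),
            class = "bead_spec")
}

# bead center in um, defaulting to the image center
bead_center <- function(spec, config) {
  if (!is.null(spec$center_um)) return(spec$center_um)
  (rev(config$image_shape) - 1) / 2 * config$pixel_size_um
}

#' Gap-distance map under a resting microsphere
#'
#' Height of the sphere surface above the sensor: at in-plane distance
#' \eqn{\rho} from the contact point,
#' \eqn{z(\rho) = r_1 - \sqrt{r_1^2 - \rho^2}} for \eqn{\rho \le r_1};
#' pixels beyond the bead footprint are `NA` ("no bead").
#'
#' @param spec a [bead_spec()].
#' @param config an [imaging_config()]; the bead must fit in the field of
#'   view.
#' @return numeric matrix of gap distances in nm (`NA` outside the bead).
#' @export
bead_height_map <- function(spec, config) {
  ctr <- bead_center(spec, config)
  px <- config$pixel_size_um
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  xs <- (seq_len(nc) - 1) * px - ctr[1]
  ys <- (seq_len(nr) - 1) * px - ctr[2]
  rho2 <- outer(ys^2, xs^2, `+`)
  r1 <- spec$radius_um
  z <- r1 - sqrt(pmax(r1^2 - rho2, 0))
  z[rho2 > r1^2] <- NA_real_
  z * 1000
}

# ---- PSF blurring -----------------------------------------------------

# Periodic 1-D kernels on the image grid (index 1 = origin), each summing
# to 1. x: Gaussian; y: Gaussian convolved with a one-sided exponential.
psf_kernels <- function(psf, pixel_size_um, shape) {
  nr <- shape[1]; nc <- shape[2]
  sg <- psf$fwhm_x_um / (2 * sqrt(2 * log(2))) / pixel_size_um
  off_x <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  off_y <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  kx <- stats::dnorm(off_x, sd = sg)
  kx <- kx / sum(kx)
  gy <- stats::dnorm(off_y, sd = sg)
  l <- psf$decay_y_um / pixel_size_um
  if (l > 1e-9) {
    ey <- ifelse(off_y >= 0, exp(-off_y / l), 0)
    ky <- Re(stats::fft(stats::fft(gy) * stats::fft(ey), inverse = TRUE)) / nr
    ky <- pmax(ky, 0)
  } else ky <- gy
  ky <- ky / sum(ky)
  list(kx = kx, ky = ky)
}

# FFT convolution with the separable anisotropic kernel (periodic edges;
# scenes keep their structures away from the border).
blur_image <- function(mat, psf, pixel_size_um) {
  if (is.null(psf)) return(mat)
  k <- psf_kernels(psf, pixel_size_um, dim(mat))
  K <- outer(stats::fft(k$ky), stats::fft(k$kx))
  Re(stats::fft(stats::fft(mat) * K, inverse = TRUE)) / length(mat)
}

add_frame_noise <- function(mat, config, seed = config$seed) {
  sd_eff <- config$noise_sigma / sqrt(config$frames_to_average)
  if (sd_eff <= 0) return(mat)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mat + matrix(stats::rnorm(length(mat), sd = sd_eff), nrow(mat))
}

# ---- renderers --------------------------------------------------------

# Noise-free p-polarized reflectance map of bead(s) over the sensor
# (pre-blur), plus operating metadata.
reflectance_map <- function(beads, stack, config) {
  ang <- config$incident_angle_deg
  at_min <- FALSE
  if (is.null(ang)) {
    op <- operating_angle(stack, config$operating_reflectance)
    ang <- op$angle_deg; at_min <- op$at_minimum
  }
  Rbg <- stack_reflectance(stack, ang, "p")
  Rmap <- matrix(Rbg, config$image_shape[1], config$image_shape[2])
  kx <- sqrt(Re(stack$eps[1])) * sin(ang * pi / 180)
  eps_d <- Re(stack$eps[3])
  kappa <- (2 * pi / stack$wavelength_nm) * sqrt(max(kx^2 - eps_d, 1e-9))
  z_cap <- 21 / (2 * kappa)         # gap beyond which |R4 - R3| < ~1e-9
  for (bead in beads) {
    z <- bead_height_map(bead, config)
    idx <- which(!is.na(z) & z <= z_cap)
    if (!length(idx)) next
    zg <- z_cap * seq(0, 1, length.out = 600)^2
    Rz <- bead_gap_reflectance(stack, bead$index, zg, ang)
    Rmap[idx] <- stats::approx(zg, Rz, z[idx])$y
  }
  list(Rmap = Rmap, angle_deg = ang, Rbg = Rbg, at_minimum = at_min)
}

#' Render an SPR image of a microsphere
#'
#' Per pixel, the reflectance of the four-layer stack glass / gold / water
#' gap (thickness given by the sphere geometry) / semi-infinite bead
#' material at the operating angle; pixels without bead carry the
#' three-layer background reflectance. The map is then blurred with the
#' anisotropic PSF and Gaussian noise of sd
#' `noise_sigma / sqrt(frames_to_average)` is added (deterministic under
#' `config$seed`).
#'
#' @param spec a [bead_spec()] or list of them (non-overlapping).
#' @param stack three-layer background [optical_stack()] (glass/gold/water).
#' @param config an [imaging_config()]; `wavelength_nm` must match the
#'   stack.
#' @return an [spr_image()] in reflectance units with attributes
#'   `background_reflectance` and `incident_angle_deg`.
#' @export
render_spr_bead_image <- function(spec, stack, config) {
  beads <- if (inherits(spec, "bead_spec")) list(spec) else spec
  rm <- reflectance_map(beads, stack, config)
  img <- blur_image(rm$Rmap, config$psf, config$pixel_size_um)
  img <- add_frame_noise(img, config)
  out <- spr_image(img, config$pixel_size_um, stack$wavelength_nm,
                   "p", "reflectance")
  attr(out, "background_reflectance") <- rm$Rbg
  attr(out, "incident_angle_deg") <- rm$angle_deg
  out
}

#' Render a bright-field image of a microsphere
#'
#' Simple disc-contrast model sufficient for radius measurement: a dark
#' ring at the projected bead boundary, with a Gaussian edge profile of
#' diffraction-limited width.
#'
#' @param spec a [bead_spec()] or list of them.
#' @param config an [imaging_config()].
#' @param contrast ring depth below the unit background, default 0.4.
#' @param edge_fwhm_um Gaussian FWHM of the edge profile, default the
#'   diffraction limit for 550 nm light at NA 1.65.
#' @return numeric matrix (bright-field intensity, background 1).
#' @export
render_brightfield_bead_image <- function(spec, config, contrast = 0.4,
                                          edge_fwhm_um =
                                            diffraction_limit(550, 1.65)) {
  beads <- if (inherits(spec, "bead_spec")) list(spec) else spec
  px <- config$pixel_size_um
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  img <- matrix(1, nr, nc)
  sg <- edge_fwhm_um / (2 * sqrt(2 * log(2)))
  for (bead in beads) {
    ctr <- bead_center(bead, config)
    xs <- (seq_len(nc) - 1) * px - ctr[1]
    ys <- (seq_len(nr) - 1) * px - ctr[2]
    rho <- sqrt(outer(ys^2, xs^2, `+`))
    img <- img - contrast * exp(-(rho - bead$radius_um)^2 / (2 * sg^2))
  }
  add_frame_noise(img, config)
}

#' Render a point source under the SPR point spread function
#'
#' A sub-pixel impulse of integrated signal `amplitude` (distributed
#' bilinearly over the four neighboring pixels) convolved with the
#' anisotropic PSF: Gaussian along x, Gaussian plus one-sided exponential
#' leakage tail along y. Total signal is conserved by the blur.
#'
#' @param config an [imaging_config()].
#' @param amplitude integrated signal in reflectance units, `> 0`.
#' @param center_um source position `(x, y)` in micrometers; default image
#'   center.
#' @return an [spr_image()] in `delta_R` units.
#' @export
render_point_source <- function(config, amplitude = 1, center_um = NULL) {
  stopifnot(amplitude > 0)
  px <- config$pixel_size_um
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  if (is.null(center_um)) center_um <- (c(nc, nr) - 1) / 2 * px
  cx <- center_um[1] / px; cy <- center_um[2] / px
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  img <- matrix(0, nr, nc)
  for (dd in list(c(0, 0, (1 - fx) * (1 - fy)), c(1, 0, fx * (1 - fy)),
                  c(0, 1, (1 - fx) * fy), c(1, 1, fx * fy))) {
    i <- y0 + dd[2] + 1; j <- x0 + dd[1] + 1
    if (i >= 1 && i <= nr && j >= 1 && j <= nc)
      img[i, j] <- img[i, j] + amplitude * dd[3]
  }
  img <- blur_image(img, config$psf, px)
  img <- add_frame_noise(img, config)
  spr_image(img, px, config$wavelength_nm, "p", "delta_R")
}

#' Smooth illumination inhomogeneity field
#'
#' Low-order polynomial field (mean 1) multiplied into both the p- and
#' s-polarized frames so that dividing p by s removes it, mirroring the
#' purpose of the s-polarized reference image.
#'
#' @param shape `c(rows, cols)`.
#' @param seed integer seed for the polynomial coefficients.
#' @param strength relative modulation amplitude, default 0.1.
#' @return numeric matrix with mean 1.
#' @export
illumination_field <- function(shape, seed = 1, strength = 0.1) {
  set.seed(as.integer(seed))
  a <- stats::runif(5, -1, 1)
  u <- seq(-1, 1, length.out = shape[2])
  v <- seq(-1, 1, length.out = shape[1])
  U <- matrix(rep(u, each = shape[1]), shape[1])
  V <- matrix(rep(v, times = shape[2]), shape[1])
  f <- 1 + strength * (a[1] * U + a[2] * V + a[3] * U * V +
                         a[4] * U^2 + a[5] * V^2)
  f / mean(f)
}

#' Render a back focal plane image
#'
#' Intensity at each pupil pixel given linear polarization along x: the
#' radial coordinate encodes the incidence angle (sine mapping), and the
#' local polarization decomposes as p along the radial x-azimuth and s
#' along y, so the SPR absorption crescents appear at the left/right edges
#' only.
#'
#' @param stack an [optical_stack()].
#' @param geom a [bfp_geometry()].
#' @param shape image dimensions `c(rows, cols)`; default fits the
#'   aperture.
#' @param illumination scalar or matrix multiplied into the image.
#' @return numeric matrix; pixels outside the aperture are 0.
#' @export
render_bfp_image <- function(stack, geom, shape = NULL, illumination = 1) {
  if (is.null(shape)) shape <- default_bfp_shape(geom)
  thetas <- seq(0, geom$max_angle_deg, length.out = 512)
  Rp <- stack_reflectance(stack, thetas, "p")
  Rs <- stack_reflectance(stack, thetas, "s")
  x <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1])
  y <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), shape[1])
  dx <- x - geom$center_px[1]
  dy <- -(y - geom$center_px[2])
  rn <- sqrt(dx^2 + dy^2) / geom$radius_px
  inside <- rn <= 1
  th <- bfp_radius_to_angle(pmin(rn, 1), geom)
  cos2 <- ifelse(rn > 0, (dx / (rn * geom$radius_px))^2, 1)
  img <- matrix(0, shape[1], shape[2])
  img[inside] <- stats::approx(thetas, Rp, th[inside])$y * cos2[inside] +
    stats::approx(thetas, Rs, th[inside])$y * (1 - cos2[inside])
  img * illumination
}

# ---- scene bundles ----------------------------------------------------

#' Render the deterministic part of a bead scene
#'
#' Computes, for one wavelength, the noise-free components shared by all
#' noisy realizations of a scene: the blurred p-polarized reflectance map,
#' the flat s-polarized reference reflectance, the bright-field image, and
#' the illumination field. [make_bead_dataset()] composes this with
#' [bead_scene_with_noise()].
#'
#' @param beads list of [bead_spec()] (or a single one).
#' @param stack three-layer [optical_stack()].
#' @param config an [imaging_config()].
#' @param illumination_seed seed for the inhomogeneity field.
#' @return list of class `bead_scene` with elements `p0` (blurred
#'   reflectance matrix), `Rs`, `Rbg`, `angle_deg`, `brightfield0`,
#'   `illumination`, `beads`, `stack`, `config`.
#' @export
render_bead_scene <- function(beads, stack, config, illumination_seed = 1) {
  beads <- if (inherits(beads, "bead_spec")) list(beads) else beads
  rm <- reflectance_map(beads, stack, config)
  p0 <- blur_image(rm$Rmap, config$psf, config$pixel_size_um)
  Rs <- stack_reflectance(stack, rm$angle_deg, "s")
  bf0 <- local({
    cfg0 <- config; cfg0$noise_sigma <- 0
    render_brightfield_bead_image(beads, cfg0)
  })
  illum <- illumination_field(config$image_shape, illumination_seed)
  structure(list(p0 = p0, Rs = Rs, Rbg = rm$Rbg, angle_deg = rm$angle_deg,
                 at_minimum = rm$at_minimum, brightfield0 = bf0,
                 illumination = illum, beads = beads, stack = stack,
                 config = config),
            class = "bead_scene")
}

#' Add frame noise to a deterministic bead scene
#'
#' Produces the acquired image triple: `p = illum * (p0 + n1)`,
#' `s = illum * Rs`, `brightfield = bf0 + n3`, with independent Gaussian
#' noise of sd `noise_sigma / sqrt(frames_to_average)` in reflectance
#' units on the measurement channels (scaled into camera counts by the
#' illumination field together with the signal, so p/s division cancels
#' the inhomogeneity in both), deterministic under `seed`. The
#' s-polarized frame is a static reference shared by a whole acquisition
#' series and is modeled as heavily frame-averaged, i.e. noise-free; its
#' role is to carry the illumination field out of the p-frame.
#'
#' @param scene a [render_bead_scene()] result.
#' @param noise_sigma per-frame noise sd (reflectance units); default from
#'   the scene config.
#' @param seed integer seed.
#' @return list with `p`, `s` ([spr_image()]s) and `brightfield` (matrix).
#' @export
bead_scene_with_noise <- function(scene, noise_sigma = NULL, seed = 1) {
  cfg <- scene$config
  if (!is.null(noise_sigma)) cfg$noise_sigma <- noise_sigma
  sd_eff <- cfg$noise_sigma / sqrt(cfg$frames_to_average)
  set.seed(as.integer(seed))
  noise <- function() if (sd_eff > 0)
    matrix(stats::rnorm(length(scene$p0), sd = sd_eff), nrow(scene$p0))
  else 0
  p <- scene$illumination * (scene$p0 + noise())
  s <- scene$illumination * matrix(scene$Rs, nrow(scene$p0), ncol(scene$p0))
  bf <- scene$brightfield0 + noise()
  list(p = spr_image(p, cfg$pixel_size_um, scene$stack$wavelength_nm,
                     "p", "counts"),
       s = spr_image(s, cfg$pixel_size_um, scene$stack$wavelength_nm,
                     "s", "counts"),
       brightfield = bf)
}

# Noise-free processed delta-R map of a scene: (p0 - Rbg) / Rs, the exact
# result of the p/s + background-subtraction pipeline without noise.
scene_delta_R0 <- function(scene) (scene$p0 - scene$Rbg) / scene$Rs

# sd of the p/s ratio image for a given per-frame noise sd (noise on the
# p channel; the s reference is noise-free)
ratio_noise_sd <- function(scene, frame_sd) frame_sd / scene$Rs

#' Calibrate frame noise so the k-sigma threshold sits at a chosen depth
#'
#' Finds the per-frame noise sd for which the pipeline's `k`-sigma
#' detection threshold delineates the bead footprint down to the gap
#' distance `depth_nm` — i.e. so that detection of the bead cuts off at
#' that depth. The calibration equates the expected above-threshold pixel
#' count of the measured (noisy) image, inside the analysis ROI, with the
#' geometric footprint \eqn{\pi \rho^2} at the calibration depth:
#' \deqn{\sum_i \Phi\!\big((v_i - k\sigma)/\sigma\big) = \pi\rho^2/A_{px},}
#' where the \eqn{v_i} are the noise-free processed delta-R pixel values.
#' In the noise-free limit this reduces to simple count matching at the
#' level the profile takes at the footprint edge; with noise it also
#' accounts for pixels of the blurred profile skirt fluctuating across the
#' threshold, which matters when the point spread function is not small
#' against the footprint. Used with `depth_nm = Lp` to restate the finding
#' that the 1/e penetration depth is the practical detection limit.
#'
#' @param scene a [render_bead_scene()] result (single- or multi-bead; the
#'   first bead is used).
#' @param depth_nm target detection depth in nm.
#' @param k threshold multiplier, default 3.
#' @param roi_margin_um margin by which the analysis ROI circle extends
#'   past the footprint, default 3; use the same value in the measurement
#'   ROI so the expected count refers to the same region.
#' @return per-frame noise sd in reflectance units, with attributes
#'   `"sigma_ratio"` (processed-image noise sd, ratio units) and
#'   `"threshold"` (`k * sigma_ratio`).
#' @export
calibrate_noise_sigma <- function(scene, depth_nm, k = 3, roi_margin_um = 3) {
  bead <- scene$beads[[1]]
  r1 <- bead$radius_um
  d_um <- depth_nm / 1000
  if (d_um >= r1) stop("depth exceeds bead radius")
  rho <- sqrt(d_um * (2 * r1 - d_um))
  px <- scene$config$pixel_size_um
  n_target <- pi * rho^2 / px^2
  if (n_target < 4) stop("footprint at the requested depth is only ",
                         round(n_target), " pixels; refine the pixel size")
  ctr <- bead_center(bead, scene$config)
  region <- circle_mask(dim(scene$p0), px, ctr[1], ctr[2],
                        rho + roi_margin_um)
  vals <- sort(scene_delta_R0(scene)[region], decreasing = TRUE)
  if (n_target >= length(vals))
    stop("analysis region smaller than the target footprint")
  T0 <- (vals[floor(n_target)] + vals[floor(n_target) + 1]) / 2
  if (T0 <= 0) stop("no positive delta-R at the requested depth")
  expected_count <- function(sigma)
    sum(stats::pnorm((vals - k * sigma) / sigma))
  # expected count decreases in sigma: from ~all positive pixels (sigma->0)
  # to ~none (threshold above the peak)
  hi <- max(vals) / k
  lo <- 1e-9 * hi
  for (it in 1:60) {
    if (expected_count(hi) < n_target) break
    hi <- 2 * hi
    if (it == 60L) stop("cannot bracket the calibration noise level")
  }
  sigma_ratio <- stats::uniroot(function(s) expected_count(s) - n_target,
                                lower = lo, upper = hi, tol = 1e-10 * hi)$root
  frame_sd <- sigma_ratio * scene$Rs * sqrt(scene$config$frames_to_average)
  structure(frame_sd, sigma_ratio = sigma_ratio,
            threshold = k * sigma_ratio)
}

#' Build a multi-wavelength bead dataset
#'
#' One scene bundle per wavelength: p- and s-polarized SPR frames sharing
#' an illumination inhomogeneity field (so that p/s division is
#' meaningful), a bright-field frame, and a truth table recording, per
#' bead, the true radius, index, the theoretical penetration depth
#' \eqn{L_p(\lambda)}, and the expected apparent SPR radius r2: the
#' circle-equivalent radius of the noise-free processed delta-R footprint
#' above the k-sigma threshold implied by `noise_sigma` (`NA` for
#' noise-free scenes), i.e. the radius at which the rendered delta-R falls
#' to the detection threshold, measured the same way the pipeline measures
#' r2.
#'
#' @param beads list of [bead_spec()].
#' @param wavelengths_nm wavelengths to image at.
#' @param config an [imaging_config()] (its `wavelength_nm` is overridden
#'   per scene).
#' @param gold metal [dispersion_table()].
#' @param gold_thickness_nm gold film thickness, default 45.
#' @param k threshold multiplier for the expected-r2 computation.
#' @param seed base seed; scene `i` uses `seed + i` for its noise draw.
#' @return list of scenes; each has `images` (`p`, `s`, `brightfield`),
#'   `scene` (the deterministic [render_bead_scene()]), and `truth`
#'   (data.frame).
#' @export
make_bead_dataset <- function(beads, wavelengths_nm, config,
                              gold = gold_dispersion(),
                              gold_thickness_nm = 45, k = 3, seed = 1) {
  stopifnot(length(beads) >= 1L, length(wavelengths_nm) >= 1L)
  beads <- if (inherits(beads, "bead_spec")) list(beads) else beads
  out <- vector("list", length(wavelengths_nm))
  for (i in seq_along(wavelengths_nm)) {
    wl <- wavelengths_nm[i]
    stack <- spr_stack(wl, gold_thickness_nm, gold = gold)
    cfg <- config; cfg$wavelength_nm <- wl
    scene <- render_bead_scene(beads, stack, cfg,
                               illumination_seed = seed + 1000L + i)
    images <- bead_scene_with_noise(scene, seed = seed + i)
    Lp <- penetration_depth(wl, dielectric_lookup(gold, wl),
                            Re(stack$eps[3]))
    dR0 <- scene_delta_R0(scene)
    sigma_ratio <- ratio_noise_sd(scene, cfg$noise_sigma /
                                    sqrt(cfg$frames_to_average))
    truth <- do.call(rbind, lapply(seq_along(beads), function(b) {
      bead <- beads[[b]]
      ctr <- bead_center(bead, cfg)
      r2 <- NA_real_
      if (sigma_ratio > 0) {
        near <- circle_mask(dim(dR0), cfg$pixel_size_um, ctr[1], ctr[2],
                            min(bead$radius_um,
                                chord_radius(bead$radius_um,
                                             min(3 * Lp,
                                                 bead$radius_um * 999))) + 3)
        n_above <- sum(dR0[near] > k * sigma_ratio)
        r2 <- sqrt(n_above * cfg$pixel_size_um^2 / pi)
      }
      data.frame(bead = b, material = bead$material,
                 wavelength_nm = wl, r1_um = bead$radius_um,
                 index = bead$index, center_x_um = ctr[1],
                 center_y_um = ctr[2], Lp_nm = Lp,
                 expected_r2_um = r2)
    }))
    out[[i]] <- list(images = images, scene = scene, truth = truth)
  }
  out
}
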