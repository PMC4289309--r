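# Back-focal-plane geometry: angle <-> pupil radius mapping, crescent
# illumination masks, angle-scan extraction from BFP images, Fresnel fits.
#
# Conventions: image origin top-left, x = column index, 0-based pixel
# centers; azimuth 0 along +x (the polarization axis), increasing
# counter-clockwise in physical coordinates (i.e. upwards in the image).

#' Back focal plane geometry
#'
#' Maps incidence angle to radial position in the objective pupil. The
#' periphery of the usable aperture is pinned to `max_angle_deg` (default 60,
#' the angle span quoted for the fully illuminated pupil) rather than derived
#' from NA/n, which would allow a slightly larger angle; the two are kept
#' independent parameters.
#'
#' @param radius_px aperture radius in pixels, `> 0`.
#' @param center_px aperture center `(x, y)` in 0-based pixel coordinates.
#' @param max_angle_deg incidence angle at the aperture periphery, degrees.
#' @param NA_obj objective numerical aperture (default 1.65).
#' @param n_immersion incidence-medium index (default 1.78); must be
#'   `>= NA_obj`.
#' @return object of class `bfp_geometry`.
#' @export
bfp_geometry <- function(radius_px, center_px, max_angle_deg = 60,
                         NA_obj = 1.65, n_immersion = 1.78) {
  stopifnot(radius_px > 0, length(center_px) == 2L,
            max_angle_deg > 0, max_angle_deg < 90)
  if (NA_obj > n_immersion) stop("NA must be <= immersion index")
  structure(list(radius_px = radius_px, center_px = as.numeric(center_px),
                 max_angle_deg = max_angle_deg, NA_obj = NA_obj,
                 n_immersion = n_immersion),
            class = "bfp_geometry")
}

#' Crescent illumination specification
#'
#' A thin arc of light in the BFP selecting a narrow band of incidence
#' angles over a limited azimuthal span (about 40 arc degrees in routine
#' imaging), centered on the plasmon coupling angle.
#'
#' @param center_angle_deg incidence angle at the crescent centerline.
#' @param radial_width_deg radial extent in incidence-angle degrees, `> 0`.
#' @param azimuthal_span_deg arc length in azimuth degrees, in `(0, 360]`.
#' @param azimuth_center_deg azimuth of the arc center (0 = +x axis).
#' @return object of class `crescent_spec`.
#' @export
crescent_spec <- function(center_angle_deg, radial_width_deg = 1,
                          azimuthal_span_deg = 40, azimuth_center_deg = 0) {
  stopifnot(radial_width_deg > 0,
            azimuthal_span_deg > 0, azimuthal_span_deg <= 360)
  structure(list(center_angle_deg = center_angle_deg,
                 radial_width_deg = radial_width_deg,
                 azimuthal_span_deg = azimuthal_span_deg,
                 azimuth_center_deg = azimuth_center_deg),
            class = "crescent_spec")
}

#' Map incidence angle to normalized BFP radius
#'
#' Abbe sine mapping normalized to the periphery angle:
#' \eqn{r/R = \sin\theta / \sin\theta_{max}}. Strictly increasing on
#' `[0, max_angle]` and exactly inverted by [bfp_radius_to_angle()].
#'
#' @param theta_deg incidence angle(s), degrees, in `[0, max_angle]`.
#' @param geom a [bfp_geometry()].
#' @return normalized radius in `[0, 1]`.
#' @export
angle_to_bfp_radius <- function(theta_deg, geom) {
  stopifnot(inherits(geom, "bfp_geometry"))
  if (any(theta_deg < 0 | theta_deg > geom$max_angle_deg))
    stop("theta outside [0, max_angle]")
  sin(theta_deg * pi / 180) / sin(geom$max_angle_deg * pi / 180)
}

#' Map normalized BFP radius to incidence angle
#'
#' @param r normalized radius in `[0, 1]`.
#' @inheritParams angle_to_bfp_radius
#' @return incidence angle in degrees.
#' @export
bfp_radius_to_angle <- function(r, geom) {
  stopifnot(inherits(geom, "bfp_geometry"))
  if (any(r < 0 | r > 1)) stop("normalized radius outside [0, 1]")
  asin(r * sin(geom$max_angle_deg * pi / 180)) * 180 / pi
}

#' Binary crescent mask for the BFP
#'
#' Pixel-center inclusion: a pixel belongs to the mask when its radial
#' coordinate maps into the requested incidence-angle band and its azimuth
#' lies within half the span of the azimuth center.
#'
#' @param spec a [crescent_spec()].
#' @param geom a [bfp_geometry()].
#' @param shape mask dimensions `c(rows, cols)`; defaults to the smallest
#'   frame containing the aperture at its center position.
#' @return logical matrix.
#' @export
make_crescent_mask <- function(spec, geom, shape = NULL) {
  stopifnot(inherits(spec, "crescent_spec"), inherits(geom, "bfp_geometry"))
  a_lo <- spec$center_angle_deg - spec$radial_width_deg / 2
  a_hi <- spec$center_angle_deg + spec$radial_width_deg / 2
  if (a_lo < 0 || a_hi > geom$max_angle_deg)
    stop("radial band outside the aperture [0, max_angle]")
  r_lo <- angle_to_bfp_radius(a_lo, geom)
  r_hi <- angle_to_bfp_radius(a_hi, geom)
  if (is.null(shape)) shape <- default_bfp_shape(geom)
  x <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1])
  y <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), shape[1])
  dx <- x - geom$center_px[1]
  dy <- -(y - geom$center_px[2])          # CCW-positive azimuth
  rn <- sqrt(dx^2 + dy^2) / geom$radius_px
  az <- atan2(dy, dx) * 180 / pi
  daz <- (az - spec$azimuth_center_deg + 180) %% 360 - 180
  rn >= r_lo & rn <= r_hi & abs(daz) <= spec$azimuthal_span_deg / 2
}

# smallest frame holding the full aperture at its center position
default_bfp_shape <- function(geom) {
  c(ceiling(geom$center_px[2] + geom$radius_px) + 2L,
    ceiling(geom$center_px[1] + geom$radius_px) + 2L)
}

# Bilinear interpolation at 0-based (x, y) positions.
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1))
    stop("sample position outside image bounds")
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  img[cbind(i, j)] * (1 - fx) * (1 - fy) +
    img[cbind(i, j + 1)] * fx * (1 - fy) +
    img[cbind(i + 1, j)] * (1 - fx) * fy +
    img[cbind(i + 1, j + 1)] * fx * fy
}

#' Extract an angle scan from a BFP image
#'
#' Samples intensity along a radial ray from the aperture center to the
#' periphery (bilinear interpolation between pixels) and converts radius to
#' incidence angle by inverting the sine mapping. Along the polarization
#' axis (azimuth 0) the p-polarized SPR dip is visible; at azimuth 90 the
#' light is s-polarized and no dip appears.
#'
#' @param bfp_image numeric matrix covering the aperture.
#' @param geom a [bfp_geometry()].
#' @param azimuth_deg ray azimuth, default 0 (+x, polarization axis).
#' @param polarization label recorded on the scan, default `"p"`.
#' @param wavelength_nm wavelength label for the scan.
#' @param step_px radial sampling step in pixels, default 0.5.
#' @return an [angle_scan()] (intensity in camera units, not normalized).
#' @export
extract_angle_scan <- function(bfp_image, geom, azimuth_deg = 0,
                               polarization = "p", wavelength_nm = NA,
                               step_px = 0.5) {
  stopifnot(is.matrix(bfp_image), inherits(geom, "bfp_geometry"))
  r_px <- seq(0, geom$radius_px, by = step_px)
  x <- geom$center_px[1] + r_px * cos(azimuth_deg * pi / 180)
  y <- geom$center_px[2] - r_px * sin(azimuth_deg * pi / 180)
  vals <- bilinear(bfp_image, x, y)
  theta <- bfp_radius_to_angle(pmin(r_px / geom$radius_px, 1), geom)
  structure(data.frame(angle_deg = theta, reflectance = vals),
            polarization = polarization, wavelength_nm = wavelength_nm,
            units = "counts",
            class = c("angle_scan", "data.frame"))
}

#' Fit a Fresnel model to a measured angle scan
#'
#' Least-squares fit of `scale * R(theta + offset; gold thickness)` to raw
#' scan intensities, used to normalize camera counts to reflectivity units.
#' Free parameters: the gold film thickness, a multiplicative intensity
#' scale, and a global angle offset. The fit is invariant to rescaling the
#' input intensities (absorbed by `scale`).
#'
#' @param scan an [angle_scan()] spanning the reflectance minimum (values
#'   may be raw counts).
#' @param stack_template an [optical_stack()] whose metal layer thickness is
#'   the starting value.
#' @param gold_layer index of the metal layer in the stack, default 2.
#' @param polarization default `"p"`.
#' @return list of class `fresnel_fit`: `thickness_nm`, `scale`,
#'   `angle_offset_deg`, `stack` (fitted), `residual_rms` (reflectance
#'   units), `converged`, `normalized` (the scan divided by `scale`, an
#'   [angle_scan()]).
#' @export
fit_fresnel_scan <- function(scan, stack_template, gold_layer = 2L,
                             polarization = "p") {
  stopifnot(inherits(scan, "angle_scan"), inherits(stack_template, "optical_stack"))
  th0 <- stack_template$thickness_nm[gold_layer]
  ang <- scan$angle_deg
  I <- scan$reflectance
  s0 <- stats::quantile(I, 0.95, names = FALSE)
  if (s0 <= 0) stop("scan intensities must be positive")
  model <- function(p) {
    st <- set_layer_thickness(stack_template, gold_layer, p[1])
    a <- ang + p[3]
    a <- pmin(pmax(a, 0), 89.999)
    p[2] * stack_reflectance(st, a, polarization)
  }
  res <- minpack.lm::nls.lm(
    par = c(th0, s0, 0),
    lower = c(1, 1e-12, -5), upper = c(500, Inf, 5),
    fn = function(p) I - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- res$par
  fitted_stack <- set_layer_thickness(stack_template, gold_layer, p[1])
  rms <- sqrt(mean((I / p[2] -
                      stack_reflectance(fitted_stack,
                                        pmin(pmax(ang + p[3], 0), 89.999),
                                        polarization))^2))
  converged <- res$info %in% 1:3
  if (!converged)
    warning("Fresnel scan fit did not converge: ", res$message)
  normalized <- angle_scan(ang, pmin(pmax(I / p[2], 0), 1), polarization,
                           stack_template$wavelength_nm)
  structure(list(thickness_nm = p[1], scale = p[2], angle_offset_deg = p[3],
                 stack = fitted_stack, residual_rms = rms,
                 converged = converged, normalized = normalized,
                 info = res$info),
            class = "fresnel_fit")
}

#' @export
print.fresnel_fit <- function(x, ...) {
  cat(sprintf(paste0("<fresnel_fit> gold %.2f nm, scale %.4g, ",
                     "offset %.4f deg, rms %.3g%s\n"),
              x$thickness_nm, x$scale, x$angle_offset_deg, x$residual_rms,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}
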