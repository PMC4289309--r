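# SPR image container: a 2-D reflectivity (or delta-R) map plus the imaging
# metadata the analysis pipeline needs.

#' SPR image
#'
#' @param pixels numeric matrix; image origin top-left, x = column index.
#' @param pixel_size_um pixel size in micrometers, `> 0`.
#' @param wavelength_nm excitation wavelength, nm.
#' @param polarization `"p"`, `"s"`, or `"ratio"` (p divided by s).
#' @param units `"reflectance"` (bounded, noise excursions above 1
#'   tolerated up to 1.2), `"delta_R"`, or `"counts"`.
#' @return object of class `spr_image`.
#' @export
spr_image <- function(pixels, pixel_size_um, wavelength_nm = NA,
                      polarization = c("p", "s", "ratio"),
                      units = c("reflectance", "delta_R", "counts")) {
  polarization <- match.arg(polarization)
  units <- match.arg(units)
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  if (units == "reflectance" &&
      any(pixels < -0.2 | pixels > 1.2, na.rm = TRUE))
    stop("reflectance-unit pixels outside plausible range [0, ~1.2]")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 wavelength_nm = wavelength_nm, polarization = polarization,
                 units = units),
            class = "spr_image")
}

#' @export
print.spr_image <- function(x, ...) {
  cat(sprintf("<spr_image> %dx%d px @ %g um/px, %s, %s, %s nm\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$polarization, x$units, format(x$wavelength_nm)))
  invisible(x)
}

#' @export
dim.spr_image <- function(x) dim(x$pixels)

# coerce helper: accept a bare matrix where an spr_image is expected
as_pixels <- function(x) if (inherits(x, "spr_image")) x$pixels else x

#' Azimuthally averaged radial profile
#'
#' Bins pixels by distance from a center point and averages within annular
#' bins; the workhorse for bead edge localization and profile-based
#' calibration.
#'
#' @param image an [spr_image()] or numeric matrix.
#' @param center_um center `(x, y)` in micrometers (0-based pixel-center
#'   coordinates times pixel size).
#' @param pixel_size_um pixel size; taken from the image when it is an
#'   `spr_image`.
#' @param bin_um radial bin width, default one pixel.
#' @param max_radius_um outermost radius; default reaches the nearest image
#'   edge.
#' @return data.frame with `r_um` (bin centers) and `value` (mean).
#' @export
radial_profile <- function(image, center_um, pixel_size_um = NULL,
                           bin_um = NULL, max_radius_um = NULL) {
  px <- if (inherits(image, "spr_image")) image$pixel_size_um else pixel_size_um
  if (is.null(px)) stop("pixel_size_um required for a bare matrix")
  mat <- as_pixels(image)
  if (is.null(bin_um)) bin_um <- px
  xs <- (seq_len(ncol(mat)) - 1) * px
  ys <- (seq_len(nrow(mat)) - 1) * px
  if (is.null(max_radius_um))
    max_radius_um <- min(center_um[1] - min(xs), max(xs) - center_um[1],
                         center_um[2] - min(ys), max(ys) - center_um[2])
  dx <- matrix(rep(xs - center_um[1], each = nrow(mat)), nrow(mat))
  dy <- matrix(rep(ys - center_um[2], times = ncol(mat)), nrow(mat))
  r <- sqrt(dx^2 + dy^2)
  keep <- r <= max_radius_um
  bin <- floor(r[keep] / bin_um)
  v <- tapply(mat[keep], bin, mean)
  idx <- as.integer(names(v))
  data.frame(r_um = (idx + 0.5) * bin_um, value = as.numeric(v))
}

# First outward crossing of a (near-monotone beyond its peak) radial profile
# below threshold `thr`; linear interpolation between bins. NA if no
# crossing.
profile_crossing_radius <- function(r_um, value, thr) {
  i0 <- which.max(value)
  below <- which(value < thr)
  below <- below[below > i0]
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(r_um[1])
  f <- (value[i - 1] - thr) / (value[i - 1] - value[i])
  r_um[i - 1] + f * (r_um[i] - r_um[i - 1])
}
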