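# The measurement pipeline: p/s normalization, delta-R conversion, annulus
# background statistics, 3-sigma bead radius, geometric depth inversion,
# FWHM estimation, multi-wavelength aggregation and linescan labeling.

#' Circular region of interest
#'
#' @param cx,cy center in micrometers (0-based pixel-center coordinates
#'   times pixel size).
#' @param radius_um circle radius in micrometers, `> 0`.
#' @return object of class `roi_circle`.
#' @export
roi_circle <- function(cx, cy, radius_um) {
  stopifnot(radius_um > 0)
  structure(list(cx = cx, cy = cy, radius_um = radius_um),
            class = "roi_circle")
}

# logical mask of pixels whose centers fall inside a circle (or annulus
# when r_in > 0)
circle_mask <- function(shape, pixel_size_um, cx, cy, r_out, r_in = 0) {
  xs <- (seq_len(shape[2]) - 1) * pixel_size_um - cx
  ys <- (seq_len(shape[1]) - 1) * pixel_size_um - cy
  r2 <- outer(ys^2, xs^2, `+`)
  r2 <= r_out^2 & r2 > r_in^2
}

#' Normalize a p-polarized image by its s-polarized reference
#'
#' Element-wise p/s division, which cancels the spatial inhomogeneity of the
#' incident light because only p-polarized light couples to the plasmons
#' while both polarizations share the illumination profile. Pixels whose s
#' value falls below a floor are masked (`NA`) and counted.
#'
#' @param p_image,s_image [spr_image()]s of the same shape, pixel size and
#'   wavelength.
#' @param s_floor_frac pixels with `s < s_floor_frac * median(s)` are
#'   masked; default `1e-6`.
#' @return an [spr_image()] with `polarization = "ratio"`, units
#'   `"counts"`, attribute `n_masked`.
#' @export
normalize_ps <- function(p_image, s_image, s_floor_frac = 1e-6) {
  stopifnot(inherits(p_image, "spr_image"), inherits(s_image, "spr_image"))
  if (!identical(dim(p_image$pixels), dim(s_image$pixels)))
    stop("p and s images differ in shape")
  if (p_image$pixel_size_um != s_image$pixel_size_um)
    stop("p and s images differ in pixel size")
  if (!isTRUE(all.equal(p_image$wavelength_nm, s_image$wavelength_nm)))
    stop("p and s images differ in wavelength")
  s <- s_image$pixels
  med <- stats::median(s)
  if (med <= 0) stop("s image has non-positive median (all-zero reference?)")
  floor_val <- s_floor_frac * med
  bad <- s < floor_val
  ratio <- p_image$pixels / s
  ratio[bad] <- NA_real_
  out <- spr_image(ratio, p_image$pixel_size_um, p_image$wavelength_nm,
                   "ratio", "counts")
  attr(out, "n_masked") <- sum(bad)
  out
}

#' Convert an image to delta-R units
#'
#' Subtracts the mean of a background region:
#' \eqn{\Delta R = R_1 - R_0}, where R0 is the mean over a background ROI
#' under plain media. The resulting background-region mean is zero to
#' machine precision.
#'
#' @param image an [spr_image()].
#' @param background a logical mask matrix of the image shape, or an
#'   `roi_circle`/annulus mask from [circle_mask()]; must select at least
#'   one pixel.
#' @return an [spr_image()] in `delta_R` units with attribute `R0`.
#' @export
to_delta_R <- function(image, background) {
  stopifnot(inherits(image, "spr_image"))
  if (inherits(background, "roi_circle"))
    background <- circle_mask(dim(image$pixels), image$pixel_size_um,
                              background$cx, background$cy,
                              background$radius_um)
  stopifnot(is.logical(background),
            identical(dim(background), dim(image$pixels)))
  vals <- image$pixels[background]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("background ROI is empty")
  R0 <- mean(vals)
  out <- spr_image(image$pixels - R0, image$pixel_size_um,
                   image$wavelength_nm, image$polarization, "delta_R")
  attr(out, "R0") <- R0
  out
}

# annulus mask around a bead ROI; errors naming the clipped side if it
# does not fit
annulus_mask <- function(image, bead_roi, dilation_um) {
  px <- image$pixel_size_um
  shape <- dim(image$pixels)
  r_out <- bead_roi$radius_um + dilation_um / 2
  lims <- c(left = bead_roi$cx - r_out,
            right = (shape[2] - 1) * px - (bead_roi$cx + r_out),
            top = bead_roi$cy - r_out,
            bottom = (shape[1] - 1) * px - (bead_roi$cy + r_out))
  clipped <- names(lims)[lims < 0]
  if (length(clipped))
    stop("background annulus clipped by image edge on the ",
         paste(clipped, collapse = ", "), " side")
  circle_mask(shape, px, bead_roi$cx, bead_roi$cy, r_out,
              r_in = bead_roi$radius_um)
}

#' Background standard deviation in a dilated annulus
#'
#' The bead ROI circle is dilated (diameter increased by `dilation_um`) and
#' the sample standard deviation of all pixels between the two circles is
#' the background noise estimate used for thresholding.
#'
#' @param image an [spr_image()] in delta-R units.
#' @param bead_roi an [roi_circle()] generously covering the bead.
#' @param dilation_um diameter dilation in micrometers, default 10.
#' @return standard deviation in delta-R units, with attribute `n_pixels`.
#' @export
background_sigma_annulus <- function(image, bead_roi, dilation_um = 10) {
  stopifnot(inherits(image, "spr_image"), inherits(bead_roi, "roi_circle"))
  mask <- annulus_mask(image, bead_roi, dilation_um)
  vals <- image$pixels[mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L) stop("annulus contains fewer than 2 pixels")
  structure(stats::sd(vals), n_pixels = length(vals))
}

#' Apparent bead radius from the k-sigma threshold
#'
#' Counts pixels inside the bead ROI whose delta-R exceeds
#' `background_mean + k * sigma` and converts the count to the
#' circle-equivalent radius \eqn{r_2 = \sqrt{N A_{px} / \pi}}. All
#' above-threshold pixels in the ROI are counted (no connected-component
#' filtering), matching the reference image-analysis routine.
#'
#' @param image an [spr_image()] in delta-R units.
#' @param bead_roi an [roi_circle()].
#' @param sigma background standard deviation, `> 0`.
#' @param k threshold multiplier, default 3.
#' @param background_mean background level, default 0 (the delta-R
#'   convention).
#' @return r2 in micrometers with attributes `n_pixels_above` and
#'   `none_above` (TRUE, with a warning, when no pixel passes).
#' @export
bead_radius_from_threshold <- function(image, bead_roi, sigma, k = 3,
                                       background_mean = 0) {
  stopifnot(inherits(image, "spr_image"), inherits(bead_roi, "roi_circle"),
            sigma > 0, k > 0)
  mask <- circle_mask(dim(image$pixels), image$pixel_size_um,
                      bead_roi$cx, bead_roi$cy, bead_roi$radius_um)
  n <- sum(image$pixels[mask] > background_mean + k * sigma, na.rm = TRUE)
  if (n == 0L) {
    warning("no pixels above threshold; r2 = 0")
    return(structure(0, n_pixels_above = 0L, none_above = TRUE))
  }
  structure(sqrt(n * image$pixel_size_um^2 / pi),
            n_pixels_above = n, none_above = FALSE)
}

#' Detectable depth from the two bead radii
#'
#' The unique depth at which a sphere of radius r1 resting on the surface
#' has a horizontal chord of radius r2:
#' \deqn{d = r_1 - \sqrt{r_1^2 - r_2^2}.}
#' This inverts the forward chord formula \eqn{r_2 = \sqrt{d (2 r_1 - d)}}
#' exactly. (The frequently quoted variant
#' \eqn{r_1^2 = r_2^2 + (r_2 - d)^2} is geometrically inconsistent for a
#' surface-resting sphere — it has no real solution for small observed
#' chords — so the consistent form is used; see the vignette.)
#'
#' @param r1_um bright-field bead radius, micrometers.
#' @param r2_um apparent SPR radius, micrometers, `0 <= r2 <= r1`.
#' @return depth d in nanometers.
#' @seealso [chord_radius()]
#' @export
depth_from_radii <- function(r1_um, r2_um) {
  stopifnot(all(r1_um > 0))
  if (any(r2_um < 0 | r2_um > r1_um))
    stop("need 0 <= r2 <= r1")
  # algebraically r1 - sqrt(r1^2 - r2^2), written without the cancellation
  # that loses precision when r2 << r1
  r2_um^2 / (r1_um + sqrt(r1_um^2 - r2_um^2)) * 1000
}

#' Chord radius of a resting sphere at depth d
#'
#' Forward geometry \eqn{r_2 = \sqrt{d (2 r_1 - d)}}; exact inverse of
#' [depth_from_radii()].
#'
#' @param r1_um sphere radius, micrometers.
#' @param d_nm depth in nanometers, `0 <= d <= 1000 * r1`.
#' @return chord radius in micrometers.
#' @export
chord_radius <- function(r1_um, d_nm) {
  d <- d_nm / 1000
  if (any(d < 0 | d > r1_um)) stop("need 0 <= d <= r1")
  sqrt(d * (2 * r1_um - d))
}

#' Full width at half maximum of a 1-D profile
#'
#' Baseline is the median of the outer quartiles of the profile; the
#' half-maximum crossings on either side of the single dominant peak are
#' located by linear interpolation between samples.
#'
#' @param values numeric profile.
#' @param pixel_size_um sample spacing in micrometers.
#' @return FWHM in micrometers.
#' @export
fwhm_from_profile <- function(values, pixel_size_um) {
  n <- length(values)
  if (n < 5L) stop("profile too short")
  q <- max(2L, floor(n / 4))
  baseline <- stats::median(c(values[1:q], values[(n - q + 1):n]))
  ipk <- which.max(values)
  half <- baseline + (values[ipk] - baseline) / 2
  cross <- function(idx) {
    # idx runs from the peak outward; find first drop below `half`
    below <- which(values[idx] < half)
    if (!length(below)) stop("no half-maximum crossing on one side of peak")
    i2 <- idx[below[1]]; i1 <- idx[below[1] - 1]
    if (below[1] == 1L) stop("profile starts below half maximum at the peak")
    f <- (values[i1] - half) / (values[i1] - values[i2])
    (i1 + f * (i2 - i1))
  }
  right <- cross(ipk:n)
  left <- cross(ipk:1)
  abs(right - left) * pixel_size_um
}

#' Bead radius from a bright-field ring image
#'
#' Azimuthally averages the image around the bead center and locates the
#' dark ring minimum with three-point parabolic sub-pixel refinement; the
#' ring centerline is taken as the bead radius r1.
#'
#' @param image bright-field matrix (background ~1, dark ring at the bead
#'   edge).
#' @param center_um bead center `(x, y)`, micrometers.
#' @param pixel_size_um pixel size.
#' @return r1 in micrometers.
#' @export
brightfield_radius <- function(image, center_um, pixel_size_um) {
  prof <- radial_profile(image, center_um, pixel_size_um)
  i <- which.min(prof$value)
  if (i == 1L || i == nrow(prof))
    stop("ring minimum at the profile boundary; center or FOV wrong?")
  y0 <- prof$value[i - 1]; y1 <- prof$value[i]; y2 <- prof$value[i + 1]
  denom <- y0 - 2 * y1 + y2
  shift <- if (abs(denom) > 1e-300) 0.5 * (y0 - y2) / denom else 0
  prof$r_um[i] + shift * (prof$r_um[2] - prof$r_um[1])
}

#' Measure one bead from an image pair
#'
#' Runs the full per-bead pipeline: p/s normalization, delta-R conversion
#' against the annulus background, annulus sigma, k-sigma radius r2,
#' bright-field radius r1, and the geometric depth inversion.
#'
#' @param p_image,s_image SPR frames ([spr_image()]).
#' @param brightfield bright-field matrix.
#' @param bead_roi an [roi_circle()] approximately centered on the bead and
#'   extending a few micrometers past its detectable edge.
#' @param k threshold multiplier, default 3.
#' @param dilation_um annulus dilation, default 10.
#' @return one-row data.frame: `r1_um`, `r2_um`, `d_nm`, `sigma`,
#'   `n_pixels_above`, `threshold_k`, `wavelength_nm`.
#' @export
measure_bead <- function(p_image, s_image, brightfield, bead_roi,
                         k = 3, dilation_um = 10) {
  ratio <- normalize_ps(p_image, s_image)
  ann <- annulus_mask(ratio, bead_roi, dilation_um)
  dR <- to_delta_R(ratio, ann)
  sigma <- background_sigma_annulus(dR, bead_roi, dilation_um)
  r2 <- bead_radius_from_threshold(dR, bead_roi, sigma, k)
  r1 <- brightfield_radius(brightfield, c(bead_roi$cx, bead_roi$cy),
                           p_image$pixel_size_um)
  r2v <- min(as.numeric(r2), r1)   # guard against noise pushing r2 > r1
  data.frame(r1_um = r1, r2_um = as.numeric(r2),
             d_nm = depth_from_radii(r1, r2v),
             sigma = as.numeric(sigma),
             n_pixels_above = attr(r2, "n_pixels_above"),
             threshold_k = k, wavelength_nm = p_image$wavelength_nm)
}

#' Automatic coarse bead ROI
#'
#' Brightest-blob detection for when no manual ROI is supplied: the
#' centroid of pixels above half the image maximum (after light 3x3 mean
#' smoothing), with a radius of 1.5 times the blob's circle-equivalent
#' radius plus a margin.
#'
#' @param image an [spr_image()] in delta-R units.
#' @param margin_um added to the detected radius, default 3.
#' @return an [roi_circle()] with attribute `auto = TRUE`.
#' @export
detect_bead_roi <- function(image, margin_um = 3) {
  m <- image$pixels
  sm <- (m +
           rbind(m[-1, ], m[nrow(m), ]) + rbind(m[1, ], m[-nrow(m), ]) +
           cbind(m[, -1], m[, ncol(m)]) + cbind(m[, 1], m[, -ncol(m)])) / 5
  thr <- max(sm, na.rm = TRUE) / 2
  idx <- which(sm > thr, arr.ind = TRUE)
  px <- image$pixel_size_um
  cx <- mean(idx[, 2] - 1) * px
  cy <- mean(idx[, 1] - 1) * px
  r_eff <- sqrt(nrow(idx) * px^2 / pi)
  out <- roi_circle(cx, cy, 1.5 * r_eff + margin_um)
  attr(out, "auto") <- TRUE
  out
}

#' Aggregate bead measurements into a penetration-depth table
#'
#' Groups measurements by wavelength and material and reports the mean and
#' sample standard deviation of the measured depths next to the theoretical
#' penetration depth Lp and the 5 percent detection-limit depth 3 Lp.
#'
#' @param measurements data.frame with columns `wavelength_nm`, `material`,
#'   `d_nm` (e.g. rows from [measure_bead()] plus a `material` column).
#' @param theory data.frame with `wavelength_nm` and `Lp_nm` (e.g. from
#'   [penetration_depth_curve()]).
#' @return data.frame: `wavelength_nm`, `material`, `mean_d_nm`, `sd_d_nm`
#'   (0 with `single_measurement = TRUE` when n = 1), `n`,
#'   `Lp_theory_nm`, `Lp3_theory_nm`.
#' @export
aggregate_penetration_depths <- function(measurements, theory) {
  stopifnot(nrow(measurements) >= 1L,
            all(c("wavelength_nm", "material", "d_nm") %in%
                  names(measurements)))
  groups <- split(measurements,
                  interaction(measurements$wavelength_nm,
                              measurements$material, drop = TRUE))
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(wavelength_nm = g$wavelength_nm[1], material = g$material[1],
               mean_d_nm = mean(g$d_nm),
               sd_d_nm = if (n > 1) stats::sd(g$d_nm) else 0,
               n = n, single_measurement = n == 1L)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$wavelength_nm, out$material), ]
  i <- match(out$wavelength_nm, theory$wavelength_nm)
  out$Lp_theory_nm <- theory$Lp_nm[i]
  out$Lp3_theory_nm <- 3 * theory$Lp_nm[i]
  rownames(out) <- NULL
  out
}

#' Linescan intensity classes
#'
#' Three ascending delta-R thresholds splitting a linescan into the four
#' canonical image features: coated substratum, extracellular deposited
#' material, basal cell surface, focal adhesions.
#'
#' @param thresholds three strictly ascending delta-R cut values.
#' @param labels four class labels, lowest first.
#' @return object of class `linescan_classes`.
#' @export
linescan_classes <- function(thresholds,
                             labels = c("substrate", "ECM", "basal cell",
                                        "focal adhesion")) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0),
            length(labels) == 4L)
  structure(list(thresholds = thresholds, labels = labels),
            class = "linescan_classes")
}

#' Classify a delta-R linescan into intensity classes
#'
#' Labels every sample by the threshold interval its delta-R falls in and
#' reports contiguous runs.
#'
#' @param values delta-R profile.
#' @param classes a [linescan_classes()].
#' @return factor of labels (same length as `values`) with attribute
#'   `runs`: data.frame of `label`, `start`, `length`.
#' @export
classify_linescan <- function(values, classes) {
  stopifnot(inherits(classes, "linescan_classes"))
  idx <- findInterval(values, classes$thresholds) + 1L
  lab <- factor(classes$labels[idx], levels = classes$labels)
  r <- rle(as.integer(lab))
  runs <- data.frame(label = classes$labels[r$values],
                     start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
                     length = r$lengths)
  structure(lab, runs = runs)
}
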