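# Multilayer Fresnel reflectance via the characteristic (transfer) matrix
# for stratified media with complex permittivities.

# Principal complex square root flipped onto the physical branch Im >= 0,
# so evanescent fields decay away from each interface.
csqrt_up <- function(z) {
  s <- sqrt(as.complex(z))
  ifelse(Im(s) < 0, -s, s)
}

# Characteristic-matrix amplitudes for a stack.
#   eps  : complex permittivity per layer (length N)
#   d_nm : thickness per layer; interior layers may be vectors (broadcast),
#          which is how the bead gap layer is swept efficiently
#   theta_deg : incidence angle(s) in the first medium, degrees
# Returns list(r, t, q1, qN) of complex vectors.
tmm_amplitudes <- function(eps, d_nm, theta_deg, wavelength_nm, polarization) {
  N <- length(eps)
  k0 <- 2 * pi / wavelength_nm
  kx2 <- Re(eps[1]) * sin(theta_deg * pi / 180)^2
  m <- max(length(kx2), if (N > 2) max(lengths(d_nm[2:(N - 1)])) else 1L)
  kx2 <- rep_len(kx2, m)
  q <- kz <- vector("list", N)
  for (j in seq_len(N)) {
    kz[[j]] <- csqrt_up(eps[j] - kx2)
    q[[j]] <- if (polarization == "p") kz[[j]] / eps[j] else kz[[j]]
  }
  M11 <- M22 <- rep(1 + 0i, m)
  M12 <- M21 <- rep(0 + 0i, m)
  if (N > 2) for (j in 2:(N - 1)) {
    beta <- k0 * rep_len(d_nm[[j]], m) * kz[[j]]
    cb <- cos(beta); sb <- sin(beta)
    a11 <- cb;                a12 <- -1i * sb / q[[j]]
    a21 <- -1i * q[[j]] * sb; a22 <- cb
    n11 <- M11 * a11 + M12 * a21; n12 <- M11 * a12 + M12 * a22
    n21 <- M21 * a11 + M22 * a21; n22 <- M21 * a12 + M22 * a22
    M11 <- n11; M12 <- n12; M21 <- n21; M22 <- n22
  }
  q1 <- q[[1]]; qN <- q[[N]]
  den <- (M11 + M12 * qN) * q1 + (M21 + M22 * qN)
  r <- ((M11 + M12 * qN) * q1 - (M21 + M22 * qN)) / den
  t <- 2 * q1 / den
  list(r = r, t = t, q1 = q1, qN = qN)
}

#' Reflectance of a multilayer stack
#'
#' \eqn{|r|^2} from the characteristic-matrix solution for a stratified
#' medium with complex indices; p and s polarizations coincide at normal
#' incidence.
#'
#' @param stack an [optical_stack()].
#' @param angle_deg incidence angle(s) in the first medium, degrees, in
#'   `[0, 90)`.
#' @param polarization `"p"` (in-plane; excites surface plasmons) or `"s"`.
#' @return numeric reflectance in `[0, 1]`, same length as `angle_deg`.
#' @export
#' @examples
#' s <- spr_stack(620)
#' stack_reflectance(s, 54, "p")
stack_reflectance <- function(stack, angle_deg, polarization = c("p", "s")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "optical_stack"), is.numeric(angle_deg))
  if (any(angle_deg < 0 | angle_deg >= 90))
    stop("angle must be in [0, 90) degrees")
  amp <- tmm_amplitudes(stack$eps, as.list(stack$thickness_nm),
                        angle_deg, stack$wavelength_nm, polarization)
  Mod(amp$r)^2
}

#' Transmittance of a multilayer stack
#'
#' Power transmittance into the final medium, the energy-flux complement of
#' [stack_reflectance()]: for lossless stacks `R + T = 1`.
#'
#' @inheritParams stack_reflectance
#' @return numeric transmittance, same length as `angle_deg`.
#' @export
stack_transmittance <- function(stack, angle_deg, polarization = c("p", "s")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "optical_stack"), is.numeric(angle_deg))
  if (any(angle_deg < 0 | angle_deg >= 90))
    stop("angle must be in [0, 90) degrees")
  amp <- tmm_amplitudes(stack$eps, as.list(stack$thickness_nm),
                        angle_deg, stack$wavelength_nm, polarization)
  Re(amp$qN) / Re(amp$q1) * Mod(amp$t)^2
}

#' Angle scan container
#'
#' @param angle_deg ascending angles in `[0, 90)` degrees.
#' @param reflectance values in `[0, 1]` (small numerical excursions above 1
#'   are clipped at validation tolerance), same length.
#' @param polarization `"p"` or `"s"`.
#' @param wavelength_nm wavelength in nm.
#' @return data.frame of class `angle_scan` with columns `angle_deg`,
#'   `reflectance` and attributes `polarization`, `wavelength_nm`.
#' @export
angle_scan <- function(angle_deg, reflectance, polarization, wavelength_nm) {
  stopifnot(length(angle_deg) == length(reflectance), length(angle_deg) >= 1L)
  if (any(angle_deg < 0 | angle_deg >= 90)) stop("angles must be in [0, 90)")
  if (is.unsorted(angle_deg)) stop("angles must be ascending")
  if (any(reflectance < -1e-9 | reflectance > 1 + 1e-9))
    stop("reflectance must lie in [0, 1]")
  structure(data.frame(angle_deg = angle_deg,
                       reflectance = pmin(pmax(reflectance, 0), 1)),
            polarization = polarization, wavelength_nm = wavelength_nm,
            class = c("angle_scan", "data.frame"))
}

#' Compute an SPR angle scan
#'
#' Element-wise [stack_reflectance()] over a set of incidence angles,
#' reproducing the reflectivity-versus-angle curve read off a fully
#' illuminated back focal plane.
#'
#' @inheritParams stack_reflectance
#' @param angles_deg nonempty ascending numeric vector of angles.
#' @return an [angle_scan()].
#' @export
spr_angle_scan <- function(stack, angles_deg, polarization = c("p", "s")) {
  polarization <- match.arg(polarization)
  if (length(angles_deg) < 1L) stop("empty angle list")
  angle_scan(angles_deg, stack_reflectance(stack, angles_deg, polarization),
             polarization, stack$wavelength_nm)
}

#' @export
plot.angle_scan <- function(x, ...) {
  graphics::plot(x$angle_deg, x$reflectance, type = "l",
                 xlab = "incidence angle (deg)", ylab = "reflectance",
                 main = sprintf("%s-pol, %g nm", attr(x, "polarization"),
                                attr(x, "wavelength_nm")), ...)
  invisible(x)
}

# Critical angle of the incidence medium against the final medium, degrees;
# NA when the final medium is absorbing or denser than the entry medium.
critical_angle <- function(stack) {
  epsN <- stack$eps[length(stack$eps)]
  if (abs(Im(epsN)) > 1e-12) return(NA_real_)
  s <- sqrt(Re(epsN) / Re(stack$eps[1]))
  if (s >= 1) return(NA_real_)
  asin(s) * 180 / pi
}

#' Angle of the surface plasmon reflectance minimum
#'
#' Locates the global p-polarized reflectance minimum beyond the critical
#' angle by a coarse grid scan (0.05 degree) followed by golden-section
#' refinement, to better than 0.01 degree. When the stack supports no
#' plasmon dip (e.g. an all-dielectric stack, where reflectance is unity
#' beyond the critical angle) the minimum is reported as absent (`NA`)
#' rather than an error.
#'
#' @param stack an [optical_stack()]; the absorbing metal film supplies the
#'   plasmon resonance.
#' @param polarization polarization of the scan, default `"p"`.
#' @return the minimum angle in degrees, with attribute `"reflectance"`
#'   (the minimum reflectance value), or `NA` if absent.
#' @export
#' @examples
#' spr_minimum_angle(spr_stack(620))
spr_minimum_angle <- function(stack, polarization = "p") {
  thc <- critical_angle(stack)
  lo <- if (is.na(thc)) 0.1 else thc + 0.05
  grid <- seq(lo, 89.9, by = 0.05)
  R <- stack_reflectance(stack, grid, polarization)
  i <- which.min(R)
  if (R[i] >= 1 - 1e-9 || i == 1L || i == length(grid)) return(NA_real_)
  opt <- stats::optimize(function(a) stack_reflectance(stack, a, polarization),
                         lower = grid[i - 1], upper = grid[i + 1], tol = 1e-4)
  structure(opt$minimum, reflectance = opt$objective)
}

#' Imaging operating angle slightly shallow of the SPR minimum
#'
#' The imaging operating point is set on the shallow (sub-critical-side)
#' flank of the SPR dip where the reflectance equals
#' `operating_reflectance`, so that index increases at the surface produce a
#' linear positive reflectivity response. When the dip never reaches the
#' requested reflectance (shallow, heavily damped resonances, e.g. gold
#' below ~520 nm) the minimum itself is used and flagged.
#'
#' @param stack an [optical_stack()].
#' @param operating_reflectance target background reflectance, default 0.1.
#' @param polarization default `"p"`.
#' @return list with `angle_deg`, `reflectance`, and `at_minimum` (TRUE when
#'   the target reflectance was unattainable and the minimum was used).
#' @export
operating_angle <- function(stack, operating_reflectance = 0.1,
                            polarization = "p") {
  amin <- spr_minimum_angle(stack, polarization)
  if (is.na(amin)) stop("stack has no SPR minimum")
  rmin <- attr(amin, "reflectance")
  if (rmin >= operating_reflectance)
    return(list(angle_deg = as.numeric(amin), reflectance = rmin,
                at_minimum = TRUE))
  # walk down from the minimum until the dip flank rises above target
  a <- as.numeric(amin)
  step <- 0.05
  lo <- a - step
  while (stack_reflectance(stack, lo, polarization) < operating_reflectance) {
    lo <- lo - step
    if (lo <= 0.1) stop("no shallow-side crossing found")
  }
  root <- stats::uniroot(function(x)
    stack_reflectance(stack, x, polarization) - operating_reflectance,
    lower = lo, upper = a, tol = 1e-6)
  list(angle_deg = root$root,
       reflectance = stack_reflectance(stack, root$root, polarization),
       at_minimum = FALSE)
}

#' Reflectance of the bead gap model versus gap thickness
#'
#' Per-pixel optical model of a microsphere over the sensor: a four-layer
#' stack glass / gold / water gap of thickness z / semi-infinite bead
#' material, evaluated at a fixed incidence angle for a vector of gap
#' thicknesses. As `z` grows the reflectance converges to the three-layer
#' background.
#'
#' @param stack the three-layer background [optical_stack()]
#'   (glass/gold/medium).
#' @param bead_index real refractive index of the bead material.
#' @param gap_nm vector of water-gap thicknesses in nm.
#' @param angle_deg incidence angle, degrees.
#' @param polarization default `"p"`.
#' @return numeric reflectance, same length as `gap_nm`.
#' @export
bead_gap_reflectance <- function(stack, bead_index, gap_nm, angle_deg,
                                 polarization = "p") {
  stopifnot(length(stack$eps) == 3L, all(gap_nm >= 0),
            length(angle_deg) == 1L)
  if (angle_deg <= 0 || angle_deg >= 90)
    stop("operating angle must be inside (0, 90) degrees")
  eps <- c(stack$eps[1:2], stack$eps[3], as.complex(bead_index)^2)
  d <- list(NA_real_, stack$thickness_nm[2], gap_nm, NA_real_)
  amp <- tmm_amplitudes(eps, d, angle_deg, stack$wavelength_nm, polarization)
  Mod(amp$r)^2
}
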