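# Evanescent-field theory: penetration depth, exponential decay profile,
# plasmon propagation length, and the lateral diffraction limit.

#' Evanescent decay profile
#'
#' Container for the single-exponential evanescent intensity profile
#' \eqn{I(z) = I_0 e^{-z/L_p}} above the metal surface.
#'
#' @param Lp_nm 1/e decay length (penetration depth) in nm, `> 0`.
#' @param I0 intensity at the surface, default 1.
#' @return object of class `evanescent_profile`.
#' @export
evanescent_profile <- function(Lp_nm, I0 = 1) {
  stopifnot(is.numeric(Lp_nm), length(Lp_nm) == 1L, Lp_nm > 0, I0 > 0)
  structure(list(Lp_nm = Lp_nm, I0 = I0), class = "evanescent_profile")
}

#' Surface plasmon penetration depth
#'
#' Closed-form 1/e decay length of the evanescent field into the dielectric,
#' \deqn{L_p = \frac{\lambda}{2\pi}\left|\frac{\mathrm{Re}(\varepsilon_m) +
#' \varepsilon_d}{\varepsilon_d^2}\right|^{1/2},}
#' defined here as the 1/e length of the plotted intensity profile
#' \eqn{I(z) = e^{-z/L_p}} (no additional factor of two is applied; see the
#' package vignette for the amplitude-versus-intensity convention and its
#' consequence for the thin-film response).
#'
#' Requires the bound-mode condition
#' \eqn{\mathrm{Re}(\varepsilon_m) < -\varepsilon_d}.
#'
#' @param wavelength_nm excitation wavelength in nm.
#' @param eps_metal complex permittivity of the metal.
#' @param eps_dielectric real permittivity of the dielectric (e.g.
#'   `1.333^2` for water).
#' @return penetration depth in nm.
#' @export
#' @examples
#' penetration_depth(620, dielectric_lookup(gold_dispersion(), 620), 1.333^2)
penetration_depth <- function(wavelength_nm, eps_metal, eps_dielectric) {
  stopifnot(is.numeric(wavelength_nm), is.numeric(eps_dielectric),
            eps_dielectric > 0)
  if (any(Re(eps_metal) >= -eps_dielectric))
    stop("bound-mode condition violated: need Re(eps_metal) < -eps_dielectric")
  (wavelength_nm / (2 * pi)) *
    sqrt(abs(Re(eps_metal) + eps_dielectric)) / eps_dielectric
}

#' Penetration depth versus wavelength for a metal table
#'
#' Evaluates [penetration_depth()] over a set of wavelengths with the metal
#' permittivity taken from a dispersion table, as used for the
#' multi-wavelength depth-calibration comparison.
#'
#' @param wavelengths_nm wavelengths in nm.
#' @param metal metal [dispersion_table()], default [gold_dispersion()].
#' @param medium_index real index of the dielectric, default `water_index()`.
#' @return data.frame with `wavelength_nm`, `Lp_nm`, `Lp3_nm` (the 3 Lp / 5
#'   percent detection-limit depth).
#' @export
penetration_depth_curve <- function(wavelengths_nm,
                                    metal = gold_dispersion(),
                                    medium_index = water_index()) {
  eps_d <- medium_index^2
  Lp <- vapply(wavelengths_nm, function(wl)
    penetration_depth(wl, dielectric_lookup(metal, wl), eps_d), 0)
  data.frame(wavelength_nm = wavelengths_nm, Lp_nm = Lp, Lp3_nm = 3 * Lp)
}

#' Evanescent field intensity at height z
#'
#' \eqn{I(z) = I_0 e^{-z/L_p}}: at `z = Lp` the intensity is 37 percent of
#' its surface value (the conventional penetration depth); at `z = 3 Lp` it
#' is about 5 percent, the practical detection limit.
#'
#' @param z_nm height(s) above the surface in nm, `>= 0`.
#' @param profile an [evanescent_profile()].
#' @return intensity, same length as `z_nm`.
#' @export
field_decay <- function(z_nm, profile) {
  stopifnot(inherits(profile, "evanescent_profile"))
  if (any(z_nm < 0)) stop("z must be >= 0")
  profile$I0 * exp(-z_nm / profile$Lp_nm)
}

#' Surface plasmon propagation length
#'
#' 1/e intensity decay length of the plasmon along the interface,
#' \eqn{L_x = 1/(2\,\mathrm{Im}\,k_{sp})} with
#' \eqn{k_{sp} = (2\pi/\lambda)\sqrt{\varepsilon_m\varepsilon_d/
#' (\varepsilon_m+\varepsilon_d)}} on the physical branch
#' (\eqn{\mathrm{Im} \ge 0}). This length sets the degraded lateral
#' resolution parallel to the plasmon propagation direction. A lossless
#' metal gives an unbounded propagation length, reported as `Inf`.
#'
#' @inheritParams penetration_depth
#' @return propagation length in micrometers (possibly `Inf`).
#' @export
#' @examples
#' propagation_length(620, dielectric_lookup(gold_dispersion(), 620), 1.333^2)
propagation_length <- function(wavelength_nm, eps_metal, eps_dielectric) {
  stopifnot(eps_dielectric > 0)
  if (any(Re(eps_metal) >= -eps_dielectric))
    stop("bound-mode condition violated: need Re(eps_metal) < -eps_dielectric")
  ksp <- (2 * pi / wavelength_nm) *
    csqrt_up(eps_metal * eps_dielectric / (eps_metal + eps_dielectric))
  im <- Im(ksp)
  ifelse(im <= 0, Inf, 1 / (2 * im) / 1000)
}

#' Lateral diffraction limit
#'
#' Rayleigh resolution \eqn{0.61 \lambda / \mathrm{NA}} in micrometers.
#'
#' @param wavelength_nm wavelength in nm.
#' @param numerical_aperture objective NA, `> 0`.
#' @return resolution in micrometers.
#' @export
#' @examples
#' diffraction_limit(620, 1.65)  # ~0.23 um
diffraction_limit <- function(wavelength_nm, numerical_aperture) {
  stopifnot(numerical_aperture > 0)
  0.61 * wavelength_nm / numerical_aperture / 1000
}
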