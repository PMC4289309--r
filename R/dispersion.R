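# Dispersion tables: tabulated complex refractive indices n + ik versus
# wavelength, interpolated linearly in n and k separately (not in epsilon).

#' Create a dispersion table
#'
#' A dispersion table holds the complex refractive index \eqn{n + ik} of a
#' material at a set of tabulated wavelengths. Lookups interpolate n and k
#' linearly in wavelength; queries outside the tabulated range are an error.
#'
#' @param wavelength_nm numeric vector of wavelengths in nm, strictly
#'   increasing, at least two entries.
#' @param n real part of the refractive index at each wavelength.
#' @param k imaginary part (extinction coefficient) at each wavelength,
#'   all `>= 0` (absorbing convention).
#' @param material optional text label.
#' @return An object of class `dispersion_table`.
#' @seealso [dielectric_lookup()], [gold_dispersion()]
#' @export
#' @examples
#' tab <- dispersion_table(c(600, 640), n = c(0.2, 0.15), k = c(3.1, 3.6))
#' dielectric_lookup(tab, 620)
dispersion_table <- function(wavelength_nm, n, k, material = "") {
  stopifnot(is.numeric(wavelength_nm), is.numeric(n), is.numeric(k))
  if (length(wavelength_nm) < 2L)
    stop("dispersion table needs at least 2 entries")
  if (length(n) != length(wavelength_nm) || length(k) != length(wavelength_nm))
    stop("wavelength_nm, n and k must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(k < 0))
    stop("k must be >= 0 (absorbing convention Im(eps) >= 0)")
  structure(
    list(wavelength_nm = as.numeric(wavelength_nm),
         n = as.numeric(n), k = as.numeric(k), material = material),
    class = "dispersion_table")
}

#' @export
print.dispersion_table <- function(x, ...) {
  cat(sprintf("<dispersion_table> %s: %d entries, %g-%g nm\n",
              if (nzchar(x$material)) x$material else "(unnamed)",
              length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Interpolate a dispersion table to a complex permittivity
#'
#' Returns \eqn{\varepsilon = (n + ik)^2} with n and k each interpolated
#' linearly in wavelength between the two bracketing table rows.
#'
#' @param table a [dispersion_table()].
#' @param wavelength_nm query wavelength(s) in nm; must lie within the
#'   tabulated range.
#' @return complex permittivity, same length as `wavelength_nm`.
#' @export
dielectric_lookup <- function(table, wavelength_nm) {
  stopifnot(inherits(table, "dispersion_table"), is.numeric(wavelength_nm))
  rng <- range(table$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm",
                 rng[1], rng[2]))
  n <- stats::approx(table$wavelength_nm, table$n, wavelength_nm)$y
  k <- stats::approx(table$wavelength_nm, table$k, wavelength_nm)$y
  complex(real = n, imaginary = k)^2
}

#' Built-in gold dispersion table
#'
#' Visible-range optical constants of evaporated gold from the Johnson and
#' Christy (1972) tabulation, converted from photon energy to wavelength.
#' This is the default metal table for the SPR stack; published gold tables
#' differ noticeably (coupling angles shift by roughly 1-2 degrees and
#' penetration depths by 10-20 percent across tabulations), so the table in
#' use should always be reported alongside derived quantities. Any
#' [dispersion_table()] can be substituted.
#'
#' @return A [dispersion_table()] covering roughly 413-984 nm.
#' @references Johnson, P. B. and Christy, R. W. (1972) Optical constants of
#'   the noble metals. Physical Review B 6, 4370-4379.
#' @export
#' @examples
#' dielectric_lookup(gold_dispersion(), 620)
gold_dispersion <- function() {
  ev <- c(1.26, 1.39, 1.51, 1.64, 1.76, 1.88, 2.01, 2.13, 2.26, 2.38,
          2.50, 2.63, 2.75, 2.88, 3.00)
  n <- c(0.22, 0.17, 0.16, 0.14, 0.13, 0.14, 0.21, 0.29, 0.43, 0.62,
         1.04, 1.31, 1.38, 1.45, 1.46)
  k <- c(6.350, 5.663, 5.083, 4.542, 4.103, 3.697, 3.272, 2.863, 2.455,
         2.081, 1.833, 1.849, 1.914, 1.948, 1.958)
  wl <- 1239.8419 / ev
  o <- order(wl)
  dispersion_table(wl[o], n[o], k[o], material = "gold (Johnson & Christy 1972)")
}

#' Refractive index of water
#'
#' The aqueous medium is treated as non-dispersive with n = 1.333 across the
#' visible range, the value used throughout the bead and cell measurements.
#'
#' @param wavelength_nm ignored except for length; present so the function
#'   can stand in wherever a dispersion lookup is expected.
#' @return real refractive index, recycled to `length(wavelength_nm)`.
#' @export
water_index <- function(wavelength_nm = 589) {
  rep_len(1.333, length(wavelength_nm))
}
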