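# Optical layers and stacks for the stratified-medium reflectance model.

#' Define one layer of an optical stack
#'
#' @param name text label ("glass", "gold", "water", ...).
#' @param thickness_nm layer thickness in nm; omit (`NULL`) for the
#'   semi-infinite first and last layers.
#' @param index real refractive index (convenience for transparent layers);
#'   converted to `permittivity = index^2`.
#' @param permittivity complex relative permittivity at the working
#'   wavelength; `Im >= 0` (absorbing convention).
#' @param dispersion a [dispersion_table()] resolved at the stack wavelength.
#'   Exactly one of `index`, `permittivity`, `dispersion` must be given.
#' @return An object of class `optical_layer`.
#' @export
optical_layer <- function(name, thickness_nm = NULL, index = NULL,
                          permittivity = NULL, dispersion = NULL) {
  given <- c(!is.null(index), !is.null(permittivity), !is.null(dispersion))
  if (sum(given) != 1L)
    stop("give exactly one of index, permittivity, dispersion")
  if (!is.null(thickness_nm)) {
    stopifnot(is.numeric(thickness_nm), length(thickness_nm) == 1L)
    if (thickness_nm < 0) stop("thickness must be >= 0")
  }
  if (!is.null(index)) permittivity <- as.complex(index)^2
  if (!is.null(permittivity)) {
    permittivity <- as.complex(permittivity)
    if (Im(permittivity) < 0)
      stop("Im(permittivity) must be >= 0 (absorbing convention)")
  }
  if (!is.null(dispersion) && !inherits(dispersion, "dispersion_table"))
    stop("dispersion must be a dispersion_table")
  structure(list(name = name, thickness_nm = thickness_nm,
                 permittivity = permittivity, dispersion = dispersion),
            class = "optical_layer")
}

#' Assemble an optical stack
#'
#' Layers are ordered along the propagation direction: light enters through
#' `layers[[1]]` (the incidence medium, e.g. the index-matched glass
#' coverslip). The first and last layers are semi-infinite; interior layers
#' need a thickness. The incidence medium must be transparent (real positive
#' permittivity).
#'
#' @param layers list of [optical_layer()] objects, at least two.
#' @param wavelength_nm working wavelength in nm; dispersion-table layers are
#'   resolved at this wavelength.
#' @return An object of class `optical_stack` with per-layer complex
#'   permittivities resolved at `wavelength_nm`.
#' @export
optical_stack <- function(layers, wavelength_nm) {
  stopifnot(is.list(layers), length(layers) >= 2L,
            is.numeric(wavelength_nm), length(wavelength_nm) == 1L,
            wavelength_nm > 0)
  if (!all(vapply(layers, inherits, TRUE, "optical_layer")))
    stop("layers must be optical_layer objects")
  n <- length(layers)
  interior <- if (n > 2) 2:(n - 1) else integer(0)
  for (j in interior)
    if (is.null(layers[[j]]$thickness_nm))
      stop(sprintf("interior layer %d ('%s') needs a thickness",
                   j, layers[[j]]$name))
  eps <- vapply(layers, function(ly) {
    if (!is.null(ly$permittivity)) ly$permittivity
    else dielectric_lookup(ly$dispersion, wavelength_nm)
  }, complex(1))
  if (abs(Im(eps[1])) > 0 || Re(eps[1]) <= 0)
    stop("incidence medium must be transparent (real positive permittivity)")
  d <- vapply(layers, function(ly)
    if (is.null(ly$thickness_nm)) NA_real_ else ly$thickness_nm, 0)
  structure(list(layers = layers, wavelength_nm = wavelength_nm,
                 eps = eps, thickness_nm = d),
            class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat(sprintf("<optical_stack> %d layers at %g nm\n",
              length(x$layers), x$wavelength_nm))
  for (j in seq_along(x$layers)) {
    d <- x$thickness_nm[j]
    cat(sprintf("  [%d] %-10s %s  eps = %.4g%+.4gi\n", j, x$layers[[j]]$name,
                if (is.na(d)) "semi-inf" else sprintf("%6.1f nm", d),
                Re(x$eps[j]), Im(x$eps[j])))
  }
  invisible(x)
}

#' Standard SPR sensor stack: glass / gold / aqueous medium
#'
#' Convenience constructor for the three-layer Kretschmann-style geometry of
#' an objective-coupled SPR imager: a high-index coverslip (n = 1.78), a thin
#' gold film, and a semi-infinite aqueous medium. The ~1 nm chromium adhesion
#' layer under the gold is ignored, consistent with a three-layer treatment.
#'
#' @param wavelength_nm excitation wavelength in nm.
#' @param gold_thickness_nm gold film thickness, default 45 nm.
#' @param n_glass coverslip/immersion index, default 1.78.
#' @param medium_index index of the aqueous medium, default `water_index()`.
#' @param gold metal [dispersion_table()], default [gold_dispersion()].
#' @return An [optical_stack()].
#' @export
#' @examples
#' spr_stack(620)
spr_stack <- function(wavelength_nm, gold_thickness_nm = 45,
                      n_glass = 1.78, medium_index = water_index(),
                      gold = gold_dispersion()) {
  optical_stack(list(
    optical_layer("glass", index = n_glass),
    optical_layer("gold", thickness_nm = gold_thickness_nm, dispersion = gold),
    optical_layer("medium", index = medium_index)
  ), wavelength_nm)
}

# Replace the thickness of one interior layer (used by the Fresnel fit).
set_layer_thickness <- function(stack, layer, thickness_nm) {
  stack$layers[[layer]]$thickness_nm <- thickness_nm
  stack$thickness_nm[layer] <- thickness_nm
  stack
}
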