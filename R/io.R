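# File formats: grayscale TIFF images with optional sidecar scale, CSV
# tables and angle scans, YAML stack/run configuration, run manifests.
#
# Conventions: image origin top-left, row-major, x = column index; lengths
# in micrometers in configs, depths in nm; angles in degrees; 0-based pixel
# indexing; circular ROIs as (cx, cy, radius) in micrometers.

sidecar_path <- function(path) paste0(path, ".scale.txt")

#' Read a grayscale TIFF image
#'
#' Images written by [write_image()] carry a plain-text sidecar file
#' (`<path>.scale.txt`) holding the affine transform back to physical
#' units, `value = stored * scale + offset`; when it is present the
#' restored values are returned (losslessly for the 32-bit float path, to
#' 1/65535 of the dynamic range for 16-bit). A TIFF without a sidecar is
#' returned as the `[0, 1]` sample fractions the file stores, flagged with
#' attribute `unscaled_counts = TRUE`.
#'
#' @param path TIFF file path.
#' @return numeric matrix with attribute `unscaled_counts` where relevant.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  img <- tryCatch(tiff::readTIFF(path, all = FALSE),
                  error = function(e)
                    stop("failed to read TIFF '", path, "': ",
                         conditionMessage(e)))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1]
    else stop("non-grayscale TIFF (", dim(img)[3], " channels): ", path)
  }
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    tr <- as.numeric(strsplit(readLines(sc, n = 1L), "[ \t]+")[[1]])
    scale <- tr[1]
    offset <- if (length(tr) > 1L) tr[2] else 0
    img <- img * scale + offset
  } else {
    attr(img, "unscaled_counts") <- TRUE
  }
  img
}

#' Write a grayscale TIFF image
#'
#' Samples are stored normalized to `[0, 1]` (the range the TIFF writer
#' accepts) with the affine transform back to physical units recorded in a
#' plain-text sidecar file (`<path>.scale.txt`, "scale offset"), so that
#' [read_image()] restores values exactly (`bits = 32`, float samples) or
#' to 16-bit quantization (`bits = 16`).
#'
#' @param image numeric matrix (an [spr_image()]'s `$pixels` or any
#'   matrix).
#' @param path output path.
#' @param bits 32 (default, float) or 16.
#' @return the path, invisibly.
#' @export
write_image <- function(image, path, bits = 32) {
  image <- as_pixels(image)
  stopifnot(is.matrix(image), bits %in% c(16, 32))
  lo <- min(image); hi <- max(image)
  scale <- hi - lo
  if (scale <= 0) scale <- 1
  tiff::writeTIFF((image - lo) / scale, path,
                  bits.per.sample = as.integer(bits))
  writeLines(paste(format(scale, digits = 17), format(lo, digits = 17)),
             sidecar_path(path))
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask))
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a results table as CSV
#'
#' Fixed column order, header row, full double precision; round-trips
#' through [read_results()] to at least 1e-9 relative precision.
#'
#' @param table nonempty data.frame.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
}

#' Write an angle scan as CSV
#'
#' Header columns `angle_deg`, `reflectance`.
#'
#' @param scan an [angle_scan()].
#' @param path output path.
#' @export
write_angle_scan <- function(scan, path) {
  stopifnot(inherits(scan, "angle_scan"))
  utils::write.csv(as.data.frame(scan)[c("angle_deg", "reflectance")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an angle scan CSV
#'
#' @param path CSV with columns `angle_deg`, `reflectance`.
#' @param polarization,wavelength_nm metadata to attach.
#' @return an [angle_scan()]-classed data.frame (values are not forced into
#'   `[0, 1]`, since scans may be raw counts destined for
#'   [fit_fresnel_scan()]).
#' @export
read_angle_scan <- function(path, polarization = "p", wavelength_nm = NA) {
  df <- utils::read.csv(path)
  stopifnot(all(c("angle_deg", "reflectance") %in% names(df)))
  structure(df[c("angle_deg", "reflectance")],
            polarization = polarization, wavelength_nm = wavelength_nm,
            class = c("angle_scan", "data.frame"))
}

#' Read an optical stack from a YAML config
#'
#' Expected layout:
#' \preformatted{
#' wavelength_nm: 620
#' layers:
#'   - {name: glass, index: 1.78}
#'   - {name: gold, thickness_nm: 45, dispersion: gold}
#'   - {name: water, index: 1.333}
#' }
#' A layer may give `index`, `permittivity` (two-element `[re, im]`),
#' `dispersion: gold` (the built-in table) or `dispersion_csv: <path>`
#' (columns `wavelength_nm`, `n`, `k`; relative paths resolve against the
#' config file).
#'
#' @param path YAML file.
#' @return an [optical_stack()].
#' @export
read_stack_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$wavelength_nm) || is.null(cfg$layers))
    stop("stack config needs 'wavelength_nm' and 'layers'")
  layers <- lapply(cfg$layers, function(ly) {
    args <- list(name = ly$name %||% "layer",
                 thickness_nm = ly$thickness_nm)
    if (!is.null(ly$index)) args$index <- ly$index
    else if (!is.null(ly$permittivity))
      args$permittivity <- complex(real = ly$permittivity[[1]],
                                   imaginary = ly$permittivity[[2]])
    else if (identical(ly$dispersion, "gold"))
      args$dispersion <- gold_dispersion()
    else if (!is.null(ly$dispersion_csv)) {
      p <- ly$dispersion_csv
      if (!file.exists(p)) p <- file.path(dirname(path), ly$dispersion_csv)
      tb <- utils::read.csv(p)
      args$dispersion <- dispersion_table(tb$wavelength_nm, tb$n, tb$k,
                                          material = ly$name %||% "")
    } else stop("layer '", ly$name,
                "' gives none of index/permittivity/dispersion")
    do.call(optical_layer, args)
  })
  optical_stack(layers, cfg$wavelength_nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration
#'
#' YAML with analysis parameters (`k`, `dilation_um`,
#' `operating_reflectance`), an imaging block passed to
#' [imaging_config()], optional `stack` block (as in
#' [read_stack_config()]) and a `seed`. All referenced files must exist at
#' load time.
#'
#' @param path YAML file.
#' @return list with `imaging` ([imaging_config()]), `stack` (or NULL),
#'   `k`, `dilation_um`, `seed`, and any further top-level entries.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in cfg$files %||% list())
    if (!file.exists(f)) stop("referenced file missing: ", f)
  imaging <- do.call(imaging_config, cfg$imaging %||% list())
  stack <- NULL
  if (!is.null(cfg$stack)) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg$stack, tmp)
    stack <- read_stack_config(tmp)
    unlink(tmp)
  }
  list(imaging = imaging, stack = stack,
       k = cfg$k %||% 3, dilation_um = cfg$dilation_um %||% 10,
       operating_reflectance = cfg$operating_reflectance %||% 0.1,
       seed = cfg$seed %||% 1L, raw = cfg)
}

#' Write a run manifest
#'
#' Records the package version, the seed, and an echo of the configuration
#' so that a run can be reproduced bit-identically (deterministic paths)
#' or statistically (stochastic ones).
#'
#' @param path output YAML path.
#' @param config list echoed into the manifest.
#' @param seed integer seed used for the run.
#' @export
write_manifest <- function(path, config, seed) {
  yaml::write_yaml(list(
    package = "sprcal",
    version = as.character(utils::packageVersion("sprcal")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config), path)
  invisible(path)
}
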