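#' Working wavelength grid
#'
#' The default integration grid for all spectral calculations: 400--700 nm in
#' 1 nm steps. This covers the visible pass band of the photography filter
#' (420--680 nm), every receptor peak of the shipped fish visual systems and
#' the 410 nm ocular-media cutoff, with padding for safe integration.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
default_grid <- function() 400:700

#' Construct a spectrum
#'
#' A spectrum is a non-negative function of wavelength sampled on a strictly
#' increasing nm grid. The same container is used for reflectance (fraction,
#' 0--1), relative irradiance, relative sensitivity and transmission
#' (fraction, 0--1); the unit depends on the role, everything downstream is
#' relative.
#'
#' @param wl Strictly increasing numeric vector of wavelengths (nm).
#' @param value Numeric vector of the same length, finite and >= 0.
#' @param name Optional label carried through I/O.
#' @return An object of class `spectrum`: a list with elements `wl`, `value`,
#'   `name`.
#' @export
spectrum <- function(wl, value, name = NULL) {
  wl <- as.numeric(wl)
  value <- as.numeric(value)
  if (length(wl) < 2L) stop("a spectrum needs at least two wavelengths")
  if (length(wl) != length(value)) {
    stop("wavelengths and values differ in length (", length(wl), " vs ",
         length(value), ")")
  }
  if (any(!is.finite(wl)) || any(diff(wl) <= 0)) {
    stop("wavelengths must be finite and strictly increasing")
  }
  if (any(!is.finite(value))) stop("spectrum values must be finite")
  if (any(value < -1e-12)) {
    stop("spectrum values must be non-negative (min = ",
         format(min(value)), ")")
  }
  structure(list(wl = wl, value = pmax(value, 0), name = name),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum%s: %d points, %g-%g nm, values %.4g-%.4g>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$wl), min(x$wl), max(x$wl),
              min(x$value), max(x$value)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the target grid must lie within the source support
#' (endpoints are clamped, i.e. a target point exactly at the boundary is
#' allowed).
#'
#' @param spec A [spectrum()].
#' @param grid Strictly increasing numeric target grid (nm).
#' @return A `spectrum` on `grid`.
#' @export
resample <- function(spec, grid = default_grid()) {
  stopifnot(is_spectrum(spec))
  grid <- as.numeric(grid)
  lo <- min(spec$wl); hi <- max(spec$wl)
  if (min(grid) < lo - 1e-9 || max(grid) > hi + 1e-9) {
    stop(sprintf(
      "target grid [%g, %g] nm overhangs source support [%g, %g] nm",
      min(grid), max(grid), lo, hi))
  }
  v <- stats::approx(spec$wl, spec$value, xout = pmin(pmax(grid, lo), hi),
                     method = "linear", rule = 2)$y
  spectrum(grid, v, name = spec$name)
}

#' Trapezoid-rule integral of a spectrum (optionally weighted)
#'
#' @param spec A [spectrum()].
#' @param weight Optional numeric vector (same grid) multiplied in.
#' @return Scalar integral value.
#' @keywords internal
spec_integral <- function(spec, weight = NULL) {
  v <- spec$value
  if (!is.null(weight)) v <- v * weight
  pracma::trapz(spec$wl, v)
}

#' Read named spectra from a wide CSV
#'
#' Expects a header row with a `wavelength_nm` column plus one column per
#' spectrum. Wavelengths must be strictly increasing and values non-negative.
#'
#' @param path CSV file path.
#' @return Named list of [spectrum()] objects.
#' @export
read_spectra_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) data.frame())
  if (!"wavelength_nm" %in% names(df)) {
    stop("no wavelength column: expected a 'wavelength_nm' column in ", path)
  }
  wl <- df[["wavelength_nm"]]
  if (any(diff(wl) <= 0)) {
    bad <- which(diff(wl) <= 0)[1L] + 1L
    stop("non-monotone wavelengths at row ", bad, " of ", path)
  }
  cols <- setdiff(names(df), "wavelength_nm")
  if (length(cols) == 0L) stop("no spectrum columns in ", path)
  out <- lapply(cols, function(nm) {
    v <- df[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      bad <- which(!is.finite(v) | v < 0)[1L]
      stop("negative or non-finite value for spectrum '", nm,
           "' at row ", bad, " of ", path)
    }
    spectrum(wl, v, name = nm)
  })
  names(out) <- cols
  out
}

#' Write named spectra to a wide CSV
#'
#' Inverse of [read_spectra_csv()]; all spectra must share one grid.
#'
#' @param spectra Named list of [spectrum()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1L, !is.null(names(spectra)))
  wl <- spectra[[1L]]$wl
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wl, wl))) {
      stop("all spectra must share the same wavelength grid; resample first")
    }
  }
  df <- data.frame(wavelength_nm = wl)
  for (nm in names(spectra)) df[[nm]] <- spectra[[nm]]$value
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' CIE D65 daylight illuminant
#'
#' The standard relative spectral power distribution of CIE illuminant D65
#' (the daylight reference used as incident illumination for all visual
#' modelling), shipped as the standard 10 nm table and interpolated onto the
#' requested grid. Only the relative shape matters: the absolute scale
#' cancels in the von Kries catch normalisation.
#'
#' @param grid Wavelength grid (nm), default [default_grid()].
#' @return A `spectrum` named `"D65"`.
#' @export
d65 <- function(grid = default_grid()) {
  path <- system.file("extdata", "d65.csv", package = "prawnvision",
                      mustWork = TRUE)
  resample(read_spectra_csv(path)$D65, grid)
}
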