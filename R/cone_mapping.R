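#' Camera model
#'
#' Per-band spectral sensitivities of the (visible-spectrum) camera. The
#' default bands are smooth Gaussian sensitivities peaking at 460/530/600 nm
#' (sd 35 nm), a plausible stand-in for a converted DSLR's blue/green/red
#' responses; real measured curves can be supplied via [read_spectra_csv()].
#'
#' @param bands Named list of sensitivity [spectrum()]s.
#' @return A `camera_model`.
#' @export
camera_model <- function(bands) {
  stopifnot(is.list(bands), length(bands) >= 1L, !is.null(names(bands)))
  for (nm in names(bands)) {
    if (!is_spectrum(bands[[nm]])) stop("band '", nm, "' is not a spectrum")
  }
  structure(list(bands = bands, band_names = names(bands)),
            class = "camera_model")
}

#' @rdname camera_model
#' @param grid Working wavelength grid.
#' @export
camera_default <- function(grid = default_grid()) {
  g <- function(peak) spectrum(grid, exp(-(grid - peak)^2 / (2 * 35^2)))
  camera_model(list(visB = g(460), visG = g(530), visR = g(600)))
}

#' Camera band catches of a reflectance spectrum
#'
#' Same von Kries-normalised integral as [cone_catch()] but through the
#' camera bands (no ocular media): a flat grey c yields c in every band.
#'
#' @param reflectance Reflectance `spectrum`.
#' @param camera A [camera_model()].
#' @param illuminant Illuminant `spectrum`.
#' @return Named numeric vector of band catches.
#' @export
camera_catch <- function(reflectance, camera, illuminant = d65()) {
  stopifnot(inherits(camera, "camera_model"))
  grid <- camera$bands[[1L]]$wl
  refl <- resample(reflectance, grid)
  illum <- resample(illuminant, grid)
  vapply(camera$bands, function(s) {
    pracma::trapz(grid, refl$value * illum$value * s$value) /
      pracma::trapz(grid, illum$value * s$value)
  }, numeric(1))
}

# polynomial term exponent matrix for k variables, total degree <= degree,
# including the intercept and all cross terms
.poly_terms <- function(k, degree) {
  ex <- as.matrix(expand.grid(rep(list(0:degree), k)))
  ex <- ex[rowSums(ex) <= degree, , drop = FALSE]
  ex[order(rowSums(ex)), , drop = FALSE]
}

.poly_design <- function(x, terms) {
  D <- vapply(seq_len(nrow(terms)), function(i) {
    apply(sweep(x, 2L, terms[i, ], `^`), 1L, prod)
  }, numeric(nrow(x)))
  matrix(D, nrow = nrow(x))
}

#' Fit a polynomial camera-to-cone-catch mapping
#'
#' Least-squares regression of each receptor channel's true catch (direct
#' spectral integration through the visual system) on polynomial terms
#' (default total degree 2, with cross terms) of the camera band catches,
#' over a training library of reflectance spectra. This is the standard
#' image-calibration shortcut that lets calibrated camera images stand in
#' for spectrometry when predicting predator cone stimulation.
#'
#' @param camera A [camera_model()].
#' @param system A [visual_system()].
#' @param training_reflectances List of >= 50 reflectance spectra spanning
#'   the gamut of interest (see [sample_spectra_library()]).
#' @param illuminant Illuminant `spectrum`, default D65.
#' @param degree Polynomial total degree (1 or 2; default 2).
#' @return A `poly_mapping`: coefficients per channel over documented terms,
#'   training R^2 per channel, band and channel names.
#' @export
fit_mapping <- function(camera, system, training_reflectances,
                        illuminant = d65(), degree = 2L) {
  stopifnot(inherits(camera, "camera_model"),
            inherits(system, "visual_system"))
  if (length(training_reflectances) < 50L) {
    stop("need >= 50 training spectra, got ", length(training_reflectances))
  }
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  cam <- t(vapply(training_reflectances, camera_catch,
                  numeric(length(camera$band_names)),
                  camera = camera, illuminant = illuminant))
  cone <- t(vapply(training_reflectances, function(r) {
    cone_catch(r, illuminant, system)$catches
  }, numeric(n_channels(system))))
  terms <- .poly_terms(ncol(cam), degree)
  X <- .poly_design(cam, terms)
  fit <- stats::lm.fit(X, cone)
  if (fit$rank < ncol(X)) {
    stop("rank-deficient polynomial design (rank ", fit$rank, " < ",
         ncol(X), "); try a lower degree or a richer training library")
  }
  pred <- X %*% fit$coefficients
  r2 <- vapply(seq_len(ncol(cone)), function(j) {
    1 - sum((cone[, j] - pred[, j])^2) / sum((cone[, j] - mean(cone[, j]))^2)
  }, numeric(1))
  structure(list(coefficients = fit$coefficients, terms = terms,
                 degree = as.integer(degree),
                 band_names = camera$band_names,
                 channel_names = system$channel_names,
                 system = system$name,
                 r_squared = stats::setNames(r2, system$channel_names),
                 catch_floor = 1e-4),
            class = "poly_mapping")
}

#' @export
print.poly_mapping <- function(x, ...) {
  cat(sprintf("<poly_mapping %s -> %s: degree %d, %d terms, R2 %s>\n",
              paste(x$band_names, collapse = "/"), x$system, x$degree,
              nrow(x$terms),
              paste(sprintf("%.4f", x$r_squared), collapse = "/")))
  invisible(x)
}

#' Predict cone catches from camera band catches
#'
#' Predictions below the positive floor (default 1e-4) are clamped, with a
#' warning, so downstream log-ratio statistics stay defined.
#'
#' @param mapping A [fit_mapping()] result.
#' @param camera_catches Named numeric vector, or matrix/data.frame with one
#'   row per subject and one column per camera band.
#' @param ... Metadata forwarded to [cone_catch_record()] (vector input only).
#' @return A [cone_catch_record()] for vector input; a matrix of catches for
#'   matrix input.
#' @export
apply_mapping <- function(mapping, camera_catches, ...) {
  stopifnot(inherits(mapping, "poly_mapping"))
  single <- is.null(dim(camera_catches))
  x <- if (single) matrix(camera_catches, nrow = 1L,
                          dimnames = list(NULL, names(camera_catches)))
       else as.matrix(camera_catches)
  missing <- setdiff(mapping$band_names, colnames(x))
  if (length(missing)) {
    stop("missing camera band(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, mapping$band_names, drop = FALSE]
  pred <- .poly_design(x, mapping$terms) %*% mapping$coefficients
  colnames(pred) <- mapping$channel_names
  n_clamped <- sum(pred < mapping$catch_floor)
  if (n_clamped > 0L) {
    warning(n_clamped, " predicted catch(es) at or below zero; clamped to ",
            mapping$catch_floor)
    pred <- pmax(pred, mapping$catch_floor)
  }
  if (single) {
    cone_catch_record(catches = pred[1L, ], ...)
  } else {
    pred
  }
}

#' Serialise / load a polynomial mapping as JSON
#'
#' @param mapping A `poly_mapping`.
#' @param path JSON file path.
#' @return `path` (write) or a `poly_mapping` (read).
#' @export
write_mapping_json <- function(mapping, path) {
  obj <- list(coefficients = unclass(mapping$coefficients),
              terms = unclass(mapping$terms), degree = mapping$degree,
              band_names = mapping$band_names,
              channel_names = mapping$channel_names, system = mapping$system,
              r_squared = as.list(mapping$r_squared),
              catch_floor = mapping$catch_floor)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_mapping_json
#' @export
read_mapping_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = as.matrix(obj$coefficients),
                 terms = as.matrix(obj$terms), degree = obj$degree,
                 band_names = obj$band_names,
                 channel_names = obj$channel_names, system = obj$system,
                 r_squared = stats::setNames(unlist(obj$r_squared),
                                             obj$channel_names),
                 catch_floor = obj$catch_floor),
            class = "poly_mapping")
}
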