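#' Multispectral image
#'
#' Aligned per-channel pixel planes plus bookkeeping. `role` tracks the
#' processing stage: `"raw"` (integer camera counts in `[0, 2^bit_depth)`),
#' `"linearised"` (reflectance-scaled linear values) or `"equalised"`
#' (standard-anchored reflectance, nominally `[0, ~1.2]`; slight over-unity
#' is allowed for specular pixels). Saturated raw pixels (>= 99% of bit
#' depth in any channel) are flagged at construction and excluded from ROI
#' means downstream.
#'
#' @param planes Named list of numeric matrices, equal shape, non-negative.
#' @param bit_depth Integer bit depth of the raw encoding.
#' @param role One of `"raw"`, `"linearised"`, `"equalised"`.
#' @param pixel_scale_mm Optional mm-per-pixel scale.
#' @param saturated Optional logical matrix of pixels to exclude; computed
#'   from the planes when `role = "raw"`.
#' @return A `multispectral_image`.
#' @export
multispectral_image <- function(planes, bit_depth = 16L,
                                role = c("raw", "linearised", "equalised"),
                                pixel_scale_mm = NA_real_, saturated = NULL) {
  role <- match.arg(role)
  stopifnot(is.list(planes), length(planes) >= 1L, !is.null(names(planes)))
  dims <- lapply(planes, dim)
  if (length(unique(dims)) != 1L) stop("channel planes differ in shape")
  for (nm in names(planes)) {
    if (any(!is.finite(planes[[nm]])) || any(planes[[nm]] < 0)) {
      stop("plane '", nm, "' has negative or non-finite pixels")
    }
  }
  if (role == "raw" && any(vapply(planes, max, numeric(1)) >= 2^bit_depth)) {
    stop("raw pixel values exceed the stated bit depth")
  }
  if (is.null(saturated)) {
    saturated <- if (role == "raw") {
      Reduce(`|`, lapply(planes, function(p) p >= 0.99 * (2^bit_depth - 1)))
    } else {
      matrix(FALSE, nrow(planes[[1L]]), ncol(planes[[1L]]))
    }
  }
  structure(list(planes = planes, bit_depth = as.integer(bit_depth),
                 role = role, pixel_scale_mm = pixel_scale_mm,
                 saturated = saturated),
            class = "multispectral_image")
}

#' @export
print.multispectral_image <- function(x, ...) {
  d <- dim(x$planes[[1L]])
  cat(sprintf("<multispectral_image [%s]: %dx%d px, %d-bit, %s, %d saturated>\n",
              paste(names(x$planes), collapse = ","), d[1L], d[2L],
              x$bit_depth, x$role, sum(x$saturated)))
  invisible(x)
}

#' Reflectance standard patch
#'
#' A grey (Spectralon-style) reference patch of known nominal reflectance
#' with its ROI mask in the image.
#'
#' @param nominal_reflectance Fraction in (0, 1).
#' @param roi_mask Logical matrix, non-empty.
#' @return A `standard_patch`.
#' @export
standard_patch <- function(nominal_reflectance, roi_mask) {
  if (!is.finite(nominal_reflectance) || nominal_reflectance <= 0 ||
      nominal_reflectance >= 1) {
    stop("nominal reflectance must be in (0, 1)")
  }
  if (!any(roi_mask)) stop("standard patch mask is empty")
  structure(list(nominal_reflectance = nominal_reflectance,
                 roi_mask = roi_mask),
            class = "standard_patch")
}

# Candidate fits for the pixel -> reflectance response, each returning a
# prediction function of pixel value or NULL when inadmissible.
.lin_candidates <- function(pixel, refl) {
  lp <- log(pixel); lr <- log(refl)
  cands <- list()
  b <- stats::lm.fit(cbind(1, lp), lr)$coefficients
  if (is.finite(b[2L]) && b[2L] > 0) {
    cands$power <- local({
      a0 <- b[1L]; b0 <- b[2L]
      function(p) exp(a0 + b0 * log(pmax(p, .Machine$double.eps)))
    })
  }
  if (length(pixel) >= 5L) {
    cf <- stats::lm.fit(cbind(1, lp, lp^2), lr)$coefficients
    if (all(is.finite(cf))) {
      f <- local({
        cf0 <- cf
        function(p) {
          l <- log(pmax(p, .Machine$double.eps))
          exp(cf0[1L] + cf0[2L] * l + cf0[3L] * l^2)
        }
      })
      # admit only if monotone over the sample hull
      grid <- seq(min(pixel), max(pixel), length.out = 200L)
      if (all(diff(f(grid)) > 0)) cands$logquad <- f
    }
  }
  cands$spline <- stats::splinefun(pixel, refl, method = "hyman")
  cands
}

#' Fit a camera linearisation curve from grey standards
#'
#' Fits a monotone pixel-value to reflectance response from measured grey
#' standards (mean ROI pixel value, nominal reflectance). Three candidate
#' forms are compared by leave-one-out cross-validation in reflectance
#' units -- a power law, a quadratic in log-log space (admitted only when
#' monotone on the sample hull) and a monotone (Hyman) interpolating
#' spline -- and the lowest-CV-error form wins.
#'
#' @param samples Data frame with columns `pixel` (mean pixel value) and
#'   `reflectance` (nominal fraction), one row per standard; at least 4
#'   standards spanning the range.
#' @return A `linearisation_curve`: list with `fun` (vectorised pixel ->
#'   reflectance), `method`, `cv_rmse` per candidate, `domain`, `residuals`.
#' @export
fit_linearisation <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("pixel", "reflectance") %in% names(samples)))
  samples <- samples[order(samples$pixel), , drop = FALSE]
  if (nrow(samples) < 4L) {
    stop("insufficient standards: need >= 4, got ", nrow(samples))
  }
  px <- samples$pixel; rf <- samples$reflectance
  if (any(px <= 0) || any(rf <= 0)) stop("pixel and reflectance must be > 0")
  d <- diff(rf)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf(
      "non-monotone standards: reflectance %.4g at pixel %.4g vs %.4g at pixel %.4g",
      rf[i], px[i], rf[i + 1L], px[i + 1L]))
  }
  loo <- function(fitfun) {
    err <- vapply(seq_along(px), function(i) {
      cands <- fitfun(px[-i], rf[-i])
      if (length(cands) == 0L || is.null(cands[[1L]])) return(NA_real_)
      cands[[1L]](px[i]) - rf[i]
    }, numeric(1))
    sqrt(mean(err^2))
  }
  methods <- c("power", "logquad", "spline")
  cv <- vapply(methods, function(m) {
    loo(function(p, r) .lin_candidates(p, r)[m])
  }, numeric(1))
  full <- .lin_candidates(px, rf)
  cv <- cv[names(cv) %in% names(full)]
  best <- names(cv)[which.min(cv)]
  f0 <- full[[best]]
  dom <- range(px)
  fun <- function(p) pmax(f0(pmin(pmax(p, dom[1L]), dom[2L])), 0)
  structure(list(fun = fun, method = best, cv_rmse = cv, domain = dom,
                 residuals = fun(px) - rf, samples = samples),
            class = "linearisation_curve")
}

#' @export
print.linearisation_curve <- function(x, ...) {
  cat(sprintf("<linearisation_curve (%s): %d standards, max |resid| %.2e>\n",
              x$method, nrow(x$samples), max(abs(x$residuals))))
  invisible(x)
}

#' Apply linearisation curves to a raw image
#'
#' @param image Raw [multispectral_image()].
#' @param curves Named list of [fit_linearisation()] curves, one per channel
#'   (a single curve is recycled to all channels).
#' @return A `linearised` multispectral image on the reflectance scale.
#' @export
linearise_image <- function(image, curves) {
  stopifnot(inherits(image, "multispectral_image"))
  if (image$role != "raw") stop("linearise_image expects a raw image")
  if (inherits(curves, "linearisation_curve")) {
    curves <- stats::setNames(rep(list(curves), length(image$planes)),
                              names(image$planes))
  }
  missing <- setdiff(names(image$planes), names(curves))
  if (length(missing)) {
    stop("no linearisation curve for channel(s): ",
         paste(missing, collapse = ", "))
  }
  planes <- lapply(names(image$planes), function(nm) {
    m <- curves[[nm]]$fun(image$planes[[nm]])
    matrix(m, nrow(image$planes[[nm]]), ncol(image$planes[[nm]]))
  })
  names(planes) <- names(image$planes)
  multispectral_image(planes, image$bit_depth, "linearised",
                      image$pixel_scale_mm, saturated = image$saturated)
}

#' Equalise a linearised image against two in-frame standards
#'
#' Per channel, the affine map sending the dark standard's ROI mean to its
#' nominal reflectance and the light standard's ROI mean to its nominal.
#' This removes photograph-to-photograph lighting differences: any linear
#' relit version of an image (pixel' = a * pixel + b, a > 0) equalises to
#' the same output. Equalising an already-equalised image against its own
#' standards is the identity.
#'
#' @param image Linearised (or equalised) [multispectral_image()].
#' @param dark,light [standard_patch()]es with `dark` nominal < `light`
#'   nominal and masks inside the image.
#' @return An `equalised` multispectral image (negative pixels clipped to 0).
#' @export
equalise <- function(image, dark, light) {
  stopifnot(inherits(image, "multispectral_image"),
            inherits(dark, "standard_patch"),
            inherits(light, "standard_patch"))
  if (image$role == "raw") stop("equalise expects a linearised image")
  if (dark$nominal_reflectance >= light$nominal_reflectance) {
    stop("dark standard nominal must be below light standard nominal")
  }
  dm <- dim(image$planes[[1L]])
  for (p in list(dark, light)) {
    if (!identical(dim(p$roi_mask), dm)) {
      stop("standard patch mask shape does not match the image")
    }
  }
  planes <- lapply(image$planes, function(pl) {
    md <- mean(pl[dark$roi_mask]); ml <- mean(pl[light$roi_mask])
    if (abs(ml - md) < 1e-12) stop("degenerate standards: identical means")
    gain <- (light$nominal_reflectance - dark$nominal_reflectance) / (ml - md)
    pmax(gain * (pl - md) + dark$nominal_reflectance, 0)
  })
  multispectral_image(planes, image$bit_depth, "equalised",
                      image$pixel_scale_mm, saturated = image$saturated)
}

#' Mean reflectance over a region of interest
#'
#' Arithmetic per-channel mean over the mask; pixels flagged as saturated in
#' the raw exposure are excluded, with the excluded count reported for QC.
#'
#' @param image An equalised (or linearised) [multispectral_image()].
#' @param mask Logical matrix, non-empty, same shape as the image.
#' @return List with `means` (named per channel), `n_pixels` (used),
#'   `n_saturated_excluded`.
#' @export
extract_roi <- function(image, mask) {
  stopifnot(inherits(image, "multispectral_image"))
  if (!identical(dim(mask), dim(image$planes[[1L]]))) {
    stop("ROI mask shape does not match the image")
  }
  if (!any(mask)) stop("empty ROI mask")
  use <- mask & !image$saturated
  n_sat <- sum(mask) - sum(use)
  if (!any(use)) stop("ROI is entirely saturated")
  means <- vapply(image$planes, function(p) mean(p[use]), numeric(1))
  list(means = means, n_pixels = sum(use), n_saturated_excluded = n_sat)
}

#' Write / read a multispectral image as per-channel TIFFs + JSON sidecar
#'
#' One 32-bit float TIFF per channel plus a JSON sidecar recording channel
#' names, bit depth, role and scale. Raw integer images are stored
#' normalised by `2^bit_depth - 1` (TIFF float convention) and restored on
#' read.
#'
#' @param image A [multispectral_image()].
#' @param prefix Path prefix; files are written as
#'   `<prefix>_<channel>.tif` and `<prefix>.json`.
#' @return `prefix` (write) or a `multispectral_image` (read).
#' @export
write_multispectral <- function(image, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF output")
  }
  scale <- if (image$role == "raw") 2^image$bit_depth - 1 else 1
  for (nm in names(image$planes)) {
    tiff::writeTIFF(image$planes[[nm]] / scale,
                    paste0(prefix, "_", nm, ".tif"),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  meta <- list(channels = names(image$planes), bit_depth = image$bit_depth,
               role = image$role, pixel_scale_mm = image$pixel_scale_mm,
               scale = scale)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_multispectral
#' @export
read_multispectral <- function(prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF input")
  }
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  planes <- lapply(meta$channels, function(nm) {
    m <- tiff::readTIFF(paste0(prefix, "_", nm, ".tif"))
    m * meta$scale
  })
  names(planes) <- meta$channels
  multispectral_image(planes, meta$bit_depth, meta$role,
                      if (is.null(meta$pixel_scale_mm)) NA_real_
                      else meta$pixel_scale_mm)
}
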