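#' Receptor channel
#'
#' One cone class of a visual system: a label, the wavelength of peak
#' sensitivity and the relative abundance eta used for receptor noise.
#'
#' @param name Channel label (conventionally SWS/MWS/LWS, shortest first).
#' @param lambda_max_nm Peak sensitivity wavelength (nm).
#' @param relative_abundance Positive abundance; after construction of a
#'   [visual_system()] the most abundant channel is scaled to exactly 1.
#' @return A `receptor_channel` list.
#' @export
receptor_channel <- function(name, lambda_max_nm, relative_abundance) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(lambda_max_nm), is.finite(relative_abundance))
  if (relative_abundance <= 0) stop("relative abundance must be > 0")
  structure(list(name = name, lambda_max_nm = lambda_max_nm,
                 relative_abundance = relative_abundance),
            class = "receptor_channel")
}

#' Visual system
#'
#' An ordered set of receptor channels (shortest to longest peak), the
#' ocular-media 50% transmission cutoff, and the reference noise-to-signal
#' ratio `nu` of the most abundant cone class. Channel abundances are
#' normalised so that the most abundant channel has eta = 1; Weber fractions
#' follow as omega_i = nu / sqrt(eta_i).
#'
#' @param name System label.
#' @param channels List of [receptor_channel()]s, peaks strictly increasing.
#' @param ocular_cutoff_nm Wavelength of 50% ocular-media transmission (nm).
#' @param nu Noise-to-signal ratio of the most abundant channel (default 0.05).
#' @param grid Working wavelength grid.
#' @return A `visual_system` object with precomputed channel sensitivities
#'   (pigment template x ocular media).
#' @export
visual_system <- function(name, channels, ocular_cutoff_nm, nu = 0.05,
                          grid = default_grid()) {
  stopifnot(length(channels) >= 2L, nu > 0)
  lmax <- vapply(channels, function(ch) ch$lambda_max_nm, numeric(1))
  if (any(diff(lmax) <= 0)) {
    stop("channel peak wavelengths must be strictly increasing")
  }
  eta <- vapply(channels, function(ch) ch$relative_abundance, numeric(1))
  eta <- eta / max(eta)
  labels <- vapply(channels, function(ch) ch$name, character(1))
  trans <- ocular_transmission(ocular_cutoff_nm, grid)
  sens <- lapply(lmax, function(lm) {
    s <- pigment_sensitivity(lm, grid)
    spectrum(grid, s$value * trans$value)
  })
  names(sens) <- labels
  structure(list(name = name,
                 channel_names = labels,
                 lambda_max_nm = lmax,
                 eta = stats::setNames(eta, labels),
                 ocular_cutoff_nm = ocular_cutoff_nm,
                 nu = nu,
                 grid = grid,
                 transmission = trans,
                 sensitivity = sens),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system '%s': %d channels (%s at %s nm), cutoff %g nm, nu %g>\n",
              x$name, length(x$channel_names),
              paste(x$channel_names, collapse = "/"),
              paste(x$lambda_max_nm, collapse = "/"),
              x$ocular_cutoff_nm, x$nu))
  invisible(x)
}

n_channels <- function(system) length(system$channel_names)

#' A1 visual pigment sensitivity template
#'
#' Govardovskii-type A1 nomogram: alpha band plus beta band, parameterised
#' only by the peak wavelength, normalised to a maximum of 1. This is the
#' standard template used in receptor-noise visual modelling when only the
#' pigment peak is known from microspectrophotometry.
#'
#' @param lambda_max_nm Peak wavelength, 400--620 nm.
#' @param grid Wavelength grid (nm).
#' @return A `spectrum` of relative sensitivity in `[0, 1]`, peak 1.
#' @export
pigment_sensitivity <- function(lambda_max_nm, grid = default_grid()) {
  if (lambda_max_nm < 400 || lambda_max_nm > 620) {
    stop("lambda_max must lie in [400, 620] nm, got ", lambda_max_nm)
  }
  if (lambda_max_nm < min(grid) || lambda_max_nm > max(grid)) {
    stop("lambda_max ", lambda_max_nm, " nm is outside the grid [",
         min(grid), ", ", max(grid), "] nm")
  }
  x <- lambda_max_nm / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max_nm
  bb <- -40.5 + 0.195 * lambda_max_nm
  beta <- 0.26 * exp(-((grid - lmb) / bb)^2)
  v <- alpha + beta
  spectrum(grid, v / max(v), name = sprintf("pigment_%g", lambda_max_nm))
}

#' Ocular media transmission
#'
#' Logistic transmission curve with 50% transmission at `cutoff_nm`, rising
#' to ~1 at long wavelengths; the slope puts the 10--90% rise over about
#' 30 nm (the source data give only the 50% point).
#'
#' @param cutoff_nm Wavelength of 50% transmission (nm).
#' @param grid Wavelength grid (nm).
#' @return A `spectrum` of transmission fractions, monotone non-decreasing.
#' @export
ocular_transmission <- function(cutoff_nm, grid = default_grid()) {
  if (cutoff_nm < min(grid) || cutoff_nm > max(grid)) {
    stop("cutoff ", cutoff_nm, " nm is outside the grid")
  }
  s <- 30 / (2 * log(9))  # 10-90% range of a logistic is 2*ln(9)*s
  spectrum(grid, 1 / (1 + exp(-(grid - cutoff_nm) / s)),
           name = "ocular_media")
}

#' The dichromatic pollack visual system
#'
#' Single cones peaking at 436 nm (SWS) and double cones at 521 nm, with
#' cone ratio 0.70:1 (shortest to longest), 50% ocular cutoff at 410 nm and
#' nu = 0.05. Each double-cone member is treated as an independent channel.
#' The 521 nm channel is the long channel of this dichromat and is accepted
#' under either label MWS or LWS (the hue ratio uses it as its denominator).
#'
#' @param grid Working wavelength grid.
#' @return A `visual_system`.
#' @export
pollack <- function(grid = default_grid()) {
  visual_system("pollack",
                list(receptor_channel("SWS", 436, 0.70),
                     receptor_channel("LWS", 521, 1.00)),
                ocular_cutoff_nm = 410, nu = 0.05, grid = grid)
}

#' The trichromatic two-spotted goby visual system
#'
#' Single cones at 456 nm (SWS) and double cones at 531 nm (MWS) and 553 nm
#' (LWS), cone ratio 0.72:1:0.60, 50% ocular cutoff at 410 nm, nu = 0.05.
#'
#' @param grid Working wavelength grid.
#' @return A `visual_system`.
#' @export
goby <- function(grid = default_grid()) {
  visual_system("goby",
                list(receptor_channel("SWS", 456, 0.72),
                     receptor_channel("MWS", 531, 1.00),
                     receptor_channel("LWS", 553, 0.60)),
                ocular_cutoff_nm = 410, nu = 0.05, grid = grid)
}

#' Read a visual system from a YAML config
#'
#' Config fields: `name`, `channels` (list of `{name, lambda_max_nm,
#' relative_abundance}`), `ocular_cutoff_nm`, `nu`. The shipped
#' `pollack.yaml` and `goby.yaml` live in `inst/extdata/visual_systems/`.
#'
#' @param path YAML file path.
#' @param grid Working wavelength grid.
#' @return A `visual_system`.
#' @export
read_visual_system <- function(path, grid = default_grid()) {
  cfg <- yaml::read_yaml(path)
  needed <- c("name", "channels", "ocular_cutoff_nm", "nu")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    stop("visual-system config ", path, " lacks field(s): ",
         paste(missing, collapse = ", "))
  }
  chans <- lapply(cfg$channels, function(ch) {
    receptor_channel(ch$name, ch$lambda_max_nm, ch$relative_abundance)
  })
  visual_system(cfg$name, chans, cfg$ocular_cutoff_nm, cfg$nu, grid)
}

#' Weber fractions of a visual system
#'
#' omega_i = nu / sqrt(eta_i), with abundances eta normalised so the most
#' abundant channel has eta = 1 and hence omega = nu exactly.
#'
#' @param system A [visual_system()].
#' @return Named numeric vector of Weber fractions, channel order preserved.
#' @export
weber_fractions <- function(system) {
  stopifnot(inherits(system, "visual_system"))
  eta <- system$eta
  if (any(eta <= 0)) stop("relative abundances must be > 0")
  system$nu / sqrt(eta)
}

#' Cone catch record
#'
#' Per-subject normalised quantum catches with metadata used by the
#' downstream analyses. Catches must be strictly positive so receptor
#' log-ratios are defined.
#'
#' @param subject_id Subject label.
#' @param catches Named numeric vector of catches q_i, all > 0.
#' @param colour_type Optional `"green"` or `"red"`.
#' @param day Optional integer day of a colour-change schedule.
#' @param substrate Optional `"sea_lettuce"` or `"dulse"`.
#' @param size_mm Optional body size (mm).
#' @return A `cone_catch_record`.
#' @export
cone_catch_record <- function(subject_id, catches, colour_type = NA_character_,
                              day = NA_integer_, substrate = NA_character_,
                              size_mm = NA_real_) {
  catches <- unlist(catches)
  if (any(!is.finite(catches)) || any(catches <= 0)) {
    stop("cone catches must be finite and strictly positive")
  }
  structure(list(subject_id = as.character(subject_id), catches = catches,
                 colour_type = colour_type, day = day, substrate = substrate,
                 size_mm = size_mm),
            class = "cone_catch_record")
}

#' @export
print.cone_catch_record <- function(x, ...) {
  cat(sprintf("<cone_catch_record '%s': %s>\n", x$subject_id,
              paste(sprintf("%s=%.4f", names(x$catches), x$catches),
                    collapse = " ")))
  invisible(x)
}

#' Cone quantum catches of a reflectance spectrum
#'
#' Computes, for each receptor channel i,
#' q_i = Int R I T S_i dl / Int I T S_i dl (trapezoid rule), i.e. the
#' quantum catch normalised von Kries-style to the catch of the illuminant
#' itself. A flat reflectance c therefore maps to q_i = c on every channel
#' under any illuminant, and catches are invariant to the illuminant's
#' absolute scale.
#'
#' @param reflectance Reflectance `spectrum` (fractions, 0--1).
#' @param illuminant Illuminant `spectrum` (relative irradiance), default D65.
#' @param system A [visual_system()].
#' @param ... Metadata passed to [cone_catch_record()] (`subject_id`,
#'   `colour_type`, `day`, `substrate`, `size_mm`).
#' @return A `cone_catch_record`.
#' @export
cone_catch <- function(reflectance, illuminant = d65(system$grid), system,
                       ...) {
  stopifnot(inherits(system, "visual_system"))
  grid <- system$grid
  refl <- resample(reflectance, grid)
  illum <- resample(illuminant, grid)
  q <- vapply(system$sensitivity, function(s) {
    num <- pracma::trapz(grid, refl$value * illum$value * s$value)
    den <- pracma::trapz(grid, illum$value * s$value)
    num / den
  }, numeric(1))
  if (any(q <= 0)) {
    stop("degenerate catch: reflectance is identically zero over a ",
         "channel's support")
  }
  args <- list(...)
  if (is.null(args$subject_id)) {
    args$subject_id <- if (!is.null(refl$name)) refl$name else "subject"
  }
  do.call(cone_catch_record, c(list(catches = q), args))
}
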