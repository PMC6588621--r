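#' Parametric reflectance spectrum model
#'
#' The generator's spectral families, chosen to emulate the study organisms:
#' `green_peak` (baseline plus a Gaussian reflectance peak, the green prawn /
#' sea lettuce shape), `red_longpass` (baseline plus a sigmoid long-pass
#' edge, the red prawn / dulse shape; red algae also carry a slightly higher
#' short-wave baseline than green tissue, which is what produces the
#' short-wave crossover when types converge), `flat` (grey standards) and
#' `mixture` (a convex blend of two models, used for colour change).
#'
#' Per-individual variation is expressed through jitter standard deviations
#' on the parameters; per-wavelength measurement noise through `noise_sd`.
#'
#' @param kind One of `"green_peak"`, `"red_longpass"`, `"flat"`,
#'   `"mixture"`.
#' @param baseline Baseline reflectance fraction.
#' @param amplitude Peak/edge amplitude above baseline.
#' @param peak_nm Gaussian peak centre (green_peak).
#' @param width_nm Gaussian sd, or sigmoid scale (red_longpass).
#' @param edge_nm Sigmoid 50% edge position (red_longpass).
#' @param m Mixing weight in `[0, 1]` (mixture; 0 = all `start`).
#' @param start,target Component models (mixture).
#' @param noise_sd Per-wavelength Gaussian noise sd.
#' @param peak_jitter_sd,amplitude_jitter_sd,baseline_jitter_sd
#'   Between-individual parameter jitter sds (peak jitter moves the edge for
#'   `red_longpass`).
#' @return A `spectrum_model`.
#' @export
spectrum_model <- function(kind = c("green_peak", "red_longpass", "flat",
                                    "mixture"),
                           baseline = 0.05, amplitude = 0.3, peak_nm = 550,
                           width_nm = 40, edge_nm = 590, m = 0.5,
                           start = NULL, target = NULL, noise_sd = 0,
                           peak_jitter_sd = 0, amplitude_jitter_sd = 0,
                           baseline_jitter_sd = 0) {
  kind <- match.arg(kind)
  if (kind == "mixture") {
    stopifnot(inherits(start, "spectrum_model"),
              inherits(target, "spectrum_model"), m >= 0, m <= 1)
  } else if (kind != "flat" && amplitude + baseline > 1) {
    stop("amplitude + baseline exceed 1: reflectance would leave [0, 1]")
  }
  structure(list(kind = kind, baseline = baseline, amplitude = amplitude,
                 peak_nm = peak_nm, width_nm = width_nm, edge_nm = edge_nm,
                 m = m, start = start, target = target, noise_sd = noise_sd,
                 peak_jitter_sd = peak_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 baseline_jitter_sd = baseline_jitter_sd),
            class = "spectrum_model")
}

# evaluate the noise-free model curve on a grid
.eval_model <- function(model, grid) {
  switch(model$kind,
    flat = rep(model$baseline, length(grid)),
    green_peak = model$baseline + model$amplitude *
      exp(-(grid - model$peak_nm)^2 / (2 * model$width_nm^2)),
    red_longpass = model$baseline + model$amplitude /
      (1 + exp(-(grid - model$edge_nm) / model$width_nm)),
    mixture = (1 - model$m) * .eval_model(model$start, grid) +
      model$m * .eval_model(model$target, grid))
}

# draw a parameter-jittered copy of a model from the current RNG stream
.jitter_model <- function(model) {
  if (model$kind == "mixture") {
    model$start <- .jitter_model(model$start)
    model$target <- .jitter_model(model$target)
    return(model)
  }
  if (model$baseline_jitter_sd > 0) {
    model$baseline <- max(model$baseline +
                            stats::rnorm(1, 0, model$baseline_jitter_sd),
                          0.001)
  }
  if (model$kind == "flat") return(model)
  if (model$amplitude_jitter_sd > 0) {
    model$amplitude <- max(model$amplitude +
                             stats::rnorm(1, 0, model$amplitude_jitter_sd),
                           0.01)
  }
  if (model$peak_jitter_sd > 0) {
    shift <- stats::rnorm(1, 0, model$peak_jitter_sd)
    if (model$kind == "green_peak") model$peak_nm <- model$peak_nm + shift
    else model$edge_nm <- model$edge_nm + shift
  }
  model
}

# evaluate with jitter + spectral noise from the current RNG stream
.sample_reflectance <- function(model, grid) {
  mj <- .jitter_model(model)
  v <- .eval_model(mj, grid)
  if (model$noise_sd > 0) v <- v + stats::rnorm(length(grid), 0, model$noise_sd)
  spectrum(grid, pmin(pmax(v, 0), 1))
}

#' Draw one reflectance spectrum from a model
#'
#' Jitters the model parameters (between-individual variation), evaluates the
#' curve, adds per-wavelength noise and clips to `[0, 1]`. Deterministic
#' under `rng_seed`.
#'
#' @param model A [spectrum_model()].
#' @param rng_seed Integer seed.
#' @param grid Wavelength grid.
#' @return A reflectance [spectrum()].
#' @export
sample_reflectance <- function(model, rng_seed, grid = default_grid()) {
  stopifnot(inherits(model, "spectrum_model"))
  with_seed(rng_seed, .sample_reflectance(model, grid))
}

#' Default spectral models of the study organisms
#'
#' `prawn_model()` and `seaweed_model()` return the generator defaults used
#' throughout tests and analyses: the green prawn matches the sea-lettuce
#' family (Gaussian peak near 550 nm) and the red prawn matches the dulse
#' family (long-pass edge near 590 nm with an elevated short-wave baseline),
#' so matched prawn-substrate pairs differ only by individual variation
#' while mismatched pairs differ in spectral shape.
#'
#' @param type `"green"`/`"red"` (prawn) or `"sea_lettuce"`/`"dulse"`.
#' @return A [spectrum_model()].
#' @export
prawn_model <- function(type = c("green", "red")) {
  type <- match.arg(type)
  if (type == "green") {
    spectrum_model("green_peak", baseline = 0.04, amplitude = 0.30,
                   peak_nm = 550, width_nm = 40, noise_sd = 0.005,
                   peak_jitter_sd = 8, amplitude_jitter_sd = 0.05,
                   baseline_jitter_sd = 0.006)
  } else {
    spectrum_model("red_longpass", baseline = 0.11, amplitude = 0.45,
                   edge_nm = 590, width_nm = 20, noise_sd = 0.005,
                   peak_jitter_sd = 8, amplitude_jitter_sd = 0.06,
                   baseline_jitter_sd = 0.008)
  }
}

#' @rdname prawn_model
#' @export
seaweed_model <- function(type = c("sea_lettuce", "dulse")) {
  type <- match.arg(type)
  if (type == "sea_lettuce") {
    spectrum_model("green_peak", baseline = 0.04, amplitude = 0.30,
                   peak_nm = 550, width_nm = 40, noise_sd = 0.005,
                   peak_jitter_sd = 8, amplitude_jitter_sd = 0.05,
                   baseline_jitter_sd = 0.006)
  } else {
    spectrum_model("red_longpass", baseline = 0.11, amplitude = 0.45,
                   edge_nm = 590, width_nm = 20, noise_sd = 0.005,
                   peak_jitter_sd = 8, amplitude_jitter_sd = 0.06,
                   baseline_jitter_sd = 0.008)
  }
}

#' Random natural-spectra library
#'
#' Training/validation library for the camera-to-cone mapping: a seeded mix
#' of Gaussian-peak spectra, long-pass edges, flat greys and two-component
#' mixtures spanning the visible gamut.
#'
#' @param n Number of spectra (default 200).
#' @param rng_seed Integer seed.
#' @param grid Wavelength grid.
#' @return List of reflectance [spectrum()]s.
#' @export
sample_spectra_library <- function(n = 200L, rng_seed, grid = default_grid()) {
  with_seed(rng_seed, {
    lapply(seq_len(n), function(i) {
      kind <- sample(c("peak", "longpass", "flat", "mixture"), 1L,
                     prob = c(0.4, 0.3, 0.15, 0.15))
      base <- stats::runif(1, 0.02, 0.25)
      mdl <- switch(kind,
        peak = spectrum_model("green_peak", baseline = base,
                              amplitude = stats::runif(1, 0.1, 1 - base - 0.05),
                              peak_nm = stats::runif(1, 430, 660),
                              width_nm = stats::runif(1, 20, 80)),
        longpass = spectrum_model("red_longpass", baseline = base,
                                  amplitude = stats::runif(1, 0.15, 1 - base - 0.05),
                                  edge_nm = stats::runif(1, 470, 660),
                                  width_nm = stats::runif(1, 8, 40)),
        flat = spectrum_model("flat", baseline = stats::runif(1, 0.03, 0.9)),
        mixture = spectrum_model("mixture", m = stats::runif(1),
          start = spectrum_model("green_peak", baseline = base,
                                 amplitude = stats::runif(1, 0.1, 0.6),
                                 peak_nm = stats::runif(1, 470, 600),
                                 width_nm = stats::runif(1, 25, 70)),
          target = spectrum_model("red_longpass", baseline = base,
                                  amplitude = stats::runif(1, 0.15, 0.6),
                                  edge_nm = stats::runif(1, 500, 640),
                                  width_nm = stats::runif(1, 10, 35))))
      s <- .sample_reflectance(mdl, grid)
      s$name <- sprintf("lib_%03d", i)
      s
    })
  })
}

#' Synthetic field survey of prawns and seaweed
#'
#' Draws individual reflectance spectra for the field camouflage analysis:
#' green and red prawns plus pools of sea-lettuce and dulse backgrounds,
#' with per-individual parameter jitter. Sample sizes default to the field
#' study design (64 prawns per colour type, 64-image background pools).
#'
#' @param n_prawns Prawns per colour type.
#' @param n_backgrounds Backgrounds per seaweed species.
#' @param rng_seed Integer seed.
#' @param grid Wavelength grid.
#' @return List of four lists of spectra: `green_prawns`, `red_prawns`,
#'   `sea_lettuce`, `dulse`.
#' @export
simulate_field_survey <- function(n_prawns = 64L, n_backgrounds = 64L,
                                  rng_seed, grid = default_grid()) {
  stopifnot(n_prawns >= 1L, n_backgrounds >= 1L)
  with_seed(rng_seed, {
    draw <- function(model, n, prefix) {
      lapply(seq_len(n), function(i) {
        s <- .sample_reflectance(model, grid)
        s$name <- sprintf("%s_%03d", prefix, i)
        s
      })
    }
    list(green_prawns = draw(prawn_model("green"), n_prawns, "green"),
         red_prawns = draw(prawn_model("red"), n_prawns, "red"),
         sea_lettuce = draw(seaweed_model("sea_lettuce"), n_backgrounds, "sl"),
         dulse = draw(seaweed_model("dulse"), n_backgrounds, "du"))
  })
}

#' Colour-change schedule
#'
#' Observation days, exponential-approach kinetics and survival hazards for
#' the colour-change experiment. The mixing trajectory is
#' m(day) = m_max (1 - exp(-k day)), which front-loads the change: with the
#' defaults most of the shift happens inside the first 10 days, as observed.
#' The rate of an individual of size s is k exp(-beta (s - size_ref)), so
#' larger individuals change more slowly when `beta > 0`. Dropout hazards
#' emulate the experiment's survival profile (no deaths to day 10, ~90% to
#' day 20, ~58% to day 30).
#'
#' @param days Observation days (default 0, 5, ..., 30).
#' @param k Rate constant (per day, default 0.15).
#' @param m_max Asymptotic mixing weight in (0, 1] (default 0.8; colour
#'   change is strong but incomplete).
#' @param beta Size-rate coupling (per mm, default 0.1).
#' @param dropout_hazard Death probability per inter-observation interval
#'   (length `length(days) - 1`).
#' @return A `colour_change_schedule`.
#' @export
colour_change_schedule <- function(days = c(0, 5, 10, 15, 20, 25, 30),
                                   k = 0.15, m_max = 0.8, beta = 0.1,
                                   dropout_hazard = c(0, 0, 0.05, 0.05,
                                                      0.2, 0.2)) {
  if (length(days) < 2L || any(diff(days) <= 0) || days[1L] != 0) {
    stop("invalid schedule: days must start at 0 and increase")
  }
  if (k <= 0 || m_max <= 0 || m_max > 1) stop("invalid schedule: k, m_max")
  if (length(dropout_hazard) != length(days) - 1L ||
      any(dropout_hazard < 0) || any(dropout_hazard >= 1)) {
    stop("invalid schedule: dropout_hazard needs one value in [0, 1) per ",
         "interval")
  }
  structure(list(days = days, k = k, m_max = m_max, beta = beta,
                 dropout_hazard = dropout_hazard),
            class = "colour_change_schedule")
}

#' Mixing trajectory of the schedule
#'
#' @param schedule A [colour_change_schedule()].
#' @param k Individual rate constant (defaults to the schedule's `k`).
#' @return Numeric m(day) for each scheduled day.
#' @export
mixing_trajectory <- function(schedule, k = schedule$k) {
  schedule$m_max * (1 - exp(-k * schedule$days))
}

#' Simulate the colour-change experiment
#'
#' Each individual gets a jittered start and target spectrum, a size drawn
#' from N(`size_mean`, `size_sd`) and hence its own rate constant; its
#' reflectance on day d is the mixture (1 - m) start + m target with
#' m = m_max (1 - exp(-k_i d)), plus measurement noise. Individuals die
#' between observations according to the schedule's hazards; spectra are
#' only emitted for days an individual was alive. Ground truth (m, size,
#' rate, survival) is returned alongside.
#'
#' @param start,target [spectrum_model()]s (e.g. green prawn -> dulse).
#' @param schedule A [colour_change_schedule()].
#' @param n_individuals Number of individuals (default 25).
#' @param rng_seed Integer seed.
#' @param colour_type Metadata label for the individuals.
#' @param size_mean,size_sd Body size distribution (mm).
#' @param grid Wavelength grid.
#' @return List with `spectra` (list over individuals of lists over observed
#'   days) and `truth` (tibble: `subject_id`, `colour_type`, `day`, `m`,
#'   `size_mm`, `k`, `alive`).
#' @export
simulate_colour_change <- function(start, target, schedule,
                                   n_individuals = 25L, rng_seed,
                                   colour_type = NA_character_,
                                   size_mean = 8, size_sd = 1.5,
                                   grid = default_grid()) {
  stopifnot(inherits(start, "spectrum_model"),
            inherits(target, "spectrum_model"),
            inherits(schedule, "colour_change_schedule"),
            n_individuals >= 1L)
  with_seed(rng_seed, {
    days <- schedule$days
    spectra <- vector("list", n_individuals)
    truth <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      id <- sprintf("%s_%02d", ifelse(is.na(colour_type), "ind", colour_type), i)
      size <- max(stats::rnorm(1, size_mean, size_sd), 3)
      k_i <- schedule$k * exp(-schedule$beta * (size - size_mean))
      start_i <- .jitter_model(start)
      target_i <- .jitter_model(target)
      dead_after <- length(days)  # index of last observed day
      for (j in seq_along(schedule$dropout_hazard)) {
        if (stats::runif(1) < schedule$dropout_hazard[j]) {
          dead_after <- j
          break
        }
      }
      m_days <- schedule$m_max * (1 - exp(-k_i * days))
      alive <- seq_along(days) <= dead_after
      day_spectra <- list()
      for (j in seq_along(days)) {
        if (!alive[j]) break
        mix <- spectrum_model("mixture", m = m_days[j], start = start_i,
                              target = target_i, noise_sd = start$noise_sd)
        s <- .sample_reflectance(mix, grid)
        s$name <- sprintf("%s_d%02d", id, days[j])
        day_spectra[[as.character(days[j])]] <- s
      }
      spectra[[i]] <- day_spectra
      truth[[i]] <- tibble::tibble(subject_id = id, colour_type = colour_type,
                                   day = days, m = m_days, size_mm = size,
                                   k = k_i, alive = alive)
    }
    names(spectra) <- vapply(truth, function(t) t$subject_id[1L], character(1))
    list(spectra = spectra, truth = dplyr::bind_rows(truth))
  })
}

#' Render a synthetic raw multispectral fixture
#'
#' Stands in for the photography chamber: lays out named spectral patches as
#' blocks in a small image, computes each patch's linear camera band values
#' by spectral integration (von Kries-normalised, so a flat grey of
#' reflectance c renders at linear value c), gamma-encodes, adds pixel
#' noise, and quantises to the bit depth. Ground-truth spectra, camera
#' catches and per-patch masks are returned so calibration can be verified
#' end to end.
#'
#' @param patches Named list of [spectrum_model()]s (include the two flat
#'   standard patches used for equalisation).
#' @param camera A [camera_model()].
#' @param illuminant Illuminant spectrum.
#' @param gamma Encoding gamma (pixel = linear^(1/gamma); 1 = linear).
#' @param noise_sd Pixel noise sd in normalised (0--1) units.
#' @param rng_seed Integer seed.
#' @param bit_depth Bit depth of the raw encoding (default 16).
#' @param patch_px Patch block edge length in pixels (default 12).
#' @return List with `image` (raw [multispectral_image()]), `masks` (named
#'   logical matrices), `spectra` (ground-truth per-patch reflectance),
#'   `camera_catches` (ground-truth linear band values per patch).
#' @export
render_fixture <- function(patches, camera = camera_default(),
                           illuminant = d65(), gamma = 2.2, noise_sd = 0.002,
                           rng_seed = 1L, bit_depth = 16L, patch_px = 12L) {
  stopifnot(is.list(patches), !is.null(names(patches)), length(patches) >= 1L)
  grid <- camera$bands[[1L]]$wl
  with_seed(rng_seed, {
    specs <- lapply(patches, function(m) .sample_reflectance(m, grid))
    catches <- lapply(specs, camera_catch, camera = camera,
                      illuminant = illuminant)
    n <- length(patches)
    h <- patch_px
    w <- patch_px * n
    maxv <- 2^bit_depth - 1
    planes <- lapply(camera$band_names, function(b) matrix(0, h, w))
    names(planes) <- camera$band_names
    masks <- list()
    for (i in seq_len(n)) {
      cols <- ((i - 1L) * patch_px + 1L):(i * patch_px)
      mask <- matrix(FALSE, h, w)
      mask[, cols] <- TRUE
      masks[[names(patches)[i]]] <- mask
      for (b in camera$band_names) {
        lin <- catches[[i]][[b]]
        enc <- lin^(1 / gamma)
        px <- enc + stats::rnorm(h * patch_px, 0, noise_sd)
        planes[[b]][, cols] <- matrix(pmin(pmax(px, 0), 1), h, patch_px)
      }
    }
    planes <- lapply(planes, function(p) round(p * maxv))
    list(image = multispectral_image(planes, bit_depth, "raw"),
         masks = masks, spectra = specs, camera_catches = catches)
  })
}

#' Simulate behavioural Y-maze choice trials
#'
#' Each trial: the prawn makes a choice with probability `p_choice_made`
#' (otherwise `no_choice`); given a choice, it picks the colour-matching
#' seaweed with probability `p_match_given_choice`. Defaults emulate the
#' experimental design: 90 trials per colour type, an overall decision rate
#' of 79/180 and a strong (0.8) matching preference.
#'
#' @param n_trials_per_type Trials per colour type.
#' @param p_choice_made Probability a trial ends in a decision.
#' @param p_match_given_choice Probability a decision matches body colour.
#' @param rng_seed Integer seed.
#' @return A tibble (trial table): `trial`, `colour_type`, `outcome`
#'   (`sea_lettuce` / `dulse` / `no_choice`), `duration_s`.
#' @export
simulate_choice_trials <- function(n_trials_per_type = 90L,
                                   p_choice_made = 79 / 180,
                                   p_match_given_choice = 0.8, rng_seed) {
  stopifnot(p_choice_made >= 0, p_choice_made <= 1,
            p_match_given_choice >= 0, p_match_given_choice <= 1)
  with_seed(rng_seed, {
    rows <- lapply(c("green", "red"), function(type) {
      match_sub <- if (type == "green") "sea_lettuce" else "dulse"
      other_sub <- if (type == "green") "dulse" else "sea_lettuce"
      chose <- stats::runif(n_trials_per_type) < p_choice_made
      matched <- stats::runif(n_trials_per_type) < p_match_given_choice
      outcome <- ifelse(!chose, "no_choice",
                        ifelse(matched, match_sub, other_sub))
      tibble::tibble(trial = seq_len(n_trials_per_type), colour_type = type,
                     outcome = outcome,
                     duration_s = ifelse(chose,
                                         round(stats::runif(n_trials_per_type,
                                                            30, 600)), 600))
    })
    dplyr::bind_rows(rows)
  })
}
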