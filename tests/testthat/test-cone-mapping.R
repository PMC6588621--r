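test_that("a camera identical to the cone set maps as the identity", {
  p <- pollack()
  cam <- camera_model(p$sensitivity)
  lib <- sample_spectra_library(80, rng_seed = 31)
  m <- fit_mapping(cam, p, lib, degree = 2)
  expect_true(all(m$r_squared > 0.9999))
  s <- sample_reflectance(prawn_model("green"), 7)
  pred <- apply_mapping(m, camera_catch(s, cam), subject_id = "g")
  truth <- cone_catch(s, system = p)
  expect_equal(pred$catches, truth$catches, tolerance = 1e-4)
})

test_that("flat greys map to the camera catch itself", {
  g <- goby()
  cam <- camera_default()
  m <- fit_mapping(cam, g, sample_spectra_library(120, rng_seed = 32))
  for (c0 in c(0.1, 0.4, 0.8)) {
    flat <- spectrum(default_grid(), rep(c0, 301))
    pred <- apply_mapping(m, camera_catch(flat, cam), subject_id = "flat")
    expect_equal(unname(pred$catches), rep(c0, 3), tolerance = 0.01)
  }
})

test_that("degree-2 mapping meets held-out accuracy on the library", {
  cam <- camera_default()
  for (sys in list(pollack(), goby())) {
    train <- sample_spectra_library(200, rng_seed = 1)
    m <- fit_mapping(cam, sys, train, degree = 2)
    held <- sample_spectra_library(100, rng_seed = 77)
    camx <- t(vapply(held, camera_catch, numeric(3), camera = cam))
    pred <- apply_mapping(m, camx)
    truth <- t(vapply(held, function(r) cone_catch(r, system = sys)$catches,
                      numeric(length(sys$channel_names))))
    expect_lt(sqrt(mean((truth - pred)^2)), 0.01)  # pooled RMSE
    r2 <- vapply(seq_len(ncol(truth)), function(j) {
      1 - sum((truth[, j] - pred[, j])^2) /
        sum((truth[, j] - mean(truth[, j]))^2)
    }, numeric(1))
    expect_true(all(r2 >= 0.97))
  }
})

test_that("in-sample predictions sit within the training residual band", {
  cam <- camera_default()
  p <- pollack()
  train <- sample_spectra_library(100, rng_seed = 41)
  m <- fit_mapping(cam, p, train)
  camx <- t(vapply(train, camera_catch, numeric(3), camera = cam))
  pred <- apply_mapping(m, camx)
  truth <- t(vapply(train, function(r) cone_catch(r, system = p)$catches,
                    numeric(2)))
  expect_lt(max(abs(pred - truth)), 0.05)
})

test_that("predictions are floored at a small positive value with warning", {
  mp <- structure(list(
    coefficients = matrix(c(-0.5, 0, 0, 0, 0.1, 0, 0, 0, 0.1),
                          nrow = 3,
                          dimnames = list(NULL, c("SWS", "MWS", "LWS"))),
    terms = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), nrow = 3, byrow = TRUE),
    degree = 1L, band_names = c("visB", "visG", "visR"),
    channel_names = c("SWS", "MWS", "LWS"), system = "goby",
    r_squared = c(SWS = 1, MWS = 1, LWS = 1), catch_floor = 1e-4),
    class = "poly_mapping")
  expect_warning(
    out <- apply_mapping(mp, c(visB = 0.1, visG = 0.1, visR = 0.1),
                         subject_id = "x"),
    "clamped")
  expect_equal(unname(out$catches["SWS"]), 1e-4)
})

test_that("missing bands and rank deficiency are rejected", {
  cam <- camera_default()
  p <- pollack()
  m <- fit_mapping(cam, p, sample_spectra_library(60, rng_seed = 51))
  expect_error(apply_mapping(m, c(visB = 0.2, visG = 0.3)), "missing")
  flats <- lapply(seq(0.1, 0.9, length.out = 60), function(c0) {
    spectrum(default_grid(), rep(c0, 301))
  })
  expect_error(fit_mapping(cam, p, flats, degree = 2), "lower degree")
  expect_error(fit_mapping(cam, p, flats[1:10]), ">= 50")
})

test_that("mapping JSON serialisation preserves predictions", {
  cam <- camera_default()
  g <- goby()
  m <- fit_mapping(cam, g, sample_spectra_library(80, rng_seed = 61))
  path <- withr::local_tempfile(fileext = ".json")
  write_mapping_json(m, path)
  m2 <- read_mapping_json(path)
  x <- c(visB = 0.2, visG = 0.5, visR = 0.3)
  expect_equal(apply_mapping(m2, x, subject_id = "x")$catches,
               apply_mapping(m, x, subject_id = "x")$catches,
               tolerance = 1e-12)
})

test_that("fixture ROI catches pushed through the mapping match direct integration", {
  cam <- camera_default()
  p <- pollack()
  m <- fit_mapping(cam, p, sample_spectra_library(200, rng_seed = 1))
  greys <- c(2, 5, 10, 20, 40, 60, 80, 99) / 100
  cal <- render_fixture(stats::setNames(
    lapply(greys, function(g) spectrum_model("flat", baseline = g)),
    paste0("s", seq_along(greys))), cam, gamma = 2.2, noise_sd = 0.002,
    rng_seed = 5)
  curves <- lapply(names(cal$image$planes), function(b) {
    px <- vapply(paste0("s", seq_along(greys)), function(nm) {
      mean(cal$image$planes[[b]][cal$masks[[nm]]])
    }, numeric(1))
    fit_linearisation(data.frame(pixel = px, reflectance = greys))
  })
  names(curves) <- names(cal$image$planes)
  scene <- render_fixture(list(
    dark = spectrum_model("flat", baseline = 0.085),
    light = spectrum_model("flat", baseline = 0.95),
    green = prawn_model("green")), cam, gamma = 2.2, noise_sd = 0.002,
    rng_seed = 9)
  eq <- equalise(linearise_image(scene$image, curves),
                 standard_patch(0.085, scene$masks$dark),
                 standard_patch(0.95, scene$masks$light))
  roi <- extract_roi(eq, scene$masks$green)
  pred <- apply_mapping(m, roi$means, subject_id = "green")
  truth <- cone_catch(scene$spectra$green, system = p)
  # combined calibration + mapping error, absolute catch units
  expect_lt(max(abs(pred$catches - truth$catches)), 0.03)
})
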