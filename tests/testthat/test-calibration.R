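# eight grey standards spanning 2-99%, as used for response linearisation
greys <- c(2, 5, 10, 20, 40, 60, 80, 99) / 100

test_that("linearisation recovers a linear response as identity", {
  s <- data.frame(pixel = greys * 1000, reflectance = greys)
  cv <- fit_linearisation(s)
  expect_lt(max(abs(cv$residuals)), 1e-9)
  expect_equal(cv$fun(500), 0.5, tolerance = 1e-6)
})

test_that("linearisation inverts a gamma-encoded response within 1%", {
  s <- data.frame(pixel = greys^(1 / 2.2) * 255, reflectance = greys)
  cv <- fit_linearisation(s)
  # off-sample pixel values, compared against the analytic inverse
  px <- seq(min(s$pixel), max(s$pixel), length.out = 50)
  truth <- (px / 255)^2.2
  expect_lt(max(abs(cv$fun(px) - truth)), 0.01)
  expect_lt(max(abs(cv$residuals)), 0.002)
})

test_that("linearisation preconditions are enforced", {
  expect_error(fit_linearisation(
    data.frame(pixel = c(10, 50, 200), reflectance = c(0.02, 0.2, 0.99))),
    "insufficient standards")
  expect_error(fit_linearisation(
    data.frame(pixel = c(10, 50, 90, 200),
               reflectance = c(0.02, 0.3, 0.2, 0.99))),
    "non-monotone")
})

test_that("equalisation is the identity when means already sit at nominals", {
  m <- matrix(0.5, 8, 8)
  m[, 1:2] <- 0.085
  m[, 7:8] <- 0.95
  img <- multispectral_image(list(ch = m), role = "linearised")
  dark_mask <- col(m) <= 2
  light_mask <- col(m) >= 7
  eq <- equalise(img, standard_patch(0.085, dark_mask),
                 standard_patch(0.95, light_mask))
  expect_equal(eq$planes$ch, m, tolerance = 1e-12)
  expect_equal(eq$role, "equalised")
})

test_that("equalisation cancels any affine relighting exactly", {
  set.seed(8)
  base <- matrix(runif(100, 0.05, 0.9), 10, 10)
  dark_mask <- row(base) <= 2
  light_mask <- row(base) >= 9
  base[dark_mask] <- 0.07
  base[light_mask] <- 0.93
  dk <- standard_patch(0.07, dark_mask)
  lt <- standard_patch(0.93, light_mask)
  ref <- equalise(multispectral_image(list(ch = base), role = "linearised"),
                  dk, lt)
  relit <- multispectral_image(list(ch = 1.8 * base + 0.04),
                               role = "linearised")
  eq2 <- equalise(relit, dk, lt)
  expect_equal(eq2$planes$ch, ref$planes$ch, tolerance = 1e-12)
  # idempotence: re-equalising the output with its own standards
  expect_equal(equalise(ref, dk, lt)$planes$ch, ref$planes$ch,
               tolerance = 1e-12)
  # degenerate standards
  flat <- multispectral_image(list(ch = matrix(0.5, 10, 10)),
                              role = "linearised")
  expect_error(equalise(flat, dk, lt), "degenerate")
})

test_that("ROI extraction averages, counts and excludes saturation", {
  m <- matrix(0.4, 5, 5)
  img <- multispectral_image(list(ch = m), role = "equalised")
  mask <- matrix(FALSE, 5, 5); mask[2:3, 2:3] <- TRUE
  r <- extract_roi(img, mask)
  expect_equal(unname(r$means), 0.4)
  expect_equal(r$n_pixels, 4L)

  m2 <- matrix(0, 2, 2); m2[1, 1] <- 0.2; m2[1, 2] <- 0.6
  img2 <- multispectral_image(list(ch = m2), role = "equalised")
  mask2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(unname(extract_roi(img2, mask2)$means), 0.4)

  expect_error(extract_roi(img, matrix(FALSE, 5, 5)), "empty")
  expect_error(extract_roi(img, matrix(TRUE, 4, 4)), "shape")

  # saturated raw pixels are carried through and excluded
  raw <- matrix(1000, 4, 4); raw[1, 1] <- 65535
  rimg <- multispectral_image(list(ch = raw), bit_depth = 16, role = "raw")
  curve <- fit_linearisation(data.frame(pixel = greys * 65535,
                                        reflectance = greys))
  lin <- linearise_image(rimg, curve)
  r3 <- extract_roi(lin, matrix(TRUE, 4, 4))
  expect_equal(r3$n_saturated_excluded, 1L)
  expect_equal(r3$n_pixels, 15L)
})

test_that("rendered fixture round-trips through the full calibration", {
  cam <- camera_default()
  cal_patches <- stats::setNames(
    lapply(greys, function(g) spectrum_model("flat", baseline = g)),
    sprintf("std_%02.0f", greys * 100))
  calfx <- render_fixture(cal_patches, cam, gamma = 2.2, noise_sd = 0.002,
                          rng_seed = 5)
  curves <- lapply(names(calfx$image$planes), function(b) {
    px <- vapply(names(cal_patches), function(nm) {
      mean(calfx$image$planes[[b]][calfx$masks[[nm]]])
    }, numeric(1))
    fit_linearisation(data.frame(pixel = px, reflectance = greys))
  })
  names(curves) <- names(calfx$image$planes)

  scene <- render_fixture(list(
    dark = spectrum_model("flat", baseline = 0.085),
    light = spectrum_model("flat", baseline = 0.95),
    green = prawn_model("green"),
    red = prawn_model("red")), cam, gamma = 2.2, noise_sd = 0.002,
    rng_seed = 6)
  lin <- linearise_image(scene$image, curves)
  eq <- equalise(lin, standard_patch(0.085, scene$masks$dark),
                 standard_patch(0.95, scene$masks$light))
  for (nm in c("green", "red")) {
    got <- extract_roi(eq, scene$masks[[nm]])$means
    truth <- unlist(scene$camera_catches[[nm]])
    expect_lt(max(abs(got - truth)), 0.02)
  }
})

test_that("multispectral TIFF + sidecar round-trips", {
  set.seed(12)
  img <- multispectral_image(list(visB = matrix(runif(36), 6, 6),
                                  visG = matrix(runif(36), 6, 6)),
                             role = "equalised")
  prefix <- file.path(withr::local_tempdir(), "fixture")
  write_multispectral(img, prefix)
  back <- read_multispectral(prefix)
  expect_equal(back$planes, img$planes, tolerance = 1e-6)
  expect_equal(back$role, "equalised")
})
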