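test_that("pigment template peaks at lambda_max, normalised to 1", {
  for (lm in c(436, 456, 521, 531, 553)) {
    s <- pigment_sensitivity(lm)
    expect_gte(s$wl[which.max(s$value)], lm - 1)
    expect_lte(s$wl[which.max(s$value)], lm + 1)
    expect_true(all(s$value >= 0 & s$value <= 1))
    expect_equal(max(s$value), 1)
  }
  expect_error(pigment_sensitivity(380), "400")
})

test_that("pigment template matches direct closed-form evaluation", {
  # independent evaluation of the alpha+beta template at chosen wavelengths
  direct <- function(lmax, lambda) {
    x <- lmax / lambda
    a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
    alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
    beta <- 0.26 * exp(-((lambda - (189 + 0.315 * lmax)) /
                           (-40.5 + 0.195 * lmax))^2)
    alpha + beta
  }
  grid <- default_grid()
  s <- pigment_sensitivity(521, grid)
  raw <- direct(521, grid)
  expect_equal(s$value, raw / max(raw), tolerance = 1e-12)
  # at x = lambda_max/lambda = 1 the alpha band hits its closed-form maximum
  at_peak <- direct(521, 521)
  expect_equal(s$value[grid == 521] * max(raw), at_peak, tolerance = 1e-12)
})

test_that("ocular transmission has its 50% point at the cutoff", {
  tr <- ocular_transmission(410)
  expect_equal(tr$value[tr$wl == 410], 0.5, tolerance = 0.01)
  expect_gte(tr$value[tr$wl == 700], 0.99)
  expect_true(all(diff(tr$value) >= 0))
  expect_error(ocular_transmission(300), "outside")
})

test_that("shipped visual systems carry the published parameters", {
  p <- pollack()
  expect_equal(p$lambda_max_nm, c(SWS = 436, LWS = 521),
               ignore_attr = TRUE)
  expect_equal(unname(p$eta), c(0.70, 1.00))
  expect_equal(p$ocular_cutoff_nm, 410)
  expect_equal(p$nu, 0.05)
  g <- goby()
  expect_equal(unname(g$lambda_max_nm), c(456, 531, 553))
  expect_equal(unname(g$eta), c(0.72, 1.00, 0.60))
})

test_that("YAML configs reproduce the built-in systems", {
  dir <- system.file("extdata", "visual_systems", package = "prawnvision")
  p <- read_visual_system(file.path(dir, "pollack.yaml"))
  expect_equal(p$eta, pollack()$eta)
  expect_equal(p$sensitivity$LWS$value, pollack()$sensitivity$LWS$value)
  g <- read_visual_system(file.path(dir, "goby.yaml"))
  expect_equal(g$lambda_max_nm, goby()$lambda_max_nm)
})

test_that("flat reflectance maps to its own value on every channel", {
  grid <- default_grid()
  for (sys in list(pollack(), goby())) {
    white <- spectrum(grid, rep(1, length(grid)))
    expect_equal(unname(cone_catch(white, system = sys)$catches),
                 rep(1, length(sys$channel_names)), tolerance = 1e-10)
    grey <- spectrum(grid, rep(0.3, length(grid)))
    expect_equal(unname(cone_catch(grey, system = sys)$catches),
                 rep(0.3, length(sys$channel_names)), tolerance = 1e-10)
  }
})

test_that("flat-spectrum identity holds under any positive illuminant", {
  grid <- default_grid()
  sys <- goby()
  set.seed(11)
  for (i in 1:5) {
    illum <- spectrum(grid, runif(length(grid), 0.1, 3))
    c0 <- runif(1, 0.05, 0.95)
    flat <- spectrum(grid, rep(c0, length(grid)))
    expect_equal(unname(cone_catch(flat, illum, sys)$catches),
                 rep(c0, 3), tolerance = 1e-10)
  }
})

test_that("cone catches agree with a hand trapezoid integration", {
  grid <- default_grid()
  refl <- spectrum(grid, 0.05 + 0.5 * exp(-(grid - 550)^2 / (2 * 40^2)))
  sys <- pollack()
  illum <- d65(grid)
  got <- cone_catch(refl, illum, sys)$catches
  for (ch in sys$channel_names) {
    s <- sys$sensitivity[[ch]]$value
    q <- trapz_oracle(grid, refl$value * illum$value * s) /
      trapz_oracle(grid, illum$value * s)
    expect_equal(unname(got[ch]), q, tolerance = 1e-12)
  }
  # the catch ratio matches the oracle too
  s1 <- sys$sensitivity[[1]]$value; s2 <- sys$sensitivity[[2]]$value
  r_oracle <- (trapz_oracle(grid, refl$value * illum$value * s2) /
                 trapz_oracle(grid, illum$value * s2)) /
    (trapz_oracle(grid, refl$value * illum$value * s1) /
       trapz_oracle(grid, illum$value * s1))
  expect_equal(unname(got[2] / got[1]), r_oracle, tolerance = 1e-12)
})

test_that("degenerate reflectance is rejected", {
  grid <- default_grid()
  zero <- spectrum(grid, rep(0, length(grid)))
  expect_error(cone_catch(zero, system = pollack()), "degenerate")
  expect_error(cone_catch_record("x", c(SWS = 0.2, LWS = 0)), "positive")
})

test_that("Weber fractions follow nu / sqrt(eta) and are scale invariant", {
  expect_equal(unname(weber_fractions(pollack())),
               c(0.05 / sqrt(0.70), 0.05), tolerance = 1e-12)
  expect_equal(unname(weber_fractions(goby())),
               c(0.05 / sqrt(0.72), 0.05, 0.05 / sqrt(0.60)),
               tolerance = 1e-12)
  # rescaling abundances before normalisation changes nothing
  scaled <- visual_system("pollack_scaled",
                          list(receptor_channel("SWS", 436, 3.5),
                               receptor_channel("LWS", 521, 5.0)),
                          ocular_cutoff_nm = 410, nu = 0.05)
  expect_equal(unname(weber_fractions(scaled)),
               unname(weber_fractions(pollack())), tolerance = 1e-12)
  expect_error(receptor_channel("SWS", 436, 0), "> 0")
})
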