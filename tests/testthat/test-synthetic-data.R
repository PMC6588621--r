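test_that("reflectance sampler handles degenerate and seeded cases", {
  flat <- spectrum_model("flat", baseline = 0.3)
  expect_equal(sample_reflectance(flat, 1)$value, rep(0.3, 301))
  nopeak <- spectrum_model("green_peak", baseline = 0.2, amplitude = 0)
  expect_equal(sample_reflectance(nopeak, 1)$value, rep(0.2, 301))
  noisy <- spectrum_model("green_peak", noise_sd = 0.02,
                          peak_jitter_sd = 5, amplitude_jitter_sd = 0.05)
  expect_identical(sample_reflectance(noisy, 42)$value,
                   sample_reflectance(noisy, 42)$value)
  expect_false(identical(sample_reflectance(noisy, 42)$value,
                         sample_reflectance(noisy, 43)$value))
  expect_true(all(sample_reflectance(noisy, 1)$value >= 0 &
                    sample_reflectance(noisy, 1)$value <= 1))
  expect_error(spectrum_model("green_peak", baseline = 0.6, amplitude = 0.6),
               "exceed 1")
})

test_that("colour-change schedules front-load the change", {
  sch <- colour_change_schedule()
  m <- mixing_trajectory(sch)
  expect_true(all(diff(m) > 0))
  expect_gt(abs(m[3] - m[1]), abs(m[7] - m[5]))  # days 10-0 vs 30-20
  expect_error(colour_change_schedule(days = c(5, 0, 10)), "invalid")
  expect_error(colour_change_schedule(k = -1), "invalid")
  expect_error(colour_change_schedule(dropout_hazard = c(1, 0, 0, 0, 0, 0)),
               "invalid")
})

test_that("colour-change simulation follows its kinetics and couplings", {
  sch_fast <- colour_change_schedule(k = 50)
  run <- simulate_colour_change(prawn_model("green"), seaweed_model("dulse"),
                                sch_fast, n_individuals = 4, rng_seed = 2,
                                colour_type = "green")
  d5 <- run$truth[run$truth$day == 5, ]
  expect_equal(d5$m, rep(sch_fast$m_max, 4), tolerance = 1e-6)

  sch0 <- colour_change_schedule(beta = 0)
  run0 <- simulate_colour_change(prawn_model("green"), seaweed_model("dulse"),
                                 sch0, n_individuals = 6, rng_seed = 3)
  expect_equal(length(unique(run0$truth$k)), 1L)

  schb <- colour_change_schedule(beta = 0.2)
  runb <- simulate_colour_change(prawn_model("green"), seaweed_model("dulse"),
                                 schb, n_individuals = 10, rng_seed = 3)
  t0 <- runb$truth[runb$truth$day == 0, ]
  expect_lt(cor(t0$size_mm, t0$k), 0)  # larger individuals change slower

  # determinism and ground-truth emission
  rep1 <- simulate_colour_change(prawn_model("red"),
                                 seaweed_model("sea_lettuce"),
                                 colour_change_schedule(), 5, rng_seed = 9,
                                 colour_type = "red")
  rep2 <- simulate_colour_change(prawn_model("red"),
                                 seaweed_model("sea_lettuce"),
                                 colour_change_schedule(), 5, rng_seed = 9,
                                 colour_type = "red")
  expect_identical(rep1$truth, rep2$truth)
  expect_identical(rep1$spectra[[1]][["30"]]$value,
                   rep2$spectra[[1]][["30"]]$value)
  # spectra only exist for days alive
  for (id in names(rep1$spectra)) {
    alive_days <- rep1$truth$day[rep1$truth$subject_id == id &
                                   rep1$truth$alive]
    expect_setequal(as.numeric(names(rep1$spectra[[id]])), alive_days)
  }
})

test_that("noise-free gamma-1 fixtures round-trip to quantisation error", {
  cam <- camera_default()
  fx <- render_fixture(list(a = spectrum_model("flat", baseline = 0.25),
                            b = prawn_model("green")),
                       cam, gamma = 1, noise_sd = 0, rng_seed = 4)
  maxv <- 2^fx$image$bit_depth - 1
  for (nm in names(fx$masks)) {
    for (b in names(fx$image$planes)) {
      got <- mean(fx$image$planes[[b]][fx$masks[[nm]]]) / maxv
      expect_lt(abs(got - fx$camera_catches[[nm]][[b]]), 2 / maxv)
    }
  }
  expect_identical(render_fixture(list(a = prawn_model("red")), cam,
                                  rng_seed = 8)$image$planes,
                   render_fixture(list(a = prawn_model("red")), cam,
                                  rng_seed = 8)$image$planes)
})

test_that("rendered standards let equalisation recover reflectance within 2%", {
  cam <- camera_default()
  scene <- render_fixture(list(
    dark = spectrum_model("flat", baseline = 0.085),
    light = spectrum_model("flat", baseline = 0.95),
    subj = seaweed_model("dulse")), cam, gamma = 1, noise_sd = 0.002,
    rng_seed = 10)
  lin <- multispectral_image(
    lapply(scene$image$planes, function(p) p / (2^16 - 1)),
    bit_depth = 16, role = "linearised")
  eq <- equalise(lin, standard_patch(0.085, scene$masks$dark),
                 standard_patch(0.95, scene$masks$light))
  got <- extract_roi(eq, scene$masks$subj)$means
  truth <- unlist(scene$camera_catches$subj)
  expect_lt(max(abs(got - truth)), 0.02)
})

test_that("choice-trial generator respects its probabilities and seed", {
  none <- simulate_choice_trials(20, p_choice_made = 0,
                                 p_match_given_choice = 0.8, rng_seed = 1)
  expect_true(all(none$outcome == "no_choice"))
  all_match <- simulate_choice_trials(40, p_choice_made = 1,
                                      p_match_given_choice = 1, rng_seed = 1)
  expect_true(all(all_match$outcome[all_match$colour_type == "green"] ==
                    "sea_lettuce"))
  expect_true(all(all_match$outcome[all_match$colour_type == "red"] ==
                    "dulse"))
  expect_identical(simulate_choice_trials(90, rng_seed = 3),
                   simulate_choice_trials(90, rng_seed = 3))
})

test_that("default choice trials give the binomial test high power", {
  # Monte-Carlo power at the design settings: the matching preference is
  # detected at alpha = 0.01 in at least 90% of replicates
  hits <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    tr <- simulate_choice_trials(90, rng_seed = 5000 + s)
    res <- summarise_choices(tr)
    hits <- hits + sum(res$per_type$two_sided_p < 0.01)
  }
  # each replicate contributes one test per colour type (analysed separately)
  expect_gte(hits / (2 * n_rep), 0.9)
})

test_that("spectra library is seeded, in-range and diverse", {
  lib <- sample_spectra_library(50, rng_seed = 2)
  expect_length(lib, 50)
  rng <- vapply(lib, function(s) max(s$value) - min(s$value), numeric(1))
  expect_true(any(rng > 0.2))  # non-flat members present
  expect_true(all(vapply(lib, function(s) all(s$value >= 0 & s$value <= 1),
                         logical(1))))
  expect_identical(sample_spectra_library(50, rng_seed = 2)[[7]]$value,
                   lib[[7]]$value)
})
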