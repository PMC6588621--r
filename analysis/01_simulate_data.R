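#!/usr/bin/env Rscript
# Generate the synthetic study inputs with known ground truth and save them
# under results/data/: the field survey spectra (64 prawns per colour type,
# 64-image seaweed pools), the 30-day colour-change experiment (25 prawns
# per type) and the Y-maze choice trials (90 per type).

suppressPackageStartupMessages(library(prawnvision))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

survey <- simulate_field_survey(n_prawns = 64, n_backgrounds = 64,
                                rng_seed = 11)
for (grp in names(survey)) {
  specs <- survey[[grp]]
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  write_spectra_csv(specs, sprintf("results/data/field_%s.csv", grp))
}
cat(sprintf("field survey: %d prawn + %d background spectra written\n",
            2 * 64, 2 * 64))

sch <- colour_change_schedule()
runs <- list(
  green = simulate_colour_change(prawn_model("green"), seaweed_model("dulse"),
                                 sch, 25, rng_seed = 7,
                                 colour_type = "green"),
  red = simulate_colour_change(prawn_model("red"),
                               seaweed_model("sea_lettuce"), sch, 25,
                               rng_seed = 8, colour_type = "red"))
truth <- dplyr::bind_rows(lapply(runs, `[[`, "truth"))
utils::write.csv(truth, "results/data/colour_change_truth.csv",
                 row.names = FALSE)
n_spec <- sum(truth$alive)
cat(sprintf("colour change: %d individuals, %d observed spectra, %d survive to day 30\n",
            length(unique(truth$subject_id)), n_spec,
            sum(truth$alive[truth$day == 30])))

trials <- simulate_choice_trials(90, rng_seed = 3)
utils::write.csv(trials, "results/data/choice_trials.csv", row.names = FALSE)
cat(sprintf("choice trials: %d rows, %d decided\n", nrow(trials),
            sum(trials$outcome != "no_choice")))
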