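#!/usr/bin/env Rscript
# Optional inferential layer over the colour-change trajectories: linear
# mixed-effects models (day as a fixed factor, size as covariate, individual
# as random intercept) with Tukey-adjusted day contrasts. This delegates
# entirely to standard modelling machinery (lme4 / lmerTest / emmeans) and
# sits outside the package's tested core; run analysis/03_colour_change.R
# first or let this script recompute the run itself.

suppressPackageStartupMessages({
  library(prawnvision)
  library(dplyr)
})
for (pkg in c("lme4", "lmerTest", "emmeans")) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this optional analysis")
  }
}
dir.create("results", showWarnings = FALSE)

cc <- run_colour_change(run_config(seed = 7))
jnds <- cc$jnds %>%
  filter(!is.na(delta_s)) %>%
  mutate(day = factor(day))

rows <- list()
for (sys in unique(jnds$system)) {
  for (type in unique(jnds$colour_type)) {
    d <- filter(jnds, system == sys, colour_type == type)
    # log response stabilises the variance of the right-skewed JNDs
    fit <- lmerTest::lmer(log(delta_s) ~ day + size_mm + (1 | subject_id),
                          data = d)
    an <- stats::anova(fit)
    em <- emmeans::emmeans(fit, "day")
    tuk <- summary(emmeans::contrast(em, "pairwise", adjust = "tukey"))
    early <- tuk[tuk$contrast %in% c("day0 - day5", "day5 - day10",
                                     "day0 - day10"), ]
    rows[[paste(sys, type)]] <- tibble::tibble(
      system = sys, colour_type = type,
      day_F = an["day", "F value"], day_p = an["day", "Pr(>F)"],
      size_F = an["size_mm", "F value"], size_p = an["size_mm", "Pr(>F)"],
      early_contrasts_sig = all(early$p.value < 0.05))
    cat(sprintf(
      "%s / %s: day effect F = %.1f (p = %.2g); size p = %.2g; early contrasts all p < 0.05: %s\n",
      sys, type, an["day", "F value"], an["day", "Pr(>F)"],
      an["size_mm", "Pr(>F)"], all(early$p.value < 0.05)))
  }
}
write.csv(bind_rows(rows), "results/colour_change_lmm.csv",
          row.names = FALSE)
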