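#!/usr/bin/env Rscript
# Colour change: green prawns moved onto red dulse and red prawns onto green
# sea lettuce for 30 days. Tracks hue (short-wave catch ratio) and the JND
# against the new substrate per observation day (survivors only; each prawn
# re-paired each day with a random image from the 26-image substrate pool).

suppressPackageStartupMessages({
  library(prawnvision)
  library(dplyr)
})
dir.create("results", showWarnings = FALSE)

cc <- run_colour_change(run_config(seed = 7))
write.csv(cc$hue, "results/colour_change_hue.csv", row.names = FALSE)
write.csv(cc$jnds, "results/colour_change_jnds.csv", row.names = FALSE)
write.csv(cc$hue_summary, "results/colour_change_hue_summary.csv",
          row.names = FALSE)
write.csv(cc$jnd_summary, "results/colour_change_jnd_summary.csv",
          row.names = FALSE)

cat("JND to the new substrate, mean (SE) by day:\n")
print(as.data.frame(arrange(cc$jnd_summary, system, colour_type, day)),
      digits = 3)

for (sys in c("pollack", "goby")) {
  for (type in c("green", "red")) {
    sel <- cc$jnd_summary$system == sys & cc$jnd_summary$colour_type == type
    d <- cc$jnd_summary[sel, ]
    cat(sprintf(
      "%s / %s prawns: JND %.2f (day 0) -> %.2f (day 30); drop in first 10 days %.2f, after %.2f\n",
      sys, type, d$mean[d$day == 0], d$mean[d$day == 30],
      d$mean[d$day == 0] - d$mean[d$day == 10],
      d$mean[d$day == 10] - d$mean[d$day == 30]))
  }
}
hp <- cc$hue_summary[cc$hue_summary$system == "pollack", ]
cat(sprintf(
  "pollack hue: green %.2f -> %.2f (rising), red %.2f -> %.2f (falling): trajectories cross\n",
  hp$mean[hp$colour_type == "green" & hp$day == 0],
  hp$mean[hp$colour_type == "green" & hp$day == 30],
  hp$mean[hp$colour_type == "red" & hp$day == 0],
  hp$mean[hp$colour_type == "red" & hp$day == 30]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  pal <- c(green = "#66bb66", red = "#cc6666")
  p1 <- ggplot(cc$hue_summary, aes(day, mean, colour = colour_type)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = mean - se, ymax = mean + se), width = 1) +
    facet_wrap(~system, scales = "free_y") +
    scale_colour_manual(values = pal) +
    labs(y = "hue (short-wave catch ratio)", x = "day") +
    theme_minimal()
  ggsave("results/colour_change_hue.png", p1, width = 7, height = 4,
         dpi = 150)
  p2 <- ggplot(cc$jnd_summary, aes(day, mean, colour = colour_type)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = mean - se, ymax = mean + se), width = 1) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    facet_wrap(~system) +
    scale_colour_manual(values = pal) +
    labs(y = "JND to new substrate", x = "day") +
    theme_minimal()
  ggsave("results/colour_change_jnds.png", p2, width = 7, height = 4,
         dpi = 150)
  cat("wrote results/colour_change_{hue,jnds}.png\n")
}
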