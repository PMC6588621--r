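# Trajectory trend summaries for colour-change checks. Group means of noisy
# survivor sets cannot be strictly ordered step by step once the kinetics
# saturate, so trends are assessed as rank correlation with day, the overall
# day-30 / day-0 ratio, and front-loading of the change into days 0-10.
trend_stats <- function(days, means) {
  o <- order(days)
  days <- days[o]; means <- means[o]
  list(rho = suppressWarnings(stats::cor(days, means, method = "spearman")),
       ratio_end = means[length(means)] / means[1L],
       drop_first10 = means[1L] - means[days == 10],
       drop_after10 = means[days == 10] - means[length(means)])
}
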