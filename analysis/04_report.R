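#!/usr/bin/env Rscript
# Render figures for the cohort analysis: a full per-observer report
# for the first observer (bias panels, thresholds, additivity scatter,
# NI histogram), plus group-level figures pooling all observers.

suppressPackageStartupMessages({
  library(huememory)
  library(ggplot2)
})

cells <- read.csv("results/independence_cells.csv", stringsAsFactors = FALSE)
if (nrow(cells) == 0) stop("run analysis/03_independence.R first")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

# detailed report for one example observer
first <- sort(list.dirs("results/trials", recursive = FALSE))[1]
tabs <- lapply(list.files(first, pattern = "^trials_.*\\.csv$",
                          full.names = TRUE), read_trials)
report_experiment(analyze_experiment(tabs, quiet = TRUE),
                  file.path("results/figures", basename(first)))

# group additivity scatter (all observers and reference/background pairs)
lim <- max(abs(c(cells$measured_joint_bias, cells$predicted_joint_bias)))
p_sc <- ggplot(cells, aes(predicted_joint_bias, measured_joint_bias,
                          colour = reference_background)) +
  geom_abline(slope = 1, intercept = 0, colour = "grey50") +
  geom_point(alpha = 0.8) +
  coord_equal(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
  labs(x = "predicted joint bias (rad)", y = "measured joint bias (rad)",
       title = "Joint biases fall short of the independence prediction") +
  theme_minimal()
ggsave("results/figures/group_additivity.png", p_sc, width = 5.5, height = 5,
       dpi = 120)

p_ni <- ggplot(cells, aes(non_additivity)) +
  geom_histogram(breaks = seq(-1, 1, 0.1), fill = "seagreen",
                 colour = "white") +
  geom_vline(xintercept = 0, linetype = 2) +
  labs(x = "non-additivity index", y = "observer x cell count",
       title = "Non-additivity across the cohort") +
  theme_minimal()
ggsave("results/figures/group_ni_hist.png", p_ni, width = 5.5, height = 4,
       dpi = 120)

p_cor <- ggplot(cells, aes(joint_threshold, non_additivity)) +
  geom_point() + geom_smooth(method = "lm", se = FALSE, formula = y ~ x) +
  labs(x = "joint threshold (rad)", y = "non-additivity index",
       title = "Less precise joint matches are more subadditive") +
  theme_minimal()
ggsave("results/figures/group_ni_vs_threshold.png", p_cor, width = 5.5,
       height = 4, dpi = 120)

message("figures written to results/figures/")
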