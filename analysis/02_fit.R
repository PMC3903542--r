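#!/usr/bin/env Rscript
# Fit cumulative-normal psychometric functions to every (condition x
# reference x reference background) cell of each simulated observer,
# and derive baseline-subtracted biases and thresholds. Writes per
# observer fit and bias tables under results/fits/.

suppressPackageStartupMessages(library(huememory))

dir.create("results/fits", showWarnings = FALSE, recursive = TRUE)
observers <- list.dirs("results/trials", recursive = FALSE)
if (length(observers) == 0) stop("run analysis/01_simulate.R first")

for (dir in observers) {
  id <- basename(dir)
  files <- list.files(dir, pattern = "^trials_.*\\.csv$", full.names = TRUE)
  tabs <- lapply(files, read_trials)
  a <- analyze_experiment(tabs)
  if (length(a$failures) > 0)
    message(id, ": unfitted cells: ", paste(a$failures, collapse = "; "))
  a$fits$observer <- id
  a$biases$observer <- id
  write.csv(a$fits, file.path("results/fits", paste0(id, "_fits.csv")),
            row.names = FALSE)
  write.csv(a$biases, file.path("results/fits", paste0(id, "_biases.csv")),
            row.names = FALSE)
}
message("fitted ", length(observers), " observers; tables in results/fits/")
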