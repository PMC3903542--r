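#!/usr/bin/env Rscript
# Simulate a cohort of eight synthetic Bayesian observers through the
# full two-phase 2AFC hue experiment (staircase then MOCS, all four
# main conditions). Observers differ moderately in sensory noise,
# memory widening, illuminant-prior width and response criterion, the
# way human observers differ in sensitivity and bias. Writes one trial
# table per observer and condition under results/trials/.

suppressPackageStartupMessages(library(huememory))

base_seed <- 2014L
n_observers <- 8L
out_root <- "results/trials"

set.seed(base_seed)
cohort <- data.frame(
  observer = sprintf("S%d", seq_len(n_observers)),
  sigma_sensory = runif(n_observers, 0.08, 0.12),
  kappa_memory = runif(n_observers, 1.6, 2.4),
  prior_illuminant_sigma = runif(n_observers, 0.12, 0.20),
  response_criterion = rnorm(n_observers, 0, 0.02)
)
write.csv(cohort, "results/cohort.csv", row.names = FALSE)

design <- experiment_design(mocs_repetitions = 150L)
for (i in seq_len(n_observers)) {
  cfg <- pipeline_config(
    observer = observer_params(
      sigma_sensory = cohort$sigma_sensory[i],
      kappa_memory = cohort$kappa_memory[i],
      prior_illuminant_sigma = cohort$prior_illuminant_sigma[i],
      response_criterion = cohort$response_criterion[i]),
    design = design,
    seed = base_seed + i)
  dir <- file.path(out_root, cohort$observer[i])
  simulate_experiment(cfg, dir = dir)
  write_pipeline_config(cfg, file.path(dir, "config.yaml"))
}
message("simulated ", n_observers, " observers into ", out_root)
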