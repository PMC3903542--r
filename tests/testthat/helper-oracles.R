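# Closed-form oracles for the Gaussian observer, derived independently
# from the posterior algebra: at the PSE the expected inferred
# reflectances of reference and test are equal,
#   w_t (t - I_test) + (1 - w_t) mu = w_r (r - I_ref) + (1 - w_r) mu - crit,
# with w = prior^2 / (prior^2 + likelihood^2) and I_* the shrunk
# nominal illuminants. Solving for t gives the expected PSE.
shrink_weight <- function(lik, prior) {
  if (is.infinite(prior)) 1 else prior^2 / (prior^2 + lik^2)
}

oracle_pse <- function(p, r, ref_bg, test_bg, delayed) {
  kap <- if (delayed) p$kappa_memory else 1
  w_r <- shrink_weight(kap * p$sigma_sensory, p$prior_reflectance_sigma)
  w_t <- shrink_weight(p$sigma_sensory, p$prior_reflectance_sigma)
  nominal <- function(bg) if (bg == "blue") p$illuminant_shift_blue else 0
  shrink_illum <- function(bg, k) {
    wi <- shrink_weight(k * p$sigma_sensory, p$prior_illuminant_sigma)
    wi * nominal(bg) + (1 - wi) * p$prior_illuminant_mean
  }
  i_ref <- shrink_illum(ref_bg, kap)
  i_test <- shrink_illum(test_bg, 1)
  mu <- p$prior_reflectance_mean
  (w_r * (r - i_ref) + (1 - w_r) * mu - (1 - w_t) * mu -
     p$response_criterion) / w_t + i_test
}

# A stimulus-free "observer" that answers from a known cumulative
# normal psychometric function of the test hue; used to test the
# experiment engine independently of the Bayesian observer.
pmf_observer <- function(location, spread, lapse = 0) {
  function(reference, test) {
    p <- lapse / 2 + (1 - lapse) * pnorm((test$hue - location) / spread)
    runif(length(test$hue)) < p
  }
}

# Deterministic observer with PSE exactly at the reference hue.
deterministic_observer <- function() {
  function(reference, test) test$hue > reference$hue
}

# Empirical PSE of a simulated observer in one cell: a dense MOCS run
# followed by a psychometric fit.
measure_pse <- function(params, r, ref_bg, test_bg, delayed,
                        center, halfwidth = 0.4, n_levels = 7,
                        repetitions = 2000, seed = 1) {
  cond_bg <- if (ref_bg == test_bg) paste0("symmetric_", ref_bg) else "asymmetric"
  cond <- condition(cond_bg, if (delayed) "delay_2s" else "simultaneous")
  lv <- data.frame(reference_hue = r, reference_background = ref_bg,
                   test_hue = seq(center - halfwidth, center + halfwidth,
                                  length.out = n_levels))
  tr <- run_mocs_block(make_observer(params), cond, lv,
                       repetitions = repetitions, seed = seed)
  fit_pmf(pool_and_bin(tr)[[1]])$location
}

# Small fast design for pipeline-level tests.
fast_design <- function(mocs_repetitions = 10L, ...) {
  experiment_design(mocs_repetitions = mocs_repetitions,
                    second_mocs_pass = FALSE, ...)
}
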