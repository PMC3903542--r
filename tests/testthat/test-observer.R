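test_that("posterior estimate matches the conjugate-Gaussian closed form", {
  # uniform prior: estimate is the signal
  expect_identical(posterior_estimate(0.7, 0.1, 0.0, Inf), 0.7)
  # uninformative signal: estimate is the prior mean
  expect_identical(posterior_estimate(0.7, Inf, 0.3, 0.2), 0.3)
  # equal widths: midpoint weighting
  expect_equal(posterior_estimate(0.5, 1, 0, 1), 0.25)

  # machine-precision agreement with the precision-weighted form
  set.seed(11)
  for (i in 1:50) {
    s <- rnorm(1); sl <- runif(1, 0.01, 2); mu <- rnorm(1); sp <- runif(1, 0.01, 3)
    expected <- (s / sl^2 + mu / sp^2) / (1 / sl^2 + 1 / sp^2)
    est <- posterior_estimate(s, sl, mu, sp)
    expect_equal(est, expected, tolerance = 1e-12)
    # estimate always lies between signal and prior mean
    expect_true(est >= min(s, mu) - 1e-12 && est <= max(s, mu) + 1e-12)
  }
})

test_that("posterior estimate rejects invalid widths", {
  expect_error(posterior_estimate(0, 0, 0, 1), "invalid-parameter")
  expect_error(posterior_estimate(0, -1, 0, 1), "invalid-parameter")
  expect_error(posterior_estimate(0, 1, 0, 0), "invalid-parameter")
})

test_that("observer parameter invariants are enforced", {
  expect_s3_class(observer_params(), "observer_params")
  expect_error(observer_params(sigma_sensory = 0), "sigma_sensory")
  expect_error(observer_params(kappa_memory = 0.5), "kappa_memory")
  expect_error(observer_params(lapse_rate = 0.5), "lapse_rate")
  expect_error(observer_params(prior_reflectance_sigma = -1),
               "prior_reflectance_sigma")
  expect_error(observer_params(sigma_decision = -0.1), "sigma_decision")
  # infinite prior widths are legitimate (uniform priors)
  expect_silent(validate_observer_params(
    observer_params(prior_reflectance_sigma = Inf,
                    prior_illuminant_sigma = Inf)))
})

test_that("identical stimuli on symmetric backgrounds are judged at chance", {
  p <- observer_params(lapse_rate = 0, response_criterion = 0)
  n <- 6000
  ref <- stimulus(rep(3.2, n))
  tst <- stimulus(rep(3.2, n))
  prop <- mean(simulate_response(p, ref, tst, seed = 5))
  expect_gt(prop, 0.5 - 3 * sqrt(0.25 / n) - 0.01)
  expect_lt(prop, 0.5 + 3 * sqrt(0.25 / n) + 0.01)
})

test_that("a noiseless observer orders stimuli deterministically", {
  p <- observer_params(sigma_sensory = 1e-9, sigma_decision = 0,
                       lapse_rate = 0, response_criterion = 0,
                       prior_reflectance_sigma = Inf,
                       prior_illuminant_sigma = Inf)
  ref <- stimulus(rep(3.2, 10))
  above <- stimulus(seq(3.21, 3.5, length.out = 10))
  below <- stimulus(seq(2.9, 3.19, length.out = 10))
  expect_true(all(simulate_response(p, ref, above, seed = 1)))
  expect_false(any(simulate_response(p, ref, below, seed = 1)))
})

test_that("response probability is non-decreasing in test hue", {
  p <- observer_params()
  levels <- seq(2.85, 3.55, length.out = 8)
  n_per <- 2500
  props <- vapply(seq_along(levels), function(i) {
    mean(simulate_response(p, stimulus(rep(3.2, n_per)),
                           stimulus(rep(levels[i], n_per)), seed = 20 + i))
  }, 0)
  se <- sqrt(0.25 / n_per)
  expect_true(all(diff(props) > -3 * se))
  expect_lt(props[1], 0.2)
  expect_gt(props[8], 0.8)
})

test_that("memory-condition PSEs follow the prior-shrinkage law", {
  # Uniform illuminant prior, symmetric gray backgrounds: the PSE of a
  # remembered reference is pulled toward the reflectance prior mean.
  mu <- 3.2
  p <- observer_params(sigma_sensory = 0.1, kappa_memory = 2,
                       prior_reflectance_mean = mu,
                       prior_reflectance_sigma = 0.25,
                       prior_illuminant_sigma = Inf,
                       lapse_rate = 0, sigma_decision = 0.02)
  for (r in c(2.8, 3.6)) {
    expected <- oracle_pse(p, r, "gray", "gray", delayed = TRUE)
    got <- measure_pse(p, r, "gray", "gray", delayed = TRUE,
                       center = expected, repetitions = 3000,
                       seed = round(r * 10))
    expect_equal(got, expected, tolerance = 0.02)
    # shrinkage is toward the prior mean, strictly between r and mu
    expect_true((expected - r) * (mu - r) > 0)
    expect_lt(abs(expected - mu), abs(r - mu))
  }
  # with a precise test stimulus the simplified law w*r + (1-w)*mu,
  # w = prior^2 / (prior^2 + (kappa*sigma)^2), holds directly
  p2 <- observer_params(sigma_sensory = 0.01, kappa_memory = 20,
                        prior_reflectance_mean = mu,
                        prior_reflectance_sigma = 0.25,
                        prior_illuminant_sigma = Inf,
                        lapse_rate = 0, sigma_decision = 0.01)
  w <- 0.25^2 / (0.25^2 + (20 * 0.01)^2)
  r <- 2.9
  expect_equal(oracle_pse(p2, r, "gray", "gray", TRUE),
               w * r + (1 - w) * mu, tolerance = 1e-4)
})

test_that("asymmetric backgrounds bias matches in opposite directions", {
  # Strong illuminant likelihood: reference on gray shifts the match
  # up (bluer test needed), reference on blue shifts it down, with
  # comparable magnitude.
  p <- observer_params(lapse_rate = 0, prior_reflectance_sigma = Inf,
                       prior_illuminant_sigma = 0.5,
                       prior_illuminant_mean = 0.075)
  r <- 3.2
  up <- measure_pse(p, r, "gray", "blue", FALSE, center = r + 0.13, seed = 31)
  down <- measure_pse(p, r, "blue", "gray", FALSE, center = r - 0.13, seed = 32)
  expect_gt(up - r, 0.05)
  expect_lt(down - r, -0.05)
  expect_lt(abs((up - r) + (down - r)), 0.04)
})

test_that("uniform priors leave every condition except constancy unbiased", {
  p <- observer_params(prior_reflectance_sigma = Inf,
                       prior_illuminant_sigma = Inf,
                       kappa_memory = 2, lapse_rate = 0)
  r <- 2.9
  for (case in list(list("gray", "gray", FALSE), list("blue", "blue", FALSE),
                    list("gray", "gray", TRUE), list("blue", "blue", TRUE))) {
    got <- measure_pse(p, r, case[[1]], case[[2]], case[[3]],
                       center = r, seed = 40)
    expect_equal(got, r, tolerance = 0.02)
  }
  # constancy: full compensation by the nominal illuminant difference
  got <- measure_pse(p, r, "gray", "blue", FALSE,
                     center = r + p$illuminant_shift_blue, seed = 41)
  expect_equal(got, r + p$illuminant_shift_blue, tolerance = 0.02)
})

test_that("dataset generation is deterministic and covers the design", {
  p <- observer_params()
  d <- fast_design()
  t1 <- generate_dataset(p, d, seed = 9)
  t2 <- generate_dataset(p, d, seed = 9)
  expect_identical(t1, t2)
  t3 <- generate_dataset(p, d, seed = 10)
  expect_false(identical(t1, t3))

  # every condition x reference x reference-background cell is present
  cells <- unique(t1[, c("condition", "reference_hue", "reference_background")])
  expect_equal(nrow(cells), 4 * 3 * 2)
  # staircase phase counts: 240 per uniform block, 480 per asymmetric
  sc <- t1[t1$phase == "staircase", ]
  counts <- table(sc$condition)
  # baseline/memory: two uniform blocks of 240; constancy/joint: one of 480
  expect_equal(as.vector(counts[c("baseline", "memory")]), c(480L, 480L))
  expect_equal(as.vector(counts[c("constancy", "joint")]), c(480L, 480L))
})

test_that("degenerate designs and parameters are rejected", {
  expect_error(experiment_design(conditions = character(0)), "empty design")
  expect_error(experiment_design(reference_hues = c(1, 2)), "three reference")
  expect_error(generate_dataset(observer_params(), list(), 1),
               "experiment_design")
})
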