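test_that("joint predictions interpolate the constancy mapping", {
  r <- c(0, 1, 2)
  cm <- c(0.2, 1.1, 2.4)
  # hand-evaluated piecewise-linear oracle
  expect_equal(predict_joint(r, cm, c(0.5, 1.0, 1.5)), c(0.65, 1.1, 1.75))
  # identity memory: prediction reproduces the constancy matches
  expect_equal(predict_joint(r, cm, r), cm)
  # affine constancy (constant bias): prediction is m + 0.3 for any m
  expect_equal(predict_joint(r, r + 0.3, c(0.1, 0.9, 1.7)),
               c(0.1, 0.9, 1.7) + 0.3)
  expect_error(predict_joint(c(0, 0, 1), cm, r), "duplicate")
})

test_that("joint prediction is exact for affine constancy, any memory", {
  set.seed(17)
  for (i in 1:25) {
    r <- sort(rnorm(3, 3, 0.5))
    a <- rnorm(1, 1, 0.2); b <- rnorm(1, 0, 0.3)
    m <- r[1] + (r[3] - r[1]) * sort(runif(3))  # inside the node range
    expect_equal(predict_joint(r, a * r + b, m), a * m + b,
                 tolerance = 1e-10)
  }
})

test_that("extrapolation warns past 4% of the range and stops past 10%", {
  r <- c(0, 1, 2); cm <- c(0.1, 1.0, 2.1)
  expect_silent(predict_joint(r, cm, c(2.05)))          # 2.5 % out
  expect_warning(predict_joint(r, cm, c(-0.12)), "extrapolating")  # 6 %
  expect_error(predict_joint(r, cm, c(2.3)), "refusing")           # 15 %
})

test_that("non-additivity index has the stated bounds and semantics", {
  expect_equal(non_additivity_index(0.4, 0.4), 0)
  expect_equal(non_additivity_index(0, 0.4), -1)
  expect_equal(non_additivity_index(0.4, 0), 1)
  # 42% of the predicted bias: NI = (0.42 - 1) / (0.42 + 1)
  expect_equal(non_additivity_index(0.42 * 0.3, 0.3), (0.42 - 1) / 1.42,
               tolerance = 1e-12)
  expect_error(non_additivity_index(0, 0), "undefined")
  # antisymmetry under swapping measured and predicted; bounds
  set.seed(23)
  m <- rnorm(100); p <- rnorm(100)
  ni <- non_additivity_index(m, p)
  expect_true(all(ni >= -1 & ni <= 1))
  expect_equal(non_additivity_index(p, m), -ni)
  # zero iff equal magnitudes
  expect_equal(non_additivity_index(-0.2, 0.2), 0)
})

test_that("central-tendency slope is the OLS slope of bias on reference", {
  expect_equal(central_tendency_slope(c(0.1, 0.1, 0.1), c(0, 1, 2)), 0)
  d <- 0.07
  expect_equal(central_tendency_slope(c(d, 0, -d), c(0, 1, 2)), -d)
  # agreement with lm() on noisy data
  set.seed(3)
  x <- c(2.8, 3.2, 3.6); y <- -0.1 * x + rnorm(3, 0, 0.01)
  expect_equal(central_tendency_slope(y, x),
               unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  expect_error(central_tendency_slope(c(1, 2), c(3, 3)), "distinct")
})

test_that("one-tailed sign tests match binomial enumeration", {
  expect_equal(sign_test_one_tailed(rep(-1, 7), "negative"), 0.5^7)
  expect_equal(sign_test_one_tailed(rep(1, 5), "negative"), 1.0)
  # 4 of 6 negative: (C(6,4) + C(6,5) + C(6,6)) / 2^6
  expect_equal(sign_test_one_tailed(c(-1, -2, -3, -4, 1, 2), "negative"),
               (choose(6, 4) + choose(6, 5) + choose(6, 6)) / 2^6)
  expect_equal(sign_test_one_tailed(c(-1, -2, -3, -4, 1, 2), "negative"),
               0.34375)
  # ties are dropped before counting
  expect_equal(sign_test_one_tailed(c(-1, 0, 0), "negative"), 0.5)
  expect_error(sign_test_one_tailed(c(0, 0), "negative"), "ties")
  expect_error(sign_test_one_tailed(numeric(0), "negative"), "non-empty")
})

test_that("bias-threshold correlations behave like Pearson's r", {
  x <- c(1, 2, 3, 4); y <- 2 * x
  expect_equal(bias_threshold_correlation(x, y)$r, 1, tolerance = 1e-12)
  expect_error(bias_threshold_correlation(x, rep(1, 4)), "zero variance")
  # hand-computed zero correlation
  out <- bias_threshold_correlation(c(0, 1, 2), c(0, 1, 0))
  expect_equal(out$r, 0, tolerance = 1e-12)
  # outlier exclusion is logged, not silent
  expect_message(
    res <- bias_threshold_correlation(c(1, 2, 3, 4, 100), c(1, 2, 3, 4, -50),
                                      exclude = 5,
                                      exclude_reason = "threshold outlier"),
    "threshold outlier")
  expect_equal(res$n, 4)
  expect_equal(res$r, 1, tolerance = 1e-12)
})

test_that("a uniform-prior observer is additive through the full pipeline", {
  p <- observer_params(prior_reflectance_sigma = Inf,
                       prior_illuminant_sigma = Inf, kappa_memory = 2)
  trials <- generate_dataset(p, fast_design(mocs_repetitions = 80), seed = 29)
  a <- analyze_experiment(trials, quiet = TRUE)
  expect_false(is.null(a$independence))
  # with uniform priors the memory bias is zero and the prediction
  # equals the constancy bias, so NI scatters around zero
  expect_lt(abs(a$independence$summary$mean_ni), 0.08)
  expect_gt(a$independence$summary$subadditivity_ratio, 0.85)
  expect_lt(a$independence$summary$subadditivity_ratio, 1.15)
})

test_that("finite priors with memory widening produce subadditivity", {
  trials <- generate_dataset(observer_params(),
                             fast_design(mocs_repetitions = 80), seed = 37)
  a <- analyze_experiment(trials, quiet = TRUE)
  s <- a$independence$summary
  expect_lt(s$mean_ni, 0)
  expect_lt(s$subadditivity_ratio, 1)
  expect_lt(mean(s$memory_slope), 0)
})
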