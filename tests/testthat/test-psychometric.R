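make_binned <- function(x, n, k, cell = NULL) {
  structure(list(test_hues = x, n_trials = n, n_test_bluer = k, cell = cell),
            class = "binned_responses")
}

test_that("pooling and binning conserve trials across phases", {
  obs <- pmf_observer(3.2, 0.15)
  cond <- condition("symmetric_gray", "simultaneous")
  sc <- run_staircase_block(obs, cond, c(2.8, 3.2, 3.6), seed = 6,
                            condition_name = "baseline")
  lv <- data.frame(reference_hue = rep(c(2.8, 3.2, 3.6), each = 5),
                   reference_background = "gray",
                   test_hue = as.vector(vapply(c(2.8, 3.2, 3.6), function(r)
                     seq(r - 0.2, r + 0.2, length.out = 5), numeric(5))))
  mocs <- run_mocs_block(obs, cond, lv, repetitions = 10, seed = 7,
                         condition_name = "baseline")
  pooled <- rbind(sc, mocs)
  bins <- pool_and_bin(pooled)
  expect_length(bins, 3)
  expect_equal(sum(vapply(bins, function(b) sum(b$n_trials), 0)), nrow(pooled))
  for (b in bins) {
    expect_true(all(diff(b$test_hues) > 0))
    expect_true(all(b$n_test_bluer >= 0 & b$n_test_bluer <= b$n_trials))
  }
  # trials from both phases sharing a hue are summed into one bin
  one <- pool_and_bin(pooled, cell = list(condition = "baseline",
                                          reference_hue = 3.2,
                                          reference_background = "gray"))
  expect_equal(sum(one$n_trials),
               sum(pooled$reference_hue == 3.2))
  expect_error(pool_and_bin(pooled, cell = list(condition = "memory",
                                                reference_hue = 3.2,
                                                reference_background = "gray")),
               "empty cell")
})

test_that("the fit recovers parameters of a known generator", {
  loc <- 0.5; spread <- 0.2
  x <- loc + spread * qnorm(seq(0.05, 0.95, length.out = 7))
  set.seed(13)
  k <- rbinom(7, 500, pnorm((x - loc) / spread))
  fit <- fit_pmf(make_binned(x, rep(500L, 7), k))
  expect_true(fit$converged)
  expect_lt(abs(fit$location - loc), 0.02)
  expect_lt(abs(fit$spread - spread), 0.03)
  expect_lt(fit$lapse, 0.05 + 1e-9)
})

test_that("mirror-symmetric responses put the location at the mirror point", {
  x <- c(-2, -1, 0, 1, 2) + 0.7
  n <- rep(60L, 5)
  k <- c(3L, 15L, 30L, 45L, 57L)  # k[i] + k[6-i] = n: exactly symmetric
  fit <- fit_pmf(make_binned(x, n, k))
  expect_equal(fit$location, 0.7, tolerance = 1e-4)
})

test_that("the optimizer beats a brute-force grid on the same likelihood", {
  # independent brute-force oracle at lapse 0
  x <- seq(-1, 1, length.out = 6)
  set.seed(21)
  k <- rbinom(6, 80, pnorm((x - 0.1) / 0.4))
  n <- rep(80L, 6)
  nll <- function(loc, spread) {
    p <- pmin(pmax(pnorm((x - loc) / spread), 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  grid <- expand.grid(loc = seq(-0.5, 0.7, by = 0.02),
                      spread = seq(0.1, 1, by = 0.02))
  grid$nll <- mapply(nll, grid$loc, grid$spread)
  best <- grid[which.min(grid$nll), ]
  fit <- fit_pmf(make_binned(x, n, k))
  # likelihood at the optimum is at least as good as every grid point
  expect_lte(-fit$log_likelihood, min(grid$nll) + 0.05)
  expect_equal(fit$location, best$loc, tolerance = 0.03)
  expect_equal(fit$spread, best$spread, tolerance = 0.04)
})

test_that("fits are translation-equivariant in hue", {
  x <- seq(2.9, 3.5, length.out = 6)
  set.seed(31)
  k <- rbinom(6, 120, pnorm((x - 3.2) / 0.15))
  f0 <- fit_pmf(make_binned(x, rep(120L, 6), k))
  f1 <- fit_pmf(make_binned(x + 5, rep(120L, 6), k))
  expect_equal(f1$location - f0$location, 5, tolerance = 1e-3)
  expect_equal(f1$spread, f0$spread, tolerance = 1e-3)
})

test_that("unidentifiable or degenerate inputs are refused", {
  expect_error(fit_pmf(make_binned(c(1, 2), c(10L, 10L), c(2L, 8L))),
               ">= 3 distinct")
  expect_error(fit_pmf(make_binned(1:5, rep(10L, 5), rep(10L, 5))),
               "non-identifiable")
  expect_error(fit_pmf(make_binned(1:5, rep(10L, 5), rep(0L, 5))),
               "non-identifiable")
})

test_that("PSE and threshold follow the underlying-normal convention", {
  fit <- structure(list(location = 0.9, spread = 0.2, lapse = 0.04,
                        converged = TRUE, cell = NULL), class = "pmf_fit")
  expect_equal(pse(fit), 0.9)               # lapse does not move the PSE
  expect_equal(threshold(fit), 0.2 * qnorm(0.75))
  expect_equal(threshold(fit), 0.1348979, tolerance = 1e-6)
  expect_equal(precision(fit), 1 / threshold(fit))
  fit$spread <- 0.4                          # doubling spread doubles threshold
  expect_equal(threshold(fit), 2 * 0.1348979, tolerance = 1e-6)
  fit$converged <- FALSE
  expect_error(pse(fit), "converge")
  expect_error(threshold(fit), "converge")
})

test_that("bias subtracts the baseline and checks the cell", {
  cell <- list(condition = "memory", reference_hue = 3.2,
               reference_background = "gray")
  base_cell <- list(condition = "baseline", reference_hue = 3.2,
                    reference_background = "gray")
  f <- structure(list(location = 1.1, spread = 0.2, lapse = 0,
                      converged = TRUE, cell = cell), class = "pmf_fit")
  b <- structure(list(location = 1.0, spread = 0.2, lapse = 0,
                      converged = TRUE, cell = base_cell), class = "pmf_fit")
  expect_equal(bias(f, b), 0.1)
  expect_equal(bias(b, b), 0)
  wrong <- b; wrong$cell$reference_background <- "blue"
  expect_error(bias(f, wrong), "cell mismatch")
})

test_that("a constant response criterion cancels in baseline-subtracted bias", {
  # observer with a response bias but no memory or context machinery
  # (no illuminant difference between backgrounds): biases relative to
  # baseline vanish in every condition
  p <- observer_params(prior_reflectance_sigma = Inf,
                       prior_illuminant_sigma = Inf, kappa_memory = 1,
                       illuminant_shift_blue = 0,
                       response_criterion = 0.08, lapse_rate = 0)
  trials <- generate_dataset(p, fast_design(mocs_repetitions = 150), seed = 15)
  a <- analyze_experiment(trials, quiet = TRUE)
  # raw PSEs are shifted away from the references by the criterion
  # (a positive criterion favors "test bluer", so a yellower test
  # already matches: PSE below the reference)
  base <- a$fits[a$fits$condition == "baseline", ]
  expect_lt(mean(base$location - base$reference_hue), -0.03)
  non_base <- a$biases[a$biases$condition != "baseline", ]
  expect_lt(max(abs(non_base$bias)), 0.045)
})

test_that("parameter recovery holds over many simulated datasets", {
  loc <- 3.2; spread <- 0.18
  x <- loc + spread * qnorm(seq(0.08, 0.92, length.out = 5))
  set.seed(99)
  errs <- replicate(60, {
    k <- rbinom(5, 150, pnorm((x - loc) / spread))
    f <- tryCatch(fit_pmf(make_binned(x, rep(150L, 5), k)),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$location - loc
  })
  expect_lt(median(abs(errs), na.rm = TRUE), 0.15 * spread)
  expect_lt(mean(is.na(errs)), 0.05)
})
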