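#' Select method-of-constant-stimuli test levels from a staircase fit
#'
#' The staircase-phase psychometric fit determines the MOCS range: the
#' endpoints are the test hues at roughly 0 and 100% selection
#' probability, operationalized as the 1st and 99th percentiles of the
#' fitted cumulative normal, and `n_levels` levels are spaced evenly
#' between them.
#'
#' @param fit A [fit_pmf()] result (or any list with finite `location`
#'   and positive `spread`).
#' @param n_levels Number of levels (default 5).
#' @param p_range Probabilities defining the endpoints (default
#'   `c(0.01, 0.99)`).
#' @return Strictly increasing numeric vector of test hues (radians).
#' @examples
#' select_mocs_levels(list(location = 0, spread = 1))
#' @export
select_mocs_levels <- function(fit, n_levels = 5L, p_range = c(0.01, 0.99)) {
  if (!is.finite(fit$location) || !is.finite(fit$spread) || fit$spread <= 0)
    stop("degenerate fit: spread must be finite and > 0")
  endpoints <- fit$location + fit$spread * stats::qnorm(p_range)
  seq(endpoints[1], endpoints[2], length.out = n_levels)
}

#' Run a method-of-constant-stimuli block
#'
#' Presents every (reference x reference-background x test level) cell
#' exactly `repetitions` times in an order randomized by `seed`, with
#' references and (in asymmetric blocks) both reference-background
#' assignments interleaved. Responses for all trials of a block are
#' drawn in one vectorized observer call, in presentation order.
#'
#' @param observer Response-generating function `f(reference, test)`.
#' @param cond A [condition()].
#' @param levels_table Data frame with columns `reference_hue`,
#'   `reference_background`, `test_hue`: the MOCS levels of every cell
#'   of this block (typically 5 rows per cell, from
#'   [select_mocs_levels()]).
#' @param repetitions Trials per cell level (default 10).
#' @param seed Integer seed.
#' @param condition_name Label written to the trial table.
#' @return A trial table in presentation order.
#' @export
run_mocs_block <- function(observer, cond, levels_table, repetitions = 10L,
                           seed = NULL,
                           condition_name = cond$background_symmetry) {
  if (repetitions < 1L) stop("repetitions must be >= 1")
  need <- c("reference_hue", "reference_background", "test_hue")
  if (!all(need %in% names(levels_table)))
    stop("levels_table must have columns ", paste(need, collapse = ", "))
  if (!all(levels_table$reference_background %in% reference_background_set(cond)))
    stop("levels_table contains a reference background not in this block")
  with_seed(seed, {
    idx <- rep(seq_len(nrow(levels_table)), times = repetitions)
    idx <- sample(idx)
    ref_hue <- levels_table$reference_hue[idx]
    ref_bg <- levels_table$reference_background[idx]
    test_hue <- levels_table$test_hue[idx]
    delayed <- cond$delay == "delay_2s"
    ref <- stimulus(ref_hue, ref_bg, interval = "first", remembered = delayed)
    tst <- stimulus(test_hue,
                    vapply(ref_bg, function(b) test_background_for(cond, b), ""),
                    interval = "second")
    response <- observer(ref, tst)
    build_trials(condition_name, cond,
                 reference_hue = ref_hue, test_hue = test_hue,
                 reference_background = ref_bg,
                 reference_side = reference_side_for(cond, ref_bg),
                 phase = "mocs", response = response, seed = seed %||% NA_integer_)
  })
}

#' Does a MOCS run need a range adjustment?
#'
#' After a complete MOCS run, the level range is adjusted and another
#' round of repetitions collected when the extreme levels did not pin
#' down the asymptotes: the trigger is any observed proportion at the
#' lowest or highest level falling strictly inside (0.25, 0.75).
#'
#' @param binned A `binned_responses` object (see [pool_and_bin()]).
#' @return Logical.
#' @export
mocs_needs_adjustment <- function(binned) {
  k <- length(binned$test_hues)
  if (k < 2L) return(TRUE)
  p <- binned$n_test_bluer[c(1L, k)] / binned$n_trials[c(1L, k)]
  any(p > 0.25 & p < 0.75)
}

#' Sample distractor hues for one trial
#'
#' Distractors shown during the retention interval are drawn from a
#' normal distribution centered 0.2 radians (about 1.5 average
#' just-noticeable differences) below the trial's reference hue, i.e.
#' toward yellower-appearing hues.
#'
#' @param reference_hue Reference hue of the trial (radians).
#' @param sd Standard deviation of the distractor distribution
#'   (radians, >= 0).
#' @param n Number of distractors (default 2: one at each stimulus
#'   location).
#' @param offset Mean offset below the reference (default 0.2 radians).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` distractor hues.
#' @examples
#' sample_distractors(1.0, sd = 0)  # both exactly 0.8
#' @export
sample_distractors <- function(reference_hue, sd, n = 2L, offset = 0.2,
                               seed = NULL) {
  if (sd < 0) stop("distractor sd must be >= 0")
  with_seed(seed, stats::rnorm(n, mean = reference_hue - offset, sd = sd))
}
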