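#' Initialize a weighted up-down staircase
#'
#' The staircase targets the 20th or 80th percentile of the
#' psychometric function with a Kaernbach-style weighted up-down rule:
#' after each response the test level moves against the response
#' direction, and the two step sizes are in a 4:1 ratio chosen so that
#' the asymptotic convergence point is the target percentile (the
#' equilibrium satisfies p * step_down = (1 - p) * step_up, so
#' p = step_up / (step_up + step_down)). Steps start at 3x the final
#' step size and are halved at each of the first two reversals
#' (flooring at the final size), a standard burn-in acceleration.
#'
#' @param target_percentile 0.2 or 0.8; the probability of "test
#'   bluer" tracked by this staircase.
#' @param start_level Initial test hue (radians).
#' @param final_step Final (smallest) base step size, radians.
#' @param max_trials Number of trials this staircase runs (default 20).
#' @return A `staircase_state` object.
#' @export
staircase_init <- function(target_percentile, start_level,
                           final_step = 0.05, max_trials = 20L) {
  if (!target_percentile %in% c(0.2, 0.8))
    stop("target_percentile must be 0.2 or 0.8")
  if (final_step <= 0) stop("final_step must be > 0")
  structure(list(target_percentile = target_percentile,
                 current_level = start_level,
                 final_step = final_step,
                 step_ratio = 4,
                 trials_completed = 0L,
                 max_trials = as.integer(max_trials),
                 reversal_levels = numeric(0),
                 last_move = 0),
            class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' Applies the weighted up-down rule: a "test bluer" response lowers
#' the level, a "reference bluer" response raises it. For the 0.8
#' target the up step is 4x the down step (so the level settles where
#' P(test bluer) = 0.8); for the 0.2 target the ratio is inverted. A
#' reversal is recorded, at the pre-update level, whenever the movement
#' direction flips; the step scale is 3x the final step before the
#' first reversal, 1.5x after it, and 1x from the second reversal on.
#'
#' @param state A `staircase_state` from [staircase_init()].
#' @param response_test_bluer Logical response of the current trial.
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, response_test_bluer) {
  if (!inherits(state, "staircase_state")) stop("not a staircase_state")
  if (state$trials_completed >= state$max_trials)
    stop("staircase exhausted: all ", state$max_trials, " trials completed")
  scale <- c(3, 1.5, 1)[min(length(state$reversal_levels), 2L) + 1L]
  step <- state$final_step * scale
  if (state$target_percentile == 0.8) {
    step_down <- step
    step_up <- state$step_ratio * step
  } else {
    step_down <- state$step_ratio * step
    step_up <- step
  }
  move <- if (isTRUE(response_test_bluer)) -step_down else step_up
  direction <- sign(move)
  if (state$last_move != 0 && direction != state$last_move)
    state$reversal_levels <- c(state$reversal_levels, state$current_level)
  state$current_level <- state$current_level + move
  state$last_move <- direction
  state$trials_completed <- state$trials_completed + 1L
  state
}

#' Run the interleaved staircase phase of one block
#'
#' Reproduces the first data-collection phase: four interleaved
#' staircases per reference-by-background cell (20%/80% targets crossed
#' with starting points above/below the reference hue), 20 trials
#' each. Staircases for the three references and, in asymmetric
#' blocks, for the two reference-background assignments are interleaved
#' in an order randomized by `seed`. A uniform-background block
#' therefore emits 3 x 4 x 20 = 240 trials and an asymmetric block 480.
#' In delay conditions the reference is always the first, remembered
#' interval.
#'
#' @param observer A response-generating function `f(reference, test)`
#'   returning logicals, e.g. from [make_observer()].
#' @param cond A [condition()].
#' @param reference_hues Exactly three reference hues (radians).
#' @param seed Integer seed for the interleaving order and the
#'   observer's responses.
#' @param final_step Final staircase step size (radians).
#' @param start_offset Distance (radians) of staircase starting points
#'   above/below the reference hue.
#' @param n_trials Trials per staircase (default 20).
#' @param condition_name Label written to the trial table.
#' @return A trial table (see [empty_trials()]) with one row per trial,
#'   in presentation order, with `staircase_id` identifying the
#'   staircase each trial belonged to.
#' @export
run_staircase_block <- function(observer, cond, reference_hues, seed,
                                final_step = 0.05, start_offset = 0.25,
                                n_trials = 20L,
                                condition_name = cond$background_symmetry) {
  if (length(reference_hues) != 3L)
    stop("exactly 3 reference hues are required, got ", length(reference_hues))
  if (!is.function(observer)) stop("observer must be a function")
  backgrounds <- reference_background_set(cond)

  with_seed(seed, {
    # One staircase per (reference background x reference x target x start).
    grid <- expand.grid(start = c(-start_offset, start_offset),
                        target = c(0.2, 0.8),
                        reference_hue = reference_hues,
                        reference_background = backgrounds,
                        stringsAsFactors = FALSE)
    states <- lapply(seq_len(nrow(grid)), function(i)
      staircase_init(grid$target[i], grid$reference_hue[i] + grid$start[i],
                     final_step = final_step, max_trials = n_trials))
    order_ids <- sample(rep(seq_len(nrow(grid)), each = n_trials))

    n_total <- length(order_ids)
    ref_bg <- grid$reference_background[order_ids]
    ref_hue <- grid$reference_hue[order_ids]
    test_hue <- numeric(n_total)
    response <- logical(n_total)
    delayed <- cond$delay == "delay_2s"
    for (t in seq_len(n_total)) {
      id <- order_ids[t]
      lvl <- states[[id]]$current_level
      ref <- stimulus(ref_hue[t], ref_bg[t],
                      interval = "first", remembered = delayed)
      tst <- stimulus(lvl, test_background_for(cond, ref_bg[t]),
                      interval = "second")
      resp <- observer(ref, tst)
      states[[id]] <- staircase_update(states[[id]], resp)
      test_hue[t] <- lvl
      response[t] <- resp
    }
    build_trials(condition_name, cond,
                 reference_hue = ref_hue, test_hue = test_hue,
                 reference_background = ref_bg,
                 reference_side = reference_side_for(cond, ref_bg, n_total),
                 phase = "staircase", staircase_id = order_ids,
                 response = response, seed = seed)
  })
}
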