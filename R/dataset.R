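#' Describe an experiment design
#'
#' Collects the structural settings of the two-phase procedure: which
#' of the six blocked conditions to run, the three reference hues, the
#' staircase-phase geometry, and the MOCS-phase level count and
#' repetitions. The defaults mirror the study conditions: three
#' greenish reference hues on the equiluminant CIELAB hue circle
#' (yellowish-green, green, bluish-green), four 20-trial staircases per
#' cell, five MOCS levels repeated 10 times, and an optional second
#' MOCS pass after range adjustment.
#'
#' @param conditions Character subset of `"baseline"`, `"constancy"`,
#'   `"memory"`, `"joint"`, `"memory_distractor"`,
#'   `"joint_distractor"`.
#' @param reference_hues Exactly three reference hues (radians).
#' @param staircase_trials Trials per staircase (default 20).
#' @param final_step Final staircase step (radians).
#' @param start_offset Staircase starting offset from the reference
#'   (radians).
#' @param mocs_levels Number of MOCS test levels per cell (default 5).
#' @param mocs_repetitions Repetitions per level and cell (default 10).
#' @param second_mocs_pass Run a second round of repetitions with an
#'   adjusted range when the first run leaves an extreme-level
#'   proportion inside (0.25, 0.75)?
#' @param distractor_sd SD of the distractor hue distribution
#'   (radians).
#' @param distractor_offset Mean distractor offset below the reference
#'   (radians, default 0.2, about 1.5 average JNDs).
#' @param distractor_prior_weight Weight with which the distractor
#'   distribution mean pulls the observer's reflectance prior in
#'   distractor blocks (0 = no effect, 1 = prior centered on the
#'   distractor mean).
#' @param block_priors Recenter the observer's priors on block
#'   statistics (default `TRUE`)? Priors are updated once per block:
#'   the reflectance prior to the block's mean reference hue, the
#'   illuminant prior to the mean nominal illuminant of the block's
#'   backgrounds. With `FALSE` the priors stay where
#'   [observer_params()] put them for every block.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(conditions = c("baseline", "constancy",
                                             "memory", "joint"),
                              reference_hues = c(2.8, 3.2, 3.6),
                              staircase_trials = 20L,
                              final_step = 0.05,
                              start_offset = 0.25,
                              mocs_levels = 5L,
                              mocs_repetitions = 10L,
                              second_mocs_pass = TRUE,
                              distractor_sd = 0.1,
                              distractor_offset = 0.2,
                              distractor_prior_weight = 0.5,
                              block_priors = TRUE) {
  if (length(conditions) == 0) stop("empty design: no conditions requested")
  bad <- setdiff(conditions, condition_names())
  if (length(bad) > 0) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (length(reference_hues) != 3L)
    stop("exactly three reference hues are required")
  if (any(diff(sort(reference_hues)) <= 0)) stop("reference hues must be distinct")
  structure(list(conditions = conditions,
                 reference_hues = sort(as.numeric(reference_hues)),
                 staircase_trials = as.integer(staircase_trials),
                 final_step = final_step,
                 start_offset = start_offset,
                 mocs_levels = as.integer(mocs_levels),
                 mocs_repetitions = as.integer(mocs_repetitions),
                 second_mocs_pass = isTRUE(second_mocs_pass),
                 distractor_sd = distractor_sd,
                 distractor_offset = distractor_offset,
                 distractor_prior_weight = distractor_prior_weight,
                 block_priors = isTRUE(block_priors)),
            class = "experiment_design")
}

# Observer parameters as seen in a given block. Priors update to block
# statistics (block-constant): the reflectance prior centers on the
# mean reference hue of the block, and the illuminant prior on the
# mean nominal illuminant of the block's backgrounds (0 in uniform
# gray blocks, illuminant_shift_blue in uniform blue blocks, the
# midpoint in asymmetric blocks). Distractor blocks additionally pull
# the reflectance prior toward the distractor distribution mean
# (block mean reference minus the distractor offset). This block-level
# prior updating is what breaks additivity between memory and context:
# only in asymmetric blocks does the remembered background's
# illuminant estimate shrink toward a prior that lies between the two
# backgrounds.
effective_block_params <- function(params, design, cond) {
  if (design$block_priors && is.finite(params$prior_reflectance_sigma))
    params$prior_reflectance_mean <- mean(design$reference_hues)
  if (cond$distractors == "present" &&
      is.finite(params$prior_reflectance_sigma)) {
    target <- mean(design$reference_hues) - design$distractor_offset
    w <- design$distractor_prior_weight
    params$prior_reflectance_mean <-
      (1 - w) * params$prior_reflectance_mean + w * target
  }
  if (design$block_priors && is.finite(params$prior_illuminant_sigma)) {
    params$prior_illuminant_mean <- switch(
      cond$background_symmetry,
      symmetric_gray = 0,
      symmetric_blue = params$illuminant_shift_blue,
      asymmetric = params$illuminant_shift_blue / 2)
  }
  params
}

# Location/spread guess from staircase levels alone, used when the
# staircase-phase fit of a cell fails; the second half of the levels
# has burnt in toward the 20%/80% percentiles.
fallback_range_fit <- function(sub) {
  lv <- sub$test_hue
  lv <- lv[seq(ceiling(length(lv) / 2), length(lv))]
  list(location = mean(lv), spread = max(stats::sd(lv), 1e-3))
}

#' Generate a complete synthetic dataset
#'
#' Runs the full two-phase procedure for every requested condition
#' with a simulated Bayesian observer: the interleaved staircase phase,
#' a cumulative-normal fit of the staircase data per cell, selection of
#' MOCS levels from those fits, the MOCS phase, and (optionally) a
#' second MOCS pass with an adjusted range for cells whose extreme
#' levels failed to pin down the asymptotes. Symmetric-background
#' conditions comprise one uniform-gray and one uniform-blue block;
#' asymmetric conditions one block with both reference backgrounds
#' interleaved. In distractor blocks the observer's reflectance prior
#' is pulled toward the distractor distribution mean. Deterministic
#' given `seed`: per-block child seeds are derived from it and recorded
#' in the trial table.
#'
#' @param params An [observer_params()] object.
#' @param design An [experiment_design()] object.
#' @param seed Integer seed for the whole dataset.
#' @return A trial table covering all requested condition x reference
#'   x reference-background cells, both phases pooled.
#' @export
generate_dataset <- function(params, design, seed) {
  validate_observer_params(params)
  if (!inherits(design, "experiment_design"))
    stop("design must be an experiment_design object")
  if (length(design$conditions) == 0) stop("empty design")
  out <- list()
  block_idx <- 0L
  for (name in design$conditions) {
    for (cond in condition_blocks(name)) {
      block_idx <- block_idx + 1L
      block_params <- effective_block_params(params, design, cond)
      observer <- make_observer(block_params)
      sc_seed <- child_seed(seed, block_idx * 10L)
      sc <- run_staircase_block(observer, cond, design$reference_hues,
                                seed = sc_seed,
                                final_step = design$final_step,
                                start_offset = design$start_offset,
                                n_trials = design$staircase_trials,
                                condition_name = name)
      levels_table <- staircase_levels_table(sc, design)
      mocs_seed <- child_seed(seed, block_idx * 10L + 1L)
      mocs <- run_mocs_block(observer, cond, levels_table,
                             repetitions = design$mocs_repetitions,
                             seed = mocs_seed, condition_name = name)
      block <- rbind(sc, mocs)
      if (design$second_mocs_pass) {
        adj <- adjusted_levels_table(block, levels_table)
        if (nrow(adj) > 0) {
          mocs2 <- run_mocs_block(observer, cond, adj,
                                  repetitions = design$mocs_repetitions,
                                  seed = child_seed(seed, block_idx * 10L + 2L),
                                  condition_name = name)
          block <- rbind(block, mocs2)
        }
      }
      out[[block_idx]] <- block
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Fit each staircase cell and derive its MOCS levels; falls back to a
# range guess from the raw staircase levels when a fit fails.
staircase_levels_table <- function(sc_trials, design) {
  bins <- pool_and_bin(sc_trials)
  rows <- lapply(bins, function(b) {
    f <- tryCatch(fit_pmf(b), error = function(e) NULL)
    if (is.null(f) || !f$converged || f$spread > 10 * design$start_offset) {
      sub <- sc_trials[sc_trials$reference_hue == b$cell$reference_hue &
                         sc_trials$reference_background ==
                           b$cell$reference_background, , drop = FALSE]
      f <- fallback_range_fit(sub)
    }
    data.frame(reference_hue = b$cell$reference_hue,
               reference_background = b$cell$reference_background,
               test_hue = select_mocs_levels(f, n_levels = design$mocs_levels),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Cells whose pooled MOCS proportions at the extreme levels remain in
# (0.25, 0.75) get a recentered, widened level range for a second pass.
adjusted_levels_table <- function(block, levels_table) {
  mocs <- block[block$phase == "mocs", , drop = FALSE]
  bins <- pool_and_bin(mocs)
  rows <- list()
  for (b in bins) {
    if (!mocs_needs_adjustment(b)) next
    f <- tryCatch(fit_pmf(pool_and_bin(block, cell = b$cell)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      old <- levels_table[levels_table$reference_hue == b$cell$reference_hue &
                            levels_table$reference_background ==
                              b$cell$reference_background, ]
      f <- list(location = mean(old$test_hue),
                spread = (max(old$test_hue) - min(old$test_hue)) / 2)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      reference_hue = b$cell$reference_hue,
      reference_background = b$cell$reference_background,
      test_hue = select_mocs_levels(f, n_levels = length(b$test_hues)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_levels_table())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

empty_levels_table <- function() {
  data.frame(reference_hue = numeric(0), reference_background = character(0),
             test_hue = numeric(0), stringsAsFactors = FALSE)
}
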