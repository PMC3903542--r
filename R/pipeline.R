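#' Pipeline configuration
#'
#' Bundles everything a reproducible simulate-fit-analyze run needs:
#' the observer parameters, the experiment design, and the master
#' seed. Configurations round-trip losslessly through the plain-text
#' (YAML key: value) format used by [write_pipeline_config()].
#'
#' @param observer An [observer_params()] object.
#' @param design An [experiment_design()] object.
#' @param seed Integer master seed; every random stage derives its
#'   child seed from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(observer = observer_params(),
                            design = experiment_design(),
                            seed = 1L) {
  validate_observer_params(observer)
  if (!inherits(design, "experiment_design"))
    stop("design must be an experiment_design object")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("config error: seed must be a single integer")
  structure(list(observer = observer, design = design,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and write pipeline configurations
#'
#' Plain-text serialization (YAML `key: value` mapping) of a
#' [pipeline_config()]. Reading validates all fields through the
#' constructors, so a malformed file fails loudly.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) stop("not a pipeline_config")
  x <- list(observer = unclass(config$observer),
            design = unclass(config$design),
            seed = config$seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  x <- yaml::read_yaml(path)
  for (part in c("observer", "design", "seed"))
    if (is.null(x[[part]])) stop("config error: missing '", part, "' section")
  pipeline_config(observer = do.call(observer_params, x$observer),
                  design = do.call(experiment_design, x$design),
                  seed = x$seed)
}

#' Simulate all conditions of a configured experiment
#'
#' Runs [generate_dataset()] once per requested condition and,
#' optionally, writes one trial table per condition plus a metadata
#' sidecar (seeds, observer parameters, design, schema version) to
#' `dir`. One log line per condition reports the seed and row count.
#'
#' @param config A [pipeline_config()].
#' @param dir Optional output directory (created if needed).
#' @param quiet Suppress log lines?
#' @return Named list of per-condition trial tables, invisibly
#'   carrying `dir` as an attribute when written.
#' @export
simulate_experiment <- function(config, dir = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) stop("not a pipeline_config")
  tables <- list()
  for (i in seq_along(config$design$conditions)) {
    name <- config$design$conditions[i]
    sub_design <- config$design
    sub_design$conditions <- name
    seed_i <- child_seed(config$seed, i)
    tables[[name]] <- generate_dataset(config$observer, sub_design, seed_i)
    if (!quiet)
      message(sprintf("simulate | condition=%s seed=%d trials=%d",
                      name, seed_i, nrow(tables[[name]])))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (name in names(tables))
      write_trials(tables[[name]], file.path(dir, paste0("trials_", name, ".csv")))
    meta <- list(schema = TRIAL_SCHEMA_VERSION,
                 seed = config$seed,
                 observer = unclass(config$observer),
                 design = unclass(config$design),
                 files = paste0("trials_", names(tables), ".csv"))
    yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
    attr(tables, "dir") <- dir
  }
  tables
}

#' Fit and analyze simulated or recorded trial tables
#'
#' Pools the supplied tables, fits a psychometric function per
#' (condition, reference, reference background) cell, derives the
#' baseline-subtracted bias table, and - when the memory, constancy
#' and joint conditions are all present - runs the independence
#' analysis. Cells that could not be fitted are listed in `failures`,
#' never silently dropped, and the trial accounting (rows in = rows in
#' fitted cells + rows in failed cells) is returned.
#'
#' @param trials A trial table or a (possibly named) list of them.
#' @param quiet Suppress log lines?
#' @return A list: `fits`, `biases`, `independence` (or `NULL`),
#'   `failures` (character), `n_trials_in`, `n_trials_fitted`.
#' @export
analyze_experiment <- function(trials, quiet = FALSE) {
  if (is.data.frame(trials)) trials <- list(trials)
  pooled <- do.call(rbind, c(unname(trials), list(make.row.names = FALSE)))
  validate_trials(pooled)
  if (nrow(pooled) == 0) stop("no valid cells: empty trial input")
  fits <- fit_cells(pooled)
  if (nrow(fits) == 0) stop("no valid cells: every psychometric fit failed")
  failures <- attr(fits, "failures")
  if (!quiet)
    message(sprintf("analyze | trials=%d cells=%d failed_cells=%d",
                    nrow(pooled), nrow(fits), length(failures)))
  biases <- bias_table(fits)
  indep <- NULL
  have <- unique(fits$condition)
  if (all(c("memory", "constancy", "joint") %in% have))
    indep <- independence_analysis(biases)
  list(fits = fits, biases = biases, independence = indep,
       failures = failures,
       n_trials_in = nrow(pooled), n_trials_fitted = sum(fits$n))
}

#' Render the analysis report
#'
#' Writes the analysis tables as delimited text and three figures:
#' bias against reference hue per reference background, predicted
#' against measured joint bias with a non-additivity-index histogram,
#' and thresholds by condition. A plain-text summary ties the numbers
#' together; every number in the report is traceable to the written
#' tables.
#'
#' @param analysis Result of [analyze_experiment()].
#' @param dir Output directory (created if needed).
#' @param quiet Suppress log lines?
#' @return Invisibly, the paths written.
#' @export
report_experiment <- function(analysis, dir, quiet = FALSE) {
  if (is.null(analysis$fits) || nrow(analysis$fits) == 0)
    stop("missing inputs: analysis contains no fitted cells")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fits = file.path(dir, "fits.csv"),
             biases = file.path(dir, "biases.csv"))
  utils::write.csv(analysis$fits, paths["fits"], row.names = FALSE)
  utils::write.csv(analysis$biases, paths["biases"], row.names = FALSE)

  b <- analysis$biases[analysis$biases$condition != "baseline", , drop = FALSE]
  p_bias <- ggplot2::ggplot(
    b, ggplot2::aes(x = .data$reference_hue, y = .data$bias,
                    colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~reference_background) +
    ggplot2::labs(x = "reference hue (rad)", y = "bias (rad)",
                  title = "Appearance bias by condition") +
    ggplot2::theme_minimal()
  paths["bias_figure"] <- file.path(dir, "bias_by_reference.png")
  ggplot2::ggsave(paths["bias_figure"], p_bias, width = 7, height = 4, dpi = 120)

  p_thr <- ggplot2::ggplot(
    analysis$biases,
    ggplot2::aes(x = .data$condition, y = .data$threshold,
                 colour = .data$reference_background)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = NULL, y = "threshold (rad)",
                  title = "Discrimination thresholds by condition") +
    ggplot2::theme_minimal()
  paths["threshold_figure"] <- file.path(dir, "thresholds.png")
  ggplot2::ggsave(paths["threshold_figure"], p_thr, width = 6, height = 4,
                  dpi = 120)

  summary_lines <- c("huememory analysis report", "")
  if (!is.null(analysis$independence)) {
    cells <- analysis$independence$cells
    paths["independence"] <- file.path(dir, "independence.csv")
    utils::write.csv(cells, paths["independence"], row.names = FALSE)
    lim <- max(abs(c(cells$measured_joint_bias, cells$predicted_joint_bias)))
    p_add <- ggplot2::ggplot(
      cells, ggplot2::aes(x = .data$predicted_joint_bias,
                          y = .data$measured_joint_bias,
                          colour = .data$reference_background)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
      ggplot2::geom_point(size = 2) +
      ggplot2::coord_equal(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
      ggplot2::labs(x = "predicted joint bias (rad)",
                    y = "measured joint bias (rad)",
                    title = "Additivity of constancy and memory biases") +
      ggplot2::theme_minimal()
    paths["additivity_figure"] <- file.path(dir, "additivity.png")
    ggplot2::ggsave(paths["additivity_figure"], p_add, width = 5, height = 5,
                    dpi = 120)
    p_ni <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$non_additivity)) +
      ggplot2::geom_histogram(breaks = seq(-1, 1, by = 0.2),
                              fill = "seagreen", colour = "white") +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::labs(x = "non-additivity index", y = "cells",
                    title = "Non-additivity indices") +
      ggplot2::theme_minimal()
    paths["ni_figure"] <- file.path(dir, "non_additivity_hist.png")
    ggplot2::ggsave(paths["ni_figure"], p_ni, width = 5, height = 4, dpi = 120)
    s <- analysis$independence$summary
    summary_lines <- c(summary_lines,
      sprintf("mean non-additivity index: %.4f", s$mean_ni),
      sprintf("subadditivity sign-test p: %.4g", s$ni_sign_test_p),
      sprintf("measured/predicted joint-bias ratio: %.3f",
              s$subadditivity_ratio),
      sprintf("memory-bias slope (%s): %.4f",
              names(s$memory_slope), s$memory_slope))
  } else {
    summary_lines <- c(summary_lines,
      "independence analysis absent: memory, constancy and joint",
      "conditions were not all present in the input")
  }
  if (length(analysis$failures) > 0)
    summary_lines <- c(summary_lines, "", "cells excluded (fit failures):",
                       paste(" -", analysis$failures))
  summary_lines <- c(summary_lines, "",
                     sprintf("trials in: %d; trials in fitted cells: %d",
                             analysis$n_trials_in, analysis$n_trials_fitted))
  paths["summary"] <- file.path(dir, "summary.txt")
  writeLines(summary_lines, paths["summary"])
  if (!quiet) message("report | wrote ", length(paths), " files to ", dir)
  invisible(paths)
}

#' @importFrom ggplot2 .data
NULL
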