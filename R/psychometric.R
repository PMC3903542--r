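#' Pool trials and bin responses per analysis cell
#'
#' Trials from both collection phases (staircase and MOCS) are pooled,
#' then split into analysis cells defined by (condition, reference hue,
#' reference background). Within a cell, trials sharing the same
#' recorded test hue (exact match) are merged into one bin counting
#' trials and "test bluer" responses; counts conserve the input rows.
#'
#' @param trials A trial table (see [empty_trials()]).
#' @param cell Optional list with elements `condition`,
#'   `reference_hue`, `reference_background` naming a single cell; by
#'   default all cells present in `trials` are returned.
#' @return A list of `binned_responses` objects, each with fields
#'   `test_hues` (strictly increasing), `n_trials`, `n_test_bluer`,
#'   and `cell`. With `cell` supplied, that single object.
#' @export
pool_and_bin <- function(trials, cell = NULL) {
  validate_trials(trials)
  if (!is.null(cell)) {
    sub <- trials[trials$condition == cell$condition &
                    abs(trials$reference_hue - cell$reference_hue) < 1e-12 &
                    trials$reference_background == cell$reference_background, ,
                  drop = FALSE]
    if (nrow(sub) == 0)
      stop("empty cell: condition=", cell$condition,
           ", reference_hue=", cell$reference_hue,
           ", reference_background=", cell$reference_background)
    return(bin_one_cell(sub, cell))
  }
  if (nrow(trials) == 0) stop("empty cell: trial table has no rows")
  key <- interaction(trials$condition, trials$reference_hue,
                     trials$reference_background, drop = TRUE)
  out <- lapply(split(trials, key), function(sub) {
    cl <- list(condition = sub$condition[1],
               reference_hue = sub$reference_hue[1],
               reference_background = sub$reference_background[1])
    bin_one_cell(sub, cl)
  })
  names(out) <- vapply(out, function(b)
    paste(b$cell$condition, signif(b$cell$reference_hue, 10),
          b$cell$reference_background, sep = "|"), "")
  out[order(names(out))]
}

#' @keywords internal
bin_one_cell <- function(sub, cell) {
  hues <- sort(unique(sub$test_hue))
  n <- vapply(hues, function(h) sum(sub$test_hue == h), 0L)
  k <- vapply(hues, function(h)
    sum(sub$response_test_bluer[sub$test_hue == h]), 0L)
  structure(list(test_hues = hues, n_trials = n, n_test_bluer = k,
                 cell = cell),
            class = "binned_responses")
}

# Negative Bernoulli log-likelihood of the lapse-scaled cumulative
# normal p(x) = lapse/2 + (1 - lapse) * Phi((x - location) / spread).
pmf_nll <- function(theta, x, n, k) {
  location <- theta[1]
  spread <- exp(theta[2])
  lapse <- theta[3]
  p <- lapse / 2 + (1 - lapse) * stats::pnorm((x - location) / spread)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

#' Fit a cumulative-normal psychometric function
#'
#' Maximum-likelihood fit of
#' `p(x) = lapse/2 + (1 - lapse) * pnorm((x - location) / spread)`
#' to binned binary responses, with a single symmetric lapse rate
#' bounded to [0, 0.05]. Optimization is a deterministic multi-start
#' L-BFGS-B over (location, log spread, lapse) from a fixed 3 x 3 grid
#' of starting values spanning the data range, so the fit depends only
#' on the data. `location` is the 50th percentile of the underlying
#' normal (the PSE); `spread` its standard deviation.
#'
#' @param binned A `binned_responses` object from [pool_and_bin()].
#' @param lapse_max Upper bound of the lapse rate (default 0.05).
#' @return A `pmf_fit` object: `location`, `spread`, `lapse`,
#'   `log_likelihood`, `n_total`, `converged`, `cell`.
#' @export
fit_pmf <- function(binned, lapse_max = 0.05) {
  x <- binned$test_hues
  n <- binned$n_trials
  k <- binned$n_test_bluer
  if (length(x) < 3L)
    stop("need >= 3 distinct test hues to fit a psychometric function, got ",
         length(x))
  if (sum(k) == 0 || sum(k) == sum(n))
    stop("non-identifiable fit: all ", sum(n), " responses identical (",
         if (sum(k) == 0) "never" else "always", " 'test bluer'); ",
         "the test range does not straddle the PSE")
  rng <- diff(range(x))
  if (rng <= 0) stop("need spread in test hues to fit")
  loc_starts <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  spread_starts <- rng / c(8, 4, 1.5)
  best <- NULL
  for (l0 in loc_starts) for (s0 in spread_starts) {
    fit <- tryCatch(
      stats::optim(c(l0, log(s0), 0.01), pmf_nll, x = x, n = n, k = k,
                   method = "L-BFGS-B",
                   lower = c(min(x) - 5 * rng, log(rng * 1e-4), 0),
                   upper = c(max(x) + 5 * rng, log(rng * 100), lapse_max),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # prefer converged solutions; break ties on likelihood
    better <- is.null(best) ||
      (fit$convergence == 0 && best$convergence != 0) ||
      (fit$value < best$value &&
         (fit$convergence == 0 || best$convergence != 0))
    if (better) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed for all starting values")
  structure(list(location = best$par[1],
                 spread = exp(best$par[2]),
                 lapse = best$par[3],
                 log_likelihood = -best$value,
                 n_total = sum(n),
                 converged = best$convergence == 0,
                 cell = binned$cell),
            class = "pmf_fit")
}

#' @export
print.pmf_fit <- function(x, ...) {
  cat(sprintf(
    "cumulative-normal PMF fit: location %.4f, spread %.4f, lapse %.3f (n = %d%s)\n",
    x$location, x$spread, x$lapse, x$n_total,
    if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' @keywords internal
stop_if_unconverged <- function(fit) {
  if (!inherits(fit, "pmf_fit")) stop("not a pmf_fit object")
  if (!isTRUE(fit$converged)) stop("psychometric fit did not converge")
  invisible(fit)
}

#' Point of subjective equality
#'
#' The PSE is the 50th percentile of the underlying cumulative normal,
#' i.e. the fitted `location`; the lapse rate scales the asymptotes but
#' does not move the percentiles of the underlying normal.
#'
#' @param fit A converged [fit_pmf()] result.
#' @return PSE in radians.
#' @export
pse <- function(fit) {
  stop_if_unconverged(fit)
  fit$location
}

#' Discrimination threshold and precision
#'
#' The threshold is the hue angle between the 75th and 50th percentile
#' of the fitted function's underlying normal: `spread * qnorm(0.75)`.
#' Precision is its reciprocal.
#'
#' @param fit A converged [fit_pmf()] result.
#' @return Threshold (radians), strictly positive.
#' @export
threshold <- function(fit) {
  stop_if_unconverged(fit)
  fit$spread * stats::qnorm(0.75)
}

#' @rdname threshold
#' @export
precision <- function(fit) 1 / threshold(fit)

#' Baseline-subtracted appearance bias
#'
#' Perceptual bias is the difference between the PSE in an experimental
#' condition and in the baseline condition for the same reference and
#' reference background. Because any constant response bias (e.g. from
#' task wording) shifts both PSEs equally, it is subtracted out; the
#' baseline's bias against itself is exactly zero. Positive bias means
#' the match shifted toward bluer hues.
#'
#' @param fit,baseline_fit Converged [fit_pmf()] results for the same
#'   (reference hue, reference background) cell.
#' @return Bias in radians.
#' @export
bias <- function(fit, baseline_fit) {
  stop_if_unconverged(fit)
  stop_if_unconverged(baseline_fit)
  if (!is.null(fit$cell) && !is.null(baseline_fit$cell)) {
    same <- isTRUE(all.equal(fit$cell$reference_hue,
                             baseline_fit$cell$reference_hue)) &&
      identical(fit$cell$reference_background,
                baseline_fit$cell$reference_background)
    if (!same)
      stop("cell mismatch: bias must compare fits of the same reference ",
           "hue and reference background")
  }
  pse(fit) - pse(baseline_fit)
}

#' Fit psychometric functions for every cell of a trial table
#'
#' Pools and bins the table (see [pool_and_bin()]) and fits each
#' (condition, reference, reference background) cell. Cells whose fit
#' fails or does not converge are reported in the `failures` attribute
#' rather than silently dropped.
#'
#' @param trials A trial table.
#' @return A data frame with one row per successfully fitted cell:
#'   condition, reference_hue, reference_background, location, spread,
#'   lapse, threshold, log_likelihood, n, converged. Attribute
#'   `failures` lists cells that could not be fitted.
#' @export
fit_cells <- function(trials) {
  bins <- pool_and_bin(trials)
  rows <- list()
  failures <- character(0)
  for (nm in names(bins)) {
    b <- bins[[nm]]
    f <- tryCatch(fit_pmf(b), error = function(e) e)
    if (inherits(f, "error") || !f$converged) {
      failures <- c(failures, paste0(nm, ": ",
                                     if (inherits(f, "error"))
                                       conditionMessage(f)
                                     else "did not converge"))
      next
    }
    rows[[nm]] <- data.frame(
      condition = b$cell$condition,
      reference_hue = b$cell$reference_hue,
      reference_background = b$cell$reference_background,
      location = f$location, spread = f$spread, lapse = f$lapse,
      threshold = threshold(f), log_likelihood = f$log_likelihood,
      n = f$n_total, converged = f$converged,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  attr(out, "failures") <- failures
  out
}

#' Baseline-subtracted bias table
#'
#' Joins each experimental condition's fitted cells with the matching
#' baseline cells (same reference hue and reference background) and
#' computes the appearance bias `location - baseline location`.
#'
#' @param fits A fit table from [fit_cells()].
#' @param baseline_condition Name of the baseline condition (default
#'   `"baseline"`).
#' @return Data frame: condition, reference_hue, reference_background,
#'   bias (radians), threshold, baseline_threshold, n.
#' @export
bias_table <- function(fits, baseline_condition = "baseline") {
  base <- fits[fits$condition == baseline_condition, , drop = FALSE]
  if (nrow(base) == 0) stop("no fitted cells for baseline condition '",
                            baseline_condition, "'")
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    r <- fits[i, ]
    j <- which(abs(base$reference_hue - r$reference_hue) < 1e-9 &
                 base$reference_background == r$reference_background)
    if (length(j) != 1L) return(NULL)
    data.frame(condition = r$condition,
               reference_hue = r$reference_hue,
               reference_background = r$reference_background,
               bias = r$location - base$location[j],
               threshold = r$threshold,
               baseline_threshold = base$threshold[j],
               n = r$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
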