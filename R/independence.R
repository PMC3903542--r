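#' Predict joint matches from pure memory and constancy matches
#'
#' If memory and context act independently, the joint
#' constancy-and-memory match to a reference `r` should equal the
#' constancy match to the memory-biased hue `m(r)` rather than to `r`
#' itself: the memory-shifted hues act as new references to which the
#' constancy mapping is applied. Since constancy matches are measured
#' only at the original references, the constancy mapping `C` is the
#' piecewise-linear interpolant through the measured pairs
#' `(r_i, c(r_i))`, assumed homogeneous over this narrow hue range.
#' Memory matches falling outside the reference range are linearly
#' extrapolated up to 10% of the range width (a warning is issued
#' beyond 4%, the departure regarded as unremarkable); beyond 10% the
#' prediction is refused.
#'
#' @param reference_hues Reference hues `r_i` (radians), distinct;
#'   typically three.
#' @param constancy_matches Constancy matches `c(r_i)`, same length.
#' @param memory_matches Memory matches `m(r_i)` at which to evaluate
#'   the interpolant.
#' @return Predicted joint matches `p(r_i) = C(m(r_i))`, radians.
#' @examples
#' predict_joint(c(0, 1, 2), c(0.2, 1.1, 2.4), c(0.5, 1.0, 1.5))
#' @export
predict_joint <- function(reference_hues, constancy_matches, memory_matches) {
  r <- as.numeric(reference_hues)
  cm <- as.numeric(constancy_matches)
  if (length(r) < 2L) stop("need at least two reference hues")
  if (length(cm) != length(r))
    stop("constancy_matches must align with reference_hues")
  if (anyDuplicated(r)) stop("duplicate reference hues")
  o <- order(r)
  r <- r[o]; cm <- cm[o]
  width <- r[length(r)] - r[1]
  frac_out <- pmax(r[1] - memory_matches, memory_matches - r[length(r)], 0) / width
  if (any(frac_out > 0.10))
    stop("memory match ", format(memory_matches[which.max(frac_out)]),
         " lies ", round(100 * max(frac_out), 1),
         "% beyond the measured reference range; refusing to extrapolate ",
         "past 10%")
  if (any(frac_out > 0.04))
    warning("extrapolating ", round(100 * max(frac_out), 1),
            "% beyond the measured reference range")
  vapply(memory_matches, function(m) {
    # segment index for piecewise-linear interpolation/extrapolation
    i <- findInterval(m, r, all.inside = TRUE)
    cm[i] + (cm[i + 1] - cm[i]) * (m - r[i]) / (r[i + 1] - r[i])
  }, 0)
}

#' Non-additivity index
#'
#' Quantifies the departure of a measured joint bias from the
#' additivity prediction as the normalized magnitude difference
#' `NI = (|measured| - |predicted|) / (|measured| + |predicted|)`,
#' bounded in [-1, 1]. Zero indicates full additivity (equal
#' magnitudes), negative values subadditivity (the measured joint bias
#' falls short of the prediction), positive values superadditivity.
#' Vectorized.
#'
#' @param measured_bias Measured joint bias(es), radians.
#' @param predicted_bias Predicted joint bias(es), radians.
#' @return Non-additivity index in [-1, 1].
#' @examples
#' non_additivity_index(0.2, 0.4)   # subadditive
#' @export
non_additivity_index <- function(measured_bias, predicted_bias) {
  am <- abs(measured_bias)
  ap <- abs(predicted_bias)
  if (any(am + ap == 0))
    stop("non-additivity index undefined: measured and predicted bias both zero")
  (am - ap) / (am + ap)
}

#' Central-tendency slope of biases across references
#'
#' Ordinary least-squares slope of bias on reference hue. A negative
#' slope is the signature of a central-tendency bias: the extreme
#' references are drawn toward the middle of the stimulus set, so the
#' yellowest reference is remembered bluer and the bluest yellower.
#'
#' @param biases Appearance biases (radians), one per reference.
#' @param reference_hues Reference hues (radians), at least two
#'   distinct.
#' @return Dimensionless OLS slope.
#' @export
central_tendency_slope <- function(biases, reference_hues) {
  if (length(biases) != length(reference_hues))
    stop("biases and reference_hues must align")
  if (length(unique(reference_hues)) < 2L)
    stop("need at least two distinct reference hues for a slope")
  x <- reference_hues - mean(reference_hues)
  sum(x * (biases - mean(biases))) / sum(x^2)
}

#' One-tailed sign test
#'
#' Exact binomial tail probability of observing at least the observed
#' number of direction-consistent signs among the non-zero values,
#' under the null that positive and negative signs are equally likely.
#' Zeros (ties) are dropped.
#'
#' @param values Numeric vector.
#' @param direction `"negative"` or `"positive"`: the direction
#'   predicted by the alternative hypothesis.
#' @return One-tailed p-value.
#' @examples
#' sign_test_one_tailed(rep(-1, 7), "negative")  # 0.5^7
#' @export
sign_test_one_tailed <- function(values, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (length(values) == 0) stop("values must be non-empty")
  values <- values[values != 0]
  if (length(values) == 0) stop("sign test undefined: all values are ties (zero)")
  n <- length(values)
  k <- if (direction == "negative") sum(values < 0) else sum(values > 0)
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Pearson correlation between bias magnitude and threshold
#'
#' Standard Pearson correlation with a t-distribution two-sided
#' p-value, used to relate appearance biases (or non-additivity
#' indices) to discrimination thresholds. Flagged outliers can be
#' excluded; the exclusion is logged with its justification rather
#' than applied silently.
#'
#' @param abs_biases Numeric vector (e.g. |bias| or NI values).
#' @param thresholds Numeric vector of the same length.
#' @param exclude Optional integer indices to drop as outliers.
#' @param exclude_reason Justification string, logged via [message()]
#'   when `exclude` is non-empty.
#' @return List with `r` (Pearson correlation), `p` (two-sided
#'   p-value), `n` (pairs used), `excluded` (indices dropped).
#' @export
bias_threshold_correlation <- function(abs_biases, thresholds, exclude = NULL,
                                       exclude_reason = NULL) {
  if (length(abs_biases) != length(thresholds))
    stop("abs_biases and thresholds must align")
  if (!is.null(exclude) && length(exclude) > 0) {
    message("excluding ", length(exclude), " pair(s) from correlation: ",
            exclude_reason %||% "flagged as outlier")
    abs_biases <- abs_biases[-exclude]
    thresholds <- thresholds[-exclude]
  }
  if (length(abs_biases) < 3L) stop("need at least 3 pairs for a correlation")
  if (stats::var(abs_biases) == 0 || stats::var(thresholds) == 0)
    stop("undefined correlation: zero variance in one of the variables")
  ct <- stats::cor.test(abs_biases, thresholds, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(abs_biases),
       excluded = exclude %||% integer(0))
}

#' Independence analysis of a bias table
#'
#' For each reference background, builds the match set (memory,
#' constancy, and joint matches `r + bias`), predicts joint matches
#' under independence with [predict_joint()], and computes per-cell
#' non-additivity indices. The summary reports the mean NI, a
#' one-tailed sign test for subadditivity (NI < 0), the subadditivity
#' ratio `mean(|measured|) / mean(|predicted|)`, and the
#' central-tendency slope of the memory biases per background.
#'
#' @param biases A bias table from [bias_table()].
#' @param memory_condition,constancy_condition,joint_condition Names
#'   of the conditions supplying the pure-memory, pure-constancy and
#'   joint cells (defaults `"memory"`, `"constancy"`, `"joint"`).
#' @return An `independence_result`: `cells` (per reference x
#'   background table with measured and predicted joint bias and NI)
#'   and `summary` (mean NI, sign-test p, subadditivity ratio, memory
#'   slopes).
#' @export
independence_analysis <- function(biases,
                                  memory_condition = "memory",
                                  constancy_condition = "constancy",
                                  joint_condition = "joint") {
  rows <- list()
  slopes <- c()
  for (bg in unique(biases$reference_background)) {
    pick <- function(cond) {
      s <- biases[biases$condition == cond &
                    biases$reference_background == bg, , drop = FALSE]
      s[order(s$reference_hue), , drop = FALSE]
    }
    mem <- pick(memory_condition)
    con <- pick(constancy_condition)
    jnt <- pick(joint_condition)
    if (nrow(mem) < 2L || nrow(con) < 2L || nrow(jnt) < 1L)
      stop("insufficient cells for independence analysis on the '", bg,
           "' reference background")
    if (!isTRUE(all.equal(mem$reference_hue, con$reference_hue)))
      stop("memory and constancy cells cover different references")
    r <- mem$reference_hue
    m <- r + mem$bias
    cmatch <- r + con$bias
    p <- predict_joint(r, cmatch, m)
    jr <- jnt$reference_hue
    keep <- match(round(jr, 9), round(r, 9))
    rows[[bg]] <- data.frame(
      reference_hue = jr,
      reference_background = bg,
      memory_bias = mem$bias[keep],
      constancy_bias = con$bias[keep],
      measured_joint_bias = jnt$bias,
      predicted_joint_bias = p[keep] - jr,
      joint_threshold = jnt$threshold,
      stringsAsFactors = FALSE)
    slopes[bg] <- central_tendency_slope(mem$bias, r)
  }
  cells <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cells$non_additivity <- non_additivity_index(cells$measured_joint_bias,
                                               cells$predicted_joint_bias)
  summary <- list(
    mean_ni = mean(cells$non_additivity),
    ni_sign_test_p = sign_test_one_tailed(cells$non_additivity, "negative"),
    subadditivity_ratio = mean(abs(cells$measured_joint_bias)) /
      mean(abs(cells$predicted_joint_bias)),
    memory_slope = slopes,
    n_cells = nrow(cells))
  structure(list(cells = cells, summary = summary),
            class = "independence_result")
}

#' @export
print.independence_result <- function(x, ...) {
  s <- x$summary
  cat("Independence analysis over", s$n_cells, "cells\n")
  cat(sprintf("  mean non-additivity index: %.3f (sign test p = %.4g)\n",
              s$mean_ni, s$ni_sign_test_p))
  cat(sprintf("  measured/predicted joint-bias ratio: %.2f\n",
              s$subadditivity_ratio))
  cat("  central-tendency slope of memory bias:\n")
  for (bg in names(s$memory_slope))
    cat(sprintf("    %s background: %.3f\n", bg, s$memory_slope[[bg]]))
  invisible(x)
}
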