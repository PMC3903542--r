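#' Parameters of the Bayesian hue observer
#'
#' Constructs the parameter set of a quantitative Bayesian observer for
#' 2AFC hue judgments on an equiluminant hue circle. The observer
#' estimates, for each stimulus interval, both the illuminant implied by
#' the background and the surface reflectance of the center patch, by
#' combining noisy measurements (Gaussian likelihoods) with Gaussian
#' priors; it then reports which of the two inferred reflectances is
#' bluer. Hue is treated as an unwrapped real line in radians (larger =
#' bluer); the stimulus range spans a small arc, so circular statistics
#' are unnecessary.
#'
#' Memory retention acts multiplicatively: likelihood widths for a
#' remembered (first-interval, delayed) stimulus and its background are
#' multiplied by `kappa_memory`, so priors gain weight for remembered
#' stimuli. That single mechanism produces both the central-tendency
#' memory bias (shrinkage toward the reflectance prior) and the
#' weakening of context compensation under delay (the remembered
#' illuminant shrinks toward the illuminant prior, making the two
#' backgrounds functionally more similar).
#'
#' @param sigma_sensory Width (radians) of the sensory hue likelihood
#'   for a simultaneously viewed patch. Must be > 0.
#' @param kappa_memory Dimensionless multiplier (>= 1) applied to
#'   likelihood widths for the remembered stimulus and its background.
#' @param prior_reflectance_mean Center (radians) of the reflectance
#'   prior; typically the mean reference hue of a block.
#' @param prior_reflectance_sigma Width (radians) of the reflectance
#'   prior; `Inf` gives a uniform (flat) prior.
#' @param prior_illuminant_mean Center (radians) of the illuminant
#'   prior, on the nominal illuminant axis where gray = 0 and blue =
#'   `illuminant_shift_blue`.
#' @param prior_illuminant_sigma Width (radians) of the illuminant
#'   prior; `Inf` gives a uniform prior.
#' @param illuminant_shift_blue Nominal illuminant value (radians)
#'   attributed to the blue background relative to gray. Only the
#'   gray/blue difference is identifiable, so gray is fixed at 0.
#' @param sigma_decision Width (radians) of zero-mean Gaussian
#'   comparison noise added at the decision stage. May be 0.
#' @param lapse_rate Probability in [0, 0.5) of a stimulus-independent
#'   uniform random response.
#' @param response_criterion Constant additive decision bias (radians)
#'   toward the "test bluer" response; models task-wording response
#'   bias, identical across conditions.
#' @return An object of class `observer_params`.
#' @examples
#' p <- observer_params()
#' p$kappa_memory
#' @export
observer_params <- function(sigma_sensory = 0.1,
                            kappa_memory = 2,
                            prior_reflectance_mean = 3.2,
                            prior_reflectance_sigma = 0.6,
                            prior_illuminant_mean = 0.075,
                            prior_illuminant_sigma = 0.15,
                            illuminant_shift_blue = 0.15,
                            sigma_decision = 0.05,
                            lapse_rate = 0.02,
                            response_criterion = 0) {
  p <- list(
    sigma_sensory = sigma_sensory,
    kappa_memory = kappa_memory,
    prior_reflectance_mean = prior_reflectance_mean,
    prior_reflectance_sigma = prior_reflectance_sigma,
    prior_illuminant_mean = prior_illuminant_mean,
    prior_illuminant_sigma = prior_illuminant_sigma,
    illuminant_shift_blue = illuminant_shift_blue,
    sigma_decision = sigma_decision,
    lapse_rate = lapse_rate,
    response_criterion = response_criterion
  )
  class(p) <- "observer_params"
  validate_observer_params(p)
  p
}

#' @keywords internal
validate_observer_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (f in names(p)) {
    if (!num1(p[[f]])) stop("invalid observer parameter '", f,
                            "': must be a single non-missing number")
  }
  if (p$sigma_sensory <= 0 || !is.finite(p$sigma_sensory))
    stop("invalid observer parameter: sigma_sensory must be finite and > 0")
  if (p$prior_reflectance_sigma <= 0)
    stop("invalid observer parameter: prior_reflectance_sigma must be > 0 (Inf allowed)")
  if (p$prior_illuminant_sigma <= 0)
    stop("invalid observer parameter: prior_illuminant_sigma must be > 0 (Inf allowed)")
  if (p$sigma_decision < 0 || !is.finite(p$sigma_decision))
    stop("invalid observer parameter: sigma_decision must be finite and >= 0")
  if (p$kappa_memory < 1 || !is.finite(p$kappa_memory))
    stop("invalid observer parameter: kappa_memory must be finite and >= 1")
  if (p$lapse_rate < 0 || p$lapse_rate >= 0.5)
    stop("invalid observer parameter: lapse_rate must lie in [0, 0.5)")
  if (!is.finite(p$prior_reflectance_mean) || !is.finite(p$prior_illuminant_mean))
    stop("invalid observer parameter: prior means must be finite")
  if (!is.finite(p$illuminant_shift_blue) || !is.finite(p$response_criterion))
    stop("invalid observer parameter: illuminant_shift_blue and response_criterion must be finite")
  invisible(p)
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Bayesian 2AFC hue observer\n")
  for (f in names(x)) cat(sprintf("  %-24s %g\n", f, x[[f]]))
  invisible(x)
}

#' Posterior mean of a conjugate-Gaussian estimate
#'
#' Combines a measured signal with a Gaussian prior, returning the
#' posterior mean `w * signal + (1 - w) * prior_mean` with
#' `w = prior_sigma^2 / (prior_sigma^2 + likelihood_sigma^2)`. An
#' infinite `prior_sigma` (uniform prior) gives `w = 1`; an infinite
#' `likelihood_sigma` (uninformative signal) under a finite prior gives
#' `w = 0`. The estimate always lies between the signal and the prior
#' mean. All arguments are vectorized.
#'
#' @param signal Measured value(s) (hue angle, radians).
#' @param likelihood_sigma Likelihood width(s), > 0 (`Inf` allowed).
#' @param prior_mean Prior mean(s) (radians).
#' @param prior_sigma Prior width(s), > 0 (`Inf` = uniform prior).
#' @return Posterior mean estimate(s), radians.
#' @examples
#' posterior_estimate(0.7, 0.1, 0, Inf)   # uniform prior: 0.7
#' posterior_estimate(0.5, 1, 0, 1)       # equal weights: 0.25
#' @export
posterior_estimate <- function(signal, likelihood_sigma, prior_mean, prior_sigma) {
  if (any(!is.finite(signal))) stop("invalid-parameter: signal must be finite")
  if (any(likelihood_sigma <= 0) || any(is.na(likelihood_sigma)))
    stop("invalid-parameter: likelihood_sigma must be > 0")
  if (any(prior_sigma <= 0) || any(is.na(prior_sigma)))
    stop("invalid-parameter: prior_sigma must be > 0 (Inf allowed)")
  w <- ifelse(is.infinite(prior_sigma), 1,
              ifelse(is.infinite(likelihood_sigma), 0,
                     prior_sigma^2 / (prior_sigma^2 + likelihood_sigma^2)))
  w * signal + (1 - w) * prior_mean
}

#' Construct stimulus presentations
#'
#' A stimulus presentation is one center patch on one background in one
#' interval of a 2AFC trial. `remembered` marks the first interval of a
#' delay condition: that stimulus (and its background) must be retained
#' across the delay, which widens its likelihoods by `kappa_memory`.
#' Vectorized over all arguments.
#'
#' @param hue Hue angle(s), radians; larger = bluer.
#' @param background `"gray"` or `"blue"`.
#' @param interval `"first"` or `"second"`.
#' @param remembered Logical; `TRUE` only allowed for first-interval
#'   stimuli.
#' @return A `stimulus` object (list of parallel vectors).
#' @export
stimulus <- function(hue, background = "gray", interval = "second",
                     remembered = FALSE) {
  n <- max(length(hue), length(background), length(interval), length(remembered))
  hue <- rep_len(as.numeric(hue), n)
  background <- rep_len(as.character(background), n)
  interval <- rep_len(as.character(interval), n)
  remembered <- rep_len(as.logical(remembered), n)
  if (any(!is.finite(hue))) stop("stimulus hue must be finite")
  if (!all(background %in% c("gray", "blue")))
    stop("stimulus background must be 'gray' or 'blue'")
  if (!all(interval %in% c("first", "second")))
    stop("stimulus interval must be 'first' or 'second'")
  if (any(remembered & interval != "first"))
    stop("a remembered stimulus must be in the first interval")
  structure(list(hue = hue, background = background,
                 interval = interval, remembered = remembered),
            class = "stimulus")
}

# Inferred reflectance for a (vector of) stimulus presentation(s):
# noisy hue signal -> illuminant estimate from the background ->
# reflectance = posterior of (signal - illuminant) under the
# reflectance prior. Likelihood widths scale with kappa_memory for
# remembered stimuli.
infer_reflectance <- function(params, stim) {
  kappa <- ifelse(stim$remembered, params$kappa_memory, 1)
  lik <- kappa * params$sigma_sensory
  signal <- stats::rnorm(length(stim$hue), mean = stim$hue, sd = lik)
  illum_nominal <- ifelse(stim$background == "blue",
                          params$illuminant_shift_blue, 0)
  illum_hat <- posterior_estimate(illum_nominal, lik,
                                  params$prior_illuminant_mean,
                                  params$prior_illuminant_sigma)
  posterior_estimate(signal - illum_hat, lik,
                     params$prior_reflectance_mean,
                     params$prior_reflectance_sigma)
}

#' Simulate 2AFC responses of the Bayesian observer
#'
#' For each trial the observer draws a noisy hue signal for the
#' reference and the test, infers the illuminant from each stimulus'
#' background (the background color dominates the illuminant estimate;
#' gray has nominal value 0, blue `illuminant_shift_blue`), infers
#' each reflectance as the posterior of (signal - inferred illuminant)
#' under the reflectance prior, and responds "test bluer" when
#' `reflectance(test) - reflectance(reference) + decision noise +
#' response_criterion > 0`. With probability `lapse_rate` the response
#' is replaced by an unbiased coin flip. Vectorized over trials; the
#' probability of "test bluer" is non-decreasing in test hue.
#'
#' @param params An [observer_params()] object.
#' @param reference,test [stimulus()] objects of equal length.
#' @param seed Optional integer seed (RNG state is restored afterwards);
#'   with `NULL` the current RNG stream is used.
#' @return Logical vector, `TRUE` where the test was judged bluer.
#' @examples
#' p <- observer_params(lapse_rate = 0)
#' r <- stimulus(rep(3.2, 5))
#' t <- stimulus(seq(3.0, 3.4, length.out = 5))
#' simulate_response(p, r, t, seed = 1)
#' @export
simulate_response <- function(params, reference, test, seed = NULL) {
  validate_observer_params(params)
  if (!inherits(reference, "stimulus") || !inherits(test, "stimulus"))
    stop("reference and test must be stimulus() objects")
  n <- length(reference$hue)
  if (length(test$hue) != n) stop("reference and test must have equal length")
  with_seed(seed, {
    refl_ref <- infer_reflectance(params, reference)
    refl_test <- infer_reflectance(params, test)
    noise <- if (params$sigma_decision > 0)
      stats::rnorm(n, 0, params$sigma_decision) else 0
    resp <- (refl_test - refl_ref + noise + params$response_criterion) > 0
    if (params$lapse_rate > 0) {
      lapse <- stats::runif(n) < params$lapse_rate
      if (any(lapse)) resp[lapse] <- stats::runif(sum(lapse)) < 0.5
    }
    resp
  })
}

#' Package an observer as a response-generating function
#'
#' Returns a closure `f(reference, test)` over fixed parameters, the
#' interface the experiment engine expects. Randomness is drawn from
#' the ambient RNG stream so the engine can control seeding.
#'
#' @param params An [observer_params()] object.
#' @return A function mapping two [stimulus()] objects to a logical
#'   response vector.
#' @export
make_observer <- function(params) {
  validate_observer_params(params)
  force(params)
  function(reference, test) simulate_response(params, reference, test)
}
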