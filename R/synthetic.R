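#' Generate a synthetic ASFR schedule
#'
#' Simulates an observed fertility schedule: the chosen family is
#' evaluated at the true parameters on the age grid and additive Gaussian
#' observation noise is superimposed, matching the homoskedastic error
#' structure the unweighted least-squares objective assumes. Negative
#' noisy rates are clipped to zero by default (observed ASFRs are
#' nonnegative). The generator is a pure function of its arguments: the
#' same seed reproduces the same schedule exactly, and the caller's RNG
#' state is left untouched.
#'
#' @inheritParams fit_objective
#' @param true_params named parameter vector of the generating family;
#'   defaults to the registry defaults of `model`.
#' @param ages age grid, within `[10, 60]` (default single years 12-50).
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   rate units (births/woman/year); 0 gives the exact model curve.
#' @param seed integer RNG seed.
#' @param clip_negative clip negative noisy rates to 0 (default TRUE).
#' @return an [asfr_schedule()] whose `label` and `truth` attribute record
#'   the generating family, parameters, noise level and seed.
#' @examples
#' s <- generate_schedule("skew_logistic_fgsl",
#'                        c(R = 1.3, mu = 29, sigma = 7, alpha = 1.2,
#'                          beta = 0.4), noise_sd = 0.002, seed = 1)
#' @export
generate_schedule <- function(model, true_params = NULL, ages = 12:50,
                              noise_sd = 0.002, seed = 1,
                              clip_negative = TRUE) {
  model <- fertility_model(model)
  if (is.null(true_params)) true_params <- model$defaults
  true_params <- conform_params(model, true_params)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0)
    stop("'noise_sd' must be a single nonnegative number", call. = FALSE)
  if (any(ages < 10 | ages > 60))
    stop("synthetic age grids must lie within [10, 60] years", call. = FALSE)
  curve <- model$eval_fun(true_params, ages)
  noise <- if (noise_sd > 0) {
    withr_seed(seed, stats::rnorm(length(ages), 0, noise_sd))
  } else {
    numeric(length(ages))
  }
  rates <- curve + noise
  if (clip_negative) rates <- pmax(rates, 0)
  out <- asfr_schedule(
    ages, rates,
    label = sprintf("synthetic %s (noise_sd=%g, seed=%d)", model$name,
                    noise_sd, seed))
  attr(out, "truth") <- list(model = model$name, params = true_params,
                             noise_sd = noise_sd, seed = seed,
                             clip_negative = clip_negative)
  out
}

#' Deterministic fixture schedules
#'
#' A small named collection of synthetic ASFR schedules covering the
#' qualitative shapes fertility schedules take, each with its generating
#' truth recorded in the `truth` attribute:
#' \describe{
#'   \item{`unimodal_symmetric`}{noiseless skew-logistic curve with no
#'     skewness (one mode at the location).}
#'   \item{`unimodal_skewed`}{noiseless skew-logistic curve with positive
#'     linear and cubic skewness — right-shifted single hump.}
#'   \item{`bimodal_two_humps`}{noiseless skew-logistic curve in the
#'     two-mode regime (location 30, scale 8, alpha 1, beta -0.8; beta
#'     frozen from a scan of this regime for bimodality), humps near ages
#'     17 and 34.}
#'   \item{`noisy_bimodal`}{the same bimodal truth with additive Gaussian
#'     noise (sd 0.003, seed 42).}
#' }
#'
#' @return named list of four [asfr_schedule()] objects.
#' @examples
#' names(preset_schedules())
#' @export
preset_schedules <- function() {
  fgsl <- "skew_logistic_fgsl"
  bimodal_truth <- c(R = 1.8, mu = 30, sigma = 8, alpha = 1, beta = -0.8)
  list(
    unimodal_symmetric = generate_schedule(
      fgsl, c(R = 1.5, mu = 29, sigma = 5, alpha = 0, beta = 0),
      noise_sd = 0),
    unimodal_skewed = generate_schedule(
      fgsl, c(R = 1.3, mu = 29, sigma = 7, alpha = 1.2, beta = 0.4),
      noise_sd = 0),
    bimodal_two_humps = generate_schedule(fgsl, bimodal_truth, noise_sd = 0),
    noisy_bimodal = generate_schedule(fgsl, bimodal_truth, noise_sd = 0.003,
                                      seed = 42)
  )
}
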