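# Model registry: every fertility curve family is wrapped as
# g(x; R, theta) = R * h(x; theta) (or an amplitude-parameterized curve for
# the normal-mixture and spline families), with a uniform named-parameter
# interface, default values and box bounds used by the fitter.

.registry <- local({

  spec <- function(name, param_names, defaults, lower, upper, scaled_by_R,
                   eval_fun, support_fun, level_param = NA_character_) {
    stopifnot(
      !anyDuplicated(param_names),
      length(defaults) == length(param_names),
      all(lower < upper),
      all(defaults >= lower & defaults <= upper)
    )
    names(defaults) <- names(lower) <- names(upper) <- param_names
    structure(
      list(name = name, param_names = param_names, defaults = defaults,
           lower = lower, upper = upper, scaled_by_R = scaled_by_R,
           level_param = level_param,
           eval_fun = eval_fun, support_fun = support_fun),
      class = "fertility_model")
  }

  eps <- 1e-6

  list(
    hadwiger = spec(
      "hadwiger",
      c("a", "b", "c"),
      defaults = c(2, 3, 28),
      lower = c(eps, eps, 15), upper = c(20, 20, 45),
      scaled_by_R = TRUE,
      eval_fun = function(p, x) hadwiger(x, p[["a"]], p[["b"]], p[["c"]]),
      support_fun = function(p) c(max(0.5, p[["c"]] / 4), 3 * p[["c"]]),
      level_param = "a"
    ),
    hadwiger_mixture = spec(
      "hadwiger_mixture",
      c("a", "m", "b1", "b2", "c1", "c2"),
      defaults = c(2, 0.5, 3, 3, 25, 32),
      lower = c(eps, 0, eps, eps, 15, 15),
      upper = c(20, 1, 20, 20, 45, 45),
      scaled_by_R = TRUE,
      eval_fun = function(p, x)
        hadwiger_mixture(x, p[["a"]], p[["m"]], p[["b1"]], p[["b2"]],
                         p[["c1"]], p[["c2"]]),
      support_fun = function(p)
        c(max(0.5, min(p[["c1"]], p[["c2"]]) / 4), 3 * max(p[["c1"]], p[["c2"]])),
      level_param = "a"
    ),
    normal_mixture = spec(
      "normal_mixture",
      c("c1", "mu1", "sigma1", "c2", "mu2", "sigma2"),
      defaults = c(0.08, 25, 5, 0.06, 33, 5),
      lower = c(0, 10, 0.5, 0, 10, 0.5),
      upper = c(2, 50, 25, 2, 50, 25),
      scaled_by_R = FALSE,
      eval_fun = function(p, x)
        normal_mixture(x, p[["c1"]], p[["mu1"]], p[["sigma1"]],
                       p[["c2"]], p[["mu2"]], p[["sigma2"]]),
      support_fun = function(p)
        c(min(p[["mu1"]] - 8 * p[["sigma1"]], p[["mu2"]] - 8 * p[["sigma2"]]),
          max(p[["mu1"]] + 8 * p[["sigma1"]], p[["mu2"]] + 8 * p[["sigma2"]]))
    ),
    quadratic_spline = spec(
      "quadratic_spline",
      c("R", "alpha_age", "beta_age",
        paste0("theta", 0:4), paste0("t", 0:4)),
      defaults = c(1.5, 14, 50, 0.002, 0, 0, 0, 0, 15, 22, 28, 34, 42),
      lower = c(eps, 10, 40, rep(-1, 5), rep(10, 5)),
      upper = c(10, 25, 60, rep(1, 5), rep(55, 5)),
      scaled_by_R = FALSE,  # R is an explicit parameter of the formula itself
      eval_fun = function(p, x)
        quadratic_spline(x, p[["R"]], p[["alpha_age"]], p[["beta_age"]],
                         theta = p[paste0("theta", 0:4)],
                         knots = p[paste0("t", 0:4)]),
      support_fun = function(p) c(p[["alpha_age"]], p[["beta_age"]])
    ),
    skew_normal_fgsn = spec(
      "skew_normal_fgsn",
      c("R", "xi", "omega", "alpha", "beta"),
      defaults = c(1.5, 28, 6, 0, 0),
      lower = c(eps, 10, 0.5, -5, -5),
      upper = c(10, 50, 25, 5, 5),
      scaled_by_R = TRUE,
      eval_fun = function(p, x)
        p[["R"]] * fgsn_pdf(x, p[["xi"]], p[["omega"]], p[["alpha"]], p[["beta"]]),
      support_fun = function(p)
        c(p[["xi"]] - 10 * p[["omega"]], p[["xi"]] + 10 * p[["omega"]]),
      level_param = "R"
    ),
    skew_logistic_fgsl = spec(
      "skew_logistic_fgsl",
      c("R", "mu", "sigma", "alpha", "beta"),
      defaults = c(1.5, 28, 6, 0, 0),
      lower = c(eps, 10, 0.5, -5, -5),
      upper = c(10, 50, 25, 5, 5),
      scaled_by_R = TRUE,
      eval_fun = function(p, x)
        p[["R"]] * fgsl_pdf(x, p[["mu"]], p[["sigma"]], p[["alpha"]], p[["beta"]]),
      support_fun = function(p)
        c(p[["mu"]] - 10 * p[["sigma"]], p[["mu"]] + 10 * p[["sigma"]]),
      level_param = "R"
    )
  )
})

#' List the registered fertility model families
#'
#' @return character vector of model identifiers.
#' @export
fertility_models <- function() names(.registry)

#' Look up a fertility model specification
#'
#' Returns the canonical specification of a registered curve family: its
#' ordered parameter names, default parameter values, and per-parameter box
#' bounds used as fitting defaults. The skewness coefficients of the two
#' skew families default to the box `[-5, 5]`; the remaining boxes reflect
#' human fertile-age ranges (location 10-50 years, scale 0.5-25 years,
#' total fertility 0-10).
#'
#' @param model a model identifier (see [fertility_models()]) or a
#'   `fertility_model` object (returned unchanged).
#' @return an object of class `fertility_model`: a list with elements
#'   `name`, `param_names`, `defaults`, `lower`, `upper`, `scaled_by_R`.
#' @examples
#' fertility_model("skew_logistic_fgsl")$param_names
#' @export
fertility_model <- function(model) {
  if (inherits(model, "fertility_model")) return(model)
  if (!is.character(model) || length(model) != 1L)
    stop("'model' must be a single model name or a fertility_model", call. = FALSE)
  if (!model %in% names(.registry))
    stop(sprintf("unknown model '%s'; available families: %s",
                 model, paste(names(.registry), collapse = ", ")),
         call. = FALSE)
  .registry[[model]]
}

#' @export
print.fertility_model <- function(x, ...) {
  cat(sprintf("Fertility model '%s' (%d parameters)\n", x$name,
              length(x$param_names)))
  print(data.frame(parameter = x$param_names, default = unname(x$defaults),
                   lower = unname(x$lower), upper = unname(x$upper)))
  invisible(x)
}

#' Number of free parameters of a model family
#'
#' @inheritParams fertility_model
#' @return integer parameter count.
#' @export
n_params <- function(model) length(fertility_model(model)$param_names)

# Coerce/validate a parameter vector against a model spec: accepts a named
# vector in any order or an unnamed vector in registry order.
conform_params <- function(model, params) {
  model <- fertility_model(model)
  if (!is.numeric(params))
    stop("'params' must be numeric", call. = FALSE)
  if (length(params) != length(model$param_names))
    stop(sprintf("model '%s' takes %d parameters (%s), got %d",
                 model$name, length(model$param_names),
                 paste(model$param_names, collapse = ", "), length(params)),
         call. = FALSE)
  if (is.null(names(params)) || !any(nzchar(names(params)))) {
    names(params) <- model$param_names
  } else {
    if (!setequal(names(params), model$param_names))
      stop(sprintf("parameter names do not match model '%s': expected %s",
                   model$name, paste(model$param_names, collapse = ", ")),
           call. = FALSE)
    params <- params[model$param_names]
  }
  if (!all(is.finite(params)))
    stop("all parameter values must be finite", call. = FALSE)
  params
}

#' Evaluate a fertility model on an age grid
#'
#' Computes the predicted fertility rate at each age under a curve family
#' and parameter vector. Families flagged `scaled_by_R` are the product of
#' a total-fertility level and a unit density; the normal-mixture and
#' quadratic-spline families are amplitude-parameterized curves evaluated
#' as published.
#'
#' @inheritParams fertility_model
#' @param params numeric parameter vector, named (any order) or unnamed in
#'   registry order; see `fertility_model(model)$param_names`.
#' @param ages numeric vector of ages (must be positive for the Hadwiger
#'   families).
#' @return numeric vector of predicted rates, one per age.
#' @examples
#' evaluate_model("skew_logistic_fgsl", c(R = 1, mu = 30, sigma = 8,
#'                                        alpha = 0, beta = 0), 30)  # 1/32
#' @export
evaluate_model <- function(model, params, ages) {
  model <- fertility_model(model)
  params <- conform_params(model, params)
  if (!is.numeric(ages) || anyNA(ages))
    stop("'ages' must be numeric without missing values", call. = FALSE)
  model$eval_fun(params, ages)
}
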