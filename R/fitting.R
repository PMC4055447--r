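#' Sum-of-squares fitting objective
#'
#' The unweighted residual sum of squares
#' \eqn{S = \sum_x \{g(x; \theta) - f_x\}^2} over the ages of an observed
#' schedule; the quantity minimized by [fit_model()] and reported as the
#' `resnorm` of a fit.
#'
#' @inheritParams evaluate_model
#' @param schedule an [asfr_schedule()].
#' @param weights optional nonnegative per-age weights (default all 1; the
#'   published objective is unweighted).
#' @return a single nonnegative number.
#' @export
fit_objective <- function(model, params, schedule, weights = NULL) {
  schedule <- as_schedule(schedule)
  w <- check_weights(weights, nrow(schedule))
  pred <- evaluate_model(model, params, schedule$age)
  sum(w * (pred - schedule$asfr)^2)
}

check_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (!is.numeric(weights) || length(weights) != n || any(weights < 0))
    stop("'weights' must be nonnegative and match the schedule length",
         call. = FALSE)
  weights
}

#' Moment-based starting values for a model fit
#'
#' Heuristic initial parameters computed from the observed schedule: the
#' location starts at the rate-weighted mean age, the scale at the
#' rate-weighted age standard deviation, and the level at the trapezoidal
#' integral of the schedule (an empirical total fertility rate). Skewness
#' coefficients start at 0 and mixtures at equal symmetric components. The
#' result is always clipped into the model's default box bounds.
#'
#' @inheritParams fit_objective
#' @return a named parameter vector conforming to the model.
#' @export
default_start <- function(model, schedule) {
  model <- fertility_model(model)
  schedule <- as_schedule(schedule)
  x <- schedule$age
  f <- schedule$asfr
  if (all(f == 0))
    stop("cannot compute starting values from an all-zero schedule",
         call. = FALSE)
  wmean <- sum(x * f) / sum(f)
  wsd <- sqrt(sum(f * (x - wmean)^2) / sum(f))
  if (wsd == 0) wsd <- diff(range(x)) / 6
  n <- length(x)
  tfr <- sum(diff(x) * (f[-1] + f[-n]) / 2)  # trapezoid rule
  peak <- max(f)

  p <- switch(model$name,
    hadwiger = {
      a <- tfr
      c(a = a, b = peak * wmean / max(a, 1e-8), c = wmean)
    },
    hadwiger_mixture = {
      a <- tfr
      b <- peak * wmean / max(a, 1e-8)
      c(a = a, m = 0.5, b1 = b, b2 = b, c1 = wmean, c2 = wmean)
    },
    normal_mixture = c(c1 = peak / 2, mu1 = wmean, sigma1 = wsd,
                       c2 = peak / 2, mu2 = wmean, sigma2 = wsd),
    quadratic_spline = {
      ts <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
      th <- c(peak / max((wmean - min(x))^2, 1), 0, 0, 0, 0)
      out <- c(tfr, min(x), max(x), th, ts)
      names(out) <- model$param_names
      out
    },
    # both skew families: level, location, scale, no skewness
    {
      out <- c(tfr, wmean, wsd, 0, 0)
      names(out) <- model$param_names
      out
    })
  p <- p[model$param_names]
  pmin(pmax(p, model$lower), model$upper)
}

#' Fit a fertility model to an observed schedule
#'
#' Estimates model parameters by minimizing the residual sum of squares
#' with box constraints, using Levenberg-Marquardt least squares on the
#' residual vector (via \pkg{minpack.lm}) from multiple starting points.
#' The first start is the moment heuristic of [default_start()]; the
#' remaining starts jitter it by seeded uniform perturbations of 10% of
#' each box width, clipped to the bounds. The best converged local minimum
#' is returned; ties in the objective break toward the lowest start index,
#' so the result is deterministic given the schedule and `seed`.
#'
#' @inheritParams fit_objective
#' @param n_starts number of multistart initializations (>= 1).
#' @param seed integer RNG seed controlling start dispersion.
#' @param start optional explicit first start (named parameter vector);
#'   replaces the moment heuristic.
#' @param lower,upper optional named vectors overriding selected box
#'   bounds.
#' @param fixed optional named vector of parameters held fixed at the
#'   given values (excluded from optimization).
#' @param tol convergence tolerance on the relative change of the
#'   objective.
#' @param max_evals cap on residual-function evaluations per start.
#' @return an object of class `fert_fit`: a list with elements `model`,
#'   `params` (full named vector, fixed values included), `resnorm`,
#'   `residuals` (signed, predicted minus observed), `fitted`,
#'   `converged`, `n_starts_used`, `best_start_index`,
#'   `objective_history`, and the input `schedule`.
#' @examples
#' truth <- c(R = 1.3, mu = 29, sigma = 7, alpha = 1.2, beta = 0.4)
#' s <- asfr_schedule(12:50, evaluate_model("skew_logistic_fgsl", truth, 12:50))
#' fit <- fit_model("skew_logistic_fgsl", s, n_starts = 4, seed = 1)
#' fit$resnorm
#' @export
fit_model <- function(model, schedule, n_starts = 8, seed = 1,
                      start = NULL, lower = NULL, upper = NULL,
                      fixed = NULL, weights = NULL,
                      tol = 1e-12, max_evals = 5000) {
  model <- fertility_model(model)
  schedule <- as_schedule(schedule)
  stopifnot(n_starts >= 1, tol > 0)
  w <- check_weights(weights, nrow(schedule))

  lo <- override_bounds(model$lower, lower, model)
  hi <- override_bounds(model$upper, upper, model)
  if (any(lo >= hi))
    stop("lower bounds must be strictly below upper bounds", call. = FALSE)

  fixed_names <- character(0)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% model$param_names))
      stop("'fixed' must be a named vector of model parameters", call. = FALSE)
    fixed_names <- names(fixed)
  }
  free_names <- setdiff(model$param_names, fixed_names)
  if (length(free_names) == 0L)
    stop("no free parameters left to fit", call. = FALSE)
  if (nrow(schedule) <= length(free_names))
    stop(sprintf(
      "schedule has %d points but the fit has %d free parameters; need more points than parameters",
      nrow(schedule), length(free_names)), call. = FALSE)

  base_start <- if (is.null(start)) default_start(model, schedule)
                else conform_params(model, fill_fixed(model, start, fixed))
  base_start <- pmin(pmax(base_start, lo), hi)

  # seeded multistart dispersion: start 1 is the heuristic, the rest jitter
  # it by <=10% of each box width
  box <- hi - lo
  starts <- vector("list", n_starts)
  starts[[1L]] <- base_start
  if (n_starts > 1L) {
    jit <- withr_seed(seed, {
      # byrow: start i consumes a fixed block of the RNG stream, so the
      # first k starts are identical for every n_starts >= k (nested sets)
      matrix(stats::runif((n_starts - 1L) * length(box), -0.1, 0.1),
             nrow = n_starts - 1L, byrow = TRUE)
    })
    for (i in seq_len(n_starts - 1L)) {
      s <- base_start + jit[i, ] * box
      starts[[i + 1L]] <- pmin(pmax(s, lo), hi)
    }
  }

  sqw <- sqrt(w)
  obs <- schedule$asfr
  resid_fn <- function(free) {
    full <- base_start
    full[free_names] <- free
    if (length(fixed_names)) full[fixed_names] <- fixed
    sqw * (model$eval_fun(full, schedule$age) - obs)
  }

  ctrl <- minpack.lm::nls.lm.control(ftol = tol, ptol = 1e-12,
                                     maxfev = max_evals,
                                     maxiter = min(1024L, max_evals))
  results <- vector("list", n_starts)
  objs <- rep(NA_real_, n_starts)
  for (i in seq_len(n_starts)) {
    st <- starts[[i]]
    if (length(fixed_names)) st[fixed_names] <- fixed
    res <- tryCatch(
      minpack.lm::nls.lm(par = st[free_names], lower = lo[free_names],
                         upper = hi[free_names], fn = resid_fn,
                         control = ctrl),
      error = function(e) e)
    if (inherits(res, "error")) {
      results[[i]] <- list(error = conditionMessage(res))
    } else {
      full <- base_start
      full[free_names] <- res$par
      if (length(fixed_names)) full[fixed_names] <- fixed
      results[[i]] <- list(par = full, deviance = res$deviance,
                           info = res$info)
      objs[i] <- res$deviance
    }
  }

  if (all(is.na(objs))) {
    msgs <- vapply(results, function(r) r$error %||% "", "")
    return(structure(
      list(model = model$name, params = base_start, resnorm = NA_real_,
           residuals = rep(NA_real_, nrow(schedule)),
           fitted = rep(NA_real_, nrow(schedule)),
           converged = FALSE, n_starts_used = n_starts,
           best_start_index = NA_integer_, objective_history = objs,
           failure_messages = msgs, schedule = schedule),
      class = "fert_fit"))
  }

  best <- which.min(objs)  # NA ignored; ties -> lowest index
  par <- results[[best]]$par
  pred <- model$eval_fun(par, schedule$age)
  residuals <- pred - obs
  resnorm <- sum(w * residuals^2)

  structure(
    list(model = model$name, params = par, resnorm = resnorm,
         residuals = residuals, fitted = pred,
         converged = results[[best]]$info %in% 1:4,
         n_starts_used = n_starts, best_start_index = best,
         objective_history = objs, schedule = schedule),
    class = "fert_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run an expression under a local RNG seed without touching the caller's
# RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

fill_fixed <- function(model, start, fixed) {
  if (is.null(fixed) || is.null(names(start))) return(start)
  miss <- setdiff(names(fixed), names(start))
  if (length(miss)) start <- c(start, fixed[miss])
  start
}

override_bounds <- function(base, override, model) {
  if (is.null(override)) return(base)
  if (is.null(names(override)) || !all(names(override) %in% model$param_names))
    stop("bound overrides must be named after model parameters", call. = FALSE)
  base[names(override)] <- override
  base
}

#' @export
print.fert_fit <- function(x, digits = 6, ...) {
  cat(sprintf("Fertility model fit: %s\n", x$model))
  if (is.na(x$resnorm)) {
    cat("  all starts failed:\n")
    for (m in unique(x$failure_messages)) if (nzchar(m)) cat("   ", m, "\n")
    return(invisible(x))
  }
  cat("  parameters:\n")
  print(signif(x$params, digits))
  cat(sprintf("  resnorm: %.*g   converged: %s   (best of %d starts, start #%d)\n",
              digits, x$resnorm, x$converged, x$n_starts_used,
              x$best_start_index))
  invisible(x)
}

#' @export
coef.fert_fit <- function(object, ...) object$params

#' @export
residuals.fert_fit <- function(object, ...) object$residuals

#' @export
fitted.fert_fit <- function(object, ...) object$fitted

#' Observed schedule, fitted curve and residuals of a fit
#'
#' @param x a `fert_fit` object.
#' @param ... further arguments passed to [graphics::plot()].
#' @return the fit, invisibly.
#' @export
plot.fert_fit <- function(x, ...) {
  if (is.na(x$resnorm)) stop("cannot plot a failed fit", call. = FALSE)
  s <- x$schedule
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$age, s$asfr, pch = 16, xlab = "age",
                 ylab = "fertility rate", main = x$model, ...)
  graphics::lines(s$age, x$fitted, col = "firebrick", lwd = 2)
  graphics::plot(s$age, x$residuals, type = "h", xlab = "age",
                 ylab = "residual (fitted - observed)")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
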