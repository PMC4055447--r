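#' Logistic probability density with rate parameterization
#'
#' Density of the logistic distribution written with a rate parameter
#' \eqn{\lambda}: \eqn{g(x) = \lambda e^{-\lambda x} / (1 + e^{-\lambda x})^2}.
#' This is the symmetric base density from which the skew-logistic family is
#' built; it equals `stats::dlogis(x, scale = 1/lam)`.
#'
#' @param x numeric vector of evaluation points.
#' @param lam positive rate parameter \eqn{\lambda}.
#' @param log logical; return the log-density.
#' @return numeric vector of densities (or log-densities).
#' @examples
#' logistic_pdf(0)        # 1/4
#' logistic_pdf(2) == logistic_pdf(-2)
#' @export
logistic_pdf <- function(x, lam = 1, log = FALSE) {
  check_rate(lam)
  stats::dlogis(x, location = 0, scale = 1 / lam, log = log)
}

#' Logistic cumulative distribution with rate parameterization
#'
#' \eqn{G(x) = 1 / (1 + e^{-\lambda x})}; the skewing cdf of the
#' skew-logistic construction.
#'
#' @inheritParams logistic_pdf
#' @param log.p logical; return log-probability.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
logistic_cdf <- function(x, lam = 1, log.p = FALSE) {
  check_rate(lam)
  stats::plogis(x, location = 0, scale = 1 / lam, log.p = log.p)
}

check_rate <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("rate parameter 'lam' must be a single finite value > 0", call. = FALSE)
  invisible(lam)
}

#' Azzalini skew-symmetric construction
#'
#' Builds the density \eqn{f(x) = 2 f_0(x) G\{\omega(x)\}} from a symmetric
#' base density \eqn{f_0}, a distribution function \eqn{G} whose density is
#' symmetric, and an odd function \eqn{\omega}. For any such triple the
#' result is a valid density, and it satisfies the reflection identity
#' \eqn{f(x) + f(-x) = 2 f_0(x)}.
#'
#' The oddness of `odd_fn` and the symmetry of `base_pdf` are contracts on
#' the caller; they are not verified pointwise.
#'
#' @param x numeric vector of evaluation points.
#' @param base_pdf function; symmetric density on the real line.
#' @param skewing_cdf function; cdf with symmetric density.
#' @param odd_fn function; odd function of x (default identity).
#' @return numeric vector `2 * base_pdf(x) * skewing_cdf(odd_fn(x))`.
#' @examples
#' # skew-normal with shape 2 at x = 1:
#' azzalini_skew(1, dnorm, pnorm, function(z) 2 * z)
#' @export
azzalini_skew <- function(x, base_pdf, skewing_cdf, odd_fn = identity) {
  stopifnot(is.function(base_pdf), is.function(skewing_cdf), is.function(odd_fn))
  2 * base_pdf(x) * skewing_cdf(odd_fn(x))
}

#' Skew-logistic density (standard form)
#'
#' \eqn{f_{sl}(x; \alpha) = 2 e^{-x} / \{(1 + e^{-x})^2 (1 + e^{-\alpha x})\}}:
#' the Azzalini construction with logistic base pdf, logistic skewing cdf
#' (both at unit rate) and linear odd function \eqn{\omega(x) = \alpha x}.
#' At `alpha = 0` it reduces to the standard logistic density.
#'
#' @param x numeric vector.
#' @param alpha skewness coefficient.
#' @param log logical; return the log-density.
#' @return numeric vector of densities.
#' @export
skew_logistic_pdf <- function(x, alpha = 0, log = FALSE) {
  fgsl_pdf(x, loc = 0, scale = 1, alpha = alpha, beta = 0, log = log)
}

# Cubic odd argument alpha*z + beta*z^3, guarded against Inf - Inf when both
# terms overflow with opposite signs (the cubic term dominates there).
cubic_odd <- function(z, alpha, beta) {
  w <- alpha * z + beta * z^3
  bad <- is.nan(w)
  if (any(bad)) w[bad] <- beta * z[bad]^3
  w
}

#' Flexible generalized skew-logistic (FGSL) density
#'
#' The location-scale skew-logistic density with a cubic odd skewing
#' argument: with \eqn{z = (y - \mu)/\sigma},
#' \deqn{f(y) = \frac{2}{\sigma} \cdot
#'   \frac{e^{-z}}{(1 + e^{-z})^2 \, (1 + e^{-\alpha z - \beta z^3})}.}
#' It integrates to 1 for every finite \eqn{(\alpha, \beta)}, reduces to the
#' location-scale skew-logistic at `beta = 0` and to the plain logistic
#' density at `alpha = beta = 0`, and can be unimodal or bimodal depending
#' on \eqn{(\alpha, \beta)}.
#'
#' Evaluation is carried out in log space
#' (`dlogis(log = TRUE)` + `plogis(log.p = TRUE)`), so the cubic exponent
#' cannot overflow to `NaN`/`Inf`: far tails return exactly 0.
#'
#' @param y numeric vector of evaluation points (ages, in the fertility use).
#' @param loc location \eqn{\mu} (years of age).
#' @param scale positive scale \eqn{\sigma} (years).
#' @param alpha linear skewness coefficient.
#' @param beta cubic skewness coefficient.
#' @param log logical; return the log-density.
#' @return numeric vector of densities.
#' @examples
#' fgsl_pdf(30, loc = 30, scale = 8)           # 1/(4*8)
#' integrate(fgsl_pdf, -60, 60, alpha = 2, beta = -1)$value
#' @export
fgsl_pdf <- function(y, loc = 0, scale = 1, alpha = 0, beta = 0, log = FALSE) {
  check_scale(scale)
  z <- (y - loc) / scale
  lf <- base::log(2) - base::log(scale) +
    stats::dlogis(z, log = TRUE) +
    stats::plogis(cubic_odd(z, alpha, beta), log.p = TRUE)
  if (log) lf else exp(lf)
}

#' Flexible generalized skew-normal (FGSN) density
#'
#' With \eqn{z = (y - \xi)/\omega}, returns
#' \eqn{(2/\omega)\,\phi(z)\,\Phi(\alpha z + \beta z^3)}. At `beta = 0` this
#' is the Azzalini skew-normal; at `alpha = beta = 0` the normal density.
#' The family has at most two modes.
#'
#' @inheritParams fgsl_pdf
#' @param loc location \eqn{\xi}.
#' @param scale positive scale \eqn{\omega}.
#' @return numeric vector of densities.
#' @export
fgsn_pdf <- function(y, loc = 0, scale = 1, alpha = 0, beta = 0, log = FALSE) {
  check_scale(scale)
  z <- (y - loc) / scale
  lf <- base::log(2) - base::log(scale) +
    stats::dnorm(z, log = TRUE) +
    stats::pnorm(cubic_odd(z, alpha, beta), log.p = TRUE)
  if (log) lf else exp(lf)
}

check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("'scale' must be a single finite value > 0", call. = FALSE)
  invisible(scale)
}

#' Hadwiger fertility function
#'
#' The classical three-parameter fertility curve, related to the
#' inverse-Gaussian density:
#' \deqn{g(x; a, b, c) = \frac{ab}{c}\left(\frac{c}{x}\right)^{3/2}
#'   \exp\left\{-b^2\left(\frac{c}{x} + \frac{x}{c} - 2\right)\right\}.}
#' The curve peaks near \eqn{x \approx c} with height \eqn{ab/c} at
#' \eqn{x = c}; \eqn{a} acts as the overall fertility level.
#'
#' @param x positive ages.
#' @param a,b,c positive shape/scale constants.
#' @return numeric vector of fertility rates.
#' @examples
#' hadwiger(28, a = 1, b = 2, c = 28)   # 2/28
#' @export
hadwiger <- function(x, a, b, c) {
  check_positive(a = a, b = b, c = c)
  if (any(x <= 0)) stop("Hadwiger function requires age x > 0", call. = FALSE)
  (a * b / c) * (c / x)^1.5 * exp(-b^2 * (c / x + x / c - 2))
}

#' Hadwiger mixture fertility function
#'
#' Two Hadwiger components with a shared level `a`, mixed with weight `m`:
#' `m * hadwiger(x, a, b1, c1) + (1 - m) * hadwiger(x, a, b2, c2)`. The
#' standard parametric choice for bimodal fertility schedules.
#'
#' @param x positive ages.
#' @param a shared positive level constant.
#' @param m mixture weight in `[0, 1]`.
#' @param b1,c1 constants of the first component.
#' @param b2,c2 constants of the second component.
#' @return numeric vector of fertility rates.
#' @export
hadwiger_mixture <- function(x, a, m, b1, b2, c1, c2) {
  if (!is.finite(m) || m < 0 || m > 1)
    stop("mixture weight 'm' must lie in [0, 1]", call. = FALSE)
  m * hadwiger(x, a, b1, c1) + (1 - m) * hadwiger(x, a, b2, c2)
}

#' Peristera-Kostaki normal-mixture fertility curve
#'
#' Sum of two unnormalized Gaussian bumps, implemented exactly in the form
#' this model class is published in — note there is no 1/2 factor in the
#' exponent and no normalizing constant; `c1`, `c2` are the component peak
#' heights directly:
#' \deqn{g(x) = c_1 e^{-\{(x-\mu_1)/\sigma_1\}^2} +
#'              c_2 e^{-\{(x-\mu_2)/\sigma_2\}^2}.}
#'
#' @param x ages.
#' @param c1,c2 nonnegative component amplitudes (peak rates).
#' @param mu1,mu2 component peak ages.
#' @param sigma1,sigma2 positive component widths.
#' @return numeric vector of fertility rates.
#' @export
normal_mixture <- function(x, c1, mu1, sigma1, c2, mu2, sigma2) {
  check_positive(sigma1 = sigma1, sigma2 = sigma2)
  if (c1 < 0 || c2 < 0)
    stop("amplitudes 'c1', 'c2' must be nonnegative", call. = FALSE)
  c1 * exp(-((x - mu1) / sigma1)^2) + c2 * exp(-((x - mu2) / sigma2)^2)
}

#' Quadratic-spline fertility curve
#'
#' Piecewise-quadratic fertility curve with compact support:
#' \eqn{g(x) = R \, I(\alpha \le x \le \beta) \sum_{k=0}^{4}
#' \theta_k (x - t_k)^2}. By default each term uses the truncated-power
#' convention (term k contributes only where \eqn{x \ge t_k}), the standard
#' reading for this spline class; `truncated = FALSE` sums all five
#' quadratic terms unconditionally (the strict-verbatim form).
#'
#' @param x ages.
#' @param R overall level (total fertility rate).
#' @param alpha_age,beta_age lower and upper age limits of the support.
#' @param theta numeric vector of 5 spline coefficients
#'   \eqn{\theta_0, \ldots, \theta_4}.
#' @param knots numeric vector of 5 nondecreasing knot ages
#'   \eqn{t_0, \ldots, t_4}.
#' @param truncated logical; use the truncated-power convention (default).
#' @return numeric vector of fertility rates, zero outside
#'   `[alpha_age, beta_age]`.
#' @export
quadratic_spline <- function(x, R, alpha_age, beta_age, theta, knots,
                             truncated = TRUE) {
  if (length(theta) != 5L || length(knots) != 5L)
    stop("'theta' and 'knots' must each have length 5", call. = FALSE)
  if (alpha_age >= beta_age)
    stop("'alpha_age' must be < 'beta_age'", call. = FALSE)
  if (is.unsorted(knots))
    stop("'knots' must be nondecreasing", call. = FALSE)
  out <- numeric(length(x))
  inside <- x >= alpha_age & x <= beta_age
  xi <- x[inside]
  s <- numeric(length(xi))
  for (k in seq_len(5L)) {
    term <- theta[k] * (xi - knots[k])^2
    if (truncated) term <- term * (xi >= knots[k])
    s <- s + term
  }
  out[inside] <- R * s
  out
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite value > 0", nm), call. = FALSE)
  }
  invisible(NULL)
}
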