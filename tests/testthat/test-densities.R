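test_that("logistic pdf/cdf match the closed forms and their symmetries", {
  expect_equal(logistic_pdf(0, lam = 1), 0.25)
  expect_equal(logistic_pdf(2), logistic_pdf(-2))
  # frozen 30-digit arbitrary-precision values (mpmath oracle)
  expect_equal(logistic_pdf(1, lam = 1), 0.196611933241481852537424733586,
               tolerance = 1e-15)
  expect_equal(logistic_cdf(1, lam = 1), 0.731058578630004879251159241822,
               tolerance = 1e-15)
  expect_equal(logistic_cdf(0, lam = 3.7), 0.5)
  expect_equal(logistic_cdf(1e6), 1)
  x <- seq(-8, 8, by = 0.5)
  expect_true(all(diff(logistic_cdf(x, lam = 2)) >= 0))
  expect_equal(logistic_cdf(x, lam = 2) + logistic_cdf(-x, lam = 2),
               rep(1, length(x)))
  expect_error(logistic_pdf(0, lam = 0), "> 0")
  expect_error(logistic_cdf(0, lam = -1), "> 0")
})

test_that("the Azzalini construction reduces, recenters and reflects correctly", {
  x <- seq(-5, 5, by = 0.25)
  # odd_fn identically zero: G(0) = 1/2 cancels the factor 2
  expect_equal(azzalini_skew(x, dnorm, pnorm, function(z) 0 * z), dnorm(x))
  # at x = 0 any odd function gives the base density back
  expect_equal(azzalini_skew(0, dnorm, pnorm, function(z) 3 * z - z^3),
               dnorm(0))
  # normal base + normal skewing cdf + linear odd fn is the skew-normal,
  # i.e. the cubic-skew family at beta = 0
  expect_equal(azzalini_skew(x, dnorm, pnorm, function(z) 1.7 * z),
               fgsn_pdf(x, loc = 0, scale = 1, alpha = 1.7, beta = 0))
})

test_that("reflection identity f(z)+f(-z) = 2 f0(z) holds for both skew families", {
  set.seed(11)
  for (i in 1:100) {
    z <- runif(1, -8, 8)
    a <- runif(1, -5, 5)
    b <- runif(1, -5, 5)
    expect_equal(fgsl_pdf(z, 0, 1, a, b) + fgsl_pdf(-z, 0, 1, a, b),
                 2 * dlogis(z), tolerance = 1e-13)
    expect_equal(fgsn_pdf(z, 0, 1, a, b) + fgsn_pdf(-z, 0, 1, a, b),
                 2 * dnorm(z), tolerance = 1e-13)
  }
})

test_that("skew-logistic density: trivial points, reduction and frozen oracle value", {
  expect_equal(skew_logistic_pdf(0, alpha = 0), 0.25)
  expect_equal(skew_logistic_pdf(0, alpha = 4.2), 0.25)
  expect_equal(skew_logistic_pdf(3, alpha = 0), logistic_pdf(3, lam = 1))
  # mpmath: 2 e^-1 / ((1+e^-1)^2 (1+e^-1))
  expect_equal(skew_logistic_pdf(1, alpha = 1),
               0.287469680914430261979904347784, tolerance = 1e-15)
})

test_that("FGSL density: central value, reductions and tail safety", {
  # at y = mu: (2/sigma) * (1/4) * (1/2) = 1/(4 sigma), for any skewness
  expect_equal(fgsl_pdf(30, loc = 30, scale = 8, alpha = 2.3, beta = -1.1),
               1 / 32)
  set.seed(21)
  y <- runif(20, 0, 60)
  expect_equal(fgsl_pdf(y, loc = 28, scale = 6),
               dlogis((y - 28) / 6) / 6, tolerance = 1e-14)
  # far tails underflow to 0, never NaN/Inf, even with the cubic active
  z <- c(-700, -350, 350, 700)
  v <- fgsl_pdf(z, 0, 1, alpha = 5, beta = -5)
  expect_true(all(is.finite(v)) && all(v >= 0))
  expect_equal(fgsl_pdf(1e7, 30, 8, 3, 2), 0)
  expect_error(fgsl_pdf(0, scale = 0), "> 0")
})

test_that("FGSL and FGSN integrate to 1 for strongly skewed shapes", {
  for (a in c(-5, -1, 0, 1, 5)) {
    for (b in c(-5, 0, 5)) {
      expect_equal(num_integral(fgsl_pdf, -60, 60, loc = 0, scale = 1,
                                alpha = a, beta = b), 1, tolerance = 1e-8)
      expect_equal(num_integral(fgsn_pdf, -15, 15, loc = 0, scale = 1,
                                alpha = a, beta = b), 1, tolerance = 1e-8)
    }
  }
})

test_that("FGSN density: central value, reductions to skew-normal and normal", {
  expect_equal(fgsn_pdf(28, loc = 28, scale = 6, alpha = 3, beta = 0.7),
               0.398942280401432677939946059934 / 6, tolerance = 1e-15)
  z <- seq(-8, 8, length.out = 1000)
  expect_equal(fgsn_pdf(z, 0, 1, alpha = 0, beta = 0), dnorm(z),
               tolerance = 1e-14)
  expect_equal(fgsn_pdf(z, 0, 1, alpha = 2, beta = 0),
               2 * dnorm(z) * pnorm(2 * z), tolerance = 1e-13)
  expect_error(fgsn_pdf(0, scale = -2), "> 0")
})

test_that("Hadwiger function peaks near c with height ab/c", {
  expect_equal(hadwiger(28, a = 1, b = 2, c = 28), 2 / 28)
  # mpmath oracle at (a,b,c,x) = (1,3,28,20)
  expect_equal(hadwiger(20, a = 1, b = 3, c = 28),
               0.0634530323273374880604070216308, tolerance = 1e-15)
  x <- seq(12, 55, by = 0.1)
  y <- hadwiger(x, a = 2, b = 3, c = 28)
  expect_lt(abs(x[which.max(y)] - 28), 3)  # mode sits slightly below c
  expect_error(hadwiger(0, 1, 2, 28), "x > 0")
  expect_error(hadwiger(20, -1, 2, 28), "> 0")
})

test_that("Hadwiger mixture degenerates correctly at m = 0, 1 and equal components", {
  x <- seq(13, 50, by = 0.5)
  expect_equal(hadwiger_mixture(x, 2, m = 1, 3, 5, 25, 35),
               hadwiger(x, 2, 3, 25))
  expect_equal(hadwiger_mixture(x, 2, m = 0, 3, 5, 25, 35),
               hadwiger(x, 2, 5, 35))
  expect_equal(hadwiger_mixture(x, 2, m = 0.5, 3, 3, 28, 28),
               hadwiger(x, 2, 3, 28))
  expect_error(hadwiger_mixture(x, 2, m = 1.2, 3, 3, 25, 35), "\\[0, 1\\]")
})

test_that("normal-mixture curve follows the published unnormalized form verbatim", {
  expect_equal(normal_mixture(25, c1 = 0.12, mu1 = 25, sigma1 = 4,
                              c2 = 0, mu2 = 35, sigma2 = 5), 0.12)
  x <- seq(15, 45, by = 0.5)
  expect_equal(normal_mixture(x, 0.1, 28, 5, 0.1, 28, 5),
               0.2 * exp(-((x - 28) / 5)^2))
  # one sigma away the bump drops by exactly e^-1 (no 1/2 in the exponent)
  expect_equal(normal_mixture(33, 0.1, 28, 5, 0, 30, 5),
               0.0367879441171442321595523770161, tolerance = 1e-15)
  expect_error(normal_mixture(30, 0.1, 28, -1, 0.1, 30, 5), "> 0")
  expect_error(normal_mixture(30, -0.1, 28, 5, 0.1, 30, 5), "nonnegative")
})

test_that("quadratic spline respects its support, truncation convention and knot order", {
  th0 <- c(1, 0, 0, 0, 0)
  kn <- c(15, 20, 25, 30, 40)
  expect_equal(quadratic_spline(5, R = 1, 10, 50, th0, kn), 0)
  expect_equal(quadratic_spline(55, R = 1, 10, 50, th0, kn), 0)
  expect_equal(quadratic_spline(seq(10, 50), 2, 10, 50, rep(0, 5), kn),
               rep(0, 41))
  expect_equal(quadratic_spline(20, R = 1, 10, 50, th0, kn), 25)
  # truncated mode drops terms left of their knot; verbatim mode keeps them
  th <- c(1, -1, 0, 0, 0)
  expect_equal(quadratic_spline(18, 1, 10, 50, th, kn), 9)          # (18-15)^2
  expect_equal(quadratic_spline(18, 1, 10, 50, th, kn, truncated = FALSE),
               9 - 4)                                               # - (18-20)^2
  expect_error(quadratic_spline(20, 1, 10, 50, th0, c(20, 15, 25, 30, 40)),
               "nondecreasing")
  expect_error(quadratic_spline(20, 1, 50, 10, th0, kn), "alpha_age")
})

test_that("all densities are nonnegative and finite over wide shape sweeps", {
  x <- seq(-50, 110, by = 0.5)
  for (a in c(-5, 0, 5)) {
    for (b in c(-5, 0, 5)) {
      for (f in list(fgsl_pdf, fgsn_pdf)) {
        v <- f(x, loc = 30, scale = 8, alpha = a, beta = b)
        expect_true(all(is.finite(v)) && all(v >= 0))
      }
    }
  }
})
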