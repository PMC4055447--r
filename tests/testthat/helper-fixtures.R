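# Shared fixtures and small numerical helpers for the suite.

# canonical skew-logistic truths used across fitting/diagnostics tests
fgsl_truth <- c(R = 1.3, mu = 29, sigma = 7, alpha = 1.2, beta = 0.4)
bimodal_truth <- c(R = 1.8, mu = 30, sigma = 8, alpha = 1, beta = -0.8)

noiseless_schedule <- function(model, params, ages = 12:50) {
  generate_schedule(model, params, ages = ages, noise_sd = 0)
}

# adaptive-quadrature oracle for density normalization checks
num_integral <- function(f, lower, upper, ...) {
  stats::integrate(f, lower, upper, ..., subdivisions = 2000L,
                   rel.tol = 1e-11, abs.tol = 1e-13)$value
}

# independent brute-force mode counter on a plain grid (no refinement);
# used to cross-check count_modes
grid_mode_count <- function(y) {
  keep <- c(TRUE, diff(y) != 0)
  y <- y[keep]
  m <- length(y)
  if (m < 3L) return(0L)
  sum(y[2:(m - 1L)] > y[1:(m - 2L)] & y[2:(m - 1L)] > y[3:m])
}
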