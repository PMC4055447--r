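#' Count the modes of a fitted fertility curve
#'
#' Locates the strict local maxima of a model curve on a dense age grid and
#' refines each candidate by golden-section search on its bracketing
#' interval. Plateaus (runs of equal grid values) count as a single mode.
#' Grid-based detection is used because the skew families' derivative — a
#' cubic inside an exponential — has no closed-form roots.
#'
#' The two flexible skew families are provably (skew-normal base) or
#' empirically (skew-logistic base) limited to at most two modes over the
#' usual skewness box; [count_modes()] is how that bound is checked.
#'
#' @inheritParams evaluate_model
#' @param lower,upper evaluation range; defaults to a model-specific
#'   support (location +/- 10 scales for the skew families).
#' @param n_grid number of grid points (>= 1000).
#' @return an object of class `mode_report`: list with `mode_ages`
#'   (ascending), `mode_heights`, and `n_modes`.
#' @examples
#' count_modes("skew_logistic_fgsl",
#'             c(R = 1, mu = 30, sigma = 8, alpha = 0, beta = 0))$n_modes
#' @export
count_modes <- function(model, params, lower = NULL, upper = NULL,
                        n_grid = 4001) {
  model <- fertility_model(model)
  params <- conform_params(model, params)
  if (n_grid < 1000)
    stop("'n_grid' must be at least 1000 for reliable mode detection",
         call. = FALSE)
  if (is.null(lower) || is.null(upper)) {
    supp <- model$support_fun(params)
    if (is.null(lower)) lower <- supp[1L]
    if (is.null(upper)) upper <- supp[2L]
  }
  x <- seq(lower, upper, length.out = n_grid)
  y <- model$eval_fun(params, x)

  # collapse plateaus: keep the first point of each run of equal values
  keep <- c(TRUE, diff(y) != 0)
  xk <- x[keep]
  yk <- y[keep]
  m <- length(yk)
  if (m < 3L)
    return(structure(list(mode_ages = numeric(0), mode_heights = numeric(0),
                          n_modes = 0L), class = "mode_report"))
  idx <- which(yk[2:(m - 1L)] > yk[1:(m - 2L)] &
               yk[2:(m - 1L)] > yk[3:m]) + 1L

  f1 <- function(z) model$eval_fun(params, z)
  ages <- heights <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    opt <- stats::optimize(f1, c(xk[i - 1L], xk[i + 1L]), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    ages[j] <- opt$maximum
    heights[j] <- opt$objective
  }
  ord <- order(ages)
  structure(list(mode_ages = ages[ord], mode_heights = heights[ord],
                 n_modes = length(ages)),
            class = "mode_report")
}

#' @export
print.mode_report <- function(x, ...) {
  cat(sprintf("%d mode(s)\n", x$n_modes))
  if (x$n_modes > 0)
    print(data.frame(age = x$mode_ages, height = x$mode_heights))
  invisible(x)
}

#' Fit several fertility models to one schedule and rank them
#'
#' Fits every requested family to the same observed schedule (same
#' multistart seed for each) and ranks them by residual sum of squares,
#' ascending — the standard comparison criterion for these curves. The
#' report also carries each family's parameter count, so parsimony can be
#' weighed against raw fit, and the full per-age residual table. An
#' individual fit failure is recorded in its row rather than aborting the
#' comparison.
#'
#' @param models character vector of at least two model identifiers.
#' @inheritParams fit_model
#' @param ... further arguments passed to [fit_model()] (e.g. `n_starts`).
#' @return an object of class `fert_comparison`: list with `label`,
#'   `table` (data frame: model, n_params, resnorm, converged, rank),
#'   `residuals` (data frame: age plus one column per model), and `fits`
#'   (the underlying `fert_fit` objects).
#' @export
compare_models <- function(models, schedule, n_starts = 8, seed = 1, ...) {
  if (!is.character(models) || length(models) < 2L)
    stop("'models' must name at least two families to compare", call. = FALSE)
  schedule <- as_schedule(schedule)
  fits <- lapply(models, function(m) {
    tryCatch(fit_model(m, schedule, n_starts = n_starts, seed = seed, ...),
             error = function(e) structure(
               list(model = m, resnorm = NA_real_, converged = FALSE,
                    failure_messages = conditionMessage(e),
                    residuals = rep(NA_real_, nrow(schedule))),
               class = "fert_fit"))
  })
  names(fits) <- models
  resnorms <- vapply(fits, function(f) f$resnorm, 0)
  tab <- data.frame(
    model = models,
    n_params = vapply(models, n_params, 0L),
    resnorm = resnorms,
    converged = vapply(fits, function(f) isTRUE(f$converged), NA),
    row.names = NULL
  )
  # ascending resnorm; NA (failed) last; ties break by input order
  tab$rank <- rank_with_ties(tab$resnorm)
  resid_tab <- data.frame(age = schedule$age)
  for (m in models) resid_tab[[m]] <- fits[[m]]$residuals
  structure(list(label = attr(schedule, "label") %||% "",
                 table = tab, residuals = resid_tab, fits = fits),
            class = "fert_comparison")
}

rank_with_ties <- function(v) {
  ord <- order(v, seq_along(v), na.last = TRUE)
  r <- integer(length(v))
  r[ord] <- seq_along(v)
  r
}

#' @export
print.fert_comparison <- function(x, digits = 6, ...) {
  cat("Fertility model comparison")
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  cat(" — ranked by resnorm (ascending):\n")
  tab <- x$table[order(x$table$rank), ]
  tab$resnorm <- signif(tab$resnorm, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param x a `fert_comparison` object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
comparison_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "fert_comparison"))
  payload <- list(
    label = x$label,
    models = x$table,
    residuals = x$residuals,
    params = lapply(x$fits, function(f) as.list(f$params))
  )
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Residual overlay plot for a model comparison
#'
#' Signed residuals (fitted minus observed) by age, one line per model —
#' the visual summary used to judge which family tracks an ASFR schedule
#' most closely.
#'
#' @param x a `fert_comparison` object.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return the comparison, invisibly.
#' @export
plot.fert_comparison <- function(x, ...) {
  r <- x$residuals
  mods <- setdiff(names(r), "age")
  graphics::matplot(r$age, as.matrix(r[mods]), type = "b", pch = 1:length(mods),
                    lty = 1, xlab = "age", ylab = "residual",
                    main = "Residuals by model", ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::legend("topright", legend = mods, col = seq_along(mods),
                   pch = seq_along(mods), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
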