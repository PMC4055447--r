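#' Construct an age-specific fertility schedule
#'
#' An ASFR schedule pairs ages over the fertile period with observed
#' fertility rates (births per woman per year by default). It is stored as
#' a two-column data frame with class `asfr_schedule` and a `label`
#' attribute recording provenance.
#'
#' @param ages strictly increasing numeric ages in years (at least 4).
#' @param rates nonnegative fertility rates, same length as `ages`.
#' @param label free-text provenance string.
#' @return an object of class `asfr_schedule` (a data frame with columns
#'   `age` and `asfr`).
#' @examples
#' s <- asfr_schedule(20:45, fgsl_pdf(20:45, loc = 29, scale = 6) * 1.4)
#' s
#' @export
asfr_schedule <- function(ages, rates, label = "") {
  if (!is.numeric(ages) || !is.numeric(rates))
    stop("'ages' and 'rates' must be numeric", call. = FALSE)
  if (length(ages) != length(rates))
    stop("'ages' and 'rates' must have the same length", call. = FALSE)
  if (length(ages) < 4L)
    stop("a schedule needs at least 4 age points", call. = FALSE)
  if (anyNA(ages) || anyNA(rates) || !all(is.finite(ages)) || !all(is.finite(rates)))
    stop("ages and rates must be finite and non-missing", call. = FALSE)
  if (any(diff(ages) <= 0))
    stop("'ages' must be strictly increasing", call. = FALSE)
  if (any(rates < 0))
    stop("fertility rates must be nonnegative", call. = FALSE)
  out <- data.frame(age = as.numeric(ages), asfr = as.numeric(rates))
  class(out) <- c("asfr_schedule", "data.frame")
  attr(out, "label") <- as.character(label)[1L]
  out
}

#' @export
print.asfr_schedule <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("ASFR schedule: %d ages %g-%g, peak rate %.4g",
              nrow(x), min(x$age), max(x$age), max(x$asfr)))
  if (!is.null(lab) && nzchar(lab)) cat(sprintf(" [%s]", lab))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @rdname asfr_schedule
#' @param x object to test.
#' @export
is_asfr_schedule <- function(x) inherits(x, "asfr_schedule")

as_schedule <- function(x) {
  if (is_asfr_schedule(x)) return(x)
  if (is.data.frame(x) && all(c("age", "asfr") %in% names(x)))
    return(asfr_schedule(x$age, x$asfr))
  stop("expected an 'asfr_schedule' (see asfr_schedule())", call. = FALSE)
}
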