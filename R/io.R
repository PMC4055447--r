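#' Read an ASFR schedule from a file
#'
#' Two layouts are supported:
#' \describe{
#'   \item{`csv`}{two-column CSV with header `age,asfr`, one row per age.}
#'   \item{`hfd`}{whitespace-delimited Human Fertility Database period
#'     ASFR layout with columns `Year`, `Age`, `ASFR` (as in HFD asfrRR
#'     files). Open-ended age labels are recoded per HFD convention
#'     (`"12-"` to 12, `"55+"` to 55); missing-value markers `"."` are
#'     dropped with a warning. Multi-year files require `year`.}
#' }
#'
#' @param path file path.
#' @param dialect `"csv"` or `"hfd"`.
#' @param year optional year filter for multi-year HFD files.
#' @return an [asfr_schedule()]; its label records the file and year.
#' @export
read_schedule <- function(path, dialect = c("csv", "hfd"), year = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "csv") read_schedule_csv(path) else read_schedule_hfd(path, year)
}

read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("age", "asfr") %in% names(df)))
    stop(sprintf("CSV schedule must have header 'age,asfr'; got: %s",
                 paste(names(df), collapse = ",")), call. = FALSE)
  age <- suppressWarnings(as.numeric(df$age))
  rate <- suppressWarnings(as.numeric(df$asfr))
  bad <- which(is.na(age) | is.na(rate))
  if (length(bad))
    stop(sprintf("unparseable schedule rows at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path), call. = FALSE)
  check_duplicate_ages(age)
  ord <- order(age)
  asfr_schedule(age[ord], rate[ord], label = basename(path))
}

read_schedule_hfd <- function(path, year = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*Year\\s+Age\\s+ASFR", lines)
  if (length(hdr) == 0L)
    stop(sprintf("no 'Year Age ASFR' header found in %s", path), call. = FALSE)
  body_idx <- seq.int(hdr[1L] + 1L, length(lines))
  body <- lines[body_idx]
  nonblank <- nzchar(trimws(body))
  body <- body[nonblank]
  lineno <- body_idx[nonblank]
  if (length(body) == 0L)
    stop(sprintf("no data rows in %s", path), call. = FALSE)

  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("unparseable HFD rows at line(s) %s of %s",
                 paste(lineno[nf < 3L], collapse = ", "), path), call. = FALSE)
  yr <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  age_lab <- vapply(fields, `[[`, "", 2L)
  rate_lab <- vapply(fields, `[[`, "", 3L)

  bad <- is.na(yr)
  if (any(bad))
    stop(sprintf("unparseable Year at line(s) %s of %s",
                 paste(lineno[bad], collapse = ", "), path), call. = FALSE)
  if (!is.null(year)) {
    keep <- yr == year
    if (!any(keep))
      stop(sprintf("no rows for year %s in %s (years present: %s)",
                   year, path, paste(sort(unique(yr)), collapse = ", ")),
           call. = FALSE)
    age_lab <- age_lab[keep]; rate_lab <- rate_lab[keep]; lineno <- lineno[keep]
  } else if (length(unique(yr)) > 1L) {
    stop(sprintf("%s contains multiple years (%s); pass 'year' to select one",
                 path, paste(sort(unique(yr)), collapse = ", ")), call. = FALSE)
  }

  # HFD open-age recoding: "12-" -> 12, "55+" -> 55
  age <- suppressWarnings(as.numeric(sub("[-+]$", "", age_lab)))
  if (anyNA(age))
    stop(sprintf("unparseable Age at line(s) %s of %s",
                 paste(lineno[is.na(age)], collapse = ", "), path),
         call. = FALSE)

  missing <- rate_lab == "."
  if (any(missing)) {
    warning(sprintf("dropping %d missing-value ('.') row(s) from %s",
                    sum(missing), path), call. = FALSE)
    age <- age[!missing]; rate_lab <- rate_lab[!missing]
    lineno <- lineno[!missing]
  }
  rate <- suppressWarnings(as.numeric(rate_lab))
  if (anyNA(rate))
    stop(sprintf("unparseable ASFR at line(s) %s of %s",
                 paste(lineno[is.na(rate)], collapse = ", "), path),
         call. = FALSE)
  if (length(age) == 0L)
    stop(sprintf("no usable rows left in %s", path), call. = FALSE)
  check_duplicate_ages(age)
  ord <- order(age)
  lab <- if (is.null(year)) basename(path)
         else sprintf("%s year %s", basename(path), year)
  asfr_schedule(age[ord], rate[ord], label = lab)
}

check_duplicate_ages <- function(age) {
  dup <- unique(age[duplicated(age)])
  if (length(dup))
    stop(sprintf("duplicate age row(s) for age(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  invisible(age)
}

#' Write an ASFR schedule to a file
#'
#' Rates are written with 10 significant digits, so a write/read round
#' trip reproduces the schedule to better than 1e-9.
#'
#' @param schedule an [asfr_schedule()].
#' @param path destination file path.
#' @param dialect `"csv"` (header `age,asfr`) or `"hfd"` (header
#'   `Year Age ASFR`).
#' @param year year written in the HFD layout (default 2000).
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, dialect = c("csv", "hfd"),
                           year = 2000L) {
  dialect <- match.arg(dialect)
  schedule <- as_schedule(schedule)
  num <- function(v) sprintf("%.10g", v)
  if (dialect == "csv") {
    lines <- c("age,asfr",
               paste(num(schedule$age), num(schedule$asfr), sep = ","))
  } else {
    lines <- c("Year Age ASFR",
               sprintf("%d %s %s", as.integer(year), num(schedule$age),
                       num(schedule$asfr)))
  }
  writeLines(lines, path)
  invisible(path)
}
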