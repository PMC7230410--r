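#' A single tolerance-test glucose curve
#'
#' Container for one measured or simulated curve: subject, animal group,
#' test type and the (time, glucose) observations. The canonical protocol
#' grids are `protocol_grid("GTT")` = 0,15,30,45,60,90,120,240 min and
#' `protocol_grid("ITT")` = 0,15,30,45,60,90,120,180 min, but arbitrary
#' strictly increasing grids starting at 0 are accepted.
#'
#' @param subject_id subject identifier (coerced to character).
#' @param group group label; the study groups are `young_male`,
#'   `young_female`, `adult_male`, `adult_female`, but any label is allowed.
#' @param test `"GTT"` or `"ITT"`.
#' @param times sampling times in minutes; strictly increasing, first 0.
#' @param glucose glucose in mmol/L; same length as `times`, all positive.
#' @return An object of class `"glucose_series"`.
#' @export
glucose_series <- function(subject_id, group, test, times, glucose) {
  test <- match.arg(test, c("GTT", "ITT"))
  times <- as.numeric(times)
  glucose <- as.numeric(glucose)
  if (length(times) < 2L)
    stop("a glucose series needs at least 2 points", call. = FALSE)
  if (length(times) != length(glucose))
    stop("times and glucose must have the same length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(glucose)))
    stop("times and glucose must be finite", call. = FALSE)
  if (times[1] != 0)
    stop("the first time point must be 0 (baseline)", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (no duplicates)", call. = FALSE)
  if (any(glucose <= 0))
    stop("glucose values must be positive", call. = FALSE)
  structure(list(subject_id = as.character(subject_id)[1],
                 group = as.character(group)[1],
                 test = test, times = times, glucose = glucose),
            class = "glucose_series")
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf("<glucose_series> %s | %s | %s | %d points\n",
              x$subject_id, x$group, x$test, length(x$times)))
  print(stats::setNames(x$glucose, x$times))
  invisible(x)
}

#' Canonical sampling grid of a tolerance-test protocol
#'
#' @param test `"GTT"` or `"ITT"`.
#' @return Numeric vector of sampling times in minutes (8 points).
#' @export
protocol_grid <- function(test = c("GTT", "ITT")) {
  test <- match.arg(test)
  if (test == "GTT") c(0, 15, 30, 45, 60, 90, 120, 240)
  else c(0, 15, 30, 45, 60, 90, 120, 180)
}

#' @export
as.data.frame.glucose_series <- function(x, ...) {
  data.frame(subject_id = x$subject_id, group = x$group, test = x$test,
             time_min = x$times, glucose_mmol_per_l = x$glucose,
             stringsAsFactors = FALSE)
}

#' Convert a cohort (list of series) to a long data frame
#'
#' @param cohort a list of [glucose_series()] objects.
#' @return Long-format data frame with columns `subject_id`, `group`,
#'   `test`, `time_min`, `glucose_mmol_per_l`.
#' @export
cohort_to_df <- function(cohort) {
  stopifnot(length(cohort) > 0L,
            all(vapply(cohort, inherits, logical(1), "glucose_series")))
  do.call(rbind, lapply(cohort, as.data.frame))
}

#' Read tolerance-test curves from a long-format CSV
#'
#' Expects columns `subject_id`, `group`, `test`, `time_min`,
#' `glucose_mmol_per_l`. Rows are grouped by subject x test, ordered by
#' time, validated against the series invariants; duplicated
#' (subject, test, time) triples or non-numeric glucose are rejected with
#' the offending rows named.
#'
#' @param path path to a CSV file (UTF-8, '.' decimal separator).
#' @return A list of [glucose_series()] objects.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("subject_id", "group", "test", "time_min", "glucose_mmol_per_l")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("input file contains no data rows: ", path, call. = FALSE)
  for (col in c("time_min", "glucose_mmol_per_l")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L)
      stop("non-numeric ", col, " in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    df[[col]] <- v
  }
  key <- paste(df$subject_id, df$test, df$time_min, sep = "\r")
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup) > 0L)
    stop("duplicated (subject, test, time) in row(s): ",
         paste(utils::head(sort(dup), 10), collapse = ", "), call. = FALSE)
  pieces <- split(df, list(df$subject_id, df$test), drop = TRUE)
  out <- lapply(pieces, function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    glucose_series(d$subject_id[1], d$group[1], d$test[1],
                   d$time_min, d$glucose_mmol_per_l)
  })
  names(out) <- NULL
  out[order(vapply(out, function(s) paste(s$test, s$subject_id), ""))]
}

#' Write a cohort to a long-format CSV
#'
#' @param cohort list of [glucose_series()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(cohort, path) {
  utils::write.csv(cohort_to_df(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read curves from a wide-format CSV (one column per time point)
#'
#' Convenience importer: columns `subject_id`, `group`, `test` plus one
#' numeric column per sampling time, named either like `t0, t15, ...` or
#' plainly `0, 15, ...` (R prefixes these with `X` on read).
#'
#' @param path path to the wide CSV.
#' @return A list of [glucose_series()] objects.
#' @export
read_timeseries_wide <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("subject_id", "group", "test")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  tcols <- setdiff(names(df), need)
  tvals <- suppressWarnings(as.numeric(sub("^[Xt]", "", tcols)))
  if (any(is.na(tvals)))
    stop("time columns must be named like t0, t15, ... (got: ",
         paste(tcols[is.na(tvals)], collapse = ", "), ")", call. = FALSE)
  ord <- order(tvals)
  lapply(seq_len(nrow(df)), function(i) {
    glucose_series(df$subject_id[i], df$group[i], df$test[i],
                   tvals[ord], as.numeric(df[i, tcols[ord]]))
  })
}
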