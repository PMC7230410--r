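#' Trapezoidal area under a measured glucose curve
#'
#' Classical AUC on the raw observations:
#' \eqn{\sum_i (t_{i+1}-t_i)(y_i+y_{i+1})/2} over the full grid. Exact for
#' piecewise-linear curves.
#'
#' @param series a [glucose_series()], or a numeric vector of times when
#'   `glucose` is supplied.
#' @param glucose glucose values matching `series` given as a time vector.
#' @return AUC in mmol*min/L.
#' @examples
#' trapezoid_auc(protocol_grid("GTT"), rep(5, 8))  # 1200
#' @export
trapezoid_auc <- function(series, glucose = NULL) {
  if (inherits(series, "glucose_series")) {
    t <- series$times; y <- series$glucose
  } else {
    t <- as.numeric(series); y <- as.numeric(glucose)
  }
  if (length(t) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(t) != length(y))
    stop("times and glucose must have the same length", call. = FALSE)
  if (any(diff(t) == 0)) stop("duplicated time points", call. = FALSE)
  if (any(diff(t) < 0)) stop("times must be increasing", call. = FALSE)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Shapiro–Wilk normality screen
#'
#' Advisory normality check of per-group AUC samples; the comparison
#' pipeline proceeds nonparametrically regardless of its outcome.
#'
#' @param values numeric sample, 3 <= n <= 50 for a defined test.
#' @return List with `W` and `p` (both `NA` with a `note` when n < 3 or the
#'   sample is degenerate).
#' @export
shapiro_normality <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L)
    return(list(W = NA_real_, p = NA_real_, note = "n < 3"))
  if (stats::sd(values) == 0)
    return(list(W = NA_real_, p = NA_real_, note = "zero variance"))
  if (n > 50L)
    stop("Shapiro-Wilk screen limited to n <= 50", call. = FALSE)
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, note = "")
}

default_contrasts <- function(groups) {
  cand <- list(c("young_male", "adult_male"),
               c("young_female", "adult_female"))
  keep <- Filter(function(p) all(p %in% groups), cand)
  if (length(keep) == 0L)
    stop("groups do not match the default young-vs-adult within-sex ",
         "contrasts; supply `comparisons` explicitly", call. = FALSE)
  keep
}

#' Rank-based group comparison of AUCs with Bonferroni correction
#'
#' Two-sided Mann–Whitney test per requested pair (exact when both samples
#' are small and tie-free, normal approximation with tie correction
#' otherwise), Bonferroni-adjusted over the number of requested comparisons:
#' `p_adjusted = min(1, k * p_raw)`, significant when `p_adjusted < alpha`.
#' The default contrast set is the two within-sex, across-age pairs
#' (young vs adult males; young vs adult females), k = 2.
#'
#' @param aucs either a named list of numeric vectors (one per group) or a
#'   data frame with columns `group` and `auc`.
#' @param comparisons list of length-2 character vectors naming group pairs;
#'   `NULL` selects the default within-sex contrasts.
#' @param alpha significance level (default 0.05).
#' @return Data frame with one row per comparison: `group_a`, `group_b`,
#'   `statistic` (rank-sum U of group_a), `p_raw`, `p_adjusted`,
#'   `significant`.
#' @examples
#' compare_groups(list(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13)),
#'                comparisons = list(c("a", "b")))
#' @export
compare_groups <- function(aucs, comparisons = NULL, alpha = 0.05) {
  if (is.data.frame(aucs)) {
    stopifnot(all(c("group", "auc") %in% names(aucs)))
    aucs <- split(aucs$auc, aucs$group)
  }
  stopifnot(is.list(aucs), !is.null(names(aucs)))
  if (is.null(comparisons)) comparisons <- default_contrasts(names(aucs))
  if (length(comparisons) == 0L)
    stop("comparisons must be non-empty", call. = FALSE)
  k <- length(comparisons)
  rows <- lapply(comparisons, function(pair) {
    stopifnot(length(pair) == 2L)
    x <- as.numeric(aucs[[pair[1]]])
    yv <- as.numeric(aucs[[pair[2]]])
    if (length(x) == 0L || length(yv) == 0L)
      stop("empty group in comparison ", pair[1], " vs ", pair[2],
           call. = FALSE)
    ties <- any(duplicated(c(x, yv)))
    use_exact <- !ties && length(x) <= 8L && length(yv) <= 8L
    wt <- suppressWarnings(
      stats::wilcox.test(x, yv, exact = use_exact, correct = TRUE))
    data.frame(group_a = pair[1], group_b = pair[2],
               statistic = unname(wt$statistic),
               p_raw = wt$p.value,
               p_adjusted = min(1, k * wt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Classify a glucose concentration into glycemic bands
#'
#' Bands: severe hypoglycemia below 2.2 mmol/L, hypoglycemia [2.2, 4.2),
#' normoglycemia [4.2, 5.5] and hyperglycemia above 5.5 mmol/L.
#'
#' @param value glucose concentration(s), mmol/L, > 0. Vectorized.
#' @return Character vector in
#'   `c("severe_hypo", "hypo", "normo", "hyper")`.
#' @examples
#' classify_glycemia(c(2.0, 3.1, 5.0, 7.0))
#' @export
classify_glycemia <- function(value) {
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("glucose must be positive and finite", call. = FALSE)
  ifelse(value < 2.2, "severe_hypo",
         ifelse(value < 4.2, "hypo",
                ifelse(value <= 5.5, "normo", "hyper")))
}
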