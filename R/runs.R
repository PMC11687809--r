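#' Extract run lengths from a numeric time series
#'
#' A "run" is a maximal streak of consecutive moves in the same direction:
#' the series is differenced, and consecutive differences with the same sign
#' are grouped. Run length is measured in moves (a streak of `N` consecutive
#' up-days is a run of length `N`). Adjacent runs alternate direction by
#' construction.
#'
#' Zero differences (consecutive equal values) have no direction, and their
#' treatment is a modelling choice that must be made explicitly:
#' * `"error"` -- refuse series containing ties;
#' * `"break"` -- a tie terminates the current run; the next non-zero move
#'   starts a new run (possibly in the same direction);
#' * `"drop"` -- remove the tied observation and recompute differences, so
#'   a flat day inside an up-trend does not interrupt it.
#'
#' @param series Numeric vector, at least 2 observations in time order.
#' @param zero_policy One of `"error"`, `"break"`, `"drop"`; no default.
#' @return A tibble with columns `length` (positive integer) and
#'   `direction` (`"up"`/`"down"`), one row per run.
#' @examples
#' runs_from_series(c(1, 2, 3, 2, 1, 2), zero_policy = "error")
#' @export
runs_from_series <- function(series, zero_policy) {
  if (missing(zero_policy)) {
    stop("`zero_policy` must be given explicitly (\"error\", \"break\" or ",
         "\"drop\"): how tied consecutive values are treated changes the ",
         "run decomposition.", call. = FALSE)
  }
  zero_policy <- match.arg(zero_policy, c("error", "break", "drop"))
  if (!is.numeric(series) || length(series) < 2L || any(!is.finite(series))) {
    stop("`series` must be a finite numeric vector of length >= 2.",
         call. = FALSE)
  }
  d <- diff(series)
  if (zero_policy == "drop") {
    while (any(d == 0)) {
      series <- series[-(which(d == 0)[1] + 1L)]
      if (length(series) < 2L) break
      d <- diff(series)
    }
    if (length(series) < 2L) d <- numeric(0)
  } else if (any(d == 0)) {
    if (zero_policy == "error") {
      stop("Series contains tied consecutive values (zero difference at ",
           "position ", which(d == 0)[1], "); choose zero_policy ",
           "\"break\" or \"drop\", or clean the series.", call. = FALSE)
    }
  }
  sgn <- sign(d)
  if (!any(sgn != 0)) {
    stop("Series has no non-zero moves; no runs can be extracted.",
         call. = FALSE)
  }
  # maximal streaks; a zero sign (policy "break") closes the current run
  streaks <- rle(sgn)
  keep <- streaks$values != 0
  tibble::tibble(
    length = as.integer(streaks$lengths[keep]),
    direction = ifelse(streaks$values[keep] > 0, "up", "down")
  )
}

#' Tally run lengths into a frequency table
#'
#' Pools upward and downward runs (the geometric run-length model does not
#' distinguish direction) and counts each observed length.
#'
#' @param runs A tibble as returned by [runs_from_series()].
#' @return A frequency-table tibble (see [as_freq_table()]).
#' @examples
#' runs_to_freq_table(runs_from_series(c(1, 2, 3, 2, 1, 2), "error"))
#' @export
runs_to_freq_table <- function(runs) {
  if (!is.data.frame(runs) || !("length" %in% names(runs)) ||
      nrow(runs) == 0L) {
    stop("`runs` must be a non-empty data frame with a `length` column.",
         call. = FALSE)
  }
  as_freq_table(runs$length)
}

#' Read a numeric series from a delimited file
#'
#' One value per row; an optional leading date/label column is ignored
#' beyond establishing row order. Comma or tab delimiters are auto-detected.
#'
#' @param path File path.
#' @return A numeric vector.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  has_header <- is.na(suppressWarnings(
    as.numeric(utils::tail(strsplit(first, delim, fixed = TRUE)[[1]], 1))))
  df <- readr::read_delim(path, delim = delim, col_names = has_header,
                          col_types = readr::cols(), progress = FALSE)
  x <- df[[ncol(df)]]
  if (!is.numeric(x)) {
    stop("Last column of ", path, " is not numeric.", call. = FALSE)
  }
  x
}
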