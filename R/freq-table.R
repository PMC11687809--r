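#' Frequency tables of positive-integer outcomes
#'
#' A frequency table records the observed count `o_i` for each outcome value
#' `i = 1, ..., k`, where `k` is the last value with a positive count. The
#' internal representation is dense: interior zero-count cells between 1 and
#' `k` are retained (they still contribute cumulative-deviation terms),
#' while trailing empty cells above `k` are dropped, so `k` is always defined
#' by the data.
#'
#' `as_freq_table()` accepts either a data frame with `value` and `count`
#' columns or a raw vector of positive-integer observations (which it
#' tallies). Counts may be fractional at this layer so that exact-fit
#' fixtures with expected counts `n * p_i` can be represented; file readers
#' enforce integer counts.
#'
#' @param x A data frame with columns `value` (positive integers, no
#'   duplicates) and `count` (non-negative), or a vector of positive-integer
#'   observations.
#' @param ... Passed between methods.
#' @return A tibble with columns `value` (`1:k`) and `count`, at least one
#'   observation, `count[k] > 0`.
#' @examples
#' as_freq_table(c(1, 1, 2, 4))
#' as_freq_table(data.frame(value = c(1, 2, 4), count = c(2, 1, 1)))
#' @export
as_freq_table <- function(x, ...) {
  UseMethod("as_freq_table")
}

#' @rdname as_freq_table
#' @export
as_freq_table.data.frame <- function(x, ...) {
  if (!all(c("value", "count") %in% names(x))) {
    stop("A frequency table needs `value` and `count` columns.",
         call. = FALSE)
  }
  value <- x$value
  count <- x$count
  if (length(value) == 0L) {
    stop("Empty frequency table: no observations.", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 1) || any(value != trunc(value))) {
    stop("`value` entries must be positive integers (outcome values start ",
         "at 1).", call. = FALSE)
  }
  if (anyDuplicated(value)) {
    stop("Duplicate `value` rows in frequency table.", call. = FALSE)
  }
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("`count` entries must be finite and non-negative.", call. = FALSE)
  }
  if (sum(count) <= 0) {
    stop("Empty frequency table: all counts are zero.", call. = FALSE)
  }
  k <- max(value[count > 0])
  dense <- numeric(k)
  keep <- value <= k
  dense[value[keep]] <- count[keep]
  out <- tibble::tibble(value = seq_len(k), count = dense)
  class(out) <- c("freq_table", class(out))
  out
}

#' @rdname as_freq_table
#' @export
as_freq_table.freq_table <- function(x, ...) x

#' @rdname as_freq_table
#' @export
as_freq_table.default <- function(x, ...) {
  x <- as.numeric(x)
  if (length(x) == 0L) {
    stop("Empty sample: no observations.", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 1) || any(x != trunc(x))) {
    stop("Raw observations must be positive integers.", call. = FALSE)
  }
  counts <- tabulate(as.integer(x))
  as_freq_table(tibble::tibble(value = seq_along(counts), count = counts))
}

n_obs <- function(tab) sum(tab$count)
k_cells <- function(tab) nrow(tab)

#' Read a frequency table or raw sample from disk
#'
#' Two plain-text layouts are supported. `format = "counts"` expects a
#' delimited file (comma or tab, auto-detected) with header columns
#' `value,count`: positive-integer values without duplicates and
#' non-negative integer counts. `format = "sample"` expects one
#' positive-integer observation per line, which is tallied. With
#' `format = "auto"` a file whose first line contains a delimiter and a
#' `value` field is treated as counts, otherwise as a raw sample.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"counts"`, `"sample"`.
#' @return A frequency-table tibble (see [as_freq_table()]).
#' @export
read_freq_table <- function(path, format = c("auto", "counts", "sample")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  if (format == "auto") {
    format <- if (grepl("value", first, ignore.case = TRUE)) "counts" else "sample"
  }
  if (format == "counts") {
    delim <- if (grepl("\t", first)) "\t" else ","
    df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                            progress = FALSE)
    names(df) <- tolower(names(df))
    bad <- which(!is.finite(df$count) | df$count < 0 |
                   df$count != trunc(df$count))
    if (length(bad)) {
      stop("Non-integer or negative count at data line ", bad[1], " of ",
           path, call. = FALSE)
    }
    bad <- which(!is.finite(df$value) | df$value < 1 |
                   df$value != trunc(df$value))
    if (length(bad)) {
      stop("Invalid outcome value at data line ", bad[1], " of ", path,
           " (values must be integers >= 1).", call. = FALSE)
    }
    as_freq_table(df)
  } else {
    x <- suppressWarnings(as.numeric(readLines(path)))
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      stop("No numeric observations found in ", path, call. = FALSE)
    }
    if (any(x < 1) || any(x != trunc(x))) {
      stop("Raw sample in ", path, " must contain positive integers only.",
           call. = FALSE)
    }
    as_freq_table(x)
  }
}

#' Published run-length frequencies for four market indices
#'
#' Counts of daily price-run lengths (pooled upward and downward runs) for
#' the NASDAQ, DJIA, Nikkei 225 and Mexican IPC indices over 2015--2022,
#' as published; shipped as a plain-text fixture. These are the worked
#' example the package documentation reproduces.
#'
#' @return A tibble with columns `length` and one count column per index
#'   (`nasdaq`, `djia`, `nikkei`, `ipc`).
#' @examples
#' runs <- market_runs()
#' theta_mle(data.frame(value = runs$length, count = runs$nasdaq))
#' @export
market_runs <- function() {
  path <- system.file("extdata", "market_runs.csv", package = "geomgof",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                  progress = FALSE)
}
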