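#' Goodness-of-fit test for the geometric distribution
#'
#' Runs the complete test procedure on a sample of positive integers (for
#' example run lengths): estimate `theta_hat = 1 / x_bar`, evaluate the
#' geometric pmf over the observed cells `1..k`, compute the discrete
#' Watson and/or Anderson-Darling statistics, look the statistics up in the
#' asymptotic critical-value table at `theta_hat` for a bracketed p-value
#' and an accept/reject decision at level `alpha`, and (optionally) compute
#' the continuous asymptotic p-value from a fresh eigen-decomposition at
#' `theta_hat`.
#'
#' @inheritParams theta_mle
#' @param statistic `"both"` (default), `"w2"` or `"a2"`.
#' @param alpha Significance level for the rejection decision; must be one
#'   of the table's levels.
#' @param cv_table Critical-value table used for brackets and the decision;
#'   defaults to the table shipped with the package. If `theta_hat` falls
#'   outside the table's `theta` grid, the bracket is skipped with a
#'   warning and only the continuous p-value is reported.
#' @param pvalue `"both"` (default), `"bracket"` (table lookup only; fast)
#'   or `"continuous"`.
#' @param level Confidence level for the reported interval on `theta`.
#' @return An object of class `geom_gof`; see [tidy.geom_gof()] and
#'   [glance.geom_gof()] for rectangular views, and `print()` for a
#'   table-style report.
#' @examples
#' runs <- market_runs()
#' fit <- gof_test(data.frame(value = runs$length, count = runs$nasdaq),
#'                 pvalue = "bracket")
#' fit
#' @export
gof_test <- function(data, statistic = c("both", "w2", "a2"), alpha = 0.05,
                     cv_table = default_critical_values(),
                     pvalue = c("both", "bracket", "continuous"),
                     level = 0.95) {
  statistic <- match.arg(statistic)
  pvalue <- match.arg(pvalue)
  stats_wanted <- if (statistic == "both") c("w2", "a2") else statistic
  tab <- as_freq_table(data)
  n <- n_obs(tab)
  x_bar <- sum(tab$value * tab$count) / n
  theta_hat <- theta_mle(tab)
  ci <- theta_wald_ci(theta_hat, n, level)

  values <- gof_statistics(tab)
  use_bracket <- pvalue %in% c("both", "bracket")
  use_cont <- pvalue %in% c("both", "continuous")
  in_grid <- theta_hat >= min(cv_table$theta) &&
    theta_hat <= max(cv_table$theta)
  if (use_bracket && !in_grid) {
    warning("theta_hat = ", signif(theta_hat, 4), " is outside the ",
            "critical-value table grid; reporting the continuous p-value ",
            "only.", call. = FALSE)
    use_bracket <- FALSE
    use_cont <- TRUE
  }
  if (use_bracket && !any(cv_table$alpha == alpha)) {
    stop("`alpha` = ", alpha, " is not a level of `cv_table`; available: ",
         paste(sort(unique(cv_table$alpha)), collapse = ", "), ".",
         call. = FALSE)
  }

  results <- purrr::map_dfr(stats_wanted, function(st) {
    value <- values$value[values$statistic == st]
    row <- tibble::tibble(
      statistic = st, value = value,
      p_lower = NA_real_, p_upper = NA_real_, p_label = NA_character_,
      p_value = NA_real_, critical_value = NA_real_, reject = NA
    )
    if (use_bracket) {
      br <- pvalue_bracket(cv_table, st, theta_hat, value)
      cv <- cv_table |>
        dplyr::filter(.data$statistic == st, .data$alpha == .env$alpha) |>
        (\(d) interp_theta(d$theta, d$critical_value, theta_hat))()
      row$p_lower <- br$p_lower
      row$p_upper <- br$p_upper
      row$p_label <- br$label
      row$critical_value <- cv
      row$reject <- value > cv
    }
    if (use_cont) {
      row$p_value <- continuous_pvalue(st, theta_hat, value)
      if (!use_bracket) {
        row$reject <- row$p_value < alpha
      }
    }
    row
  })

  structure(
    list(data = tab, n = n, x_bar = x_bar, theta_hat = theta_hat,
         ci = ci, level = level, alpha = alpha, results = results,
         pvalue_mode = pvalue),
    class = "geom_gof"
  )
}

#' @export
print.geom_gof <- function(x, digits = 3, ...) {
  cat("Geometric goodness-of-fit test (estimated theta)\n")
  cat(sprintf("  n = %d   x_bar = %.*f   theta_hat = %.*f   %g%% CI [%.*f, %.*f]\n",
              x$n, digits, x$x_bar, digits, x$theta_hat, 100 * x$level,
              digits, x$ci$lower, digits, x$ci$upper))
  for (i in seq_len(nrow(x$results))) {
    r <- x$results[i, ]
    name <- if (r$statistic == "w2") "W2" else "A2"
    line <- sprintf("  %s = %.*f", name, digits, r$value)
    if (!is.na(r$p_label)) line <- paste0(line, "   ", r$p_label)
    if (!is.na(r$p_value)) {
      line <- paste0(line, sprintf("   p = %.*f", digits, r$p_value))
    }
    if (!is.na(r$reject)) {
      line <- paste0(line, if (r$reject) {
        sprintf("   reject at alpha = %g", x$alpha)
      } else {
        sprintf("   no rejection at alpha = %g", x$alpha)
      })
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Serialise or restore a test report
#'
#' `format = "json"` writes every field at full precision and round-trips
#' losslessly through `read_gof_report()`; `format = "text"` renders the
#' same table-style summary as `print()`, rounded to 3 decimals.
#'
#' @param x A `geom_gof` object.
#' @param path Output file, or `NULL` to return the serialised text.
#' @param format `"json"` or `"text"`.
#' @return The serialised report (character), invisibly when written to
#'   `path`; `read_gof_report()` returns the restored `geom_gof` object.
#' @export
write_gof_report <- function(x, path = NULL, format = c("json", "text")) {
  stopifnot(inherits(x, "geom_gof"))
  format <- match.arg(format)
  out <- if (format == "json") {
    jsonlite::toJSON(
      list(n = x$n, x_bar = x$x_bar, theta_hat = x$theta_hat,
           ci_lower = x$ci$lower, ci_upper = x$ci$upper, level = x$level,
           alpha = x$alpha, pvalue_mode = x$pvalue_mode,
           data = as.data.frame(x$data),
           results = as.data.frame(x$results)),
      auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    paste(utils::capture.output(print(x)), collapse = "\n")
  }
  if (is.null(path)) {
    return(as.character(out))
  }
  writeLines(as.character(out), path)
  invisible(as.character(out))
}

#' @rdname write_gof_report
#' @export
read_gof_report <- function(path) {
  j <- jsonlite::fromJSON(path)
  results <- tibble::as_tibble(j$results)
  results$reject <- as.logical(results$reject)
  structure(
    list(data = as_freq_table(j$data), n = j$n, x_bar = j$x_bar,
         theta_hat = j$theta_hat,
         ci = tibble::tibble(lower = j$ci_lower, upper = j$ci_upper),
         level = j$level, alpha = j$alpha, results = results,
         pvalue_mode = j$pvalue_mode),
    class = "geom_gof"
  )
}
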