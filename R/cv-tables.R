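#' Asymptotic critical-value tables
#'
#' Regenerates the grid of upper-tail percentage points of the asymptotic
#' null distribution over a grid of `theta` values and significance levels:
#' each cell is the `alpha` upper quantile of `sum(lambda_i nu_i^2)` with
#' eigenvalues from [eigen_spectrum()] at truncation chosen by
#' [choose_truncation()] (convergence checked at the deepest requested tail
#' level, and the spectrum reused across levels).
#'
#' A pre-generated copy over the default grid ships with the package
#' ([default_critical_values()]); `critical_value_table()` is the
#' regeneration command.
#'
#' @param statistic Character vector among `"w2"`, `"a2"`; both by default.
#' @param thetas Grid of success probabilities in (0, 1). The default grid
#'   spans 0.05--0.95 in steps of 0.05 with extra resolution around 0.5.
#' @param alphas Significance levels; default
#'   `c(0.50, 0.25, 0.15, 0.10, 0.05, 0.025, 0.01)`.
#' @param estimated Whether the tables are for the estimated-`theta`
#'   statistics (the default) or the known-`theta` case.
#' @param verbose Print one progress line per `(statistic, theta)` pair.
#' @return A tibble with columns `statistic`, `theta`, `alpha`,
#'   `critical_value`, `estimated`; rows are strictly decreasing in
#'   `critical_value` as `alpha` increases within each `(statistic, theta)`.
#' @examples
#' \donttest{
#' critical_value_table("w2", thetas = 0.5, alphas = 0.05)
#' }
#' @export
critical_value_table <- function(statistic = c("w2", "a2"),
                                 thetas = default_theta_grid(),
                                 alphas = default_alpha_levels(),
                                 estimated = TRUE, verbose = FALSE) {
  statistic <- match.arg(statistic, c("w2", "a2"), several.ok = TRUE)
  stopifnot(length(thetas) > 0, length(alphas) > 0,
            all(alphas > 0), all(alphas < 1))
  alphas <- sort(unique(alphas), decreasing = TRUE)
  grid <- tidyr::expand_grid(statistic = statistic, theta = sort(thetas))
  purrr::pmap_dfr(grid, function(statistic, theta) {
    det <- truncation_details(statistic, theta, estimated, min(alphas))
    cv <- vapply(alphas, function(a) {
      if (a == min(alphas)) det$quantile else wchi2_quantile(det$lambdas, a)
    }, numeric(1))
    if (verbose) {
      message(sprintf("%s theta = %.2f k = %d done", statistic, theta, det$k))
    }
    tibble::tibble(statistic = statistic, theta = theta, alpha = alphas,
                   critical_value = cv, estimated = estimated)
  })
}

#' @rdname critical_value_table
#' @export
default_theta_grid <- function() {
  sort(unique(c(seq(0.05, 0.95, by = 0.05), 0.48, 0.49, 0.51, 0.52)))
}

#' @rdname critical_value_table
#' @export
default_alpha_levels <- function() {
  c(0.50, 0.25, 0.15, 0.10, 0.05, 0.025, 0.01)
}

#' @rdname critical_value_table
#' @export
default_critical_values <- function() {
  path <- system.file("extdata", "critical_values.csv", package = "geomgof",
                      mustWork = TRUE)
  read_cv_table(path)
}

#' Read/write a critical-value table as CSV
#'
#' Plain CSV with columns `statistic`, `theta`, `alpha`, `critical_value`,
#' `estimated`; values round-trip at full double precision.
#'
#' @param table A table as returned by [critical_value_table()].
#' @param path File path.
#' @export
write_cv_table <- function(table, path) {
  check_cv_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_cv_table
#' @export
read_cv_table <- function(path) {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      statistic = readr::col_character(),
      theta = readr::col_double(),
      alpha = readr::col_double(),
      critical_value = readr::col_double(),
      estimated = readr::col_logical()
    ),
    progress = FALSE
  )
  check_cv_table(tab)
  tab
}

check_cv_table <- function(table) {
  need <- c("statistic", "theta", "alpha", "critical_value", "estimated")
  if (!all(need %in% names(table))) {
    stop("Critical-value table must have columns ",
         paste(need, collapse = ", "), ".", call. = FALSE)
  }
  if (any(table$critical_value <= 0)) {
    stop("Critical values must be positive.", call. = FALSE)
  }
  invisible(table)
}

#' Bracketed p-value from a critical-value table
#'
#' Mirrors table-based reporting: the observed statistic is compared with
#' the row of critical values at the estimated `theta` (linearly
#' interpolated between adjacent grid values of `theta`), and the pair of
#' adjacent tabulated significance levels straddling it is returned, e.g.
#' `0.25 < p < 0.50`. Values below the weakest tabulated level give
#' `p > 0.50`, values above the strongest give `p < 0.01` (for the default
#' levels).
#'
#' @param table A critical-value table (see [critical_value_table()]).
#' @param statistic `"w2"` or `"a2"`.
#' @param theta_hat Estimated success probability; must lie within the
#'   table's `theta` range.
#' @param value Observed statistic value (non-negative).
#' @return A tibble with columns `p_lower`, `p_upper` (`NA` for an
#'   open-ended side) and a human-readable `label`.
#' @examples
#' tab <- default_critical_values()
#' pvalue_bracket(tab, "w2", theta_hat = 0.512, value = 0.060)
#' @export
pvalue_bracket <- function(table, statistic = c("w2", "a2"), theta_hat,
                           value) {
  statistic <- match.arg(statistic)
  check_cv_table(table)
  check_theta(theta_hat, "theta_hat")
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  sub <- dplyr::filter(table, .data$statistic == .env$statistic)
  if (nrow(sub) == 0L) {
    stop("Table has no rows for statistic '", statistic, "'.", call. = FALSE)
  }
  if (theta_hat < min(sub$theta) || theta_hat > max(sub$theta)) {
    stop("theta_hat = ", signif(theta_hat, 4), " lies outside the table ",
         "grid [", min(sub$theta), ", ", max(sub$theta), "]; use ",
         "continuous_pvalue() to compute the p-value directly.",
         call. = FALSE)
  }
  cv <- sub |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(
      critical_value = interp_theta(.data$theta, .data$critical_value,
                                    .env$theta_hat),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$alpha))  # critical values increasing
  exceeded <- cv$critical_value < value
  if (!any(exceeded)) {
    out <- tibble::tibble(p_lower = max(cv$alpha), p_upper = NA_real_)
  } else if (all(exceeded)) {
    out <- tibble::tibble(p_lower = NA_real_, p_upper = min(cv$alpha))
  } else {
    j <- max(which(exceeded))
    out <- tibble::tibble(p_lower = cv$alpha[j + 1L], p_upper = cv$alpha[j])
  }
  out$label <- bracket_label(out$p_lower, out$p_upper)
  out
}

# linear interpolation in theta, tolerating a single-row grid at theta_hat
interp_theta <- function(theta, cv, theta_hat) {
  if (length(theta) == 1L) {
    return(cv)
  }
  stats::approx(theta, cv, xout = theta_hat)$y
}

bracket_label <- function(p_lower, p_upper) {
  if (is.na(p_upper)) {
    sprintf("p > %.2f", p_lower)
  } else if (is.na(p_lower)) {
    sprintf("p < %.2f", p_upper)
  } else {
    sprintf("%.2f < p < %.2f", p_lower, p_upper)
  }
}

#' Continuous asymptotic p-value
#'
#' Upper-tail probability of the observed statistic under the asymptotic
#' null law evaluated at the estimated `theta` itself -- a fresh
#' eigen-decomposition at `theta_hat` rather than interpolation in a table.
#' This is the recommended reporting path; the bracket from
#' [pvalue_bracket()] always contains it (up to the table's own accuracy).
#'
#' @inheritParams pvalue_bracket
#' @param estimated Whether `theta_hat` was estimated from the data.
#' @return A single probability.
#' @examples
#' \donttest{
#' continuous_pvalue("w2", theta_hat = 0.512, value = 0.060)
#' }
#' @export
continuous_pvalue <- function(statistic = c("w2", "a2"), theta_hat, value,
                              estimated = TRUE) {
  statistic <- match.arg(statistic)
  check_theta(theta_hat, "theta_hat")
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  if (value == 0) {
    return(1)
  }
  det <- truncation_details(statistic, theta_hat, estimated, alpha = 0.05)
  wchi2_tail(det$lambdas, value)
}
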