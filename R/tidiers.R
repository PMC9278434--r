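#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group comparison
#'
#' One row per group with the summary style the test family dictates
#' (mean/SD for the t-test, median/R70 for Kruskal-Wallis).
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return A tibble: `group`, `n`, `location`, `spread`, `location_stat`,
#'   `spread_stat`.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$groups
}

#' Glance at a group comparison
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return A one-row tibble: `test_name`, `statistic`, `p_value`, `gate`,
#'   `normality_p_control`, `summary_style`.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    test_name = x$test_name,
    statistic = x$statistic,
    p_value = x$p_value,
    gate = x$gate,
    normality_p_control = unname(x$normality_p["control"]),
    summary_style = x$summary_style
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (%s)\n",
              x$test_name, x$statistic, x$p_value, x$gate))
  print(x$groups)
  invisible(x)
}
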