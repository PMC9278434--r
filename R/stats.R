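#' R70: the 15th-to-85th percentile range
#'
#' A robust spread statistic: the width of the central 70% of the sample
#' (about 1 SD either side of the mean for Gaussian data, which holds ~68%).
#' Percentiles use the Hazen convention (linear interpolation between order
#' statistics at plotting positions (i - 0.5)/n), so `r70(1:100)` is exactly
#' 70. R70 is translation-invariant and positively homogeneous.
#'
#' @param values numeric vector with >= 2 finite values.
#' @return The 85th minus the 15th percentile.
#' @examples
#' r70(1:100)
#' @export
r70 <- function(values) {
  values <- values[is.finite(values)]
  abort_if(length(values) < 2, "r70 needs >= 2 values")
  quantile_hazen(values, 0.85) - quantile_hazen(values, 0.15)
}

#' Normality gate on the control group
#'
#' Shapiro-Wilk on the control (sham) sample only: the distributional
#' assumption is checked where the null phenotype lives, and the verdict
#' selects the test family for the whole comparison.
#'
#' @param control_values control-group sample (3 <= n <= 5000).
#' @param alpha gate level.
#' @return `"gaussian"` when the Shapiro-Wilk p-value is >= `alpha`,
#'   otherwise `"non-gaussian"`; the p-value is attached as attribute
#'   `shapiro_p`.
#' @export
shapiro_gate <- function(control_values, alpha = 0.05) {
  n <- length(control_values)
  abort_if(n < 3 || n > 5000, "Shapiro-Wilk requires 3 <= n <= 5000")
  p <- stats::shapiro.test(control_values)$p.value
  structure(if (p >= alpha) "gaussian" else "non-gaussian", shapiro_p = p)
}

#' Compare two groups with normality-gated test selection
#'
#' When the control group passes the Shapiro-Wilk gate the comparison is an
#' unpaired t-test and groups are summarised as mean and SD; otherwise a
#' Kruskal-Wallis test with median and R70 summaries. Strict mode gates on
#' both groups.
#'
#' @param a,b numeric samples; `a` is the control (gated) group.
#' @param labels length-2 group labels.
#' @param alpha gate level.
#' @param strict gate on both groups.
#' @param var_equal classical (Student) unpaired t-test when `TRUE`
#'   (default), Welch otherwise.
#' @return A list of class `group_comparison`: `test_name`, `statistic`,
#'   `p_value`, `gate`, `normality_p`, `groups` (tibble of per-group
#'   summaries), `summary_style`, `percentile_convention`.
#' @export
compare_groups <- function(a, b, labels = c("control", "treatment"),
                           alpha = 0.05, strict = FALSE, var_equal = TRUE) {
  abort_if(length(a) < 3 || length(b) < 3, "each group needs >= 3 values")
  abort_if(any(!is.finite(a)) || any(!is.finite(b)),
           "groups must be finite")
  gate <- shapiro_gate(a, alpha)
  p_b <- NA_real_
  if (strict) {
    gate_b <- shapiro_gate(b, alpha)
    p_b <- attr(gate_b, "shapiro_p")
    if (gate_b == "non-gaussian") gate[] <- "non-gaussian"
  }
  if (gate == "gaussian") {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(test_name = "unpaired-t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
    groups <- tibble::tibble(
      group = labels, n = c(length(a), length(b)),
      location = c(mean(a), mean(b)), spread = c(stats::sd(a), stats::sd(b)),
      location_stat = "mean", spread_stat = "sd")
    style <- "mean_sd"
  } else {
    kw <- stats::kruskal.test(list(a, b))
    res <- list(test_name = "kruskal-wallis",
                statistic = unname(kw$statistic), p_value = kw$p.value)
    groups <- tibble::tibble(
      group = labels, n = c(length(a), length(b)),
      location = c(stats::median(a), stats::median(b)),
      spread = c(r70(a), r70(b)),
      location_stat = "median", spread_stat = "r70")
    style <- "median_r70"
  }
  structure(list(
    test_name = res$test_name,
    statistic = res$statistic,
    p_value = res$p_value,
    gate = as.character(gate),
    normality_p = c(control = attr(gate, "shapiro_p"), other = p_b),
    groups = groups,
    summary_style = style,
    percentile_convention = "hazen (type 5)"
  ), class = "group_comparison")
}

#' Weekly median and R70 table
#'
#' Per-week medians with R70 spreads for the event count (AHI) and dyspnoea
#' duration, the longitudinal stability table format.
#'
#' @param data a data frame with columns `week`, `count` and `duration`
#'   (one row per animal-week).
#' @return A tibble: `week`, `n`, `median_count`, `r70_count`,
#'   `median_duration`, `r70_duration`.
#' @export
weekly_table <- function(data) {
  abort_if(!all(c("week", "count", "duration") %in% names(data)),
           "data needs columns week, count, duration")
  abort_if(nrow(data) == 0, "no rows")
  safe_r70 <- function(x) if (length(x) >= 2) r70(x) else 0
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$week),
    n = dplyr::n(),
    median_count = stats::median(.data$count),
    r70_count = safe_r70(.data$count),
    median_duration = stats::median(.data$duration),
    r70_duration = safe_r70(.data$duration),
    .groups = "drop")
}

#' Iglewicz-Hoaglin modified-Z outlier filter
#'
#' Flags values whose modified Z score `0.6745 * (x - median) / MAD` is at
#' least `threshold` (3.5 by convention). Off by default in pipelines;
#' provided for parity with hand-curated group tables.
#'
#' @param values numeric vector.
#' @param threshold modified-Z cutoff.
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @export
modified_z_outliers <- function(values, threshold = 3.5) {
  med <- stats::median(values)
  mad <- stats::median(abs(values - med))
  if (mad == 0) return(rep(FALSE, length(values)))
  abs(0.6745 * (values - med) / mad) >= threshold
}
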