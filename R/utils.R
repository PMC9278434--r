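# Internal numerical helpers shared across modules.

#' Locate local maxima of a numeric vector
#'
#' Simple sign-change peak finder with a minimum-separation rule: when two
#' candidate maxima fall closer than `min_dist` samples, the larger one wins
#' (ties: earliest sample wins).
#'
#' @param x numeric vector.
#' @param min_dist minimum separation between retained peaks, in samples.
#' @return integer vector of peak indices, sorted.
#' @noRd
local_maxima <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  dx <- diff(x)
  # strict rise followed by fall-or-flat; plateaus keep their first sample
  idx <- which(dx[-length(dx)] > 0 & dx[-1L] <= 0) + 1L
  if (length(idx) == 0L || min_dist <= 1L) return(idx)
  # greedy by height, earliest first on ties
  ord <- order(-x[idx], idx)
  keep <- logical(length(idx))
  taken <- rep(FALSE, n)
  for (k in ord) {
    i <- idx[k]
    lo <- max(1L, i - min_dist + 1L)
    hi <- min(n, i + min_dist - 1L)
    if (!any(taken[lo:hi])) {
      keep[k] <- TRUE
      taken[i] <- TRUE
    }
  }
  sort(idx[keep])
}

#' First-order exponential smoother
#'
#' Causal recursive filter `y[i] = a * x[i] + (1 - a) * y[i-1]` with
#' `a = 1 - exp(-dt / tau)`, the discrete analogue of an RC smoother with
#' time constant `tau` seconds.
#'
#' @noRd
exp_smooth <- function(x, rate_hz, tau_s) {
  if (tau_s <= 0) return(x)
  a <- 1 - exp(-1 / (rate_hz * tau_s))
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive", init = x[1]))
}

#' Rolling median over a trailing time window with an optional mask
#'
#' For each element, the median of `values[j]` with
#' `t[i] - window_s <= t[j] < t[i]` and `use[j]`. Elements with no usable
#' history fall back to the median of the first `window_s` of usable values.
#'
#' @noRd
rolling_median_time <- function(t, values, window_s, use = NULL) {
  n <- length(t)
  if (is.null(use)) use <- rep(TRUE, n)
  out <- numeric(n)
  head_med <- stats::median(values[use & t <= t[1] + window_s])
  if (!is.finite(head_med)) head_med <- stats::median(values[use])
  lo <- 1L
  for (i in seq_len(n)) {
    while (t[lo] < t[i] - window_s) lo <- lo + 1L
    j <- lo:i
    j <- j[j < i]
    j <- j[use[j]]
    out[i] <- if (length(j) >= 3L) stats::median(values[j]) else head_med
  }
  out
}

#' Rolling median over a centred index window
#' @noRd
rolling_median_k <- function(x, k) {
  k <- min(k, length(x))
  if (k %% 2L == 0L) k <- k - 1L
  if (k < 3L) return(rep(stats::median(x), length(x)))
  stats::runmed(x, k, endrule = "median")
}

#' Zero-phase Butterworth filter (low-pass or band-pass)
#' @noRd
butter_filtfilt <- function(x, rate_hz, low = NULL, high = NULL, order = 4L) {
  nyq <- rate_hz / 2
  if (is.null(low)) {
    bf <- signal::butter(order, high / nyq, type = "low")
  } else {
    stopifnot(low > 0, high < nyq)
    bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Quantile with the package-wide convention (Hazen, type 5)
#'
#' Linear interpolation between order statistics with plotting position
#' (i - 0.5)/n. This is the convention used for the R70 spread statistic.
#' @noRd
quantile_hazen <- function(x, p) {
  unname(stats::quantile(x, p, type = 5, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
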