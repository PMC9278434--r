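# Scripted sleep architecture: a semi-Markov alternation
# WAKE -> NREM -> (WAKE | REM), REM -> WAKE, with exponential dwell times.
#
# With embedded-chain visit rates nu = (WAKE 1, NREM 1, REM p), the long-run
# time fraction of state s is nu_s * d_s / sum(nu * d). Given target fractions
# pi and the NREM/REM dwell means, the WAKE dwell mean and the NREM->REM
# branching probability p follow:
#   d_WAKE = d_NREM * pi_W / pi_N,   p = pi_R * d_NREM / (pi_N * d_REM).

derive_architecture <- function(p) {
  sf <- p$state_fractions
  if (any(sf == 1)) {
    return(list(constant = names(sf)[sf == 1]))
  }
  d_n <- p$nrem_dwell_s
  d_r <- p$rem_dwell_s
  d_w <- d_n * sf[["WAKE"]] / sf[["NREM"]]
  p_rem <- if (sf[["REM"]] > 0) sf[["REM"]] * d_n / (sf[["NREM"]] * d_r) else 0
  abort_if(p_rem > 1,
           "state fractions and dwell means are inconsistent (NREM->REM probability > 1); lengthen rem_dwell_s")
  list(constant = NULL, dwell = c(WAKE = d_w, NREM = d_n, REM = d_r),
       p_rem = p_rem)
}

# Bout table for one recording: state, start_s, end_s, and for WAKE bouts a
# quiet/active flag (bimodal muscle tone; the first, scripted calm-onset bout
# is always quiet).
script_bouts <- function(protocol, seed = protocol$seed) {
  arch <- derive_architecture(protocol)
  dur <- protocol$duration_s
  if (!is.null(arch$constant)) {
    return(tibble::tibble(state = arch$constant, start_s = 0, end_s = dur,
                          quiet = arch$constant == "WAKE"))
  }
  min_bout <- c(WAKE = 10, NREM = 15, REM = 12)
  with_local_seed(seed, {
    states <- character(0); starts <- numeric(0); ends <- numeric(0)
    quiet <- logical(0)
    t <- 0
    # scripted calm-wakefulness onset
    if (protocol$state_fractions[["WAKE"]] > 0 && protocol$quiet_onset_s > 0) {
      states <- "WAKE"; starts <- 0; ends <- protocol$quiet_onset_s
      quiet <- TRUE
      t <- protocol$quiet_onset_s
    }
    cur <- "NREM"
    while (t < dur) {
      m <- arch$dwell[[cur]]
      mb <- min(min_bout[[cur]], 0.5 * m)
      d <- mb + stats::rexp(1, rate = 1 / max(m - mb, 1e-6))
      states <- c(states, cur); starts <- c(starts, t)
      t2 <- min(t + d, dur)
      ends <- c(ends, t2)
      quiet <- c(quiet, if (cur == "WAKE") stats::runif(1) < 0.4 else NA)
      t <- t2
      cur <- switch(cur,
        WAKE = "NREM",
        NREM = if (stats::runif(1) < arch$p_rem) "REM" else "WAKE",
        REM  = "WAKE")
    }
    tibble::tibble(state = states, start_s = starts, end_s = ends,
                   quiet = quiet)
  })
}

#' Script a ground-truth hypnogram
#'
#' Generates a 5 s-epoch label sequence from a semi-Markov bout model whose
#' long-run state fractions converge to the protocol's targets. REM is entered
#' only from NREM, and every REM bout ends in wakefulness. Each epoch takes
#' the state occupying its midpoint.
#'
#' @param protocol a [simulation_protocol()].
#' @param seed integer seed (defaults to the protocol's).
#' @param epoch_s epoch length, seconds.
#' @return Character vector of epoch labels in `WAKE`/`NREM`/`REM`.
#' @examples
#' p <- protocol_preset("sham", duration_s = 600)
#' table(script_hypnogram(p))
#' @export
script_hypnogram <- function(protocol, seed = protocol$seed, epoch_s = 5) {
  bouts <- script_bouts(protocol, seed)
  bouts_to_epochs(bouts, protocol$duration_s, epoch_s)
}

bouts_to_epochs <- function(bouts, duration_s, epoch_s = 5) {
  n_ep <- floor(duration_s / epoch_s)
  mid <- (seq_len(n_ep) - 0.5) * epoch_s
  bouts$state[findInterval(mid, bouts$start_s)]
}

state_at <- function(bouts, times) {
  i <- findInterval(times, bouts$start_s)
  i[i < 1L] <- 1L
  bouts$state[i]
}
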