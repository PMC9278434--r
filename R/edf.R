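# Minimal EDF (European Data Format) I/O.
#
# EDF is the interchange standard for polysomnography. This implementation
# covers what the pipeline needs: continuous 16-bit records, one-second data
# records, any number of channels at integer sample rates. Physical scaling
# follows the EDF header convention; the round-trip error is bounded by the
# 16-bit quantization step (phys range / 65535).

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE, digits = 7), width)

#' Write signal traces to an EDF file
#'
#' @param traces a named list of [signal_trace()] objects (names become EDF
#'   channel labels; unnamed lists use the traces' own labels). All traces must
#'   have integer sample rates; the recording is truncated to whole seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(traces, path) {
  if (inherits(traces, "signal_trace")) traces <- list(traces)
  labels <- names(traces) %||% vapply(traces, function(x) attr(x, "label"), "")
  if (is.null(names(traces))) names(traces) <- labels
  labels[labels == ""] <- paste0("ch", which(labels == ""))
  rates <- vapply(traces, trace_rate, 1.0)
  abort_if(any(abs(rates - round(rates)) > 1e-9),
           "EDF writer requires integer sample rates")
  rates <- as.integer(round(rates))
  n_rec <- min(floor(vapply(traces, nrow, 1L) / rates))
  abort_if(n_rec < 1L, "traces shorter than one 1 s data record")
  ns <- length(traces)

  phys_min <- phys_max <- numeric(ns)
  digitized <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- traces[[i]]$value[seq_len(n_rec * rates[i])]
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    pad <- diff(rng) * 0.001
    phys_min[i] <- rng[1] - pad
    phys_max[i] <- rng[2] + pad
    digitized[[i]] <- as.integer(round(
      (v - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 - 32768
    ))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X X X X", 80),
    "01.01.00", "00.00.00", .edf_num(256L * (1L + ns), 8),
    .edf_pad("", 44), .edf_num(n_rec, 8), .edf_num(1L, 8),
    .edf_pad(ns, 4)
  )
  units <- vapply(traces, function(x) attr(x, "units") %||% "", "")
  sig_hdr <- paste0(
    paste(.edf_pad(labels, 16), collapse = ""),
    paste(.edf_pad(rep("", ns), 80), collapse = ""),
    paste(.edf_pad(units, 8), collapse = ""),
    paste(.edf_num(phys_min, 8), collapse = ""),
    paste(.edf_num(phys_max, 8), collapse = ""),
    paste(.edf_num(rep(-32768L, ns), 8), collapse = ""),
    paste(.edf_num(rep(32767L, ns), 8), collapse = ""),
    paste(.edf_pad(rep("", ns), 80), collapse = ""),
    paste(.edf_num(rates, 8), collapse = ""),
    paste(.edf_pad(rep("", ns), 32), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * rates[i] + 1L):(r * rates[i])
      writeBin(digitized[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' @param path EDF file path.
#' @param channel channel label as stored in the EDF header.
#' @return A [signal_trace()] in physical units.
#' @export
read_edf <- function(path, channel) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); units <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)

  k <- match(channel, labels)
  abort_if(is.na(k), paste0("channel `", channel, "` not found in EDF (have: ",
                            paste(labels, collapse = ", "), ")"))
  out <- numeric(n_rec * spr[k])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (i == k) out[((r - 1L) * spr[k] + 1L):(r * spr[k])] <- raw
    }
  }
  phys <- (out - dig_min[k]) / (dig_max[k] - dig_min[k]) *
    (phys_max[k] - phys_min[k]) + phys_min[k]
  signal_trace(phys, rate_hz = spr[k] / rec_dur, label = channel,
               units = units[k])
}
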