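#' Stimulation protocols
#'
#' Declarative description of one stimulation run. Three kinds are supported,
#' mirroring standard in-vivo evoked-response practice:
#'
#' * `io_series` — input/output series: pairs of pulses at a 50 ms interval
#'   delivered over a range of currents (50-600 uA); only the first pulse of
#'   each pair enters the I/O curve.
#' * `paired_pulse` — pairs at one inter-pulse interval drawn from
#'   25, 50, 100, 200, 500 or 1000 ms; pairs separated by 3 s, repeated
#'   20 times.
#' * `train` — a single train of 20 pulses at 5 Hz.
#'
#' Stimulus pulse width is 0.2 ms throughout.
#'
#' @param kind One of `"io_series"`, `"paired_pulse"`, `"train"`.
#' @param current_ua Stimulus current in uA; a vector for `io_series`
#'   (default 50-600 uA in 50 uA steps), a scalar otherwise.
#' @param ppi_ms Paired-pulse interval, ms; must be one of
#'   25, 50, 100, 200, 500, 1000. Ignored for trains.
#' @param n_repeats Number of pair repeats (default 20; `io_series` defaults
#'   to 5 pairs per current).
#' @param train_len,train_hz Train length and frequency (20 pulses at 5 Hz).
#' @param pulse_width_ms Stimulus duration, ms.
#' @param inter_pair_gap_s Gap between successive pairs, s.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol("paired_pulse", ppi_ms = 50)
#' stimulus_protocol("train")
#' @export
stimulus_protocol <- function(kind = c("paired_pulse", "train", "io_series"),
                              current_ua = NULL, ppi_ms = 50,
                              n_repeats = NULL, train_len = 20, train_hz = 5,
                              pulse_width_ms = 0.2, inter_pair_gap_s = 3) {
  kind <- match.arg(kind)
  valid_ppi <- c(25, 50, 100, 200, 500, 1000)
  if (!is.null(current_ua)) current_ua <- as.numeric(current_ua)
  ppi_ms <- as.numeric(ppi_ms)
  train_hz <- as.numeric(train_hz)
  pulse_width_ms <- as.numeric(pulse_width_ms)
  inter_pair_gap_s <- as.numeric(inter_pair_gap_s)
  stopifnot(pulse_width_ms > 0, inter_pair_gap_s > 0)
  if (kind == "io_series") {
    if (is.null(current_ua)) current_ua <- seq(50, 600, by = 50)
    stopifnot(length(current_ua) >= 2, all(diff(current_ua) > 0),
              all(current_ua >= 50 & current_ua <= 600))
    ppi_ms <- 50
    if (is.null(n_repeats)) n_repeats <- 5L
  } else {
    if (is.null(current_ua)) current_ua <- 200
    stopifnot(length(current_ua) == 1L)
    if (is.null(n_repeats)) n_repeats <- 20L
  }
  if (kind == "paired_pulse" && !ppi_ms %in% valid_ppi)
    stop("ppi_ms must be one of ", paste(valid_ppi, collapse = ", "))
  if (kind == "train") stopifnot(train_len >= 2, train_hz > 0)
  p <- list(kind = kind, current_ua = current_ua, ppi_ms = ppi_ms,
            n_repeats = as.integer(n_repeats), train_len = as.integer(train_len),
            train_hz = train_hz, pulse_width_ms = pulse_width_ms,
            inter_pair_gap_s = inter_pair_gap_s)
  class(p) <- "stimulus_protocol"
  p
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  desc <- switch(x$kind,
    io_series = sprintf("I/O series, %d currents (%g-%g uA), %d pairs each",
                        length(x$current_ua), min(x$current_ua),
                        max(x$current_ua), x$n_repeats),
    paired_pulse = sprintf("paired pulses, PPI %g ms, %d repeats at %g uA",
                           x$ppi_ms, x$n_repeats, x$current_ua),
    train = sprintf("train of %d pulses at %g Hz, %g uA",
                    x$train_len, x$train_hz, x$current_ua))
  cat("<stimulus_protocol>", desc, "\n")
  invisible(x)
}

# Pulse onset times (s, relative to recording start after `pad_s` of
# baseline) and per-pulse metadata for one protocol.
protocol_pulses <- function(protocol, pad_s = 0.5) {
  p <- protocol
  if (p$kind == "train") {
    t <- pad_s + (seq_len(p$train_len) - 1) / p$train_hz
    info <- data.frame(pulse_index = seq_len(p$train_len), rep = 1L,
                       current_ua = p$current_ua)
  } else if (p$kind == "paired_pulse") {
    starts <- pad_s + (seq_len(p$n_repeats) - 1) * p$inter_pair_gap_s
    t <- as.vector(rbind(starts, starts + p$ppi_ms / 1000))
    info <- data.frame(pulse_index = rep(1:2, p$n_repeats),
                       rep = rep(seq_len(p$n_repeats), each = 2),
                       current_ua = p$current_ua)
  } else { # io_series: n_repeats pairs per current, currents in order
    t <- c(); pulse <- c(); rp <- c(); cur <- c()
    t0 <- pad_s
    for (ci in seq_along(p$current_ua)) {
      for (r in seq_len(p$n_repeats)) {
        t <- c(t, t0, t0 + p$ppi_ms / 1000)
        pulse <- c(pulse, 1L, 2L); rp <- c(rp, r, r)
        cur <- c(cur, rep(p$current_ua[ci], 2))
        t0 <- t0 + p$inter_pair_gap_s
      }
    }
    info <- data.frame(pulse_index = pulse, rep = rp, current_ua = cur)
  }
  info$ppi_ms <- if (p$kind == "train") NA_real_ else p$ppi_ms
  list(times_s = t, info = info)
}
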