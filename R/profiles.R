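#' Excitability profiles
#'
#' A profile programs how evoked component amplitudes evolve across pulses,
#' when granule-layer population spikes (PS) occur, and whether long-latency
#' re-entrant activity emerges during 5 Hz trains. Two stock profiles are
#' provided: [control_profile()] (paired-pulse depression in DG at short
#' intervals, re-entrance only by the last train pulse) and [ad_profile()]
#' (paired-pulse facilitation at short intervals, earlier re-entrance, as in
#' hyper-excitable transgenic phenotypes).
#'
#' @param ppi_gain Named numeric: multiplicative gain on pulse-2 component
#'   amplitudes for paired-pulse intervals 25, 50, 100, 200, 500, 1000 ms
#'   (all six required, all > 0).
#' @param train_gain Numeric length-20 vector of per-pulse gains (> 0).
#' @param ps_threshold DG amplitude (mV at the granule-layer contact) above
#'   which a PS transient is added to a pulse.
#' @param ps_prob Optional per-sweep PS probability; when set, PS insertion
#'   on pulse 2 of each pair is Bernoulli(`ps_prob`) instead of
#'   threshold-driven (used for probability-recovery studies).
#' @param reentry_first_pulse Train pulse (1-20) at which a long-latency
#'   re-entrant component first appears, or `NULL` for none.
#' @param reentry_latency_ms Peak latency of the re-entrant component, ms;
#'   must lie in 12-25 ms when re-entrance is programmed.
#' @param reentry_layer Layer receiving the re-entrant component
#'   (`"CA1sr"`, `"CA1slm"` or `"DG"`).
#' @param reentry_gain Amplitude of the re-entrant component relative to the
#'   layer's direct component.
#' @param label Free-text profile label.
#' @return An object of class `excitability_profile`.
#' @export
excitability_profile <- function(ppi_gain, train_gain, ps_threshold = Inf,
                                 ps_prob = NULL, reentry_first_pulse = NULL,
                                 reentry_latency_ms = 15,
                                 reentry_layer = "CA1sr", reentry_gain = 0.6,
                                 label = "custom") {
  valid_ppi <- c(25, 50, 100, 200, 500, 1000)
  ppi_gain <- ppi_gain[order(as.numeric(names(ppi_gain)))]
  if (!identical(as.numeric(names(ppi_gain)), valid_ppi))
    stop("ppi_gain must be named with exactly the intervals ",
         paste(valid_ppi, collapse = ", "), " ms")
  stopifnot(all(ppi_gain > 0), length(train_gain) == 20, all(train_gain > 0))
  if (!is.null(reentry_first_pulse)) {
    stopifnot(reentry_first_pulse >= 1, reentry_first_pulse <= 20,
              reentry_latency_ms >= 12, reentry_latency_ms <= 25)
    reentry_layer <- match.arg(reentry_layer, c("CA1sr", "CA1slm", "DG"))
  }
  if (!is.null(ps_prob)) stopifnot(ps_prob >= 0, ps_prob <= 1)
  structure(list(ppi_gain = ppi_gain, train_gain = train_gain,
                 ps_threshold = ps_threshold, ps_prob = ps_prob,
                 reentry_first_pulse = if (is.null(reentry_first_pulse)) NULL
                                       else as.integer(reentry_first_pulse),
                 reentry_latency_ms = reentry_latency_ms,
                 reentry_layer = reentry_layer, reentry_gain = reentry_gain,
                 label = label),
            class = "excitability_profile")
}

#' @export
print.excitability_profile <- function(x, ...) {
  cat(sprintf("<excitability_profile> '%s'\n", x$label))
  cat("  ppi_gain:", paste(sprintf("%g ms: %.2f", as.numeric(names(x$ppi_gain)),
                                   x$ppi_gain), collapse = ", "), "\n")
  cat(sprintf("  train_gain: %.2f ... %.2f over 20 pulses\n",
              x$train_gain[1], x$train_gain[20]))
  if (!is.null(x$reentry_first_pulse))
    cat(sprintf("  re-entrance: %s from pulse %d, peak latency %g ms\n",
                x$reentry_layer, x$reentry_first_pulse, x$reentry_latency_ms))
  invisible(x)
}

#' @rdname excitability_profile
#' @export
control_profile <- function() {
  excitability_profile(
    ppi_gain = c(`25` = 0.80, `50` = 0.85, `100` = 0.95, `200` = 1.00,
                 `500` = 1.00, `1000` = 1.00),
    train_gain = 1 + 0.30 * (seq_len(20) - 1) / 19,
    ps_threshold = Inf,
    reentry_first_pulse = 20, reentry_latency_ms = 17.5,
    reentry_layer = "CA1sr", label = "control-like")
}

#' @rdname excitability_profile
#' @export
ad_profile <- function() {
  excitability_profile(
    ppi_gain = c(`25` = 1.35, `50` = 1.25, `100` = 1.10, `200` = 1.00,
                 `500` = 1.00, `1000` = 1.00),
    train_gain = 1 + 0.15 * (seq_len(20) - 1) / 19,
    ps_threshold = Inf,
    reentry_first_pulse = 10, reentry_latency_ms = 15.7,
    reentry_layer = "CA1sr", label = "ad-like")
}
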