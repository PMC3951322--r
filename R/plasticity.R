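#' Build an input/output curve
#'
#' Stimulus current versus first-pulse response amplitude, per layer, from
#' an I/O-series feature table. Only first-pulse (P1) rows enter the curve;
#' amplitudes are the per-current sweep-average measurements (falling back
#' to the mean of per-sweep rows when averages are absent). Monotonicity is
#' empirical, not enforced.
#'
#' @param features A `feature_table` from an `io_series` recording.
#' @return An object of class `io_curve`: data.frame with `layer`,
#'   `current_ua`, `amplitude_mv`.
#' @export
build_io_curve <- function(features) {
  stopifnot(is.data.frame(features))
  f <- features[features$pulse_index == 1L & !is.na(features$amplitude_mv), ]
  if (length(unique(f$current_ua)) < 2)
    stop("io curve needs >= 2 distinct currents")
  src <- if (any(f$source == "sweep_average")) "sweep_average" else "per_sweep"
  f <- f[f$source == src, ]
  if (nrow(f) == 0) stop("missing layer data for io curve")
  agg <- stats::aggregate(amplitude_mv ~ layer + current_ua, data = f, FUN = mean)
  agg <- agg[order(agg$layer, agg$current_ua), ]
  rownames(agg) <- NULL
  class(agg) <- c("io_curve", "data.frame")
  agg
}

#' Half-maximal stimulation current
#'
#' The smallest current at which the reference layer's amplitude reaches
#' 50% of its maximum over the tested range (the current used for
#' paired-pulse and train protocols is set to evoke a half-maximal CA1sr
#' fEPSP). Piecewise-linear interpolation between tested currents by
#' default; with `interpolate = FALSE` the result is the smallest tested
#' current whose amplitude reaches the criterion. Uniform scaling of all
#' amplitudes leaves the result unchanged.
#'
#' @param curve An `io_curve`.
#' @param reference_layer Layer defining the criterion (default CA1sr).
#' @param interpolate Interpolate between tested currents?
#' @return Current, uA.
#' @export
half_maximal_current <- function(curve, reference_layer = "CA1sr",
                                 interpolate = TRUE) {
  stopifnot(inherits(curve, "io_curve"))
  f <- curve[curve$layer == reference_layer, ]
  if (nrow(f) == 0) stop("reference layer absent from curve")
  amp <- abs(f$amplitude_mv)
  cur <- f$current_ua
  if (max(amp) <= 0) stop("all-zero io curve")
  target <- 0.5 * max(amp)
  reach <- which(amp >= target)
  i <- min(reach)
  if (!interpolate || i == 1L || amp[i] == target) return(cur[i])
  # linear interpolation on the segment crossing the criterion
  x0 <- cur[i - 1L]; x1 <- cur[i]; y0 <- amp[i - 1L]; y1 <- amp[i]
  x0 + (target - y0) * (x1 - x0) / (y1 - y0)
}

#' Percent change from a reference
#'
#' `100 * (value - reference) / reference`. Positive values indicate
#' facilitation for amplitude; for latency the raw signed formula is stored
#' and a decrease (faster response) is negative.
#'
#' @param value,reference Numeric (reference must be nonzero).
#' @return Percent change. A zero reference yields `NA` with a warning.
#' @export
percent_change <- function(value, reference) {
  out <- 100 * (value - reference) / reference
  bad <- !is.na(reference) & reference == 0
  if (any(bad)) {
    warning("zero reference in percent_change; result flagged NA")
    out[bad] <- NA_real_
  }
  out
}

#' Paired-pulse plasticity profile
#'
#' Percent change of the second-pulse measurement relative to the first,
#' computed per repeat (P2 and P1 matched within each pair) and averaged
#' across the repeats of each interval; the SEM across repeats is carried
#' along. Covers both amplitude and latency, per layer.
#'
#' @param features A `feature_table` (rows from one or more paired-pulse
#'   recordings at different intervals; per-sweep rows are used).
#' @return An object of class `plasticity_curve`: data.frame with `layer`,
#'   `measure` (`"amplitude"`/`"latency"`), `ppi_ms`, `pct_change`, `sem`,
#'   `n`.
#' @export
paired_pulse_profile <- function(features) {
  f <- features[features$source == "per_sweep", ]
  rows <- list()
  for (layer in unique(f$layer)) {
    for (ppi in sort(unique(f$ppi_ms))) {
      fl <- f[f$layer == layer & f$ppi_ms == ppi, ]
      p1 <- fl[fl$pulse_index == 1L, ]
      p2 <- fl[fl$pulse_index == 2L, ]
      if (nrow(p1) == 0 || nrow(p2) == 0)
        stop("interval ", ppi, " ms has only one pulse measured for ", layer)
      m <- merge(p1[, c("rep", "amplitude_mv", "latency_ms")],
                 p2[, c("rep", "amplitude_mv", "latency_ms")],
                 by = "rep", suffixes = c("_p1", "_p2"))
      for (meas in c("amplitude", "latency")) {
        v1 <- m[[paste0(if (meas == "amplitude") "amplitude_mv" else "latency_ms", "_p1")]]
        v2 <- m[[paste0(if (meas == "amplitude") "amplitude_mv" else "latency_ms", "_p2")]]
        pc <- percent_change(v2, v1)
        pc <- pc[is.finite(pc)]
        rows[[length(rows) + 1L]] <- data.frame(
          layer = layer, measure = meas, ppi_ms = ppi,
          pct_change = mean(pc),
          sem = if (length(pc) > 1) stats::sd(pc) / sqrt(length(pc)) else NA_real_,
          n = length(pc))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("plasticity_curve", "data.frame")
  attr(out, "condition_axis") <- "ppi_ms"
  attr(out, "reference") <- "P1"
  out
}

#' Train plasticity profile
#'
#' Per-pulse raw amplitude and latency across a 20-pulse train plus their
#' percent change from pulse 1, per layer. The reference (pulse 1) entry is
#' exactly 0%.
#'
#' @param features A `feature_table` from a train recording (one sweep per
#'   pulse; `sweep_average` rows are used since each pulse's average is the
#'   pulse itself).
#' @return An object of class `plasticity_curve`: data.frame with `layer`,
#'   `measure`, `pulse_index`, `raw`, `pct_change`.
#' @export
train_profile <- function(features) {
  f <- features[features$source == "sweep_average", ]
  rows <- list()
  for (layer in unique(f$layer)) {
    fl <- f[f$layer == layer, ]
    fl <- fl[order(fl$pulse_index), ]
    expected <- seq_len(max(fl$pulse_index))
    missing <- setdiff(expected, fl$pulse_index[!is.na(fl$amplitude_mv)])
    if (length(missing) > 0)
      stop("missing pulses for ", layer, ": ", paste(missing, collapse = ", "))
    for (meas in c("amplitude", "latency")) {
      v <- if (meas == "amplitude") fl$amplitude_mv else fl$latency_ms
      rows[[length(rows) + 1L]] <- data.frame(
        layer = layer, measure = meas, pulse_index = fl$pulse_index,
        raw = v, pct_change = percent_change(v, v[1]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("plasticity_curve", "data.frame")
  attr(out, "condition_axis") <- "pulse_index"
  attr(out, "reference") <- "pulse_1"
  out
}

#' @export
print.plasticity_curve <- function(x, ...) {
  cat(sprintf("<plasticity_curve> %s vs %s, reference %s\n",
              paste(unique(x$measure), collapse = "/"),
              attr(x, "condition_axis"), attr(x, "reference")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a plasticity curve
#' @param x A `plasticity_curve`.
#' @param measure Which measure to draw.
#' @param y,... Ignored / passed to [graphics::plot()].
#' @export
plot.plasticity_curve <- function(x, y, measure = "amplitude", ...) {
  ax <- attr(x, "condition_axis")
  f <- x[x$measure == measure, ]
  layers <- unique(f$layer)
  xx <- f[[ax]]
  graphics::plot(range(xx), range(f$pct_change, na.rm = TRUE), type = "n",
                 xlab = if (ax == "ppi_ms") "paired-pulse interval (ms)" else "pulse",
                 ylab = sprintf("%s change from first pulse (%%)", measure),
                 log = if (ax == "ppi_ms") "x" else "", ...)
  graphics::abline(h = 0, col = "grey")
  for (i in seq_along(layers)) {
    fl <- f[f$layer == layers[i], ]
    graphics::lines(fl[[ax]], fl$pct_change, type = "b", col = i, pch = 16)
  }
  graphics::legend("topright", legend = layers, col = seq_along(layers),
                   pch = 16, bty = "n")
  invisible(x)
}

#' Detect long-latency re-entrance in a train
#'
#' Re-entrant (polysynaptic, entorhinal-loop) responses appear mid-train as
#' long-latency deflections. For each pulse the scaled pulse-1 trace (the
#' direct response template, least-squares scaling over the early window)
#' is subtracted; the residual, smoothed by a zero-phase Gaussian kernel at
#' the component timescale, is
#' tested in the re-entrance window against `k` x the pooled pre-stimulus
#' baseline SD of the raw traces (small absolute floor for the noise-free
#' case). The polarity of the expected deflection at the layer's contact is
#' one-sided (sink-driven layers deflect negative, the DG granule layer
#' positive). A call requires the deflection to be sustained on all later
#' pulses up to the end of the train; `first_pulse` is the earliest such
#' pulse, with latency and amplitude read from it.
#'
#' @param s A train `sweep_set`.
#' @param window_ms Re-entrance latency window, ms (default 12-25 ms,
#'   bracketing reported in-vivo re-entrance latencies).
#' @param layers Layer map (see [layer_channels()]).
#' @param k Threshold in baseline SDs (default 3).
#' @param floor_mv Absolute threshold floor, mV.
#' @param early_window_ms Window for least-squares template scaling, ms.
#' @param tau_ms Component time constant setting the smoothing kernel
#'   width, ms.
#' @return An object of class `reentrance_calls`: data.frame with `layer`,
#'   `first_pulse` (`NA` when no call), `latency_ms`, `amplitude_mv`.
#' @export
detect_reentrance <- function(s, window_ms = c(12, 25), layers = NULL,
                              k = 3, floor_mv = 0.02,
                              early_window_ms = c(1.5, 11), tau_ms = 1.7) {
  stopifnot(inherits(s, "sweep_set"))
  if (s$protocol$kind != "train") stop("re-entrance detection expects a train sweep set")
  if (window_ms[2] > max(s$t_ms))
    stop("re-entrance window exceeds sweep length")
  if (is.null(layers)) {
    layers <- if (!is.null(s$truth)) s$truth$layer_map
              else layer_channels(s$geometry)
  }
  dt <- s$t_ms[2] - s$t_ms[1]
  # zero-phase smoothing kernel at the component timescale (Gaussian,
  # sd ~ tau/2, odd length so the filter introduces no lag)
  sd_ms <- tau_ms / 2
  half <- ceiling(3 * sd_ms / dt)
  kt <- seq(-half, half) * dt
  kern <- exp(-kt^2 / (2 * sd_ms^2))
  kern <- kern / sum(kern)
  n_pulses <- dim(s$sweeps)[1]
  pre <- s$t_ms < 0
  early <- s$t_ms >= early_window_ms[1] & s$t_ms <= early_window_ms[2]
  win <- s$t_ms >= window_ms[1] & s$t_ms <= window_ms[2]
  rows <- list()
  for (li in seq_len(nrow(layers))) {
    ch <- layers$channel[li]
    sgn <- if (layers$polarity[li] == "positive_going") 1 else -1
    tmpl <- s$sweeps[1, ch, ]
    base_sd <- stats::sd(as.vector(s$sweeps[, ch, pre]))
    thr <- max(k * base_sd, floor_mv)
    qual <- logical(n_pulses); pk_t <- pk_a <- rep(NA_real_, n_pulses)
    for (p in seq_len(n_pulses)) {
      tr <- s$sweeps[p, ch, ]
      a <- sum(tr[early] * tmpl[early]) / sum(tmpl[early]^2)
      res <- tr - a * tmpl
      sm <- as.vector(stats::filter(res, kern, sides = 2))
      sm[is.na(sm)] <- 0
      dwin <- sgn * sm[win]
      if (max(dwin) > thr) {
        qual[p] <- TRUE
        j <- which.max(dwin)
        pk_t[p] <- s$t_ms[win][j]
        pk_a[p] <- sgn * max(dwin)
      }
    }
    qual[1] <- FALSE # pulse 1 is the template; no residual by construction
    first <- NA_integer_
    for (p in 2:n_pulses) {
      if (all(qual[p:n_pulses])) { first <- p; break }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      layer = layers$layer[li],
      first_pulse = first,
      latency_ms = if (is.na(first)) NA_real_ else pk_t[first],
      amplitude_mv = if (is.na(first)) NA_real_ else pk_a[first])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reentrance_calls", "data.frame")
  out
}
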