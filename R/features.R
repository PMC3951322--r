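#' Five-point measurement template
#'
#' The measurement template marks five cursor positions on a response:
#' point 1 is the last sample before the stimulus artifact, points 2 and 3
#' bracket the response onset, and points 4 and 5 bracket the response peak
#' (positive-going) or trough (negative-going). Amplitude is the extremum
#' between points 4-5 minus the mean between points 2-3; latency is the
#' centre timestamp of points 4-5 minus the timestamp of point 1.
#'
#' `five_point_template()` builds a template manually;
#' [place_template()] places one automatically on a mean trace.
#'
#' @param p1,p2,p3,p4,p5 Sample indices with `p1 < p2 < p3 <= p4 < p5`.
#' @param polarity `"positive_going"` or `"negative_going"`.
#' @param t_ms Time axis of the trace the template refers to, ms.
#' @return An object of class `five_point_template`.
#' @export
five_point_template <- function(p1, p2, p3, p4, p5,
                                polarity = c("negative_going", "positive_going"),
                                t_ms) {
  polarity <- match.arg(polarity)
  idx <- c(p1, p2, p3, p4, p5)
  stopifnot(all(idx == round(idx)), p1 < p2, p2 < p3, p3 <= p4, p4 < p5,
            p1 >= 1, p5 <= length(t_ms))
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5,
                 polarity = polarity, t_ms = t_ms,
                 no_response = FALSE, low_confidence = FALSE),
            class = "five_point_template")
}

#' @export
print.five_point_template <- function(x, ...) {
  if (x$no_response) {
    cat("<five_point_template> no response\n")
  } else {
    cat(sprintf("<five_point_template> %s; p1-p5 at %s ms%s\n", x$polarity,
                paste(sprintf("%.1f", x$t_ms[c(x$p1, x$p2, x$p3, x$p4, x$p5)]),
                      collapse = ", "),
                if (x$low_confidence) " [low confidence]" else ""))
  }
  invisible(x)
}

#' Automatic template placement
#'
#' Places the five points on a mean trace: point 1 at the last sample before
#' the stimulus artifact onset (t = 0); points 2/3 surrounding the response
#' onset (the two samples just before the trace first departs from the
#' pre-stimulus baseline by more than `k_onset` baseline SDs after
#' `artifact_end_ms`); points 4/5
#' bracketing the global extremum of the requested polarity in the
#' `search_window_ms` window (ties broken by the earliest sample). When no
#' sample reaches the departure threshold the result is a "no response"
#' template, not an error. If the opposite-polarity extremum is larger than
#' the requested one the template is flagged low-confidence.
#'
#' @param mean_trace Numeric trace (typically a sweep average), mV.
#' @param t_ms Time axis, ms, with t = 0 at pulse onset.
#' @param polarity Expected response polarity.
#' @param artifact_end_ms End of the stimulus artifact, ms.
#' @param k_onset Onset threshold in baseline SDs.
#' @param search_window_ms Extremum search window, ms.
#' @param floor_mv Absolute threshold floor, mV (guards the noise-free case
#'   where the baseline SD is exactly zero).
#' @param rel_onset_frac Fraction of the extremum magnitude that the onset
#'   departure must also exceed; makes placement scale-invariant.
#' @return A `five_point_template` (possibly with `no_response = TRUE`).
#' @export
place_template <- function(mean_trace, t_ms,
                           polarity = c("negative_going", "positive_going"),
                           artifact_end_ms = 1, k_onset = 3,
                           search_window_ms = c(2, 30), floor_mv = 0.02,
                           rel_onset_frac = 0.05) {
  polarity <- match.arg(polarity)
  stopifnot(length(mean_trace) == length(t_ms))
  pre <- t_ms < 0
  if (!any(pre)) stop("trace has no pre-stimulus samples")
  p1 <- max(which(pre))
  bmean <- mean(mean_trace[pre])
  thr <- max(k_onset * stats::sd(mean_trace[pre]), floor_mv)

  win <- which(t_ms >= search_window_ms[1] & t_ms <= search_window_ms[2])
  if (length(win) == 0) stop("search window outside trace")
  dev <- mean_trace[win] - bmean
  ext_rel <- if (polarity == "positive_going") which.max(dev) else which.min(dev)
  ext_idx <- win[ext_rel]
  ext_mag <- abs(dev[ext_rel])
  opp_mag <- if (polarity == "positive_going") abs(min(dev)) else abs(max(dev))

  no_resp <- structure(list(p1 = p1, p2 = NA, p3 = NA, p4 = NA, p5 = NA,
                            polarity = polarity, t_ms = t_ms,
                            no_response = TRUE, low_confidence = TRUE),
                       class = "five_point_template")
  if (ext_mag <= thr) return(no_resp)

  # the onset threshold also scales with the response so template placement
  # is invariant to amplitude scaling (P1 and P2 templates land on the same
  # relative positions on identically shaped responses)
  onset_thr <- max(thr, rel_onset_frac * ext_mag)
  onset_cand <- which(t_ms >= artifact_end_ms & t_ms <= t_ms[ext_idx] &
                        abs(mean_trace - bmean) > onset_thr)
  if (length(onset_cand) == 0) return(no_resp)
  onset_idx <- min(onset_cand)

  p4 <- ext_idx - 1L
  p5 <- min(ext_idx + 1L, length(t_ms))
  # points 2/3 are the two samples just before the first supra-threshold
  # departure: they surround the response onset at its level period, so the
  # baseline they define is the local pre-response level, not the rising edge
  p3 <- min(onset_idx - 1L, p4)
  p2 <- p3 - 1L
  if (p2 <= p1) { p2 <- p1 + 1L; p3 <- max(p3, p2 + 1L) }
  if (p3 > p4) p3 <- p4
  tpl <- five_point_template(p1, p2, p3, p4, p5, polarity, t_ms)
  tpl$low_confidence <- opp_mag > ext_mag
  tpl
}

#' Measure response amplitude
#'
#' Amplitude (mV) = extremum of the trace between points 4-5 (maximum for
#' positive-going, minimum for negative-going responses) minus the mean of
#' the trace between points 2-3. The sign is retained (negative for
#' troughs). Adding a constant offset to the trace leaves the amplitude
#' unchanged.
#'
#' @param trace Numeric trace, mV.
#' @param tpl A `five_point_template` valid for this trace length.
#' @return Signed amplitude, mV (`NA` for a no-response template).
#' @export
measure_amplitude <- function(trace, tpl) {
  stopifnot(inherits(tpl, "five_point_template"))
  if (tpl$no_response) return(NA_real_)
  if (tpl$p5 > length(trace)) stop("template indices out of range")
  baseline <- mean(trace[tpl$p2:tpl$p3])
  seg <- trace[tpl$p4:tpl$p5]
  ext <- if (tpl$polarity == "positive_going") max(seg) else min(seg)
  ext - baseline
}

#' Measure response latency
#'
#' Latency (ms) = centre timestamp between points 4 and 5 minus the
#' timestamp of point 1. Latency to response onset is deliberately not
#' measured (there is seldom a defined level period between the stimulus
#' artifact and the response).
#'
#' @inheritParams measure_amplitude
#' @return Latency, ms (`NA` for a no-response template).
#' @export
measure_latency <- function(trace, tpl) {
  stopifnot(inherits(tpl, "five_point_template"))
  if (tpl$no_response) return(NA_real_)
  if (tpl$p5 > length(trace)) stop("template indices out of range")
  (tpl$t_ms[tpl$p4] + tpl$t_ms[tpl$p5]) / 2 - tpl$t_ms[tpl$p1]
}

#' Detect a population spike
#'
#' A population spike is a fast transient superimposed on the smooth fEPSP.
#' Detection: subtract a Savitzky-Golay-smoothed copy of the trace; a PS is
#' present when the high-pass residual within the window exceeds
#' `k` x the median absolute deviation of the pre-stimulus residual (with a
#' small absolute floor) and the width of the transient at half height is
#' below 3 ms. Returns the first qualifying transient.
#'
#' @param sweep_trace Granule-layer trace for one sweep, mV.
#' @param t_ms Time axis, ms.
#' @param window_ms Search window `(lo, hi)`, ms.
#' @param k Threshold in MADs of the pre-stimulus residual (default 6).
#' @param floor_mv Absolute threshold floor, mV. The default sits above
#'   the Savitzky-Golay residual a smooth millivolt-scale fEPSP leaves
#'   (~0.16 mV) and far below a population-spike residual (>0.8 mV), so a
#'   smooth noise-free response never triggers.
#' @param max_width_ms Maximum width at half height, ms.
#' @param sg_n Savitzky-Golay window length (odd number of samples).
#' @return list with `detected` (logical), `ps_time_ms` (time of the
#'   transient extremum, `NA` if none), `amplitude_mv` (residual extremum).
#' @export
detect_ps <- function(sweep_trace, t_ms, window_ms = c(2, 30), k = 6,
                      floor_mv = 0.25, max_width_ms = 3, sg_n = 15) {
  stopifnot(length(sweep_trace) == length(t_ms))
  if (window_ms[1] < min(t_ms) || window_ms[2] > max(t_ms))
    stop("PS window outside sweep")
  smooth <- signal::sgolayfilt(sweep_trace, p = 3, n = sg_n)
  res <- sweep_trace - smooth
  pre <- t_ms < 0
  thr <- max(k * stats::mad(res[pre]), floor_mv)
  win <- which(t_ms >= window_ms[1] & t_ms <= window_ms[2])
  sup <- win[abs(res[win]) > thr]
  none <- list(detected = FALSE, ps_time_ms = NA_real_,
               amplitude_mv = NA_real_)
  if (length(sup) == 0) return(none)
  dt <- t_ms[2] - t_ms[1]
  # split supra-threshold samples into transient clusters (gap > 1 ms)
  runs <- split(sup, cumsum(c(1, diff(sup) * dt > 1)))
  for (r in runs) {
    # extend to the contiguous half-height region around the cluster peak
    pk <- r[which.max(abs(res[r]))]
    half <- abs(res[pk]) / 2
    lo <- pk; while (lo > 1 && abs(res[lo - 1]) > half) lo <- lo - 1
    hi <- pk; while (hi < length(res) && abs(res[hi + 1]) > half) hi <- hi + 1
    if ((hi - lo) * dt < max_width_ms)
      return(list(detected = TRUE, ps_time_ms = t_ms[pk],
                  amplitude_mv = res[pk]))
  }
  none
}

#' Population-spike probability
#'
#' Fraction of sweeps in which a PS was evoked, reported with its count
#' basis (n flagged out of N sweeps) as attributes `n_ps` and `n_sweeps`.
#'
#' @param ps_flags Logical vector of per-sweep PS flags (>= 1 sweep).
#' @return Probability in `[0, 1]` with count attributes.
#' @export
ps_probability <- function(ps_flags) {
  if (length(ps_flags) == 0) stop("empty input: no sweeps")
  p <- mean(as.logical(ps_flags))
  attr(p, "n_ps") <- sum(as.logical(ps_flags))
  attr(p, "n_sweeps") <- length(ps_flags)
  p
}

#' Extract a feature table from a sweep set
#'
#' For each pulse condition (pulse index x current x interval) and each
#' analysed layer, a template is placed on the condition's sweep-average
#' trace and then used to measure every individual sweep (rows with
#' `source = "per_sweep"`) as well as the average itself
#' (`source = "sweep_average"`). PS detection runs per sweep on the
#' granule-layer (DG) channel.
#'
#' @param s A `sweep_set`.
#' @param layers data.frame with columns `layer`, `channel`, `polarity`
#'   (defaults to [layer_channels()] for the sweep set's geometry).
#' @param artifact_end_ms,k_onset,search_window_ms,floor_mv Passed to
#'   [place_template()].
#' @param ps_window_ms,ps_k Passed to [detect_ps()].
#' @return data.frame (class `feature_table`) with one row per sweep x
#'   layer plus per-condition average rows: columns `protocol`, `layer`,
#'   `channel`, `pulse_index`, `rep`, `current_ua`, `ppi_ms`,
#'   `amplitude_mv`, `latency_ms`, `ps_flag`, `source`, `low_confidence`.
#' @export
extract_features <- function(s, layers = NULL, artifact_end_ms = 1,
                             k_onset = 3, search_window_ms = c(2, 30),
                             floor_mv = 0.02, ps_window_ms = c(2, 30),
                             ps_k = 6) {
  stopifnot(inherits(s, "sweep_set"))
  if (is.null(layers)) {
    layers <- if (!is.null(s$truth)) s$truth$layer_map
              else layer_channels(s$geometry)
  }
  info <- s$info
  # condition = current x interval; pulses within a pair share the template
  # placed on the P1 mean (one template per mean response); trains re-place
  # the template on every pulse to track the rapid waveform changes
  cond <- interaction(info$current_ua,
                      ifelse(is.na(info$ppi_ms), -1, info$ppi_ms),
                      drop = TRUE)
  per_pulse_tpl <- s$protocol$kind == "train"
  # for paired protocols the search and PS windows must end before the
  # second pulse (and its artifact) arrives
  if (s$protocol$kind %in% c("paired_pulse", "io_series")) {
    search_window_ms[2] <- min(search_window_ms[2], s$protocol$ppi_ms - 2)
    ps_window_ms[2] <- min(ps_window_ms[2], s$protocol$ppi_ms - 2)
  }
  rows <- list()
  dg_ch <- if ("DG" %in% layers$layer) layers$channel[layers$layer == "DG"] else NA
  mean_of <- function(sel, ch)
    if (length(sel) > 1)
      colMeans(s$sweeps[sel, ch, , drop = FALSE][, 1, ]) else s$sweeps[sel, ch, ]
  for (cl in levels(cond)) {
    csel <- which(cond == cl)
    pulse_levels <- sort(unique(info$pulse_index[csel]))
    for (li in seq_len(nrow(layers))) {
      ch <- layers$channel[li]
      tpl_ref <- place_template(mean_of(csel[info$pulse_index[csel] ==
                                               pulse_levels[1]], ch),
                                s$t_ms, layers$polarity[li], artifact_end_ms,
                                k_onset, search_window_ms, floor_mv)
      for (pk in pulse_levels) {
        sel <- csel[info$pulse_index[csel] == pk]
        mt <- mean_of(sel, ch)
        tpl <- if (per_pulse_tpl && pk != pulse_levels[1])
          place_template(mt, s$t_ms, layers$polarity[li], artifact_end_ms,
                         k_onset, search_window_ms, floor_mv)
          else tpl_ref
        mk_row <- function(amp, lat, ps, src, inf_row) {
          data.frame(protocol = s$protocol$kind, layer = layers$layer[li],
                     channel = ch, pulse_index = inf_row$pulse_index,
                     rep = inf_row$rep, current_ua = inf_row$current_ua,
                     ppi_ms = inf_row$ppi_ms, amplitude_mv = amp,
                     latency_ms = lat, ps_flag = ps, source = src,
                     low_confidence = tpl$low_confidence || tpl$no_response,
                     stringsAsFactors = FALSE)
        }
        for (k in sel) {
          tr <- s$sweeps[k, ch, ]
          ps <- NA
          if (identical(ch, dg_ch))
            ps <- detect_ps(tr, s$t_ms, ps_window_ms, ps_k)$detected
          rows[[length(rows) + 1L]] <-
            mk_row(measure_amplitude(tr, tpl), measure_latency(tr, tpl), ps,
                   "per_sweep", info[k, ])
        }
        avg_inf <- info[sel[1], ]
        avg_inf$rep <- NA_integer_
        rows[[length(rows) + 1L]] <-
          mk_row(measure_amplitude(mt, tpl), measure_latency(mt, tpl), NA,
                 "sweep_average", avg_inf)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}
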