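#' Segment a recording into stimulus-locked sweeps
#'
#' Cuts one slice per stimulus pulse, with the time axis re-zeroed to pulse
#' onset. Pulse indices (P1/P2 for pairs, 1-20 for trains), repeat numbers
#' and currents are carried over from the protocol structure. The default
#' window (10 ms pre, 40 ms post) covers the longest re-entrance latencies
#' plus after-potentials.
#'
#' @param rec A `laminar_recording`.
#' @param pre_ms,post_ms Window before/after pulse onset, ms. `post_ms`
#'   must be >= 30 ms so the longest analysis latencies fit.
#' @return An object of class `sweep_set`: `sweeps` (sweeps x channels x
#'   time array), `t_ms` (window time axis), `info` (per-sweep metadata),
#'   plus geometry/protocol references.
#' @export
segment_sweeps <- function(rec, pre_ms = 10, post_ms = 40) {
  stopifnot(inherits(rec, "laminar_recording"), pre_ms >= 0)
  if (post_ms < 30)
    stop("post_ms must be >= 30 ms to contain the longest analysis latency")
  fs <- rec$sampling_rate
  n_pre <- as.integer(round(pre_ms * fs / 1000))
  n_post <- as.integer(round(post_ms * fs / 1000))
  n <- ncol(rec$potentials)
  for (k in seq_along(rec$stim_times)) {
    s <- rec$stim_times[k]
    if (s - n_pre < 1L || s + n_post > n)
      stop("sweep window out of recording range at pulse ", k,
           " (stim sample ", s, ")")
  }
  nt <- n_pre + n_post + 1L
  sw <- array(NA_real_,
              dim = c(length(rec$stim_times), nrow(rec$potentials), nt))
  for (k in seq_along(rec$stim_times)) {
    s <- rec$stim_times[k]
    sw[k, , ] <- rec$potentials[, (s - n_pre):(s + n_post)]
  }
  info <- rec$pulse_info
  info$sweep <- seq_len(nrow(info))
  ss <- list(sweeps = sw, t_ms = seq(-n_pre, n_post) * 1000 / fs,
             info = info, geometry = rec$geometry, protocol = rec$protocol,
             sampling_rate = fs, pre_ms = pre_ms, post_ms = post_ms,
             truth = rec$truth)
  class(ss) <- "sweep_set"
  ss
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d ch x %d samples (%g ms pre, %g ms post)\n",
              dim(x$sweeps)[1], dim(x$sweeps)[2], dim(x$sweeps)[3],
              x$pre_ms, x$post_ms))
  invisible(x)
}

#' Average sweeps
#'
#' Pointwise arithmetic mean across the sweeps matched by the selector
#' (standard practice: the mean of the 20 stimulus-response repeats).
#'
#' @param s A `sweep_set`.
#' @param pulse_index Optional pulse index filter (e.g. `1` for P1).
#' @param which Optional explicit sweep numbers (row indices); combined with
#'   `pulse_index` by intersection.
#' @return channels x time matrix of the mean trace.
#' @export
average_sweeps <- function(s, pulse_index = NULL, which = NULL) {
  stopifnot(inherits(s, "sweep_set"))
  sel <- seq_len(dim(s$sweeps)[1])
  if (!is.null(pulse_index))
    sel <- intersect(sel, base::which(s$info$pulse_index %in% pulse_index))
  if (!is.null(which)) sel <- intersect(sel, which)
  if (length(sel) == 0) stop("empty sweep selection")
  out <- apply(s$sweeps[sel, , , drop = FALSE], c(2, 3), mean)
  dimnames(out) <- NULL
  out
}

#' Exclude unstable sweeps
#'
#' Stability screen: a sweep is excluded when its pre-stimulus baseline mean
#' deviates from the session median baseline by more than `drift_tol`. The
#' exclusion report (attribute `"exclusions"`) lists removed sweeps and the
#' reason. An empty result is permitted and flagged in the report.
#'
#' @param s A `sweep_set`.
#' @param drift_tol Tolerated baseline drift, mV (> 0; `Inf` keeps all).
#' @return The filtered `sweep_set`; `attr(, "exclusions")` holds the
#'   report (`sweep`, `baseline_mv`, `deviation_mv`, `reason`).
#' @export
exclude_unstable <- function(s, drift_tol = 2) {
  stopifnot(inherits(s, "sweep_set"), drift_tol > 0)
  pre <- s$t_ms < 0
  base <- apply(s$sweeps[, , pre, drop = FALSE], 1, mean)
  dev <- base - stats::median(base)
  drop_i <- which(abs(dev) > drift_tol)
  report <- data.frame(sweep = drop_i, baseline_mv = base[drop_i],
                       deviation_mv = dev[drop_i],
                       reason = rep("baseline drift beyond drift_tol",
                                    length(drop_i)))
  keep <- setdiff(seq_along(base), drop_i)
  out <- s
  out$sweeps <- s$sweeps[keep, , , drop = FALSE]
  out$info <- s$info[keep, , drop = FALSE]
  out$info$sweep <- seq_len(nrow(out$info)) # re-index to array rows
  if (length(keep) == 0) report$reason <- paste(report$reason, "(all sweeps excluded)")
  attr(out, "exclusions") <- report
  out
}
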