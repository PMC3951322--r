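mk_feature_rows <- function(layer, pulse, current, amp, rep = 1,
                            ppi = 50, source = "sweep_average") {
  data.frame(protocol = "io_series", layer = layer, channel = 1,
             pulse_index = pulse, rep = rep, current_ua = current,
             ppi_ms = ppi, amplitude_mv = amp, latency_ms = 8,
             ps_flag = NA, source = source, low_confidence = FALSE)
}

test_that("io curves reproduce first-pulse amplitudes and ignore P2", {
  ft <- rbind(mk_feature_rows("CA1sr", 1, 100, 1.0),
              mk_feature_rows("CA1sr", 1, 200, 2.0),
              mk_feature_rows("CA1sr", 2, 100, 99), # P2 must be ignored
              mk_feature_rows("CA1sr", 2, 200, 99))
  curve <- build_io_curve(ft)
  expect_equal(curve$amplitude_mv, c(1.0, 2.0))
  expect_equal(curve$current_ua, c(100, 200))
  expect_error(build_io_curve(mk_feature_rows("CA1sr", 1, 100, 1)), ">= 2")
})

test_that("half-maximal current follows linear interpolation", {
  ft <- rbind(mk_feature_rows("CA1sr", 1, 50, 0),
              mk_feature_rows("CA1sr", 1, 300, 1.0),
              mk_feature_rows("CA1sr", 1, 600, 2.0))
  curve <- build_io_curve(ft)
  expect_equal(half_maximal_current(curve), 300) # 50% of max 2.0 is at 300
  # flat nonzero curve: criterion reached at the smallest tested current
  ftf <- rbind(mk_feature_rows("CA1sr", 1, 100, 1.5),
               mk_feature_rows("CA1sr", 1, 400, 1.5))
  expect_equal(half_maximal_current(build_io_curve(ftf)), 100)
  # uniform amplitude scaling leaves the result unchanged
  ft2 <- ft; ft2$amplitude_mv <- ft2$amplitude_mv * 7
  expect_equal(half_maximal_current(build_io_curve(ft2)),
               half_maximal_current(curve))
  ftz <- ft; ftz$amplitude_mv <- 0
  expect_error(half_maximal_current(build_io_curve(ftz)), "zero")
  expect_error(half_maximal_current(curve, reference_layer = "DG"), "absent")
})

test_that("half-maximal current recovers the analytic saturating curve", {
  currents <- seq(50, 600, by = 50)
  amps <- 2 * current_gain(currents) # amplitude proportional to gain
  ft <- do.call(rbind, lapply(seq_along(currents), function(i)
    mk_feature_rows("CA1sr", 1, currents[i], amps[i])))
  est <- half_maximal_current(build_io_curve(ft))
  # oracle: numeric inversion of the saturating curve at 50% of its maximum
  target <- 0.5 * current_gain(600)
  analytic <- uniroot(function(I) current_gain(I) - target, c(50, 600))$root
  expect_lt(abs(est - analytic), 50) # within one current step
})

test_that("percent change is the standard normalized difference", {
  expect_equal(percent_change(1.5, 1.0), 50)
  expect_equal(percent_change(1.0, 1.0), 0)
  expect_equal(percent_change(0.8, 1.0), -20)
  expect_warning(out <- percent_change(1, 0), "zero reference")
  expect_true(is.na(out))
})

test_that("paired-pulse profiles recover programmed gains at zero noise", {
  ppis <- c(25, 100)
  fts <- lapply(ppis, function(ppi) {
    rec <- simulate_protocol(control_profile(),
                             stimulus_protocol("paired_pulse", ppi_ms = ppi,
                                               n_repeats = 5),
                             noise_sd = 0, artifact_amp = 0, seed = 1)
    extract_features(segment_sweeps(rec))
  })
  pp <- paired_pulse_profile(do.call(rbind, fts))
  for (ppi in ppis) {
    prog <- 100 * (control_profile()$ppi_gain[[as.character(ppi)]] - 1)
    a <- pp[pp$measure == "amplitude" & pp$ppi_ms == ppi, ]
    # residual alpha-tail overlap at the shortest interval is ~0.003 points
    expect_equal(a$pct_change, rep(prog, nrow(a)), tolerance = 1e-3)
  }
  # unit gains give a flat 0% profile
  unit <- excitability_profile(
    ppi_gain = c(`25` = 1, `50` = 1, `100` = 1, `200` = 1, `500` = 1,
                 `1000` = 1),
    train_gain = rep(1, 20), label = "unit")
  rec <- simulate_protocol(unit, stimulus_protocol("paired_pulse",
                                                   ppi_ms = 50,
                                                   n_repeats = 5),
                           noise_sd = 0, artifact_amp = 0, seed = 2)
  pp0 <- paired_pulse_profile(extract_features(segment_sweeps(rec)))
  expect_equal(pp0$pct_change, rep(0, nrow(pp0)), tolerance = 1e-6)
  # an interval with only one pulse measured is an error
  broken <- fts[[1]]
  broken <- broken[broken$pulse_index == 1, ]
  expect_error(paired_pulse_profile(broken), "only one pulse")
})

test_that("train profiles are exact against programmed per-pulse gains", {
  ramp <- no_reentry_profile(train_gain = seq(1, 2, length.out = 20))
  rec <- simulate_protocol(ramp, stimulus_protocol("train"), noise_sd = 0,
                           artifact_amp = 0, seed = 1)
  tp <- train_profile(extract_features(segment_sweeps(rec)))
  a <- tp[tp$measure == "amplitude" & tp$layer == "DG", ]
  expect_equal(a$pct_change[20], 100, tolerance = 1e-6)
  expect_equal(a$pct_change,
               100 * (seq(1, 2, length.out = 20) - 1), tolerance = 1e-6)
  expect_equal(a$pct_change[1], 0)
  # arithmetic: 2 -> 2.5 mV is +25%
  expect_equal(percent_change(2.5, 2), 25)
  # constant gains: flat raw profile, 0% change
  flat <- no_reentry_profile(train_gain = rep(1, 20))
  rec0 <- simulate_protocol(flat, stimulus_protocol("train"), noise_sd = 0,
                            artifact_amp = 0, seed = 1)
  tp0 <- train_profile(extract_features(segment_sweeps(rec0)))
  expect_equal(tp0$pct_change, rep(0, nrow(tp0)), tolerance = 1e-6)
  # missing pulses are listed
  ft <- extract_features(segment_sweeps(rec))
  expect_error(train_profile(ft[ft$pulse_index != 5, ]), "5")
})

test_that("re-entrance detection recovers programmed onsets at zero noise", {
  for (first in c(10, 20)) {
    prof <- excitability_profile(
      ppi_gain = ad_profile()$ppi_gain, train_gain = ad_profile()$train_gain,
      reentry_first_pulse = first, reentry_latency_ms = 15,
      reentry_layer = "CA1sr", label = "r")
    rec <- simulate_protocol(prof, stimulus_protocol("train"), noise_sd = 0,
                             artifact_amp = 0, seed = 1)
    rc <- detect_reentrance(segment_sweeps(rec))
    sr <- rc[rc$layer == "CA1sr", ]
    expect_equal(sr$first_pulse, first)
    expect_lt(abs(sr$latency_ms - 15), 1)
  }
  # no programmed re-entrance: no call at zero noise
  rec0 <- simulate_protocol(no_reentry_profile(), stimulus_protocol("train"),
                            noise_sd = 0, artifact_amp = 0, seed = 1)
  rc0 <- detect_reentrance(segment_sweeps(rec0))
  expect_true(all(is.na(rc0$first_pulse)))
  # window beyond the sweep is an error
  expect_error(detect_reentrance(segment_sweeps(rec0), window_ms = c(12, 60)),
               "window")
})
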