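# single-component noise-free sweep at the component's own contact:
# the closed-form peak (onset + tau) is the oracle for template placement
solo_sweep <- function(onset_ms = 4.5, tau_ms = 1.5) {
  fixture(sprintf("solo_sweep_%g_%g", onset_ms, tau_ms), {
    geom <- probe_geometry()
    cc <- single_component(onset_ms = onset_ms, tau_ms = tau_ms)
    t_win <- seq(0, 40, by = 0.1)
    pot <- solve_forward(build_evoked_density(list(cc), 1, t_win, geom), geom)
    ch <- which.min(abs(contact_depths(geom) - cc$center_depth_um))
    list(trace = c(rep(0, 100), pot[ch, ]), t_ms = seq(-10, 40, by = 0.1),
         peak_ms = onset_ms + tau_ms, clean_pot = pot[ch, ], t_win = t_win)
  })
}

test_that("template ordering invariants are enforced", {
  t_ms <- seq(-10, 40, by = 0.1)
  expect_s3_class(five_point_template(100, 140, 141, 170, 172,
                                      "negative_going", t_ms),
                  "five_point_template")
  expect_error(five_point_template(100, 99, 141, 170, 172,
                                   "negative_going", t_ms))
  expect_error(five_point_template(100, 140, 141, 140, 172,
                                   "negative_going", t_ms))
})

test_that("automatic placement brackets the analytic alpha peak", {
  sw <- solo_sweep()
  tpl <- place_template(sw$trace, sw$t_ms, "negative_going")
  expect_false(tpl$no_response)
  mid_ms <- (sw$t_ms[tpl$p4] + sw$t_ms[tpl$p5]) / 2
  expect_lte(abs(mid_ms - sw$peak_ms), 0.1 + 1e-9) # within one sample
  lat <- measure_latency(sw$trace, tpl)
  expect_lte(abs(lat - sw$peak_ms), 0.1 + 1e-9)
})

test_that("measured amplitude matches the forward-model potential within 1%", {
  sw <- solo_sweep()
  tpl <- place_template(sw$trace, sw$t_ms, "negative_going")
  amp <- measure_amplitude(sw$trace, tpl)
  oracle <- min(sw$clean_pot) # noise-free potential trough at the contact
  expect_lt(abs(amp - oracle) / abs(oracle), 0.01)
})

test_that("amplitude follows the points 2-3 / 4-5 arithmetic", {
  t_ms <- seq(-1, 5, by = 0.1)
  tr <- rep(0.5, length(t_ms))
  tr[t_ms >= 3 & t_ms <= 4] <- 2.0
  tpl <- five_point_template(10, 13, 16, 40, 45, "positive_going", t_ms)
  expect_equal(measure_amplitude(tr, tpl), 1.5)
  # constant trace measures 0
  expect_equal(measure_amplitude(rep(3, length(t_ms)), tpl), 0)
  # offset invariance and scaling linearity
  sw <- solo_sweep()
  tpl2 <- place_template(sw$trace, sw$t_ms, "negative_going")
  a0 <- measure_amplitude(sw$trace, tpl2)
  expect_equal(measure_amplitude(sw$trace + 5, tpl2), a0)
  expect_equal(measure_amplitude(sw$trace * 3, tpl2), 3 * a0)
  expect_error(measure_amplitude(sw$trace[1:100], tpl2), "range")
})

test_that("latency is the centre of points 4-5 minus point 1", {
  t_ms <- seq(0, 10, by = 1) # p1 at 0 ms, p4 at 7, p5 at 9 -> 8 ms
  tpl <- five_point_template(1, 3, 4, 8, 10, "positive_going", t_ms)
  expect_equal(measure_latency(rep(1, 11), tpl), 8)
  # shifting trace and time axis together leaves latency unchanged
  tpl_shift <- five_point_template(1, 3, 4, 8, 10, "positive_going", t_ms + 5)
  expect_equal(measure_latency(rep(1, 11), tpl_shift), 8)
})

test_that("flat traces yield a no-response outcome, not an error", {
  t_ms <- seq(-10, 40, by = 0.1)
  tpl <- place_template(rep(0, length(t_ms)), t_ms, "negative_going")
  expect_true(tpl$no_response)
  expect_true(is.na(measure_amplitude(rep(0, length(t_ms)), tpl)))
  expect_true(is.na(measure_latency(rep(0, length(t_ms)), tpl)))
})

test_that("polarity mismatch still measures the requested polarity, flagged", {
  sw <- solo_sweep() # negative-going response
  tpl <- place_template(sw$trace, sw$t_ms, "positive_going")
  if (!tpl$no_response) {
    expect_true(tpl$low_confidence)
    expect_gte(measure_amplitude(sw$trace, tpl), 0)
  } else {
    expect_true(tpl$no_response) # small positive lobe below threshold
  }
})

test_that("population spikes are detected at the injected time", {
  sw <- solo_sweep(onset_ms = 6, tau_ms = 1.8)
  t_ms <- sw$t_ms
  set.seed(11)
  hits <- 0; terr <- numeric(0)
  for (i in 1:50) {
    tr <- sw$trace + as.numeric(band_limited_noise(1, length(t_ms), 0.1))
    tr_ps <- tr + 1.5 * ((t_ms - 7.8) / 0.25) * exp(0.5 - (t_ms - 7.8)^2 / (2 * 0.25^2))
    r <- detect_ps(tr_ps, t_ms)
    hits <- hits + r$detected
    if (r$detected) terr <- c(terr, abs(r$ps_time_ms - 7.8))
  }
  expect_gte(hits / 50, 0.95)
  expect_true(all(terr <= 0.5))
})

test_that("smooth responses and noise-only sweeps are not called as PS", {
  sw <- solo_sweep(onset_ms = 6, tau_ms = 1.8)
  expect_false(detect_ps(sw$trace, sw$t_ms)$detected)
  set.seed(12)
  fp <- 0
  for (i in 1:200)
    fp <- fp + detect_ps(as.numeric(band_limited_noise(1, length(sw$t_ms), 0.1)),
                         sw$t_ms)$detected
  expect_lte(fp / 200, 0.01)
})

test_that("PS probability is the flagged fraction with its count basis", {
  expect_equal(as.numeric(ps_probability(rep(FALSE, 20))), 0)
  expect_equal(as.numeric(ps_probability(rep(TRUE, 20))), 1)
  p <- ps_probability(c(rep(TRUE, 12), rep(FALSE, 8)))
  expect_equal(as.numeric(p), 0.6)
  expect_equal(attr(p, "n_ps"), 12)
  expect_equal(attr(p, "n_sweeps"), 20)
  expect_error(ps_probability(logical(0)), "empty")
})

test_that("per-sweep and average measurements agree at zero noise", {
  rec <- clean_pair_rec()
  ft <- extract_features(segment_sweeps(rec))
  for (layer in c("CA1sr", "CA1slm", "DG")) {
    f <- ft[ft$layer == layer & ft$pulse_index == 1, ]
    avg <- f$amplitude_mv[f$source == "sweep_average"]
    per <- f$amplitude_mv[f$source == "per_sweep"]
    expect_true(all(abs(per - avg) < 1e-9))
  }
})
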