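test_that("every generated density grid conserves current", {
  geom <- probe_geometry(8, 100, 1500)
  t_ms <- seq(0, 40, by = 0.1)
  set.seed(7)
  for (i in 1:10) {
    cc <- csd_component("x", runif(1, 1700, 2000), runif(1, 80, 200),
                        runif(1, 2, 10), runif(1, 1, 3),
                        sample(c("sink", "source"), 1),
                        runif(1, 0.5, 2) * 1e-4,
                        return_offset_um = sample(c(0, 150, -200), 1),
                        return_spatial_sd_um = runif(1, 80, 250))
    g <- build_evoked_density(list(cc), 1, t_ms, geom)
    expect_lt(max(abs(colSums(g$density))), 1e-9 * max(abs(g$density)))
  }
})

test_that("density peaks at the analytic alpha-function peak time", {
  geom <- probe_geometry()
  t_ms <- seq(0, 40, by = 0.1)
  c1 <- single_component(onset_ms = 5.5, tau_ms = 1.5, center = 1700)
  c2 <- single_component(onset_ms = 7.5, tau_ms = 2.0, center = 2200)
  g <- build_evoked_density(list(c1, c2), 1, t_ms, geom)
  for (cc in list(c1, c2)) {
    row <- which.min(abs(g$depths_um - cc$center_depth_um))
    t_peak <- t_ms[which.max(abs(g$density[row, ]))]
    expect_equal(t_peak, cc$onset_ms + cc$tau_ms, tolerance = 1e-12)
  }
})

test_that("zero density solves to zero potentials", {
  geom <- probe_geometry(8, 100, 1500)
  g <- build_evoked_density(list(single_component(amp = 0)), 1,
                            seq(0, 10, 0.1), geom)
  expect_true(all(g$density == 0))
  expect_true(all(solve_forward(g, geom) == 0))
})

test_that("a symmetric sink/source pair gives antisymmetric potentials", {
  geom <- probe_geometry(8, 100, 1500)      # contacts 1500..2200
  mid <- mean(range(contact_depths(geom)))  # 1850
  cc <- csd_component("pair", mid - 150, 100, 5, 1.5, "sink", 1e-4,
                      return_offset_um = 300) # source mirrored about mid
  pot <- solve_forward(build_evoked_density(list(cc), 1, seq(0, 20, 0.1),
                                            geom), geom)
  expect_equal(pot, -pot[nrow(pot):1, ], tolerance = 1e-8)
})

test_that("the CSD estimator inverts the forward solver on smooth grids", {
  for (geom in list(probe_geometry(16, 100, 1100),
                    probe_geometry(32, 50, 1100))) {
    sd_um <- 2 * geom$spacing_um
    cc <- csd_component("wide", 1800, sd_um, 5, 1.5, "sink", 1e-4,
                        return_offset_um = 0,
                        return_spatial_sd_um = 2.2 * sd_um)
    g <- build_evoked_density(list(cc), 1, seq(0, 20, 0.5), geom)
    pot <- solve_forward(g, geom)
    est <- estimate_csd(pot, geom$spacing_um)
    d <- contact_depths(geom)
    truth <- g$density[match(d[2:(length(d) - 1)], g$depths_um), ]
    rel_rms <- sqrt(mean((est$density - truth)^2)) / sqrt(mean(truth^2))
    expect_lt(rel_rms, 0.05)
    expect_gt(cor(as.vector(est$density), as.vector(truth)), 0.99)
  }
})

test_that("solver rejects coarse grids and non-finite densities", {
  geom <- probe_geometry(8, 100, 1500)
  t_ms <- seq(0, 10, 0.5)
  g <- build_evoked_density(list(single_component(center = 1800)), 1,
                            t_ms, geom)
  coarse <- list(density = g$density[seq(1, nrow(g$density), by = 4), ],
                 depths_um = g$depths_um[seq(1, nrow(g$density), by = 4)])
  expect_error(solve_forward(coarse, geom), "finer")
  bad <- g; bad$density[1, 1] <- NaN
  expect_error(solve_forward(bad, geom), "non-finite")
  short <- list(density = g$density[30:100, ], depths_um = g$depths_um[30:100])
  expect_error(solve_forward(short, geom), "500 um")
})

test_that("potentials scale linearly with peak density", {
  geom <- probe_geometry(8, 100, 1500)
  t_ms <- seq(0, 20, 0.1)
  p1 <- solve_forward(build_evoked_density(
    list(single_component(center = 1800, amp = 1e-4)), 1, t_ms, geom), geom)
  p2 <- solve_forward(build_evoked_density(
    list(single_component(center = 1800, amp = 2e-4)), 1, t_ms, geom), geom)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
})

test_that("simulation is bit-identical under a fixed seed", {
  proto <- stimulus_protocol("train")
  r1 <- simulate_protocol(ad_profile(), proto, seed = 9)
  r2 <- simulate_protocol(ad_profile(), proto, seed = 9)
  expect_identical(r1, r2)
  r3 <- simulate_protocol(ad_profile(), proto, seed = 10)
  expect_false(identical(r1$potentials, r3$potentials))
})

test_that("unit paired-pulse gain reproduces P1 exactly on P2", {
  prof <- excitability_profile(
    ppi_gain = c(`25` = 1, `50` = 1, `100` = 1, `200` = 1, `500` = 1,
                 `1000` = 1),
    train_gain = rep(1, 20), label = "unit")
  rec <- simulate_protocol(prof, stimulus_protocol("paired_pulse",
                                                   ppi_ms = 50),
                           noise_sd = 0, artifact_amp = 0, seed = 1)
  ss <- segment_sweeps(rec)
  f <- extract_features(ss)
  f <- f[f$source == "sweep_average" & !is.na(f$amplitude_mv), ]
  for (layer in unique(f$layer)) {
    a <- f[f$layer == layer, ]
    expect_equal(a$amplitude_mv[a$pulse_index == 2],
                 a$amplitude_mv[a$pulse_index == 1], tolerance = 1e-6)
  }
})

test_that("re-entrance ground truth flags start at the programmed pulse", {
  rec <- clean_train_rec()
  first <- rec$truth$profile$reentry_first_pulse
  expect_true(all(rec$truth$reentry_flags[rec$pulse_info$pulse_index >= first]))
  expect_false(any(rec$truth$reentry_flags[rec$pulse_info$pulse_index < first]))
})

test_that("io series amplitudes are non-decreasing in current", {
  prof <- no_reentry_profile()
  proto <- stimulus_protocol("io_series",
                             current_ua = seq(50, 600, by = 50),
                             n_repeats = 1)
  rec <- simulate_protocol(prof, proto, noise_sd = 0, artifact_amp = 0,
                           seed = 3)
  # oracle: clean component amplitudes straight from the ground truth
  truth_amp <- rec$truth$clean_amplitudes["CA1sr",
                                          rec$pulse_info$pulse_index == 1]
  expect_true(all(diff(abs(truth_amp)) >= -1e-12))
  ft <- extract_features(segment_sweeps(rec))
  curve <- build_io_curve(ft)
  sr <- curve[curve$layer == "CA1sr", ]
  expect_true(all(diff(abs(sr$amplitude_mv)) >= -1e-9))
})

test_that("PS flags follow the threshold rule on the clean DG amplitude", {
  prof <- no_reentry_profile(train_gain = seq(0.5, 2.4, length.out = 20))
  prof$ps_threshold <- 2.0
  rec <- simulate_protocol(prof, stimulus_protocol("train"), noise_sd = 0,
                           artifact_amp = 0, seed = 5)
  dg_amp <- rec$truth$clean_amplitudes["DG", ]
  expect_identical(rec$truth$ps_flags, dg_amp > 2.0)
  expect_true(any(rec$truth$ps_flags) && !all(rec$truth$ps_flags))
})

test_that("invalid simulator inputs are rejected", {
  prof <- control_profile()
  expect_error(simulate_protocol(prof, stimulus_protocol("train"),
                                 noise_sd = -1, seed = 1), "negative")
  expect_error(simulate_protocol(prof, stimulus_protocol("train")), "seed")
  expect_error(stimulus_protocol("paired_pulse", ppi_ms = 60), "ppi_ms")
  expect_error(excitability_profile(ppi_gain = c(`25` = 1), train_gain = rep(1, 20)))
})

test_that("stim times are strictly increasing and within the recording", {
  rec <- noisy_pair_rec()
  expect_true(all(diff(rec$stim_times) > 0))
  expect_true(all(rec$stim_times >= 1 &
                    rec$stim_times <= ncol(rec$potentials)))
  # 20 pulses at 5 Hz span 3.8 s plus padding
  tr <- clean_train_rec()
  span_s <- diff(range(tr$stim_times)) / tr$sampling_rate
  expect_equal(span_s, 3.8, tolerance = 1e-6)
})
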