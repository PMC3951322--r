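# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a single closed-field component, peak exactly on the sample grid
single_component <- function(onset_ms = 4.5, tau_ms = 1.5,
                             center = 1700, amp = 1.7e-4)
  csd_component("solo", center, 110, onset_ms, tau_ms, "sink", amp,
                return_offset_um = 0, return_spatial_sd_um = 200)

single_catalogue <- function(...) {
  cc <- single_component(...)
  list(ca1slm = cc,
       dg_gc = csd_component("dg_gc", 2200, 90, 6, 1.8, "source", 0,
                             0, 190),
       ca1sr = csd_component("ca1sr", 1400, 100, 6.3, 1.7, "sink", 0,
                             0, 190))
}

# paired-pulse recording at 50 ms, default noise (shared by io/feature tests)
noisy_pair_rec <- function()
  fixture("noisy_pair_rec",
          simulate_protocol(control_profile(),
                            stimulus_protocol("paired_pulse", ppi_ms = 50),
                            seed = 42))

clean_pair_rec <- function()
  fixture("clean_pair_rec",
          simulate_protocol(control_profile(),
                            stimulus_protocol("paired_pulse", ppi_ms = 50),
                            noise_sd = 0, artifact_amp = 0, seed = 42))

clean_train_rec <- function(profile = ad_profile())
  fixture(paste0("clean_train_", profile$label),
          simulate_protocol(profile, stimulus_protocol("train"),
                            noise_sd = 0, artifact_amp = 0, seed = 42))

no_reentry_profile <- function(train_gain = 1 + 0.3 * (0:19) / 19)
  excitability_profile(
    ppi_gain = c(`25` = 0.8, `50` = 0.85, `100` = 0.95, `200` = 1,
                 `500` = 1, `1000` = 1),
    train_gain = train_gain, label = "no-reentry")
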