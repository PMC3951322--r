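# Example pipeline configuration (see read_pipeline_config()).
geometry:
  n_contacts: 16
  spacing_um: 100
  depth_of_first_contact_um: 1100
ppi_ms: [25, 50, 100, 200, 500, 1000]
run_train: true
noise_sd: 0.1
artifact_amp: 2
seed: 1
profiles:
  control:
    ppi_gain: {25: 0.80, 50: 0.85, 100: 0.95, 200: 1.0, 500: 1.0, 1000: 1.0}
    train_gain: [1, 1.016, 1.032, 1.047, 1.063, 1.079, 1.095, 1.111, 1.126,
                 1.142, 1.158, 1.174, 1.189, 1.205, 1.221, 1.237, 1.253,
                 1.268, 1.284, 1.3]
    reentry_first_pulse: 20
    reentry_latency_ms: 17.5
    reentry_layer: CA1sr
    label: control-like
  ad:
    ppi_gain: {25: 1.35, 50: 1.25, 100: 1.10, 200: 1.0, 500: 1.0, 1000: 1.0}
    train_gain: [1, 1.008, 1.016, 1.024, 1.032, 1.039, 1.047, 1.055, 1.063,
                 1.071, 1.079, 1.087, 1.095, 1.103, 1.111, 1.118, 1.126,
                 1.134, 1.142, 1.15]
    reentry_first_pulse: 10
    reentry_latency_ms: 15.7
    reentry_layer: CA1sr
    label: ad-like
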