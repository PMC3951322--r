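# laminarephys

Analysis of stimulus-evoked laminar field potentials recorded along the
hippocampal CA1–dentate gyrus axis with linear multi-electrode arrays,
plus a forward simulator that generates such recordings with exactly
known ground truth.

The package is written for in-vivo electrophysiologists who record
perforant-path-evoked responses on 16×100 µm or 32×50 µm probes at
10 kHz and need the standard quantitative chain:

* **fEPSP measurement** by the five-point template: amplitude =
  extremum between points 4–5 minus the mean between points 2–3;
  latency = centre timestamp of points 4–5 minus the timestamp of
  point 1 (the sample before the stimulus artifact).
* **Population-spike (PS) detection** in the granule-cell layer and PS
  probability out of the 20 sweeps of each paired-pulse interval.
* **Input/output curves** over 50–600 µA and the half-maximal
  stimulation current (50% of the maximal CA1sr fEPSP).
* **Short-term plasticity**: paired-pulse percent change
  (100·(P2−P1)/P1) at intervals of 25, 50, 100, 200, 500 and 1000 ms,
  and per-pulse raw/percent-change profiles across 20-pulse 5 Hz trains.
* **Re-entrance detection**: long-latency (12–25 ms) responses that
  emerge mid-train when evoked activity reverberates through the
  entorhinal loop, called when sustained through the end of the train.
* **1-D current source density (CSD)**:
  `CSD(z,t) = −σ·[φ(z+Δ) − 2φ(z) + φ(z−Δ)]/Δ²` across neighbouring
  contacts (smoothing degree 2), 20-step linear depth interpolation, and
  self-normalized rendering (sources warm, neutral green, sinks cool).

The simulator solves the same 1-D Poisson physics in the forward
direction (`∂²φ/∂z² = −C/σ`, homogeneous σ, zero potential 500 µm beyond
the probe): Gaussian-in-depth, alpha-in-time sink/source components with
exact discrete current conservation, programmable paired-pulse and train
gain profiles, additive PS transients, re-entrant components, a
saturating current→gain curve, band-limited noise and stimulus
artifacts. Because the ground truth (per-pulse gains, clean amplitudes,
PS and re-entrance flags) is attached to every recording, every analysis
stage is verifiable end to end.

## A worked example

```r
library(laminarephys)

cfg <- pipeline_config(ppi_ms = c(25, 50), seed = 3)
res <- run_pipeline(cfg, out_dir = "laminar_out", quiet = TRUE)

subset(res$results$control$ppf, measure == "amplitude" & layer == "DG")
#>    layer   measure ppi_ms pct_change      sem  n
#> 9     DG amplitude     25  -17.92640 1.718358 20
#> 11    DG amplitude     50  -16.04163 1.960598 20

subset(res$results$ad$ppf, measure == "amplitude" & layer == "DG")
#>    layer   measure ppi_ms pct_change      sem  n
#> 9     DG amplitude     25   33.11959 1.492955 20
#> 11    DG amplitude     50   25.57386 2.159125 20

res$results$ad$reentrance
#>    layer first_pulse latency_ms amplitude_mv
#> 1  CA1sr          10       16.1   -0.8385325
#> 2 CA1slm          NA         NA           NA
#> 3     DG          NA         NA           NA
```

The dentate response *depresses* at short intervals under the
control-like excitability profile (−17.9% at 25 ms; programmed gain
0.80) and *facilitates* under the AD-like profile (+33.1%; programmed
gain 1.35) — the sign contrast the pipeline is designed to resolve — and
the AD-like train shows re-entrance into CA1sr from pulse 10 at 16.1 ms
latency (programmed: pulse 10, 15.7 ms), against pulse 20 at 17.8 ms for
the control-like profile. `run_pipeline()` also writes
tidy feature CSVs, PS-probability tables, the train-average CSD map
(PNG), a Markdown report contrasting the profiles, and a JSON manifest
with seeds and a config hash. A thin command-line wrapper is installed
at `inst/scripts/laminar-ephys` (`run-all`, `simulate`).

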