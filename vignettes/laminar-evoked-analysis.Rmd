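---
title: "Analysing evoked laminar field potentials along the CA1-DG axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing evoked laminar field potentials along the CA1-DG axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarephys)
```

## The problem

A linear multi-electrode array lowered through dorsal hippocampus records
evoked local field potentials simultaneously in CA1 stratum radiatum
(CA1sr), stratum lacunosum-moleculare (CA1slm) and the dentate gyrus (DG)
while the perforant-path input is stimulated electrically. Three questions
recur in such experiments:

1. **How large and how fast is the synaptic response in each layer?**
   (fEPSP amplitude and latency to peak/trough, input/output curves,
   half-maximal stimulation current.)
2. **How does the response change with repeated activation?**
   (Paired-pulse facilitation or depression across intervals of
   25-1000 ms; per-pulse gain across a 20-pulse 5 Hz train; granule-cell
   population-spike probability; long-latency "re-entrant" responses that
   appear mid-train when activity reverberates through the
   entorhinal loop.)
3. **Where do the underlying currents flow?** (1-D current source density
   along the probe.)

`laminarephys` implements this full analysis chain, together with a
forward simulator of laminar recordings whose ground truth is known
exactly, so that every stage — template measurement, PS detection, CSD
estimation, plasticity indices, re-entrance calls — can be verified
quantitatively without animal data.

## The forward model

The simulator and the CSD estimator share one physical model: currents
flow parallel to the probe axis through a homogeneous conductor, so the
extracellular potential obeys the 1-D Poisson relation

$$ \frac{\partial^2 \phi}{\partial z^2} = -\frac{C(z, t)}{\sigma}, $$

with $C$ the current source density (sinks negative) and $\sigma$ the
conductivity (1 by convention; the output is in arbitrary units). The
solver discretises this on a grid at least 4x finer than the contact
spacing, extended 500 µm beyond the probe ends where the potential is
pinned to zero (far-field assumption). Because the second difference of a
linear ramp vanishes, the choice of boundary condition cannot bias the
CSD estimate.

Each evoked component is a Gaussian profile in depth with an
alpha-function time course
$a(t) = \frac{t - t_0}{\tau} \exp\!\big(1 - \frac{t - t_0}{\tau}\big)$,
peaking at $t_0 + \tau$. Every component carries a balancing
opposite-polarity return whose discrete integral is matched exactly, so
current is conserved on the grid to machine precision.

The default catalogue uses **concentric returns** (same centre, wider
spatial SD): the component is then a sink flanked above and below by its
return current. This closed-field arrangement has zero dipole moment, so
each component's potential stays local to its layer. In a strict 1-D
conductor a separated sink/source pair generates a potential that extends
unattenuated across the whole probe (there is no 3-D $1/r$ decay to
suppress it), which would contaminate every other layer's trace with the
wrong polarity; closed fields are both the physically sensible and the
practically usable choice, and separated pairs remain available via
`return_offset_um` for users who want them.

Default components (peak latencies chosen within the ranges typical for
urethane-anaesthetised mouse at half-maximal subicular stimulation, and
placed on the 0.1 ms sample grid): CA1slm sink peaking at 6.0 ms, DG
granule-cell source at 7.8 ms (its return sinks lie in the molecular
layers of both blades), CA1sr sink at 8.0 ms. Peak densities are
calibrated to evoke 1.3-1.7 mV fEPSPs at the measurement contacts. The
probe defaults to 16 contacts at 100 µm (32 at 50 µm is the other stock
geometry), sampled at 10 kHz.

## What the simulator emulates — and what it does not

`simulate_protocol()` produces a continuous multi-channel recording for
one protocol: single-pulse input/output series (pairs at 50 ms over
50-600 µA, first pulse analysed), paired pulses at one of
{25, 50, 100, 200, 500, 1000} ms repeated 20 times 3 s apart, or a single
20-pulse train at 5 Hz. Per pulse, all component amplitudes are scaled by

* a saturating (Hill, $n = 2$, half-saturation 200 µA) current-to-gain
  map — the calibration between stimulus current and fEPSP size in real
  tissue is not derivable from first principles, so this curve is a
  modelling choice, normalized to gain 1 at the typical half-maximal
  current;
* the profile's `ppi_gain` (pulse 2 of a pair) or `train_gain`
  (per train pulse).

Population spikes are additive fast biphasic transients
(derivative-of-Gaussian, ~1 ms at half height, 1.5 mV) at the
granule-layer contact, inserted either when the scaled DG amplitude
exceeds `ps_threshold` or — for probability-recovery studies — as
per-sweep Bernoulli draws (`ps_prob`). Re-entrant activity is the layer's
own component re-inserted with its peak at `reentry_latency_ms`
(re-entrance latencies are peak latencies, matching the amplitude/latency
measurement convention) from `reentry_first_pulse` onward. Noise is white
Gaussian high-passed at 0.1 Hz (the acquisition band's 6 kHz analogue
edge lies above the 5 kHz Nyquist frequency); the default SD of 0.1 mV
gives a realistic single-sweep SNR against 1.3-1.7 mV responses. A ±2 mV,
0.2 ms biphasic artifact marks each stimulus.

The generator does **not** emulate: spiking neurons or conductance-based
synapses (the PS is a waveform, not an emergent event), 3-D volume
conduction, latency shifts with plasticity (component timing is fixed
across pulses, so latency percent-change has ground truth 0), electrode
drift, or line noise. Passing tests therefore demonstrate that the
analysis recovers what the model encodes — measurement correctness,
estimator consistency, detector calibration — not that it is robust to
every artefact of real tissue.

Two stock excitability profiles encode the phenotypes the pipeline is
meant to distinguish: `control_profile()` (paired-pulse depression at
25/50 ms: gains 0.80/0.85; recovery by 200 ms; train facilitation to
1.3x; re-entrance only at pulse 20, peak latency 17.5 ms) and
`ad_profile()` (facilitation 1.35/1.25 at 25/50 ms; weaker train
facilitation to 1.15x; earlier re-entrance from pulse 10 at 15.7 ms,
as in hyper-excitable amyloid/tau transgenic phenotypes).

## Measurement conventions

**Five-point template.** Point 1 is the last sample before the stimulus
artifact; points 2/3 surround the response onset; points 4/5 bracket the
response peak (DG, positive-going) or trough (CA1sr/CA1slm,
negative-going). Amplitude is the extremum between points 4-5 minus the
mean between points 2-3 (sign retained); latency is the centre timestamp
of points 4-5 minus the timestamp of point 1. Latency to onset is
deliberately not measured. Automatic placement substitutes for manual
cursors: the onset is the first departure from the pre-stimulus baseline
exceeding max(3 baseline SDs, 0.02 mV, 5% of the extremum). The
5%-of-extremum term makes placement invariant to amplitude scaling, and
points 2/3 are the two samples just *before* that departure, so on a
clean response the baseline they define is the local pre-response level
and the measured amplitude equals the underlying potential. Ties in the
extremum search (2-30 ms window) break to the earliest sample. A trace
with no supra-threshold deflection returns a "no response" outcome; if
the opposite-polarity extremum is larger than the requested one the
template is flagged low-confidence. Manual templates
(`five_point_template()`) are accepted everywhere.

For paired protocols one template is placed per condition on the P1 mean
and reused for P2 (one template per mean response; this keeps P2/P1
amplitude ratios strictly consistent, at the cost that pair latency
changes are not separately measurable — the simulator programs none).
Train analysis re-places the template on every pulse, since waveforms
change rapidly along the train.

**Population spikes.** The PS is separated from the smooth fEPSP by a
Savitzky-Golay residual (cubic, 15-sample window — the best
transient-to-smooth separation among the windows we examined). A PS is
called when the residual exceeds max(6 x MAD of the pre-stimulus
residual, 0.25 mV) with width at half height < 3 ms. The absolute floor
sits above the residual a smooth millivolt-scale fEPSP leaves (~0.16 mV)
and far below a PS residual (>0.8 mV); it exists because on noise-free
sweeps the MAD is exactly zero. PS probability is reported out of the
sweeps of one interval (n/20).

**Re-entrance.** For each train pulse the scaled pulse-1 trace
(least-squares over 1.5-11 ms) is subtracted; the residual is smoothed by
a zero-phase Gaussian at the component timescale and tested one-sided (in
the layer's polarity) in the 12-25 ms window — a window bracketing
reported in-vivo re-entrance latencies — against 3 x the pooled
pre-stimulus SD of the raw traces (floor 0.02 mV). Referencing the
threshold to the *raw* baseline SD while testing the *smoothed* residual
is what keeps the false-positive rate of this visual-inspection
surrogate at or below 1%: smoothing suppresses noise about six-fold, so
three raw SDs correspond to roughly eighteen smoothed ones. A call
requires the deflection on every later pulse up to pulse 20 ("sustained
once it appears"), which protects against single-pulse noise blips while
still admitting a pulse-20-only call.

**Plasticity indices.** Everything is a percent change,
$100 (x - x_{\mathrm{ref}})/x_{\mathrm{ref}}$, with P1 (pairs) or pulse 1
(trains) as reference; the reference entry is exactly 0%. Paired-pulse
changes are computed per repeat and averaged with their SEM. The
input/output curve uses first-pulse amplitudes only; the half-maximal
current is the smallest current reaching 50% of the reference layer's
(CA1sr) maximum, linearly interpolated between tested currents (or the
nearest tested current with `interpolate = FALSE`).

**CSD.** The estimator is the plain neighbouring-contact second
difference, $-\sigma\,[\phi(z{+}\Delta) - 2\phi(z) +
\phi(z{-}\Delta)]/\Delta^2$ — smoothing degree 2 — with edge contacts
dropped (no extrapolated density; a replicate-edge mode exists for
plotting parity only). Degrees above 2 activate a Hamming-weighted
spatial pre-smoother. Depth rendering inserts 20 linear interpolation
steps between contacts and normalizes each map to its own min/max on
[-1, 1]: sources warm, neutral green, sinks cool. Zero is neutral only
when the map is symmetric; self-normalization makes rendering invariant
to uniform scaling. No temporal filtering is applied before CSD.

## Numerical choices and degenerate inputs

* Forward grid: spacing/8, margin 500 µm, contacts on grid nodes
  (sampling at contacts is exact; the Dirichlet matrix is factored once).
* Discrete current conservation is enforced exactly by rescaling each
  return profile to the integral of its main profile.
* Zero-noise paths avoid thresholds that collapse to zero via small
  absolute floors (0.02 mV for template onset and re-entrance, 0.25 mV
  for PS).
* Extremum ties break earliest; constant traces return 0 mV amplitude;
  flat traces return "no response" rather than an error; a zero
  percent-change reference is flagged `NA` with a warning.
* At the 25 ms interval the P1 alpha tail overlaps the P2 window at the
  ~1e-4 relative level, so "exact" zero-noise recovery is exact to about
  0.003 percentage points; tests assert at that resolution.

## Verification scale

The test suite verifies estimator algebra exactly (naive-loop
equivalence, linear/quadratic profiles), forward/inverse consistency on
both stock geometries (< 5% relative RMS, r > 0.99 for components at
least twice the contact spacing), exact zero-noise recovery of all
programmed gain profiles, and Monte-Carlo recovery at the default noise
level. The Monte-Carlo designs are: 100 seeded replicates of the
control-vs-AD paired-pulse contrast, split evenly between the 25 and
50 ms intervals (each replicate simulates one full 20-pair session per
profile); 200 sessions of 20 sweeps for PS-probability recovery at
programmed 0.6, plus 1000 noise-only sweeps for the false-positive rate;
re-entrance onset recovery at programmed pulses {7, 10, 15, 20} and 200
no-re-entrance trains for its false-positive rate. `scripts/acceptance.R`
re-runs the same studies at half scale (50 replicates/sessions, 100
no-re-entrance trains) — sizes chosen so the whole script completes in a
few minutes on one core while keeping Monte-Carlo standard errors well
inside the decision margins.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(ppi_ms = c(25, 50, 100), seed = 1)
res <- run_pipeline(cfg, out_dir = "laminar_out")
res$results$ad$ppf          # paired-pulse percent change per layer
res$results$ad$reentrance   # re-entrance calls for the train
plot(res$results$control$csd)
```

The report (`report.md`) contrasts the two profiles: DG percent change
negative (depression) for the control-like profile and positive
(facilitation) for the AD-like one at 25/50 ms, and an earlier
re-entrance onset pulse in the AD-like profile.

## Known limitations

* The 1-D model cannot represent currents oblique to the probe; CSD
  output is in arbitrary units and comparable only within a recording.
* PS detection and re-entrance calling are operationalizations of what
  experimenters judge by eye; their thresholds are calibrated on this
  generator's waveforms and should be re-examined before use on real
  recordings with different noise spectra.
* Group-level inferential statistics (mixed ANOVA, post-hoc contrasts)
  are intentionally out of scope; the exported tidy CSVs feed directly
  into any stats package.
* Percent-change measures are undefined when the reference response is
  absent; such sweeps surface as `NA` with a low-confidence flag rather
  than being imputed.
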