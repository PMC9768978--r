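# meaburst

Analysis of in vitro neural network activity recorded on microelectrode
arrays (MEA), for electrophysiologists and screening scientists who work
with cultured neurons — 2D cultures, neural spheroids, or scaffold-grown
networks — on conventional 16-electrode probes or high-density CMOS
arrays.

The package implements, end to end and with a seeded synthetic-recording
generator for validation:

* **Spike detection** on zero-phase high-pass filtered traces: a spike is
  counted when the signal exceeds ±5σ, where σ is the baseline-noise SD
  estimated robustly (MAD/0.6745) per electrode.
* **Network-burst (NB) detection** by the 4-step method on the pooled
  spike train: (1) spikes with interspike intervals ≤ 5–15 ms join a
  candidate; (2) candidates under 50–100 spikes are eliminated;
  (3) candidates closer than 100–200 ms are combined; (4) an NB must
  contain more than 500–1,500 spikes. Defaults: 10 ms / 50 / 100 ms / 500.
* **The ten-parameter burst panel**: total spikes, NB count, mean and CV
  of NB duration, spikes per NB, maximum frequency (spikes per 50 ms bin
  at the burst peak), and intermaximum frequency interval (IMFI).
* **Complex-Morlet wavelet scalograms** of the raw low-frequency signal,
  `W(b,a) = (1/√a) ∫ f(t) G((t−b)/a) dt` with
  `G(x) = (πF_B)^(-1/2) exp(−x²/F_B) exp(2iπF_C x)`, F_B = 5, F_C = 1,
  181 frequency pixels spanning 0.1–250 Hz (f = 1/a), 50 µs time pixels;
  band quantification by the per-pixel coefficient
  `WT_A = WT_S / (N_X · N_Y)` and its percent change against baseline.
* **Propagation and conduction velocity**: per-burst onset delays between
  electrode pairs (spheroid preparations); network propagation velocity
  and axonal conduction velocity from ordinary least squares of
  inter-electrode distance on spike-time latency, with soma localisation
  from spike-amplitude maps, 4 ms spike-triggered averages (−1.5/+2.5 ms),
  and automated axon-path extraction on CMOS grids.
* **Dose–response statistics**: one-way ANOVA with Dunnett's many-to-one
  comparisons per parameter (the significance heat map), PCA on the
  5-parameter set, pairwise MANOVA (Wilks' Λ) on the first two component
  scores, and two-tailed paired t-tests.

Everything is tidyverse-shaped: spike events, burst tables, metric panels
and dose–response tables are plain tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a 16-electrode well with 20 planted network bursts (600 pooled
spikes each, spike amplitude 8× the noise SD), then run the full
detection chain:

```r
library(meaburst)

sim    <- simulate_preset("burst16", seed = 42)   # recording + ground truth
rec    <- highpass(sim$rec, cutoff_hz = 100)      # spike band
spikes <- detect_spikes(rec, k = 5)               # ±5σ threshold
nbs    <- detect_network_bursts(spikes, burst_params())
nbs
#> # A tibble: 20 × 6
#>   nb_id t_start t_end n_spikes t_peak peak_rate
#>   <int>   <dbl> <dbl>    <int>  <dbl>     <int>
#> 1     1   1.000  1.40      562   1.17        84
#> 2     2   3.00   3.40      571   3.17        95
#> 3     3   5.00   5.40      564   5.22        90
#> # i 17 more rows
```

All 20 planted bursts are recovered (boundaries match the ground truth to
well under a millisecond); each holds ~560 of its 600 planted spikes —
the shortfall is the detector's 1 ms dead time at burst-peak rates. The
ten-parameter panel summarises the well:

```r
compute_metrics(spikes, nbs, rec_duration(rec))
#> total_spikes 11301, n_nb 20, mean_nb_duration_s 0.3996,
#> mean_spikes_per_nb 562.85, mean_max_frequency 89.45, mean_imfi_s 2.0,
#> cv_nb_duration 0.0011, cv_spikes_per_nb 0.012, cv_max_frequency 0.0625,
#> cv_imfi 0.0204
```

A regular 2 s burst schedule gives an IMFI of exactly 2 s with tiny CVs,
as it should. For propagation, the `spheroid_pair` preset plants a
0.375 s mean onset delay between two spheroid electrodes 1398.75 µm
apart; `nb_onset_delays()` recovers the per-burst delays and
`pair_velocity(1398.75, 0.375)` gives 3.73 mm/s. See the methods
vignette (`vignettes/meaburst-methods.Rmd`) for the models, parameter
choices and limitations.

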