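---
title: "Methods: burst detection, wavelet quantification, and velocity estimation in meaburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, wavelet quantification, and velocity estimation in meaburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

This vignette is the package's account of the science behind each stage:
what is computed, under which assumptions, which parameters matter, and
where the design was genuinely open and a choice had to be made. The
companion generator (`gen_spiketrains()`, `render_traces()`,
`gen_axon_dataset()`, `gen_param_samples()`) produces the seeded
synthetic recordings on which every stage is validated; its scope and
blind spots are discussed at the end.

## Signal model and spike detection

An MEA recording is an `n_channels × n_samples` matrix of extracellular
voltages in µV at a sampling rate of 20 kHz per channel (the acquisition
rate of the Presto- and CMOS-class systems this package targets), with
an electrode layout in µm. Two high-pass corners are used: 1 Hz for
field-potential work and 100 Hz to isolate the spike band before
detection. The filter is an order-4 Butterworth applied
forward–backward (`signal::filtfilt`), i.e. zero phase, so spike times
are not skewed by filter delay; the channel mean is removed first so the
edge transient is independent of any DC offset. The realisation (order,
zero-phase) is a package choice — only the corner frequencies are fixed
by the measurement convention.

A spike is counted when the filtered signal exceeds **±5σ**, with σ the
standard deviation of the baseline noise. "Baseline during quiescent
periods" is not an operational definition, so the default estimator is
the median absolute deviation divided by 0.6745, which equals the
quiescent SD for Gaussian noise and is insensitive to sparse spikes; an
iterative-exclusion estimator (drop |v| > 4σ, re-estimate, two passes)
is provided for comparison. σ is estimated **per electrode** — noise
levels differ across electrodes, and a global σ would mis-threshold the
quietest channels.

Detection places one event per threshold crossing: the event time is the
extremum of |v| within the **alignment window** (±0.5 ms) after the
crossing, the amplitude is the signed extremum, and further crossings
within the **dead time** (1 ms) are ignored. Both windows are package
choices (configurable); 1 ms matches the refractory scale of a single
unit and guarantees at most one event per biphasic deflection. The
detector is validated against a naive sample-by-sample crossing scan
(exact agreement on the same realisation) and is monotone in the
threshold multiplier.

Degenerate inputs: a silent channel (σ = 0, all zeros) yields no events;
σ = 0 with a non-zero trace is an error rather than an infinite-rate
detector.

## The 4-step network-burst detector

Network bursts (NBs) are detected on the spike train **pooled across all
electrodes of a well** — the standard reading of "network" burst;
the NB list is therefore invariant to electrode relabelling. The four
steps, with the accepted parameter ranges and the package defaults:

| step | rule | range | default |
|---|---|---|---|
| 1 | join spikes with inter-spike interval ≤ `isi_join_s` | 5–15 ms | 10 ms |
| 2 | eliminate candidates with fewer than `min_candidate_spikes` | 50–100 | 50 |
| 3 | combine candidates separated by less than `merge_gap_s` | 100–200 ms | 100 ms |
| 4 | keep bursts with **more than** `min_final_spikes` | 500–1500 | 500 |

Spikes falling between candidates merged in step 3 are included in the
burst; step 4 is strict (`>`), following the "more than" phrasing of the
method. Burst boundaries are the first and last member spike. The
implementation is verified exactly against an independent brute-force
nested scan over hundreds of random spike sets, and is monotone in its
thresholds (raising `min_final_spikes` never increases the count).

Step 2's wording ("datasets … were eliminated") is ambiguous between a
per-candidate filter and a well-level exclusion; it is implemented as a
per-candidate filter, the reading under which steps 3–4 remain
meaningful.

**The ten-parameter panel** (`compute_metrics()`): total spikes (the
whole recording, not only bursts), NB count, and mean plus CV of four
per-burst quantities — duration, spikes per NB, maximum frequency, and
IMFI. The *maximum frequency* of a burst is the count in the maximal
50 ms bin of its pooled spikes (ties go to the earliest bin; the bin
grid starts at the burst's first spike). The *intermaximum frequency
interval* (IMFI) is defined here as the interval between the peak-rate
times of consecutive bursts — the reading that matches the name, since
no formal definition is printed. CVs use the sample SD (n−1
denominator). Whether "maximum frequency" should be a per-50 ms count or
a Hz rate is ambiguous; the panel reports counts per bin (the printed
display convention), and a Hz conversion is a multiplication by 20 left
to the caller. Fields requiring at least two bursts (three for the IMFI
CV) are `NaN` below that count, and propagate as missing cells into the
statistics layer.

One boundary convention differs deliberately from a literal reading:
spikes are counted in `[t_start, t_end]` inclusive when locating the
peak bin, because `t_end` *is* the burst's last spike and a half-open
window would silently drop it.

## Morlet scalograms and the band statistic

The continuous wavelet transform of the **raw** trace (the low-frequency
content is the object of interest, so no high-pass is applied) is

$$W(b,a) = \frac{1}{\sqrt{a}} \int f(t)\, G\!\left(\frac{t-b}{a}\right) dt,
\qquad
G(x) = \frac{1}{\sqrt{\pi F_B}}\, e^{-x^2/F_B}\, e^{2i\pi F_C x},$$

with bandwidth $F_B = 5$ and centre frequency $F_C = 1$, so scale maps
to frequency exactly as $f = 1/a$. The frequency axis has **181 pixels
spanning 0.1–250 Hz**; the spacing is logarithmic
($f_k = 0.1 \cdot 2500^{k/180}$), the scalogram convention that resolves
a 3.4-decade band sensibly — the endpoints and pixel count are fixed,
the spacing is a package choice. The time axis is pixelised at **50 µs
per pixel** (one sample per pixel at 20 kHz; at other rates each pixel
averages an integer number of samples, and non-integer ratios are
rejected rather than silently resampled).

Numerically, the wavelet is sampled at the trace's sampling interval,
truncated at $|x| \ge 4\sqrt{F_B}$ (envelope below $e^{-16}$), and the
convolution is evaluated per scale by FFT with zero padding and dt
weighting. Each row carries a cone-of-influence mask (half the truncated
support at each end); rows whose support exceeds the trace are flagged
edge-dominated. The FFT path is validated against direct trapezoidal
integration of the integral at interior points, and pure tones localise
to within one frequency pixel.

The band statistic is the per-pixel coefficient

$$WT_A = \frac{WT_S}{N_X \times N_Y},$$

where $WT_S$ sums $|W|$ over the band's frequency rows and all time
pixels. Two open points were resolved as follows. (1) *Magnitude vs
power*: the transform's amplitude is stated to be its absolute value, so
$WT_A$ uses $|W|$, not $|W|^2$ — callers wanting power can square the
scalogram first. (2) *Edge handling*: by default, pixels inside the cone
of influence are excluded from both $WT_S$ and the pixel count, so edge
transients do not inflate the statistic; with `edge_exclude = FALSE` the
formula above holds verbatim. Drug- or stimulation-induced changes are
expressed as the signed percent change of $WT_A$ against baseline over
the 0.1–250 Hz band (the "low-frequency component"), with the post/pre
ratio also reported; a zero baseline is an error, not an infinity.

$WT_A$ is linear in signal amplitude, shift-invariant for interior
content, and stable under duration doubling for stationary signals —
all tested properties.

## Propagation and conduction velocity

**Pairwise (two-spheroid) case.** For each NB, the onset delay is the
difference between the first spikes of the target and reference
electrodes inside the pooled burst window; bursts where either electrode
is silent are excluded and counted. One refinement: the per-electrode
onset is the electrode's first *sustained* spike — one followed by
another spike from the same electrode within 50 ms — falling back to the
first spike when no spike has a companion. An isolated background spike
early in a long burst window is not the "beginning point of the NB
detected at that electrode", and without this rule sparse background
activity biases the delay estimate substantially. The velocity is
distance/mean-delay, reported in mm/s — the natural scale for
polysynaptic propagation (a 1398.75 µm separation crossed in 0.375 s is
3.73 mm/s).

**Distance-versus-latency fits.** Both the network velocity (identified
neurons on a CMOS grid; per burst, each neuron contributes its distance
from that burst's earliest-firing neuron against its first-spike delay,
fitted jointly across bursts) and the axonal conduction velocity use
ordinary least squares of **distance (response) on latency (predictor)**
— the orientation named by the phrase "distance versus the spike-time
latency" — with the slope as velocity and a free intercept absorbing
alignment offsets. R² is reported for that orientation; two-point fits
are exact and flagged. Note one consequence of this orientation: noise
in the latencies (the predictor) attenuates the slope slightly, so
jittered network-velocity estimates sit a few percent below the planted
value — visible in the acceptance output and inherent to the convention,
not a bug. The fit is verified against the closed-form normal-equations
solution and is invariant to time origin and unit conversion.

**CMOS single-neuron chain.** Somata are local maxima of the per-electrode
spike-amplitude map (median absolute spike amplitude), greedily accepted
in decreasing amplitude order subject to a minimum separation; ties
break toward the larger amplitude, then the lower electrode id. The
4 ms spike-triggered average (1.5 ms before to 2.5 ms after each
firing, edge-clipped triggers dropped and counted) gives per-electrode
mean waveforms whose residual noise shrinks as σ/√N — a tested law. The
manual "similar waveform" electrode picking is automated by a
deterministic rule: an electrode joins the axon path if its STA trough
is at least `amp_min` and its maximum normalised cross-correlation with
the soma STA (over lags) is at least `rho_min` (default 0.7); the path
is ordered by trough latency and its cumulative Euclidean length is the
distance axis. Trough latencies are refined by 3-point parabolic
interpolation around the sampled minimum: at 0.57 m/s and tens of µm
electrode pitch, per-electrode latency steps are ~2 samples at 20 kHz,
and without sub-sample refinement the quantisation alone would exceed
the few-percent recovery the noiseless case achieves.

## The statistics layer

The dose–response table has one row per well per condition per
concentration and the ten panel metrics as columns; `NaN`-flagged
metrics become missing cells, dropped pairwise with counts. Per
parameter, a one-way ANOVA across conditions is followed by **Dunnett's
many-to-one comparisons** against the vehicle; the adjustment uses the
multivariate-t machinery of `multcomp`/`mvtnorm`, whose randomised
quantile integration is run under a fixed internal seed (caller RNG
untouched) so p-values are reproducible. Significance tiers are p < 0.05
and p < 0.01, and the stacked parameter × condition table is the heat
map. No correction is applied *across* the ten parameters, matching the
display convention being reproduced. Family-wise error under a null is a
tested calibration (α = 0.05 within Monte-Carlo bounds).

The **PCA** uses the 5-parameter set (total spikes, mean NB duration,
mean IMFI, CV of NB duration, CV of spikes per NB). Columns are z-scored
— the parameters have incommensurate units, and no scaling convention is
printed — and the correlation matrix is eigendecomposed; scores equal
the SVD of the z-scored matrix up to the fixed sign convention (largest
|loading| positive). Zero-variance columns are dropped with a warning.
**Pairwise MANOVA** on the first two score dimensions uses Wilks' Λ with
the F approximation (the statistic is unstated; Wilks is the default
convention), giving a symmetric p matrix; null p-values are
approximately uniform (tested). The **paired t-test** is two-tailed on
the differences; constant differences degenerate to p = 1 (zero mean) or
p = 0.

## What the generator emulates — and what it does not

Every generator is a pure function of its configuration and seed, with
the caller's RNG state preserved.

* `gen_spiketrains()` plants a burst schedule on a layout. Within a
  burst the pooled count is split evenly across electrodes; each
  electrode's window starts at the scheduled onset plus, with
  propagation, distance/velocity plus per-burst Gaussian jitter (the
  source ignites exactly on schedule). The first spike of each electrode
  is pinned to its window start (the ignition event); the rest follow an
  80% uniform floor + 20% truncated-Gaussian peak. The floor matters:
  burst boundaries are only well defined for an ISI-chain detector if
  the edge spike density stays well above 1/`isi_join`, and a purely
  Gaussian profile has tails that fragment under the detector's ~5–7%
  dead-time thinning, moving boundaries by tens of ms. With the floor
  (~1200 pooled spikes/s in the `burst16` preset, i.e. 75 Hz per
  electrode) recovery is exact and boundaries are sub-millisecond. The
  ground truth records both the raw planted spans and the *recoverable
  core* (the 4-step result on the true, noise-free spike times) — the
  latter is the right reference for closed-loop tests, because the
  profile's edges are partly unchainable by construction and no detector
  working from spikes could attach them.
* `render_traces()` turns events into raw voltage: i.i.d. Gaussian noise,
  a biphasic template (0.4 ms trough, 30% overshoot, 2 ms total,
  evaluated continuously so sub-sample event times are honoured), and
  optional gated sinusoids as field-potential components.
* Preset study conditions: `burst16` (4×4 grid, 450 µm pitch, 20 bursts
  × 600 spikes, noise σ = 4 µV, spike amplitude 8σ); `spheroid_pair`
  (two spheroid electrodes 1398.75 µm apart, 31 bursts, planted 0.375 s
  delay at 3.73 mm/s, onset jitter SD 166 ms, 300 spikes per electrode
  per burst — spheroid recordings are multiunit, and the source
  electrode's solo leading segment must itself be densely chainable or
  its onset is measured late); `cmos_axon` (16×16 grid, 35 µm pitch,
  14-electrode path at 0.57 m/s, sharp lateral decay so off-path
  electrodes are pure noise); `cmos_network` (7 neurons spanning
  ~2.4 mm, 4 bursts, 0.14 m/s, 1 ms onset jitter).
* `gen_param_samples()` draws the ten metrics as independent Gaussians
  around specified group means — adequate for calibrating the testing
  machinery, deliberately ignorant of the correlations real panels show.

What passing these tests does **not** show about real data: the noise is
white and Gaussian (no line hum, no electrode drift, no shared
artefacts), spike waveforms are identical within an electrode (no
amplitude variability, no overlapping units, no bursting adaptation),
field potentials are pure gated sinusoids, axons are straight electrode
rows, and drug effects are additive mean shifts. The synthetic results
demonstrate correctness of the algorithms under known ground truth, not
robustness to every artefact of a wet recording.

## Problem sizes and numerical conventions

Validation runs at desk scale, chosen so the full suite completes in
about two minutes: 16-channel, 41 s renders at 20 kHz for the burst
loop; 4 s, 2 kHz signals for wavelet properties (with the time pixel set
to one sample at that rate); 500-replicate nulls for the statistical
calibrations; 200 random spike sets for the burst-detector oracle.
Windows and bins are half-open `[t0, t1)` throughout (with the single
documented exception above); times are seconds, positions µm, voltages
µV everywhere; all tie-breaks (earliest bin, larger amplitude then lower
electrode id) are deterministic, and the whole pipeline is
byte-reproducible under a fixed seed.

## Known limitations

No spike sorting: threshold events are multiunit, and the "neuron"
positions on CMOS grids are amplitude-map peaks, not sorted units.
Burst-boundary agreement between a thinned (detected) and unthinned
(true) spike train is intrinsically discontinuous through the 4-step
count filters; the generator's floor rate keeps that margin wide, but
recordings whose bursts taper gradually will show boundary variability
near the candidate thresholds. The distance-on-latency fit orientation
attenuates velocities when latencies are noisy (documented above). The
Dunnett implementation assumes homoscedastic groups (pooled SE), as the
classical procedure does.
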