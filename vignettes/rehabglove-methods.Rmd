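---
title: "Models and methods behind rehabglove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rehabglove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabglove)
```

rehabglove implements the computation stack of a wearable rehabilitation
system for the post-stroke hemiparetic hand: a sensory glove with two
resistive flex sensors (middle finger and thumb, read as raw 12-bit ADC
counts through a voltage divider) and a six-axis IMU, sampled at a nominal
21 Hz, feeding a moving-window classifier that rates how correctly a
prescribed wrist/forearm exercise is being executed. On top of the device
logic sits the statistical machinery of a small two-arm feasibility trial
over three clinical scales: FMA-UE (motor impairment, 0--66), FIM
(functional independence, 18--126) and MORE (motivation, 17 items). This
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## Sensor streams and windowing

A stream is a strictly time-ordered table of 8 channels (2 flex + 3
accelerometer + 3 gyroscope). The classifier consumes fixed windows of
`round(window_seconds * sampling_rate)` samples -- exactly 42 at the 2-s /
21 Hz defaults. Windows are half-open `[start, start + 42)` in 0-based
sample indices and start at multiples of the hop, so a stream of `L`
samples yields `floor((L - 42) / hop) + 1` windows.

Open parameters, fixed as follows:

* **Hop = 21 samples** (1 s, 50% overlap). The device is only described as
  using a "moving" window; a 50% overlap is standard practice in human
  activity recognition and keeps per-exercise window counts usable at
  session length. Configurable everywhere the window length is.
* **ADC range 0--4095.** The microcontroller family's ADC is 12-bit; the
  flex channels are stored as raw counts because the physical sensors are
  used uncalibrated.
* **Jitter tolerance ±10%** of the nominal period: real embedded sampling
  is never exactly periodic, so spacing violations warn rather than abort.
* Column order of a window matrix is fixed (`flex_middle, flex_thumb, ax,
  ay, az, gx, gy, gz`); the CSV reader maps columns by name so file column
  order is irrelevant.

## The synthetic exercise-signal generator

No raw recordings are published, so the package generates them. Each of
the eight catalogue exercises is a deterministic multichannel template:
a class-specific fundamental (0.55--1.6 Hz, below the 10.5 Hz Nyquist
limit) plus a second harmonic with exercise-and-channel-specific phases,
superimposed on a motion component shared by all exercises, plus i.i.d.
Gaussian channel noise (relative SD 0.35 by default). Flex channels swing
±600 counts around mid-range 2048 and are integer-quantized; accelerometer
channels swing ±3 m/s² (gravity on `az`), gyroscope ±60 deg/s.

The one structural knob is `imu_signal_share`: the fraction of
class-discriminative signal energy carried by the six IMU channels
(default 0.75). The deployed device's ablation analysis found the IMU to
be the dominant feature set, and the generator encodes that asymmetry *by
construction* so the ablation harness has a known ground truth to recover.
"Incorrect execution" is undefined in any published source, so it is
modelled as a seeded corruption of the discriminative component: tempo
halving, amplitude damping (× 0.4), or phase scrambling.

What the generator deliberately does **not** emulate: biomechanically
realistic wrist kinematics, inter-patient variability, spasticity
severity, sensor drift, or cross-user distribution shift. Passing tests
on this data show the pipeline recovers structure it was built to contain;
they say nothing about accuracy on real patients (the deployed system is
known to degrade on users outside its training set).

## The window classifier

A small 1-D convolutional network: one convolution layer (default 8
filters, kernel 7 time steps) with ReLU, global average pooling over time,
and a logistic head, trained full-batch with Adam (default 200 epochs,
learning rate 0.02) on the binary cross-entropy. The target is binary --
correct vs incorrect execution -- because the application always knows
which exercise it asked for; multi-class operation over exercises is a
configuration extension, not the default. Windows are presented
time-major (42 time steps × channels). The convolution is unrolled into
an im2col matrix so both passes are dense matrix products; with fixed
seeds and single-threaded BLAS the whole fit is bit-reproducible, which is
the documented determinism contract.

Ablation retrains from scratch with a channel group removed (`no_IMU`
keeps the two flex channels, `no_flex` the six IMU channels) rather than
zeroing channels at test time, and the mask is applied identically at
train and predict time, so excluded channels cannot leak. On the default
synthetic data the mean held-out accuracies over five seeds order as
no_IMU < no_flex ≤ full; per-seed the no_flex/full gap can sit inside
Monte-Carlo noise, which is why the harness reports per-group accuracies
and deltas instead of a single verdict.

## Star scoring and sessions

Five stars are awarded at ≥ 80% of windows classified correct -- the
scheme's built-in margin of error (perfection is never required; the
classifier's own tolerance adds no extra slack term). Below that, the
published scheme defines nothing, so stars fall in equal-width 0.16 bins:
the unique monotone, exhaustive linear binning that reaches five stars
exactly at 0.80. Accuracy is computed over windows (not repetitions or
time), and no minimum-repetition floor is imposed -- neither is specified
anywhere.

Sessions draw 5 exercises uniformly **with replacement** from the
8-exercise catalogue (patients of the deployed system reported frequent
repetition of the same exercise, which is consistent with replacement;
without-replacement is a flag). Timing is fixed bookkeeping: 5 min per
exercise, 5-min breaks except after the last, hence 25 min active /
20 min rest / 45 min total for every plan.

## The cohort generator

Per-patient scores are simulated at three assessment points for each
(scale, group) cell. The only published ground truth is the summary table
of change scores (n, mean Δ, SD Δ per cell), so change scores use
**summary-calibrated sampling**: standard normal deviates are standardized
and rescaled to the cell's target moments, making every simulated cell
reproduce its printed mean and SD exactly. The cost is a mild negative
dependence among deviates relative to i.i.d. sampling; the benefit is that
a simulated trial is faithful to the only data that exists. FIM change
scores -- which deviated from normality in the trial -- are additionally
rounded to integers and right-censored at mean + 3 SD (a ceiling-effect
emulation chosen because the true shape is unpublished); this perturbs the
matched moments by well under the 1% recovery budget while breaking
normality.

Baselines are not published at all and are package choices: MORE 50
(SD 8) on an assumed 17--85 range (17 items, response scale unstated,
configurable), FIM 85 (SD 12) on 18--126, FMA-UE 25 (SD 7) on 0--66 --
levels typical of a subacute/chronic post-stroke inpatient cohort, placed
so range clipping stays rare. Changes are clamped to the scale span and
the baseline is drawn from a truncated normal confined so week 1 and
week 3 both respect the range without distorting the change; clamp counts
are logged on the result. Week 2 is generated (midpoint plus noise) but
unused by the headline analysis, which compares week 3 to week 1.

## Trial statistics

All tests are two-sided at α = 0.05 (configurable). From a summary triple
(n, m, s): paired t = m/(s/√n) on n − 1 df with paired d = m/s;
Student's t pools variances on n₁ + n₂ − 2 df; Welch's t uses the
Welch--Satterthwaite df. Cohen's d for any between-group comparison uses
the pooled SD -- including the Welch case, so each comparison reports one
d under one formula. The t statistic is signed by (week3 − week1);
published tables that print the opposite sign agree in magnitude.

Test selection follows the trial's rule: Welch's t if and only if the
variance-equality check rejects. On the raw path that check is Levene's
test -- **mean-centred** (classic Levene), since the centring was never
specified and the raw patient data needed to match its printed p-values is
unpublished; median-centring is a flag. On the summary path Levene is
impossible, so the gate is the two-sided F ratio test on the two SDs --
with the published summaries it selects Welch for FMA-UE and Student for
MORE and FIM, the same choices the trial reports. A boundary p exactly at
α is treated as *not* indicating unequal variances.

Non-parametric sensitivity checks (Wilcoxon signed-rank within groups,
Mann--Whitney between) use exact distributions up to n = 25 when there are
no ties, otherwise the normal approximation with tie correction, and the
mode used is recorded. Shapiro--Wilk covers normality on the raw path.
No multiple-testing correction is applied, matching the analysis being
reproduced. MCID/MDC annotation compares |mean change| with published
thresholds: FMA-UE MCID 9 points (lower bound of the cited ~9--10 range)
and MDC 5.2; FIM total MCID ≈ 22; MORE has no published MCID, so its
annotation reports the thresholds as unknown rather than inventing one.

## Numerical and testing choices

Problem sizes in the test suite are chosen for a laptop-class single-CPU
run: ablation uses 6 recordings per (exercise, correctness) class of 8 s
each (≈ 670 windows) over five seeds; type-I error calibration uses 2,000
replicates at n = 8 per group; cohort recovery uses n = 10⁴ per cell.
Expected p-values in unit tests were frozen from independent oracles --
numerical integration of the t density, and full enumeration of sign
patterns (2ⁿ) and group assignments (C(n₁+n₂, n₁)) for the rank tests --
not from the functions they check. Stream CSVs print doubles with 17
significant digits so write/read round-trips are bit-identical.

Known limitations: the conv-net is a deliberately small reference
architecture, not a tuned model; the signal family is sinusoidal, so
classifier accuracies on it say nothing quantitative about real
recordings; summary-calibrated cohorts cannot reproduce per-patient
trajectories or the trial's raw-data assumption-check p-values, which is
precisely why the raw-data path exists for datasets that do have
per-patient scores.
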