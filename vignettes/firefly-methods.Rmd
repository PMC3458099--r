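---
title: "The Firefly phase-alignment model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Firefly phase-alignment model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fireflyeeg)
```

## The model

Event-related EEG phenomena are conventionally split into *evoked* responses
(a stimulus-locked waveform added to the ongoing EEG, recovered by trial
averaging) and *induced* responses (non-phase-locked band-power changes,
ERD/ERS). The Firefly model collapses this distinction: it generates both
from a single mechanism — transient, frequency-dependent phase alignment of
the ongoing oscillations — with **no change in signal power at any time**.

Each simulated trial is a weighted sum of sinusoids on a dense frequency
grid,

$$V(t) = \sum_f a_f \cos\varphi_f(t),$$

where the amplitude weights $a_f$ describe the baseline spectrum and each
oscillation's phase $\varphi_f(t)$ follows a five-stage piecewise schedule:

1. **Baseline** ($t < t_\mathrm{start}$): the oscillation runs at its
   preferred frequency $f_0$ with a random offset $\Delta\varphi_f \sim
   U(-\pi, \pi]$ from the channel's *target oscillation*
   $\cos(2\pi f (t - t_\mathrm{start}) + \varphi_\mathrm{target})$.
2. **Synchronization** ($t_\mathrm{start} \le t < t_\mathrm{synch}$): a
   linear phase ramp accumulates $-\Delta\varphi'_f$, where
   $\Delta\varphi'_f = \Delta\varphi_f \bmod 2\pi \in [0, 2\pi)$, so the
   oscillation reaches the target phase exactly at $t_\mathrm{synch}$. The
   modulus mapping makes every ramp non-positive: alignment is always
   achieved by *slowing* (the instantaneous frequency during this stage is
   $f_0 - \Delta\varphi'_f / (2\pi(t_\mathrm{synch} - t_\mathrm{start}))$).
   The symmetric draw of $\Delta\varphi_f$ and slowing-only alignment cannot
   both hold without this mapping; we resolve the tension in favour of
   slowing, which is the mechanism the model is named for.
3. **Phase-locked** ($t_\mathrm{synch} \le t < t_\mathrm{desynch}$): the
   oscillation is identical to the target oscillation.
4. **Desynchronization** ($t_\mathrm{desynch} \le t < t_\mathrm{end}$): the
   ramp reverses (a rebound *above* $f_0$), restoring the baseline offset.
5. **Baseline again** ($t \ge t_\mathrm{end}$).

The stage boundaries scale with the square root of the period $T = 1/f$:

$$t_\mathrm{synch} = t_\mathrm{start} + k_\mathrm{synch}\sqrt{T}, \qquad
  t_\mathrm{desynch} = t_\mathrm{start} + k_\mathrm{desynch}\sqrt{T} + c_\mathrm{desynch},$$

so high frequencies align early and briefly, low frequencies late and long.
Because the target phase is anchored for *all* frequencies at
$t_\mathrm{start}$ while each frequency reaches it at its own
$t_\mathrm{synch}$, the trial average acquires the amplitude-modulated
*down-chirp* shape characteristic of sensory and cognitive ERPs. The same
staggered slowing moves spectral power transiently downwards (alpha into
theta, beta into alpha), which reproduces the classical ERD/ERS sign pattern
and the post-stimulus "smearing" of the alpha peak — all without any power
modulation.

We anchor the square-root laws at `t_start` rather than at the stimulus:
with a modulation onset delayed by 80 ms (roughly the cortical arrival time
of a visual stimulus) the constraint
$t_\mathrm{start} < t_\mathrm{synch}(T)$ must hold for every grid frequency,
which is only possible if the laws measure offsets from `t_start`.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `f_min`, `f_max`, `f_step` | 0.1, 250, 0.1 | Hz | frequency grid; grid points at or above Nyquist are dropped with a warning |
| `t_start` | 0.08 | s | onset of phase modulation after the stimulus |
| `k_synch` | 0.5 | s^1/2 | synchronization-time law coefficient |
| `k_desynch`, `c_desynch` | 0.9, 0.05 | s^1/2, s | desynchronization-time law |
| `t_end_offset` | 1.5 | s | `t_end - t_desynch` |
| `phi_target` | 0 | rad | per-channel target phase; the ERP's only shape-free parameter |
| `responding_fraction` | 0.5 | — | fraction of amplitude at every frequency that is phase-modulated |
| `n_trials` | 100 | — | trials per simulated set |

`k_synch`, `k_desynch` and `c_desynch` are **calibration parameters**, not
measured constants: their defaults place the synchronization times near the
phase-locking peak latencies observed in empirical-mode analyses of
event-related EEG (a PLV peak around 150–350 ms for components between about
35 and 4 Hz). `t_end_offset = 1.5` s follows the observation that results
are insensitive to `t_end` provided the rebound is at least as long as the
slowing. `responding_fraction = 0.5` reflects the finding that letting only
about half of the EEG respond brings the simulated frequency excursions to
empirically realistic size.

`responding_fraction` is implemented as a per-trial Bernoulli($r$) subset of
*responding oscillators*, each keeping its full amplitude, rather than as an
amplitude split at every frequency ($a_f r$ modulated plus $a_f(1-r)$
stationary). The split looks equivalent but is not: the two same-frequency
halves share a phase at baseline and decohere during the response, which
silently cuts mean-square power to $r^2 + (1-r)^2$ of baseline (a broadband
~4-fold Welch power deficit at $r = 0.5$) — violating the model's central
no-power-change assumption. With a responding subset, every oscillator's
amplitude is constant and power conservation holds exactly.

Per trial, one $\Delta\varphi_f$ draw is shared across channels; channels
differ only in `phi_target` (and optionally in spectra). The per-channel sum
is assembled from quadrature components, so the target phase enters as an
exact rotation — this is also what makes the target-phase grid search cheap
(see below).

## The synthetic baseline spectrum

`synthetic_spectrum()` models resting EEG as a $1/f$ *power* law with a
Gaussian alpha bump: amplitude weights $a_f \propto f^{-1/2}$ plus a bump at
`alpha_peak_hz` (default 10 Hz, width 1 Hz) whose height is `alpha_gain`
times the aperiodic floor, normalized to $\sum_f a_f^2 = 1$. Two choices
deserve comment:

* **Power, not amplitude, goes as 1/f.** Weighting *amplitudes* by $1/f$
  would put $10^4$ times more power at 0.1 Hz than at 10 Hz; no recorded EEG
  (acquisition band-passed at 0.1–100 Hz, baseline spectra estimated from
  ~1 s windows) behaves that way, and simulations so weighted are dominated
  by sub-delta drift.
* **`alpha_gain = 5`.** The theta-synchronization mechanism requires the
  alpha band to carry more power than the theta band at baseline, so that
  alpha-range oscillations slowing through theta produce a net amplitude
  gain there. A five-fold amplitude (≈25-fold power) peak is typical of
  posterior EEG under fixation and realizes that precondition. With
  `alpha_gain = 1` the spectrum is the pure power law and the theta ERS
  disappears — which is itself a model prediction, not a defect.

`spectrum_from_psd()` builds the same weight table from a measured Welch
spectrum (amplitude = square root of power), for use with real baselines.

## The analysis chain

**EMD.** `sift()` extracts intrinsic mode functions by iterated subtraction
of the mean natural-cubic-spline envelope through the local maxima and
minima. Design choices the literature leaves open, fixed here: a Cauchy-type
stop for each IMF ($\mathrm{SD} = \sum(h_{k-1}-h_k)^2 / \sum h_{k-1}^2 <
0.2$, hard cap 50 passes); boundary handling by mirroring the two nearest
extrema of each kind about the record ends; plateau extrema resolved to the
plateau centre; exactly six IMFs per trial with early-terminated
decompositions zero-filled so aggregation by ordinal number is always
defined. Reconstruction ($\sum \mathrm{IMF} + \mathrm{residual} = x$) is
exact by construction and asserted to $10^{-8}$ of the input RMS in the
tests. On white noise the sifter behaves as a dyadic filter bank
(successive mean-frequency ratios near 2), the standard sanity check.

**Hilbert measures.** `analytic()` forms the analytic signal in the
frequency domain. Instantaneous frequency comes from convolving the
unwrapped phase with a derivative-of-Gaussian kernel (σ = 20 ms by default)
— exact on linear phase, and with noise suppression well over five-fold
relative to two-point differencing, while still resolving the ~100 ms
frequency dip the model predicts. The first and last 100 ms of every
analytic series are flagged and excluded from downstream statistics (Hilbert
edge distortion). The per-IMF baseline mean frequency is amplitude-weighted,
so low-amplitude stretches with unreliable phase contribute little.

**Summaries.** `summarize_imfs()` aggregates by ordinal IMF number across
trials and channels — evoked (trial mean), induced (mean envelope), PLV
(modulus of the mean unit phasor) and trial-mean instantaneous frequency —
with a baseline-frequency 95% CI across trials (mean ± 1.96·SE over
−500..0 ms). Aggregating by ordinal number follows standard practice even
though IMFs are not guaranteed frequency-homogeneous across trials; the
consequences are discussed under *Limitations*.

**Classical measures.** ERPs are baseline-corrected (−200..0 ms) trial
means smoothed by a zero-phase 20 Hz FIR low-pass; ERD/ERS is the
trial-mean Hilbert envelope of zero-phase FIR band-passed trials expressed
as percent change from the −500..0 ms baseline (amplitude convention:
positive = synchronization); Welch spectra use 512-sample Hanning segments
with 50% overlap (0.98 Hz bins at 500 Hz). FIR filters are windowed-sinc
designs of order three times the longest period in the band (capped so the
forward–backward pass fits the record), applied with `filtfilt`.

**PLS.** Condition contrasts are tested by SVD of the covariance between a
deviation-coded condition design and subject-by-condition cell means;
significance by permutation of condition labels *within* subject with the
add-one estimator $p = (1 + \#\{d_\pi \ge d\})/(n_\pi + 1)$; salience
reliability by bootstrap over subjects with dot-product sign alignment
(SVD sign indeterminacy) and salience/SE ratios on a z-score scale.

## The discrimination experiment

`run_discrimination_experiment()` operationalizes the model's central
testable claim: phase-aligned and additively evoked data are
indistinguishable by ERP and PLV but differ in their IMF amplitude and
frequency dynamics. It simulates a Firefly set, uses its plain trial mean as
the evoked template over an otherwise identical *unmodulated* background,
decomposes both, and scores per-IMF excursions of the summary time courses
outside a baseline band.

The excursion band is the baseline mean ± 1.96·SD *of the summary series
itself*, estimated over the whole clean pre-stimulus stretch (epoch start
+ 200 ms up to −50 ms). Two alternatives were rejected: the across-trial SE
band of the window-mean baseline frequency is an order of magnitude
narrower than the sample-to-sample variability of the plotted curve (a
stationary series exits it constantly), and a −500..0 ms band is unstable
for the slowest IMFs, which complete less than one baseline cycle in half a
second. A dip or rebound is only scored when at least 2% of post-stimulus
samples (0.08–1.2 s) fall beyond the band, so single-sample noise crossings
do not count.

At the defaults, the Firefly arm shows the predicted slowing-then-rebound
for the mid IMFs (20–48% of post-stimulus samples outside the band, dip
first) and both arms show a post-stimulus PLV peak. One honest caveat: the
evoked arm is *not* perfectly silent in frequency. The shared template is a
strong coherent down-chirp (its peak exceeds the single-trial RMS), and
wherever it transiently dominates the background it drags the trial-mean
instantaneous frequency along its own downward sweep, producing band exits
at 10–12% of post-stimulus samples in the two IMFs its chirp traverses —
above the ~5% a stationary series would show. The qualitative contrast with
the phase-aligned arm remains large, but a strict "evoked stays within the
band at ≥90% of samples in *every* IMF" reading fails narrowly at this
template-to-background ratio. We report the measured fractions rather than
forcing the cleaner dichotomy.

A second caveat concerns closed-loop recovery of the timing law. The target
phase is recovered essentially exactly (0–1° at 100 trials), but estimating
`k_synch` from per-IMF PLV peak latencies only works down to mid
frequencies: the same stimulus-locked transient mode-mixes into the two
slowest IMFs, and its early coherence — compounded by partial-ramp
coherence, since a single oscillator's PLV rises as sinc(1−s) well before
`t_synch` — outweighs the slow oscillators' own phase-locked plateau at 100
trials. Estimated latencies increase with period from IMF1 through IMF4 and
the square-root fit over those scales is sound, but a fit that includes the
slowest IMFs underestimates `k_synch` badly. This is a measurable
limitation of PLV-peak timing as an estimator at this trial count, and the
package reports it as measured.

## Problem sizes and numerical choices

Simulations in the tests and the acceptance script use the full study-scale
conditions where the claim concerns them: the default 0.1–250 Hz grid at
0.1 Hz (2499 oscillators below Nyquist), 500 Hz sampling over −2..+2 s, and
100 trials per arm (~1.5 min for the full discrimination experiment on one
core). Unit tests of individual operations use reduced grids (0.5–45 Hz at
0.5 Hz, 250 Hz sampling, 10–60 trials) — the properties tested there are
scale-free. PLS calibration uses 200 null datasets of 10 subjects × 2
conditions × 30 cells at 200 permutations; power uses the injected-effect
design (3× noise SD at 10% of cells, 20 subjects, 1000 permutations).
Seeded runs are bit-reproducible; a single pipeline seed expands into
per-stage sub-seeds (`seed * 101 + stage`) so module-level reruns match
pipeline runs.

Degenerate inputs are handled explicitly: monotonic signals raise a typed
condition that ends sifting; constant series make phase, correlation and
normalization errors rather than NaNs; all-rejected artifact screens, empty
Nyquist-filtered grids, and mismatched sidecars are hard errors.

## Limitations

* The simulator models a single channel family with one target phase per
  channel and no volume conduction, electrode geometry, or condition
  (old/new) effects; contingent negative variation and other slow
  anticipatory potentials are explicitly out of scope.
* The synthetic spectrum is a two-parameter idealization; real baseline
  spectra (via `spectrum_from_psd()`) carry channel-specific structure the
  defaults cannot imitate. Passing tests on synthetic data show the
  machinery is correct under the model's own assumptions, not that the
  model fits any particular recording.
* Ordinal-IMF aggregation can smear frequency-specific effects across
  adjacent IMFs when decompositions vary between trials; mean IMF
  frequencies in any given run will not match any fixed set of published
  band centres.
* The square-root timing law is extrapolated to the fastest grid
  frequencies, where phase-locking peaks are hard to measure; estimates of
  `k_synch` from data therefore use the mid IMFs only.
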