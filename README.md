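# fireflyeeg

Simulation and analysis of event-related EEG under the **Firefly
phase-alignment model** — a generative account in which event-related
potentials (ERPs), event-related (de)synchronization (ERD/ERS) and
post-stimulus spectral changes all arise from one mechanism: ongoing
cortical oscillations transiently *slow down* to align their phases with a
target oscillation, then rebound, with **no change in signal power**. The
package is aimed at EEG methodologists who want to test whether
"evoked-looking" features in their data require an additive evoked signal at
all.

## The model

A simulated trial is a weighted sum of sinusoids on a dense frequency grid,

&nbsp;&nbsp;&nbsp;&nbsp;V(t) = Σ_f a_f · cos φ_f(t),

where a_f is the baseline amplitude spectrum (1/f power law plus an alpha
peak, or weights taken from a measured Welch spectrum) and each oscillation's
phase φ_f(t) passes through five stages: random-phase baseline → linear
slowing that accumulates the offset −Δφ′_f by t_synch → phase-locked to the
target oscillation until t_desynch → linear rebound → baseline again. Stage
latencies scale with the square root of the period T = 1/f,

&nbsp;&nbsp;&nbsp;&nbsp;t_synch = t_start + k_synch·√T,&nbsp;&nbsp;
t_desynch = t_start + k_desynch·√T + c_desynch,

so high frequencies align early and low frequencies late — which gives the
trial average the amplitude-modulated *down-chirp* shape of real ERPs, and
moves spectral power transiently downwards (alpha → theta), reproducing the
classical ERD/ERS sign pattern without any amplitude modulation.

Alongside the simulator the package provides the full analysis chain used to
discriminate phase alignment from an added evoked signal:

* **`sift()` / `emd_epochs()`** — empirical mode decomposition by envelope
  sifting (natural cubic splines, mirrored ends, Cauchy stop);
* **`analytic()` / `inst_frequency()` / `plv()` / `summarize_imfs()`** —
  Hilbert envelope, phase, derivative-of-Gaussian instantaneous frequency,
  phase-locking value, and per-IMF trial summaries;
* **`erp()` / `erd_ers()` / `welch_psd()`** — conventional event-related
  measures (zero-phase FIR filtering throughout);
* **`pls_task()`** — partial least squares condition contrasts with
  permutation p-values and bootstrap salience ratios;
* **`lagged_correlation()` / `fit_sqrt_law()` / `search_target_phase()` /
  `estimate_tsynch_from_plv()`** — model-to-data comparison and closed-loop
  recovery of the timing law and target phase;
* **`run_discrimination_experiment()`** — the headline experiment: matched
  phase-aligned and additive-evoked datasets, decomposed and scored for
  post-stimulus frequency excursions.

Everything takes and returns tibbles, chains with the pipe, and has
`autoplot()` / `tidy()` / `glance()` methods where a result is worth
plotting or summarizing.

## Worked example

```r
library(fireflyeeg)

cfg <- firefly_config(f_min = 0.5, f_max = 45, f_step = 0.5, n_trials = 40,
                      phi_target = pi / 3, rng_seed = 42)
e <- simulate_firefly(cfg, sampling = sampling_spec(250, -1, 1.5))
e
#> <epoch_set> 40 trial(s) x 1 channel(s) x 625 samples @ 250 Hz (-1..1.5 s)

fit <- erp(e)
max(abs(fit$value))                      # ERP peak: 1.401 uV

th <- erd_ers(e, "theta")
mean(th$erd[th$time >= 0.05 & th$time <= 0.3])   #  +32.4 %  (theta ERS)
al <- erd_ers(e, "alpha")
mean(al$erd[al$time >= 0.3 & al$time <= 1.0])    #   -6.9 %  (alpha ERD)

s <- summarize_imfs(emd_epochs(e, n_imfs = 4))
glance(s)
#> # A tibble: 4 x 5
#>     imf freq_mean ci_lo ci_hi n_trials
#>   <int>     <dbl> <dbl> <dbl>    <int>
#> 1     1     25.3  23.4  27.3        40
#> 2     2      9.56  9.16  9.95       40
#> 3     3      3.76  3.49  4.02       40
#> 4     4      1.63  1.48  1.78       40
autoplot(s)   # evoked / induced / PLV / frequency time courses per IMF
```

The trial average of purely phase-aligned oscillations is a genuine ERP
(1.4 µV against a 0.68 µV single-trial RMS here), theta amplitude rises ~32%
shortly after the stimulus while alpha drops — the textbook ERD/ERS pattern
— and the IMF baseline frequencies fall roughly dyadically, all from a
signal whose power never changes. (At the full default grid and 100 trials
the contrast sharpens: theta +109%, alpha −20%, beta1 −23%.)

A command-line wrapper for the same pipeline lives at
`inst/cli/firefly.R` (`simulate`, `decompose`, `analyze`, `experiment`,
`validate`, `reject`).

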