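# gaborclean

Tonic scalp and neck muscle activity (EMG) contaminates the gamma band
(> 30 Hz) of the scalp EEG so heavily that most of the apparent gamma
signal in uncorrected recordings is myogenic. Because each scalp muscle
fibre group is a separate, spatially focal source, spatial
source-separation (ICA/CCA) cannot remove it, and frequency-domain
regression cannot be used when gamma itself is the signal of interest.

`gaborclean` removes this contamination in the time domain, spike by
spike. Each muscle spike is modelled as a **Gabor atom** — a sinusoid
under a Gaussian envelope,

    g(t) = A · sin(2π f (t − t0) + φ) · exp(−(t − t0)² / (2σ²)),

detected by its sharp potential change over 3.5 ms, localised by the
anticorrelation of the first and third differentials, fitted by
quadrature regression, and subtracted — leaving activity outside the atom
supports untouched. Around this core the package provides the complete
analysis chain for validating the correction on a self-paced motor task:
power-line harmonic regression, saccade-muscle-potential (eye-corner
reference) regression, sliding Hanning-windowed FFT time–frequency
analysis, adaptive per-subject epoch rejection, event-related gamma
synchronisation (ERS) statistics (65–85 Hz, paired one-tailed t tests,
Z-score topographies), and a fully seeded synthetic-EEG generator with
ground-truth spike and burst inventories.

## Worked example

Simulate a 70-press recording (background EEG, mu rhythm, Poisson muscle
spikes at 5/s, event-locked 75 Hz gamma bursts), correct it, and test for
the motor gamma ERS on the C3–CZ derivation:

```r
library(gaborclean)

sim <- simulate_eeg(simulation_spec(
  channels = c("C3", "CZ"), n_events = 70,
  mains_amp_uv = 0, include_mains_channel = FALSE,
  smp_rate_hz = 0, include_smp_refs = FALSE, seed = 7))

res <- reduce_emg(sim$recording)        # detect, fit and subtract spikes
head(res$spikes[, c("channel", "t0_s", "sigma_ms", "amp_uv", "corr")], 3)
#>   channel   t0_s sigma_ms amp_uv  corr
#> 1      C3 0.0793     4.04   12.1 0.826
#> 2      C3 0.5886     1.68   16.7 0.955
#> 3      C3 0.6509     3.33   17.9 0.859

sc <- score_correction(sim, res$recording, derivation = "C3")
sc$residual_spike_energy_frac           # spike energy left after correction
#> [1] 0.091
sc$band_reduction                       # amplitude reduction per band
#>  65-85 60-130
#>  0.237  0.394

tb <- trial_band_amplitudes(res$recording, sim$events, "C3", "CZ")
ers_test(tb$peak, tb$baseline)          # corrected data
#> <ers_result> n=70  mean peak 0.1474, baseline 0.1418 (ERS 0.005635)
#>   t(69)=1.449, one-tailed p=0.07589
```

The inventory rows are the fitted atoms (centre time in seconds, spread
in ms, amplitude in µV, and the atom–EEG correlation); the correction is
exactly `input − spikes_waveform(inventory, …)`. Here the correction
removes 91% of the injected spike energy and lowers the 65–85 Hz
amplitude by 24% — the contaminated data for the same subject give
one-tailed p = 0.26 for the ERS, the corrected data p = 0.076; a single
synthetic subject is underpowered, and across a cohort of eight the
across-subject test (`run_synthetic_cohort()`) detects the ERS with
p < 0.05 in well over 80% of seeded cohorts.

A pipeline wrapper (`run_pipeline()`) chains all stages on files
(EDF or delimited text + events CSV) and writes per-stage corrected
recordings, the spike inventory, the epoch mask, ERS results and a JSON
run log; `inst/cli/gaborclean.R` exposes `simulate` and `pipeline`
subcommands for shell use.

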