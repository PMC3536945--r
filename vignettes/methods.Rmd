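---
title: "Reducing tonic muscle artifacts in the EEG gamma band by Gabor-atom subtraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing tonic muscle artifacts in the EEG gamma band by Gabor-atom subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Scalp EEG above ~30 Hz (the gamma band) is heavily contaminated by
electromyographic (EMG) activity from tonically active scalp and neck
muscle fibres. Each fibre group is a separate, spatially focal source, so
spatial source-separation methods (ICA/CCA) do not remove it, and
frequency-domain regression cannot be used when the gamma band itself is
the signal of interest. `gaborclean` takes a time-domain route: individual
muscle spikes have a stereotyped waveform that is well modelled by a
**Gabor atom** — a sinusoid under a Gaussian envelope,

$$ g(t) = A\,\sin\!\big(2\pi f\,(t - t_0) + \varphi\big)\,
   \exp\!\Big(-\frac{(t - t_0)^2}{2\sigma^2}\Big), $$

with centre time $t_0$, spread $\sigma$ (1–4 ms for typical spikes),
carrier $f$, phase $\varphi$ and amplitude $A$. Spikes are detected one by
one, fitted, and the fitted waveform subtracted, leaving lower-amplitude
activity — including neural gamma oscillations of a few hundredths of a
microvolt — untouched outside the atom supports.

The package implements the full analysis chain used to validate such a
correction on a self-paced button-press task: power-line cancellation,
saccade-muscle-potential (SMP) regression, the EMG spike reduction itself,
sliding Hanning-windowed FFT time–frequency analysis, adaptive epoch
rejection, and event-related synchronisation (ERS) statistics for the
65–85 Hz motor gamma, plus a fully seeded synthetic-EEG generator with
ground-truth inventories.

## The spike-reduction algorithm

Per channel, `reduce_emg()` runs five stages; all tunables live in
`detection_config()`.

1. **Detection.** Candidates are local maxima of the absolute potential
   change over 3.5 ms exceeding `v_thresh` (default 7 µV; a useful range
   is 4–9 µV), computed on a copy high-passed at 10 Hz with a zero-phase
   FIR filter so that slow waves neither trigger nor delay detections.
   Candidates closer than 3.5 ms are merged, keeping the larger change.
   All later stages use the unfiltered signal.

2. **Centre location.** Near the envelope centre the atom approximates a
   sinusoid, whose first and third discrete differentials are inversely
   proportional. Within ±5 ms of the candidate, the sliding-window
   correlation of d1 and d3 (window 3.5 ms) is minimised; candidates whose
   best correlation is weaker than `corr_thresh` (−0.78 at 2 kHz, −0.84
   at 5 kHz) are discarded. A subtlety matters here: d1 and d3 are paired
   at equal start index, i.e. *deliberately offset by one sample*. Had
   they been re-centred to a common time point, d3 would be the second
   difference of d1 and *any* broadband signal would show a correlation
   near −0.95, leaving the gate unable to reject noise. With the offset
   pairing a heavily oversampled carrier still correlates near
   $-\cos(2\pi f/f_s)$ (≈ −0.98 at 5 kHz) while broadband noise flips to
   positive correlation. The growth of the one-sample phase error at
   coarser sampling also explains why the gate must be laxer at 2 kHz
   than at 5 kHz. For odd-phase atoms the correlation minimum sits up to
   ~1 ms off the true centre (the centre itself is envelope-dominated in
   d1); this is only the first guess and is refined next.

3. **Spread estimation.** The ratio of the gradient at the centre to the
   gradient 1 ms earlier is compared with a closed-form table over a σ
   grid (0.5–6 ms in 0.05 ms steps). The analytic ratio has a *pole* near
   σ ≈ 1.2 ms at the default carrier, where envelope and carrier
   contributions to the gradient cancel: above the pole the ratio falls
   monotonically from +∞ towards ~1.7 (the invertible branch); below it
   the ratio is negative and non-monotone. Measured ratios on the branch
   are inverted by interpolation; ratios off the branch fall back to a
   coarse grid search on the projection objective below.

4. **Refinement.** The centre time is hill-climbed in 0.01 ms steps
   (atoms regenerated on the sample grid at each sub-sample shift),
   alternating with a line search on σ, both maximising the energy
   captured by the quadrature atom pair (see below). The energy — rather
   than the energy *fraction* — is the matching-pursuit objective: noise
   contributes a roughly position-independent two-degree-of-freedom
   share, while the atom's captured energy peaks sharply at its true
   parameters. On noiseless atoms the refined $(t_0, \sigma, A)$ agree
   with an exhaustive grid-search least-squares fit to within one grid
   step (the oracle-equivalence test), so the refinement is at the
   attainable optimum; under noise, residual $t_0$/amplitude scatter is
   information-limited, because with the phase free the centre time is
   constrained only through the slow Gaussian envelope.

5. **Amplitude fit and subtraction.** Amplitude and phase are fitted
   jointly by ordinary least squares of the signal on a sin/cos
   quadrature pair over the support window $t_0 \pm 4\sigma$; at sampling
   rates ≥ 5 kHz a second quadrature pair at $2f$ captures
   higher-frequency spike components (`extra_hf`). The fitted waveform is
   subtracted from the unfiltered signal; samples outside the support are
   untouched, and the returned inventory reproduces the subtraction
   exactly: `corrected = input - spikes_waveform(inventory, ...)`.

Candidates are processed in temporal order and each subtraction is
applied before later candidates are evaluated, so overlapping spikes are
fitted on the residual (sequential greedy, matching-pursuit style).

The carrier frequency is not an observable of the published method; the
default $f = 1/(2 \cdot 3.5\,\mathrm{ms}) \approx 142.9$ Hz makes the
steepest half-cycle of the sinusoid span the 3.5 ms detection signature.
Phase is never discretised: the quadrature regression fits it implicitly.

## Surrounding pipeline

**Power-line cancellation** (`cancel_powerline()`): the mains fundamental
is extracted from a dedicated noise channel (or the channel average) by a
zero-phase FIR band-pass (f0 ± 1 Hz), normalised to unit envelope, and
its quadrature obtained from the analytic signal. Harmonics are generated
by the angle-addition recursion
$\sin((k{+}1)\theta) = \sin(k\theta)\cos\theta + \cos(k\theta)\sin\theta$,
which tracks slow frequency wander without ever estimating the phase
explicitly. Each channel is regressed on the basis (OLS) and the fitted
mains part subtracted. Defaults: all harmonics below $0.9 f_s/2$, capped
at 8; optional block-wise fitting (`block_s`) for non-stationary mains.

**SMP correction** (`fit_smp()`/`apply_smp()`): each channel is regressed
jointly on the left/right eye-corner reference channels and the weighted
references subtracted. Two free coefficients are strictly more expressive
than a constrained weighted average; `constrain_average = TRUE` gives the
literal single-coefficient reading. Weights are fitted once over the
whole recording (saccade topography is stationary at this timescale).
Mains removal runs first by default: line noise shared by the references
and the EEG would bias the SMP weights.

**Time–frequency analysis** (`sliding_fft_amplitude()`): Hanning-tapered
windows every 5 ms; 512 samples (256 ms) at 2 kHz and 2,048 samples
(409.6 ms) at 5 kHz. Amplitudes use coherent-gain normalisation (an
on-bin unit sinusoid reads 1 µV) divided by the bin width, giving a
window-length-independent µV/Hz scale; this makes the epoch-rejection
constants meaningful across sampling rates. Band summaries
(`band_amplitude()`) average bins with both edges inclusive; time stamps
are window centres. A fast path computes single-band series by FFT
convolution with modulated window kernels; it is numerically identical to
the full map (tested to 1e-12) and is what `trial_band_amplitudes()`
uses.

**Epoch rejection** (`build_mask()`, `anomaly_reject()`): the per-subject
threshold is $\min(1.5 \times \text{mean 60–130 Hz amplitude} + 0.06,\,
0.4)$ µV/Hz, raised just enough if it would reject more than 30 of 70
trials. The mask is decided once, on post-SMP/pre-EMG data, and the same
trials are excluded in every condition (enforced by
`check_same_mask()`). A final single pass drops trials whose maximum
65–85 Hz amplitude exceeds mean + 6 SD of the kept trials; mean and SD
are computed leave-one-out, because with ~70 trials a single extreme
trial inflates the pooled SD enough to mask itself (a nominal 8 SD
outlier would otherwise never be rejected).

**ERS statistics** (`ers_test()`, `correction_effect_test()`,
`topography_z()`): the per-trial "peak" is the mean 65–85 Hz amplitude
over 0–250 ms after the press (a `peak_window` argument changes this);
the baseline is the second before the press, shortened to start 250 ms
after the previous press when presses are close, and dropped when the gap
is ≤ 250 ms. Within- and across-subject tests are paired one-tailed t
tests (peak > baseline); the effect of a correction stage on the baseline
is one-tailed (reduction expected), on the baseline-corrected peak
two-tailed (no predicted direction). Z topographies divide the mean
baseline-corrected ERS by its across-trial SD. No multiple-testing
correction is applied. p values use the t distribution with $n-1$ df.

## The synthetic generator

`simulate_eeg()` composes, additively and from a single seed:

* **1/f background** (3 µV RMS, exponent 1), band-limited at 200 Hz by a
  4th-order low-pass magnitude. The band limit reflects the emulated
  acquisition chain's anti-alias filter and the sub-µV level of scalp EEG
  above a couple of hundred Hz; mathematically ideal 1/f noise extending
  to Nyquist would put unphysical energy into the third differential and
  blind the d1/d3 gate. The RMS is calibrated so the artifact-free
  60–130 Hz sliding-window amplitude sits near 0.1 µV/Hz, the scale the
  rejection constants (b = 0.06, cap = 0.4 µV/Hz) are expressed in.
* **Mu rhythm**: 10 Hz with phase-locked harmonics (saw-tooth-like
  shape), exercising the harmonic-confound pathway that limits low-gamma
  measures.
* **Mains**: 50 Hz plus harmonics with a shared phase, per-channel gains,
  and a dedicated noise channel.
* **Muscle spikes**: per-channel Poisson trains (5/s) of Gabor atoms,
  A ~ U[8, 30] µV, σ ~ U[1, 4] ms, phase uniform; the truth table shares
  the inventory schema so `spikes_waveform()` reconstructs them exactly.
* **Saccade potentials**: a ~30 ms biphasic template at Poisson times,
  carried fully by the eye-corner reference channels and propagated into
  scalp channels with fixed per-channel coefficients.
* **Event-locked gamma bursts**: 75 Hz, 250 ms Hanning-enveloped bursts
  at each press on the left central channel. The default source amplitude
  is 0.55 µV, calibrated so the *measured* trial-averaged event-related
  increase is ~3.7% of the 65–85 Hz baseline — the middle of the
  2.9–4.6% relative ERS scale reported for this task. The distinction
  matters: a burst well below the in-band background raises measured band
  amplitude only quadratically (amplitudes add in quadrature), so the
  source amplitude must be several times the measured increment.
* **Self-paced presses**: 70 per recording, truncated-normal intervals
  with mean 1.53 s.

What the generator does *not* emulate: non-stationary muscle tone,
spike-waveform deviations from the Gabor shape, volume-conducted EMG
shared across channels, electrode drift and movement artifacts, and
heavy-tailed noise. Passing tests therefore demonstrate correctness of
the algorithms under the stated model, not performance on arbitrary real
recordings.

`score_correction()` compares a corrected recording with the ground
truth: residual spike energy within the true atom supports, band
amplitude reductions, the 65–85 Hz change on spike-free data (false-
positive damage), the fraction of modification energy spent outside true
supports, and burst recovery. Burst recovery is measured by a matched
filter — the mean projection coefficient of the corrected signal on each
trial's known burst waveform — which is an unbiased amplitude estimator
immune to the quadratic band-amplitude suppression.

## Numerical choices and problem sizes

* Zero-phase filtering is FFT convolution with symmetric FIR taps and
  reflection padding; whole-signal transforms are padded to composite
  lengths.
* The quadrature fits solve 2×2 (or 4×4) normal equations directly with
  an `rcond` guard; atoms with σ far below a carrier cycle are skipped.
* The per-candidate chain (locate → spread → refine → fit) is compiled
  (Rcpp) because realistic recordings carry thousands of candidates; the
  exported R operations implement the same algorithms and are what the
  unit tests exercise against the compiled path's output.
* Sub-grid σ values are resolved by golden-section search with 0.02 ms
  tolerance; t0 refinement is capped at 200 steps (±2 ms).
* The validation suite uses: 50 noiseless atoms for oracle equivalence,
  200 noisy atoms for parameter recovery, 1,000 noise draws for the
  null gate, and 50 + 20 synthetic cohorts (8 subjects × 70 presses,
  2 channels at 2 kHz) for the end-to-end ERS experiment. Cohort
  recordings omit mains and SMP components — those stages are validated
  by their own module tests — and skip epoch rejection, since after EMG
  correction the contaminated trials are already cleaned.

## Known limitations

* With amplitude and phase free, a single atom's centre time is
  constrained only through its envelope; at low SNR even the exhaustive
  least-squares fit scatters by ~0.1 ms and ~10% in amplitude. The
  pipeline matches that bound but cannot beat it.
* Each subtraction removes the local two-degree-of-freedom projection of
  *everything* under the atom, including any concurrent neural
  oscillation whose frequency falls inside the atom's band. At 5 spikes/s
  this removes roughly 10–20% of a weak in-band burst's amplitude on the
  affected channel — consistent with the original observation that task
  gamma is not *significantly* reduced, but a real cost of the greedy
  subtraction. Fitting a joint model of spikes plus oscillations would
  reduce it, at substantial complexity.
* Locally sinusoidal non-spike features (mains residue, sharp mu
  harmonics) pass the d1/d3 gate if they also produce a 7 µV change in
  3.5 ms; mains must therefore be cancelled before spike reduction, and
  on spike-free data the false-fit rate still removes a few percent of
  gamma-band amplitude under this generator's background.
* The EDF reader handles continuous recordings with a uniform sampling
  rate; EDF+ annotation streams are ignored (events travel as CSV).
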