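---
title: "Motor-imagery EEG: simulation, wavelet band analysis, ERD/ERS, and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery EEG: simulation, wavelet band analysis, ERD/ERS, and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mierd)
```

## The analysis in one paragraph

Imagining a hand movement suppresses the sensorimotor mu (~10 Hz) and beta
(~20 Hz) rhythms over the *contralateral* motor cortex (electrode C4 for
left-hand imagery, C3 for right-hand) and often enhances them ipsilaterally.
The suppression is event-related desynchronization (ERD), the enhancement
event-related synchronization (ERS), quantified per channel and band as

$$\mathrm{ERD/ERS} = 100 \cdot \frac{E - R}{R}\,[\%],$$

where $R$ is the band power in a reference window before the imagery cue and
$E$ the band power in an event window after it; negative values are ERD.
`mierd` packages this analysis end to end: a synthetic session generator with
known ground truth, a Daubechies-6 (db6) three-level wavelet decomposition
that isolates the 6.25–25 Hz band, periodogram band-power estimation, the
ERD/ERS map, and compact CNN/LSTM classifiers evaluated with stratified
5-fold cross-validation.

## The synthetic-data generator

No public accession accompanies the recordings that motivated this pipeline,
so the generator is the canonical input source and is itself tested code.
It emulates two acquisition protocols: `comp118` (118-channel cap, 100 Hz,
280 trials: 140 left, 140 right) and `lab32` (32 leads, 250 Hz), plus fully
custom montages (any 10-20-style channel set containing C3 and C4).

Each trial is

* **rhythms** — mu and beta sinusoids with trial-random phase, sourced at C3
  and C4 (defaults 10 µV and 5 µV peak, typical scalp-EEG rhythm amplitudes);
* **modulation** — at the cue, the contralateral source's band *power* is
  multiplied by $(1 - d)$ and the ipsilateral by $(1 + g)$, with a 250 ms
  raised-cosine ramp. Parameterizing the power ratio directly makes the
  expected ERD/ERS exactly $-100\,d$, turning parameter recovery into a
  closed-form check. The ramp avoids the spectral splatter a hard step would
  inject into the PSD tests;
* **spatial spread** — all other channels carry an *unmodulated* copy of the
  rhythms, scaled by a Gaussian kernel of inter-electrode distance on an
  approximate 10-20 layout. Class information therefore lives only at C3/C4,
  giving the CNN's spatial filters realistic but uninformative structure to
  reject;
* **noise** — per-channel $1/f$ background (unit variance, spectral floor at
  0.5 Hz), spatially mixed by a distance kernel with row-normalized power,
  scaled so that the pre-cue rhythm-to-background power ratio at C3/C4 equals
  `snr_db` (default 6 dB, a strong idle-rhythm subject);
* **artifacts (optional)** — ~100 µV, 300 ms blink transients on frontal
  channels at `blink_rate` per minute, and a mains sinusoid at `line_freq`
  (rejected at or above Nyquist).

The default epoch spans $[-2, 3.5)$ s around the cue at 100 Hz (550
samples). With trial-averaged band energies, the expected *measured* ERD at
depth $d$ is biased toward zero by the in-band noise floor:
$-100\,d \cdot S/(S + N)$ with $S$ the in-band rhythm power and $N$ the
in-band noise power. At the 6 dB default, $N/S \approx 0.08$ in the mu band,
so recovering $-100 d$ to within a few points is expected and is what the
tests assert (tolerance ±8 points over 140 trials).

What the generator does **not** emulate: volume-conducted source mixtures
(each channel is a kernel-weighted rhythm copy, not a forward head model),
non-stationary rhythm amplitude, EMG and eye-movement spectra beyond the
blink bump, inter-subject variability, or electrode artifacts. Passing tests
therefore certify the *pipeline's* correctness and sensitivity, not
performance on real recordings.

## Wavelet band decomposition

The 100 Hz signal is decomposed three levels deep with the 12-tap orthonormal
db6 filter pair (hardcoded from the standard table; an orthonormality
self-test runs at package load). The Mallat pyramid halves the band at each
level, tiling $[0, 50)$ Hz as D1 = 25–50, D2 = 12.5–25, D3 = 6.25–12.5,
A3 = 0–6.25 Hz. Denoising keeps D2 + D3 — beta and mu — and zeroes D1
(high-frequency noise) and A3 (drift, blinks). Texts sometimes round the
lower edge to 6.5 Hz; a dyadic transform can only realize 6.25 Hz at 100 Hz,
and `band_map()` reports the exact dyadic edges.

Numerical choices:

* **Boundary handling.** Default is half-point symmetric extension, which
  minimizes edge artifacts on short epochs; coefficient vectors then carry
  $\lfloor (L + 11)/2 \rfloor$ entries per level, the length required for
  perfect reconstruction with a 12-tap filter. A `periodic` mode (circular
  convolution, $L/2$ coefficients, even lengths only) is also provided; it is
  exactly orthogonal, so coefficient energy equals signal energy to machine
  precision, and it is the mode under which the energy-conservation tests
  run.
* **Perfect reconstruction** (all bands kept) holds to ~1e-15 relative in
  both modes; band reconstructions are linear, so single-band signals sum to
  the full reconstruction.
* **Band selectivity is filter-limited.** db6 half-band filters have wide
  transition bands. A 20 Hz tone — 80% of the way to the 25 Hz band edge —
  retains only $|H(2\pi\,20/100)|^2/2 = 85.9\%$ of its energy through
  keep = {D2, D3}; the rest leaks into D1. This is a property of every
  faithful db6 implementation (verified against the closed-form filter
  response and an independent implementation), not an artifact of this one.
  Mid-band tones (e.g. 10 Hz) retain >99%, and out-of-band tones (2 Hz) are
  suppressed below 0.01%.
* **Other sampling rates.** The dyadic band semantics assume 100 Hz, so
  250 Hz (`lab32`) sessions are polyphase-resampled to 100 Hz
  (`resample_epochs()`, anti-aliased) before decomposition.

## Spectral estimation and ERD/ERS

`periodogram()` is the plain one-sided periodogram
$P[k] = |X[k]|^2/(N f_s)$ with interior bins doubled; no windowing or
segment averaging, so the Parseval identity
$\sum_k P[k]\,\Delta f = \overline{x^2}$ holds to rounding error and band
powers are rectangle-rule integrals over half-open bands (the Nyquist bin is
included when the band reaches $f_s/2$, so the full-band power is exactly
the mean square).

`band_energy()` returns band power of a windowed segment times the window
duration (µV²·s) and refuses windows shorter than four cycles of the band's
lower edge. `erd_ers_map()` averages event- and reference-window energies
across trials *before* forming the ratio (the standard, lower-variance ERD
estimator) and normalizes each by its window duration so that unequal
windows — default reference $[-1.5, -0.5)$ s and event $[0.5, 2.5)$ s, both
clear of the 250 ms ramp — cannot bias the percentage. The sign convention
is negative = ERD, as the formula's structure dictates.

## Classifiers

No deep-learning framework is assumed: both networks are compact enough that
the package implements them directly (RcppArmadillo, full backpropagation,
Adam at learning rate 1e-3, minibatches of 32, at most 100 epochs with
early stopping after 10 stale validation epochs on a stratified 20%
validation split; the stopper only arms after 20 epochs because the small
validation split is noisy while the loss surface settles, and stopping
earlier can strand a run at an undertrained snapshot). All randomness — initialisation, split, batch order —
derives from R's RNG under the configured seed, and the numeric kernels are
deterministic, so training is reproducible run to run.

Inputs are the wavelet-preprocessed epochs, z-scored per channel with
training-partition statistics only and decimated by 2 (the retained band
ends at 25 Hz, so 50 Hz sampling is lossless for the features and halves
compute).

* **CNN** (spectral-spatial): temporal convolution (kernel 11 samples, 8
  filters, linear) → spatial convolution across all channels and temporal
  filters (16 filters, linear) → squaring → non-overlapping average pooling
  → log → dense softmax. Squaring + pooling + log makes each feature an
  estimate of log band power in a local time window, exactly the quantity
  ERD modulates. The pooling window is the one free constant that matters:
  with 4 samples (80 ms) the per-window power estimates are so noisy that
  cross-validated accuracy on strongly separable synthetic data plateaued
  near 0.8 while a linear read-out of windowed log band powers achieved 1.0;
  at the default of 10 samples (200 ms, a physiologically sensible
  integration time) the CNN reaches the linear read-out's performance.
* **LSTM** (temporal baseline): one layer of 64 cells reading the channel
  vector per timestep, hidden-state mean over time, dense softmax (forget
  bias initialised to 1).

`cross_validate()` uses seeded, class-stratified folds;
`compare_archs()` runs several configurations on one shared fold assignment
and reports paired per-fold differences. On the generator's data the
discriminative structure is spectral-spatial rather than temporal, and the
CNN consistently matches or beats the LSTM — the expected ordering for this
class of signal. A pooled-versus-per-subject comparison harness is the same
machinery applied to concatenated or single-session epoch sets; no direction
is asserted, since either can win depending on inter-subject variability,
which the generator does not model.

## Pipeline and reproducibility

`run_all()` chains simulate → preprocess → PSD → ERD → cross-validation,
persisting every intermediate (epochs containers, PSD and ERD tables) under
one output directory and writing `report.json`. One master seed fans out to
stage seeds by a fixed rule (generator = seed + 1000, classifier =
seed + 2000). The report contains the configuration hash (excluding the
output path), the seeds, the ERD table and the CV block — and no timestamps
or absolute paths — so reruns with the same configuration are bit-identical.
Stage timings go to the message stream instead.

Problem sizes used by the test suite and the acceptance script: wavelet
identities on 500 random length-1024 signals; ERD recovery on 140 trials per
class (16-channel motor montage — the ERD read-out only uses C3/C4);
classifier checks on 200 trials (100 per class) at `erd_depth = 0.5`,
`snr_db = 5`, where held-out accuracy approaches 1; null checks
(`erd_depth = 0`) on 280 trials, where accuracy must stay inside the
binomial chance band.

## Known limitations

* The generator's simplifications listed above; in particular, real
  single-trial EEG has far lower effective SNR, and real cross-validated
  accuracies (roughly 70–80% for two-class motor imagery) are much lower
  than on this synthetic ground truth.
* Only two classes (left/right hand), one wavelet family (db6), and plain
  periodograms (no Welch averaging or multitaper) are implemented.
* EDF support is a minimal subset (uniform sampling rate across channels,
  16-bit quantization on write); GDF is not read — recordings in other
  formats should be converted to EDF or to the epochs container first.
* The LSTM is a single-layer baseline by design; its role is the
  architecture comparison, not state-of-the-art sequence modelling.
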