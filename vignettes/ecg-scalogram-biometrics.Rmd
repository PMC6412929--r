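---
title: "ECG biometrics with Morse-wavelet scalograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG biometrics with Morse-wavelet scalograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgscalo)
```

## The problem

ECG biometrics identifies or verifies a person from the shape of their
heartbeats. A single lead (lead I, the arm-to-arm channel) is enough: the
relative amplitudes, widths and timings of the P, Q, R, S and T waves are
stable within a subject over time and differ between subjects. The approach
taken here converts each beat into a time–frequency *image* and treats
identification as image classification, which makes the method robust to
the phase and amplitude ambiguities that plague raw-sample matching.

The pipeline has five stages — denoise, segment, transform, render,
classify — each exposed as ordinary functions so any stage can be used,
tested or replaced on its own.

## Preprocessing

Raw ECG carries two characteristic disturbances: baseline wander (slow
drift from respiration and electrode movement, typically below 0.5 Hz) and
mains interference (50/60 Hz plus harmonics and broadband sensor noise).
Both are handled with uniform moving averages, whose widths are expressed
in *samples* and default to values appropriate for a 1 kHz sampling rate:

| parameter | default | meaning |
|---|---|---|
| `baseline_width` | 500 samples (0.5 s) | window of the baseline estimate that is *subtracted* from the signal |
| `smooth_width` | 10 samples (10 ms) | direct smoothing window; a 10-sample boxcar has a spectral null at exactly 100 Hz at 1 kHz and strong attenuation across the mains band |
| `trim_n` | 600 samples | dropped at each end, where the filters were fed reflected rather than measured data |
| `beat_length` | 784 samples | window cut around each R-peak |

Two readings of "removing low-frequency noise with a wide average filter"
are possible; a plain 500-point average is itself a low-pass filter and
would *keep* the drift, so the package subtracts the smoothed signal — the
standard baseline-correction construction. The moving averages use
symmetric reflection at the edges so lengths are preserved; the subsequent
trim discards the affected margins anyway.

R-peak detection follows the classic energy-envelope recipe: a short 15 ms
pre-average, first difference, squaring, and a 120 ms moving-window
integration produce an envelope in which QRS complexes stand out. The
detection threshold sits a configurable fraction (default 0.3) of the way
from the envelope's median — its between-beat floor — up to its 99th
percentile. Anchoring the threshold at the floor rather than using a plain
percentile fraction matters at low SNR, where a raised noise floor would
otherwise swallow the QRS peaks. Candidates are localised at the
absolute-amplitude maximum of the signal near each above-threshold region
(absolute, so inverted-polarity leads still anchor on R), and a 0.25 s
refractory period keeps the stronger of any two close candidates. Beat
windows are *centred* on the R-peak, `[r − 392, r + 392)`; windows crossing
a record boundary are dropped.

## Generalized Morse wavelets

The continuous wavelet transform correlates the signal with shifted (`b`)
and dilated (`a`) copies of an analytic mother wavelet. The generalized
Morse family is defined directly in the frequency domain,

$$\Psi_{\beta,\gamma}(\omega) \;=\; U(\omega)\, a_{\beta,\gamma}\,
\omega^{\beta} e^{-\omega^{\gamma}},$$

where the unit step $U$ makes the wavelet analytic (no response at negative
frequencies), $\gamma$ sets symmetry and $\beta$ decay. The family is
usually parameterised by the time–bandwidth product $P^2 = \beta\gamma$.
Defaults are $\gamma = 3$ and $P^2 = 60$: the $\gamma = 3$ member has zero
demodulate skewness and minimal Heisenberg area, a standard choice for
oscillatory biosignals. Cauchy ($\gamma = 1$) and Bessel-like
($\beta = 8, \gamma = 1/4$) wavelets are reachable as parameter settings.

Two derived quantities matter:

* **peak frequency** $\omega^* = (\beta/\gamma)^{1/\gamma}$, the analytic
  maximiser of $\Psi$ (about 1.882 rad/sample at the defaults), used to
  label each scale with a centre frequency
  $f_c(s) = \omega^* f_s / (2\pi s)$;
* **normalization** $a_{\beta,\gamma} = 2(e\gamma/\beta)^{\beta/\gamma}$,
  the peak normalization that fixes $\max_\omega \Psi = 2$ — the common
  convention for analytic wavelets. The absolute scale is immaterial
  downstream because images are min–max normalized per beat.

### Scale grid

Scales form a geometric grid with 12 voices per octave,
$s_j = s_{\min} 2^{j/12}$. The limits are set by two rules:

* $s_{\min}$: the smallest scale whose dilated filter has value below
  $10^{-8}$ at the Nyquist frequency $\omega = \pi$ (with the peak at or
  below Nyquist), so no scale wraps energy past the sampling limit;
* $s_{\max}$: the wavelet's time-domain standard deviation (computed
  numerically once per parameter set) must not exceed a quarter of the
  signal length, a boundary-effect guard.

For 784-sample beats at the default parameters this yields 72 scales
spanning roughly 4.7–282 Hz at 1 kHz. The sampling rate enters only as an
axis label: the coefficient matrix of a given sample sequence is the same
whatever `fs` says.

### Transform mechanics

The CWT is evaluated in the frequency domain: the beat is extended by
symmetric reflection (half the signal length on each side), zero-padded to
the next power of two, and each scale's coefficients are the inverse FFT of
the signal spectrum multiplied by the dilated filter, one coefficient per
input sample. Negative-frequency bins carry zero response, so coefficients
are complex analytic. The boundary extension is part of the transform's
definition here; the test suite verifies the FFT path against a direct
time-domain summation (with the wavelet's time samples obtained by
independent quadrature of the definition above) to relative error below
$10^{-6}$ — in practice around $10^{-10}$ — at interior time points, and
offers a `boundary = "periodic"` mode that is exactly covariant under
circular shifts. The scalogram is the entrywise modulus.

## Image rendering

Scalograms become CNN inputs by min–max normalization (a constant matrix
maps to zeros), mapping through an explicit 64-entry jet-like lookup table
with linear interpolation (a grayscale mode replicates the value into all
channels), and bilinear resizing with the align-corners convention, under
which resizing to the source size is exactly the identity. Magnitudes are
mapped linearly by default; a `log_magnitude` switch applies `log1p` first.
Rows are ordered smallest scale (highest frequency) at the top; a config
flag flips them. Because normalization cancels any positive gain, the
rendered image is invariant to amplitude calibration of the recording —
scaling a beat by any $\alpha > 0$ yields a bitwise-identical image.

## Classifier

The built-in network takes 28 × 28 × 3 images through
conv(3×3, 8, pad 1) → pool(2,2) → conv(3×3, 16, pad 1) → pool(2,2) →
conv(3×3, 32, pad 1) → fully-connected → softmax, with feature maps
28×28×8 → 14×14×8 → 14×14×16 → 7×7×16 → 7×7×32. A ReLU follows each
convolution: without a nonlinearity the stack would collapse to a linear
map. Weights are Glorot-uniform initialized from a seed.

Training minimises categorical cross-entropy with one of three optimizers —
SGDM (momentum 0.9), RMSProp (squared-gradient decay 0.9) or Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) — at initial
learning rate $10^{-4}$. The momentum and decay constants are the common
defaults of deep-learning toolchains. A `last_layer_lr_multiplier` scales
the learning rate of the final fully-connected layer's weight and bias
(zero freezes that layer bitwise). Shuffling is seeded; on one thread two
runs with the same configuration produce identical loss curves and
parameters. Gradients of the hand-written backward pass are verified
against central differences in the test suite.

External architectures (pretrained deep models) are not re-implemented;
they enter through a backbone registry whose adapters return opaque
trainable models, with optional transfer of parameter groups from saved
weights. All desk-scale experiments use the built-in CNN.

The default desk-scale training configuration is minibatch 4 for 10
epochs: on a 5-subject × 60-beat cohort this gives the optimizer roughly
700 update steps, enough for the small CNN to converge at the fixed
$10^{-4}$ learning rate while a full pipeline run stays near ten seconds.

## Evaluation

Identification accuracy is `CC/(CC + WC)`. Verification recasts the
dataset one-against-all: the positive class is a fixed number of beats
(default 60) of one subject, the negative class one beat from each of as
many *distinct* other subjects, so the classes are balanced and no
impostor dominates. From the confusion counts the five standard ratios are
reported: accuracy, sensitivity, specificity, FPR, FNR.

ROC curves sweep thresholds at midpoints between consecutive distinct
scores (plus sentinels); a score equal to the threshold counts as a
negative decision, so ties move together. The equal error rate is the FPR
at the `FPR = FNR` crossing, linearly interpolated between the two
bracketing ROC points — the conventional biometric reading, since the
quantity is not otherwise pinned down by the ratios alone. The package
evaluates verification on a held-out half of the one-against-all dataset
(stratified 50:50): training and evaluating on the same 120 items would
conflate fit with generalisation, and the held-out protocol is stated
explicitly here because other conventions exist.

## Synthetic cohort generator

The generator exists so every stage has ground truth. Each subject is a
template of five Gaussian waves — amplitude, centre offset from R, width
per wave — drawn uniformly around physiological defaults (±30% amplitude
and width, ±20% timing; R amplitude 0.8–1.4 mV, so R always dominates),
plus a mean RR interval in 0.7–1.1 s with 30 ms Gaussian jitter. A beat is
the closed-form sum of the five Gaussians, which makes expected values in
tests exact. Recordings place the first R at half a mean RR, add the
remaining beats at jittered RR intervals, and superimpose sinusoidal
baseline wander (default 0.1 mV at 0.3 Hz), sinusoidal mains interference
(0.05 mV at 60 Hz) and white Gaussian noise (default σ = 0.05 mV), all at
`fs` = 1000 Hz — the rate at which the 500/10/600-sample stage parameters
have their intended physical meaning. Exact R indices are returned as
ground truth and coincide with local maxima of the clean signal.

What the generator does **not** emulate: pathological morphologies,
arrhythmic rhythm changes, respiration-modulated RR dynamics, electrode
motion artefacts, or session-to-session drift of a subject's morphology.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that it separates subjects whose beat shapes differ as the
template distribution prescribes — not that it reaches any particular
accuracy on clinical recordings.

## Numerical choices and degenerate inputs

* Min–max normalization maps constant scalograms to all-zero images (tie
  rule) rather than dividing by zero.
* Argmax classification and max-pooling break ties at the lowest index,
  deterministically.
* The detector returns an empty index list (not an error) for records too
  short to contain a beat or with no energy above threshold.
* Beat windows that would cross record boundaries are dropped, never
  padded.
* `epochs = 0` returns the initialized model unchanged with an empty
  metrics table.
* The Morse filter is evaluated on the log scale
  ($\exp(\beta\log\omega - \omega^\gamma)$) to avoid overflow of
  $\omega^{20}$.
* PNG export quantises to 8 bits deterministically, so identical
  configurations give byte-identical images, training logs and reports —
  reproducibility is part of the contract, tested at the byte level.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen so the mathematics is
exercised without large-model training: transform equivalence on length-64
signals across 8 scales; ridge checks on 784-sample tones and chirps;
detector scoring on 70 s recordings (≈ 66 beats) at 10 dB SNR; and the
end-to-end pipeline on 5 subjects × 60 beats with the built-in CNN at
three white-noise levels (σ = 0.05, 0.5, 1.5 mV), where identification
accuracy at the low-noise setting exceeds 90% and degrades monotonically
with noise. Large pretrained backbones, GPU-scale sweeps and clinical
databases are out of scope; the configuration system can express those
experiments, but their reported accuracies are not reproducible at this
scale.

## Known limitations

* The R-peak detector is tuned for adult resting rhythm; refractory and
  window constants are config keys but have only been validated on the
  generator's rhythm range.
* Filter widths are in samples, faithful to the reference parameterisation;
  at sampling rates far from 1 kHz they must be rescaled explicitly.
* The verification protocol evaluates a single positive subject per run;
  multi-positive protocols and score fusion are out of scope.
* The WFDB reader covers the common header + format-16 subset only.
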