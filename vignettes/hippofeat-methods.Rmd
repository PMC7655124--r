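---
title: "Methods: high-frequency iEEG features of the epileptic hippocampus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-frequency iEEG features of the epileptic hippocampus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

hippofeat implements an interictal intracranial-EEG feature pipeline for
distinguishing epileptic (EH) from non-epileptic (NEH) hippocampus across
resting-state and cognitive-task recordings: a multi-band Hilbert-envelope
detector for high-frequency oscillations (HFOs), an amplitude/slope detector
for interictal epileptiform discharges (IEDs), windowed high-frequency
functional connectivity between adjacent contacts, a per-channel feature
battery with paired-t / Mann-Whitney / ROC statistics, and an SVM classifier
evaluated by leave-one-hippocampus-out (LOHO) cross-validation. Because
clinical recordings of this kind are not freely distributable, the package
ships a synthetic cohort generator with ground truth; every stage is
validated against it.

## The HFO detector

Each channel is decomposed into 300 logarithmically spaced analysis bands
between 60 and 800 Hz. Per band, the analytic amplitude envelope is z-scored
against the mean and SD of consecutive 10-s statistical windows and
thresholded at 3 SD; suprathreshold intervals overlapping in time in
adjacent bands are joined into time-frequency blobs; a blob survives only if
its time span exceeds 4 cycles of its peak frequency (strict inequality) and
its lowest member band is not the 60-Hz floor band (which absorbs filtered
spikes). The peak frequency is the center of the band holding the blob's
maximum z, and that maximum is the event's relative amplitude (unitless).
Events are labelled ripple (R, 80 <= f < 250 Hz) or fast ripple
(FR, 250 <= f < 600 Hz) by peak frequency.

**Band realization.** The band centers are log-spaced; each band is realized
as a Gaussian band-pass with spectral sigma `center / band_q`
(constant-Q, default `band_q = 4.5`). A gapless tiling of 300 non-overlapping
bands would make each band about 0.9 % of its center frequency wide; a
filter with a ~1.5 Hz passband rings for roughly a second, so a 35-ms ripple
would be smeared beyond recognition and the 4-cycle rule could never act.
Constant-Q bands ring for a fixed number of cycles at every frequency, which
matches the cycle-based event definition. The default Q was chosen by a
design scan balancing three requirements: duration accuracy of recovered
bursts (favoring wide bands), false-positive control on pure noise
(overlapping narrow bands let short noise excursions chain into blobs that
pass the cycle rule), and frequency resolution. At `band_q = 4.5` the detector
recovers injected bursts with ~1-2 ms median duration error and a
false-positive rate of a few events per 10 min on pure 1/f^2 noise.

**Numerics.** Envelopes are computed from one FFT of the mirror-padded
channel (even-symmetric extension: circular filtering then has no edge
jumps). Each band's spectral support is heterodyned to baseband and
inverse-transformed at a reduced length that divides the padded length, so
the decimated envelope samples coincide with full-rate samples and the cost
per band scales with its bandwidth rather than the recording length. The
per-band loop is compiled (C++/FFTW); an R reference implementation of the
identical computation is kept and the two are asserted equal in the test
suite. Threshold crossings are refined by linear interpolation between
envelope samples; the interval *sample* semantics exposed by
`threshold_bands()` remain exact maximal runs. Statistical windows are
non-overlapping; a final partial window reuses the last complete window's
mean/SD, avoiding inflated SD estimates from truncated windows.

## The IED detector

Channels are scaled by `reference_background / median(|1-35 Hz signal|)`
(default reference 30 uV), then filtered to 20-50 Hz; local extrema become
detections when the peak-to-trough amplitudes to both neighboring extrema
and the corresponding slopes exceed thresholds (defaults 60 uV and
3 uV/ms in scaled units - the source method fixes only the two bands and
the scaling logic, so the thresholds are exposed configuration). Events
closer than a 200-ms refractory gap are reduced by strongest-first
suppression, which unlike chained merging is monotone in the thresholds.
Reported amplitude is measured peak-to-trough on the unfiltered signal
within +/-40 ms (physiological microvolts, matching the scale on which
interictal spike amplitudes are reported).

## Connectivity

Both channels of every adjacent contact pair (consecutive `contact_index`
on one electrode within one hippocampus) are band-passed to the ripple and
fast-ripple ranges and cut into non-overlapping 1-s windows. Per window the
package computes the Pearson correlation and the relative entropy
(Kullback-Leibler divergence) between the two windows' amplitude-sample
histograms over 10 shared equal-width bins spanning the pooled range, with
additive smoothing `1/(n*bins)` keeping the divergence finite. KL divergence
is directed; both directions are retained and their mean is the pair's
symmetric value, so results do not depend on contact ordering. A channel's
connectivity feature is the mean over all windows of all pairs including it.

## Features and statistics

The 14 per-channel features are the R/FR rates (scaled to a 10-min basis),
mean relative amplitudes, dominant frequencies and durations, IED rate and
mean amplitude, and the band-wise correlation and relative entropy. Event
features of a channel without events are missing, not zero - a mean
frequency of zero events is meaningless, and zero-imputation would bias the
group statistics; such channels are dropped from the affected test with
counts recorded. Rest-versus-task changes are tested per label with paired
t-tests; EH-versus-NEH contrasts per condition with Mann-Whitney tests; and
each feature's discriminative value with the ROC AUC (EH positive) for rest
values, task values and rest-minus-task differences, tested against chance
with the Hanley-McNeil closed-form standard error. When several tasks were
performed, task features are first averaged across tasks; statistics are
run at the channel level and repeated per hippocampus (channel medians) to
guard against outlying channel subgroups. No multiple-testing correction is
applied by default (a Benjamini-Hochberg option exists); alpha is 0.05.

## Classification

Features whose grouped-task ROC is significant (in the rest, task and/or
difference scope) form the design matrix. Per LOHO fold, median imputation,
standardization and PCA (all components, for decorrelation) are fitted on
the training rows only; an SVM (linear or RBF) is trained with
inverse-frequency class weights and scores the held-out hippocampus's
channels. Pooled held-out probabilities give the cross-validated ROC; a
hippocampus is called epileptic when its channels' mean probability exceeds
0.5. A per-fold ROC would be undefined here (each fold holds one class), so
pooling is the only well-defined reading of fold-wise ROC averaging.
Hyperparameters are tuned by grid search over both kernels with one
geometric refinement pass around the best cell; ties prefer smaller C, then
the linear kernel.

Two numerical choices deserve note. First, probabilities come from a
Platt-style sigmoid fitted to the training fold's own decision values with
class-balanced weights: the library-internal Platt cross-validation can
invert under weak signal on small folds, and an imbalance-tracking intercept
(each fold is missing one hippocampus's channels) would systematically
depress the held-out class's probabilities. Both pathologies were observed
and are regression-tested: under label permutation on structureless features
the pooled AUC now sits at chance. Second, class weights in the SVM itself
compensate the same fold imbalance.

## The synthetic cohort generator

The generator emulates the statistical structure of interictal hippocampal
SEEG across the four (EH/NEH x rest/task) cells. Its defaults are the
emulated study conditions: per-channel event rates, amplitudes, frequencies
and durations equal to the reported cell means (e.g. EH-rest ripple rate
120.1 per 10 min, ripple amplitude 6.87 z, frequency 176.75 Hz, duration
34.56 ms), 22 + 23 hippocampi with ~6 contacts each, 10-min segments, and a
5-kHz sampling rate.

- **Background**: Gaussian noise with PSD proportional to 1/f^2 above an
  AC-coupling cutoff of 0.5 Hz, SD 50 uV. The cutoff matters: without it the
  overall-SD normalization is dominated by a few near-DC components and the
  in-band content scale varies ~50 % between realizations, which would
  masquerade as connectivity contrast.
- **HFO injection**: Tukey-tapered sinusoidal bursts at Poisson counts.
  Amplitudes are specified in detector units: the target z is converted to
  microvolts using the channel's measured band-envelope mean/SD and the
  burst's filter gain, with a first-order correction for the envelope-SD
  inflation the events themselves cause in event-dense channels. Durations
  are also calibrated: the detector measures the span where the envelope
  exceeds the 3-SD crossing, which truncates burst flanks, so the raw
  injection is lengthened such that the *measured* span equals the drawn
  duration. Both calibrations are numerical, on the actual filter templates.
- **IED injection**: a biphasic derivative-of-Gaussian transient (default
  width 55 ms; wide enough that its ripple-band leakage stays below the
  band's background, sharp enough for strong 20-50 Hz content) plus a smooth
  slow wave, at Poisson counts with the reported amplitude distributions.
- **Coupling**: per hippocampus and band, channel band content is replaced
  by a mixture of a shared band-limited component and the channel's own,
  with mixing chosen so the pairwise correlation equals the `coupling`
  parameter. Replacement bands extend slightly past the analysis bands so
  the measurement filters' transition skirts see coupled content. One band
  scale is used for the whole hippocampus (per-channel normalization jitter
  would otherwise read as relative-entropy contrast).
- **REN contrast**: adjacent contacts receive static alternating band gains
  `exp(+/-kappa)`. A static gain is invisible to the z-scored detector (mean
  and SD scale together) and to within-window Pearson correlation, but
  scales the amplitude distributions relative entropy compares - the
  simplest knob that moves REN without moving the other features. The
  default kappas per cell were calibrated once against the measured
  REN-versus-kappa mapping to land near the reported relative-entropy cell
  means.

What the generator does **not** emulate: task-evoked potentials, seizures,
sleep structure, electrode artifacts, non-stationary background spectra, or
any within-subject correlation beyond the shared-hippocampus coupling.
Passing tests therefore show that the pipeline recovers known structure of
this generative family, not that it certifies performance on clinical
recordings.

## Validation experiments and problem sizes

The packaged experiments (also driven by `scripts/acceptance.R`) use
simulation sizes chosen to give stable estimates at desk scale:

- *Injection recovery*: 20 channels x 2 min at 2 kHz, EH-rest event
  statistics, scored on injections with amplitude target >= 3 z and >= 6
  cycles (~1,000 events). Sensitivity, median frequency error (in units of
  the local band FWHM) and median duration error are reported.
- *False positives*: 3 x 10 min of pure colored noise.
- *Type-I calibration*: 5 null cohorts (all generative cells identical) of
  8+8 hippocampi x 2 contacts x 60 s per condition; >= 500 feature-tests.
  Channels of one hippocampus are correlated by construction, so the
  battery is scored on one contact per hippocampus (and on the
  per-hippocampus medians), where the tests' independence assumptions hold.
- *Permutation null*: 20 grouped label permutations of the null cohort's
  feature matrix.
- *Direction recovery*: 50 cohorts of 1+1 hippocampi x 2 contacts x 30 s;
  the sign of each of the 44 catalogued significant contrasts
  (`direction_catalogue()`) is checked on the seed-pooled means.
- *Classification*: one cohort of 4+4 hippocampi x 2 contacts x 60 s,
  full grid search.

The sampling rate of 2 kHz used in simulations keeps the full 60-800 Hz
analysis range below Nyquist; results are insensitive to the rate because
the detector operates on band envelopes.

## Known limitations

- The detector's peak-frequency estimate inherits a small upward bias on
  steep 1/f backgrounds (higher bands have smaller background SD, tilting
  the z surface); it is well inside one band FWHM.
- Overlapping injections are allowed (realistic) and occasionally merge
  into one detection, mildly inflating measured durations in event-dense
  channels.
- Relative-entropy magnitudes depend on the histogram estimator (bin count,
  smoothing, window length); comparisons are meaningful within a
  configuration, and bin count and symmetrization are recorded in output
  rather than guessed silently.
- With one hippocampus per class fold-wise training is impossible;
  `fit_loho()` requires at least two per class.
- EDF support is read-only and limited to uniform-rate, non-annotated
  files.
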