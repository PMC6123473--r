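---
title: "Detecting typing errors on a gaze keyboard from EEG and eye motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting typing errors on a gaze keyboard from EEG and eye motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

On a dwell-time gaze keyboard a key is committed once the eyes fixate it for
a fixed dwell (0.5 s here). Eye trackers misread intent often enough --
roughly one press in ten -- that typo correction dominates the typing time.
`errpkey` implements an error-detection system (EDS) that flags a press as
erroneous right after it is committed, using two physiological signatures
that need no extra action from the user:

* **EEG.** Perceiving an erroneous action elicits an error-related
  potential: a frontocentral negative deflection near 300 ms after the key
  registration, followed by a centro-parietal positivity near 400 ms.
  Correct presses show a weaker central biphasic response (positive near
  200 ms, negative near 300 ms).
* **Eye motion.** After a correct press the gaze saccades to the next,
  usually distant, key; after a typo it only makes a small corrective
  adjustment near the intended key. The path length of the gaze within the
  post-press window therefore separates the two outcomes.

A press flagged erroneous is deleted automatically, saving the backspace
press that a regular gaze keyboard would need.

## Pipeline

Every stage operates on one session clock with the key-registration instant
as latency 0.

1. **Filtering.** The EEG is band-passed 1--16 Hz with a 4th-order
   Butterworth applied forward and backward (`signal::filtfilt`), i.e.
   zero-phase, because the error-related response lives in low frequencies
   and phase shifts would displace its latencies.
2. **Epoching.** Both streams are cut into half-open windows
   `[-0.2, 0.5)` s around each *letter* registration (backspace presses are
   never epoched). The latency-0 sample is the first sample at or after the
   onset; the epoch takes `floor(0.2 * rate)` samples before it and
   `floor(0.5 * rate)` from it on -- exactly 179 EEG and 21 gaze samples at
   256/30 Hz. This anchored convention removes every off-by-one ambiguity
   and makes epoching commute with sample-aligned stream cropping.
3. **Labelling.** In the error-aware protocol the typist ignores typos and
   retypes, so the intended sentence is a subsequence of the typed one.
   `label_key_events()` walks the intended text with a pointer: a typed
   character matching the pointed one is *correct* (pointer advances),
   anything else is *erroneous* (pointer stays). For
   intended `"my dog is brown"` and typed `"muyb dog ias browqn"` exactly
   the letters u, b, a, q come out erroneous.
4. **Class balancing.** Erroneous presses are ~10x rarer than correct
   ones. SMOTE synthesizes minority instances on segments between minority
   points and their k = 5 nearest minority neighbours, until both classes
   are equal. It runs on the *raw* representations -- the vectorized
   band-passed EEG epoch and the accumulated gaze-distance series -- before
   any label-aware fitting, so the spatial filter benefits from the
   augmentation. One set of interpolation triplets (parent, neighbour, u)
   is shared by both modalities, keeping synthetic EEG/gaze pairs coherent.
5. **EEG features: DSP.** The Discriminant Spatial Pattern filter is the
   channel weighting `w` maximizing the Fisher ratio of the class-mean
   difference energy to the pooled within-class covariance,

   `max_w  [w' (Xbar - Ybar)(Xbar - Ybar)' w] / [w' (Cx + Cy) w]`,

   solved as the leading generalized eigenvector. `Xbar`, `Ybar` are the
   class-average channels-by-time responses over the full window; `Cx`,
   `Cy` average each epoch's spatial covariance after subtracting its class
   mean. The filter is fitted on the full `[-0.2, 0.5)` window but applied
   only post-onset, yielding a 128-sample "virtual sensor" feature vector
   (no decimation by default). One component is extracted; `w` is unit-norm
   with its sign fixed so the time-summed projected class difference is
   non-negative.
6. **Gaze features: Hjorth descriptors** of the accumulated-distance
   series: activity (population variance), mobility (root variance ratio
   of first derivative to signal), complexity (mobility of the derivative
   over mobility of the signal). Derivatives are forward differences
   scaled by the sampling rate. They summarize path length, speed changes
   and irregularity in three numbers.
7. **Classification.** Features are z-scored with training-set constants
   and fed to linear SVMs (cost 1): one per modality, one on the
   concatenated 128 + 3 features (*early fusion*), and a *late fusion*
   rule that lets the modality with the larger absolute normalized score
   decide. Scores are raw decision values divided by the maximum absolute
   training decision value, so training scores span [-1, 1]; the decision
   threshold theta moves within that range, with scores at or below theta
   classified erroneous. All fitting -- SMOTE, DSP, normalization, SVMs --
   sees training data only.

## Tuning by expected utility

Accuracy is misleading at a 10% error rate, so operating points are scored
by a utility ratio. The package adopts an expected-progress renewal model:
every selection costs the same nominal time; without assistance an
erroneous press must be undone by a backspace, giving expected net progress
`(1 - p)/(1 + p)` per selection; with the detector, flagged errors cost
nothing extra, missed errors cost a backspace and false alarms void a
correct press. The ratio of the two utilities is

```
gain(p, se, sp) = sp * (1 + p) / (1 + p * (1 - se))
```

with the identities `gain(se = 0, sp = 1) = 1` (detector never intervenes)
and `gain(p, 1, 1) = 1 + p` as the ceiling. The gain is strictly increasing
in both rates, and near realistic operating points its slope in
specificity exceeds that in sensitivity: false alarms are the expensive
failure mode, which is why sweeping the threshold toward its negative end
(high specificity) raises the gain. This closed form is the package's own
model of the trade-off, stated here rather than borrowed; absolute gains
from other utility definitions will differ, the ordering of operating
points is what matters.

`threshold_sweep()` repeats Monte-Carlo splits, fits once per split, and
evaluates the whole theta grid (step 0.05, endpoints included) on the fixed
test scores, reporting the gain-maximizing threshold at the dataset's
empirical error rate.

## Evaluation harnesses

* `monte_carlo_cv()` repeats (100 times by default) a ratio-preserving
  split: 10 erroneous epochs plus `round(10 (1 - p) / p)` correct ones form
  the test set, the rest train.
* `loso_cv()` holds out one sentence at a time, and
  `loso_timing()` turns its per-press predictions into typing-time totals:
  `T1 = t1 + (d - k1) b_avg + k2 l_avg` for the error-aware keyboard
  (`d` = edit distance typed vs intended, `k1` = detected errors, `k2` =
  false alarms) and `T2 = t2 + d_control b_avg` for the regular keyboard,
  where each task's edit distance comes from its own recording
  (`d_control` is usually 0, since the control protocol requires a correct
  final sentence). `b_avg` and `l_avg` are estimated as the mean
  inter-press interval ending in a backspace resp. letter registration in
  the control recordings.
* `direction_subaverages()` reproduces the ocular-artefact control
  analysis: k-means (k = 4) on the aggregate gaze displacement of correct
  presses, then per-direction sub-averages of the EEG and eye-speed
  traces. Genuinely cortical responses show no polarity inversion between
  opposite movement directions.

## The synthetic-session generator

Real recordings of this kind are not bundled with the package; a seeded
generator (`sim_spec()`, `simulate_session()`) produces sessions with the
statistical structure the pipeline assumes, so every stage is testable end
to end:

* **Typing.** Each press of an intended character fails independently with
  probability `p = 0.1` (the realistic mistype rate for fast dwell
  settings); wrong keys are drawn uniformly from the 8-neighbourhood of
  the target on a qwerty layout, emulating tracker misinterpretation of
  adjacent keys. Inter-press overheads beyond the 0.5 s dwell are
  log-normal, with backspace slower than letters
  (medians 0.6 s vs 0.35 s), because reaching the corner backspace key is
  a longer saccade.
* **EEG.** Spatially mixed 1/f noise (exponent 1, per-channel RMS 10 uV,
  random orthogonal mixing) plus deterministic class-specific templates at
  each letter onset: sums of Gaussian bumps with fixed frontocentral /
  centro-parietal / central spatial profiles over an approximate 10-10
  montage, peak-normalized and scaled by `snr` times the noise RMS. The
  default `snr = 10` is a deliberately well-separated regime that makes
  end-to-end recovery checks sharp; `snr = 0` is the null. Single-trial
  human ErrPs sit far below this default, so synthetic
  sensitivity/specificity must not be read as forecasts for real data --
  only the pipeline's mechanics, monotonicities and identities transfer.
* **Gaze.** Fixation at each pressed key through its dwell, then a
  saccade (1500 px/s) toward the next pressed key; after a typo that next
  key is the nearby intended one, so the adjustment is small. Per-fixation
  offsets (SD 8 px) and per-sample jitter (SD 4 px) are superimposed.
  `gaze_informative = FALSE` replaces all of it with centre-screen jitter,
  a null control for the gaze modality.

What the generator does *not* emulate: eye blinks and muscle artefacts,
latency/amplitude variability of the responses, drifting electrode
impedances, tracker dropouts, and user adaptation over a session. Passing
tests therefore certify the algorithmic chain, not clinical performance.

## Numerical choices and degenerate inputs

* Generalized eigenproblem: the noise pool gets a Tikhonov ridge
  `eps = 1e-6 * trace / channels` before symmetric whitening; a
  single-channel input returns the scalar filter 1.
* Hjorth degeneracies: a constant series has activity 0 and undefined
  mobility/complexity; a constant-derivative ramp has mobility 0 and
  undefined complexity. Undefined entries become zeros with a `degenerate`
  flag before classification, so feature matrices stay finite.
* Zero-variance features get unit SD in the z-scoring (their weight is
  then immaterial); an SVM scale constant of 0 falls back to 1.
* SMOTE with a singleton minority duplicates it (with a warning); k is
  reduced to n - 1 for minorities smaller than k + 1.
* Score orientation is enforced after fitting (positive = correct), since
  SVM sign conventions depend on label order; late-fusion ties in
  |score| go to EEG, the primary modality (a measure-zero event).
* Gaze gaps of at most 2 consecutive missing samples are linearly
  interpolated; longer gaps drop the epoch with a warning.
* Monte-Carlo repetitions draw per-repetition seeds from one master seed,
  so runs are reproducible and fits are bit-identical under refitting.

## Problem sizes used by the tests

The bundled checks run the full study geometry -- 20 sentences, 64
channels, 100 Monte-Carlo repetitions, leave-one-sentence-out timing -- for
the end-to-end recovery checks, and a 6-sentence, 8-channel fixture for
unit-level properties; both complete on a laptop-class single core in
minutes. The same quantities (error chance, late-fusion
sensitivity/specificity, best-threshold utility gain, typing-time gain)
are recomputed from scratch by `scripts/acceptance.R`.

## Limitations

The utility model is a stated surrogate; absolute gains depend on the
utility definition. Only one discriminant component is extracted; no
artefact removal is attempted (the direction-conditioned diagnostic argues
it is unnecessary at the electrodes of interest, it does not make it so for
every montage). The generator's wrong-key model is purely spatial and its
templates are deterministic per class. None of the synthetic performance
numbers are comparable to human-subject results; reproducing those requires
the original recordings.
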