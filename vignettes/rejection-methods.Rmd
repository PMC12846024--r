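---
title: "Reject-option motion classification from tactile forearm signals: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reject-option motion classification from tactile forearm signals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A prosthetic-hand controller driven by forearm surface sensing must decide,
for every detected muscle-activity transient, which of a small repertoire of
trained wrist–hand motions the user intended — and, just as importantly,
when to say nothing. Unintended activations come from three sources:
*ambiguous* executions of trained motions (weak or intermediate activations
that the classifier gets wrong), *unknown* motions never present in
training (here: wrist radial and ulnar deviation), and *non-target* body
movements (here: elbow flexion). A classifier with a *reject option* may
withhold its output instead of emitting a class, trading responsiveness for
safety.

`tactrej` implements this pipeline for two-channel piezoelectric (PVDF)
tactile recordings over the flexor carpi radialis (FCR) and extensor carpi
radialis longus (ECRL), compares three rejection mechanisms under identical
conditions, and — because the underlying human recordings are not publicly
deposited — ships a seeded simulator of the experimental protocol so that
the full pipeline is testable and reproducible end to end.

## Signal path

1. **Conditioning** (`apply_digital_filters`): a first-order 0.5 Hz
   Butterworth high-pass (bilinear transform) removes offset and baseline
   drift, then a second-order notch biquad at 50 Hz with quality factor
   Q = 25 removes mains interference. Both are applied causally
   (forward-only), because the target system is an online controller that
   cannot look ahead; tests of attenuation therefore measure steady-state
   amplitudes against the transfer-function magnitude computed from the
   coefficients, not zero-phase responses.
2. **Downsampling** (`downsample_signal`): block means of 10 consecutive
   samples, 1000 Hz → 100 Hz; a trailing partial block is truncated.
3. **Detection** (`estimate_thresholds`, `detect_onsets`): per-channel
   thresholds are calibrated on a motion-free resting baseline as
   `theta_i = mean(|x_i|) + k sd(|x_i|)` with `k = 5` by default. The
   threshold *formula* is a package choice (a conventional onset rule);
   only the use of resting segments for calibration is inherited from the
   experimental design. An event fires at the first 100 Hz sample where
   any channel exceeds its threshold in absolute value; detection is then
   suppressed for a 1 s refractory window (motions complete within about
   1 s, cues arrive every 2 s). One rule serves all motion categories —
   the controller cannot know the category in advance.
4. **Features** (`extract_feature`): the 200 ms window centered on the
   detection moment — samples `nd − 10 … nd + 9`, i.e. 20 samples per
   channel at 100 Hz — concatenated channel 1 first into a 40-dimensional
   vector. No amplitude normalization is applied by default: the raw
   voltage scale carries class information (flexion-dominant motions load
   FCR, extension-dominant load ECRL).

Detection runs at 100 Hz rather than 1000 Hz because the feature window is
indexed on the 100 Hz series; applying the threshold rule after
downsampling keeps one index space throughout.

## Classifiers and rejection mechanisms

All backbones are trained on the identical stratified 50/50 split of
target-category trials (unknown and non-target trials never enter
training), with hyperparameters fixed globally — no session- or
class-specific tuning:

* **Baseline OvR SVM** (`train_ovr_svm`): six one-vs-rest RBF SVMs,
  C = 16, γ = 0.0625, emitting decision values `f_1 … f_6`; prediction is
  the argmax, ties to the lowest class index, and no rejection ever.
* **OCSVM** (`train_ocsvm`): a one-class SVM on the pooled target training
  features, ν = 0.1, RBF width from the scale heuristic
  γ = 1/(d · Var(z)) with d = 40 and Var(z) the variance of the flattened
  training matrix. An input is accepted only when its signed score
  Δ(z) > 0 (strictly); the emitted class is the baseline SVM's.
* **BPNN-Entropy** (`train_bpnn`, `decide_bpnn_entropy`): a 40–25–6
  multilayer perceptron, tanh hidden layer and softmax output, trained
  full-batch for 1000 epochs with Adam (α = 0.001, β₁ = 0.9, β₂ = 0.999,
  ε = 1e−8) to minimize multiclass cross-entropy. Initial weights are
  drawn from U[0, 1). That initialization is asymmetric and unusual; it is
  implemented literally as the reference recipe, with
  `bpnn_config(init = "symmetric")` available as a switch. An input is
  rejected when the Shannon entropy of the softmax output exceeds
  τ = 0.7; otherwise the argmax class is emitted. The entropy logarithm is
  natural: against the six-class maximum ln 6 ≈ 1.79 a threshold of 0.7
  sits plausibly mid-scale, whereas in bits the maximum is 2.58 and 0.7
  would be aggressive; the base is configurable.
* **OvR-RO** (`decide_ovr_ro`): the parameter-free sign-consistency check.
  Count the strictly positive entries of `(f_1, …, f_6)`; accept exactly
  when the count is 1, emitting that class, otherwise reject. A decision
  value of exactly 0 counts as non-positive. The function signature takes
  nothing but the decision values (and optional class labels) — the
  parameter-freeness is structural, and a test enforces it.

Because a single strictly positive `f_k` is necessarily the maximum, an
accepted OvR-RO class always coincides with the baseline prediction; this
composition property is property-tested on random decision vectors.

`e1071` (libsvm) provides both SVM solvers. libsvm orients each binary
decision function toward whichever label appears first in the training
data, so the package normalizes the sign of every `f_k` (detected from the
decision-value column name) to mean "class k supported". The MLP is
implemented in the package directly, since the training recipe —
optimizer, initialization, schedule — is part of the method under study.

## Evaluation framework

Per session and mechanism (`evaluate_session`):

* **Accuracy** on accepted target trials: correct accepted / accepted;
  undefined when everything was rejected.
* **Rejection rate** per category (target, ambiguous, unknown,
  non-target): rejected / total in category.
* **Rejection precision** for ambiguous motions: ambiguous among rejected
  target trials / rejected target trials; undefined at zero rejections.

*Ambiguous* is not a recorded category: it is labeled retrospectively as
the target trials misclassified by the corresponding base classifier on a
no-rejection pass — the baseline SVM's errors for the SVM-based
mechanisms, the MLP's own errors for the entropy mechanism. Undefined
rates propagate as `NA` and are never coerced to 0 or 1; in paired
comparisons such sessions are dropped pairwise.

Study-level statistics (`paired_tests`) are two-sided paired t-tests over
session-wise values with Bonferroni correction `α_adj = 0.05/N_comp`:
`N_comp = 6` for accuracy (four systems) and `N_comp = 3` for rejection
metrics (three mechanisms — the baseline has no reject option). Degenerate
pairs with zero-variance differences resolve analytically to t = 0, p = 1
(no difference) rather than erroring. `select_operating_point` implements
ROC-style operating-point selection — the candidate minimizing the
Euclidean distance to the ideal `(RR_target, RR_unintended) = (0, 1)`,
ties to the smaller parameter — as a utility; the shipped thresholds are
treated as fixed constants of the method.

## The simulator

`generate_session` emulates the experimental protocol: a ≥ 10 s motion-free
baseline, then cued trials every 2 s in seeded random interleaved order, 50
repetitions of each motion — six target motions (300 target trials), two
unknown motions (100 trials) and one non-target movement (50 trials) when a
session includes those protocols. `generate_study` derives per-session
sub-seeds and applies per-session protocol overrides; the canonical layout
(`study_overrides()`) gives 12 sessions of which 7 include the
unknown-motion protocol and 4 the non-target protocol.

Each motion's deterministic signature is a per-channel damped sinusoid
`A e^{−λt} sin(2πft)` — a biphasic transient, f = 2.5 Hz, λ = 3 s⁻¹,
duration 1 s for wrist–hand motions; 1.2 Hz, λ = 2.5 s⁻¹, 1.4 s for elbow
flexion — with class-specific two-channel amplitude/polarity patterns:
flexion-type motions load the FCR channel (e.g. palmar flexion 1.4 V FCR
vs 0.2 V ECRL), extension-type motions the ECRL channel, rotations both
channels with opposite polarity, and the unknown wrist deviations
intermediate both-channel signatures. Amplitudes (0.2–1.4 V) sit well
inside the ±5 V acquisition range, to which the simulator also hard-clips.

Stochastic components, all derived from one seed:

* additive white Gaussian noise (SD 0.1 V),
* slow sinusoidal baseline drift (0.1 V at 0.2 Hz, below the high-pass
  edge) and 50 Hz mains interference (0.05 V),
* per-trial multiplicative amplitude jitter (SD 0.2, truncated to
  [0.3, 2]) and onset-latency jitter (SD 0.03 s), emulating natural
  execution variability,
* an *ambiguous fraction* (default 0.15) of target trials replaced by a
  convex blend of the scheduled and one other target template (weight
  uniform in [0.35, 0.65]); an alternative attenuation mode scales a
  trial to 20–50 % amplitude instead.

### Difficulty calibration

The simulator's purpose is to reproduce the *confusability structure* on
which the comparative conclusions rest, not any absolute performance
number. Two regimes fail that purpose: with very low trial-to-trial
variability the converged MLP is uncertain on exactly the blended trials
and nothing else, making entropy rejection unrealistically surgical; with
very high variability the sign-consistency check rejects large numbers of
cleanly executed trials. The shipped defaults (noise SD 0.1 V, amplitude
jitter SD 0.2) were selected from a small grid as the regime in which the
expected qualitative behavior — every rejection mechanism improving
accepted-trial accuracy, OvR-RO withholding the fewest target trials while
being the most selective toward genuinely misclassified ones — holds
consistently across independent seeds, with baseline accuracy in the
high-80s (the human data averaged 84.5 %). These are package constants;
per-study deviations belong in `session_spec()` arguments, not in edits to
the defaults.

## Numerical choices and degenerate inputs

* Argmax ties (baseline and entropy mechanisms) resolve to the lowest
  class index; documented and tested.
* `f_k = 0` is non-positive for OvR-RO; `Δ = 0` rejects for OCSVM (both
  strict inequalities as specified).
* All-zero resting channels would give a zero threshold; a floor of
  1e−6 V keeps `theta_i > 0`.
* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e−300 before the log and errors on a non-finite loss.
* Detection events whose 20-sample window would cross a signal edge are
  discarded.
* Probability vectors passed to the entropy must sum to 1 within 1e−6;
  zero components contribute zero entropy.
* Recording, feature, decision and report tables are plain columnar text
  with a `# config_hash:` header line (MD5 of the deparsed configuration)
  so every output traces to its exact settings.

## Problem sizes

The shipped study runs 12 sessions × 50 trials/motion (the full protocol:
450 trials and about 15 minutes of signal per full session at 1000 Hz),
which completes in a few minutes on one core; unit tests use reduced
sessions (6–10 trials per motion, 4 s baselines) chosen so each test stays
in the seconds range while still exercising every code path. The MLP's
1000-epoch full-batch schedule on 150 × 40 training matrices is fast in
plain matrix arithmetic; no compiled code is needed.

## What passing tests do and do not show

The simulator demonstrates that the pipeline's comparative logic behaves
as designed under a controlled, known-ground-truth world with graded
ambiguity. It does **not** establish performance on real PVDF recordings:
real signals carry session-to-session nonstationarity (electrode
placement, posture), fatigue and perspiration effects, and richer
waveform families than damped sinusoids — none of which are modeled
(deliberately: biomechanical realism is out of scope).

One known divergence deserves emphasis: in the human study the entropy
mechanism was the strongest rejector of unknown motions, while here the
one-class SVM dominates that category and the converged MLP often maps
out-of-distribution inputs to confident (low-entropy) predictions — the
well-known overconfident-extrapolation behavior of softmax networks, which
the cleaner synthetic world exposes more starkly than noisy human data
did. The package's study-level assertions are therefore restricted to the
orderings that are structural consequences of the mechanisms' designs:
accuracy gains from rejection, OvR-RO's low target rejection rate, and
OvR-RO's high ambiguous-rejection precision.

## Limitations

* Templates are qualitative emulations; no quantitative waveform
  parameters exist for the original sensors, so all amplitudes, decay
  rates and latencies are generator parameters.
* The threshold formula (mean + 5 SD of |rest|) and the 50/50 split scheme
  are package choices where the experimental description is silent; both
  are configurable.
* Entropy-based rejection quality depends on calibration of the
  probabilistic network; conclusions about it transfer to real data only
  qualitatively (see above).
* The evaluation's ROC calibration utility operates on whatever pooled
  decision sets the caller provides; the original study's choice of
  calibration data is not documented and is left to the user.
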