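---
title: "Methods: prespeech semantic-category decoding and cross-temporal coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prespeech semantic-category decoding and cross-temporal coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prespeech)
```

## The problem

During overt word reading, the semantic category of the word (here: body
vs. nonbody concepts) is represented in cortical activity *before* speech
begins. The analysis this package implements asks two questions of
trial-structured intracranial recordings:

1. **Where and when** can category be decoded from high-gamma (70–170 Hz)
   amplitude in the 0–500 ms prespeech window, per (hemisphere, Brodmann
   area)?
2. **How do regions relate over time**: does activity in an early-decoding
   region predict activity in a late-decoding region, trial by trial?

Clinical intracranial recordings cannot be redistributed, so the package
ships a synthetic-data module that emulates the recording conditions with
*known planted ground truth*, making every stage testable: calibration can
be checked on null data and recovery on planted effects.

## The synthetic signal model

Each trial × channel signal is

$$x(t) = \underbrace{n_{1/f}(t)}_{\text{pink background}}
       + \underbrace{\textstyle\sum_k A_k \sin(2\pi f_k t + \phi)}_{\text{line noise, } f_k \in \{60,120,180\}\,\text{Hz}}
       + \underbrace{A_c \, g(t)\, c(t)}_{\text{high-gamma carrier}}$$

where $c(t)$ is a *unit-envelope* frequency-modulated tone whose
instantaneous frequency wanders smoothly inside 75–165 Hz, and $g(t)$ is
the envelope gain:

$$g = g_0 + \varepsilon_{\text{area}} + \varepsilon_{\text{channel}}
      + \delta \cdot \tfrac{1}{2}\,\mathrm{sign}(\text{category})\cdot
        \mathbf{1}[\text{region} \times \text{time window}]
      + \textstyle\sum_j b_j z_j \cdot \mathbf{1}[\cdot]$$

Design choices worth knowing:

* **Category effects are multiplicative envelope-gain modulations** of the
  band-limited carrier, so they are invisible outside 70–170 Hz — matching
  the premise that decoding rides on high-gamma amplitude.
* **Constant-envelope carrier.** Because the FM carrier has unit Hilbert
  envelope by construction, the planted gain *is* the envelope, and planted
  effect sizes and coupling strengths are exact by construction rather than
  approximate. Effect size `effect_size_d` is calibrated against the total
  per-channel gain SD $\sqrt{\sigma^2_{\text{area}} + \sigma^2_{\text{chan}}}$
  (defaults 0.25 and 0.10).
* **Gain noise has an area-level component** shared by channels within a
  region (per trial), plus independent channel jitter. This mirrors regional
  population co-modulation and has a practical consequence: within one
  subject, pooling channels cannot average the area-level noise away, while
  pooling *across subjects* can. Group-level decoding therefore gains power
  with cohort size, exactly as in the real design.
* **Couplings are word-locked.** The latent $z$ of a planted coupling is
  drawn per word and shared across subjects (words are the trial-alignment
  unit). Symmetric loadings $a = b = s\sqrt{\rho/(1-\rho)}$, with
  $s^2 = \sigma^2_{\text{area}} + \sigma^2_{\text{chan}}/n_{\text{chan}}$ and
  $\rho = \sqrt{R^2_{\text{target}}}$, give the target simple-regression
  $R^2$ between the two area-mean window gains for a single subject.
  When several subjects are averaged the realized $R^2$ *rises* (independent
  noise shrinks, the word-locked signal does not); single-subject runs are
  the calibrated condition.
* **Speech onsets** are drawn from a normal distribution with mean 881 ms
  and SD 228 ms, truncated below at 500 ms (inverse-CDF sampling), matching
  the behavioral statistics; the 0–500 ms analysis span therefore always
  precedes speech.
* **Artifacts**: interictal-discharge-like transients are biphasic — a
  flat-topped main phase over 70 % of the duration and an opposite-polarity
  rebound — with peak amplitude expressed as a multiple of the channel's
  robust background level.
* The default sampling rate is 1000 Hz (Nyquist-safe for 170 Hz) rather
  than the 2 kHz clinical rate, for speed; 2 kHz is available via
  `sample_rate`. The default epoch is −1000…+3000 ms around word onset.

What the generator does **not** emulate: articulation and post-onset speech
activity, realistic epileptiform morphology beyond the 2×/20–200 ms
detection rule, within-trial gain dynamics (the per-trial gain is constant
over the epoch, so window features are strongly correlated across windows —
real data decorrelates faster), volume conduction, and non-stationary line
noise. Passing tests therefore demonstrate correctness of the *procedures*,
not performance claims about clinical recordings.

## Preprocessing

Fixed stage order: common average reference (within subject, over good
channels) → notch filtering at 60/120/180 Hz → impedance-based channel
exclusion → discharge trial rejection → 70–170 Hz envelope → baseline
normalization.

* **Zero-phase filtering in the frequency domain.** Filters are designed as
  Butterworth prototypes (`signal::butter`; order 2 band-stops of ±2 Hz for
  the notches, an order-4 band-pass for high gamma) and applied as the
  squared magnitude response $|H(\omega)|^2$ on the FFT of each series —
  the transfer function realized by forward–backward filtering, with
  exactly zero phase. No latency shift can bias the 50 ms feature grid.
* **Impedance boundary**: the exclusion criterion is *strictly* above
  10 kΩ; a channel at exactly 10 kΩ is retained.
* **Discharge detection.** The background level of a channel is
  1.4826 × MAD of its raw signal over the −300…0 ms baselines pooled across
  trials — robust, so the spikes being detected do not inflate their own
  threshold. The rectified trace is smoothed with a 10 ms moving average
  and sub-threshold gaps shorter than 5 ms are bridged (morphological
  closing); a trial is flagged when any channel shows an excursion above
  2 × background lasting 20–200 ms. Smoothing and gap-closing exist because
  a biphasic transient crosses zero: without them its excursion fragments
  into sub-20 ms runs and the duration rule can never fire reliably.
* **Envelope backends.** Default: band-pass + analytic-signal magnitude
  (FFT-based Hilbert transform). Alternative: a Morlet wavelet filterbank
  (7 cycles, 10 Hz spacing) whose kernels are jointly normalized so the
  summed response is exactly 1 wherever the bank has appreciable gain — an
  in-band unit tone yields envelope 1 under both backends.
* **Baseline normalization** is a z-score per channel against the mean and
  SD of its −300…0 ms baseline samples pooled across non-rejected trials.
  Pooling (rather than per-trial moments) prevents single-trial baselines
  of near-zero variance from exploding the transform; a per-trial mode
  exists behind `baseline_per_trial`. Channels with degenerate baseline SD
  (< 1e−12) are flagged bad and the division guarded.

## Features and channel selection

Ten 100 ms windows advanced in 50 ms steps cover 0–500 ms; window $k$ is
the half-open interval $[50(k{-}1), 50(k{-}1){+}100)$ ms and is labeled by
its **center** $50k$ ms. Center labeling reconciles "windows covering
0–500 ms" with peak times reported on a 50–500 ms grid; start labeling is
available via `window_grid("start")`.

To avoid information leakage, 70 % of the words are allocated to feature
selection (per category: $\lfloor 0.7 n_c \rfloor$, remainder assigned by
largest fractional part with seeded tie-break — 34 balanced trials split
24/10). Each channel is then evaluated independently with fivefold
stratified cross-validated linear max-margin classification of its 10
window features (features standardized within each training fold, unit
margin penalty — the classifier family is fixed but hyperparameters were
unstated, so the simplest regularized choice is used), and retained iff
mean fold accuracy is **strictly** above 0.50. Under pure noise this rule
retains roughly half the channels — that is its documented behavior, not a
bug; the group-level permutation statistics downstream account for it.

## Group decoding

Retained channels are pooled across subjects within each (hemisphere, BA).
Because all subjects share the 34-word list, rows are word-aligned; a word
rejected in *any* contributing subject is dropped (intersection policy).
The default trial policy cross-validates over **all** non-rejected aligned
words — 30 % of 34 trials cannot support fivefold stratified CV per
category — while a strict mode restricts decoding to the held-out words
(`trial_policy = "evaluation"`). Neither mode is asserted to be the
original study's choice; the default is documented here.

The classifier menu is linear max-margin (default; implemented in compiled
code as dual coordinate descent on the hinge-loss SVM dual, C = 1,
regularized intercept, deterministic sweeps — cross-checked against
`e1071::svm` in the tests), linear discriminant analysis (`MASS::lda`),
and a randomized-tree ensemble (`randomForest`, 500 trees, seeded).
Accuracy ties across windows break to the earliest window.

## Permutation statistics

* **Label-shuffle null**: each of $B$ draws permutes the category labels
  and re-runs the identical stratified-fold/classifier procedure over all
  windows (2,000 draws in the full analysis; a reduced 500-draw mode is
  used for desk-scale runs). Empirical p values use the add-one formula
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, which cannot return
  zero under finite permutations.
* **FDR**: Benjamini–Hochberg step-up at $\alpha = 0.05$ across the 10
  windows within each region (`stats::p.adjust`; the test suite verifies
  exact agreement with a brute-force step-up oracle).
* **Time-shuffle threshold**: each draw permutes the window-index
  assignment *independently per trial* (consistently across channels) and
  recomputes the curve with a fresh fold draw; the threshold is the 95th
  percentile of all pooled null accuracies for the region. This is a
  temporal-specificity test: a window passes only if its accuracy cannot
  be reproduced once window identities are scrambled within trials. The
  per-trial scheme was chosen over a single trial-consistent permutation
  because the latter merely reshuffles the observed curve, so its pooled
  percentile converges onto the observed peak itself and even strong
  planted effects fail it about half the time; the per-trial scheme shows
  ~5 % exceedance on temporally unstructured data and reliably passes
  planted effects (both properties are asserted in the tests). The number
  of time-shuffle draws (1,000 by default, 200 at desk scale) was an open
  parameter.
* **Peaks and troughs**: the peak is the maximum accuracy among windows
  passing *both* criteria (upper-tail FDR and the time threshold); troughs
  mirror this with lower-tail p values and the reflected threshold
  $1 - \text{thr}$. Earliest window wins ties; no qualifying window means
  no peak.

## Cross-temporal coupling

Regions with significant peaks are labeled early (≤ 250 ms) or late
(> 250 ms). For an early→late pair, the **region timecourse** is the
channel-mean of the normalized window features per trial (a single
predictor — with ~34 trials a multichannel regressor would not be
identifiable), computed with all trials pooled and separately per category.
Cell $(i,j)$ of the coupling map is the OLS coefficient of determination
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ of target window $j$ on source
window $i$ across trials — equal to the squared Pearson correlation, so
the map is symmetric under role exchange; directionality lives in the
source/target time ordering, not in the regression. Zero-variance
predictors yield $R^2 = 0$ with a flag rather than an error.

Significance: 1,000 permutations (500 at desk scale) of the trial
correspondence between source and target (rows of the target permuted —
the natural exchangeable null that preserves both margins), add-one
upper-tail p per cell, BH-FDR across the 100 cells of each map
(per-map, not across maps). Clusters are found by seed-and-grow: seeds
need $q \le 0.05$ and $R^2 \ge 0.20$, growth accretes 8-connected cells
with $q \le 0.05$ and $R^2 \ge 0.10$, grown sets sharing cells merge, and
clusters under 5 cells are dropped. The implementation is verified against
an exhaustive connected-components oracle on random grids.

## Problem sizes and numerical choices

Test-suite and calibration runs use deliberately small problem sizes,
chosen once as the package's desk-scale study conditions:

* a short epoch of −400…+700 ms — fully covering the −300…0 ms baseline
  and the 0…550 ms feature span — instead of the full −1000…+3000 ms;
* calibration runs: one subject, 4 regions × 10 channels, 34 trials,
  500 label / 200 time permutations, 20 replicates;
* effect-recovery runs: an 8-subject cohort (2 regions × 6 channels,
  artifact-free), because the recovery question concerns the *group*
  analysis: with a single subject the shared area-level gain noise caps
  group accuracy near 0.78 regardless of channel count, and d = 1.5 cannot
  reach 90 % detection power at 34 trials; pooling subjects restores it.
  Artifacts are disabled there because the word-alignment intersection
  policy would otherwise discard about a third of the rows across eight
  subjects, which tests artifact handling rather than localization;
* coupling-recovery runs: one subject with 200 trials (the calibrated
  condition for the planted-R² budget).

Other numerical details: the SVM dual coordinate descent stops at
projected-gradient tolerance 1e−4 or 300 epochs (tiny standardized
problems converge far earlier; predictions agree with the reference SVM);
stratified folds deal shuffled class members round-robin so fold class
counts differ by at most one; single-class training folds fall back to
majority-class prediction; a global seed fans out to per-stage seeds via a
counter-based hash so any stage can be re-run in isolation; all seeds stay
below 2³¹.

## Known limitations

* Synthetic trials have epoch-constant gain noise, so features correlate
  strongly across windows; real high-gamma decorrelates faster. Null
  calibration is unaffected (the permutation nulls respect the structure),
  but the effective number of independent windows is smaller than 10.
* Word-locked couplings grow stronger under cross-subject averaging;
  planted `target_r2` is calibrated for single-subject timecourses.
* The channel-selection rule admits ~half of all noise channels by design;
  significance therefore rests entirely on the permutation machinery, not
  on selection.
* The default trial policy reuses selection trials inside the group CV
  (as discussed above); the time-shuffle criterion is indifferent to this
  bias because it affects all windows equally, and the null-calibration
  acceptance run bounds the combined false-positive rate.
* `compare_classifiers` treats (fold × window) accuracies as paired
  samples; folds are not independent, so its signed-rank p values are
  descriptive, mirroring the original comparison's role (no significant
  differences expected).
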