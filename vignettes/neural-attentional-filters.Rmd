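---
title: "Quantifying neural attentional filters in dichotic listening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neural attentional filters in dichotic listening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichotr)
```

## The problem

When two talkers speak at once, a listener's brain must filter one stream
in and the other out. Two neurophysiological signatures of this filtering
are widely studied in EEG work on spatial auditory attention:

* **Alpha-power lateralization.** 8--12 Hz oscillatory power over auditory
  (and parietal) cortex rises in the hemisphere ipsilateral to the attended
  ear and falls contralaterally. The single-trial *alpha lateralization
  index* (ALI) contrasts the two:
  ALI = (power_ipsi - power_contra) / (power_ipsi + power_contra).
* **Selective neural speech tracking.** Slow (1--8 Hz) cortical activity
  tracks the temporal envelope of speech, and more strongly so for an
  attended than an ignored talker. Backward ("decoding") models reconstruct
  the onset envelope of each talker from the multichannel neural response;
  the *neural tracking index* contrasts the reconstruction accuracies:
  NTI = (r_attended - r_ignored) / (r_attended + r_ignored).

`dichotr` implements both measures, their temporal alignment on a common
percent-of-sentence axis with a permutation-surrogate cross-correlation,
and the state/trait mixed-effects models that link the neural filters to
single-trial listening behaviour — all exercised end to end on a synthetic
dichotic-listening dataset with known ground truth, so that every stage is
testable by parameter recovery.

## The synthetic dichotic-listening experiment

The generator emulates a 2 x 2 cued dichotic task: a spatial cue (which ear
will be probed: informative vs. uninformative) crossed with a semantic cue
(specific vs. general), 60 trials per cell per subject (240 total). Each
trial presents one five-word sentence per ear; the probed sentence's final
word is the task target.

**Stimuli.** Each "sentence" is an onset envelope: five non-negative
Hann-shaped word pulses at quasi-regular 350--550 ms spacing, spanning a
duration drawn uniformly from 2183--2963 ms. Word-pulse widths vary per
word (120--200 ms): with a fixed width, the two streams' temporally aligned
final words would have *identical* envelope shapes, and any contrast of
reconstruction accuracies would be degenerate in the final-word window.
The two sentences of a pair are aligned at their common offset (the
final-word region), so the onset asynchrony — drawn uniformly from 0 to
580 ms, either stream leading — equals the duration difference, as in a
paradigm where pairs are aligned on the task-relevant final word. We align
at the sentence offset rather than at the final-pulse onset so that the
drawn asynchrony is exact on the sample grid even though word lengths vary.

**Source signals.** Ten parcels (five per hemisphere) of a bilateral
auditory region of interest are simulated at 250 Hz over -0.5--6.5 s
relative to cue onset, with sentences presented from 3.5 s:

* *Envelope encoding*: each parcel carries the convolution of a lag kernel
  (default: a biphasic curve peaking at ~110 ms with a ~190 ms negative
  deflection, the shape of auditory onset-envelope response functions) with
  the gain-weighted sum of the two streams. Under an informative cue the
  attended stream has gain 1.0 and the ignored stream 0.3 (defaults);
  under an uninformative cue both streams receive the mean gain. Each
  ear's input is weighted 1.0 in the contralateral and 0.5 in the
  ipsilateral hemisphere.
* *Attentional state*: the per-trial gain contrast is jittered
  (multiplicative SD 0.15) to create trial-to-trial filter-state
  variation; the same latent state feeds the behavioural model, so
  brain--behaviour coupling exists by construction.
* *Alpha*: a 10 Hz sinusoid whose ipsi/contralateral amplitude ratio (with
  respect to the probed ear) is sqrt of the planted power ratio — 1.5
  under an informative cue, 1.0 under an uninformative cue by default. The
  amplitude is constant across the epoch: within-trial ALI dynamics are
  not emulated, which is sufficient for index-recovery testing but means
  the synthetic cross-correlation of ALI and tracking time courses has no
  planted lead--lag structure.
* *Noise*: pink (1/f) noise plus 50% white noise, scaled so that the
  envelope-driven component has the configured RMS signal-to-noise ratio
  (default 1) in the sentence window. No published value constrains this
  SNR, so it is an exposed parameter rather than a constant.

**Behaviour.** Single-trial accuracy is Bernoulli with a logistic linear
predictor over deviation-coded cues and probed ear, z-scored age and
hearing level (PTA), the trial's tracking-state deviation, and subject and
item random intercepts. The default cue effect sizes are an odds ratio of
3.5 for the spatial cue and a standardized response-speed slope of 0.57,
with residual variances chosen so that standardized speed has unit total
variance; the planted values are therefore recoverable on the fitted
scale. The tracking-state deviation is centered within cue condition, so
it is orthogonal to the cue regressor and the cue coefficient equals the
planted value exactly. Speed is 1/RT around 0.62 1/s (SD 0.17); a small
fraction of trials (2%) times out. Incorrect answers split 2:1 into
spatial stream confusions versus random errors, mirroring the empirical
dominance of choosing the ignored stream's final word.

```{r quick-look, eval = FALSE}
cfg <- sim_config(n_subjects = 2, seed = 1)
ds <- generate_dataset(cfg)
head(ds$trials)
head(ds$ground_truth)
```

## Alpha-power lateralization

Per trial, Morlet wavelet power (6 cycles) is computed at 8, 9, ..., 12 Hz
for every parcel over -0.5--6.5 s. Power is variance-stabilized with a
Box-Cox transform ((x^p - 1)/p, p = 0.5) and normalized by subtracting,
per parcel and frequency, the whole-trial power averaged over all of the
subject's trials. Transformed, normalized power is averaged over ROI
parcels per hemisphere and over the five frequencies; the robust ALI then
applies the inverse logit to the ipsi- and contralateral series (mapping
both into (0, 1)) before forming the normalized contrast, which bounds the
index in (-1, 1) and removes denominator instability.

Choices worth noting:

* The frequency grid is integer 8--12 Hz (the band is specified, the grid
  is not); frequencies are averaged after transformation.
* The inverse-logit robustification is applied after ROI averaging; power
  is averaged over parcels *before* the index is formed.
* Samples within half a wavelet support of the epoch edges are discarded
  from window summaries, which is what the -0.5/+6.5 s padding around the
  3.5--6.5 s sentence window is for.

Window summaries per trial are the sentence-window mean and the final-word
mean (the final 35% of the percent-warped series, the interval covering
final-word onset across sentence pairs).

## Backward models and neural speech tracking

Envelope reconstruction uses ridge regression on a time-lagged copy of the
parcel responses, with lags spanning -100 to +500 ms (the reconstruction at
time t uses neural samples from t-100 ms to t+500 ms; neural activity lags
the stimulus). At 125 Hz the lag grid holds 76 integer-sample lags starting
at floor(-0.1 x 125) = -13 samples; -100 ms is not an integer sample at
125 Hz, so the grid covers -104..496 ms. The closed form is

    g = (R'R + lambda * m * I)^{-1} R' s,

with m the mean of the trace of R'R, making the penalty scale-free across
subjects. Design columns and the envelope are mean-centered per training
set; there is no intercept column. Decoders are trained on
selective-attention trials only, separately per attend side and per role
(attended vs. ignored), on trials concatenated with 600 ms zero padding on
both sides of each trial (the padding side is unstated in standard
descriptions; symmetric padding serves both lag signs). The ridge grid
10^-5..10^10 is searched by pooled leave-one-out reconstruction quality,
maximizing the mean sliding-window correlation with ties broken by lower
MSE; both decoder roles are pooled. The pipeline default is lambda = 1.

Every trial's two envelopes are reconstructed leave-one-out from the
models of its own attention condition; divided-attention trials are
decoded with the full selective models of the side matching the probed ear
(probed-left trials use the attend-left/ignore-right models, and
conversely). Reconstructions are compared to the presented onset envelopes
with a 248-ms (31-sample) sliding Pearson correlation stepped by one
sample; windows with zero variance (silences between words) yield missing
values, never 0. The tracking index is formed per time point and stored
unclipped. Because the index is a ratio of correlations it is unbounded
where r_attended is close to -r_ignored; denominators below 1e-6 in
magnitude are set to missing, but heavy tails remain. Summaries that
average the index over windows are therefore noisy at the single-trial
level, and group descriptions in the acceptance report use medians. This
instability is inherent to the index definition, which we preserve.

Backward weights are made interpretable by the standard transformation to
forward (encoding) weights — multiplying by the covariance of the lagged
responses and dividing by the variance of the reconstructed stimulus —
which recovers the planted kernel shape on clean synthetic data (r ~0.95).

**What clean-data tests can and cannot show.** In a noise-free simulation
with the default contralateral dominance (1.0/0.5), the two-stream mixing
is exactly invertible, so *both* envelopes are reconstructed equally well;
correlation is scale-invariant, so the 1.0 vs 0.3 gain contrast produces
no tracking-index asymmetry. The attended > ignored asymmetry that the
index is designed to capture is a noise-floor phenomenon: with the default
SNR of 1, the reconstruction error floor is common to both streams while
the signal scales with gain, and r_attended (~0.82) clearly exceeds
r_ignored (~0.68). Noise-free runs are therefore used to validate decoder
*recovery* (weights, forward kernels, label-swap antisymmetry), while
index asymmetry and null-safety are validated on noisy data. A second
intrinsic ceiling: reconstructing a sharp onset envelope through a
band-limited response kernel from a truncated lag window caps the mean
sliding-window correlation near 0.88 even without noise.

## Temporal alignment of the two filters

Sentences differ in length, so per-trial time courses are mapped onto 100
bins of 1% of sentence duration (ALI series included, after restriction to
the sentence window) and smoothed with a centred 3-bin rectangular window
evaluated at every bin — the reading of a "3% window, 1% overlap" that
preserves the 100-bin axis; a step-2 reading would halve it. Group time
courses average within subjects first, then across subjects (between-
subject SEM). The cross-correlation of the grand-average tracking and ALI
time courses is mean-removed and normalized by the product of the two
full-series standard deviations and the overlap length, so the zero-lag
autocorrelation is exactly 1; a positive peak lag means the first series
leads. Missing bins drop out pairwise. The surrogate band independently
permutes the bin order of both series 5000 times and takes per-lag
2.5th/97.5th percentiles; bin-order permutation is the plainest reading of
"independently permuted time courses", and the permutation unit is
exposed should trial- or subject-level permutation be preferred. Lags in
bins convert to milliseconds via the mean sentence duration (lag x
duration/100); the conversion rule is not standardized, so the simulated
(or supplied) mean duration is used explicitly.

## State/trait brain-behaviour models

Behavioural preprocessing excludes timeouts (no response within 4 s) from
the accuracy table; response speed (1/RT) uses correct trials only. Error
proportions per subject (spatial stream confusions vs. random errors) are
compared by a paired t test on logit-transformed proportions with a
(k + 0.5)/(n + 1) adjustment so zero counts stay finite.

Each neural measure enters the models twice: a *trait* (between-subject)
regressor — the subject mean, z-scored across subjects — and a *state*
(within-subject) regressor — the trial deviation from the subject mean,
z-scored globally after the decomposition (a convention the literature
leaves open; the global choice keeps one scale for all subjects). The two
are orthogonal by construction. Categorical predictors are deviation-coded
-0.5/+0.5 so coefficients are full-range effects and an exponentiated
accuracy coefficient is the informative-vs-uninformative odds ratio;
continuous covariates are z-scored with the n-1 denominator on the
analysis sample after exclusions.

Accuracy is modelled by a binomial (logit) GLMM and speed by a Gaussian
LMM on z-scored speed, both with subject and item random intercepts
(lme4, Laplace approximation), Wald z (t-as-z) p values, and
Benjamini-Hochberg FDR correction at q = 0.05 across the reported fixed
effects. Random-slope extensions (spatial cue, semantic cue, probed ear by
subject) are adopted only when a likelihood-ratio test on nested ML fits
is significant. The fixed-effect roster is a configurable formula string,
so cue-only, brain-behaviour, brain-brain (tracking regressed on ALI), and
control models are all expressible without new code.

## Pipeline, containers, and reproducibility

`run_stage()` exposes the stages `simulate`, `features`, `decode`, `warp`,
`crosscorr`, `stats`, and `report`; each consumes the previous stage's
artifacts from the output directory and is idempotent and byte-identical
given identical inputs. The dataset container is an RDS-serialized list
plus a plain CSV trial table and YAML configuration; `validate_container()`
checks trial-count consistency and the 125 Hz envelope rate the decoding
stage requires. One master seed is expanded into independent per-stage
substreams (`derive_seed()`), so re-running one stage never perturbs
another's randomness. A thin command-line wrapper lives at
`inst/cli/dichotr.R`.

Problem sizes in the test-suite and acceptance script are deliberate
choices: decoder recovery uses one subject at the full 240-trial design;
null-safety uses 200 trials; mixed-model recovery uses 50 subjects x 240
trials with 20 replicates for coverage and 20 for the null false-positive
rate; the surrogate coverage check uses 50 replicates of 500 permutations.
These sizes give stable pass/fail behaviour at desk scale.

## Known limitations

* The tracking index is unbounded near vanishing denominators; means over
  index series have heavy tails (medians are stable). Clipping conventions
  are left to the user because the published definition does not state one.
* The generator plants no within-trial dynamics for alpha amplitude and no
  lead-lag between tracking and ALI; the cross-correlation machinery is
  validated on constructed delays instead.
* Parcel time series are direct linear mixtures; no sensor-level EEG,
  source projection, or head modelling is simulated, so passing tests
  speak to the analysis chain, not to source-reconstruction quality.
* Divided-attention behaviour is generated with both streams at the mean
  gain; listeners' spontaneous attention switches are not modelled beyond
  the onset-lead covariate.
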