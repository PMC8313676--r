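# dichotr

Neural attentional-filter analysis of dichotic listening in R.

When two talkers compete, listeners rely on neural "filters" that favour
the relevant stream. `dichotr` implements the two canonical EEG signatures
of this filtering and the statistics that link them to single-trial
behaviour:

* **Alpha-power lateralization** — Morlet-wavelet 8–12 Hz power, Box-Cox
  variance stabilization, whole-trial normalization, and the robust
  single-trial alpha lateralization index
  `ALI = (α-power_ipsi − α-power_contra) / (α-power_ipsi + α-power_contra)`
  computed after inverse-logit scaling of the two ROI power series.
* **Neural speech tracking** — backward (decoding) models
  `g = (R'R + λmI)^{-1} R's` over −100…500 ms lags, trained per attend
  side and role (attended/ignored) on selective-attention trials,
  evaluated by leave-one-out reconstruction and a 248-ms sliding
  Pearson correlation, summarized by the neural tracking index
  `NTI = (r_attended − r_ignored) / (r_attended + r_ignored)`, and
  forward-transformed into interpretable encoding weights.
* **Temporal alignment** — percent-of-sentence warping (100 bins, 3-bin
  smoother), final-word (last 35%) summaries, and the normalized
  cross-correlation of the two filters' group time courses with a
  5000-permutation surrogate band.
* **State/trait mixed-effects models** — within/between-subject
  decomposition of neural measures, deviation-coded binomial GLMMs for
  accuracy and Gaussian LMMs for response speed (1/RT), Wald tests, and
  Benjamini-Hochberg FDR correction.

Because the real study data live in an external repository, the package
ships a first-class synthetic dichotic-listening generator (stimulus
envelope pairs, source-parcel epochs with planted attention gains and
alpha ratios, behaviour from a logistic model with planted effects) so
every stage is testable by parameter recovery. See the vignette
`vignettes/neural-attentional-filters.Rmd` for the model details and the
design decisions.

## Worked example

Simulate one subject, compute both neural filters, and summarize:

```r
library(dichotr)

cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 15, seed = 42)
ds  <- generate_dataset(cfg)

alpha    <- compute_alpha_features(ds)          # Morlet -> Box-Cox -> ALI
td       <- decoding_data(ds)                   # 125 Hz decoding view
tracking <- loo_reconstruct(td, lambda = 1)     # leave-one-out decoders

sel <- ds$trials$spatial_cue == "informative"
mean(alpha$features$ALI_sentence[sel])          # vs [!sel]
```

Output (seed 42):

```
ALI (sentence window): informative 0.073 vs uninformative 0.058
reconstruction r: attended 0.84, ignored 0.69 (selective trials)
tracking index (median): selective 0.067, divided -0.061
accuracy: 87.9% of 58 answered trials
```

Read: with an informative spatial cue, alpha power lateralizes toward the
probed ear (positive ALI) and the attended envelope is reconstructed much
better than the ignored one (r 0.84 vs 0.69), giving a positive tracking
index; with an uninformative cue the probed/unprobed contrast is near
zero. The behavioural generator lands in the realistic high-80s accuracy
range.

The full stage-wise pipeline (simulate → features → decode → warp →
crosscorr → stats → report) is driven by `run_pipeline()` /
`run_stage()`, or from a shell:

```sh
Rscript inst/cli/dichotr.R all --seed 1 --out out_dir
```

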