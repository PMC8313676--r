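test_that("dataset generation is deterministic and refuses a missing seed", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 2, seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_error(generate_dataset(sim_config(n_trials_per_cell = 2)), "seed")
})

test_that("trial design is balanced across cells and probed ears", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_cell = 5, seed = 1)
  ds <- generate_dataset(cfg, epochs = FALSE)
  expect_equal(nrow(ds$trials), 40)
  tb <- table(ds$trials$spatial_cue, ds$trials$semantic_cue,
              ds$trials$subject)
  expect_true(all(tb == 5))
  cfg2 <- sim_config(n_subjects = 1, n_trials_per_cell = 4, seed = 1)
  ds2 <- generate_dataset(cfg2, epochs = FALSE)
  tb2 <- table(ds2$trials$spatial_cue, ds2$trials$probed_ear)
  expect_true(all(tb2 == 4))  # ears balanced within cue level for even n
})

test_that("stimulus pairs have the specified durations, asynchrony and pulses", {
  cfg <- sim_config(seed = 1)
  set.seed(123)
  durs <- numeric(0)
  for (i in 1:200) {
    p <- simulate_stimulus_pair(cfg)
    durs <- c(durs, p$durations_ms)
    expect_true(p$asynchrony_ms >= 0 && p$asynchrony_ms <= 580)
    expect_true(all(p$durations_ms >= 2183 & p$durations_ms <= 2963))
    starts <- vapply(p$envelopes, `[[`, 1L, "start")
    # onset offset equals the drawn asynchrony, on the sample grid
    expect_equal(abs(diff(starts)),
                 round(p$asynchrony_ms / 1000 * cfg$sample_rate))
    expect_equal(which.min(starts), p$lead)
    for (e in p$envelopes) {
      expect_true(all(e$values >= 0))
      seg <- e$values[e$start:e$end]
      expect_equal(n_peaks_above(seg, 0.5), 5)
    }
  }
  # law of large numbers: mean duration near the 2573 ms midpoint
  expect_true(mean(durs) > 2523 && mean(durs) < 2623)
})

test_that("an impulse kernel with no competition reproduces the envelope", {
  cfg <- sim_config(
    n_subjects = 1, n_trials_per_cell = 1,
    trf_kernel = data.frame(lag = 0, weight = 1),
    gain_attended = 1, gain_ignored = 0, attention_jitter_sd = 0,
    alpha_amplitude = 0, snr_envelope = Inf, seed = 1
  )
  set.seed(2)
  pair <- simulate_stimulus_pair(cfg)
  trial <- data.frame(spatial_cue = "informative", probed_ear = "left",
                      gain_att = 1, gain_ign = 0, alpha_ratio = 1)
  ep <- simulate_source_epoch(pair, trial, cfg)
  # right hemisphere is contralateral to the attended left ear; parcel 8
  # has unit parcel gain (gains span 0.6..1.4 over 5 parcels)
  env <- pair$envelopes[[1]]$values
  onset <- round((ep$sentence_onset_s - ep$t0) * ep$fs) + 1L
  got <- ep$data[8, onset + 2 * (seq_along(env) - 1)]
  expect_equal(got, env, tolerance = 1e-10)
  # ipsilateral parcels carry the envelope at half weight
  got_ipsi <- ep$data[3, onset + 2 * (seq_along(env) - 1)]
  expect_equal(got_ipsi, 0.5 * env, tolerance = 1e-10)
})

test_that("planted alpha power ratio is recovered spectrally within 1%", {
  cfg <- sim_config(
    n_subjects = 1, n_trials_per_cell = 1,
    gain_attended = 0, gain_ignored = 0, attention_jitter_sd = 0,
    alpha_power_ratio_selective = 2, snr_envelope = Inf, seed = 1
  )
  set.seed(5)
  pair <- simulate_stimulus_pair(cfg)
  trial <- data.frame(spatial_cue = "informative", probed_ear = "left",
                      gain_att = 0, gain_ign = 0, alpha_ratio = 2)
  ep <- simulate_source_epoch(pair, trial, cfg)
  # band power around 10 Hz from the periodogram, per hemisphere
  idx <- which(seq(-0.5, 6.5, by = 1 / ep$fs) >= 3.5)
  band_power <- function(x) {
    n <- length(x)
    f <- (seq_len(n) - 1) * ep$fs / n
    P <- Mod(stats::fft(x))^2
    sum(P[f >= 9 & f <= 11])
  }
  p_l <- mean(apply(ep$data[ep$hemisphere == "L", idx], 1, band_power))
  p_r <- mean(apply(ep$data[ep$hemisphere == "R", idx], 1, band_power))
  expect_equal(p_l / p_r, 2, tolerance = 0.01)  # L ipsi to probed-left ear
})

test_that("null behaviour model yields 50% accuracy and no timeouts when disabled", {
  coefs <- default_behaviour_coefs()
  coefs$accuracy[] <- 0
  coefs$speed[] <- 0
  coefs$subject_sd_accuracy <- 0
  coefs$item_sd_accuracy <- 0
  cfg <- sim_config(n_subjects = 2, n_trials_per_cell = 60,
                    behaviour_coefs = coefs, timeout_frac = 0, seed = 1)
  trials <- simulate_trial_table(cfg)
  trials <- do.call(rbind, replicate(20, trials, simplify = FALSE))
  trials$trial <- seq_len(nrow(trials))
  set.seed(11)
  beh <- simulate_behaviour(trials, 0, cfg)
  expect_equal(mean(beh$correct), 0.5, tolerance = 0.02)
  expect_false(any(beh$accuracy == "timeout"))
  tabs <- preprocess_behaviour(beh)
  expect_equal(nrow(tabs$accuracy), nrow(beh))
})

test_that("epochs that overrun the analysis window are rejected", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 1, seed = 1)
  set.seed(3)
  pair <- simulate_stimulus_pair(cfg)
  # stretch the grid beyond 3 s so placement at 3.5 s exceeds 6.5 s
  long <- pair
  long$envelopes[[1]]$values <- rep(pair$envelopes[[1]]$values, 2)
  long$envelopes[[2]]$values <- rep(pair$envelopes[[2]]$values, 2)
  trial <- data.frame(spatial_cue = "informative", probed_ear = "left",
                      gain_att = 1, gain_ign = 0.3, alpha_ratio = 1)
  expect_error(simulate_source_epoch(long, trial, cfg), "epoch window")
})
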