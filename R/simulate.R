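#' Simulate one dichotic sentence-pair of onset envelopes
#'
#' Each "sentence" is a train of 5 smooth non-negative word pulses
#' (Hann-windowed, 150 ms wide, quasi-regular spacing) whose total span is
#' drawn uniformly from 2183--2963 ms. The two sentences are temporally
#' aligned at the onset of their final (task-relevant) word pulse, so the
#' onset asynchrony of the pair equals the difference of their durations;
#' the asynchrony is drawn uniformly from 0--580 ms with equal probability
#' of either stream leading.
#'
#' @param config A [sim_config()].
#' @return A list with elements `envelopes` (list of two `onset_envelope`
#'   objects on a common time grid: `values`, `fs`, `start`, `end` sample
#'   indices), `asynchrony_ms`, `lead` (1 or 2, the earlier-starting
#'   stream), and `durations_ms`.
#' @export
simulate_stimulus_pair <- function(config) {
  fs <- config$sample_rate
  asyn <- stats::runif(1, 0, 580)
  lead <- sample(1:2, 1)
  d_short <- stats::runif(1, 2183, 2963 - asyn)
  d_long <- d_short + asyn
  durations <- c(0, 0)
  durations[lead] <- d_long   # earlier onset = longer sentence (ends align)
  durations[3 - lead] <- d_short

  onsets_ms <- c(0, 0)
  onsets_ms[3 - lead] <- asyn
  span <- max(onsets_ms + durations)
  n_grid <- round(span / 1000 * fs)

  envelopes <- vector("list", 2)
  for (i in 1:2) {
    tr <- pulse_train(durations[i], fs)
    start <- as.integer(round(onsets_ms[i] / 1000 * fs)) + 1L
    values <- numeric(n_grid)
    stop_at <- min(n_grid, start + length(tr) - 1L)
    values[start:stop_at] <- tr[seq_len(stop_at - start + 1L)]
    envelopes[[i]] <- structure(
      list(values = values, fs = fs, start = start, end = stop_at),
      class = "onset_envelope"
    )
  }
  list(envelopes = envelopes, asynchrony_ms = asyn, lead = lead,
       durations_ms = durations)
}

# 5 Hann word pulses spanning exactly duration_ms; pulse widths vary per
# word (words differ in temporal extent), amplitudes mildly so
pulse_train <- function(duration_ms, fs, n_words = 5,
                        pulse_ms_range = c(120, 200)) {
  n <- round(duration_ms / 1000 * fs)
  widths_ms <- stats::runif(n_words, pulse_ms_range[1], pulse_ms_range[2])
  gaps <- stats::runif(n_words - 1, 350, 550)
  gaps <- gaps * (duration_ms - widths_ms[n_words]) / sum(gaps)
  onsets <- round(c(0, cumsum(gaps)) / 1000 * fs) + 1L
  amps <- stats::runif(n_words, 0.8, 1.2)
  values <- numeric(n)
  for (k in seq_len(n_words)) {
    w <- max(3L, round(widths_ms[k] / 1000 * fs))
    pulse <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = w)))
    idx <- onsets[k]:min(n, onsets[k] + w - 1L)
    values[idx] <- values[idx] + amps[k] * pulse[seq_along(idx)]
  }
  values
}

# interpolate a (lag, weight) kernel spec onto the sample grid
kernel_fir <- function(trf_kernel, fs) {
  lag_max <- max(trf_kernel$lag)
  xout <- seq(0, lag_max, by = 1 / fs)
  if (nrow(trf_kernel) == 1) {
    k <- numeric(round(lag_max * fs) + 1)
    k[length(k)] <- trf_kernel$weight
    return(k)
  }
  stats::spline(trf_kernel$lag, trf_kernel$weight, xout = xout,
                method = "natural")$y
}

# 1/f^exponent noise via spectral shaping of white Gaussian noise
pink_noise <- function(n, exponent = 1) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # two-sided frequency index
  X <- X / f^(exponent / 2)
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  out / stats::sd(out)
}

#' Simulate one source-space epoch for a trial
#'
#' Builds the per-parcel time series of the bilateral auditory ROI for one
#' trial: lag-structured envelope encoding (stronger contralateral to each
#' ear's input and stronger for the attended stream), a 10 Hz alpha
#' sinusoid whose ipsi/contralateral power ratio (relative to the probed
#' ear) matches the trial's planted ratio, and 1/f plus white background
#' noise scaled to the configured envelope SNR. The epoch spans -0.5 to
#' 6.5 s relative to cue onset; sentences are placed from 3.5 s onward.
#'
#' @param pair Output of [simulate_stimulus_pair()].
#' @param trial One-row data frame with at least `spatial_cue`,
#'   `probed_ear`, `gain_att`, `gain_ign`, `alpha_ratio` (per-trial planted
#'   values; see [generate_dataset()]).
#' @param config A [sim_config()].
#' @return A `source_epoch`: list with `data` (parcels x time matrix),
#'   `fs`, `t0`, `hemisphere` labels, `sentence_onset_s`, and per-stream
#'   start/end times in seconds (`att_window`, `ign_window`).
#' @export
simulate_source_epoch <- function(pair, trial, config) {
  fs_e <- config$epoch_rate
  t <- seq(-0.5, 6.5, by = 1 / fs_e)
  n <- length(t)
  onset_s <- 3.5
  fs_env <- pair$envelopes[[1]]$fs
  span_s <- length(pair$envelopes[[1]]$values) / fs_env
  if (onset_s + span_s > 6.5 + 1e-9) {
    stop("sentence placement exceeds the epoch window (ends at ",
         round(onset_s + span_s, 3), " s > 6.5 s)")
  }

  # ear assignment: envelope 1 = left ear, 2 = right ear
  probed_idx <- if (trial$probed_ear == "left") 1L else 2L
  selective <- trial$spatial_cue == "informative"
  gains <- c(0, 0)
  if (selective) {
    gains[probed_idx] <- trial$gain_att
    gains[3 - probed_idx] <- trial$gain_ign
  } else {
    gains[] <- (trial$gain_att + trial$gain_ign) / 2
  }

  # envelopes upsampled onto the epoch grid
  env_e <- lapply(pair$envelopes, function(e) {
    te <- onset_s + (seq_along(e$values) - 1) / fs_env
    out <- numeric(n)
    idx <- t >= onset_s & t <= max(te)
    out[idx] <- stats::approx(te, e$values, xout = t[idx], rule = 2)$y
    out
  })

  kern <- kernel_fir(config$trf_kernel, fs_e)
  npH <- config$n_parcels_per_hemisphere
  hemis <- rep(c("L", "R"), each = npH)
  parcel_gain <- rep(seq(0.6, 1.4, length.out = npH), 2)

  # contralateral dominance: ear input weighted 1.0 contra, 0.5 ipsi
  ear_weight <- function(hemi, ear) {
    if ((hemi == "L" && ear == "right") || (hemi == "R" && ear == "left")) 1.0
    else 0.5
  }
  ears <- c("left", "right")

  data <- matrix(0, nrow = 2 * npH, ncol = n)
  env_part <- matrix(0, nrow = 2 * npH, ncol = n)
  ipsi_hemi <- if (trial$probed_ear == "left") "L" else "R"
  for (p in seq_len(2 * npH)) {
    mix <- numeric(n)
    for (i in 1:2) {
      mix <- mix + ear_weight(hemis[p], ears[i]) * gains[i] * env_e[[i]]
    }
    enc <- stats::filter(mix, kern, method = "convolution", sides = 1)
    enc[is.na(enc)] <- 0
    env_part[p, ] <- parcel_gain[p] * as.numeric(enc)

    amp <- config$alpha_amplitude *
      if (hemis[p] == ipsi_hemi) sqrt(trial$alpha_ratio) else 1
    phase <- stats::runif(1, 0, 2 * pi)
    data[p, ] <- env_part[p, ] + amp * sin(2 * pi * config$alpha_freq * t + phase)
  }

  if (is.finite(config$snr_envelope)) {
    sent_idx <- t >= onset_s & t <= onset_s + span_s
    env_rms <- sqrt(mean(env_part[, sent_idx]^2))
    if (env_rms == 0) env_rms <- 1   # null gains: unit-RMS noise
    for (p in seq_len(2 * npH)) {
      nz <- pink_noise(n, config$noise_exponent) +
        config$noise_white_frac * stats::rnorm(n)
      nz <- nz / sqrt(1 + config$noise_white_frac^2)
      data[p, ] <- data[p, ] + nz * env_rms / config$snr_envelope
    }
  }

  w <- lapply(pair$envelopes, function(e)
    onset_s + (c(e$start, e$end) - 1) / fs_env)
  structure(list(
    data = data, fs = fs_e, t0 = -0.5, hemisphere = hemis,
    sentence_onset_s = onset_s, span_s = span_s,
    att_window = w[[probed_idx]], ign_window = w[[3 - probed_idx]]
  ), class = "source_epoch")
}

#' Build the balanced 2 x 2 trial design for one or more subjects
#'
#' Each subject receives `n_trials_per_cell` trials in each of the four
#' spatial-cue x semantic-cue cells, with the probed ear balanced within
#' each cell. Items (sentence-pair ids) are shared across subjects.
#'
#' @param config A [sim_config()].
#' @return Data frame with subject, trial, item, cue, ear, age, pta columns.
#' @export
simulate_trial_table <- function(config) {
  k <- config$n_trials_per_cell
  cells <- expand.grid(
    spatial_cue = c("informative", "uninformative"),
    semantic_cue = c("specific", "general"),
    stringsAsFactors = FALSE
  )
  one <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      spatial_cue = cells$spatial_cue[i],
      semantic_cue = cells$semantic_cue[i],
      probed_ear = rep_len(c("left", "right"), k),
      stringsAsFactors = FALSE
    )
  }))
  one$item <- seq_len(nrow(one))
  ages <- stats::runif(config$n_subjects, config$age_range[1], config$age_range[2])
  ptas <- stats::runif(config$n_subjects, config$pta_range[1], config$pta_range[2])
  out <- do.call(rbind, lapply(seq_len(config$n_subjects), function(s) {
    d <- one
    d$subject <- s
    d$trial <- seq_len(nrow(one))
    d$age <- ages[s]
    d$pta <- ptas[s]
    d
  }))
  rownames(out) <- NULL
  out[, c("subject", "trial", "item", "spatial_cue", "semantic_cue",
          "probed_ear", "age", "pta")]
}

#' Simulate behavioural outcomes for a trial table
#'
#' Accuracy follows a Bernoulli draw from the inverse logit of a linear
#' predictor with deviation-coded cue/ear effects, z-scored age and PTA,
#' a per-trial neural-tracking deviation, and subject and item random
#' intercepts. Response speed (1/RT) follows the analogous Gaussian linear
#' model on a standardized scale, rescaled to the configured speed mean and
#' SD. A configured fraction of trials is marked as timeouts; incorrect
#' responses are split into spatial stream confusions and random errors.
#'
#' @param trials Data frame from [simulate_trial_table()] (any extra
#'   columns are carried through).
#' @param tracking_dev Per-trial neural tracking deviation (centered);
#'   recycled scalar allowed.
#' @param config A [sim_config()].
#' @return `trials` with added columns `accuracy` (correct /
#'   spatial_confusion / random_error / timeout), `correct`,
#'   `reaction_time` (s), `speed` (1/s) and `eta_accuracy`, `eta_speed`
#'   (generative linear predictors).
#' @export
simulate_behaviour <- function(trials, tracking_dev, config) {
  bc <- config$behaviour_coefs
  n <- nrow(trials)
  tracking_dev <- rep_len(tracking_dev, n)

  sc <- ifelse(trials$spatial_cue == "informative", 0.5, -0.5)
  sem <- ifelse(trials$semantic_cue == "specific", 0.5, -0.5)
  ear <- ifelse(trials$probed_ear == "right", 0.5, -0.5)
  zs <- function(x) {
    out <- if (length(unique(x)) > 1) as.numeric(scale(x)) else rep(0, length(x))
    names(out) <- names(x)
    out
  }
  subj_age <- tapply(trials$age, trials$subject, mean)
  subj_pta <- tapply(trials$pta, trials$subject, mean)
  age_z <- zs(subj_age)[as.character(trials$subject)]
  pta_z <- zs(subj_pta)[as.character(trials$subject)]

  subj_ids <- sort(unique(trials$subject))
  item_ids <- sort(unique(trials$item))
  re_acc <- stats::rnorm(length(subj_ids), 0, bc$subject_sd_accuracy)
  re_item <- stats::rnorm(length(item_ids), 0, bc$item_sd_accuracy)
  re_spd <- stats::rnorm(length(subj_ids), 0, bc$subject_sd_speed)
  re_item_spd <- stats::rnorm(length(item_ids), 0,
                              if (is.null(bc$item_sd_speed)) 0 else bc$item_sd_speed)
  names(re_acc) <- names(re_spd) <- subj_ids
  names(re_item) <- names(re_item_spd) <- item_ids

  ca <- bc$accuracy
  eta_acc <- ca["intercept"] + ca["spatial_cue"] * sc +
    ca["semantic_cue"] * sem + ca["probed_ear"] * ear +
    ca["tracking"] * tracking_dev + ca["age"] * age_z + ca["pta"] * pta_z +
    re_acc[as.character(trials$subject)] + re_item[as.character(trials$item)]
  correct <- stats::rbinom(n, 1, stats::plogis(eta_acc)) == 1

  cs <- bc$speed
  eta_spd <- cs["intercept"] + cs["spatial_cue"] * sc +
    cs["semantic_cue"] * sem + cs["probed_ear"] * ear +
    cs["tracking"] * tracking_dev + cs["age"] * age_z + cs["pta"] * pta_z +
    re_spd[as.character(trials$subject)] +
    re_item_spd[as.character(trials$item)]
  z_speed <- eta_spd + stats::rnorm(n, 0, bc$resid_sd_speed)
  speed <- pmax(bc$speed_mean + bc$speed_sd * z_speed, 0.26)
  rt <- 1 / speed

  timeout <- stats::runif(n) < config$timeout_frac
  acc_cat <- ifelse(timeout, "timeout",
                    ifelse(correct, "correct", NA))
  # errors: spatial stream confusions about twice as frequent as random errors
  err <- which(is.na(acc_cat))
  acc_cat[err] <- ifelse(stats::runif(length(err)) < 2 / 3,
                         "spatial_confusion", "random_error")

  trials$accuracy <- acc_cat
  trials$correct <- ifelse(timeout, NA, correct)
  trials$reaction_time <- ifelse(timeout, NA_real_, rt)
  trials$speed <- ifelse(timeout, NA_real_, speed)
  trials$eta_accuracy <- as.numeric(eta_acc)
  trials$eta_speed <- as.numeric(eta_spd)
  trials
}

#' Generate a complete synthetic dichotic-listening dataset
#'
#' Produces, deterministically for a given seed, the trial table with
#' behavioural outcomes, per-trial onset-envelope pairs, per-trial source
#' epochs, and a ground-truth table recording every planted quantity.
#'
#' @param config A [sim_config()]; `config$seed` must be set.
#' @param epochs If `FALSE`, skip source-epoch synthesis (behaviour-only
#'   datasets for the statistics module are much faster to generate).
#' @return A `dl_dataset`: list with `config`, `trials`, `envelopes`
#'   (list of stimulus pairs), `epochs` (list of `source_epoch` or NULL),
#'   and `ground_truth`.
#' @export
generate_dataset <- function(config, epochs = TRUE) {
  if (is.null(config$seed)) {
    stop("config$seed must be set: dataset generation is only defined ",
         "relative to an explicit seed")
  }
  set.seed(derive_seed(config$seed, "design"))
  trials <- simulate_trial_table(config)
  n <- nrow(trials)

  set.seed(derive_seed(config$seed, "stimuli"))
  pairs <- vector("list", n)
  probed_first <- logical(n)
  asyn <- numeric(n)
  for (i in seq_len(n)) {
    pairs[[i]] <- simulate_stimulus_pair(config)
    probed_idx <- if (trials$probed_ear[i] == "left") 1L else 2L
    probed_first[i] <- pairs[[i]]$lead == probed_idx ||
      pairs[[i]]$asynchrony_ms == 0
    asyn[i] <- pairs[[i]]$asynchrony_ms
  }
  trials$probed_first <- probed_first
  trials$asynchrony_ms <- asyn

  # per-trial attentional filter state (jittered gain contrast)
  set.seed(derive_seed(config$seed, "gains"))
  mid <- (config$gain_attended + config$gain_ignored) / 2
  d <- config$gain_attended - config$gain_ignored
  state <- stats::rnorm(n, 1, config$attention_jitter_sd)
  selective <- trials$spatial_cue == "informative"
  gain_att <- ifelse(selective, pmax(mid + d * state / 2, 0), mid)
  gain_ign <- ifelse(selective, pmax(mid - d * state / 2, 0), mid)
  trials$gain_att <- gain_att
  trials$gain_ign <- gain_ign
  trials$alpha_ratio <- ifelse(selective, config$alpha_power_ratio_selective,
                               config$alpha_power_ratio_divided)
  denom <- gain_att + gain_ign
  planted_nti <- ifelse(denom > 0, (gain_att - gain_ign) / denom, 0)
  # trial-to-trial filter state beyond the cue: centered within cue condition
  cond_mean <- stats::ave(planted_nti, trials$spatial_cue)
  tracking_dev <- planted_nti - cond_mean

  set.seed(derive_seed(config$seed, "behaviour"))
  trials <- simulate_behaviour(trials, tracking_dev, config)

  eps <- NULL
  if (epochs) {
    eps <- vector("list", n)
    for (i in seq_len(n)) {
      set.seed(derive_seed(config$seed, "epoch", i))
      eps[[i]] <- simulate_source_epoch(pairs[[i]], trials[i, ], config)
    }
  }

  ground_truth <- data.frame(
    subject = trials$subject, trial = trials$trial,
    attended_ear = ifelse(selective, trials$probed_ear, NA),
    asynchrony_ms = asyn,
    alpha_ratio = trials$alpha_ratio,
    gain_att = gain_att, gain_ign = gain_ign,
    planted_tracking = planted_nti,
    eta_accuracy = trials$eta_accuracy,
    eta_speed = trials$eta_speed
  )

  structure(list(config = config, trials = trials, envelopes = pairs,
                 epochs = eps, ground_truth = ground_truth),
            class = "dl_dataset")
}
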