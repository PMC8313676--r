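#' Simulation configuration for the synthetic dichotic-listening dataset
#'
#' Bundles every parameter of the generative model: the 2 x 2 cue design,
#' stimulus timing, the lag-structured envelope encoding kernel, the planted
#' attentional gains, the alpha-oscillation lateralization ratios, background
#' noise, and the behavioural (logistic / linear) coefficients.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_trials_per_cell Trials per cue-cue cell (4 cells per subject).
#' @param sample_rate Envelope / decoding sample rate in Hz.
#' @param epoch_rate Source-epoch sample rate in Hz (alpha analysis rate).
#' @param n_parcels_per_hemisphere Parcels per hemisphere in the auditory ROI.
#' @param trf_kernel Data frame with columns `lag` (seconds) and `weight`
#'   describing the envelope-encoding kernel; interpolated onto the epoch
#'   sample grid by a monotone-in-lag cubic spline anchored at zero outside
#'   the stated support.
#' @param gain_attended,gain_ignored Envelope gains for the attended and
#'   ignored stream under selective attention. Divided-attention trials use
#'   the mean of the two for both streams.
#' @param attention_jitter_sd SD of the per-trial multiplicative jitter on
#'   the attentional gain contrast (trial-to-trial filter-state variation).
#' @param alpha_freq Alpha oscillation frequency in Hz.
#' @param alpha_amplitude Baseline alpha sinusoid amplitude (contralateral
#'   hemisphere).
#' @param alpha_power_ratio_selective Planted ipsi/contra alpha power ratio
#'   under an informative spatial cue.
#' @param alpha_power_ratio_divided Planted ratio under an uninformative cue.
#' @param noise_exponent Spectral slope of the 1/f^exponent background noise.
#' @param noise_white_frac RMS of the additional white noise, as a fraction
#'   of the pink-noise RMS.
#' @param snr_envelope RMS ratio of the envelope-driven component to the
#'   total noise in the sentence window; 0 disables the envelope component,
#'   `Inf` disables noise.
#' @param behaviour_coefs Named list of generative behaviour coefficients;
#'   see [default_behaviour_coefs()].
#' @param timeout_frac Fraction of trials marked as timeouts (no response
#'   within the 4-s window).
#' @param age_range,pta_range Uniform ranges for subject age (years) and
#'   pure-tone average (dB HL).
#' @param seed Integer seed; mandatory for reproducibility.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 1,
                       n_trials_per_cell = 60,
                       sample_rate = 125,
                       epoch_rate = 250,
                       n_parcels_per_hemisphere = 5,
                       trf_kernel = default_trf_kernel(),
                       gain_attended = 1.0,
                       gain_ignored = 0.3,
                       attention_jitter_sd = 0.15,
                       alpha_freq = 10,
                       alpha_amplitude = 1.0,
                       alpha_power_ratio_selective = 1.5,
                       alpha_power_ratio_divided = 1.0,
                       noise_exponent = 1,
                       noise_white_frac = 0.5,
                       snr_envelope = 1,
                       behaviour_coefs = default_behaviour_coefs(),
                       timeout_frac = 0.02,
                       age_range = c(39, 80),
                       pta_range = c(0, 40),
                       seed = NULL) {
  cfg <- list(
    n_subjects = n_subjects,
    n_trials_per_cell = n_trials_per_cell,
    sample_rate = sample_rate,
    epoch_rate = epoch_rate,
    n_parcels_per_hemisphere = n_parcels_per_hemisphere,
    trf_kernel = trf_kernel,
    gain_attended = gain_attended,
    gain_ignored = gain_ignored,
    attention_jitter_sd = attention_jitter_sd,
    alpha_freq = alpha_freq,
    alpha_amplitude = alpha_amplitude,
    alpha_power_ratio_selective = alpha_power_ratio_selective,
    alpha_power_ratio_divided = alpha_power_ratio_divided,
    noise_exponent = noise_exponent,
    noise_white_frac = noise_white_frac,
    snr_envelope = snr_envelope,
    behaviour_coefs = behaviour_coefs,
    timeout_frac = timeout_frac,
    age_range = age_range,
    pta_range = pta_range,
    seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1,
    cfg$n_trials_per_cell >= 1,
    cfg$sample_rate > 0,
    cfg$epoch_rate > 0,
    cfg$n_parcels_per_hemisphere >= 1,
    is.data.frame(cfg$trf_kernel),
    all(c("lag", "weight") %in% names(cfg$trf_kernel))
  )
  if (cfg$gain_attended < cfg$gain_ignored || cfg$gain_ignored < 0) {
    stop("gain_attended >= gain_ignored >= 0 is required ",
         "(equality allowed for null simulations)")
  }
  if (cfg$alpha_power_ratio_selective <= 0 ||
      cfg$alpha_power_ratio_divided <= 0) {
    stop("alpha power ratios must be positive")
  }
  if (cfg$timeout_frac < 0 || cfg$timeout_frac >= 1) {
    stop("timeout_frac must be in [0, 1)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default envelope-encoding kernel
#'
#' A biphasic lag kernel with an early positive deflection (~110 ms) and a
#' later negative one (~190 ms), the shape typically seen in forward TRFs of
#' the speech onset envelope in auditory cortex.
#'
#' @return Data frame with columns `lag` (seconds) and `weight`.
#' @export
default_trf_kernel <- function() {
  data.frame(
    lag = c(0, 0.05, 0.11, 0.19, 0.30),
    weight = c(0, 0.35, 1.0, -0.6, 0)
  )
}

#' Default generative behaviour coefficients
#'
#' Log-odds (accuracy model) and standardized slopes (speed model) used by
#' [simulate_behaviour()]. Cue and ear regressors are deviation-coded
#' (-0.5/+0.5), so coefficients are full-range effects: the default spatial
#' cue log-odds of `log(3.5)` plants an odds ratio of 3.5 for informative
#' versus uninformative spatial cues, and the default standardized speed
#' slope for the spatial cue is 0.57.
#'
#' @return Named list with elements `accuracy` and `speed` (named numeric
#'   vectors), plus `speed_mean`, `speed_sd`, `subject_sd_accuracy`,
#'   `subject_sd_speed`, `resid_sd_speed`.
#' @export
default_behaviour_coefs <- function() {
  list(
    accuracy = c(
      intercept = 2.0,
      spatial_cue = log(3.5),
      semantic_cue = log(1.1),
      probed_ear = log(1.25),
      tracking = 0.4,
      age = log(0.80),
      pta = log(0.75)
    ),
    speed = c(
      intercept = 0,
      spatial_cue = 0.57,
      semantic_cue = 0.20,
      probed_ear = 0.08,
      tracking = 0.05,
      age = -0.15,
      pta = -0.05
    ),
    speed_mean = 0.62,
    speed_sd = 0.17,
    subject_sd_accuracy = 0.7,
    item_sd_accuracy = 0.3,
    subject_sd_speed = 0.4,
    item_sd_speed = 0.1,
    resid_sd_speed = 0.84
  )
}

#' Derive a reproducible sub-seed
#'
#' Expands one master seed into independent per-stage / per-subject streams
#' so that re-running one stage never perturbs another stage's randomness.
#'
#' @param seed Master integer seed.
#' @param ... Integers or strings identifying the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    }
    h <- (h * 48271 + as.double(p) * 16807 + 1) %% 2147483647
  }
  as.integer(h)
}
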