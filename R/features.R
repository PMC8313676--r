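#' Onset envelope of a broadband amplitude envelope
#'
#' Smooths the amplitude envelope with a short moving average, takes the
#' first difference, half-wave rectifies it (negative values set to zero),
#' and resamples the result to the decoding rate. The onset envelope is the
#' non-negative rate-of-change of acoustic energy that the backward models
#' reconstruct.
#'
#' @param x Non-negative amplitude envelope.
#' @param fs_in Input sample rate in Hz (must be positive).
#' @param fs_out Output sample rate in Hz (default 125).
#' @param smooth_ms Moving-average width in ms applied before differencing.
#' @return Numeric vector at `fs_out`, all values >= 0.
#' @export
onset_envelope <- function(x, fs_in, fs_out = 125, smooth_ms = 20) {
  if (fs_in <= 0) stop("fs_in must be positive")
  if (any(x < 0)) stop("amplitude envelope must be non-negative")
  w <- max(1L, round(smooth_ms / 1000 * fs_in))
  sm <- stats::filter(x, rep(1 / w, w), method = "convolution", sides = 2)
  sm[is.na(sm)] <- x[is.na(sm)]
  d <- c(0, diff(as.numeric(sm)))
  d[d < 0] <- 0
  if (fs_out == fs_in) return(d)
  t_in <- (seq_along(d) - 1) / fs_in
  t_out <- seq(0, max(t_in), by = 1 / fs_out)
  stats::approx(t_in, d, xout = t_out)$y
}

# complex Morlet wavelet kernel, unit L2 norm
morlet_kernel <- function(freq, fs, n_cycles = 6, width_sd = 3.5) {
  sigma_t <- n_cycles / (2 * pi * freq)
  t <- seq(-width_sd * sigma_t, width_sd * sigma_t, by = 1 / fs)
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# same-length FFT convolution with a complex kernel
conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nf <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  K <- stats::fft(c(k, rep(0, nf - m)))
  full <- stats::fft(X * K, inverse = TRUE) / nf
  offset <- (m - 1) %/% 2
  full[(offset + 1):(offset + n)]
}

#' Morlet-wavelet alpha power of a source epoch
#'
#' Computes squared magnitudes of complex Morlet coefficients (6 cycles by
#' default) at 8--12 Hz for every parcel and time point of an epoch.
#'
#' @param epoch A `source_epoch` from [simulate_source_epoch()], or a
#'   parcels x time matrix (then `fs` must be given).
#' @param freqs Analysis frequencies in Hz.
#' @param n_cycles Wavelet cycles.
#' @param fs Sample rate, taken from the epoch if omitted.
#' @return An `alpha_power` array `[parcel, frequency, time]` with
#'   attributes `fs`, `t0`, `freqs`, `edge_margin_s` (half the longest
#'   wavelet support; summaries should discard samples this close to the
#'   epoch edges) and `state = "raw"`.
#' @export
morlet_alpha_power <- function(epoch, freqs = 8:12, n_cycles = 6, fs = NULL) {
  if (inherits(epoch, "source_epoch")) {
    data <- epoch$data
    fs <- epoch$fs
    t0 <- epoch$t0
  } else {
    data <- epoch
    if (is.null(fs)) stop("fs required for a bare matrix input")
    t0 <- 0
  }
  n <- ncol(data)
  kerns <- lapply(freqs, morlet_kernel, fs = fs, n_cycles = n_cycles)
  k_max <- max(vapply(kerns, length, 1L))
  if (n < k_max) {
    stop("epoch too short for the wavelet support: needs at least ",
         k_max, " samples (", round(k_max / fs, 3), " s) at ",
         min(freqs), " Hz")
  }
  out <- array(NA_real_, dim = c(nrow(data), length(freqs), n))
  for (p in seq_len(nrow(data))) {
    for (f in seq_along(freqs)) {
      out[p, f, ] <- Mod(conv_same(data[p, ], kerns[[f]]))^2
    }
  }
  structure(out, fs = fs, t0 = t0, freqs = freqs,
            edge_margin_s = (k_max / 2) / fs, state = "raw")
}

#' Box-Cox power transform
#'
#' Elementwise `(x^p - 1) / p`, the variance-stabilizing transform applied
#' to oscillatory power before statistical analysis. Monotone increasing;
#' `p = 0.5` by default.
#'
#' @param x Numeric array of non-negative power values.
#' @param p Box-Cox exponent.
#' @return Transformed array; for `alpha_power` inputs the `state`
#'   attribute becomes `"boxcox"`.
#' @export
boxcox_transform <- function(x, p = 0.5) {
  out <- (x^p - 1) / p
  a <- attributes(x)
  if (!is.null(a$state)) {
    attributes(out) <- a
    attr(out, "state") <- "boxcox"
  }
  out
}

#' Whole-trial power normalization across a subject's trials
#'
#' Per parcel and frequency, subtracts the scalar mean of power over all
#' time points of all trials, so residual values express deviations from
#' the subject's overall hemispheric power profile.
#'
#' @param tensors List of `alpha_power` arrays (one per trial), all with
#'   identical parcel/frequency/time dimensions.
#' @return List of arrays of the same shape with per-parcel-frequency grand
#'   mean zero; `state` becomes `"normalized"`.
#' @export
normalize_whole_trial <- function(tensors) {
  stopifnot(length(tensors) >= 1)
  d <- dim(tensors[[1]])
  acc <- matrix(0, d[1], d[2])
  for (tn in tensors) {
    stopifnot(all(dim(tn) == d))
    acc <- acc + apply(tn, c(1, 2), mean)
  }
  acc <- acc / length(tensors)
  lapply(tensors, function(tn) {
    out <- tn - array(rep(acc, d[3]), dim = d)
    attributes(out) <- attributes(tn)
    attr(out, "state") <- "normalized"
    out
  })
}

#' Single-trial alpha lateralization index (robust variant)
#'
#' Applies the inverse logit to the (normalized, Box-Cox-transformed) ROI
#' power series of the hemispheres ipsilateral and contralateral to the
#' probed ear, mapping both into (0, 1), and forms the normalized contrast
#' `(ipsi - contra) / (ipsi + contra)`. Positive values indicate relatively
#' higher alpha power ipsilateral to the probed ear.
#'
#' @param power_ipsi,power_contra Numeric series of equal length.
#' @return Numeric series in (-1, 1).
#' @export
alpha_lateralization_index <- function(power_ipsi, power_contra) {
  if (length(power_ipsi) != length(power_contra)) {
    stop("power series must have equal length")
  }
  a <- stats::plogis(power_ipsi)
  b <- stats::plogis(power_contra)
  (a - b) / (a + b)
}

#' Window summaries of a per-trial index series
#'
#' Extracts the sentence-presentation mean and the final-word mean (mean of
#' the final 35% of the percent-warped series) from a time-resolved
#' per-trial measure such as the ALI or the neural tracking index.
#'
#' @param series Numeric series (e.g. an ALI time course).
#' @param fs Sample rate of `series`.
#' @param t0 Time of the first sample, in seconds relative to cue onset.
#' @param window Two-element numeric, sentence start/end in seconds.
#' @param edge_margin_s Samples within this margin of the series edges are
#'   excluded (wavelet edge handling); the window is clipped accordingly.
#' @return List with `sentence_mean`, `final_word_mean`, and the
#'   `warped` 100-bin series used for the final-word summary.
#' @export
roi_window_summaries <- function(series, fs, t0, window,
                                 edge_margin_s = 0) {
  t_end <- t0 + (length(series) - 1) / fs
  lo <- max(window[1], t0 + edge_margin_s)
  hi <- min(window[2], t_end - edge_margin_s)
  if (hi <= lo) stop("summary window empty after edge-margin clipping")
  i0 <- max(1L, round((lo - t0) * fs) + 1L)
  i1 <- min(length(series), round((hi - t0) * fs) + 1L)
  seg <- series[i0:i1]
  warped <- warp_to_percent(seg, 1L, length(seg))
  list(sentence_mean = mean(seg, na.rm = TRUE),
       final_word_mean = final_word_mean(warped),
       warped = warped)
}

#' Per-trial alpha lateralization features for a dataset
#'
#' Runs the full alpha pipeline for every subject of a synthetic dataset:
#' Morlet power, Box-Cox transform, whole-trial normalization across the
#' subject's trials, ROI (hemisphere) averaging over parcels and
#' frequencies, ipsi/contra assignment by probed ear, the robust ALI, and
#' window summaries.
#'
#' @param dataset A `dl_dataset` with epochs.
#' @param freqs,n_cycles Wavelet parameters.
#' @return List with `features` (data frame: subject, trial, ALI_sentence,
#'   ALI_final) and `warped` (trials x 100 matrix of percent-warped ALI
#'   time courses, rows aligned with `features`).
#' @export
compute_alpha_features <- function(dataset, freqs = 8:12, n_cycles = 6) {
  stopifnot(inherits(dataset, "dl_dataset"), !is.null(dataset$epochs))
  trials <- dataset$trials
  res <- vector("list", nrow(trials))
  warped <- matrix(NA_real_, nrow(trials), 100)
  for (s in unique(trials$subject)) {
    idx <- which(trials$subject == s)
    tensors <- lapply(dataset$epochs[idx], morlet_alpha_power,
                      freqs = freqs, n_cycles = n_cycles)
    margin <- attr(tensors[[1]], "edge_margin_s")
    fs <- attr(tensors[[1]], "fs")
    t0 <- attr(tensors[[1]], "t0")
    tensors <- normalize_whole_trial(lapply(tensors, boxcox_transform))
    hemis <- dataset$epochs[[idx[1]]]$hemisphere
    for (j in seq_along(idx)) {
      i <- idx[j]
      ep <- dataset$epochs[[i]]
      # ROI average over parcels and frequencies per hemisphere
      roi <- lapply(c("L", "R"), function(h) {
        apply(tensors[[j]][hemis == h, , , drop = FALSE], 3, mean)
      })
      names(roi) <- c("L", "R")
      ipsi <- if (trials$probed_ear[i] == "left") "L" else "R"
      ali <- alpha_lateralization_index(roi[[ipsi]],
                                        roi[[setdiff(c("L", "R"), ipsi)]])
      win <- c(ep$sentence_onset_s, ep$sentence_onset_s + ep$span_s)
      sm <- roi_window_summaries(ali, fs, t0, win, edge_margin_s = margin)
      warped[i, ] <- sm$warped
      res[[i]] <- data.frame(subject = s, trial = trials$trial[i],
                             ALI_sentence = sm$sentence_mean,
                             ALI_final = sm$final_word_mean)
    }
  }
  list(features = do.call(rbind, res), warped = warped)
}
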