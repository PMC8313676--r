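#' Warp a per-trial series onto a percent-of-sentence axis
#'
#' Sentences differ in length, so per-trial time courses are mapped onto a
#' common axis of 100 bins covering the sentence in 1% increments (bin b
#' covers ((b-1), b]% of the sentence). Bin means are then smoothed with a
#' centred rectangular 3-bin sliding window evaluated at every bin; edge
#' bins average over the available neighbours.
#'
#' @param series Numeric series.
#' @param start,end Sample indices of sentence start and end within
#'   `series`.
#' @return A `warped_series`: numeric vector of exactly 100 bins with
#'   attribute `smoothed = TRUE`.
#' @export
warp_to_percent <- function(series, start, end) {
  stopifnot(start >= 1, end <= length(series), start < end)
  seg <- series[start:end]
  n <- length(seg)
  if (n < 100) {
    stop("sentence segment has ", n,
         " samples; at least 100 are required for 1% bins")
  }
  bin <- ceiling(100 * seq_len(n) / n)
  means <- as.numeric(tapply(seg, factor(bin, levels = 1:100),
                             function(v) mean(v, na.rm = TRUE)))
  means[is.nan(means)] <- NA_real_
  sm <- vapply(1:100, function(b) {
    nb <- means[max(1, b - 1):min(100, b + 1)]
    if (all(is.na(nb))) NA_real_ else mean(nb, na.rm = TRUE)
  }, 1.0)
  structure(sm, smoothed = TRUE, class = "warped_series")
}

#' Final-word mean of a warped series
#'
#' Mean over the final 35% of sentence presentation (bins 66--100), the
#' interval covering final-word onset across sentence pairs. Missing bins
#' are skipped; the number of bins actually used is attached.
#'
#' @param warped A `warped_series` (or any 100-bin numeric vector).
#' @return Scalar mean with attribute `n_used`.
#' @export
final_word_mean <- function(warped) {
  stopifnot(length(warped) == 100)
  v <- warped[66:100]
  n_used <- sum(!is.na(v))
  if (n_used < length(v)) {
    message("final_word_mean: ", length(v) - n_used, " of 35 bins missing")
  }
  structure(mean(v, na.rm = TRUE), n_used = n_used)
}

#' Group-level time course of a warped measure
#'
#' Averages within subjects first, then reports the grand mean and the
#' between-subject SEM per bin.
#'
#' @param warped Trials x 100 matrix of warped series.
#' @param subject Subject id per row.
#' @param keep Optional logical filter over rows (e.g. a condition).
#' @return Data frame with `bin`, `mean`, `sem`, `n_subjects`; `sem` is NA
#'   with a single subject.
#' @export
group_timecourse <- function(warped, subject, keep = NULL) {
  if (!is.null(keep)) {
    warped <- warped[keep, , drop = FALSE]
    subject <- subject[keep]
  }
  subs <- unique(subject)
  sub_means <- t(vapply(subs, function(s) {
    colMeans(warped[subject == s, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(warped))))
  m <- colMeans(sub_means, na.rm = TRUE)
  sem <- if (length(subs) > 1) {
    apply(sub_means, 2, stats::sd, na.rm = TRUE) / sqrt(length(subs))
  } else {
    rep(NA_real_, ncol(warped))
  }
  data.frame(bin = seq_len(ncol(warped)), mean = m, sem = sem,
             n_subjects = length(subs))
}

#' Normalized cross-correlation of two warped time courses
#'
#' Mean-removed cross-correlation normalized by the product of the two full
#' series' (population) standard deviations and the overlap length, so the
#' zero-lag value of a series with itself is exactly 1. Sign convention: a
#' positive peak lag means `x` leads `y` (fluctuations in `x` occur
#' earlier).
#'
#' @param x,y Numeric series of equal length (e.g. 100-bin grand averages).
#' @param max_lag Maximum lag in bins.
#' @return List with `lags`, `cc`, `peak_lag`, `peak_value` (peak of the
#'   positive cross-correlation).
#' @export
crosscorrelate <- function(x, y, max_lag = 50) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  xm <- x - mean(x, na.rm = TRUE)
  ym <- y - mean(y, na.rm = TRUE)
  sx <- sqrt(mean(xm^2, na.rm = TRUE))
  sy <- sqrt(mean(ym^2, na.rm = TRUE))
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    stop("zero variance input: cross-correlation undefined")
  }
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- xm[seq_len(n - k)]
      b <- ym[seq_len(n - k) + k]
    } else {
      a <- xm[seq_len(n + k) - k]
      b <- ym[seq_len(n + k)]
    }
    ok <- !is.na(a) & !is.na(b)   # missing bins drop out pairwise
    if (!any(ok)) return(NA_real_)
    sum(a[ok] * b[ok]) / (sum(ok) * sx * sy)
  }, 1.0)
  i <- which.max(cc)
  list(lags = lags, cc = cc, peak_lag = lags[i], peak_value = cc[i])
}

#' Permutation surrogate band for a cross-correlation
#'
#' Derives a per-lag null band by independently permuting the bin order of
#' both series, recomputing the cross-correlation for each of
#' `n_permutations` surrogate pairs, and taking the 2.5th and 97.5th
#' percentile per lag.
#'
#' @param x,y Numeric series of equal length.
#' @param n_permutations Number of surrogate pairs (5000 by default).
#' @param max_lag Maximum lag in bins.
#' @return List with `lags`, `lo`, `hi` (per-lag percentile band) and
#'   `n_permutations`.
#' @export
surrogate_band <- function(x, y, n_permutations = 5000, max_lag = 50) {
  sx <- stats::sd(x, na.rm = TRUE)
  sy <- stats::sd(y, na.rm = TRUE)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    stop("zero variance input: surrogates undefined")
  }
  sur <- matrix(NA_real_, n_permutations, 2 * max_lag + 1)
  for (i in seq_len(n_permutations)) {
    sur[i, ] <- crosscorrelate(sample(x), sample(y), max_lag)$cc
  }
  list(lags = -max_lag:max_lag,
       lo = apply(sur, 2, stats::quantile, probs = 0.025, names = FALSE),
       hi = apply(sur, 2, stats::quantile, probs = 0.975, names = FALSE),
       n_permutations = n_permutations)
}

#' Convert a percent-bin lag to milliseconds
#'
#' One bin is 1% of a sentence, so a lag of `k` bins corresponds to
#' `k / 100` of the mean sentence duration.
#'
#' @param lag_bins Lag in bins (sign preserved).
#' @param mean_sentence_duration_ms Mean sentence duration in ms.
#' @return Lag in milliseconds.
#' @export
lag_to_ms <- function(lag_bins, mean_sentence_duration_ms) {
  lag_bins * mean_sentence_duration_ms / 100
}
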