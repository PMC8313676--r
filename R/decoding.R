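#' Integer-sample lag grid for backward models
#'
#' The reconstruction at time t uses neural samples from about t - 100 ms
#' up to t + 500 ms (neural activity lagging the stimulus). The grid holds
#' `round((tmax - tmin) * fs) + 1` integer-sample lags starting at
#' `floor(tmin * fs)`; at 125 Hz the default -0.1..0.5 s range yields 76
#' lags of 8 ms spacing.
#'
#' @param fs Sample rate in Hz.
#' @param tmin,tmax Lag range in seconds.
#' @return Integer vector of lags in samples.
#' @export
lag_grid <- function(fs, tmin = -0.1, tmax = 0.5) {
  n <- round((tmax - tmin) * fs) + 1L
  floor(tmin * fs) + seq_len(n) - 1L
}

#' Time-lagged design matrix of a parcel response
#'
#' Sample-wise time-lagged replication of the parcel x time response: the
#' row for time t holds r(t + tau, n) for every parcel n and lag tau, with
#' out-of-range samples zero-filled. Columns are grouped by parcel, lags
#' varying fastest.
#'
#' @param resp Parcels x time numeric matrix.
#' @param fs Sample rate in Hz.
#' @param tmin,tmax Lag range in seconds (ignored when `lags` is given).
#' @param lags Optional explicit integer lag vector (samples).
#' @return A `lag_design`: list with `X` (time x (parcels * lags) matrix),
#'   `lags`, `fs`, `n_parcels`.
#' @export
build_lag_design <- function(resp, fs, tmin = -0.1, tmax = 0.5, lags = NULL) {
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = 1)
  if (is.null(lags)) lags <- lag_grid(fs, tmin, tmax)
  n_t <- ncol(resp)
  n_p <- nrow(resp)
  n_l <- length(lags)
  X <- matrix(0, n_t, n_p * n_l)
  for (p in seq_len(n_p)) {
    for (l in seq_len(n_l)) {
      sh <- lags[l]
      t0 <- max(1L, 1L - sh)
      t1 <- min(n_t, n_t - sh)
      if (t0 <= t1) {
        X[t0:t1, (p - 1L) * n_l + l] <- resp[p, (t0 + sh):(t1 + sh)]
      }
    }
  }
  structure(list(X = X, lags = lags, fs = fs, n_parcels = n_p),
            class = "lag_design")
}

design_matrix <- function(design) {
  if (inherits(design, "lag_design")) design$X else design
}

# sufficient statistics of one (design, envelope-pair) block, so that
# leave-one-out training sets can be formed by subtraction
gram_stats <- function(X, s_list) {
  list(XtX = crossprod(X),
       Xts = lapply(s_list, function(s) crossprod(X, s)),
       colsum = colSums(X),
       ssum = vapply(s_list, sum, 1.0),
       n = nrow(X))
}

add_stats <- function(a, b, sign = 1) {
  if (is.null(a)) return(b)
  list(XtX = a$XtX + sign * b$XtX,
       Xts = Map(function(u, v) u + sign * v, a$Xts, b$Xts),
       colsum = a$colsum + sign * b$colsum,
       ssum = a$ssum + sign * b$ssum,
       n = a$n + sign * b$n)
}

# closed-form ridge from sufficient statistics (centered, no intercept)
ridge_from_stats <- function(st, lambda, role_idx = 1) {
  mu <- st$colsum / st$n
  ms <- st$ssum[role_idx] / st$n
  XtX_c <- st$XtX - st$n * tcrossprod(mu)
  Xts_c <- st$Xts[[role_idx]] - st$n * mu * ms
  m <- mean(diag(XtX_c))
  A <- XtX_c + diag(lambda * m, ncol(XtX_c))
  g <- tryCatch(solve(A, Xts_c), error = function(e) {
    stop("rank-deficient system at lambda = ", lambda,
         ": ", conditionMessage(e))
  })
  list(g = as.numeric(g), m = m, mu = mu, mean_s = ms)
}

#' Train an envelope reconstruction (backward) model
#'
#' Closed-form ridge regression `g = (R'R + lambda * m * I)^{-1} R' s`,
#' where `m` is the mean of the trace of the (centered) `R'R`. The design
#' columns and the envelope are mean-centered over the training set; no
#' intercept column is used.
#'
#' @param design A `lag_design` or plain numeric design matrix (time x
#'   features); multiple trials should be concatenated (zero-padded) rows.
#' @param s Target onset envelope, one value per design row.
#' @param lambda Ridge parameter.
#' @param attend_side,role Optional labels ("left"/"right",
#'   "attended"/"ignored") carried on the decoder.
#' @return A `decoder`: list with `weights` (feature vector), `weights_mat`
#'   (lags x parcels when lag metadata is available), `lambda`, `m`,
#'   `mu`, `mean_s`, `lags`, `fs`, `attend_side`, `role`.
#' @export
train_decoder <- function(design, s, lambda, attend_side = NA, role = NA) {
  X <- design_matrix(design)
  if (nrow(X) != length(s)) stop("design and envelope must be time-aligned")
  st <- gram_stats(X, list(s))
  fit <- ridge_from_stats(st, lambda)
  new_decoder(fit, lambda, design, attend_side, role)
}

new_decoder <- function(fit, lambda, design = NULL, attend_side = NA,
                        role = NA) {
  wmat <- NULL
  lags <- NULL
  fs <- NULL
  if (inherits(design, "lag_design")) {
    lags <- design$lags
    fs <- design$fs
    wmat <- matrix(fit$g, nrow = length(lags), ncol = design$n_parcels)
  }
  structure(list(weights = fit$g, weights_mat = wmat, lambda = lambda,
                 m = fit$m, mu = fit$mu, mean_s = fit$mean_s,
                 lags = lags, fs = fs, attend_side = attend_side,
                 role = role),
            class = "decoder")
}

#' Reconstruct an envelope with a trained decoder
#'
#' @param decoder A `decoder` from [train_decoder()].
#' @param design A `lag_design` or design matrix for the test trial.
#' @return Numeric reconstructed envelope.
#' @export
predict_decoder <- function(decoder, design) {
  X <- design_matrix(design)
  as.numeric(X %*% decoder$weights) -
    sum(decoder$mu * decoder$weights) + decoder$mean_s
}

#' Select the ridge parameter on pooled reconstruction metrics
#'
#' One global lambda is chosen as the grid value maximizing the mean
#' Pearson correlation of reconstructed and presented envelopes pooled over
#' trials (and subjects); exact ties are broken by the lower mean squared
#' error. Non-finite metrics (e.g. from pure-noise envelopes) are treated
#' as worst-case rather than propagated.
#'
#' @param grid Candidate lambda values.
#' @param corr_mean,mse_mean Mean correlation and MSE per grid value.
#' @return The selected lambda.
#' @export
select_lambda <- function(grid, corr_mean, mse_mean) {
  stopifnot(length(grid) == length(corr_mean),
            length(grid) == length(mse_mean))
  corr_mean[!is.finite(corr_mean)] <- -Inf
  mse_mean[!is.finite(mse_mean)] <- Inf
  best <- which(corr_mean == max(corr_mean))
  if (length(best) > 1) best <- best[which.min(mse_mean[best])]
  grid[best]
}

#' Sliding-window Pearson correlation
#'
#' Correlation of two series within a centred rectangular window (default
#' 31 samples = 248 ms at 125 Hz) stepped by one sample. Windows with zero
#' variance in either series, or incomplete windows at the edges, yield NA
#' rather than 0.
#'
#' @param x,y Numeric series of equal length.
#' @param window Window length in samples (odd).
#' @return Numeric series of per-window correlations, same length as `x`.
#' @export
sliding_correlation <- function(x, y, window = 31) {
  stopifnot(length(x) == length(y))
  if (window %% 2 == 0) stop("window must be odd (centred window)")
  n <- length(x)
  if (n < window) return(rep(NA_real_, n))
  w <- window
  msum <- function(v) as.numeric(stats::filter(v, rep(1, w), sides = 2))
  sx <- msum(x); sy <- msum(y)
  sxx <- msum(x^2); syy <- msum(y^2); sxy <- msum(x * y)
  vx <- sxx - sx^2 / w
  vy <- syy - sy^2 / w
  cov <- sxy - sx * sy / w
  tol_x <- 1e-12 * pmax(sxx, 1e-300)
  tol_y <- 1e-12 * pmax(syy, 1e-300)
  r <- ifelse(!is.na(vx) & vx > tol_x & vy > tol_y,
              cov / sqrt(vx * vy), NA_real_)
  r
}

#' Neural tracking index
#'
#' Normalized contrast of the attended and ignored reconstruction accuracy,
#' `(r_att - r_ign) / (r_att + r_ign)`, computed elementwise. Positive
#' values indicate stronger tracking of the attended (probed) stream. The
#' index is stored unclipped; samples where either input is missing or the
#' denominator magnitude falls below `tol` are missing.
#'
#' @param r_att,r_ign Correlation series of equal length.
#' @param tol Denominator tolerance.
#' @return Numeric index series.
#' @export
tracking_index <- function(r_att, r_ign, tol = 1e-6) {
  stopifnot(length(r_att) == length(r_ign))
  den <- r_att + r_ign
  out <- (r_att - r_ign) / den
  out[is.na(r_att) | is.na(r_ign) | abs(den) < tol] <- NA_real_
  out
}

#' Transform a backward model into forward (encoding) weights
#'
#' Backward-model weights are not directly interpretable; the standard
#' transformation multiplies them by the covariance of the (lagged) neural
#' responses and rescales by the inverse variance of the reconstructed
#' stimulus, yielding forward weights per parcel and lag that can be read
#' as a temporal response function.
#'
#' @param decoder A `decoder`.
#' @param response_cov Covariance matrix of the lagged design (features x
#'   features).
#' @param recon_var Variance of the reconstructed stimulus.
#' @return Matrix of forward weights (lags x parcels when lag metadata is
#'   available, otherwise a feature vector).
#' @export
forward_transform <- function(decoder, response_cov, recon_var) {
  a <- as.numeric(response_cov %*% decoder$weights) / recon_var
  if (!is.null(decoder$lags)) {
    matrix(a, nrow = length(decoder$lags),
           ncol = length(a) / length(decoder$lags))
  } else {
    a
  }
}

#' Forward transform computed from a design matrix
#'
#' Convenience wrapper around [forward_transform()] that estimates the
#' response covariance and reconstruction variance from a given design.
#'
#' @param decoder A `decoder`.
#' @param design A `lag_design` or design matrix.
#' @return Forward weights as in [forward_transform()].
#' @export
forward_from_design <- function(decoder, design) {
  X <- design_matrix(design)
  Xc <- sweep(X, 2, colMeans(X))
  covR <- crossprod(Xc) / (nrow(Xc) - 1)
  shat <- as.numeric(Xc %*% decoder$weights)
  forward_transform(decoder, covR, stats::var(shat))
}
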