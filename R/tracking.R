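# fit attended and ignored decoders sharing one factorization
ridge_pair_from_stats <- function(st, lambda) {
  mu <- st$colsum / st$n
  XtX_c <- st$XtX - st$n * tcrossprod(mu)
  m <- mean(diag(XtX_c))
  A <- XtX_c + diag(lambda * m, ncol(XtX_c))
  B <- cbind(st$Xts[[1]] - st$n * mu * (st$ssum[1] / st$n),
             st$Xts[[2]] - st$n * mu * (st$ssum[2] / st$n))
  G <- tryCatch(solve(A, B), error = function(e) {
    stop("rank-deficient system at lambda = ", lambda, ": ",
         conditionMessage(e))
  })
  list(att = list(g = G[, 1], m = m, mu = mu, mean_s = st$ssum[1] / st$n),
       ign = list(g = G[, 2], m = m, mu = mu, mean_s = st$ssum[2] / st$n))
}

#' Extract decoding-ready trials from a synthetic dataset
#'
#' Converts source epochs to the decoding representation: each trial's
#' parcel responses are low-pass filtered (zero-phase FIR, default 8 Hz
#' cutoff, removing alpha-band content), decimated to the 125 Hz envelope
#' rate, and cut to the sentence-pair grid, together with the attended
#' (probed) and ignored (unprobed) onset envelopes and their sentence
#' extents.
#'
#' @param dataset A `dl_dataset` with epochs.
#' @param lowpass Low-pass cutoff in Hz (NULL to skip filtering).
#' @param fir_order FIR filter order.
#' @return List of trials; each holds `resp` (parcels x time at 125 Hz),
#'   `env_att`, `env_ign`, `att_idx`, `ign_idx` (start/end samples),
#'   `side` (attended ear, or probed ear under divided attention),
#'   `condition`, `subject`, `trial`, `fs`.
#' @export
decoding_data <- function(dataset, lowpass = 8, fir_order = 100) {
  stopifnot(inherits(dataset, "dl_dataset"), !is.null(dataset$epochs))
  trials <- dataset$trials
  fs_out <- dataset$config$sample_rate
  out <- vector("list", nrow(trials))
  b <- NULL
  for (i in seq_len(nrow(trials))) {
    ep <- dataset$epochs[[i]]
    dec <- as.integer(round(ep$fs / fs_out))
    resp <- ep$data
    if (!is.null(lowpass)) {
      # symmetric FIR applied centred = zero-phase low-pass
      if (is.null(b)) b <- signal::fir1(fir_order, lowpass / (ep$fs / 2))
      resp <- t(apply(resp, 1, function(r) {
        y <- stats::filter(r, b, sides = 2)
        y[is.na(y)] <- 0
        as.numeric(y)
      }))
    }
    pair <- dataset$envelopes[[i]]
    probed_idx <- if (trials$probed_ear[i] == "left") 1L else 2L
    env_att <- pair$envelopes[[probed_idx]]
    env_ign <- pair$envelopes[[3 - probed_idx]]
    n_env <- length(env_att$values)
    start_idx <- round((ep$sentence_onset_s - ep$t0) * ep$fs) + 1L
    idx <- start_idx + dec * (seq_len(n_env) - 1L)
    idx <- idx[idx <= ncol(resp)]
    n_use <- length(idx)
    out[[i]] <- list(
      resp = resp[, idx, drop = FALSE],
      env_att = env_att$values[seq_len(n_use)],
      env_ign = env_ign$values[seq_len(n_use)],
      att_idx = c(env_att$start, min(env_att$end, n_use)),
      ign_idx = c(env_ign$start, min(env_ign$end, n_use)),
      side = trials$probed_ear[i],
      condition = ifelse(trials$spatial_cue[i] == "informative",
                         "selective", "divided"),
      subject = trials$subject[i],
      trial = trials$trial[i],
      fs = fs_out
    )
  }
  out
}

pad_trial <- function(trial, pad) {
  p <- nrow(trial$resp)
  z <- matrix(0, p, pad)
  list(resp = cbind(z, trial$resp, z),
       env_att = c(numeric(pad), trial$env_att, numeric(pad)),
       env_ign = c(numeric(pad), trial$env_ign, numeric(pad)))
}

trial_stats <- function(trial, pad, tmin, tmax) {
  pt <- pad_trial(trial, pad)
  X <- build_lag_design(pt$resp, trial$fs, tmin, tmax)$X
  gram_stats(X, list(pt$env_att, pt$env_ign))
}

#' Leave-one-out envelope reconstruction and tracking indices
#'
#' Trains attended and ignored backward models per attend side on the
#' subject's selective-attention trials (concatenated with 600 ms zero
#' padding on both sides of each trial) and reconstructs every trial's two
#' envelopes: selective trials with the models trained on all other trials
#' of the same side, divided trials with the full selective models of the
#' side matching the probed ear (probed-left/unprobed-right trials use the
#' attend-left/ignore-right models and conversely). Reconstructions are
#' compared to the presented onset envelopes with a sliding-window Pearson
#' correlation, from which the neural tracking index and its window
#' summaries are derived.
#'
#' @param trials_list Trials from [decoding_data()] (one subject).
#' @param lambda Ridge parameter.
#' @param tmin,tmax Lag range in seconds.
#' @param window Sliding-correlation window in samples (31 = 248 ms).
#' @param pad_s Zero padding per trial side, in seconds.
#' @return List with `trials` (data frame: subject, trial, condition, side,
#'   r_att_mean, r_ign_mean, NTI_sentence, NTI_final, and decoder
#'   specificity correlations r_attmod_att, r_attmod_ign, r_ignmod_ign,
#'   r_ignmod_att), `warped` (trials x 100 matrix of warped index series),
#'   `series` (per-trial r/index series), and `decoders` (full-data decoder
#'   pair per side).
#' @export
loo_reconstruct <- function(trials_list, lambda = 1, tmin = -0.1,
                            tmax = 0.5, window = 31, pad_s = 0.6) {
  n <- length(trials_list)
  fs <- trials_list[[1]]$fs
  pad <- round(pad_s * fs)
  cond <- vapply(trials_list, `[[`, "", "condition")
  side <- vapply(trials_list, `[[`, "", "side")

  totals <- list(left = NULL, right = NULL)
  usable <- c(left = FALSE, right = FALSE)
  for (sd in c("left", "right")) {
    sel <- which(cond == "selective" & side == sd)
    if (length(sel) < 2) {
      if (any(side == sd)) {
        warning("fewer than 2 selective attend-", sd,
                " trials: skipping this side")
      }
      next
    }
    usable[sd] <- TRUE
    for (i in sel) {
      totals[[sd]] <- add_stats(totals[[sd]],
                                trial_stats(trials_list[[i]], pad, tmin, tmax))
    }
  }

  full_fit <- lapply(c(left = "left", right = "right"), function(sd) {
    if (usable[sd]) ridge_pair_from_stats(totals[[sd]], lambda) else NULL
  })

  rows <- vector("list", n)
  series <- vector("list", n)
  warped <- matrix(NA_real_, n, 100)
  for (i in seq_len(n)) {
    tr <- trials_list[[i]]
    if (!usable[tr$side]) next
    if (cond[i] == "selective") {
      st <- add_stats(totals[[tr$side]], trial_stats(tr, pad, tmin, tmax), -1)
      fit <- ridge_pair_from_stats(st, lambda)
    } else {
      fit <- full_fit[[tr$side]]
    }
    X <- build_lag_design(tr$resp, fs, tmin, tmax)$X
    shat_att <- as.numeric(X %*% fit$att$g) -
      sum(fit$att$mu * fit$att$g) + fit$att$mean_s
    shat_ign <- as.numeric(X %*% fit$ign$g) -
      sum(fit$ign$mu * fit$ign$g) + fit$ign$mean_s

    r_att <- sliding_correlation(shat_att, tr$env_att, window)
    r_ign <- sliding_correlation(shat_ign, tr$env_ign, window)
    nti <- tracking_index(r_att, r_ign)

    a0 <- tr$att_idx[1]; a1 <- tr$att_idx[2]
    g0 <- tr$ign_idx[1]; g1 <- tr$ign_idx[2]
    wv <- warp_to_percent(nti, a0, a1)
    warped[i, ] <- wv
    mean_in <- function(v, i0, i1) mean(v[i0:i1], na.rm = TRUE)
    rows[[i]] <- data.frame(
      subject = tr$subject, trial = tr$trial, condition = cond[i],
      side = tr$side,
      r_att_mean = mean_in(r_att, a0, a1),
      r_ign_mean = mean_in(r_ign, g0, g1),
      NTI_sentence = mean_in(nti, a0, a1),
      NTI_final = as.numeric(final_word_mean(wv)),
      r_attmod_att = mean_in(sliding_correlation(shat_att, tr$env_att, window), a0, a1),
      r_attmod_ign = mean_in(sliding_correlation(shat_att, tr$env_ign, window), g0, g1),
      r_ignmod_ign = mean_in(sliding_correlation(shat_ign, tr$env_ign, window), g0, g1),
      r_ignmod_att = mean_in(sliding_correlation(shat_ign, tr$env_att, window), a0, a1)
    )
    series[[i]] <- list(r_att = r_att, r_ign = r_ign, index = nti)
  }

  decoders <- lapply(c(left = "left", right = "right"), function(sd) {
    if (!usable[sd]) return(NULL)
    lg <- lag_grid(fs, tmin, tmax)
    n_parc <- nrow(trials_list[[1]]$resp)
    mk <- function(fit, role) {
      structure(list(weights = fit$g,
                     weights_mat = matrix(fit$g, length(lg), n_parc),
                     lambda = lambda, m = fit$m, mu = fit$mu,
                     mean_s = fit$mean_s, lags = lg, fs = fs,
                     attend_side = sd, role = role), class = "decoder")
    }
    list(attended = mk(full_fit[[sd]]$att, "attended"),
         ignored = mk(full_fit[[sd]]$ign, "ignored"))
  })

  keep <- !vapply(rows, is.null, TRUE)
  list(trials = do.call(rbind, rows[keep]),
       warped = warped,
       series = series,
       decoders = decoders)
}

#' Tune the ridge parameter by pooled leave-one-out reconstruction
#'
#' Runs the leave-one-out reconstruction of the selective trials at every
#' grid value and selects the lambda maximizing the mean sliding-window
#' correlation pooled over trials and decoder roles (ties broken by lower
#' MSE), mirroring a grid search over `10^-5 .. 10^10`.
#'
#' @param trials_list Trials from [decoding_data()].
#' @param grid Candidate lambdas.
#' @param tmin,tmax,window,pad_s As in [loo_reconstruct()].
#' @return List with `lambda` and a `metrics` data frame (lambda,
#'   corr_mean, mse_mean).
#' @export
tune_lambda <- function(trials_list, grid = 10^(-5:10), tmin = -0.1,
                        tmax = 0.5, window = 31, pad_s = 0.6) {
  fs <- trials_list[[1]]$fs
  pad <- round(pad_s * fs)
  cond <- vapply(trials_list, `[[`, "", "condition")
  side <- vapply(trials_list, `[[`, "", "side")
  corr_acc <- numeric(length(grid))
  mse_acc <- numeric(length(grid))
  n_acc <- numeric(length(grid))

  for (sd in c("left", "right")) {
    sel <- which(cond == "selective" & side == sd)
    if (length(sel) < 2) next
    tot <- NULL
    for (i in sel) {
      tot <- add_stats(tot, trial_stats(trials_list[[i]], pad, tmin, tmax))
    }
    for (i in sel) {
      tr <- trials_list[[i]]
      st <- add_stats(tot, trial_stats(tr, pad, tmin, tmax), -1)
      X <- build_lag_design(tr$resp, fs, tmin, tmax)$X
      for (k in seq_along(grid)) {
        fit <- ridge_pair_from_stats(st, grid[k])
        for (role in c("att", "ign")) {
          f <- fit[[role]]
          shat <- as.numeric(X %*% f$g) - sum(f$mu * f$g) + f$mean_s
          s <- if (role == "att") tr$env_att else tr$env_ign
          rs <- sliding_correlation(shat, s, window)
          corr_acc[k] <- corr_acc[k] + mean(rs, na.rm = TRUE)
          mse_acc[k] <- mse_acc[k] + mean((shat - s)^2)
          n_acc[k] <- n_acc[k] + 1
        }
      }
    }
  }
  if (all(n_acc == 0)) stop("no side had >= 2 selective trials")
  metrics <- data.frame(lambda = grid, corr_mean = corr_acc / n_acc,
                        mse_mean = mse_acc / n_acc)
  list(lambda = select_lambda(grid, metrics$corr_mean, metrics$mse_mean),
       metrics = metrics)
}

#' Decoder specificity summary
#'
#' Per subject, the mean correlation of each reconstruction (attended and
#' ignored model) with both presented envelopes, and the attended-vs-
#' ignored contrast per decoder role. Positive contrasts indicate that each
#' model's reconstruction resembles its own target envelope more than the
#' competing one.
#'
#' @param loo_trials The `trials` data frame from [loo_reconstruct()]
#'   (possibly row-bound over subjects).
#' @return Data frame per subject with mean correlations and contrasts
#'   `contrast_att`, `contrast_ign`.
#' @export
validate_decoder_specificity <- function(loo_trials) {
  out <- do.call(rbind, lapply(split(loo_trials, loo_trials$subject),
    function(d) {
      data.frame(
        subject = d$subject[1],
        n_trials = nrow(d),
        r_attmod_att = mean(d$r_attmod_att, na.rm = TRUE),
        r_attmod_ign = mean(d$r_attmod_ign, na.rm = TRUE),
        r_ignmod_ign = mean(d$r_ignmod_ign, na.rm = TRUE),
        r_ignmod_att = mean(d$r_ignmod_att, na.rm = TRUE)
      )
    }))
  out$contrast_att <- out$r_attmod_att - out$r_attmod_ign
  out$contrast_ign <- out$r_ignmod_ign - out$r_ignmod_att
  rownames(out) <- NULL
  out
}
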