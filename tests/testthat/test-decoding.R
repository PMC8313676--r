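test_that("the lag grid and design replicate responses at the stated lags", {
  lg <- lag_grid(125, -0.1, 0.5)
  expect_length(lg, 76)
  r <- matrix(rnorm(10 * 100), 10)
  expect_equal(ncol(build_lag_design(r, 125)$X), 760)
  # single parcel, lag 0: design equals the series
  x <- rnorm(50)
  d0 <- build_lag_design(matrix(x, 1), 125, lags = 0L)
  expect_equal(as.numeric(d0$X), x)
  # impulse with lags {0, +1}: column 2 holds r(t + 1)
  imp <- numeric(30); imp[12] <- 1
  d1 <- build_lag_design(matrix(imp, 1), 125, lags = c(0L, 1L))
  expect_equal(d1$X[, 1], imp)
  oracle <- c(imp[-1], 0)          # brute-force shift
  expect_equal(d1$X[, 2], oracle)
})

test_that("closed-form ridge matches an iterative least-squares oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n)
    s <- rnorm(n)
    lambda <- 10^runif(1, -3, 2)
    dec <- train_decoder(X, s, lambda)
    expect_lt(max(abs(dec$weights - cg_ridge(X, s, lambda))), 1e-8)
  }
})

test_that("ridge shrinkage is monotone and recovers a planted decoder", {
  set.seed(8)
  resp <- matrix(rnorm(3 * 400), 3)
  X <- build_lag_design(resp, 125, lags = 0:4)
  g_star <- rnorm(15)
  s <- as.numeric(X$X %*% g_star)
  dec <- train_decoder(X, s, 1e-5)
  expect_lt(max(abs(dec$weights - g_star)), 1e-3)
  norms <- vapply(10^seq(-5, 10), function(l) {
    sqrt(sum(train_decoder(X, s, l)$weights^2))
  }, 1.0)
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[length(norms)], 1e-6 * norms[1])
})

test_that("lambda selection maximizes correlation with MSE tie-breaking", {
  expect_equal(select_lambda(5, 0.2, 1), 5)
  grid <- 10^(-2:2)
  corr <- c(0.1, 0.5, 0.5, 0.3, NaN)
  mse <- c(1, 0.8, 0.4, 1, NaN)
  expect_equal(select_lambda(grid, corr, mse), grid[3])
  expect_equal(select_lambda(grid, rep(NaN, 5), rep(NaN, 5)), grid[1])
  # oracle equivalence on random metrics
  set.seed(9)
  for (i in 1:20) {
    cm <- round(runif(5), 2)
    mm <- runif(5)
    best <- which(cm == max(cm))
    best <- best[which.min(mm[best])]
    expect_equal(select_lambda(grid, cm, mm), grid[best])
  }
})

test_that("pooled LOO tuning picks an interior lambda on noisy data", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 3, seed = 17)
  ds <- generate_dataset(cfg)
  td <- decoding_data(ds)
  grid <- 10^(-5:10)
  tl <- tune_lambda(td, grid = grid)
  expect_true(is.finite(tl$lambda))
  expect_gt(tl$lambda, min(grid))
  expect_lt(tl$lambda, max(grid))
  expect_equal(nrow(tl$metrics), length(grid))
})

test_that("sliding correlation matches a brute-force Pearson oracle", {
  set.seed(10)
  x <- rnorm(200)
  y <- rnorm(200)
  r <- sliding_correlation(x, y, 31)
  for (c0 in c(16, 57, 100, 185)) {
    idx <- (c0 - 15):(c0 + 15)
    expect_equal(r[c0], naive_pearson(x[idx], y[idx]), tolerance = 1e-12)
  }
  expect_true(all(is.na(r[1:15])) && all(is.na(r[186:200])))
  z <- x; z[50:90] <- 2   # zero variance stretch
  expect_true(all(is.na(sliding_correlation(z, y, 31)[66:74])))
  x2 <- cumsum(rnorm(100))
  expect_equal(unique(stats::na.omit(sliding_correlation(x2, x2, 31))), 1)
  expect_equal(unique(stats::na.omit(sliding_correlation(x2, -x2, 31))), -1)
  expect_error(sliding_correlation(x, y, 30), "odd")
})

test_that("the tracking index contrasts reconstruction accuracies", {
  expect_equal(tracking_index(0.5, 0.5), 0)
  expect_equal(tracking_index(0.6, 0.2), 0.5)
  set.seed(11)
  a <- runif(50); b <- runif(50)
  expect_equal(tracking_index(b, a), -tracking_index(a, b))
  expect_true(is.na(tracking_index(0.3, -0.3)))       # denominator ~ 0
  expect_true(is.na(tracking_index(NA_real_, 0.5)))
})

test_that("forward transformation inverts to interpretable weights", {
  set.seed(12)
  dec <- train_decoder(matrix(rnorm(200 * 4), 200), rnorm(200), 1)
  fw <- forward_transform(dec, diag(4), 1)
  expect_equal(as.numeric(fw), dec$weights)
  # scale equivariance: doubling responses leaves the pattern shape intact
  resp <- matrix(rnorm(2 * 500), 2)
  X <- build_lag_design(resp, 125, lags = 0:9)
  k <- c(0, 0.5, 1, 0.5, 0, 0, 0, 0, 0, 0)
  s <- as.numeric(X$X %*% rep(k, 2))
  d1 <- train_decoder(X, s, 1e-3)
  X2 <- build_lag_design(2 * resp, 125, lags = 0:9)
  d2 <- train_decoder(X2, s, 1e-3)
  f1 <- forward_from_design(d1, X)
  f2 <- forward_from_design(d2, X2)
  expect_gt(abs(cor(as.numeric(f1), as.numeric(f2))), 1 - 1e-6)
})

test_that("leave-one-out uses the held-out decoders and the divided mapping", {
  set.seed(13)
  mk <- function(i, cond, side) {
    resp <- matrix(rnorm(2 * 200), 2)
    env <- pmax(as.numeric(stats::filter(rnorm(200), rep(0.3, 5))), 0)
    env[is.na(env)] <- 0
    env2 <- pmax(as.numeric(stats::filter(rnorm(200), rep(0.3, 5))), 0)
    env2[is.na(env2)] <- 0
    make_trial(resp, env, env2, side = side, condition = cond, trial = i)
  }
  trials <- list(mk(1, "selective", "left"), mk(2, "selective", "left"),
                 mk(3, "divided", "left"))
  res <- suppressMessages(suppressWarnings(
    loo_reconstruct(trials, lambda = 1, pad_s = 0.2)))
  # manual: trial 1 decoded by a model trained on trial 2 alone
  pad <- 25
  pt <- dichotr:::pad_trial(trials[[2]], pad)
  Xtr <- build_lag_design(pt$resp, 125)
  dec <- train_decoder(Xtr, pt$env_att, 1)
  X1 <- build_lag_design(trials[[1]]$resp, 125)
  shat <- predict_decoder(dec, X1)
  r_manual <- sliding_correlation(shat, trials[[1]]$env_att, 31)
  expect_equal(res$series[[1]]$r_att, r_manual, tolerance = 1e-10)
  # divided trial decoded by the model trained on all selective trials
  pt2 <- dichotr:::pad_trial(trials[[1]], pad)
  Xall <- rbind(Xtr$X, build_lag_design(pt2$resp, 125)$X)
  dec_all <- train_decoder(
    structure(list(X = rbind(build_lag_design(pt2$resp, 125)$X, Xtr$X),
                   lags = Xtr$lags, fs = 125, n_parcels = 2),
              class = "lag_design"),
    c(pt2$env_att, pt$env_att), 1)
  X3 <- build_lag_design(trials[[3]]$resp, 125)
  r_div <- sliding_correlation(predict_decoder(dec_all, X3),
                               trials[[3]]$env_att, 31)
  expect_equal(res$series[[3]]$r_att, r_div, tolerance = 1e-10)
})

test_that("relabelling attended and ignored envelopes flips the index sign", {
  set.seed(14)
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 4, seed = 31)
  ds <- generate_dataset(cfg)
  td <- decoding_data(ds)
  swapped <- lapply(td, function(tr) {
    tmp <- tr
    tmp$env_att <- tr$env_ign; tmp$env_ign <- tr$env_att
    tmp$att_idx <- tr$ign_idx; tmp$ign_idx <- tr$att_idx
    tmp
  })
  r1 <- suppressMessages(loo_reconstruct(td, lambda = 1))
  r2 <- suppressMessages(loo_reconstruct(swapped, lambda = 1))
  for (i in seq_along(td)) {
    a <- r1$series[[i]]$index
    b <- r2$series[[i]]$index
    ok <- !is.na(a) & !is.na(b)
    expect_equal(b[ok], -a[ok], tolerance = 1e-10)
  }
})

test_that("training on a trial inflates its own reconstruction accuracy", {
  set.seed(15)
  diffs <- numeric(20)
  for (rep in 1:20) {
    trials <- lapply(1:2, function(i) {
      resp <- matrix(rnorm(2 * 150), 2)
      env <- as.numeric(resp[1, ]) + rnorm(150, sd = 2)
      make_trial(resp, env, rnorm(150), trial = i)
    })
    pad <- 12
    sts <- lapply(trials, dichotr:::trial_stats, pad = pad,
                  tmin = -0.1, tmax = 0.5)
    X1 <- build_lag_design(trials[[1]]$resp, 125)$X
    fit_excl <- dichotr:::ridge_pair_from_stats(sts[[2]], 1)
    fit_incl <- dichotr:::ridge_pair_from_stats(
      dichotr:::add_stats(sts[[1]], sts[[2]]), 1)
    rc <- function(fit) {
      shat <- as.numeric(X1 %*% fit$att$g) - sum(fit$att$mu * fit$att$g) +
        fit$att$mean_s
      cor(shat, trials[[1]]$env_att)
    }
    diffs[rep] <- rc(fit_incl) - rc(fit_excl)
  }
  expect_gt(mean(diffs), 0)
})

test_that("fewer than two selective trials on a side is skipped with a warning", {
  set.seed(16)
  trials <- list(make_trial(matrix(rnorm(2 * 150), 2),
                            abs(rnorm(150)), abs(rnorm(150))))
  expect_warning(loo_reconstruct(trials, lambda = 1), "fewer than 2")
})
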