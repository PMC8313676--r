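# Independent oracles used to cross-check the implementation.

# conjugate-gradient solver for (X'X + lambda_m I) g = X' s on centered
# data: an iterative least-squares path independent of the closed form
cg_ridge <- function(X, s, lambda, tol = 1e-14, maxit = 5000) {
  Xc <- sweep(X, 2, colMeans(X))
  sc <- s - mean(s)
  A <- crossprod(Xc)
  m <- mean(diag(A))
  b <- crossprod(Xc, sc)
  apply_A <- function(v) as.numeric(A %*% v) + lambda * m * v
  g <- numeric(ncol(X))
  r <- as.numeric(b) - apply_A(g)
  p <- r
  rs <- sum(r^2)
  for (i in seq_len(maxit)) {
    Ap <- apply_A(p)
    alpha <- rs / sum(p * Ap)
    g <- g + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (sqrt(rs_new) < tol * (1 + sqrt(sum(b^2)))) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  g
}

# brute-force Pearson correlation in a single window
naive_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# count local maxima above a fraction of the global maximum
n_peaks_above <- function(v, frac = 0.5) {
  thr <- frac * max(v)
  d <- diff(v)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  # plateau-safe: also count isolated maxima at flat tops
  sum(v[peaks] > thr)
}

# sample skewness
skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# small decoding trial for constructed tests
make_trial <- function(resp, env_att, env_ign, side = "left",
                       condition = "selective", subject = 1, trial = 1,
                       fs = 125) {
  n <- length(env_att)
  list(resp = resp, env_att = env_att, env_ign = env_ign,
       att_idx = c(1L, n), ign_idx = c(1L, n), side = side,
       condition = condition, subject = subject, trial = trial, fs = fs)
}

# smooth random series (low-pass filtered white noise), unit variance
smooth_series <- function(n, span = 7) {
  z <- stats::filter(rnorm(n + 2 * span), rep(1 / span, span), sides = 2)
  z <- z[!is.na(z)][seq_len(n)]
  as.numeric(scale(z))
}
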