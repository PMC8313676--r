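make_beh <- function(n_subjects = 4, n_per = 40, seed = 1) {
  cfg <- sim_config(n_subjects = n_subjects, n_trials_per_cell = n_per,
                    seed = seed)
  generate_dataset(cfg, epochs = FALSE)$trials
}

test_that("behaviour preprocessing splits accuracy and speed tables", {
  d <- data.frame(
    subject = 1,
    accuracy = c("correct", "correct", "timeout", "spatial_confusion"),
    reaction_time = c(2, 2, NA, 1)
  )
  tabs <- preprocess_behaviour(d)
  expect_equal(nrow(tabs$accuracy), 3)
  expect_equal(tabs$speed$speed, c(0.5, 0.5))
  # RT at or beyond the 4-s response window counts as a timeout
  d2 <- d; d2$reaction_time[1] <- 4.2
  expect_equal(nrow(preprocess_behaviour(d2)$accuracy), 2)
  d3 <- data.frame(subject = 1, accuracy = rep("random_error", 3),
                   reaction_time = rep(1, 3))
  expect_warning(tabs3 <- preprocess_behaviour(d3), "empty")
  expect_equal(nrow(tabs3$speed), 0)
})

test_that("error breakdown compares confusion and random error rates", {
  base <- expand.grid(subject = 1:20, i = 1:40)
  base$reaction_time <- 1
  d <- base
  d$accuracy <- rep(c("correct", "spatial_confusion", "correct",
                      "random_error"), length.out = nrow(d))
  eb <- error_breakdown(d)
  expect_equal(eb$t, 0, tolerance = 1e-10)
  # confusions double the random errors: positive paired t
  d2 <- base
  d2$accuracy <- rep(c("spatial_confusion", "spatial_confusion",
                       "random_error", rep("correct", 5)),
                     length.out = nrow(d2))
  eb2 <- error_breakdown(d2)
  expect_gt(eb2$t, 0)
  # zero counts stay finite through the adjusted logit
  d3 <- base
  d3$accuracy <- "correct"
  eb3 <- error_breakdown(d3)
  expect_true(all(is.finite(eb3$by_subject$logit_confusion)))
})

test_that("within/between decomposition is orthogonal and zero-sum", {
  x <- c(1, 1, 1, 3, 3, 3)
  subject <- c(1, 1, 1, 2, 2, 2)
  dec <- decompose_within_between(x, subject)
  expect_equal(dec$within, rep(0, 6))
  expect_equal(dec$between, c(rep(-sqrt(2) / 2, 3), rep(sqrt(2) / 2, 3)))
  set.seed(2)
  x2 <- rnorm(300)
  s2 <- rep(1:10, each = 30)
  d2 <- decompose_within_between(x2, s2)
  expect_lt(abs(sum(d2$within * d2$between)), 1e-10)
  within_sums <- tapply(d2$within, s2, sum)
  expect_lt(max(abs(within_sums)), 1e-10)
})

test_that("BH-FDR matches the hand-derived step-up values", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  p <- runif(10)
  expect_true(all(fdr_correct(p) >= p))
})

test_that("accuracy model recovers the null and planted cue effects", {
  trials <- make_beh(n_subjects = 12, n_per = 30, seed = 5)
  tabs <- preprocess_behaviour(trials)
  fit <- suppressWarnings(
    fit_accuracy_model(tabs$accuracy,
                       formula_rhs = "spatial + semantic + ear"))
  tab <- fit$table
  expect_true(all(tab$p_fdr[-1] >= tab$p[-1] - 1e-12))
  expect_equal(tab$or, exp(tab$estimate))
  sp <- tab[tab$term == "spatial", ]
  expect_gt(sp$or, 1)   # informative cue helps
  # intercept-only model on 50% accuracy: intercept near 0 logits
  coefs <- default_behaviour_coefs()
  coefs$accuracy[] <- 0
  coefs$subject_sd_accuracy <- 0.05
  coefs$item_sd_accuracy <- 0
  cfg <- sim_config(n_subjects = 8, n_trials_per_cell = 60,
                    behaviour_coefs = coefs, timeout_frac = 0, seed = 6)
  null_trials <- generate_dataset(cfg, epochs = FALSE)$trials
  nt <- preprocess_behaviour(null_trials)
  f0 <- suppressWarnings(fit_accuracy_model(nt$accuracy, formula_rhs = "1"))
  expect_lt(abs(f0$table$estimate[1]), 0.15)
})

test_that("speed model recovers exact coefficients from noise-free data", {
  set.seed(7)
  d <- expand.grid(subject = 1:6, item = 1:40)
  d$spatial <- rep(c(-0.5, 0.5), length.out = nrow(d))
  d$speed <- 1 + 0.3 * d$spatial
  fit <- suppressWarnings(
    fit_speed_model(d, formula_rhs = "spatial", z_outcome = FALSE))
  expect_equal(fit$table$estimate[fit$table$term == "spatial"], 0.3,
               tolerance = 1e-6)
})

test_that("flipping a deviation code flips the slope and keeps the likelihood", {
  trials <- make_beh(n_subjects = 6, n_per = 20, seed = 8)
  tabs <- preprocess_behaviour(trials)
  d <- tabs$speed
  d <- dichotr:::code_predictors(d)
  f1 <- suppressWarnings(fit_speed_model(d, formula_rhs = "spatial"))
  d2 <- d
  d2$spatial <- -d2$spatial
  f2 <- suppressWarnings(fit_speed_model(d2, formula_rhs = "spatial"))
  e1 <- f1$table[f1$table$term == "spatial", ]
  e2 <- f2$table[f2$table$term == "spatial", ]
  expect_equal(e2$estimate, -e1$estimate, tolerance = 1e-6)
  expect_equal(as.numeric(f1$logLik), as.numeric(f2$logLik),
               tolerance = 1e-6)
})

test_that("a purely between-subject effect leaves the within slope null", {
  set.seed(9)
  n_sub <- 24
  d <- expand.grid(subject = seq_len(n_sub), item = 1:30)
  x <- rnorm(nrow(d))
  sub_shift <- rnorm(n_sub, sd = 1)
  x <- x + sub_shift[d$subject]
  dec <- decompose_within_between(x, d$subject)
  d$m_within <- dec$within
  d$m_between <- dec$between
  zm <- tapply(x, d$subject, mean)
  d$speed <- 0.5 * as.numeric(scale(zm))[d$subject] + rnorm(nrow(d), sd = 0.3)
  fit <- suppressWarnings(
    fit_speed_model(d, formula_rhs = "m_within + m_between",
                    random = "(1 | subject)", z_outcome = FALSE))
  tw <- fit$table[fit$table$term == "m_within", ]
  tb <- fit$table[fit$table$term == "m_between", ]
  expect_true(tw$ci_lo < 0 && tw$ci_hi > 0)
  expect_gt(tb$estimate, 0.2)
})

test_that("likelihood-ratio tests gate random-slope extensions", {
  trials <- make_beh(n_subjects = 10, n_per = 20, seed = 10)
  tabs <- preprocess_behaviour(trials)
  d <- dichotr:::code_predictors(tabs$speed)
  base <- suppressWarnings(fit_speed_model(d, formula_rhs = "spatial"))
  same <- lrt_random_slopes(base, base)
  expect_equal(same$statistic, 0)
  expect_false(same$adopt_extension)
  ext <- suppressWarnings(
    fit_speed_model(d, formula_rhs = "spatial",
                    random = "(1 + spatial | subject) + (1 | item)"))
  expect_error(lrt_random_slopes(ext, base), "nested")
  # strong planted slope heterogeneity is detected and adopted
  set.seed(11)
  d2 <- expand.grid(subject = 1:20, item = 1:40)
  d2$spatial <- sample(c(-0.5, 0.5), nrow(d2), replace = TRUE)
  slopes <- rnorm(20, 0, 2)
  d2$speed <- (0.3 + slopes[d2$subject]) * d2$spatial + rnorm(nrow(d2), 0, 0.4)
  b2 <- suppressWarnings(
    fit_speed_model(d2, formula_rhs = "spatial",
                    random = "(1 | subject) + (1 | item)"))
  e2 <- suppressWarnings(
    fit_speed_model(d2, formula_rhs = "spatial",
                    random = "(1 + spatial | subject) + (1 | item)"))
  lrt <- lrt_random_slopes(b2, e2)
  expect_true(lrt$adopt_extension)
})
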