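#' Pipeline configuration
#'
#' Nested configuration for the stage-wise pipeline. Defaults follow the
#' standard analysis settings: 8--12 Hz Morlet power at 6 cycles, decoder
#' lags of -100..500 ms, a 248-ms sliding correlation window, 100 warp
#' bins with a 3-bin smoother, the final 35% summary window, 5000
#' surrogate permutations, and FDR control at q = 0.05.
#'
#' @param simulation A [sim_config()] (its seed is overridden by `seed`).
#' @param features,decoding,temporal,stats Stage parameter lists; partial
#'   lists are merged over the defaults.
#' @param seed Master integer seed, expanded into per-stage substreams.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            features = list(),
                            decoding = list(),
                            temporal = list(),
                            stats = list(),
                            seed = 1L) {
  merge_defaults <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    simulation = simulation,
    features = merge_defaults(list(freqs = 8:12, n_cycles = 6), features),
    decoding = merge_defaults(
      list(tmin = -0.1, tmax = 0.5, lambda = 1, lambda_grid = NULL,
           window = 31, pad_s = 0.6, lowpass = 8), decoding),
    temporal = merge_defaults(
      list(max_lag = 50, n_permutations = 5000), temporal),
    stats = merge_defaults(
      list(q = 0.05,
           accuracy_rhs = paste("spatial * semantic + ear + onset_lead +",
                                "age_z + pta_z + nti_within + nti_between +",
                                "ali_within + ali_between"),
           speed_rhs = paste("spatial * semantic + ear + onset_lead +",
                             "age_z + pta_z + nti_within + nti_between +",
                             "ali_within + ali_between")), stats),
    seed = as.integer(seed)
  )
  cfg$simulation$seed <- derive_seed(cfg$seed, "simulate")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  plain$simulation <- unclass(plain$simulation)
  plain$simulation$trf_kernel <- as.list(plain$simulation$trf_kernel)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  sim$trf_kernel <- as.data.frame(sim$trf_kernel)
  sim <- do.call(sim_config, sim)
  pipeline_config(simulation = sim, features = raw$features,
                  decoding = raw$decoding, temporal = raw$temporal,
                  stats = raw$stats, seed = raw$seed)
}

stage_names <- c("simulate", "features", "decode", "warp", "crosscorr",
                 "stats", "report")

require_artifact <- function(out_dir, file, producer) {
  path <- file.path(out_dir, file)
  if (!file.exists(path)) {
    stop("missing upstream artifact '", file, "': run the '", producer,
         "' stage first")
  }
  path
}

#' Run one pipeline stage
#'
#' Stages consume the previous stage's on-disk container and are
#' deterministic and idempotent given identical inputs: `simulate` writes
#' the dataset (RDS container + trial-table CSV), `features` the per-trial
#' alpha lateralization features, `decode` the leave-one-out tracking
#' features, `warp` group-level warped time courses, `crosscorr` the
#' tracking/ALI cross-correlation with its surrogate band, `stats` the
#' mixed-effects model tables, and `report` a plain-text summary.
#'
#' @param stage One of `simulate`, `features`, `decode`, `warp`,
#'   `crosscorr`, `stats`, `report`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
run_stage <- function(stage, config, out_dir) {
  stage <- match.arg(stage, stage_names)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t_start <- Sys.time()
  paths <- switch(stage,
    simulate = stage_simulate(config, out_dir),
    features = stage_features(config, out_dir),
    decode = stage_decode(config, out_dir),
    warp = stage_warp(config, out_dir),
    crosscorr = stage_crosscorr(config, out_dir),
    stats = stage_stats(config, out_dir),
    report = stage_report(config, out_dir)
  )
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  invisible(paths)
}

stage_simulate <- function(config, out_dir) {
  ds <- generate_dataset(config$simulation)
  rds <- file.path(out_dir, "dataset.rds")
  saveRDS(ds, rds)
  csv <- file.path(out_dir, "trials.csv")
  utils::write.csv(ds$trials, csv, row.names = FALSE)
  truth <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(ds$ground_truth, truth, row.names = FALSE)
  c(rds, csv, truth)
}

stage_features <- function(config, out_dir) {
  ds <- readRDS(require_artifact(out_dir, "dataset.rds", "simulate"))
  af <- compute_alpha_features(ds, freqs = config$features$freqs,
                               n_cycles = config$features$n_cycles)
  rds <- file.path(out_dir, "alpha_features.rds")
  saveRDS(af, rds)
  csv <- file.path(out_dir, "features_alpha.csv")
  utils::write.csv(af$features, csv, row.names = FALSE)
  c(rds, csv)
}

stage_decode <- function(config, out_dir) {
  ds <- readRDS(require_artifact(out_dir, "dataset.rds", "simulate"))
  if (ds$config$sample_rate != 125) {
    stop("decoding requires the 125 Hz envelope rate; dataset has ",
         ds$config$sample_rate, " Hz")
  }
  dc <- config$decoding
  td <- decoding_data(ds, lowpass = dc$lowpass)
  subs <- unique(ds$trials$subject)
  lambda <- dc$lambda
  if (!is.null(dc$lambda_grid)) {
    tuned <- tune_lambda(td[ds$trials$subject == subs[1]],
                         grid = dc$lambda_grid, tmin = dc$tmin,
                         tmax = dc$tmax, window = dc$window,
                         pad_s = dc$pad_s)
    lambda <- tuned$lambda
  }
  res <- lapply(subs, function(s) {
    loo_reconstruct(td[ds$trials$subject == s], lambda = lambda,
                    tmin = dc$tmin, tmax = dc$tmax, window = dc$window,
                    pad_s = dc$pad_s)
  })
  trials <- do.call(rbind, lapply(res, `[[`, "trials"))
  warped <- do.call(rbind, lapply(res, `[[`, "warped"))
  out <- list(trials = trials, warped = warped, lambda = lambda,
              m = mean(unlist(lapply(res, function(r) {
                unlist(lapply(r$decoders, function(d) {
                  if (!is.null(d)) d$attended$m
                }))
              }))),
              decoders = lapply(res, `[[`, "decoders"))
  rds <- file.path(out_dir, "tracking.rds")
  saveRDS(out, rds)
  csv <- file.path(out_dir, "features_tracking.csv")
  utils::write.csv(trials, csv, row.names = FALSE)
  c(rds, csv)
}

stage_warp <- function(config, out_dir) {
  ds <- readRDS(require_artifact(out_dir, "dataset.rds", "simulate"))
  af <- readRDS(require_artifact(out_dir, "alpha_features.rds", "features"))
  tk <- readRDS(require_artifact(out_dir, "tracking.rds", "decode"))
  sel <- ds$trials$spatial_cue == "informative"
  gt <- list(
    nti_selective = group_timecourse(tk$warped, ds$trials$subject, sel),
    nti_divided = group_timecourse(tk$warped, ds$trials$subject, !sel),
    ali_selective = group_timecourse(af$warped, ds$trials$subject, sel),
    ali_divided = group_timecourse(af$warped, ds$trials$subject, !sel)
  )
  rds <- file.path(out_dir, "warped_group.rds")
  saveRDS(gt, rds)
  csv <- file.path(out_dir, "group_timecourse.csv")
  flat <- do.call(rbind, Map(function(d, nm) {
    d$measure <- nm
    d
  }, gt, names(gt)))
  utils::write.csv(flat, csv, row.names = FALSE)
  c(rds, csv)
}

stage_crosscorr <- function(config, out_dir) {
  gt <- readRDS(require_artifact(out_dir, "warped_group.rds", "warp"))
  ds <- readRDS(require_artifact(out_dir, "dataset.rds", "simulate"))
  set.seed(derive_seed(config$seed, "crosscorr"))
  x <- gt$nti_selective$mean
  y <- gt$ali_selective$mean
  tc <- config$temporal
  cc <- crosscorrelate(x, y, max_lag = tc$max_lag)
  band <- surrogate_band(x, y, n_permutations = tc$n_permutations,
                         max_lag = tc$max_lag)
  mean_dur <- mean(unlist(lapply(ds$envelopes, `[[`, "durations_ms")))
  res <- list(lags = cc$lags, cc = cc$cc, lo = band$lo, hi = band$hi,
              peak_lag_bins = cc$peak_lag, peak_value = cc$peak_value,
              peak_lag_ms = lag_to_ms(cc$peak_lag, mean_dur),
              mean_sentence_duration_ms = mean_dur)
  rds <- file.path(out_dir, "crosscorr.rds")
  saveRDS(res, rds)
  csv <- file.path(out_dir, "crosscorr.csv")
  utils::write.csv(data.frame(lag_bins = res$lags, cc = res$cc,
                              lo = res$lo, hi = res$hi),
                   csv, row.names = FALSE)
  js <- file.path(out_dir, "crosscorr_summary.json")
  jsonlite::write_json(res[c("peak_lag_bins", "peak_lag_ms", "peak_value",
                             "mean_sentence_duration_ms")],
                       js, auto_unbox = TRUE, digits = NA)
  c(rds, csv, js)
}

stage_stats <- function(config, out_dir) {
  trials <- utils::read.csv(require_artifact(out_dir, "trials.csv",
                                             "simulate"))
  alpha <- utils::read.csv(require_artifact(out_dir, "features_alpha.csv",
                                            "features"))
  track <- utils::read.csv(require_artifact(out_dir, "features_tracking.csv",
                                            "decode"))
  d <- merge(merge(trials, alpha, by = c("subject", "trial")),
             track[, c("subject", "trial", "NTI_sentence", "NTI_final")],
             by = c("subject", "trial"))
  d <- code_predictors(d)
  nti <- decompose_within_between(d$NTI_final, d$subject)
  ali <- decompose_within_between(d$ALI_final, d$subject)
  d$nti_within <- nti$within
  d$nti_between <- nti$between
  d$ali_within <- ali$within
  d$ali_between <- ali$between
  tabs <- preprocess_behaviour(d)
  acc_fit <- fit_accuracy_model(tabs$accuracy,
                                formula_rhs = config$stats$accuracy_rhs)
  spd_fit <- fit_speed_model(tabs$speed,
                             formula_rhs = config$stats$speed_rhs)
  # brain-brain model: does alpha lateralization explain neural tracking?
  bb_fit <- fit_speed_model(
    transform(d, speed = NTI_final),
    formula_rhs = "spatial + ear + ali_within + ali_between",
    z_outcome = TRUE)
  out <- list(accuracy = acc_fit$table, speed = spd_fit$table,
              brain_brain = bb_fit$table,
              errors = error_breakdown(d))
  rds <- file.path(out_dir, "stats.rds")
  saveRDS(out, rds)
  paths <- rds
  for (nm in c("accuracy", "speed", "brain_brain")) {
    p <- file.path(out_dir, paste0("model_", nm, ".csv"))
    utils::write.csv(out[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}

stage_report <- function(config, out_dir) {
  st <- readRDS(require_artifact(out_dir, "stats.rds", "stats"))
  cc <- readRDS(require_artifact(out_dir, "crosscorr.rds", "crosscorr"))
  track <- utils::read.csv(require_artifact(out_dir, "features_tracking.csv",
                                            "decode"))
  spec <- validate_decoder_specificity(track)
  trials <- utils::read.csv(file.path(out_dir, "trials.csv"))
  answered <- trials[trials$accuracy != "timeout", ]
  lines <- c(
    "Dichotic listening analysis report",
    "==================================",
    "",
    sprintf("Trials: %d (%d subjects); mean accuracy %.1f%%",
            nrow(trials), length(unique(trials$subject)),
            100 * mean(answered$accuracy == "correct")),
    sprintf("Error breakdown: confusions %.1f%%, random %.1f%% (t = %.2f, p = %.3g)",
            100 * mean(st$errors$by_subject$prop_confusion),
            100 * mean(st$errors$by_subject$prop_random),
            st$errors$t, st$errors$p),
    "",
    "Decoder specificity (attended-model contrast per subject):",
    sprintf("  mean contrast_att = %.4f, contrast_ign = %.4f",
            mean(spec$contrast_att, na.rm = TRUE),
            mean(spec$contrast_ign, na.rm = TRUE)),
    "",
    sprintf("Cross-correlation peak: lag %d bins (%.1f ms), cc = %.3f",
            cc$peak_lag_bins, cc$peak_lag_ms, cc$peak_value),
    "",
    "Accuracy model:",
    utils::capture.output(print(format(st$accuracy, digits = 3))),
    "",
    "Speed model:",
    utils::capture.output(print(format(st$speed, digits = 3))),
    "",
    "Brain-brain model (tracking ~ alpha lateralization):",
    utils::capture.output(print(format(st$brain_brain, digits = 3)))
  )
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  path
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Stages to run, in order.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, out_dir, stages = stage_names) {
  for (s in stages) run_stage(s, config, out_dir)
  invisible(out_dir)
}

#' Validate a pipeline output container
#'
#' Checks that the dataset container and trial-table CSV agree on trial
#' counts, that the schema fields are present, and that the envelope
#' sample rate matches the 125 Hz decoding requirement.
#'
#' @param out_dir Pipeline output directory.
#' @return List with `ok` and a character vector of `problems`.
#' @export
validate_container <- function(out_dir) {
  problems <- character()
  rds <- file.path(out_dir, "dataset.rds")
  csv <- file.path(out_dir, "trials.csv")
  if (!file.exists(rds)) problems <- c(problems, "dataset.rds missing")
  if (!file.exists(csv)) problems <- c(problems, "trials.csv missing")
  if (length(problems) == 0) {
    ds <- readRDS(rds)
    tb <- utils::read.csv(csv)
    if (!inherits(ds, "dl_dataset")) {
      problems <- c(problems, "dataset.rds is not a dl_dataset container")
    } else {
      if (nrow(ds$trials) != nrow(tb)) {
        problems <- c(problems, sprintf(
          "trial count mismatch: container has %d rows, trials.csv has %d",
          nrow(ds$trials), nrow(tb)))
      }
      if (ds$config$sample_rate != 125) {
        problems <- c(problems, sprintf(
          "sample rate %g Hz != 125 Hz required by the decode stage",
          ds$config$sample_rate))
      }
    }
  }
  list(ok = length(problems) == 0, problems = problems)
}
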