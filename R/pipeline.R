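# End-to-end pipeline: simulate -> events -> sync -> stance dataset ->
# train -> evaluate, with a single config and one global seed.

#' Pipeline configuration
#'
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param n_rfs,n_ffs cohort composition.
#' @param sync a [sync_config()].
#' @param events an [event_config()].
#' @param rules a [cycle_rules()].
#' @param train a [train_config()]; its seed is derived from `seed`.
#' @param axes `"three"` (m = 3) or `"sagittal"` (m = 1).
#' @param sagittal_channel acceleration channel used when `axes = "sagittal"`.
#' @param models activations to train (`"morlet"` = WNN, `"sigmoid"` = FFNN).
#' @param test_subjects held-out subject ids; `NULL` picks one per strike
#'   pattern at random (seeded).
#' @param seed global seed; propagates to simulation and training.
#' @param out_dir optional directory for the JSON report and CSV tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), n_rfs = 8, n_ffs = 7,
                            sync = sync_config(), events = event_config(),
                            rules = cycle_rules(), train = train_config(),
                            axes = c("three", "sagittal"),
                            sagittal_channel = "sagittal",
                            models = c("morlet", "sigmoid"),
                            test_subjects = NULL, seed = 1L,
                            out_dir = NULL) {
  axes <- match.arg(axes)
  structure(list(sim = sim, n_rfs = n_rfs, n_ffs = n_ffs, sync = sync,
                 events = events, rules = rules, train = train, axes = axes,
                 sagittal_channel = sagittal_channel, models = models,
                 test_subjects = test_subjects, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Detect events, synchronize, and extract annotated stance samples for one
# generated trial.  Returns list(samples, sync, errors, n_matched).
process_trial <- function(trial, events_cfg = event_config(),
                          sync_cfg = sync_config()) {
  imu <- trial$imu; force <- trial$force; truth <- trial$truth
  toeoff_imu <- detect_toeoff_imu(imu$gyro[, "coronal"], imu$rate, events_cfg)
  fev <- detect_events_force(force$vgrf, force$rate, events_cfg$threshold_n,
                             events_cfg)
  d_imu <- stride_durations(toeoff_imu)
  d_force <- stride_durations(fev$toe_off)
  sync <- stws_offset(d_imu, d_force, sync_cfg)
  pairs <- align_strides(toeoff_imu, fev$toe_off, sync)
  samples <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- extract_stance(pairs[i, ], imu, force, sync, truth$mass,
                        force_strikes = fev$foot_strike, cfg = events_cfg)
    if (inherits(s, "stance_sample")) {
      s$subject_id <- truth$subject_id
      s$speed <- truth$speed
      s$strike_pattern <- truth$strike_pattern
    }
    s
  })
  list(samples = samples, sync = sync,
       errors = stride_time_errors(pairs), n_matched = nrow(pairs),
       events = list(toeoff_imu = toeoff_imu, force = fev))
}

#' Run the full synchronization-and-prediction pipeline
#'
#' Generates a synthetic cohort, detects gait events in both streams,
#' synchronizes them with STWS, assembles the stance dataset with a
#' subject-wise split, trains the configured networks per strike pattern,
#' and evaluates curve, peak and Bland-Altman agreement on the held-out
#' subjects, grouped by speed.  Rerunning with the same config reproduces
#' the report byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return A list of class `pipeline_report` with elements `counts`,
#'   `stride_time` (pooled and per-speed error reports), `sync` (per-trial
#'   offsets and window sizes), `curve`, `peak` and `bland_altman` metric
#'   tables (per model x strike pattern x speed), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  cfg_sim <- config$sim
  cfg_sim$seed <- config$seed

  say("[simulate] %d RFS + %d FFS subjects at %s km/h",
      config$n_rfs, config$n_ffs, paste(cfg_sim$speeds, collapse = "/"))
  cohort <- make_cohort(config$n_rfs, config$n_ffs, cfg_sim)

  say("[segment+sync] %d trials", sum(lengths(lapply(cohort, `[[`, "trials"))))
  all_samples <- list(); sync_rows <- list(); err_rows <- list()
  for (subject in cohort) {
    for (trial in subject$trials) {
      pr <- tryCatch(
        process_trial(trial, config$events, config$sync),
        error = function(e) stop(errorCondition(
          sprintf("stage sync failed for subject %s at %g km/h: %s",
                  trial$truth$subject_id, trial$truth$speed,
                  conditionMessage(e)),
          class = class(e))))
      all_samples <- c(all_samples, pr$samples)
      sync_rows[[length(sync_rows) + 1L]] <- data.frame(
        subject_id = trial$truth$subject_id, speed = trial$truth$speed,
        stride_offset = pr$sync$stride_offset,
        true_stride_offset = trial$truth$true_stride_offset,
        k_final = pr$sync$k_final, n_matched = pr$n_matched)
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        speed = trial$truth$speed,
        abs_err_ms = pr$errors$abs_err_ms,
        rel_err_pct = pr$errors$rel_err_pct)
    }
  }
  sync_tab <- do.call(rbind, sync_rows)
  err_tab <- do.call(rbind, err_rows)

  flt <- filter_cycles(all_samples, config$rules)
  say("[dataset] %d cycles kept, %d excluded", length(flt$kept),
      nrow(flt$excluded))

  # held-out subject per strike pattern (seeded choice when unspecified)
  subj_pat <- unique(data.frame(
    id = vapply(flt$kept, function(s) s$subject_id, ""),
    pat = vapply(flt$kept, function(s) s$strike_pattern, "")))
  test_subjects <- config$test_subjects
  if (is.null(test_subjects)) {
    set.seed(derive_seed(config$seed, 7L))
    test_subjects <- unlist(lapply(split(subj_pat$id, subj_pat$pat),
                                   function(ids) sample(ids, 1L)))
  }
  m <- if (config$axes == "three") 3L else 1L
  datasets <- build_datasets(flt$kept, split_spec(test_subjects), m,
                             config$sagittal_channel)

  summarize_errors <- function(g)
    list(n_strides = nrow(g), MAE = mean(g$abs_err_ms),
         MXAE = max(g$abs_err_ms), MRE = mean(g$rel_err_pct),
         MXRE = max(g$rel_err_pct))
  stride_time <- list(
    pooled = structure(summarize_errors(err_tab), class = "stride_time_errors"),
    per_speed = lapply(split(err_tab, err_tab$speed), summarize_errors))

  curve_out <- list(); peak_out <- list(); ba_out <- list()
  model_names <- c(morlet = "WNN", sigmoid = "FFNN")
  trained <- list()
  for (act in config$models) {
    for (pat in names(datasets)) {
      say("[train] %s / %s", model_names[[act]], pat)
      tc <- config$train
      tc$seed <- derive_seed(config$seed, match(act, config$models) * 13L +
                               match(pat, names(datasets)))
      fit <- train_vgrf(datasets[[pat]]$train, tc, act)
      trained[[paste(act, pat, sep = "_")]] <- fit
      test <- datasets[[pat]]$test
      pred <- predict_dataset(fit$model, test)
      key <- paste(model_names[[act]], pat, sep = ".")
      by_speed <- split(seq_len(nrow(pred)), test$speed)
      curve_out[[key]] <- lapply(by_speed, function(i)
        strip_values(curve_metrics(test$y[i, , drop = FALSE],
                                   pred[i, , drop = FALSE])))
      peak_out[[key]] <- lapply(by_speed, function(i)
        strip_values(peak_metrics(apply(test$y[i, , drop = FALSE], 1, max),
                                  apply(pred[i, , drop = FALSE], 1, max))))
      ba_out[[key]] <- lapply(by_speed, function(i) {
        mp <- apply(test$y[i, , drop = FALSE], 1, max)
        pp <- apply(pred[i, , drop = FALSE], 1, max)
        if (length(mp) < 2L) return(NULL)
        strip_values(suppressWarnings(bland_altman(mp, pp)))
      })
    }
  }

  report <- structure(list(
    counts = list(
      subjects = length(cohort), trials = nrow(sync_tab),
      cycles_extracted = length(all_samples),
      cycles_kept = length(flt$kept), cycles_excluded = nrow(flt$excluded),
      test_subjects = as.list(test_subjects)),
    stride_time = stride_time,
    sync = sync_tab,
    curve = curve_out, peak = peak_out, bland_altman = ba_out,
    manifest = list(package = "imugrf",
                    version = as.character(utils::packageVersion("imugrf")),
                    seed = config$seed, axes = config$axes,
                    models = as.list(config$models),
                    speeds = as.list(cfg_sim$speeds),
                    n_strides = cfg_sim$n_strides,
                    K = config$train$K, epochs = config$train$epochs)),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    data.table::fwrite(sync_tab, file.path(config$out_dir, "sync.csv"))
  }
  report
}

# drop bulky per-sample vectors so reports stay compact and serializable
strip_values <- function(x) {
  x$values <- NULL
  for (f in c("RMSE", "NRMSE", "R2"))
    if (is.list(x[[f]])) x[[f]]$values <- NULL
  x$ape_pct <- NULL; x$differences <- NULL; x$means <- NULL
  x$abs_err_ms <- NULL; x$rel_err_pct <- NULL
  unclass(x)
}

report_to_json <- function(report) {
  out <- unclass(report)
  out$stride_time$pooled <- unclass(out$stride_time$pooled)
  out$stride_time$pooled$abs_err_ms <- NULL
  out$stride_time$pooled$rel_err_pct <- NULL
  out
}

#' Serialize a pipeline report deterministically
#'
#' @param report a `pipeline_report`.
#' @return A JSON string; identical configs give identical strings.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(report_to_json(report), digits = NA,
                                auto_unbox = TRUE, pretty = TRUE))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects, %d trials, %d/%d cycles kept\n",
              x$counts$subjects, x$counts$trials, x$counts$cycles_kept,
              x$counts$cycles_extracted))
  cat(sprintf("  stride time: MAE %.2f ms, MRE %.3f%% (n = %d)\n",
              x$stride_time$pooled$MAE, x$stride_time$pooled$MRE,
              x$stride_time$pooled$n_strides))
  for (key in names(x$curve)) {
    cm <- x$curve[[key]]
    pooled_nrmse <- mean(vapply(cm, function(g) g$NRMSE$mean, numeric(1)))
    pooled_cmc <- mean(vapply(cm, function(g) g$CMC, numeric(1)))
    cat(sprintf("  %s: mean CMC %.3f, mean NRMSE %.2f%%\n",
                key, pooled_cmc, pooled_nrmse))
  }
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Maps the YAML sections (`sim`, `sync`, `events`, `rules`, `train`, plus
#' top-level `n_rfs`, `n_ffs`, `axes`, `models`, `seed`, `out_dir`) onto
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  pipeline_config(
    sim = build(sim_config, y$sim),
    n_rfs = y$n_rfs %||% 8, n_ffs = y$n_ffs %||% 7,
    sync = build(sync_config, y$sync),
    events = build(event_config, y$events),
    rules = build(cycle_rules, y$rules),
    train = build(train_config, y$train),
    axes = y$axes %||% "three",
    sagittal_channel = y$sagittal_channel %||% "sagittal",
    models = y$models %||% c("morlet", "sigmoid"),
    test_subjects = y$test_subjects,
    seed = y$seed %||% 1L,
    out_dir = y$out_dir)
}
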