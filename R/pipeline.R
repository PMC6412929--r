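#' Default pipeline configuration
#'
#' One flat key set covering every stage, mirroring how identification
#' experiments are usually tabulated (optimizer, minibatch, epochs,
#' learning-rate multiplier, split ratio, ...). Keys default to the standard
#' parameter set of the pipeline: 500/10-sample filter widths, 600-sample
#' trim, 784-sample beats, Morse wavelet with gamma 3 and time-bandwidth
#' product 60 at 12 voices per octave, 28 x 28 images for the small CNN, Adam
#' at learning rate 1e-4.
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    # synthetic cohort
    n_subjects = 5L, beats_per_subject = 60L, fs = 1000,
    noise_baseline_mv = 0.1, noise_baseline_hz = 0.3,
    noise_mains_mv = 0.05, noise_mains_hz = 60, noise_white_sd = 0.05,
    # preprocessing (widths in samples)
    baseline_width = 500L, smooth_width = 10L, trim_n = 600L,
    beat_length = 784L,
    # wavelet
    gamma = 3, tbp = 60, voices_per_octave = 12L,
    # image rendering
    image_size = 28L, colormap = "jet", log_magnitude = FALSE,
    flip_rows = FALSE,
    # training
    method = "adam", initial_lr = 1e-4, minibatch = 4L, epochs = 10L,
    lr_multiplier = 1, train_ratio = 90, test_ratio = 50,
    backbone = "simple_cnn",
    # verification
    verification = FALSE, positive_subject = "", samples_per_person = 60L,
    # misc
    seed = 1L, input = "", out_dir = ""
  ), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Plain `key = value` lines (`#` comments allowed). Unknown keys are
#' rejected rather than silently ignored; values are coerced to the type of
#' the corresponding default.
#'
#' @param path Config file path.
#' @param base Configuration the file overrides (default
#'   [default_pipeline_config()]).
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, base = default_pipeline_config()) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    base <- set_config_value(base, key, val)
  }
  base
}

set_config_value <- function(config, key, value) {
  if (!key %in% names(config)) {
    stop(sprintf("unknown config key '%s'", key), call. = FALSE)
  }
  cur <- config[[key]]
  config[[key]] <- if (is.logical(cur)) {
    if (!toupper(value) %in% c("TRUE", "FALSE", "T", "F", "0", "1")) {
      stop(sprintf("config key '%s' expects a logical, got '%s'", key, value),
           call. = FALSE)
    }
    toupper(value) %in% c("TRUE", "T", "1")
  } else if (is.integer(cur)) {
    v <- suppressWarnings(as.integer(value))
    if (is.na(v)) stop(sprintf("config key '%s' expects an integer, got '%s'",
                               key, value), call. = FALSE)
    v
  } else if (is.numeric(cur)) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop(sprintf("config key '%s' expects a number, got '%s'",
                               key, value), call. = FALSE)
    v
  } else {
    value
  }
  config
}

#' Write a pipeline configuration file
#'
#' @param config A `pipeline_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.logical(v)) as.character(v) else if (is.numeric(v)) sprintf("%.10g", v)
    else as.character(v)
  }, character(1))
  writeLines(sprintf("%s = %s", names(config), fmt), path)
  invisible(path)
}

config_noise <- function(config) {
  noise_spec(
    baseline_mv = config$noise_baseline_mv, baseline_hz = config$noise_baseline_hz,
    mains_mv = config$noise_mains_mv, mains_hz = config$noise_mains_hz,
    white_sd = config$noise_white_sd
  )
}

#' Generate the pipeline's input dataset from synthetic recordings
#'
#' Simulates one continuous recording per subject and runs the full
#' beat-extraction chain on it (baseline removal, smoothing, trimming,
#' R-peak *detection*, segmentation) — the beats come from the detector, not
#' from the generator's ground truth, so this exercises the same path real
#' recordings take. Each subject contributes at most `beats_per_subject`
#' beats; the dataset is truncated to the smallest per-subject count so
#' classes stay balanced.
#'
#' @param config A `pipeline_config`.
#' @return Tibble with `subject_id`, `beat`, `samples`.
#' @export
pipeline_dataset <- function(config) {
  noise <- config_noise(config)
  half <- config$beat_length %/% 2L
  per_subject <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    tpl <- sample_subject_template(config$seed + s, subject_id = sprintf("S%02d", s))
    duration <- (config$beats_per_subject + 6) * tpl$rr_mean +
      2 * (config$trim_n + half) / config$fs
    sim <- synthesize_recording(tpl, duration, config$fs, noise,
                                seed = config$seed * 1000L + s)
    beats <- preprocess_record(sim$record,
                               baseline_width = config$baseline_width,
                               smooth_width = config$smooth_width,
                               trim_n = config$trim_n,
                               beat_length = config$beat_length)
    if (nrow(beats) > config$beats_per_subject) {
      beats <- beats[seq_len(config$beats_per_subject), ]
    }
    beats$beat <- seq_len(nrow(beats))
    per_subject[[s]] <- beats
  }
  n_min <- min(vapply(per_subject, nrow, integer(1)))
  if (n_min < 2L) stop("pipeline produced fewer than 2 beats for a subject", call. = FALSE)
  dplyr::bind_rows(lapply(per_subject, function(b) b[seq_len(n_min), ]))
}

#' Render every beat of a dataset as a scalogram image
#'
#' Builds the scale grid once for the beat length and maps each beat through
#' CWT, magnitude normalization, colormap and resize.
#'
#' @param beats Tibble with `samples` (and `subject_id`) columns.
#' @param config A `pipeline_config`.
#' @return The input tibble with an added `image` list-column and a `label`
#'   column equal to `subject_id`.
#' @export
beats_to_images <- function(beats, config = default_pipeline_config()) {
  params <- morse_params(config$gamma, config$tbp, config$voices_per_octave)
  grid <- build_scale_grid(config$beat_length, config$fs, params)
  size <- rep(as.integer(config$image_size), 2L)
  beats$image <- purrr::map(beats$samples, function(x) {
    scalogram_image(beat_scalogram(x, config$fs, params, grid),
                    size = size, colormap = config$colormap,
                    log_magnitude = config$log_magnitude,
                    flip_rows = config$flip_rows)
  })
  beats$label <- beats$subject_id
  beats
}

#' Run the end-to-end identification pipeline
#'
#' Simulate (or accept) a beat dataset, render scalogram images, split
#' subjects' beats 50:50 into train and test (stratified, seeded), carve a
#' validation part out of the training half, train the CNN and report test
#' identification accuracy. With `config$verification = TRUE` the dataset is
#' first recast one-against-all and the report additionally carries the
#' verification ratios, ROC points and the equal error rate computed on the
#' held-out half.
#'
#' @param config A `pipeline_config`.
#' @param beats Optional precomputed beat tibble (bypasses simulation).
#' @return A list of class `pipeline_report`: `config`, `fit` (the
#'   [train_cnn()] result), `identification` (tibble), and optionally
#'   `verification`, `roc`, `eer`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), beats = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(beats)) {
    beats <- if (nzchar(config$input)) read_beats(config$input)
             else pipeline_dataset(config)
  }
  data <- beats_to_images(beats, config)

  if (isTRUE(config$verification)) {
    pos <- if (nzchar(config$positive_subject)) config$positive_subject
           else sort(unique(data$subject_id))[1]
    data <- build_one_against_all(data, pos, config$samples_per_person)
  }

  test_ratio <- c(100 - config$test_ratio, config$test_ratio)
  halves <- split_train_validation(data, ratio = test_ratio, seed = config$seed)
  train_part <- halves$train; test_part <- halves$validation
  tv <- split_train_validation(train_part,
                               ratio = c(config$train_ratio, 100 - config$train_ratio),
                               seed = config$seed + 1L)

  n_classes <- length(unique(data$label))
  model <- load_backbone(config$backbone, n_classes = n_classes, seed = config$seed)
  cfg <- train_config(method = config$method, initial_lr = config$initial_lr,
                      minibatch = config$minibatch, epochs = config$epochs,
                      last_layer_lr_multiplier = config$lr_multiplier,
                      train_val_ratio = c(config$train_ratio, 100 - config$train_ratio),
                      seed = config$seed)
  fit <- train_cnn(model, tv$train, cfg, validation = tv$validation)

  preds <- predict(fit, test_part)
  correct <- sum(preds$.pred_class == as.character(test_part$label))
  ident <- identification_accuracy(correct, nrow(test_part) - correct)

  report <- list(config = config, fit = fit, identification = ident)
  if (isTRUE(config$verification)) {
    pos_scores <- preds[[".pred_positive"]]
    truth <- as.character(test_part$label)
    pred_lab <- preds$.pred_class
    counts <- confusion_counts(
      tp = sum(pred_lab == "positive" & truth == "positive"),
      tn = sum(pred_lab == "negative" & truth == "negative"),
      fp = sum(pred_lab == "positive" & truth == "negative"),
      fn = sum(pred_lab == "negative" & truth == "positive")
    )
    roc <- roc_curve(pos_scores, truth == "positive")
    report$verification <- verification_metrics(counts)
    report$roc <- roc
    report$eer <- equal_error_rate(roc)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  identification accuracy: %.4f (%d/%d)\n",
              x$identification$accuracy, x$identification$cc,
              x$identification$cc + x$identification$wc))
  if (!is.null(x$verification)) {
    v <- x$verification
    cat(sprintf("  verification: acc %.4f sens %.4f spec %.4f fpr %.4f fnr %.4f eer %.4f\n",
                v$accuracy, v$sensitivity, v$specificity, v$fpr, v$fnr, x$eer))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits a key-value text summary, a JSON summary, and (when present)
#' two-column ROC points, all with deterministic formatting so identical
#' runs give byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    identification_accuracy = report$identification$accuracy,
    correct = report$identification$cc,
    wrong = report$identification$wc
  )
  if (!is.null(report$verification)) {
    v <- report$verification
    summary <- c(summary, list(
      verification_accuracy = v$accuracy, sensitivity = v$sensitivity,
      specificity = v$specificity, fpr = v$fpr, fnr = v$fnr, eer = report$eer
    ))
    utils::write.table(
      data.frame(fpr = sprintf("%.10g", report$roc$fpr),
                 tpr = sprintf("%.10g", report$roc$tpr)),
      file.path(dir, "roc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(sprintf("%s = %.10g", names(summary), unlist(summary)),
             file.path(dir, "report.txt"))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(epoch = report$fit$metrics$epoch,
               loss = sprintf("%.10g", report$fit$metrics$loss),
               train_acc = sprintf("%.10g", report$fit$metrics$train_accuracy),
               val_acc = sprintf("%.10g", report$fit$metrics$val_accuracy)),
    file.path(dir, "training_log.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Simulate a cohort and write it to disk (CLI backend)
#'
#' @param config A `pipeline_config`; `out_dir` must be set.
#' @return Output prefix, invisibly.
#' @export
cmd_simulate <- function(config) {
  if (!nzchar(config$out_dir)) stop("`out_dir` must be set", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- synthesize_cohort(config$n_subjects, config$beats_per_subject,
                              config$fs, config_noise(config), config$seed,
                              config$beat_length)
  prefix <- file.path(config$out_dir, "cohort")
  write_beats(cohort, prefix)
  gt <- data.frame(subject_id = cohort$subject_id, r_index = cohort$r_index)
  utils::write.table(gt, paste0(prefix, "_rpeaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(sprintf("simulate: wrote %d beats (%d subjects x %d) to %s",
                  nrow(cohort), config$n_subjects,
                  nrow(cohort) / config$n_subjects, prefix))
  invisible(prefix)
}

#' Run the pipeline and write its report (CLI backend)
#'
#' @param config A `pipeline_config`; `out_dir` must be set.
#' @return The report, invisibly.
#' @export
cmd_pipeline <- function(config) {
  if (!nzchar(config$out_dir)) stop("`out_dir` must be set", call. = FALSE)
  report <- run_pipeline(config)
  write_pipeline_report(report, config$out_dir)
  message(sprintf("pipeline: identification accuracy %.4f; report in %s",
                  report$identification$accuracy, config$out_dir))
  invisible(report)
}
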