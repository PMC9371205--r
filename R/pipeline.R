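#' Preprocess a simulated session to the working rate
#'
#' Filters and downsamples the raw recording and maps the ground-truth
#' labels onto the same 50 Hz grid (standardization is applied separately
#' once a scaler fitted on training subjects exists).
#'
#' @param session a [generate_session()] result (or any list with
#'   `recording` and `labels`).
#' @param cutoff,order,target_rate see [preprocess_recording()].
#' @return The session with `recording` and `labels` replaced by their
#'   50 Hz versions (original lap table untouched; lap times are expressed
#'   in seconds and are rate-independent).
#' @export
preprocess_session <- function(session, cutoff = 10, order = 2,
                               target_rate = 50) {
  rec <- preprocess_recording(session$recording, cutoff = cutoff,
                              order = order, target_rate = target_rate)
  session$recording <- rec
  if (!is.null(session$labels)) {
    session$labels <- resample_labels(session$labels, target_rate,
                                      n_out = nrow(rec$samples))
  }
  session
}

#' Hold-one-subject-out experiment on a synthetic cohort
#'
#' The package's end-to-end experiment: simulate a cohort, preprocess,
#' split subject-wise, fit the channel scaler on training subjects only,
#' train the bidirectional LSTM classifier, predict the held-out test
#' subject frame by frame, filter the prediction, and score both the
#' frame-level classification (before and after filtering) and the derived
#' lap times against the simulator's ground truth.
#'
#' @param n_subjects cohort size (>= 3).
#' @param seed master seed for simulation, splitting, initialization and
#'   training.
#' @param epochs training epochs.
#' @param train_stride stride (frames) between training windows; 1 uses
#'   every frame, larger values thin the training set without changing the
#'   per-frame prediction semantics.
#' @param val_stride stride for the validation-monitoring windows.
#' @param plan session plan template.
#' @param policy label [filter_policy()].
#' @param cfg [model_config()].
#' @param scaler_scope fit the standardization scaler on `"train"` subjects
#'   only (default; no information crosses the subject split) or on `"all"`
#'   subjects.
#' @param verbose print per-stage progress.
#' @return List with `report_raw`, `report_filtered`
#'   ([classification_report()]s on the test subject), `agreement`
#'   ([agreement_report()] of predicted vs true lap durations), `pairs`,
#'   `model`, `split`, `history`.
#' @export
run_hoscv_experiment <- function(n_subjects = 6, seed = 1L, epochs = 10L,
                                 train_stride = 6L, val_stride = 25L,
                                 plan = default_session_plan(),
                                 policy = filter_policy(),
                                 cfg = model_config(strict_reference = TRUE),
                                 scaler_scope = c("train", "all"),
                                 verbose = FALSE) {
  scaler_scope <- match.arg(scaler_scope)
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating %d-subject cohort (seed %d)", n_subjects, seed)
  cohort <- generate_cohort(n_subjects, plan, seed = seed)
  ids <- vapply(cohort, function(s) s$recording$subject_id, "")
  names(cohort) <- ids
  split <- split_hoscv(ids, seed = seed)
  say("split: train %s | val %s | test %s",
      paste(split$train, collapse = ","), split$validation, split$test)
  say("preprocessing to 50 Hz")
  cohort <- lapply(cohort, preprocess_session)
  scaler_ids <- if (scaler_scope == "train") split$train else ids
  scaler <- fit_scaler(lapply(cohort[scaler_ids], `[[`, "recording"))
  cohort <- lapply(cohort, function(s) {
    s$recording <- apply_scaler(s$recording, scaler)
    s
  })
  say("windowing (train stride %d)", train_stride)
  train_batch <- bind_windows(lapply(cohort[split$train], function(s) {
    make_windows(s$recording, s$labels, stride = train_stride,
                 layout = cfg$layout, window = cfg$window)
  }))
  val_batch <- make_windows(cohort[[split$validation]]$recording,
                            cohort[[split$validation]]$labels,
                            stride = val_stride, layout = cfg$layout,
                            window = cfg$window)
  model <- build_model(cfg, seed = seed)
  model$scaler <- scaler
  say("training %d epochs on %d windows", epochs, dim(train_batch$x)[1])
  model <- train_model(model, train_batch, val_batch,
                       training_config(epochs = epochs, seed = seed))
  say("final val accuracy %.4f",
      utils::tail(model$history$val_accuracy, 1))
  test <- cohort[[split$test]]
  say("predicting test subject %s", split$test)
  pred <- predict_sequence(model, test$recording)
  filtered <- filter_predictions(pred$labels, policy)
  report_raw <- classification_report(pred$labels, test$labels)
  report_filtered <- classification_report(filtered, test$labels)
  lap_pred <- compute_lap_times(filtered, subject_id = split$test)
  paired <- pair_lap_tables(lap_pred, test$laps)
  agreement <- if (nrow(paired$pairs) >= 2L) agreement_report(paired$pairs)
  say("weighted F1 raw %.4f -> filtered %.4f; %d/%d laps matched",
      report_raw$weighted[["f1"]], report_filtered$weighted[["f1"]],
      nrow(paired$pairs), nrow(test$laps))
  list(report_raw = report_raw, report_filtered = report_filtered,
       agreement = agreement, pairs = paired, model = model, split = split,
       history = model$history)
}
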