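#' Read and write IMU recordings as CSV
#'
#' The on-disk format is a plain comma-separated file with a header row,
#' a `time_s` column and the six channel columns `ax,ay,az,gx,gy,gz`
#' (any column order; extra columns ignored), preceded by `#key=value`
#' metadata lines (subject_id, session_id, sample_rate, preprocessed).
#' Timestamps must be uniform to within 1e-6 s.
#'
#' @param rec an [imu_recording()].
#' @param path file path.
#' @return `read_imu_csv()`: an [imu_recording()].
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s",
                     c("subject_id", "session_id", "sample_rate", "preprocessed"),
                     c(rec$subject_id, rec$session_id,
                       format(rec$sample_rate, digits = 15),
                       rec$preprocessed)), con)
  df <- data.frame(time_s = (seq_len(nrow(rec$samples)) - 1L) / rec$sample_rate,
                   rec$samples)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @param sample_rate declared rate in Hz, overriding/validating the file's
#'   time column and metadata.
#' @export
read_imu_csv <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- .read_meta(path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse IMU CSV ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("empty IMU file: ", path)
  missing <- setdiff(imu_channels(), names(df))
  if (length(missing)) {
    stop("missing channel column: ", paste(missing, collapse = ", "))
  }
  rate <- sample_rate
  if (is.null(rate) && !is.null(meta$sample_rate)) {
    rate <- as.numeric(meta$sample_rate)
  }
  if ("time_s" %in% names(df) && nrow(df) > 1L) {
    dt <- diff(df$time_s)
    if (max(dt) - min(dt) > 1e-6) {
      stop("non-uniform timestamps (spread ",
           format(max(dt) - min(dt)), " s) in ", path)
    }
    rate_file <- 1 / stats::median(dt)
    if (is.null(rate)) rate <- rate_file
    else if (abs(rate_file - rate) / rate > 1e-6) {
      stop(sprintf("declared rate %g Hz does not match time column (%g Hz)",
                   rate, rate_file))
    }
  }
  if (is.null(rate)) stop("no sample rate: give sample_rate or a time_s column")
  imu_recording(as.matrix(df[imu_channels()]), rate,
                subject_id = meta$subject_id %||% "S1",
                session_id = meta$session_id %||% "A",
                preprocessed = isTRUE(as.logical(meta$preprocessed %||% FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_meta <- function(path) {
  head_lines <- readLines(path, n = 20L, warn = FALSE)
  kv <- grep("^#[^=]+=", head_lines, value = TRUE)
  if (!length(kv)) return(list())
  keys <- sub("^#([^=]+)=.*$", "\\1", kv)
  vals <- sub("^#[^=]+=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read and write per-frame label files
#'
#' Two formats are supported: an interval CSV with columns
#' `start_s,end_s,activity` (half-open intervals in seconds; frames
#' `floor(start*rate) .. floor(end*rate) - 1` take the class, intervals
#' must tile the session), or a single-column file `activity` with one
#' class token per frame. [write_labels()] writes the interval form (it is
#' ~3 orders of magnitude smaller).
#'
#' @param seq a [label_sequence()].
#' @param path file path.
#' @export
write_labels <- function(seq, path) {
  stopifnot(inherits(seq, "label_sequence"))
  segs <- labels_to_segments(seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample_rate=%s", format(seq$sample_rate, digits = 15)),
             con)
  writeLines(sprintf("#provenance=%s", seq$provenance), con)
  df <- data.frame(
    start_s = format(segs$start_frame / seq$sample_rate, digits = 15),
    end_s = format(segs$end_frame / seq$sample_rate, digits = 15),
    activity = segs$activity
  )
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @param sample_rate frames per second of the decoded sequence (defaults
#'   to the rate recorded in the file).
#' @export
read_labels <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- .read_meta(path)
  rate <- sample_rate %||%
    (if (!is.null(meta$sample_rate)) as.numeric(meta$sample_rate))
  if (is.null(rate)) stop("no sample rate: give sample_rate= or file metadata")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  prov <- meta$provenance %||% "ground_truth"
  if (all(c("start_s", "end_s", "activity") %in% names(df))) {
    activity_code(df$activity) # validate tokens
    df <- df[order(df$start_s), , drop = FALSE]
    start_f <- as.integer(floor(df$start_s * rate + 1e-9))
    end_f <- as.integer(floor(df$end_s * rate + 1e-9))
    if (start_f[1] != 0L) stop("label intervals must start at 0 s")
    if (any(start_f[-1] != end_f[-nrow(df)])) {
      stop("label intervals have gaps or overlaps")
    }
    segs <- data.frame(activity = df$activity, start_frame = start_f,
                       end_frame = end_f, stringsAsFactors = FALSE)
    segments_to_labels(segs, rate, prov)
  } else if ("activity" %in% names(df)) {
    label_sequence(df$activity, rate, prov)
  } else {
    stop("unrecognized label file format (need start_s,end_s,activity ",
         "intervals or an activity column)")
  }
}

#' Read and write lap tables as CSV
#'
#' Columns `subject, session, block, lap_index, technique, lap_type,
#' start_s, end_s, duration_s`; second values carry >= 4 decimals so the
#' 0.02 s working resolution round-trips exactly.
#'
#' @param laps a lap table ([compute_lap_times()]).
#' @param path file path.
#' @export
write_lap_table <- function(laps, path) {
  df <- as.data.frame(laps)
  cols <- c("subject", "session", "block", "lap_index", "technique",
            "lap_type", "start_s", "end_s", "duration_s")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  df <- df[, cols, drop = FALSE]
  for (cc in c("start_s", "end_s", "duration_s")) {
    df[[cc]] <- sprintf("%.6f", df[[cc]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lap_table
#' @export
read_lap_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject = "character",
                                       session = "character"))
  class(df) <- c("lap_table", "data.frame")
  df
}

#' Persist and restore a trained model bundle
#'
#' A bundle is a directory holding `metadata.json` (architecture and
#' training configuration, channel scaler, batch-norm statistics, class
#' vocabulary, training history) and `weights.csv` (one row per scalar
#' weight: parameter name, row, column, value), both plain text, so a
#' trained classifier round-trips without binary artifacts.
#'
#' @param model a trained [swim_model].
#' @param dir bundle directory (created if needed).
#' @export
save_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "swim_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- model$weights
  flat <- list()
  put <- function(name, x) {
    x <- as.matrix(x)
    if (nrow(x) > 1L && ncol(x) == 1L) x <- t(x) # store vectors as rows
    flat[[name]] <<- data.frame(
      param = name,
      row = as.vector(row(x)), col = as.vector(col(x)),
      value = as.vector(x)
    )
  }
  for (l in seq_len(w$n_layers)) {
    for (nm in c("Wf", "Uf", "bf", "Wb", "Ub", "bb")) {
      put(sprintf("l%d.%s", l, nm), w$layers[[l]][[nm]])
    }
  }
  for (nm in c("W1", "b1", "gamma", "beta", "rmean", "rvar", "W2", "b2")) {
    put(nm, w[[nm]])
  }
  wdf <- do.call(rbind, flat)
  utils::write.csv(wdf, file.path(dir, "weights.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(
    format_version = 1L,
    classes = activity_levels(),
    cfg = unclass(model$cfg),
    tcfg = if (!is.null(model$tcfg)) unclass(model$tcfg),
    scaler = if (!is.null(model$scaler)) {
      list(means = unname(model$scaler$means), sds = unname(model$scaler$sds),
           fitted_on = model$scaler$fitted_on)
    },
    history = model$history,
    trained = model$trained,
    shapes = lapply(flat, function(d) c(max(d$row), max(d$col)))
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  mpath <- file.path(dir, "metadata.json")
  wpath <- file.path(dir, "weights.csv")
  if (!file.exists(mpath) || !file.exists(wpath)) {
    stop("not a model bundle (missing metadata.json/weights.csv): ", dir)
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.character(meta$classes), activity_levels())) {
    stop("bundle class vocabulary does not match this package")
  }
  cfg <- do.call(model_config, meta$cfg[c("units", "dense_units", "n_classes",
                                          "dropout", "recurrent_dropout",
                                          "dense_dropout", "batch_size",
                                          "layout", "window", "strict_reference")])
  wdf <- utils::read.csv(wpath, stringsAsFactors = FALSE)
  get_mat <- function(name) {
    d <- wdf[wdf$param == name, , drop = FALSE]
    shape <- meta$shapes[[name]]
    m <- matrix(0, shape[1], shape[2])
    m[cbind(d$row, d$col)] <- d$value
    if (shape[1] == 1L) as.numeric(m) else m
  }
  layers <- lapply(seq_along(cfg$units), function(l) {
    stats::setNames(
      lapply(c("Wf", "Uf", "bf", "Wb", "Ub", "bb"), function(nm) {
        get_mat(sprintf("l%d.%s", l, nm))
      }),
      c("Wf", "Uf", "bf", "Wb", "Ub", "bb"))
  })
  weights <- c(
    list(n_layers = length(cfg$units), layers = layers),
    stats::setNames(
      lapply(c("W1", "b1", "gamma", "beta", "rmean", "rvar", "W2", "b2"),
             get_mat),
      c("W1", "b1", "gamma", "beta", "rmean", "rvar", "W2", "b2"))
  )
  model <- structure(
    list(cfg = cfg, weights = weights, scaler = NULL,
         history = meta$history, trained = isTRUE(meta$trained)),
    class = "swim_model"
  )
  if (length(meta$scaler)) {
    model$scaler <- structure(
      list(means = stats::setNames(as.numeric(meta$scaler$means),
                                   imu_channels()),
           sds = stats::setNames(as.numeric(meta$scaler$sds), imu_channels()),
           fitted_on = meta$scaler$fitted_on),
      class = "channel_scaler")
  }
  if (length(meta$tcfg)) {
    model$tcfg <- do.call(training_config,
                          meta$tcfg[c("epochs", "learning_rate", "lr_base",
                                      "lr_scale", "seed")])
  }
  model
}
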