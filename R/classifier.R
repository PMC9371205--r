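#' Network architecture configuration
#'
#' Describes the stacked bidirectional LSTM classifier: four Bi-LSTM layers
#' of 64/32/16/16 units per direction (tanh activations, dropout 0.25 and
#' recurrent dropout 0.25), a dense ReLU layer of 50 units followed by batch
#' normalization and dropout 0.5, and a dense softmax output over the 8
#' activity classes. Under the default `"channels_as_time"` layout the network consumes
#' 6 sequence steps (one per IMU channel) of 90-frame feature vectors; with
#' `strict_reference = TRUE`, [build_model()] refuses any configuration whose
#' per-layer parameter counts deviate from the reference architecture
#' (79,360 / 41,216 / 10,368 / 6,272 / 0 / 1,650 / 200 / 408).
#'
#' @param units recurrent units per direction for each Bi-LSTM layer.
#' @param dense_units width of the dense ReLU head.
#' @param n_classes number of output classes.
#' @param dropout,recurrent_dropout dropout rates on the recurrent layers.
#' @param dense_dropout dropout rate on the dense head.
#' @param batch_size minibatch size.
#' @param layout tensor layout, see [make_windows()].
#' @param window window length in frames.
#' @param strict_reference if TRUE, enforce the reference per-layer counts.
#' @return An object of class `model_config`.
#' @export
model_config <- function(units = c(64L, 32L, 16L, 16L), dense_units = 50L,
                         n_classes = 8L, dropout = 0.25,
                         recurrent_dropout = 0.25, dense_dropout = 0.5,
                         batch_size = 64L,
                         layout = c("channels_as_time", "frames_as_time"),
                         window = 90L, strict_reference = FALSE) {
  layout <- match.arg(layout)
  structure(
    list(units = as.integer(units), dense_units = as.integer(dense_units),
         n_classes = as.integer(n_classes), dropout = dropout,
         recurrent_dropout = recurrent_dropout, dense_dropout = dense_dropout,
         batch_size = as.integer(batch_size), layout = layout,
         window = as.integer(window), strict_reference = isTRUE(strict_reference)),
    class = "model_config"
  )
}

#' Training regime configuration
#'
#' Ten epochs of ADAM with an initial learning rate of 0.001 declining
#' per epoch as `lr = 0.001 * 800^(-epoch/100)` (see [lr_schedule()]),
#' Xavier-uniform weight initialization and sparse categorical
#' cross-entropy loss.
#'
#' @param epochs number of passes over the training windows.
#' @param learning_rate initial learning rate.
#' @param lr_base,lr_scale schedule shape parameters, see [lr_schedule()].
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @param class_weights optional numeric vector of 8 per-class loss weights
#'   (e.g., inverse class frequencies); NULL for unweighted loss.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 10L, learning_rate = 0.001,
                            lr_base = 800, lr_scale = 100, seed = 1L,
                            class_weights = NULL) {
  stopifnot(epochs >= 1L, learning_rate > 0)
  if (!is.null(class_weights)) stopifnot(length(class_weights) == 8L,
                                         all(class_weights > 0))
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         lr_base = lr_base, lr_scale = lr_scale, seed = as.integer(seed),
         class_weights = class_weights),
    class = "training_config"
  )
}

#' Epoch-dependent learning-rate decline
#'
#' `lr(epoch) = learning_rate * lr_base^(-epoch / lr_scale)` with epoch
#' counted from 0, so the first epoch trains at the initial rate and the
#' rate decays geometrically thereafter (about 6.5% per epoch with the
#' defaults). The schedule is non-increasing by construction.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param tcfg a [training_config()].
#' @return Learning rate(s) for the given epoch(s).
#' @export
lr_schedule <- function(epoch, tcfg = training_config()) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  tcfg$learning_rate * tcfg$lr_base^(-epoch / tcfg$lr_scale)
}

# input feature dimension seen by the first recurrent layer
.input_dims <- function(cfg) {
  if (cfg$layout == "channels_as_time") c(steps = 6L, features = cfg$window)
  else c(steps = cfg$window, features = 6L)
}

#' Per-layer trainable parameter counts
#'
#' A bidirectional LSTM layer with `u` units per direction over `d`-dim
#' inputs has `2 * 4 * u * (d + u + 1)` parameters; the dense head adds
#' `d*50 + 50`, batch normalization `4*50` (half of them the non-trained
#' moving statistics, counted as in common DL framework summaries), and the
#' softmax layer `50*8 + 8`.
#'
#' @param cfg a [model_config()] or a fitted [build_model()] handle.
#' @return Named integer vector of per-layer parameter counts
#'   (4 Bi-LSTM layers, flatten, dense, batch_norm, dense).
#' @export
count_parameters <- function(cfg) {
  if (inherits(cfg, "swim_model")) cfg <- cfg$cfg
  stopifnot(inherits(cfg, "model_config"))
  d <- .input_dims(cfg)[["features"]]
  counts <- integer(0)
  for (u in cfg$units) {
    counts <- c(counts, 2L * 4L * u * (d + u + 1L))
    d <- 2L * u
  }
  counts <- c(counts, 0L,
              d * cfg$dense_units + cfg$dense_units,
              4L * cfg$dense_units,
              cfg$dense_units * cfg$n_classes + cfg$n_classes)
  names(counts) <- c(paste0("bilstm_", seq_along(cfg$units)), "flatten",
                     "dense", "batch_norm", "output")
  counts
}

.reference_counts <- c(79360L, 41216L, 10368L, 6272L, 0L, 1650L, 200L, 408L)

.xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained classifier
#'
#' Initializes all weights Xavier-uniform (biases zero, except the LSTM
#' forget-gate biases initialized to 1, the usual stabilization) and
#' returns an untrained model handle. With `cfg$strict_reference = TRUE` the
#' constructor verifies the per-layer parameter counts against the
#' reference architecture and errors on any deviation.
#'
#' @param cfg a [model_config()].
#' @param seed seed for the weight initialization.
#' @return An object of class `swim_model`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$strict_reference) {
    got <- count_parameters(cfg)
    if (!identical(unname(got), .reference_counts)) {
      stop("strict_reference: parameter counts (",
           paste(got, collapse = ", "),
           ") do not match the reference architecture (",
           paste(.reference_counts, collapse = ", "), ")")
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  d <- .input_dims(cfg)[["features"]]
  layers <- list()
  for (u in cfg$units) {
    b0 <- c(rep(0, u), rep(1, u), rep(0, 2 * u)) # forget bias 1
    layers[[length(layers) + 1L]] <- list(
      Wf = .xavier(d, 4L * u), Uf = .xavier(u, 4L * u), bf = b0,
      Wb = .xavier(d, 4L * u), Ub = .xavier(u, 4L * u), bb = b0
    )
    d <- 2L * u
  }
  weights <- list(
    n_layers = length(cfg$units), layers = layers,
    W1 = .xavier(d, cfg$dense_units), b1 = rep(0, cfg$dense_units),
    gamma = rep(1, cfg$dense_units), beta = rep(0, cfg$dense_units),
    rmean = rep(0, cfg$dense_units), rvar = rep(1, cfg$dense_units),
    W2 = .xavier(cfg$dense_units, cfg$n_classes), b2 = rep(0, cfg$n_classes)
  )
  structure(
    list(cfg = cfg, weights = weights, scaler = NULL, history = NULL,
         trained = FALSE),
    class = "swim_model"
  )
}

#' @export
print.swim_model <- function(x, ...) {
  counts <- count_parameters(x$cfg)
  cat(sprintf("<swim_model> %s, %s layout, %s total parameters\n",
              if (x$trained) "trained" else "untrained", x$cfg$layout,
              format(sum(counts), big.mark = ",")))
  print(counts)
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("last epoch: loss %.4f, accuracy %.4f%s\n",
                utils::tail(h$loss, 1), utils::tail(h$accuracy, 1),
                if (length(h$val_accuracy)) {
                  sprintf(", val accuracy %.4f", utils::tail(h$val_accuracy, 1))
                } else ""))
  }
  invisible(x)
}

#' Hold-one-subject-out split of a cohort
#'
#' Picks holdout subjects for validation and testing (one whole subject
#' each by default, drawn without replacement) and assigns every remaining
#' subject to training. Using two distinct subjects keeps the
#' validation-monitored quantities independent of the test subject;
#' `single_holdout_subject = TRUE` reuses one subject for both sets.
#'
#' @param cohort list of sessions (each with a `subject_id`, e.g. elements
#'   of [generate_cohort()]), or a character vector of subject ids.
#' @param seed integer seed for the draw.
#' @param single_holdout_subject reuse the same subject for validation and
#'   test.
#' @return List with character vectors `train`, `validation`, `test` of
#'   subject ids.
#' @export
split_hoscv <- function(cohort, seed = 1L, single_holdout_subject = FALSE) {
  ids <- if (is.character(cohort)) cohort else {
    vapply(cohort, function(s) {
      if (inherits(s, "imu_recording")) s$subject_id else s$recording$subject_id
    }, "")
  }
  ids <- unique(ids)
  if (length(ids) < 3L) stop("HOSCV needs at least 3 subjects")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  if (single_holdout_subject) {
    hold <- sample(ids, 1L)
    list(train = setdiff(ids, hold), validation = hold, test = hold)
  } else {
    hold <- sample(ids, 2L)
    list(train = setdiff(ids, hold), validation = hold[1], test = hold[2])
  }
}

#' Train the classifier
#'
#' Runs minibatch ADAM with backpropagation through time over the training
#' windows for `tcfg$epochs` epochs, using the epoch-dependent learning-rate
#' decline of [lr_schedule()], inverted dropout/recurrent dropout, and batch
#' normalization with moving statistics (frozen at inference). Training is
#' deterministic for a fixed seed in single-threaded execution.
#'
#' @param model a [build_model()] handle.
#' @param train_batch a [make_windows()] batch with targets.
#' @param val_batch optional validation batch with targets (per-epoch
#'   accuracy monitoring).
#' @param tcfg a [training_config()].
#' @return The trained `swim_model`, with `history` (per-epoch loss,
#'   training accuracy and validation accuracy).
#' @export
train_model <- function(model, train_batch, val_batch = NULL,
                        tcfg = training_config()) {
  stopifnot(inherits(model, "swim_model"),
            inherits(train_batch, "window_batch"))
  if (is.null(train_batch$targets)) stop("training batch has no targets")
  if (any(train_batch$targets < 0L | train_batch$targets >= model$cfg$n_classes)) {
    stop("target class code outside 0..", model$cfg$n_classes - 1L)
  }
  if (train_batch$layout != model$cfg$layout) {
    stop("window batch layout does not match the model configuration")
  }
  lr <- lr_schedule(seq_len(tcfg$epochs) - 1L, tcfg)
  cw <- if (is.null(tcfg$class_weights)) numeric(0) else tcfg$class_weights
  xval <- yval <- NULL
  if (!is.null(val_batch)) {
    stopifnot(inherits(val_batch, "window_batch"), !is.null(val_batch$targets))
    xval <- val_batch$x
    yval <- as.integer(val_batch$targets)
  }
  fit <- .bilstm_train_cpp(model$weights, train_batch$x,
                           as.integer(train_batch$targets),
                           tcfg$epochs, model$cfg$batch_size, lr,
                           model$cfg$dropout, model$cfg$recurrent_dropout,
                           model$cfg$dense_dropout, cw, tcfg$seed,
                           xval, yval)
  model$weights <- fit$weights
  model$history <- list(loss = as.numeric(fit$loss),
                        accuracy = as.numeric(fit$accuracy),
                        val_accuracy = as.numeric(fit$val_accuracy),
                        learning_rate = lr)
  model$tcfg <- tcfg
  model$trained <- TRUE
  model
}

#' Predict the per-frame activity sequence of a recording
#'
#' Preprocesses the recording if it is still raw (requires the scaler
#' stored on the model), slides a window over every frame (edge frames
#' replicated) and emits one label per 0.02 s frame at the working rate,
#' the class of maximal softmax probability at each window's median frame.
#'
#' @param model a trained [swim_model].
#' @param rec an [imu_recording()], raw (280 Hz) or preprocessed (50 Hz).
#' @param batch_windows forward-pass chunk size.
#' @return List with `labels` (a [label_sequence()] with provenance
#'   `raw_prediction`) and `probs` (frames x 8 matrix of class
#'   probabilities, rows summing to 1).
#' @export
predict_sequence <- function(model, rec, batch_windows = 1024L) {
  stopifnot(inherits(model, "swim_model"), inherits(rec, "imu_recording"))
  if (!model$trained) warning("predicting with an untrained model")
  if (!rec$preprocessed) {
    if (is.null(model$scaler)) {
      stop("raw recording but the model stores no scaler; preprocess first")
    }
    rec <- preprocess_recording(rec, scaler = model$scaler)
  }
  batch <- make_windows(rec, stride = 1L, pad_edges = TRUE,
                        window = model$cfg$window, layout = model$cfg$layout)
  probs <- .bilstm_predict_cpp(model$weights, batch$x, as.integer(batch_windows))
  colnames(probs) <- activity_levels()
  labels <- activity_from_code(max.col(probs, ties.method = "first") - 1L)
  list(labels = label_sequence(labels, rec$sample_rate, "raw_prediction"),
       probs = probs)
}
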