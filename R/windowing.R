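#' Sliding-window segmentation into the network input tensor
#'
#' Cuts a preprocessed 50 Hz recording into 90-frame (1.8 s) sliding
#' windows and stacks them into the 3-D array the classifier consumes. Each
#' window is labelled with the activity of its median frame (0-based index
#' 45 of 0..89), so predictions land on a single frame and the model emits
#' one label per 0.02 s time step.
#'
#' Two tensor layouts are supported. The default `"channels_as_time"` layout feeds the
#' recurrent layers the 6 channels as sequence steps, each step being the
#' 90-frame vector of that channel — the layout whose per-layer parameter
#' counts match the published architecture (see [count_parameters()]). The
#' `"frames_as_time"` layout is the conventional alternative (90 steps of
#' 6-channel frames) and yields a different, smaller network.
#'
#' @param rec a preprocessed [imu_recording()] (50 Hz in the default
#'   pipeline).
#' @param labels optional [label_sequence()] of the same length supplying
#'   per-window targets.
#' @param stride window start step in frames.
#' @param pad_edges if `TRUE`, boundary frames are replicated so every frame
#'   (at the given stride) gets a window centred on it; if `FALSE`, windows
#'   are fully interior and a recording shorter than one window is an error.
#' @param window window length in frames.
#' @param layout `"channels_as_time"` or `"frames_as_time"` (see Details).
#' @return An object of class `window_batch`: list with the array `x`
#'   (n x steps x features), integer `targets` (class codes 0..7, or NULL),
#'   `frame_index` (0-based centre frame of each window), `window`, `stride`,
#'   `layout`, `sample_rate`.
#' @export
make_windows <- function(rec, labels = NULL, stride = 1L, pad_edges = TRUE,
                         window = 90L, layout = c("channels_as_time", "frames_as_time")) {
  stopifnot(inherits(rec, "imu_recording"))
  layout <- match.arg(layout)
  n <- nrow(rec$samples)
  window <- as.integer(window)
  stride <- as.integer(stride)
  stopifnot(window >= 2L, stride >= 1L)
  center_off <- window %/% 2L # median frame: index 45 of 0..89
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_sequence"))
    if (length(labels$labels) != n) {
      stop("labels length does not match recording frame count")
    }
  }
  if (pad_edges) {
    centers <- seq.int(0L, n - 1L, by = stride)
  } else {
    if (n < window) stop("recording shorter than one window (padding disabled)")
    starts <- seq.int(0L, n - window, by = stride)
    centers <- starts + center_off
  }
  nw <- length(centers)
  # frame indices per window, clamped to the valid range (edge replication)
  rel <- seq.int(-center_off, window - center_off - 1L)
  idx <- outer(centers, rel, "+")
  idx[idx < 0L] <- 0L
  idx[idx > n - 1L] <- n - 1L
  sel <- rec$samples[as.vector(idx) + 1L, , drop = FALSE] # (nw*window) x 6
  if (layout == "channels_as_time") {
    # steps = 6 channels, features = `window` frames of that channel
    x <- array(sel, dim = c(nw, window, 6L))
    x <- aperm(x, c(1L, 3L, 2L))
  } else {
    x <- array(sel, dim = c(nw, window, 6L))
  }
  targets <- if (!is.null(labels)) activity_code(labels$labels[centers + 1L])
  structure(
    list(x = x, targets = targets, frame_index = centers, window = window,
         stride = stride, layout = layout, sample_rate = rec$sample_rate),
    class = "window_batch"
  )
}

#' @export
print.window_batch <- function(x, ...) {
  cat(sprintf("<window_batch> %d windows of %d frames (%s layout, stride %d)%s\n",
              dim(x$x)[1], x$window, x$layout, x$stride,
              if (is.null(x$targets)) "" else ", with targets"))
  invisible(x)
}

#' Deterministically shuffle a window batch
#'
#' Permutes windows and their targets by the same seeded permutation
#' (training batches are shuffled to break the temporal ordering of
#' consecutive windows).
#'
#' @param batch a [make_windows()] result.
#' @param seed integer seed; the same seed yields the same order.
#' @return The permuted `window_batch`.
#' @export
shuffle_windows <- function(batch, seed) {
  stopifnot(inherits(batch, "window_batch"))
  nw <- dim(batch$x)[1]
  if (nw < 1L) stop("empty window batch")
  # local RNG scope: save/restore .Random.seed
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  p <- sample.int(nw)
  batch$x <- batch$x[p, , , drop = FALSE]
  if (!is.null(batch$targets)) batch$targets <- batch$targets[p]
  batch$frame_index <- batch$frame_index[p]
  batch
}

#' Concatenate window batches (e.g., several training subjects)
#'
#' @param ... `window_batch` objects with identical window length and layout.
#' @return A single `window_batch`.
#' @export
bind_windows <- function(...) {
  batches <- list(...)
  if (length(batches) == 1L && is.list(batches[[1]]) &&
      !inherits(batches[[1]], "window_batch")) {
    batches <- batches[[1]]
  }
  stopifnot(length(batches) >= 1L)
  b1 <- batches[[1]]
  for (b in batches) {
    stopifnot(inherits(b, "window_batch"), b$window == b1$window,
              b$layout == b1$layout)
  }
  xs <- lapply(batches, `[[`, "x")
  n_total <- sum(vapply(xs, function(a) dim(a)[1], 0L))
  out <- array(0, dim = c(n_total, dim(b1$x)[2], dim(b1$x)[3]))
  at <- 1L
  for (a in xs) {
    k <- dim(a)[1]
    out[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  tg <- lapply(batches, `[[`, "targets")
  b1$x <- out
  b1$targets <- if (!any(vapply(tg, is.null, TRUE))) unlist(tg)
  b1$frame_index <- unlist(lapply(batches, `[[`, "frame_index"))
  b1
}
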