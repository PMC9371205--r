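#' Per-frame activity label sequence
#'
#' One activity class per frame of a recording, together with the sampling
#' rate (so frame k covers time `k / sample_rate` seconds, 0-based) and a
#' provenance tag distinguishing video-derived ground truth from raw and
#' filtered network predictions.
#'
#' @param labels character vector of activity codes (see [activity_levels()]),
#'   or a factor over those levels.
#' @param sample_rate frames per second.
#' @param provenance one of `"ground_truth"`, `"raw_prediction"`,
#'   `"filtered_prediction"`.
#' @return An object of class `label_sequence`.
#' @export
label_sequence <- function(labels, sample_rate,
                           provenance = c("ground_truth", "raw_prediction",
                                          "filtered_prediction")) {
  provenance <- match.arg(provenance)
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("label sequence must contain at least 1 frame")
  activity_code(labels) # validates tokens
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  structure(
    list(labels = labels, sample_rate = as.numeric(sample_rate),
         provenance = provenance),
    class = "label_sequence"
  )
}

#' @export
print.label_sequence <- function(x, ...) {
  segs <- labels_to_segments(x)
  cat(sprintf("<label_sequence> %d frames @ %g Hz, %d segments, %s\n",
              length(x$labels), x$sample_rate, nrow(segs), x$provenance))
  invisible(x)
}

#' Run-length encode a label sequence into segments
#'
#' A segment is one maximal run of a single activity class with half-open
#' 0-based frame bounds `[start_frame, end_frame)`. Consecutive segments have
#' distinct activities and tile the frame range without gaps, so the encoding
#' is lossless.
#'
#' @param seq a [label_sequence()].
#' @return data.frame with columns `activity`, `start_frame`, `end_frame`
#'   (0-based, half-open) and `duration_s`.
#' @seealso [segments_to_labels()] for the inverse.
#' @export
labels_to_segments <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  if (length(seq$labels) == 0L) stop("empty label sequence: no frames")
  r <- rle(seq$labels)
  end <- cumsum(r$lengths)
  start <- c(0L, end[-length(end)])
  data.frame(
    activity = r$values,
    start_frame = as.integer(start),
    end_frame = as.integer(end),
    duration_s = r$lengths / seq$sample_rate,
    stringsAsFactors = FALSE
  )
}

#' Decode segments back into a per-frame label sequence
#'
#' Inverse of [labels_to_segments()]. Segments must tile a contiguous
#' half-open range starting at frame 0; a gap or overlap is an error.
#'
#' @param segs data.frame with columns `activity`, `start_frame`, `end_frame`.
#' @param sample_rate frames per second of the decoded sequence.
#' @param provenance provenance tag for the result.
#' @return A [label_sequence()].
#' @export
segments_to_labels <- function(segs, sample_rate, provenance = "ground_truth") {
  stopifnot(is.data.frame(segs), nrow(segs) >= 1L)
  segs <- segs[order(segs$start_frame), , drop = FALSE]
  if (segs$start_frame[1] != 0L) stop("segments must start at frame 0")
  if (any(segs$end_frame <= segs$start_frame)) {
    stop("segment with end_frame <= start_frame")
  }
  if (nrow(segs) > 1L) {
    nxt <- segs$start_frame[-1]
    prv <- segs$end_frame[-nrow(segs)]
    if (any(nxt != prv)) stop("segments have gaps or overlaps")
  }
  labels <- rep(as.character(segs$activity), segs$end_frame - segs$start_frame)
  label_sequence(labels, sample_rate, provenance)
}

#' Map a label sequence onto a lower sampling rate
#'
#' Used to align 280 Hz ground-truth labels with the 50 Hz preprocessed
#' signal: output frame k takes the label of the source frame covering time
#' `k / target_rate`.
#'
#' @param seq a [label_sequence()].
#' @param target_rate target frames per second (must not exceed the source).
#' @param n_out optional output length (defaults to the length the signal
#'   resampler produces for the same input length).
#' @return A [label_sequence()] at `target_rate`.
#' @export
resample_labels <- function(seq, target_rate, n_out = NULL) {
  stopifnot(inherits(seq, "label_sequence"))
  if (target_rate > seq$sample_rate) stop("upsampling labels is unsupported")
  n_in <- length(seq$labels)
  if (is.null(n_out)) {
    n_out <- floor((n_in - 1L) * target_rate / seq$sample_rate) + 1L
  }
  idx <- floor((seq_len(n_out) - 1L) * seq$sample_rate / target_rate) + 1L
  idx <- pmin(idx, n_in)
  label_sequence(seq$labels[idx], target_rate, seq$provenance)
}
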