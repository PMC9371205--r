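#' Minimum-duration policy for prediction filtering
#'
#' Each activity class gets a minimum plausible segment duration; predicted
#' segments shorter than their class minimum are treated as artefacts
#' ("prediction skips") and absorbed into a neighbour. The defaults reflect
#' phase physiology — a wallpush lasts a fraction of a second, a turn well
#' under a second, whereas a stroke bout shorter than ~1.5 s cannot be a
#' real lap segment — and are deliberately config-exposed rather than
#' canonical.
#'
#' @param min_duration_s named numeric vector of per-class minimum segment
#'   durations in seconds (names are activity codes; every class must be
#'   covered).
#' @param max_iterations safety bound on the merge loop.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_duration_s = c(WP = 0.2, UN = 0.5, BU = 1.5,
                                             BA = 1.5, BR = 1.5, FR = 1.5,
                                             TU = 0.6, RS = 1.0),
                          max_iterations = 10000L) {
  missing <- setdiff(activity_levels(), names(min_duration_s))
  if (length(missing)) {
    stop("policy misses classes: ", paste(missing, collapse = ", "))
  }
  if (any(min_duration_s <= 0)) stop("minimum durations must be positive")
  structure(
    list(min_duration_s = min_duration_s[activity_levels()],
         max_iterations = as.integer(max_iterations)),
    class = "filter_policy"
  )
}

#' Filter a raw prediction sequence
#'
#' Removes classification artefacts from a raw per-frame prediction: while
#' any interior segment is shorter than its class minimum duration, the
#' shortest violating segment (ties: the earliest) is reassigned to its
#' longer adjacent segment (ties: the preceding one) and runs are re-merged,
#' until a fixpoint. The first and last segments of a session are exempt
#' (a recording may legitimately start or stop mid-phase). Frame count and
#' timebase are unchanged; the result is idempotent under re-filtering.
#'
#' @param raw a [label_sequence()] (typically provenance `raw_prediction`).
#' @param policy a [filter_policy()].
#' @return A [label_sequence()] with provenance `filtered_prediction`.
#' @export
filter_predictions <- function(raw, policy = filter_policy()) {
  stopifnot(inherits(raw, "label_sequence"), inherits(policy, "filter_policy"))
  rate <- raw$sample_rate
  min_frames <- pmax(1L, as.integer(round(policy$min_duration_s * rate)))
  segs <- labels_to_segments(raw)
  it <- 0L
  repeat {
    n <- nrow(segs)
    if (n <= 2L) break
    len <- segs$end_frame - segs$start_frame
    need <- min_frames[match(segs$activity, activity_levels())]
    interior <- seq_len(n) > 1L & seq_len(n) < n
    viol <- which(interior & len < need)
    if (!length(viol)) break
    it <- it + 1L
    if (it > policy$max_iterations) {
      warning("filter_predictions: iteration cap reached before fixpoint")
      break
    }
    k <- viol[which.min(len[viol])]
    # absorb into the longer neighbour; ties favour the preceding segment
    into <- if (len[k - 1L] >= len[k + 1L]) k - 1L else k + 1L
    segs$activity[k] <- segs$activity[into]
    # merge equal-activity runs
    r <- rle(segs$activity)
    end_idx <- cumsum(r$lengths)
    segs <- data.frame(
      activity = r$values,
      start_frame = segs$start_frame[c(1L, end_idx[-length(end_idx)] + 1L)],
      end_frame = segs$end_frame[end_idx],
      stringsAsFactors = FALSE
    )
  }
  segments_to_labels(segs, rate, "filtered_prediction")
}
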