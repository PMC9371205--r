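#' Lap boundary events from class transitions
#'
#' Scans a (filtered) label sequence for the transition events that anchor
#' lap times. A swim block is a maximal run of non-rest segments. Within a
#' block:
#'
#' * for front crawl and backstroke (tumble-turn techniques), a lap anchor
#'   is the end of a wallpush segment when one exists, otherwise the first
#'   frame of an underwater segment not immediately preceded by a wallpush
#'   (the post-turn glide);
#' * for butterfly and breaststroke (hand-touch techniques), the first
#'   anchor is the end of the initial wallpush and every turn start (the
#'   wall touch) is an intermediate anchor;
#' * the final anchor of a block is the first frame of the rest segment
#'   that terminates it.
#'
#' @param seq a [label_sequence()] (filtered predictions or ground truth).
#' @param technique a stroke class code; selects the anchor rule.
#' @return data.frame of events with columns `frame`, `time_s`, `kind`
#'   (`wallpush_end`, `underwater_start`, `turn_start`, `rest_start`).
#' @export
detect_boundaries <- function(seq, technique) {
  stopifnot(inherits(seq, "label_sequence"))
  if (!is_stroke(technique)) stop("technique must be a stroke class")
  segs <- labels_to_segments(seq)
  blocks <- .swim_blocks(segs)
  ev <- list()
  for (b in blocks) {
    if (!any(segs$activity[b$rows] == technique)) next
    ev[[length(ev) + 1L]] <- .block_anchors(segs, b, technique)
  }
  if (!length(ev)) {
    return(data.frame(frame = integer(0), time_s = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  out$time_s <- out$frame / seq$sample_rate
  out[, c("frame", "time_s", "kind")]
}

# maximal runs of non-RS segments, with the index of the RS segment (if
# any) that terminates each run
.swim_blocks <- function(segs) {
  is_rest <- segs$activity == "RS"
  grp <- cumsum(is_rest)
  blocks <- list()
  for (g in unique(grp[!is_rest])) {
    rows <- which(grp == g & !is_rest)
    if (!length(rows)) next
    after <- max(rows) + 1L
    rest_row <- if (after <= nrow(segs) && segs$activity[after] == "RS") after
    blocks[[length(blocks) + 1L]] <- list(rows = rows, rest_row = rest_row)
  }
  blocks
}

.block_anchors <- function(segs, block, technique) {
  rows <- block$rows
  acts <- segs$activity[rows]
  anchors <- data.frame(frame = integer(0), kind = character(0),
                        stringsAsFactors = FALSE)
  add <- function(frame, kind) {
    rbind(anchors, data.frame(frame = as.integer(frame), kind = kind,
                              stringsAsFactors = FALSE))
  }
  if (technique %in% c("FR", "BA")) {
    for (i in seq_along(rows)) {
      r <- rows[i]
      if (acts[i] == "WP") {
        anchors <- add(segs$end_frame[r], "wallpush_end")
      } else if (acts[i] == "UN" &&
                 (i == 1L || acts[i - 1L] != "WP")) {
        anchors <- add(segs$start_frame[r], "underwater_start")
      }
    }
  } else { # BU / BR: hand-touch at turn start
    first_wp <- which(acts == "WP")[1]
    if (!is.na(first_wp)) {
      anchors <- add(segs$end_frame[rows[first_wp]], "wallpush_end")
    } else {
      first_un <- which(acts == "UN")[1]
      if (!is.na(first_un)) {
        anchors <- add(segs$start_frame[rows[first_un]], "underwater_start")
      }
    }
    for (i in which(acts == "TU")) {
      anchors <- add(segs$start_frame[rows[i]], "turn_start")
    }
  }
  if (!is.null(block$rest_row)) {
    anchors <- add(segs$start_frame[block$rest_row], "rest_start")
  } else {
    # session cropped before the rest: close the block at its last frame
    anchors <- add(segs$end_frame[max(rows)], "rest_start")
  }
  anchors
}

#' Derive typed lap times from a label sequence
#'
#' Splits the sequence into swim blocks, anchors lap boundaries with
#' [detect_boundaries()] (using each block's dominant stroke class to pick
#' the anchor rule), and emits one lap record per inter-anchor interval.
#' The first lap of a multi-lap block is typed `START`, the lap ending at
#' the rest boundary `END`, all others `MIDDLE`; a single-lap block is
#' typed `END` (it terminates at rest). Each lap's technique is the
#' dominant stroke class within its interval, which is robust to brief
#' misclassified stroke frames.
#'
#' @param seq a [label_sequence()] — filtered predictions, or ground truth
#'   for reference lap tables.
#' @param subject_id,session_id identifiers copied into the output.
#' @return data.frame of class `lap_table`: `subject`, `session`, `block`,
#'   `lap_index`, `technique`, `lap_type`, `start_frame`, `end_frame`,
#'   `start_s`, `end_s`, `duration_s`.
#' @export
compute_lap_times <- function(seq, subject_id = "S1", session_id = "A") {
  stopifnot(inherits(seq, "label_sequence"))
  rate <- seq$sample_rate
  segs <- labels_to_segments(seq)
  blocks <- .swim_blocks(segs)
  recs <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    acts <- segs$activity[b$rows]
    lens <- (segs$end_frame - segs$start_frame)[b$rows]
    sframes <- sum(lens[acts %in% stroke_classes()])
    if (sframes == 0L) next
    tech_tab <- tapply(lens[acts %in% stroke_classes()],
                       acts[acts %in% stroke_classes()], sum)
    block_tech <- names(tech_tab)[which.max(tech_tab)]
    anchors <- .block_anchors(segs, b, block_tech)
    if (nrow(anchors) < 2L) next
    frames <- anchors$frame
    n_lap <- length(frames) - 1L
    for (k in seq_len(n_lap)) {
      s <- frames[k]; e <- frames[k + 1L]
      if (e <= s) next
      lap_type <- if (k == n_lap) "END" else if (k == 1L) "START" else "MIDDLE"
      # dominant stroke class inside the interval
      in_lap <- segs$start_frame < e & segs$end_frame > s &
        segs$activity %in% stroke_classes()
      tech <- block_tech
      if (any(in_lap)) {
        ov <- pmin(segs$end_frame[in_lap], e) - pmax(segs$start_frame[in_lap], s)
        tt <- tapply(ov, segs$activity[in_lap], sum)
        tech <- names(tt)[which.max(tt)]
      }
      recs[[length(recs) + 1L]] <- data.frame(
        subject = subject_id, session = session_id, block = bi,
        lap_index = k, technique = tech, lap_type = lap_type,
        start_frame = s, end_frame = e,
        start_s = s / rate, end_s = e / rate, duration_s = (e - s) / rate,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else data.frame(
    subject = character(0), session = character(0), block = integer(0),
    lap_index = integer(0), technique = character(0), lap_type = character(0),
    start_frame = integer(0), end_frame = integer(0), start_s = numeric(0),
    end_s = numeric(0), duration_s = numeric(0), stringsAsFactors = FALSE
  )
  class(out) <- c("lap_table", "data.frame")
  out
}

#' Pair predicted and reference lap tables
#'
#' Matches laps by block order and lap position within block (both tables
#' are assumed to describe the same session). Laps without a counterpart
#' are reported and excluded from the paired rows.
#'
#' @param pred,ref lap tables from [compute_lap_times()] (or read from
#'   file).
#' @return List with `pairs` (data.frame: block, lap_index, technique,
#'   lap_type, pred_s, ref_s, diff_s) and `unmatched` (data.frame with a
#'   `source` column).
#' @export
pair_lap_tables <- function(pred, ref) {
  key <- function(d) paste(d$block, d$lap_index)
  kp <- key(pred); kr <- key(ref)
  common <- intersect(kp, kr)
  ip <- match(common, kp); ir <- match(common, kr)
  pairs <- data.frame(
    block = ref$block[ir], lap_index = ref$lap_index[ir],
    technique = ref$technique[ir], lap_type = ref$lap_type[ir],
    pred_s = pred$duration_s[ip], ref_s = ref$duration_s[ir],
    diff_s = pred$duration_s[ip] - ref$duration_s[ir],
    stringsAsFactors = FALSE
  )
  un <- rbind(
    if (length(setdiff(kp, kr))) cbind(pred[match(setdiff(kp, kr), kp),
                                            c("block", "lap_index")],
                                       source = "pred"),
    if (length(setdiff(kr, kp))) cbind(ref[match(setdiff(kr, kp), kr),
                                           c("block", "lap_index")],
                                       source = "ref")
  )
  list(pairs = pairs,
       unmatched = if (is.null(un)) data.frame(block = integer(0),
                                               lap_index = integer(0),
                                               source = character(0)) else un)
}
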