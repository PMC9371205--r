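#' Synthetic swimming-session simulator
#'
#' Generates labelled synthetic pool-swimming sessions — raw 280 Hz
#' 6-channel inertial signals, per-frame ground-truth activity labels, and
#' the true lap table — following the block grammar of a training protocol:
#' every block starts with a wallpush and underwater glide, laps are
#' separated by turn + underwater, and each block ends in rest
#' (`WP -> UN -> stroke -> (TU -> UN -> stroke)* -> RS`).
#'
#' Signal primitives are stylized but spectrally plausible: a half-sine
#' acceleration impulse for the wallpush, a decaying ~2 Hz undulation for
#' the underwater glide, technique-specific harmonic oscillations for the
#' four strokes (distinct base frequencies and channel weightings, plus an
#' orientation cue on the z accelerometer separating supine backstroke from
#' the prone techniques), a high-amplitude gyroscope burst for turns, and
#' near-zero signal at rest, all with additive Gaussian sensor noise. They
#' make the eight classes statistically separable without claiming
#' biomechanical fidelity.
#'
#' @name synthetic_swim
NULL

#' Subject profile for the simulator
#'
#' Captures inter-subject variability: multiplicative amplitude and
#' stroke-frequency scales, a lap-duration scale, and the four pace-level
#' speed multipliers (strictly increasing from low to maximal, so lap
#' duration strictly decreases with pace).
#'
#' @param subject_id identifier.
#' @param amp_scale,freq_scale,lap_scale positive multiplicative factors.
#' @param pace_speed named numeric vector of speed multipliers for the
#'   `low`, `moderate`, `high`, `maximal` pace levels, strictly increasing.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S1", amp_scale = 1,
                            freq_scale = 1, lap_scale = 1,
                            pace_speed = c(low = 0.87, moderate = 1,
                                           high = 1.14, maximal = 1.3)) {
  stopifnot(amp_scale > 0, freq_scale > 0, lap_scale > 0)
  need <- c("low", "moderate", "high", "maximal")
  if (!all(need %in% names(pace_speed))) {
    stop("pace_speed must name the four levels low/moderate/high/maximal")
  }
  pace_speed <- pace_speed[need]
  if (any(diff(pace_speed) <= 0)) {
    stop("pace_speed must be strictly increasing from low to maximal")
  }
  structure(
    list(subject_id = as.character(subject_id), amp_scale = amp_scale,
         freq_scale = freq_scale, lap_scale = lap_scale,
         pace_speed = pace_speed),
    class = "subject_profile"
  )
}

#' Session plan: blocks of laps by technique and pace
#'
#' @param blocks list of blocks; each block is a list with `technique` (a
#'   stroke class), `laps` (>= 1) and `paces` (pace level per lap, recycled
#'   to `laps`).
#' @param rest_s rest duration after each block, seconds.
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(blocks, rest_s = 20) {
  if (!length(blocks)) stop("session plan must contain at least one block")
  blocks <- lapply(blocks, function(b) {
    stopifnot(is_stroke(b$technique), b$laps >= 1L)
    b$laps <- as.integer(b$laps)
    b$paces <- rep(b$paces, length.out = b$laps)
    stopifnot(all(b$paces %in% c("low", "moderate", "high", "maximal")))
    b
  })
  structure(list(blocks = blocks, rest_s = rest_s), class = "session_plan")
}

#' @rdname session_plan
#' @param techniques stroke class per block.
#' @param laps_per_block laps in every block.
#' @param paces pace level per lap within each block (recycled); the
#'   default sweeps low to maximal across 4 laps, emulating a progressive
#'   4 x 25 m set.
#' @export
default_session_plan <- function(techniques = stroke_classes(),
                                 laps_per_block = 4L,
                                 paces = c("low", "moderate", "high",
                                           "maximal"),
                                 rest_s = 20) {
  session_plan(lapply(techniques, function(tech) {
    list(technique = tech, laps = laps_per_block, paces = paces)
  }), rest_s = rest_s)
}

# stroke signal primitives: base frequency (Hz) and per-channel harmonic
# recipes; amplitudes in g (accelerometer) and deg/s (gyroscope)
.stroke_params <- list(
  BU = list(f0 = 0.90, az_dyn = 0.50, az_h2 = 0.20, gy = 60, ax_h2 = 0.25,
            gx = 10, az0 = 1),
  BA = list(f0 = 0.70, az_dyn = 0.15, az_h2 = 0.00, gy = 10, ax_h2 = 0.10,
            gx = 80, az0 = -1, ay = 0.20),
  BR = list(f0 = 0.55, az_dyn = 0.30, az_h2 = 0.00, gy = 40, ax_h2 = 0.00,
            gx = 5, az0 = 1, ax_surge = 0.50),
  FR = list(f0 = 0.75, az_dyn = 0.10, az_h2 = 0.00, gy = 8, ax_h2 = 0.20,
            gx = 70, az0 = 1, ay = 0.15)
)

.noise_sd <- c(ax = 0.05, ay = 0.05, az = 0.05, gx = 4, gy = 4, gz = 4)

# one phase worth of signal; t is the within-phase time vector (seconds)
.phase_signal <- function(activity, t, technique, speed, profile, dur) {
  n <- length(t)
  m <- matrix(0, n, 6L, dimnames = list(NULL, imu_channels()))
  amp <- profile$amp_scale * speed
  if (activity == "WP") {
    m[, "ax"] <- 1.5 * amp * sin(pi * t / dur)
    m[, "az"] <- 1
  } else if (activity == "UN") {
    f <- 2.2 * profile$freq_scale
    decay <- exp(-t / max(dur, 1))
    m[, "az"] <- 1 + 0.35 * amp * sin(2 * pi * f * t) * decay
    m[, "gy"] <- 30 * amp * sin(2 * pi * f * t + 0.8) * decay
  } else if (activity == "TU") {
    a <- if (technique %in% c("FR", "BA")) "gx" else "gz"
    m[, a] <- 250 * amp * sin(pi * t / dur)
    m[, "az"] <- cos(pi * t / dur) * if (technique == "BA") -1 else 1
  } else if (activity == "RS") {
    m[, "ax"] <- 1 # upright at the wall: gravity on the cranial axis
  } else { # stroke
    p <- .stroke_params[[activity]]
    f <- p$f0 * profile$freq_scale * sqrt(speed)
    w <- 2 * pi * f * t
    m[, "az"] <- p$az0 + amp * (p$az_dyn * sin(w) + p$az_h2 * sin(2 * w))
    m[, "gy"] <- amp * p$gy * sin(w + 0.5)
    m[, "gx"] <- amp * p$gx * sin(w)
    m[, "ax"] <- amp * p$ax_h2 * sin(2 * w)
    if (!is.null(p$ax_surge)) {
      m[, "ax"] <- m[, "ax"] +
        amp * p$ax_surge * (sin(w) + 0.6 * sin(2 * w - 1))
    }
    if (!is.null(p$ay)) m[, "ay"] <- amp * p$ay * sin(w + 0.7)
  }
  m
}

#' Generate one labelled synthetic session
#'
#' Assembles the session from the plan's blocks, drawing per-phase
#' durations from plausible ranges (wallpush 0.8-1.2 s, underwater glide
#' 3-5 s shortened at higher pace, turn 0.8-1.2 s) and sizing each stroke
#' bout so the resulting lap duration matches the subject's pace-dependent
#' target (base 26 s per lap at moderate pace). The emitted lap table is
#' computed directly from the generator's internal phase switch frames
#' using the lap anchor conventions (wallpush-end / post-turn underwater
#' anchors for front crawl and backstroke, turn-start anchors for
#' butterfly and breaststroke, rest-start as the final anchor).
#'
#' @param plan a [session_plan()].
#' @param profile a [subject_profile()].
#' @param seed integer seed; fixed (plan, profile, seed) reproduce the
#'   session bit for bit.
#' @param sample_rate raw sampling rate in Hz.
#' @param session_id identifier.
#' @param base_lap_s lap-duration target at unit speed, seconds.
#' @param with_signal set FALSE to skip signal synthesis (labels and lap
#'   table only), e.g. for fast grammar-level checks.
#' @return List with `recording` ([imu_recording()] or NULL), `labels`
#'   (ground-truth [label_sequence()] at `sample_rate`) and `laps`
#'   (the true lap table).
#' @export
generate_session <- function(plan, profile, seed, sample_rate = 280,
                             session_id = "A", base_lap_s = 26,
                             with_signal = TRUE) {
  stopifnot(inherits(plan, "session_plan"), inherits(profile, "subject_profile"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rate <- sample_rate
  phases <- list() # activity, technique, speed, frames
  laps <- list()
  frame_at <- 0L
  add_phase <- function(activity, dur_s, technique, speed) {
    frames <- max(1L, as.integer(round(dur_s * rate)))
    phases[[length(phases) + 1L]] <<- list(
      activity = activity, technique = technique, speed = speed,
      frames = frames, start = frame_at)
    frame_at <<- frame_at + frames
    frame_at # returns end frame
  }
  for (bi in seq_along(plan$blocks)) {
    b <- plan$blocks[[bi]]
    tech <- b$technique
    anchors <- integer(0)
    for (k in seq_len(b$laps)) {
      pace <- b$paces[k]
      speed <- profile$pace_speed[[pace]]
      lap_target <- base_lap_s * profile$lap_scale / speed
      if (k == 1L) {
        wp_end <- add_phase("WP", stats::runif(1, 0.8, 1.2), tech, speed)
        anchors <- c(anchors, wp_end) # wallpush end = first anchor
      } else {
        tu_start <- frame_at
        add_phase("TU", stats::runif(1, 0.8, 1.2), tech, speed)
        if (tech %in% c("BU", "BR")) anchors <- c(anchors, tu_start)
      }
      un_dur <- stats::runif(1, 3, 5) / sqrt(speed)
      un_start <- frame_at
      add_phase("UN", un_dur, tech, speed)
      if (k > 1L && tech %in% c("FR", "BA")) {
        anchors <- c(anchors, un_start) # post-turn underwater anchor
      }
      used <- if (k == 1L) (frame_at - anchors[1]) / rate
              else (frame_at - anchors[length(anchors)]) / rate
      stroke_dur <- max(lap_target - used - if (k < b$laps) 1 else 0, 8)
      add_phase(tech, stroke_dur, tech, speed)
    }
    rs_start <- frame_at
    add_phase("RS", plan$rest_s * stats::runif(1, 0.9, 1.1), tech, 1)
    anchors <- c(anchors, rs_start)
    n_lap <- length(anchors) - 1L
    for (k in seq_len(n_lap)) {
      laps[[length(laps) + 1L]] <- data.frame(
        subject = profile$subject_id, session = session_id, block = bi,
        lap_index = k, technique = tech,
        lap_type = if (k == n_lap) "END" else if (k == 1L) "START" else "MIDDLE",
        start_frame = anchors[k], end_frame = anchors[k + 1L],
        start_s = anchors[k] / rate, end_s = anchors[k + 1L] / rate,
        duration_s = (anchors[k + 1L] - anchors[k]) / rate,
        stringsAsFactors = FALSE
      )
    }
  }
  labels <- label_sequence(
    rep(vapply(phases, `[[`, "", "activity"),
        vapply(phases, `[[`, 0L, "frames")),
    rate, "ground_truth"
  )
  recording <- NULL
  if (with_signal) {
    sig <- do.call(rbind, lapply(phases, function(ph) {
      t <- (seq_len(ph$frames) - 1L) / rate
      .phase_signal(ph$activity, t, ph$technique, ph$speed, profile,
                    ph$frames / rate)
    }))
    noise <- matrix(stats::rnorm(length(sig)), nrow(sig), 6L)
    sig <- sig + sweep(noise, 2L, .noise_sd, "*")
    recording <- imu_recording(sig, rate, profile$subject_id, session_id)
  }
  lap_table <- do.call(rbind, laps)
  class(lap_table) <- c("lap_table", "data.frame")
  list(recording = recording, labels = labels, laps = lap_table)
}

#' Generate a reproducible synthetic cohort
#'
#' Draws one subject profile per subject (log-normal-ish jitter around unit
#' amplitude/frequency/lap scales, subject-specific pace multipliers) and
#' generates one session each from the plan template. Distinct subjects
#' differ in their profiles; each session spans the plan's pace levels.
#'
#' @param n_subjects number of subjects (>= 3 so hold-one-subject-out
#'   splits exist).
#' @param plan_template a [session_plan()] used for every subject.
#' @param seed integer master seed; profiles and per-session seeds derive
#'   from it.
#' @param ... passed on to [generate_session()].
#' @return List of sessions as returned by [generate_session()], each with
#'   the profile attached as `$profile`.
#' @export
generate_cohort <- function(n_subjects, plan_template = default_session_plan(),
                            seed = 1L, ...) {
  if (n_subjects < 3L) stop("need at least 3 subjects for HOSCV")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  profiles <- lapply(seq_len(n_subjects), function(i) {
    base <- c(low = 0.87, moderate = 1, high = 1.14, maximal = 1.3)
    subject_profile(
      subject_id = sprintf("S%02d", i),
      amp_scale = exp(stats::rnorm(1, 0, 0.10)),
      freq_scale = exp(stats::rnorm(1, 0, 0.07)),
      lap_scale = exp(stats::rnorm(1, 0, 0.07)),
      pace_speed = base * exp(stats::rnorm(1, 0, 0.04))
    )
  })
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    s <- generate_session(plan_template, profiles[[i]], seed = seeds[i], ...)
    s$profile <- profiles[[i]]
    s
  })
}
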