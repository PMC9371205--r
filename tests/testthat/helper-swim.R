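# Shared fixtures: all built in code at test time.

# a small two-block session plan used across tests
tiny_plan <- function(techniques = c("FR", "BU"), laps = 2L, rest_s = 6) {
  default_session_plan(techniques = techniques, laps_per_block = laps,
                       paces = c("moderate", "high"), rest_s = rest_s)
}

# pure-sine recording helper
sine_recording <- function(freq, rate = 280, dur_s = 10, amp = 1) {
  t <- (seq_len(round(dur_s * rate)) - 1L) / rate
  imu_recording(matrix(amp * sin(2 * pi * freq * t), ncol = 6,
                       nrow = length(t)), rate)
}

# flip a fraction of frames to a random *different* class
corrupt_labels <- function(seq, frac, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- length(seq$labels)
  k <- max(1L, round(frac * n))
  idx <- sample.int(n, k)
  wrong <- vapply(seq$labels[idx], function(cur) {
    sample(setdiff(activity_levels(), cur), 1L)
  }, "")
  out <- seq$labels
  out[idx] <- wrong
  label_sequence(out, seq$sample_rate, "raw_prediction")
}

# a random but grammar-valid label sequence (for round-trip properties)
random_label_sequence <- function(seed, rate = 50) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n_seg <- sample(1:12, 1)
  labs <- unlist(lapply(seq_len(n_seg), function(i) {
    rep(sample(activity_levels(), 1), sample(1:30, 1))
  }))
  label_sequence(labs, rate)
}
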