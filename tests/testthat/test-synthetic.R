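test_that("fixed (plan, profile, seed) reproduces the session bit for bit", {
  plan <- tiny_plan()
  prof <- subject_profile()
  s1 <- generate_session(plan, prof, seed = 42)
  s2 <- generate_session(plan, prof, seed = 42)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$labels$labels, s2$labels$labels)
  expect_identical(s1$laps, s2$laps)
  s3 <- generate_session(plan, prof, seed = 43)
  expect_false(identical(s1$recording$samples, s3$recording$samples))
})

test_that("recording and labels share the frame count and the grammar holds", {
  for (seed in 1:6) {
    set.seed(seed * 31)
    plan <- default_session_plan(
      techniques = sample(stroke_classes(), sample(1:3, 1), replace = TRUE),
      laps_per_block = sample(1:4, 1), rest_s = 5
    )
    ses <- generate_session(plan, subject_profile(), seed = seed)
    expect_identical(nrow(ses$recording$samples), length(ses$labels$labels))
    # block grammar: WP UN S (TU UN S)* RS per block
    segs <- labels_to_segments(ses$labels)
    acts <- paste(segs$activity, collapse = " ")
    stroke_re <- "(BU|BA|BR|FR)"
    block_re <- paste0("WP UN ", stroke_re, "( TU UN ", stroke_re, ")* RS")
    expect_match(acts, paste0("^", block_re, "( ", block_re, ")*$"))
  }
})

test_that("a zero-block plan is rejected", {
  expect_error(session_plan(list()), "at least one block")
})

test_that("stroke oscillation lands at the configured frequency (FFT oracle)", {
  # front crawl tuned to 0.7 Hz roll at moderate pace
  prof <- subject_profile(freq_scale = 0.7 / 0.75)
  plan <- default_session_plan(techniques = "FR", laps_per_block = 1L,
                               paces = "moderate", rest_s = 5)
  ses <- generate_session(plan, prof, seed = 9)
  segs <- labels_to_segments(ses$labels)
  fr <- segs[segs$activity == "FR", ][1, ]
  gx <- ses$recording$samples[(fr$start_frame + 1):fr$end_frame, "gx"]
  spec <- Mod(stats::fft(gx - mean(gx)))
  freqs <- (seq_along(gx) - 1) / length(gx) * 280
  keep <- freqs > 0.1 & freqs < 140
  peak <- freqs[keep][which.max(spec[keep])]
  expect_gt(peak, 0.6)
  expect_lt(peak, 0.8)
})

test_that("cohorts are reproducible with pairwise-distinct profiles", {
  c1 <- generate_cohort(3, tiny_plan(), seed = 5, with_signal = FALSE)
  c2 <- generate_cohort(3, tiny_plan(), seed = 5, with_signal = FALSE)
  expect_identical(lapply(c1, `[[`, "laps"), lapply(c2, `[[`, "laps"))
  profs <- lapply(c1, `[[`, "profile")
  for (i in 1:2) for (j in (i + 1):3) {
    expect_false(identical(profs[[i]]$amp_scale, profs[[j]]$amp_scale))
  }
  expect_error(generate_cohort(2, tiny_plan()), "at least 3")
})

test_that("pace levels speed up laps within a session", {
  ses <- generate_session(default_session_plan(techniques = "FR",
                                               laps_per_block = 4),
                          subject_profile(), seed = 10, with_signal = FALSE)
  # paces sweep low -> maximal, so durations strictly decrease
  expect_true(all(diff(ses$laps$duration_s) < 0))
})

test_that("label frequencies mirror the protocol's class imbalance", {
  cohort <- generate_cohort(3, default_session_plan(rest_s = 20), seed = 2,
                            with_signal = FALSE)
  counts <- table(factor(unlist(lapply(cohort, function(s) s$labels$labels)),
                         levels = activity_levels()))
  expect_gt(counts[["RS"]], counts[["WP"]])
  for (st in stroke_classes()) expect_gt(counts[[st]], counts[["WP"]])
})

test_that("profile validation enforces increasing pace speeds", {
  expect_error(subject_profile(pace_speed = c(low = 1, moderate = 0.9,
                                              high = 1.1, maximal = 1.2)),
               "strictly increasing")
  expect_error(subject_profile(amp_scale = -1), "amp_scale")
})
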