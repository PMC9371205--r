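make_seq <- function(...) {
  # build a label sequence from (activity, n_frames) pairs at 50 Hz
  spec <- list(...)
  label_sequence(unlist(lapply(spec, function(p) rep(p[[1]], p[[2]]))), 50)
}

test_that("front-crawl anchors: wallpush end, post-turn underwater, rest", {
  seq <- make_seq(list("WP", 50), list("UN", 150), list("FR", 1000),
                  list("TU", 50), list("UN", 150), list("FR", 950),
                  list("RS", 200))
  ev <- detect_boundaries(seq, "FR")
  expect_identical(ev$frame, c(50L, 1250L, 2350L))
  expect_identical(ev$kind, c("wallpush_end", "underwater_start", "rest_start"))
})

test_that("an all-rest sequence yields no boundary events", {
  seq <- make_seq(list("RS", 500))
  ev <- detect_boundaries(seq, "FR")
  expect_identical(nrow(ev), 0L)
})

test_that("a block without an initial wallpush falls back to underwater", {
  seq <- make_seq(list("UN", 100), list("FR", 800), list("RS", 100))
  ev <- detect_boundaries(seq, "FR")
  expect_identical(ev$frame[1], 0L)
  expect_identical(ev$kind[1], "underwater_start")
})

test_that("hand-touch techniques anchor on turn starts", {
  seq <- make_seq(list("WP", 50), list("UN", 100), list("BR", 900),
                  list("TU", 60), list("UN", 100), list("BR", 900),
                  list("RS", 150))
  ev <- detect_boundaries(seq, "BR")
  expect_identical(ev$kind, c("wallpush_end", "turn_start", "rest_start"))
  expect_identical(ev$frame, c(50L, 1050L, 2110L))
})

test_that("a 4-lap block is typed START/MIDDLE/MIDDLE/END", {
  ses <- generate_session(default_session_plan(techniques = "FR",
                                               laps_per_block = 4),
                          subject_profile(), seed = 3, with_signal = FALSE)
  expect_identical(ses$laps$lap_type, c("START", "MIDDLE", "MIDDLE", "END"))
  lt <- compute_lap_times(ses$labels)
  expect_identical(lt$lap_type, c("START", "MIDDLE", "MIDDLE", "END"))
})

test_that("a single-lap block is typed END", {
  seq <- make_seq(list("WP", 50), list("UN", 100), list("FR", 1000),
                  list("RS", 200))
  lt <- compute_lap_times(seq)
  expect_identical(nrow(lt), 1L)
  expect_identical(lt$lap_type, "END")
  expect_equal(lt$duration_s, (1150 - 50) / 50) # UN + stroke span
})

test_that("lap technique is the dominant stroke class within the interval", {
  seq <- make_seq(list("WP", 50), list("UN", 100), list("FR", 800),
                  list("BA", 30), list("FR", 200), list("RS", 200))
  lt <- compute_lap_times(seq)
  expect_identical(lt$technique, "FR")
})

test_that("ground-truth lap times equal the simulator's table (oracle)", {
  for (seed in 1:8) {
    ses <- generate_session(tiny_plan(techniques = c("FR", "BA", "BU", "BR")),
                            subject_profile(), seed = seed,
                            with_signal = FALSE)
    lt <- compute_lap_times(ses$labels)
    expect_identical(nrow(lt), nrow(ses$laps))
    expect_identical(lt$lap_type, ses$laps$lap_type)
    expect_identical(lt$technique, ses$laps$technique)
    # within 1 frame at 280 Hz
    expect_lt(max(abs(lt$duration_s - ses$laps$duration_s)), 1 / 280 + 1e-9)
  }
})

test_that("pair_lap_tables matches by block and position, reports leftovers", {
  ses <- generate_session(tiny_plan(), subject_profile(), seed = 5,
                          with_signal = FALSE)
  lt <- compute_lap_times(ses$labels)
  p <- pair_lap_tables(lt, ses$laps)
  expect_identical(nrow(p$pairs), nrow(lt))
  expect_identical(nrow(p$unmatched), 0L)
  expect_true(all(p$pairs$diff_s == 0))
  # drop one predicted lap
  p2 <- pair_lap_tables(lt[-2, ], ses$laps)
  expect_identical(nrow(p2$pairs), nrow(lt) - 1L)
  expect_identical(p2$unmatched$source, "ref")
  # order-preserving within blocks
  expect_identical(p$pairs$lap_index,
                   ses$laps$lap_index[order(ses$laps$block,
                                            ses$laps$lap_index)])
})

test_that("small corruption plus filtering barely moves lap durations", {
  ses <- generate_session(tiny_plan(laps = 3L, rest_s = 10),
                          subject_profile(), seed = 17, with_signal = FALSE)
  truth <- resample_labels(ses$labels, 50)
  ref <- compute_lap_times(truth)
  for (seed in 1:5) {
    noisy <- corrupt_labels(truth, 0.02, seed)
    filt <- filter_predictions(noisy)
    lt <- compute_lap_times(filt)
    p <- pair_lap_tables(lt, ref)
    expect_identical(nrow(p$pairs), nrow(ref))
    expect_lt(max(abs(p$pairs$diff_s)), 0.2)
  }
})
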