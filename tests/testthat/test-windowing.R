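test_that("window counts and centers follow the sliding-window arithmetic", {
  rec <- imu_recording(matrix(rnorm(600), 100, 6), 50, preprocessed = TRUE)
  b <- make_windows(rec, stride = 1L, pad_edges = FALSE)
  expect_identical(dim(b$x)[1], 11L) # 100 - 90 + 1
  expect_identical(b$frame_index, 45:55)

  bp <- make_windows(rec, stride = 1L, pad_edges = TRUE)
  expect_identical(dim(bp$x)[1], 100L)
  expect_identical(bp$frame_index, 0:99)

  short <- imu_recording(matrix(0, 50, 6), 50, preprocessed = TRUE)
  expect_error(make_windows(short, pad_edges = FALSE), "shorter than one window")
})

test_that("one window spans 1.8 s at the 50 Hz working rate", {
  rec <- imu_recording(matrix(0, 200, 6), 50, preprocessed = TRUE)
  b <- make_windows(rec)
  expect_equal(b$window / rec$sample_rate, 1.8)
  expect_identical(b$window %/% 2L, 45L) # median-frame index, 0-based
})

test_that("stride generalizes the unpadded window count", {
  rec <- imu_recording(matrix(0, 230, 6), 50, preprocessed = TRUE)
  for (stride in c(1L, 3L, 7L, 20L)) {
    b <- make_windows(rec, stride = stride, pad_edges = FALSE)
    expect_identical(dim(b$x)[1],
                     as.integer(floor((230 - 90) / stride) + 1L))
  }
})

test_that("interior window centered at k contains frames k-45..k+44", {
  n <- 150
  samples <- matrix(rep(0:(n - 1), 6), n, 6) # channel value = frame index
  rec <- imu_recording(samples, 50, preprocessed = TRUE)
  b <- make_windows(rec, pad_edges = TRUE, layout = "channels_as_time")
  for (k in c(45L, 70L, 104L)) {
    # channels-as-time layout: step = channel, features = that channel's 90 frames
    expect_equal(b$x[k + 1L, 1, ], (k - 45):(k + 44))
  }
  # edge replication: frames below 0 clamp to frame 0
  expect_equal(b$x[1, 1, ], c(rep(0, 46), 1:44))
})

test_that("frames_as_time layout transposes steps and features", {
  rec <- imu_recording(matrix(rnorm(600), 100, 6), 50, preprocessed = TRUE)
  bp <- make_windows(rec, layout = "channels_as_time")
  bf <- make_windows(rec, layout = "frames_as_time")
  expect_identical(dim(bp$x)[2:3], c(6L, 90L))
  expect_identical(dim(bf$x)[2:3], c(90L, 6L))
  expect_equal(bp$x[10, , ], t(bf$x[10, , ]))
})

test_that("window targets take the median-frame label", {
  labs <- label_sequence(rep(c("WP", "FR"), each = 50), 50)
  rec <- imu_recording(matrix(0, 100, 6), 50, preprocessed = TRUE)
  b <- make_windows(rec, labs, pad_edges = TRUE)
  expect_identical(b$targets, activity_code(labs$labels))
})

test_that("shuffle_windows is deterministic and keeps pairs together", {
  rec <- imu_recording(matrix(rnorm(720), 120, 6), 50, preprocessed = TRUE)
  labs <- label_sequence(sample(activity_levels(), 120, TRUE), 50)
  b <- make_windows(rec, labs)
  s1 <- shuffle_windows(b, seed = 9)
  s2 <- shuffle_windows(b, seed = 9)
  expect_identical(s1$frame_index, s2$frame_index)
  expect_false(identical(s1$frame_index, b$frame_index))
  expect_identical(sort(s1$targets), sort(b$targets))
  # pairing preserved: target at shuffled position matches its frame label
  expect_identical(s1$targets,
                   activity_code(labs$labels[s1$frame_index + 1L]))
  expect_equal(s1$x[1, , ], b$x[match(s1$frame_index[1], b$frame_index), , ])
})
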