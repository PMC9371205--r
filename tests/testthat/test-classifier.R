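test_that("per-layer parameter counts reproduce the reference architecture", {
  cfg <- model_config(strict_reference = TRUE)
  counts <- count_parameters(cfg)
  expect_identical(unname(counts),
                   c(79360L, 41216L, 10368L, 6272L, 0L, 1650L, 200L, 408L))
  # closed-form bidirectional count oracle: 2 * 4u * (d + u + 1)
  d <- 90L
  for (i in seq_along(cfg$units)) {
    u <- cfg$units[i]
    expect_identical(counts[[i]], 2L * 4L * u * (d + u + 1L))
    d <- 2L * u
  }
  # a model built under strict_reference carries exactly these counts
  m <- build_model(cfg, seed = 1)
  got <- vapply(m$weights$layers, function(L) {
    length(L$Wf) + length(L$Uf) + length(L$bf) +
      length(L$Wb) + length(L$Ub) + length(L$bb)
  }, 0L)
  expect_identical(got, counts[1:4], ignore_attr = TRUE)
  expect_identical(length(m$weights$W1) + length(m$weights$b1), 1650L)
  expect_identical(length(m$weights$W2) + length(m$weights$b2), 408L)
})

test_that("strict_reference refuses a deviating architecture", {
  bad <- model_config(units = c(64L, 32L, 16L, 8L), strict_reference = TRUE)
  expect_error(build_model(bad), "strict_reference")
  # frames_as_time layout gives different counts and must also be refused
  alt <- model_config(layout = "frames_as_time", strict_reference = TRUE)
  expect_error(build_model(alt), "strict_reference")
})

test_that("learning rate starts at 0.001 and declines geometrically", {
  tcfg <- training_config()
  expect_equal(lr_schedule(0, tcfg), 0.001)
  lrs <- lr_schedule(0:20, tcfg)
  expect_true(all(diff(lrs) < 0))
  expect_equal(lr_schedule(10, tcfg), 0.001 * 800^(-10 / 100))
  expect_error(lr_schedule(-1, tcfg), "non-negative")
})

test_that("HOSCV splits are subject-disjoint, exhaustive and seeded", {
  ids <- sprintf("S%02d", 1:35)
  sp <- split_hoscv(ids, seed = 4)
  expect_length(sp$train, 33L)
  expect_length(sp$validation, 1L)
  expect_length(sp$test, 1L)
  expect_false(sp$validation == sp$test)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_identical(split_hoscv(ids, seed = 4), sp)
  expect_error(split_hoscv(ids[1:2], seed = 1), "at least 3")
  sp1 <- split_hoscv(ids, seed = 4, single_holdout_subject = TRUE)
  expect_identical(sp1$validation, sp1$test)
  expect_length(sp1$train, 34L)
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- model_config(units = c(3L, 2L), dense_units = 4L, window = 5L)
  m <- build_model(cfg, seed = 3)
  set.seed(11)
  n <- 6
  X <- array(rnorm(n * 6 * 5), dim = c(n, 6, 5))
  y <- sample(0:7, n, replace = TRUE)
  g <- swimlaps:::.bilstm_lossgrad_cpp(m$weights, X, y)
  eps <- 1e-6
  loss_at <- function(w) swimlaps:::.bilstm_lossgrad_cpp(w, X, y)$loss
  # spot-check a handful of coordinates in every parameter family
  check_coord <- function(get, set, ana) {
    w0 <- get(m$weights)
    for (k in unique(pmin(length(w0), c(1L, 7L, length(w0))))) {
      wp <- w0; wp[k] <- wp[k] + eps
      wm <- w0; wm[k] <- wm[k] - eps
      gn <- (loss_at(set(m$weights, wp)) - loss_at(set(m$weights, wm))) /
        (2 * eps)
      expect_equal(as.vector(ana)[k], gn, tolerance = 1e-5)
    }
  }
  check_coord(function(w) w$layers[[1]]$Wf,
              function(w, v) { w$layers[[1]]$Wf <- matrix(v, 5); w },
              g$layers[[1]]$Wf)
  check_coord(function(w) w$layers[[2]]$Ub,
              function(w, v) { w$layers[[2]]$Ub <- matrix(v, 2); w },
              g$layers[[2]]$Ub)
  check_coord(function(w) w$W1,
              function(w, v) { w$W1 <- matrix(v, nrow(w$W1)); w }, g$W1)
  check_coord(function(w) w$gamma,
              function(w, v) { w$gamma <- as.numeric(v); w }, g$gamma)
  check_coord(function(w) w$b2,
              function(w, v) { w$b2 <- as.numeric(v); w }, g$b2)
})

toy_batch <- function(n = 200, seed = 5) {
  set.seed(seed)
  x <- array(rnorm(n * 6 * 90, sd = 0.1), dim = c(n, 6, 90))
  y <- sample(0:7, n, replace = TRUE)
  for (i in seq_len(n)) {
    x[i, (y[i] %% 6) + 1, ] <- x[i, (y[i] %% 6) + 1, ] + (1 + y[i] %/% 6) * 2
  }
  structure(list(x = x, targets = y, frame_index = seq_len(n) - 1L,
                 window = 90L, stride = 1L, layout = "channels_as_time",
                 sample_rate = 50),
            class = "window_batch")
}

test_that("the network overfits a small separable set to accuracy 1.0", {
  batch <- toy_batch()
  cfg <- model_config(dropout = 0, recurrent_dropout = 0, dense_dropout = 0)
  m <- train_model(build_model(cfg, seed = 1), batch, batch,
                   training_config(epochs = 30, seed = 2))
  expect_equal(tail(m$history$accuracy, 1), 1.0)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  # emitted labels on the training inputs equal the targets
  probs <- swimlaps:::.bilstm_predict_cpp(m$weights, batch$x, 64L)
  expect_gt(mean(max.col(probs) - 1L == batch$targets), 0.95)
})

test_that("training is deterministic for a fixed seed", {
  batch <- toy_batch(n = 96)
  m1 <- train_model(build_model(model_config(), 7), batch,
                    tcfg = training_config(epochs = 2, seed = 3))
  m2 <- train_model(build_model(model_config(), 7), batch,
                    tcfg = training_config(epochs = 2, seed = 3))
  expect_identical(m1$weights$W1, m2$weights$W1)
  expect_identical(m1$weights$layers[[1]]$Wf, m2$weights$layers[[1]]$Wf)
  expect_identical(m1$history$loss, m2$history$loss)
})

test_that("targets outside 0..7 are rejected", {
  batch <- toy_batch(n = 10)
  batch$targets[1] <- 9L
  expect_error(train_model(build_model(model_config(), 1), batch,
                           tcfg = training_config(epochs = 1)),
               "outside 0..7")
})

test_that("predict_sequence emits one label per frame with unit row sums", {
  ses <- generate_session(tiny_plan(techniques = "FR", laps = 2L, rest_s = 5),
                          subject_profile(), seed = 12)
  pre <- preprocess_session(ses)
  sc <- fit_scaler(pre$recording)
  pre$recording <- apply_scaler(pre$recording, sc)
  m <- build_model(model_config(), seed = 1)
  m$scaler <- sc
  m$trained <- TRUE # untrained weights, but the contract is shape-level
  out <- predict_sequence(m, pre$recording)
  expect_length(out$labels$labels, nrow(pre$recording$samples))
  expect_equal(rowSums(out$probs), rep(1, nrow(out$probs)), tolerance = 1e-6)
  expect_identical(out$labels$labels,
                   activity_from_code(max.col(out$probs,
                                              ties.method = "first") - 1L))
  expect_identical(out$labels$provenance, "raw_prediction")
})
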