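test_that("perfect predictions score 1.0 everywhere", {
  truth <- random_label_sequence(1)
  rep <- classification_report(truth, truth)
  expect_equal(rep$accuracy, 1)
  present <- rep$per_class$support > 0
  expect_true(all(rep$per_class$f1[present] == 1))
  expect_equal(rep$weighted[["f1"]], 1)
})

test_that("hand-computed two-class example matches", {
  truth <- c("BU", "BU", "BA")
  pred <- c("BU", "BA", "BA")
  rep <- classification_report(pred, truth)
  pc <- rep$per_class
  expect_equal(pc$precision[pc$class == "BU"], 1.0)
  expect_equal(pc$recall[pc$class == "BU"], 0.5)
  expect_equal(pc$f1[pc$class == "BU"], 2 / 3)
  expect_equal(pc$precision[pc$class == "BA"], 0.5)
  expect_equal(pc$recall[pc$class == "BA"], 1.0)
  expect_equal(pc$f1[pc$class == "BA"], 2 / 3)
  expect_equal(rep$accuracy, 2 / 3)
})

test_that("report agrees with a brute-force recomputation on random data", {
  lv <- activity_levels()
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(50:200, 1)
    truth <- sample(lv, n, replace = TRUE)
    pred <- sample(lv, n, replace = TRUE)
    rep <- classification_report(pred, truth)
    # independent brute-force implementation
    for (cl in lv) {
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      P <- if (tp + fp > 0) tp / (tp + fp) else 0
      R <- if (tp + fn > 0) tp / (tp + fn) else 0
      F <- if (P + R > 0) 2 * P * R / (P + R) else 0
      i <- match(cl, rep$per_class$class)
      expect_equal(rep$per_class$precision[i], P)
      expect_equal(rep$per_class$recall[i], R)
      expect_equal(rep$per_class$f1[i], F)
    }
    expect_equal(rep$weighted[["f1"]],
                 sum(rep$per_class$f1 * rep$per_class$support) / n)
    expect_equal(unname(rowSums(rep$confusion)),
                 vapply(lv, function(cl) sum(truth == cl), 0,
                        USE.NAMES = FALSE))
  }
})

test_that("bias_ci: exact cases and bootstrap cross-check", {
  expect_error(bias_ci(1, 1), "at least 2")
  b0 <- bias_ci(c(3, 4, 5), c(3, 4, 5))
  expect_equal(b0$bias, 0)
  expect_equal(b0$ci, c(0, 0))
  b1 <- bias_ci(c(11, 9), c(10, 10)) # differences +1, -1
  expect_equal(b1$bias, 0)

  set.seed(31)
  ref <- runif(500, 20, 30)
  prd <- ref + rnorm(500, 0.1, 0.5)
  b <- bias_ci(prd, ref)
  boots <- replicate(2000, mean(sample(prd - ref, 500, replace = TRUE)))
  bci <- quantile(boots, c(0.025, 0.975))
  expect_lt(abs(b$ci[1] - bci[[1]]) / diff(b$ci), 0.05)
  expect_lt(abs(b$ci[2] - bci[[2]]) / diff(b$ci), 0.05)
})

test_that("tem_ci: sd/sqrt(2) convention and Monte-Carlo recovery", {
  t1 <- tem_ci(c(11, 9), c(10, 10)) # sd of (+1, -1) = sqrt(2)
  expect_equal(t1$tem, 1.0)
  t0 <- tem_ci(c(5, 5, 5), c(5, 5, 5))
  expect_equal(t0$tem, 0)

  set.seed(32)
  sigma <- 0.8
  d <- rnorm(10000, 0, sigma)
  t2 <- tem_ci(d, rep(0, 10000))
  expect_equal(t2$tem, sigma / sqrt(2), tolerance = 0.02)
  expect_true(t2$ci[1] < t2$tem && t2$tem < t2$ci[2])
})

test_that("bland_altman limits are bias +/- 1.96 sd", {
  z <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$bias, 0)
  expect_equal(unname(z$loa), c(0, 0))

  set.seed(33)
  ref <- runif(200, 20, 30)
  prd <- ref + rnorm(200)
  ba <- bland_altman(prd, ref)
  d <- prd - ref
  expect_equal(unname(ba$loa),
               c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)))
  expect_equal(ba$points$diff, d)
})

test_that("mape: exact cases and the seconds form via the reference mean", {
  expect_equal(mape(c(10, 20), c(10, 20))$mape_pct, 0)
  expect_equal(mape(11, 10)$mape_pct, 10)
  expect_error(mape(c(1, 2), c(1, 0)), "positive")

  # seconds form: a 1.77% MAPE against laps averaging 23.73 s is 0.42 s
  ref <- rep(23.73, 10)
  prd <- ref * 1.0177
  m <- mape(prd, ref)
  expect_equal(m$mape_pct, 1.77, tolerance = 1e-9)
  expect_equal(round(m$mape_s, 2), 0.42)
})

test_that("agreement statistics are invariant to pair order", {
  set.seed(34)
  ref <- runif(60, 18, 30)
  prd <- ref + rnorm(60, 0, 0.4)
  p <- sample(60)
  expect_equal(bias_ci(prd, ref)$bias, bias_ci(prd[p], ref[p])$bias)
  expect_equal(tem_ci(prd, ref)$tem, tem_ci(prd[p], ref[p])$tem)
  expect_equal(unname(bland_altman(prd, ref)$loa),
               unname(bland_altman(prd[p], ref[p])$loa))
  expect_equal(mape(prd, ref)$mape_pct, mape(prd[p], ref[p])$mape_pct)
})
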