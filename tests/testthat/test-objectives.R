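test_that("class statistics match hand-computed masses and means", {
  cs <- classStatistics(twoPointHistogram(), 128)
  expect_equal(cs$omega, c(0.5, 0.5))
  expect_equal(cs$mu, c(0, 255))

  cs2 <- classStatistics(uniformHistogram(), 127)
  expect_equal(cs2$omega, c(0.5, 0.5))
  expect_equal(cs2$mu, c(63.5, 191.5))

  p <- numeric(256); p[11] <- 1
  cs3 <- classStatistics(histogramFromProbs(p), 200)
  expect_equal(cs3$omega, c(1, 0))
  expect_identical(cs3$empty, c(FALSE, TRUE))
  expect_equal(cs3$mu[2], 0)
})

test_that("Otsu between-class variance matches hand evaluations", {
  p <- numeric(256); p[43] <- 1
  expect_equal(otsuFitness(histogramFromProbs(p), 100)$fitness, 0)
  expect_equal(otsuFitness(twoPointHistogram(), 128)$fitness, 16256.25)
  expect_equal(otsuFitness(uniformHistogram(), 127)$fitness, 4096)
})

test_that("Kapur entropy matches hand evaluations and conventions", {
  # both classes single point masses
  expect_equal(kapurFitness(twoPointHistogram(), 0)$fitness, 0)
  # uniform over 4 levels, threshold after level 1: ln 2 + ln 2
  expect_equal(kapurFitness(histogramFromProbs(rep(0.25, 4)), 1)$fitness,
               2 * log(2), tolerance = 1e-12)
  # an empty class contributes exactly 0
  p <- numeric(256); p[1:50] <- 1 / 50
  r <- kapurFitness(histogramFromProbs(p), c(24, 200))
  expect_identical(r$perClass$entropy[3], 0)
  expect_equal(r$fitness, sum(r$perClass$entropy))
})

test_that("objectives agree with independent direct-summation oracles", {
  set.seed(31)
  for (i in 1:25) {
    h <- randomHistogram()
    k <- sample(1:4, 1)
    th <- sort(sample(0:254, k))
    expect_equal(otsuFitness(h, th)$fitness, directOtsu(probs(h), th),
                 tolerance = 1e-9)
    expect_equal(kapurFitness(h, th)$fitness, directKapur(probs(h), th),
                 tolerance = 1e-9)
  }
})

test_that("between/within variance decomposition recovers total variance", {
  set.seed(17)
  for (i in 1:50) {
    h <- randomHistogram()
    p <- probs(h); lev <- 0:255
    th <- sort(sample(0:254, sample(1:4, 1)))
    muT <- sum(lev * p)
    total <- sum(p * (lev - muT)^2)
    within <- 0
    bounds <- c(-1L, th, 255L)
    for (j in seq_len(length(th) + 1L)) {
      idx <- which(lev > bounds[j] & lev <= bounds[j + 1L])
      w <- sum(p[idx])
      if (w > 0) {
        mu <- sum(lev[idx] * p[idx]) / w
        within <- within + w * sum(p[idx] / w * (lev[idx] - mu)^2)
      }
    }
    expect_lt(abs(otsuFitness(h, th)$fitness + within - total), 1e-9)
  }
})

test_that("Kapur with no thresholds equals whole-histogram Shannon entropy", {
  set.seed(5)
  for (i in 1:5) {
    h <- randomHistogram()
    p <- probs(h)[probs(h) > 0]
    expect_equal(kapurFitness(h, integer(0))$fitness, -sum(p * log(p)),
                 tolerance = 1e-12)
  }
})

test_that("objectives are invariant to padding with zero-probability levels", {
  p <- c(0.2, 0.3, 0.5)
  h1 <- histogramFromProbs(c(p, numeric(5)))
  h2 <- histogramFromProbs(c(p, numeric(60)))
  expect_equal(otsuFitness(h1, 1)$fitness, otsuFitness(h2, 1)$fitness)
  expect_equal(kapurFitness(h1, 1)$fitness, kapurFitness(h2, 1)$fitness)
})

test_that("exhaustive search at k = 1 equals a naive per-threshold scan", {
  set.seed(23)
  for (i in 1:100) {
    h <- randomHistogram()
    obj <- if (i %% 2) "otsu" else "kapur"
    fit <- exhaustiveOptimal(h, 1, obj)
    fn <- thresholdFitness(h, obj)
    scan <- fn(matrix(0:254, ncol = 1))
    expect_identical(fitnessValue(fit), max(scan))
    expect_identical(thresholds(fit), which.max(scan) - 1L)
  }
})

test_that("exhaustive search at k = 2 and 3 finds the enumerated optimum", {
  # reduced-L histogram so full enumeration with the direct oracle is cheap
  set.seed(9)
  p <- stats::rexp(32); p[sample(32, 8)] <- 0; p <- p / sum(p)
  h <- histogramFromProbs(p)
  for (obj in c("otsu", "kapur")) {
    direct <- if (obj == "otsu") directOtsu else directKapur
    for (k in 2:3) {
      combos <- utils::combn(0:30, k)
      vals <- apply(combos, 2, function(th) direct(p, th))
      fit <- exhaustiveOptimal(h, k, obj)
      expect_equal(fitnessValue(fit), max(vals), tolerance = 1e-12)
      expect_identical(thresholds(fit),
                       as.integer(combos[, which.max(vals)]))
    }
  }
})

test_that("exhaustive ties break toward the lexicographically smallest", {
  fit <- exhaustiveOptimal(twoPointHistogram(), 1, "otsu")
  # every threshold in 0..254 separates the two masses equally well
  expect_identical(thresholds(fit), 0L)
  expect_equal(fitnessValue(fit), 16256.25)
})

test_that("exhaustive search rejects k beyond its capability", {
  expect_error(exhaustiveOptimal(uniformHistogram(), 4, "otsu"), "k <= 3")
})

test_that("a bimodal histogram is split strictly between its modes", {
  h <- generateHistogram(mixtureSpec(c(80, 180), c(12, 12)))
  th <- thresholds(exhaustiveOptimal(h, 1, "otsu"))
  expect_gt(th, 80)
  expect_lt(th, 180)
})

test_that("threshold decoding clamps, rounds and sorts", {
  h <- twoPointHistogram()
  fn <- thresholdFitness(h, "otsu")
  decode <- attr(fn, "decode")
  expect_identical(decode(matrix(c(300, -5, 10.6), 1)),
                   matrix(c(0L, 11L, 254L), 1))
  # duplicate thresholds after rounding are tolerated (empty class)
  expect_identical(fn(matrix(c(100.2, 99.8), 1)),
                   otsuFitness(h, 100)$fitness)
})
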