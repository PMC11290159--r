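test_that("Mantegna sigma matches an independent evaluation of the formula", {
  # written out afresh from the closed form, term by term
  mantegna <- function(b) {
    num <- gamma(1 + b) * sin(pi * b / 2)
    den <- gamma((1 + b) / 2) * b * 2^((b - 1) / 2)
    (num / den)^(1 / b)
  }
  for (b in c(1.1, 1.3, 1.5, 1.7, 1.9))
    expect_lt(abs(levySigma(b) - mantegna(b)), 1e-12)
  expect_equal(levySigma(1.5), 0.6965745, tolerance = 1e-7)
  expect_equal(levySigma(2), 0)
  for (b in seq(1, 1.99, by = 0.11)) {
    s <- levySigma(b)
    expect_true(is.finite(s) && s > 0)
  }
  expect_error(levySigma(0.5), "1, 2")
  expect_error(levySigma(2.5), "1, 2")
})

test_that("Levy steps are zero-scaled correctly and heavy-tailed", {
  expect_identical(levyStep(5, levyConfig(scale = 0)), numeric(5))
  set.seed(77)
  s <- levyStep(1e5, levyConfig())
  kurt <- mean((s - mean(s))^4) / stats::var(s)^2
  expect_gt(kurt, 3)  # far exceeds the Gaussian kurtosis in practice
})

test_that("Levy procreation reduces to plain procreation at scale zero", {
  x1 <- c(10, 40, 200); x2 <- c(30, 20, 100)
  set.seed(5)
  a <- levyProcreate(x1, x2, levyConfig(scale = 0), 4)
  set.seed(5)
  b <- procreate(x1, x2, 4)
  expect_identical(a, b)
})

test_that("Levy procreation conserves the pair sum for its exploit half
           and stays finite", {
  x1 <- c(10, 40); x2 <- c(200, 90)
  set.seed(31)
  off <- levyProcreate(x1, x2, levyConfig(), 4)
  expect_true(all(is.finite(off)))
  expect_identical(dim(off), c(4L, 2L))
})

test_that("opposition is the exact box reflection and an involution", {
  expect_equal(oppositePoint(3, 0, 10), 7)
  set.seed(14)
  for (i in 1:20) {
    lo <- runif(3, -5, 0); up <- runif(3, 1, 6)
    x <- lo + runif(3) * (up - lo)
    y <- oppositePoint(x, lo, up)
    expect_equal(oppositePoint(y, lo, up), x)
    expect_true(all(y >= lo - 1e-12 & y <= up + 1e-12))
  }
  mid <- c(0.5, 0.5)
  expect_equal(oppositePoint(mid, c(0, 0), c(1, 1)), mid)
})

test_that("quasi-opposites land between the midpoint and the opposite", {
  set.seed(9)
  lo <- 0; up <- 10
  for (i in 1:200) {
    x <- runif(1, lo, up)
    q <- quasiOppositePoint(x, lo, up)
    m <- (lo + up) / 2; o <- up + lo - x
    expect_gte(q, min(m, o) - 1e-12)
    expect_lte(q, max(m, o) + 1e-12)
  }
  # a midpoint input is a fixed point
  expect_equal(quasiOppositePoint(5, 0, 10), 5)
  set.seed(2); q1 <- quasiOppositePoint(c(1, 2), c(0, 0), c(10, 10))
  set.seed(2); q2 <- quasiOppositePoint(c(1, 2), c(0, 0), c(10, 10))
  expect_identical(q1, q2)
})

test_that("IBWOA with both improvements disabled is bit-identical to BWOA", {
  h <- generateHistogram(mixtureSpec(c(60, 140, 210), c(10, 12, 10)))
  fn <- thresholdFitness(h, "otsu")
  cfg <- bwoaConfig(kVar = 2, lower = 0, upper = 254, maxIter = 80,
                    seed = 13)
  base <- bwoaOptimize(cfg, fn)
  red <- ibwoaOptimize(cfg, fn, levy = levyConfig(scale = 0),
                       qoblJumpRate = 0)
  expect_identical(base$trace, red$trace)
  expect_identical(base$position, red$position)
})

test_that("IBWOA is at least as good as BWOA on a paired sphere benchmark", {
  fn <- function(X) -rowSums((X - 1.234)^2)
  deltas <- vapply(1:20, function(s) {
    cfg <- bwoaConfig(kVar = 2, lower = -5, upper = 5, maxIter = 80,
                      nPop = 30, seed = s)
    ibwoaOptimize(cfg, fn)$fitness - bwoaOptimize(cfg, fn)$fitness
  }, numeric(1))
  # both converge on a smooth bowl; a tie at convergence-jitter scale is a
  # pass, a genuine regression (fitness scale is O(10)) is not
  expect_gte(stats::median(deltas), -1e-3)
})

test_that("IBWOA traces are monotone and reproducible", {
  h <- generateHistogram(mixtureSpec(c(80, 180), c(12, 12)))
  fn <- thresholdFitness(h, "kapur")
  cfg <- bwoaConfig(kVar = 2, lower = 0, upper = 254, maxIter = 60,
                    seed = 21)
  r1 <- ibwoaOptimize(cfg, fn)
  r2 <- ibwoaOptimize(cfg, fn)
  expect_identical(r1$trace, r2$trace)
  expect_true(!is.unsorted(r1$trace$bestFitness))
})

test_that("IBWOA matches the exhaustive oracle more often than BWOA on
           mixture histograms", {
  # 20 two-mode analytic histograms, k = 2, Otsu, paired over 5 seeds
  set.seed(61)
  specs <- replicate(20, {
    m1 <- runif(1, 40, 120)
    mixtureSpec(means = c(m1, m1 + runif(1, 60, 100)),
                sds = runif(2, 8, 14))
  }, simplify = FALSE)
  hitI <- 0; hitB <- 0
  for (sp in specs) {
    h <- generateHistogram(sp)
    oracle <- exhaustiveOptimal(h, 2, "otsu")
    for (s in 1:5) {
      fI <- optimalThresholds(h, 2, "otsu", "ibwoa", seed = s)
      fB <- optimalThresholds(h, 2, "otsu", "bwoa", seed = s)
      hitI <- hitI + (abs(fitnessValue(fI) - fitnessValue(oracle)) <= 1e-9)
      hitB <- hitB + (abs(fitnessValue(fB) - fitnessValue(oracle)) <= 1e-9)
    }
  }
  expect_gte(hitI, hitB)
})
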