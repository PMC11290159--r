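sphereFitness <- function(target) {
  force(target)
  function(X) -rowSums((X - matrix(target, nrow(X), length(target),
                                   byrow = TRUE))^2)
}

test_that("initial populations are bounded, evaluated and reproducible", {
  cfg <- bwoaConfig(kVar = 3, lower = c(-1, 0, 5), upper = c(1, 2, 6),
                    nPop = 30)
  fn <- function(X) rowSums(X)
  set.seed(99)
  pop <- initializePopulation(cfg, fn)
  expect_identical(nrow(pop@positions), 30L)
  for (j in 1:3) {
    expect_true(all(pop@positions[, j] >= cfg@lower[j]))
    expect_true(all(pop@positions[, j] <= cfg@upper[j]))
  }
  expect_equal(pop@fitness, fn(pop@positions))
  set.seed(99)
  pop2 <- initializePopulation(cfg, fn)
  expect_identical(pop@positions, pop2@positions)
})

test_that("procreation is a symmetric convex recombination", {
  x1 <- c(1, 2, 3); x2 <- c(7, 5, 3)
  # alpha = 1 reproduces the parents
  off <- procreate(x1, x2, 2, alpha = rep(1, 3))
  expect_equal(off[1, ], x1); expect_equal(off[2, ], x2)
  # alpha = 0.5 collapses both children to the midpoint
  off <- procreate(x1, x2, 2, alpha = rep(0.5, 3))
  expect_equal(off[1, ], (x1 + x2) / 2)
  expect_equal(off[2, ], (x1 + x2) / 2)
  # pairwise sum is conserved for any alpha
  set.seed(4)
  off <- procreate(x1, x2, 6)
  for (p in 1:3)
    expect_equal(off[p, ] + off[p + 3, ], x1 + x2)
  expect_error(procreate(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("cannibalism keeps the female parent and the CR-best offspring", {
  P <- rbind(c(0, 0), c(1, 1))
  off <- matrix(seq(0.1, 0.8, by = 0.1), 4, 2)
  offFit <- c(3, 1, 4, 2)
  # CR = 1: all offspring survive, plus the fitter parent
  s <- cannibalism(P, c(5, 9), off, offFit, CR = 1)
  expect_identical(nrow(s$positions), 5L)
  expect_equal(s$positions[1, ], c(1, 1))
  # CR -> 0: exactly the single best offspring survives
  s <- cannibalism(P, c(5, 9), off, offFit, CR = 1e-9)
  expect_identical(nrow(s$positions), 2L)
  expect_equal(s$fitness[2], 4)
  # equal parent fitness: the first-listed parent survives
  s <- cannibalism(P, c(7, 7), off, offFit, CR = 0.5)
  expect_equal(s$positions[1, ], c(0, 0))
  expect_equal(s$fitness, c(7, 4, 3))
})

test_that("mutation respects rate, strategies and bounds", {
  fn <- function(X) rowSums(X)
  pop <- new("WidowPopulation",
             positions = matrix(as.numeric(1:20), 10, 2),
             fitness = fn(matrix(as.numeric(1:20), 10, 2)))
  expect_identical(mutateWidows(pop, 0, "reset", c(0, 0), c(30, 30), fn),
                   pop)
  set.seed(12)
  m <- mutateWidows(pop, 1, "swap", c(0, 0), c(30, 30), fn)
  # swap permutes each row's components
  for (i in 1:10)
    expect_setequal(m@positions[i, ], pop@positions[i, ])
  expect_equal(m@fitness, fn(m@positions))
  set.seed(12)
  r <- mutateWidows(pop, 0.5, "reset", c(0, 0), c(30, 30), fn)
  expect_true(all(r@positions >= 0 & r@positions <= 30))
  # swap is impossible in one dimension
  pop1 <- new("WidowPopulation", positions = matrix(1:4 * 1.0, 4, 1),
              fitness = as.numeric(1:4))
  expect_warning(mutateWidows(pop1, 0.5, "swap", 0, 10, fn), "reset")
})

test_that("the optimizer finds a known analytic optimum", {
  cfg <- bwoaConfig(kVar = 2, lower = -5, upper = 5, seed = 3)
  res <- bwoaOptimize(cfg, sphereFitness(c(1.7, -2.3)))
  expect_lt(max(abs(res$position - c(1.7, -2.3))), 1e-2)
})

test_that("runs are bit-reproducible and traces monotone", {
  cfg <- bwoaConfig(kVar = 2, lower = 0, upper = 254, maxIter = 60,
                    nPop = 20, seed = 42)
  fn <- thresholdFitness(generateHistogram(
    mixtureSpec(c(70, 190), c(12, 12))), "otsu")
  r1 <- bwoaOptimize(cfg, fn)
  r2 <- bwoaOptimize(cfg, fn)
  expect_identical(r1$trace, r2$trace)
  expect_true(!is.unsorted(r1$trace$bestFitness))
  expect_equal(nrow(r1$trace), 60L)
})

test_that("population size and bounds are maintained through the run", {
  cfg <- bwoaConfig(kVar = 3, lower = 0, upper = 10, maxIter = 40,
                    nPop = 24, seed = 5)
  res <- bwoaOptimize(cfg, sphereFitness(c(2, 5, 8)))
  expect_identical(nrow(res$population@positions), 24L)
  expect_true(all(res$population@positions >= 0 &
                    res$population@positions <= 10))
})

test_that("with no procreation and no mutation the best initial widow wins", {
  cfg <- bwoaConfig(kVar = 2, lower = -3, upper = 3, nPop = 16,
                    maxIter = 25, procreateRate = 0, mutationRate = 0,
                    seed = 8)
  fn <- sphereFitness(c(0, 0))
  set.seed(cfg@seed)
  init <- initializePopulation(cfg, fn)
  res <- bwoaOptimize(cfg, fn)
  expect_identical(res$fitness, max(init@fitness))
})

test_that("early stopping rules cut the trace short", {
  fn <- sphereFitness(c(1, 1))
  cfgT <- bwoaConfig(kVar = 2, lower = 0, upper = 2, maxIter = 300,
                     seed = 2, stopRule = "target_fitness",
                     targetFitness = -1e-4)
  rT <- bwoaOptimize(cfgT, fn)
  expect_lt(nrow(rT$trace), 300L)
  expect_gte(rT$fitness, -1e-4)
  cfgS <- bwoaConfig(kVar = 2, lower = 0, upper = 2, maxIter = 300,
                     seed = 2, stopRule = "fitness_stall",
                     stallPatience = 10L)
  rS <- bwoaOptimize(cfgS, fn)
  expect_lt(nrow(rS$trace), 300L)
})

test_that("configuration validity is enforced", {
  expect_error(bwoaConfig(kVar = 2, lower = 1, upper = 0), "strictly")
  expect_error(bwoaConfig(kVar = 2, lower = 0, upper = Inf), "finite")
  expect_error(bwoaConfig(kVar = 2, nPop = 2), "nPop")
  expect_error(bwoaConfig(kVar = 2, procreateRate = 1.2), "rates")
  expect_error(bwoaConfig(kVar = 2, nOffspring = 3), "even")
})

test_that("traces round-trip through CSV", {
  cfg <- bwoaConfig(kVar = 2, lower = 0, upper = 1, maxIter = 10,
                    nPop = 8, seed = 1)
  res <- bwoaOptimize(cfg, sphereFitness(c(0.5, 0.5)))
  f <- tempfile(fileext = ".csv")
  writeTrace(res$trace, f)
  back <- utils::read.csv(f)
  expect_equal(back$bestFitness, res$trace$bestFitness)
  unlink(f)
})
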