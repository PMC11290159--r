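# Black Widow Optimization Algorithm: population lifecycle of procreation
# (convex recombination), sexual + sibling cannibalism (selection) and
# mutation, with elitist truncation to nPop each generation.
#
# The engine (.bwoaEngine) is shared by bwoaOptimize and ibwoaOptimize; the
# IBWOA extras (Levy-perturbed mixing, quasi-opposition jumps) are switched
# on by arguments and draw no random numbers when disabled, so the improved
# algorithm with both extras off consumes exactly the baseline random
# stream.
#
# Fitness contract: fitnessFn takes an n x kVar matrix of positions (one row
# per widow) and returns a length-n numeric vector; the engine maximizes.

#' WidowPopulation: a population of candidate solutions
#'
#' @slot positions numeric matrix, one widow per row.
#' @slot fitness numeric vector of evaluated fitness values.
#' @exportClass WidowPopulation
setClass("WidowPopulation",
  representation(positions = "matrix", fitness = "numeric"))

setValidity("WidowPopulation", function(object) {
  if (nrow(object@positions) != length(object@fitness))
    return("one fitness value per widow is required")
  if (nrow(object@positions) < 2L) return("population size must be >= 2")
  TRUE
})

setMethod("show", "WidowPopulation", function(object) {
  cat(sprintf("WidowPopulation: %d widows, %d dims, best fitness %.6g\n",
              nrow(object@positions), ncol(object@positions),
              max(object@fitness)))
})

.uniformMatrix <- function(n, lower, upper) {
  K <- length(lower)
  U <- matrix(stats::runif(n * K), n, K)
  sweep(sweep(U, 2L, upper - lower, "*"), 2L, lower, "+")
}

.clampBounds <- function(X, lower, upper) {
  X <- pmax(X, rep(lower, each = nrow(X)))
  pmin(X, rep(upper, each = nrow(X)))
}

#' Initialize a random population
#'
#' Draws \code{nPop} widows uniformly within the box bounds and evaluates
#' them.  Uses the current RNG state (callers seed via
#' \code{\link{bwoaOptimize}}'s config).
#'
#' @param cfg a \linkS4class{BWOAConfig}.
#' @param fitnessFn vectorized fitness: matrix of positions (rows) ->
#'   numeric vector.
#' @return A \linkS4class{WidowPopulation}.
#' @export
initializePopulation <- function(cfg, fitnessFn) {
  stopifnot(is(cfg, "BWOAConfig"))
  X <- .uniformMatrix(cfg@nPop, cfg@lower, cfg@upper)
  new("WidowPopulation", positions = X, fitness = as.numeric(fitnessFn(X)))
}

#' Procreation: convex recombination of a parent pair
#'
#' Offspring are produced in pairs.  Each pair draws a fresh mixing vector
#' \eqn{\alpha} with components uniform on \code{[0, 1]} and forms
#' \eqn{V_1 = \alpha \odot x_1 + (1-\alpha) \odot x_2} and
#' \eqn{V_2 = \alpha \odot x_2 + (1-\alpha) \odot x_1}, so that
#' \eqn{V_1 + V_2 = x_1 + x_2} componentwise.
#'
#' @param x1,x2 numeric parent position vectors of equal length.
#' @param nOffspring even number of offspring to produce.
#' @param alpha optional fixed mixing matrix (\code{nOffspring/2} rows) used
#'   instead of fresh uniform draws; mainly for testing.
#' @return matrix with \code{nOffspring} rows of offspring positions.
#' @examples
#' procreate(c(0, 0), c(1, 1), 2)
#' @export
procreate <- function(x1, x2, nOffspring = 2L, alpha = NULL) {
  if (length(x1) != length(x2)) stop("parents must have equal dimension")
  if (nOffspring < 2L || nOffspring %% 2L != 0L)
    stop("nOffspring must be an even integer >= 2")
  K <- length(x1); np <- nOffspring %/% 2L
  A <- if (is.null(alpha)) matrix(stats::runif(np * K), np, K)
       else matrix(alpha, np, K)
  X1 <- matrix(x1, np, K, byrow = TRUE)
  X2 <- matrix(x2, np, K, byrow = TRUE)
  rbind(A * X1 + (1 - A) * X2, A * X2 + (1 - A) * X1)
}

#' Cannibalism: sexual and sibling selection
#'
#' Sexual cannibalism discards the lower-fitness parent (the fitter parent,
#' the "female", survives; on an exact tie the first-listed parent
#' survives).  Sibling cannibalism keeps the \code{ceiling(CR * n)} best of
#' the n offspring.  Survivors are the surviving parent plus the kept
#' offspring.
#'
#' @param parentPositions 2-row matrix of parent positions.
#' @param parentFitness length-2 numeric.
#' @param offspring matrix of offspring positions.
#' @param offspringFitness numeric, one value per offspring row.
#' @param CR cannibalism rate in \code{[0, 1]}.
#' @return list with \code{positions} (matrix) and \code{fitness} (vector),
#'   surviving parent first.
#' @export
cannibalism <- function(parentPositions, parentFitness, offspring,
                        offspringFitness, CR) {
  stopifnot(nrow(parentPositions) == 2L, length(parentFitness) == 2L,
            CR >= 0, CR <= 1)
  fem <- if (parentFitness[2L] > parentFitness[1L]) 2L else 1L
  n <- nrow(offspring)
  nkeep <- min(n, max(1L, as.integer(ceiling(CR * n))))
  keep <- order(offspringFitness, decreasing = TRUE)[seq_len(nkeep)]
  list(positions = rbind(parentPositions[fem, , drop = FALSE],
                         offspring[keep, , drop = FALSE]),
       fitness = c(parentFitness[fem], offspringFitness[keep]))
}

#' Mutation of a population fraction
#'
#' Selects \code{round(PM * n)} widows uniformly without replacement and
#' perturbs each: \code{"swap"} exchanges two distinct randomly chosen
#' components; \code{"reset"} redraws one randomly chosen component
#' uniformly within its bounds.  Mutants are re-evaluated.
#'
#' @param pop a \linkS4class{WidowPopulation}.
#' @param PM mutation rate in \code{[0, 1]}.
#' @param strategy \code{"reset"} or \code{"swap"}.
#' @param lower,upper box bounds (needed for \code{"reset"}).
#' @param fitnessFn vectorized fitness function.
#' @return The mutated \linkS4class{WidowPopulation}.
#' @export
mutateWidows <- function(pop, PM, strategy = c("reset", "swap"),
                         lower, upper, fitnessFn) {
  stopifnot(is(pop, "WidowPopulation"), PM >= 0, PM <= 1)
  strategy <- match.arg(strategy)
  X <- pop@positions; Fv <- pop@fitness
  K <- ncol(X)
  if (strategy == "swap" && K < 2L) {
    warning("swap mutation needs at least 2 components; falling back to reset")
    strategy <- "reset"
  }
  nm <- min(round(PM * nrow(X)), nrow(X))
  if (nm == 0L) return(pop)
  mi <- sample.int(nrow(X), nm)
  if (strategy == "swap") {
    c1 <- sample.int(K, nm, replace = TRUE)
    c2 <- (c1 - 1L + sample.int(K - 1L, nm, replace = TRUE)) %% K + 1L
    tmp <- X[cbind(mi, c1)]
    X[cbind(mi, c1)] <- X[cbind(mi, c2)]
    X[cbind(mi, c2)] <- tmp
  } else {
    cj <- sample.int(K, nm, replace = TRUE)
    X[cbind(mi, cj)] <- lower[cj] + stats::runif(nm) * (upper[cj] - lower[cj])
  }
  Fv[mi] <- fitnessFn(X[mi, , drop = FALSE])
  new("WidowPopulation", positions = X, fitness = Fv)
}

# The shared lifecycle engine.  levy = NULL disables Levy procreation
# entirely; qoblRate = 0 disables quasi-opposition (including the
# initialization sweep).  Disabled extras draw no random numbers, so the
# improved algorithm with both extras off replays the baseline stream
# exactly.
.bwoaEngine <- function(cfg, fitnessFn, levy = NULL, qoblRate = 0) {
  K <- length(cfg@lower)
  lower <- cfg@lower; upper <- cfg@upper
  boxRange <- upper - lower
  set.seed(cfg@seed)
  useLevy <- !is.null(levy) && levy@scale != 0
  sigma <- if (useLevy) levySigma(levy@beta) else 0
  strategy <- cfg@mutationStrategy
  if (strategy == "swap" && K < 2L) {
    warning("swap mutation needs at least 2 components; falling back to reset")
    strategy <- "reset"
  }

  X <- .uniformMatrix(cfg@nPop, lower, upper)
  Fv <- as.numeric(fitnessFn(X))

  mergeBest <- function(X, Fv, Y, Fy, n) {
    ALL <- rbind(X, Y); Fa <- c(Fv, Fy)
    top <- order(Fa, decreasing = TRUE)[seq_len(n)]
    list(X = ALL[top, , drop = FALSE], Fv = Fa[top])
  }

  if (qoblRate > 0) {
    Q <- .qoblMatrix(X, lower, upper)
    m <- mergeBest(X, Fv, Q, as.numeric(fitnessFn(Q)), cfg@nPop)
    X <- m$X; Fv <- m$Fv
  }

  nr <- round(cfg@procreateRate * cfg@nPop)
  nps <- cfg@nOffspring %/% 2L
  nkeep <- max(1L, as.integer(ceiling(cfg@cannibalismRate * cfg@nOffspring)))
  nkeep <- min(nkeep, cfg@nOffspring)

  traceBest <- numeric(cfg@maxIter)
  traceMean <- numeric(cfg@maxIter)
  tracePos <- matrix(NA_real_, cfg@maxIter, K)
  stallBest <- max(Fv); stallCount <- 0L
  iters <- 0L

  drawLevy <- function(n) {
    R6 <- matrix(stats::rnorm(n * K, sd = sigma), n, K)
    R7 <- matrix(stats::rnorm(n * K), n, K)
    bad <- R7 == 0
    while (any(bad)) {  # measure-zero guard
      R7[bad] <- stats::rnorm(sum(bad))
      bad <- R7 == 0
    }
    levy@scale * R6 / abs(R7)^(1 / levy@beta)
  }

  for (it in seq_len(cfg@maxIter)) {
    if (qoblRate > 0 && stats::runif(1L) < qoblRate) {
      # generation jumping over the population's current per-dimension
      # interval (quasi-oppositional-DE convention): as the swarm
      # contracts, jumps become local refinements
      lo <- apply(X, 2L, min); up <- apply(X, 2L, max)
      Q <- .qoblMatrix(X, lo, up)
      m <- mergeBest(X, Fv, Q, as.numeric(fitnessFn(Q)), cfg@nPop)
      X <- m$X; Fv <- m$Fv
    }

    npair <- nr %/% 2L
    bi <- which.max(Fv)
    bestX <- X[bi, , drop = FALSE]; bestF <- Fv[bi]

    if (npair >= 1L) {
      pool <- order(Fv, decreasing = TRUE)[seq_len(nr)]
      perm <- pool[sample.int(nr)]
      i1 <- perm[seq_len(npair) * 2L - 1L]
      i2 <- perm[seq_len(npair) * 2L]
      sw <- Fv[i2] > Fv[i1]
      tmp <- i1[sw]; i1[sw] <- i2[sw]; i2[sw] <- tmp  # i1 = fitter (female)

      nhalf <- npair * nps
      A <- matrix(stats::runif(nhalf * K), nhalf, K)
      X1 <- X[rep(i1, nps), , drop = FALSE]
      X2 <- X[rep(i2, nps), , drop = FALSE]
      if (useLevy) {
        # first child of each brood pair: Levy-perturbed mixing weight
        # (unclamped, so offspring may extrapolate past the parents);
        # second child: plain mixing plus a Levy flight in position space
        A1 <- A + drawLevy(nhalf)
        V1 <- A1 * X1 + (1 - A1) * X2
        V2 <- A * X2 + (1 - A) * X1 +
          drawLevy(nhalf) * rep(boxRange, each = nhalf)
        OFF <- rbind(V1, V2)
      } else {
        OFF <- rbind(A * X1 + (1 - A) * X2, A * X2 + (1 - A) * X1)
      }
      OFF <- .clampBounds(OFF, lower, upper)
      Foff <- as.numeric(fitnessFn(OFF))

      fam <- rep.int(seq_len(npair), 2L * nps)
      o <- order(fam, -Foff)
      sel <- o[rep((seq_len(npair) - 1L) * cfg@nOffspring, each = nkeep) +
                 rep.int(seq_len(nkeep), npair)]
      surv <- rbind(X[i1, , drop = FALSE], OFF[sel, , drop = FALSE])
      Fs <- c(Fv[i1], Foff[sel])

      # the best survivor is exempt from mutation: a just-discovered
      # optimum lives only in the survivor pool until replacement, and
      # mutating it in place would destroy it before elitism can act
      nm <- min(round(cfg@mutationRate * cfg@nPop), nrow(surv) - 1L)
      if (nm >= 1L) {
        bs <- which.max(Fs)
        mi <- setdiff(sample.int(nrow(surv)), bs)[seq_len(nm)]
        if (strategy == "swap") {
          c1 <- sample.int(K, nm, replace = TRUE)
          c2 <- (c1 - 1L + sample.int(K - 1L, nm, replace = TRUE)) %% K + 1L
          tmp <- surv[cbind(mi, c1)]
          surv[cbind(mi, c1)] <- surv[cbind(mi, c2)]
          surv[cbind(mi, c2)] <- tmp
        } else {
          cj <- sample.int(K, nm, replace = TRUE)
          surv[cbind(mi, cj)] <- lower[cj] +
            stats::runif(nm) * (upper[cj] - lower[cj])
        }
        Fs[mi] <- as.numeric(fitnessFn(surv[mi, , drop = FALSE]))
      }

      # next generation: nPop best of (merged survivor pool U current
      # best); any shortfall is topped up with freshly drawn widows
      # (random immigrants), which keeps the size invariant and a steady
      # trickle of exploration
      cand <- rbind(surv, bestX); Fc <- c(Fs, bestF)
      if (nrow(cand) >= cfg@nPop) {
        top <- order(Fc, decreasing = TRUE)[seq_len(cfg@nPop)]
        X <- cand[top, , drop = FALSE]; Fv <- Fc[top]
      } else {
        fresh <- .uniformMatrix(cfg@nPop - nrow(cand), lower, upper)
        X <- rbind(cand, fresh)
        Fv <- c(Fc, as.numeric(fitnessFn(fresh)))
      }
    }
    # with procreation disabled there is no offspring pool and the
    # generation is carried over unchanged

    iters <- it
    b <- which.max(Fv)
    traceBest[it] <- Fv[b]
    traceMean[it] <- mean(Fv)
    tracePos[it, ] <- X[b, ]

    if (cfg@stopRule == "target_fitness" && !is.na(cfg@targetFitness) &&
        Fv[b] >= cfg@targetFitness) break
    if (cfg@stopRule == "fitness_stall") {
      if (Fv[b] > stallBest + cfg@stallTol) {
        stallBest <- Fv[b]; stallCount <- 0L
      } else stallCount <- stallCount + 1L
      if (stallCount >= cfg@stallPatience) break
    }
  }

  b <- which.max(Fv)
  trace <- data.frame(iteration = seq_len(iters),
                      bestFitness = traceBest[seq_len(iters)],
                      meanFitness = traceMean[seq_len(iters)])
  trace <- cbind(trace, as.data.frame(tracePos[seq_len(iters), , drop = FALSE]))
  names(trace)[-(1:3)] <- paste0("x", seq_len(K))
  list(position = X[b, ], fitness = Fv[b], trace = trace,
       population = new("WidowPopulation", positions = X, fitness = Fv))
}

#' Run the baseline Black Widow Optimization Algorithm
#'
#' Maximizes \code{fitnessFn} over the box in \code{cfg}.  Each generation:
#' the best \code{round(PP * nPop)} widows form the breeding pool and are
#' paired at random; each pair procreates (\code{\link{procreate}}) and is
#' culled by \code{\link{cannibalism}}; mutation
#' (\code{\link{mutateWidows}}) perturbs a fraction of the merged survivor
#' pool; the next generation is the \code{nPop} best of the survivor pool
#' plus the current best widow (elitist truncation, so the best fitness
#' never decreases), topped up with freshly drawn random widows whenever
#' the pool is smaller than \code{nPop}.  The run is seeded from
#' \code{cfg@seed} and is bit-reproducible.
#'
#' @param cfg a \linkS4class{BWOAConfig}.
#' @param fitnessFn vectorized fitness: n x kVar matrix -> length-n numeric.
#' @return list with \code{position} (best widow), \code{fitness},
#'   \code{trace} (per-iteration data.frame: iteration, bestFitness,
#'   meanFitness, best position), \code{population} (final
#'   \linkS4class{WidowPopulation}).
#' @examples
#' cfg <- bwoaConfig(kVar = 2, lower = -5, upper = 5, maxIter = 60,
#'                   nPop = 20, seed = 7)
#' fit <- function(X) -rowSums((X - 1)^2)
#' bwoaOptimize(cfg, fit)$position
#' @export
bwoaOptimize <- function(cfg, fitnessFn) {
  stopifnot(is(cfg, "BWOAConfig"))
  .bwoaEngine(cfg, fitnessFn, levy = NULL, qoblRate = 0)
}

#' Write a convergence trace to CSV
#'
#' @param trace data.frame as returned in \code{bwoaOptimize()$trace}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a BWOA/IBWOA configuration from a YAML file
#'
#' Top-level keys correspond to \code{\link{bwoaConfig}} arguments; optional
#' \code{levy:} (\code{beta}, \code{scale}) and \code{qobl:}
#' (\code{jumpRate}) sections configure the improved variant.
#'
#' @param path YAML file path.
#' @param kVar problem dimension used for scalar bounds.
#' @return list with \code{config} (\linkS4class{BWOAConfig}), \code{levy}
#'   (\linkS4class{LevyConfig}) and \code{qoblJumpRate}.
#' @export
readOptimizerConfig <- function(path, kVar = 2L) {
  y <- yaml::read_yaml(path)
  levy <- y$levy; qobl <- y$qobl
  y$levy <- NULL; y$qobl <- NULL
  args <- y[names(y) %in% names(formals(bwoaConfig))]
  if (is.null(args$kVar)) args$kVar <- kVar
  cfg <- do.call(bwoaConfig, args)
  lv <- levyConfig(beta = if (is.null(levy$beta)) 1.5 else levy$beta,
                   scale = if (is.null(levy$scale)) 0.01 else levy$scale)
  jr <- if (is.null(qobl$jumpRate)) 0.3 else qobl$jumpRate
  list(config = cfg, levy = lv, qoblJumpRate = jr)
}
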