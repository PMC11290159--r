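# Improved BWOA: Levy-flight-perturbed procreation plus quasi-opposition-
# based learning (QOBL), layered on the shared engine in bwoa.R.

#' Mantegna standard deviation for Levy-stable steps
#'
#' \deqn{\sigma = \left[\frac{\Gamma(1+\beta)\,\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta}}
#'
#' At \eqn{\beta = 1.5} this is approximately 0.6966.  At \eqn{\beta = 2}
#' the numerator's \eqn{\sin(\pi)} makes it 0.
#'
#' @param beta stability index in \code{[1, 2]}.
#' @return The Mantegna sigma (numeric scalar).
#' @examples
#' levySigma(1.5)
#' @export
levySigma <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 1 || beta > 2)
    stop("beta must be a single number in [1, 2]")
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Draw Levy-flight step lengths (Mantegna's algorithm)
#'
#' Each step is \code{scale * R6 / |R7|^(1/beta)} with
#' \eqn{R_6 \sim N(0, \sigma^2)} (\eqn{\sigma} from
#' \code{\link{levySigma}}) and \eqn{R_7 \sim N(0, 1)}.  A draw of exactly
#' 0 for \eqn{R_7} is redrawn.  The resulting distribution is heavy-tailed:
#' mostly small steps with occasional large excursions.
#'
#' @param n number of steps to draw.
#' @param cfg a \linkS4class{LevyConfig}.
#' @return numeric vector of n steps.
#' @export
levyStep <- function(n, cfg = levyConfig()) {
  stopifnot(is(cfg, "LevyConfig"))
  if (cfg@scale == 0) return(numeric(n))
  sigma <- levySigma(cfg@beta)
  r6 <- stats::rnorm(n, sd = sigma)
  r7 <- stats::rnorm(n)
  bad <- r7 == 0
  while (any(bad)) {
    r7[bad] <- stats::rnorm(sum(bad))
    bad <- r7 == 0
  }
  cfg@scale * r6 / abs(r7)^(1 / cfg@beta)
}

#' Levy-perturbed procreation
#'
#' As \code{\link{procreate}}, but each brood pair splits its roles.  The
#' first child mixes the parents with a Levy-perturbed weight
#' \eqn{\alpha' = \alpha + \mathrm{Levy}} (unclamped, so it can
#' extrapolate slightly past a parent along the line joining them); the
#' second child takes the complementary plain mixture
#' \eqn{\alpha x_2 + (1-\alpha) x_1} and then makes an independent Levy
#' flight in position space, scaled by the box width per dimension.  The
#' exploit/explore split keeps half of every brood on the recombination
#' line while the other half can jump out of it; offspring are clamped to
#' the box.  With \code{scale = 0} no Levy numbers are drawn and the
#' result is identical to \code{\link{procreate}}.
#'
#' @inheritParams procreate
#' @param levy a \linkS4class{LevyConfig}; \code{scale = 0} reduces exactly
#'   to \code{\link{procreate}}.
#' @param lower,upper box bounds used to scale the position-space flight
#'   and clamp offspring (scalars are recycled).
#' @return matrix with \code{nOffspring} rows of offspring positions
#'   (first all exploit children, then their explore siblings).
#' @export
levyProcreate <- function(x1, x2, levy = levyConfig(), nOffspring = 2L,
                          lower = 0, upper = 1, alpha = NULL) {
  if (length(x1) != length(x2)) stop("parents must have equal dimension")
  if (nOffspring < 2L || nOffspring %% 2L != 0L)
    stop("nOffspring must be an even integer >= 2")
  K <- length(x1); np <- nOffspring %/% 2L
  if (length(lower) == 1L) lower <- rep(lower, K)
  if (length(upper) == 1L) upper <- rep(upper, K)
  A <- if (is.null(alpha)) matrix(stats::runif(np * K), np, K)
       else matrix(alpha, np, K)
  X1 <- matrix(x1, np, K, byrow = TRUE)
  X2 <- matrix(x2, np, K, byrow = TRUE)
  if (levy@scale == 0)
    return(rbind(A * X1 + (1 - A) * X2, A * X2 + (1 - A) * X1))
  A1 <- A + matrix(levyStep(np * K, levy), np, K)
  V1 <- A1 * X1 + (1 - A1) * X2
  V2 <- A * X2 + (1 - A) * X1 +
    matrix(levyStep(np * K, levy), np, K) * rep(upper - lower, each = np)
  OFF <- rbind(V1, V2)
  OFF <- pmax(OFF, rep(lower, each = 2L * np))
  pmin(OFF, rep(upper, each = 2L * np))
}

#' Opposition-based learning point
#'
#' Reflects a position through the center of the box:
#' \eqn{y_i = u_i + l_i - x_i}.  An involution: applying it twice returns
#' the original point.
#'
#' @param x numeric position vector.
#' @param lower,upper box bounds (scalars are recycled).
#' @return The opposite position vector.
#' @examples
#' oppositePoint(3, 0, 10)  # 7
#' @export
oppositePoint <- function(x, lower, upper) {
  upper + lower - x
}

#' Quasi-opposite point
#'
#' Componentwise uniform draw on the closed interval between the box
#' midpoint \eqn{m_i = (u_i + l_i)/2} and the opposite point
#' \eqn{u_i + l_i - x_i}.  A point at the midpoint maps to itself.
#'
#' @inheritParams oppositePoint
#' @return The quasi-opposite position vector (stochastic).
#' @export
quasiOppositePoint <- function(x, lower, upper) {
  m <- (upper + lower) / 2
  o <- upper + lower - x
  m + stats::runif(length(x)) * (o - m)
}

# matrix version used by the engine: one quasi-opposite row per widow
.qoblMatrix <- function(X, lower, upper) {
  n <- nrow(X); K <- ncol(X)
  M <- matrix((upper + lower) / 2, n, K, byrow = TRUE)
  O <- matrix(upper + lower, n, K, byrow = TRUE) - X
  M + matrix(stats::runif(n * K), n, K) * (O - M)
}

#' Run the Improved Black Widow Optimization Algorithm
#'
#' \code{\link{bwoaOptimize}} with two modifications: (a) procreation is
#' Levy-driven (\code{\link{levyProcreate}}): half of every brood mixes
#' the parents with an extrapolating Levy-perturbed weight, the other half
#' additionally takes a heavy-tailed flight in position space, boosting
#' exploration; (b) quasi-opposition-based learning is applied to the
#' initial population (the quasi-opposite of every widow is evaluated and
#' the best \code{nPop} of the 2 nPop candidates are kept) and, with
#' probability \code{qoblJumpRate} per generation, to the current
#' generation over its own per-dimension interval (the
#' quasi-oppositional-DE jumping convention), sharpening exploitation as
#' the swarm contracts.  Elitism is preserved throughout.
#'
#' With \code{levy@scale = 0} and \code{qoblJumpRate = 0} no Levy or QOBL
#' random draws are made and the run is bit-identical to
#' \code{\link{bwoaOptimize}} under the same seed.
#'
#' @inheritParams bwoaOptimize
#' @param levy a \linkS4class{LevyConfig}.
#' @param qoblJumpRate per-generation probability of a QOBL jump
#'   (default 0.3); 0 disables QOBL including the initialization sweep.
#' @return As \code{\link{bwoaOptimize}}.
#' @examples
#' cfg <- bwoaConfig(kVar = 2, lower = -5, upper = 5, maxIter = 60,
#'                   nPop = 20, seed = 7)
#' fit <- function(X) -rowSums((X - 1)^2)
#' ibwoaOptimize(cfg, fit)$fitness
#' @export
ibwoaOptimize <- function(cfg, fitnessFn, levy = levyConfig(),
                          qoblJumpRate = 0.3) {
  stopifnot(is(cfg, "BWOAConfig"), is(levy, "LevyConfig"),
            qoblJumpRate >= 0, qoblJumpRate <= 1)
  .bwoaEngine(cfg, fitnessFn, levy = levy, qoblRate = qoblJumpRate)
}
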