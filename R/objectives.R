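# Otsu between-class variance and Kapur entropy objectives over a gray-level
# histogram, evaluated via prefix sums so that every class contributes O(1)
# work, plus an exhaustive-search oracle exact at small k.
#
# Conventions (shared with applyThresholds and both optimizers):
#   * class j spans gray levels th_{j-1}+1 .. th_j, sentinels -1 and L-1,
#     i.e. each threshold belongs to its lower class;
#   * an empty class (omega_j = 0) contributes 0 to either objective;
#   * Kapur entropies use the natural logarithm.

# Prefix-sum context: S[i+1] = sum p_0..p_{i-1}, likewise for i*p and p*ln p.
.prefixContext <- function(h) {
  p <- h@p
  lev <- seq_along(p) - 1
  plogp <- ifelse(p > 0, p * log(p), 0)
  list(S = c(0, cumsum(p)), Sm = c(0, cumsum(lev * p)),
       Se = c(0, cumsum(plogp)), L = length(p), muT = sum(lev * p))
}

# Vectorized objective over the rows of a sorted integer threshold matrix.
# Returns a numeric vector of fitness values, one per row.
.evalThresholdMatrix <- function(ctx, TH, objective) {
  n <- nrow(TH); k <- ncol(TH)
  B <- cbind(rep.int(-1L, n), TH, rep.int(ctx$L - 1L, n))
  f <- numeric(n)
  S <- ctx$S
  if (objective == "otsu") {
    Sm <- ctx$Sm
    for (j in seq_len(k + 1L)) {
      lo <- B[, j] + 1L; hi <- B[, j + 1L]
      w <- S[hi + 2L] - S[lo + 1L]
      m <- Sm[hi + 2L] - Sm[lo + 1L]
      pos <- w > 0
      f[pos] <- f[pos] + m[pos] * m[pos] / w[pos]
    }
    f - ctx$muT * ctx$muT
  } else {
    Se <- ctx$Se
    for (j in seq_len(k + 1L)) {
      lo <- B[, j] + 1L; hi <- B[, j + 1L]
      w <- S[hi + 2L] - S[lo + 1L]
      e <- Se[hi + 2L] - Se[lo + 1L]
      pos <- w > 0
      f[pos] <- f[pos] + log(w[pos]) - e[pos] / w[pos]
    }
    f
  }
}

#' Per-class probability mass and mean
#'
#' For each of the k+1 classes induced by the thresholds, the zeroth-order
#' cumulative moment \eqn{\omega_j = \sum_{i \in C_j} p_i} and class mean
#' \eqn{\mu_j = \sum_{i \in C_j} i p_i / \omega_j}.  An empty class
#' (\eqn{\omega_j = 0}) has \eqn{\mu_j} reported as 0 and is flagged.
#'
#' @param h an \linkS4class{IntensityHistogram}.
#' @param th sorted integer thresholds (may be empty: one class).
#' @return data.frame with columns \code{class}, \code{lower}, \code{upper},
#'   \code{omega}, \code{mu}, \code{empty}.
#' @examples
#' h <- histogramFromProbs(rep(1 / 256, 256))
#' classStatistics(h, 127)
#' @export
classStatistics <- function(h, th) {
  stopifnot(is(h, "IntensityHistogram"))
  L <- length(h@p)
  th <- .checkThresholds(th, L)
  ctx <- .prefixContext(h)
  bounds <- c(-1L, th, L - 1L)
  k1 <- length(th) + 1L
  lo <- bounds[seq_len(k1)] + 1L
  hi <- bounds[seq_len(k1) + 1L]
  w <- ctx$S[hi + 2L] - ctx$S[lo + 1L]
  m <- ctx$Sm[hi + 2L] - ctx$Sm[lo + 1L]
  mu <- ifelse(w > 0, m / w, 0)
  data.frame(class = seq_len(k1), lower = lo, upper = hi,
             omega = w, mu = mu, empty = w == 0)
}

.objectiveResult <- function(h, th, objective) {
  L <- length(h@p)
  th <- .checkThresholds(th, L)
  ctx <- .prefixContext(h)
  TH <- matrix(th, nrow = 1L)
  fit <- if (length(th) == 0L) {
    if (objective == "otsu") 0 else -ctx$Se[L + 1L]
  } else .evalThresholdMatrix(ctx, TH, objective)
  stats <- classStatistics(h, th)
  if (objective == "kapur") {
    # per-class entropy H_j = ln(omega_j) - e_j / omega_j
    bounds <- c(-1L, th, L - 1L)
    k1 <- length(th) + 1L
    e <- ctx$Se[bounds[seq_len(k1) + 1L] + 2L] -
         ctx$Se[bounds[seq_len(k1)] + 2L]
    stats$entropy <- ifelse(stats$omega > 0,
                            log(pmax(stats$omega, .Machine$double.xmin)) -
                              e / pmax(stats$omega, .Machine$double.xmin),
                            0)
  }
  list(fitness = as.numeric(fit), perClass = stats, objective = objective)
}

#' Otsu between-class variance of a threshold vector
#'
#' The weighted squared deviation of the class means from the global mean,
#' \eqn{\sigma_B^2 = \sum_{j=1}^{k+1} \omega_j (\mu_j - \mu_T)^2}, which the
#' optimizers maximize.  Empty classes contribute 0.
#'
#' @param h an \linkS4class{IntensityHistogram}.
#' @param th sorted integer thresholds (an empty vector gives fitness 0).
#' @return list with \code{fitness}, \code{perClass} (data.frame of
#'   \eqn{\omega_j, \mu_j}), \code{objective}.
#' @examples
#' p <- numeric(256); p[c(1, 256)] <- 0.5
#' otsuFitness(histogramFromProbs(p), 128)$fitness  # 16256.25
#' @export
otsuFitness <- function(h, th) {
  stopifnot(is(h, "IntensityHistogram"))
  .objectiveResult(h, th, "otsu")
}

#' Kapur entropy of a threshold vector
#'
#' The sum over classes of the Shannon entropy (natural log) of the
#' normalized within-class distribution,
#' \eqn{H_j = -\sum_{i \in C_j} (p_i/\omega_j) \ln (p_i/\omega_j)}.
#' Zero-probability levels and empty classes contribute 0.  With an empty
#' threshold vector this is the Shannon entropy of the whole histogram.
#'
#' @inheritParams otsuFitness
#' @return list with \code{fitness}, \code{perClass} (including a per-class
#'   \code{entropy} column), \code{objective}.
#' @examples
#' p <- numeric(4); p[] <- 0.25
#' kapurFitness(histogramFromProbs(p), 1)$fitness  # 2 * log(2)
#' @export
kapurFitness <- function(h, th) {
  stopifnot(is(h, "IntensityHistogram"))
  .objectiveResult(h, th, "kapur")
}

# 256 x 256 table of single-class scores: G[a+1, b+1] = score of class a..b
# (m^2/w for Otsu without the -muT^2 constant; w*ln w - e contribution is
# log(w) - e/w... stored directly as the class's additive fitness term).
.classScoreTable <- function(ctx, objective) {
  L <- ctx$L
  a <- rep(0:(L - 1L), times = L)
  b <- rep(0:(L - 1L), each = L)
  w <- ctx$S[b + 2L] - ctx$S[a + 1L]
  if (objective == "otsu") {
    m <- ctx$Sm[b + 2L] - ctx$Sm[a + 1L]
    g <- ifelse(w > 0, m * m / pmax(w, .Machine$double.xmin), 0)
  } else {
    e <- ctx$Se[b + 2L] - ctx$Se[a + 1L]
    g <- ifelse(w > 0, log(pmax(w, .Machine$double.xmin)) -
                         e / pmax(w, .Machine$double.xmin), 0)
  }
  g[b < a] <- 0  # empty class
  matrix(g, L, L)
}

#' Exhaustive-search oracle for optimal thresholds
#'
#' Enumerates all \eqn{C(L-1, k)} sorted threshold vectors and returns the
#' global maximizer of the chosen objective.  Per-class statistics come from
#' prefix sums, so each candidate costs O(k).  Intended as an exact oracle
#' for k of at most 3; beyond that the search space grows combinatorially
#' and the metaheuristic should be used instead.
#'
#' Ties are broken in favor of the lexicographically smallest threshold
#' vector.
#'
#' @param h an \linkS4class{IntensityHistogram}.
#' @param k number of thresholds, 1 to 3.
#' @param objective \code{"otsu"} or \code{"kapur"}.
#' @return A \linkS4class{ThresholdFit} with \code{algorithm = "exhaustive"}.
#' @examples
#' p <- numeric(256); p[c(1, 256)] <- 0.5
#' thresholds(exhaustiveOptimal(histogramFromProbs(p), 1, "otsu"))
#' @export
exhaustiveOptimal <- function(h, k, objective = c("otsu", "kapur")) {
  stopifnot(is(h, "IntensityHistogram"))
  objective <- match.arg(objective)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > 3L)
    stop("exhaustive search supports k <= 3 only; use bwoaOptimize/",
         "ibwoaOptimize for larger k")
  ctx <- .prefixContext(h)
  L <- ctx$L
  G <- .classScoreTable(ctx, objective)
  const <- if (objective == "otsu") -ctx$muT^2 else 0
  topv <- L - 2L  # largest admissible threshold (L-2)
  best <- -Inf; bt <- NULL
  if (k == 1L) {
    # single threshold: evaluate through the shared prefix-sum path so the
    # result is bit-identical to a per-threshold scan
    f <- .evalThresholdMatrix(ctx, matrix(0:topv, ncol = 1L), objective)
    i <- which.max(f)  # first maximum: lexicographic tie-break
    return(new("ThresholdFit", thresholds = i - 1L, fitness = f[i],
               objective = objective, position = as.numeric(i - 1L),
               algorithm = "exhaustive", trace = data.frame()))
  } else {
    # tailv[t + 1] = score of the top class [t+1, L-1], t = 0..topv
    tailv <- G[cbind(2:(topv + 2L), L)]
    if (k == 2L) {
      for (t1 in 0:(topv - 1L)) {
        t2 <- (t1 + 1L):topv
        f <- G[1L, t1 + 1L] + G[t1 + 2L, t2 + 1L] + tailv[t2 + 1L]
        i <- which.max(f)
        if (f[i] > best) { best <- f[i]; bt <- c(t1, t2[i]) }
      }
    } else {
      for (t1 in 0:(topv - 2L)) {
        g1 <- G[1L, t1 + 1L]
        for (t2 in (t1 + 1L):(topv - 1L)) {
          t3 <- (t2 + 1L):topv
          f <- g1 + G[t1 + 2L, t2 + 1L] + G[t2 + 2L, t3 + 1L] +
            tailv[t3 + 1L]
          i <- which.max(f)
          if (f[i] > best) { best <- f[i]; bt <- c(t1, t2, t3[i]) }
        }
      }
    }
  }
  # re-evaluate the winner through the shared path: the score-table sums
  # can differ from it in the last ulp, and downstream comparisons expect
  # oracle fitness and evaluator fitness to agree exactly
  fitness <- .evalThresholdMatrix(ctx, matrix(as.integer(bt), nrow = 1L),
                                  objective)
  new("ThresholdFit", thresholds = as.integer(bt),
      fitness = fitness, objective = objective,
      position = as.numeric(bt), algorithm = "exhaustive",
      trace = data.frame())
}

#' Build a vectorized thresholding fitness function
#'
#' Returns a function mapping a matrix of real-valued positions (one row per
#' candidate, k columns) to the objective value of the decoded threshold
#' vector.  Decoding clamps to \code{[0, L-2]}, rounds to integers and sorts
#' each row; duplicate thresholds after rounding simply yield an empty class
#' (contributing 0), so the search space needs no constraint handling.
#'
#' @param h an \linkS4class{IntensityHistogram}.
#' @param objective \code{"otsu"} or \code{"kapur"}.
#' @return function(X) -> numeric vector of fitness values, with an
#'   attribute-free decoded-threshold helper available via
#'   \code{attr(fn, "decode")}.
#' @export
thresholdFitness <- function(h, objective = c("otsu", "kapur")) {
  stopifnot(is(h, "IntensityHistogram"))
  objective <- match.arg(objective)
  ctx <- .prefixContext(h)
  topv <- ctx$L - 2L
  decode <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    TH <- matrix(as.integer(round(pmin(pmax(X, 0), topv))),
                 nrow(X), ncol(X))
    .sortRows(TH)
  }
  fn <- function(X) {
    .evalThresholdMatrix(ctx, decode(X), objective)
  }
  attr(fn, "decode") <- decode
  fn
}

# row-wise sort specialised for k <= 3 (sorting networks); general fallback
.sortRows <- function(TH) {
  k <- ncol(TH)
  if (k == 1L) return(TH)
  if (k == 2L) {
    a <- pmin.int(TH[, 1L], TH[, 2L]); b <- pmax.int(TH[, 1L], TH[, 2L])
    return(cbind(a, b, deparse.level = 0))
  }
  if (k == 3L) {
    a <- TH[, 1L]; b <- TH[, 2L]; c <- TH[, 3L]
    lo <- pmin.int(a, b); hi <- pmax.int(a, b)
    m2 <- pmin.int(hi, c); hi2 <- pmax.int(hi, c)
    lo2 <- pmin.int(lo, m2); m3 <- pmax.int(lo, m2)
    return(cbind(lo2, m3, hi2, deparse.level = 0))
  }
  t(apply(TH, 1L, sort))
}
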