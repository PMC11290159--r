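# Synthetic thermogram-like fixtures: Gaussian intensity mixtures rendered
# as nested elliptical regions (hot core, cooler surround) so that both the
# histogram-level contracts (mode masses) and the spatial structure needed
# by gradient/phase metrics exist.  Everything is seeded and reproducible.

# deterministic radial field: mildly anisotropic, mildly lobed ellipse
.radialField <- function(height, width, seed) {
  rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  cx <- width * stats::runif(1, 0.42, 0.58)
  cy <- height * stats::runif(1, 0.42, 0.58)
  ax <- stats::runif(1, 0.8, 1.25)
  phase <- stats::runif(1, 0, 2 * pi)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  dx <- (x - cx) / ax; dy <- (y - cy) * ax
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  r * (1 + 0.08 * sin(3 * phi + phase))
}

# discrete per-level probabilities of clamp(round(N(mean, sd)), 0, 255):
# interior levels take the rounding-bin mass, levels 0 and 255 absorb the
# tails, so the sampled histogram converges to this exactly.
.modeLevelProbs <- function(mean, sd) {
  g <- 0:255
  up <- stats::pnorm(g + 0.5, mean, sd)
  lo <- stats::pnorm(g - 0.5, mean, sd)
  p <- up - lo
  p[1L] <- up[1L]
  p[256L] <- 1 - lo[256L]
  p
}

#' Generate a synthetic thermogram-like image
#'
#' Pixels are partitioned into nested elliptical regions with areas
#' proportional to the mode weights (the mode whose mean is farthest from
#' the background level forms the core; the mode nearest the background the
#' outermost surround).  Each region's pixel values are stratified draws
#' from its mode's Gaussian (jittered quantiles in random spatial order),
#' rounded and clamped to \code{[0, 255]}, so each mode's histogram mass
#' matches its weight up to boundary rounding and the image histogram
#' converges rapidly to \code{\link{generateHistogram}}'s analytic form.
#'
#' @param spec a \linkS4class{MixtureSpec}.
#' @return A \linkS4class{GrayImage}.
#' @examples
#' img <- generateImage(mixtureSpec(c(80, 180), c(12, 12), seed = 3))
#' @export
generateImage <- function(spec) {
  stopifnot(is(spec, "MixtureSpec"))
  m <- spec@modes
  h <- spec@height; w <- spec@width
  n <- h * w
  ord <- order(abs(m$mean - spec@background), decreasing = TRUE)  # core first
  r <- .radialField(h, w, spec@seed)
  rk <- rank(r, ties.method = "first")
  # cumulative pixel counts per region, inner -> outer
  cum <- round(cumsum(m$weight[ord]) * n)
  cum[length(cum)] <- n
  region <- findInterval(rk, c(0, cum), left.open = TRUE)
  set.seed(spec@seed + 1L)
  px <- integer(n)
  for (j in seq_len(nrow(m))) {
    idx <- which(region == j)
    nj <- length(idx)
    if (!nj) next
    # stratified inverse-CDF sampling: one jittered quantile per pixel,
    # shuffled spatially, so the empirical histogram tracks the analytic
    # mixture at O(1/n) rather than O(1/sqrt(n))
    u <- (seq_len(nj) - stats::runif(nj)) / nj
    v <- round(stats::qnorm(u, m$mean[ord[j]], m$sd[ord[j]]))
    px[idx] <- pmin(pmax(v[sample.int(nj)], 0), 255)
  }
  grayImage(matrix(as.integer(px), h, w))
}

#' Analytic histogram of a mixture specification
#'
#' The mixture density discretized to 256 levels exactly as
#' \code{\link{generateImage}} samples it (rounding bins, tails clamped
#' into levels 0 and 255), with no sampling noise.  Useful for fast, exact
#' oracle and optimizer tests.
#'
#' @param spec a \linkS4class{MixtureSpec}.
#' @return An \linkS4class{IntensityHistogram}.
#' @export
generateHistogram <- function(spec) {
  stopifnot(is(spec, "MixtureSpec"))
  m <- spec@modes
  p <- numeric(256)
  for (j in seq_len(nrow(m)))
    p <- p + m$weight[j] * .modeLevelProbs(m$mean[j], m$sd[j])
  histogramFromProbs(p)
}

#' Generate a reproducible fixture corpus with oracle answers
#'
#' Builds \code{n} well-separated, equal-weight mixture images (cycling
#' through 2, 3 and 4 modes), computes each image's histogram, and caches
#' the exhaustive-search optimum for every requested (k, objective)
#' combination.  Optionally serializes each fixture as PNG plus a JSON
#' sidecar (spec and oracle answers).
#'
#' @param n number of fixtures.
#' @param seed corpus seed; fixture i uses \code{seed + i}.
#' @param ks threshold counts to solve exactly (subset of 1:3).
#' @param objectives objectives to solve.
#' @param dir optional output directory for PNG + JSON serialization.
#' @param width,height fixture image size.
#' @return list of fixtures, each with elements \code{name}, \code{spec},
#'   \code{image}, \code{histogram} and \code{oracle} (nested list:
#'   \code{oracle[[objective]][[as.character(k)]]} is a
#'   \linkS4class{ThresholdFit}).
#' @export
fixtureSuite <- function(n = 20L, seed = 1L, ks = 1:3,
                         objectives = c("otsu", "kapur"), dir = NULL,
                         width = 128L, height = 128L) {
  stopifnot(n >= 1L, all(ks %in% 1:3))
  rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  nmodesSeq <- rep_len(c(2L, 3L, 4L), n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- nmodesSeq[i]
    centers <- seq(45, 215, length.out = nm)
    means <- centers + stats::runif(nm, -8, 8)
    sds <- stats::runif(nm, 8, 14)
    specs[[i]] <- mixtureSpec(means, sds, width = width, height = height,
                              seed = seed + i)
  }
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())

  out <- vector("list", n)
  for (i in seq_len(n)) {
    img <- generateImage(specs[[i]])
    hst <- computeHistogram(img)
    oracle <- list()
    for (obj in objectives) {
      oracle[[obj]] <- list()
      for (k in ks)
        oracle[[obj]][[as.character(k)]] <- exhaustiveOptimal(hst, k, obj)
    }
    name <- sprintf("fixture_%02d_m%d", i, nmodesSeq[i])
    out[[i]] <- list(name = name, spec = specs[[i]], image = img,
                     histogram = hst, oracle = oracle)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeGrayImage(img, file.path(dir, paste0(name, ".png")))
      side <- list(
        modes = specs[[i]]@modes, seed = specs[[i]]@seed,
        width = specs[[i]]@width, height = specs[[i]]@height,
        oracle = lapply(oracle, function(oo) lapply(oo, function(f)
          list(thresholds = f@thresholds, fitness = f@fitness))))
      jsonlite::write_json(side, file.path(dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
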