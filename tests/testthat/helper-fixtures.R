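# shared fixtures, built in code

# two point masses at 0 and 255
twoPointHistogram <- function() {
  p <- numeric(256); p[c(1L, 256L)] <- 0.5
  histogramFromProbs(p)
}

uniformHistogram <- function(L = 256L) histogramFromProbs(rep(1 / L, L))

randomHistogram <- function(L = 256L) {
  p <- stats::rexp(L)
  # sprinkle structural zeros like a real sparse histogram
  p[sample.int(L, L %/% 4L)] <- 0
  if (sum(p) == 0) p[1L] <- 1
  histogramFromProbs(p)
}

randomImage <- function(nr = 16L, nc = 16L) {
  grayImage(matrix(sample.int(256L, nr * nc, replace = TRUE) - 1L, nr, nc))
}

# independent (definition-level) objective implementations used as oracles;
# deliberately plain-sum, no prefix machinery
directOtsu <- function(p, th) {
  L <- length(p); lev <- seq_len(L) - 1
  bounds <- c(-1L, th, L - 1L)
  muT <- sum(lev * p)
  f <- 0
  for (j in seq_len(length(th) + 1L)) {
    idx <- which(lev > bounds[j] & lev <= bounds[j + 1L])
    w <- sum(p[idx])
    if (w > 0) {
      mu <- sum(lev[idx] * p[idx]) / w
      f <- f + w * (mu - muT)^2
    }
  }
  f
}

directKapur <- function(p, th) {
  L <- length(p); lev <- seq_len(L) - 1
  bounds <- c(-1L, th, L - 1L)
  f <- 0
  for (j in seq_len(length(th) + 1L)) {
    idx <- which(lev > bounds[j] & lev <= bounds[j + 1L])
    w <- sum(p[idx])
    if (w > 0) {
      q <- p[idx][p[idx] > 0] / w
      f <- f - sum(q * log(q))
    }
  }
  f
}

# the 20-image corpus used by the acceptance experiments; built once per
# test session
.suiteCache <- new.env(parent = emptyenv())
acceptanceSuite <- function() {
  if (is.null(.suiteCache$suite))
    .suiteCache$suite <- fixtureSuite(20, seed = 1)
  .suiteCache$suite
}
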