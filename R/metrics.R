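# Full-reference quality metrics between an original image and its
# thresholded reconstruction: RMSE, PSNR, SSIM (whole-image statistics, with
# an optional windowed mode), and FSIM built on a log-Gabor phase-congruency
# map.

.checkSameDim <- function(a, b) {
  stopifnot(is(a, "GrayImage"), is(b, "GrayImage"))
  if (!identical(dim(a@.Data), dim(b@.Data)))
    stop("images must have identical dimensions")
}

#' Root-mean-square error between two images
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_{ij} (a_{ij} - b_{ij})^2 / (MN)}}.
#'
#' @param a,b \linkS4class{GrayImage}s of identical size.
#' @return numeric scalar >= 0.
#' @export
imageRMSE <- function(a, b) {
  .checkSameDim(a, b)
  sqrt(mean((as.numeric(a@.Data) - as.numeric(b@.Data))^2))
}

#' Peak signal-to-noise ratio in dB
#'
#' \eqn{\mathrm{PSNR} = 20 \log_{10}(255 / \mathrm{RMSE})}; identical
#' images give \code{Inf}.
#'
#' @inheritParams imageRMSE
#' @return numeric scalar in dB (possibly \code{Inf}).
#' @export
imagePSNR <- function(a, b) {
  r <- imageRMSE(a, b)
  if (r == 0) Inf else 20 * log10(255 / r)
}

#' Structural similarity index
#'
#' Single-statistic SSIM computed from whole-image moments:
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_a\mu_b + C_1)(2\sigma_{ab} + C_2)}
#'   {(\mu_a^2 + \mu_b^2 + C_1)(\sigma_a^2 + \sigma_b^2 + C_2)}}
#' with the 8-bit stabilizers \eqn{C_1 = (0.01 \cdot 255)^2 = 6.5025} and
#' \eqn{C_2 = (0.03 \cdot 255)^2 = 58.5225}.  Variances and the covariance
#' are population moments (divide by MN).  \code{windowed = TRUE} instead
#' averages local SSIM over an 11x11 Gaussian window (sd 1.5), the common
#' mean-SSIM construction, for cross-checking against windowed
#' implementations.
#'
#' @inheritParams imageRMSE
#' @param windowed compute mean local SSIM instead of the global statistic.
#' @param C1,C2 stabilizing constants.
#' @return numeric scalar in \code{[-1, 1]}.
#' @export
imageSSIM <- function(a, b, windowed = FALSE, C1 = 6.5025, C2 = 58.5225) {
  .checkSameDim(a, b)
  x <- a@.Data * 1.0; y <- b@.Data * 1.0
  if (!windowed) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  kern <- stats::dnorm(-5:5, sd = 1.5); kern <- kern / sum(kern)
  smooth <- function(z) .sepConv(z, kern)
  mx <- smooth(x); my <- smooth(y)
  vx <- smooth(x * x) - mx^2; vy <- smooth(y * y) - my^2
  cxy <- smooth(x * y) - mx * my
  mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}

# separable 2-D convolution with edge-replicated padding
.sepConv <- function(z, kern) {
  r <- (length(kern) - 1L) %/% 2L
  nr <- nrow(z); nc <- ncol(z)
  ri <- pmin(pmax(seq(1L - r, nr + r), 1L), nr)
  ci <- pmin(pmax(seq(1L - r, nc + r), 1L), nc)
  P <- z[ri, ci, drop = FALSE]
  acc <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(kern))
    acc <- acc + kern[i] * P[seq_len(nr) + i - 1L, , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(kern))
    out <- out + kern[i] * acc[, seq_len(nc) + i - 1L, drop = FALSE]
  out
}

# 3x3 convolution with edge replication, vectorized over matrix shifts
.conv3 <- function(z, kern) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    w <- kern[di + 2L, dj + 2L]
    if (w == 0) next
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    out <- out + w * z[ri, ci]
  }
  out
}

# Scharr gradient magnitude
.gradientMagnitude <- function(z) {
  kx <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3, 3, byrow = TRUE) / 16
  sqrt(.conv3(z, kx)^2 + .conv3(z, t(kx))^2)
}

#' Phase congruency map
#'
#' Per-pixel phase congruency in \code{[0, 1]} computed with a multi-scale
#' log-Gabor filter bank: local energy (where Fourier components are
#' maximally in phase) normalized by the summed filter response amplitudes,
#' with noise compensation estimated from the smallest-scale response and a
#' sigmoid weighting of the filter-response spread.  A constant image has
#' no phase structure and maps to (numerically) zero everywhere.
#'
#' @param img a \linkS4class{GrayImage}, at least 16 x 16.
#' @param nscale,norient number of wavelet scales and orientations.
#' @param minWavelength wavelength of the smallest-scale filter, pixels.
#' @param mult scaling factor between successive scales.
#' @param sigmaOnf bandwidth parameter of the log-Gabor radial component
#'   (ratio of sd of the Gaussian describing the filter's log-frequency
#'   response to the filter center frequency).
#' @param k number of noise standard deviations for the energy threshold.
#' @param cutOff,g parameters of the frequency-spread sigmoid weight.
#' @return numeric matrix of per-pixel phase congruency in \code{[0, 1]}.
#' @export
phaseCongruency <- function(img, nscale = 4L, norient = 4L,
                            minWavelength = 6, mult = 2, sigmaOnf = 0.55,
                            k = 2, cutOff = 0.5, g = 10) {
  stopifnot(is(img, "GrayImage"))
  z <- img@.Data * 1.0
  if (nrow(z) < 16L || ncol(z) < 16L)
    stop("phase congruency needs an image of at least 16 x 16")
  nr <- nrow(z); nc <- ncol(z)
  eps <- 1e-4

  fftfreq <- function(n) {
    c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L)) / n
  }
  fy <- matrix(fftfreq(nr), nr, nc)
  fx <- matrix(fftfreq(nc), nr, nc, byrow = TRUE)
  radius <- sqrt(fx^2 + fy^2); radius[1L, 1L] <- 1
  theta <- atan2(-fy, fx)
  sintheta <- sin(theta); costheta <- cos(theta)
  lp <- 1 / (1 + (radius / 0.45)^30)  # suppress extreme frequencies

  logGabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    fo <- 1 / (minWavelength * mult^(s - 1))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigmaOnf)^2)) * lp
    lg[1L, 1L] <- 0
    logGabor[[s]] <- lg
  }

  IM <- stats::fft(z)
  thetaSigma <- pi / norient / 1.5
  pcSum <- matrix(0, nr, nc)
  anTot <- matrix(0, nr, nc)

  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * thetaSigma^2))

    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumAn <- matrix(0, nr, nc); maxAn <- matrix(0, nr, nc)
    eS <- vector("list", nscale); oS <- vector("list", nscale)
    tau <- 0
    for (s in seq_len(nscale)) {
      filt <- logGabor[[s]] * spread
      EO <- stats::fft(IM * filt, inverse = TRUE) / length(z)
      e <- Re(EO); od <- Im(EO)
      An <- sqrt(e^2 + od^2)
      eS[[s]] <- e; oS[[s]] <- od
      sumE <- sumE + e; sumO <- sumO + od
      sumAn <- sumAn + An
      if (s == 1L) {
        tau <- stats::median(An) / sqrt(log(4))
        maxAn <- An
      } else maxAn <- pmax(maxAn, An)
    }

    XEnergy <- sqrt(sumE^2 + sumO^2) + eps
    MeanE <- sumE / XEnergy; MeanO <- sumO / XEnergy
    Energy <- matrix(0, nr, nc)
    for (s in seq_len(nscale))
      Energy <- Energy + eS[[s]] * MeanE + oS[[s]] * MeanO -
        abs(eS[[s]] * MeanO - oS[[s]] * MeanE)

    # Rayleigh-based noise energy threshold from the smallest-scale tau
    totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - (1 / mult))
    noiseMean <- totalTau * sqrt(pi / 2)
    noiseSigma <- totalTau * sqrt((4 - pi) / 2)
    Energy <- pmax(Energy - (noiseMean + k * noiseSigma), 0)

    width <- sumAn / (maxAn + eps) / nscale
    weight <- 1 / (1 + exp(g * (cutOff - width)))

    pcSum <- pcSum + weight * Energy
    anTot <- anTot + sumAn
  }
  pc <- pcSum / (anTot + eps)
  pmin(pmax(pc, 0), 1)
}

#' Feature similarity index
#'
#' Combines phase-congruency similarity
#' \eqn{S_{PC} = (2 PC_1 PC_2 + T_1)/(PC_1^2 + PC_2^2 + T_1)} and gradient
#' similarity \eqn{S_G = (2 G_1 G_2 + T_2)/(G_1^2 + G_2^2 + T_2)} (Scharr
#' gradients) into \eqn{S_L = S_{PC} S_G}, then averages weighted by
#' \eqn{PC_m = \max(PC_1, PC_2)}:
#' \eqn{\mathrm{FSIM} = \sum S_L PC_m / \sum PC_m}.  Defaults
#' \eqn{T_1 = 0.85}, \eqn{T_2 = 160} are the published 8-bit constants.
#'
#' @inheritParams imageRMSE
#' @param T1,T2 stabilizing constants for the phase-congruency and gradient
#'   terms.
#' @param ... further arguments passed to \code{\link{phaseCongruency}}.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
imageFSIM <- function(a, b, T1 = 0.85, T2 = 160, ...) {
  .checkSameDim(a, b)
  pc1 <- phaseCongruency(a, ...)
  pc2 <- phaseCongruency(b, ...)
  pcm <- pmax(pc1, pc2)
  if (sum(pcm) < 1e-12)
    stop("FSIM undefined: no phase structure in either image ",
         "(both images constant?)")
  g1 <- .gradientMagnitude(a@.Data * 1.0)
  g2 <- .gradientMagnitude(b@.Data * 1.0)
  spc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  sg <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  sum(spc * sg * pcm) / sum(pcm)
}

#' Assemble a QualityReport for a pair of images
#'
#' Computes RMSE, PSNR, SSIM and (for images of at least 16 x 16) FSIM
#' between an original image and a reconstruction.  FSIM is reported as
#' \code{NA} when it cannot be computed (too-small or degenerate images).
#'
#' @inheritParams imageRMSE
#' @param windowedSSIM use the windowed mean-SSIM variant.
#' @return A \linkS4class{QualityReport}.
#' @examples
#' sp <- mixtureSpec(c(80, 180), c(12, 12))
#' img <- generateImage(sp)
#' seg <- applyThresholds(img, 128, mode = "class-mean")
#' qualityReport(img, seg)
#' @export
qualityReport <- function(a, b, windowedSSIM = FALSE) {
  .checkSameDim(a, b)
  fs <- if (nrow(a@.Data) >= 16L && ncol(a@.Data) >= 16L)
    tryCatch(imageFSIM(a, b), error = function(e) NA_real_)
  else NA_real_
  new("QualityReport", rmse = imageRMSE(a, b), psnr = imagePSNR(a, b),
      ssim = imageSSIM(a, b, windowed = windowedSSIM), fsim = fs)
}

#' Serialize a QualityReport to JSON
#'
#' @param report a \linkS4class{QualityReport}.
#' @param path output path.
#' @param ... extra fields (e.g. image name, objective, k) stored alongside
#'   the metrics.
#' @return \code{path}, invisibly.
#' @export
writeQualityReport <- function(report, path, ...) {
  x <- c(list(rmse = report@rmse,
              psnr = if (is.finite(report@psnr)) report@psnr else "Inf",
              ssim = report@ssim, fsim = report@fsim),
         list(...))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
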