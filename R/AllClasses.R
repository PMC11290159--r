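#' @import methods
NULL

#' GrayImage: an 8-bit (or general L-level) grayscale image
#'
#' A matrix of integer pixel intensities in \code{[0, L-1]}, row-major with
#' origin top-left.  \code{L} defaults to 256 (8-bit).
#'
#' @slot .Data integer matrix of pixel intensities.
#' @slot levels integer, the number of gray levels L.
#' @exportClass GrayImage
setClass("GrayImage",
  contains = "matrix",
  representation(levels = "integer"),
  prototype(levels = 256L)
)

setValidity("GrayImage", function(object) {
  px <- object@.Data
  if (length(dim(px)) != 2L || nrow(px) < 1L || ncol(px) < 1L)
    return("pixels must form an M x N matrix with M >= 1, N >= 1")
  if (length(object@levels) != 1L || is.na(object@levels) || object@levels < 2L)
    return("levels must be a single integer >= 2")
  if (anyNA(px)) return("pixels must not contain NA")
  if (any(px != as.integer(px))) return("pixels must be integer-valued")
  if (min(px) < 0L || max(px) > object@levels - 1L)
    return(sprintf("pixels must lie in [0, %d]", object@levels - 1L))
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric or integer matrix of intensities in \code{[0, L-1]}.
#' @param levels number of gray levels L (default 256).
#' @return A \linkS4class{GrayImage}.
#' @examples
#' img <- grayImage(matrix(c(0, 0, 255, 255), 2, 2))
#' @export
grayImage <- function(pixels, levels = 256L) {
  if (is.null(dim(pixels))) stop("pixels must be a matrix")
  if (is.double(pixels)) {
    if (anyNA(pixels) || any(pixels != floor(pixels)))
      stop("pixels must be integer-valued")
  }
  storage.mode(pixels) <- "integer"
  new("GrayImage", pixels, levels = as.integer(levels))
}

#' IntensityHistogram: per-level counts and probabilities
#'
#' Gray-level occupancy of an image: counts \eqn{n_i}, probabilities
#' \eqn{p_i = n_i / N} with \eqn{\sum_i p_i = 1}, for levels
#' \eqn{i = 0, \dots, L-1}.  Histograms may also be purely analytic
#' (probabilities without integer counts), in which case \code{counts} is
#' zero-length and \code{nPixels} is 0.
#'
#' @slot p numeric vector of length L, the probability of each gray level.
#' @slot counts integer vector of per-level pixel counts (may be empty for
#'   analytic histograms).
#' @slot nPixels integer, total number of pixels (0 for analytic histograms).
#' @exportClass IntensityHistogram
setClass("IntensityHistogram",
  representation(p = "numeric", counts = "integer", nPixels = "integer"))

setValidity("IntensityHistogram", function(object) {
  if (length(object@p) < 2L) return("p must have length L >= 2")
  if (any(object@p < 0)) return("probabilities must be non-negative")
  if (abs(sum(object@p) - 1) > 1e-12) return("probabilities must sum to 1")
  if (length(object@counts)) {
    if (length(object@counts) != length(object@p))
      return("counts and p must have equal length")
    if (any(object@counts < 0L)) return("counts must be non-negative")
    if (sum(object@counts) != object@nPixels)
      return("counts must sum to nPixels")
    if (max(abs(object@p - object@counts / object@nPixels)) > 1e-12)
      return("p must equal counts / nPixels")
  }
  TRUE
})

#' BWOAConfig: Black Widow Optimization run configuration
#'
#' Hyperparameters of the BWOA/IBWOA lifecycle.  Defaults follow the usual
#' protocol for multilevel thresholding: population 50, 350 iterations,
#' procreating (crossover) rate 0.8, cannibalism rate 0.5, mutation rate 0.4.
#'
#' @slot nPop population size (>= 4).
#' @slot maxIter maximum number of generations.
#' @slot procreateRate fraction PP of the population admitted to the
#'   breeding pool each generation.
#' @slot cannibalismRate fraction CR of each brood surviving sibling
#'   cannibalism (the \code{ceiling(CR * n)} best offspring are kept).
#' @slot mutationRate fraction PM of widows mutated per generation.
#' @slot nOffspring offspring per mating pair (even integer).
#' @slot mutationStrategy \code{"reset"} (redraw one component uniformly in
#'   bounds) or \code{"swap"} (exchange two components).
#' @slot lower,upper numeric per-dimension box bounds.
#' @slot seed integer RNG seed for the run.
#' @slot stopRule \code{"max_iter"}, \code{"fitness_stall"} or
#'   \code{"target_fitness"}.
#' @slot stallPatience,stallTol,targetFitness parameters of the optional
#'   early-stopping rules.
#' @exportClass BWOAConfig
setClass("BWOAConfig",
  representation(nPop = "integer", maxIter = "integer",
    procreateRate = "numeric", cannibalismRate = "numeric",
    mutationRate = "numeric", nOffspring = "integer",
    mutationStrategy = "character",
    lower = "numeric", upper = "numeric", seed = "integer",
    stopRule = "character", stallPatience = "integer",
    stallTol = "numeric", targetFitness = "numeric"))

setValidity("BWOAConfig", function(object) {
  if (object@nPop < 4L) return("nPop must be >= 4")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  for (r in c(object@procreateRate, object@cannibalismRate,
              object@mutationRate))
    if (r < 0 || r > 1) return("rates must lie in [0, 1]")
  if (object@nOffspring < 2L || object@nOffspring %% 2L != 0L)
    return("nOffspring must be an even integer >= 2")
  if (!object@mutationStrategy %in% c("reset", "swap"))
    return("mutationStrategy must be 'reset' or 'swap'")
  if (length(object@lower) != length(object@upper))
    return("lower and upper must have equal length")
  if (!all(is.finite(object@lower)) || !all(is.finite(object@upper)))
    return("bounds must be finite")
  if (any(object@lower >= object@upper))
    return("lower must be strictly below upper in every dimension")
  if (!object@stopRule %in% c("max_iter", "fitness_stall", "target_fitness"))
    return("unknown stopRule")
  TRUE
})

#' Construct a BWOAConfig
#'
#' @param kVar problem dimension (used to replicate scalar bounds; ignored
#'   when \code{lower}/\code{upper} are full-length vectors).
#' @param lower,upper box bounds, scalars or vectors of length \code{kVar}.
#' @param nPop population size.
#' @param maxIter generations to run.
#' @param procreateRate,cannibalismRate,mutationRate lifecycle rates PP, CR,
#'   PM.
#' @param nOffspring offspring per pair; default \code{max(2, 2 *
#'   ceiling(kVar / 2))}.
#' @param mutationStrategy \code{"reset"} or \code{"swap"}.
#' @param seed RNG seed.
#' @param stopRule,stallPatience,stallTol,targetFitness stopping rule; the
#'   default runs all \code{maxIter} generations.
#' @return A \linkS4class{BWOAConfig}.
#' @examples
#' cfg <- bwoaConfig(kVar = 2, lower = 0, upper = 254, maxIter = 50)
#' @export
bwoaConfig <- function(kVar = length(lower), lower = 0, upper = 1,
                       nPop = 50L, maxIter = 350L,
                       procreateRate = 0.8, cannibalismRate = 0.5,
                       mutationRate = 0.4,
                       nOffspring = max(2L, 2L * as.integer(ceiling(kVar / 2))),
                       mutationStrategy = "reset", seed = 1L,
                       stopRule = "max_iter", stallPatience = 50L,
                       stallTol = 0, targetFitness = NA_real_) {
  kVar <- as.integer(kVar)
  if (length(lower) == 1L) lower <- rep(as.numeric(lower), kVar)
  if (length(upper) == 1L) upper <- rep(as.numeric(upper), kVar)
  new("BWOAConfig", nPop = as.integer(nPop), maxIter = as.integer(maxIter),
      procreateRate = procreateRate, cannibalismRate = cannibalismRate,
      mutationRate = mutationRate, nOffspring = as.integer(nOffspring),
      mutationStrategy = mutationStrategy,
      lower = as.numeric(lower), upper = as.numeric(upper),
      seed = as.integer(seed), stopRule = stopRule,
      stallPatience = as.integer(stallPatience), stallTol = stallTol,
      targetFitness = as.numeric(targetFitness))
}

#' LevyConfig: Mantegna Levy-flight step parameters
#'
#' @slot beta stability index in \code{[1, 2]}; 1.5 is the customary choice.
#' @slot scale multiplier applied to each raw Levy step (0.01 by default).
#' @exportClass LevyConfig
setClass("LevyConfig", representation(beta = "numeric", scale = "numeric"))

setValidity("LevyConfig", function(object) {
  if (object@beta < 1 || object@beta > 2) return("beta must lie in [1, 2]")
  if (!is.finite(object@scale)) return("scale must be finite")
  TRUE
})

#' Construct a LevyConfig
#'
#' @param beta stability index in \code{[1, 2]}.
#' @param scale step-size multiplier.
#' @return A \linkS4class{LevyConfig}.
#' @export
levyConfig <- function(beta = 1.5, scale = 0.01)
  new("LevyConfig", beta = beta, scale = scale)

#' ThresholdFit: result of a thresholding optimization
#'
#' @slot thresholds sorted integer threshold vector.
#' @slot fitness objective value at the returned thresholds.
#' @slot objective \code{"otsu"} or \code{"kapur"}.
#' @slot position raw (real-valued) best position, for metaheuristic runs.
#' @slot algorithm \code{"bwoa"}, \code{"ibwoa"} or \code{"exhaustive"}.
#' @slot trace per-iteration convergence data.frame with columns
#'   \code{iteration}, \code{bestFitness}, \code{meanFitness}, plus the best
#'   position components (empty for the exhaustive oracle).
#' @exportClass ThresholdFit
setClass("ThresholdFit",
  representation(thresholds = "integer", fitness = "numeric",
    objective = "character", position = "numeric",
    algorithm = "character", trace = "data.frame"))

setValidity("ThresholdFit", function(object) {
  th <- object@thresholds
  if (length(th) && is.unsorted(th, strictly = TRUE))
    return("thresholds must be strictly increasing")
  if (nrow(object@trace) &&
      is.unsorted(object@trace$bestFitness))
    return("best fitness must be non-decreasing along the trace")
  TRUE
})

#' QualityReport: full-reference segmentation quality metrics
#'
#' RMSE, PSNR (dB), SSIM and FSIM between an original image and its
#' class-mean (or class-midpoint) reconstruction.  \code{psnr} is \code{Inf}
#' when the images are identical (RMSE 0).
#'
#' @slot rmse root-mean-square error, >= 0.
#' @slot psnr peak signal-to-noise ratio in dB (possibly \code{Inf}).
#' @slot ssim structural similarity in \code{[-1, 1]}.
#' @slot fsim feature similarity in \code{[0, 1]} (may be \code{NA} when not
#'   computed).
#' @exportClass QualityReport
setClass("QualityReport",
  representation(rmse = "numeric", psnr = "numeric", ssim = "numeric",
                 fsim = "numeric"))

setValidity("QualityReport", function(object) {
  if (object@rmse < 0) return("rmse must be >= 0")
  if (is.finite(object@psnr) && object@rmse == 0)
    return("psnr must be Inf when rmse is 0")
  if (!is.na(object@ssim) && (object@ssim < -1 - 1e-9 ||
                              object@ssim > 1 + 1e-9))
    return("ssim must lie in [-1, 1]")
  TRUE
})

#' MixtureSpec: specification of a synthetic thermogram-like image
#'
#' A Gaussian intensity mixture on \code{[0, 255]} rendered as smooth nested
#' elliptical regions (hot core, cooler surround), emulating the multimodal
#' histograms of breast thermograms.
#'
#' @slot modes data.frame with columns \code{mean}, \code{sd}, \code{weight};
#'   weights sum to 1.
#' @slot width,height image dimensions.
#' @slot background nominal background gray level; the mode nearest to it is
#'   rendered outermost.
#' @slot seed RNG seed used when sampling pixel values.
#' @exportClass MixtureSpec
setClass("MixtureSpec",
  representation(modes = "data.frame", width = "integer", height = "integer",
                 background = "numeric", seed = "integer"))

setValidity("MixtureSpec", function(object) {
  m <- object@modes
  if (!all(c("mean", "sd", "weight") %in% names(m)))
    return("modes must have columns mean, sd, weight")
  if (nrow(m) < 1L || nrow(m) > 6L)
    return("between 1 and 6 modes are supported")
  if (any(m$mean < 0 | m$mean > 255)) return("mode means must lie in [0, 255]")
  if (any(m$sd <= 0)) return("mode sds must be > 0")
  if (any(m$weight <= 0)) return("mode weights must be > 0")
  if (abs(sum(m$weight) - 1) > 1e-9) return("mode weights must sum to 1")
  if (object@width < 8L || object@height < 8L)
    return("image must be at least 8 x 8")
  TRUE
})

#' Construct a MixtureSpec
#'
#' @param means,sds,weights mode parameters; \code{weights} are normalized
#'   to sum to 1.
#' @param width,height image size in pixels.
#' @param background nominal background gray level.
#' @param seed sampling seed.
#' @return A \linkS4class{MixtureSpec}.
#' @examples
#' sp <- mixtureSpec(means = c(80, 180), sds = c(12, 12))
#' @export
mixtureSpec <- function(means, sds, weights = rep(1, length(means)),
                        width = 128L, height = 128L, background = 0,
                        seed = 1L) {
  w <- weights / sum(weights)
  new("MixtureSpec",
      modes = data.frame(mean = as.numeric(means), sd = as.numeric(sds),
                         weight = w),
      width = as.integer(width), height = as.integer(height),
      background = as.numeric(background), seed = as.integer(seed))
}
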