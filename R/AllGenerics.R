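#' Accessors for widowseg classes
#'
#' Small accessor generics: \code{nLevels} (gray levels of an image or
#' histogram), \code{probs} (per-level probabilities), \code{levelCounts}
#' (per-level pixel counts), \code{nPixels}, \code{thresholds},
#' \code{fitnessValue}, \code{objectiveName}, \code{convergenceTrace}, and
#' \code{modes} (mixture components of a \linkS4class{MixtureSpec}).
#'
#' @param x an object of the appropriate class.
#' @return The slot contents (vector, scalar or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname accessors
#' @export
setGeneric("levelCounts", function(x) standardGeneric("levelCounts"))

#' @rdname accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("fitnessValue", function(x) standardGeneric("fitnessValue"))

#' @rdname accessors
#' @export
setGeneric("objectiveName", function(x) standardGeneric("objectiveName"))

#' @rdname accessors
#' @export
setGeneric("convergenceTrace", function(x) standardGeneric("convergenceTrace"))

#' @rdname accessors
#' @export
setGeneric("modes", function(x) standardGeneric("modes"))

#' @rdname accessors
#' @export
setMethod("nLevels", "GrayImage", function(x) x@levels)

#' @rdname accessors
#' @export
setMethod("nLevels", "IntensityHistogram", function(x) length(x@p))

#' @rdname accessors
#' @export
setMethod("probs", "IntensityHistogram", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("levelCounts", "IntensityHistogram", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("nPixels", "IntensityHistogram", function(x) x@nPixels)

#' @rdname accessors
#' @export
setMethod("thresholds", "ThresholdFit", function(x) x@thresholds)

#' @rdname accessors
#' @export
setMethod("fitnessValue", "ThresholdFit", function(x) x@fitness)

#' @rdname accessors
#' @export
setMethod("objectiveName", "ThresholdFit", function(x) x@objective)

#' @rdname accessors
#' @export
setMethod("convergenceTrace", "ThresholdFit", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("modes", "MixtureSpec", function(x) x@modes)

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage: %d x %d, %d gray levels, range [%d, %d]\n",
              nrow(object), ncol(object), object@levels,
              min(object@.Data), max(object@.Data)))
})

setMethod("show", "IntensityHistogram", function(object) {
  occ <- sum(object@p > 0)
  src <- if (length(object@counts)) sprintf("%d pixels", object@nPixels)
         else "analytic"
  cat(sprintf("IntensityHistogram: %d levels (%d occupied), %s\n",
              length(object@p), occ, src))
})

setMethod("show", "ThresholdFit", function(object) {
  cat(sprintf("ThresholdFit [%s/%s]: k = %d, thresholds = {%s}, fitness = %.6g\n",
              object@algorithm, object@objective, length(object@thresholds),
              paste(object@thresholds, collapse = ", "), object@fitness))
  if (nrow(object@trace))
    cat(sprintf("  %d iterations traced, final best %.6g\n",
                nrow(object@trace), max(object@trace$bestFitness)))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: RMSE %.4f | PSNR %s dB | SSIM %.4f | FSIM %s\n",
              object@rmse,
              if (is.finite(object@psnr)) sprintf("%.4f", object@psnr)
              else "Inf",
              object@ssim,
              if (is.na(object@fsim)) "NA" else sprintf("%.4f", object@fsim)))
})

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf("MixtureSpec: %d modes (means %s), %d x %d, seed %d\n",
              nrow(object@modes),
              paste(round(object@modes$mean), collapse = "/"),
              object@height, object@width, object@seed))
})

#' Convert a QualityReport to a one-row data.frame
#'
#' @param x a \linkS4class{QualityReport}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return A one-row data.frame with columns rmse, psnr, ssim, fsim.
#' @export
as.data.frame.QualityReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(rmse = x@rmse, psnr = x@psnr, ssim = x@ssim, fsim = x@fsim)
}
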