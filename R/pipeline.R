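# High-level front end: optimize thresholds for an image, write segmented
# outputs and quality reports, and run repeated-seed studies with a
# documented seeding protocol (base seed + run index) so paired
# algorithm comparisons are honest.

#' Optimal thresholds for a histogram
#'
#' Dispatches to the exhaustive oracle (k <= 3) or one of the
#' metaheuristics.  Metaheuristic positions live in \code{[0, L-2]} per
#' dimension and are decoded (clamp, round, sort) before evaluation, so the
#' objective value always corresponds to a valid sorted threshold vector.
#'
#' @param h an \linkS4class{IntensityHistogram}.
#' @param k number of thresholds (1-8; exhaustive requires k <= 3).
#' @param objective \code{"otsu"} or \code{"kapur"}.
#' @param algorithm \code{"ibwoa"} (default), \code{"bwoa"} or
#'   \code{"exhaustive"}.
#' @param config optional \linkS4class{BWOAConfig}; by default the standard
#'   protocol (pop 50, 350 iterations, PP 0.8, CR 0.5, PM 0.4) with bounds
#'   \code{[0, L-2]}.
#' @param levy \linkS4class{LevyConfig} for IBWOA.
#' @param qoblJumpRate QOBL jump probability for IBWOA.
#' @param seed RNG seed (overrides \code{config@seed}).
#' @return A \linkS4class{ThresholdFit}.
#' @examples
#' h <- generateHistogram(mixtureSpec(c(80, 180), c(12, 12)))
#' thresholds(optimalThresholds(h, 1, "otsu", "exhaustive"))
#' @export
optimalThresholds <- function(h, k, objective = c("otsu", "kapur"),
                              algorithm = c("ibwoa", "bwoa", "exhaustive"),
                              config = NULL, levy = levyConfig(),
                              qoblJumpRate = 0.3, seed = 1L) {
  stopifnot(is(h, "IntensityHistogram"))
  objective <- match.arg(objective)
  algorithm <- match.arg(algorithm)
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("k must be between 1 and 8")
  if (algorithm == "exhaustive") {
    if (k > 3L)
      stop("exhaustive search supports k <= 3 only; choose algorithm ",
           "'ibwoa' or 'bwoa' for k = ", k)
    return(exhaustiveOptimal(h, k, objective))
  }
  L <- length(h@p)
  if (is.null(config))
    config <- bwoaConfig(kVar = k, lower = 0, upper = L - 2, seed = seed)
  else {
    config@seed <- as.integer(seed)
    if (length(config@lower) != k)
      stop("config bounds must have length k = ", k)
  }
  fn <- thresholdFitness(h, objective)
  res <- if (algorithm == "ibwoa")
    ibwoaOptimize(config, fn, levy = levy, qoblJumpRate = qoblJumpRate)
  else bwoaOptimize(config, fn)
  th <- attr(fn, "decode")(res$position)[1L, ]
  th <- unique(sort(th))
  new("ThresholdFit", thresholds = as.integer(th), fitness = res$fitness,
      objective = objective, position = as.numeric(res$position),
      algorithm = algorithm, trace = res$trace)
}

.asGrayImage <- function(image) {
  if (is(image, "GrayImage")) image else readGrayImage(image)
}

#' Segment one image and report quality
#'
#' Optimizes k thresholds for the image's histogram, reconstructs the
#' segmented image (class-mean by default), and computes the quality
#' metrics.  When \code{outDir} is given, writes the segmented PNG, a JSON
#' quality report (including the thresholds) and a CSV convergence trace.
#'
#' @param image a \linkS4class{GrayImage} or a path readable by
#'   \code{\link{readGrayImage}}.
#' @inheritParams optimalThresholds
#' @param mode reconstruction mode passed to \code{\link{applyThresholds}}.
#' @param outDir optional output directory.
#' @param name stem for output files.
#' @param windowedSSIM use windowed mean-SSIM in the report.
#' @return list with \code{fit} (\linkS4class{ThresholdFit}),
#'   \code{segmented} (\linkS4class{GrayImage}), \code{report}
#'   (\linkS4class{QualityReport}) and \code{files} (paths written, if
#'   any).
#' @export
runSegment <- function(image, k, objective = c("otsu", "kapur"),
                       algorithm = c("ibwoa", "bwoa", "exhaustive"),
                       config = NULL, levy = levyConfig(),
                       qoblJumpRate = 0.3, seed = 1L,
                       mode = "class-mean", outDir = NULL,
                       name = "segment", windowedSSIM = FALSE) {
  img <- .asGrayImage(image)
  h <- computeHistogram(img)
  fit <- optimalThresholds(h, k, objective, algorithm, config = config,
                           levy = levy, qoblJumpRate = qoblJumpRate,
                           seed = seed)
  seg <- applyThresholds(img, fit@thresholds, mode = mode)
  rep <- qualityReport(img, seg, windowedSSIM = windowedSSIM)
  files <- character(0)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    pngPath <- file.path(outDir, paste0(name, "_segmented.png"))
    writeGrayImage(seg, pngPath)
    jsonPath <- file.path(outDir, paste0(name, "_report.json"))
    writeQualityReport(rep, jsonPath, thresholds = fit@thresholds,
                       fitness = fit@fitness, objective = fit@objective,
                       algorithm = fit@algorithm, k = k, seed = seed)
    files <- c(pngPath, jsonPath)
    if (nrow(fit@trace)) {
      csvPath <- file.path(outDir, paste0(name, "_trace.csv"))
      writeTrace(fit@trace, csvPath)
      files <- c(files, csvPath)
    }
  }
  list(fit = fit, segmented = seg, report = rep, files = files)
}

#' Repeated-seed segmentation study
#'
#' Runs each requested algorithm \code{runs} times on the image with seeds
#' \code{baseSeed + 0, ..., baseSeed + runs - 1}, and aggregates mean and
#' standard deviation of fitness, PSNR, SSIM and FSIM.  For k <= 3 the
#' exhaustive optimum is computed once and each run is flagged as an
#' oracle hit when its fitness matches to within \code{1e-9}.  With two
#' algorithms the same seeds are reused, giving an honest paired
#' comparison (per-seed fitness deltas are reported).
#'
#' @inheritParams runSegment
#' @param algorithms character vector, subset of \code{c("ibwoa", "bwoa")}.
#' @param runs number of independent runs per algorithm (default 35).
#' @param baseSeed first seed of the protocol.
#' @param metrics also compute image-quality metrics per run (set
#'   \code{FALSE} for fitness-only studies).
#' @return list with \code{perRun} (one row per run: algorithm, seed,
#'   fitness, thresholds, metrics, oracleHit), \code{summary} (per
#'   algorithm: means, sds, oracle hit rate), \code{oracle} (the
#'   \linkS4class{ThresholdFit} or NULL), and \code{paired} (per-seed
#'   fitness deltas ibwoa - bwoa, when both algorithms run).
#' @export
runStudy <- function(image, k, objective = c("otsu", "kapur"),
                     algorithms = "ibwoa", runs = 35L, baseSeed = 1L,
                     config = NULL, levy = levyConfig(),
                     qoblJumpRate = 0.3, mode = "class-mean",
                     metrics = TRUE) {
  stopifnot(runs >= 1L, all(algorithms %in% c("ibwoa", "bwoa")))
  objective <- match.arg(objective)
  img <- .asGrayImage(image)
  h <- computeHistogram(img)
  oracle <- if (k <= 3L) exhaustiveOptimal(h, k, objective) else NULL

  rows <- list()
  for (alg in algorithms) {
    for (r in seq_len(runs)) {
      seed <- as.integer(baseSeed) + r - 1L
      fit <- optimalThresholds(h, k, objective, alg, config = config,
                               levy = levy, qoblJumpRate = qoblJumpRate,
                               seed = seed)
      row <- data.frame(algorithm = alg, seed = seed,
                        fitness = fit@fitness,
                        thresholds = paste(fit@thresholds, collapse = " "),
                        oracleHit = if (is.null(oracle)) NA
                        else abs(fit@fitness - oracle@fitness) <= 1e-9)
      if (metrics) {
        seg <- applyThresholds(img, fit@thresholds, mode = mode)
        qr <- qualityReport(img, seg)
        row <- cbind(row, as.data.frame(qr))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  perRun <- do.call(rbind, rows)

  aggOne <- function(d) {
    num <- d[, intersect(c("fitness", "rmse", "psnr", "ssim", "fsim"),
                         names(d)), drop = FALSE]
    means <- vapply(num, mean, numeric(1))
    sds <- vapply(num, stats::sd, numeric(1))
    if (nrow(d) == 1L) sds[] <- 0
    out <- data.frame(algorithm = d$algorithm[1L], runs = nrow(d))
    for (nm in names(means)) {
      out[[paste0("mean_", nm)]] <- means[[nm]]
      out[[paste0("sd_", nm)]] <- sds[[nm]]
    }
    out$oracleHitRate <- if (all(is.na(d$oracleHit))) NA_real_
    else mean(d$oracleHit)
    out
  }
  summary <- do.call(rbind, lapply(split(perRun, perRun$algorithm), aggOne))
  rownames(summary) <- NULL

  paired <- NULL
  if (all(c("ibwoa", "bwoa") %in% algorithms)) {
    a <- perRun[perRun$algorithm == "ibwoa", ]
    b <- perRun[perRun$algorithm == "bwoa", ]
    a <- a[order(a$seed), ]; b <- b[order(b$seed), ]
    paired <- data.frame(seed = a$seed,
                         ibwoaFitness = a$fitness, bwoaFitness = b$fitness,
                         delta = a$fitness - b$fitness)
  }
  list(perRun = perRun, summary = summary, oracle = oracle, paired = paired)
}
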