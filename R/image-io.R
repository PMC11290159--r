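# Grayscale image reading/writing (PNG, TIFF, PGM) and the histogram /
# threshold-application operations that feed the objectives.

# Rec.601 luma weights, rounded half-up (round() in R is round-half-even).
.roundHalfUp <- function(x) floor(x + 0.5)

.toGray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nc <- dim(arr)[3L]
  g <- if (nc <= 2L) arr[, , 1L]  # gray or gray+alpha
  else 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
  dim(g) <- dim(arr)[1:2]  # single-pixel slices drop dims otherwise
  g
}

.readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # token scanner that skips whitespace and '#' comments
  nextToken <- function() {
    tok <- ""
    repeat {
      ch <- readBin(con, "raw", 1L)
      if (!length(ch)) {
        if (nzchar(tok)) return(tok)
        stop("truncated PGM header: ", path)
      }
      c1 <- rawToChar(ch)
      if (c1 == "#") {
        repeat {
          ch <- readBin(con, "raw", 1L)
          if (!length(ch) || rawToChar(ch) == "\n") break
        }
      } else if (grepl("[[:space:]]", c1)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, c1)
    }
  }
  w <- as.integer(nextToken()); h <- as.integer(nextToken())
  maxval <- as.integer(nextToken())
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1L || h < 1L)
    stop("invalid PGM header in ", path)
  n <- w * h
  if (magic == "P5") {
    px <- as.integer(readBin(con, "raw", n))
    if (length(px) < n) stop("truncated PGM pixel data: ", path)
  } else {
    txt <- rawToChar(readBin(con, "raw", file.info(path)$size))
    txt <- gsub("#[^\n]*", " ", txt)
    px <- suppressWarnings(as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]]))
    px <- px[!is.na(px)]
    if (length(px) < n) stop("truncated PGM pixel data: ", path)
    px <- px[seq_len(n)]
  }
  if (maxval != 255L) px <- as.integer(.roundHalfUp(px * 255 / maxval))
  grayImage(matrix(px, nrow = h, ncol = w, byrow = TRUE))
}

#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM (ASCII \code{P2} or binary \code{P5}).  Color
#' inputs are converted to luminance with the Rec.601 weights
#' (0.299 R + 0.587 G + 0.114 B) and rounded half-up to integers.  The
#' format is detected from the file's magic bytes, falling back to the
#' extension.
#'
#' @param path file path.
#' @return A \linkS4class{GrayImage} with L = 256.
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeGrayImage(grayImage(matrix(c(0L, 128L, 64L, 255L), 2, 2)), f)
#' readGrayImage(f)
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  magic <- readBin(path, "raw", 4L)
  fmt <- if (length(magic) >= 4L &&
             identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) "png"
    else if (length(magic) >= 2L && rawToChar(magic[1:2]) %in% c("P2", "P5")) "pgm"
    else if (length(magic) >= 2L &&
             rawToChar(magic[1:2]) %in% c("II", "MM")) "tiff"
    else tolower(tools::file_ext(path))
  arr <- switch(fmt,
    png  = tryCatch(png::readPNG(path),
                    error = function(e) stop("cannot decode PNG ", path, ": ",
                                             conditionMessage(e))),
    tiff = , tif = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("cannot decode TIFF ", path, ": ",
                                             conditionMessage(e))),
    pgm  = return(.readPGM(path)),
    stop("unsupported image format for ", path)
  )
  if (length(arr) == 0L || prod(dim(arr)[1:2]) == 0L)
    stop("zero-area image: ", path)
  g <- .toGray(arr)
  grayImage(matrix(as.integer(.roundHalfUp(g * 255)), nrow(g), ncol(g)))
}

#' Write a grayscale image
#'
#' Writes PNG (via the png package) or ASCII PGM (\code{P2}), chosen from the
#' file extension.  A write/read round-trip reproduces pixels bit-exactly.
#'
#' @param img a \linkS4class{GrayImage}.
#' @param path output path ending in \code{.png} or \code{.pgm}.
#' @return \code{path}, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  stopifnot(is(img, "GrayImage"))
  ext <- tolower(tools::file_ext(path))
  px <- img@.Data
  if (ext == "png") {
    png::writePNG(px / (img@levels - 1L), path)
  } else if (ext == "pgm") {
    hdr <- sprintf("P2\n%d %d\n%d", ncol(px), nrow(px), img@levels - 1L)
    body <- apply(px, 1L, paste, collapse = " ")
    writeLines(c(hdr, body), path)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

#' Compute the gray-level histogram of an image
#'
#' Counts \eqn{n_i} of pixels at each level i and probabilities
#' \eqn{p_i = n_i / N} where N is the total pixel count.
#'
#' @param img a \linkS4class{GrayImage}.
#' @return An \linkS4class{IntensityHistogram}.
#' @examples
#' h <- computeHistogram(grayImage(matrix(c(0L, 0L, 255L, 255L), 2, 2)))
#' probs(h)[c(1, 256)]
#' @export
computeHistogram <- function(img) {
  stopifnot(is(img, "GrayImage"))
  L <- img@levels
  n <- tabulate(img@.Data + 1L, nbins = L)
  N <- length(img@.Data)
  new("IntensityHistogram", p = n / N, counts = as.integer(n),
      nPixels = as.integer(N))
}

#' Build an analytic histogram from a probability vector
#'
#' @param p non-negative vector of length L; normalized to sum to 1.
#' @return An \linkS4class{IntensityHistogram} with no counts.
#' @export
histogramFromProbs <- function(p) {
  new("IntensityHistogram", p = p / sum(p), counts = integer(0),
      nPixels = 0L)
}

# validate a threshold vector against L; sorted increasing in [0, L-2]
.checkThresholds <- function(th, L) {
  th <- as.integer(th)
  if (length(th) == 0L) return(th)
  if (anyNA(th)) stop("thresholds must not contain NA")
  if (is.unsorted(th, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (th[1L] < 0L || th[length(th)] > L - 2L)
    stop(sprintf("thresholds must lie in [0, %d]", L - 2L))
  th
}

#' Segment an image with a threshold vector
#'
#' Partitions gray levels into k+1 classes: pixel g belongs to class j when
#' \eqn{th_{j-1} < g \le th_j} (with sentinels \eqn{th_0 = -1} and
#' \eqn{th_{k+1} = L-1}), i.e. each threshold belongs to its lower class.
#' The output pixel is the class index (\code{"labels"}), the rounded mean
#' gray level of the class (\code{"class-mean"}, the reconstruction used for
#' quality metrics), or the rounded midpoint of the class interval
#' (\code{"class-midpoint"}).
#'
#' @param img a \linkS4class{GrayImage}.
#' @param th sorted integer thresholds in \code{[0, L-2]}; may be empty
#'   (single class).
#' @param mode \code{"labels"}, \code{"class-mean"} or
#'   \code{"class-midpoint"}.
#' @return A \linkS4class{GrayImage} of the same size.
#' @examples
#' img <- grayImage(matrix(c(0L, 100L, 200L), 1, 3))
#' applyThresholds(img, c(50, 150), mode = "labels")
#' @export
applyThresholds <- function(img, th,
                            mode = c("class-mean", "labels",
                                     "class-midpoint")) {
  stopifnot(is(img, "GrayImage"))
  mode <- match.arg(mode)
  L <- img@levels
  th <- .checkThresholds(th, L)
  bounds <- c(-1L, th, L - 1L)
  # class of each gray level, then table lookup per pixel
  lev <- 0:(L - 1L)
  cls <- findInterval(lev, bounds + 1L)  # 1-based class index per level
  px <- img@.Data
  if (mode == "labels") {
    out <- matrix(cls[px + 1L] - 1L, nrow(px), ncol(px))
  } else {
    k1 <- length(th) + 1L
    val <- integer(k1)
    for (j in seq_len(k1)) {
      lo <- bounds[j] + 1L; hi <- bounds[j + 1L]
      if (mode == "class-midpoint") {
        val[j] <- as.integer(.roundHalfUp((lo + hi) / 2))
      } else {
        inC <- px >= lo & px <= hi
        val[j] <- if (any(inC)) as.integer(.roundHalfUp(mean(px[inC])))
                  else as.integer(.roundHalfUp((lo + hi) / 2))
      }
    }
    out <- matrix(val[cls[px + 1L]], nrow(px), ncol(px))
  }
  grayImage(out, levels = L)
}
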