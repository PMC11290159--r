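test_that("PGM and PNG round-trips reproduce pixels bit-exactly", {
  set.seed(42)
  for (i in 1:5) {
    img <- randomImage(nr = sample(1:20, 1), nc = sample(1:20, 1))
    for (ext in c(".pgm", ".png")) {
      f <- tempfile(fileext = ext)
      writeGrayImage(img, f)
      back <- readGrayImage(f)
      expect_identical(back@.Data, img@.Data)
      unlink(f)
    }
  }
})

test_that("ASCII PGM content is parsed as written, comments and all", {
  f <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "# a comment", "2 2", "255", "0 0", "255 255"), f)
  img <- readGrayImage(f)
  expect_identical(as.integer(img@.Data), c(0L, 255L, 0L, 255L))
  expect_equal(dim(img@.Data), c(2L, 2L))
  unlink(f)
})

test_that("color PNG is converted by Rec.601 luminance", {
  f <- tempfile(fileext = ".png")
  # single pure-white pixel
  png::writePNG(array(1, dim = c(1, 1, 3)), f)
  expect_identical(as.integer(readGrayImage(f)@.Data), 255L)
  # pure red: 0.299 * 255 = 76.245 -> 76
  png::writePNG(array(c(1, 0, 0), dim = c(1, 1, 3)), f)
  expect_identical(as.integer(readGrayImage(f)@.Data), 76L)
  unlink(f)
})

test_that("unreadable or truncated files raise informative errors", {
  expect_error(readGrayImage(file.path(tempdir(), "no-such-file.png")),
               "no such file")
  f <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "4 4", "255", "0 1 2"), f)  # too few pixels
  expect_error(readGrayImage(f), "truncated")
  f2 <- tempfile(fileext = ".png")
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x00)), f2)  # truncated PNG
  expect_error(readGrayImage(f2), "PNG")
  unlink(c(f, f2))
})

test_that("GrayImage validity rejects malformed input", {
  expect_error(grayImage(matrix(c(0, 300), 1, 2)), "lie in")
  expect_error(grayImage(matrix(numeric(0), 0, 0)), "M >= 1")
  expect_error(grayImage(matrix(c(0.5, 1), 1, 2)), "integer")
})

test_that("histogram counts and probabilities follow the definition", {
  h <- computeHistogram(grayImage(matrix(c(0L, 0L, 255L, 255L), 2, 2)))
  expect_equal(probs(h)[c(1, 256)], c(0.5, 0.5))
  expect_equal(sum(probs(h)), 1, tolerance = 1e-15)
  expect_identical(nPixels(h), 4L)

  h2 <- computeHistogram(grayImage(matrix(7L, 3, 5)))
  expect_equal(probs(h2)[8], 1)
  expect_equal(sum(probs(h2)[-8]), 0)

  h3 <- computeHistogram(grayImage(matrix(c(1L, 2L, 2L, 3L), 1, 4)))
  expect_equal(probs(h3)[2:4], c(0.25, 0.5, 0.25))
})

test_that("histogram probabilities sum to one for arbitrary images", {
  set.seed(7)
  for (i in 1:10) {
    h <- computeHistogram(randomImage(32, 32))
    expect_lt(abs(sum(probs(h)) - 1), 1e-12)
  }
})

test_that("thresholds partition pixels with inclusive-upper classes", {
  img <- grayImage(matrix(c(0L, 100L, 200L), 1, 3))
  lab <- applyThresholds(img, c(50, 150), mode = "labels")
  expect_identical(as.integer(lab@.Data), c(0L, 1L, 2L))

  # a threshold equal to a pixel value puts that pixel in the lower class
  img2 <- grayImage(matrix(c(0L, 255L), 1, 2))
  cm <- applyThresholds(img2, 0, mode = "class-mean")
  expect_identical(as.integer(cm@.Data), c(0L, 255L))

  # empty threshold vector: one class at the rounded global mean
  img3 <- grayImage(matrix(c(10L, 11L), 1, 2))
  one <- applyThresholds(img3, integer(0), mode = "class-mean")
  expect_true(all(one@.Data == 11L))  # mean 10.5 rounds half-up to 11
})

test_that("label images are monotone in gray level with expected cardinality", {
  set.seed(11)
  for (i in 1:10) {
    img <- randomImage(24, 24)
    th <- sort(sample(0:254, sample(1:4, 1)))
    lab <- applyThresholds(img, th, mode = "labels")
    # monotone: label is a non-decreasing function of the gray level
    o <- order(as.integer(img@.Data))
    expect_true(!is.unsorted(as.integer(lab@.Data)[o]))
    # occupied classes only
    occupied <- length(unique(findInterval(unique(as.integer(img@.Data)),
                                           c(-1L, th, 255L) + 1L)))
    expect_identical(length(unique(as.integer(lab@.Data))), occupied)
  }
})

test_that("invalid threshold vectors are rejected", {
  img <- randomImage(4, 4)
  expect_error(applyThresholds(img, c(150, 50)), "increasing")
  expect_error(applyThresholds(img, 255), "lie in")
  expect_error(applyThresholds(img, -1), "lie in")
})
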