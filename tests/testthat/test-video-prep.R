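# Face cropping (no alignment) and tile decomposition; the bicubic
# resampler that backs both.

test_that("passthrough detection on a pre-cropped frame is the identity", {
  frame <- randomImage(448L, seed = 1L)
  crop <- detectAndCrop(frame, passthroughDetector())
  expect_identical(crop@image, frame)
})

test_that("a detector box is squared, cropped and resized to 448", {
  frame <- randomImage(300L, seed = 2L)
  det <- function(f) list(list(box = c(51, 61, 150, 210), confidence = 0.9))
  crop <- detectAndCrop(frame, det)
  expect_identical(dim(crop@image), c(448L, 448L, 3L))
  # reference: bounding square of the box (side 150), same resize
  side <- 150
  cx <- (51 + 150) / 2; cy <- (61 + 210) / 2
  x0 <- round(cx - side / 2 + 0.5); y0 <- round(cy - side / 2 + 0.5)
  ref <- bicubicResize(frame[y0:(y0 + side - 1), x0:(x0 + side - 1), ],
                       448L, 448L)
  expect_equal(crop@image, ref)
})

test_that("no-face errors carry the frame index and previous boxes are reused", {
  frame <- randomImage(100L, seed = 3L)
  none <- function(f) list()
  err <- tryCatch(detectAndCrop(frame, none, frameIndex = 7L),
                  noFace = function(e) e)
  expect_s3_class(err, "noFace")
  expect_identical(err$frameIndex, 7L)
  crop <- detectAndCrop(frame, none, previousBox = c(1, 1, 100, 100))
  expect_identical(dim(crop@image), c(448L, 448L, 3L))
})

test_that("cropping applies no alignment: rotation passes through", {
  frame <- randomImage(448L, seed = 4L)
  rot90 <- function(a) {
    out <- array(0, dim(a))
    for (ch in 1:3) out[, , ch] <- t(a[dim(a)[1L]:1, , ch])
    out
  }
  rotated <- rot90(frame)
  cropPlain <- detectAndCrop(frame, passthroughDetector())
  cropRot <- detectAndCrop(rotated, passthroughDetector())
  expect_identical(cropRot@image, rot90(cropPlain@image))
})

test_that("tiles are the exact disjoint quadrants and reassemble losslessly", {
  crop <- randomImage(448L, seed = 5L)
  ts <- makeTileset(crop)
  expect_identical(ts@tiles[[1L]], crop[1:224, 1:224, , drop = FALSE])
  expect_identical(ts@tiles[[2L]], crop[1:224, 225:448, , drop = FALSE])
  expect_identical(ts@tiles[[3L]], crop[225:448, 1:224, , drop = FALSE])
  expect_identical(ts@tiles[[4L]], crop[225:448, 225:448, , drop = FALSE])
  rebuilt <- array(0, c(448L, 448L, 3L))
  rebuilt[1:224, 1:224, ] <- ts@tiles[[1L]]
  rebuilt[1:224, 225:448, ] <- ts@tiles[[2L]]
  rebuilt[225:448, 1:224, ] <- ts@tiles[[3L]]
  rebuilt[225:448, 225:448, ] <- ts@tiles[[4L]]
  expect_identical(rebuilt, crop)
  expect_identical(dim(ts@full), c(224L, 224L, 3L))
  expect_error(makeTileset(randomImage(100L)), class = "invalidArgument")
})

test_that("a constant crop yields five constant images", {
  crop <- array(0.5, c(448L, 448L, 3L))
  ts <- makeTileset(crop)
  for (img in c(list(ts@full), ts@tiles))
    expect_true(all(abs(img - 0.5) < 1e-12))
})

test_that("bicubic resampling matches a naive direct evaluation", {
  # independent oracle: literal cubic-convolution double loop
  naive <- function(m, oh, ow) {
    k <- function(t, a = -0.5) {
      t <- abs(t)
      if (t <= 1) (a + 2) * t^3 - (a + 3) * t^2 + 1
      else if (t < 2) a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a
      else 0
    }
    out <- matrix(0, oh, ow)
    for (i in 1:oh) for (j in 1:ow) {
      sy <- (i - 0.5) * nrow(m) / oh - 0.5
      sx <- (j - 0.5) * ncol(m) / ow - 0.5
      acc <- 0; wsum <- 0
      for (dy in -1:2) for (dx in -1:2) {
        py <- floor(sy) + dy; px <- floor(sx) + dx
        w <- k(sy - py) * k(sx - px)
        py <- min(max(py, 0), nrow(m) - 1); px <- min(max(px, 0), ncol(m) - 1)
        acc <- acc + w * m[py + 1, px + 1]; wsum <- wsum + w
      }
      out[i, j] <- acc / wsum
    }
    out
  }
  m <- matrix(withSeed(6L, rnorm(20)), 4, 5)
  expect_equal(bicubicResize(m, 8L, 10L), naive(m, 8L, 10L), tolerance = 1e-10)
  expect_equal(bicubicResize(m, 3L, 7L), naive(m, 3L, 7L), tolerance = 1e-10)
})

test_that("bicubic resampling preserves constants and is identity at size", {
  m <- matrix(3.7, 6, 9)
  expect_true(all(abs(bicubicResize(m, 13L, 4L) - 3.7) < 1e-12))
  r <- matrix(withSeed(7L, rnorm(48)), 6, 8)
  expect_equal(bicubicResize(r, 6L, 8L), r, tolerance = 1e-12)
})
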