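# Fourier position features, the cross-attention heart-rate encoder and the
# bicubic expansion to the video-embedding length.

test_that("Fourier position features follow the closed form", {
  P <- fourierPositions(5L, 4L)
  expect_identical(dim(P), c(5L, 2L * 4L + 1L))
  # position 0: raw coordinate 0, all sines 0, all cosines 1
  expect_equal(P[1L, ], c(0, rep(0, 4), rep(1, 4)), ignore_attr = TRUE)
  # midpoint at band frequency 1: sin(pi * 0.5) = 1
  mid <- fourierPositions(3L, 3L)[2L, ]
  expect_equal(mid[1L], 0.5, ignore_attr = TRUE)
  expect_equal(mid[2L], sin(pi * 0.5), ignore_attr = TRUE)
  # frequencies are log-spaced from 1 to the Nyquist of the index axis
  L <- 9L; B <- 5L
  f <- exp(seq(log(1), log(L / 2), length.out = B))
  x <- (seq_len(L) - 1) / (L - 1)
  expect_equal(fourierPositions(L, B)[, 1L + B + seq_len(B)],
               cos(outer(x, pi * f)), ignore_attr = TRUE)
  expect_identical(nrow(fourierPositions(1L, 2L)), 1L)
})

test_that("heart-rate encoding maps theta points to the flattened latents", {
  mod <- hrEncoder(hrEncoderConfig(), seed = 1L)
  h <- c(72, 74, 71, 73, 75)
  e <- hrEncode(mod, h)
  expect_length(e, 2048L)
  expect_identical(e, hrEncode(mod, h))
  # accepts a HeartRateSeries and any theta >= 1
  hrs <- methods::new("HeartRateSeries", values = c(80, 82, 81),
                      filledMask = rep(FALSE, 3L))
  expect_length(hrEncode(mod, hrs), 2048L)
  expect_length(hrEncode(mod, 68), 2048L)
  expect_error(hrEncode(mod, numeric(0)), class = "invalidArgument")
})

test_that("toy encoder output length is nLatents * internalDim", {
  mod <- hrEncoder(toyHrConfig(), seed = 2L)
  expect_length(hrEncode(mod, c(70, 75)), 4L * 32L)
})

test_that("bicubic expansion preserves constants and identity at same size", {
  expect_equal(bicubicExpand(rep(2.5, 2048L), 13800L), rep(2.5, 13800L),
               tolerance = 1e-10)
  e <- withSeed(3L, rnorm(2048))
  expect_identical(bicubicExpand(e, 2048L), e)
  expect_error(bicubicExpand(e, 0L), class = "invalidArgument")
})

test_that("bicubic expansion matches the matrix resampler on the 2-D grid", {
  e <- withSeed(4L, rnorm(128))          # 8 x 16 grid
  out <- bicubicExpand(e, 512L)
  sc <- sqrt(512 / 128)
  oh <- ceiling(8 * sc); ow <- ceiling(16 * sc)
  ref <- as.numeric(t(bicubicResize(matrix(e, 8L, 16L, byrow = TRUE),
                                    oh, ow)))[1:512]
  expect_equal(out, ref, tolerance = 1e-5)
})

test_that("expansion overshoot stays within the cubic kernel bound", {
  ramp <- seq(-1, 1, length.out = 512)
  out <- bicubicExpand(ramp, 2000L)
  expect_lte(max(abs(out)), 1.5 * max(abs(ramp)))
})

test_that("the full heart-rate chain matches the video embedding length", {
  hMod <- hrEncoder(toyHrConfig(), seed = 5L)
  for (ecfg in list(c(theta = 5, f = 138, d = 100),
                    c(theta = 2, f = 4, d = 20))) {
    h <- rep(75, ecfg[["theta"]])
    N <- ecfg[["f"]] * ecfg[["d"]]
    expect_length(bicubicExpand(hrEncode(hMod, h), N), N)
  }
})
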