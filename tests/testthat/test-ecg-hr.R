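# Pan-Tompkins preprocessing and decision stages, mean-IBI / heart-rate
# formulas, per-second extraction with the gap-fill rule.

test_that("preprocessing stages have the documented structure", {
  zero <- ECGSignal(rep(0, 512 * 3), 512)
  st <- panTompkinsPreprocess(zero)
  for (nm in names(st)) {
    expect_length(st[[nm]], 512L * 3L)
    expect_true(all(st[[nm]] == 0), label = nm)
  }

  t <- seq(0, 4, by = 1 / 512)
  mains <- ECGSignal(sin(2 * pi * 50 * t), 512)
  stm <- panTompkinsPreprocess(mains)
  expect_lt(sum(stm$bandpassed^2), 0.05 * sum(samples(mains)^2))

  e <- synthECG(80, fs = 512, duration = 4, noiseSd = 0.05, seed = 2L)
  ste <- panTompkinsPreprocess(e)
  expect_identical(ste$squared, ste$derivative^2)

  expect_error(panTompkinsPreprocess(ECGSignal(rnorm(100), 25)),
               class = "invalidArgument")
})

test_that("clean synthetic beats are detected exactly, noisy ones sensitively", {
  e <- synthECG(60, fs = 512, duration = 5.5, noiseSd = 0, seed = 1L)
  det <- detectRPeaks(e)
  expect_identical(length(rPeaks(det)), length(rPeaks(e)))
  expect_true(all(abs(rPeaks(det) - rPeaks(e)) <= 10))

  flat <- detectRPeaks(ECGSignal(rep(0, 512 * 3), 512))
  expect_length(rPeaks(flat), 0L)
  expect_true("no-peaks" %in% flat@flags)

  expect_error(detectRPeaks(ECGSignal(rnorm(256), 512)),
               class = "invalidArgument")

  # Monte-Carlo sensitivity at 10% of the R amplitude
  hits <- misses <- 0L
  for (s in 1:20) {
    e <- synthECG(75, fs = 512, duration = 5.5, noiseSd = 0.1, seed = s)
    det <- rPeaks(detectRPeaks(e))
    found <- vapply(rPeaks(e), function(p) any(abs(det - p) <= 26), logical(1))
    hits <- hits + sum(found)
    misses <- misses + sum(!found)
  }
  expect_gte(hits / (hits + misses), 0.95)
})

test_that("detected peak series always satisfies the refractory invariant", {
  for (s in 1:5) {
    bpm <- withSeed(s, runif(5, 55, 150))
    e <- synthECG(bpm, fs = 512, duration = 5.5, noiseSd = 0.15, seed = s)
    det <- detectRPeaks(e)
    if (length(rPeaks(det)) >= 2L)
      expect_true(all(diff(rPeaks(det)) >= 0.2 * 512))
  }
})

test_that("mean IBI matches brute-force pairwise differences", {
  mk <- function(idx) methods::new("RPeakSeries", indices = as.integer(idx),
                                   fs = 512)
  expect_equal(computeMeanIBI(mk(c(0, 512, 1024)))@mu, 512)
  expect_equal(computeMeanIBI(mk(c(0, 400, 1000)))@mu, 500)
  expect_error(computeMeanIBI(mk(7L)), class = "insufficientBeats")

  for (s in 1:10) {
    idx <- cumsum(withSeed(s, sample(103:400, 8)))
    ib <- computeMeanIBI(mk(idx))
    brute <- mean(vapply(seq_len(length(idx) - 1L),
                         function(i) idx[i + 1L] - idx[i], numeric(1)))
    expect_equal(ib@mu, brute)
    expect_identical(ib@n, length(idx) - 1L)
  }
})

test_that("heart rate is 60 * fs / mu and scale-invariant", {
  mk <- function(mu) methods::new("IBISummary", intervals = mu,
                                  n = 1L, mu = mu)
  expect_equal(computeHeartRate(mk(512), 512), 60)
  expect_equal(computeHeartRate(mk(256), 512), 120)
  expect_equal(computeHeartRate(mk(426.67), 512), 72.0, tolerance = 1e-3)
  expect_error(computeHeartRate(mk(0), 512), class = "invalidArgument")
  # doubling fs and spacing jointly leaves HR unchanged
  expect_equal(computeHeartRate(mk(410), 512), computeHeartRate(mk(820), 1024))
})

test_that("gap filling averages the nearest computed neighbours", {
  f <- fillGaps(c(80, NA, 90, 88, 86))
  expect_equal(f$values, c(80, 85, 90, 88, 86))
  expect_identical(which(f$filledMask), 2L)
  # boundary gaps take the single nearest value
  g <- fillGaps(c(NA, 70, NA))
  expect_equal(g$values, c(70, 70, 70))
  expect_error(fillGaps(c(NA, NA)), class = "unrecoverableRecord")
})

test_that("per-second heart rate recovers constant profiles within 2 BPM", {
  for (b in c(50, 60, 75, 100, 140)) {
    e <- synthECG(b, fs = 512, duration = 5.5, noiseSd = 0, seed = 3L)
    hr <- hrPerSecond(e, 5.5)
    expect_length(hrValues(hr), 5L)
    expect_true(all(abs(hrValues(hr) - b) <= 2),
                label = sprintf("recovery at %g BPM", b))
  }
  expect_error(hrPerSecond(synthECG(60, 512, 5.5), windowS = 1),
               class = "invalidArgument")
})

test_that("heart-rate series round-trips through CSV", {
  e <- synthECG(72, fs = 512, duration = 5.5, noiseSd = 0, seed = 1L)
  hr <- hrPerSecond(e)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  writeHeartRateCsv(hr, path)
  df <- read.csv(path)
  expect_equal(df$bpm, hrValues(hr))
  expect_equal(as.logical(df$filled_flag), filledMask(hr))
  expect_true(all(abs(hrValues(hr) - 72) <= 2))
})
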