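# Synthetic-data generator: beat spacing, protocol counts, label effects,
# determinism.

test_that("synthetic ECG places beats at round(60 * fs / BPM) spacings", {
  cases <- list(list(bpm = 60, spacing = 512L),
                list(bpm = 120, spacing = 256L),
                list(bpm = 75, spacing = 410L))  # round(60*512/75) = 410
  for (cs in cases) {
    e <- synthECG(cs$bpm, fs = 512, duration = 5.5, noiseSd = 0, seed = 1L)
    expect_true(all(diff(rPeaks(e)) == cs$spacing),
                label = sprintf("spacing at %g BPM", cs$bpm))
  }
  e <- synthECG(60, fs = 512, duration = 5.5)
  expect_identical(length(samples(e)), 2816L)
  expect_identical(hrValues(e), rep(60, 5))
})

test_that("synthetic ECG rejects out-of-range arguments", {
  expect_error(synthECG(25, fs = 512, duration = 5), class = "invalidArgument")
  expect_error(synthECG(60, fs = -1, duration = 5), class = "invalidArgument")
  expect_error(synthECG(60, fs = 512, duration = 0), class = "invalidArgument")
})

test_that("sessions are deterministic and label effects are as configured", {
  spec <- protocolSpec(windowS = 2, fps = 2, fs = 256,
                       bpmSessionSd = 0, bpmSecondSd = 0, seed = 5L)
  s1 <- synthSession("S001", "P2", spec, rep = 3L)
  s2 <- synthSession("S001", "P2", spec, rep = 3L)
  expect_identical(s1@frames, s2@frames)
  expect_identical(samples(s1@ecg), samples(s2@ecg))

  # NP: zero deformation and zero BPM offset from the subject baseline
  np <- synthSession("S007", "NP", spec, rep = 1L)
  p4 <- synthSession("S007", "P4", spec, rep = 1L)
  base <- mean(hrValues(np@ecg))
  expect_equal(mean(hrValues(p4@ecg)), base + 4 * spec@bpmEffect,
               tolerance = 1e-8)
  # NP frames carry no deformation: first and last frame differ only by the
  # (zero-amplitude) ramp, i.e. are identical
  expect_identical(np@frames[[1L]], np@frames[[length(np@frames)]])
  expect_false(identical(p4@frames[[1L]], p4@frames[[length(p4@frames)]]))
})

test_that("session geometry follows the protocol window", {
  spec <- protocolSpec(windowS = 2, fps = 4, fs = 128)
  s <- synthSession("S001", "P1", spec)
  expect_length(s@frames, round(2 * 4))
  expect_identical(dim(s@frames[[1L]]), c(448L, 448L, 3L))
  expect_length(samples(s@ecg), round(2 * 128))
})

test_that("dataset manifest realises the protocol counts for any spec", {
  small <- synthDataset(protocolSpec(nSubjects = 2L, repsPerLevel = 1L,
                                     nBaseline = 1L))
  expect_identical(nrow(small$manifest), 10L)

  spec <- protocolSpec(nSubjects = 4L, repsPerLevel = 3L, nBaseline = 5L,
                       seed = 2L)
  ds <- synthDataset(spec)
  expect_identical(nrow(ds$manifest), 4L * (5L + 4L * 3L))
  for (s in unique(ds$manifest$subject)) {
    tab <- table(ds$manifest$label[ds$manifest$subject == s])
    expect_identical(as.integer(tab[["NP"]]), 5L)
    expect_true(all(tab[c("P1", "P2", "P3", "P4")] == 3L))
  }
  # stimulation order is shuffled per subject, not blocked
  first <- ds$manifest$label[ds$manifest$subject == "S001"]
  expect_false(identical(first, sort(first)))
})

test_that("manifest sessions rematerialise identically", {
  spec <- protocolSpec(nSubjects = 2L, repsPerLevel = 2L, nBaseline = 2L,
                       windowS = 2, fps = 2, fs = 128, seed = 9L)
  ds <- synthDataset(spec)
  a <- sessionFromManifest(ds, 5L)
  b <- sessionFromManifest(ds, 5L)
  expect_identical(a@frames, b@frames)
  expect_identical(a@label, ds$manifest$label[5L])
})

test_that("session round-trips through the on-disk layout", {
  spec <- protocolSpec(windowS = 2, fps = 2, fs = 128, seed = 3L)
  s <- synthSession("S001", "P3", spec)
  dir <- tempfile("session")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  writeSession(s, dir)
  frames <- readFrameDir(dir)
  expect_length(frames, 4L)
  # PNG stores 8-bit samples; allow the quantisation step
  expect_true(max(abs(frames[[1L]] - s@frames[[1L]])) <= 1 / 255)
  ecg <- readECGcsv(file.path(dir, "ecg.csv"), fs = 128)
  expect_equal(samples(ecg), samples(s@ecg))
})
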