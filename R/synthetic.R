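# Synthetic session generator: ECG with known R-peak/heart-rate ground truth
# and procedurally drawn face frames whose deformation tracks the pain level.

#' Generate a synthetic ECG with ground truth
#'
#' Builds an amplitude sequence as baseline wander plus a QRS-like wavelet
#' train (with a smaller, broader T wave after each beat) placed at spacings
#' of `round(60 * fs / BPM)` samples, plus optional white noise. The true
#' R-peak indices and the per-second BPM profile are stored alongside the
#' samples so that detection and heart-rate extraction can be scored against
#' ground truth.
#'
#' @param bpmProfile numeric BPM per second (values in \[30, 220\]); recycled
#'   or truncated to `floor(duration)` entries.
#' @param fs sampling frequency in Hz.
#' @param duration record length in seconds.
#' @param noiseSd standard deviation of additive white noise (R amplitude
#'   is 1).
#' @param seed RNG seed for the noise and wander phase.
#' @return A [SyntheticECG-class] with `length = round(duration * fs)`
#'   samples.
#' @examples
#' e <- synthECG(60, fs = 512, duration = 5.5)
#' diff(rPeaks(e))  # exactly 512 samples between beats
#' @export
synthECG <- function(bpmProfile, fs = 512, duration = 5.5, noiseSd = 0,
                     seed = 1L) {
  if (fs <= 0 || duration <= 0)
    pfStop("invalidArgument", "fs and duration must be positive")
  if (any(bpmProfile < 30 | bpmProfile > 220))
    pfStop("invalidArgument", "BPM values must lie in [30, 220]")
  nSec <- max(floor(duration), 1L)
  bpm <- rep_len(bpmProfile, nSec)
  n <- round(duration * fs)

  # beat positions: instantaneous BPM read from the profile second the
  # current beat falls in; spacing round(60 * fs / BPM)
  peaks <- integer(0)
  cur <- round(0.25 * fs)             # first beat at 0.25 s
  while (cur < n) {
    peaks <- c(peaks, cur)
    sec <- min(floor(cur / fs) + 1L, nSec)
    cur <- cur + round(60 * fs / bpm[sec])
  }

  withSeed(seed, {
    t <- (seq_len(n) - 1) / fs
    sig <- 0.1 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
    idx <- seq_len(n) - 1L
    qrsW <- 0.012 * fs                # ~24 ms QRS half-width
    tW <- 0.05 * fs
    for (p in peaks) {
      d2 <- (idx - p) / qrsW
      near <- abs(d2) < 6
      # Ricker (Mexican-hat) wavelet: sharp positive R with small side lobes
      sig[near] <- sig[near] + (1 - d2[near]^2) * exp(-d2[near]^2 / 2)
      dt <- (idx - (p + round(0.24 * fs))) / tW
      nearT <- abs(dt) < 5
      sig[nearT] <- sig[nearT] + 0.2 * exp(-dt[nearT]^2 / 2)
    }
    if (noiseSd > 0) sig <- sig + stats::rnorm(n, sd = noiseSd)
    methods::new("SyntheticECG", samples = sig, fs = fs,
                 rPeaksTruth = as.integer(peaks), hrTruth = bpm)
  })
}

# level index of a pain label: NP = 0, P1..P4 = 1..4
painLevel <- function(label) {
  match(label, PAIN_LEVELS) - 1L
}

# subject-specific stable quantities (baseline BPM, face geometry jitter)
subjectTraits <- function(subjectId, seed) {
  subjNum <- sum(utf8ToInt(as.character(subjectId)))
  withSeed(subSeed(seed, 7L, subjNum), {
    list(baselineBpm = 70 + stats::runif(1, -8, 8),
         faceJitter = stats::runif(3, -0.03, 0.03))
  })
}

# draw one 448 x 448 x 3 face surrogate: ellipse head, eyes, brow and mouth
# strokes; `deform` bends brows and stretches the mouth, scaled by the
# within-session ramp `frameFrac`.
drawFaceFrame <- function(deform, frameFrac, jitter = c(0, 0, 0),
                          size = 448L) {
  u <- (seq_len(size) - size / 2) / (size / 2)  # vertical, -1..1
  v <- u                                        # horizontal
  U <- matrix(u, size, size)
  V <- matrix(v, size, size, byrow = TRUE)
  amp <- deform * (0.3 + 0.7 * frameFrac)

  img <- matrix(0.15, size, size)
  head <- (U / (0.85 + jitter[1]))^2 + (V / (0.62 + jitter[2]))^2 <= 1
  img[head] <- 0.75

  eyeY <- -0.25 + jitter[3]
  for (ex in c(-0.25, 0.25)) {
    eye <- ((U - eyeY) / 0.06)^2 + ((V - ex) / 0.1)^2 <= 1
    img[eye] <- 0.2
  }
  # brows: quadratic strokes whose curvature increases with deformation
  for (ex in c(-0.25, 0.25)) {
    browY <- eyeY - 0.14 + amp * 0.1 * sign(ex) * (V - ex) / 0.12 -
      amp * 0.25 * ((V - ex) / 0.12)^2
    brow <- abs(U - browY) <= 0.025 & abs(V - ex) <= 0.13
    img[brow] <- 0.05
  }
  # mouth: horizontal stroke that opens/curves downward with deformation
  mouthY <- 0.4 + amp * 0.3 * (V / 0.2)^2
  mouth <- abs(U - mouthY) <= (0.03 + amp * 0.06) & abs(V) <= (0.2 + amp * 0.05)
  img[mouth] <- 0.1

  array(rep(img, 3L) * rep(c(1, 0.85, 0.75), each = size * size),
        c(size, size, 3L))
}

#' Generate one synthetic session
#'
#' Produces a paired video + ECG sample for one subject and pain label.
#' Facial deformation amplitude grows with the pain level and ramps up
#' toward the end of the session; the ECG BPM is offset from the subject's
#' baseline by `level * bpmEffect`. Deterministic under
#' `(subjectId, label, spec@seed, rep)`.
#'
#' @param subjectId subject identifier (character or coercible).
#' @param label pain class, one of `"NP"`, `"P1"`..`"P4"`.
#' @param spec a [ProtocolSpec-class].
#' @param rep repetition index, distinguishing a subject's sessions at the
#'   same level.
#' @param materializeFrames if `FALSE`, skip drawing the frame arrays (the
#'   ECG and ground truth are still generated).
#' @return A [SyntheticSession-class].
#' @export
synthSession <- function(subjectId, label, spec = protocolSpec(), rep = 1L,
                         materializeFrames = TRUE) {
  if (!label %in% PAIN_LEVELS)
    pfStop("invalidArgument", paste("invalid label:", label))
  level <- painLevel(label)
  traits <- subjectTraits(subjectId, spec@seed)
  subjNum <- sum(utf8ToInt(as.character(subjectId)))
  sSeed <- subSeed(spec@seed, subjNum, level, rep)

  nSec <- max(floor(spec@windowS), 1L)
  bpm <- withSeed(sSeed, {
    base <- traits$baselineBpm + level * spec@bpmEffect +
      stats::rnorm(1, sd = spec@bpmSessionSd)
    pmin(pmax(base + stats::rnorm(nSec, sd = spec@bpmSecondSd), 30), 220)
  })
  ecg <- synthECG(bpm, fs = spec@fs, duration = spec@windowS,
                  noiseSd = spec@ecgNoiseSd, seed = subSeed(sSeed, 11L))

  frames <- list()
  if (materializeFrames) {
    nFrames <- round(spec@windowS * spec@fps)
    deform <- level * spec@deformEffect
    frames <- lapply(seq_len(nFrames), function(i) {
      frac <- if (nFrames > 1L) (i - 1) / (nFrames - 1) else 1
      drawFaceFrame(deform, frac, traits$faceJitter)
    })
  }
  methods::new("SyntheticSession", frames = frames, ecg = ecg,
               label = label, subjectId = as.character(subjectId))
}

#' Generate a full synthetic dataset manifest
#'
#' Lays out the complete protocol: for every subject, `nBaseline` NP
#' sessions plus `repsPerLevel` sessions at each pain level, shuffled per
#' subject with a subject-derived seed to emulate randomised stimulation
#' order. Sessions are materialised lazily via [sessionFromManifest()]; the
#' manifest carries everything needed to regenerate any session
#' deterministically.
#'
#' @param spec a [ProtocolSpec-class].
#' @param dir optional directory; when given, the manifest is written there
#'   as `manifest.csv` and per-session data can be exported with
#'   [writeSession()].
#' @return A list with `manifest` (data.frame: subject, session, label, rep,
#'   path) and `spec`.
#' @examples
#' ds <- synthDataset(protocolSpec(nSubjects = 2, repsPerLevel = 1,
#'                                 nBaseline = 1))
#' nrow(ds$manifest)  # 2 subjects x 5 sessions
#' @export
synthDataset <- function(spec = protocolSpec(), dir = NULL) {
  perSub <- sessionsPerSubject(spec)
  rows <- vector("list", spec@nSubjects)
  for (s in seq_len(spec@nSubjects)) {
    subjectId <- sprintf("S%03d", s)
    labels <- c(rep("NP", spec@nBaseline),
                rep(PAIN_LEVELS[seq_len(spec@nPainLevels) + 1L],
                    each = spec@repsPerLevel))
    reps <- c(seq_len(spec@nBaseline),
              rep(seq_len(spec@repsPerLevel), times = spec@nPainLevels))
    ord <- withSeed(subSeed(spec@seed, 13L, s), sample.int(perSub))
    rows[[s]] <- data.frame(subject = subjectId,
                            session = seq_len(perSub),
                            label = labels[ord], rep = reps[ord],
                            path = NA_character_,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, sprintf("%s_%03d", manifest$subject,
                                            manifest$session))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, spec = spec)
}

#' Materialise one session from a dataset manifest
#' @param dataset the list returned by [synthDataset()].
#' @param row manifest row index.
#' @param materializeFrames whether to draw the frame arrays.
#' @return A [SyntheticSession-class].
#' @export
sessionFromManifest <- function(dataset, row, materializeFrames = TRUE) {
  r <- dataset$manifest[row, ]
  synthSession(r$subject, r$label, dataset$spec, rep = r$rep,
               materializeFrames = materializeFrames)
}

#' Write a session to disk
#'
#' Frames are written as zero-padded PNG files `frame_%04d.png`, the ECG as
#' a two-column CSV (`sample_index`, `amplitude`) and the ground truth as
#' `truth.csv`.
#'
#' @param session a [SyntheticSession-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(session@frames)) {
    png::writePNG(session@frames[[i]],
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  utils::write.csv(data.frame(sample_index = seq_along(session@ecg@samples) - 1L,
                              amplitude = session@ecg@samples),
                   file.path(dir, "ecg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(r_peak = session@ecg@rPeaksTruth),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
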