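# S4 classes for the framework's central data objects.

PAIN_LEVELS <- c("NP", "P1", "P2", "P3", "P4")

#' @title Single-lead ECG signal
#' @description Amplitude samples with their sampling frequency.
#' @slot samples numeric amplitude sequence (arbitrary units).
#' @slot fs sampling frequency in Hz.
#' @exportClass ECGSignal
setClass("ECGSignal",
         representation(samples = "numeric", fs = "numeric"),
         validity = function(object) {
           if (length(object@fs) != 1L || object@fs <= 0)
             return("fs must be a single positive number")
           TRUE
         })

#' Construct an ECGSignal
#' @param samples numeric amplitude vector.
#' @param fs sampling frequency in Hz.
#' @return An [ECGSignal-class] object.
#' @export
ECGSignal <- function(samples, fs) {
  methods::new("ECGSignal", samples = as.numeric(samples), fs = fs)
}

#' @title Synthetic ECG with ground truth
#' @description An [ECGSignal-class] carrying the R-peak positions and the
#'   per-second heart rate it was generated from.
#' @slot rPeaksTruth integer 0-based sample indices of the true R peaks.
#' @slot hrTruth numeric true BPM per 1-second segment.
#' @exportClass SyntheticECG
setClass("SyntheticECG", contains = "ECGSignal",
         representation(rPeaksTruth = "integer", hrTruth = "numeric"))

#' @title Detected R-peak series
#' @slot indices integer 0-based sample positions of R waves, strictly
#'   increasing, spacing at least the 200 ms refractory period.
#' @slot fs sampling frequency in Hz.
#' @slot flags character vector of warning flags (e.g. `"no-peaks"`).
#' @exportClass RPeakSeries
setClass("RPeakSeries",
         representation(indices = "integer", fs = "numeric",
                        flags = "character"),
         prototype(flags = character(0)),
         validity = function(object) {
           idx <- object@indices
           if (length(idx) >= 2L) {
             d <- diff(idx)
             if (any(d <= 0)) return("indices must be strictly increasing")
             if (any(d < 0.2 * object@fs))
               return("peak spacing violates the 200 ms refractory period")
           }
           TRUE
         })

#' @title Inter-beat interval summary
#' @slot intervals numeric sample-count differences of consecutive R peaks.
#' @slot n number of IBIs.
#' @slot mu mean IBI in samples.
#' @exportClass IBISummary
setClass("IBISummary",
         representation(intervals = "numeric", n = "integer", mu = "numeric"),
         validity = function(object) {
           if (object@n != length(object@intervals))
             return("n must equal length(intervals)")
           if (object@n > 0 &&
               abs(object@mu - mean(object@intervals)) > 1e-8 * max(1, object@mu))
             return("mu must be the arithmetic mean of intervals")
           TRUE
         })

#' @title Per-second heart-rate series
#' @slot values BPM per 1-second segment (length theta = floor(duration)).
#' @slot filledMask logical flags for gap-filled entries.
#' @exportClass HeartRateSeries
setClass("HeartRateSeries",
         representation(values = "numeric", filledMask = "logical"),
         validity = function(object) {
           if (length(object@values) != length(object@filledMask))
             return("values and filledMask must have equal length")
           if (any(!is.finite(object@values)) || any(object@values <= 0))
             return("all values must be positive and finite after filling")
           TRUE
         })

#' @title Cropped face image
#' @slot image 448 x 448 x 3 RGB array, values in [0, 1].
#' @slot sourceFrameIndex index of the originating video frame.
#' @exportClass FaceCrop
setClass("FaceCrop",
         representation(image = "array", sourceFrameIndex = "integer"),
         validity = function(object) {
           d <- dim(object@image)
           if (length(d) != 3L || d[1L] != 448L || d[2L] != 448L || d[3L] != 3L)
             return("image must be 448 x 448 x 3")
           TRUE
         })

#' @title Tile decomposition of a face crop
#' @description One bicubic-resized full frame plus the four disjoint
#'   quadrants, each 224 x 224 x 3, ordered top-left, top-right,
#'   bottom-left, bottom-right.
#' @slot full 224 x 224 x 3 resized whole crop.
#' @slot tiles list of 4 quadrant arrays.
#' @exportClass TileSet
setClass("TileSet",
         representation(full = "array", tiles = "list"),
         validity = function(object) {
           ok <- function(a) identical(dim(a), c(224L, 224L, 3L))
           if (!ok(object@full)) return("full must be 224 x 224 x 3")
           if (length(object@tiles) != 4L || !all(vapply(object@tiles, ok, TRUE)))
             return("tiles must be 4 arrays of 224 x 224 x 3")
           TRUE
         })

#' @title Stimulation protocol specification
#' @description Session layout of the heat-pain protocol being emulated:
#'   per subject, `nBaseline` no-pain sessions plus `repsPerLevel`
#'   stimulations at each of `nPainLevels` intensities, each session
#'   `windowS` seconds of video at `fps` and ECG at `fs`. Effect-size slots
#'   control how strongly pain level shifts the synthetic signals.
#' @slot nSubjects,repsPerLevel,nPainLevels,nBaseline protocol counts.
#' @slot windowS session length in seconds.
#' @slot fps video frame rate (frames/second).
#' @slot fs ECG sampling frequency (Hz).
#' @slot seed base RNG seed.
#' @slot bpmEffect per-level heart-rate offset in BPM (level 0 = NP).
#' @slot deformEffect per-level facial deformation amplitude.
#' @slot bpmSessionSd between-session BPM standard deviation.
#' @slot bpmSecondSd within-session per-second BPM standard deviation.
#' @slot ecgNoiseSd white-noise amplitude added to the synthetic ECG.
#' @exportClass ProtocolSpec
setClass("ProtocolSpec",
         representation(nSubjects = "integer", repsPerLevel = "integer",
                        nPainLevels = "integer", nBaseline = "integer",
                        windowS = "numeric", fps = "numeric", fs = "numeric",
                        seed = "integer", bpmEffect = "numeric",
                        deformEffect = "numeric", bpmSessionSd = "numeric",
                        bpmSecondSd = "numeric", ecgNoiseSd = "numeric"),
         validity = function(object) {
           if (object@nSubjects < 1L || object@repsPerLevel < 0L ||
               object@nPainLevels < 1L || object@nBaseline < 0L)
             return("protocol counts must be positive")
           if (object@windowS <= 0 || object@fps <= 0 || object@fs <= 0)
             return("windowS, fps and fs must be positive")
           TRUE
         })

#' Construct a ProtocolSpec
#'
#' Defaults reproduce the emulated protocol: 87 subjects, 20 baseline plus
#' 20 stimulations at each of 4 pain levels (100 sessions/subject, 8,700
#' total), 5.5 s windows at 25 FPS video and 512 Hz ECG.
#'
#' @param nSubjects,repsPerLevel,nPainLevels,nBaseline protocol counts.
#' @param windowS,fps,fs session window (s), frame rate, ECG sampling rate.
#' @param seed base seed for all derived randomness.
#' @param bpmEffect heart-rate offset per pain level in BPM.
#' @param deformEffect facial deformation amplitude per pain level.
#' @param bpmSessionSd,bpmSecondSd between-/within-session BPM variability.
#' @param ecgNoiseSd additive white-noise amplitude for the synthetic ECG.
#' @return A [ProtocolSpec-class] object.
#' @export
protocolSpec <- function(nSubjects = 87L, repsPerLevel = 20L,
                         nPainLevels = 4L, nBaseline = 20L,
                         windowS = 5.5, fps = 25, fs = 512, seed = 1L,
                         bpmEffect = 3, deformEffect = 0.15,
                         bpmSessionSd = 4, bpmSecondSd = 1,
                         ecgNoiseSd = 0.02) {
  methods::new("ProtocolSpec", nSubjects = as.integer(nSubjects),
               repsPerLevel = as.integer(repsPerLevel),
               nPainLevels = as.integer(nPainLevels),
               nBaseline = as.integer(nBaseline), windowS = windowS,
               fps = fps, fs = fs, seed = as.integer(seed),
               bpmEffect = bpmEffect, deformEffect = deformEffect,
               bpmSessionSd = bpmSessionSd, bpmSecondSd = bpmSecondSd,
               ecgNoiseSd = ecgNoiseSd)
}

#' @title Synthetic session
#' @description One paired video + ECG sample: procedurally drawn face
#'   frames, a synthetic ECG with ground truth, the pain label and subject id.
#' @slot frames list of 448 x 448 x 3 frame arrays (possibly empty when the
#'   session has not been materialised).
#' @slot ecg a [SyntheticECG-class].
#' @slot label pain class, one of NP, P1, P2, P3, P4.
#' @slot subjectId subject identifier.
#' @exportClass SyntheticSession
setClass("SyntheticSession",
         representation(frames = "list", ecg = "SyntheticECG",
                        label = "character", subjectId = "character"),
         validity = function(object) {
           if (!object@label %in% PAIN_LEVELS)
             return(paste("label must be one of", paste(PAIN_LEVELS, collapse = ", ")))
           TRUE
         })

#' @title Per-frame embedding
#' @slot D fused frame embedding of length d.
#' @slot components list of the 5 unfused part embeddings (full frame first,
#'   then the 4 tiles), retained for testing the fusion rule.
#' @exportClass FrameEmbedding
setClass("FrameEmbedding",
         representation(D = "numeric", components = "list"))

#' @title Concatenated video embedding
#' @slot vd numeric vector of length N = d * f.
#' @slot d per-frame embedding width.
#' @slot f number of frames.
#' @exportClass VideoEmbedding
setClass("VideoEmbedding",
         representation(vd = "numeric", d = "integer", f = "integer"),
         validity = function(object) {
           if (length(object@vd) != object@d * object@f)
             return("length(vd) must equal d * f")
           TRUE
         })

#' @title Classifier prediction
#' @slot logits numeric vector, one per class.
#' @slot probabilities softmax of the logits (sums to 1).
#' @slot label index (1-based) of the argmax class.
#' @exportClass Prediction
setClass("Prediction",
         representation(logits = "numeric", probabilities = "numeric",
                        label = "integer"),
         validity = function(object) {
           if (abs(sum(object@probabilities) - 1) > 1e-6)
             return("probabilities must sum to 1")
           TRUE
         })

#' @title Parameter/FLOP summary of the framework
#' @slot paramsM named per-module trainable-parameter counts in millions.
#' @slot flopsG named per-module FLOP estimates in Giga for one forward pass.
#' @slot paramsRaw named raw parameter counts.
#' @exportClass ModelSummary
setClass("ModelSummary",
         representation(paramsM = "numeric", flopsG = "numeric",
                        paramsRaw = "numeric"))

#' @title Metrics report for a cross-validated evaluation
#' @slot confusion pooled confusion matrix (rows = truth, cols = predicted).
#' @slot accuracy,precision,recall,f1 pooled accuracy and macro-averaged
#'   precision, recall and F1.
#' @slot perFold list of per-fold confusion matrices.
#' @exportClass MetricsReport
setClass("MetricsReport",
         representation(confusion = "matrix", accuracy = "numeric",
                        precision = "numeric", recall = "numeric",
                        f1 = "numeric", perFold = "list"))

# ---- accessors & show methods ------------------------------------------

#' Number of trainable parameters
#' @param object a model module.
#' @return Integer parameter count.
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

countWeights <- function(w) {
  sum(vapply(w, function(x) {
    if (is.list(x)) countWeights(x) else length(x)
  }, numeric(1)))
}

#' @describeIn ECGSignal-class amplitude samples
#' @param object an object.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
setMethod("samples", "ECGSignal", function(object) object@samples)

#' @describeIn ECGSignal-class sampling frequency (Hz)
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
setMethod("samplingRate", "ECGSignal", function(object) object@fs)
setMethod("samplingRate", "RPeakSeries", function(object) object@fs)

#' @describeIn RPeakSeries-class 0-based R-peak sample indices
#' @export
setGeneric("rPeaks", function(object) standardGeneric("rPeaks"))
setMethod("rPeaks", "RPeakSeries", function(object) object@indices)
setMethod("rPeaks", "SyntheticECG", function(object) object@rPeaksTruth)

#' @describeIn HeartRateSeries-class per-second BPM values
#' @export
setGeneric("hrValues", function(object) standardGeneric("hrValues"))
setMethod("hrValues", "HeartRateSeries", function(object) object@values)
setMethod("hrValues", "SyntheticECG", function(object) object@hrTruth)

#' @describeIn HeartRateSeries-class logical mask of gap-filled entries
#' @export
setGeneric("filledMask", function(object) standardGeneric("filledMask"))
setMethod("filledMask", "HeartRateSeries", function(object) object@filledMask)

setMethod("show", "ECGSignal", function(object) {
  cat(sprintf("%s: %d samples at %g Hz (%.2f s)\n", class(object),
              length(object@samples), object@fs,
              length(object@samples) / object@fs))
})

setMethod("show", "RPeakSeries", function(object) {
  cat(sprintf("RPeakSeries: %d peaks at %g Hz", length(object@indices),
              object@fs))
  if (length(object@flags)) cat(" [", paste(object@flags, collapse = ", "), "]")
  cat("\n")
})

setMethod("show", "HeartRateSeries", function(object) {
  cat("HeartRateSeries:", paste(sprintf("%.1f", object@values), collapse = " "),
      "BPM;", sum(object@filledMask), "gap-filled\n")
})

setMethod("show", "ProtocolSpec", function(object) {
  perSub <- object@nBaseline + object@nPainLevels * object@repsPerLevel
  cat(sprintf(paste0("ProtocolSpec: %d subjects x %d sessions (=%d), ",
                     "%.1f s windows, %g FPS video, %g Hz ECG\n"),
              object@nSubjects, perSub, object@nSubjects * perSub,
              object@windowS, object@fps, object@fs))
})

setMethod("show", "Prediction", function(object) {
  cat("Prediction: class", object@label, "| p =",
      paste(sprintf("%.3f", object@probabilities), collapse = " "), "\n")
})

setMethod("show", "ModelSummary", function(object) {
  df <- data.frame(`params (M)` = sprintf("%.2f", object@paramsM),
                   `FLOPs (G)` = sprintf("%.2f", object@flopsG),
                   check.names = FALSE, row.names = names(object@paramsM))
  print(df)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport over %d folds: accuracy %.4f, ",
                     "precision %.4f, recall %.4f, F1 %.4f\n"),
              length(object@perFold), object@accuracy, object@precision,
              object@recall, object@f1))
  print(object@confusion)
})

#' Sessions per subject implied by a protocol
#' @param spec a [ProtocolSpec-class].
#' @return Integer count `nBaseline + nPainLevels * repsPerLevel`.
#' @export
sessionsPerSubject <- function(spec) {
  spec@nBaseline + spec@nPainLevels * spec@repsPerLevel
}
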