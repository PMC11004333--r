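# ECG preprocessing and heart-rate extraction: Pan-Tompkins QRS detection
# (band-pass, derivative, squaring, moving-window integration, adaptive
# thresholds with search-back and T-wave discrimination), mean inter-beat
# interval and per-second heart rate with the gap-fill rule.

PT_REFRACTORY_S <- 0.200   # minimum spacing between accepted beats
PT_TWAVE_S     <- 0.360    # T-wave discrimination window
PT_MWI_S       <- 0.150    # moving-window integration length

#' Pan-Tompkins preprocessing stages
#'
#' Applies the four classical preprocessing stages to a raw ECG: 5--15 Hz
#' band-pass (zero-phase Butterworth, so R indices stay aligned with the raw
#' axis), five-point derivative emphasising QRS slope, element-wise
#' squaring, and a 150 ms moving-window integration. All outputs have the
#' input length (edges are replicate-padded).
#'
#' @param ecg an [ECGSignal-class].
#' @return A list with `bandpassed`, `derivative`, `squared` and
#'   `integrated` numeric vectors.
#' @export
panTompkinsPreprocess <- function(ecg) {
  fs <- ecg@fs
  x <- ecg@samples
  if (fs < 30)
    pfStop("invalidArgument", "fs below 30 Hz cannot support the 5-15 Hz pass-band")
  if (length(x) < 3 * fs / 5)
    pfStop("invalidArgument", "record shorter than the filter warm-up")

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))

  # symmetric five-point derivative (zero-phase counterpart of the classical
  # causal (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4]) filter)
  kd <- c(2, 1, 0, -1, -2) / 8 * (fs / 10)
  der <- as.numeric(stats::filter(c(rep(bp[1], 2), bp, rep(bp[length(bp)], 2)),
                                  kd, sides = 2))[3:(length(bp) + 2)]
  sq <- der * der
  w <- max(round(PT_MWI_S * fs), 1L)
  kw <- rep(1 / w, w)
  pad <- ceiling(w / 2)
  mwi <- as.numeric(stats::filter(c(rep(sq[1], pad), sq,
                                    rep(sq[length(sq)], pad)),
                                  kw, sides = 2))[(pad + 1):(pad + length(sq))]
  list(bandpassed = bp, derivative = der, squared = sq, integrated = mwi)
}

# local maxima of v (plateau-tolerant), as integer positions
localMaxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# greedy non-maximum suppression: drop any candidate within minDist of a
# larger one, so noise bumps riding the flank of a QRS cannot pre-empt it
suppressNeighbours <- function(pos, amp, minDist) {
  keep <- logical(length(pos))
  for (i in order(amp, decreasing = TRUE)) {
    if (!any(keep & abs(pos - pos[i]) < minDist)) keep[i] <- TRUE
  }
  sort(pos[keep])
}

#' Detect R peaks with adaptive thresholds
#'
#' Decision stage of the Pan-Tompkins detector: candidate peaks are local
#' maxima of the integrated signal; running signal/noise levels are updated
#' with 0.125/0.875 coefficients; when more than 1.66 times the running RR
#' average elapses without a beat, a search-back re-examines rejected
#' candidates at half threshold; candidates within 360 ms of the previous
#' beat whose maximal slope is below half the previous beat's slope are
#' rejected as T waves; a 200 ms refractory period is enforced. Accepted
#' peaks are refined to the band-passed maximum within +/-100 ms so indices
#' live on the raw sample axis.
#'
#' @param ecg an [ECGSignal-class] of at least 2 s.
#' @return An [RPeakSeries-class]; empty with flag `"no-peaks"` if nothing
#'   is found (possible asystole or flat input).
#' @export
detectRPeaks <- function(ecg) {
  fs <- ecg@fs
  n <- length(ecg@samples)
  if (n < 2 * fs)
    pfStop("invalidArgument", "R-peak detection needs at least 2 s of signal")
  st <- panTompkinsPreprocess(ecg)
  mwi <- st$integrated
  cand <- localMaxima(mwi)
  cand <- cand[mwi[cand] > 1e-12 * max(mwi, 1e-300)]
  cand <- suppressNeighbours(cand, mwi[cand], PT_REFRACTORY_S * fs)
  if (!length(cand) || max(mwi) <= 0) {
    return(methods::new("RPeakSeries", indices = integer(0), fs = fs,
                        flags = "no-peaks"))
  }

  refr <- PT_REFRACTORY_S * fs
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  slope <- function(p) {                      # max |derivative| near p
    lo <- max(1L, p - round(0.075 * fs)); hi <- min(n, p + round(0.075 * fs))
    max(abs(st$derivative[lo:hi]))
  }

  accepted <- integer(0)
  acceptedSlope <- numeric(0)
  rrBuf <- numeric(0)
  rejected <- integer(0)

  acceptPeak <- function(p, searchBack = FALSE) {
    if (searchBack) spki <<- 0.25 * mwi[p] + 0.75 * spki
    else spki <<- 0.125 * mwi[p] + 0.875 * spki
    if (length(accepted)) {
      rrBuf <<- c(rrBuf, p - accepted[length(accepted)])
      if (length(rrBuf) > 8L) rrBuf <<- rrBuf[(length(rrBuf) - 7L):length(rrBuf)]
    }
    accepted <<- c(accepted, p)
    acceptedSlope <<- c(acceptedSlope, slope(p))
  }

  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    last <- if (length(accepted)) accepted[length(accepted)] else -Inf

    # search-back: expected-beat window elapsed without an accepted beat
    if (length(rrBuf) >= 2L && length(rejected)) {
      rrAvg <- mean(rrBuf)
      if (p - last > 1.66 * rrAvg) {
        sb <- rejected[rejected > last + refr & rejected < p - refr]
        sb <- sb[mwi[sb] >= 0.5 * thr]
        if (length(sb)) {
          acceptPeak(sb[which.max(mwi[sb])], searchBack = TRUE)
          last <- accepted[length(accepted)]
        }
      }
    }

    if (p - last < refr) next                # refractory: not even noise
    if (mwi[p] >= thr) {
      # T-wave discrimination inside the 360 ms window
      if (p - last < PT_TWAVE_S * fs &&
          slope(p) < 0.5 * acceptedSlope[length(acceptedSlope)]) {
        npki <- 0.125 * mwi[p] + 0.875 * npki
        rejected <- c(rejected, p)
      } else {
        acceptPeak(p)
      }
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      rejected <- c(rejected, p)
    }
  }

  if (!length(accepted)) {
    return(methods::new("RPeakSeries", indices = integer(0), fs = fs,
                        flags = "no-peaks"))
  }

  # refine to the band-passed maximum; band-pass is zero-phase so the index
  # lies on the original axis
  half <- round(0.100 * fs)
  refined <- vapply(accepted, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(st$bandpassed[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  keep <- c(TRUE, diff(refined) >= refr)     # enforce refractory after refinement
  refined <- refined[keep]

  methods::new("RPeakSeries", indices = as.integer(refined - 1L), fs = fs)
}

#' Mean inter-beat interval
#'
#' Summarises consecutive R-peak spacings: `mu` is the arithmetic mean of
#' the `n` inter-beat intervals, in samples.
#'
#' @param peaks an [RPeakSeries-class] with at least 2 peaks.
#' @return An [IBISummary-class].
#' @export
computeMeanIBI <- function(peaks) {
  idx <- peaks@indices
  if (length(idx) < 2L)
    pfStop("insufficientBeats", "at least 2 R peaks are required")
  iv <- as.numeric(diff(idx))
  methods::new("IBISummary", intervals = iv, n = length(iv), mu = mean(iv))
}

#' Heart rate from a mean inter-beat interval
#'
#' `HR = 60 * fs / mu`, converting the mean IBI in samples to beats per
#' minute.
#'
#' @param ibi an [IBISummary-class] (or a single numeric mean IBI).
#' @param fs sampling frequency in Hz.
#' @return Heart rate in BPM.
#' @export
computeHeartRate <- function(ibi, fs) {
  mu <- if (methods::is(ibi, "IBISummary")) ibi@mu else as.numeric(ibi)
  if (!is.finite(mu) || mu <= 0)
    pfStop("invalidArgument", "mean IBI must be positive")
  60 * fs / mu
}

# fill NA entries with the mean of the nearest computed neighbours;
# boundary gaps take the single nearest computed value
fillGaps <- function(values) {
  filled <- is.na(values)
  if (all(filled)) pfStop("unrecoverableRecord", "no segment yields a heart rate")
  comp <- which(!filled)
  for (k in which(filled)) {
    before <- comp[comp < k]
    after <- comp[comp > k]
    values[k] <- if (length(before) && length(after)) {
      (values[max(before)] + values[min(after)]) / 2
    } else if (length(before)) values[max(before)] else values[min(after)]
  }
  list(values = values, filledMask = filled)
}

#' Per-second heart-rate series
#'
#' Splits the record into `floor(windowS)` consecutive 1-second segments.
#' R peaks are detected once over the whole record; an inter-beat interval
#' is attributed to the segment its earlier peak falls in (half-open
#' `[k*fs, (k+1)*fs)` convention, so the interval bracketing a boundary
#' contributes to the earlier segment). Segments without a usable interval
#' -- fewer than 2 attributable peaks, the case in which the mean-IBI
#' formula is undefined -- are gap-filled with the mean of the nearest
#' preceding and following computed values (boundary gaps take the single
#' nearest value).
#'
#' @param ecg an [ECGSignal-class] covering at least `windowS` seconds.
#' @param windowS analysis window in seconds (>= 2 so the fill rule has
#'   neighbours).
#' @return A [HeartRateSeries-class] of length `floor(windowS)`.
#' @export
hrPerSecond <- function(ecg, windowS = length(ecg@samples) / ecg@fs) {
  fs <- ecg@fs
  if (windowS < 2)
    pfStop("invalidArgument", "windowS must be at least 2 s")
  if (length(ecg@samples) < windowS * fs - 1e-9)
    pfStop("invalidArgument", "record shorter than windowS")
  theta <- floor(windowS)
  pk <- detectRPeaks(ecg)@indices            # 0-based
  vals <- rep(NA_real_, theta)
  if (length(pk) >= 2L) {
    iv <- diff(pk)
    seg <- floor(pk[-length(pk)] / fs)       # segment of the earlier peak
    for (k in seq_len(theta) - 1L) {
      ivk <- iv[seg == k]
      if (length(ivk)) vals[k + 1L] <- 60 * fs / mean(ivk)
    }
  }
  f <- fillGaps(vals)
  methods::new("HeartRateSeries", values = f$values, filledMask = f$filledMask)
}

#' Read an ECG from a two-column CSV
#' @param path CSV with columns `sample_index`, `amplitude` (header
#'   optional; the second column is used).
#' @param fs sampling frequency in Hz.
#' @return An [ECGSignal-class].
#' @export
readECGcsv <- function(path, fs) {
  df <- utils::read.csv(path)
  ECGSignal(df[[2L]], fs = fs)
}

#' Write a heart-rate series as CSV
#' @param hrs a [HeartRateSeries-class].
#' @param path output CSV path; columns `second_index`, `bpm`,
#'   `filled_flag`.
#' @return `path`, invisibly.
#' @export
writeHeartRateCsv <- function(hrs, path) {
  utils::write.csv(data.frame(second_index = seq_along(hrs@values) - 1L,
                              bpm = hrs@values,
                              filled_flag = as.integer(hrs@filledMask)),
                   path, row.names = FALSE)
  invisible(path)
}
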