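#' QRS detector configuration
#'
#' All stage constants of the classic real-time QRS detection algorithm:
#' bandpass edges, derivative span, moving-integration window, refractory
#' period, running-estimate update weights and the search-back factor.
#'
#' @param bandpassLow,bandpassHigh passband edges in Hz (QRS energy is
#'   concentrated around 5-15 Hz).
#' @param derivativeSpan span of the five-point derivative, samples.
#' @param integrationWindowSeconds moving-window integration length.
#' @param refractorySeconds minimum spacing between accepted peaks.
#' @param searchbackRrFactor a missed-beat search-back is triggered when the
#'   gap since the last accepted peak exceeds this multiple of the running
#'   R-R average.
#' @param thresholdUpdateWeights length-2 numeric: exponential update weight
#'   of the running signal and noise level estimates.
#'
#' @return validated list of class `detectorConfig`.
#' @export
detectorConfig <- function(bandpassLow = 5, bandpassHigh = 15,
                           derivativeSpan = 5L,
                           integrationWindowSeconds = 0.150,
                           refractorySeconds = 0.200,
                           searchbackRrFactor = 1.66,
                           thresholdUpdateWeights = c(0.125, 0.125)) {
  if (bandpassLow <= 0 || bandpassHigh <= bandpassLow) {
    stop("need 0 < bandpassLow < bandpassHigh")
  }
  if (integrationWindowSeconds <= 0 || refractorySeconds <= 0) {
    stop("integration and refractory windows must be positive")
  }
  if (length(thresholdUpdateWeights) != 2L) {
    stop("thresholdUpdateWeights must have length 2")
  }
  structure(
    list(
      bandpassLow = bandpassLow, bandpassHigh = bandpassHigh,
      derivativeSpan = as.integer(derivativeSpan),
      integrationWindowSeconds = integrationWindowSeconds,
      refractorySeconds = refractorySeconds,
      searchbackRrFactor = searchbackRrFactor,
      thresholdUpdateWeights = thresholdUpdateWeights
    ),
    class = "detectorConfig"
  )
}

# detector core on one chunk; returns 0-based indices into `x`
pan_tompkins_chunk <- function(x, fs, config) {
  n <- length(x)
  ## 1. bandpass (zero-phase to keep peaks aligned with the input)
  bf <- signal::butter(2, c(config$bandpassLow, config$bandpassHigh) / (fs / 2),
    type = "pass"
  )
  xb <- signal::filtfilt(bf, x)
  ## 2. five-point derivative  (1/8)[-1 -2 0 2 1]
  d <- stats::filter(xb, c(1, 2, 0, -2, -1) / 8, sides = 2)
  d[is.na(d)] <- 0
  ## 3. squaring
  sq <- as.numeric(d)^2
  ## 4. moving-window integration
  w <- max(1L, round(config$integrationWindowSeconds * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  ## candidate peaks: local maxima of the integrated signal
  refr <- round(config$refractorySeconds * fs)
  isPk <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(isPk)) {
    return(integer(0))
  }

  ## 5. adaptive dual thresholds with running signal/noise estimates
  wSig <- config$thresholdUpdateWeights[1L]
  wNoi <- config$thresholdUpdateWeights[2L]
  init <- mwi[seq_len(min(n, 2L * fs))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  accepted <- integer(0)
  rrAvg <- NA_real_
  lastQrs <- -Inf
  noiseBuf <- integer(0) # rejected candidates, for search-back

  accept <- function(i) {
    spki <<- wSig * mwi[i] + (1 - wSig) * spki
    rr <- i - lastQrs
    if (is.finite(rr)) {
      rrAvg <<- if (is.na(rrAvg)) rr else 0.875 * rrAvg + 0.125 * rr
    }
    lastQrs <<- i
    accepted <<- c(accepted, i)
  }

  ## snap each candidate to the nearest bandpass-energy maximum: the MWI of
  ## a narrow QRS is a plateau, so its local maximum can sit half an
  ## integration window away from the R apex
  snap <- function(i) {
    lo <- max(1L, as.integer(i - w))
    hi <- min(n, as.integer(i + w))
    as.integer(lo + which.max(abs(xb[lo:hi])) - 1L)
  }

  for (i in isPk) {
    thr1 <- npki + 0.25 * (spki - npki)
    if (i - lastQrs < refr) next
    if (mwi[i] > thr1) {
      accept(i)
      noiseBuf <- integer(0)
    } else {
      npki <- wNoi * mwi[i] + (1 - wNoi) * npki
      noiseBuf <- c(noiseBuf, i)
      ## search-back: if a beat is overdue, take the best rejected
      ## candidate above the lower threshold thr1/2
      if (!is.na(rrAvg) && (i - lastQrs) > config$searchbackRrFactor * rrAvg &&
        length(noiseBuf)) {
        cand <- noiseBuf[noiseBuf - lastQrs >= refr]
        if (length(cand)) {
          best <- cand[which.max(mwi[cand])]
          if (mwi[best] > thr1 / 2) {
            accept(best)
            noiseBuf <- integer(0)
          }
        }
      }
    }
  }
  sort(unique(vapply(accepted, snap, integer(1)))) - 1L
}

# refine 0-based candidate indices to the local maximum of `x` within +/- tol
refine_peaks <- function(peaks0, x, tolSamples) {
  n <- length(x)
  vapply(peaks0, function(p) {
    lo <- max(0L, as.integer(p - tolSamples))
    hi <- min(n - 1L, as.integer(p + tolSamples))
    seg <- x[(lo:hi) + 1L]
    lo + which.max(seg) - 1L
  }, integer(1))
}

#' Pan-Tompkins R-peak detection
#'
#' Classic QRS detection pipeline: bandpass filter, five-point derivative,
#' squaring, moving-window integration, adaptive dual-threshold peak picking
#' with running signal/noise estimates, refractory suppression and R-R
#' search-back for missed beats. The signal is processed in 60-second chunks
#' with 1 s overlap (duplicate detections in the overlap are merged),
#' and detected peaks are refined to the local maximum of the input within
#' +/- 50 ms so they align with the R apex rather than the integrator lag.
#'
#' @param x numeric vector: single-channel (denoised) ECG, millivolts.
#' @param fs sampling rate, Hz; must be at least `2 * bandpassHigh`.
#' @param config a [detectorConfig()].
#'
#' @return strictly increasing integer vector of 0-based R-peak sample
#'   indices (empty for e.g. a flat signal).
#' @examples
#' gen <- generateRecord(rhythmSpec(meanBpm = 75, duration = 20, seed = 2))
#' peaks <- panTompkins(channelSignal(gen$record), 360)
#' length(peaks)
#' @export
panTompkins <- function(x, fs, config = detectorConfig()) {
  if (fs < 2 * config$bandpassHigh) {
    stop("fs must be at least twice bandpassHigh")
  }
  if (length(x) < 2 * fs) stop("signal must be at least 2 seconds long")
  if (max(x) - min(x) < 1e-12) {
    return(integer(0))
  }

  chunk <- 60L * fs
  overlap <- 1L * fs
  starts <- seq(0L, max(0L, length(x) - 1L), by = chunk)
  peaks <- integer(0)
  for (s in starts) {
    e <- min(length(x), s + chunk + overlap)
    if (e - s < 2 * fs) {
      # tail shorter than the detector minimum: extend the previous chunk
      next
    }
    p <- pan_tompkins_chunk(x[(s + 1L):e], fs, config) + s
    peaks <- c(peaks, p)
  }
  peaks <- sort(unique(peaks))

  tol <- round(0.05 * fs)
  peaks <- sort(unique(refine_peaks(peaks, x, tol)))

  ## de-duplicate: enforce the refractory period, keeping the larger peak
  refr <- round(config$refractorySeconds * fs)
  if (length(peaks) > 1L) {
    keep <- logical(length(peaks))
    keep[1L] <- TRUE
    lastKept <- 1L
    for (i in 2L:length(peaks)) {
      if (peaks[i] - peaks[lastKept] >= refr) {
        keep[i] <- TRUE
        lastKept <- i
      } else if (x[peaks[i] + 1L] > x[peaks[lastKept] + 1L]) {
        keep[lastKept] <- FALSE
        keep[i] <- TRUE
        lastKept <- i
      }
    }
    peaks <- peaks[keep]
  }
  as.integer(peaks)
}

#' R-R interval series
#'
#' @param rPeaks strictly increasing 0-based R-peak sample indices.
#' @param fs sampling rate, Hz.
#' @return list of class `rriSeries` with `valuesMs` (intervals in
#'   milliseconds, length `n_peaks - 1`) and `pairedBeatIndices` (two-column
#'   matrix of the flanking peak indices, 1-based into `rPeaks`). Fewer than
#'   two peaks yield an empty series.
#' @examples
#' computeRri(c(0L, 360L, 720L), 360)$valuesMs # 1000 1000
#' @export
computeRri <- function(rPeaks, fs) {
  if (fs <= 0) stop("fs must be positive")
  if (length(rPeaks) > 1L && any(diff(rPeaks) <= 0)) {
    stop("rPeaks must be strictly increasing")
  }
  if (length(rPeaks) < 2L) {
    return(structure(
      list(
        valuesMs = numeric(0),
        pairedBeatIndices = matrix(integer(0), ncol = 2L)
      ),
      class = "rriSeries"
    ))
  }
  vals <- diff(rPeaks) / fs * 1000
  structure(
    list(
      valuesMs = as.numeric(vals),
      pairedBeatIndices = cbind(
        seq_len(length(rPeaks) - 1L),
        2:length(rPeaks)
      )
    ),
    class = "rriSeries"
  )
}

#' Per-beat R-R interval features
#'
#' Computes the four-feature RRI vector used as the classifier's parallel
#' input: the interval preceding the beat, the interval following it, the
#' local mean interval over a window of beats, and the ratio of the
#' preceding interval to the local mean (values near 1 indicate a regular
#' rhythm; values well below 1 flag a premature beat). Missing neighbours
#' at record edges are imputed with the local mean.
#'
#' @param rri an `rriSeries` from [computeRri()].
#' @param beatPosition 1-based index of the beat among the detected peaks.
#' @param localWindow number of surrounding intervals in the local mean.
#'
#' @return named numeric vector
#'   `c(pre_rr_ms, post_rr_ms, local_mean_rr_ms, pre_over_local)` with an
#'   attribute `imputed` (logical) marking edge imputation.
#' @examples
#' rri <- computeRri(seq(0L, 3600L, by = 288L), 360)
#' rriFeatures(rri, 3) # regular 800 ms rhythm -> ratio 1
#' @export
rriFeatures <- function(rri, beatPosition, localWindow = 10L) {
  v <- rri$valuesMs
  if (!length(v)) {
    stop("empty RRI series: drop this beat (record has fewer than 2 peaks)")
  }
  nBeats <- length(v) + 1L
  if (beatPosition < 1L || beatPosition > nBeats) {
    stop("beatPosition out of range")
  }
  # intervals v[i] connect beat i to beat i+1 (1-based beats)
  preIdx <- beatPosition - 1L
  postIdx <- beatPosition
  lo <- max(1L, beatPosition - localWindow %/% 2L - 1L)
  hi <- min(length(v), beatPosition + localWindow %/% 2L)
  localMean <- mean(v[lo:hi])
  imputed <- c(pre = FALSE, post = FALSE)
  pre <- if (preIdx >= 1L) v[preIdx] else {
    imputed["pre"] <- TRUE
    localMean
  }
  post <- if (postIdx <= length(v)) v[postIdx] else {
    imputed["post"] <- TRUE
    localMean
  }
  out <- c(
    pre_rr_ms = pre, post_rr_ms = post,
    local_mean_rr_ms = localMean, pre_over_local = pre / localMean
  )
  attr(out, "imputed") <- imputed
  out
}

#' Match detected peaks against ground truth
#'
#' Greedy one-to-one interval matching at a tolerance, the standard way of
#' scoring a QRS detector against reference annotations.
#'
#' @param detected,truth 0-based sample indices.
#' @param fs sampling rate, Hz.
#' @param tolSeconds match tolerance (default 50 ms).
#' @return list with counts `TP`, `FP`, `FN` and rates `sensitivity`
#'   (TP / (TP + FN)) and `ppv` (TP / (TP + FP)).
#' @export
matchPeaks <- function(detected, truth, fs, tolSeconds = 0.05) {
  tol <- tolSeconds * fs
  usedDet <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    cand <- which(!usedDet & abs(detected - t) <= tol)
    if (length(cand)) {
      best <- cand[which.min(abs(detected[cand] - t))]
      usedDet[best] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!usedDet)
  fn <- length(truth) - tp
  list(
    TP = tp, FP = fp, FN = fn,
    sensitivity = if (length(truth)) tp / (tp + fn) else NA_real_,
    ppv = if (length(detected)) tp / (tp + fp) else NA_real_
  )
}
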