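#' Segment a record into fixed-length beat windows
#'
#' Cuts a window of `L` samples around each annotated R-peak (the R apex is
#' placed at 0-based index `rOffset` inside the window), attaches the AAMI
#' label and the per-beat RRI features, and z-score normalizes each window
#' (mean 0, sd 1, sd floor 1e-6). Beats whose window would cross a record
#' boundary are dropped; the count of dropped beats is attached as attribute
#' `droppedBoundaryBeats`.
#'
#' @param record an [ECGRecord-class] (or a numeric vector plus `fs`).
#' @param annotations a [beatAnnotations()] table with one row per beat.
#' @param L window length in samples (>= 32).
#' @param rOffset 0-based index of the R-peak inside the window
#'   (`0 <= rOffset < L`).
#' @param channel channel to segment (index or name).
#' @param localWindow RRI local-mean window (see [rriFeatures()]).
#'
#' @return a [BeatSegmentSet-class].
#' @examples
#' gen <- generateRecord(rhythmSpec(meanBpm = 75, duration = 30, seed = 5))
#' seg <- segmentBeats(gen$record, gen$annotations)
#' ncol(seg)
#' @export
segmentBeats <- function(record, annotations, L = 250L, rOffset = 90L,
                         channel = 1L, localWindow = 10L) {
  L <- as.integer(L)
  rOffset <- as.integer(rOffset)
  if (L < 32L) stop("L must be >= 32")
  if (rOffset < 0L || rOffset >= L) stop("need 0 <= rOffset < L")
  x <- channelSignal(record, channel)
  fs <- samplingRate(record)
  n <- length(x)
  idx <- annotations$sampleIndex
  rri <- computeRri(idx, fs)

  starts <- idx - rOffset # 0-based window starts
  ends <- starts + L - 1L
  ok <- starts >= 0L & ends <= n - 1L
  nDropped <- sum(!ok)

  kept <- which(ok)
  windows <- matrix(0, L, length(kept))
  feats <- matrix(0, length(kept), 4L)
  for (j in seq_along(kept)) {
    b <- kept[j]
    windows[, j] <- znorm(x[(starts[b] + 1L):(ends[b] + 1L)])
    feats[j, ] <- if (length(rri$valuesMs)) {
      rriFeatures(rri, b, localWindow)
    } else {
      c(NA_real_, NA_real_, NA_real_, NA_real_)
    }
  }
  if (!length(rri$valuesMs) && length(kept)) {
    stop("record has fewer than 2 annotated beats: RRI features undefined")
  }
  out <- BeatSegmentSet(
    windows,
    label = annotations$aamiClass[kept],
    rri = feats,
    source = sprintf("%s:%d", recordId(record), kept),
    augmented = rep(FALSE, length(kept)),
    fs = fs, rOffset = rOffset
  )
  attr(out, "droppedBoundaryBeats") <- nDropped
  out
}

#' Time-warp augmentation
#'
#' Resamples the window by linear interpolation to length `round(L /
#' factor)` (factor > 1 compresses, < 1 stretches), then center-crops or
#' edge-pads back to length `L`. Labels and RRI features are preserved; the
#' result is flagged augmented.
#'
#' @param window numeric vector of length L.
#' @param factor warp factor in `[0.5, 2]`.
#' @return numeric vector of length L.
#' @export
timeWarp <- function(window, factor) {
  if (factor < 0.5 || factor > 2.0) stop("factor must lie in [0.5, 2]")
  L <- length(window)
  if (factor == 1.0) {
    return(window)
  }
  newLen <- max(2L, round(L / factor))
  warped <- stats::approx(seq_len(L), window, n = newLen)$y
  if (newLen >= L) {
    # center-crop
    off <- (newLen - L) %/% 2L
    warped[(off + 1L):(off + L)]
  } else {
    # edge-pad, keeping the warped content centered
    padL <- (L - newLen) %/% 2L
    padR <- L - newLen - padL
    c(rep(warped[1L], padL), warped, rep(warped[newLen], padR))
  }
}

#' Noise-injection augmentation
#'
#' Adds white Gaussian noise scaled so the realized SNR (ratio of window
#' power to noise power) equals `snrDb` exactly. Deterministic given `seed`.
#'
#' @param window numeric vector.
#' @param snrDb requested signal-to-noise ratio in dB, `0 < snrDb <= 60`.
#' @param seed integer seed.
#' @return numeric vector, same length.
#' @export
noiseInject <- function(window, snrDb, seed = 1L) {
  if (snrDb <= 0 || snrDb > 60) stop("snrDb must lie in (0, 60]")
  p <- mean(window^2)
  if (p <= 0) stop("zero-power window: cannot scale noise")
  noise <- with_local_seed(seed, stats::rnorm(length(window)))
  noise <- noise * sqrt(p / (mean(noise^2) * 10^(snrDb / 10)))
  window + noise
}

#' Balance classes by augmentation
#'
#' Brings every class to the same count. All original segments are always
#' retained (majority classes are never discarded); deficits are filled by
#' sampling originals of the class uniformly with replacement and applying
#' [timeWarp()] with factor ~ U(0.9, 1.1) followed by [noiseInject()] with
#' SNR ~ U(15, 30) dB. Augmented segments inherit their source's label and
#' RRI features and carry `augmented = TRUE` plus the source's provenance
#' string, which [makeFolds()] and the training loop use to prevent
#' leakage.
#'
#' @param segments a [BeatSegmentSet-class].
#' @param targetPerClass `"max"` (count of the largest class) or an integer
#'   of at least the largest class count.
#' @param seed integer seed; the result is deterministic given it.
#' @param warpRange,snrRange numeric length-2: augmentation parameter ranges.
#' @return a [BeatSegmentSet-class] with equal class counts.
#' @export
balanceClasses <- function(segments, targetPerClass = "max", seed = 1L,
                           warpRange = c(0.9, 1.1), snrRange = c(15, 30)) {
  lab <- beatLabels(segments)
  counts <- table(lab)
  if (any(counts == 0L)) {
    stop("empty class: ", paste(names(counts)[counts == 0L], collapse = ", "))
  }
  target <- if (identical(targetPerClass, "max")) {
    max(counts)
  } else {
    as.integer(targetPerClass)
  }
  if (target < max(counts)) {
    stop("targetPerClass must be at least the largest class count (originals are never discarded)")
  }
  deficits <- target - counts
  if (all(deficits == 0L)) {
    return(segments)
  }

  w <- beatWindows(segments)
  rri <- rriMatrix(segments)
  cd <- colData(segments)
  newW <- list()
  newLab <- character(0)
  newSrc <- character(0)
  newRri <- list()
  with_local_seed(seed, {
    for (cl in names(counts)) {
      d <- deficits[cl]
      if (d == 0L) next
      pool <- which(lab == cl)
      pick <- sample(pool, d, replace = TRUE)
      factors <- stats::runif(d, warpRange[1L], warpRange[2L])
      snrs <- stats::runif(d, snrRange[1L], snrRange[2L])
      seeds <- sample.int(.Machine$integer.max, d)
      for (j in seq_len(d)) {
        aug <- timeWarp(w[, pick[j]], factors[j])
        aug <- noiseInject(aug, snrs[j], seed = seeds[j])
        newW[[length(newW) + 1L]] <- aug
        newLab <- c(newLab, cl)
        newSrc <- c(newSrc, cd$source[pick[j]])
        newRri[[length(newRri) + 1L]] <- rri[pick[j], ]
      }
    }
  })
  allW <- cbind(w, do.call(cbind, newW))
  allRri <- rbind(rri, do.call(rbind, newRri))
  BeatSegmentSet(
    allW,
    label = c(lab, newLab),
    rri = allRri,
    source = c(cd$source, newSrc),
    augmented = c(cd$augmented, rep(TRUE, length(newLab))),
    fs = metadata(segments)$fs, rOffset = metadata(segments)$rOffset
  )
}

#' Stratified k-fold assignment
#'
#' Partitions the *original* (non-augmented) segments into `k` folds,
#' stratified by class so per-class counts differ by at most 1 across
#' folds. Augmented segments are not assigned here: augmentation is re-done
#' inside each training split by [runCrossValidation()], which prevents any
#' augmented copy of a validation beat from reaching the training set.
#'
#' @param segments a [BeatSegmentSet-class] of original segments.
#' @param k number of folds (>= 2).
#' @param seed integer seed; assignment is deterministic given it.
#' @return list of class `foldSplit`: `k`, `assignments` (integer in
#'   `0..k-1`, one per segment), `seed`.
#' @export
makeFolds <- function(segments, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (any(colData(segments)$augmented)) {
    stop("makeFolds expects original (non-augmented) segments")
  }
  lab <- beatLabels(segments)
  counts <- table(lab)
  if (any(counts < k)) {
    stop(
      "class(es) with fewer than k segments: ",
      paste(names(counts)[counts < k], collapse = ", ")
    )
  }
  assignments <- integer(length(lab))
  with_local_seed(seed, {
    for (cl in names(counts)) {
      members <- sample(which(lab == cl)) # shuffle within class
      assignments[members] <- rep_len(0:(k - 1L), length(members))
    }
  })
  structure(
    list(k = k, assignments = assignments, seed = as.integer(seed)),
    class = "foldSplit"
  )
}

#' Combine several BeatSegmentSets
#'
#' Column-binds beat sets that share window length, sampling rate and R
#' offset.
#'
#' @param ... [BeatSegmentSet-class] objects.
#' @return a single [BeatSegmentSet-class].
#' @export
combineSegments <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  L <- nrow(parts[[1L]])
  fs <- metadata(parts[[1L]])$fs
  ro <- metadata(parts[[1L]])$rOffset
  for (p in parts) {
    if (nrow(p) != L || metadata(p)$fs != fs || metadata(p)$rOffset != ro) {
      stop("segment sets differ in window length, sampling rate or R offset")
    }
  }
  BeatSegmentSet(
    do.call(cbind, lapply(parts, beatWindows)),
    label = unlist(lapply(parts, beatLabels)),
    rri = do.call(rbind, lapply(parts, rriMatrix)),
    source = unlist(lapply(parts, function(p) colData(p)$source)),
    augmented = unlist(lapply(parts, function(p) colData(p)$augmented)),
    fs = fs, rOffset = ro
  )
}

#' Subset a BeatSegmentSet by index
#'
#' @param segments a [BeatSegmentSet-class].
#' @param idx integer or logical index over beats (columns).
#' @return a [BeatSegmentSet-class].
#' @export
subsetSegments <- function(segments, idx) {
  segments[, idx]
}
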