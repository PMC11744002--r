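#' ECGRecord: a multi-channel ECG waveform
#'
#' Container for a raw or preprocessed ECG signal: a channels-by-samples
#' matrix in millivolts, the sampling rate in Hz, channel names and a record
#' identifier. Beat annotations (see [beatAnnotations()]) travel alongside the
#' record but are not part of the object itself, mirroring the separation of
#' signal and annotation files in the WFDB format family.
#'
#' @slot samples numeric matrix, `n_channels x n_samples`, in millivolts.
#' @slot fs sampling rate in Hz (positive scalar).
#' @slot channelNames character vector, one per channel.
#' @slot recordId single string identifying the record.
#'
#' @seealso [ECGRecord()], [readRecord()], [generateRecord()]
#' @export
setClass("ECGRecord",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelNames = "character",
    recordId = "character"
  )
)

setValidity("ECGRecord", function(object) {
  msg <- character()
  if (!is.numeric(object@samples)) {
    msg <- c(msg, "'samples' must be a numeric matrix")
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "'fs' must be a single positive finite number")
  }
  if (ncol(object@samples) < 1L) {
    msg <- c(msg, "record must contain at least one sample")
  }
  if (!all(is.finite(object@samples))) {
    msg <- c(msg, "all samples must be finite")
  }
  if (length(object@channelNames) != nrow(object@samples)) {
    msg <- c(msg, "'channelNames' length must equal the number of channels")
  }
  if (length(object@recordId) != 1L) {
    msg <- c(msg, "'recordId' must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecord
#'
#' @param samples numeric matrix (`n_channels x n_samples`) or vector (one
#'   channel), in millivolts.
#' @param fs sampling rate, Hz.
#' @param channelNames optional channel names; defaults to `"ch1"`, `"ch2"`, ...
#' @param recordId record identifier string.
#'
#' @return An [ECGRecord-class] object.
#' @examples
#' rec <- ECGRecord(sin(2 * pi * 1.2 * seq(0, 2, by = 1 / 360)), fs = 360)
#' nSamples(rec)
#' @export
ECGRecord <- function(samples, fs, channelNames = NULL, recordId = "record") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nrow(samples)))
  new("ECGRecord",
    samples = samples, fs = as.numeric(fs),
    channelNames = as.character(channelNames), recordId = as.character(recordId)
  )
}

#' Beat annotation table
#'
#' Creates a `DataFrame` of per-beat annotations: the 0-based sample index of
#' the R-peak (MIT-BIH convention: the index marks the R apex itself), the
#' single-character source symbol, and the AAMI class (one of N, S, V, F, Q)
#' derived from the symbol via [mapSymbolToAami()] unless given explicitly.
#'
#' @param sampleIndex integer vector of 0-based R-peak sample positions.
#' @param symbol character vector of single-character beat symbols.
#' @param aamiClass optional character vector of AAMI classes; derived from
#'   `symbol` when missing.
#'
#' @return A `DataFrame` with columns `sampleIndex`, `symbol`, `aamiClass`,
#'   sorted by `sampleIndex`.
#' @examples
#' beatAnnotations(c(100L, 400L), c("N", "V"))
#' @export
beatAnnotations <- function(sampleIndex, symbol, aamiClass = NULL) {
  sampleIndex <- as.integer(sampleIndex)
  symbol <- as.character(symbol)
  stopifnot(length(sampleIndex) == length(symbol))
  if (is.null(aamiClass)) {
    aamiClass <- vapply(symbol, mapSymbolToAami, character(1), USE.NAMES = FALSE)
  }
  if (!all(aamiClass %in% AAMI_CLASSES)) {
    bad <- setdiff(unique(aamiClass), AAMI_CLASSES)
    stop("invalid AAMI class(es): ", paste(bad, collapse = ", "))
  }
  if (any(sampleIndex < 0L)) stop("sampleIndex must be >= 0")
  ord <- order(sampleIndex)
  DataFrame(
    sampleIndex = sampleIndex[ord], symbol = symbol[ord],
    aamiClass = as.character(aamiClass)[ord]
  )
}

#' The five AAMI beat classes
#'
#' Normal (N), supraventricular ectopic (S), ventricular ectopic (V),
#' fusion (F) and unknown (Q), in canonical order.
#' @export
AAMI_CLASSES <- c("N", "S", "V", "F", "Q")

#' BeatSegmentSet: fixed-length beat windows with labels and RRI features
#'
#' Extends `SummarizedExperiment`: the `"window"` assay holds one column per
#' beat (L samples, millivolts, z-score normalized by [segmentBeats()]);
#' `colData` carries the AAMI class label, the four R-R interval features,
#' the beat's provenance (`source` = record id + original beat index, used
#' for leakage checks), and an `augmented` flag.
#'
#' @seealso [segmentBeats()], [balanceClasses()], [makeFolds()]
#' @export
setClass("BeatSegmentSet", contains = "SummarizedExperiment")

setValidity("BeatSegmentSet", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c(
    "label", "source", "augmented",
    "rri_pre_ms", "rri_post_ms", "rri_local_ms", "rri_ratio"
  )
  missing_cols <- setdiff(need, colnames(cd))
  if (length(missing_cols)) {
    msg <- c(msg, paste0("colData lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"window" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'window' is required")
  }
  if (!length(msg)) {
    if (!all(cd$label %in% AAMI_CLASSES)) {
      msg <- c(msg, "labels must be AAMI classes N/S/V/F/Q")
    }
    w <- assay(object, "window")
    if (ncol(object) > 0 && !all(is.finite(w))) {
      msg <- c(msg, "window values must be finite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BeatSegmentSet
#'
#' Usually produced by [segmentBeats()]; this constructor assembles one from
#' raw pieces (used internally and by tests).
#'
#' @param windows numeric matrix, `L x n_beats`, one beat window per column.
#' @param label character vector of AAMI classes, one per beat.
#' @param rri numeric matrix `n_beats x 4` of RRI features
#'   (pre, post, local mean, pre/local ratio), or NULL for zeros.
#' @param source character vector of provenance identifiers.
#' @param augmented logical vector; defaults to all FALSE.
#' @param fs sampling rate of the source record, stored in `metadata`.
#' @param rOffset index of the R-peak within each window (0-based), stored in
#'   `metadata`.
#'
#' @return A [BeatSegmentSet-class].
#' @export
BeatSegmentSet <- function(windows, label, rri = NULL, source = NULL,
                           augmented = NULL, fs = 360, rOffset = 90L) {
  windows <- as.matrix(windows)
  n <- ncol(windows)
  if (is.null(rri)) rri <- matrix(0, n, 4L)
  if (is.null(source)) source <- paste0("beat", seq_len(n))
  if (is.null(augmented)) augmented <- rep(FALSE, n)
  cd <- DataFrame(
    label = as.character(label),
    source = as.character(source),
    augmented = as.logical(augmented),
    rri_pre_ms = as.numeric(rri[, 1L]),
    rri_post_ms = as.numeric(rri[, 2L]),
    rri_local_ms = as.numeric(rri[, 3L]),
    rri_ratio = as.numeric(rri[, 4L])
  )
  se <- SummarizedExperiment(
    assays = list(window = windows), colData = cd,
    metadata = list(fs = fs, rOffset = as.integer(rOffset))
  )
  new("BeatSegmentSet", se)
}
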