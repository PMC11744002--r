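#' Number of samples per channel in a record
#' @param x an [ECGRecord-class].
#' @return integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Number of channels in a record
#' @param x an [ECGRecord-class].
#' @return integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Sampling rate accessor
#' @param x an [ECGRecord-class] or [BeatSegmentSet-class].
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel names accessor
#' @param x an [ECGRecord-class].
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Record identifier accessor
#' @param x an [ECGRecord-class].
#' @return record id string.
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' Extract one channel as a numeric vector
#' @param x an [ECGRecord-class].
#' @param channel channel index or name (default first channel).
#' @return numeric vector in millivolts.
#' @export
setGeneric("channelSignal", function(x, channel = 1L) standardGeneric("channelSignal"))

#' Beat class labels of a segment set
#' @param x a [BeatSegmentSet-class].
#' @return character vector of AAMI classes.
#' @export
setGeneric("beatLabels", function(x) standardGeneric("beatLabels"))

#' Beat window matrix of a segment set
#' @param x a [BeatSegmentSet-class].
#' @return numeric matrix `L x n_beats`.
#' @export
setGeneric("beatWindows", function(x) standardGeneric("beatWindows"))

#' RRI feature matrix of a segment set
#' @param x a [BeatSegmentSet-class].
#' @return numeric matrix `n_beats x 4` (pre, post, local mean, ratio).
#' @export
setGeneric("rriMatrix", function(x) standardGeneric("rriMatrix"))

setMethod("nSamples", "ECGRecord", function(x) ncol(x@samples))
setMethod("nChannels", "ECGRecord", function(x) nrow(x@samples))
setMethod("samplingRate", "ECGRecord", function(x) x@fs)
setMethod("channelNames", "ECGRecord", function(x) x@channelNames)
setMethod("recordId", "ECGRecord", function(x) x@recordId)
setMethod("channelSignal", "ECGRecord", function(x, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, x@channelNames)
  if (is.na(channel) || channel < 1L || channel > nrow(x@samples)) {
    stop("no such channel")
  }
  as.numeric(x@samples[channel, ])
})

setMethod("samplingRate", "BeatSegmentSet", function(x) metadata(x)$fs)
setMethod("beatLabels", "BeatSegmentSet", function(x) colData(x)$label)
setMethod("beatWindows", "BeatSegmentSet", function(x) assay(x, "window"))
setMethod("rriMatrix", "BeatSegmentSet", function(x) {
  cd <- colData(x)
  cbind(
    pre_rr_ms = cd$rri_pre_ms, post_rr_ms = cd$rri_post_ms,
    local_mean_rr_ms = cd$rri_local_ms, pre_over_local = cd$rri_ratio
  )
})

setMethod("show", "ECGRecord", function(object) {
  cat(
    "ECGRecord '", object@recordId, "': ",
    nrow(object@samples), " channel(s) x ", ncol(object@samples),
    " samples @ ", object@fs, " Hz (",
    sprintf("%.1f", ncol(object@samples) / object@fs), " s)\n",
    sep = ""
  )
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "BeatSegmentSet", function(object) {
  tab <- table(factor(beatLabels(object), levels = AAMI_CLASSES))
  cat(
    "BeatSegmentSet: ", ncol(object), " beats, window L = ", nrow(object),
    " samples @ ", metadata(object)$fs, " Hz, R offset ",
    metadata(object)$rOffset, "\n", sep = ""
  )
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  augmented:", sum(colData(object)$augmented), "\n")
})
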