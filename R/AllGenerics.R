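#' Accessors for coupleEEG containers
#'
#' Small accessor generics shared by the package's data classes:
#' `samplingRate()` returns the sampling rate in Hz, `trialKeys()` the
#' per-trial key table, `channelNames()` the channel labels,
#' `roiLabels()` the region-of-interest labels, `nTrials()` /
#' `nChannels()` the respective dimensions, and `epochTimes()` the epoch
#' time axis in seconds relative to movie onset.
#'
#' @param object a coupleEEG container.
#' @return the requested component.
#' @name accessors
#' @aliases samplingRate trialKeys channelNames roiLabels nTrials nChannels
#'   epochTimes
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("trialKeys", function(object) standardGeneric("trialKeys"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))

#' @rdname accessors
setMethod("samplingRate", "Recording", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "SourceEpochs", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "SlopeTimecourse", function(object) object@fs)

#' @rdname accessors
setMethod("trialKeys", "EpochSet", function(object) object@trialKeys)
#' @rdname accessors
setMethod("trialKeys", "SourceEpochs", function(object) object@trialKeys)

#' @rdname accessors
setMethod("channelNames", "Recording", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelNames", "LeadField", function(object) object@channelNames)

#' @rdname accessors
setMethod("roiLabels", "LeadField", function(object) object@roiLabels)

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(object) dim(object@data)[3L])
#' @rdname accessors
setMethod("nTrials", "SourceEpochs", function(object) dim(object@data)[1L])

#' @rdname accessors
setMethod("nChannels", "Recording", function(object) nrow(object@data))
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(object) dim(object@data)[1L])
#' @rdname accessors
setMethod("nChannels", "LeadField", function(object) nrow(object@matrix))

#' @rdname accessors
setMethod("epochTimes", "EpochSet", function(object)
  object@t0 + (seq_len(dim(object@data)[2L]) - 1L) / object@fs)
#' @rdname accessors
setMethod("epochTimes", "SourceEpochs", function(object)
  object@t0 + (seq_len(dim(object@data)[3L]) - 1L) / object@fs)

#' Extract the gain block of one ROI
#'
#' Returns the channels x 3 lead-field block of a single region of
#' interest.
#'
#' @param object a [LeadField-class].
#' @param roi ROI label or index.
#' @return numeric matrix, channels x 3.
#' @export
setGeneric("roiBlock", function(object, roi) standardGeneric("roiBlock"))

#' @rdname roiBlock
setMethod("roiBlock", "LeadField", function(object, roi) {
  if (is.character(roi)) {
    r <- match(roi, object@roiLabels)
    if (is.na(r)) stop("unknown ROI label: ", roi)
  } else r <- as.integer(roi)
  object@matrix[, (3L * r - 2L):(3L * r), drop = FALSE]
})

#' Subset an EpochSet by trial
#'
#' `x[i]` keeps the trials selected by `i` (logical or integer), pruning
#' `trialKeys` consistently.
#'
#' @param x an [EpochSet-class].
#' @param i trial index (integer or logical).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nTrials(x))[i]
  new("EpochSet", data = x@data[, , idx, drop = FALSE], fs = x@fs,
      t0 = x@t0, events = x@events, channelNames = x@channelNames,
      trialKeys = x@trialKeys[idx, , drop = FALSE])
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  epoch [%g, %g] s relative to movie onset\n",
              object@t0, object@t0 + d[2] / object@fs))
  if (length(object@events))
    cat("  events:", paste(sprintf("%s=%g s", names(object@events),
                                   object@events), collapse = ", "), "\n")
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d channels, %d ROIs (%s)\n",
              nrow(object@matrix), length(object@roiLabels),
              paste(object@roiLabels, collapse = ", ")))
})

setMethod("show", "Covariance", function(object) {
  cat(sprintf("Covariance: %d x %d (condition '%s', %d samples)\n",
              nrow(object@matrix), ncol(object@matrix),
              object@condition, object@nSamples))
})

setMethod("show", "SourceEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("SourceEpochs '%s': %d trials x 3 dipoles x %d samples @ %g Hz\n",
              object@roiLabel, d[1], d[3], object@fs))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: amp = %g + %g * z within [%g, %g] s, ROI '%s'\n",
    object@couplingIntercept, object@couplingSlope,
    object@window[1], object@window[2], object@targetRoi))
})

setMethod("show", "SlopeTimecourse", function(object) {
  d <- dim(object@slopes)
  cat(sprintf(
    "SlopeTimecourse '%s'/'%s': %d subjects x %d dipoles x %d samples\n",
    object@roiLabel, object@condition, d[1], d[2], d[3]))
  cat(sprintf("  time [%g, %g] s relative to noxious event\n",
              min(object@time), max(object@time)))
})

setMethod("show", "StatTimecourse", function(object) {
  cat(sprintf(
    "StatTimecourse: %d time points, df = (%g, %g), max F = %.3f\n",
    length(object@time), object@df[1], object@df[2],
    suppressWarnings(max(object@Fstat[!object@singular], na.rm = TRUE))))
  if (any(object@singular))
    cat(sprintf("  %d singular time points excluded\n",
                sum(object@singular)))
})
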