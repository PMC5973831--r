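#' @import methods
NULL

#' Continuous multi-channel recording
#'
#' A minimal container for an unsegmented multi-channel signal: a
#' channels-by-time matrix together with its sampling rate.  Used as the
#' input to [segmentEpochs()] and produced by [readBrainVision()].
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one name per row of `data`.
#' @export
setClass("Recording",
  slots = c(data = "matrix", fs = "numeric", channelNames = "character"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "channelNames must match the number of rows of data")
  if (length(msg)) msg else TRUE
})

#' Segmented EEG epochs
#'
#' Epoched sensor data stored as a channels x time x trials array, with the
#' epoch time axis expressed in seconds relative to stimulus-movie onset.
#' `events` holds named within-epoch latencies (e.g. `fixation`,
#' `movie_onset`, `noxious_event`), also relative to movie onset.
#' `trialKeys` carries one row per trial (subject, condition, session,
#' trial and, when available, the behavioral response), keeping the array
#' aligned with the behavioral trial table throughout preprocessing.
#'
#' @slot data numeric array, channels x time x trials (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot t0 epoch start in seconds relative to movie onset (negative for
#'   pre-stimulus baseline).
#' @slot events named numeric vector of event latencies (s, movie-onset
#'   relative); all latencies must fall inside the epoch.
#' @slot channelNames character vector of channel labels.
#' @slot trialKeys data.frame with one row per trial.
#' @export
setClass("EpochSet",
  slots = c(data = "array", fs = "numeric", t0 = "numeric",
            events = "numeric", channelNames = "character",
            trialKeys = "data.frame"))

.keyCols <- c("subject", "condition", "session", "trial")

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-d array (channels x time x trials)")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelNames) != d[1L])
    msg <- c(msg, "channelNames must match dim(data)[1]")
  if (nrow(object@trialKeys) != d[3L])
    msg <- c(msg, "trialKeys must have one row per trial")
  if (length(object@events)) {
    tEnd <- object@t0 + d[2L] / object@fs
    if (is.null(names(object@events)) || any(!nzchar(names(object@events))))
      msg <- c(msg, "events must be named")
    if (any(object@events < object@t0 - 1e-9 | object@events > tEnd + 1e-9))
      msg <- c(msg, "all event latencies must lie inside the epoch")
  }
  keys <- intersect(.keyCols, names(object@trialKeys))
  if (length(keys) && nrow(object@trialKeys) &&
      anyDuplicated(object@trialKeys[keys]))
    msg <- c(msg, "trialKeys rows must be unique over (subject, condition, session, trial)")
  if (length(msg)) msg else TRUE
})

#' Forward model gains for a set of regions of interest
#'
#' A channels x (3 * nROI) gain matrix.  Each consecutive block of three
#' columns holds the scalp topographies of the three orthogonal dipole
#' components of one region of interest; every block must have rank 3 so
#' that the beamformer's unit-gain constraint is solvable.
#'
#' @slot matrix numeric matrix, channels x (3 * number of ROIs).
#' @slot roiLabels character vector of ROI labels (one per column block).
#' @slot channelNames character vector of channel labels.
#' @export
setClass("LeadField",
  slots = c(matrix = "matrix", roiLabels = "character",
            channelNames = "character"))

setValidity("LeadField", function(object) {
  msg <- character()
  m <- object@matrix
  if (!all(is.finite(m))) msg <- c(msg, "lead field entries must be finite")
  if (ncol(m) != 3L * length(object@roiLabels))
    msg <- c(msg, "matrix must have 3 columns per ROI label")
  if (length(object@channelNames) != nrow(m))
    msg <- c(msg, "channelNames must match the number of rows")
  if (all(is.finite(m))) {
    for (r in seq_along(object@roiLabels)) {
      blk <- m[, (3L * r - 2L):(3L * r), drop = FALSE]
      if (qr(blk)$rank < 3L)
        msg <- c(msg, sprintf("ROI block '%s' is rank deficient",
                              object@roiLabels[r]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Sensor covariance matrix
#'
#' Channel-by-channel covariance, by default computed from the evoked
#' response (ERP) over the entire epoch; see [erpCovariance()].
#'
#' @slot matrix symmetric positive semi-definite covariance (microvolts^2).
#' @slot nSamples number of time samples that entered the estimate.
#' @slot condition condition label the estimate belongs to.
#' @export
setClass("Covariance",
  slots = c(matrix = "matrix", nSamples = "integer", condition = "character"))

setValidity("Covariance", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "covariance must be square")
  else if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    msg <- c(msg, "covariance must be symmetric")
  else {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * sum(diag(m)) - 1e-12)
      msg <- c(msg, "covariance must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

#' Reconstructed source epochs for one region of interest
#'
#' Single-trial source activity along the three dipole axes of one ROI,
#' stored trials x 3 x time.  The dipole axes are those defined by the
#' columns of the ROI's lead-field block; no orientation optimisation is
#' applied, so downstream statistics treat the three components jointly.
#'
#' @slot data numeric array, trials x 3 dipoles x time (arbitrary units).
#' @slot roiLabel label of the reconstructed ROI.
#' @slot fs sampling rate in Hz.
#' @slot t0 epoch start (s, movie-onset relative).
#' @slot events named event latencies inherited from the sensor epochs.
#' @slot trialKeys data.frame with one row per trial, aligned with `data`.
#' @export
setClass("SourceEpochs",
  slots = c(data = "array", roiLabel = "character", fs = "numeric",
            t0 = "numeric", events = "numeric", trialKeys = "data.frame"))

setValidity("SourceEpochs", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L || d[2L] != 3L)
    msg <- c(msg, "data must be trials x 3 dipoles x time")
  else if (nrow(object@trialKeys) != d[1L])
    msg <- c(msg, "trialKeys must have one row per trial")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Ground-truth coupling parameters for the synthetic generator
#'
#' Describes how the single-trial amplitude of the target ROI's source is
#' tied to the standardized behavioral response: inside `window` the source
#' waveform is scaled by `couplingIntercept + couplingSlope * z + eta` and
#' oriented along `orientation` in the ROI's dipole coordinate frame.
#'
#' @slot couplingIntercept baseline source amplitude (a.u.).
#' @slot couplingSlope amplitude change per unit of Z-scored response.
#' @slot window numeric length-2, coupling window in seconds relative to
#'   movie onset (must satisfy start < end and lie inside the epoch).
#' @slot targetRoi label of the coupled ROI.
#' @slot orientation unit 3-vector, dipole-frame orientation of the source.
#' @export
setClass("GroundTruth",
  slots = c(couplingIntercept = "numeric", couplingSlope = "numeric",
            window = "numeric", targetRoi = "character",
            orientation = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (length(object@window) != 2L || !(object@window[1] < object@window[2]))
    msg <- c(msg, "window must be c(start, end) with start < end")
  if (length(object@orientation) != 3L ||
      abs(sqrt(sum(object@orientation^2)) - 1) > 1e-8)
    msg <- c(msg, "orientation must be a unit 3-vector")
  if (length(msg)) msg else TRUE
})

#' Per-subject robust slope time courses
#'
#' The first-level output of the coupling analysis: for every subject,
#' dipole and time sample, the robust-regression slope of the Z-scored
#' behavioral response on source amplitude.  The time axis is expressed in
#' seconds relative to the noxious event so that cluster boundaries can be
#' reported on the scale used for the group results.
#'
#' @slot slopes numeric array, subjects x 3 dipoles x time.
#' @slot fs sampling rate in Hz.
#' @slot time numeric vector of time points (s relative to noxious event).
#' @slot roiLabel ROI the slopes belong to.
#' @slot condition condition label.
#' @slot subjects character vector of subject identifiers.
#' @export
setClass("SlopeTimecourse",
  slots = c(slopes = "array", fs = "numeric", time = "numeric",
            roiLabel = "character", condition = "character",
            subjects = "character"))

setValidity("SlopeTimecourse", function(object) {
  d <- dim(object@slopes)
  msg <- character()
  if (length(d) != 3L)
    return("slopes must be subjects x dipoles x time")
  if (d[1L] < 2L) msg <- c(msg, "at least 2 subjects are required")
  if (!all(is.finite(object@slopes)))
    msg <- c(msg, "slopes must be finite")
  if (length(object@time) != d[3L])
    msg <- c(msg, "time axis must match dim(slopes)[3]")
  if (length(object@subjects) != d[1L])
    msg <- c(msg, "subjects must match dim(slopes)[1]")
  if (length(msg)) msg else TRUE
})

#' Hotelling T-squared statistic time course
#'
#' Per time point: the one-sample Hotelling T-squared statistic over the
#' subjects' dipole slope vectors, its F transform
#' `F = T2 * (n - p) / (p * (n - 1))` with degrees of freedom `(p, n - p)`,
#' and the uncorrected p value from the F distribution.  Time points with a
#' singular slope covariance are flagged and excluded from cluster
#' formation.
#'
#' @slot time time axis (s relative to noxious event).
#' @slot T2 Hotelling T-squared values.
#' @slot Fstat F-transformed statistics.
#' @slot p uncorrected p values.
#' @slot df length-2 numeric, the F degrees of freedom `(p_dim, n - p_dim)`.
#' @slot singular logical, TRUE where the covariance was not invertible.
#' @export
setClass("StatTimecourse",
  slots = c(time = "numeric", T2 = "numeric", Fstat = "numeric",
            p = "numeric", df = "numeric", singular = "logical"))

setValidity("StatTimecourse", function(object) {
  msg <- character()
  nt <- length(object@time)
  if (length(object@T2) != nt || length(object@Fstat) != nt ||
      length(object@p) != nt || length(object@singular) != nt)
    msg <- c(msg, "time, T2, Fstat, p and singular must have equal length")
  ok <- !object@singular
  if (any(object@T2[ok] < -1e-12, na.rm = TRUE))
    msg <- c(msg, "T2 must be non-negative")
  if (any(object@p[ok] <= 0 | object@p[ok] > 1, na.rm = TRUE))
    msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
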