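# Sensor-space conditioning: zero-phase filtering, common-average
# reference, segmentation, baseline correction, amplitude-based rejection.

.zeroPhase <- function(filt, x) as.numeric(signal::filtfilt(filt, x))

.applyFilters <- function(mat, fs, lowpassHz, bandstop) {
  filts <- list()
  if (!is.null(lowpassHz))
    filts <- c(filts, list(signal::butter(4, lowpassHz / (fs / 2),
                                          type = "low")))
  if (!is.null(bandstop))
    filts <- c(filts, list(signal::butter(4, bandstop / (fs / 2),
                                          type = "stop")))
  for (f in filts)
    mat <- t(apply(mat, 1L, function(ch) .zeroPhase(f, ch)))
  mat
}

#' Zero-phase low-pass and line-noise band-stop filtering
#'
#' Applies a 4th-order Butterworth low-pass at `lowpassHz` and a 4th-order
#' Butterworth band-stop over `bandstop` (default 49.5-50.5 Hz, the
#' European line-noise band), each run forward and backward
#' (zero-phase), to every channel of every trial.  Signal length is
#' preserved and the DC gain stays within 1% of unity.  Pass `NULL` for
#' either cutoff to skip that filter.
#'
#' @param x an [EpochSet-class], a [Recording-class], or a channels x time
#'   matrix (then `fs` is required).
#' @param lowpassHz low-pass cutoff in Hz, or NULL.
#' @param bandstop length-2 band-stop edges in Hz, or NULL.
#' @param fs sampling rate, only used for matrix input.
#' @return the filtered object, same type and dimensions as the input.
#' @export
filterSignal <- function(x, lowpassHz = 60, bandstop = c(49.5, 50.5),
                         fs = NULL) {
  checkNyquist <- function(fs) {
    .stopIf(!is.null(lowpassHz) && fs <= 2 * lowpassHz,
            "low-pass cutoff must be below the Nyquist frequency")
    .stopIf(!is.null(bandstop) && max(bandstop) >= fs / 2,
            "band-stop edges must be below the Nyquist frequency")
  }
  if (is(x, "EpochSet")) {
    checkNyquist(x@fs)
    out <- x@data
    for (k in seq_len(dim(out)[3L])) {
      m <- out[, , k, drop = FALSE]
      dim(m) <- dim(m)[1:2]
      out[, , k] <- .applyFilters(m, x@fs, lowpassHz, bandstop)
    }
    initialize(x, data = out)
  } else if (is(x, "Recording")) {
    checkNyquist(x@fs)
    initialize(x, data = .applyFilters(x@data, x@fs, lowpassHz, bandstop))
  } else if (is.matrix(x)) {
    .stopIf(is.null(fs), "fs is required for matrix input")
    checkNyquist(fs)
    .applyFilters(x, fs, lowpassHz, bandstop)
  } else stop("unsupported input type")
}

#' Re-reference epochs to the common average
#'
#' Subtracts the across-channel mean from every sample of every trial, so
#' that the channel mean is zero everywhere.  The operation is a projection
#' (idempotent) and reduces the rank of full-rank data by exactly one.
#'
#' @param epochs an [EpochSet-class] with at least 2 channels.
#' @return the re-referenced [EpochSet-class].
#' @export
rereferenceCommonAverage <- function(epochs) {
  .stopIf(!is(epochs, "EpochSet"), "epochs must be an EpochSet")
  d <- dim(epochs@data)
  .stopIf(d[1L] < 2L, "common-average reference needs at least 2 channels")
  m <- colMeans(epochs@data)                    # time x trials
  initialize(epochs, data = epochs@data - rep(m, each = d[1L]))
}

#' Segment a continuous recording into fixed-length epochs
#'
#' Cuts epochs of `tPre` seconds before to `tPost` seconds after each movie
#' onset.  Every epoch has exactly `round((tPre + tPost) * fs)` samples and
#' trials follow onset order.  Onsets too close to the recording edges are
#' an error naming the offending trial(s) rather than a silent drop.
#'
#' @param recording a [Recording-class].
#' @param movieOnsets numeric vector of onset times (s from recording
#'   start).
#' @param tPre,tPost epoch extent before/after onset (s).
#' @param events named event latencies stored in the result (s,
#'   movie-onset relative).
#' @param trialKeys optional data.frame of per-trial keys (one row per
#'   onset); defaults to a plain trial index.
#' @return an [EpochSet-class] with `t0 = -tPre`.
#' @export
segmentEpochs <- function(recording, movieOnsets, tPre = 5, tPost = 2,
                          events = c(fixation = -1, movie_onset = 0,
                                     noxious_event = 1),
                          trialKeys = NULL) {
  .stopIf(!is(recording, "Recording"), "recording must be a Recording")
  fs <- recording@fs
  nSamp <- as.integer(round((tPre + tPost) * fs))
  nRec <- ncol(recording@data)
  movieOnsets <- as.numeric(movieOnsets)
  start <- as.integer(round((movieOnsets - tPre) * fs)) + 1L
  bad <- which(start < 1L | start + nSamp - 1L > nRec)
  .stopIf(length(bad) > 0,
          "onset(s) too close to the recording edge for trial(s): ",
          paste(bad, collapse = ", "))
  nTr <- length(movieOnsets)
  if (is.null(trialKeys))
    trialKeys <- data.frame(trial = seq_len(nTr))
  .stopIf(nrow(trialKeys) != nTr, "trialKeys must have one row per onset")
  data <- array(0, dim = c(nrow(recording@data), nSamp, nTr))
  for (k in seq_len(nTr))
    data[, , k] <- recording@data[, start[k]:(start[k] + nSamp - 1L),
                                  drop = FALSE]
  new("EpochSet", data = data, fs = fs, t0 = -tPre,
      events = if (nTr > 0) events else events,
      channelNames = recording@channelNames, trialKeys = trialKeys)
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and trial, the mean signal over a baseline
#' window.  The window is specified relative to a named event (default:
#' 400 to 200 ms before the fixation cross), or relative to movie onset
#' with `relativeTo = "movie_onset"`.  The operation is affine and
#' idempotent.
#'
#' @param epochs an [EpochSet-class].
#' @param window length-2 numeric, window relative to the reference event
#'   (s).
#' @param relativeTo name of the reference event in `epochs@events`.
#' @return the corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, window = c(-0.400, -0.200),
                            relativeTo = "fixation") {
  .stopIf(!is(epochs, "EpochSet"), "epochs must be an EpochSet")
  .stopIf(!relativeTo %in% names(epochs@events),
          "unknown reference event '", relativeTo, "'")
  absWin <- epochs@events[[relativeTo]] + sort(as.numeric(window))
  tt <- epochTimes(epochs)
  idx <- which(tt >= absWin[1] - 1e-9 & tt <= absWin[2] + 1e-9)
  .stopIf(length(idx) == 0 || absWin[1] < epochs@t0 - 1e-9 ||
            absWin[2] > max(tt) + 1e-9,
          "baseline window lies outside the epoch")
  d <- dim(epochs@data)
  base <- apply(epochs@data[, idx, , drop = FALSE], c(1L, 3L), mean)
  expand <- aperm(array(base, dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  initialize(epochs, data = epochs@data - expand)
}

#' Reject trials by peak-to-peak amplitude
#'
#' Removes every trial in which any channel's peak-to-peak amplitude
#' exceeds `peakToPeak` (microvolts) -- an automated, reproducible
#' surrogate for visual artifact screening.  `trialKeys` are pruned
#' consistently; rejecting all trials is an error.
#'
#' @param epochs an [EpochSet-class].
#' @param peakToPeak rejection threshold in microvolts (> 0); default 150.
#' @return list with `epochs` (retained trials), `keepMask` (logical, one
#'   entry per input trial) and `report` (data.frame of per-trial maximum
#'   peak-to-peak amplitudes).
#' @export
rejectTrials <- function(epochs, peakToPeak = 150) {
  .stopIf(!is(epochs, "EpochSet"), "epochs must be an EpochSet")
  .stopIf(peakToPeak <= 0, "peakToPeak threshold must be positive")
  nTr <- nTrials(epochs)
  p2p <- vapply(seq_len(nTr), function(k) {
    M <- epochs@data[, , k, drop = FALSE]
    dim(M) <- dim(M)[1:2]
    max(apply(M, 1L, function(r) diff(range(r))))
  }, numeric(1))
  keep <- p2p <= peakToPeak
  .stopIf(!any(keep), "all trials exceed the rejection threshold")
  list(epochs = epochs[keep], keepMask = keep,
       report = data.frame(trial = seq_len(nTr), maxPeakToPeak = p2p,
                           kept = keep))
}
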