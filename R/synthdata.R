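#' Stimulus-set intensity count presets
#'
#' Returns the number of validated stimulus videos per perceived-intensity
#' level and condition used by the donation experiments: `"table2_eeg"`
#' (Hand 13/2/0/27/1 at intensities 2-6, Face 23/3/4/10/11/1 at 2-7; 95
#' trials in total) and `"table2_tms"` (per-session counts, Hand
#' 4/10/4/10/2 and Face 10/4/4/6/6 at intensities 2-6).
#'
#' @param name preset name, `"table2_eeg"` or `"table2_tms"`.
#' @return named list of named integer vectors; names of the outer list are
#'   conditions, names of each vector are intensity levels.
#' @examples
#' vapply(intensityCountsPreset("table2_eeg"), sum, 0)  # 43 Hand + 52 Face
#' @export
intensityCountsPreset <- function(name = c("table2_eeg", "table2_tms")) {
  name <- match.arg(name)
  switch(name,
    table2_eeg = list(
      Hand = c(`2` = 13L, `3` = 2L, `4` = 0L, `5` = 27L, `6` = 1L),
      Face = c(`2` = 23L, `3` = 3L, `4` = 4L, `5` = 10L, `6` = 11L,
               `7` = 1L)),
    table2_tms = list(
      Hand = c(`2` = 4L, `3` = 10L, `4` = 4L, `5` = 10L, `6` = 2L),
      Face = c(`2` = 10L, `3` = 4L, `4` = 4L, `5` = 6L, `6` = 6L)))
}

.checkCounts <- function(intensityCounts) {
  .stopIf(!is.list(intensityCounts) || is.null(names(intensityCounts)) ||
            !length(intensityCounts),
          "intensityCounts must be a named list with one entry per condition")
  for (cond in names(intensityCounts)) {
    cnt <- intensityCounts[[cond]]
    .stopIf(is.null(names(cnt)) || anyNA(suppressWarnings(
              as.numeric(names(cnt)))),
            "counts for condition '", cond, "' must be named by intensity")
    .stopIf(any(cnt < 0) || any(cnt != round(cnt)),
            "counts for condition '", cond,
            "' must be non-negative integers")
    .stopIf(sum(cnt) < 1, "condition '", cond, "' has no trials")
  }
  invisible(TRUE)
}

.cellLabel <- function(condition, session) paste(condition, session, sep = ":")

#' Simulate a donation trial table
#'
#' Generates per-trial donation records for a costly-helping experiment in
#' which a participant watches a video of known perceived pain intensity
#' (2-7) and donates an integer amount between 0 and 6 euro.  Each subject
#' draws a private intensity-to-donation slope `b_s ~ N(slopeMean,
#' slopeSd^2)`; the donation on trial i is
#' `round(clip(intercept + b_s * intensity_i + eps_i, 0, 6))` with
#' `eps_i ~ N(0, noiseSd^2)` and rounding half away from zero (the donation
#' bar moves in 1-euro steps tied to intensity units).
#'
#' `slopeAdjust` perturbs the slope in selected condition/session cells
#' (named list, names `"condition:session"`), which is how session-specific
#' manipulation effects (e.g. a stimulation-induced flattening of the
#' intensity-donation relationship) are emulated.
#'
#' @param nSubjects number of subjects.
#' @param intensityCounts named list of per-condition intensity counts; see
#'   [intensityCountsPreset()].  The default is the EEG stimulus set.
#' @param sessions character vector of session labels (default a single
#'   `"none"` session).
#' @param slopeMean,slopeSd mean and SD of the between-subject slope
#'   distribution (euro per intensity unit).
#' @param intercept donation intercept (euro).
#' @param noiseSd trial noise SD (euro); must be non-negative.
#' @param slopeAdjust optional named list of additive slope offsets per
#'   `"condition:session"` cell.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with columns `subject`, `condition`, `session`,
#'   `trial`, `intensity`, `response`.
#' @examples
#' tab <- generateDonationTable(nSubjects = 4, seed = 7)
#' table(tab$condition)  # 43 Hand and 52 Face trials per subject
#' @export
generateDonationTable <- function(nSubjects = 28,
                                  intensityCounts =
                                    intensityCountsPreset("table2_eeg"),
                                  sessions = "none",
                                  slopeMean = 0.6, slopeSd = 0.15,
                                  intercept = -0.2, noiseSd = 0.8,
                                  slopeAdjust = NULL, seed = 1) {
  .stopIf(nSubjects < 1, "nSubjects must be at least 1")
  .stopIf(noiseSd < 0, "noiseSd must be non-negative")
  .checkCounts(intensityCounts)
  .withSeed(.subSeed(seed, "donation-table"), {
    subjects <- sprintf("S%02d", seq_len(nSubjects))
    bSubj <- stats::rnorm(nSubjects, slopeMean, slopeSd)
    rows <- vector("list", 0L)
    for (s in seq_len(nSubjects)) {
      for (cond in names(intensityCounts)) {
        cnt <- intensityCounts[[cond]]
        intens <- rep(as.numeric(names(cnt)), cnt)
        for (ses in sessions) {
          b <- bSubj[s]
          adj <- slopeAdjust[[.cellLabel(cond, ses)]]
          if (!is.null(adj)) b <- b + adj
          eps <- stats::rnorm(length(intens), 0, noiseSd)
          don <- .roundHalfAway(.clip(intercept + b * intens + eps, 0, 6))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subjects[s], condition = cond, session = ses,
            trial = seq_along(intens), intensity = intens,
            response = don, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a pain/saturation rating trial table
#'
#' Like [generateDonationTable()] but for rating experiments: the response
#' is an integer 0-10 rating of the perceived intensity,
#' `round(clip(intercept + b_s * intensity + eps, 0, 10))`.  Per-cell noise
#' overrides (`noiseAdjust`, named `"condition:session"`) emulate
#' manipulations that sharpen or blur the intensity-rating mapping, i.e.
#' change rating accuracy without shifting its mean.
#'
#' @inheritParams generateDonationTable
#' @param noiseSd baseline trial noise SD (rating units).
#' @param noiseAdjust optional named list replacing `noiseSd` in selected
#'   `"condition:session"` cells.
#' @return data.frame with columns `subject`, `condition`, `session`,
#'   `trial`, `intensity`, `response`.
#' @export
generateRatingTable <- function(nSubjects = 25,
                                intensityCounts =
                                  intensityCountsPreset("table2_tms"),
                                sessions = c("real", "sham"),
                                slopeMean = 1, slopeSd = 0.1,
                                intercept = 0, noiseSd = 1.2,
                                noiseAdjust = NULL, seed = 1) {
  .stopIf(nSubjects < 1, "nSubjects must be at least 1")
  .stopIf(noiseSd < 0, "noiseSd must be non-negative")
  .checkCounts(intensityCounts)
  .withSeed(.subSeed(seed, "rating-table"), {
    subjects <- sprintf("S%02d", seq_len(nSubjects))
    bSubj <- stats::rnorm(nSubjects, slopeMean, slopeSd)
    rows <- vector("list", 0L)
    for (s in seq_len(nSubjects)) {
      for (cond in names(intensityCounts)) {
        cnt <- intensityCounts[[cond]]
        intens <- rep(as.numeric(names(cnt)), cnt)
        for (ses in sessions) {
          sd0 <- noiseAdjust[[.cellLabel(cond, ses)]]
          if (is.null(sd0)) sd0 <- noiseSd
          eps <- stats::rnorm(length(intens), 0, sd0)
          rat <- .roundHalfAway(.clip(intercept + bSubj[s] * intens + eps,
                                      0, 10))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subjects[s], condition = cond, session = ses,
            trial = seq_along(intens), intensity = intens,
            response = rat, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Sunflower layout: nChannels positions on the unit disc, approximating an
# evenly spread electrode cap without any electrode database.
.sensorLayout <- function(nChannels) {
  i <- seq_len(nChannels)
  r <- sqrt((i - 0.5) / nChannels)
  theta <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(theta), y = r * sin(theta))
}

#' Generate a parametric lead field
#'
#' Builds a channels x (3 * nRois) forward-gain matrix for sensors laid out
#' on a unit disc (a parametric stand-in for an electrode cap).  Each ROI
#' contributes three columns: two tangential dipole components, modelled as
#' oriented first derivatives of a 2-D Gaussian centred on the ROI
#' projection, and one radial component modelled as the Gaussian itself.
#' This construction makes every 3-column block full rank by design.
#' Columns are scaled to unit norm; with `orthonormalize = TRUE` each block
#' is replaced by its QR orthonormal basis so that `t(B) %*% B = I3`.
#'
#' @param nChannels number of sensors; must be at least `3 * nRois + 1`.
#' @param nRois number of regions of interest.
#' @param spread Gaussian spatial spread of the topographies (disc units).
#' @param seed integer seed (ROI centres and orientations are random).
#' @param orthonormalize logical; orthonormalize each ROI block.
#' @param roiLabels optional character vector of ROI labels.
#' @return a [LeadField-class].
#' @examples
#' lf <- generateLeadField(nChannels = 16, nRois = 2, seed = 3)
#' qr(roiBlock(lf, "ROI1"))$rank  # 3
#' @export
generateLeadField <- function(nChannels = 64, nRois = 2, spread = 0.35,
                              seed = 1, orthonormalize = FALSE,
                              roiLabels = NULL) {
  .stopIf(nChannels < 3 * nRois + 1,
          "nChannels must be at least 3 * nRois + 1 for full-rank blocks")
  .stopIf(spread <= 0, "spread must be positive")
  if (is.null(roiLabels)) roiLabels <- paste0("ROI", seq_len(nRois))
  .stopIf(length(roiLabels) != nRois, "need one label per ROI")
  pos <- .sensorLayout(nChannels)
  .withSeed(.subSeed(seed, "lead-field"), {
    M <- matrix(0, nChannels, 3L * nRois)
    for (r in seq_len(nRois)) {
      for (attempt in 1:20) {
        rad <- 0.6 * sqrt(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        ctr <- c(rad * cos(ang), rad * sin(ang))
        phi <- stats::runif(1, 0, 2 * pi)
        u1 <- c(cos(phi), sin(phi))
        u2 <- c(-sin(phi), cos(phi))
        d <- sweep(pos, 2, ctr)
        g <- exp(-rowSums(d^2) / (2 * spread^2))
        blk <- cbind((d %*% u1) / spread * g,
                     (d %*% u2) / spread * g,
                     g)
        nrm <- sqrt(colSums(blk^2))
        if (any(nrm < 1e-8)) next
        blk <- sweep(blk, 2, nrm, "/")
        if (qr(blk)$rank == 3L) break
      }
      .stopIf(qr(blk)$rank < 3L,
              "could not build a full-rank block for ROI ", roiLabels[r])
      if (orthonormalize) {
        dec <- qr(blk)
        Q <- qr.Q(dec)
        sgn <- sign(diag(qr.R(dec)))
        sgn[sgn == 0] <- 1
        blk <- sweep(Q, 2, sgn, "*")
      }
      M[, (3L * r - 2L):(3L * r)] <- blk
    }
    colnames(M) <- paste(rep(roiLabels, each = 3L), c("x", "y", "z"),
                         sep = ".")
    new("LeadField", matrix = M, roiLabels = roiLabels,
        channelNames = paste0("Ch", seq_len(nChannels)))
  })
}

#' Construct ground-truth coupling parameters
#'
#' Convenience constructor for [GroundTruth-class].  The default window,
#' 1.42-1.48 s after movie onset, corresponds to 420-480 ms after a
#' noxious event placed at +1 s.
#'
#' @param couplingIntercept baseline source amplitude (a.u.).
#' @param couplingSlope amplitude per unit Z-scored response.
#' @param window coupling window, seconds relative to movie onset.
#' @param targetRoi label of the coupled ROI.
#' @param orientation dipole-frame orientation (normalized internally).
#' @return a [GroundTruth-class].
#' @export
groundTruth <- function(couplingIntercept = 5, couplingSlope = 1,
                        window = c(1.42, 1.48), targetRoi = "ROI1",
                        orientation = c(1, 1, 1)) {
  nrm <- sqrt(sum(orientation^2))
  .stopIf(nrm == 0, "orientation must be non-zero")
  new("GroundTruth", couplingIntercept = couplingIntercept,
      couplingSlope = couplingSlope, window = as.numeric(window),
      targetRoi = targetRoi, orientation = orientation / nrm)
}

#' Default evoked waveform
#'
#' A Gaussian bump (SD `sigma` seconds) centred in the coupling window,
#' emulating a transient evoked deflection after the noxious event.
#'
#' @param window coupling window (s, movie-onset relative).
#' @param sigma temporal SD in seconds.
#' @return function of a time vector returning waveform amplitudes.
#' @export
gaussianWaveform <- function(window, sigma = 0.05) {
  mid <- mean(window)
  function(t) exp(-(t - mid)^2 / (2 * sigma^2))
}

#' Simulate sensor epochs with known brain-behavior coupling
#'
#' Mixes ROI dipole sources through a known lead field into sensor epochs.
#' For each trial of `table`, the target ROI receives a source
#' `(g0 + g1 * z + eta) * waveform(t)` oriented along the ground-truth
#' orientation, where `z` is the trial's response Z-scored within subject
#' and condition, `g0`/`g1` are the ground-truth coupling intercept and
#' slope and `eta ~ N(0, ampNoiseSd^2)` is trial-amplitude noise.  All
#' dipoles additionally receive white background activity
#' (`backgroundNoiseSd`), and white sensor noise (`sensorNoiseSd`) is added
#' after mixing.  With every noise term at zero the epochs are an exact
#' linear mixture of the stated sources.
#'
#' @param leadfield a [LeadField-class].
#' @param table trial table (typically one subject's rows) with columns
#'   `subject`, `condition`, `session`, `trial`, `response`.
#' @param truth a [GroundTruth-class]; its window must lie inside the epoch
#'   and the waveform support is confined to it implicitly by the Gaussian
#'   default.
#' @param erpWaveform function of a time vector, or NULL for
#'   [gaussianWaveform()] centred in the truth window.
#' @param backgroundNoiseSd SD of white background source activity (a.u.).
#' @param sensorNoiseSd SD of white sensor noise (microvolts).
#' @param ampNoiseSd SD of the trial-amplitude noise `eta`.
#' @param fs sampling rate (Hz).
#' @param tPre,tPost epoch extent before/after movie onset (s).
#' @param events named event latencies (s, movie-onset relative).
#' @param seed integer seed.
#' @return list with elements `epochs` (an [EpochSet-class] whose
#'   `trialKeys` carry `response` and `zResponse`) and `sourceTruth`
#'   (trials x 3 x time array of the coupled target-ROI source, dipole
#'   coordinates).
#' @export
generateCoupledEpochs <- function(leadfield, table, truth = groundTruth(),
                                  erpWaveform = NULL,
                                  backgroundNoiseSd = 1, sensorNoiseSd = 1,
                                  ampNoiseSd = 0.5, fs = 500,
                                  tPre = 5, tPost = 2,
                                  events = c(fixation = -1, movie_onset = 0,
                                             noxious_event = 1),
                                  seed = 1) {
  .stopIf(!is(leadfield, "LeadField"), "leadfield must be a LeadField")
  .stopIf(!is(truth, "GroundTruth"), "truth must be a GroundTruth")
  .stopIf(nrow(table) < 1, "table has no trials")
  nt <- as.integer(round((tPre + tPost) * fs))
  times <- -tPre + (seq_len(nt) - 1L) / fs
  .stopIf(truth@window[1] < -tPre || truth@window[2] > tPost,
          "ground-truth window lies outside the epoch")
  roiIdx <- match(truth@targetRoi, leadfield@roiLabels)
  .stopIf(is.na(roiIdx), "target ROI '", truth@targetRoi,
          "' not present in the lead field")
  if (is.null(erpWaveform)) erpWaveform <- gaussianWaveform(truth@window)
  w <- erpWaveform(times)
  .stopIf(length(w) != nt || !all(is.finite(w)),
          "erpWaveform must return one finite value per time sample")
  # confine the waveform support to the coupling window so the coupled
  # source is exactly zero outside it
  w[times < truth@window[1] - 1e-9 | times > truth@window[2] + 1e-9] <- 0

  z <- zscoreWithin(table$response,
                    interaction(table$subject, table$condition,
                                drop = TRUE))
  L <- leadfield@matrix
  nCh <- nrow(L)
  nDip <- ncol(L)
  tgtCols <- (3L * roiIdx - 2L):(3L * roiIdx)
  nTr <- nrow(table)

  .withSeed(.subSeed(seed, "coupled-epochs"), {
    eta <- stats::rnorm(nTr, 0, ampNoiseSd)
    amp <- truth@couplingIntercept + truth@couplingSlope * z + eta
    data <- array(0, dim = c(nCh, nt, nTr))
    sourceTruth <- array(0, dim = c(nTr, 3L, nt))
    for (k in seq_len(nTr)) {
      S <- matrix(0, nDip, nt)                     # dipoles x time
      tgt <- truth@orientation %o% (amp[k] * w)    # 3 x time
      S[tgtCols, ] <- tgt
      if (backgroundNoiseSd > 0)
        S <- S + matrix(stats::rnorm(nDip * nt, 0, backgroundNoiseSd),
                        nDip, nt)
      X <- L %*% S
      if (sensorNoiseSd > 0)
        X <- X + matrix(stats::rnorm(nCh * nt, 0, sensorNoiseSd), nCh, nt)
      data[, , k] <- X
      sourceTruth[k, , ] <- tgt
    }
    keys <- table
    keys$zResponse <- z
    rownames(keys) <- NULL
    epochs <- new("EpochSet", data = data, fs = fs, t0 = -tPre,
                  events = events, channelNames = leadfield@channelNames,
                  trialKeys = keys)
    list(epochs = epochs, sourceTruth = sourceTruth)
  })
}
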