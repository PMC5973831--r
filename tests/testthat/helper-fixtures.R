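# Shared fixture builders: all data are generated in code.

# Minimal epochs container around a given array.
makeEpochs <- function(data, fs = 100,
                       t0 = -(dim(data)[2] / fs) / 2,
                       events = c(movie_onset = 0),
                       keys = NULL) {
  d <- dim(data)
  if (is.null(keys)) keys <- data.frame(trial = seq_len(d[3]))
  new("EpochSet", data = data, fs = fs, t0 = t0, events = events,
      channelNames = paste0("Ch", seq_len(d[1])), trialKeys = keys)
}

# SourceEpochs with given trials x 3 x time data and a response column.
makeSource <- function(data, response, fs = 100, t0 = 0,
                       events = c(movie_onset = 0, noxious_event = 0),
                       subject = "S01", roi = "ROI1") {
  keys <- data.frame(subject = subject, condition = "Hand",
                     session = "none", trial = seq_len(dim(data)[1]),
                     zResponse = response, response = response)
  new("SourceEpochs", data = data, roiLabel = roi, fs = fs, t0 = t0,
      events = events, trialKeys = keys)
}

# SlopeTimecourse around a subjects x p x time array.
makeSlopes <- function(S, fs = 100, time = NULL) {
  if (is.null(time)) time <- (seq_len(dim(S)[3]) - 1) / fs
  new("SlopeTimecourse", slopes = S, fs = fs, time = time,
      roiLabel = "ROI1", condition = "Hand",
      subjects = paste0("S", seq_len(dim(S)[1])))
}

# A pure sinusoid recording for filter checks.
sineRecording <- function(freq, fs = 500, dur = 10, nChannels = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  new("Recording",
      data = matrix(rep(sin(2 * pi * freq * t), each = nChannels),
                    nrow = nChannels),
      fs = fs, channelNames = paste0("Ch", seq_len(nChannels)))
}

# RMS over the central fraction of a vector (discard filter edge
# transients; narrow-band notches ring longer, so deep-attenuation checks
# use a narrower central window on a longer signal).
centralRMS <- function(x, frac = 0.8) {
  n <- length(x)
  idx <- seq(ceiling(n * (1 - frac) / 2), floor(n * (1 + frac) / 2))
  sqrt(mean(x[idx]^2))
}

# Independent brute-force quadrature oracle for the JZS Bayes factor:
# trapezoid rule on a dense grid after the substitution delta = r tan(u).
bf01Quadrature <- function(t, n, rscale = sqrt(2) / 2) {
  df <- n - 1
  u <- seq(-pi / 2 + 1e-9, pi / 2 - 1e-9, length.out = 20001)
  d <- rscale * tan(u)
  jac <- rscale / cos(u)^2
  f <- suppressWarnings(stats::dt(t, df, ncp = d * sqrt(n))) *
    stats::dcauchy(d, 0, rscale) * jac
  m1 <- sum((f[-1] + f[-length(f)]) / 2 * diff(u))
  stats::dt(t, df) / m1
}
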