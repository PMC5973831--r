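test_that("donation tables are seeded, bounded and monotone without noise", {
  t1 <- generateDonationTable(nSubjects = 3, seed = 7)
  t2 <- generateDonationTable(nSubjects = 3, seed = 7)
  expect_identical(t1, t2)
  t3 <- generateDonationTable(nSubjects = 3, seed = 8)
  expect_false(identical(t1, t3))

  expect_true(all(t1$response %in% 0:6))
  expect_true(all(t1$intensity >= 2 & t1$intensity <= 7))
  expect_identical(anyDuplicated(t1[c("subject", "condition", "session",
                                      "trial")]), 0L)

  # deterministic monotone map: slope 1, no noise, no slope spread
  t0 <- generateDonationTable(nSubjects = 2, slopeMean = 1, slopeSd = 0,
                              intercept = -2, noiseSd = 0, seed = 3)
  mono <- tapply(seq_len(nrow(t0)), paste(t0$subject, t0$condition),
                 function(i) {
                   o <- order(t0$intensity[i])
                   all(diff(t0$response[i][o]) >= 0)
                 })
  expect_true(all(mono))

  expect_error(generateDonationTable(intensityCounts =
                                       list(Hand = c(`2` = 1.5))),
               "integer")
  expect_error(generateDonationTable(intensityCounts = list()),
               "named list")
})

test_that("default stimulus counts reproduce the published set sizes", {
  cnt <- intensityCountsPreset("table2_eeg")
  expect_identical(sum(cnt$Hand), 43L)
  expect_identical(sum(cnt$Face), 52L)
  expect_identical(sum(cnt$Hand) + sum(cnt$Face), 95L)
  tab <- generateDonationTable(nSubjects = 1, seed = 1)
  expect_identical(as.integer(table(tab$condition)[c("Hand", "Face")]),
                   c(43L, 52L))
})

test_that("null donation tables give nominal type-I rate for group slope tests", {
  # 200 replicate null datasets (flat response-intensity relation), group
  # one-sample t on per-subject robust slopes at alpha = .05
  counts <- list(Hand = c(`2` = 8L, `3` = 8L, `4` = 8L, `5` = 8L,
                          `6` = 8L))
  hits <- vapply(seq_len(200), function(d) {
    tab <- generateDonationTable(nSubjects = 20, intensityCounts = counts,
                                 slopeMean = 0, slopeSd = 0,
                                 intercept = 3, noiseSd = 2,
                                 seed = 5000 + d)
    slopes <- vapply(unique(tab$subject), function(s) {
      sel <- tab$subject == s
      robustFit(tab$intensity[sel], tab$response[sel])$slope
    }, numeric(1))
    oneSampleT(slopes)$p <= 0.05
  }, logical(1))
  # binomial 99% CI around 0.05 for 200 draws: [0.010, 0.090]
  expect_gte(mean(hits), 0.010)
  expect_lte(mean(hits), 0.090)
})

test_that("lead-field blocks are full rank, orthonormalizable and seeded", {
  lf <- generateLeadField(nChannels = 16, nRois = 3, seed = 3)
  for (r in 1:3) expect_identical(qr(roiBlock(lf, r))$rank, 3L)
  expect_identical(dim(lf@matrix), c(16L, 9L))

  lfo <- generateLeadField(nChannels = 16, nRois = 2, seed = 3,
                           orthonormalize = TRUE)
  for (r in 1:2)
    expect_lt(max(abs(crossprod(roiBlock(lfo, r)) - diag(3))), 1e-10)

  expect_identical(generateLeadField(nChannels = 12, seed = 9)@matrix,
                   generateLeadField(nChannels = 12, seed = 9)@matrix)
  expect_error(generateLeadField(nChannels = 6, nRois = 2), "at least")
})

test_that("coupled epochs are an exact mixture without noise", {
  lf <- generateLeadField(nChannels = 10, nRois = 2, seed = 4)
  tab <- generateDonationTable(nSubjects = 1,
                               intensityCounts =
                                 list(Hand = c(`2` = 5, `5` = 5, `7` = 5)),
                               seed = 2)
  tr <- groundTruth(couplingIntercept = 0, couplingSlope = 1,
                    window = c(0.4, 0.5), targetRoi = "ROI2")
  noiseless <- function(slope, seed = 5)
    generateCoupledEpochs(lf, tab,
                          groundTruth(couplingIntercept = 0,
                                      couplingSlope = slope,
                                      window = c(0.4, 0.5),
                                      targetRoi = "ROI2"),
                          backgroundNoiseSd = 0, sensorNoiseSd = 0,
                          ampNoiseSd = 0, fs = 100, tPre = 0.2,
                          tPost = 0.8,
                          events = c(movie_onset = 0,
                                     noxious_event = 0.2),
                          seed = seed)
  ge <- noiseless(1)

  # pseudo-inverse of the lead field recovers the true sources
  P <- solve(crossprod(lf@matrix)) %*% t(lf@matrix)
  err <- vapply(seq_len(nTrials(ge$epochs)), function(k) {
    rec <- P %*% ge$epochs@data[, , k]
    max(max(abs(rec[4:6, ] - ge$sourceTruth[k, , ])),
        max(abs(rec[1:3, ])))
  }, numeric(1))
  expect_lt(max(err), 1e-8)

  # with intercept 0 and slope 1 the waveform-projected amplitude is the
  # Z-donation exactly, trial by trial
  tt <- epochTimes(ge$epochs)
  w <- gaussianWaveform(c(0.4, 0.5))(tt)
  w[tt < 0.4 | tt > 0.5] <- 0
  v <- ge$epochs@trialKeys$zResponse
  for (k in c(1, 7, 15)) {
    comp <- crossprod(tr@orientation, ge$sourceTruth[k, , ])  # 1 x time
    amp <- sum(comp * w) / sum(w^2)
    expect_equal(amp, v[k], tolerance = 1e-10)
  }

  # zero slope and zero noise: all trials identical
  g0 <- noiseless(0)
  base <- g0$epochs@data[, , 1]
  for (k in 2:nTrials(g0$epochs))
    expect_equal(g0$epochs@data[, , k], base, tolerance = 1e-12)

  # linearity in the coupling slope at fixed seed
  g2 <- noiseless(2)
  d1 <- ge$epochs@data - g0$epochs@data
  d2 <- g2$epochs@data - g0$epochs@data
  expect_equal(d2, 2 * d1, tolerance = 1e-10)

  # seeded determinism
  expect_identical(noiseless(1)$epochs@data, ge$epochs@data)
  expect_error(generateCoupledEpochs(lf, tab,
                                     groundTruth(window = c(5, 6)),
                                     fs = 100, tPre = 0.2, tPost = 0.8),
               "outside the epoch")
})
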