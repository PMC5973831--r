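test_that("slope time courses equal mapping robustFit over time", {
  set.seed(61)
  nTr <- 20; nt <- 12
  mkSubj <- function(sid) {
    y <- rnorm(nTr)
    act <- array(rnorm(nTr * 3 * nt), c(nTr, 3, nt))
    # inject coupling at samples 5:7, dipole 2
    act[, 2, 5:7] <- act[, 2, 5:7] + 2 * y
    makeSource(act, y, subject = sid)
  }
  srcs <- list(mkSubj("S01"), mkSubj("S02"), mkSubj("S03"))
  sl <- slopeTimecourses(srcs)
  expect_identical(dim(sl@slopes), c(3L, 3L, 12L))

  # compositional identity with the scalar robust fit
  for (s in 1:3) for (d in 1:3) for (t in c(1, 6, 12)) {
    f <- robustFit(srcs[[s]]@data[, d, t],
                   trialKeys(srcs[[s]])$zResponse)
    expect_equal(sl@slopes[s, d, t], f$slope, tolerance = 1e-6)
  }

  # mismatched trial counts are caught
  bad <- srcs
  bad[[2]]@trialKeys <- bad[[2]]@trialKeys[-1, ]
  expect_error(slopeTimecourses(bad), "disagree")
})

test_that("null slope time courses stay near zero, coupled ones peak in-window", {
  lf <- generateLeadField(nChannels = 12, nRois = 1, seed = 62)
  counts <- list(Hand = c(`2` = 8, `4` = 8, `6` = 8))
  mk <- function(slope, sid, seed) {
    tab <- generateDonationTable(nSubjects = 1, intensityCounts = counts,
                                 seed = seed)
    tab$subject <- sid
    ge <- generateCoupledEpochs(lf, tab,
                                groundTruth(couplingSlope = slope,
                                            window = c(0.4, 0.5),
                                            targetRoi = "ROI1"),
                                backgroundNoiseSd = if (slope == 0) 1 else 0,
                                sensorNoiseSd = if (slope == 0) 1 else 0,
                                ampNoiseSd = 0,
                                fs = 50, tPre = 0.2, tPost = 0.8,
                                events = c(movie_onset = 0,
                                           noxious_event = 0.2),
                                seed = seed)
    cv <- erpCovariance(ge$epochs)
    W <- lcmvWeights(roiBlock(lf, 1), cv, 0.05)
    reconstructSources(W, ge$epochs, "ROI1")
  }
  # noise-free coupling: slopes peak inside the window, vanish outside
  srcs <- lapply(1:4, function(i) mk(1, paste0("S", i), 70 + i))
  sl <- slopeTimecourses(srcs)
  tt <- epochTimes(srcs[[1]])
  inWin <- tt >= 0.4 - 1e-9 & tt <= 0.5 + 1e-9
  m <- apply(abs(sl@slopes), 3, max)
  expect_gt(max(m[inWin]), 10 * max(m[!inWin], 1e-12))
  expect_lt(max(m[!inWin]), 1e-8)

  # pure-noise sources: group mean slope within 3 SE of zero everywhere
  srcs0 <- lapply(1:8, function(i) mk(0, paste0("S", i), 80 + i))
  sl0 <- slopeTimecourses(srcs0)
  mean0 <- apply(sl0@slopes, c(2, 3), mean)
  se0 <- apply(sl0@slopes, c(2, 3), sd) / sqrt(8)
  expect_true(mean(abs(mean0) < 3 * se0) > 0.9)
})

test_that("Hotelling time course matches oracles and flags singularities", {
  set.seed(63)
  S <- array(rnorm(15 * 3 * 30), c(15, 3, 30))
  sl <- makeSlopes(S)
  h <- hotellingTimecourse(sl)
  # independent oracle: mahalanobis form at a few time points
  for (t in c(1, 10, 30)) {
    x <- S[, , t]
    T2o <- 15 * stats::mahalanobis(colMeans(x), rep(0, 3), cov(x))
    expect_equal(h@T2[t], T2o, tolerance = 1e-8)
  }
  expect_equal(h@Fstat, h@T2 * 12 / (3 * 14), tolerance = 1e-12)
  expect_identical(h@df, c(3L, 12L))

  # all-zero slopes at one time point: T2 = 0 ... covariance singular
  S2 <- S; S2[, , 4] <- 0
  h2 <- hotellingTimecourse(makeSlopes(S2))
  expect_true(h2@singular[4])

  # 1-dipole degenerate mode: F equals the squared one-sample t
  S1 <- array(rnorm(15 * 1 * 10), c(15, 1, 10))
  h1 <- hotellingTimecourse(makeSlopes(S1))
  for (t in c(2, 9)) {
    tt <- oneSampleT(S1[, 1, t])
    expect_equal(h1@Fstat[t], tt$t^2, tolerance = 1e-10)
    expect_equal(h1@p[t], tt$p, tolerance = 1e-10)
  }
})

test_that("T2 is invariant under common invertible dipole transforms", {
  set.seed(64)
  S <- array(rnorm(12 * 3 * 20), c(12, 3, 20))
  A <- matrix(c(2, 0.3, -1, 0.5, 1.5, 0.2, -0.7, 0.1, 3), 3, 3)
  SA <- array(0, dim(S))
  for (i in 1:12) SA[i, , ] <- A %*% S[i, , ]
  h <- hotellingTimecourse(makeSlopes(S))
  hA <- hotellingTimecourse(makeSlopes(SA))
  expect_lt(max(abs(h@T2 - hA@T2)), 1e-8)
})

test_that("cluster formation sums supra-threshold runs", {
  # constructed statistic [0,9,9,0,9,0] with threshold 5: masses 18 and 9
  n <- 20; p <- 3
  Fv <- c(0, 9, 9, 0, 9, 0)
  T2v <- Fv * p * (n - 1) / (n - p)
  st <- new("StatTimecourse", time = (0:5) / 100, T2 = T2v, Fstat = Fv,
            p = stats::pf(Fv, p, n - p, lower.tail = FALSE),
            df = c(p, n - p), singular = rep(FALSE, 6))
  cl <- thresholdClusters(st, threshold = 5)
  expect_identical(nrow(cl), 2L)
  expect_equal(cl$mass, c(18, 9))
  expect_identical(cl$startIdx, c(2L, 5L))
  expect_identical(cl$endIdx, c(3L, 5L))

  # all sub-threshold: empty; single point: one cluster of length 1
  expect_identical(nrow(thresholdClusters(st, threshold = 10)), 0L)
  one <- thresholdClusters(st, threshold = 8.9)
  expect_true(all(one$startIdx == one$endIdx | one$mass == 18))

  # the printed threshold: qf at alpha 0.01 with 28 subjects
  expect_equal(round(clusterFormingThreshold(28, 3, 0.01), 3), 4.675)
})

test_that("sign-flip permutation test is seeded and detects strong coupling", {
  set.seed(65)
  n <- 24; nt <- 40
  S <- array(rnorm(n * 3 * nt, sd = 0.2), c(n, 3, nt))
  # strong common effect at samples 15:20
  S[, 1, 15:20] <- S[, 1, 15:20] + 1
  sl <- makeSlopes(S, time = seq(0, 0.39, by = 0.01))
  r1 <- signflipClusterTest(sl, nPerm = 200, seed = 9)
  r2 <- signflipClusterTest(sl, nPerm = 200, seed = 9)
  expect_identical(r1$clusters$pseudoP, r2$clusters$pseudoP)
  expect_identical(r1$nullMax, r2$nullMax)

  expect_gt(nrow(r1$clusters), 0)
  top <- r1$clusters[which.max(r1$clusters$mass), ]
  expect_lte(top$startIdx, 15)
  expect_gte(top$endIdx, 15)
  expect_equal(top$pseudoP, 1 / 201)

  # pseudo-p bounds
  expect_true(all(r1$clusters$pseudoP >= 1 / 201 &
                    r1$clusters$pseudoP <= 1))
  expect_error(signflipClusterTest(sl, nPerm = 0), "at least 1")
})

test_that("pseudo-p values are valid under a sign-symmetric null", {
  # slope-level null: pseudo-p of the max cluster should be (super)uniform
  set.seed(66)
  ps <- replicate(60, {
    S <- array(rnorm(10 * 3 * 25), c(10, 3, 25))
    r <- signflipClusterTest(makeSlopes(S), nPerm = 99,
                             seed = sample.int(1e6, 1))
    if (nrow(r$clusters)) min(r$clusters$pseudoP) else 1
  })
  # stochastically no smaller than uniform: the hit rate at any level
  # stays at or below that level plus Monte-Carlo slack
  expect_lte(mean(ps <= 0.05), 0.15)
  expect_lte(mean(ps <= 0.2), 0.35)
})

test_that("stronger coupling never raises the true-window pseudo-p (median)", {
  gammas <- c(0, 0.4, 0.8)
  medp <- vapply(seq_along(gammas), function(gi) {
    ps <- vapply(1:6, function(rep) {
      set.seed(1000 * gi + rep)
      S <- array(rnorm(12 * 3 * 30, sd = 0.5), c(12, 3, 30))
      S[, 2, 10:14] <- S[, 2, 10:14] + gammas[gi]
      r <- signflipClusterTest(makeSlopes(S), nPerm = 99,
                               seed = 100 + rep)
      cl <- r$clusters
      hit <- cl[cl$startIdx <= 14 & cl$endIdx >= 10, , drop = FALSE]
      if (nrow(hit)) min(hit$pseudoP) else 1
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(medp) <= 0))
})

test_that("Bonferroni correction applies the family threshold", {
  expect_true(bonferroniCorrect(0.004, 8))       # 0.004 < 0.05/8
  expect_false(bonferroniCorrect(0.009, 8))
  expect_identical(bonferroniCorrect(c(0.04, 0.06), 1), c(TRUE, FALSE))
  expect_error(bonferroniCorrect(0.01, 0), "at least 1")
})

test_that("median split partitions trials and exposes coupling", {
  # donations 1,2,3,4: split 2 low / 2 high
  act <- array(rnorm(4 * 3 * 10), c(4, 3, 10))
  se <- makeSource(act, c(1, 2, 3, 4))
  g <- medianSplitGrandAverage(list(se))
  y <- trialKeys(se)$response
  med <- median(y)
  expect_identical(sum(y <= med), 2L)
  expect_identical(sum(y > med), 2L)
  expect_equal(g$low, apply(act[y <= med, , ], c(2, 3), mean),
               tolerance = 1e-12)
  expect_equal(g$high, apply(act[y > med, , ], c(2, 3), mean),
               tolerance = 1e-12)

  # constant-donation subject excluded with report
  se2 <- makeSource(array(rnorm(120), c(4, 3, 10)), rep(2, 4),
                    subject = "S09")
  g2 <- medianSplitGrandAverage(list(se, se2))
  expect_identical(g2$excluded, "S09")
  expect_identical(g2$nSubjects, 1L)

  # positive coupling: high-minus-low difference larger inside the window
  set.seed(67)
  srcs <- lapply(1:6, function(s) {
    y <- rnorm(30)
    act <- array(rnorm(30 * 3 * 20, sd = 0.3), c(30, 3, 20))
    act[, 1, 8:12] <- act[, 1, 8:12] + 2 * y
    makeSource(act, y, subject = paste0("S", s))
  })
  g3 <- medianSplitGrandAverage(srcs)
  diffWave <- abs(g3$high[1, ] - g3$low[1, ])
  expect_gt(max(diffWave[8:12]), max(diffWave[-(8:12)]))
})
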