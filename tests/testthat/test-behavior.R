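test_that("within-group Z-scores have unit sample SD and survive re-application", {
  expect_equal(zscoreWithin(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  set.seed(31)
  v <- rnorm(40)
  g <- rep(c("x", "y"), each = 20)
  z <- zscoreWithin(v, g)
  for (gg in c("x", "y")) {
    expect_lt(abs(mean(z[g == gg])), 1e-12)
    expect_equal(sd(z[g == gg]), 1, tolerance = 1e-12)
  }
  # projection: re-applying changes nothing
  expect_equal(zscoreWithin(z, g), z, tolerance = 1e-12)
  expect_error(zscoreWithin(c(1, 1, 1, 2, 3), rep(c("k", "m"), c(3, 2))),
               "'k'")
})

test_that("robust regression recovers exact lines and resists outliers", {
  f <- robustFit(1:10, 2 * (1:10) + 1)
  expect_lt(abs(f$slope - 2), 1e-10)
  expect_lt(abs(f$intercept - 1), 1e-10)
  expect_true(f$converged)

  # contaminated fixture: robust slope closer to truth than OLS
  x <- 1:20
  y <- as.numeric(x); y[20] <- y[20] + 100
  fr <- robustFit(x, y)
  ols <- unname(coef(stats::lm(y ~ x))[2])
  expect_lt(abs(fr$slope - 1), abs(ols - 1))
  # independent cross-check against the reference M-estimator
  frlm <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                    maxit = 100)
  expect_equal(fr$slope, unname(coef(frlm)[2]), tolerance = 1e-6)

  # equal-magnitude residuals give equal weights, so the robust fit IS the
  # OLS fit (perturbation orthogonal to the design keeps OLS at the truth)
  x8 <- 1:8
  r8 <- 0.05 * c(1, -1, -1, 1, 1, -1, -1, 1)
  y8 <- 2 * x8 + 1 + r8
  f8 <- robustFit(x8, y8)
  ols8 <- coef(stats::lm(y8 ~ x8))
  expect_lt(abs(f8$slope - ols8[2]), 1e-6)
  expect_lt(abs(f8$intercept - ols8[1]), 1e-6)

  # affine equivariance: scaling y scales both coefficients
  f3 <- robustFit(x, 3 * y)
  expect_equal(f3$slope, 3 * fr$slope, tolerance = 1e-10)
  expect_equal(f3$intercept, 3 * fr$intercept, tolerance = 1e-10)

  expect_error(robustFit(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(robustFit(1:2, 1:2), "at least 3")
})

test_that("per-cell slopes recover generating slopes and ignore row order", {
  counts <- list(Hand = c(`2` = 6, `4` = 6, `6` = 6),
                 Face = c(`2` = 6, `4` = 6, `6` = 6))
  tab <- generateDonationTable(nSubjects = 4, intensityCounts = counts,
                               slopeMean = 0.6, slopeSd = 0,
                               intercept = 0.5, noiseSd = 0, seed = 41)
  tab$zResponse <- zscoreWithin(tab$response,
                                interaction(tab$subject, tab$condition))
  sl <- slopesByCell(tab)
  expect_true(all(sl$estimable))
  # noise-free: z-slope equals raw slope divided by the response SD
  for (i in seq_len(nrow(sl))) {
    sel <- tab$subject == sl$subject[i] & tab$condition == sl$condition[i]
    raw <- robustFit(tab$intensity[sel], tab$response[sel])$slope
    expect_equal(sl$slope[i], raw / sd(tab$response[sel]),
                 tolerance = 1e-6)
  }
  # permutation invariance
  perm <- sample(nrow(tab))
  sl2 <- slopesByCell(tab[perm, ])
  expect_equal(sl2$slope, sl$slope, tolerance = 1e-12)

  # degenerate cell reported, not dropped
  bad <- tab[tab$subject == "S01" & tab$condition == "Hand" &
               tab$intensity == 2, ]
  bad$zResponse <- rnorm(nrow(bad))
  out <- slopesByCell(rbind(tab[tab$subject != "S01", ], bad))
  row <- out[out$subject == "S01" & out$condition == "Hand", ]
  expect_false(row$estimable)
  expect_match(row$reason, "intensity")
  expect_error(slopesByCell(tab[0, ]), "empty")
})

test_that("t statistics match the closed form", {
  r <- oneSampleT(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_identical(r$df, 2L)
  ref <- stats::t.test(c(1, 2, 3))
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  sym <- c(-2, -1, 1, 2)
  expect_equal(oneSampleT(sym)$t, 0)
  expect_equal(oneSampleT(sym)$p, 1)

  a <- c(1, 4, 2, 8)
  b <- c(0, 5, 1, 6)
  ref2 <- stats::t.test(a, b, paired = TRUE)
  expect_equal(pairedT(a, b)$t, unname(ref2$statistic), tolerance = 1e-12)
  expect_error(pairedT(a, a), "zero variance")
})

test_that("repeated-measures ANOVA matches paired-t and handles degenerate data", {
  set.seed(42)
  Y <- array(rnorm(12 * 2 * 2), c(12, 2, 2))
  an <- rmAnovaFactorial(Y, c("Condition", "TMS"))
  # every 1-df F equals the squared paired t of its contrast
  tA <- oneSampleT((Y[, 1, 1] + Y[, 1, 2]) / 2 - (Y[, 2, 1] + Y[, 2, 2]) / 2)
  tB <- oneSampleT((Y[, 1, 1] + Y[, 2, 1]) / 2 - (Y[, 1, 2] + Y[, 2, 2]) / 2)
  tAB <- oneSampleT((Y[, 1, 1] - Y[, 1, 2]) - (Y[, 2, 1] - Y[, 2, 2]))
  expect_lt(abs(an$F[1] - tA$t^2), 1e-8)
  expect_lt(abs(an$F[2] - tB$t^2), 1e-8)
  expect_lt(abs(an$F[3] - tAB$t^2), 1e-8)
  expect_identical(an$dfNum, c(1L, 1L, 1L))
  expect_identical(an$dfDen, c(11L, 11L, 11L))
  expect_equal(an$petaSq,
               an$F * an$dfNum / (an$F * an$dfNum + an$dfDen),
               tolerance = 1e-12)

  # perfectly additive data: interaction F = 0
  s <- rnorm(8)
  Yad <- array(0, c(8, 2, 3))
  for (j in 1:2) for (k in 1:3) Yad[, j, k] <- s + j + 2 * k
  expect_identical(rmAnovaFactorial(Yad)$F[3], 0)

  # all-constant data: every F = 0
  expect_identical(rmAnovaFactorial(array(5, c(6, 2, 2)))$F, c(0, 0, 0))
})

test_that("Newman-Keuls reduces to the range test and is monotone over nesting", {
  # two identical means are never significant
  same <- newmanKeuls(c(a = 1, b = 1), n = 8, msError = 1, dfError = 7)
  expect_false(same$significant)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # two-group identity: q = sqrt(2) * t, p equals the two-sided t-test p
  msE <- 2; n <- 10; dfE <- 9; diff <- 1.3
  nk <- newmanKeuls(c(a = 0, b = diff), n = n, msError = msE, dfError = dfE)
  tstat <- diff / sqrt(2 * msE / n)
  expect_equal(nk$q, sqrt(2) * tstat, tolerance = 1e-10)
  expect_equal(nk$p, 2 * stats::pt(-abs(tstat), dfE), tolerance = 1e-10)

  # the widest pair never has a larger p than any pair it encloses
  set.seed(43)
  for (i in 1:20) {
    m <- sort(rnorm(4))
    names(m) <- letters[1:4]
    tb <- newmanKeuls(m, n = 6, msError = 0.5, dfError = 15)
    widest <- tb[tb$span == 4, ]
    expect_true(all(widest$p <= tb$p + 1e-12))
  }
  expect_error(newmanKeuls(c(a = 1, b = 2), n = 5, msError = 0,
                           dfError = 4), "positive")
})

test_that("JZS Bayes factors agree with brute-force quadrature", {
  expect_gt(jzsBF01(0, 20), 1)

  # strictly decreasing in |t| at fixed n
  ts <- seq(0, 4, by = 0.5)
  bfs <- vapply(ts, jzsBF01, numeric(1), n = 20)
  expect_true(all(diff(bfs) < 0))

  # two-sided values within 1% of the independent dense-grid oracle
  for (tv in c(0.3, 1.1, 2.2, 3.5)) for (nn in c(10, 25)) {
    expect_equal(jzsBF01(tv, nn), bf01Quadrature(tv, nn),
                 tolerance = 0.01)
  }
  # one-sided: prior truncation; evidence for the null grows when the
  # data point away from the alternative direction
  expect_gt(jzsBF01(1.5, 15, alternative = "less"),
            jzsBF01(1.5, 15, alternative = "greater"))
  expect_error(jzsBF01(1, 10, rscale = 0), "positive")
})

test_that("Fisher z is the odd closed form with guarded edges", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  r <- c(-0.9, -0.3, 0.2, 0.7)
  expect_equal(fisherZ(-r), -fisherZ(r), tolerance = 1e-12)
  expect_error(fisherZ(1), "below 1")
})

test_that("rating accuracy composes Pearson r with Fisher z", {
  tab <- generateRatingTable(nSubjects = 3, sessions = "none",
                             intensityCounts =
                               list(Hand = c(`2` = 5, `4` = 5, `6` = 5)),
                             noiseSd = 1, seed = 51)
  tab$zResponse <- zscoreWithin(tab$response,
                                interaction(tab$subject, tab$condition))
  acc <- ratingAccuracy(tab)
  expect_true(all(acc$estimable))
  for (i in seq_len(nrow(acc))) {
    sel <- tab$subject == acc$subject[i]
    expect_equal(acc$z[i], fisherZ(cor(tab$intensity[sel],
                                       tab$zResponse[sel])),
                 tolerance = 1e-12)
  }

  # ratings equal to intensities: perfect correlation is clipped, not fatal
  perf <- tab
  perf$zResponse <- zscoreWithin(perf$intensity,
                                 interaction(perf$subject, perf$condition))
  perf1 <- perf[perf$subject == "S01", ]
  expect_warning(accP <- ratingAccuracy(perf1), "clipped")
  expect_true(all(is.finite(accP$z)))

  # intensity-independent ratings: mean z across many cells is near zero
  set.seed(52)
  zs <- replicate(150, {
    x <- rep(c(2, 4, 6), each = 5)
    y <- sample(rnorm(15))
    fisherZ(cor(x, y))
  })
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)) + 0.05)
})

test_that("per-subject SDs use the sample formula and scale with the data", {
  tab <- data.frame(subject = rep(c("S1", "S2"), each = 8),
                    condition = rep(rep(c("Hand", "Face"), each = 4), 2),
                    session = "none", trial = rep(1:4, 4),
                    intensity = rep(c(2, 4, 5, 7), 4),
                    response = c(0, 2, 4, 6, 1, 2, 3, 4,
                                 0, 3, 3, 6, 2, 2, 4, 4))
  out <- perSubjectSD(tab)
  # closed form for the sample SD of 0,2,4,6
  expect_equal(out$sds$sd[out$sds$subject == "S1" &
                            out$sds$condition == "Hand"],
               sqrt(sum((c(0, 2, 4, 6) - 3)^2) / 3), tolerance = 1e-12)

  dbl <- tab; dbl$response <- 2 * dbl$response
  expect_equal(perSubjectSD(dbl)$sds$sd, 2 * out$sds$sd,
               tolerance = 1e-12)

  # identical trial sets in both conditions: paired t is exactly 0
  mir <- tab
  mir$response[mir$condition == "Face"] <-
    mir$response[mir$condition == "Hand"]
  expect_identical(perSubjectSD(mir)$tests$t, 0)
  expect_identical(perSubjectSD(mir)$tests$p, 1)

  # singleton cells are an error, not silence
  expect_error(perSubjectSD(tab[-c(2:4), ]), "singleton")
})

test_that("stimulus-set statistics reproduce the published numbers", {
  cnt <- intensityCountsPreset("table2_eeg")
  s <- stimulusSetStats(cnt$Hand, cnt$Face, labels = c("Hand", "Face"))
  expect_equal(round(s$mean, 1), c(4.0, 3.7))
  expect_equal(round(s$sd, 1), c(1.4, 1.7))
  expect_identical(s$dfT, 93L)
  expect_equal(round(s$t, 2), 0.88)
  expect_equal(round(s$F, 2), 1.49)

  tms <- intensityCountsPreset("table2_tms")
  s2 <- stimulusSetStats(tms$Face, tms$Hand, labels = c("Face", "Hand"),
                         replicateFactor = 2)
  expect_identical(s2$dfT, 118L)
  expect_equal(round(s2$t, 2), -0.26)
  expect_equal(round(s2$mean, 1), c(3.8, 3.9))
  expect_equal(round(s2$F, 2), 1.67)

  # equal sets: t = 0 and F = 1
  eq <- stimulusSetStats(cnt$Hand, cnt$Hand)
  expect_equal(eq$t, 0)
  expect_equal(eq$F, 1)
})
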