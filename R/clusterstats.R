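# Group inference engine: per-subject robust slope time courses, one-
# sample Hotelling T-squared over the three dipoles, temporal cluster
# formation, sign-flip max-cluster permutation, Bonferroni control, and
# median-split grand averages.

#' Per-subject robust slope time courses
#'
#' The first level of the summary-statistics approach: for every subject,
#' dipole and time sample, fit a robust regression with the source
#' amplitude as the predictor and the Z-scored response as the observed
#' variable, and keep the slope.  All regressions of one subject share the
#' response vector, so they are fit jointly by a vectorized IRLS sweep.
#'
#' @param sourceList list of [SourceEpochs-class], one per subject, same
#'   ROI/condition and time axis.
#' @param response name of the (Z-scored) response column in the trial
#'   keys.
#' @param noxiousEvent name of the event defining time zero of the
#'   reported axis.
#' @param ... tuning arguments passed to the IRLS engine (see
#'   [robustFit()]).
#' @return a [SlopeTimecourse-class] (subjects x 3 x time; time in seconds
#'   relative to the noxious event).
#' @export
slopeTimecourses <- function(sourceList, response = "zResponse",
                             noxiousEvent = "noxious_event", ...) {
  .stopIf(length(sourceList) < 2L, "need at least 2 subjects")
  .stopIf(!all(vapply(sourceList, is, TRUE, "SourceEpochs")),
          "sourceList must contain SourceEpochs objects")
  ref <- sourceList[[1L]]
  nt <- dim(ref@data)[3L]
  slopes <- array(0, dim = c(length(sourceList), 3L, nt))
  subjects <- character(length(sourceList))
  for (s in seq_along(sourceList)) {
    se <- sourceList[[s]]
    .stopIf(dim(se@data)[3L] != nt,
            "subjects disagree on the number of time samples")
    keys <- trialKeys(se)
    .stopIf(!response %in% names(keys),
            "response column '", response, "' missing from trial keys")
    y <- keys[[response]]
    .stopIf(nrow(keys) != dim(se@data)[1L],
            "trial keys and source data disagree on trial count")
    .stopIf(length(y) < 3L, "each subject needs at least 3 trials")
    X <- matrix(se@data, nrow = dim(se@data)[1L])   # trials x (3 * time)
    fit <- .irlsMany(X, y, ...)
    slopes[s, , ] <- matrix(fit$slope, 3L, nt)
    subjects[s] <- if ("subject" %in% names(keys))
      as.character(keys$subject[1L]) else paste0("S", s)
  }
  tt <- epochTimes(ref)
  t0ev <- if (noxiousEvent %in% names(ref@events))
    ref@events[[noxiousEvent]] else 0
  new("SlopeTimecourse", slopes = slopes, fs = ref@fs, time = tt - t0ev,
      roiLabel = ref@roiLabel, condition =
        if ("condition" %in% names(trialKeys(ref)))
          as.character(trialKeys(ref)$condition[1L]) else "all",
      subjects = subjects)
}

# Vectorized one-sample Hotelling T2 from sufficient statistics.
# G: p x p x T array of per-time cross-products sum_i x_i x_i'; M: p x T
# matrix of means (possibly sign-flipped); n: subjects.  Returns list
# (T2, singular).  Sign flips leave G untouched because x x' is even.
.hotellingFromMoments <- function(G, M, n) {
  p <- nrow(M)
  nt <- ncol(M)
  if (p == 3L) {
    C11 <- (G[1, 1, ] - n * M[1, ]^2) / (n - 1)
    C22 <- (G[2, 2, ] - n * M[2, ]^2) / (n - 1)
    C33 <- (G[3, 3, ] - n * M[3, ]^2) / (n - 1)
    C12 <- (G[1, 2, ] - n * M[1, ] * M[2, ]) / (n - 1)
    C13 <- (G[1, 3, ] - n * M[1, ] * M[3, ]) / (n - 1)
    C23 <- (G[2, 3, ] - n * M[2, ] * M[3, ]) / (n - 1)
    A11 <- C22 * C33 - C23^2
    A12 <- C13 * C23 - C12 * C33
    A13 <- C12 * C23 - C13 * C22
    A22 <- C11 * C33 - C13^2
    A23 <- C12 * C13 - C11 * C23
    A33 <- C11 * C22 - C12^2
    det <- C11 * A11 + C12 * A12 + C13 * A13
    scale <- (abs(C11) + abs(C22) + abs(C33)) / 3
    singular <- !is.finite(det) | abs(det) <= (1e-12 * pmax(scale, 1e-300))^3
    quad <- M[1, ]^2 * A11 + M[2, ]^2 * A22 + M[3, ]^2 * A33 +
      2 * (M[1, ] * M[2, ] * A12 + M[1, ] * M[3, ] * A13 +
             M[2, ] * M[3, ] * A23)
    T2 <- ifelse(singular, NA_real_, n * quad / det)
    T2[!singular & T2 < 0] <- 0          # numerical guard
    list(T2 = T2, singular = singular)
  } else {
    T2 <- numeric(nt)
    singular <- logical(nt)
    for (t in seq_len(nt)) {
      Ct <- (G[, , t] - n * tcrossprod(M[, t])) / (n - 1)
      sol <- tryCatch(solve(Ct, M[, t]), error = function(e) NULL)
      if (is.null(sol)) {
        singular[t] <- TRUE; T2[t] <- NA_real_
      } else T2[t] <- n * sum(M[, t] * sol)
    }
    list(T2 = T2, singular = singular)
  }
}

.momentsFromSlopes <- function(S) {
  n <- dim(S)[1L]; p <- dim(S)[2L]; nt <- dim(S)[3L]
  G <- array(0, dim = c(p, p, nt))
  for (a in seq_len(p)) for (b in a:p) {
    g <- colSums(S[, a, , drop = FALSE] * S[, b, , drop = FALSE], dims = 1)
    G[a, b, ] <- g
    G[b, a, ] <- g
  }
  G
}

#' Hotelling T-squared statistic time course
#'
#' At every time point, tests whether the subjects' mean dipole slope
#' vector is zero with the one-sample Hotelling T-squared statistic
#' `T2 = n * xbar' S^-1 xbar`, its F transform
#' `F = T2 * (n - p) / (p * (n - 1))` with degrees of freedom
#' `(p, n - p)`, and the uncorrected p value from the F distribution.
#' Time points with a singular slope covariance are flagged as such and
#' later excluded from cluster formation.
#'
#' @param slopes a [SlopeTimecourse-class] with more subjects than
#'   dipoles.
#' @return a [StatTimecourse-class].
#' @export
hotellingTimecourse <- function(slopes) {
  .stopIf(!is(slopes, "SlopeTimecourse"),
          "slopes must be a SlopeTimecourse")
  S <- slopes@slopes
  n <- dim(S)[1L]; p <- dim(S)[2L]; nt <- dim(S)[3L]
  .stopIf(n <= p, "need more subjects than dipole dimensions")
  M <- colMeans(S)                       # p x T  (mean over subjects)
  dim(M) <- c(p, nt)
  h <- .hotellingFromMoments(.momentsFromSlopes(S), M, n)
  Fst <- h$T2 * (n - p) / (p * (n - 1))
  pv <- stats::pf(Fst, p, n - p, lower.tail = FALSE)
  new("StatTimecourse", time = slopes@time, T2 = h$T2, Fstat = Fst,
      p = pv, df = c(p, n - p), singular = h$singular)
}

#' Cluster-forming threshold on the F scale
#'
#' The critical value of the F transform of the one-sample Hotelling
#' T-squared statistic at uncorrected level `alpha`: `qf(1 - alpha, p,
#' n - p)`.  With `n = 28` subjects and `p = 3` dipoles at `alpha = 0.01`
#' this is 4.675.
#'
#' @param n number of subjects.
#' @param p dimensionality (number of dipoles, default 3).
#' @param alpha uncorrected cluster-forming level (default 0.01).
#' @return the critical F value.
#' @export
clusterFormingThreshold <- function(n, p = 3, alpha = 0.01) {
  .stopIf(n <= p, "need n > p")
  stats::qf(1 - alpha, p, n - p)
}

#' Form temporal clusters of supra-threshold statistics
#'
#' Combines maximal runs of temporally adjacent time points whose F-scale
#' statistic exceeds the cluster-forming threshold into clusters; the
#' cluster mass is the sum of the statistic over the run.  Singular time
#' points never enter a cluster (they break adjacency).
#'
#' @param stat a [StatTimecourse-class].
#' @param clusterAlpha uncorrected level defining the threshold (used when
#'   `threshold` is NULL).
#' @param threshold explicit F-scale threshold, overriding `clusterAlpha`.
#' @param statScale `"F"` (default) sums the F-transformed statistic;
#'   `"T2"` sums raw T-squared values over the same supra-threshold runs.
#' @return data.frame with one row per cluster: `startIdx`, `endIdx`,
#'   `startMs`, `endMs` (relative to the noxious event), `mass`.  Empty
#'   when nothing exceeds the threshold.
#' @export
thresholdClusters <- function(stat, clusterAlpha = 0.01, threshold = NULL,
                              statScale = c("F", "T2")) {
  statScale <- match.arg(statScale)
  .stopIf(!is(stat, "StatTimecourse"), "stat must be a StatTimecourse")
  if (is.null(threshold))
    threshold <- stats::qf(1 - clusterAlpha, stat@df[1], stat@df[2])
  vals <- if (statScale == "F") stat@Fstat else stat@T2
  above <- !stat@singular & !is.na(stat@Fstat) & stat@Fstat > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(startIdx = integer(), endIdx = integer(),
                      startMs = numeric(), endMs = numeric(),
                      mass = numeric()))
  out <- data.frame(
    startIdx = starts[keep], endIdx = ends[keep],
    startMs = 1000 * stat@time[starts[keep]],
    endMs = 1000 * stat@time[ends[keep]],
    mass = vapply(keep, function(i)
      sum(vals[starts[i]:ends[i]]), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Sign-flip max-cluster permutation test
#'
#' Non-parametric correction for multiple time-point testing.  The
#' observed Hotelling time course is thresholded into clusters; the null
#' distribution of the maximum cluster mass is built by multiplying each
#' subject's entire slope time course (all dipoles and time points) by an
#' independent fair-coin sign on each of `nPerm` permutations and
#' recomputing the maximal cluster mass.  (Sign flips leave each subject's
#' slope cross-products unchanged, so only the flipped means are
#' recomputed per permutation.)  Each observed cluster receives the
#' pseudo-p `(1 + #(null >= mass)) / (nPerm + 1)`, which can never be
#' exactly zero.  Deterministic given `seed`; the identity flip is an
#' admissible draw.
#'
#' @param slopes a [SlopeTimecourse-class].
#' @param nPerm number of permutations (>= 1), default 1000.
#' @param clusterAlpha uncorrected cluster-forming level.
#' @param seed integer seed.
#' @param statScale `"F"` (default) or `"T2"`; scale on which cluster
#'   masses are summed.
#' @return list with `clusters` (data.frame: `startIdx`, `endIdx`,
#'   `startMs`, `endMs`, `mass`, `pseudoP`), `nullMax` (numeric vector of
#'   per-permutation maximum masses), `threshold` (F scale), `stat` (the
#'   observed [StatTimecourse-class]), `nPerm` and `seed`.
#' @export
signflipClusterTest <- function(slopes, nPerm = 1000, clusterAlpha = 0.01,
                                seed = 1, statScale = c("F", "T2")) {
  statScale <- match.arg(statScale)
  .stopIf(!is(slopes, "SlopeTimecourse"),
          "slopes must be a SlopeTimecourse")
  .stopIf(nPerm < 1, "nPerm must be at least 1")
  S <- slopes@slopes
  n <- dim(S)[1L]; p <- dim(S)[2L]; nt <- dim(S)[3L]
  .stopIf(n <= p, "need more subjects than dipole dimensions")
  threshold <- stats::qf(1 - clusterAlpha, p, n - p)
  G <- .momentsFromSlopes(S)
  # subjects x (p * nt) view for fast flipped means
  Sm <- matrix(S, nrow = n)
  obsStat <- hotellingTimecourse(slopes)
  obsClusters <- thresholdClusters(obsStat, threshold = threshold,
                                   statScale = statScale)
  f2mass <- function(T2, singular) {
    Fst <- T2 * (n - p) / (p * (n - 1))
    vals <- if (statScale == "F") Fst else T2
    above <- !singular & !is.na(Fst) & Fst > threshold
    if (!any(above)) return(0)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    max(vapply(keep, function(i) sum(vals[starts[i]:ends[i]]),
               numeric(1)))
  }
  nullMax <- numeric(nPerm)
  .withSeed(.subSeed(seed, "sign-flip"), {
    for (b in seq_len(nPerm)) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      M <- crossprod(Sm, flips) / n       # (p * nt) x 1
      dim(M) <- c(p, nt)
      h <- .hotellingFromMoments(G, M, n)
      nullMax[b] <- f2mass(h$T2, h$singular)
    }
  })
  if (nrow(obsClusters)) {
    obsClusters$pseudoP <- vapply(obsClusters$mass, function(m)
      (1 + sum(nullMax >= m)) / (nPerm + 1), numeric(1))
  } else obsClusters$pseudoP <- numeric(0)
  list(clusters = obsClusters, nullMax = nullMax, threshold = threshold,
       stat = obsStat, nPerm = nPerm, seed = seed)
}

#' Bonferroni correction over ROI x condition tests
#'
#' Flags a pseudo-p as significant iff `p <= alpha / m`, where `m` is the
#' number of ROI x condition analyses performed in the family.
#'
#' @param pseudoPs numeric vector of pseudo-p values in `[0, 1]`.
#' @param m family size (>= 1).
#' @param alpha family-wise level (default 0.05).
#' @return logical vector of significance flags.
#' @export
bonferroniCorrect <- function(pseudoPs, m, alpha = 0.05) {
  .stopIf(m < 1, "m must be at least 1")
  .stopIf(any(pseudoPs < 0 | pseudoPs > 1, na.rm = TRUE),
          "pseudo-p values must lie in [0, 1]")
  !is.na(pseudoPs) & pseudoPs <= alpha / m
}

#' Median-split grand-average source time courses
#'
#' Splits each subject's trials at the subject's median response (trials
#' at or below the median are "low", above it "high"), averages within
#' subject, then grand-averages the subject means, per dipole.  Subjects
#' with a constant response cannot be split and are excluded with a
#' report.
#'
#' @param sourceList list of [SourceEpochs-class], one per subject.
#' @param response name of the response column in the trial keys.
#' @return list with `low` and `high` (3 x time grand averages), `time`
#'   (movie-onset relative), `nSubjects` (number contributing) and
#'   `excluded` (character vector of skipped subjects).
#' @export
medianSplitGrandAverage <- function(sourceList, response = "response") {
  .stopIf(!length(sourceList), "sourceList is empty")
  ref <- sourceList[[1L]]
  nt <- dim(ref@data)[3L]
  lowSum <- highSum <- matrix(0, 3L, nt)
  used <- 0L
  excluded <- character(0)
  for (s in seq_along(sourceList)) {
    se <- sourceList[[s]]
    keys <- trialKeys(se)
    y <- keys[[response]]
    sid <- if ("subject" %in% names(keys))
      as.character(keys$subject[1L]) else paste0("S", s)
    if (length(unique(y)) < 2L) {
      excluded <- c(excluded, sid)
      next
    }
    med <- stats::median(y)
    lowIdx <- which(y <= med)
    highIdx <- which(y > med)
    if (!length(highIdx)) {              # median equals the maximum
      excluded <- c(excluded, sid)
      next
    }
    lowSum <- lowSum + apply(se@data[lowIdx, , , drop = FALSE],
                             c(2L, 3L), mean)
    highSum <- highSum + apply(se@data[highIdx, , , drop = FALSE],
                               c(2L, 3L), mean)
    used <- used + 1L
  }
  .stopIf(used == 0L, "no subject could be median-split")
  list(low = lowSum / used, high = highSum / used,
       time = epochTimes(ref), nSubjects = used, excluded = excluded)
}
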