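# Experiment-level orchestration: configuration, the EEG source-coupling
# pipeline, and the two behavioral stimulation pipelines.

#' Analysis configuration
#'
#' Bundles every tunable parameter of the experiment pipelines with the
#' field defaults: 60 Hz low-pass and 49.5-50.5 Hz band-stop zero-phase
#' filtering, baseline 400-200 ms before the fixation cross, 150 uV
#' peak-to-peak trial rejection, evoked-response covariance with 5%
#' regularization, cluster-forming alpha 0.01, 1000 sign-flip
#' permutations, and Bonferroni family size 8 (four ROIs -- two left plus
#' two mirrored right -- times two conditions).
#'
#' @param lowpassHz low-pass cutoff (Hz); NULL to skip.
#' @param bandstop band-stop edges (Hz); NULL to skip.
#' @param filter logical, run the filtering stage.
#' @param baselineWindow baseline window relative to `baselineRef` (s);
#'   NULL skips baseline correction.
#' @param baselineRef event name anchoring the baseline window.
#' @param rejectThreshold peak-to-peak rejection threshold (uV).
#' @param covarianceMode `"erp"` or `"trials"`, see [erpCovariance()].
#' @param lambdaReg beamformer regularization fraction.
#' @param analysisWindow optional length-2 window (s, movie-onset
#'   relative) to which source epochs are cropped before slope fitting.
#' @param clusterAlpha uncorrected cluster-forming level.
#' @param nPerm number of sign-flip permutations.
#' @param bonferroniM Bonferroni family size for cluster pseudo-p values.
#' @param alpha family-wise significance level.
#' @param statScale `"F"` or `"T2"` cluster-mass scale.
#' @param seed master seed; every random stage derives its own sub-stream
#'   from it.
#' @return list of class `"analysisConfig"`.
#' @export
analysisConfig <- function(lowpassHz = 60, bandstop = c(49.5, 50.5),
                           filter = TRUE,
                           baselineWindow = c(-0.400, -0.200),
                           baselineRef = "fixation",
                           rejectThreshold = 150,
                           covarianceMode = "erp", lambdaReg = 0.05,
                           analysisWindow = NULL,
                           clusterAlpha = 0.01, nPerm = 1000,
                           bonferroniM = 8, alpha = 0.05,
                           statScale = "F", seed = 1) {
  cfg <- list(lowpassHz = lowpassHz, bandstop = bandstop, filter = filter,
              baselineWindow = baselineWindow, baselineRef = baselineRef,
              rejectThreshold = rejectThreshold,
              covarianceMode = covarianceMode, lambdaReg = lambdaReg,
              analysisWindow = analysisWindow,
              clusterAlpha = clusterAlpha, nPerm = nPerm,
              bonferroniM = bonferroniM, alpha = alpha,
              statScale = statScale, seed = seed)
  class(cfg) <- "analysisConfig"
  cfg
}

#' @export
print.analysisConfig <- function(x, ...) {
  cat("analysisConfig:\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm,
                paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

# Crop a SourceEpochs object to a movie-onset-relative time window.
.cropSource <- function(se, window) {
  tt <- epochTimes(se)
  idx <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  .stopIf(!length(idx), "analysis window lies outside the epoch")
  initialize(se, data = se@data[, , idx, drop = FALSE],
             t0 = tt[idx[1L]])
}

.getEpochs <- function(provider, subject) {
  ep <- if (is.function(provider)) provider(subject) else provider[[subject]]
  .stopIf(!is(ep, "EpochSet"),
          "epochs provider did not return an EpochSet for subject ",
          subject)
  ep
}

.provenance <- function(config, experiment) {
  list(experiment = experiment, configHash = .fnv1a(unclass(config)),
       seed = config$seed,
       version = as.character(utils::packageVersion("coupleEEG")))
}

#' Run the EEG brain-behavior coupling pipeline
#'
#' Executes the full analysis chain for every ROI and condition:
#' preprocessing (filter, common-average reference, baseline, trial
#' rejection), Z-transform of the response within subject and condition,
#' per-condition evoked covariance and LCMV filters (filters are built
#' separately per condition), single-trial source reconstruction, robust
#' slope time courses, sign-flip max-cluster permutation testing,
#' Bonferroni control across the ROI x condition family, and median-split
#' grand averages.
#'
#' @param epochsProvider a function mapping a subject identifier to an
#'   [EpochSet-class], or a named list of EpochSets.
#' @param table behavioral trial table covering all subjects.
#' @param leadfield a [LeadField-class].
#' @param config an [analysisConfig()].
#' @return a report list (class `"couplingReport"`) with elements
#'   `clusters` (data.frame over all ROI x condition cells with pseudo-p
#'   and Bonferroni-significant flag), `tests` (per-cell permutation
#'   results), `grandAverages`, `rejection` (per-subject retention),
#'   `config` and `provenance`.
#' @export
runEEGPipeline <- function(epochsProvider, table, leadfield,
                           config = analysisConfig()) {
  .stopIf(!is(leadfield, "LeadField"), "leadfield must be a LeadField")
  .stopIf(!all(c("subject", "condition", "response") %in% names(table)),
          "table needs subject, condition and response columns")
  subjects <- unique(table$subject)
  conditions <- unique(table$condition)
  rois <- leadfield@roiLabels
  # the data are re-referenced to the common average below, so the same
  # reference transform must be applied to the forward model: without it
  # the unit-gain constraint would hold in a different reference frame
  # than the data
  leadfield@matrix <- sweep(leadfield@matrix, 2L,
                            colMeans(leadfield@matrix))
  validObject(leadfield)
  table$zResponse <- zscoreWithin(table$response,
                                  interaction(table$subject,
                                              table$condition,
                                              drop = TRUE))
  if (!"session" %in% names(table)) table$session <- "none"

  sources <- list()
  rejection <- list()
  for (subj in subjects) {
    ep <- .getEpochs(epochsProvider, subj)
    if (isTRUE(config$filter))
      ep <- filterSignal(ep, config$lowpassHz, config$bandstop)
    ep <- rereferenceCommonAverage(ep)
    if (!is.null(config$baselineWindow))
      ep <- baselineCorrect(ep, config$baselineWindow, config$baselineRef)
    rj <- rejectTrials(ep, config$rejectThreshold)
    ep <- rj$epochs
    rejection[[as.character(subj)]] <-
      data.frame(subject = subj, nTrials = length(rj$keepMask),
                 kept = sum(rj$keepMask))
    keys <- trialKeys(ep)
    .stopIf(!all(c("condition", "trial") %in% names(keys)),
            "epoch trial keys must carry condition and trial")
    if (!"session" %in% names(keys)) keys$session <- "none"
    idx <- match(paste(subj, keys$condition, keys$session, keys$trial),
                 paste(table$subject, table$condition, table$session,
                       table$trial))
    .stopIf(anyNA(idx), "stage 'align': epoch trials of subject ", subj,
            " not found in the behavioral table")
    keys$response <- table$response[idx]
    keys$zResponse <- table$zResponse[idx]
    ep@trialKeys <- keys
    for (cond in conditions) {
      sel <- keys$condition == cond
      if (!any(sel)) next
      sub <- ep[sel]
      cv <- erpCovariance(sub, mode = config$covarianceMode)
      for (roi in rois) {
        W <- lcmvWeights(roiBlock(leadfield, roi), cv, config$lambdaReg)
        src <- reconstructSources(W, sub, roi)
        if (!is.null(config$analysisWindow))
          src <- .cropSource(src, config$analysisWindow)
        sources[[roi]][[cond]][[as.character(subj)]] <- src
      }
    }
  }

  tests <- list()
  clusterRows <- list()
  grand <- list()
  for (roi in rois) for (cond in conditions) {
    srcList <- sources[[roi]][[cond]]
    if (is.null(srcList) || length(srcList) < 2L) next
    cell <- paste(roi, cond, sep = "/")
    sl <- slopeTimecourses(srcList)
    res <- signflipClusterTest(sl, nPerm = config$nPerm,
                               clusterAlpha = config$clusterAlpha,
                               seed = .subSeed(config$seed,
                                               paste0("perm-", cell)),
                               statScale = config$statScale)
    tests[[cell]] <- res
    if (nrow(res$clusters))
      clusterRows[[cell]] <- data.frame(roi = roi, condition = cond,
                                        res$clusters,
                                        stringsAsFactors = FALSE)
    grand[[cell]] <- medianSplitGrandAverage(srcList)
  }
  clusters <- if (length(clusterRows)) {
    cl <- do.call(rbind, clusterRows)
    cl$significant <- bonferroniCorrect(cl$pseudoP, config$bonferroniM,
                                        config$alpha)
    rownames(cl) <- NULL
    cl
  } else data.frame()

  out <- list(clusters = clusters, tests = tests, grandAverages = grand,
              rejection = do.call(rbind, rejection), config = config,
              provenance = .provenance(config, "eeg"))
  class(out) <- "couplingReport"
  out
}

#' @export
print.couplingReport <- function(x, ...) {
  cat(sprintf("couplingReport (%s), config %s, seed %s\n",
              x$provenance$experiment, x$provenance$configHash,
              format(x$provenance$seed)))
  if (!is.null(x$clusters) && NROW(x$clusters)) {
    cat("clusters:\n")
    print(x$clusters, digits = 4)
  } else if (!is.null(x$clusters)) cat("no supra-threshold clusters\n")
  invisible(x)
}

.requireLevels <- function(table, col, levels) {
  .stopIf(!all(levels %in% unique(table[[col]])),
          "table must contain ", col, " levels: ",
          paste(levels, collapse = ", "))
}

# subjects x levelsA x levelsB array from a per-cell summary.
.cellArray <- function(table, value, levelsA, colA, levelsB, colB) {
  subjects <- sort(unique(table$subject))
  Y <- array(NA_real_,
             dim = c(length(subjects), length(levelsA), length(levelsB)),
             dimnames = list(subjects, levelsA, levelsB))
  for (i in seq_along(subjects)) for (a in seq_along(levelsA))
    for (b in seq_along(levelsB)) {
      sel <- table$subject == subjects[i] & table[[colA]] == levelsA[a] &
        table[[colB]] == levelsB[b]
      if (any(sel)) Y[i, a, b] <- value(which(sel))
    }
  .stopIf(anyNA(Y), "incomplete design: empty subject x cell combinations")
  Y
}

#' Run the TMS slope-interference analysis
#'
#' Behavioral analysis of a 2 Condition (Hand, Face) x 2 Session (active,
#' sham) stimulation experiment on donations: per-cell donation SDs and
#' their ANOVA, Z-transform of donations within subject and condition
#' (sessions pooled to preserve stimulation effects), ANOVA on the mean
#' Z-donation, per-cell robust intensity-to-donation slopes, the 2 x 2
#' repeated-measures ANOVA on those slopes, a Newman-Keuls post-hoc test
#' on the four cell means (using the interaction error term), and a
#' one-sided JZS Bayes factor on the Face slope index (active minus sham;
#' alternative: the index is negative).
#'
#' @param table trial table with conditions Hand/Face and sessions
#'   active/sham.
#' @param config an [analysisConfig()] (only `alpha` and `seed` are used).
#' @return a report list (class `"couplingReport"`) with elements
#'   `sdAnova`, `meanAnova`, `slopes`, `slopeAnova`, `posthoc`,
#'   `faceIndexTest`, `faceBF01`, `config`, `provenance`.
#' @export
runTMSPipeline <- function(table, config = analysisConfig()) {
  .requireLevels(table, "condition", c("Hand", "Face"))
  .requireLevels(table, "session", c("active", "sham"))
  conds <- c("Hand", "Face")
  sess <- c("active", "sham")
  sdY <- .cellArray(table, function(i) stats::sd(table$response[i]),
                    conds, "condition", sess, "session")
  sdAnova <- rmAnovaFactorial(sdY, c("Condition", "TMS"))
  table$zResponse <- zscoreWithin(table$response,
                                  interaction(table$subject,
                                              table$condition,
                                              drop = TRUE))
  meanY <- .cellArray(table, function(i) mean(table$zResponse[i]),
                      conds, "condition", sess, "session")
  meanAnova <- rmAnovaFactorial(meanY, c("Condition", "TMS"))
  slopes <- slopesByCell(table, "zResponse")
  .stopIf(!all(slopes$estimable),
          "unestimable slope cells: ",
          paste(slopes$subject[!slopes$estimable], collapse = ", "))
  slopeY <- .cellArray(slopes, function(i) slopes$slope[i],
                       conds, "condition", sess, "session")
  slopeAnova <- rmAnovaFactorial(slopeY, c("Condition", "TMS"))
  cellMeans <- c(apply(slopeY, c(2L, 3L), mean))
  names(cellMeans) <- as.vector(outer(conds, sess, paste, sep = ":"))
  inter <- slopeAnova[slopeAnova$effect == "Condition:TMS", ]
  posthoc <- newmanKeuls(cellMeans, n = dim(slopeY)[1L],
                         msError = inter$msError, dfError = inter$dfDen,
                         alpha = config$alpha)
  faceIndex <- slopeY[, "Face", "active"] - slopeY[, "Face", "sham"]
  faceIndexTest <- oneSampleT(faceIndex)
  faceBF01 <- jzsBF01(faceIndexTest$t, faceIndexTest$n,
                      alternative = "less")
  out <- list(sdAnova = sdAnova, meanAnova = meanAnova, slopes = slopes,
              slopeAnova = slopeAnova, posthoc = posthoc,
              faceIndexTest = faceIndexTest, faceBF01 = faceBF01,
              config = config, provenance = .provenance(config, "tms"))
  class(out) <- "couplingReport"
  out
}

#' Run the HD-tDCS rating-accuracy analysis
#'
#' Behavioral analysis of a 2 Stimulation (real, sham) x 3 Condition
#' (Hand, Face, Color) rating experiment: ANOVAs on the per-cell rating
#' SD and mean, Z-transform of ratings within subject and condition
#' (stimulation sessions pooled), per-cell Pearson correlations between
#' validated intensity and Z-rating normalized by the Fisher
#' z-transformation, the 2 x 3 repeated-measures ANOVA on those
#' correlations, planned paired t-tests (sham vs real) per condition, and
#' a two-sided JZS Bayes factor on the Color accuracy index (real minus
#' sham).
#'
#' @param table trial table with conditions Hand/Face/Color and sessions
#'   real/sham.
#' @param config an [analysisConfig()].
#' @return a report list (class `"couplingReport"`) with elements
#'   `sdAnova`, `meanAnova`, `accuracy`, `accuracyAnova`, `plannedT`,
#'   `colorIndexTest`, `colorBF01`, `config`, `provenance`.
#' @export
runTDCSPipeline <- function(table, config = analysisConfig()) {
  .requireLevels(table, "condition", c("Hand", "Face", "Color"))
  .requireLevels(table, "session", c("real", "sham"))
  conds <- c("Hand", "Face", "Color")
  sess <- c("real", "sham")
  sdY <- .cellArray(table, function(i) stats::sd(table$response[i]),
                    sess, "session", conds, "condition")
  sdAnova <- rmAnovaFactorial(sdY, c("Stimulation", "Condition"))
  meanY <- .cellArray(table, function(i) mean(table$response[i]),
                      sess, "session", conds, "condition")
  meanAnova <- rmAnovaFactorial(meanY, c("Stimulation", "Condition"))
  table$zResponse <- zscoreWithin(table$response,
                                  interaction(table$subject,
                                              table$condition,
                                              drop = TRUE))
  accuracy <- ratingAccuracy(table, "zResponse")
  .stopIf(!all(accuracy$estimable),
          "unestimable accuracy cells present")
  accY <- .cellArray(accuracy, function(i) accuracy$z[i],
                     sess, "session", conds, "condition")
  accuracyAnova <- rmAnovaFactorial(accY, c("Stimulation", "Condition"))
  plannedT <- do.call(rbind, lapply(conds, function(cc) {
    tt <- pairedT(accY[, "sham", cc], accY[, "real", cc])
    data.frame(condition = cc, t = tt$t, df = tt$df, p = tt$p,
               meanSham = mean(accY[, "sham", cc]),
               meanReal = mean(accY[, "real", cc]),
               stringsAsFactors = FALSE)
  }))
  colorIndex <- accY[, "real", "Color"] - accY[, "sham", "Color"]
  colorIndexTest <- oneSampleT(colorIndex)
  colorBF01 <- jzsBF01(colorIndexTest$t, colorIndexTest$n,
                       alternative = "two.sided")
  out <- list(sdAnova = sdAnova, meanAnova = meanAnova,
              accuracy = accuracy, accuracyAnova = accuracyAnova,
              plannedT = plannedT, colorIndexTest = colorIndexTest,
              colorBF01 = colorBF01, config = config,
              provenance = .provenance(config, "tdcs"))
  class(out) <- "couplingReport"
  out
}
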