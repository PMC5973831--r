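# End-to-end simulation studies on synthetic data with known ground
# truth: study builders, the null family-wise error rate experiment, and
# the coupling-window recovery experiment.

#' Assemble a synthetic EEG study
#'
#' Builds the three ingredients of a full EEG coupling analysis -- a
#' donation trial table, a parametric lead field, and a lazy per-subject
#' epochs provider -- from one master seed.  Epochs are generated on
#' demand per subject so that a study never needs to hold all subjects'
#' sensor data in memory at once.
#'
#' @param nSubjects number of subjects.
#' @param intensityCounts per-condition stimulus counts (default the EEG
#'   stimulus set).
#' @param nChannels,nRois,spread lead-field geometry, see
#'   [generateLeadField()].
#' @param truth a [GroundTruth-class] describing the coupling.
#' @param fs,tPre,tPost,events epoch layout, see
#'   [generateCoupledEpochs()].
#' @param backgroundNoiseSd,sensorNoiseSd,ampNoiseSd noise levels.
#' @param seed master seed.
#' @param ... passed to [generateDonationTable()].
#' @return list with `table`, `leadfield`, `provider` (function:
#'   subject id -> [EpochSet-class]) and `truth`.
#' @export
simulateEEGStudy <- function(nSubjects = 24,
                             intensityCounts =
                               intensityCountsPreset("table2_eeg"),
                             nChannels = 64, nRois = 2, spread = 0.35,
                             truth = groundTruth(),
                             fs = 500, tPre = 5, tPost = 2,
                             events = c(fixation = -1, movie_onset = 0,
                                        noxious_event = 1),
                             backgroundNoiseSd = 1, sensorNoiseSd = 1,
                             ampNoiseSd = 0.5, seed = 1, ...) {
  table <- generateDonationTable(nSubjects = nSubjects,
                                 intensityCounts = intensityCounts,
                                 seed = .subSeed(seed, "study-table"), ...)
  leadfield <- generateLeadField(nChannels = nChannels, nRois = nRois,
                                 spread = spread,
                                 seed = .subSeed(seed, "study-leadfield"))
  provider <- function(subject) {
    generateCoupledEpochs(leadfield, table[table$subject == subject, ,
                                           drop = FALSE],
                          truth = truth,
                          backgroundNoiseSd = backgroundNoiseSd,
                          sensorNoiseSd = sensorNoiseSd,
                          ampNoiseSd = ampNoiseSd, fs = fs,
                          tPre = tPre, tPost = tPost, events = events,
                          seed = .subSeed(seed, paste0("epochs-", subject))
                          )$epochs
  }
  list(table = table, leadfield = leadfield, provider = provider,
       truth = truth)
}

#' Family-wise error rate of the cluster test under the null
#'
#' Repeatedly simulates complete null studies (the ground-truth coupling
#' slope is zero, so source activity carries no information about the
#' donation), runs the full pipeline -- reconstruction, robust slope time
#' courses, Hotelling time course, sign-flip max-cluster permutation --
#' and counts the fraction of studies in which any cluster reaches a
#' pseudo-p at or below `alpha`.  Under a valid procedure this fraction
#' estimates the family-wise error rate and should sit near `alpha`.
#'
#' The default study size is deliberately compact (12 subjects, 12
#' channels, one ROI, 40 trials, 1.5 s of data at 100 Hz) so that
#' hundreds of replicate studies are affordable; the procedure under test
#' is identical to the full-size one.
#'
#' @param nDatasets number of replicate null studies.
#' @param nPerm permutations per study.
#' @param nSubjects,nChannels,fs study size parameters.
#' @param alpha cluster-level significance threshold tested.
#' @param seed master seed.
#' @return list with `fwer` (fraction of studies with a false-positive
#'   cluster), `hits` (logical per study), `nDatasets`, `nPerm`.
#' @export
fwerSimulation <- function(nDatasets = 200, nPerm = 200, nSubjects = 12,
                           nChannels = 12, fs = 100, alpha = 0.05,
                           seed = 1) {
  counts <- list(Hand = c(`2` = 8L, `3` = 8L, `4` = 8L, `5` = 8L,
                          `6` = 8L))
  events <- c(movie_onset = 0, noxious_event = 0.5)
  truth <- groundTruth(couplingIntercept = 5, couplingSlope = 0,
                       window = c(0.65, 0.75), targetRoi = "ROI1")
  cfg <- analysisConfig(filter = FALSE, baselineWindow = NULL,
                        rejectThreshold = Inf, nPerm = nPerm,
                        bonferroniM = 1)
  hits <- logical(nDatasets)
  for (d in seq_len(nDatasets)) {
    dseed <- .subSeed(seed, paste0("fwer-", d))
    study <- simulateEEGStudy(nSubjects = nSubjects,
                              intensityCounts = counts,
                              nChannels = nChannels, nRois = 1,
                              truth = truth, fs = fs,
                              tPre = 0.5, tPost = 1.0, events = events,
                              seed = dseed)
    cfg$seed <- dseed
    res <- runEEGPipeline(study$provider, study$table, study$leadfield,
                          cfg)
    hits[d] <- NROW(res$clusters) > 0 &&
      any(res$clusters$pseudoP <= alpha)
  }
  list(fwer = mean(hits), hits = hits, nDatasets = nDatasets,
       nPerm = nPerm)
}

#' Recovery of a known coupling window by the full pipeline
#'
#' Simulates studies in which the ground-truth coupling is confined to a
#' short window after the noxious event (by default 420-480 ms, i.e.
#' 1.42-1.48 s after movie onset with the event at +1 s), runs the full
#' EEG pipeline, and checks per study whether a Bonferroni-significant
#' cluster in the target ROI overlaps the true window.
#'
#' The study size is compact (16 channels, 125 Hz, 4 s epochs, slopes fit
#' over the post-event second) while keeping the full stimulus set and
#' the default number of subjects and noise levels.
#'
#' @param nDatasets number of replicate studies.
#' @param nSubjects subjects per study.
#' @param nPerm permutations per ROI x condition cell.
#' @param windowMs true coupling window in ms relative to the noxious
#'   event.
#' @param seed master seed.
#' @return list with `overlapRate` (fraction of studies in which a
#'   significant cluster overlaps the true window), `hits`, `clusters`
#'   (list of per-study cluster tables).
#' @export
clusterRecoverySimulation <- function(nDatasets = 20, nSubjects = 24,
                                      nPerm = 399,
                                      windowMs = c(420, 480), seed = 1) {
  truth <- groundTruth(window = 1 + windowMs / 1000, targetRoi = "ROI1")
  cfg <- analysisConfig(filter = FALSE, rejectThreshold = Inf,
                        analysisWindow = c(1.0, 2.0), nPerm = nPerm)
  hits <- logical(nDatasets)
  allClusters <- vector("list", nDatasets)
  for (d in seq_len(nDatasets)) {
    dseed <- .subSeed(seed, paste0("recovery-", d))
    study <- simulateEEGStudy(nSubjects = nSubjects, nChannels = 16,
                              nRois = 2, truth = truth, fs = 125,
                              tPre = 2, tPost = 2, seed = dseed)
    cfg$seed <- dseed
    res <- runEEGPipeline(study$provider, study$table, study$leadfield,
                          cfg)
    cl <- res$clusters
    allClusters[[d]] <- cl
    hits[d] <- NROW(cl) > 0 && any(
      cl$significant & cl$roi == truth@targetRoi &
        cl$startMs <= windowMs[2] & cl$endMs >= windowMs[1])
  }
  list(overlapRate = mean(hits), hits = hits, clusters = allClusters,
       nDatasets = nDatasets, nPerm = nPerm)
}
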