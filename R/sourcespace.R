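# LCMV beamforming: ERP covariance, unit-gain spatial filters, and
# single-trial source reconstruction along three dipole axes per ROI.

#' Evoked-response channel covariance
#'
#' Averages the epochs of one condition over trials (the ERP) and computes
#' the channel covariance across the entire epoch time axis.  Covariance
#' centring removes per-channel time-constant offsets, and the output is
#' symmetric positive semi-definite by construction.  This evoked
#' covariance is the default input to [lcmvWeights()]; set
#' `mode = "trials"` to pool single-trial covariances instead (a
#' sensitivity-analysis option).
#'
#' @param epochs an [EpochSet-class].
#' @param condition optional condition label; trials are subset via
#'   `trialKeys(epochs)$condition`.  NULL uses all trials.
#' @param mode `"erp"` (covariance of the trial-averaged signal, default)
#'   or `"trials"` (average of single-trial covariances).
#' @return a [Covariance-class].
#' @export
erpCovariance <- function(epochs, condition = NULL,
                          mode = c("erp", "trials")) {
  mode <- match.arg(mode)
  .stopIf(!is(epochs, "EpochSet"), "epochs must be an EpochSet")
  if (!is.null(condition)) {
    keep <- trialKeys(epochs)$condition == condition
    .stopIf(!any(keep), "no trials in condition '", condition, "'")
    epochs <- epochs[keep]
  }
  d <- dim(epochs@data)
  .stopIf(d[2L] < 2L, "need at least 2 time samples")
  .stopIf(d[3L] < 1L, "need at least 1 trial")
  if (mode == "erp") {
    erp <- apply(epochs@data, c(1L, 2L), mean)     # channels x time
    cv <- stats::cov(t(erp))
  } else {
    cv <- 0
    for (k in seq_len(d[3L])) {
      m <- epochs@data[, , k, drop = FALSE]
      dim(m) <- d[1:2]
      cv <- cv + stats::cov(t(m))
    }
    cv <- cv / d[3L]
  }
  cv <- (cv + t(cv)) / 2
  new("Covariance", matrix = cv, nSamples = as.integer(d[2L]),
      condition = if (is.null(condition)) "all" else condition)
}

#' LCMV beamformer weights for one ROI
#'
#' Computes the linearly constrained minimum variance spatial filter
#' `W = (L' C^-1 L)^-1 L' C^-1` for a channels x 3 lead-field block `L`,
#' where `C` is the (regularized) sensor covariance
#' `C = Sigma + lambdaReg * (trace(Sigma)/channels) * I`.  The filter has
#' unit gain at the target (`W %*% L = I3`) and minimizes output variance,
#' thereby suppressing contributions from other sources.  Regularization
#' defaults to 5% of the mean sensor power because common-average-
#' referenced data are rank deficient.
#'
#' @param L channels x 3 lead-field block (see [roiBlock()]), full rank.
#' @param cov a [Covariance-class] (or plain symmetric matrix).
#' @param lambdaReg regularization fraction (>= 0), default 0.05.
#' @return 3 x channels weight matrix.
#' @export
lcmvWeights <- function(L, cov, lambdaReg = 0.05) {
  if (is(cov, "Covariance")) cov <- cov@matrix
  .stopIf(!is.matrix(L) || ncol(L) != 3L,
          "L must be a channels x 3 matrix")
  .stopIf(nrow(cov) != nrow(L),
          "covariance and lead field disagree on channel count")
  .stopIf(lambdaReg < 0, "lambdaReg must be non-negative")
  .stopIf(qr(L)$rank < 3L, "lead-field block is rank deficient")
  C <- cov + lambdaReg * (sum(diag(cov)) / nrow(cov)) *
    diag(nrow(cov))
  Ci <- tryCatch(solve(C), error = function(e)
    stop("regularized covariance is singular; increase lambdaReg",
         call. = FALSE))
  A <- crossprod(L, Ci)                       # 3 x channels
  W <- solve(A %*% L, A)
  dimnames(W) <- list(c("x", "y", "z"), rownames(L))
  W
}

#' Reconstruct single-trial source time courses
#'
#' Applies a 3 x channels beamformer weight matrix to every trial:
#' `source[k, , ] = W %*% data[, , k]`.  The operation is linear in the
#' sensor data.
#'
#' @param W 3 x channels weight matrix from [lcmvWeights()].
#' @param epochs an [EpochSet-class].
#' @param roiLabel label stored in the result.
#' @return a [SourceEpochs-class] (trials x 3 x time).
#' @export
reconstructSources <- function(W, epochs, roiLabel = "ROI") {
  .stopIf(!is(epochs, "EpochSet"), "epochs must be an EpochSet")
  d <- dim(epochs@data)
  .stopIf(ncol(W) != d[1L],
          "weight matrix and epochs disagree on channel count")
  out <- array(0, dim = c(d[3L], 3L, d[2L]))
  for (k in seq_len(d[3L])) {
    m <- epochs@data[, , k, drop = FALSE]
    dim(m) <- d[1:2]
    out[k, , ] <- W %*% m
  }
  new("SourceEpochs", data = out, roiLabel = roiLabel, fs = epochs@fs,
      t0 = epochs@t0, events = epochs@events,
      trialKeys = epochs@trialKeys)
}
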