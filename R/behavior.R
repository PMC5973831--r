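# Behavioral statistics: within-group Z-transforms, robust slopes,
# t-tests, repeated-measures ANOVA, Newman-Keuls, JZS Bayes factors,
# Fisher-z accuracy correlations and stimulus-set arithmetic.

#' Z-score values within groups
#'
#' Standardizes `values` to mean 0 and sample SD 1 (n - 1 denominator)
#' separately within each group, preserving the input order.  Groups with
#' fewer than 2 values or zero variance raise an error naming the group.
#'
#' @param values numeric vector.
#' @param groups grouping factor (or a data.frame/list of key columns,
#'   combined via [interaction()]).
#' @return numeric vector of Z-scores, same length and order as `values`.
#' @examples
#' zscoreWithin(c(1, 2, 3), rep("a", 3))  # -1 0 1
#' @export
zscoreWithin <- function(values, groups) {
  if (is.list(groups) || is.data.frame(groups))
    groups <- interaction(groups, drop = TRUE)
  groups <- as.factor(groups)
  .stopIf(length(values) != length(groups),
          "values and groups must have equal length")
  z <- numeric(length(values))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    .stopIf(length(idx) < 2L,
            "group '", g, "' has fewer than 2 values")
    s <- stats::sd(values[idx])
    .stopIf(!is.finite(s) || s == 0,
            "group '", g, "' has zero variance; cannot Z-score")
    z[idx] <- (values[idx] - mean(values[idx])) / s
  }
  z
}

# Tukey bisquare weights for standardized residuals u = r / (tuning * s).
.bisquareW <- function(u) ifelse(abs(u) < 1, (1 - u^2)^2, 0)
.huberW <- function(u) ifelse(abs(u) < 1, 1, 1 / abs(u))

# Column-wise medians via a single radix order over all columns; the
# mass-univariate IRLS calls this thousands of times per subject.
.colMedians <- function(M) {
  n <- nrow(M); K <- ncol(M)
  S <- matrix(M[order(col(M), M)], n, K)
  if (n %% 2L) S[(n + 1L) / 2L, ] else (S[n / 2L, ] + S[n / 2L + 1L, ]) / 2
}

# Vectorized IRLS for many simple regressions sharing the response:
# each column of X is a separate predictor, y is common.  Returns slopes,
# intercepts, robust t for the slope, scale, iterations, convergence.
# This is the engine behind both robustFit() (one column) and the
# mass-univariate slope time courses (thousands of columns per subject).
.irlsMany <- function(X, y, tuning = 4.685, psi = c("bisquare", "huber"),
                      maxIter = 50L, tol = 1e-8) {
  psi <- match.arg(psi)
  wfun <- if (psi == "bisquare") .bisquareW else .huberW
  n <- length(y)
  K <- ncol(X)
  # OLS start
  sx <- colMeans(X)
  sy <- mean(y)
  vxy <- colMeans(X * y) - sx * sy
  vxx <- colMeans(X^2) - sx^2
  # constant predictor columns (e.g. identically-zero source samples) get
  # a zero slope; scalar callers reject constant x before reaching here
  const <- vxx <= 0
  slope <- ifelse(const, 0, vxy / vxx)
  inter <- sy - slope * sx
  iter <- 0L
  converged <- rep(FALSE, K)
  scale <- rep(NA_real_, K)
  yM <- matrix(y, n, K)
  W <- matrix(1, n, K)
  yScale <- max(abs(y), 1)
  repeat {
    iter <- iter + 1L
    R <- yM - sweep(X, 2L, slope, "*") - matrix(inter, n, K, byrow = TRUE)
    med <- .colMedians(R)
    madR <- .colMedians(abs(R - matrix(med, n, K, byrow = TRUE)))
    s <- madR / 0.6745
    # a zero MAD means the majority of points are fit exactly; freeze the
    # coefficients there instead of rescaling (MAD breakdown guard)
    exact <- s < 1e-10 * yScale
    s[exact] <- 1
    scale <- ifelse(exact, 0, s)
    U <- R / matrix(tuning * s, n, K, byrow = TRUE)
    W <- wfun(U)
    if (any(exact))
      W[, exact] <- (abs(R[, exact, drop = FALSE]) <= 1e-8 * yScale) * 1
    Sw <- colSums(W)
    Swx <- colSums(W * X)
    Swy <- colSums(W * yM)
    Swxx <- colSums(W * X^2)
    Swxy <- colSums(W * X * yM)
    den <- Sw * Swxx - Swx^2
    bad <- den <= 0 | Sw <= 0 | exact
    newSlope <- ifelse(bad, slope, (Sw * Swxy - Swx * Swy) / den)
    newInter <- ifelse(bad, inter, (Swy - newSlope * Swx) / Sw)
    delta <- pmax(abs(newSlope - slope), abs(newInter - inter))
    slope <- newSlope
    inter <- newInter
    converged <- converged | delta < tol | exact
    if (all(converged) || iter >= maxIter) break
  }
  # robust slope covariance from the final weighted least squares
  R <- yM - sweep(X, 2L, slope, "*") - matrix(inter, n, K, byrow = TRUE)
  Sw <- colSums(W)
  Swx <- colSums(W * X)
  Swxx <- colSums(W * X^2)
  s2 <- colSums(W * R^2) / pmax(Sw - 2, 1)
  seSlope <- sqrt(pmax(s2 * Sw / pmax(Sw * Swxx - Swx^2, .Machine$double.eps),
                       0))
  tSlope <- ifelse(seSlope > 0, slope / seSlope, Inf * sign(slope))
  list(slope = slope, intercept = inter, tSlope = tSlope,
       seSlope = seSlope, scale = scale, iterations = iter,
       converged = converged, df = n - 2L)
}

#' Robust simple linear regression (IRLS, Tukey bisquare)
#'
#' Fits `y ~ x` by iteratively reweighted least squares with Tukey
#' bisquare weights (tuning constant 4.685, the 95%-efficiency default),
#' re-estimating scale each iteration as `MAD(residuals) / 0.6745`.
#' Starts from the ordinary least squares fit, iterates to a coefficient
#' change below `tol` (at most `maxIter` iterations; non-convergence is
#' flagged, not an error).  On outlier-free data all weights are ~1 and the
#' fit coincides with OLS.  The slope t statistic uses the final weighted
#' least-squares covariance with `n - 2` degrees of freedom.
#'
#' @param x predictor (not constant), length >= 3.
#' @param y response, same length.
#' @param psi weight function, `"bisquare"` (default) or `"huber"`.
#' @param tuning tuning constant (4.685 for bisquare).
#' @param maxIter,tol iteration cap and coefficient tolerance.
#' @return list of class `"robustFit"` with elements `slope`, `intercept`,
#'   `tSlope`, `pSlope`, `scale`, `iterations`, `converged`, `df`, `n`.
#' @examples
#' f <- robustFit(1:10, 2 * (1:10) + 1)
#' c(f$slope, f$intercept)  # 2 and 1
#' @export
robustFit <- function(x, y, psi = c("bisquare", "huber"), tuning = 4.685,
                      maxIter = 50L, tol = 1e-8) {
  psi <- match.arg(psi)
  .stopIf(length(x) != length(y), "x and y must have equal length")
  .stopIf(length(x) < 3L, "need at least 3 observations")
  .stopIf(stats::sd(x) == 0, "x is constant")
  fit <- .irlsMany(matrix(x, ncol = 1L), y, tuning = tuning, psi = psi,
                   maxIter = maxIter, tol = tol)
  p <- 2 * stats::pt(-abs(fit$tSlope), df = fit$df)
  out <- list(slope = fit$slope[1L], intercept = fit$intercept[1L],
              tSlope = fit$tSlope[1L], pSlope = p[1L],
              seSlope = fit$seSlope[1L], scale = fit$scale[1L],
              iterations = fit$iterations, converged = fit$converged[1L],
              df = fit$df, n = length(y))
  class(out) <- "robustFit"
  out
}

#' @export
print.robustFit <- function(x, ...) {
  cat(sprintf(
    "robustFit: slope %.4g (t = %.3g, p = %.3g), intercept %.4g\n",
    x$slope, x$tSlope, x$pSlope, x$intercept))
  cat(sprintf("  scale %.4g, %d iteration(s), converged: %s\n",
              x$scale, x$iterations, x$converged))
  invisible(x)
}

#' Per-cell robust intensity-to-response slopes
#'
#' Fits [robustFit()] of the (Z-scored) response on stimulus intensity
#' separately for every (subject, condition, session) cell of a trial
#' table.  Cells with fewer than 3 trials or fewer than 2 distinct
#' intensity levels are reported as unestimable rather than silently
#' dropped.
#'
#' @param table trial table with columns `subject`, `condition`,
#'   `session`, `intensity` and the response column.
#' @param response name of the response column (default `"zResponse"`).
#' @param ... passed on to [robustFit()].
#' @return data.frame with one row per cell: keys, `n`, `slope`,
#'   `intercept`, `tSlope`, `pSlope`, `converged`, `estimable`, `reason`.
#' @export
slopesByCell <- function(table, response = "zResponse", ...) {
  .stopIf(nrow(table) == 0, "empty trial table")
  .stopIf(!response %in% names(table),
          "response column '", response, "' not found")
  if (!"session" %in% names(table)) table$session <- "none"
  cells <- unique(table[c("subject", "condition", "session")])
  cells <- cells[order(cells$subject, cells$condition, cells$session), ,
                 drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$subject == cells$subject[i] &
      table$condition == cells$condition[i] &
      table$session == cells$session[i]
    x <- table$intensity[sel]
    y <- table[[response]][sel]
    base <- data.frame(cells[i, , drop = FALSE], n = sum(sel),
                       slope = NA_real_, intercept = NA_real_,
                       tSlope = NA_real_, pSlope = NA_real_,
                       converged = NA, estimable = FALSE, reason = "",
                       stringsAsFactors = FALSE)
    if (sum(sel) < 3L) {
      base$reason <- "fewer than 3 trials"
    } else if (length(unique(x)) < 2L) {
      base$reason <- "single intensity level"
    } else {
      f <- robustFit(x, y, ...)
      base$slope <- f$slope; base$intercept <- f$intercept
      base$tSlope <- f$tSlope; base$pSlope <- f$pSlope
      base$converged <- f$converged; base$estimable <- TRUE
    }
    base
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' One-sample and paired Student t-tests
#'
#' Closed-form Student statistics: `oneSampleT()` tests the mean of
#' `values` against `mu0`; `pairedT()` is the one-sample test on the
#' element-wise differences `a - b`.
#'
#' @param values numeric vector (n >= 2, non-zero variance).
#' @param mu0 null mean.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `t`, `df`, `p`, `mean`, `sd`, `n`.
#' @examples
#' oneSampleT(c(1, 2, 3))$t  # 2 / (1 / sqrt(3)) = 3.4641
#' @export
oneSampleT <- function(values, mu0 = 0,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  .stopIf(n < 2L, "need at least 2 values")
  s <- stats::sd(values)
  .stopIf(s == 0, "values have zero variance")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  df <- n - 1L
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  list(t = t, df = df, p = p, mean = mean(values), sd = s, n = n)
}

#' @rdname oneSampleT
#' @param a,b paired numeric vectors of equal length.
#' @export
pairedT <- function(a, b, mu0 = 0,
                    alternative = c("two.sided", "greater", "less")) {
  .stopIf(length(a) != length(b), "a and b must have equal length")
  oneSampleT(a - b, mu0 = mu0, alternative = match.arg(alternative))
}

#' Two-factor repeated-measures ANOVA
#'
#' Fully within-subject two-way ANOVA on a complete balanced design with
#' one observation per subject and cell, fit via `stats::aov` with the
#' error stratification `Error(subject/(A*B))`.  Each effect is tested
#' against its own Subject x Effect error term.  Partial eta squared is
#' `F * dfNum / (F * dfNum + dfDen)`.  Effects whose sum of squares
#' vanishes (e.g. perfectly additive data for the interaction) are
#' reported as F = 0, p = 1.  In a 2 x 2 design each 1-df F equals the
#' squared paired t of the corresponding contrast.
#'
#' @param Y numeric array, subjects x levels(A) x levels(B).
#' @param factorNames length-2 character, names of the two factors.
#' @return data.frame with one row per effect (`A`, `B`, `A:B`): `F`,
#'   `dfNum`, `dfDen`, `p`, `petaSq`, `msError`.
#' @export
rmAnovaFactorial <- function(Y, factorNames = c("A", "B")) {
  d <- dim(Y)
  .stopIf(length(d) != 3L, "Y must be subjects x levelsA x levelsB")
  .stopIf(d[1L] < 2L, "need at least 2 subjects")
  .stopIf(anyNA(Y), "missing cells are not supported")
  la <- dimnames(Y)[[2]]; if (is.null(la)) la <- paste0("a", seq_len(d[2]))
  lb <- dimnames(Y)[[3]]; if (is.null(lb)) lb <- paste0("b", seq_len(d[3]))
  df <- expand.grid(subject = factor(seq_len(d[1])),
                    A = factor(la, levels = la),
                    B = factor(lb, levels = lb))
  df$y <- as.vector(Y)
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = df)
  sm <- summary(fit)
  pick <- function(stratum, effect) {
    tb <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tb))
    i <- match(effect, rn)
    j <- match("Residuals", rn)
    ssE <- tb[i, "Sum Sq"]; dfN <- tb[i, "Df"]
    ssR <- tb[j, "Sum Sq"]; dfD <- tb[j, "Df"]
    msE <- ssE / dfN; msR <- ssR / dfD
    scaleY <- max(1, sum(df$y^2))
    if (ssE <= 1e-12 * scaleY) {          # no effect variance: F = 0
      F <- 0; p <- 1
    } else if (ssR <= 1e-12 * scaleY) {   # exact effect, no error
      F <- Inf; p <- 0
    } else {
      F <- msE / msR
      p <- stats::pf(F, dfN, dfD, lower.tail = FALSE)
    }
    data.frame(effect = effect, F = F, dfNum = as.integer(dfN),
               dfDen = as.integer(dfD), p = p,
               petaSq = if (is.finite(F)) F * dfN / (F * dfN + dfD) else 1,
               msError = msR, stringsAsFactors = FALSE)
  }
  out <- rbind(pick("Error: subject:A", "A"),
               pick("Error: subject:B", "B"),
               pick("Error: subject:A:B", "A:B"))
  out$effect <- c(factorNames[1], factorNames[2],
                  paste(factorNames, collapse = ":"))
  rownames(out) <- NULL
  out
}

#' Newman-Keuls stepwise post-hoc test
#'
#' Stepwise studentized-range procedure on ordered cell means.  Pairs are
#' compared at critical values `q(alpha, r, dfError) * sqrt(msError / n)`
#' where `r` is the number of means spanned; a non-significant span blocks
#' all comparisons it encloses.  Reported p values are adjusted to be
#' monotone over nesting (an enclosed pair never has a smaller p than an
#' enclosing one), which reproduces the blocking rule as
#' `significant = p <= alpha`.  With exactly two means the test reduces to
#' the studentized-range test with r = 2, i.e. an alpha-level t-test on
#' the error term (`q = sqrt(2) * |t|`).
#'
#' @param means named numeric vector of cell means (>= 2).
#' @param n number of observations per cell mean.
#' @param msError error mean square from the ANOVA (> 0).
#' @param dfError error degrees of freedom (>= 1).
#' @param alpha significance level.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `span`, `q`, `p`, `significant`.
#' @export
newmanKeuls <- function(means, n, msError, dfError, alpha = 0.05) {
  .stopIf(length(means) < 2L, "need at least 2 means")
  .stopIf(msError <= 0, "msError must be positive")
  .stopIf(dfError < 1, "dfError must be at least 1")
  if (is.null(names(means))) names(means) <- paste0("g", seq_along(means))
  ord <- order(means)
  m <- means[ord]
  k <- length(m)
  se <- sqrt(msError / n)
  pairs <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    span <- j - i + 1L
    q <- (m[j] - m[i]) / se
    pRaw <- stats::ptukey(q, nmeans = span, df = dfError,
                          lower.tail = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(
      i = i, j = j, group1 = names(m)[i], group2 = names(m)[j],
      diff = unname(m[j] - m[i]), span = span, q = unname(q), p = pRaw,
      stringsAsFactors = FALSE)
  }
  tb <- do.call(rbind, pairs)
  # monotone adjustment: an enclosed pair inherits the largest p among the
  # pairs enclosing it (Newman-Keuls blocking)
  tb <- tb[order(-tb$span, tb$i), , drop = FALSE]
  for (r in seq_len(nrow(tb))) {
    encl <- tb$i <= tb$i[r] & tb$j >= tb$j[r]
    tb$p[r] <- max(tb$p[encl])
  }
  tb$significant <- tb$p <= alpha
  rownames(tb) <- NULL
  tb[, c("group1", "group2", "diff", "span", "q", "p", "significant")]
}

#' JZS default-prior Bayes factor for a one-sample t-test
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor `BF01` (evidence for
#' the point null over the alternative) from a one-sample t statistic.
#' Under the alternative the standardized effect size carries a Cauchy
#' prior with scale `rscale` (default `sqrt(2)/2 = 0.707`, the common
#' default); the marginal likelihood integrates the non-central t density
#' over that prior (numerical quadrature via [stats::integrate()]).
#' One-sided alternatives truncate the prior to the stated direction,
#' matching the informed-direction convention of standard Bayesian t-test
#' software.
#'
#' @param t observed t statistic.
#' @param n sample size (>= 2); degrees of freedom are `n - 1`.
#' @param rscale Cauchy prior scale (> 0).
#' @param alternative `"two.sided"` (default), `"greater"` (prior on
#'   delta > 0) or `"less"` (prior on delta < 0).
#' @return the Bayes factor BF01 (> 0); values above 1 favor the null.
#' @examples
#' jzsBF01(0, 20) > 1  # t = 0 favors the null
#' @export
jzsBF01 <- function(t, n, rscale = sqrt(2) / 2,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  .stopIf(!is.finite(t), "t must be finite")
  .stopIf(n < 2, "n must be at least 2")
  .stopIf(rscale <= 0, "rscale must be positive")
  df <- n - 1
  lik <- function(delta) stats::dt(t, df = df, ncp = delta * sqrt(n))
  dens <- function(delta) stats::dcauchy(delta, 0, rscale)
  m1 <- suppressWarnings(switch(alternative,
    two.sided = stats::integrate(function(d) lik(d) * dens(d),
                                 -Inf, Inf, rel.tol = 1e-9)$value,
    greater = 2 * stats::integrate(function(d) lik(d) * dens(d),
                                   0, Inf, rel.tol = 1e-9)$value,
    less = 2 * stats::integrate(function(d) lik(d) * dens(d),
                                -Inf, 0, rel.tol = 1e-9)$value))
  stats::dt(t, df = df) / m1
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`, an odd function defined for `|r| < 1`.
#'
#' @param r correlation coefficient(s), `|r| < 1`.
#' @return transformed value(s).
#' @export
fisherZ <- function(r) {
  .stopIf(any(abs(r) >= 1), "|r| must be strictly below 1")
  atanh(r)
}

#' Per-cell rating accuracy (Fisher-z correlations)
#'
#' For every (subject, condition, session) cell, correlates the validated
#' stimulus intensity with the Z-scored rating (Pearson) and Fisher
#' z-transforms the result.  Numerically perfect correlations are clipped
#' at `|r| = 1 - 1e-12` with a warning before the transform.  Degenerate
#' cells (fewer than 3 trials or a single intensity level) are reported
#' as unestimable.
#'
#' @param table trial table with `subject`, `condition`, `session`,
#'   `intensity` and the response column.
#' @param response name of the (Z-scored) rating column.
#' @return data.frame with keys, `n`, `r`, `z`, `estimable`, `reason`.
#' @export
ratingAccuracy <- function(table, response = "zResponse") {
  .stopIf(nrow(table) == 0, "empty trial table")
  if (!"session" %in% names(table)) table$session <- "none"
  cells <- unique(table[c("subject", "condition", "session")])
  cells <- cells[order(cells$subject, cells$condition, cells$session), ,
                 drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$subject == cells$subject[i] &
      table$condition == cells$condition[i] &
      table$session == cells$session[i]
    x <- table$intensity[sel]
    y <- table[[response]][sel]
    base <- data.frame(cells[i, , drop = FALSE], n = sum(sel),
                       r = NA_real_, z = NA_real_, estimable = FALSE,
                       reason = "", stringsAsFactors = FALSE)
    if (sum(sel) < 3L) base$reason <- "fewer than 3 trials"
    else if (length(unique(x)) < 2L) base$reason <- "single intensity level"
    else if (stats::sd(y) == 0) base$reason <- "constant response"
    else {
      r <- stats::cor(x, y)
      if (abs(r) >= 1 - 1e-12) {
        warning("perfect correlation clipped before Fisher z in cell ",
                cells$subject[i], "/", cells$condition[i], "/",
                cells$session[i])
        r <- sign(r) * (1 - 1e-12)
      }
      base$r <- r
      base$z <- fisherZ(r)
      base$estimable <- TRUE
    }
    base
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-subject response variability
#'
#' Sample standard deviations of the response per subject-condition cell
#' (optionally split by session), plus paired t-tests across subjects
#' between every pair
#' of conditions (cells averaged over sessions first when sessions are
#' present and not requested as a grouping key).
#'
#' @param table trial table.
#' @param bySession logical; keep sessions as separate cells.
#' @return list with `sds` (per-cell data.frame) and `tests` (pairwise
#'   condition comparisons: `condition1`, `condition2`, `t`, `df`, `p`).
#' @export
perSubjectSD <- function(table, bySession = FALSE) {
  .stopIf(nrow(table) == 0, "empty trial table")
  if (!"session" %in% names(table)) table$session <- "none"
  keys <- if (bySession) c("subject", "condition", "session")
          else c("subject", "condition")
  agg <- stats::aggregate(table["response"], table[keys],
                          function(v) {
                            if (length(v) < 2L) NA_real_ else stats::sd(v)
                          })
  names(agg)[names(agg) == "response"] <- "sd"
  .stopIf(anyNA(agg$sd), "singleton cells: SD undefined")
  conds <- sort(unique(agg$condition))
  tests <- NULL
  if (length(conds) >= 2L) {
    bySubj <- stats::aggregate(agg["sd"],
                               agg[c("subject", "condition")], mean)
    wide <- stats::reshape(bySubj, idvar = "subject",
                           timevar = "condition", direction = "wide")
    cmb <- utils::combn(conds, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- wide[[paste0("sd.", cmb[1, i])]]
      b <- wide[[paste0("sd.", cmb[2, i])]]
      d <- a - b
      if (stats::sd(d) == 0 && all(d == 0)) {
        # identical variability in both conditions: no effect by definition
        tt <- list(t = 0, df = length(d) - 1L, p = 1)
      } else tt <- pairedT(a, b)
      data.frame(condition1 = cmb[1, i], condition2 = cmb[2, i],
                 t = tt$t, df = tt$df, p = tt$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(sds = agg, tests = tests)
}

#' Stimulus-set statistics from intensity counts
#'
#' Count-weighted means and sample SDs of the perceived intensities of two
#' stimulus sets, the pooled-variance two-sample t-test between them
#' (`df = n1 + n2 - 2`) and the variance-ratio F (larger over smaller
#' sample variance, upper-tail p).  `replicateFactor` duplicates the
#' counts, for designs in which the per-session set is presented in every
#' session.
#'
#' @param countsA,countsB named numeric vectors (names are intensity
#'   levels, values are video counts).
#' @param labels length-2 character, names of the two sets.
#' @param replicateFactor integer multiplier on all counts.
#' @return list with per-set `mean`, `sd`, `n`; `t`, `dfT`, `pT` for the
#'   mean comparison (A minus B); `F`, `dfF`, `pF` for the variance ratio;
#'   and `display`, the same numbers rounded for reporting (means/SDs to 1
#'   decimal, t and F to 2).
#' @examples
#' cnt <- intensityCountsPreset("table2_eeg")
#' s <- stimulusSetStats(cnt$Hand, cnt$Face, labels = c("Hand", "Face"))
#' s$display  # mean 4 +/- 1.4 vs 3.7 +/- 1.7, t(93) = 0.88
#' @export
stimulusSetStats <- function(countsA, countsB, labels = c("A", "B"),
                             replicateFactor = 1L) {
  .stopIf(replicateFactor < 1 || replicateFactor != round(replicateFactor),
          "replicateFactor must be a positive integer")
  expand <- function(cnt) {
    .stopIf(any(cnt < 0), "counts must be non-negative")
    v <- rep(as.numeric(names(cnt)), cnt * replicateFactor)
    .stopIf(length(v) < 2L, "need at least 2 stimuli per set")
    v
  }
  a <- expand(countsA)
  b <- expand(countsB)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  dfT <- na + nb - 2L
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / dfT)
  t <- (mean(a) - mean(b)) / (sp * sqrt(1 / na + 1 / nb))
  pT <- 2 * stats::pt(-abs(t), dfT)
  if (va >= vb) {
    F <- va / vb; dfF <- c(na - 1L, nb - 1L)
  } else {
    F <- vb / va; dfF <- c(nb - 1L, na - 1L)
  }
  pF <- stats::pf(F, dfF[1], dfF[2], lower.tail = FALSE)
  out <- list(labels = labels,
              mean = c(mean(a), mean(b)), sd = c(sqrt(va), sqrt(vb)),
              n = c(na, nb), t = t, dfT = dfT, pT = pT,
              F = F, dfF = dfF, pF = pF)
  out$display <- sprintf(
    "%s: %.1f +/- %.1f (n=%d); %s: %.1f +/- %.1f (n=%d); t(%d) = %.2f, F(%d,%d) = %.2f",
    labels[1], out$mean[1], out$sd[1], na,
    labels[2], out$mean[2], out$sd[2], nb,
    dfT, t, dfF[1], dfF[2], F)
  out
}
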