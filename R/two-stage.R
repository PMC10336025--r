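# Two-stage (inference-for-margins) maximum likelihood for a taxon pair:
# stage 1 fits the two ZIB margins separately; stage 2 maximizes the profile
# log-likelihood in the Frank dependence parameter theta by bounded
# one-dimensional search on [-THETA_MAX, THETA_MAX].

.checkPairPreconditions <- function(xi, xj) {
  if (length(xi) != length(xj)) stop("xi and xj must be paired")
  nzi <- sum(xi > 0); nzj <- sum(xj > 0)
  if (nzi < 3L || nzj < 3L)
    .insufficientData(sprintf(
      "each margin needs >= 3 nonzero observations (got %d and %d)", nzi, nzj))
  joint <- sum(xi > 0 & xj > 0)
  if (joint < 2L)
    .insufficientData(sprintf(
      "at least 2 jointly nonzero observations are required (got %d)", joint))
  invisible(NULL)
}

# stage 2 given precomputed profile data
.optimizeTheta <- function(pd, tol = 1e-8) {
  opt <- stats::optimize(.profileLL, c(-THETA_MAX, THETA_MAX), pd = pd,
                         maximum = TRUE, tol = tol)
  theta <- opt$maximum
  llMax <- opt$objective
  llNull <- .profileLL(0, pd)
  if (llNull > llMax) {  # guard: independence beats the interior candidate
    theta <- 0
    llMax <- llNull
  }
  list(theta = theta, llMax = llMax, llNull = llNull,
       boundary = abs(theta) > THETA_MAX - 1e-3)
}

# light-weight two-stage fit on plain lists; margins may be passed in
# pre-fitted (e.g. reused across pairs of a table-wide scan)
.twoStageCore <- function(xi, xj, modelI = list(), modelJ = list(),
                          margI = NULL, margJ = NULL, start = NULL) {
  .checkPairPreconditions(xi, xj)
  if (is.null(margI))
    margI <- do.call(.fitMarginCore, c(list(x = xi), modelI,
                                       list(start = start$margI)))
  if (is.null(margJ))
    margJ <- do.call(.fitMarginCore, c(list(x = xj), modelJ,
                                       list(start = start$margJ)))
  pd <- .profileData(xi, xj, margI$gamma, margJ$gamma)
  st2 <- .optimizeTheta(pd)
  c(list(margI = margI, margJ = margJ, counts = pd$counts), st2)
}

.asMarginFit <- function(m, n) {
  new("ZibMarginFit", coefficients = m$coef, gamma = m$gamma,
      logLik = m$logLik, nObs = n, nZero = m$nZero,
      converged = m$converged, links = m$links, model = m$designs)
}

#' Two-stage copula fit for a pair of taxa
#'
#' Fits the Frank copula with zero-inflated beta margins to a pair of
#' relative-abundance vectors by the two-stage (inference-for-margins)
#' method: each margin is fitted by maximum likelihood on its own, then the
#' profile log-likelihood is maximized over the dependence parameter
#' \eqn{\theta} with the marginal estimates plugged in. Optionally the
#' delete-one jackknife variance of \eqn{\tilde\theta} is computed, with
#' both stages re-run on every leave-one-out subset (warm-started at the
#' full-data estimates).
#'
#' @param xi,xj paired vectors of relative abundances in \[0, 1).
#' @param modelI,modelJ optional marginal model specifications: lists with
#'   any of `designP`, `designMu`, `designPhi` (design matrices) and `links`
#'   (see [fitZibMargin()]).
#' @param computeVar logical; compute the jackknife variance
#'   \eqn{\hat\sigma^2_\theta = \sum_l (\tilde\theta_{(l)} - \tilde\theta)^2}.
#' @param thetaTol stage-2 optimizer tolerance on \eqn{\theta}.
#' @return a [ZibPairFit-class] object.
#' @examples
#' set.seed(7)
#' d <- simulateZibPair(100, theta = 1.5, gammaI = c(0.1, 2/7, 7),
#'                      gammaJ = c(0.25, 5/7, 7))
#' fitPairCopula(d$xi, d$xj)
#' @export
fitPairCopula <- function(xi, xj, modelI = list(), modelJ = list(),
                          computeVar = FALSE, thetaTol = 1e-8) {
  xi <- .clampUnit(xi); xj <- .clampUnit(xj)
  core <- .twoStageCore(xi, xj, modelI, modelJ)
  n <- length(xi)
  varTheta <- NA_real_
  skipped <- 0L
  if (computeVar) {
    jk <- .jackknifeCore(xi, xj, modelI, modelJ, core)
    varTheta <- jk$varTheta
    skipped <- jk$skipped
  }
  new("ZibPairFit",
      marginI = .asMarginFit(core$margI, n),
      marginJ = .asMarginFit(core$margJ, n),
      theta = core$theta,
      varTheta = varTheta,
      logLikMax = core$llMax,
      logLikNull = core$llNull,
      diagnostics = list(boundary = core$boundary,
                         jackknifeSkipped = skipped,
                         scenarioCounts = core$counts),
      nObs = as.integer(n))
}

.jackknifeCore <- function(xi, xj, modelI, modelJ, core) {
  n <- length(xi)
  if (n < 10L)
    .insufficientData("jackknife variance requires n >= 10")
  warm <- list(
    margI = list(rho = core$margI$coef$rho, delta = core$margI$coef$delta,
                 kappa = core$margI$coef$kappa),
    margJ = list(rho = core$margJ$coef$rho, delta = core$margJ$coef$delta,
                 kappa = core$margJ$coef$kappa))
  dropRow <- function(model, l) {
    for (nm in c("designP", "designMu", "designPhi"))
      if (!is.null(model[[nm]]))
        model[[nm]] <- as.matrix(model[[nm]])[-l, , drop = FALSE]
    model
  }
  thetaL <- rep(NA_real_, n)
  for (l in seq_len(n)) {
    fitL <- tryCatch(
      .twoStageCore(xi[-l], xj[-l], dropRow(modelI, l), dropRow(modelJ, l),
                    start = warm),
      zibInsufficientData = function(e) NULL,
      zibConvergenceError = function(e) NULL)
    if (!is.null(fitL)) thetaL[l] <- fitL$theta
  }
  skipped <- sum(is.na(thetaL))
  if (skipped > 0L)
    warning(sprintf(
      "%d of %d jackknife replicates violated fit preconditions; variance is partial",
      skipped, n))
  ok <- !is.na(thetaL)
  if (!any(ok)) .insufficientData("no jackknife replicate could be fitted")
  list(varTheta = sum((thetaL[ok] - core$theta)^2), skipped = skipped,
       thetaL = thetaL)
}

#' Jackknife variance of the two-stage dependence estimate
#'
#' Delete-one jackknife variance
#' \eqn{\hat\sigma^2_\theta = \sum_{l=1}^n (\tilde\theta_{(l)} -
#' \tilde\theta)^2}, where \eqn{\tilde\theta_{(l)}} re-runs both estimation
#' stages with observation \eqn{l} removed. Replicates whose leave-one-out
#' subset violates the fit preconditions are skipped with a warning and the
#' variance is marked partial. This estimator stands in for the analytic
#' inference-function covariance, whose mixed partial derivatives are
#' impractical to compute; it is known to be conservative (upwardly biased).
#'
#' @inheritParams fitPairCopula
#' @param fit optional pre-computed [ZibPairFit-class] for the full data
#'   (avoids re-fitting).
#' @return list with elements `varTheta` (the variance), `thetaL`
#'   (leave-one-out estimates, `NA` where skipped) and `skipped`.
#' @export
jackknifeVarTheta <- function(xi, xj, modelI = list(), modelJ = list(),
                              fit = NULL) {
  xi <- .clampUnit(xi); xj <- .clampUnit(xj)
  core <- if (is.null(fit)) {
    .twoStageCore(xi, xj, modelI, modelJ)
  } else {
    list(theta = fit@theta,
         margI = list(coef = fit@marginI@coefficients),
         margJ = list(coef = fit@marginJ@coefficients))
  }
  .jackknifeCore(xi, xj, modelI, modelJ, core)
}
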