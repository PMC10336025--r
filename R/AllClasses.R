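#' @include AllGenerics.R
NULL

#' Fitted zero-inflated beta margin
#'
#' A zero-inflated beta (ZIB) marginal model fitted by maximum likelihood.
#' The margin places probability \eqn{p} on an exact zero and \eqn{1-p} on a
#' beta density parameterized by mean \eqn{\mu} and dispersion \eqn{\phi}
#' (shapes \eqn{\mu\phi} and \eqn{(1-\mu)\phi}). Each of \eqn{p}, \eqn{\mu}
#' and \eqn{\phi} may depend on covariates through a link function, so the
#' fitted parameters are stored per sample.
#'
#' @slot coefficients list with components `rho` (zero-part coefficients),
#'   `delta` (mean coefficients) and `kappa` (dispersion coefficients), on
#'   the link scale.
#' @slot gamma numeric n-by-3 matrix of per-sample `(p, mu, phi)`.
#' @slot logLik maximized marginal log-likelihood.
#' @slot nObs,nZero number of observations and number of exact zeros.
#' @slot converged logical convergence flag.
#' @slot links character vector of the three link names.
#' @slot model list holding the design matrices used for the fit.
#' @seealso [fitZibMargin()]
#' @export
setClass("ZibMarginFit",
  representation(
    coefficients = "list",
    gamma = "matrix",
    logLik = "numeric",
    nObs = "integer",
    nZero = "integer",
    converged = "logical",
    links = "character",
    model = "list"
  )
)

setValidity("ZibMarginFit", function(object) {
  g <- object@gamma
  if (ncol(g) != 3L) return("gamma must have 3 columns (p, mu, phi)")
  if (nrow(g) != object@nObs) return("gamma rows must match nObs")
  if (any(g[, 1] < 0 | g[, 1] >= 1)) return("p outside [0, 1)")
  if (any(g[, 2] <= 0 | g[, 2] >= 1)) return("mu outside (0, 1)")
  if (any(g[, 3] <= 0)) return("phi must be positive")
  if (object@nZero < 0L || object@nZero > object@nObs)
    return("nZero outside [0, nObs]")
  TRUE
})

#' Two-stage copula fit for a taxon pair
#'
#' Result of the two-stage (inference-for-margins) maximum-likelihood fit of
#' the Frank copula with ZIB margins: stage 1 fits each margin separately,
#' stage 2 maximizes the profile log-likelihood in the dependence parameter
#' \eqn{\theta} with the marginal estimates plugged in.
#'
#' @slot marginI,marginJ the stage-1 [ZibMarginFit-class] objects.
#' @slot theta stage-2 estimate \eqn{\tilde\theta}.
#' @slot varTheta delete-one jackknife variance of \eqn{\tilde\theta}
#'   (`NA_real_` when not requested).
#' @slot logLikMax profile log-likelihood at \eqn{\tilde\theta}.
#' @slot logLikNull profile log-likelihood at independence (\eqn{\theta = 0}).
#' @slot diagnostics list: `boundary` flag (estimate at the working bound),
#'   `jackknifeSkipped` count of leave-one-out replicates that violated the
#'   fit preconditions, `scenarioCounts` of the four zero patterns.
#' @slot nObs sample size.
#' @seealso [fitPairCopula()]
#' @export
setClass("ZibPairFit",
  representation(
    marginI = "ZibMarginFit",
    marginJ = "ZibMarginFit",
    theta = "numeric",
    varTheta = "numeric",
    logLikMax = "numeric",
    logLikNull = "numeric",
    diagnostics = "list",
    nObs = "integer"
  )
)

setValidity("ZibPairFit", function(object) {
  if (length(object@theta) != 1L) return("theta must be scalar")
  if (!is.na(object@varTheta) && object@varTheta < 0)
    return("varTheta must be nonnegative")
  if (object@logLikMax < object@logLikNull - 1e-8)
    return("logLikMax must be >= logLikNull")
  TRUE
})

#' Rescaled likelihood-ratio test for copula dependence
#'
#' The two-stage likelihood-ratio test of \eqn{H_0: \theta = \theta_0}.
#' The statistic \eqn{\Lambda' = -2\omega\,[\ell(\theta_0) - \ell(\tilde\theta)]}
#' is asymptotically \eqn{\chi^2_1}; the rescaling factor \eqn{\omega}
#' corrects for the plugged-in margins and equals 1 exactly when
#' \eqn{\theta_0} is the independence value.
#'
#' @slot lambda the statistic \eqn{\Lambda' \ge 0}.
#' @slot omega rescaling factor in (0, 1].
#' @slot pValue upper-tail \eqn{\chi^2_1} p-value.
#' @slot thetaNull the tested value \eqn{\theta_0}.
#' @slot df degrees of freedom (1).
#' @slot fit the underlying [ZibPairFit-class].
#' @seealso [testPairDependence()]
#' @export
setClass("ZibPairTest",
  representation(
    lambda = "numeric",
    omega = "numeric",
    pValue = "numeric",
    thetaNull = "numeric",
    df = "numeric",
    fit = "ZibPairFit"
  )
)

setValidity("ZibPairTest", function(object) {
  if (object@lambda < 0) return("lambda must be nonnegative")
  if (object@pValue < 0 || object@pValue > 1) return("pValue outside [0, 1]")
  if (object@omega <= 0 || object@omega > 1 + 1e-12)
    return("omega must lie in (0, 1]")
  if (object@thetaNull == 0 && abs(object@omega - 1) > 1e-12)
    return("omega must be 1 under the independence null")
  TRUE
})

#' Microbial covariation network
#'
#' All-pairs dependence analysis of a samples-by-taxa relative-abundance
#' table: \eqn{\tilde\theta}-weighted symmetric adjacency with
#' Benjamini--Yekutieli FDR-controlled edge calls, optional hierarchical
#' clustering and graph summaries.
#'
#' @slot taxa ordered taxon labels (the nodes).
#' @slot thetaMatrix symmetric matrix of dependence estimates, zero diagonal.
#' @slot pMatrix,pAdjMatrix symmetric matrices of raw and BY-adjusted
#'   p-values (`NA` where a pair could not be fitted).
#' @slot adjacency logical symmetric edge matrix at FDR level `q`.
#' @slot q FDR level used for the edge calls.
#' @slot pairs data.frame with one row per unordered pair (labels, theta,
#'   p-values, significance, fit status).
#' @slot clusters named integer cluster ids (length 0 until
#'   [clusterNetwork()] is applied).
#' @slot summaries list of graph summaries (length 0 until
#'   [graphSummaries()] is applied).
#' @seealso [covariationNetwork()]
#' @export
setClass("CovariationNetwork",
  representation(
    taxa = "character",
    thetaMatrix = "matrix",
    pMatrix = "matrix",
    pAdjMatrix = "matrix",
    adjacency = "matrix",
    q = "numeric",
    pairs = "data.frame",
    clusters = "integer",
    summaries = "list"
  )
)

setValidity("CovariationNetwork", function(object) {
  m <- length(object@taxa)
  for (nm in c("thetaMatrix", "pMatrix", "pAdjMatrix", "adjacency")) {
    mat <- slot(object, nm)
    if (!all(dim(mat) == c(m, m))) return(sprintf("%s has wrong dimension", nm))
  }
  if (!isTRUE(all.equal(object@thetaMatrix, t(object@thetaMatrix))))
    return("thetaMatrix must be symmetric")
  if (any(diag(object@adjacency)))
    return("adjacency diagonal must be FALSE")
  if (!identical(object@adjacency, t(object@adjacency)))
    return("adjacency must be symmetric")
  nEdge <- sum(object@adjacency) / 2
  nRej <- sum(object@pairs$significant, na.rm = TRUE)
  if (nEdge != nRej) return("edge count must equal the number of BY rejections")
  TRUE
})

## ---- accessors ----

#' @rdname thetaHat
#' @export
setMethod("thetaHat", "ZibPairFit", function(object) object@theta)

#' @rdname thetaHat
#' @export
setMethod("thetaHat", "ZibPairTest", function(object) object@fit@theta)

#' @rdname thetaHat
#' @export
setMethod("thetaHat", "CovariationNetwork", function(object) object@thetaMatrix)

#' @rdname varTheta
#' @export
setMethod("varTheta", "ZibPairFit", function(object) object@varTheta)

#' @rdname varTheta
#' @export
setMethod("varTheta", "ZibPairTest", function(object) object@fit@varTheta)

#' @rdname pValues
#' @export
setMethod("pValues", "ZibPairTest", function(object, adjusted = FALSE) object@pValue)

#' @rdname pValues
#' @export
setMethod("pValues", "CovariationNetwork", function(object, adjusted = FALSE) {
  if (adjusted) object@pAdjMatrix else object@pMatrix
})

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "CovariationNetwork", function(object) object@adjacency)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "CovariationNetwork", function(object, allPairs = FALSE) {
  tab <- object@pairs
  if (!allPairs) tab <- tab[!is.na(tab$significant) & tab$significant, , drop = FALSE]
  rownames(tab) <- NULL
  tab
})

#' @rdname clusterAssignments
#' @export
setMethod("clusterAssignments", "CovariationNetwork", function(object) {
  if (length(object@clusters) == 0L) NULL else object@clusters
})

## ---- show ----

setMethod("show", "ZibMarginFit", function(object) {
  cat("ZibMarginFit:", object@nObs, "observations,",
      object@nZero, "zeros\n")
  g1 <- object@gamma[1L, ]
  if (all(apply(object@gamma, 2L, function(col) diff(range(col)) == 0))) {
    cat(sprintf("  p = %.4f, mu = %.4f, phi = %.4f\n", g1[1], g1[2], g1[3]))
  } else {
    cat("  covariate-adjusted margins; per-sample (p, mu, phi) in @gamma\n")
  }
  cat(sprintf("  logLik = %.4f, converged = %s\n",
              object@logLik, object@converged))
})

setMethod("show", "ZibPairFit", function(object) {
  cat("ZibPairFit (two-stage Frank copula with ZIB margins)\n")
  cat(sprintf("  n = %d, theta = %.4f", object@nObs, object@theta))
  if (!is.na(object@varTheta))
    cat(sprintf(" (jackknife SE = %.4f)", sqrt(object@varTheta)))
  cat("\n")
  sc <- object@diagnostics$scenarioCounts
  if (!is.null(sc))
    cat(sprintf("  zero patterns: both>0: %d, i=0: %d, j=0: %d, both=0: %d\n",
                sc[1], sc[2], sc[3], sc[4]))
  if (isTRUE(object@diagnostics$boundary))
    cat("  NOTE: estimate at the working boundary\n")
})

setMethod("show", "ZibPairTest", function(object) {
  cat("Two-stage likelihood-ratio test of theta =", object@thetaNull, "\n")
  cat(sprintf("  theta = %.4f, Lambda' = %.4f (omega = %.4f), df = 1, p = %.4g\n",
              object@fit@theta, object@lambda, object@omega, object@pValue))
})

setMethod("show", "CovariationNetwork", function(object) {
  m <- length(object@taxa)
  tab <- object@pairs
  nTested <- sum(!is.na(tab$pValue))
  nEdge <- sum(object@adjacency) / 2
  cat("CovariationNetwork:", m, "taxa,", nrow(tab), "pairs (",
      nTested, "tested )\n")
  cat(sprintf("  %d edges at BY FDR q = %g\n", nEdge, object@q))
  if (length(object@clusters))
    cat("  clusters:", paste(table(object@clusters), collapse = " / "),
        "taxa per cluster\n")
})
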