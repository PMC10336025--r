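#' @include AllGenerics.R
NULL

#' Estimated dependence parameter
#'
#' Extract the estimated Frank copula dependence parameter \eqn{\tilde\theta}
#' from a fitted object.
#'
#' @param object a [ZibPairFit-class], [ZibPairTest-class] or
#'   [CovariationNetwork-class] object.
#' @return For a pair fit or test, a single numeric value; for a network, the
#'   symmetric taxa-by-taxa matrix of estimates.
#' @export
setGeneric("thetaHat", function(object) standardGeneric("thetaHat"))

#' Jackknife variance of the dependence estimate
#'
#' @param object a [ZibPairFit-class] or [ZibPairTest-class] object.
#' @return the delete-one jackknife variance \eqn{\hat\sigma^2_\theta}
#'   (`NA` if it was not computed).
#' @export
setGeneric("varTheta", function(object) standardGeneric("varTheta"))

#' P-values of dependence tests
#'
#' @param object a [ZibPairTest-class] or [CovariationNetwork-class] object.
#' @param adjusted logical; for networks, return Benjamini--Yekutieli
#'   adjusted values instead of raw ones.
#' @return a numeric value, or a symmetric matrix for networks.
#' @export
setGeneric("pValues", function(object, adjusted = FALSE) standardGeneric("pValues"))

#' Binary adjacency matrix of a covariation network
#'
#' @param object a [CovariationNetwork-class] object.
#' @return logical taxa-by-taxa matrix; `TRUE` where the dependence test was
#'   rejected after FDR control.
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' Edge table of a covariation network
#'
#' @param object a [CovariationNetwork-class] object.
#' @param allPairs logical; return every tested pair rather than only the
#'   significant edges.
#' @return a data.frame with one row per pair: taxon labels, \eqn{\tilde\theta},
#'   raw and BY-adjusted p-values, significance flag and fit status.
#' @export
setGeneric("edgeTable", function(object, allPairs = FALSE) standardGeneric("edgeTable"))

#' Cluster assignment of network nodes
#'
#' @param object a [CovariationNetwork-class] object that has been passed
#'   through [clusterNetwork()].
#' @return named integer vector of cluster ids, or `NULL` when clustering has
#'   not been run.
#' @export
setGeneric("clusterAssignments", function(object) standardGeneric("clusterAssignments"))
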