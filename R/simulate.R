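# Synthetic data generation: Rosenblatt-transform sampling from the Frank
# copula with zero-inflated beta margins, a covariate-adjusted variant, a
# Gaussian-copula misspecification variant, and multivariate unit-sum
# abundance tables for network benchmarking.

# redo rules shared by all pair simulators: a whole dataset is redrawn when
# (a) either margin has < 3 nonzero values (marginal parameters would be
# unidentifiable), (b) the taxa are mutually exclusive (no jointly nonzero
# pair), or (c) exactly one pair is jointly nonzero. These configurations
# push the dependence estimate to the boundary and destabilize variances,
# so acceptance amounts to truncating the data distribution to usable sets.
.pairIsDegenerate <- function(xi, xj) {
  sum(xi > 0) < 3L || sum(xj > 0) < 3L || sum(xi > 0 & xj > 0) < 2L
}

.redoLoop <- function(drawOnce, redoLimit) {
  for (attempt in seq_len(redoLimit)) {
    d <- drawOnce()
    if (!.pairIsDegenerate(d$xi, d$xj)) {
      d$attempts <- attempt
      return(d)
    }
  }
  stop(structure(class = c("zibSimulationDegenerate", "error", "condition"),
                 list(message = sprintf(
                   "no acceptable dataset in %d attempts; configuration is degenerate",
                   redoLimit), call = sys.call(-1))))
}

#' Simulate a dependent pair of zero-inflated beta margins
#'
#' Draws paired relative abundances from the Frank copula with ZIB margins
#' by the Rosenblatt transformation: \eqn{U, B} independent uniforms,
#' \eqn{v = C^{-1}_{b|u}(B, U)}, then \eqn{x_i = F_i^{-1}(U)},
#' \eqn{x_j = F_j^{-1}(v)} through the ZIB quantile function. Datasets with
#' fewer than three nonzero values in either margin, mutually exclusive
#' taxa, or only one jointly nonzero pair are redrawn in full (acceptance is
#' a truncation of the data distribution; the attempt count is returned).
#'
#' @param n sample size (>= 4).
#' @param theta Frank dependence parameter (0 gives independence).
#' @param gammaI,gammaJ marginal parameters `c(p, mu, phi)`.
#' @param seed optional integer seed (one stream per dataset; redraws
#'   consume further values from the same stream).
#' @param redoLimit maximum number of whole-dataset redraws.
#' @return list with `xi`, `xj` and `attempts`.
#' @examples
#' d <- simulateZibPair(50, theta = 1.5, gammaI = c(0.1, 2/7, 7),
#'                      gammaJ = c(0.25, 5/7, 7), seed = 1)
#' @export
simulateZibPair <- function(n, theta, gammaI, gammaJ, seed = NULL,
                            redoLimit = 1000L) {
  stopifnot(n >= 4, redoLimit >= 1)
  .checkGamma(gammaI[1], gammaI[2], gammaI[3])
  .checkGamma(gammaJ[1], gammaJ[2], gammaJ[3])
  if (!is.null(seed)) set.seed(seed)
  .redoLoop(function() {
    u <- stats::runif(n); b <- stats::runif(n)
    v <- frankCondQuantile(b, u, theta)
    list(xi = qzib(u, gammaI[1], gammaI[2], gammaI[3]),
         xj = qzib(v, gammaJ[1], gammaJ[2], gammaJ[3]))
  }, redoLimit)
}

#' Simulate a pair with covariate-adjusted zero inflation
#'
#' As [simulateZibPair()], but the zero-inflation probability of each margin
#' follows a logistic regression on its own standard-normal covariate:
#' \eqn{\mathrm{logit}(p_k) = \rho_{k0} + \rho_{k1} Q_{k1}}. Defaults follow
#' the low-low benchmark configuration: coefficients `(-0.5, 0.7)` and
#' `(-0.3, 0.4)`, beta means \eqn{e^{-0.7}/(1+e^{-0.7})} and
#' \eqn{e^{-1}/(1+e^{-1})}, dispersions \eqn{e^{1.5}}.
#'
#' @inheritParams simulateZibPair
#' @param rhoI,rhoJ length-2 intercept/slope vectors of the logistic
#'   zero-part models.
#' @param muI,muJ,phiI,phiJ beta means and dispersions (constant across
#'   samples).
#' @return list with `xi`, `xj`, covariate columns `qI`, `qJ`, the
#'   per-sample zero probabilities `pI`, `pJ`, and `attempts`.
#' @export
simulateZibPairCovariate <- function(n, theta,
                                     rhoI = c(-0.5, 0.7), rhoJ = c(-0.3, 0.4),
                                     muI = stats::plogis(-0.7),
                                     muJ = stats::plogis(-1),
                                     phiI = exp(1.5), phiJ = exp(1.5),
                                     seed = NULL, redoLimit = 1000L) {
  stopifnot(n >= 4, redoLimit >= 1)
  if (!is.null(seed)) set.seed(seed)
  .redoLoop(function() {
    qI <- stats::rnorm(n); qJ <- stats::rnorm(n)
    pI <- stats::plogis(rhoI[1] + rhoI[2] * qI)
    pJ <- stats::plogis(rhoJ[1] + rhoJ[2] * qJ)
    u <- stats::runif(n); b <- stats::runif(n)
    v <- frankCondQuantile(b, u, theta)
    list(xi = qzib(u, pI, muI, phiI), xj = qzib(v, pJ, muJ, phiJ),
         qI = qI, qJ = qJ, pI = pI, pJ = pJ)
  }, redoLimit)
}

#' Simulate a pair from a Gaussian copula (model misspecification)
#'
#' Draws the latent uniforms from a bivariate Gaussian copula (correlated
#' standard normals mapped through the normal CDF) instead of the Frank
#' copula, keeping the ZIB margins. Used to probe robustness of the
#' Frank-copula inference under copula misspecification.
#'
#' @inheritParams simulateZibPair
#' @param rho latent normal correlation in (-1, 1).
#' @return list with `xi`, `xj` and `attempts`.
#' @export
simulateGaussianPair <- function(n, rho, gammaI, gammaJ, seed = NULL,
                                 redoLimit = 1000L) {
  stopifnot(n >= 4, abs(rho) < 1, redoLimit >= 1)
  .checkGamma(gammaI[1], gammaI[2], gammaI[3])
  .checkGamma(gammaJ[1], gammaJ[2], gammaJ[3])
  if (!is.null(seed)) set.seed(seed)
  .redoLoop(function() {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    u <- .clampProb(stats::pnorm(z1)); v <- .clampProb(stats::pnorm(z2))
    list(xi = qzib(u, gammaI[1], gammaI[2], gammaI[3]),
         xj = qzib(v, gammaJ[1], gammaJ[2], gammaJ[3]))
  }, redoLimit)
}

#' Block layout of truly dependent taxon pairs
#'
#' Builds a dependency pair list in which the truly correlated pairs form
#' equicorrelated blocks of taxa (all within-block pairs dependent, no
#' between-block dependence). Block designs keep the latent correlation
#' matrix positive definite by construction and mimic the modular structure
#' of real microbial communities.
#'
#' @param nTaxa total number of taxa.
#' @param blockSizes integer vector of block sizes (must sum to <= `nTaxa`;
#'   remaining taxa are isolated).
#' @param rho latent correlation shared by all within-block pairs.
#' @return data.frame with columns `a`, `b` (taxon indices) and `rho`.
#' @examples
#' blockDependency(20, c(5, 4, 3), 0.6)  # 19 of 190 pairs dependent
#' @export
blockDependency <- function(nTaxa, blockSizes, rho = 0.6) {
  stopifnot(sum(blockSizes) <= nTaxa, all(blockSizes >= 2))
  offset <- 0L
  out <- list()
  for (s in blockSizes) {
    idx <- offset + seq_len(s)
    cmb <- utils::combn(idx, 2L)
    out[[length(out) + 1L]] <- data.frame(a = cmb[1, ], b = cmb[2, ], rho = rho)
    offset <- offset + s
  }
  do.call(rbind, out)
}

#' Simulate a multivariate unit-sum abundance table
#'
#' Draws `n` samples of `nTaxa` zero-beta mixture margins tied by a
#' multivariate Gaussian copula in which a designated subset of taxon pairs
#' carries nonzero latent correlation, then normalizes each sample to unit
#' sum, emulating microbial relative-abundance data. Truth labels for every
#' pair are returned for benchmarking network-recovery methods.
#'
#' If the requested latent correlation matrix is not positive definite it is
#' repaired by eigenvalue clipping (with a warning); block designs from
#' [blockDependency()] never need repair.
#'
#' @param nTaxa number of taxa (>= 3).
#' @param n number of samples.
#' @param dependency data.frame of truly dependent pairs with columns `a`,
#'   `b` and `rho`, e.g. from [blockDependency()]. `NULL` means complete
#'   independence.
#' @param gammas optional `nTaxa`-by-3 matrix of marginal `(p, mu, phi)`.
#'   By default each taxon draws its zero-inflation probability from
#'   \{0.10, 0.25, 0.40, 0.50, 0.60, 0.75\} and its beta parameters from
#'   \{(2/7,7), (5/7,7), (1/2,4), (1/3,9), (2/3,9), (1/2,6)\}, the benchmark
#'   marginal grids.
#' @param normalize logical; divide each row by its sum (rows that are all
#'   zero are left at zero).
#' @param seed optional integer seed.
#' @return list with `table` (n-by-nTaxa matrix, columns `taxon_1`, ...),
#'   `truth` (data.frame of all pairs with logical `dependent`), and
#'   `gammas` (the marginal parameters used).
#' @export
simulateAbundanceTable <- function(nTaxa, n, dependency = NULL,
                                   gammas = NULL, normalize = TRUE,
                                   seed = NULL) {
  stopifnot(nTaxa >= 3, n >= 4)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gammas)) {
    pPool <- c(0.10, 0.25, 0.40, 0.50, 0.60, 0.75)
    muPhiPool <- matrix(c(2 / 7, 7, 5 / 7, 7, 1 / 2, 4,
                          1 / 3, 9, 2 / 3, 9, 1 / 2, 6),
                        ncol = 2L, byrow = TRUE)
    pick <- sample.int(nrow(muPhiPool), nTaxa, replace = TRUE)
    gammas <- cbind(p = sample(pPool, nTaxa, replace = TRUE),
                    mu = muPhiPool[pick, 1], phi = muPhiPool[pick, 2])
  }
  gammas <- as.matrix(gammas)
  stopifnot(nrow(gammas) == nTaxa, ncol(gammas) == 3L)
  .checkGamma(gammas[, 1], gammas[, 2], gammas[, 3])

  Sigma <- diag(nTaxa)
  if (!is.null(dependency) && nrow(dependency)) {
    for (r in seq_len(nrow(dependency))) {
      a <- dependency$a[r]; b <- dependency$b[r]
      Sigma[a, b] <- Sigma[b, a] <- dependency$rho[r]
    }
  }
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    warning("latent correlation matrix not positive definite; repaired by eigenvalue clipping")
    vals <- pmax(ev$values, 1e-6)
    Sigma <- ev$vectors %*% (vals * t(ev$vectors))
    Sigma <- stats::cov2cor(Sigma)
    ev <- eigen(Sigma, symmetric = TRUE)
  }
  R <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  Z <- matrix(stats::rnorm(n * nTaxa), n, nTaxa) %*% R
  U <- .clampProb(stats::pnorm(Z))
  X <- vapply(seq_len(nTaxa), function(k)
    qzib(U[, k], gammas[k, 1], gammas[k, 2], gammas[k, 3]),
    numeric(n))
  if (normalize) {
    rs <- rowSums(X)
    pos <- rs > 0
    X[pos, ] <- X[pos, , drop = FALSE] / rs[pos]
    X <- .clampUnit(X, warn = FALSE)
  }
  colnames(X) <- paste0("taxon_", seq_len(nTaxa))
  rownames(X) <- paste0("sample_", seq_len(n))

  cmb <- utils::combn(nTaxa, 2L)
  truth <- data.frame(a = cmb[1, ], b = cmb[2, ], dependent = FALSE)
  if (!is.null(dependency) && nrow(dependency)) {
    key <- paste(pmin(dependency$a, dependency$b),
                 pmax(dependency$a, dependency$b))
    truth$dependent <- paste(truth$a, truth$b) %in% key
  }
  list(table = X, truth = truth, gammas = gammas)
}
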