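# Bivariate joint density of two zero-inflated beta margins tied by a Frank
# copula. Each margin mixes an atom at 0 with a continuous beta part, so the
# joint density has four cases determined by the zero pattern:
#
#   S1 (x_i > 0, x_j > 0): c(F_i(x_i), F_j(x_j)) f_i(x_i) f_j(x_j)
#   S2 (x_i = 0, x_j > 0): C_{u|v}(p_i | F_j(x_j)) f_j(x_j)
#   S3 (x_i > 0, x_j = 0): C_{v|u}(F_i(x_i) | p_j) ... i.e. dC/du at v = p_j
#   S4 (x_i = 0, x_j = 0): C(p_i, p_j)
#
# where f_k is the continuous part (1 - p_k) f_beta and the difference
# operator over the atom reduces to these because F_k(0^-) = 0.

.LOG_FLOOR <- log(1e-300)

.clampProb <- function(u) pmin(pmax(u, 1e-12), 1 - 1e-12)

#' Joint density of a zero-inflated beta pair under a Frank copula
#'
#' Evaluates the mixed discrete-continuous joint density of a pair of
#' relative abundances: a product of the copula density and continuous
#' marginal densities when both values are positive, a copula conditional
#' probability times one continuous density when exactly one is zero, and
#' the copula evaluated at the two atom masses when both are zero.
#'
#' @param xi,xj paired values in \[0, 1); vectorized.
#' @param gammaI,gammaJ marginal parameters: either a length-3 numeric
#'   `c(p, mu, phi)` or an n-by-3 matrix of per-sample parameters (from a
#'   covariate-adjusted fit).
#' @param theta Frank dependence parameter.
#' @param log logical; return the log density. Per-observation log densities
#'   are floored at `log(1e-300)` to avoid `-Inf` from underflow.
#' @return numeric vector of densities/masses.
#' @examples
#' zibPairDensity(0, 0, c(0.3, 0.5, 2), c(0.2, 0.5, 2), theta = 0)  # 0.06
#' @export
zibPairDensity <- function(xi, xj, gammaI, gammaJ, theta, log = FALSE) {
  n <- max(length(xi), length(xj))
  xi <- rep_len(xi, n); xj <- rep_len(xj, n)
  .checkSupport(xi); .checkSupport(xj)
  gi <- .asGammaMatrix(gammaI, n)
  gj <- .asGammaMatrix(gammaJ, n)
  out <- numeric(n)
  zi <- xi == 0; zj <- xj == 0

  s1 <- !zi & !zj
  if (any(s1)) {
    u <- .clampProb(pzib(xi[s1], gi[s1, 1], gi[s1, 2], gi[s1, 3]))
    v <- .clampProb(pzib(xj[s1], gj[s1, 1], gj[s1, 2], gj[s1, 3]))
    out[s1] <- frankPdf(u, v, theta, log = TRUE) +
      log(pmax(dzib(xi[s1], gi[s1, 1], gi[s1, 2], gi[s1, 3]), 1e-300)) +
      log(pmax(dzib(xj[s1], gj[s1, 1], gj[s1, 2], gj[s1, 3]), 1e-300))
  }
  s2 <- zi & !zj
  if (any(s2)) {
    v <- .clampProb(pzib(xj[s2], gj[s2, 1], gj[s2, 2], gj[s2, 3]))
    pi <- .clampProb(gi[s2, 1])
    # dC/dv at (p_i, v): by symmetry of C, condition on the continuous margin
    out[s2] <- log(pmax(frankCondCdf(v, pi, theta), 1e-300)) +
      log(pmax(dzib(xj[s2], gj[s2, 1], gj[s2, 2], gj[s2, 3]), 1e-300))
  }
  s3 <- !zi & zj
  if (any(s3)) {
    u <- .clampProb(pzib(xi[s3], gi[s3, 1], gi[s3, 2], gi[s3, 3]))
    pj <- .clampProb(gj[s3, 1])
    out[s3] <- log(pmax(frankCondCdf(u, pj, theta), 1e-300)) +
      log(pmax(dzib(xi[s3], gi[s3, 1], gi[s3, 2], gi[s3, 3]), 1e-300))
  }
  s4 <- zi & zj
  if (any(s4)) {
    out[s4] <- log(pmax(frankCdf(.clampProb(gi[s4, 1]),
                                 .clampProb(gj[s4, 1]), theta), 1e-300))
  }
  out <- pmax(out, .LOG_FLOOR)
  if (log) out else exp(out)
}

.asGammaMatrix <- function(gamma, n) {
  if (is.matrix(gamma)) {
    if (nrow(gamma) != n) stop("per-sample gamma matrix must have n rows")
    .checkGamma(gamma[, 1], gamma[, 2], gamma[, 3])
    gamma
  } else {
    if (length(gamma) != 3L) stop("gamma must be c(p, mu, phi)")
    .checkGamma(gamma[1], gamma[2], gamma[3])
    matrix(gamma, n, 3L, byrow = TRUE)
  }
}

# Precompute everything theta-free for fast profile log-likelihood
# evaluation: marginal CDF values, atom masses and the additive constant
# contributed by the continuous marginal densities.
.profileData <- function(xi, xj, gammaI, gammaJ) {
  n <- length(xi)
  gi <- .asGammaMatrix(gammaI, n)
  gj <- .asGammaMatrix(gammaJ, n)
  zi <- xi == 0; zj <- xj == 0
  s1 <- !zi & !zj; s2 <- zi & !zj; s3 <- !zi & zj; s4 <- zi & zj
  const <- 0
  if (any(s1))
    const <- const +
      sum(log(pmax(dzib(xi[s1], gi[s1, 1], gi[s1, 2], gi[s1, 3]), 1e-300))) +
      sum(log(pmax(dzib(xj[s1], gj[s1, 1], gj[s1, 2], gj[s1, 3]), 1e-300)))
  if (any(s2))
    const <- const +
      sum(log(pmax(dzib(xj[s2], gj[s2, 1], gj[s2, 2], gj[s2, 3]), 1e-300)))
  if (any(s3))
    const <- const +
      sum(log(pmax(dzib(xi[s3], gi[s3, 1], gi[s3, 2], gi[s3, 3]), 1e-300)))
  list(
    u1 = .clampProb(pzib(xi[s1], gi[s1, 1], gi[s1, 2], gi[s1, 3])),
    v1 = .clampProb(pzib(xj[s1], gj[s1, 1], gj[s1, 2], gj[s1, 3])),
    v2 = .clampProb(pzib(xj[s2], gj[s2, 1], gj[s2, 2], gj[s2, 3])),
    p2 = .clampProb(gi[s2, 1]),
    u3 = .clampProb(pzib(xi[s3], gi[s3, 1], gi[s3, 2], gi[s3, 3])),
    p3 = .clampProb(gj[s3, 1]),
    p4i = .clampProb(gi[s4, 1]),
    p4j = .clampProb(gj[s4, 1]),
    const = const,
    counts = c(s1 = sum(s1), s2 = sum(s2), s3 = sum(s3), s4 = sum(s4))
  )
}

.profileLL <- function(theta, pd) {
  ll <- pd$const
  if (length(pd$u1))
    ll <- ll + sum(pmax(frankPdf(pd$u1, pd$v1, theta, log = TRUE), .LOG_FLOOR))
  if (length(pd$v2))
    ll <- ll + sum(pmax(log(pmax(frankCondCdf(pd$v2, pd$p2, theta), 1e-300)),
                        .LOG_FLOOR))
  if (length(pd$u3))
    ll <- ll + sum(pmax(log(pmax(frankCondCdf(pd$u3, pd$p3, theta), 1e-300)),
                        .LOG_FLOOR))
  if (length(pd$p4i))
    ll <- ll + sum(pmax(log(pmax(frankCdf(pd$p4i, pd$p4j, theta), 1e-300)),
                        .LOG_FLOOR))
  ll
}

#' Profile log-likelihood in the dependence parameter
#'
#' The bivariate log-likelihood \eqn{\ell(\theta, \tilde\gamma_i,
#' \tilde\gamma_j)} with the fitted marginal parameters plugged in
#' (inference-for-margins stage 2): the sum over observations of the log
#' mixed joint density, vectorized over a grid of `theta` values.
#'
#' @param theta numeric vector of dependence values.
#' @param xi,xj paired observations in \[0, 1).
#' @param gammaI,gammaJ marginal parameters (`c(p, mu, phi)` or per-sample
#'   n-by-3 matrices), typically from [fitZibMargin()].
#' @return numeric vector of log-likelihood values, one per `theta`.
#' @export
pairProfileLogLik <- function(theta, xi, xj, gammaI, gammaJ) {
  if (length(xi) != length(xj)) stop("xi and xj must be paired")
  .checkSupport(xi); .checkSupport(xj)
  pd <- .profileData(xi, xj, gammaI, gammaJ)
  if (pd$counts["s4"] == length(xi))
    stop("degenerate pair: every observation has both taxa at zero")
  vapply(theta, .profileLL, numeric(1), pd = pd)
}
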