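# Frank copula primitives.
#
# C(u,v; theta) = -(1/theta) log{1 + (e^{-theta u}-1)(e^{-theta v}-1) /
#                                    (e^{-theta}-1)}
#
# theta spans (-Inf, Inf) \ {0}; theta -> 0 is the independence limit
# C = uv. All arithmetic uses expm1/log1p so the functions stay accurate
# through the puncture at 0 and out to the working bound |theta| = 35.

#' Working bound for the Frank dependence parameter
#'
#' At `|theta| = 35` the Frank copula is within about 1e-6 (in Kendall's tau)
#' of the Frechet bound; optimizers are confined to `[-THETA_MAX, THETA_MAX]`.
#' @export
THETA_MAX <- 35

# below this |theta| the independence-limit formulas are used
.THETA_EPS <- 1e-6

.checkUV <- function(u, v, openU = FALSE, openV = FALSE) {
  if (openU) {
    if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  } else if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  if (openV) {
    if (any(v <= 0 | v >= 1)) stop("v must lie strictly inside (0, 1)")
  } else if (any(v < 0 | v > 1)) stop("v must lie in [0, 1]")
  invisible(NULL)
}

#' Frank copula distribution function
#'
#' @param u,v probabilities in \[0, 1\]; vectorized with recycling.
#' @param theta dependence parameter; values within 1e-6 of 0 dispatch to the
#'   independence limit \eqn{C(u,v) = uv}.
#' @return numeric vector of copula values.
#' @examples
#' frankCdf(0.5, 0.5, 3)   # about 0.3361
#' frankCdf(0.37, 1, 2.4)  # boundary identity: 0.37
#' @export
frankCdf <- function(u, v, theta) {
  .checkUV(u, v)
  if (abs(theta) < .THETA_EPS) return(u * v)
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  num <- expm1(-theta * u) * expm1(-theta * v) / expm1(-theta)
  out <- -log1p(num) / theta
  # uniform-margin boundary identities, made exact
  out[u == 0 | v == 0] <- 0
  out[v == 1] <- u[v == 1]
  out[u == 1] <- v[u == 1]
  out
}

#' Frank copula density
#'
#' Mixed partial \eqn{\partial^2 C / \partial u \partial v}; equals 1
#' everywhere at the independence limit.
#'
#' @param u,v probabilities strictly inside (0, 1).
#' @inheritParams frankCdf
#' @param log logical; return the log density.
#' @return numeric vector of densities.
#' @export
frankPdf <- function(u, v, theta, log = FALSE) {
  .checkUV(u, v, openU = TRUE, openV = TRUE)
  if (abs(theta) < .THETA_EPS) {
    out <- rep_len(0, max(length(u), length(v)))
    return(if (log) out else exp(out))
  }
  em <- expm1(-theta)
  # denominator e^-t(u+v) - e^-tu - e^-tv + e^-t regrouped into two
  # same-sign terms (no cancellation at large |theta|)
  den <- exp(-theta * u) * expm1(-theta * v) +
    exp(-theta * v) * expm1(-theta * (1 - v))
  logNum <- log(abs(theta * em)) - theta * (u + v)
  out <- logNum - 2 * log(abs(den))
  if (log) out else exp(out)
}

#' Frank copula conditional distribution function
#'
#' \eqn{C_{v|u}(u,v) = \partial C(u,v)/\partial u = \Pr(V \le v \mid U = u)};
#' nondecreasing in `v` from 0 to 1, equal to `v` at the independence limit.
#'
#' @param u conditioning probability strictly inside (0, 1).
#' @param v probability in \[0, 1\].
#' @inheritParams frankCdf
#' @return numeric vector of conditional probabilities.
#' @export
frankCondCdf <- function(u, v, theta) {
  .checkUV(u, v, openU = TRUE)
  if (abs(theta) < .THETA_EPS) return(v + 0 * u)
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  den <- exp(-theta * u) * expm1(-theta * v) +
    exp(-theta * v) * expm1(-theta * (1 - v))
  out <- exp(-theta * u) * expm1(-theta * v) / den
  out[v == 0] <- 0
  out[v == 1] <- 1
  out
}

#' Frank copula inverse conditional (Rosenblatt inverse)
#'
#' Closed-form inverse of [frankCondCdf()] in `v`:
#' \eqn{v = -\frac{1}{\theta}\log\left\{1 +
#'   \frac{b(e^{-\theta}-1)}{b + e^{-\theta u}(1-b)}\right\}},
#' the workhorse of conditional-distribution sampling from the Frank copula.
#'
#' @param b target conditional probability strictly inside (0, 1).
#' @param u conditioning probability strictly inside (0, 1).
#' @inheritParams frankCdf
#' @return `v` with `frankCondCdf(u, v, theta) == b` (round-trip error below
#'   1e-10).
#' @export
frankCondQuantile <- function(b, u, theta) {
  if (any(b <= 0 | b >= 1)) stop("b must lie strictly inside (0, 1)")
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  if (abs(theta) < .THETA_EPS) return(b + 0 * u)
  if (abs(theta) < 1) {
    # small |theta|: the log1p form is exact
    -log1p(b * expm1(-theta) / (b + exp(-theta * u) * (1 - b))) / theta
  } else {
    # large |theta|: evaluate the ratio inside the log directly, avoiding
    # the cancellation of 1 + x with x near -1
    num <- exp(-theta * u) * (1 - b) + b * exp(-theta)
    den <- b + exp(-theta * u) * (1 - b)
    -(log(num) - log(den)) / theta
  }
}

# first Debye function D1(t) = (1/t) int_0^t s/(e^s - 1) ds, t > 0
.debye1 <- function(t) {
  f <- function(s) ifelse(s == 0, 1, s / expm1(s))
  stats::integrate(f, 0, t, rel.tol = 1e-12)$value / t
}

#' Map Frank theta to Kendall's tau
#'
#' \eqn{\tau = 1 + 4(D_1(\theta) - 1)/\theta} with \eqn{D_1} the first Debye
#' function (computed by adaptive quadrature). Odd in \eqn{\theta}, zero at
#' independence, strictly increasing.
#'
#' @param theta dependence parameter(s); vectorized.
#' @return Kendall's tau in (-1, 1).
#' @examples
#' frankKendallTau(3)  # about 0.307
#' @export
frankKendallTau <- function(theta) {
  vapply(theta, function(th) {
    if (abs(th) < .THETA_EPS) return(th / 9)  # tau ~ theta/9 near 0
    s <- sign(th); a <- abs(th)
    s * (1 + 4 * (.debye1(a) - 1) / a)
  }, numeric(1))
}

#' Map Frank theta to Spearman's rho
#'
#' \eqn{\rho_s = 12\int_0^1\!\!\int_0^1 C(u,v;\theta)\,du\,dv - 3}, computed
#' by nested adaptive quadrature. Odd in \eqn{\theta}, zero at independence,
#' strictly increasing.
#'
#' @inheritParams frankKendallTau
#' @return Spearman's rho in (-1, 1).
#' @export
frankSpearmanRho <- function(theta) {
  vapply(theta, function(th) {
    if (abs(th) < .THETA_EPS) return(th / 6)  # rho_s ~ theta/6 near 0
    quad <- function(f, tol) tryCatch(
      stats::integrate(f, 0, 1, rel.tol = tol)$value,
      error = function(e) stats::integrate(f, 0, 1, rel.tol = 1e-7)$value)
    inner <- function(u) {
      vapply(u, function(uu)
        quad(function(v) frankCdf(uu, v, th), 1e-9), numeric(1))
    }
    12 * quad(inner, 1e-9) - 3
  }, numeric(1))
}
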