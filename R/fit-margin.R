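# Maximum-likelihood fitting of zero-inflated beta margins.
#
# The ZIB log-likelihood factorizes into a binomial part for the zero
# indicator and a beta part over the nonzero observations, so the two blocks
# are fitted separately: the zero part by (possibly covariate-adjusted)
# binary regression, the beta part by Newton-Raphson with analytic gradient.

.clampUnit <- function(x, warn = TRUE) {
  hi <- 1 - 1e-12
  if (any(x > hi)) {
    if (warn) warning("values above 1 - 1e-12 clamped to the open support [0, 1)")
    x[x > hi] <- hi
  }
  x
}

.insufficientData <- function(msg) {
  stop(structure(class = c("zibInsufficientData", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.convergenceError <- function(msg, lastIterate) {
  stop(structure(class = c("zibConvergenceError", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      lastIterate = lastIterate)))
}

# beta log-likelihood and derivatives in (mu, phi) on nonzero data,
# via sufficient statistics
.betaLL <- function(mu, phi, npos, slx, sl1x) {
  npos * (lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi)) +
    (mu * phi - 1) * slx + ((1 - mu) * phi - 1) * sl1x
}

.betaGrad <- function(mu, phi, npos, slx, sl1x) {
  a <- mu * phi; b <- (1 - mu) * phi
  c(mu = phi * (npos * (digamma(b) - digamma(a)) + slx - sl1x),
    phi = npos * (digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b)) +
      mu * slx + (1 - mu) * sl1x)
}

.betaHess <- function(mu, phi, npos, slx, sl1x) {
  a <- mu * phi; b <- (1 - mu) * phi
  hmm <- -npos * phi^2 * (trigamma(a) + trigamma(b))
  hmp <- npos * (digamma(b) - digamma(a)) -
    npos * phi * (mu * trigamma(a) - (1 - mu) * trigamma(b)) + slx - sl1x
  hpp <- npos * (trigamma(phi) - mu^2 * trigamma(a) -
                   (1 - mu)^2 * trigamma(b))
  matrix(c(hmm, hmp, hmp, hpp), 2L, 2L)
}

# Method-of-moments start for the beta part
.betaMoments <- function(y) {
  m <- mean(y)
  v <- stats::var(y)
  if (!is.finite(v) || v <= 0) v <- 1e-4
  phi0 <- m * (1 - m) / v - 1
  if (!is.finite(phi0) || phi0 <= 0.01) phi0 <- 0.01
  c(mu = min(max(m, 1e-4), 1 - 1e-4), phi = phi0)
}

# Newton-Raphson for the intercept-only beta part. Returns c(mu, phi).
.fitBetaIntercept <- function(y, start = NULL,
                              tolLL = 1e-10, tolGrad = 1e-8, maxit = 100L) {
  npos <- length(y)
  slx <- sum(log(y)); sl1x <- sum(log1p(-y))
  th <- if (is.null(start)) .betaMoments(y) else start
  ll <- .betaLL(th[1], th[2], npos, slx, sl1x)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    gr <- .betaGrad(th[1], th[2], npos, slx, sl1x)
    if (max(abs(gr)) <= tolGrad) { conv <- TRUE; break }
    H <- .betaHess(th[1], th[2], npos, slx, sl1x)
    step <- tryCatch(-solve(H, gr), error = function(e) NULL)
    # fall back to a scaled ascent step if the Hessian is not invertible
    # or does not give an ascent direction
    if (is.null(step) || sum(step * gr) <= 0) step <- gr / max(abs(gr), 1)
    ok <- FALSE
    for (h in 0:30) {
      cand <- th + step / 2^h
      if (cand[1] <= 1e-8 || cand[1] >= 1 - 1e-8 || cand[2] <= 1e-8) next
      llNew <- .betaLL(cand[1], cand[2], npos, slx, sl1x)
      if (is.finite(llNew) && llNew >= ll - 1e-14) {
        relImpr <- abs(llNew - ll) / (abs(ll) + 1e-10)
        th <- cand
        improved <- llNew > ll
        ll <- llNew
        ok <- TRUE
        if (relImpr <= tolLL && improved) conv <- TRUE
        break
      }
    }
    if (!ok) { conv <- TRUE; break }  # no uphill step exists: at the optimum
    if (conv) break
  }
  if (!conv) {
    # quasi-Newton rescue on the unconstrained scale
    opt <- stats::optim(c(stats::qlogis(th[1]), log(th[2])),
      fn = function(t) -.betaLL(stats::plogis(t[1]), exp(t[2]), npos, slx, sl1x),
      method = "BFGS", control = list(maxit = 200L))
    th <- c(stats::plogis(opt$par[1]), exp(opt$par[2]))
    conv <- opt$convergence == 0
  }
  list(par = unname(th),
       logLik = unname(.betaLL(th[[1]], th[[2]], npos, slx, sl1x)),
       converged = conv)
}

# covariate-adjusted beta part: eta_mu = W delta, eta_phi = Z kappa
.betaRegLL <- function(coefs, y, W, Z, linkMu, linkPhi) {
  w <- ncol(W)
  mu <- linkMu$linkinv(drop(W %*% coefs[seq_len(w)]))
  phi <- linkPhi$linkinv(drop(Z %*% coefs[-seq_len(w)]))
  if (any(mu <= 0 | mu >= 1 | phi <= 0)) return(-Inf)
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

.betaRegGrad <- function(coefs, y, W, Z, linkMu, linkPhi) {
  w <- ncol(W)
  etaMu <- drop(W %*% coefs[seq_len(w)])
  etaPhi <- drop(Z %*% coefs[-seq_len(w)])
  mu <- linkMu$linkinv(etaMu)
  phi <- linkPhi$linkinv(etaPhi)
  a <- mu * phi; b <- (1 - mu) * phi
  dldmu <- phi * (digamma(b) - digamma(a) + log(y) - log1p(-y))
  dldphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
    mu * log(y) + (1 - mu) * log1p(-y)
  c(drop(crossprod(W, dldmu * linkMu$mu.eta(etaMu))),
    drop(crossprod(Z, dldphi * linkPhi$mu.eta(etaPhi))))
}

.fitBetaRegression <- function(y, W, Z, linkMu, linkPhi, start = NULL,
                               tolLL = 1e-10, tolGrad = 1e-8, maxit = 100L) {
  d <- ncol(W) + ncol(Z)
  if (is.null(start)) {
    mom <- .betaMoments(y)
    start <- numeric(d)
    start[1L] <- linkMu$linkfun(mom[1])
    start[ncol(W) + 1L] <- linkPhi$linkfun(mom[2])
  }
  th <- start
  ll <- .betaRegLL(th, y, W, Z, linkMu, linkPhi)
  conv <- FALSE
  numHess <- function(t0) {
    h <- 1e-5 * pmax(abs(t0), 1)
    H <- matrix(0, d, d)
    for (k in seq_len(d)) {
      e <- numeric(d); e[k] <- h[k]
      H[, k] <- (.betaRegGrad(t0 + e, y, W, Z, linkMu, linkPhi) -
                 .betaRegGrad(t0 - e, y, W, Z, linkMu, linkPhi)) / (2 * h[k])
    }
    (H + t(H)) / 2
  }
  for (it in seq_len(maxit)) {
    gr <- .betaRegGrad(th, y, W, Z, linkMu, linkPhi)
    if (max(abs(gr)) <= tolGrad) { conv <- TRUE; break }
    H <- numHess(th)
    step <- tryCatch(-solve(H, gr), error = function(e) NULL)
    if (is.null(step) || sum(step * gr) <= 0) step <- gr / max(abs(gr), 1)
    ok <- FALSE
    for (h in 0:30) {
      cand <- th + step / 2^h
      llNew <- .betaRegLL(cand, y, W, Z, linkMu, linkPhi)
      if (is.finite(llNew) && llNew >= ll - 1e-14) {
        relImpr <- abs(llNew - ll) / (abs(ll) + 1e-10)
        improved <- llNew > ll
        th <- cand; ll <- llNew; ok <- TRUE
        if (relImpr <= tolLL && improved) conv <- TRUE
        break
      }
    }
    if (!ok) { conv <- TRUE; break }
    if (conv) break
  }
  if (!conv) {
    opt <- stats::optim(th, fn = function(t) -.betaRegLL(t, y, W, Z, linkMu, linkPhi),
                        gr = function(t) -.betaRegGrad(t, y, W, Z, linkMu, linkPhi),
                        method = "BFGS", control = list(maxit = 500L))
    if (opt$convergence == 0 && -opt$value >= ll) {
      th <- opt$par; ll <- -opt$value; conv <- TRUE
    }
  }
  list(par = th, logLik = ll, converged = conv)
}

# zero-part fit: binary regression of the zero indicator
.fitZeroPart <- function(isZero, Q, link, start = NULL) {
  n <- length(isZero)
  if (ncol(Q) == 1L && all(Q == 1)) {
    # closed-form binomial MLE p-hat = z / n
    z <- sum(isZero)
    pHat <- z / n
    pSafe <- min(max(pHat, 1e-12), 1 - 1e-12)
    rho <- stats::setNames(.unitLink(link)$linkfun(pSafe), "(Intercept)")
    ll <- if (z == 0) 0 else z * log(pHat) + (n - z) * log1p(-pHat)
    return(list(coef = rho, p = rep(pHat, n), logLik = ll, converged = TRUE))
  }
  fam <- stats::binomial(link = if (link == "loglog") .loglogLink() else link)
  fit <- suppressWarnings(stats::glm.fit(Q, as.numeric(isZero), family = fam,
                                         start = start))
  p <- fit$fitted.values
  pSafe <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(isZero * log(pSafe) + (1 - isZero) * log1p(-pSafe))
  list(coef = fit$coefficients, p = p, logLik = ll, converged = fit$converged)
}

#' Fit a zero-inflated beta margin
#'
#' Maximum-likelihood fit of the ZIB marginal model, optionally adjusting
#' the zero-inflation probability \eqn{p}, beta mean \eqn{\mu} and dispersion
#' \eqn{\phi} for covariates through generalized-linear-model links
#' \eqn{h_1(p) = Q\rho}, \eqn{h_2(\mu) = W\delta}, \eqn{h_3(\phi) = Z\kappa}.
#' The likelihood factorizes into a binary-regression part for the zero
#' indicator and a beta-regression part over the nonzero observations; the
#' two are fitted separately (the zero part via [stats::glm.fit()], the beta
#' part by safeguarded Newton--Raphson with step-halving and a quasi-Newton
#' fallback).
#'
#' Intercept-only fits reproduce the closed forms: \eqn{\hat p = z/n} with
#' \eqn{z} the number of exact zeros, and the univariate beta MLE on the
#' nonzero subset.
#'
#' @param x observations in \[0, 1). Values within 1e-12 of 1 are clamped
#'   into the open support with a warning.
#' @param designP,designMu,designPhi optional numeric design matrices (with
#'   intercept column) for the three parameters; `NULL` means intercept-only.
#' @param links named character vector with elements `p`, `mu` (one of
#'   `"logit"`, `"probit"`, `"loglog"`) and `phi` (`"log"` or `"sqrt"`).
#' @param control list of optimizer settings: `tolLL` (relative
#'   log-likelihood change, default 1e-10), `tolGrad` (gradient sup-norm,
#'   default 1e-8), `maxit` (default 100).
#' @param start optional warm-start list with components `rho`, `delta`,
#'   `kappa` on the link scale.
#' @return a [ZibMarginFit-class] object.
#' @examples
#' set.seed(1)
#' x <- rzib(200, p = 0.25, mu = 2/7, phi = 7)
#' fitZibMargin(x)
#' @export
fitZibMargin <- function(x, designP = NULL, designMu = NULL, designPhi = NULL,
                         links = c(p = "logit", mu = "logit", phi = "log"),
                         control = list(), start = NULL) {
  fit <- .fitMarginCore(x, designP, designMu, designPhi, links, control, start)
  new("ZibMarginFit",
      coefficients = fit$coef,
      gamma = fit$gamma,
      logLik = fit$logLik,
      nObs = length(x),
      nZero = fit$nZero,
      converged = fit$converged,
      links = fit$links,
      model = fit$designs)
}

# internal light-weight fit used by the two-stage machinery; returns a list
.fitMarginCore <- function(x, designP = NULL, designMu = NULL,
                           designPhi = NULL,
                           links = c(p = "logit", mu = "logit", phi = "log"),
                           control = list(), start = NULL) {
  links <- c(p = unname(links["p"]), mu = unname(links["mu"]),
             phi = unname(links["phi"]))
  links[is.na(links)] <- c(p = "logit", mu = "logit", phi = "log")[is.na(links)]
  ctl <- modifyList(list(tolLL = 1e-10, tolGrad = 1e-8, maxit = 100L), control)

  x <- .clampUnit(x)
  .checkSupport(x)
  n <- length(x)
  isZero <- x == 0
  nZero <- sum(isZero)
  if (n - nZero < 3L)
    .insufficientData(sprintf(
      "at least 3 nonzero observations are required to fit the margin (got %d)",
      n - nZero))

  one <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  Q <- if (is.null(designP)) one else as.matrix(designP)
  W <- if (is.null(designMu)) one else as.matrix(designMu)
  Z <- if (is.null(designPhi)) one else as.matrix(designPhi)
  if (nrow(Q) != n || nrow(W) != n || nrow(Z) != n)
    stop("design matrices must have one row per observation")

  ## zero part
  zp <- .fitZeroPart(isZero, Q, links["p"], start = start$rho)

  ## beta part on the nonzero subset
  y <- x[!isZero]
  interceptBeta <- ncol(W) == 1L && ncol(Z) == 1L &&
    all(W == 1) && all(Z == 1)
  linkMu <- .unitLink(links["mu"])
  linkPhi <- .posLink(links["phi"])
  if (interceptBeta) {
    st <- NULL
    if (!is.null(start$delta))
      st <- c(linkMu$linkinv(start$delta[1]), linkPhi$linkinv(start$kappa[1]))
    bf <- .fitBetaIntercept(y, start = st, tolLL = ctl$tolLL,
                            tolGrad = ctl$tolGrad, maxit = ctl$maxit)
    mu <- rep(bf$par[1], n); phi <- rep(bf$par[2], n)
    delta <- stats::setNames(linkMu$linkfun(bf$par[1]), "(Intercept)")
    kappa <- stats::setNames(linkPhi$linkfun(bf$par[2]), "(Intercept)")
  } else {
    st <- if (!is.null(start$delta)) c(start$delta, start$kappa) else NULL
    bf <- .fitBetaRegression(y, W[!isZero, , drop = FALSE],
                             Z[!isZero, , drop = FALSE], linkMu, linkPhi,
                             start = st, tolLL = ctl$tolLL,
                             tolGrad = ctl$tolGrad, maxit = ctl$maxit)
    delta <- stats::setNames(bf$par[seq_len(ncol(W))], colnames(W))
    kappa <- stats::setNames(bf$par[-seq_len(ncol(W))], colnames(Z))
    mu <- linkMu$linkinv(drop(W %*% delta))
    phi <- linkPhi$linkinv(drop(Z %*% kappa))
  }
  if (!zp$converged || !bf$converged)
    .convergenceError("margin fit did not converge",
                      list(rho = zp$coef, delta = delta, kappa = kappa))

  gamma <- cbind(p = zp$p, mu = mu, phi = phi)
  list(coef = list(rho = zp$coef, delta = delta, kappa = kappa),
       gamma = gamma,
       logLik = zp$logLik + bf$logLik,
       nZero = as.integer(nZero),
       converged = zp$converged && bf$converged,
       links = links,
       designs = list(designP = designP, designMu = designMu,
                      designPhi = designPhi))
}
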