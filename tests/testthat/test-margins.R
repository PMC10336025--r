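test_that("beta density in mean/dispersion form matches a quadrature-normalized oracle", {
  # uniform case: mu*phi = (1-mu)*phi = 1
  expect_equal(dbetaMuPhi(0.5, 0.5, 2), 1)
  expect_equal(dbetaMuPhi(0.3, 0.5, 2), 1)
  # brute-force oracle: normalize the kernel x^(a-1)(1-x)^(b-1) numerically
  mu <- 2 / 7; phi <- 7
  kernel <- function(x) x^(mu * phi - 1) * (1 - x)^((1 - mu) * phi - 1)
  nc <- integrate(kernel, 0, 1, rel.tol = 1e-12)$value
  expect_equal(dbetaMuPhi(0.5, mu, phi), kernel(0.5) / nc, tolerance = 1e-10)
  expect_error(dbetaMuPhi(0.5, mu = 1.2, phi = 7), "mu")
})

test_that("ZIB density, CDF and quantile agree with the mixture construction", {
  expect_equal(dzib(0, 0.3, 0.5, 2), 0.3)
  expect_equal(dzib(0.5, 0.3, 0.5, 2), 0.7)
  expect_equal(dzib(0, 0.0, 0.5, 2), 0.0)
  expect_error(dzib(1, 0.3, 0.5, 2), "0, 1")

  # jump of size p at the atom, left limit zero
  expect_equal(pzib(0, 0.4, 0.5, 2), 0.4)
  expect_equal(pzib(0, 0.4, 0.5, 2, leftLimit = TRUE), 0)
  expect_equal(pzib(0.5, 0.4, 0.5, 2), 0.4 + 0.6 * 0.5)
  expect_equal(pzib(0.5, 0.4, 0.5, 2, leftLimit = TRUE),
               pzib(0.5, 0.4, 0.5, 2))

  expect_equal(qzib(0.3, 0.4, 0.5, 2), 0)
  expect_equal(qzib(0.7, 0.4, 0.5, 2), 0.5)  # uniform-beta quantile of 0.5
  # round trip away from the atom
  u <- seq(0.45, 0.99, by = 0.02)
  expect_equal(pzib(qzib(u, 0.4, 0.5, 2), 0.4, 0.5, 2), u, tolerance = 1e-9)
})

test_that("ZIB density integrates to one and the CDF is a valid mixed CDF", {
  for (p in c(0, 0.2, 0.6)) for (mu in c(0.3, 0.5, 0.7)) for (phi in c(2, 7)) {
    total <- p + integrate(function(x) dzib(x, p, mu, phi), 0, 1,
                           rel.tol = 1e-10)$value - p  # continuous part only
    cont <- integrate(function(x) (1 - p) * dbetaMuPhi(x, mu, phi), 0, 1,
                      rel.tol = 1e-10)$value
    expect_equal(p + cont, 1, tolerance = 1e-8)
    x <- seq(0, 0.999, length.out = 101)
    Fx <- pzib(x, p, mu, phi)
    expect_true(all(diff(Fx) >= -1e-12))
    expect_equal(Fx[1] - pzib(0, p, mu, phi, leftLimit = TRUE), p)
  }
})

test_that("ZIB log-likelihood matches the closed form and the density sum", {
  expect_equal(zibLogLik(c(0, 0.5), 0.5, 0.5, 2), 2 * log(0.5))
  expect_equal(zibLogLik(0.5, 0.0, 0.5, 2), 0)
  set.seed(4)
  x <- rzib(200, 0.3, 0.4, 5)
  z <- sum(x == 0); n <- length(x); y <- x[x > 0]
  eq4 <- z * log(0.3) + (n - z) * log(0.7) +
    (n - z) * (lgamma(5) - lgamma(2) - lgamma(3)) +
    (0.4 * 5 - 1) * sum(log(y)) + (0.6 * 5 - 1) * sum(log(1 - y))
  expect_equal(zibLogLik(x, 0.3, 0.4, 5), eq4, tolerance = 1e-10)
  expect_equal(zibLogLik(x, 0.3, 0.4, 5), sum(dzib(x, 0.3, 0.4, 5, log = TRUE)),
               tolerance = 1e-10)
})

test_that("intercept-only fit reproduces the closed-form zero fraction and the beta MLE", {
  x <- c(rep(0, 20), rbeta(30, 2, 3))
  f <- fitZibMargin(x)
  expect_identical(unname(f@gamma[1, "p"]), 0.4)
  expect_identical(f@nZero, 20L)
  # p part and (mu, phi) part decouple: beta part matches a generic optimizer
  y <- x[x > 0]
  opt <- optim(c(0, 1), function(t) {
    mu <- plogis(t[1]); phi <- exp(t[2])
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(f@gamma[1, "mu"]), plogis(opt$par[1]), tolerance = 1e-6)
  expect_equal(unname(f@gamma[1, "phi"]), exp(opt$par[2]), tolerance = 1e-5)
  # the stored log-likelihood is the likelihood actually attained
  expect_equal(f@logLik, zibLogLik(x, f@gamma[1, 1], f@gamma[1, 2], f@gamma[1, 3]),
               tolerance = 1e-10)
})

test_that("parameter recovery at n = 2000 is within 3 standard errors", {
  set.seed(101)
  x <- rzib(2000, 0.25, 2 / 7, 7)
  f <- fitZibMargin(x)
  seP <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(unname(f@gamma[1, "p"]) - 0.25), 3 * seP)
  # SEs of (mu, phi) from the observed information at the truth
  y <- x[x > 0]
  H <- optimHess(c(2 / 7, 7), function(t)
    -sum(dbeta(y, t[1] * t[2], (1 - t[1]) * t[2], log = TRUE)))
  se <- sqrt(diag(solve(H)))
  expect_lt(abs(f@gamma[1, "mu"] - 2 / 7), 3 * se[1])
  expect_lt(abs(f@gamma[1, "phi"] - 7), 3 * se[2])
})

test_that("logistic zero-part regression recovers its coefficients", {
  set.seed(202)
  n <- 2000
  d <- simulateZibPairCovariate(n, theta = 0, rhoI = c(-0.5, 0.7))
  Q <- cbind("(Intercept)" = 1, q = d$qI)
  f <- fitZibMargin(d$xi, designP = Q)
  # oracle: the same GLM fitted directly, with its asymptotic SEs
  or <- glm((d$xi == 0) ~ d$qI, family = binomial())
  expect_equal(unname(f@coefficients$rho), unname(coef(or)), tolerance = 1e-6)
  se <- sqrt(diag(vcov(or)))
  expect_lt(abs(f@coefficients$rho[1] - (-0.5)), 3 * se[1])
  expect_lt(abs(f@coefficients$rho[2] - 0.7), 3 * se[2])
})

test_that("fitted log-likelihood dominates the truth on simulated data", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- rzib(60, 0.3, 0.4, 5)
    if (sum(x > 0) < 3) next
    f <- fitZibMargin(x)
    expect_gte(f@logLik, zibLogLik(x, 0.3, 0.4, 5) - 1e-8)
  }
})

test_that("covariate-adjusted beta regression matches a generic optimizer", {
  set.seed(33)
  n <- 300
  w <- rnorm(n)
  mu <- plogis(-0.3 + 0.5 * w); phi <- exp(1.2)
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  y <- pmin(pmax(y, 1e-10), 1 - 1e-10)
  W <- cbind(1, w)
  f <- fitZibMargin(y, designMu = W)
  opt <- optim(c(0, 0, 1), function(t) {
    m <- plogis(W %*% t[1:2]); ph <- exp(t[3])
    -sum(dbeta(y, m * ph, (1 - m) * ph, log = TRUE))
  }, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(f@coefficients$delta), opt$par[1:2], tolerance = 1e-4)
  expect_equal(unname(f@coefficients$kappa), opt$par[3], tolerance = 1e-4)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(fitZibMargin(c(0, 0, 0, 0.5, 0.4)), "3 nonzero",
               class = "zibInsufficientData")
  expect_warning(fitZibMargin(c(runif(30), 1)), "clamped")
})
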