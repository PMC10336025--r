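test_that("Frank CDF satisfies the copula boundary identities exactly", {
  for (th in c(-2.5, -1e-9, 1e-9, 2.4, 30)) {
    expect_identical(frankCdf(0.37, 1, th), 0.37)
    expect_identical(frankCdf(1, 0.42, th), 0.42)
    expect_identical(frankCdf(0, 0.8, th), 0)
    expect_identical(frankCdf(0.8, 0, th), 0)
  }
  expect_equal(frankCdf(0.5, 0.5, 0), 0.25)
  expect_equal(frankCdf(0.5, 0.5, 3), 0.3360887, tolerance = 1e-6)
})

test_that("Frank CDF respects the Frechet bounds, symmetry, and the independence limit", {
  grid <- seq(0.05, 0.95, by = 0.09)
  for (th in c(-30, -2.5, -0.5, 0.5, 3, 30)) {
    for (u in grid) {
      C <- frankCdf(u, grid, th)
      expect_true(all(C >= pmax(u + grid - 1, 0) - 1e-12))
      expect_true(all(C <= pmin(u, grid) + 1e-12))
      expect_equal(C, frankCdf(grid, u, th))  # exchangeable
    }
  }
  # continuity through the theta = 0 puncture: no catastrophic cancellation
  for (u in grid) for (v in grid) {
    expect_lt(abs(frankCdf(u, v, 1e-8) - u * v), 1e-7)
    expect_lt(abs(frankCdf(u, v, -1e-8) - u * v), 1e-7)
  }
})

test_that("Frank density is the mixed partial of the CDF and a proper density", {
  # finite-difference oracle for d2C/dudv
  fdPdf <- function(u, v, th, h = 1e-5) {
    (frankCdf(u + h, v + h, th) - frankCdf(u + h, v - h, th) -
       frankCdf(u - h, v + h, th) + frankCdf(u - h, v - h, th)) / (4 * h^2)
  }
  expect_equal(frankPdf(0.5, 0.5, 3), fdPdf(0.5, 0.5, 3), tolerance = 1e-6)
  expect_equal(frankPdf(0.2, 0.7, -2.5), fdPdf(0.2, 0.7, -2.5), tolerance = 1e-6)
  expect_equal(frankPdf(0.31, 0.62, 0), 1)
  # radial symmetry c(u, v) = c(1-u, 1-v)
  expect_equal(frankPdf(0.2, 0.7, 3), frankPdf(0.8, 0.3, 3), tolerance = 1e-12)
  # integrates to 1
  for (th in c(-2.5, 3)) {
    total <- integrate(function(u) vapply(u, function(uu)
      integrate(function(v) frankPdf(uu, v, th), 0 + 1e-10, 1 - 1e-10,
                rel.tol = 1e-10)$value, numeric(1)),
      1e-10, 1 - 1e-10, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  expect_error(frankPdf(0, 0.5, 3), "strictly inside")
})

test_that("conditional CDF is dC/du, monotone from 0 to 1, with closed-form inverse", {
  fdCond <- function(u, v, th, h = 1e-6)
    (frankCdf(u + h, v, th) - frankCdf(u - h, v, th)) / (2 * h)
  expect_equal(frankCondCdf(0.3, 0.6, 1.5), fdCond(0.3, 0.6, 1.5),
               tolerance = 1e-6)
  expect_equal(frankCondCdf(0.5, 0.5, 3), 0.5, tolerance = 1e-12)
  expect_equal(frankCondCdf(0.2, 1, -1), 1)
  expect_equal(frankCondCdf(0.2, 0, -1), 0)
  v <- seq(0.02, 0.98, by = 0.02)
  for (th in c(-8, -0.3, 2, 25)) {
    cc <- frankCondCdf(0.37, v, th)
    expect_true(all(diff(cc) > 0))
    # round-trip through the inverse
    b <- seq(0.05, 0.95, by = 0.05)
    for (u in c(0.1, 0.5, 0.9)) {
      vv <- frankCondQuantile(b, u, th)
      expect_equal(frankCondCdf(u, vv, th), b, tolerance = 1e-10)
    }
  }
  expect_equal(frankCondQuantile(0.73, 0.21, -2.5) |>
                 frankCondCdf(u = 0.21, theta = -2.5), 0.73, tolerance = 1e-10)
  expect_equal(frankCondQuantile(0.4, 0.9, 0), 0.4)
  expect_equal(frankCondCdf(0.9, 0.4, 0), 0.4)
})

test_that("theta maps to Kendall tau and Spearman rho per the copula identities", {
  expect_identical(frankKendallTau(0), 0)
  expect_equal(frankKendallTau(3), 0.3072467, tolerance = 1e-6)
  # independent oracle: tau = 4 int int C(u,v) c(u,v) du dv - 1
  tauOracle <- function(th) {
    4 * integrate(function(u) vapply(u, function(uu)
      integrate(function(v) frankCdf(uu, v, th) * frankPdf(uu, v, th),
                1e-10, 1 - 1e-10, rel.tol = 1e-11)$value, numeric(1)),
      1e-10, 1 - 1e-10, rel.tol = 1e-11)$value - 1
  }
  for (th in c(-2.5, 1.5, 3))
    expect_equal(frankKendallTau(th), tauOracle(th), tolerance = 1e-6)
  # independent closed form via Debye functions:
  # rho_s = 1 - (12/theta)(D1(theta) - D2(theta))
  Dk <- function(k, th) k / th^k *
    integrate(function(t) t^k / expm1(t), 0, th, rel.tol = 1e-12)$value
  rhoOracle <- function(th) 1 - 12 / th * (Dk(1, th) - Dk(2, th))
  expect_equal(frankSpearmanRho(3), rhoOracle(3), tolerance = 1e-6)
  expect_equal(frankSpearmanRho(3), 0.4487, tolerance = 1e-3)
  # odd functions, strictly increasing, sign-matching theta
  th <- seq(-30, 30, by = 3)
  tau <- frankKendallTau(th); rho <- frankSpearmanRho(th)
  expect_equal(tau, -rev(tau), tolerance = 1e-9)
  expect_equal(rho, -rev(rho), tolerance = 1e-6)
  expect_true(all(diff(tau) > 0))
  expect_true(all(diff(rho) > 0))
  expect_equal(sign(tau[th != 0]), sign(th[th != 0]))
})
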