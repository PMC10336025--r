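test_that("Rosenblatt sampling reproduces the marginal and dependence structure", {
  n <- 10000
  d0 <- simulateZibPair(n, 0, GAMMA_I, GAMMA_J, seed = 1)
  # independence: Spearman correlation near zero (MC SE ~ 1/sqrt(n))
  expect_lt(abs(cor(d0$xi, d0$xj, method = "spearman")), 2 / sqrt(n))
  # marginal zero fractions
  expect_lt(abs(mean(d0$xi == 0) - GAMMA_I["p"]),
            2 * sqrt(GAMMA_I["p"] * (1 - GAMMA_I["p"]) / n))
  expect_lt(abs(mean(d0$xj == 0) - GAMMA_J["p"]),
            2 * sqrt(GAMMA_J["p"] * (1 - GAMMA_J["p"]) / n))
  # dependence: with no zero inflation, Kendall tau matches the Debye map
  d3 <- simulateZibPair(4000, 3, c(0, 2 / 7, 7), c(0, 5 / 7, 7), seed = 2)
  tauSE <- sqrt(2 * (2 * 4000 + 5) / (9 * 4000 * 3999))
  expect_lt(abs(cor(d3$xi, d3$xj, method = "kendall") - frankKendallTau(3)),
            2 * tauSE)
})

test_that("whole-dataset redo rules enforce usable zero patterns", {
  d <- simulateZibPair(8, 0, c(0.6, 0.5, 4), c(0.75, 0.5, 4), seed = 3)
  expect_gte(sum(d$xi > 0), 3)
  expect_gte(sum(d$xj > 0), 3)
  expect_gte(sum(d$xi > 0 & d$xj > 0), 2)
  expect_gte(d$attempts, 1)
  # an impossible configuration exhausts the redo budget
  expect_error(
    simulateZibPair(4, 0, c(0.9, 0.5, 4), c(0.9, 0.5, 4), seed = 4,
                    redoLimit = 5),
    "degenerate", class = "zibSimulationDegenerate")
})

test_that("covariate-adjusted sampling matches its logistic zero model", {
  n <- 10000
  d <- simulateZibPairCovariate(n, theta = 0, rhoI = c(-0.5, 0.7), seed = 5)
  # Gauss-Hermite style oracle for E[plogis(-0.5 + 0.7 Z)]
  target <- integrate(function(z) plogis(-0.5 + 0.7 * z) * dnorm(z),
                      -Inf, Inf, rel.tol = 1e-10)$value
  expect_lt(abs(mean(d$xi == 0) - target), 2 * sqrt(target * (1 - target) / n))
  # per-sample p follows the regression exactly
  expect_equal(d$pI, plogis(-0.5 + 0.7 * d$qI))
  # zero slope reduces to the constant-p sampler
  dFlat <- simulateZibPairCovariate(200, 0, rhoI = c(-0.5, 0), rhoJ = c(-0.3, 0),
                                    seed = 6)
  expect_equal(unique(round(dFlat$pI, 12)), round(plogis(-0.5), 12))
  # covariate stream is reproducible under a fixed seed
  d2 <- simulateZibPairCovariate(n, theta = 0, rhoI = c(-0.5, 0.7), seed = 5)
  expect_identical(d$qI, d2$qI); expect_identical(d$xi, d2$xi)
})

test_that("Gaussian-copula sampling honors its closed-form rank correlation", {
  n <- 10000
  d <- simulateGaussianPair(n, 0.8, c(0, 0.4, 5), c(0, 0.6, 4), seed = 7)
  target <- (6 / pi) * asin(0.8 / 2)
  expect_lt(abs(cor(d$xi, d$xj, method = "spearman") - target), 2.5 / sqrt(n))
  d0 <- simulateGaussianPair(n, 0, GAMMA_I, GAMMA_J, seed = 8)
  expect_lt(abs(cor(d0$xi, d0$xj, method = "spearman")), 2 / sqrt(n))
  expect_lt(abs(mean(d0$xi == 0) - GAMMA_I["p"]),
            2 * sqrt(GAMMA_I["p"] * (1 - GAMMA_I["p"]) / n))
})

test_that("multivariate tables are unit-sum with correct truth labels", {
  sim <- simulateAbundanceTable(12, 60, dependency = NULL, seed = 9)
  expect_false(any(sim$truth$dependent))
  dep <- blockDependency(12, c(4, 3), 0.6)
  expect_identical(nrow(dep), 6L + 3L)
  sim2 <- simulateAbundanceTable(12, 60, dep, seed = 10)
  rs <- rowSums(sim2$table)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  expect_identical(sum(sim2$truth$dependent), nrow(dep))
  # determinism
  sim3 <- simulateAbundanceTable(12, 60, dep, seed = 10)
  expect_identical(sim2$table, sim3$table)
  # a non-PD request is repaired with a warning
  badDep <- data.frame(a = c(1, 2, 1), b = c(2, 3, 3), rho = c(0.9, 0.9, -0.9))
  expect_warning(simulateAbundanceTable(5, 50, badDep, seed = 11),
                 "positive definite")
})

test_that("the estimator recovers every theta on the benchmark grid", {
  # 24 cells: theta x zero-inflation grids; per-cell 2-MC-SE bands at 100
  # replicates, allowing the expected number of marginal exceedances for
  # simultaneous coverage
  thetas <- c(-2.5, -1, 0, 0.5, 1.5, 3)
  zeroSettings <- list(c(0.10, 0.25), c(0.40, 0.50), c(0.60, 0.75), c(0.20, 0.75))
  misses <- 0L
  set.seed(600)
  for (ps in zeroSettings) for (th in thetas) {
    est <- replicate(100, fitTheta(
      simulateZibPair(50, th, c(ps[1], 2 / 7, 7), c(ps[2], 5 / 7, 7))))
    if (abs(mean(est) - th) > 2 * mcSE(est)) misses <- misses + 1L
  }
  # ~5% of 24 independent 2-SE bands may miss by chance
  expect_lte(misses, 3L)
})
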