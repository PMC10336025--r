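test_that("all unordered pairs are enumerated and the edge set equals the BY rejections", {
  sim <- simulateAbundanceTable(3, 60, seed = 1)
  net <- covariationNetwork(sim$table, q = 0.05)
  expect_identical(nrow(net@pairs), 3L)
  # un-normalized table: closure would induce real (if weak) dependence
  # among the nominally null pairs, which n = 500 is powerful enough to see
  sim10 <- simulateAbundanceTable(10, 500, blockDependency(10, c(4, 3), 0.8),
                                  normalize = FALSE, seed = 2)
  net10 <- covariationNetwork(sim10$table, q = 0.01)
  tab <- edgeTable(net10, allPairs = TRUE)
  # strong dependence, large n: every true pair ranks above every null pair
  truth <- sim10$truth$dependent
  expect_lt(max(tab$pValue[truth]), min(tab$pValue[!truth]))
  # the stored edge set is exactly the BY rejection set on the raw p-values
  redo <- byFdr(tab$pValue, q = 0.01)
  expect_setequal(which(tab$significant), redo$rejected)
  expect_equal(sum(adjacencyMatrix(net10)) / 2, length(redo$rejected))
})

test_that("permuting taxon columns permutes all outputs consistently", {
  sim <- simulateAbundanceTable(6, 120, blockDependency(6, 3, 0.7), seed = 3)
  net <- covariationNetwork(sim$table, q = 0.05)
  perm <- c(4, 1, 6, 2, 5, 3)
  netP <- covariationNetwork(sim$table[, perm], q = 0.05)
  # swapping the roles of the two margins is analytically neutral but the
  # one-dimensional optimizer stops within its tolerance
  expect_equal(netP@thetaMatrix, net@thetaMatrix[perm, perm], tolerance = 1e-5)
  expect_identical(netP@adjacency, net@adjacency[perm, perm])
  # clustering is invariant to input order up to label permutation
  clA <- clusterAssignments(clusterNetwork(net, k = 2))
  clB <- clusterAssignments(clusterNetwork(netP, k = 2))
  tabAB <- table(clA[net@taxa], clB[net@taxa])
  expect_true(all(rowSums(tabAB > 0) == 1))  # one-to-one correspondence
})

test_that("clustering recovers planted blocks and degenerates deterministically", {
  # two perfectly separated positive-theta blocks
  m <- 6
  theta <- matrix(0, m, m)
  theta[1:3, 1:3] <- 2; theta[4:6, 4:6] <- 3; diag(theta) <- 0
  adj <- theta > 0
  net <- networkFromAdjacency(adj, theta)
  cl <- clusterAssignments(clusterNetwork(net, k = 2))
  expect_identical(length(unique(cl[1:3])), 1L)
  expect_identical(length(unique(cl[4:6])), 1L)
  expect_false(cl[1] == cl[4])
  # edgeless network: single-cluster warning, deterministic assignment
  net0 <- networkFromAdjacency(matrix(FALSE, 4, 4))
  expect_warning(cl0 <- clusterAssignments(clusterNetwork(net0, k = 2)),
                 "single cluster")
  expect_warning(cl0b <- clusterAssignments(clusterNetwork(net0, k = 2)))
  expect_identical(cl0, cl0b)
})

test_that("graph summaries match hand computations on canonical graphs", {
  # complete graph on 4 nodes
  K4 <- matrix(TRUE, 4, 4); diag(K4) <- FALSE
  gs <- graphSummaries(networkFromAdjacency(K4))
  expect_equal(gs$perNode$degree, rep(1, 4))
  expect_equal(gs$global$edgeDensity, 1)
  expect_equal(gs$global$diameter, 1)
  # path graph 1-2-3-4: normalized betweenness and closeness by brute force
  P4 <- matrix(FALSE, 4, 4)
  P4[cbind(1:3, 2:4)] <- TRUE; P4 <- P4 | t(P4)
  gsP <- graphSummaries(networkFromAdjacency(P4))
  # distances: node1 (1+2+3), node2 (1+1+2)
  expect_equal(gsP$perNode$closeness, c(3 / 6, 3 / 4, 3 / 4, 3 / 6))
  # interior nodes lie on 2 of the 3 shortest paths among the others
  expect_equal(gsP$perNode$betweenness, c(0, 2 / 3, 2 / 3, 0))
  expect_equal(gsP$global$diameter, 3)
  # empty graph: density zero, no diameter, flagged as disconnected
  gs0 <- graphSummaries(networkFromAdjacency(matrix(FALSE, 4, 4)))
  expect_equal(gs0$global$edgeDensity, 0)
  expect_true(is.na(gs0$global$diameter))
  expect_true(gs0$global$disconnected)
})

test_that("Erdos-Renyi nulls are self-calibrated and match ER theory", {
  # a large-ish sparse ER graph: average clustering ~ density
  set.seed(20)
  g <- igraph::sample_gnm(60, 180)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  er <- erNullComparison(networkFromAdjacency(adj), nGraphs = 60, seed = 21)
  dens <- 180 / choose(60, 2)
  expect_lt(abs(mean(er$nullClustering) - dens), 0.03)
  # determinism of the ensemble
  er2 <- erNullComparison(networkFromAdjacency(adj), nGraphs = 60, seed = 21)
  expect_identical(er$nullClustering, er2$nullClustering)
  # self-calibration: an observed graph drawn from G(m, M) gives roughly
  # uniform upper-tail p-values across seeds
  set.seed(22)
  pU <- replicate(40, {
    gObs <- igraph::sample_gnm(25, 50)
    aObs <- igraph::as_adjacency_matrix(gObs, sparse = FALSE) > 0
    erNullComparison(networkFromAdjacency(aObs), nGraphs = 79)$pClustering["upper"]
  })
  expect_gt(suppressWarnings(ks.test(pU, "punif"))$p.value, 0.01)
})

test_that("a genuinely modular network exceeds its ER null modularity", {
  # normalization is off: compositional closure would add weak cross-block
  # dependence and blur the planted modular structure this test relies on
  sim <- simulateAbundanceTable(12, 300, blockDependency(12, c(4, 4, 4), 0.8),
                                normalize = FALSE, seed = 23)
  net <- clusterNetwork(covariationNetwork(sim$table, q = 0.01), k = 3)
  er <- erNullComparison(net, nGraphs = 200, seed = 24)
  expect_gt(er$observed$modularity, quantile(er$nullModularity, 0.99))
})

test_that("bootstrap consistency reports correct set similarity", {
  # overlap and Dice against brute-force set arithmetic on |A|=4, |B|=5,
  # |A intersect B|=3, plus the identical/disjoint degenerate cases
  setStats <- function(A, B) {
    inter <- length(intersect(A, B))
    c(overlap = if (min(length(A), length(B)) == 0) 0 else
        inter / min(length(A), length(B)),
      dice = if (length(A) + length(B) == 0) 0 else
        2 * inter / (length(A) + length(B)))
  }
  A <- c("a|b", "a|c", "b|c", "c|d"); B <- c("a|b", "a|c", "b|c", "d|e", "e|f")
  expect_equal(unname(setStats(A, B)), c(0.75, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(setStats(A, A)), c(1, 1))
  expect_equal(unname(setStats(A, c("x|y"))), c(0, 0))
  # a strong-signal table is highly reproducible under resampling
  sim <- simulateAbundanceTable(8, 300, blockDependency(8, c(4, 3), 0.8),
                                seed = 25)
  net <- covariationNetwork(sim$table, q = 0.01)
  bc <- bootstrapConsistency(sim$table, q = 0.01, nBoot = 8, seed = 26,
                             network = net)
  expect_true(all(bc$overlap >= 0 & bc$overlap <= 1, na.rm = TRUE))
  expect_true(all(bc$dice <= bc$overlap + 1e-12, na.rm = TRUE))
  expect_gt(bc$meanOverlap, 0.8)
  # selection frequencies cover the persistent block edges
  expect_true(all(bc$selectionFrequency$frequency <= 1 + 1e-12))
  expect_identical(bc$nSkipped, 0L)
})
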