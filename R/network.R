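# All-pairs covariation analysis and network construction: two-stage fits
# and likelihood-ratio tests for every unordered taxon pair, BY FDR edge
# calls, hierarchical clustering, graph summaries, Erdos-Renyi null
# comparison and bootstrap consistency.

#' All-pairs copula dependence analysis of an abundance table
#'
#' Runs the two-stage Frank-copula fit and likelihood-ratio test for
#' independence on every unordered pair of taxa, applies Benjamini--Yekutieli
#' FDR control across the tested pairs, and assembles the
#' \eqn{\tilde\theta}-weighted covariation network. Each margin is fitted
#' once and reused across all pairs involving that taxon (the stage-1
#' problems are identical). Pairs that fail the fit preconditions (too few
#' nonzero or jointly nonzero observations) are recorded with a reason code
#' and excluded from FDR control.
#'
#' @param table samples-by-taxa numeric matrix of relative abundances in
#'   \[0, 1) with taxon column names.
#' @param model optional marginal model specification (a list with
#'   `designP`, `designMu`, `designPhi`, `links`, as in [fitZibMargin()])
#'   applied to every margin.
#' @param q FDR level for the edge calls (default 0.01).
#' @param verbose logical; report progress every 500 pairs.
#' @return a [CovariationNetwork-class] object.
#' @examples
#' sim <- simulateAbundanceTable(6, 80, blockDependency(6, 3, 0.7), seed = 2)
#' net <- covariationNetwork(sim$table, q = 0.05)
#' @export
covariationNetwork <- function(table, model = list(), q = 0.01,
                               verbose = FALSE) {
  table <- .clampUnit(as.matrix(table))
  m <- ncol(table)
  if (m < 3L) stop("at least 3 taxa are required")
  taxa <- colnames(table)
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_len(m))

  margins <- vector("list", m)
  marginStatus <- character(m)
  for (k in seq_len(m)) {
    margins[[k]] <- tryCatch(
      do.call(.fitMarginCore, c(list(x = table[, k]), model)),
      zibInsufficientData = function(e) conditionMessage(e),
      zibConvergenceError = function(e) conditionMessage(e))
    marginStatus[k] <- if (is.list(margins[[k]])) "ok" else margins[[k]]
  }

  cmb <- utils::combn(m, 2L)
  nPair <- ncol(cmb)
  theta <- pRaw <- rep(NA_real_, nPair)
  status <- character(nPair)
  for (pr in seq_len(nPair)) {
    i <- cmb[1, pr]; j <- cmb[2, pr]
    if (!is.list(margins[[i]]) || !is.list(margins[[j]])) {
      status[pr] <- "margin_unfittable"
      next
    }
    xi <- table[, i]; xj <- table[, j]
    res <- tryCatch({
      .checkPairPreconditions(xi, xj)
      pd <- .profileData(xi, xj, margins[[i]]$gamma, margins[[j]]$gamma)
      st2 <- .optimizeTheta(pd)
      lambda <- max(-2 * (st2$llNull - st2$llMax), 0)
      list(theta = st2$theta,
           p = stats::pchisq(lambda, 1, lower.tail = FALSE),
           status = if (st2$boundary) "boundary" else "ok")
    }, zibInsufficientData = function(e) conditionMessage(e))
    if (is.list(res)) {
      theta[pr] <- res$theta; pRaw[pr] <- res$p; status[pr] <- res$status
    } else {
      status[pr] <- res
    }
    if (verbose && pr %% 500L == 0L)
      message(sprintf("  tested %d / %d pairs", pr, nPair))
  }

  fdr <- byFdr(pRaw, q = q)
  significant <- ifelse(is.na(pRaw), NA, seq_len(nPair) %in% fdr$rejected)

  mkMat <- function(vals, fill = NA_real_) {
    M <- matrix(fill, m, m, dimnames = list(taxa, taxa))
    M[t(cmb)] <- vals
    M[t(cmb)[, 2:1, drop = FALSE]] <- vals
    M
  }
  thetaMat <- mkMat(theta); thetaMat[is.na(thetaMat)] <- 0; diag(thetaMat) <- 0
  adj <- mkMat(ifelse(is.na(significant), FALSE, significant), fill = FALSE)
  diag(adj) <- FALSE
  storage.mode(adj) <- "logical"

  pairs <- data.frame(
    taxonA = taxa[cmb[1, ]], taxonB = taxa[cmb[2, ]],
    theta = theta, pValue = pRaw, pAdjusted = fdr$adjusted,
    significant = significant, status = status,
    stringsAsFactors = FALSE)

  pm <- mkMat(pRaw); diag(pm) <- NA_real_
  pam <- mkMat(fdr$adjusted); diag(pam) <- NA_real_
  new("CovariationNetwork",
      taxa = taxa, thetaMatrix = thetaMat, pMatrix = pm, pAdjMatrix = pam,
      adjacency = adj, q = q, pairs = pairs,
      clusters = integer(0), summaries = list())
}

# dissimilarity used for hierarchical clustering of the weighted adjacency:
# significant pairs at 1 - |theta| / max |theta|, everything else at 1
.networkDissimilarity <- function(thetaMat, adjacency) {
  m <- nrow(thetaMat)
  W <- abs(thetaMat) * adjacency
  mx <- max(W)
  D <- matrix(1, m, m, dimnames = dimnames(thetaMat))
  if (mx > 0) D[adjacency] <- 1 - W[adjacency] / mx
  diag(D) <- 0
  D
}

#' Cluster the taxa of a covariation network
#'
#' Complete-linkage agglomerative hierarchical clustering of the taxa on a
#' dissimilarity derived from the \eqn{\tilde\theta}-weighted adjacency
#' (\eqn{d_{ij} = 1 - |\tilde\theta_{ij}| / \max|\tilde\theta|} for
#' significant pairs, 1 otherwise), with cluster membership obtained by
#' cutting the dendrogram into `k` groups.
#'
#' @param network a [CovariationNetwork-class] object.
#' @param k number of clusters to cut the dendrogram into (default 3).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return the network with the `clusters` slot filled (named integer
#'   vector); the dendrogram is attached as `attr(clusterAssignments(x),
#'   "hclust")`.
#' @export
clusterNetwork <- function(network, k = 3, linkage = "complete") {
  m <- length(network@taxa)
  if (m < 2L) stop("clustering requires at least 2 nodes")
  D <- .networkDissimilarity(network@thetaMatrix, network@adjacency)
  off <- D[upper.tri(D)]
  if (length(unique(round(off, 12))) == 1L && sum(network@adjacency) == 0) {
    warning("all dissimilarities equal (no significant edges); single cluster")
  }
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  k <- min(k, m)
  cl <- stats::cutree(hc, k = k)
  names(cl) <- network@taxa
  attr(cl, "hclust") <- hc
  network@clusters <- cl
  network
}

.networkGraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network@adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Node and global summaries of a covariation network
#'
#' Per-node normalized degree (degree / (m - 1)), closeness, betweenness
#' and eigenvector centrality, with across-node means and SDs; global edge
#' density, diameter, mean distance, average (local) clustering coefficient,
#' and the modularity of the stored cluster assignment, when present. On a
#' disconnected graph, diameter and mean distance are computed on the
#' largest connected component and flagged.
#'
#' @param network a [CovariationNetwork-class] object.
#' @return list with `perNode` (data.frame) and `global` (list).
#' @export
graphSummaries <- function(network) {
  g <- .networkGraph(network)
  m <- igraph::vcount(g)
  hasEdges <- igraph::ecount(g) > 0
  perNode <- data.frame(
    taxon = network@taxa,
    degree = igraph::degree(g) / (m - 1),
    closeness = if (hasEdges)
      suppressWarnings(igraph::closeness(g, normalized = TRUE)) else
        rep(NA_real_, m),
    betweenness = igraph::betweenness(g, normalized = TRUE),
    eigenvector = if (hasEdges) igraph::eigen_centrality(g)$vector else
      rep(0, m),
    stringsAsFactors = FALSE)

  comps <- igraph::components(g)
  disconnected <- comps$no > 1L
  gLargest <- if (disconnected) {
    igraph::induced_subgraph(g, which(comps$membership ==
                                        which.max(comps$csize)))
  } else g
  global <- list(
    edgeDensity = igraph::edge_density(g),
    diameter = if (hasEdges) igraph::diameter(gLargest) else NA_real_,
    meanDistance = if (hasEdges) igraph::mean_distance(gLargest) else NA_real_,
    avgClustering = igraph::transitivity(g, type = "localaverage",
                                         isolates = "zero"),
    modularity = if (length(network@clusters))
      igraph::modularity(g, membership = network@clusters) else NA_real_,
    disconnected = disconnected,
    summary = vapply(c("degree", "closeness", "betweenness", "eigenvector"),
                     function(cn) c(mean = mean(perNode[[cn]], na.rm = TRUE),
                                    sd = stats::sd(perNode[[cn]], na.rm = TRUE)),
                     numeric(2)))
  if (!hasEdges) global$avgClustering <- NA_real_
  list(perNode = perNode, global = global)
}

# modularity of a graph under the network's clustering recipe: complete
# linkage on 1 - A, cut into k groups
.graphModularity <- function(g, k) {
  m <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  D <- 1 - A
  diag(D) <- 0
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "complete"),
                      k = min(k, m))
  igraph::modularity(g, membership = cl)
}

#' Erdos-Renyi null comparison for a covariation network
#'
#' Simulates `nGraphs` random graphs from the \eqn{G(m, M)} model with the
#' same node and edge counts as the observed network and compares its
#' average clustering coefficient, modularity (computed by the same
#' complete-linkage clustering recipe on every null graph) and cumulative
#' degree distribution against the null ensemble. Empirical p-values are
#' tail fractions of the null ensemble at least as extreme as the observed
#' value (with the +1 correction).
#'
#' @param network a [CovariationNetwork-class] object (ideally after
#'   [clusterNetwork()], so that observed modularity uses its own
#'   assignment).
#' @param nGraphs number of null graphs (default 1000).
#' @param seed optional integer seed.
#' @return list with observed values, null distributions (`nullClustering`,
#'   `nullModularity`, `nullDegrees`), and upper/lower-tail empirical
#'   p-values for clustering and modularity.
#' @export
erNullComparison <- function(network, nGraphs = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- .networkGraph(network)
  m <- igraph::vcount(g)
  M <- igraph::ecount(g)
  k <- if (length(network@clusters)) max(network@clusters) else 3L
  obsCC <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  obsMod <- if (length(network@clusters))
    igraph::modularity(g, membership = network@clusters) else
      .graphModularity(g, k)

  nullCC <- nullMod <- numeric(nGraphs)
  nullDeg <- matrix(0L, nGraphs, m)
  for (b in seq_len(nGraphs)) {
    gb <- igraph::sample_gnm(m, M)
    nullCC[b] <- igraph::transitivity(gb, type = "localaverage",
                                      isolates = "zero")
    nullMod[b] <- .graphModularity(gb, k)
    nullDeg[b, ] <- sort(igraph::degree(gb))
  }
  pTail <- function(null, obs) c(
    upper = (1 + sum(null >= obs)) / (nGraphs + 1),
    lower = (1 + sum(null <= obs)) / (nGraphs + 1))
  list(observed = list(clustering = obsCC, modularity = obsMod,
                       degrees = sort(igraph::degree(g))),
       nullClustering = nullCC, nullModularity = nullMod,
       nullDegrees = nullDeg,
       pClustering = pTail(nullCC, obsCC),
       pModularity = pTail(nullMod, obsMod))
}

.edgeKeys <- function(network) {
  tab <- edgeTable(network)
  if (nrow(tab) == 0L) return(character(0))
  paste(pmin(tab$taxonA, tab$taxonB), pmax(tab$taxonA, tab$taxonB), sep = "|")
}

#' Bootstrap consistency of the identified edge set
#'
#' Resamples the rows (samples) of the abundance table with replacement
#' `nBoot` times, reruns the all-pairs analysis with BY control at level
#' `q`, and compares each bootstrap edge set \eqn{B} with the original set
#' \eqn{A} via the overlap coefficient \eqn{|A \cap B| / \min(|A|, |B|)}
#' and the Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)}. Also reports
#' each pair's selection frequency across bootstraps. Replicates on which
#' the analysis degenerates are skipped and counted.
#'
#' @inheritParams covariationNetwork
#' @param nBoot number of bootstrap resamples (default 50).
#' @param seed optional integer seed.
#' @param network optional pre-computed original-network
#'   [CovariationNetwork-class] (avoids recomputation).
#' @return list with `overlap` and `dice` (per-bootstrap vectors), their
#'   means, `selectionFrequency` (data.frame over pairs), `edgeCounts`
#'   (edges per bootstrap) and `nSkipped`.
#' @export
bootstrapConsistency <- function(table, model = list(), q = 0.01,
                                 nBoot = 50L, seed = NULL, network = NULL) {
  if (!is.null(seed)) set.seed(seed)
  table <- as.matrix(table)
  if (is.null(network)) network <- covariationNetwork(table, model, q)
  orig <- .edgeKeys(network)

  setStats <- function(A, B) {
    inter <- length(intersect(A, B))
    c(overlap = if (min(length(A), length(B)) == 0) 0 else
        inter / min(length(A), length(B)),
      dice = if (length(A) + length(B) == 0) 0 else
        2 * inter / (length(A) + length(B)))
  }
  subModel <- function(model, idx) {
    for (nm in c("designP", "designMu", "designPhi"))
      if (!is.null(model[[nm]]))
        model[[nm]] <- as.matrix(model[[nm]])[idx, , drop = FALSE]
    model
  }

  overlap <- dice <- edgeCounts <- rep(NA_real_, nBoot)
  freq <- integer(0)
  nSkipped <- 0L
  for (b in seq_len(nBoot)) {
    idx <- sample.int(nrow(table), replace = TRUE)
    netB <- tryCatch(
      suppressWarnings(covariationNetwork(table[idx, , drop = FALSE],
                                          subModel(model, idx), q)),
      error = function(e) NULL)
    if (is.null(netB)) { nSkipped <- nSkipped + 1L; next }
    keysB <- .edgeKeys(netB)
    st <- setStats(orig, keysB)
    overlap[b] <- st["overlap"]; dice[b] <- st["dice"]
    edgeCounts[b] <- length(keysB)
    freq <- c(freq, keysB)
  }
  freqTab <- as.data.frame(table(factor(freq)), stringsAsFactors = FALSE)
  names(freqTab) <- c("pair", "count")
  freqTab$frequency <- freqTab$count / sum(!is.na(overlap))
  list(overlap = overlap, dice = dice,
       meanOverlap = mean(overlap, na.rm = TRUE),
       meanDice = mean(dice, na.rm = TRUE),
       selectionFrequency = freqTab,
       edgeCounts = edgeCounts,
       nSkipped = nSkipped,
       originalEdges = orig)
}
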