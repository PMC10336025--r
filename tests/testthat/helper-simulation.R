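# Shared settings and small utilities for the simulation-based tests.

# benchmark marginal settings: low zero inflation, beta parts (2/7, 7) and
# (5/7, 7)
GAMMA_I <- c(p = 0.10, mu = 2 / 7, phi = 7)
GAMMA_J <- c(p = 0.25, mu = 5 / 7, phi = 7)

# Monte-Carlo standard error of a replicate mean
mcSE <- function(x) stats::sd(x) / sqrt(length(x))

# rank (Wilcoxon) AUC of ranking positives by SMALL score values
rankAUC <- function(score, positive) {
  ok <- !is.na(score)
  score <- score[ok]; positive <- positive[ok]
  r <- rank(score)
  nPos <- sum(positive); nNeg <- sum(!positive)
  (sum(r[!positive]) - nNeg * (nNeg + 1) / 2) / (nPos * nNeg)
}

# quick two-stage theta estimate for a simulated pair
fitTheta <- function(d) fitPairCopula(d$xi, d$xj)@theta

# jackknife variance of theta for a simulated pair
fitPairCopula2Var <- function(d)
  fitPairCopula(d$xi, d$xj, computeVar = TRUE)@varTheta

# build a minimal CovariationNetwork around a given logical adjacency
# matrix (used by the graph-summary tests)
networkFromAdjacency <- function(adj, theta = NULL) {
  m <- nrow(adj)
  taxa <- paste0("t", seq_len(m))
  dimnames(adj) <- list(taxa, taxa)
  if (is.null(theta)) theta <- adj * 1
  dimnames(theta) <- dimnames(adj)
  cmb <- utils::combn(m, 2L)
  sig <- adj[t(cmb)]
  pairs <- data.frame(
    taxonA = taxa[cmb[1, ]], taxonB = taxa[cmb[2, ]],
    theta = theta[t(cmb)],
    pValue = ifelse(sig, 1e-6, 0.9),
    pAdjusted = ifelse(sig, 1e-4, 1),
    significant = sig, status = "ok", stringsAsFactors = FALSE)
  pm <- matrix(NA_real_, m, m, dimnames = dimnames(adj))
  pm[t(cmb)] <- pairs$pValue; pm[t(cmb)[, 2:1]] <- pairs$pValue
  pam <- matrix(NA_real_, m, m, dimnames = dimnames(adj))
  pam[t(cmb)] <- pairs$pAdjusted; pam[t(cmb)[, 2:1]] <- pairs$pAdjusted
  new("CovariationNetwork", taxa = taxa, thetaMatrix = theta,
      pMatrix = pm, pAdjMatrix = pam, adjacency = adj, q = 0.01,
      pairs = pairs, clusters = integer(0), summaries = list())
}
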