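# zibcopula

Copula models with zero-inflated beta margins for inferring microbial
covariation networks from relative-abundance data.

## Why

16S/metagenomic profiles arrive as relative abundances: every value lies in
[0, 1) and a large share of entries are exactly zero. For such data, sample
correlations (Pearson, Spearman, Kendall) are biased toward zero and
log-ratio methods need pseudocounts. `zibcopula` models each taxon pair with
a genuine bivariate likelihood and tests dependence directly, for anyone who
wants co-occurrence/co-exclusion networks with calibrated error control:
microbiome statisticians, computational ecologists, and methodologists
benchmarking network inference.

## The model

Each margin is zero-inflated beta (ZIB),

f(x) = p·I(x = 0) + (1 − p)·f_beta(x; μ, φ)·I(x > 0),

with the beta density in mean/dispersion form (shapes μφ and (1 − μ)φ), and
p, μ, φ optionally GLMs in per-sample covariates (logit/probit/loglog links
for p and μ, log/sqrt for φ). A pair of margins is tied by the Frank copula

C(u, v; θ) = −(1/θ) log{ 1 + (e^{−θu} − 1)(e^{−θv} − 1)/(e^{−θ} − 1) },

which spans the whole dependence range θ ∈ (−∞, ∞) \ {0} (negative θ =
co-exclusion) with independence as the θ → 0 limit. Because the margins mix
an atom with a continuous part, the joint density has four cases by zero
pattern; all four are implemented in `zibPairDensity()`.

Estimation is two-stage (inference for margins): margins first, then the
profile likelihood in θ, with a delete-one jackknife variance for θ̃.
Dependence is tested with the rescaled likelihood-ratio statistic
Λ′ = −2ω[ℓ(θ₀) − ℓ(θ̃)] ~ χ²₁, where ω = 1 exactly under the independence
null. All-pairs scans are corrected by the Benjamini–Yekutieli procedure and
assembled into θ̃-weighted networks with clustering, graph summaries,
Erdős–Rényi null comparison and bootstrap consistency. A Rosenblatt-transform
simulator generates ZIB data under Frank or Gaussian copula dependence,
including unit-sum multivariate abundance tables with known truth.

See `vignettes/copula-covariation.Rmd` for the methods account.

## Worked example

```r
library(zibcopula)

# one pair: simulate at theta = 1.5 with 10% / 25% zero inflation
set.seed(42)
d <- simulateZibPair(100, theta = 1.5,
                     gammaI = c(0.10, 2/7, 7), gammaJ = c(0.25, 5/7, 7))
fit <- fitPairCopula(d$xi, d$xj, computeVar = TRUE)
fit
#> ZibPairFit (two-stage Frank copula with ZIB margins)
#>   n = 100, theta = 1.4546 (jackknife SE = 0.5413)
#>   zero patterns: both>0: 65, i=0: 10, j=0: 24, both=0: 1
testPairDependence(d$xi, d$xj)
#> Two-stage likelihood-ratio test of theta = 0
#>   theta = 1.4546, Lambda' = 6.2461 (omega = 1.0000), df = 1, p = 0.01245
```

The estimate θ̃ = 1.45 sits close to the generating value 1.5; the jackknife
SE (0.54) and the LRT p-value (0.012) quantify the evidence for dependence.
`frankKendallTau(1.4546)` ≈ 0.158 converts the estimate to a rank scale.

```r
# a network: 10 taxa in three dependent blocks (4 + 3 + 3), n = 300
sim <- simulateAbundanceTable(10, 300, blockDependency(10, c(4, 3, 3), 0.8),
                              normalize = FALSE, seed = 3)
net <- clusterNetwork(covariationNetwork(sim$table, q = 0.01), k = 3)
net
#> CovariationNetwork: 10 taxa, 45 pairs ( 45 tested )
#>   12 edges at BY FDR q = 0.01
#>   clusters: 4 / 3 / 3 taxa per cluster
graphSummaries(net)$global[c("edgeDensity", "avgClustering", "modularity")]
#> $edgeDensity   0.2666667
#> $avgClustering 1
#> $modularity    0.625
head(edgeTable(net), 3)
#>    taxonA  taxonB    theta       pValue    pAdjusted significant status
#> 1 taxon_1 taxon_2 8.069114 3.376468e-43 9.539616e-42        TRUE     ok
#> 2 taxon_1 taxon_3 7.860796 6.267016e-39 1.377161e-37        TRUE     ok
#> 3 taxon_1 taxon_4 7.763158 4.761168e-38 9.416289e-37        TRUE     ok
```

The 12 edges found at FDR 1% are exactly the 6 + 3 + 3 planted within-block
pairs, and cutting the dendrogram at k = 3 recovers the blocks.

A command-line front end over the same functions ships at
`inst/scripts/zibcopula-cli.R` (subcommands `simulate`, `fit-pair`,
`test-pair`, `network`, `bootstrap`; each writes TSV outputs plus a seed/
version manifest).

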