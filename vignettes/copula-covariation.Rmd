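---
title: "Copula models with zero-inflated beta margins for microbial covariation"
author: "zibcopula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copula models with zero-inflated beta margins for microbial covariation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zibcopula)
```

## The problem

Microbiome sequencing yields *relative* abundances: per sample, each taxon's
count divided by the total, so every observation lives in $[0,1)$ and a large
fraction of entries are exactly zero. Pairwise covariation between taxa —
co-occurrence and co-exclusion — is of direct ecological interest, but
sample correlations (Pearson, Spearman, Kendall) are biased toward zero when
both margins carry heavy atoms at zero, and log-ratio approaches require
pseudocounts. `zibcopula` instead models each pair with a full bivariate
likelihood: zero-inflated beta (ZIB) margins tied together by a Frank
copula, so that the marginal shape (including the zero mass and optional
covariate effects) is cleanly separated from the dependence of interest.

## The model

Each margin is a mixture
$$f(x) = p\,I(x = 0) + (1-p)\,f_{\mathrm{beta}}(x;\mu,\phi)\,I(x > 0),$$
with the beta density parameterized by mean $\mu \in (0,1)$ and dispersion
$\phi > 0$ (shapes $\mu\phi$ and $(1-\mu)\phi$). Each of $p$, $\mu$, $\phi$
may be a GLM in per-sample covariates: links logit/probit/loglog for $p$ and
$\mu$, log/sqrt for $\phi$ (defaults logit, logit, log — the conventional
choices; all are configurable in `fitZibMargin()`).

Dependence is modeled by the Frank copula
$$C(u,v;\theta) = -\frac{1}{\theta}\log\left\{1 +
  \frac{(e^{-\theta u}-1)(e^{-\theta v}-1)}{e^{-\theta}-1}\right\},$$
chosen because it spans the full dependence range $\theta \in
(-\infty,\infty)\setminus\{0\}$ — co-exclusion needs negative dependence,
which Gumbel/Joe cannot express — is radially symmetric, and has no tail
dependence. $\theta \to 0$ is the independence limit $C = uv$.

Because the margins mix an atom with a continuous part, the joint density
has four cases by zero pattern: both positive (copula density times the two
continuous densities), exactly one zero (a copula conditional probability
of the atom mass, times one continuous density), and both zero (the copula
evaluated at the two atom masses). `zibPairDensity()` implements all four;
its unit total mass is verified by quadrature in the test suite.

## Two-stage estimation and the jackknife

Full maximum likelihood for one pair is a 7-parameter problem (more with
covariates). The package instead uses the inference-for-margins two-stage
scheme: each marginal likelihood is maximized on its own (`fitZibMargin()`;
the zero part is an ordinary binary GLM, the beta part a safeguarded
Newton–Raphson with step-halving and a quasi-Newton fallback, since beta
dispersion likelihoods can be ill-conditioned at small $n$), and the profile
log-likelihood in $\theta$, with marginal estimates plugged in, is then
maximized by bounded one-dimensional search. A small-instance oracle test
confirms the two-stage $\tilde\theta$ tracks the full joint MLE.

The asymptotic covariance of the two-stage estimator involves mixed partial
derivatives that are impractical analytically, so the variance of
$\tilde\theta$ is estimated by the delete-one jackknife
$\hat\sigma^2_\theta = \sum_l (\tilde\theta_{(l)} - \tilde\theta)^2$, with
*both* stages re-run on every leave-one-out subset (the estimator is defined
through the full leave-one-out parameter vector; refits are warm-started at
the full-data estimates, and replicates whose subset violates the fit
preconditions are skipped with a warning). The jackknife is conservative
(upwardly biased) — the suite checks this against the empirical replicate
variance.

## The rescaled likelihood-ratio test

$H_0: \theta = \theta_0$ is tested with
$$\Lambda' = -2\,\omega\,[\ell(\theta_0,\tilde\gamma_i,\tilde\gamma_j) -
  \ell(\tilde\theta,\tilde\gamma_i,\tilde\gamma_j)]
  \;\xrightarrow{D}\; \chi^2_1 .$$
The factor $\omega \in (0,1]$ corrects for the fact that the margins were
estimated rather than known. Under the independence null ($\theta_0 = 0$)
the cross-information blocks vanish and $\omega = 1$ exactly, so the common
case is an ordinary likelihood ratio test; `omegaFactor()` short-circuits
accordingly. For $\theta_0 \neq 0$ no estimation recipe is canonical, and
this package estimates the information blocks by sample averages of score
products, with all scores from central finite differences (step $10^{-5}$)
at the fitted parameters — a design choice of this implementation, validated
by the calibration check that $\Lambda'$ has mean $\approx 1$ when testing
the true non-null $\theta$.

Estimates that hit the working boundary $|\theta| = 35$ are still reported
but flagged in the fit diagnostics: simulation designs can exclude such
data sets, but real pairs do produce them and silently dropping them would
bias a scan.

## Networks

`covariationNetwork()` runs the fit and independence test on all
$m(m-1)/2$ unordered pairs (each margin is fitted once and reused — stage 1
does not depend on the partner taxon), applies Benjamini–Yekutieli FDR
control across the tested pairs (valid under the arbitrary dependence of
overlapping pairs; level `q = 0.01` by default), and returns a
$\tilde\theta$-weighted network. Pairs failing the preconditions (fewer
than 3 nonzero per margin, fewer than 2 jointly nonzero) are recorded with
a reason code and excluded from FDR control rather than erroring the scan.

Clustering uses complete-linkage agglomerative hierarchical clustering on
$d_{ij} = 1 - |\tilde\theta_{ij}|/\max|\tilde\theta|$ for significant pairs
and $d_{ij} = 1$ otherwise, cut into $k$ groups (default $k = 3$); no
canonical metric exists for a $\theta$-weighted heatmap, and both the
dissimilarity and $k$ are exposed as arguments. Non-significant pairs enter
the weighted adjacency as 0. Reported centralities are normalized (degree
divided by $m-1$, normalized closeness/betweenness), matching the convention
in which average degree and edge density are directly comparable. The
Erdős–Rényi comparison draws $G(m, M)$ graphs with the observed node and
edge counts and recomputes the average local clustering coefficient and the
modularity *under the same clustering recipe* on every null graph; the
observed modularity uses the network's own cluster assignment (a
partition-under-test choice, not a modularity-maximizing partition).
Bootstrap consistency resamples samples with replacement and compares edge
sets by overlap and Dice coefficients.

## The simulator

`simulateZibPair()` samples exactly the data-generating process the
inference assumes: $U, B$ independent uniforms, $V$ from the closed-form
inverse conditional Frank copula (Rosenblatt transformation), then ZIB
quantile transforms. Whole data sets are redrawn when a margin has fewer
than 3 nonzero values, the taxa are mutually exclusive, or only one pair is
jointly nonzero — these configurations push $\tilde\theta$ to the boundary
and destabilize variances. Acceptance is therefore a truncation of the data
law; the attempt count is returned so acceptance rates can be audited, and
the redo budget is capped (default 1000) so degenerate configurations fail
loudly instead of looping forever.

Variants: `simulateZibPairCovariate()` adds per-margin standard-normal
covariates acting on the zero probability through logistic models (defaults
follow the benchmark grids: coefficient pairs such as $(-0.5, 0.7)$ and
$(-0.3, 0.4)$, beta means $e^{-0.7}/(1+e^{-0.7})$, $e^{-1}/(1+e^{-1})$,
dispersion $e^{1.5}$); `simulateGaussianPair()` swaps the Frank copula for
a Gaussian copula to probe misspecification; `simulateAbundanceTable()`
builds an $n \times m$ table from a multivariate Gaussian copula with ZIB
margins drawn from the benchmark grids
($p \in \{0.10, 0.25, 0.40, 0.50, 0.60, 0.75\}$,
$(\mu,\phi) \in \{(2/7,7), (5/7,7), (1/2,4), (1/3,9), (2/3,9), (1/2,6)\}$)
and normalizes rows to unit sum. Truly dependent pairs default to
equicorrelated blocks (`blockDependency()`): block designs keep the latent
correlation matrix positive definite by construction and mimic the modular
structure of real communities; arbitrary pair sets are accepted and
repaired by eigenvalue clipping with a warning. The default latent
correlation (0.6) and true-pair fraction (~10%) are stated assumptions, not
reproductions of any published configuration.

What the simulator does *not* emulate: sequencing-depth variation and
count-level noise (data are drawn directly on the relative scale), taxonomic
correlation between marginal parameters, and — except through the unit-sum
normalization of the multivariate generator — compositional closure.
Passing tests on simulated data therefore certify the estimator and test
under the model's own assumptions and under Gaussian-copula
misspecification, not under every artifact of real pipelines. Note also
that after unit-sum normalization the margins are no longer exactly ZIB and
nominally independent pairs acquire weak negative dependence; with enough
samples the test can detect this real (compositional) dependence, which is
a property of the estimand, not a false positive of the test.

## Numerical choices

* All copula arithmetic uses `expm1`/`log1p` forms, and the density and
  conditional denominators are regrouped into same-sign terms so there is
  no catastrophic cancellation out to the working bound
  $|\theta| = 35$ (`THETA_MAX`; Frank at 35 is within about $10^{-6}$ of
  the Fréchet bound in Kendall's $\tau$, so the cap only stops optimizer
  excursions).
* $|\theta| < 10^{-6}$ dispatches to the independence-limit formulas,
  keeping every function continuous through the puncture at $\theta = 0$.
* Margin fits converge on relative log-likelihood change $\le 10^{-10}$ or
  gradient sup-norm $\le 10^{-8}$, max 100 iterations, with method-of-moments
  initialization (fast and deterministic); the stage-2 search uses tolerance
  $10^{-8}$ on $\theta$.
* Per-observation log densities are floored at $\log(10^{-300})$ so extreme
  $\theta$ proposals degrade smoothly instead of producing $-\infty$.
* Exact zeros are the atom; values above $1 - 10^{-12}$ are clamped into
  the open support with a warning (unit-sum rows can place a taxon at
  exactly 1).
* $\hat p = 0$ (no observed zeros) is allowed and degenerates to a pure
  beta margin; in the $\omega$ blocks the corresponding null score
  direction is projected out by a Moore–Penrose inverse.

## Problem sizes

The test suite validates calibration at the benchmark design sizes: 500
replicates for type-I error and null-distribution checks, 200 replicates
per cell for bias and jackknife checks at $n = 50$, and a 20-taxon
unit-sum recovery experiment at $n = 100$. The acceptance script runs the
75-margin unit-sum experiment at $n = 50$ and averages three tables. These
sizes are the package's validation design; all are arguments, so users can
rerun any of them larger.

## Known limitations

* Pairwise (marginal) covariation only — no conditional-independence or
  partial-correlation structure.
* The Frank family is hard-wired as the dependence model (the module
  boundary would admit other Archimedean families, but none are shipped).
* Covariance of the full two-stage parameter vector is not reported, only
  the jackknife variance of $\tilde\theta$; Wald intervals are left to the
  caller.
* No BIOM/HDF5 ingestion; input is TSV/CSV tables of counts or relative
  abundances.
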