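---
title: "Identifying seeds of heterotic pools from sparse hybrid testcross trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying seeds of heterotic pools from sparse hybrid testcross trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hybrid breeding in a selfing crop such as wheat starts from a panel of inbred
parents with no established heterotic pools. The workflow in this package
asks: given F1 testcross yields from a sparse multi-environment trial (MET),
which genetically distinct parent subgroups combine well across which groups
of environments, and which specific crosses are most promising as the seeds
of complementary pools?

The package implements the full chain on synthetic data with known ground
truth, so every stage can be validated by parameter recovery:

1. **Synthetic study generator** — structured inbred founder panels, genetic
   maps, sparse partially replicated (p-rep) testcross designs, and
   plot-level yields with a known variance decomposition.
2. **Germplasm structure** — marker QC, Rogers' distance, principal
   coordinate analysis, and a cross-validated admixture model.
3. **Single-trial mixed models** — REML fits with design factors, an
   additive/non-additive partition of hybrid effects and optional AR1
   spatial residuals.
4. **Multi-environment factor-analytic model** — between-site additive
   covariance, genetic correlations, environment clusters.
5. **GBLUP** — genomic parental effects and backsolved per-marker effects.
6. **Stability** — Shukla's stability variance and quadrant classification.
7. **Usefulness** — doubled-haploid (DH) progeny simulation and the
   usefulness criterion for inter- vs intra-population crosses.

## The synthetic study and what it does (not) emulate

`simulate_founders()` draws subgroup allele frequencies from the
Balding–Nichols model: ancestral frequency $p \sim U(0.05, 0.95)$ per
marker, subgroup frequency $\sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$
with divergence $F$ (an $F_{st}$ analogue). Every line draws a single
allele per marker and is coded as dosage 0/2: parents are fully inbred by
construction.

`simulate_met()` builds per-site plot tables as

$$y = \mu_s + \text{row} + \text{col} + \text{block} + (g_{male} + g_{female})
     + s_{hybrid} + \varepsilon_{spatial} + \varepsilon$$

where the parental GCA vectors $g$ are drawn jointly across sites from a
multivariate normal with a user-specified between-site correlation matrix
(or derived from true marker effects), the SCA term $s$ is iid per hybrid
and site, and the optional spatial field is separable AR1$\otimes$AR1 on the
row/column grid. Per-parent GCA variance is $\sigma^2_a/2$, so hybrid
additive variance equals $\sigma^2_a$ — the quantity the recovery
experiments target.

The **desk preset** (`desk_config()`) is the scale used throughout the
tests and the acceptance script: 40 parents (30 male, 10 female) in 3
subgroups, 300 SNPs on 10 chromosomes, 200 hybrids over 8 sites in two
environment clusters (additive correlation 0.8 within, $-0.2$ between),
$\sigma^2_a = 0.5$, $\sigma^2_{SCA} = 0.1$, $\sigma^2_e = 1.0$, 30% p-rep.
Each site receives 100 of the 200 hybrids, so every hybrid is evaluated at
about 4 sites. We chose that allocation after observing that much sparser
subsets (e.g. 60/site) leave some sites with too little parent concurrence
for the additive/non-additive partition: the site's GCA variance component
then collapses to the boundary and its BLUP vector carries no signal. How
real programmes apportion hybrids to sites is a design-optimization problem
(parent concurrence across the MET) that this generator deliberately does
not solve; the subset size is exposed as a parameter instead.

The generator does **not** emulate marker ascertainment of commercial
arrays, multi-allelic loci, meteorological covariates, or optimized design
concurrence. Passing recovery tests therefore shows the estimators are
correct under the stated generative model, not that they are robust to
every feature of real trial data (spatially trending fertility, outliers,
genotyping error).

## Population structure

Rogers' distance for biallelic dosage data reduces per locus to
$|d_1 - d_2|/2$, averaged over loci non-missing in both lines; it is a
metric and, on inbreds, reaches 1 for opposite homozygotes. Principal
coordinates come from classical metric scaling (`stats::cmdscale`);
negative eigenvalues are reported and excluded from the returned axes.

The admixture model maximises the binomial likelihood
$\ell(Q, P) = \sum_{ij} d_{ij}\log(q_i^\top p_j) + (2 - d_{ij})
\log(1 - q_i^\top p_j)$ by alternating EM updates of the ancestry
proportions $Q$ and ancestral frequencies $P$. The update never decreases
$\ell$ (asserted in the tests); convergence is declared at
$\Delta\ell < 10^{-6}$ with a 2000-iteration cap, initialisation is from
k-means on the dosage rows, and frequencies are clamped to
$[10^{-6}, 1 - 10^{-6}]$. The number of populations is chosen by
masked-entry cross-validation: a random third of genotype cells is hidden,
the model is fitted on the rest, and hidden dosages are scored by squared
error against $2\,q_i^\top p_j$. Inside CV the EM budget is reduced (150
iterations, $\Delta\ell < 10^{-3}$): the fit only needs to rank candidate
K values, and the ranking is stable long before full convergence.

## Single-trial REML

The solver maximises the restricted likelihood of
$y = Xb + \sum_k Z_k u_k + e$ by average-information (AI) updates with
step-halving and an EM fallback whose ascent is guaranteed; components are
floored at $10^{-8}$. AI proposals that would decrease the restricted
likelihood are rejected, so the iteration trace is monotone — a property
the tests assert. Checks are fixed effects (one column each); hybrids share
one intercept; row, column and block are iid random; the additive term maps
each plot onto its two parents (incidence rows summing to 2, reciprocal
crosses identical) with an optional relationship matrix; the non-additive
term is indexed by hybrid identity. Reliability of an effect is
$1 - \mathrm{PEV}_i / (\sigma^2_u K_{ii})$, and the site-level summary is
the mean reliability of the additive effects.

A non-identity residual (AR1$\otimes$AR1 over the plot grid, which also
covers incomplete grids through $\rho_r^{|\Delta r|}\rho_c^{|\Delta c|}$)
is handled by Cholesky whitening, so one iid-residual core serves every
model; the autocorrelations are profiled by Nelder–Mead on the atanh scale
with warm-started inner fits. `compare_spatial()` fits both residual
variants and selects by AIC on the REML log-likelihood — valid because the
fixed part is identical — and always returns both fits.

## Factor-analytic MET model

The between-site additive covariance is modelled as
$G = \Lambda\Lambda^\top + \Psi$ with $\Lambda$ the site-by-factor
loadings and $\Psi \ge 0$ diagonal. We fit it in two stages: per-site
additive BLUPs form a genotype-by-site table (sparse, since each hybrid
visits a subset of sites) and a weighted EM factor analysis maximises the
Gaussian likelihood of each genotype's observed subvector, with optional
per-entry precision weights scaling $\Psi$. A one-stage FA-REML with a
genomic kernel estimates the same surface at much higher cost; the
two-stage route is the standard desk-scale approximation, and its known
cost is attenuation: BLUP shrinkage deflates the apparent correlations
without reordering them. Loadings are rotated to the lower-triangular
identification. Initialisation is from the eigendecomposition of the
pairwise-complete covariance; with the data pre-centred the EM target is
the divisor-$n$ ML covariance (visible in the saturated-order test).

`variance_explained()` reports, per site, $100\sum_{f\le m}\lambda_{if}^2 /
(\sum_f \lambda_{if}^2 + \psi_i)$, and two overall summaries — the
unweighted site mean and the variance-weighted mean — because reasonable
aggregation conventions differ.

Sites are clustered on the distance $1 - r$ from the additive genetic
correlation matrix with average linkage. The cluster count is either fixed
by the user or chosen at the largest relative gap between successive merge
heights; equal heights mean no structure and yield one cluster with a
warning. In the recovery experiments we fix the count at the known value
of two, because the quantity under test is the partition; the automatic
rule tends to over-split when shrinkage attenuates within-cluster
correlations and remains the default where the count is genuinely unknown.

## GBLUP and marker effects

The genomic relationship matrix is VanRaden method 1,
$K = ZZ^\top / (2\sum_j p_j(1-p_j))$ with $Z$ the dosage centred at twice
the observed allele frequency and missing dosages mean-imputed per marker.
On a fully inbred panel the mean diagonal is near 2 ($f = 1$ under this
scaling). GBLUP solves the mixed model with parental effects
$g \sim N(0, K\sigma^2_a)$; the observation design maps hybrid-level
records onto their two parents. Equivalence with ridge regression on
markers at $\lambda = \sigma^2_e/\sigma^2_m$ is the module's core oracle,
tested against an independently coded ridge solution. Marker effects are
backsolved as $\alpha = Z^\top K^{-1}\hat g / (2\sum p(1-p))$;
$Z\alpha = \hat g$ exactly when $K$ has full rank (with observed-frequency
centring $K$ has rank $n-1$ and the pseudo-inverse route preserves the
identity on the centred space, as the tests verify). A near-singular $K$
in the GBLUP equations gets a reported $10^{-8}$ ridge.

## Stability and quadrants

Shukla's stability variance partitions genotype-by-environment interaction:
with interaction residuals $w_{ij}$ over $G$ genotypes and $E$
environments,
$$\sigma^2_i = \frac{G}{(G-2)(E-1)}\sum_j w_{ij}^2 -
  \frac{\sum_{ij} w_{ij}^2}{(G-1)(G-2)(E-1)}.$$
The estimator is unbiased and can be negative; negative estimates are kept
with a truncated-at-zero companion, and the square root uses the truncated
value. The quadrant classification splits parents at a mean threshold
(default 0) and a stability threshold (default the panel median of the
square-root stability); "stable positive" means mean above and stability
below the thresholds — low interaction variance is stability, so the
orientation is recorded in the output metadata rather than assumed from
any plot's axis direction.

## DH simulation and the usefulness criterion

DH progeny of a cross between two inbreds are produced by simulating one
recombinant gamete per progeny and doubling it. Crossovers follow a
no-interference (Poisson) process on the centimorgan scale, which makes
the parental phase along a chromosome a two-state Markov chain at the
marker positions with switch probability given by Haldane's map function
$r = (1 - e^{-2d/100})/2$; we simulate that chain directly (the marker
loci are the only observables, so the distributions are identical) with a
fair-coin phase at each chromosome start. Interference models are out of
scope. Unmapped markers are excluded with a message.

Progeny are scored as $\text{GEBV} = \text{dosage}\cdot\alpha +
\bar y_{site}$ and summarised by the usefulness criterion
$UC = \mu + i\,h\,\sigma$, with $\sigma$ the $n-1$ sample standard
deviation, $i = \varphi(z_p)/p$ the selection intensity of the normal
upper tail (no finite-population correction) at selected fraction
$p = 0.10$, and accuracy $h = 1$ since selection is on the marker effects
themselves. `compare_cross_sets()` simulates every cross anchored on one
subgroup and groups UC values into intra- and inter-population categories.

## Numerical choices

* REML: AI with step-halving, EM fallback, floor $10^{-8}$, convergence
  $|\Delta\ell| < 10^{-6}$ and relative component change $< 10^{-5}$,
  200-iteration cap; non-convergence returns the last iterate with a
  warning flag rather than an error.
* Complete-linkage pruning drops monomorphic markers first ($r^2$
  undefined), keeps the first marker in genome order of each $r^2 = 1$
  group, and uses a $10^{-12}$ tolerance on $|r|$.
* Admixture: simplex floor $10^{-9}$ on $Q$, frequency clamp $10^{-6}$.
* FA EM: $\psi$ floored at $10^{-10}$; ridge $10^{-10}$ in the loading
  update solve.
* All randomness flows from one master seed through named component
  streams (`derive_seed()`), so adding draws in one component does not
  shift another; equal seeds reproduce every table bit-for-bit.

## Problem sizes used in the checks

The test-suite and acceptance experiments run at the desk preset: 20
replicate METs for variance and cluster recovery (the mean estimated
$\sigma^2_a$ is compared with the truth 0.5 via its empirical standard
error; cluster recovery must be exact in at least 95% of runs), 10
repetitions of the K-selection experiment (60 inbreds, 500 SNPs, true
K = 3, candidates 2–6, at least 80% correct), 10,000 gametes for the
Haldane calibration ($\pm 0.01$), and 20 seeds of the complementarity
contrast (250 DH per cross, inter-population median UC above the
intra-population median in at least 90% of seeds). The spatial
model-selection simulation uses a 14×14 grid. These sizes are the
package's chosen desk scale: large enough for the recovery targets'
tolerances, small enough to run routinely.

## Known limitations

* The two-stage FA underestimates genetic correlations under heavy
  shrinkage; a one-stage FA-REML hook would remove the attenuation.
* Reliability aggregation per trial is the mean over parental additive
  effects; other summaries (e.g. generalized heritability) are not
  implemented.
* The admixture model ignores linkage; it is a frequency model on pruned
  markers.
* Negative Shukla estimates are reported as-is; no shrinkage across
  genotypes is attempted.
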