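---
title: "Genetic correlation networks: models, estimators, and design choices"
author: "gencorrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic correlation networks: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Psychiatric nosology increasingly leans on genetics: when a candidate
condition's GWAS signal correlates genetically with depression, anxiety, and
neuroticism but not with impulsivity or hearing loss, that pattern argues for
one classification over another. gencorrnet implements the full chain that
produces such an argument from GWAS summary statistics alone: per-trait SNP
heritability and pairwise genetic correlations by LD-score regression (LDSC),
the trait-by-trait correlation matrix with a proper sampling covariance,
community detection on the correlation network, a Monte-Carlo assessment of
how stable those communities are, and a spectral multiple-testing correction
for correlated test panels.

No individual-level genotypes are touched anywhere; everything runs off
per-SNP association z-scores, sample sizes, and reference LD scores.

## The LDSC model

For a polygenic trait with SNP heritability $h^2$ analysed in $N$ samples
over $M$ SNPs, the expected association chi-square of SNP $j$ is linear in
its LD score $\ell_j$ (the sum of squared correlations with nearby SNPs):

$$E[\chi^2_j] = 1 + a + \frac{N h^2}{M}\,\ell_j ,$$

where $1 + a$ is the intercept; $a > 0$ signals confounding such as
population stratification. For two traits, the product of z-scores obeys the
bivariate analogue

$$E[z_{1j} z_{2j}] = c + \frac{\sqrt{N_1 N_2}\,\rho_g}{M}\,\ell_j ,$$

with $\rho_g$ the genetic covariance and the cross-trait intercept $c$
absorbing phenotypic correlation in overlapping samples. The genetic
correlation is the normalized ratio
$r_G = \rho_g / \sqrt{h^2_1 h^2_2}$.

`fitUnivariate()` and `fitBivariate()` estimate these regressions by
weighted least squares with the slope rescaled by $M/\bar N$ (univariate) or
$M/\sqrt{\bar N_1 \bar N_2}$ (bivariate).

### Weighting

Weighting is two-pass rather than fully iterative:

1. pass 1 weights $1/\max(\ell_j, 1)$ (heteroskedasticity rises with
   $\ell$, and the floor guards against pathological sub-1 LD scores);
2. pass 2 divides additionally by the squared predicted variance
   $(1 + \bar N \hat h^2_{(1)} \ell_j / M)^2$ — or its product analogue
   $(1 + \bar N_1 \hat h^2_1 \ell_j/M)(1 + \bar N_2 \hat h^2_2 \ell_j/M)$
   for z-score products — with the pass-1 heritability clamped to $[0, 1]$
   so the predicted variance stays positive even for null traits.

Two passes are enough for moment recovery, keep the estimator deterministic,
and make its behaviour easy to reason about; further iterations move the
weights, not the consistency of the slope. One deliberate detail: the
bivariate pass-2 weights reuse the *univariate fits'* weight-stage
heritabilities, so a trait regressed against itself reproduces its
univariate weights exactly and $r_G(\text{self}) = 1$ holds to machine
precision, not just in expectation.

### The reference-M convention

$M$ is the number of SNPs the polygenic signal is spread over. The package
defaults to the count of regression SNPs and exposes `mOverride` for panels
where the regression set is a down-sampled subset of the reference set. With
simulated data the two coincide, so the default is exact.

### Block jackknife

Standard errors come from a delete-one-block jackknife over 200 contiguous
SNP blocks in genomic order (`nBlocks` is configurable). Pseudovalues are
$B\hat\theta - (B-1)\hat\theta_{(-b)}$; the SE is
$\sqrt{\mathrm{var}(\text{pseudovalues})/B}$. Two implementation choices
matter:

* **Weights are frozen** at their full-sample pass-2 values during the
  jackknife. Re-deriving weights inside each leave-one-out fold would change
  the estimand of each fold slightly and costs an extra pass; freezing
  matches the convention of LDSC-style software and lets the leave-one-out
  regressions be computed by block-sum subtraction in $O(M + B)$ total.
* **The rg ratio is jackknifed as a whole**: each leave-block-out recomputes
  $\hat\rho_{g(-b)} / \sqrt{\hat h^2_{1(-b)} \hat h^2_{2(-b)}}$ from
  leave-one-out slopes of all three regressions on the *same* block
  partition. This propagates the (correlated) uncertainty of the two
  heritabilities into the rg SE, which a delta-method shortcut on the
  numerator alone would miss.

Because every trait and pair is jackknifed on one shared partition, the
pseudovalue columns can be assembled into the full sampling covariance of
all estimates at once (`pairwiseSamplingCovariance()`): for $T$ traits the
$K = T(T+1)/2$ unique elements of the correlation matrix (diagonal
included — 44 traits give $K = 990$) get a $K \times K$ covariance $V$.
Diagonal elements of a correlation matrix are fixed at 1, so their rows and
columns of $V$ are zero; they stay in the index space so that $V$ matches
the vech convention exactly (lower triangle, column-major, diagonal
included).

Edge cases: when either heritability is non-positive, rg is *flagged
undefined*, never thrown as an error — null traits are a legitimate input.
An rg outside $[-1, 1]$ is reported as-is with a flag; ratio estimators
legitimately exceed the bounds in small samples and clamping would bias
downstream resampling.

## Sign alignment and FDR

Traits arrive with arbitrary coding direction (e.g. "friendship
satisfaction" versus "loneliness"). `alignSigns()` identifies reverse-coded
traits from the loadings on the first unrotated principal component of the
correlation matrix and negates all correlations of traits loading below
−0.05. The raw eigenvector sign is arbitrary, so the component is oriented
to make its loading sum non-negative before thresholding — without this
convention the −0.05 rule is not well defined. The pass runs once (no
iteration); flipping is a similarity transform by a diagonal ±1 matrix, so
|S| and the eigenvalue spectrum are untouched and V is sign-updated
consistently. Missing correlations are zero-filled for the decomposition
only.

P-values of all trait pairs form one family and are adjusted by
Benjamini–Hochberg FDR (`bhFDR()`, a validated front-end to
`stats::p.adjust`).

## Graph clustering

`buildClusterGraph()` weights the complete trait graph by $|r_G|$: the sign
is disregarded, so a robustly *negative* correlation still ties two traits
together. The whole graph is clustered; the familiar figure-style reduction
(per-vertex top-10 edges above 0.10, eigenvector centrality of the absolute
matrix scaled to max 1) is display-only and implemented separately
(`displayGraph()`). A weight threshold for the clustering graph is exposed
as an option but defaults to 0 (complete graph), since nothing in the method
requires sparsification.

Louvain community detection and weighted Newman–Girvan modularity are
computed through igraph — the same implementation family the surrounding
literature uses — behind a seeded, deterministic wrapper
(`louvainCluster()`; node-order tie-breaks are fixed by the seed). The test
suite holds this to an exhaustive standard: on small random graphs the
attained modularity is compared against enumeration of *all* partitions
(Bell(7) = 877), and the modularity value against an independent double-loop
recomputation at 1e-12.

Hierarchical ordering for heatmap display uses average-linkage
agglomeration on $d = 1 - r_G$. Base `hclust` resolves tied merges in an
order-dependent way, so ties are broken deterministically by a vanishing
(1e-9) index-ordered offset and the dendrogram is reoriented by mean leaf
index; an all-tied (identity) matrix then reproduces the input order.

## Cluster stability

How trustworthy is a community assignment given the estimation noise in S?
`stabilityRun()` draws `n` vech vectors from
$\mathcal N(\mathrm{vech}(S), V)$, reshapes each into a correlation-form
matrix (symmetry forced, diagonal reset to 1), re-clusters every draw, and
reports the fraction of draws in which each pair of traits shares a
community (`ConcordanceMatrix`). Choices worth recording:

* **Correlation form, not covariance form.** The resampling operates on the
  standardized correlation matrix with the diagonal reset to 1. One could
  instead resample an unstandardized matrix with heritabilities on the
  diagonal; since the clustering consumes only off-diagonal $|r_G|$, the
  correlation form is the minimal object that carries the relevant noise,
  and it is the form whose sampling covariance the jackknife delivers here.
* **PSD projection.** A jackknife covariance of $K$ entries estimated from
  $B < K$ blocks is rank-deficient by construction (990 entries from 200
  blocks). Negative eigenvalues are clipped to zero before sampling — the
  nearest-PSD projection in Frobenius norm — and the event is logged.
* **No clipping of draws.** Resampled correlations may stray outside
  $[-1, 1]$; they are left alone. Clipping would bias the resampling
  distribution, and the clustering is insensitive because it uses absolute
  weights.
* **No re-alignment of draws.** Sign alignment cannot change absolute
  weights, so re-running it per draw would cost time and alter nothing.
* **Seeds.** Draw $r$ is clustered with seed $\texttt{seed} + r$: stable
  streams per resample, reproducible end to end.

A named focal trait gets a co-cluster frequency summary against every other
trait — the natural headline number for "how consistently does trait X sit
with cluster Y".

## Effective number of independent tests

Test panels over tissues are strongly correlated; Bonferroni over the raw
count is too harsh. `effectiveDf()` eigen-decomposes the (possibly
pairwise-complete) correlation matrix of the test statistics and applies
Nyholt's estimator

$$M_{\mathrm{eff}} = 1 + (M-1)\left(1 - \frac{\mathrm{var}(\lambda)}{M}\right),$$

with the sample variance ($M-1$ denominator) of the eigenvalues — the
denominator follows the estimator's original publication, and the resulting
df is non-integer in general (a 2×2 matrix with $r = 0.5$ gives exactly
1.75). The corrected threshold is $\alpha / M_{\mathrm{eff}}$.

The Li–Ji variant ($\sum_i I(\lambda_i \ge 1) + \mathrm{frac}(\lambda_i)$)
is available as `method = "liji"`. The two estimators genuinely disagree on
block structure: for $B$ identical all-ones blocks Li–Ji returns exactly
$B$, while the eigenvalue-variance formula sits above $B$ (e.g. 4 for two
3-trait blocks) because it spreads df across the within-block zeros. The
package treats the exact-$B$ behaviour as a Li–Ji property and tests it as
such. Numerics: Li–Ji's $\mathrm{floor}$ is applied to eigenvalues rounded
at 9 decimals, since a floating $3 - 10^{-13}$ would otherwise contribute a
spurious fractional df. Pairwise-complete correlation matrices may be
indefinite; negative eigenvalues enter $\mathrm{var}(\lambda)$ as-is (the
formula remains defined) and $M_{\mathrm{eff}}$ is floored at 1.

In the orchestrated pipeline the effective-df stage consumes an external
z-matrix when one is configured; otherwise it applies the estimator to the
assembled genetic correlation matrix itself, reporting the effective number
of independent *traits* — a self-contained and interpretable default.

## The simulator: what it emulates, and what it does not

`simulateSumstats()` inverts the LDSC moment model: for SNP $j$, the
$T$-vector of z-scores is multivariate normal with covariance

$$\Sigma_j = A + \frac{\ell_j}{M} B, \qquad
A = I + \mathrm{diag}(a) + C, \quad
B = D\,R_G\,D, \quad D = \mathrm{diag}(\sqrt{N_t h^2_t}),$$

so heritabilities, genetic correlations, confounding intercepts $1 + a_t$,
and sample-overlap cross-intercepts $C$ are all exact population parameters
of the generator, and LDSC is *consistent by construction* for them.
$\Sigma_j$ is affine in $\ell_j$, hence PSD for every SNP iff $A$ and $B$
are; sampling then vectorizes through the symmetric square roots of $A$ and
$B$. An invalid configuration is rejected naming the first offending SNP.

Default generator conditions (fixed once, as the study conditions): LD
scores $1 + \Gamma(\text{shape}=2, \text{scale}=20)$ — mean 41 and a long
right tail, the shape reference-panel LD scores have; MAF uniform on
$[0.01, 0.5]$; 2% of SNPs inside an MHC stand-in window
(chr6:26,000,000–34,000,000, the conventional exclusion region) and 5%
withheld from the include-list so the QC filters are always exercised;
per-trait $N$ constant across SNPs, as in single-cohort GWAS.

What the simulator deliberately does **not** model: realized LD between SNP
rows (draws are independent given $\ell_j$), minor-allele-frequency- or
annotation-dependent architecture, ancestry structure, or any coupling
between the QC fields (MAF, HWE p) and the association signal — those
fields exist solely to give the filters casualties. Consequently, passing
tests demonstrate that the estimators recover the parameters of the LDSC
moment model and that their jackknife uncertainty is calibrated *under that
model*; they cannot demonstrate robustness to model misspecification
(attenuation from unmodelled LD structure, stratification that mimics
polygenicity, and so on) any more than the estimator itself can.

## Filters and harmonization

Filtering applies the conventional thresholds MAF > 0.01 and HWE
p > 1e-8, with missing QC fields passing their rule ("insofar available"),
region exclusion (default: the MHC stand-in window, configurable because
published analyses rarely print their exact coordinates), and an optional
include-list. The report attributes each casualty to the *first* failing
rule in the fixed order maf → hwe → region → include-list, which makes the
counts deterministic and testable; filtering is idempotent.
Strand-ambiguous (A/T, C/G) SNPs are retained by default with a flag to
drop them — simulated alleles are under the package's control, and real
pipelines differ on this point.

`harmonizePair()` aligns a pair on shared SNP ids, negating z where the
allele pair is swapped and dropping irreconcilable allele sets with a
logged count, so that products $z_1 z_2$ are sign-consistent regardless of
argument order.

## Orchestration and reproducibility

`runAll()` drives simulate → filter → ldsc → corr → cluster → stability →
effdf from one JSON config, writing every intermediate in plain TSV/JSON
and a manifest with md5 hashes, per-stage record counts, and the seeds
used. All randomness flows from the global seed through fixed per-stage
offsets, so a rerun is byte-identical and single stages can be reproduced
in isolation. Matrices are serialized at 17 significant digits so doubles
round-trip bit-exactly. A stage failure aborts with the stage's name;
completed artifacts are kept. A thin Rscript dispatcher
(`inst/cli/gencorrnet.R`) exposes the stages as shell subcommands; the R
functions remain the primary interface.

All fits in the pipeline share one SNP panel (the intersection across
traits after filtering) so that every univariate and bivariate fit rides
the same jackknife block partition — the precondition for assembling a
joint sampling covariance.

## Problem sizes used by the tests

The suite and the acceptance script exercise the chain at desk scale,
chosen to keep Monte-Carlo error well inside the asserted tolerances:
recovery and calibration runs use $M = 20{,}000$ SNPs, $N = 20{,}000$
samples, $h^2 = 0.4$, $r_G = 0.5$, 200 jackknife blocks, with 25 replicates
(4 traits) for recovery and null calibration and 50 replicates (2 traits)
for jackknife calibration; stability uses a planted two-block 8-trait
matrix (within 0.5, between 0.05, SE 0.02 per entry) with 200 resamples;
the Louvain oracle enumerates all partitions of graphs up to 7 vertices.
Unit tests use smaller panels (hundreds to a few thousand SNPs) where only
code paths, not statistical power, are at stake.

## Known limitations

* No realized-LD simulation: the block jackknife is exercised under
  independence, where blocks are exchangeable; its behaviour under strong
  local LD is inherited from the LDSC literature, not tested here.
* Per-SNP sample sizes are scalar per trait; variable-N meta-analysed
  inputs are averaged, not weighted per SNP.
* Partitioned (annotation-stratified) heritability, constrained-intercept
  fits, and common-factor models on S are out of scope.
* Louvain is a greedy heuristic; the enumeration oracle shows it attains
  the optimum on small graphs in ≥ 90% of cases, which is the guarantee the
  stability analysis relies on (consistency of *re*-clustering under
  perturbation), not a global-optimality guarantee at 44 traits.

## A minimal session

```{r example}
library(gencorrnet)

cfg <- simConfig(nTraits = 4, nSnps = 20000, sampleSizes = 20000,
                 h2 = 0.4, rg = 0.5, seed = 1)
study <- simulateStudy(cfg)

fits <- lapply(traitLabels(cfg), function(l)
  fitUnivariate(study$sumstats[[l]], study$ldscores, label = l))
names(fits) <- traitLabels(cfg)

pairs <- combn(traitLabels(cfg), 2, simplify = FALSE)
bivs <- lapply(pairs, function(p) {
  h <- harmonizePair(study$sumstats[[p[1]]], study$sumstats[[p[2]]])
  fitBivariate(h$stats1, h$stats2, study$ldscores,
               fits[[p[1]]], fits[[p[2]]])
})

gcm <- alignSigns(assembleGenCorr(fits, bivs))
partition <- louvainCluster(buildClusterGraph(gcm), seed = 1)
conc <- stabilityRun(gcm, n = 1000, seed = 1, focal = "trait1")
effectiveDf(corrMat(gcm))
```
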