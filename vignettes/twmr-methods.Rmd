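---
title: "Multi-gene Mendelian randomization from summary statistics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-gene Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twmr)
```

## The problem

Genome-wide association studies find loci, not genes. Transcriptome-wide
Mendelian randomization (MR) treats cis-regulatory variants (eQTLs) as
instrumental variables for a gene's expression level and asks whether
genetically predicted expression shifts the trait — a causal claim rather
than a colocalization claim. Single-gene MR at a cis locus is fragile:
regulatory variants are frequently shared between neighboring genes, so an
instrument for the focal gene may act on the trait through a co-regulated
gene instead (horizontal pleiotropy through expression), biasing the
estimate and inflating false positives.

`twmr` addresses this with a multivariable (multi-gene), multi-instrument
MR estimator: all genes sharing instruments with the focal gene enter the
model as exposures, so each gene's effect is estimated conditionally on
its neighbors.

## The estimator

For a locus with $n$ instrument SNPs and $k$ exposure genes, let $E$ be
the $n \times k$ matrix of univariate SNP–expression effects (from an eQTL
study), $G$ the length-$n$ vector of univariate SNP–trait effects (from a
GWAS in a non-overlapping sample), and $C$ the $n \times n$ LD correlation
matrix of the SNPs from a reference panel. The causal-effect vector is the
generalized inverse-variance weighted solution

$$\hat\alpha = (E' C^{-1} E)^{-1} E' C^{-1} G,$$

computed via Cholesky factorizations (no explicit matrix inverse). With
$k = 1$, $C = I$ it collapses to the classical IVW combination of per-SNP
Wald ratios. Effects are interpreted on the standardized scale: the trait
shift, in trait SDs, per SD of expression.

Standard errors come from the first-order delta method, propagating the
entry-wise sampling variances of $E$ and $G$ through the estimator with
analytic Jacobians ($\partial\hat\alpha/\partial G = (E'C^{-1}E)^{-1}E'C^{-1}$;
the $E$-Jacobian assembled from the product rule). The cross term is zero
because the eQTL and GWAS samples do not overlap. On the standardized
scale the entry variances default to $1/N_{eQTL}$ and $1/N_{GWAS}$ — the
sampling variance of a standardized regression coefficient — and can be
overridden with per-entry squared standard errors. The delta-method SE is
validated in the test suite against a Monte-Carlo resampling oracle
(agreement within 10%) and against finite-difference Jacobians.

Assumptions worth stating: instruments are relevant (enforced by the
eQTL significance screen), act on the trait only through the modeled
expression levels (relaxed to the InSIDE condition by using many
instruments, policed by the heterogeneity filter below), and the two
summary sources refer to the same alleles (enforced by harmonization) and
populations with comparable LD (the reference panel stands in for both).

## Instrument and exposure assembly

For each focal gene:

1. cis-eQTLs passing the marginal screen ($P < 1.829\times 10^{-5}$, the
   study-wide FDR < 0.05 equivalent) are reduced to independent signals by
   forward stepwise conditional selection on summary statistics. The
   conditional Z of candidate $j$ given selected set $S$ is
   $z_{j|S} = (z_j - R_{jS}R_{SS}^{-1}z_S)/\sqrt{1 - R_{jS}R_{SS}^{-1}R_{Sj}}$
   with $R$ the panel LD — the joint least-squares solution reconstructed
   from marginal effects, on the standardized scale. Entry requires
   conditional $P < 10^{-3}$; candidates with $r^2 > 0.9$ to a selected
   SNP are ineligible (collinearity guard).
2. every gene for which a selected SNP is a significant eQTL joins the
   exposure set;
3. instruments extend to each included gene's own independent eQTLs;
4. the SNP union is greedily pruned to pairwise $r^2 < 0.1$ (priority:
   focal-gene p-value, then the minimum p over included genes; ties by
   position and id, so assembly is order-invariant);
5. $E$ is filled with marginal eQTL betas, zero where a SNP is not a
   significant eQTL of a gene; $G$ comes from the harmonized GWAS.

Genes whose instrument effect profiles are nearly collinear make the
design ill-conditioned; of each gene pair whose eQTL Z-scores over at
least 3 shared SNPs have squared Pearson correlation $\ge 0.4$, the gene
with fewer instruments is dropped. The threshold is applied to the
squared Pearson correlation of the Z-scores (the quantity usually
written "$r^2$" in this context).

The cis window is ±1 Mb around the gene (the convention of the blood
eQTL meta-analysis this pipeline is designed for). Coordinates are
1-based GRCh37; QC removes non-autosomal variants, strand-ambiguous
(A/T, C/G) SNPs, indels/multi-allelics and the extended MHC
(chr6:26.2–33.8 Mb, inclusive). Variants are keyed by id with a
(chromosome, position) consistency check across sources.

## Heterogeneity (pleiotropy) filter

Instruments acting on the trait outside the modeled expression channel
leave a residual $d_i = G_i - \sum_k \hat\alpha_k E_{ik}$ larger than its
sampling variance

$$\mathrm{var}(d_i) = \mathrm{var}(G_i) + \textstyle\sum_k E_{ik}^2\,
\mathrm{var}(\hat\alpha_k) + \sum_k \hat\alpha_k^2\, \mathrm{var}(E_{ik})
+ \sum_k \mathrm{var}(E_{ik})\,\mathrm{var}(\hat\alpha_k),$$

and $T_i = d_i^2/\mathrm{var}(d_i)$ is referred to $\chi^2_1$ — each
$T_i$ is a single squared standardized residual, hence one degree of
freedom. While any SNP has $P < 10^{-4}$: remove the SNP with the largest
$|d_i|$ (ties broken by variant id), re-estimate $\hat\alpha$, re-test.
After three removals a still-heterogeneous locus is discarded — beyond
that point the filter mostly chases noise, and a locus needing more
surgery is not trustworthy. The $\mathrm{var}(d_i)$ expression contracts
each row of $E$ against the vector $\alpha$ element-wise, as written
above; the resulting SE calibration is validated against the Monte-Carlo
oracle in the test suite.

## The simulation study

The generator reproduces the study conditions used to compare the
multi-gene and single-gene estimators: a locus of 30 SNPs and 3 genes;
10,000 individuals in the eQTL cohort and an independent 100,000 in the
GWAS cohort. Per SNP, genotypes are $s \sim B(2, q)$ with
$q \sim U(0.05, 0.5)$, standardized by the generating $q$. Each SNP
regulates $l \sim \text{Poisson}(\lambda)$ genes ($\lambda$ defaults to
0.4; values above the gene count are capped; target genes drawn uniformly
without replacement), with effects $\beta \sim N(0, h_j^2/l)$ and
per-gene heritability $h_j^2 \sim U(0.01, 0.4)$. Expression is
$E_j = \sum_i \beta_{ij} z_i + \gamma_E c + \epsilon_j$ with
$\gamma_E = 0.2$; the trait is
$T = \sum_j E_j \alpha_j + \gamma_T c' + \epsilon$ with $\gamma_T = 0.1$
and $\alpha_j \sim N(0, \text{sd } 0.05)$ (0.05 is a standard
deviation, not a variance; the comparative conclusions are insensitive
to this choice at the margins involved). The confounders $c$ and $c'$ are
distinct variables drawn independently, as the two model equations write
them. Residual variances are set so each $E_j$ and $T$ has unit variance;
parameter draws implying negative residual variance are redrawn (the
constraint binds increasingly at high $\lambda$, which is part of the
stated model). Marginal summary statistics are per-SNP simple
regressions within each cohort; LD is estimated from the eQTL cohort's
genotypes.

Two implementation notes. First, the genotype-level generator is compiled
code (RcppArmadillo) driven by R's RNG, so `set.seed()` governs every
draw; each replicate runs under a sub-seed derived from
(seed, cell, replicate), making any cell reproducible in isolation.
Second, when only summary statistics are needed the GWAS cohort's latent
expression noise is integrated out analytically — the trait given
genotypes is Gaussian with mean $Z(B\alpha)$ — which is distributionally
identical to the full generative path (verified by a KS test against the
full path in the suite) at a fraction of the cost.
`simulate_locus(keep_cohorts = TRUE)` still materializes both cohorts.

### Estimator protocols in the simulation

The generative model does not by itself pin down which SNPs serve as
instruments for each estimator, so `run_comparison()` makes the protocol
explicit. The default, `selection = "significant"`, mirrors
the real-data pipeline: instruments are SNPs passing the marginal eQTL
screen for at least one gene, $E$ entries are zeroed where a SNP is not a
significant eQTL of that gene, and the single-gene comparator is the same
machinery restricted to gene 1's significant eQTLs with $k = 1$ (the
definition of the single-gene approach used throughout). Replicates where
gene 1 has no significant eQTL are unestimable for both approaches and
excluded from that estimator's aggregates. `selection = "none"` applies
the estimator to all 30 SNPs. In both protocols the delta-method entry
variances are the per-SNP squared regression standard errors computed
within each simulated cohort, exactly as a real analysis would read them
from the summary files.

Under the default protocol and the conditions above, the suite reproduces
the two headline robustness contrasts: the single-gene estimator's
type-I error at nominal 5% climbs well above 20% as pleiotropy grows
while the multi-gene estimator stays near 5%, and the single-gene RMSE
for gene 1 exceeds the multi-gene RMSE by more than twofold at moderate
and high pleiotropy. Two quantitative notes, both computed by the suite
rather than asserted: at the lowest pleiotropy level ($\lambda = 0.2$)
the RMSE ratio falls short of twofold (about 1.7–1.9) because shared
instruments are rare there and the two designs nearly coincide; and the
multi-gene estimator's *power* advantage does not materialize against a
multi-instrument single-gene comparator — at small effects the
single-gene estimator's pleiotropy-driven dispersion produces spurious
rejections that count as "power", so its rejection rate at
$\alpha_1 = 0.01$ exceeds the multi-gene rate even though its estimates
are far worse calibrated. A positive average power gain re-emerges only
against a top-eQTL (single-instrument) comparator. We report what the
stated comparator produces.

### What the generator does not emulate

Simulated genotypes are independent binomials: there is no LD structure,
no allele-frequency spectrum, no cis-window geometry, and the confounders
are cohort-internal only (no shared confounding between the eQTL and GWAS
cohorts, as the generative equations specify). Passing simulation tests
therefore demonstrates the estimator's sampling behavior under the
generative model, not robustness to realistic LD misspecification,
sample overlap, or population mismatch between panel and study.

## Numerical choices and degenerate inputs

- All linear systems are solved by Cholesky factorization; the LD matrix
  is ridge-regularized ($+10^{-6} I$) only when its condition number
  exceeds $10^8$, and the event is recorded on the returned object.
- Rank-deficient exposure designs and underdetermined loci ($n < k$) are
  refused with the offending genes named; the per-gene screen records
  machine-readable reason codes (`no_instruments`, `rank_deficient`,
  `too_few_snps`, `het_discarded`) instead of failing the run.
- Greedy operations (pruning, stepwise selection, heterogeneity removal)
  break ties deterministically (priority, then position, then id), so all
  pipelines are invariant to input row order.
- Missing panel dosages are mean-imputed per variant; constant variants
  are never retained.

## Problem sizes in the checks

The acceptance computations use 1,000 replicates per simulation cell for
the type-I and power grids, and the test suite uses 500 replicates per
cell for the RMSE grid, 400-replicate cells for distributional checks,
and 10,000 draws for the Monte-Carlo SE oracle; these sizes put the
Monte-Carlo error of each reported rate near half a percentage point,
the precision at which such rates are conventionally quoted.

## Known limitations

- The stepwise conditional selection reconstructs joint effects from
  marginal statistics and panel LD; with a small or mismatched panel the
  conditional p-values are approximate (the classical caveat of
  summary-based conditional analysis).
- The per-SNP heterogeneity statistic ignores LD between instruments
  (each $T_i$ is marginal); after $r^2 < 0.1$ pruning the induced
  dependence is mild.
- The "independent genes" policy used for trait–trait expression
  correlation (no shared instruments, ≥1 Mb apart, greedy in genomic
  order) is one defensible choice among several; it is recorded in the
  output's `policy` attribute so downstream consumers can tell which
  rule produced the subset.
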