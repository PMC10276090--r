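---
title: "Trio-based polygenic score analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based polygenic score analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triopgs)
```

## The scientific setting

Children ascertained for a clinical diagnosis (here the motivating case is
ADHD) frequently present comorbid conditions such as sleep disturbances.
Two complementary questions arise. First, is common-variant liability for a
comorbid trait *over-transmitted* from parents to affected children — which
would indicate shared polygenic aetiology with the ascertained disorder?
Second, within the case group, does higher polygenic liability predict which
children actually develop the comorbid phenotype?

Case–control polygenic score (PGS) comparisons confound both questions with
population stratification and with every factor that differs between cases
and screened controls. The trio design avoids this: each child is compared
with their own parents, so ancestry and family background cancel exactly.
`triopgs` implements this workflow end to end — summary-statistic
harmonization, multi-threshold scoring with principal-component aggregation
(PGS-PCA), the polygenic transmission disequilibrium test (pTDT) with
cross-cohort pooling, and case-only logistic association with
family-clustered sandwich standard errors — together with a
liability-threshold trio simulator used to validate every stage.

## Polygenic scores

For harmonized variants $j$ with discovery log odds ratios $w_j$ and
discovery p-values $p_j$, the raw score of individual $i$ at threshold $t$
is

$$ S_{i,t} \;=\; \sum_{j\,:\,p_j < t} w_j\, d_{ij}, $$

where $d_{ij} \in \{0,1,2\}$ counts alt-allele copies and missing dosages
are mean-imputed as twice the panel allele frequency — the behaviour of
standard scoring tools. The comparison is strictly `<` to avoid boundary
ambiguity at $p = t$. Scores are weight *sums*, not SNP-count averages;
because the composite is z-standardized downstream, this choice does not
affect any reported statistic, but it is fixed for reproducibility.

### Harmonization

Summary statistics are matched to the panel by variant ID (falling back to
`chrom:pos` where IDs are absent). Weights are re-oriented to count
alt-allele copies: a reversed allele pair negates the weight, and a pair
that matches only after complementing both alleles is treated as a strand
flip. A/T and C/G pairs cannot be disambiguated without strand information
and are dropped by default — the conservative standard, configurable off.
Variants with panel minor-allele frequency at or below 5% are removed; the
MAF is computed in the target panel, the natural place when the filter is
defined by overlap with the genotyped sample. A harmonization report
accounts for every input variant exactly once (retained, low-MAF,
ambiguous, unmatched, or absent from the panel).

### PGS-PCA aggregation

Threshold choice is arbitrary, so scores are computed on a ladder of seven
cutoffs (default $\{0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 1.0\}$, a
conventional span from sparse to all-SNP) and aggregated: each column is
standardized, a PCA is run across columns, and the first component — which
typically captures almost all shared variance — is extracted and
z-standardized. The PC sign is unidentifiable; we flip PC1 so that the sum
of its loadings is positive, making the composite positively oriented with
the threshold scores and comparable across runs. Constant columns (e.g. an
empty threshold) are excluded; if a single usable column remains the
composite is that column standardized. The composite is standardized over
the full scored set (parents and children together); standardizing within
analysis subsets instead would rescale, but not reorder, every downstream
statistic — deviations are invariant to location and positive scale.

## The pTDT

Under Mendelian transmission the child's expected PGS is the mid-parent
average $M_f = (PGS_{father} + PGS_{mother})/2$. For complete trios, we
form standardized deviations

$$ t_f \;=\; \frac{PGS_{child,f} - M_f}{\mathrm{SD}(M)} $$

and test $H_0: \mathbb{E}[t_f] = 0$ with a one-sample two-sided t-test.
Standardizing by the mid-parent SD (computed over the analyzed trios) makes
the mean deviation a unitless effect size, so deviations from different
cohorts — each scored and standardized within itself — can be pooled
directly: the combined analysis concatenates per-cohort deviation vectors
and repeats the t-test on the pooled sample. Whether one should pool raw
child-minus-midparent differences instead is not identifiable from the
effect sizes alone; the within-cohort standardized form is adopted because
it makes cohorts with different score scales commensurable.

Only one child per family enters the pTDT. Where several children are
scored, one is chosen by a seeded uniform draw and the seed is recorded, so
the selection is reproducible; any deterministic rule would do, and the
choice does not bias the mean because siblings are exchangeable under the
null. Incomplete trios (a missing parental score) are excluded from the
pTDT but remain available for case-only association. Two-sided p-values
are used throughout since both over- and under-transmission are of
interest, and Benjamini–Hochberg FDR correction is applied across the
panel of discovery phenotypes tested in one run.

## Case-only association

Within probands, each binary comorbid outcome is modelled as

$$ \mathrm{logit}\, P(y_i = 1) = \beta_0 + \beta_1 \mathrm{PGS}_i +
   \boldsymbol{\gamma}^\top \mathbf{z}_i, $$

with covariates $\mathbf{z}$ defaulting to the top 5 ancestry PCs,
genotyping batch and age. The PGS is scaled to unit SD so $e^{\beta_1}$ is
the odds ratio per SD. Families contribute correlated children, so
standard errors use the GEE-type sandwich estimator under an independence
working model: coefficients are the ordinary logistic MLE, and the
covariance is $A^{-1} B A^{-1}$ with $A$ the observed information and $B$
the sum of squared cluster score sums. With singleton clusters this is
exactly HC0. The 95% CI uses the normal quantile on the log-odds scale
(a t-quantile option exists). Variance explained is reported as the
Nagelkerke $R^2$ difference between the full and covariates-only models,
both referenced to the intercept-only model; an alternative referencing
the covariates-only model directly is available behind a flag. Rows with
missing outcome, predictor or covariates are dropped per analysis
(complete-case), so each row of a results table carries its own $n$.
FDR correction is applied within each results battery by default — the
grouping is configurable since reasonable analysts differ on whether the
family of tests spans one table or all analyses.

Three sensitivity modes are built in: substituting parent-reported outcome
columns, adding sex and ADHD-medication status as covariates, and
excluding children on sleep medication. They are implemented as row
filters / covariate additions, so a vacuous filter reproduces the primary
result exactly.

## The synthetic-cohort generator

Since trio genotype data of this kind are never publicly deposited, the
package ships a generator whose statistical structure matches what the
analysis assumes:

* **Genetics.** Unlinked biallelic variants with allele frequencies drawn
  from a configurable range (default 0.05–0.5, i.e. common variants);
  parental dosages are $\mathrm{Binomial}(2, p_j)$ (random mating,
  Hardy–Weinberg), and children receive one uniformly drawn allele per
  parent. Ref/alt pairs are never complementary: synthetic variants carry
  no strand uncertainty, so strand-flip handling is exercised on crafted
  fixtures instead.
* **Liability and ascertainment.** A set of causal variants (default 200)
  carries normal effects scaled so the score explains a fraction
  $h^2_{PGS}$ (default 0.3) of a unit-variance liability; the remainder is
  independent Gaussian environment. Probands are retained when liability
  exceeds the $(1-q)$ population quantile — a liability-threshold model of
  clinical ascertainment, parameterized by quantile for transparency.
  The defaults (328 trios, top-5% ascertainment) mirror a clinical cohort
  of a few hundred ascertained trios; the true severity of clinic
  recruitment is unknown, so $q$ is an illustrative, configurable choice.
* **Outcomes.** Binary comorbid phenotypes follow a logistic model in the
  child's standardized true PGS, with simulated age, sex (ADHD-typical
  ratio), batch and medication flags; a parent-reported copy of each
  outcome (10% under-report) supports the sensitivity modes. Multi-child
  families are available to exercise cluster-robust inference.
* **Discovery GWAS.** Emitted weights are true effects plus noise with the
  standard per-variant GWAS standard error $1/\sqrt{2Np(1-p)}$ at a
  configurable effective discovery size $N$; p-values are the matching
  z-test p-values. $N = \infty$ gives the noise-free limit used by
  exactness tests.
* **Reproducibility.** All randomness flows from one integer seed; a fixed
  configuration reproduces byte-identical cohorts.

What the generator does *not* emulate: linkage disequilibrium (the scoring
pipeline uses thresholding without clumping, so LD structure is out of
scope), assortative mating, parental phenotypes, imputation uncertainty,
and informative missingness (missingness is completely at random). Passing
tests therefore demonstrate the statistical machinery is correct under the
stated model, not that any particular real cohort satisfies that model.

## Numerical choices and degenerate inputs

* Logistic fits use iteratively reweighted least squares via `glm`;
  non-convergence and (quasi-)separation (an extreme coefficient together
  with fitted probabilities at 0/1) are errors naming the coefficient.
* The pTDT refuses fewer than 2 trios, zero-variance deviations, and a
  degenerate (zero-SD) mid-parent distribution.
* PGS-PCA refuses all-constant score matrices; ancestry PCA excludes
  monomorphic variants and truncates (with a warning) when the requested
  number of PCs exceeds the matrix rank. PC signs are fixed by the
  largest-magnitude loading (ancestry) and the loading-sum rule (PGS-PCA).
* Nagelkerke ΔR² is clamped to [0, 1]; a full-model likelihood below the
  null beyond 1e-6 is treated as a fit failure rather than silently
  clamped.
* Summary-statistic rows violating invariants (p outside (0,1], identical
  alleles, non-finite weights, duplicate IDs) are dropped with per-reason
  counts; an empty result is fatal rather than silently empty.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route: naive
per-SNP scoring loops, direct eigen-decompositions, hand-computed t-tests,
contingency-table closed forms, the step-up FDR formula, brute-force HC0
covariances, and Monte-Carlo oracles for calibration (type-I error of the
pTDT over 1000 null cohorts of 200 trios; robust-CI coverage over 500
clustered replicates; ascertained transmission compared with a direct
simulation of the infinitesimal model at $10^4$ trios). Simulation sizes
(100–2000 variants, 200–844 trios, 40–1000 replicates per study) were
chosen so each Monte-Carlo comparison has error small relative to the
effect it checks while the full suite stays quick to run; all are stated
in the tests and the acceptance script.

## Known limitations

* No LD-aware scoring (no clumping or pruning) and no liftover or
  imputation: inputs are assumed QC'd and on a shared build.
* QC beyond the MAF and strand-ambiguity filters (call rate, HWE,
  relatedness checks) is expected to have happened upstream.
* The independence working model is the only GEE structure offered;
  sandwich correction makes the SEs valid regardless, at some efficiency
  cost for strongly clustered designs.
* Wald-normal CIs can undercover at small cluster counts; with hundreds of
  families (the intended regime) coverage is within the binomial band, as
  the calibration study checks.
* The X chromosome and parent-of-origin effects are out of scope.
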