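---
title: "From exposure-associated methylation to causal inference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From exposure-associated methylation to causal inference: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`meqtlmr` chains five analyses that are usually run as separate tools:
genotype-based ancestry assignment, exposure EWAS with meta-analysis,
cis-meQTL mapping with LD clumping, pleiotropy screening, and two-sample
Mendelian randomization. This vignette explains the statistical model at
each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
and design decisions that were genuinely open.

## The two-stage methylation model

Methylation is analysed on the M-value scale, `M = log2(beta/(1-beta))`
with betas clamped to `[1e-6, 1-1e-6]` — the variance-stabilizing scale
on which linear models on array data behave well. Candidate selection is
a two-stage regression per cohort:

1. a *technical* model of M on age, tobacco use, alcohol use, log10
   viral load, medication adherence, white blood count, the estimated
   cell-type proportions, and the top 20 principal components of
   control-probe methylation. The top 5 PCs of this model's residuals
   are retained as additional covariates. The exposure is deliberately
   absent from the technical model: residual PCs are meant to absorb
   unmeasured batch structure (plates, chip position), and including the
   phenotype would let them absorb signal instead.
2. the *association* model `M = a0 + a1*Y + sum(a_i C_i)` with all of
   the above plus the residual PCs; `a1` is the exposure effect, tested
   two-sided on the t distribution with the residual degrees of freedom
   (correct at the modest cohort sizes simulated here; the normal
   approximation would be anticonservative).

The cohorts are combined by fixed-effects inverse-variance
meta-analysis (`w = 1/se^2`; `beta = sum(w b)/sum(w)`;
`se = 1/sqrt(sum(w))`) and candidates kept at meta `p < 1e-4` — a
deliberately liberal screen whose purpose is to feed the meQTL stage,
not to declare epigenome-wide significance. Genomic inflation lambda
(median association chi-squared over 0.4549) is reported per run; it is
data-dependent and is not a reproduction target.

Cell-type proportions are estimated by reference-based deconvolution:
constrained least squares `min ||m - P w||^2` subject to `w >= 0`,
`sum(w) <= 1`, where `P` holds the expected M-values of purified cell
types at the reference CpGs. Non-negativity is solved by Lawson–Hanson
NNLS; when the unconstrained optimum exceeds total proportion one, the
sum constraint is activated through a heavily weighted penalty row
(equivalent to the equality-constrained solve to about 1e-6, which the
tests assert). A quadratic-programming solver would be the textbook
route; the penalty formulation needs only the NNLS primitive and its
accuracy is verified rather than assumed.

## Ancestry

The reference panel is LD-pruned by a greedy left-to-right scan
(drop a variant whose squared dosage correlation with any retained
in-window variant exceeds 0.02), variants are centred and scaled by
`sqrt(2p(1-p))` from the reference frequencies, and query samples are
projected onto the reference SVD loadings. Admixture proportions are
estimated per sample by EM on the binomial likelihood with the K = 4
reference allele frequencies held fixed — a supervised, deterministic
replacement for unsupervised block relaxation, appropriate because the
reference panel defines the ancestral groups. The log-likelihood is
non-decreasing across iterations (asserted in tests). Near a vertex of
the simplex the EM converges sublinearly; the default cap of 1,000
iterations then returns the best iterate with a warning, which is
adequate for classification features, while recovery experiments that
need tight estimates raise `max_iter`.

Admixed samples are flagged when their distance to every reference
centroid (PC1–PC3) exceeds that class's 99th percentile of within-class
reference distances — a data-driven radius in place of a magic constant.
Classification is a majority vote over the k = 20 Euclidean nearest
training neighbours in the standardized 14-dimensional feature space
(10 PCs + 4 proportions); the training set is the labelled reference
groups plus a seeded random draw of 20 flagged admixed samples, and vote
ties break to the label with the smallest mean neighbour distance.
Feature standardization is our choice (the convention is not fixed by
the cited tooling); it makes the PC and proportion scales commensurate.
All downstream stages keep only the samples labelled with the target
ancestry (default AFR), mirroring a single-ancestry study design — this
also removes most stratification-driven confounding from the in-sample
regressions.

## cis-meQTL mapping

Genotype QC removes variants with MAF < 0.05 (kept at equality),
missingness > 0.05, or Hardy–Weinberg chi-squared p < 1e-6 (dosages
rounded to calls; monomorphic variants return p = 1 by convention).
Every variant within ±500 kb of a candidate CpG (inclusive) is tested
per cohort with the same covariates as the technical model — by default
*without* the residual PCs, matching the narrower covariate list of the
meQTL model; per-pair regressions use covariate partialling with the
full-model residual degrees of freedom, which is algebraically exact
OLS. Missing dosages are mean-imputed inside the regression only, so QC
counts are unaffected. BH-FDR is applied to the meta p-values of all
tested pairs as one family (the survivor count is a single number),
and FDR-passing pairs are clumped per CpG: greedily take the
smallest-p unassigned variant as an index (p ties break to the lower
genomic position — deterministic), and absorb all unassigned variants
with in-sample dosage r² > 0.1. In-sample LD is used because no external
LD reference is assumed. Nearest genes come from a linear scan with an
explicit lower-coordinate tie rule.

## Pleiotropy screening

The PheWAS-style lookup takes index meQTLs with meta p < 5e-8, collects
their catalog associations at p < 0.05, and keeps those below
`alpha / (n selected variants x n studies in the catalog)` — both family
sizes recomputed from the inputs, so the scheme generalizes while
reproducing 1.70E-07 on a 62-variant, 4,756-study input. Trait
enrichment builds, per trait, the 2×2 table of meQTL × risk-variant
membership over the tested-variant universe and applies a one-sided
(greater) Fisher exact test — the enrichment direction is the scientific
question; a two-sided flag exists. The odds ratio is reported as the
cross-product `ad/bc` (infinite when `bc = 0`, undefined with a
no-overlap flag when a margin is empty). Trait labels from the two
screens are matched exactly after lowercasing and trimming; no fuzzy
matching is attempted.

## Mendelian randomization

Instruments are index meQTLs (one per LD clump, keeping instruments
approximately independent) whose linear regression on the 0/1 exposure
gives p < 0.05. The linear — not logistic — fit on a binary exposure is
intentional: it mirrors the common PLINK-style screening practice this
pipeline emulates, and the Wald-ratio scale cancels in relative
comparisons. Exposure and outcome tables are harmonized on the effect
allele (outcome betas sign-flipped when alleles are swapped);
strand-ambiguous A/T and C/G variants are dropped outright, the
conservative default when strand information is absent.

Three estimators are reported per outcome study: fixed-effect IVW
(weighted no-intercept regression of outcome on exposure effects,
`se = 1/sqrt(sum(w bx^2))`); the interpolated weighted median with
per-variant weights `bx^2/se_y^2` and a parametric-bootstrap SE
(default 1,000 replicates), robust to up to half-invalid instruments by
weight; and a simulation-based pleiotropy-residual test. The latter
computes the observed weighted residual sum of squares of each outcome
effect against its leave-one-out IVW prediction, simulates outcome
effects from normals centred at those predictions, and — crucially —
recomputes the leave-one-out statistic on each simulated dataset, so
estimator noise is in both the observed and null statistics and the
global test holds its nominal size (empirically 0.048 at the 0.05 level
over 1,000 null replicates in the test suite). Per-variant outlier
p-values are Bonferroni-corrected over instruments; note the empirical
p floor of `1/(n_sim+1)` means `n_sim` must exceed `n_iv/alpha` for any
outlier to be flaggable — the default `n_sim = 1000` suffices for up to
50 instruments. The corrected estimate is IVW on the non-outlier set
(an identity the tests assert), and a distortion summary (relative
change of the estimate) is reported as informational only. Family-wise
significance uses `alpha / (n studies x 3 methods)` — 1.28E-3 for 13
pairs by 3 methods.

## The synthetic study

`simulate_bundle()` generates the whole input set with known truth.
Population structure is Balding–Nichols: ancestral frequencies uniform
on [0.1, 0.5], population frequencies Beta-distributed around them at
Fst 0.1 per population. LD is block-wise with exchangeable within-block
dosage correlation, implemented by a common-cause haplotype draw (each
haplotype copies a block anchor allele with probability `sqrt(r)`),
which hits the target correlation `r = 0.8` exactly in expectation —
clumping and pruning need controllable r², not coalescent realism.
Allele frequencies are constant within a block, so each block is one
locus; loci sit 2 Mb apart and CpGs scatter ±300 kb around a random
locus, making every CpG's cis window cover exactly its own locus.

Cohort sizes default to 423 ("450K", 39% exposed) and 388 ("EPIC", 33%
exposed) with 13% strongly admixed samples; 2,000 SNPs and 1,000 CpGs
keep a full pipeline run under about a minute. Sixty CpGs carry an
exposure effect of |0.5| M-units (three-quarters hypomethylated in the
exposed, the direction imbalance typical of exposure EWAS); fifty of
them also carry a cis effect |β₁| ∈ [0.4, 0.5] from a variant in their
own LD block — planted meQTL CpGs are a subset of exposure CpGs because
only candidates are carried into meQTL mapping. The exposure itself is
logistic in 40 of the planted variants (log-OR ±0.4), the intercept
tuned numerically to the target prevalence. The methylome adds Dirichlet
cell mixtures against strong reference profiles (the written reference
is baseline + profile, i.e. the expected M-value of a purified cell
type, as a published reference would be), a per-cohort batch shift, a
control-probe-correlated technical factor, five *unmeasured*
within-cohort batch factors (the structure residual PCs exist to
capture — without them, in a 1,000-CpG genome the planted exposure
signal itself would be the dominant residual direction and the residual
PCs would absorb it, an artifact of scale rather than of the method),
mild age and tobacco effects, and Gaussian noise (sd 0.5).

Outcome GWAS cohorts (n = 5,000, four studies over three traits) are
fresh draws sharing only frequencies and LD with the discovery cohort —
the two-sample structure. The outcome is γ·exposure (γ = 0.3) plus
direct effects of three pleiotropic variants (per-allele 1.0) plus
noise; marginal regressions are adjusted for the simulated admixture
proportions, as published GWAS adjust for genotype PCs — without this,
admixture correlates every variant with the pleiotropic effects and
biases all instruments coherently, which no outlier test can see. The
catalog plants eight enriched traits whose risk variants are drawn from
the planted meQTL blocks at eight times the background rate, with
genome-wide-significant p-values, against twelve null traits.

What the generator does **not** emulate: realistic 450K/EPIC probe
annotation and probe-type chemistry, raw-intensity normalization,
imputation uncertainty, coalescent haplotype structure, and
non-European-bias of outcome GWAS. Passing tests therefore demonstrate
that the *procedures* are correct and calibrated under a faithful
structural model, not that real-data artifacts specific to array
chemistry are handled.

## Numerical choices and degenerate inputs

- PCA signs are fixed deterministically (largest-magnitude loading
  positive); ties elsewhere (KNN votes, clump p-values, nearest genes,
  equidistant intervals) all have explicit documented rules, so every
  stage is bit-reproducible given the seed, which the determinism tests
  check byte-for-byte on the stage TSVs.
- Monomorphic variants: undefined LD is treated as r² = 0 (retained in
  pruning); per-pair regressions emit a degenerate record with p = 1.
- Betas are clamped before the M-transform; probabilities are validated
  into (0, 1]; a candidate threshold of zero is rejected at
  configuration time, and a run whose screen empties any stage stops
  with a stage-named error rather than propagating empty tables.
- The discrete Fisher test cannot attain size exactly 0.05 at small
  margins; the null-calibration experiment uses margins (universe
  1,000; 125 × 125) whose exact attained size is 0.0488, computed from
  the hypergeometric null before any simulation.
- Problem sizes in the test suite (cohorts of 140/130 for pipeline
  smoke tests, 2,000 independent SNPs for ancestry recovery, 1,000
  replicates for calibration experiments) were chosen so the whole
  suite exercises every claim at meaningful power on a single CPU;
  scaled-down fixtures raise planted effect sizes so per-test power is
  comparable to the full design.

## Alternative phenotype codings

Nothing in the pipeline is specific to the primary exposure contrast: a
secondary binary coding (e.g. high- versus low-frequency exposure within
the exposed subset) reuses every stage unchanged — recode the `exposure`
column of the covariate tables, drop the out-of-contrast samples, and
rerun. This is a configuration of the inputs, not a code path, which is
why no separate mode exists.

## Known limitations

One-sample bias in instrument selection (exposure betas come from the
discovery cohort) is inherited from the emulated design, as is the
linear fit on a binary exposure. The pipeline maps cis effects only; no
trans-meQTLs, no conditional multi-SNP models, no permutation-based
per-CpG thresholds. MR-Egger and multivariable MR are out of scope; the
weighted median and outlier-corrected IVW are the robustness margin.
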