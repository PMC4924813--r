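---
title: "Models and methods in neuroqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in neuroqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroqtl)
```

This vignette is the package's own account of the statistics it
implements: the models, the choices made where more than one reasonable
construction exists, the synthetic-data generator's assumptions, and the
limits of what the test suite demonstrates.

## The SNP × ROI association model

For a subject with minor-allele dosage $g \in \{0,1,2\}$ at one SNP, the
measured trait of one region of interest (ROI) is modelled by ordinary
least squares as

$$y = \alpha + \beta_1 g + \boldsymbol\beta^\top \mathbf{c} + \varepsilon,$$

where $\mathbf{c}$ collects the declared covariates — by default age
(continuous), sex, ethnicity and handedness (categorical, dummy-coded
against the first level in lexicographic order) and a trait-matched
global measure (total brain volume for regional volumes, total surface
area for areas, mean thickness for thicknesses). Fits use complete cases
per SNP × ROI pair. A validation-style model (scanner field strength in,
handedness out) is expressed purely through the `covariates` argument of
`assoc_model_spec()`; no code path changes.

**The per-test chi-square.** The aggregate statistic sums, over the
model's ROI set, a 1-df chi-square per SNP × ROI test. Several 1-df
statistics could play this role (Wald, likelihood ratio, score); they
are asymptotically equivalent, and the squared Wald $t$ of $\beta_1$ is
the only one directly exposed by the stated per-pair model, so
$\chi^2 = t^2$ is used and asserted as an invariant of every fit.

**ROI sets.** Volume aggregates over lh.insula, rh.ACC, the corpus
callosum, left temporal white matter, and lh.SMG. Surface area and
thickness are undefined for the two non-cortical structures, so their
sets hold the three cortical ROIs only; `assoc_model_spec()` refuses a
surface-area or thickness set containing CC or lh.tempWM.

## The permutation test

Significance of $X^2_0 = \sum_{\text{ROI}} \chi^2$ is assessed by
permutation. Each replicate draws **one** random permutation of subjects
and applies it to the genotype rows of *all* SNPs simultaneously:

- permuting genotype rather than phenotype keeps the
  phenotype–covariate relationship intact, so the null being sampled is
  "genotype is independent of (phenotype, covariates)" — the relevant
  null when covariates genuinely predict the phenotype;
- sharing the shuffle across SNPs preserves their LD, which is what
  makes the max-T family-wise modes valid;
- missing genotype calls travel with the shuffled vector and are
  dropped per fit, mirroring the complete-case rule of the observed
  fits.

Monte-Carlo p-values use the add-one rule
$p = (1 + \#\{X^2_n \ge X^2_0\})/(1 + n_\text{perm})$, which is a valid
p-value and never exactly zero. With `exhaustive = TRUE` all $n!$
permutations are enumerated (practical for $n \le 8$) and
$p = \#\{X^2_n \ge X^2_0\}/n!$, the identity permutation included.

Three correction modes are offered because "permutation corrected" can
mean different families: `per_snp` compares each SNP's aggregate with
its own permutation distribution (correcting over that SNP's ROIs only);
`max_t_snps` compares with the distribution of the maximum aggregate
across SNPs; `max_t_snp_roi` compares each single pair's chi-square with
the maximum pair chi-square across all SNPs and ROIs. `per_snp` is the
default; which family a published "corrected" value controls is often
ambiguous, so the mode is always recorded in the output.

A Freedman–Lane scheme (permuting covariate-model residuals instead of
genotypes) is available behind `scheme = "freedman_lane"` for users who
prefer conditioning on the observed genotype margins; with complete
genotype data the two schemes agree closely.

**Implementation.** The permutation loop avoids refitting full models:
with the covariate design fixed, the genotype coefficient's $t$ is
computed through the Frisch–Waugh–Lovell projection (residualize $y$
once, residualize each permuted $g$ against the same orthonormal basis),
which reduces a replicate to a handful of matrix products. This is exact
OLS, verified against explicit normal-equations solves to 1e-8 relative,
and is what makes 500 × 1,000-permutation calibration runs take seconds
per hundred datasets on one CPU.

## Genotype QC, LD, and tagging

- **MAF** folds to $\le 0.5$ and records when the labelled minor allele
  was in fact the major one, so dosage direction stays reconstructible.
- **HWE** uses the exact conditional test (enumeration of heterozygote
  counts given allele counts, summing probabilities no larger than the
  observed configuration's), rather than the chi-square approximation:
  the panels this pipeline sees are small, where the exact test's
  behaviour is the point. A mid-p variant is available.
- **LD r²** defaults to EM over the two-locus haplotype ambiguity
  (initialised at linkage equilibrium; stopped at max change < 1e-8 or
  100 iterations; only the double heterozygote is ambiguous), with
  $r^2 = D^2/(p_A p_a p_B p_b)$. A dosage-correlation fallback (squared
  Pearson correlation of dosages) is provided. The two are distinct
  estimators: without double heterozygotes the EM reduces *exactly* to
  counting realized haplotypes, while the dosage correlation also picks
  up the within-individual cross-haplotype covariance and coincides with
  the haplotype r² only in expectation under random union of gametes.
  The tests assert the exact identity for the former and consistency in
  expectation for the latter.
- **Tag selection** is pairwise greedy set cover at a threshold
  (default 0.8): repeatedly take the SNP covering the most uncovered
  SNPs, ties to the lower index. Greedy cover is within the classical
  logarithmic factor of optimal; on random 8-SNP instances it is checked
  against the exhaustive minimal cover and stays within 2×. Multi-marker
  tagging is out of scope.

## Expression and the TF screen

Expression is averaged within individuals across their regional samples
(unweighted arithmetic mean — no region weighting is attempted), then
regressed on dosage with no covariates by default; a covariate hook
exists but stays empty to mirror a single-probe candidate-variant test,
which also needs no multiplicity correction. The TF screen computes
Pearson correlations on the same per-individual averages; significance
comes from a lack-of-fit style F-test of the regression of target on TF.
With a continuous regressor there are normally no replicated $x$ levels
and hence no pure-error term, in which case the classical lack-of-fit
partition is undefined; the function then falls back to the overall
regression F-test and flags the fallback in its output. When replicates
do exist, the residual sum of squares is partitioned into pure error and
lack of fit and $F = (SS_\text{lof}/df_\text{lof})/(SS_\text{pe}/df_\text{pe})$
is used. Bonferroni multiplies by the size of the *screened panel*
(`n_tests`, default 127 for a motif-annotated human TF set), not by the
number of probes that happened to be testable.

## Motif scoring and allele-specific calls

PWMs are count matrices over A, C, G, T with a background-distributed
pseudocount: $p = (\text{count} + s \cdot bg)/(\text{colsum} + s)$, the
JASPAR-ecosystem convention, with $s = 0.8$ by default, configurable
including 0, and a uniform default background. The relative score of a
window is min–max normalized log₂-odds, so the consensus scores exactly
1 and the anti-consensus exactly 0. With $s = 0$ a zero-count base has
log-odds $-\infty$; the per-column minimum is then taken over
positive-probability bases and any window containing such a base scores
exactly 0 — the one construction that keeps both boundary identities
intact at zero pseudocount.

Only windows overlapping the variant are scanned (a window elsewhere
cannot be genotype-sensitive), on both strands by default; reverse
windows are scored on the reverse complement, and the motif column
aligned over the variable base is mapped accordingly. Ties prefer the
forward strand, then the lower offset. A *differential* call requires
(a) one allele's best overlapping window at or above the match threshold
(default 0.8) and (b) information content
$IC = 2 + \sum_b p_b \log_2 p_b \ge 1$ bit at the aligned column.
Fold-affinity between two single-base alleles is the ratio of the
pseudocounted column probabilities at that column; whole-site odds
ratios reduce to the same number when the flanking columns are shared
by both alleles. For indel alleles the aligned column differs per allele
and the column-ratio is undefined, so indels get their differential flag
from the score comparison alone and `NA` fold — a deliberately
conservative rule.

Prioritization is a pure function of three facts: the sign of the
TF–target correlation, the allele associated with increased expression,
and the allele with the stronger predicted binding. No differential
binding ⇒ `not_genotype_sensitive`; an activator-like (+) TF preferring
the low-expression allele, or a repressor-like (−) TF preferring the
high-expression allele ⇒ `inconsistent`; otherwise `retained`. The full
truth table is property-tested.

## The synthetic-data generator

The generator exists to give every stage inputs with the right
*statistical* structure, not to imitate any real cohort:

- **Genotypes**: per-SNP MAFs drawn uniformly from `maf_range` (default
  0.15–0.5, a common-variant tagging panel); LD blocks via a Gaussian
  copula with exchangeable latent correlation `within_block_r`,
  thresholded at allele-frequency quantiles; haplotypes paired at
  random, so Hardy–Weinberg proportions hold in expectation. Missing
  calls are injected as a separate post-step (default rate 0) so QC
  tests control missingness exactly. Note that the *allelic* r² induced
  by a latent correlation of, say, 0.9 is lower than 0.9 and depends on
  the two MAFs; perfect LD requires equal MAFs and `within_block_r = 1`.
- **Covariates**: age uniform 18–65; sex and handedness binary
  (handedness 10% left, the one nod to neuro cohort convention);
  ethnicity three equally likely levels; scanner field strength binary.
  These exercise dummy coding without imitating any cohort's
  demographics — the defaults are arbitrary and documented as such.
- **Phenotypes**: intercept 50, planted `beta × dosage` effects from
  `effect_map`, optional covariate slopes, Gaussian noise with
  `noise_sd` (default 1, so planted betas read as SD units); the global
  measure is N(100, 10).
- **Expression**: per individual, TF expression is standard normal and
  target = 10 + `eqtl_beta`·dosage + λ·TF + noise, with λ solved so the
  population TF–target correlation equals `tf_target_r`; regional
  samples add independent noise (`region_noise_sd`) around the
  individual value. Defaults (134 individuals × 9 regions, target
  correlation 0.6) give a brain-expression-resource-sized panel in which
  a correlation of that size is comfortably detectable.
- **Motifs**: the designated column's information content is matched to
  within 0.05 bits using a two-base (p, 1−p) profile for targets ≥ 1 bit
  (so 1 bit is exactly 50/50 and 2 bits a single base) and a
  consensus/uniform mixture below 1 bit, where no two-base profile can
  reach. The motif consensus is embedded across the variant for one
  allele.

Every simulator draws from one RNG stream seeded explicitly from its
config; identical seeds give bit-identical outputs, which the pipeline's
manifest makes auditable. What passing tests on these inputs shows is
that the *machinery* is correct and calibrated; they say nothing about
scanner batch effects, population stratification, non-Gaussian phenotype
tails, region-specific expression structure, or any other feature of
real data the generator deliberately omits.

## Numerical and degenerate-input choices

- Constant phenotype in a single fit: β = t = χ² = 0 by definition
  (nothing to explain); in a scan, the pair is instead reported `NA`
  with the reason, so one degenerate column cannot silently flatten a
  grid of results.
- Rank-deficient designs error naming the collinear columns, rather
  than silently dropping them.
- Subjects are aligned across tables on radix-sorted shared IDs, which
  makes permutation p-values exactly invariant to input row order.
- Permutation comparisons use a 1e-12 slack so ties between the observed
  and permuted statistics count as exceedances (conservative).
- EM for haplotype frequencies starts at linkage equilibrium; with no
  double heterozygotes it converges in one step to realized counts.
- The exact HWE enumeration works on the log scale and normalizes by the
  maximum term, so it is stable at any count size used here.

## Problem sizes in the checks

The calibration study uses 500 simulated null datasets of 100 subjects
with 1,000 permutations each; recovery studies use 100 replicates at
n = 1,000 (imaging) and n = 134 (expression); oracle comparisons use 50
random regression designs, 100 random motif/sequence fixtures, 20
exhaustive-permutation fixtures at n = 6, and 25 random 8-SNP tagging
instances. These sizes give the binomial/KS assertions enough resolution
to detect miscalibration of a few percentage points while keeping a full
run in the tens of seconds on a single CPU.

One statistical note on the exhaustive-permutation comparison: a
10,000-replicate Monte-Carlo estimate sits within 2 of its own standard
errors of the exhaustive value about 95% of the time *per fixture*, so
across 20 fixtures the right check is binomial coverage of the 2-SE
band (plus an outlier bound), not a demand that all 20 fall inside — a
correct implementation would fail that demand about a third of the time.

## Known limitations

- No mixed models or kinship/stratification correction; subjects are
  assumed unrelated and exchangeable under the null.
- Two-SNP EM only; no phasing or imputation, no multi-marker tags.
- The eQTL model carries no covariates by default and no region-level
  modelling; averaging across regions discards region-specific signal.
- Motif scoring uses a mononucleotide background and no score p-value
  calibration; fold-affinity for indels is undefined by design.
- The pipeline's synthetic validation cohort shares its effect map with
  discovery; it demonstrates the covariate-specification change, not
  independent replication.
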