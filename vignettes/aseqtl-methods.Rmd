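---
title: "Statistical methods in aseqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in aseqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseqtl)
```

# Scope

`aseqtl` implements the statistical core of a paired genotype/transcriptome
analysis of bulk brain tissue: allele-specific expression (ASE) calling and
site classification, evidence-tier characterisation of unannotated expressed
regions (ERs), cis-eQTL mapping with stepwise conditional analysis, a
mixed-model likelihood-ratio test for slope heterogeneity across a gene's
expression features, and read-depth-matched randomization tests for
enrichment. Everything upstream of these statistics — read alignment,
personal-genome construction, imputation, PEER/CQN normalization, WGCNA
network construction — is out of scope: the package consumes their outputs
(allele counts, residualized expression, covariates, module assignments).

# ASE calling

The unit of analysis is an individual's pair of read counts $(C_1, C_2)$ at
a heterozygous SNP, alleles ordered alphabetically. A site-sample pair is
*valid* when $C_1 + C_2 > 5$ (strictly more than five reads). The effect
size is the adjusted ratio $(C_1 + 0.5)/(C_2 + 0.5)$; the half-count offset
reduces the small-sample bias of the raw ratio.

Significance comes from the two-sided exact binomial test of
$H_0: C_1 = C_2$ (success probability $1/2$), with the minimum-likelihood
two-sided definition: $p = \sum_k P(X = k)$ over all $k$ with
$P(X = k) \le P(X = c_1)$, $n = C_1 + C_2$. This matches the conventional
exact binomial test; a doubled-smaller-tail alternative is available via
`method = "central"`. A numerical subtlety: mirror outcomes $(k, n-k)$ are
mathematically tied but floating-point evaluation can separate them by a few
ulps at $n \approx 200$, so ties are detected with a $1 + 10^{-7}$ relative
tolerance. Non-tied point probabilities at $p = 1/2$ differ by factors of at
least $1 + 2/n$, so the tolerance cannot capture a non-tie.

P-values are converted to FDR by Benjamini–Hochberg *within each sample*:
the multiplicity unit is the individual's own set of valid sites.
Significance is adjusted $p < 0.05$. Pooling across samples is available
behind `pooled = TRUE` for sensitivity analysis only.

Site-level classification: direction is 1 when $C_1 > C_2$, 0 when
$C_1 < C_2$, and undefined at ties (ties never break consistency — direction
is meaningless at equality). A site with at least 10 significant individuals
is *consistent* when every defined direction agrees and *inconsistent*
otherwise; fewer significant individuals give *insufficient*. The
inconsistent pattern is the imprinting-like signature (random
parent-of-origin silencing flips the direction between individuals). The
threshold counts individuals *with a significant call*; counting all tested
individuals is available via `use_all_individuals = TRUE` — the rule is
defined over signals, so the significant-call reading is the default.
Mono-allelic expression — the pattern expected under effective
nonsense-mediated decay — is flagged when strictly more than 95% of reads
come from one allele, and can be corroborated by `dosage_effect_test()`
(t-test for carrier vs non-carrier, one-way ANOVA across three genotype
classes).

# Expressed-region tiers

An unannotated ER is linked to a known gene with *strong* evidence when
split reads (one block on the ER, the other on an exon of the gene) occur in
at least 4 distinct samples; the count is of samples, never of junctions.
Otherwise the nearest gene (boundary-to-boundary distance to the merged exon
span; ties to the lower start coordinate) is considered: *moderate* evidence
requires maximum exon $r^2 > 0.2$ (squared Pearson correlation between ER
and each exon of the nearest gene) *and* distance $< 5\,\mathrm{kb}$, both
strict; anything else with a defined correlation and an available gene is
*weak*; degenerate cases (no gene on the chromosome, constant expression)
are *unclassified*. Distance is measured to the gene span rather than to the
TSS because the downstream $r^2$ rule already uses all exons — the span is
the object the evidence refers to. Tier precedence is
strong > moderate > weak: junction evidence can never demote a region.

Re-expression validation declares a region transcribed when its RPKM exceeds
0.1 in at least 80% of samples. Enhancer overlap is computed on merged
interval sets as the percentage of bases inside enhancers, plus the same
percentage normalized per Mb of set size (adjusting for annotation size)
and the target/reference fold change of the per-Mb values.

# cis-eQTL mapping

Genotype QC removes monomorphic SNPs, SNPs with minor allele frequency
below 0.05, SNPs deviating from Hardy–Weinberg equilibrium (exact
conditional test, $p < 10^{-4}$) and SNPs with fewer than two
heterozygotes. The HWE and heterozygote filters need hard calls and are
skipped, with a warning, for fractional dosages. An optional per-SNP
imputation-quality column (threshold $R^2 > 0.5$) is off by default because
imputation happens upstream of this package. Features are kept when RPKM
exceeds 0.1 in at least 80% of samples.

A SNP–feature pair is *cis* when the distance between the SNP position and
the feature's span is at most 1 Mb, inclusive — "within" is read as $\le$.
Distance is to the full span, not a single anchor, since no anchor is
privileged by the model. Association is ordinary least squares of
residualized expression on dosage plus covariates (the study design used
sex, age and three genetic principal components; any covariate matrix is
accepted, and `residualize()` provides simple least-squares residualization
when a pre-residualized matrix is not supplied). Missing dosages drop the
sample for that test only — no within-analysis imputation. FDR is BH within
each feature's family of cis tests; a global mode exists behind a flag.

Stepwise conditional analysis iterates: add the lead SNP (smallest p) to
the covariates, refit the remaining cis SNPs, re-apply BH within the
feature, stop when nothing passes the FDR level or after `max_steps`
(default 5, bounding runtime). Each signal carries its discovery step as
`conditional_rank`. A consequence of this stopping rule worth knowing: under
the conditional global null the BH family still rejects with probability
$\approx \alpha$ (Simes equality for independent p-values), so after both
true signals are found a spurious third appears in roughly 5% of data sets.
The probability of recovering *exactly* the planted signals is therefore
capped near $(1 - \alpha) \times \text{power}$; the tests account for this
ceiling with Monte-Carlo error allowances rather than pretending the rate
can reach 1.

# Beta-heterogeneity test

Whether an eQTL's effect is shared across a gene's expression features
(exons, junctions, linked ERs) is decided by comparing two linear mixed
models on a long frame of (individual, feature, dosage, expression) rows:

* single slope: `expression ~ dosage + (1 | individual) + (1 | feature)`
* multiple slope: the same plus a fixed `dosage:feature` interaction.

Both are fitted by maximum likelihood, *not* REML: the models differ in
fixed effects and an LRT on fixed effects is invalid under REML. The
statistic $2(\ell_1 - \ell_0)$ (clipped at 0) is referred to a chi-square
with $n_{\text{features}} - 1$ degrees of freedom. The usual
boundary-mixture correction is unnecessary because the random-effect
structure is identical in both models. Fitting uses lme4; singular fits
(variance components at the 0 boundary) are flagged and retained, while
genuine non-convergence is an error and such genes are excluded from the
FDR step. With both variance components at zero the test collapses to the
classical OLS interaction LRT, which the test suite verifies. Genes are
labeled *distinct* when the BH-adjusted heterogeneity p (within a class
pair) is below 0.05, *shared* otherwise. For an intergenic eQTL the
comparator is the known exon with the smallest association p-value for the
same SNP (ties to the lower exon coordinate).

# Depth-matched randomization

To ask whether ASE sites are enriched for GWAS signal without confounding
by read depth (deeper sites have more power to be called ASE), ASE and
non-ASE sites are restricted to SNPs present in the GWAS table, binned by
mean read depth — deciles of the pooled depth distribution by default, the
bin count being configurable since no particular width is canonical — and
the null is built by repeatedly (default $10^5$ iterations) sampling
non-ASE sites with replacement, matching the ASE set's per-bin counts
exactly. Each iteration records $r_i$, the mean $-\log_{10} p$ of the
sample; the observed ASE mean is standardized by the mean and SD of the
$r_i$ and referred to the upper normal tail (the question is enrichment;
two-sided is a flag). The same scaffold with the statistic "fraction of
sampled SNPs that are eQTLs" tests eQTL overlap. With one bin the procedure
is a plain bootstrap, which the tests use as a cross-check. Degenerate
nulls (all values identical) are an error for the GWAS flavour; the overlap
flavour maps them to $z \in \{0, \pm\infty\}$ so that an empty eQTL set
yields $z \le 0$ rather than an error.

Module eigengenes are first principal components of standardized member
features, sign-oriented so the mean member correlation is positive;
membership (kME) is the Pearson correlation of a feature with the
eigengene, with assignment at $\ge 0.3$ (the inclusive reading; strict is a
flag). Cell-type enrichment and GWAS-catalogue overlap use two-sided Fisher
exact tests, BH-corrected across cell types; overlap is by exact SNP id —
no LD-aware locus collapsing is attempted.

# Synthetic data

The generator produces every input with planted truth emitted separately
from the data, at the study's stated conditions where it states them:
Hardy–Weinberg genotypes at MAF uniform in [0.05, 0.5]; additive cis
effects `beta * dosage` with Gaussian noise and an optional shared
per-individual offset (creating the within-individual correlation the
mixed model absorbs); allele counts with four site classes — null
($p = 0.5$), cis-regulated (fixed $p_{alt}$, one direction), imprinted
(direction flipped per individual with probability $1/2$) and NMD
($p_{alt} \ge 0.95$); split reads linking regions to genes in exactly the
requested number of distinct samples; GWAS $-\log_{10} p$ drawn from
Exponential($\ln 10$) (uniform p) with an additive shift on the enriched
subset. Read depth follows a discretized log-normal, median 20,
$\sigma_{\log} = 0.8$, truncated at 1 — the source study does not state
its depth distribution, and this shape reproduces the long right tail of
exome coverage; any positive-support alternative can be passed. All SNPs
and features live on one synthetic chromosome with cis relationships
planted within 1 Mb by construction, which exercises the interval logic
without a genome build.

What the generator does *not* emulate: mapping bias and its personal-genome
correction, LD between SNPs (dosages are independent, except where a test
plants correlated copies deliberately), batch structure, and the real
study's scale (hundreds of thousands of het sites per sample). Passing
tests therefore demonstrate correctness of the statistics under their own
assumptions, not robustness to alignment artefacts.

# Problem sizes and numerical choices

The test suite uses desk-scale sizes chosen to make Monte-Carlo bounds
meaningful: $10^5$ null sites for type-I calibration, 500 replicates for
eQTL recovery and heterogeneity type-I, 200 for stepwise recovery, 500
scaled-down randomization runs of 2,000 iterations, and full enumeration up
to totals of 200 for the exact test. The acceptance script runs the whole
pipeline at 100 samples x 120 SNPs x 48 exon features, 40 individuals x 60
ASE sites, and 20,000 randomization iterations. Stochastic assertions use
3-Monte-Carlo-SE bounds around the quantity's expectation; exact
comparisons (BH, enumeration, cis pairing, tier rules) demand identity.

Other numerical choices: BH ties and monotonicity come from
`stats::p.adjust`; mixed-model convergence failures are errors carrying the
optimizer diagnostics, while boundary (singular) fits are flagged and kept;
variance estimates are clamped at zero rather than rejected; the LRT
statistic is clipped at zero and a likelihood *decrease* beyond $10^{-6}$
is treated as an optimizer failure; all internal coordinates are 0-based
half-open with conversion only at the VCF boundary (1-based), preventing
off-by-one drift between modules.

# Known limitations

* No LD-aware enrichment: overlap tests match exact SNP ids.
* The stepwise procedure's exactly-k recovery is bounded by
  $(1-\alpha)$ as described above; report counts, not certainties.
* Consistency classification needs $\ge 10$ significant individuals;
  sparsely covered sites return *insufficient* rather than a guess.
* The heterogeneity chi-square reference is asymptotic; at very small
  individual counts (the package refuses fewer than 10) it can be
  mildly anticonservative.
* Fractional dosages skip HWE/heterozygote QC (they need hard calls).
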