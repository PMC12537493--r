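---
title: "Methods: population analysis of gene-body methylation epialleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analysis of gene-body methylation epialleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant genomes carry two very different kinds of intragenic DNA
methylation. Gene-body methylation (gbM) is CG-context-only methylation
inside transcribed genes; TE-like methylation (teM) combines CG with
non-CG (CHG/CHH) methylation and silences. Across natural *Arabidopsis*
accessions a gene can be gbM in some accessions and unmethylated (UM) in
others: a heritable epiallele. This package implements the statistical
machinery needed to ask whether such epialleles matter — whether gbM
variation explains expression variation beyond what linked DNA sequence
variation explains, and whether epialleles associate with organismal
traits — together with a synthetic-data generator that reproduces the
statistical structure of such a study so every stage is testable without
any external download.

## Site calling and gene states

Per-site methylation status is decided from bisulfite read counts in two
steps. First, coverage sufficiency: a site's coverage `n` is sufficient
when the most extreme achievable outcome at that coverage would reach
one-sided Fisher's-exact significance against an idealized same-coverage
reference sample under *both* alternatives — fully unmethylated with
conversion error, and fully methylated with the symmetric error. At
`alpha = 0.05` this makes 4 reads the smallest sufficient coverage
(at `n = 2` the smallest attainable Fisher p is 1/6). We chose this
construction because the exact 2x2 table used historically for this
filter is not recoverable; it is isolated in one function
(`call_site()`) so the policy can be swapped. Second, for sufficient
sites, a one-sided binomial test asks whether methylated reads exceed
the conversion-error expectation; significant sites with a
methylated-read fraction below 0.45 are *partial* (treated as missing),
the rest are *methylated*; insignificant sufficient sites are
*unmethylated*. The error rate is supplied per accession (in real data
it comes from the chloroplast, which is unmethylated; synthetic runs
pass the known simulation rate; default 0.005).

Segmentation is a deliberately simple gap-merge policy (the published
analyses defer to an external segmentation tool whose algorithm is not
restated): maximal runs of methylated sites separated by at most
`max_gap` (default 200 bp) form segments; a segment containing a
methylated non-CG site is teM-like, otherwise gbM-like. The
classification rules that consume segments are fully specified and
implemented exactly: a gene with a gbM-like segment spanning three or
more CG sites (at least one methylated) is gbM unless a teM-like segment
at least 25% as long (bp; the unit is our choice, the source is
ambiguous) also overlaps it, in which case it is *both*; symmetrically
for teM; a gene with no segments and at least three unmethylated-called
sites is UM; everything else is *indeterminate*. *Both* and
*indeterminate* genes are carried in the matrix but excluded from the
association analyses. Mean mCG of a gene is methylated CG sites over
binomially called CG sites (partial/insufficient sites excluded); with
no called site it is missing, never zero.

## The epimutation simulator

The generator's steady-state model is a per-site cooperative gain/loss
Markov chain: each generation an unmethylated site gains methylation
with probability `gain_base + gain_coop * f`, where `f` is the mean
state of the other sites in the locus, and each methylated site loses
it with probability `loss_rate`; updates are synchronous and lineages
independent, starting fully unmethylated and run for 100,000
generations by default. Whole-locus coupling is the simplest
cooperativity that yields the known qualitative behaviour — a bimodal
population distribution of per-gene mCG with most lineages near 0 or
near the methylated fixed point — while remaining exactly checkable
against the stationary vector of the explicit `2^k`-state chain for
small loci (the test suite does this for 2 and 3 sites). Default rates
(`gain_base = 1e-6`, `gain_coop = 0.3`, `loss_rate = 0.05`) were chosen
once so that seeding of an unmethylated locus is rare on the 100,000
generation horizon while reinforcement after seeding is fast: about
half the default panel ends low, a third high, and few in between. The
exact published epimutation-rate parameterization is intentionally out
of scope; these are stand-in rates for a qualitative regime, not
estimates. Read counts are Poisson with configurable mean depth (the
standard shotgun model; depth distribution is otherwise unspecified),
with non-conversion and over-conversion error rates defaulting to 0.005
each. Genotypes are haploid 0/1 by default, matching essentially
homozygous inbred accessions; subpopulations diverge under a
Balding-Nichols model and within-block LD decays geometrically via a
latent Gaussian AR(1).

## Variance partitioning

Expression of each gene is modelled as
`y = X_gbM b_gbM + X_teM b_teM + X_snp b_snp + e` with every effect drawn
from a mixture of a point mass at zero and three normal slabs whose
variances are `{1e-4, 1e-3, 1e-2}` times a per-group scale (the scale
constants follow the BayesR convention; the software used in the
original analyses does not print its constants). The sampler is a
single-site Gibbs sampler written in C++: each effect is updated
conditional on all other effects in its own and the other groups;
mixture proportions, per-group scales and the residual variance are
drawn from their conjugate conditionals. Marker columns are
standardized and the response is centred — the sampler fits no
intercept, so an uncentred response would inflate the residual
variance. Per kept iteration the group
PVE is `Var(X_g b_g) / Var(y)`; defaults keep 5,000 samples after a
2,000-iteration burn-in.

Two numerical choices deserve note. First, the Dirichlet prior on the
mixture proportions is spike-weighted (concentration 19 on the spike,
1/3 on each slab) rather than flat: at a few hundred accessions the
spike and the smallest slab are likelihood-indistinguishable for a null
marker, and a flat prior lets mixture occupancy random-walk into the
slabs, inflating null group PVEs; the spike-weighted prior keeps the
spike occupancy at or above 90% under the null while leaving real
signals (which enter through likelihood, not prior) essentially
untouched. Second, the reported residual fraction is the unattributed
remainder `1 - sum(PVE_g)`, which makes the per-sample accounting exact;
the realized-residual fraction `Var(e)/Var(y)` is also returned
(`noise_frac`) and differs from it only by posterior cross-covariance
terms — a few percent at these scales. Genes are retained only when two
independently seeded runs agree (maximum group-PVE discrepancy and
within-chain drift both below 0.1 by default); a single run falls back
to a split-half diagnostic, recorded in the output.

Marker filters mirror the study design: genes without detected
expression in more than half the accessions are dropped; gbM/teM marker
genes need a methylated CG call in more than 20% of accessions for
variance partitioning (10% for eQTL mapping); SNPs need allele frequency
at or above 15%. Missing marker values are mean-imputed before
standardization; constant columns are dropped and counted.

## eQTL mapping and genetic confounding

Per gene, expression is regressed on its own mCG level: the package
reports Pearson `R` with its t-distribution p-value, the slope on
original scales `beta = R * sigma_P / sigma_mCG`, and
`PVE = 100 * beta^2 * V_mCG / V_P` — algebraically `100 R^2`, an identity
the tests assert to 1e-12. Missing pairs are dropped listwise.
Significance tiers are Bonferroni (`alpha/m` with `m` computed from the
eligible gene count, never hard-coded) and Benjamini-Hochberg at 0.05
and 0.10; tiered genes are classed `+eQTL`/`-eQTL` by the sign of `R`.

A significant mCG-expression association may be a shadow of linked DNA
sequence variation. The confound pipeline decides this per gene: a cis
scan over window SNPs (gene span plus 4 kb flanks; the flank is stated
for haplotypes and structural variants and we unify the cis window with
it) at the Bonferroni level; if a colocalized SNP exists, the panel is
split into the two nested populations fixed for that SNP and the
association is re-tested within each — *retained* if significant in at
least one valid nested population (at least 15 accessions and non-zero
mCG variance), *lost* if testable but nowhere significant, *untestable*
otherwise (with a flag to collapse untestable into lost for replication
of analyses that did so). The 15-accession floor is stated for
haplogroups and reused for nested and SV-invariant subpopulations as a
single smallest-analysable-group policy. Haplogroups are equivalence
classes of identical window genotypes (missing genotypes exclude the
accession rather than being imputed); within-haplogroup tests use a
two-sample t-test for binary epialleles and correlation for quantitative
mCG. LD between an epiallele and a SNP is computed from haplotype
frequencies (`r`, `D`, `D'` with the standard sign-dependent `D_max`,
p from the 1-df chi-square `n r^2`). Trans-QTL variance for a focal
gene's mCG is the sum of squares of jointly fitted Bonferroni-significant
genome-wide SNPs (after all other model terms) over the total sum of
squares; re-estimating it in small subsampled panels reproduces the
Beavis effect — conditioning on significance inflates the mean estimate.

## Epigenome-wide association

Binary epiallelic states (gbM = 1 vs UM = 0; teM analogously; *both* and
*indeterminate* are missing) are the markers. Filters: minor epiallele
frequency at least 5% and methylated-class frequency above 10%. Models:
a fixed-effects LM; a GLM that adds structure covariates Q (the top
principal components of the epiallele matrix, default 3 — the number
used originally is unstated); and an MLM `Y = X beta + Z u + e` with the
polygenic covariance proportional to the identity-by-state kinship K
(fraction of shared states over markers non-missing in both accessions,
diagonal 1, negative eigenvalues clipped at zero with a count). The MLM
estimates variance components once by REML under the null model on the
eigenbasis of K and reuses them for every marker (the P3D/EMMAX
convention, which the original tooling also uses); with `K = I` it
reduces to the LM, a degenerate-case equivalence the tests assert at
1e-6 relative precision. Genomic control computes
`lambda = median(observed chi^2) / median(expected chi^2)` on 1-df
quantiles; corrected p-values divide each chi-square by lambda. The
correction is applied as computed by default; a flag skips it when
lambda is below 1 (deflation handling is not specified by the source
analyses). All tested markers enter the lambda computation by default,
with an optional thinning stride standing in for the unspecified
"unlinked" subset. Significance is Benjamini-Hochberg at FDR 0.05 on
corrected p-values. A plain LM on quantitative mCG is provided but, as
the calibration tests show, inflates badly in structured populations —
the MLM is the recommended model there.

## Perturbation contrasts

For met1-style experiments the package classifies genes by methylation
change with the printed thresholds: *demethylated* requires wild-type
mCG above 10%, a loss of more than 5%, and mutant mCG below 5%;
eligible genes gaining non-CG methylation (mutant mCHG or mCHH above
0.01) are excluded; remaining eligible genes are *kept* — the "keeps
methylation" class has no printed threshold, so we define it as
eligibility without demethylation, configurable. Genes whose TSS window
(-100 to +250 bp, strand-aware) has mCG above 5% are excluded from
expression contrasts; genes with no CG site in the window are kept and
flagged (missing-window handling is unspecified). Interreplicate
variability is the coefficient of variation across biological
replicates, computed only for genes detected in every replicate.
Expression contrasts between eQTL classes and the non-associated class
use a two-sample t-test — Welch by default, pooled optional, since the
original variant is unstated.

## Problem sizes and what the tests show

The packaged checks run at deliberately moderate scale, chosen once:
variance-partition recovery at 500 accessions with 1,400 markers and
5,000 kept samples; state-calling recovery over 600 accessions by 200
genes at 30x depth; epiGWA calibration with 2,000 markers at 600
accessions and 100 seeded causal-recovery repeats; the epimutation
stationary check with 5,000 lineages on a 3-site locus; trans-PVE
subsampling with 50 seeds. The generator emulates the statistical
skeleton of a natural-accession study — bimodal gbM from cooperative
epimutation, sparse group-structured expression effects, LD between
epialleles and SNPs, population stratification, epiallele-driven traits,
bisulfite counting noise. It does not emulate alignment artefacts,
SNP/indel masking, non-CG methylation level variation beyond teM
flagging, recombination or demography, or real LD structure beyond
block-AR(1) decay; passing tests therefore validate the statistical
machinery, not those upstream steps.

## Known limitations

The segmentation policy is interchangeable preprocessing, not a
reimplementation of the published segmenter; haplogroup definitions are
exact-match and will fragment in panels with high SNP density; the MLM
assumes a single variance-component structure (no multi-kinship or
multi-trait support); the sampler's hyperparameters are conventional
defaults, not calibrated equivalents of any external software.
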