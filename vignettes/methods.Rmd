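---
title: "Allele-resolved methylation analysis in a reciprocal cross: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-resolved methylation analysis in a reciprocal cross: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmeth)
```

## The design and what it identifies

crossmeth analyses reduced representation bisulfite sequencing (RRBS) from a
reciprocal cross of two inbred mouse strains, C57BL/6J (B6) and DBA/2J (DBA):
female and male parents of each strain plus BXD F1s (B6 mother, DBA father)
and DXB F1s (DBA mother, B6 father) — eight samples in all. The reciprocal
design decouples the two explanations for an allelic methylation difference
in an F1: a *genotype* effect follows the strain of the chromosome in both
cross directions, while a *parent-of-origin* (imprinting) effect follows the
mother/father axis and therefore swaps strains between BXD and DXB. Inbred
parents add a third lever: each parent carries two genotype-identical
chromosomes, so any within-sample allelic structure in a parent cannot be
genotype-driven.

Four questions are asked of the data, each with its own screen:

1. **Strain differences** — per-site comparison of the two parental strains.
2. **Allele differences** — B6 versus DBA chromosomes across all samples,
   using SNP-phased reads in the F1s.
3. **Sex differences** — females versus males, pooled over genotypes.
4. **Imprinting** — maternal versus paternal chromosomes in the F1s, and,
   independently of genotype, allelically methylated regions (AMRs) shared
   between F1s and parents.

A fifth analysis compares each parent with the genotype-identical chromosome
in its own offspring to count intergenerational *epimutations*.

## Site-level statistics

### Pairwise binomial criterion

For two samples at one cytosine with counts $(k_a, n_a)$ and $(k_b, n_b)$,
the site is differentially methylated when

* both coverages are at least 10 reads,
* each sample's level $k/n$ lies outside the other's exact (Clopper-Pearson)
  95% confidence interval, and
* the absolute level difference (delta) exceeds 0.5.

The Clopper-Pearson interval is the equal-tailed inversion of the binomial
tails, computed through the beta quantile closed form; the test suite checks
it against a direct bisection on the binomial tail probabilities to 1e-9.
The criterion is symmetric in its arguments. Fixed thresholds rather than a
per-site multiple-testing correction are used deliberately: the operating
characteristic is measured afterwards by simulation (below).

### Group t-tests

The allele, sex and imprinting screens compare per-sample methylation
fractions between two groups with a pooled-variance two-sample t-test
(`group_ttest()`, equivalent to `t.test(var.equal = TRUE)`). Per-sample
fractions — not pooled read counts — are the replicate unit, so
between-mouse variation enters the error term. Presets:

| screen     | p threshold | delta threshold | groups |
|------------|-------------|-----------------|--------|
| allele     | 0.05        | 0.5             | B6 vs DBA chromosomes (parents + phased F1 alleles) |
| sex        | 0.001       | 0.2             | all females vs all males |
| imprinting | 1e-6        | none            | maternal vs paternal F1 alleles |

Sites enter a t-test only with coverage of at least 10 reads in a sample and
at least `min_group_size = 3` usable samples per group (the replicate floor
is a package choice; with fewer than three values a pooled variance is too
unstable to interpret). Zero pooled variance with equal means returns p = 1;
with unequal means the p-value is reported at the machine floor and flagged
degenerate rather than silently zero.

The sex screen pools parents and F1s (sex is a property of the mouse, not of
a chromosome). A consequence handled explicitly elsewhere: parent-offspring
comparisons cross sexes, so the epimutation stage removes sex-differential
sites (see below).

### Simulation-based FDR

Every screen's fixed thresholds are calibrated by resampling the observed
counts under a binomial null: each compared sample's methylated count at a
site is replaced by a Binomial(n, p) draw with n the sample's observed
coverage and p the site's methylation level pooled across the compared
samples (the natural null of "no difference at this site"). The false
discovery rate is reported as x/y, where y is the number of significant
sites in the observed data and x the mean significant count over the null
replicates (1000 replicates for the t-test screens; a single draw is
recovered with `n_sims = 1`). Pooling p across the compared groups is a
design choice; the per-sample coverage pattern is preserved exactly.

Storey q-values (`storey_qvalue()`) serve the expression screens:
$\hat\pi_0 = \min(1, \overline{\#\{p > \lambda\}} / (1-\lambda))$ with
$\lambda = 0.5$ (exposed as a parameter; the estimate is insensitive to
lambda in the data sizes used here), and step-up q-values capped at 1.

## SNP calling and read phasing

Bisulfite conversion turns unmethylated C into T, so C/T base differences on
a read are uninterpretable as SNPs; on reads originating from the minus
strand the same confound appears as G/A. `call_snps()` therefore pools
A/C/G/T counts across the B6, DBA and BXD samples and emits a biallelic call
only when total coverage is at least 6, the minor allele frequency is at
least 10%, counts on third alleles stay below 5%, and the allele pair is not
the strand's confounded pair. The six-count minimum is interpreted as total
coverage (not minor-allele depth). Parental genotypes are then read off the
strain-pure parental counts, and each F1 read votes with its observed bases:
strict majority assigns B6 or DBA, ties are ambiguous, reads without
informative SNPs are uninformative, and bases matching neither parent are
counted as mismatches (sequencing error) without voting.

`parent_of_origin()` is the exact map (B6, BXD) -> maternal,
(DBA, BXD) -> paternal, and its mirror for DXB.

## The two-allele AMR scan

Phasing reaches only reads that overlap a SNP. The AMR scan removes that
limitation: it asks, genotype-free, whether the reads over a window of 10
consecutive CpGs segregate into two methylation patterns. Two nested models
are fitted to the reads-by-CpGs state matrix (M = 1, U = 0, N missing):

* **single profile** — one per-CpG level vector, maximum-likelihood
  frequencies clamped to [1e-3, 1 - 1e-3];
* **two-allele mixture** — an equal-weight (0.5/0.5, two chromosomes per
  cell) mixture of two profiles with independent Bernoulli emissions per
  CpG, fitted by EM over read responsibilities.

The clamping bound keeps single-read log-likelihoods finite and acts as a
weak prior against degenerate profiles. The EM starts from the pooled
profile — a fixed point whose likelihood equals the single-profile model, so
the likelihood ratio is never negative — plus five random starts; the
observed-data log-likelihood is monotone across iterations (verified on
1000 random windows in the tests) and iteration stops when the change falls
below a tolerance relative to 1 + |logL|. Reads stay fractionally assigned;
they are never hard-clustered.

Windows slide one CpG at a time. Significance uses the likelihood-ratio
statistic against a chi-square with 10 degrees of freedom (one per CpG level
duplicated by the second component). Mixture LRTs are irregular at the
boundary, so this reference is approximate by construction; a permutation
alternative (shuffling states within CpG columns) is provided for
calibration. A window is reported at p < 0.01 with a fitted between-profile
delta above 0.5; overlapping significant windows merge into maximal regions
(any-overlap union, carrying the minimum p and maximum delta). Known
limitation: the fitted separation overshoots the true one by roughly
0.05-0.1 at moderate separations (finite-sample mixture bias), so the
delta > 0.5 filter admits true separations somewhat below 0.5; the tests
exercise the filter well away from the boundary.

A cluster of per-sample AMRs becomes a **candidate imprinted region** when
present in at least 6 of the 8 samples *including at least one parent and
one F1*: parents are inbred, so a parental AMR cannot be genotype-driven,
and requiring parental presence discards the genotype-ASM regions that F1s
alone would contribute.

## Epimutations

Each F1 chromosome is compared with the parent that actually transmitted
it: the B6 chromosome of a BXD F1 with the B6 mother, the DBA chromosome
with the DBA father, and the mirrored pairing in DXB — eight parent-F1
chromosome pairs per cross. Each pair is tested with the pairwise binomial
criterion (delta > 0.5). A site's reproducibility class is the number of
pairs significant in a consistent direction (direction consistency is a
package choice; opposite-direction changes are different events). Sites in
known imprinted genes are excluded — imprinted regions sit near 50%
methylation in a parent but near 0 or 100% on a phased F1 allele, a
systematic artefact of the comparison, not an epimutation. For the same
reason the pipeline also excludes its own sex-screen hits, because the
transmitting parent and the offspring can differ in sex.

## The synthetic data generator

`build_truth_model()` + `simulate_cross()` generate the eight-sample design
with a fully known truth. Defaults are the study conditions the package
targets:

* ~60x mean per-CpG coverage (Poisson), symmetric state/base error rate
  0.01 (combined bisulfite non-conversion and sequencing error);
* CG baseline drawn from a two-component beta mixture (low ~0.05 for
  island-like CpGs, high ~0.85 elsewhere) with the weight solved so the mean
  is 48.39%; CHG/CHH baselines with means 0.71% and 0.75%;
* 12 regions of 60 CpGs (10-40 bp spacing) across 4 chromosomes — large
  enough for every screen to be exercised at study-scale coverage while a
  full pipeline run stays in the minutes range on one CPU;
* 10 SNPs per region, one quarter C/T (deliberately uncallable, to exercise
  the bisulfite exclusion); non-C/T pairs drawn from the remaining pairs;
* planted effects on disjoint sites: 100 strain CpGs at delta 0.8, two
  12-CpG strain-region blocks (genotype ASM), 60 sex CpGs at delta 0.6,
  three imprinted regions of 12 CpGs (maternal 0.95 / paternal 0.05,
  expressed on the maternal allele in both cross directions), and four
  epimutation sites (base 0.05 shifted to 0.9 on one F1 chromosome, or on
  both F1s of one cross direction to produce reproducibility class 2).
  Epimutation sites are planted only at CpGs within read range of a usable
  SNP, since an unphaseable epimutation is invisible to the comparison the
  class definitions describe.

Reads are fixed-width windows of 8 consecutive CpGs whose starts tile past
the region edges, so per-CpG coverage is uniform in expectation; restriction
fragment and size-selection mechanics are not modelled — coverage is drawn
directly. Each read comes from one of the sample's two chromosomes (strain,
parental origin) and records the bases it observes at overlapping SNPs; the
true chromosome rides along in a hidden truth channel that only tests may
consult. Sex-effect levels depend on the sample's sex, not the chromosome.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: mouse genome scale and sequence composition,
fragment-level coverage autocorrelation, PCR duplicates, quality scores,
strand asymmetries, between-mouse biological dispersion beyond binomial
sampling (an intra-group dispersion knob is deliberately absent rather than
set to an invented value), and realistic SNP density. Recovery rates on
synthetic data are statements about the implementation under the stated
conditions, not power claims for an arbitrary experiment.

## Pipeline and problem sizes

`run_pipeline()` chains simulate -> SNP calling -> allele assignment ->
the four screens with their FDR calibrations -> epimutations -> AMR scan
and candidate intersection -> allelic-expression and sex-expression screens,
writing per-stage TSV/BED/JSON plus a `summary.json` whose counts equal the
line counts of the detail files, and a truth-versus-detected recovery block.
All randomness derives from the single configured seed, so reruns are
byte-identical. Stages whose required samples are absent are skipped with a
logged reason.

The calibration analyses use 10,000 null plus 500 planted sites (pairwise
screen, 25 resamplings), and 5,000 sites with 8 or 4 samples per group
(t-test screens, 1000 and 200 resamplings) — sizes at which the x/y ratio is
stable to well under the bounds being checked while each analysis completes
in seconds to a couple of minutes on one CPU.

## Known limitations

* The chi-square reference for the AMR LRT is anti-conservative in
  principle; the delta filter dominates in practice, and the permutation
  p-value is available where calibration matters.
* The imprinting t-test screen is power-limited by phasing: only CpGs
  within read range of a SNP have per-allele fractions, and at four samples
  per group the p < 1e-6 bar is passed only by strong, well-covered sites.
  This mirrors the motivation for the genotype-free AMR route, which the
  candidate-region intersection then backs with parental evidence.
* Allelic expression tables are analysed per gene; per-SNP aggregation
  within a gene is upstream of this package.
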