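---
title: "Methods behind snpdiv: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind snpdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical content of `snpdiv`: what each
stage computes, under which assumptions, which parameters matter, and
where a design decision was genuinely open and how it was resolved. It is
written for a reader who wants to judge whether the defaults fit their
data, not as a usage tutorial (see the README for a worked example).

## Data model

The central object is a `genotype_matrix`: diploid individuals × biallelic
loci, each call coded as the dosage of a designated B allele
(0, 1, 2, `NA`). Everything downstream is allele-frequency arithmetic on
this matrix. Two deliberate conventions:

* When genotypes arrive as letter pairs without a chip manifest
  (PLINK ped/map or the TSV matrix dialect), the lexicographically later
  observed allele at each locus is designated B. This is deterministic and
  reproducible, but it means the A/B orientation of a locus monomorphic in
  the data is arbitrary (the single observed allele becomes B). All
  statistics in the package are invariant to allele orientation, so only
  file round-trips of monomorphic loci are affected.
* Coordinates are 1-based inclusive throughout, matching the convention of
  livestock genome annotation tables.

## Marker quality control

Five filters run **sequentially** — GenTrain score, pooled MAF, per-locus
missingness, unmapped probes, multi-hit probes — and each step's removal
count refers only to loci that survived the earlier steps, so the counts
sum exactly to the survivor deficit. This sequential (not marginal)
bookkeeping is the convention under which a published filter cascade's
per-step counts add up; it is asserted as an invariant
(`initial = surviving + Σ removed`) on every run.

Defaults: GenTrain ≥ 0.6 (Illumina's usual cluster-quality floor for
50K-class arrays), pooled MAF ≥ 0.05, missingness ≤ 0.05, uniquely mapped
probes only. Hardy–Weinberg equilibrium is tested (pooled-sample χ² with
1 df, no continuity correction) but **reported rather than filtered** by
default: on a structured multi-breed pool a modest HWE excess is expected
(Wahlund effect), and removing those loci would bias differentiation
estimates. Setting `hwe_alpha` to a number turns the report into a sixth
removal step.

Two open points were resolved as follows. The MAF filter uses the pooled
(all-breeds) frequency, so within-breed MAFs below 0.05 can and do remain
afterwards — which is why the rare class of the per-breed MAF histogram is
not empty. Sample-level QC is a per-sample call-rate threshold (default
0.95): chip studies routinely drop one or two samples for low call rate,
but published methods rarely state the exact criterion, so it is exposed
as a parameter rather than hard-coded.

## Within-population diversity

Per locus, H_O is the heterozygote fraction among non-missing calls and
H_E is the gene diversity 2p(1−p), multiplied by Nei's (1978) small-sample
factor 2n/(2n−1) by default (`unbiased = TRUE`). The correction exactly
cancels the downward bias of the plug-in 2p̂q̂, so the estimator's
expectation is the true 2pq; at n ≈ 24 the correction is ~1%, visible in
the third decimal.

F_IS is the multilocus Wright form 1 − H̄_O/H̄_E — a **ratio of means
over loci**, not a mean of per-locus ratios, which would blow up at
low-diversity loci. Its confidence interval resamples loci with
replacement (default 1000 replicates) and applies the bias-corrected (BC)
percentile method; BC without acceleration was chosen because the
acceleration constant adds nothing detectable at these locus counts and
the plain percentile interval is noticeably biased for a ratio statistic.
The estimate is called significant when the interval excludes 0. The
probit transform inside BC is guarded against degenerate bootstrap
distributions (all replicates on one side) by clamping the bias proportion
to [1/(2R), 1 − 1/(2R)].

Percent polymorphic counts loci where both alleles are observed in the
subset, over loci with at least one call. The MAF histogram uses the four
conventional classes with half-open bins [0, .05), [.05, .10), [.10, .30),
[.30, .50] — the published class limits overlap at the boundaries, and the
half-open convention (closed only at 0.5) is the unique assignment that
conserves totals.

## F_ST: Weir–Cockerham θ

Per-locus differentiation uses the Weir & Cockerham (1984)
variance-components estimator for diploid biallelic data with unequal
sample sizes: among-population (a), among-individual (b) and
within-individual (c) components, θ = a/(a+b+c). The multilocus estimate
is the ratio of summed components Σa/Σ(a+b+c) — invariant to locus order
and to duplication, and the form under which loci with more information
weigh more. Three numerical details:

* Loci where any population has zero calls are skipped for that contrast;
  loci monomorphic overall (a+b+c = 0) are marked undefined and excluded
  from the sums.
* Negative estimates are preserved, never clamped: θ̂ < 0 is the
  estimator's correct behaviour when observed between-population variance
  falls below its null expectation. In particular, two populations with
  *identical* genotype counts give a slightly **negative** θ̂ (s² = 0
  makes a = −b for HWE-ish counts), not zero; the exact-zero case is the
  degenerate all-heterozygote configuration. The test suite asserts these
  closed forms against an independently coded textbook implementation to
  1e−12.
* Significance comes from a locus bootstrap of the ratio estimator
  (default 1000 replicates): the percentile interval at level 1−α with
  α = 0.005 (Bonferroni-style for six pairwise tests) must exclude 0; a
  second tier at α = 0.01 flags "suggestive" contrasts. Note that with
  tens of thousands of informative loci this bootstrap is powerful: any
  genuinely non-zero drift, however small, will be declared significant.

One-vs-rest contrasts pool the remaining breeds into a single population
and keep the per-locus θ vector, which downstream outlier validation
thresholds at mean + k·SD.

## Distances, clustering, AMOVA, kinship

Nei's (1972) standard distance is computed between individuals by treating
each individual as a "population" with allele frequencies in {0, ½, 1};
J-terms are averaged over **pairwise-complete** loci (with ≤5% post-QC
missingness, listwise deletion would discard most loci for no benefit).
Opposite fixation at every shared locus gives J_XY = 0 and D = +∞; the
matrix keeps the infinity and the pipeline substitutes 2× the largest
finite distance only for clustering, so the pathology stays visible in the
output. Small negative logs from rounding are clamped to 0.

The Reynolds (1983) coancestry distance between populations is the
weighted least-squares estimator (ratio of locus-summed numerator and
denominator with the (n₁+n₂−1) sample-size corrections), floored at 0; it
is 0 for identical profiles and exactly 1 for a fixed difference at any
sample size. Manhattan distance is the mean absolute dosage difference
over pairwise-complete loci — per-locus normalisation keeps missingness
patterns from scaling distances — and IBS kinship is its complement,
K = 1 − d/2.

Clustering is `stats::hclust`, default complete linkage (the R default a
typical chip study uses implicitly), with average/single/ward available;
trees export to Newick through `ape::as.phylo`, so merge heights become
branch lengths.

AMOVA is the two-level Excoffier (1992) decomposition of squared
inter-individual distances: SS_total = Σ_{i<j} d²/N, SS_within summed per
group over d²/n_g, variance components from the expected mean squares with
n₀ = (N − Σn_g²/N)/(G−1), and Φ_ST = σ²_among/(σ²_among+σ²_within).
Published livestock AMOVA tables sometimes label the within component
"within individuals"; since the two printed percentages sum to 100 the
decomposition is genuinely two-level, and that is what is implemented.
Significance permutes individuals among groups of fixed sizes;
p = (1 + #{Φ* ≥ Φ})/(1 + P), default P = 10,000 (a claimed p < 10⁻⁶ would
need ≥10⁶ permutations; P is a parameter).

## PCA contribution selection and F_ST validation

PCA runs on the per-locus mean-imputed, column-centered dosage matrix via
`stats::prcomp`, **without** variance scaling by default: scaling is not
part of standard genotype PCA, monomorphic loci would break it, and the
selection statistic below is cleaner without it (a `scale` flag exists).
For reproducibility each loading column is oriented so its
largest-magnitude entry is positive.

The per-SNP selection statistic follows the variable-correlation chain:
r_j = loading_j × sd(PC), cos²_j = r_j², contribution_j = 100·cos²_j/Σcos².
With unit-norm loading columns this is algebraically identical to
100·loading_j² — the identity is asserted to 1e−9 on every call, which
also settles an ambiguity in the published chain ("percentage of total
variation"): the FactoMineR-style per-component cos² sum is the only
reading consistent with the printed expected contribution 100/M %.
Selection keeps SNPs with contribution ≥ factor × 100/M (inclusive ≥,
default factor 10); validation counts selected SNPs **strictly above**
mean + k·SD (default k = 2) of the genome-wide one-vs-rest per-locus θ —
inclusive selection but strict validation mirrors the wording conventions
of the thresholds ("≥" vs "higher than"), and the degenerate sd = 0 case
therefore counts zero. Per-individual contributions are the score-share
analogue 100·score²/Σscore².

A caveat the simulations quantify: the 10×-expected threshold is a fixed
fraction of PC1's loading mass, so its sensitivity to planted outlier loci
depends on how much of PC1 is carried by genome-wide background drift.
With 50 loci shifted by δ = 0.35 in one of four populations (24
individuals each, 10,000 loci), the acceptance suite measures mean
sensitivity around one half when the background drift is uniform
(F = 0.02) and far lower when the target population also carries strong
genome-wide drift (F = 0.08) — while false selections stay below 1% and
the drifted population dominates the validation counts in essentially
every run. The selected count also grows with locus number at fixed
planted count (the background tail above the threshold is proportional to
M). Selection is a high-precision, moderate-recall screen, not an
exhaustive outlier catalogue.

## Gene windows

Windows are [max(1, pos − h), pos + h] with h = 250 kb by default — a
"500 kb cis-window" read as total width, the window-size convention of
SNP-annotation tools; a flag allows h = 500 kb for the half-width reading,
which published gene counts alone cannot arbitrate. Overlap is any shared
base between closed 1-based intervals, computed with
GenomicRanges/IRanges; per-window lists are kept un-merged, deduplication
happens only in the global gene list, and "chr1"/"1" label styles are
normalised before matching.

## The synthetic-data generator

The generator is Balding–Nichols: ancestral B-allele frequency p per locus
(from a configurable MAF spectrum, randomly folded so B is not
systematically minor), population frequency
p_k ~ Beta(p(1−F_k)/F_k, (1−p)(1−F_k)/F_k), genotypes Binomial(2, p_k),
missingness uniform at random. It reproduces exactly the quantities this
pipeline estimates — drift-scale F_ST (E[θ̂_kl] ≈ (F_k+F_l)/2 for small
F), within-population HWE (F_IS ≈ 0), heterozygosity set by the ancestral
spectrum — and it is deterministic under a seed. Outlier loci are planted
by shifting the target population's frequency by δ (default 0.35, clipped
to [0.01, 0.99]), the simplest generator of elevated one-vs-rest θ at
known loci. Synthetic SNP metadata (positions on 29 autosomes,
GenTrain-like scores with a few-percent failure tail, mapping-hit counts)
and a gene annotation with genes planted 100 kb from each outlier locus
(inside a 250 kb half-window) plus decoys at 400 kb make the QC and
gene-window stages testable end to end.

What it does **not** emulate — and what passing tests therefore cannot
show about real chip data: linkage disequilibrium (loci are independent,
so locus bootstraps are better calibrated here than on a real chip),
ascertainment bias of array content, pedigree structure/cryptic
relatedness (kinship has no elevated pairs unless you plant them),
genotype-calling artefacts correlated with GenTrain score, and
non-tree-like covariance between populations (each population drifts
independently from one ancestor, so an arbitrary 4×4 table of pairwise
F_ST values is generally not exactly representable).

`paper_shaped_preset()` encodes a published four-breed study design as the
generator's defaults: breeds NU/D/T/NI with n = 23/24/24/24 (one sample
lost to call-rate QC), 48,505 loci, ancestral MAF spectrum
0.05 + 0.45·Beta(2.22, 1.78) — chosen to give mean MAF 0.30 and ancestral
heterozygosity 0.40, the printed total-population values — per-breed drift
F = (0.005, 0.006, 0.029, 0.009), the least-squares fit of independent
drift parameters to the published pairwise F_ST magnitudes (six pairwise
values cannot all be matched by four parameters; the fit reproduces their
scale and ordering, with the T breed strongly drifted), 49 planted
outliers in T at δ = 0.35, and 2% missing calls.

## Problem sizes and runtime choices

The test suite runs simulations at 2,000–10,000 loci and the end-to-end
study-shaped check at 12,000 loci with 300-replicate bootstraps — sizes at
which every estimator's error is comfortably inside the asserted
tolerances and the whole suite runs in a few minutes. The acceptance
script runs the preset at its full 48,505 loci with 1000-replicate
bootstraps and 10,000 AMOVA permutations (about a minute on one CPU). All
randomness flows from a single command-line seed; reruns are
byte-identical.

## Known limitations

* Biallelic loci only; no haplotype, sliding-window or multi-allelic
  statistics.
* AMOVA is two-level; no region/breed/individual three-level design.
* The locus bootstrap assumes exchangeable loci — anti-conservative under
  strong LD (see the generator caveats above).
* No admixture-model ancestry estimation; model-based clustering is
  outside scope, and the PCA stage is not a substitute for it.
* Bootstrap support values on dendrograms are not computed.
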