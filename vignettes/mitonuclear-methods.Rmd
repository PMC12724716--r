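---
title: "Mito-nuclear systems genetics in an inbred strain panel: models and methods"
author: "ccmito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mito-nuclear systems genetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmito)
```

## The scientific setting

Mitochondria are inherited maternally and do not recombine, so every strain of
a recombinant inbred panel descended from 8 founder lines carries the complete
mitochondrial genome of exactly one founder. In a Collaborative Cross (CC)
style panel this makes mitochondrial genetics unusually tractable: the
haplotype of each strain is known from its pedigree, the nuclear background is
scrambled across strains, and a mitochondrial marker's genotype is a pure
function of the maternal founder. `ccmito` implements the analysis chain for
such a panel subjected to a two-arm intervention (a saline control arm and a
catecholamine-stress arm): mitochondrial genotype imputation, trait-GWAS and
trans-eQTL scans against the mitochondrial markers with permutation-based
family-wise error control, rank aggregation and preranked gene-set enrichment,
tanglegram comparison of trait and sequence dendrograms, and a dual-genome
candidate-gene overlap. A synthetic cohort generator with a planted-effect
truth registry makes every stage testable without access to animal data.

## Genotypes: imputation is table lookup

`impute_genotypes()` maps each strain to its founder's allele at every marker.
There is no probabilistic imputation: pedigree determines the haplotype
exactly, and homoplasmy is assumed (heteroplasmy is out of scope). Dosage
coding is 0 for the major allele among the 8 founders (ties broken
alphabetically) and 1 for the minor allele; markers with more than two founder
alleles are kept and tested with a joint F-test on the allele factor.

Because only 8 founder genomes exist, the dosage columns of many markers
induce the same partition of strains. `distinct_patterns()` groups such
markers (including complementary codings). These *strain-distribution
patterns* are the effective tests in the scan; the family-wise error
machinery must handle, say, 21 markers that carry only 4 independent signals.

One consequence of the arbitrary major/minor orientation is worth noting: two
perfectly correlated markers can carry t statistics of opposite sign. Unsigned
quantities (p-values, hit calls) are unaffected, but signed aggregation across
markers (the median rank score below) partially cancels for genes whose
association lives in a pattern with mixed codings. This mirrors the general
non-identifiability of allele orientation and is documented rather than hidden.

## Preprocessing

The trait path, per treatment arm: z-transform each trait across animals
(mean 0, sample SD 1, denominator $n-1$; missing values preserved and dropped
per trait), remove sex and experimenter effects by ordinary least squares on
the factor design, then collapse to unweighted strain means. The expression
path: retain genes with at least 10 counts in at least 50% of all samples
(both bounds inclusive), transform to $\log_2(\mathrm{CPM} + 1)$ with library
sizes computed over the retained genes, remove sex and library-plate effects,
and collapse to strain means per arm.

Two genuinely open choices were resolved as follows and are configurable:

* **Fit unit.** Whether the association model should see animals or strains
  is not dictated by the design; we fit at the strain level (the unit at which
  the genotype varies), which keeps the permutation null exchangeable and the
  per-test degrees of freedom honest.
* **Weighting.** Strain means are unweighted by animal count; with a nearly
  balanced design the difference is negligible, and unweighted means keep the
  collapse order-invariant and simple to reason about.

## The association engine and its error control

Every feature (trait or gene) is regressed on marker dosage at the strain
level: $y = a + b\,d + \varepsilon$, two-sided p from the t distribution on
$n-2$ degrees of freedom; markers with a monomorphic dosage or any allele
class under 3 strains are skipped and reported. The scan is vectorized
closed-form OLS, so transcriptome-wide scans are effectively free.

Family-wise error control follows the permutation min-p approach: draw
standard-normal strain phenotypes, scan each against all markers, record the
minimum p per permutation, and take the empirical `fwer_level` quantile
(type-7) of that distribution as the genome-wide threshold. Because the
z-transformed, residualized phenotypes are exchangeable normals under the
null, the min-p null distribution depends only on the genotype correlation
structure — so one threshold serves every trait and every gene scanned
against the same genotype matrix (a fingerprint check enforces this). A
label-permutation variant (`observed =`) is available for comparison. Two
analytic limits pin the estimator down: with one effective marker the
threshold converges to the nominal level, and with $k$ orthogonal balanced
patterns it approaches the Šidák value $1 - (1-\alpha)^{1/k}$. Hit calling is
strictly below the threshold; best markers break p ties by genome position.

## Enrichment and overlap

Per-gene scores are aggregated across contrasts by the signed statistic of
maximal magnitude (`aggregate_ranks_maxabs()`, for differential-expression
style inputs) or across markers by the signed median
(`aggregate_ranks_median()`, for the trans-eQTL ranking; see the orientation
caveat above). `gsea_preranked()` implements the classic weighted
Kolmogorov–Smirnov running sum (weight exponent 1 on |score|; 0 gives the
unweighted KS statistic), with a gene-label permutation null,
$\mathrm{NES} = \mathrm{ES} / \overline{|\mathrm{ES}_{\mathrm{null}}|}$ over
matching-sign permutations, the +1-corrected permutation p, and
Benjamini–Hochberg adjustment across sets; sets are bounded to sizes 5–500
after intersection with the ranked universe. On an exact magnitude tie between
the positive and negative running-sum extremum the positive one is reported.
Over-representation of an annotation among hits is one-sided hypergeometric;
the Iso-vs-Ctrl comparison of annotation ranks is a two-sided Wilcoxon
rank-sum test, exact when both groups have at most 8 untied values, otherwise
normal approximation with tie and continuity correction.
`overlap_candidates()` intersects the stress-arm eQTL hit genes with an
external nuclear eQTL gene list and carries best p, statistic, associated
marker positions, mito-GWAS trait labels sharing those markers, external trait
labels, and the MitoCarta flag, sorted by p.

## Dendrogram comparison

`sequence_distance()` computes the p-distance between aligned founder
sequences with pairwise gap deletion. `hcluster()` wraps standard
agglomerative clustering (UPGMA by default; items are canonically ordered by
label first so distance ties resolve deterministically). The tanglegram
statistics are:

* **Entanglement** between two leaf orders: $\sum_i |u_i - v_i|^L$ normalized
  by the identity-vs-reversal worst case, with $L = 1.5$ by default; 0 means
  identical orders.
* **CPCC**, here the tree-vs-tree Pearson correlation of cophenetic distances
  (the classical tree-vs-data mode is `cpcc_tree_data()`).

`untangle()` minimizes entanglement over child rotations by deterministic
greedy alternating sweeps (single flips kept only when they strictly lower the
score); for trees of at most 8 leaves an exhaustive search over all rotation
combinations runs alongside. The greedy value can never fall below the
exhaustive optimum; it attains it on the package's shipped fixtures, but
single-flip hill climbing does have local optima on arbitrary tree pairs, so
the exhaustive value is the one to trust when it is available. Linkage
(average) and distance (euclidean on z-scored trait columns) defaults are
recorded choices, not field mandates, and are switches.

## The synthetic cohort

`generate_dataset()` simulates the full input bundle under one seed (per-stage
child seeds keep the stages independently reproducible): 63 strains spread
over the 8 haplotypes, 21 markers in 4 strain-distribution patterns (the
first seven available patterns are balanced, mutually orthogonal 4/4 founder
splits, so threshold calibration has a clean analytic limit), two arms with 2
animals per strain per arm, alternating sex within strain and round-robin
experimenter/plate assignment so every covariate is estimable.

Traits are sums of a per-trait sex coefficient, experimenter effects,
per-(strain, trait) random effects, planted marker effects (in residual-SD
units, applied through the strain's haplotype allele in the planted arm), and
Gaussian noise. Counts are negative binomial with log-normal gene baselines, a
shared dispersion, log-scale sex and plate effects, and planted log2 eQTL
effects; planted genes get a high fixed baseline so they survive the
expression filter. Defaults — `strain_sd` 0.5, `noise_sd` 1, `sex_effect_sd`
and `batch_effect_sd` 0.25, `nb_dispersion` 0.1 — put strain heritability and
batch structure in the range a practitioner would call realistic for organ
weight and echocardiography traits while keeping a 1.5-SD planted effect
detectable but not trivial at 63 strains.

Founder sequences are built on a common random backbone with the marker
alleles written at dedicated alignment columns, plus private substitutions
whose count *varies* across founders (sampled without replacement around the
configured mean). The variation matters twice: real CC founders differ widely
in mitochondrial divergence (the wild-derived lineages carry far more private
variation than the classical strains), and unequal counts keep pairwise
distances generically untied so the founder tree is well determined — with
equal counts the orthogonal pattern structure makes many founder pairs
exactly equidistant and the tree topology becomes an artifact of tie-breaking.

The `haplotype_trait_alignment` option plants, in one arm, per-trait
haplotype effects whose euclidean geometry reproduces the founder tree: the
target distances are the cophenetic (ultrametric) distances of the
sequence UPGMA tree, which embed exactly in euclidean space; the embedding is
a factorization of the doubly centered Gram matrix with column energies
balanced by pairwise rotations so that the per-trait z-scoring applied
downstream is a uniform rescaling rather than a distortion. One embedding
block is drawn per trait class, so each class alone (and any union of
classes) carries the planted geometry. An alignment strength of 2 makes the
stress arm's haplotype trait profiles track mt-DNA relatedness closely; the
acceptance experiments use strength 4, the strongly mt-driven regime in which
the planted haplotype signal is roughly an order of magnitude above the
haplotype-mean sampling noise, because the tanglegram contrast is a statement
about that regime. Even there the contrast cannot succeed in every replicate:
about 2–3% of null-arm tree pairs untangle to exactly zero entanglement,
which no effect-arm value can strictly undercut.

What the generator does *not* model — and hence what green tests do not
certify about real data: nuclear-genome relatedness and population structure
(no kinship correction is implemented or needed for the null to hold here),
realistic RNA-seq library-size variation and gene–gene correlation,
trait–trait correlation beyond the planted structure, heteroplasmy, and any
real trait architecture. Conclusions about the method's calibration transfer
to real cohorts only to the extent that preprocessing leaves strain-level
values exchangeable under the null.

## Numerical and edge-case conventions

Z-transformation refuses constant or nearly empty vectors by name;
residualization refuses rank-deficient designs and lists the aliased columns.
All-missing cells stay missing through strain collapse; strains absent from an
arm are dropped and reported. P-values are clamped to $(0, 1]$; exact
threshold equality is not a hit. The permutation threshold refuses
configurations with fewer than 5 expected tail permutations. Manifest and
genotype fingerprints are MD5 over canonical text serializations, so a scan
can never be compared against a threshold from different genotypes, and two
runs of `run_all()` with one seed produce byte-identical outputs.

## Problem sizes used in the shipped experiments

The test-suite and acceptance experiments run at the cohort's native scale
(63 strains, 21 markers, 252 animals) with 500 null traits for calibration,
10,000 permutations for the analytic threshold limits, 2,000 otherwise, 200
replicates for power, effect-recovery, and tanglegram-contrast estimates, and
a 200–400 gene transcriptome; these sizes give Monte-Carlo error comfortably
inside the assertion tolerances while keeping a full run in the low minutes
on one core.
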