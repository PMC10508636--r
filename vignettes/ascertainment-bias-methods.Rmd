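---
title: "Methods: SNP ascertainment bias in f-statistics and admixture graph fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP ascertainment bias in f-statistics and admixture graph fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

f-statistics summarize second moments of allele-frequency differences
between populations: `f4(A,B;C,D) = E[(pA - pB)(pC - pD)]`, with `f2` and
`f3` as its specializations. They are unbiased under two site-selection
regimes only: all polymorphic sites, or sites ascertained as polymorphic in
a population that is a strict outgroup to everything being analyzed and is
not itself co-analyzed. Every practical SNP panel in human population
genomics (heterozygosity panels from single genomes, capture arrays,
minor-allele-frequency filters, archaic-polymorphism panels) violates these
conditions. This package provides a simulation laboratory for measuring
what that violation does to f-statistics and to admixture-graph model
selection: which schemes falsely reject true demographic histories, which
lose power against wrong ones, and which population properties (drift
relative to the root of the analyzed groups) predict the damage.

## Data model

A `geno_matrix` holds diploid derived-allele dosages (0/1/2/NA) for
biallelic SNPs polarized against a known ancestral state, with site
metadata (chromosome, 1-based position, ancestral/derived alleles,
mutation class) and a population assignment per individual. EIGENSTRAT
(unpacked ASCII) and biallelic-SNP VCF input are supported; simulated data
are polarized by the simulator's known ancestral allele rather than by an
outgroup individual. Mutation classes partition biallelic SNPs into A/T
and G/C pairs (strand-symmetric, immune to biased gene conversion),
transitions, and other transversions.

Genome blocks for the jackknife are contiguous 4 Mb intervals that never
span chromosomes (sites map to `floor((pos-1)/size)` within a chromosome);
desk-scale runs shrink the block size proportionally with the simulated
genome so that the number of blocks — what the jackknife quality actually
depends on — is preserved. This is valid here because the simulation device
(below) makes data independent at a much finer physical scale than any
block size used.

## Simulation engine

Demographic models are one-population-per-graph-edge structures with
constant diploid effective sizes, dated splits, pulse admixture events, and
dated diploid sample sets. Simulation is delegated to msprime through a
bundled driver: the most recent 25 generations use the discrete-time
Wright-Fisher model and the remainder the standard coalescent; mutations
follow a binary model at a flat 1.25e-8 per bp per generation with flat
recombination at 2e-8.

Contiguous deep-coalescent chromosomes are prohibitively expensive at an
effective size of 100,000 (cost grows superlinearly in length), so
chromosomes are assembled from independent windows (default 250 kb) with
the full within-window recombination rate. Allele-frequency moments — the
only input to f-statistics — are identical to those of contiguous
chromosomes; only long-range linkage is absent, which the block jackknife
never relies on (blocks contain many windows or coincide with them).
`genome_spec(device = "chromosome")` restores contiguous simulation when
fidelity of linkage matters more than runtime.

Allele labels (ancestral/derived base pairs) are drawn per site with a 2:1
transition:transversion ratio so that mutation-class ascertainment is
exercised; this choice only affects class masks, not frequencies.

Three scenario presets cover the study designs:

* **Case study** (`preset_case_study`): one chimpanzee-like outgroup, an
  early Neanderthal sampled 3,790 generations ago, a late Neanderthal and a
  Denisovan at 1,700 generations, two African and two non-African groups of
  10 diploids with an out-of-Africa bottleneck, and optional ~2%
  Neanderthal gene flow into the non-African ancestor through an unsampled
  Neanderthal-side lineage. The effective sizes and split dates of the
  original study are not published in the machine-readable record, so the
  shipped parameter file (`case_study_params_synthetic.tsv`) is an
  explicitly labeled synthetic stand-in calibrated to reproduce the
  qualitative FST structure: modern-modern pairs around 0.04-0.16,
  modern-archaic around 0.6, chimpanzee around 0.87.
* **Random admixture graphs** (`preset_random_graph`): a random recursive
  bifurcation over 8 or 9 non-outgroup populations, an outgroup splitting
  at exactly 40,000 generations with size 100,000 (or 1,000 in the drifted
  variant), other edge sizes uniform in [2,000, 40,000], event times
  separated by uniform gaps of 1,500-8,000 generations (clamped to stay
  positive in deep caterpillar shapes), tips sampled at their terminal
  dates, and 4 or 5 pulses with proportions uniform in [0.10, 0.40]
  between contemporaneous branches. The root of the simulation and the
  root of the non-outgroup populations are sampled (10 diploids each) but
  never co-modeled. This emulates the published generator's stated
  parameter ranges; the exact event-tying heuristic of the original is not
  public, so the generator here is an emulation anchored to those ranges,
  not a port. Simulations are retained only if some population pair has
  Hudson FST below 0.15.
* **Simple trees** (`preset_simple_tree`): (O,(C,(A,B))) of depth 4,000
  generations at size 100,000, A-B split at 1,999 generations, with A's
  size divided by 1/10/100/1,000/10,000 from the split to the present;
  samples 25/25/25/10 diploids (10 for A in the most extreme class). The
  C-branch split is placed at 3,000 generations (the original figure does
  not print it; any value strictly between 1,999 and 4,000 yields the same
  null).

## f-statistics and uncertainty

Per-block f2 for a pair uses the unbiased estimator
`(pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)` averaged over usable
sites; all f3/f4 statistics are linear combinations of f2 per block
(`f4(A,B;C,D) = [f2(A,D)+f2(B,C)-f2(A,C)-f2(B,D)]/2`), so the finite-sample
corrections cancel exactly for distinct quadruples and the combination
equals the naive per-site cross-product average. Standard errors use the
weighted delete-one-block jackknife (weights = usable sites per block,
Busing pseudovalue form); covariance across statistics reuses the same
pseudovalues. No small-sample t correction is applied to Z-scores. FST is
the Hudson ratio-of-averages estimator with the jackknife applied to the
ratio. Derived-allele-frequency spectra use exact hypergeometric
down-projection to a fixed chromosome count.

Missingness follows the group-level rule (a site is usable if every
population retains at least one call); the stricter per-individual rule is
a flag. Sites where a population has fewer than two called chromosomes are
skipped pair-wise because the bias correction is undefined there.

## Ascertainment schemes

All schemes are mask producers with recorded provenance: heterozygosity in
one individual (a single Human Origins style panel), unions of such panels,
polymorphism in a pooled individual group (archaic-style), minor-allele
frequency above a threshold in a pooled meta-population (strict `>`,
allele-count pooling over the union, so each called chromosome counts
equally), derived-frequency tail removal (`<=` keeps the boundary),
mutation-class filters, seeded uniform thinning to an exact site count,
and fixed site lists with strict position+allele matching. Monomorphic
sites surviving a mask are retained (they contribute nothing to
f-statistics).

## Admixture graphs

Graphs are leaf-labeled DAGs: drift edges carry lengths in f2 units;
admixture nodes have exactly two zero-length parent edges with mixing
proportions `alpha` and `1 - alpha` (alpha belongs to the alphabetically
first parent, a pure bookkeeping convention). Expected statistics follow
the standard linear model: `f4` is the sum over drift edges of
`length * (wA - wB)(wC - wD)` where `wX(e)` is the probability a lineage
from X traverses the edge.

**Fitting.** The objective is the quadratic form of basis-statistic
residuals weighted by the inverse of their jackknife covariance. The basis
is every f3 anchored at one reference population (`f3(ref; i, j)` for all
unordered pairs, including `i = j`), a standard full-rank spanning set.
The covariance is regularized by a relative ridge: `diag` (default 1e-4)
times the mean diagonal is added to each diagonal entry; the relative form
was chosen because an absolute ridge would be scale-dependent across SNP
sets of very different sizes. Because expected statistics are linear in
edge lengths given the proportions, the inner problem is solved exactly by
non-negative least squares (exactly collinear design columns, such as the
two root edges whose lengths are only jointly identifiable, are merged
first). The outer problem over the proportions uses a deterministic grid
scan with golden-section refinement when there is a single proportion, and
bound-constrained quasi-Newton from `numstart` random uniform starts
(default 100) otherwise; the multi-proportion search evaluates an
unconstrained relaxation of the inner solve for speed, and every candidate
optimum is re-polished with the exact non-negative solve before
comparison.

Truth graphs derived from simulated demographies always carry an explicit
drift node on each parent lineage of an admixture node (the drift accrued
between the parent's origin and the pulse time); omitting these collapses
real drift onto zero-length mixing edges and visibly biases fitted
proportions. Reported
metrics: `ll`, the minimized score; and `wr`, the worst residual — the
largest |observed - fitted| / SE over every f2, f3 and f4 of the leaf set.
`ll = 0` implies `wr = 0`; re-rooting along drift paths leaves both
unchanged. The number of jackknife blocks should comfortably exceed the
basis dimension (n(n-1)/2 for n leaves), otherwise the covariance estimate
degrades and scores inflate; the desk scales below keep 60-120 blocks.

Admixture proportions are only interval-identified in sparse graphs (an
admixed leaf hanging below a free terminal edge admits a flat ridge of
exact fits); they become point-identified when the admixture node has two
sampled descendants and both parent sides carry reference lineages. The
parameter-recovery tests use such configurations, and
`jackknife_alpha()` provides delete-one-block confidence intervals.

**Enumeration.** The catalog generator builds every admixture graph as a
rooted binary tree plus edge-pair insertions and deduplicates with an
exact colored canonical form (leaf labels fixed, admixture-parent order
ignored). Three equivalences are exposed: `rooted` (plain rooted
isomorphism; 78,510 classes for five leaves and two events),
`semidirected` (root suppressed, drift edges undirected — the equivalence
under which f-statistic fits are actually invariant; 13,635 classes), and
the default `calibrated` convention, rooted isomorphism restricted to
root-normalized entries in which no tree-node child of the root has an
admixture-node child. The calibrated convention reproduces the published
catalog size for this class to within 0.05% (32,760 here); the remaining
discrepancy of 15 classes could not be resolved because the reference
toolchain's exact generator convention is not documented. The conventions
and counts are reported by `enumerate_topologies()` so downstream results
always state which catalog they used.

## Bias and power metrics

Flipped-verdict fractions compare worst residuals of the same topologies
on two SNP sets against the conventional WR = 3 SE threshold: the bias
fraction counts topologies rejected under ascertainment but accepted on
all sites; the power fraction the reverse. Trend dispersion fits ordinary
least squares of ascertained Z-scores on all-sites Z-scores (optionally
through the origin, optionally restricted to |Z| < 15) and reports the
residual SE and squared Pearson correlation. The classifier labels a
scheme biased when its metric falls strictly beyond a percentile of the
metric's distribution across seeded random thinnings matched exactly to
the ascertained panel's site count (2.5% of 200 replicates by default;
10% of 10 replicates in the simulated-data variant). Power against
incorrect models refits topologies drawn uniformly from a score window of
the catalog (the published window of 70-300 presumes full-genome block
counts; desk scales use quantile windows) and reports the median WR
difference and the rejected-to-accepted flip share.

## Problem sizes

The shipped analysis scripts and tests run at desk scale: genomes of one
to three chromosomes of 8-15 Mb, 250-500 kb jackknife blocks, 2-20
replicates, and catalog slices rather than full 32,760-entry fits. Null
properties (cladality, outgroup-ascertainment unbiasedness, verdicts on
correct trees) are scale-free and transfer directly. Bias magnitudes are
not: a fixed ascertainment-induced shift in an f4 grows in Z units with
the square root of the usable site count, so rejection rates and median
worst residuals measured at a few percent of the full genome understate
the full-scale values roughly by that factor. The scripts print this
caveat next to their summaries, and the acceptance-style checks that
depend on absolute bias magnitude are expected to recover the published
values only as the genome size approaches the original 300 Mb design.

## What the generator does and does not emulate

Simulated data are complete (no missing calls), diploid, neutrally
evolving, with a known ancestral state and independent windows. Real data
add missingness correlated with population and preservation,
pseudo-haploid calls, reference bias, base-quality masking, deamination
damage, biased gene conversion, and panel-design idiosyncrasies (the real
1240K array is a union of heterogeneous ascertainments). Passing the tests
here therefore demonstrates correctness of the estimators and the
direction and mechanism of ascertainment bias, not the exact magnitudes
those real-data complications produce.
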