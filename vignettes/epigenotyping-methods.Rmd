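---
title: "Epigenotype maps from DNA methylation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenotype maps from DNA methylation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapr)
```

## The problem

In a cross between two genetically (near-)identical plants — for example
two *Arabidopsis thaliana* mutation-accumulation lines — SNP-based
genotyping of the offspring is impossible: there is nothing to genotype.
DNA methylation, however, is inherited in *cis* with high fidelity, so the
two parental chromosomes can be told apart wherever their methylomes
differ. `epimapr` turns whole-genome bisulfite sequencing (WGBS) of the
parents and offspring into a per-individual *epigenotype map*: a
chromosome-scale labeling of each genomic bin as maternal homozygous,
heterozygous, or paternal homozygous.

## The procedure

**Methylation calls.** Per-cytosine data arrive as allc-style tables of
methylated (`mc`) and total read counts. The methylation level of a
position or region is the weighted level mC/(mC + uC). A position is
*methylated* when a one-sided binomial test of `mc` out of `total` against
the bisulfite non-conversion rate survives Benjamini-Hochberg correction
(`callMethylationStatus()`); positions with fewer than three reads are not
tested. The BH family is all tested positions of one sample, contexts
pooled — we found no reason to stratify by context, and pooling makes the
family size unambiguous.

**Informative positions.** A position is informative when it is covered by
at least three reads in both parents and exactly one parent is methylated.
Downstream, only positions covered by at least three reads in *every*
sample are used, so all samples share one feature space.

**Bins and the per-bin classifier.** Each chromosome is tiled with
fixed-width bins (default 50 kb); bins with fewer than three informative
positions are merged — forward into the next bin, the terminal bin
backward — until all bins have at least three (a deterministic single
rule; the direction is immaterial to the result but makes maps
reproducible). For each bin, the mother's and father's level vectors and
their average (the mid-parent vector, the expectation for a heterozygote)
form the training set of an L2-regularized multinomial logistic
regression, with classes weighted 0.25/0.5/0.25 to reflect the 1:2:1
Mendelian expectation for an F2 (`trainClassifyBin()`). Parental
replicates, when supplied, add further training vectors per class. The
classifier is applied to every sample — including the parents and the
mid-parent pseudo-sample — and its probability 3-vector per bin is the
emission for the smoothing stages; the argmax is the preliminary state.

Two choices here deserve explanation:

* *Softmax rather than one-vs-rest.* The mid-parent training vector is the
  exact midpoint of the parental vectors, and any linear score satisfies
  f(mpv) = (f(m) + f(f))/2. Under a one-vs-rest scheme, the balanced
  MPV-vs-rest subproblem therefore optimizes to the flat solution — MPV
  probability 0.5 for every input — which caps homozygous bins at 2:1 odds
  and biases the HMM toward the heterozygous state, visibly eroding every
  block boundary by about one bin. A single multinomial softmax with the
  same penalty and class weights has no such cap: only score *differences*
  matter, and those are unconstrained at the midpoint. The one-vs-rest
  scheme remains available (`classifierScheme = "ovr"`) for comparison.
* *Weak regularization (`C = 100`).* The training set is a handful of
  noiseless prototype vectors, not a noisy sample; the classifier's job is
  a soft nearest-prototype rule. With strong regularization (small `C`)
  the data term is dwarfed by the penalty and the class-weight imbalance
  dominates the intercepts, collapsing calls onto the heterozygous class.
  `C` is exposed (`classifierC`) for users who want to experiment.

**HMM smoothing.** Crossovers are rare at the 50-kb scale, so isolated
state flips are far more likely classifier noise than double recombination.
A three-state HMM per chromosome smooths them: the transition matrix is
estimated from the preliminary states of all classified samples except the
mother and father (adjacent-bin transition counts, pseudo-count 1,
row-normalized; `estimateTransitions()`), and a scaled forward-backward
pass (`forwardBackward()`) produces per-bin posteriors. A second
transition matrix is then estimated from the forward-backward states, and
Viterbi decoding with the posteriors as emissions (`viterbiPath()`) gives
the final map. The initial distribution is uniform (nothing in the design
argues otherwise); all recursions are scaled or in log space and remain
finite beyond 10^4 bins. Argmax and path ties break deterministically in
the fixed order MOTHER < MPV < FATHER.

**Centromere masking.** Pericentromeric repeats confuse the classifier, so
bins overlapping a supplied centromere interval contribute emission 1.0
for every state — their labels are carried by the transition structure
alone. `athalianaCentromeres()` ships the conventional TAIR10 intervals
(spline-minimum of gene density ± 1.5 Mb; chromosome 4 split around the
heterochromatic knob); any user-supplied table overrides them, and
`defineCentromere()` recomputes the definition from a gene-density vector.

**epiRIL mode.** For F8 epigenetic recombinant inbred lines the expected
residual heterozygosity is (1/2)^7 = 0.0078125, so class weights become
0.4961/0.0078/0.4961 (127:2:127, `epirilWeights()`). Because the
classifier splits the methylation-mutant parent's mass between the father
and MPV states while true MPV calls are implausible at F8, the MPV
emission is folded into the father state before smoothing
(`epirilAdjust()`).

## The simulation framework

`synthParents()` emulates the input the pipeline consumes after parental
differential-methylation screening: `nPositions` cytosines scattered
uniformly over one chromosome (defaults used in validation: 20,000 over
20 Mb), one parent per position drawing a high level from Beta(8, 2), the
other a low level from Beta(2, 8), parent assignment random per position.
Levels are stored as counts out of 100 so that count-derived levels are
exact, and the methylation call is assigned by construction. This emulates
the *informative-position* landscape of a real cross — it does not emulate
read-depth variation, missing data, context composition, or the spatial
autocorrelation of real methylomes, so passing simulations demonstrate the
recovery machinery, not robustness to those real-data features.

`simulateOffspring()` places `k` equally spaced potential breakpoints
(samples 1..20 carry k = 0..19), draws a genotype per region with
probabilities 0.25/0.5/0.25 (adjacent regions may repeat, so actual
changes range from 0 to k), and draws each position's level uniformly from
`[max(0, x - y), min(1, x + y)]`, where `x` is the genotype-expected level
and `y` the error half-width. Accuracy is the micro-averaged F1 of the
final map against the truth projected to bins (`accuracyF1()`), which for
single-label bins equals plain per-bin accuracy; `runGrid()` averages 25
iterations per condition.

Three numerical notes:

* The error interval is the clamp written above; a degenerate reading with
  min/max swapped would produce an empty interval and is plainly not the
  intended "uniform error around the expected level".
* Truth projection assigns each bin the genotype covering the largest
  share of its width. A bin straddling a breakpoint near its middle has no
  meaningful single label, and agreement between a width-majority label
  and a decoder that sees only the positions inside the bin is not
  guaranteed for any method; the noiseless-recovery property is therefore
  exact on bins wholly inside one genotype block, and holds to better than
  99.9% including straddled bins.
* Sharp softmax emissions are what make noiseless recovery exact, but they
  concede graceful degradation at extreme error (y ≥ 0.5), where
  overconfident wrong emissions defeat the HMM's smoothing; the
  one-vs-rest scheme degrades more gently there at the cost of boundary
  erosion everywhere else. The package optimizes for the regime the
  validation targets (y ≤ 0.3).

## Population checks

A credible F2 map must look Mendelian. `countCrossovers()` counts
adjacent-bin state changes; `crossoverTest()` fits a per-chromosome
Poisson by the mean count, computes expected category probabilities for
0-6 crossovers with the residual mass in a ">6" bucket (with ~20 samples,
less than one individual is expected beyond six), and compares observed to
expected with an exact multinomial test — enumerated exactly up to 10^6
outcomes, Monte Carlo with fixed seed beyond. `alleleFrequencyTest()`
checks each bin's maternal:paternal allele ratio (a heterozygote
contributes one of each) against 1:1 by chi-square, BH-corrected across
bins.

## Regions, epialleles, inheritance categories

Candidate differentially methylated regions come from an external caller;
the package implements the downstream filters and tests. Regions are
retained when at least 40 bp long, with at least ten cytosines covered by
at least three reads in all samples, and at least a 20% level span across
generations (`filterRegions()`). Transgenerational epialleles are called
by a one-sided z-test for a greater-than-25% level difference between
adjacent generations on region-summed counts with the unpooled binomial
standard error (the test is classical; the variance estimator is our
choice and is stated here because it is not forced), BH-corrected within a
line (`callEpialleles()`); regions with one change are epiloci, with
several, instability hotspots. Parent-parent DMRs need 40 bp and a 25%
absolute difference and are discarded on any 1-bp overlap with a
sibling-specific DMR (`parentDmrFilter()`). The pooled-level retention
screen (`retainMethylatedRegions()`) tests region level > 25%/n
generations on pan-methylome counts; the threshold's intent is a
conservative "methylated in at least one generation" screen and is
documented as such since other readings are possible — users who prefer a
per-generation test can apply `ztestLevelDifference()` directly.

Feature categorization assigns every base exactly one class by priority
ncRNA > UTR > intron > CDS > promoter > TE (promoter = 1 kb upstream of
the TSS; unassigned bases are intergenic) and reports per-region base
proportions (`assignFeatures()`).

Inheritance categorization at parent-parent DMRs compares F2 methylation
levels between epigenotype groups with a Welch-type pairwise statistic
(`gamesHowellT()`; the studentized-range constant of the classical
Games-Howell procedure cancels under the permutation null and is omitted),
judged against the 99th percentile of 2000 label-permutation bootstrap
t-values (`bootstrapNull()`; permutation preserves the observed label
multiset — sampling with replacement is available as a flag). Rules apply
in order: all three pairs significant → *expected* (additive); mean F2
level within 0.10 (absolute) of one parent and every F2 closer to that
parent → *parental dominant*; no heterozygous pair significant → *no
association*; exactly one heterozygous pair significant → *ambiguous*.
Regions where both heterozygous pairs are significant without the
maternal-paternal pair — a pattern the rules do not anticipate — are also
labeled ambiguous. Regions lacking a t-value (a group below two members,
or no variance anywhere) are removed as unassessable.

## Problem sizes and reproducibility

The shipped validation runs 20 offspring × 25 iterations on a 20-Mb
synthetic chromosome with 20,000 informative positions at 50-kb bins —
about 400 bins per map — which exercises every stage at realistic density
while one run of the full grid cell completes in roughly a minute and a
half. All stochastic components (parent synthesis, genotype assignment,
error draws, bootstrap, Monte Carlo) are seeded; a fixed seed reproduces
results bit for bit.

## Known limitations

* The simulator draws per-position errors independently; real bisulfite
  noise is depth-dependent and spatially structured.
* Transition matrices are estimated per chromosome from the cohort itself;
  very small cohorts (a handful of offspring) give noisy estimates, though
  the pseudo-count keeps them proper.
* The epiRIL mode expects a position whitelist (e.g. CG sites in gene-body
  methylated genes) to be applied upstream when remethylation is a
  concern.
* Polyploid genomes, imputation from sparse coverage, and SNP-based
  verification are out of scope.
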