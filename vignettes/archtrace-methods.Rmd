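---
title: "Reference-free archaic local ancestry inference with archtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free archaic local ancestry inference with archtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Modern human populations outside Africa carry a small fraction of their
genomes from admixture with archaic hominins such as Neanderthals. *Archaic
local ancestry inference* asks, for each segment of each haplotype in a
present-day sample, whether that segment descends from the archaic
population. Most methods need a sequenced archaic reference genome; many
admixture events of interest (e.g. putative "ghost" introgression into
African populations) have none. `archtrace` implements a *reference-free*
approach: a logistic-regression classifier over haplotype summary
statistics, trained entirely on coalescent simulations of a specified
demography, applied in sliding windows along phased haplotypes.

## The demographic model and its simulator

Training data come from a four-population split/admixture history: an
ancestral population of diploid size $N_0$ splits $T_0$ generations ago
into an archaic lineage (size $N_a$) and a modern lineage; the modern
lineage splits $T_s$ generations ago into a *reference* population ($N_1$,
never admixed) and a *target* population ($N_2$); at $T_a$ the archaic
population contributes a single-generation pulse of proportion $m$ into
the target. The defaults (`demography()`) are a Neanderthal-like history:
all sizes 10,000, $T_0 = 12{,}000$, $T_s = 2{,}500$, $T_a = 2{,}000$
generations, $m = 2\%$, $\mu = 1.25\times 10^{-8}$ and
$r = 10^{-8}$ per bp per generation. The 50 kb default window length is
the expected introgressed tract length $1/(r\,T_a)$ after 2,000
generations of recombination.

Simulation is delegated to msprime through a bundled driver script; the
admixture pulse is a backwards-in-time mass migration at $T_a$, and
archaic ancestry tracts are recovered exactly by placing a census on every
lineage at $T_a + 0.5$ generations and mapping each sampled segment to the
population of its census ancestor. Tracts are reported as 0-based,
half-open bp intervals per target haplotype. Mutations follow an
infinite-sites model on a continuous coordinate, mapped to a strictly
increasing integer bp grid (collisions bumped to the next free integer);
all variants are biallelic with the ancestral state known. One archaic
haplotype is sampled at the present alongside the modern samples, but it
is used only by the match diagnostics, never as a classifier feature.

Every batch takes a single integer seed; per-replicate seeds are derived
through a splittable seed sequence, so any `(seed, replicate)` pair is
reproducible bit for bit.

Two checks pin the engine to theory: with all four sizes equal and $m=0$,
a target-only sample is *exactly* a constant-size panmictic coalescent
(the population relabelings at $T_s$ and $T_0$ change nothing), so mean
pairwise differences must equal $4 N \mu L = 25$ per pair at 50 kb; and the
genome-wide mean archaic fraction over replicates must match $m$ within
Monte-Carlo error. Both run in the test suite.

### Structure scenarios

Two confounder scenarios probe whether population structure alone can
mimic introgression. In the *recent* scenario 25% of the target population
separates 2,499 generations ago (immediately after the target-reference
split) and rejoins 2,001 generations ago; in the *ancestral* scenario 25%
of the ancestral population separates 12,000 generations ago and rejoins
2,600 generations ago. Both set $m = 0$, so every archaic call on such
data is a false positive. Two choices the literature leaves open: the
separated deme is fully isolated while apart, and its size is
`fraction` × the host population's size (the host keeps its own size).
The 25% figure is interpreted as the lineage-sampling probability at the
separation.

## Features

For a focal haplotype in a window with target panel size $n$, the feature
vector concatenates, in fixed order:

1. the **individual frequency spectrum** (length $n$): entry $i$ counts
   focal-carried derived alleles whose derived count in the target panel
   is $i$ (entry $n$ = sites fixed derived in the target);
2. the **sorted Euclidean distance vector** (length $n$) from the focal
   haplotype to every target haplotype (self-distance 0 included; sorting
   makes the features invariant to haplotype order), and its **mean,
   variance, skew and kurtosis** (population moments; skew and kurtosis
   defined as 0 for degenerate zero-variance vectors);
3. the **minimum distance to the reference panel**;
4. the **number of private SNPs** (focal derived alleles absent from the
   reference panel);
5. **S\***, the chain statistic over private sites (below);
6. optionally (default on) the **total focal derived-allele count**.

That is $2n + 7$ features, plus the optional count for $2n + 8 = 208$ at
$n = 100$. The described statistics sum to 207; the extra count closes
the gap to the published 208-feature layout. It is exactly collinear with
the IFS (its sum), just as the distance mean is collinear with the sorted
distance vector, so the fit drops both as aliased — they are kept in the
layout for fidelity and cost nothing. Distances are computed over all
segregating sites in the window (target and reference panels jointly);
sites private to the archaic haplotype are all-zero in both panels, which
is what guarantees the no-leakage invariant (removing the archaic
haplotype changes no feature — tested).

### The S\* dialect

S\* rewards long, high-LD chains of derived alleles absent from the
reference. Candidate sites are focal-derived, reference-absent positions;
the dynamic program is
$S(j) = \max\big(0, \max_{i<j} S(i) + s(i,j)\big)$ with
$s(i,j) = \mathrm{bp}(i,j) + 5000$ when the spacing is at least 10 bp and
$-10{,}000$ otherwise, and $S^* = \max_j S(j)$ (0 with fewer than two
candidates). The published descriptions of this statistic family do not
enumerate one canonical constant set, so the constants are exposed via
`sstar_params()` and the default dialect is the one above. The test suite
checks the DP against exhaustive subset maximization for up to 12
candidate sites. Because the candidate set is conditioned on absence from
the reference, S\* counts as a reference-dependent feature and is removed
from the `no_reference` ablation.

## Classifier

Haplotype-windows are labeled by their true archaic base fraction: archaic
when $\geq 70\%$, non-archaic when $\leq 30\%$, discarded in between (at
the default demography about 1.2% of 1,000,000 training haplotypes are
discarded). The fit is an unpenalized maximum-likelihood binomial logit on
the raw features — deliberately the plain logistic model, keeping weights
interpretable. The solver is an IRLS on the normal equations (the same
MLE `glm` computes, but one BLAS crossproduct per iteration, which is
what makes hundreds of thousands of 208-feature training rows cheap);
exactly collinear features are detected once by pivoted Cholesky and
aliased to weight zero, constant features are dropped with a message, and
if the likelihood fails to converge (e.g. complete separation on tiny
subsets) a scale-invariant tiny-ridge fallback is used and flagged on the
object. Class imbalance (~2% positives) is left as-is.
Standardization (weight × feature SD) is a reporting device only
(`standardized_weights()`, `plot()`); features enter the fit
unstandardized. Positive checks on the default demography: the weight on
the minimum reference distance is positive, on the distance skew negative,
and those two are among the largest standardized non-IFS weights.

## Window scan and per-SNP aggregation

Long haplotypes are scanned in 50 kb windows sliding 10 kb; every
(window, haplotype) pair gets a probability, and each SNP receives the
arithmetic mean over all windows that overlap it (5 for interior SNPs;
fewer near edges — the count is recorded rather than reweighted, keeping
edge effects auditable). Trailing truncated windows are featurized on
their actual span. For empirical, CEU-protocol-style runs, setting
`step = window` gives non-overlapping tiling. Calls threshold the mean
probability; the default 0.62 is the operating point reaching precision
0.8 (20% FDR) on unperturbed simulated test data at the default training
scale.

## Evaluation harness

Curves enumerate every distinct score as a threshold (ties grouped).
AUPR uses the Davis–Goadrich interpolation — one interpolated point per
unit of true positives with false positives linear in TP — because linear
interpolation of precision is biased; AUROC is the trapezoid over the ROC
step curve (= Mann–Whitney with half-ties). Standard errors use a
delete-one-block jackknife with 1 Mb replicate blocks,
$SE = \sqrt{\frac{B-1}{B}\sum_b(\theta_{(b)} - \bar\theta)^2}$. The S\*
baseline computes S\* for every focal haplotype in its window cohort and
aggregates the window scores per SNP exactly like the classifier, so the
two methods are compared under an identical protocol. By default the raw
scores are averaged; empirical-CDF rank conversion (per window cohort or
region-wide) is available but off, because rank conversion before
averaging compresses the informative upper tail of the score
distribution and measurably weakens the baseline's precision-recall
behavior — the raw-averaging variant is the one that reproduces the
published baseline operating characteristics. The perturbation
harness halves and doubles one demographic parameter at a time, skipping
combinations that break the event ordering (e.g. doubling $T_a$ past
$T_s$), and reports precision/recall at a fixed threshold as log10 fold
changes against the unperturbed baseline; a joint $(\mu, r)$ pair list
drives the rate-heterogeneity variant.

## Match diagnostics

To validate calls against an actual archaic sequence when one exists, the
match statistic of a focal haplotype in a window is $S/(N+H)$ with $N$ the
archaic-genome mutation count (sites with at least one derived allele,
homozygous or heterozygous — the archaic genome may be unphased), $H$ the
count of target-segregating sites at which the archaic genome is not
variant, and $S$ the focal derived alleles shared with the archaic
genome. The exact site universes for $N$ and $H$ are not pinned down in
the literature; the definitions above keep $S \le N + H$ by construction
and make the statistic computable from any VCF-style genotype dosage. The
archaic/non-archaic contrast per window is normalized by the window's
overall mean (controlling mutation-rate heterogeneity), restricted to
windows with $\ge 90\%$ callable bases, averaged genome-wide, and tested
with a 100 kb block jackknife; B-value binning uses the four canonical
bins and a 50 kb block jackknife for the lowest-vs-highest contrast. In
simulation the sampled archaic haplotype stands in for the archaic
reference, giving a positive control (true tracts match the archaic
genome, $\Delta > 0$) without any external data.

## Study sizes and numerical choices

The package's standard evaluation uses training on 3,000 replicate 50 kb
loci × 100 target haplotypes (~300,000 examples before filtering) and
testing on 30-60 fresh 1 Mb replicates; the labeling-retention check runs
the full 10,000-replicate labeling through a fast tracts-only simulation
path; the reduced-sample arm trains on 3,000 loci at $n = 30$ and tests
on up to 30 × 1 Mb; structure scenarios use 8 × 1 Mb each. These sizes were
chosen as the package's own defaults: they reproduce the published
operating characteristics to within roughly their jackknife standard
errors while keeping a full run on a single CPU in minutes. One caveat is
intrinsic: at this training scale the PR curve is nearly flat around
precision 0.8, so the precision-0.8 threshold and its recall are
ill-conditioned — across test draws they range roughly 0.5-0.7 and
0.10-0.25 — and more test replicates temper but do not remove this.
Training on fewer loci mainly costs AUPR/AUROC (at 400 loci the per-SNP
AUPR drops by ~0.1); jackknife SEs are always reported so scaled runs
stay interpretable.

What the simulations do *not* emulate: selection (including background
selection), gene conversion, multiple or continuous admixture, phasing
error, genotyping error, and accessibility masks. Passing tests therefore
demonstrate correctness of the method under its own model, not calibrated
performance on real data; the robustness grid and rate-heterogeneity
experiment quantify sensitivity to the most important mismatches.

Other numerical conventions: inclusive labeling bounds (exactly 0.7 is
archaic, exactly 0.3 is non-archaic); curve thresholds at distinct scores
with ties grouped; the operating point is the *smallest* threshold whose
precision reaches the target; empty windows featurize to all-zero vectors;
`ecdf` ranks give ties their maximal rank. Seeds are mandatory everywhere
randomness enters — omitting one is an error, not a silent default.
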