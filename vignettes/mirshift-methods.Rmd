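---
title: "Methods: quantifying miRNA redistribution between tumour and serum"
author: "mirshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying miRNA redistribution between tumour and serum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirshift)
library(dplyr)
```

## The analysis problem

`mirshift` implements the computational analysis of a pooled small-RNA
sequencing design in which microRNA profiles are compared between two
compartments — tumour tissue and blood serum — under a therapeutic
intervention. Each compartment contributes one pooled control and one pooled
treated sequencing library (`L1`/`L2` for tumour, `L3`/`L4` for serum), so
the whole experiment is four libraries with no biological replicates. The
pipeline covers five stages: RPKM quantification and read-class composition,
per-compartment differential calls, prioritization of qPCR validation
candidates by the TS/TF statistic, Z-score/UPGMA heat-map clustering, and
analysis of the stem-loop RT-qPCR validation arm. A seeded synthetic-data
generator emulates the whole design so every stage is testable without raw
sequencing data.

## Quantification

Abundance is expressed as RPKM,

$$Q_{fl} = \frac{c_{fl}}{(L_f/1000)\,(N_l/10^6)},$$

with $c_{fl}$ the read count of miRNA $f$ in library $l$, $L_f$ the mature
length in nucleotides and $N_l$ the total number of reads in the library.
The mature length is the default normalizer because mature species are what
stem-loop qPCR validates; a hairpin-length column can be supplied instead.
Composition percentages are class counts over *total* library reads, rounded
half-up to one decimal — the only convention consistent with typical
published read-classification tables, though such tables occasionally print
single inconsistent cells (the package follows arithmetic and documents the
discrepancy rather than reproducing it).

## Differential calls without replicates

With one library per condition, replicate-based dispersion estimation is
impossible. The package therefore tests, per feature, equality of relative
abundance given the two library depths with a two-sided exact test on the
2×2 table (feature count versus library remainder) — the hypergeometric /
Fisher construction — followed by Benjamini–Hochberg correction across
features. The two-sided p-value sums all outcomes no more probable than the
observed one; it is computed with $O(\log n)$ tail searches exploiting
unimodality of the hypergeometric pmf, so it remains fast when counts run
into the millions.

Fold changes are ratios of RPKM, reported symmetrically (value $\ge 1$ plus
a direction). Features with a zero count on either side receive a 0.5
pseudocount on both raw counts before the ratio, keeping folds finite — a
standard device. An *affected* call requires both `q <= alpha` (default
0.05) and a symmetric fold of at least `min_fold` (default 1.5), emulating
"reliable change" tables; features with fewer than 10 reads in both
libraries are flagged low-evidence rather than removed.

Two caveats are inherent to the design and documented rather than hidden.
First, a conditional exact test is exactly calibrated only under Poisson
sampling; with biological overdispersion it is anti-conservative, which is
a fundamental limitation of pooled two-library comparisons, not of the
implementation. The type-I calibration test therefore runs in the Poisson
limit (`dispersion = 0`) on moderately abundant features (expected counts
roughly 30–600), where the discrete test's size is close to nominal.
Second, two negative-binomial libraries with overdispersion $d$ carry an
irreducible log2-fold noise floor of $\sqrt{2d}/\ln 2$ (about 0.65 at the
default $d = 0.1$) that no sequencing depth removes; the fold-recovery
property test is likewise run at counting noise only.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults are the study
conditions the package targets:

* library depths equal to the four pooled library totals
  (7.17, 5.14, 4.26 and 5.65 ×10⁷ reads);
* 615 tumour-detectable and 617 serum-detectable miRNAs, 550 shared;
* 116 tumour-up and 7 tumour-down, 137 serum-down and 2 serum-up designed
  effects, with 81 affected miRNAs common to both compartments
  (42 tumour-only, 58 serum-only);
* tumour boosts uniform on 2–10×, serum drops uniform on 2–6×;
* base abundance log-normal with `meanlog 3`, `sdlog 2` on the RPKM scale;
* read-class composition fractions per library drawn multinomially from the
  class proportions of the four libraries;
* negative-binomial counts with overdispersion 0.1, feature mean
  `base_abundance × effect × length_kb × depth/1e6`, so expected RPKM equals
  `base_abundance × effect`.

Two structural choices deserve explanation. Affected features are sampled
with probability proportional to `base_abundance^2` and the serum-only
affected set is drawn before the tumour-only set. Both encode the same
fact: an affected list in this design is the *output* of a
detectability-filtered differential call, so designed modest changes must
sit on miRNAs covered well enough for the change to be callable at all —
and serum drops (2–6×) demand far more coverage than tumour boosts (2–10×).
For the same reason, drawn fold magnitudes are coupled to abundance by rank
within each affected set and direction: the smallest folds land on the most
abundant features. Without these choices a substantial fraction of the
designed truth would be unrecoverable by *any* two-library test, and the
generator would be simulating a study that could not have produced its own
affected lists.

Randomness uses one master seed with fixed stage streams (catalog = seed,
counts = seed + 1, qPCR = seed + 2); identical seed and configuration give
bit-identical experiments.

What the generator does **not** emulate: read-level artifacts (adapters,
quality, colour space), mapping ambiguity, batch effects, and — most
importantly — biological replicate variance, which the pooled design makes
unrecoverable (`replicates` exists as a config extension but carries no
variance model between pools). Passing tests therefore demonstrate the
pipeline's arithmetic and its behaviour under the declared sampling model,
not robustness to the full messiness of real libraries.

## TS/TF candidate prioritization

Validation candidates are ranked by the total-score over total-fold
statistic. With `L1`/`L3` the control abundances (the "scores") and
tumour/serum folds `L2/L1` and `L3/L4`:

$$\mathrm{TS} = Q_{L1} + Q_{L3}, \qquad
  \mathrm{TF} = \frac{Q_{L2}}{Q_{L1}} + \frac{Q_{L3}}{Q_{L4}}, \qquad
  \text{rank by } \mathrm{TS}/\mathrm{TF} \text{ ascending.}$$

The algorithm proceeds exactly in the published order: abundance-sorted
views with treated libraries superposed, compartment folds, a top-`n`
shortlist by tumour-control abundance (default 100; the union of the
`L1`/`L2` top lists is a config switch, since "the top 100 miRNAs of the L1
and L2 libraries" is ambiguous), rejection of features absent from any
library, then the TS/TF window: selected means `0 < TS/TF <= 20` and
`TF >= min_tf`. "High TF" is undefined in the source procedure, so it is
exposed as `min_tf` with default 4 — two compartment folds of at least 2
each, matching the reported effect regimes. Ties in the ranking resolve by
TF descending then feature id, making the output fully deterministic. Note
that TS scales with global library scaling while TF does not, so the
selection window is an absolute-abundance criterion by construction.

The final literature filter is data-driven: a curated table of oncomirs and
tumour suppressors (the package ships the nine validated miRNAs of the
motivating study plus the let-7 family) annotates the ranked list, and
"annotated selections" are the validation set.

## Clustering

Heat-map dendrograms are computed from Z-scored RPKM (sample standard
deviation, `ddof = 1`; the convention is declared because sources rarely
state it) with features scaled by row and libraries by column,
independently. Agglomeration is UPGMA on Euclidean distances, implemented
in-package so that tie-breaking is deterministic: equal minimum distances
(detected up to relative rounding error 1e-12) resolve to the smallest pair
of cluster ids, and leaf ordering puts the smaller-id subtree first at
every merge. Constant vectors Z-score to zeros with a warning rather than
an error, since all-zero features are legitimate in sparse compartments.
Dendrograms export as `hclust`-compatible objects and Newick trees.

## qPCR validation arm

Standard curves are least-squares fits of Ct on $\log_{10}$ dilution over
serial dilutions (factors $10^{-2}$–$10^{-4}$ plus the undiluted point);
amplification efficiency is $E = 10^{-1/\text{slope}} - 1$, so a slope of
$-\log_2 10 \approx -3.32$ cycles per decade is perfect doubling. Fits with
positive slopes are flagged invalid rather than silently inverted.

Reference genes are ranked by the geNorm stability measure $M$: the mean,
over all other candidates, of the standard deviation across samples of the
pairwise log2 expression ratio. The package implements the published
definition directly; single-pass $M$ is the default and stepwise exclusion
is available via `iterate = TRUE`. The minimal-$M$ pair is the recommended
normalizer.

Relative expression is efficiency-corrected by default,
$\log_2 q = -\,\mathrm{Ct}\,\log_2(1+E)$, normalized per sample by the
geometric mean of the reference quantities (or by input serum volume in
volume mode — a label on the same arithmetic, with the volume replacing the
reference term), and compared between groups with an unpaired two-tailed
Student t-test on the log2 scale (Welch via flag). At $E = 1$ everywhere
the machinery reduces exactly to $2^{-\Delta\Delta \mathrm{Ct}}$, which is
asserted symbolically in the tests; a plain uncorrected mode falls out of
simply not supplying efficiencies. Stars follow the 0.05/0.01/0.001
convention with inclusive thresholds.

## Problem sizes and numerical choices

The test suite and the acceptance script run the default catalog (682
features, four libraries at study-scale depths), a 2 000-feature null
calibration at uniform depth 10⁷, 200 random UPGMA instances of up to six
items against an exhaustive oracle, and a six-replicate qPCR arm at Ct noise
0.2 — sizes chosen so the full suite completes in well under a minute while
keeping every stochastic margin wide (recovery ≈ 95 % against a 90 % bound;
type-I error within three binomial standard deviations of 0.05). Exact-test
p-values match `fisher.test` to its internal relative tolerance 1e-7;
UPGMA heights match oracles to 1e-10; closed-form qPCR identities hold to
1e-12.

## Known limitations

* No replicate-variance model: all significance statements are conditional
  on the pooled two-library sampling model.
* The exact test is anti-conservative under overdispersion (above); its
  q-values should be read as ordering evidence, not as calibrated FDR, on
  real overdispersed data.
* The TS/TF window is absolute in RPKM, so rescaled abundance units change
  the selection — intended by the published procedure, but worth knowing.
* Heat-map rendering is a thin display layer; the tested artifact is the
  scaled matrix and the dendrograms.
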