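---
title: "Comparing tissue methylomes with tdmrscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing tissue methylomes with tdmrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmrscan)
```

## The problem

Placental tissue (chorionic villus samples, CVS) is globally less
methylated than somatic tissue such as maternal blood cells (MBC).  On a
CpG array, MBC methylation is strongly bimodal -- most sites are either
fully methylated or fully unmethylated -- while CVS loses much of the
hypermethylated mode in favour of intermediate methylation.  On top of
this global shift sit tissue-specific differentially methylated
sites/regions (T-DMRs), with several-fold more loci hypomethylated in CVS
than in MBC, and the differences cluster into chromosomal domains that
tend to be gene-poor.  Finally, promoter methylation represses
transcription, but only below roughly 50 percent methylation; above it
the relationship is flat, and genes split into low- and high-CpG promoter
classes with distinct methylation and expression behaviour.

`tdmrscan` implements this analysis end to end for two array chemistries
and ships a seeded synthetic-data generator that reproduces the
statistical structure above, so every stage can be exercised and
benchmarked without access to the original arrays.

## Site-level scores

**Infinium-style arrays** interrogate each CpG with an unmethylated (A)
and a methylated (B) probe.  Two scores are computed per site and sample:

* the beta value `B / (A + B + 100)` in `[0, 1)`; the +100 keeps dim
  probes away from the extremes;
* `log(B/A)` (natural log, pseudocount 1 on both channels); a site is
  *hypomethylated* when `log(B/A)` is significantly below 0.

**MSRE arrays** hybridize a HpaII-digested sample (HpaII+) against the
undigested sample (HpaII-).  HpaII cuts only unmethylated CCGG (MspI)
sites, so digestion removes signal where the site is unmethylated and
`log(HpaII-/HpaII+)` is a *hypomethylation* score: significantly above 0
means hypomethylated.  Note the inverted direction convention relative to
`log(B/A)`; `classify_sites()` encapsulates both.

Log ratios use the natural log (the downstream analysis only uses signs
and thresholds, so the base is cosmetic and configurable); expression is
log2, the scale expression arrays are usually summarized on.

## Normalization

Channels are normalized separately across arrays with cyclic loess
(`limma::normalizeCyclicLoess`, pairwise method): for every array pair a
loess curve of M on A is fitted on the log2 scale and half of it is
subtracted from one array and added to the other.  Defaults are span 0.7,
degree 1 and 3 cycles; three cycles are needed for the residual pairwise
trend to drop below 0.01 on well-behaved arrays, and it is also limma's
default.  Two caveats are worth knowing:

* normalization assumes most sites are non-differential between arrays.
  Normalizing across tissues whose methylomes differ at a third of all
  sites makes the pairwise fits chase genuine signal; since per-array
  scale factors cancel in both `B/A` and `HpaII-/HpaII+` ratios, the
  test pipeline is robust to skipping normalization, and the
  benchmarking runs do so;
* intensities are clamped at zero after back-transformation, matching
  the assumption `A, B >= 0` of the beta value.

## Differential methylation calls

Per-site tests use a moderated t statistic with an empirical-Bayes
variance prior.  Site variances are modelled as
`s^2 ~ s0^2 F(d, d0)`; on `z = log(s^2)` this gives
`var(z) = trigamma(d/2) + trigamma(d0/2)`, so the prior degrees of
freedom `d0` solve `trigamma(d0/2) = max(0, var(z) - trigamma(d/2))`
(infinite when the site variances are no more dispersed than chi-square
sampling noise) and `s0^2` follows from `mean(z)` through the digamma
bias relation.  The moderated variance is
`(d0 s0^2 + d s^2)/(d0 + d)` with `d0 + d` total degrees of freedom; at
`d0 = 0` the statistic is the ordinary t, at `d0 = infinity` a z
statistic with sigma = s0 (both limits are verified numerically in the
tests, and the prior estimator is cross-checked against
`limma::fitFDist`).  Shrinkage is what makes the 2-pools-per-tissue MSRE
design testable at all (residual df = 1 per site).

Tests are two-sided and the direction is read off the effect sign; p
values are Benjamini-Hochberg adjusted (`stats::p.adjust`) within one
family per platform and contrast, with the FDR controlled at 5 percent
by default.  Hyperparameters are estimated genome-wide per platform.

## The sliding-window region scan

For each MspI site the scan computes, per tissue, the proportion of
hypomethylated sites among the `k = 50` sites nearest to it (the focal
site is included, keeping the denominator exactly 50; distance ties
break towards the lower coordinate so results are deterministic), and
the difference of the two proportions.  Significance is assessed against
a simulated null in which methylation is uniform along the chromosome
and the two tissues are independent: each replicate draws i.i.d.
Bernoulli flags per tissue at the observed chromosome-wide rates and
recomputes every window statistic.  All replicates and sites are pooled
(default 1,000 replicates) and add-one empirical p values
`(1 + #{null >= obs}) / (1 + n_null)` are assigned -- upper tail for the
rates, both tails for the difference -- then BH-adjusted per chromosome
and per track family.  Window sums are integers in `0..k`, so the pooled
null is stored as exact counts over that support; whole chromosomes cost
a few hundred integers of memory regardless of the replicate count.

Significant sites merge into regions whenever fewer than 50 sites lie
between them; a region spans its outermost member sites (0-based
half-open), and isolated significant sites stand as single-site regions.
Regions of one type never overlap by construction.

A scale subtlety discovered during development: the null is
*chromosome-relative* (the Bernoulli rates are the observed
chromosome-wide hypomethylation rates).  If planted difference regions
cover a large fraction of a chromosome -- as happens when the default 8
regions of 60-200 sites per chromosome are planted on 1/10-scale test
chromosomes -- the two tissues' chromosome-wide rates separate, the null
difference distribution shifts away from zero, and the *background*
becomes significant in the opposite tail.  That is faithful behaviour of
a chromosome-relative null, not a bug, but it means region-recovery
benchmarks are run at the study's full chromosome sizes
(49,285 / 42,978 / 25,878 sites), where planted regions cover ~4 percent
of each chromosome, the regime the method was designed for.  The
1/10-scale default remains in place for fast unit tests that do not
score the difference tracks.

## Genomic context and enrichment

Feature membership (gene body, promoter, exon, CpG island) is half-open
interval containment of the 0-based site position, computed with
GenomicRanges.  Promoters are 1,500 bp upstream to 1,500 bp downstream
of the TSS for the Infinium analysis and 1,500/1,000 bp for the MSRE
analysis, mirrored on the minus strand and clipped at zero.

Enrichment uses a two-sided Fisher exact test defined by the
point-probability criterion: the p value sums the probabilities of all
tables with the observed margins whose point probability does not exceed
the observed one (relative tolerance 1e-7).  This convention reproduces
published worked examples exactly and is verified against exhaustive
enumeration.  The odds ratio reported is the sample cross-product
`ad/bc`.  For gene-ontology-style tests the complement row excludes the
gene set itself (a set of 20 genes in a 786-gene universe is compared
against the other 766), since the null hypothesis compares the set
against *all other* genes.

## Methylation and expression

Per-gene promoter methylation is the mean score over array sites inside
the promoter window, averaged over the declared samples (CVS by
default); gene-body methylation aggregates MSRE sites inside the gene
body.  Associations are quantified three ways:

* Pearson correlation with the usual t test;
* piecewise correlations on either side of a threshold (0 for
  `log(B/A)`, i.e. 50 percent methylation; 0.03 for
  `log(HpaII-/HpaII+)`), which exposes the nonlinearity: negative and
  roughly linear below the threshold, flat above;
* a cubic smoothing spline (`stats::smooth.spline`) whose penalty is
  chosen so that the trace of the smoother matrix equals a target
  effective df (default 4; generalized cross-validation is available
  via `smooth.spline` directly but a fixed, modest df keeps the F test
  interpretable), with
  `F = [(RSS0 - RSS1)/(tr(S) - 1)] / [RSS1/(n - tr(S))]` referred to
  the F distribution with `(tr(S) - 1, n - tr(S))` df.

The trace-df F test treats the penalized fit as if it were a projection
of rank `tr(S)`, which makes it mildly liberal: its empirical size at
alpha = 0.05 is about 0.066 (n = 100, df = 4, 10,000 null fits) rather
than 0.050.  This is a property of the published procedure, documented
here rather than corrected; the acceptance simulation sizes are chosen
so the Monte Carlo error of that estimate (about 0.0025) is small
against the 0.03-0.07 acceptance band.  On rare predictor designs
(about 1 in 3,000 uniform draws) `smooth.spline`'s df search collapses;
the implementation falls back to the full knot set and finally to a
stability-aware bisection on the smoothing parameter, accepting the
closest numerically stable trace when the target is not reachable.

Promoter CpG density is the Gardiner-Garden and Frommer
observed/expected ratio `(n_CpG * L) / (n_C * n_G)` with `L` the full
sequence length (`N` ignored in counts but counted in `L`); genes split
into low and high classes at O/E = 0.4, with the low class taken
inclusively (`<= 0.4`).

## What the synthetic data emulates

The generators are pure functions of (config, seed) and return truth
labels sufficient to score every detection task without re-simulation.
Parameter values not fixed by the study design were chosen once to
reproduce the qualitative figures and quantitative recovery targets and
are documented here.

**Infinium (27,578 sites, 12 CVS vs 12 MBC by default).**  MBC betas are
drawn from `0.55 Beta(1.5, 30) + 0.45 Beta(30, 1.5)` (the bimodal
pattern).  CVS betas equal the MBC betas site for site except at:

* *flattened* sites -- two thirds of the hypermethylated component,
  whose CVS value is redrawn from `Beta(5, 5)` truncated so the beta
  difference is at least 0.3.  This moves the hypermethylated weight
  from 0.45 to 0.15 and creates a 0.30 intermediate class, i.e. the
  placental loss of the hypermethylated mode.  These sites are genuine
  CVS-hypomethylated differences and are labelled as such in the truth.
  Making the two tissues' betas independent draws instead would turn
  *every* site into a true difference and make false-discovery scoring
  meaningless, which is why the coupled construction is used;
* a *planted panel* of 3 percent of sites with a 5:1
  CVS-hypo : MBC-hypo direction split and |delta beta| >= 0.3.  The
  detected direction ratio is estimated on this labelled panel, because
  genome-wide the flattening (which is entirely CVS-hypo, the Fig-1-style
  global bias) swamps the ratio.

Intensities are `B = beta T_i c_j eps`, `A = (1 - beta) T_i c_j eps'`
with per-site totals `T ~ lognormal(7, 0.4)` (arbitrary units), per-array
scale factors `c ~ U(0.7, 1.4)` and measurement noise
`eps ~ lognormal(0, 0.1)`.  There is no per-sample biological
variability beyond measurement noise; real cohorts have more, so
real-data sensitivity will be lower than the benchmark's.

**MSRE (chromosomes of 49,285 / 42,978 / 25,878 MspI sites, scaled by
`scale`; 2 pools per tissue).**  Positions follow exponential gaps (mean
2 kb).  Background hypomethylation is a two-state Markov chain along
site order (stationary rate 0.3, mean hypomethylated run 30 sites),
*shared* between tissues so that the background difference track is
null.  Planted difference regions (8 per chromosome of 60-200
consecutive sites, plus a genome-wide total of 5 reversed regions, the
1:5 minority) force the tissues apart.  Digestion removes 80 percent of
signal at unmethylated sites and 4 percent at methylated sites; 4 rather
than 5 percent keeps the mean methylated-site score
(`-log(1 - d) = 0.041`) below 0.05, consistent with the construction
the tests assert.  The 0.03 gene-body threshold sits between the two.

**Annotation.**  Genes (lognormal lengths, median 20 kb, 1-12 exons)
are placed without overlap, and with *gene-desert coupling* they avoid
planted regions entirely, reproducing the observation that
differentially methylated domains are gene-poor.  Promoter sequences
(2 kb) are generated from a first-order Markov chain whose C-to-G
transition probability is tuned to a target O/E drawn from a two-mode
mixture (normals at 0.25 and 0.65, sd 0.08); sequences are regenerated
until the realized O/E is within 0.05 of target.  CpG islands (1 kb
around the TSS) are placed at 60 percent of high-O/E promoters.

**Expression.**  `expr = mu_g + a h(beta_prom) - b w_g + N(0, 1)` in
log2 units, where `mu_g` is 7 plus 0.75 for high-O/E promoters (high-CpG
genes are more expressed), `h` is linear below promoter beta 0.5 and
flat above (the planted nonlinearity), and `w_g` is the gene-body
hypomethylation score implied by the MSRE truth.  The slopes `a` and
`b` are calibrated per realization by root-finding on the sample-moment
expression for the correlation, so that the *expected* genome-wide
Pearson r between expression and promoter `log(B/A)` is -0.35 and
between expression and gene-body `log(HpaII-/HpaII+)` is -0.111.  The
expression benchmark uses 300 genes per cohort and averages estimates
over 10 cohorts.

## Problem sizes used in the shipped checks

Unit tests run on reduced sizes (thousands of sites, hundreds of
genes).  The acceptance suite uses the study-design sizes: 27,578
Infinium sites with 12 samples per tissue, full-size MSRE chromosomes
for region recovery, 20,000 simulated variances for prior recovery,
10,000 null spline fits, 20 null scan replicates of 2,000 sites, and 10
expression cohorts of 300 genes.

## Known limitations

* No background correction, dye-bias modelling, detection p values,
  cell-composition deconvolution or batch correction; inputs are assumed
  to be summarized, artifact-free intensities.
* The generators do not simulate bisulfite chemistry, probe
  cross-hybridization, SNPs under probes, or biological between-sample
  variance; passing benchmarks here demonstrates the statistical
  machinery, not robustness to those artifacts.
* The chromosome-relative null makes background calls on chromosomes
  where one tissue's hypomethylation is broadly elevated (see the scan
  section); interpret difference regions relative to the chromosome, not
  absolutely.
* The trace-df spline F test is mildly liberal (size ~0.066 at nominal
  0.05); treat marginal p values accordingly.
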