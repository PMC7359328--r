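---
title: "Scoring pooled AsCas12a screens and calling genetic interactions"
author: "duoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled AsCas12a screens and calling genetic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoscreen)
```

## The problem

A pooled dropout screen transduces a cell population with a library of
AsCas12a crRNAs (or dual-crRNA cassettes encoding two guides on one
transcript), cultures it, and deep-sequences the guide-encoding cassette at
an initial and a final timepoint. Guides that knock out genes required for
proliferation deplete. `duoscreen` implements the full analysis path: read
quantification, per-guide scoring, domain-level aggregation, and — for
dual-crRNA libraries — a position-sensitive Gaussian null model that calls
synthetic sick/lethal genetic interactions between gene pairs.

## Scoring model

Counts for each sample are rescaled to a common total (default $10^6$).
Guides with a raw initial count below 50 are discarded before
normalization; "read count" refers to sequenced reads, so the filter acts
on raw counts. The per-guide score is a capped log2 fold-change

$$\mathrm{LFC} = \log_2\!\left(\min\!\left(\frac{f + 1}{i},\, 100\right)\right),$$

with $f$ and $i$ the normalized final and initial abundances. The
pseudocount sits on the final abundance only, following the fold-change
definition literally; the cap acts on the fold scale, so enrichment is
bounded at $\log_2 100 \approx 6.64$ while dropout is uncapped (no lower
cap is defined). The CRISPR Score (CS) of a protein domain is the
arithmetic mean LFC of its guides; in single screens LFCs are computed per
replicate and averaged per guide first, whereas dual screens condense
replicates by summing raw counts before normalization — both choices
mirror how the two screen types are conventionally processed, and the
second makes condensation commute with normalization exactly.

## The interaction null model

A dual cassette carries an ordered pair of guides. Position matters: the
guide in position 1 tends to show the stronger phenotype, so all null fits
are position-sensitive — the distribution of a guide paired with negative
controls while sitting in position 1 ($f_g(\mathrm{exp\_neg})$) is a
different object from the same guide in position 2
($f_g(\mathrm{neg\_exp})$).

Three detection filters precede any fitting, all with overridable
defaults:

* an experimental guide needs at least 4 distinct negative controls
  detected opposite it *in each position*; otherwise every cassette
  containing it (either position) is eliminated;
* a gene pair needs at least 8 detected experimental-by-experimental
  cassettes (both orientations counted);
* a gene needs at least 2 surviving guides.

For a gene pair $(A, B)$, gene-level null fits are built per position by
pooling the negative-paired LFCs of the gene's surviving guides. The
expected no-interaction distribution combines the two orientation
convolutions $\mathcal{N}(\mu_{A,1} + \mu_{B,2},\, \sigma_{A,1}^2 +
\sigma_{B,2}^2)$ and $\mathcal{N}(\mu_{B,1} + \mu_{A,2},\, \sigma_{B,1}^2
+ \sigma_{A,2}^2)$ as an equal-weight mixture summarized by its overall
mean and variance. The additive convolution is the default because the
expected log2 effect of a double knockout under no interaction is the sum
of the single-knockout log2 effects; a literal density product of the two
Gaussians would place the expected mean *between* the two single effects,
under which a "more depleted than expected" differential test is
incoherent. The density-product combination is retained behind
`expectedMode = "density-product"` for comparison.

The observed distribution pools all surviving cassette LFCs for the pair,
both orientations. A one-sample two-sided Kolmogorov–Smirnov test compares
the observed values against the expected Gaussian CDF (the expected side
is a fitted parametric distribution, not a sample, so a one-sample test is
the coherent choice); p-values are asymptotic. Benjamini–Hochberg q-values
are computed across all retained pairs, and a pair is a hit iff

$$q < 0.05 \quad\text{and}\quad \Delta = \mu_{\mathrm{expected}} -
\mu_{\mathrm{observed}} > 2.5,$$

i.e. the observed pair is substantially more depleted than expected
(synthetic sick). The z-score $\Delta / \sigma_{\mathrm{expected}}$ is
reported alongside but not used for gating. Only the depletion direction
is tested; buffering (alleviating) interactions are out of scope.

## Read-to-cassette mapping and uncoupling

Cassette quantification follows three rules: reads shorter than 60 bases
are discarded (empty-vector products); a read is assigned to the reference
entry of minimum edit distance, where substitutions, indels and unaligned
tails all cost 1 and N bases count as mismatches; the assignment stands
only if that distance is at most 2 *and* the minimum is strictly unique —
ties go unmapped, a deliberate conservative resolution since no tie rule
is defined for the underlying aligner-based procedure. The reference
contains the designed library plus every ordered spacer pair absent from
the design (the possible recombination products); enumeration is eager
with a 500k-entry guard, which is ample for the library sizes in scope.
The uncoupling frequency is the fraction of mapped reads assigned to a
recombination product. Single-guide libraries are counted by exact spacer
match with no mismatches permitted.

## crRNA design rules

`scanPamSites()` reports every TTTV PAM (V ∈ {A, C, G}) on either strand
with a complete 23-nt downstream spacer. Sites are classified by a
cut-position proxy — the midpoint of protospacer positions 18–23,
reflecting the PAM-distal staggered cut of Cas12a; the exact coordinate
rule is a package choice since only the targeted-region classes are
defined. Class precedence is domain > nondomain (exonic) > noncoding.
Spacers with a perfect match (either strand) anywhere other than their own
locus are filtered out; no mismatch-tolerant off-target scoring is
attempted. Per-domain selection takes up to 5 guides, leftmost cut first —
a deterministic stand-in for an unspecified ranking — and flags domains
with fewer than 3 candidates rather than dropping them. All coordinates
are 0-based half-open on the forward strand (BED dialect).

## The synthetic-screen generator

The simulator exists so every estimator in the package can be tested
against known truth. It emulates:

* log-normal initial library skew (`abundanceLogSd`, natural-log sd,
  default 0.5 — a few-fold spread typical of cloned pooled libraries);
* per-guide true effects: gene mean effect plus
  $\mathcal{N}(0, \texttt{guideSd}^2)$ guide noise (default sd 0.5 log2
  units); negative controls are exactly 0;
* a one-interval exponential growth model: final expected proportion
  $\propto$ initial $\times\, 2^{\mathrm{LFC}}$, renormalized — the
  multi-day culture is collapsed into one effective interval because only
  initial and final counts enter the analysis;
* multinomial sequencing at fixed depth (default $10^6$), independently
  per replicate (default 2), so column sums are conserved exactly;
* in dual cassettes, a position-1 effect multiplier $\beta$
  (`positionBias`) and planted interactions $(A, B, \delta)$ adding
  $\delta$ to every cassette whose two guides target the planted pair;
* cassette recombination for read simulation: with probability `r`
  (default 0.0033) the position-2 spacer is re-paired uniformly at random
  over the other library spacers — the simplest exchangeable model of
  uncoupling as re-assortment — with truth labels emitted alongside, and a
  per-base substitution error rate.

The default composition (15 genes × 3 guides + 22 negative controls,
giving 105 testable gene pairs at depth $10^6$) is the design used by the
package's calibration, type-I and power checks. What the generator does
*not* model — PCR amplification bias, indel errors, infection
multiplicity, guide efficiency variation, chromatin context — bounds what
passing tests show: they demonstrate that the estimators are correct and
calibrated under the stated statistical assumptions, not that those
assumptions exhaust real screen data.

## Numerical choices and degenerate inputs

* Gaussian fits use the sample sd (n−1); fits need ≥ 2 values, guaranteed
  post-filter. A fit with sd 0 is representable; an expected distribution
  with sd 0 makes the KS test undefined and the pair is flagged rather
  than tested.
* Mann–Whitney category comparisons are exact for small untied groups
  (product of sizes ≤ $10^4$) and tie-corrected normal otherwise.
* All-zero sample columns, empty references, duplicate spacers, missing
  negative controls and undersized depths fail with explicit messages
  rather than propagating NaNs.
* Every stochastic step flows from the single `seed` in `simConfig()`;
  guide annotation (ids, spacers) is deliberately seed-independent so that
  changing the seed changes counts but never the library.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1,
                 plantedInteractions = data.frame(
                   geneA = "gene03", geneB = "gene11", delta = -4))
sim <- simulateDualScreen(cfg)
res <- analyzeDualScreen(sim$counts, sim$annotation)
subset(as.data.frame(res$pairs), hit)
```

The planted pair is recovered with a differential near $-\delta = 4$ and a
vanishing q-value; with no planted pairs the hit table is empty — the
differential gate alone keeps null pairs (whose differentials are within a
few hundredths of 0) far from the 2.5 threshold.

## Known limitations

* The expected-pair model assumes guide effects combine additively in
  log2 space; strong epistasis in the *negative-control* pairings would
  violate the null construction.
* The pseudocount on the final abundance compresses very strong dropout
  (an LFC of −6 is measured as roughly −5.6 at typical coverage), which
  slightly shrinks differentials for extreme planted effects.
* Recombinant-reference enumeration is quadratic in guide number; the
  eager strategy is intended for focused libraries (hundreds of guides),
  not genome-scale designs.
* Only depletion-direction (synthetic sick/lethal) interactions are
  called.
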