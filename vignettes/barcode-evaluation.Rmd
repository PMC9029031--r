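---
title: "Evaluating a DNA barcode marker: methods and design notes"
author: "barcodeEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a DNA barcode marker: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeEval)
```

## The problem

A DNA barcode is a short, standardised marker (here the model is a
nuclear spacer such as ITS2, a few hundred base pairs) used to assign a
query sequence to a species by comparison against a reference library.
Whether that works for a given family of organisms is an empirical
question with three classic diagnostics:

1. **Variability** — does the marker vary at all within the group?
   Alignment site categories (conserved, variable,
   parsimony-informative, singleton) and the overall mean distance
   summarise this.
2. **The barcode gap** — are conspecific sequences systematically closer
   to each other than to heterospecific ones? Compared through the five
   divergence indices and the intra/interspecific distance-frequency
   distributions.
3. **Identification success** — does a nearest-neighbour criterion
   actually return the right species? Scored leave-one-out with Best
   Match (BM), Best Close Match (BCM) and a best-hit (BLAST1-style)
   rule.

All of it is computed at four nested taxonomic levels — species
complex, genus, subfamily, family — because a marker that separates
genera cleanly can still be useless inside a complex of recently
diverged, hybridising species. Conifer groups such as the *Pinus mugo*
aggregate are the motivating example: morphologically intergrading
taxa that share identical haplotypes, which drives every
nearest-neighbour method to 100 % ambiguity.

## Distances

Pairwise distances use the Kimura two-parameter (K2P) model with
*pairwise deletion*: for each pair, sites where either sequence has a
gap or an ambiguity code are excluded, leaving $L$ comparable sites
with transition proportion $P$ and transversion proportion $Q$, and

$$d = -\tfrac12 \ln\!\left[(1-2P-Q)\sqrt{1-2Q}\,\right].$$

When $L=0$ or the logarithm argument is non-positive (saturation —
common between unrelated sequences) the pair is **undefined**. We
propagate undefined distances as missing values, never as infinities or
clamped maxima: every summary excludes them and reports how many were
dropped. This is an explicit design choice; distance software differs
in how it treats saturated pairs, and silent clamping biases means.

## Site categories

Columns are classified ignoring gaps and ambiguity codes: *conserved*
(one base type, at least two usable residues), *parsimony-informative*
(≥ 2 base types each in ≥ 2 sequences), *singleton* (variable, at most
one base type occurring more than once), *indeterminate* (fewer than
two usable residues; counted in the aligned length but in neither CS
nor VS). Under this rule every variable column is either
parsimony-informative or a singleton; the API keeps a
`variable-other` factor level because published tables computed with
other tools sometimes show VS > PIS + SS, implying a convention that
leaves some variable columns unassigned — that convention is not
documented anywhere we could verify, so we implement the transparent
rule and expose the discrepancy rather than emulate an unknown one.

The overall mean distance (OMD) is the arithmetic mean of all defined
pairwise K2P distances; the distance model behind OMD is a package
choice (the same K2P/pairwise-deletion machinery as everything else)
since summary tables in the literature rarely state it.

## Divergence indices

For a group at any level:

* **all interspecific distance** — mean over defined heterospecific
  pairs (SD over those pairs);
* **minimum interspecific distance** — per species, the smallest
  defined distance to any non-conspecific sequence, averaged over
  species. The alternative reading (a single group-wide minimum) is
  indistinguishable in most published tables because shared haplotypes
  force both to 0.0000; the per-species average is adopted because it
  remains informative for groups without haplotype sharing;
* **all intraspecific distance** — pooled mean over defined
  conspecific pairs;
* **theta** — per-species mean conspecific distance averaged with
  equal species weights, so heavily sampled species do not dominate;
* **coalescent depth** — per-species maximum conspecific distance,
  likewise averaged.

Species with one sequence have no conspecific pairs; they are skipped
for theta and coalescent depth (zero-filling would bias both
downward) but still contribute interspecific pairs. The dispersion
printed as "±" is the sample SD of the constituent values; published
tables rarely define their "±", and SD over constituents reproduces
the large spreads seen when a group mixes near-identical and highly
divergent species. The SE is also carried in the result for readers
who prefer it. A single-species group reports 0 for all five indices,
the convention used for single-taxon genera in comparable surveys.

## Barcode gap and histograms

Defined distances are expressed in percent and binned into half-open
intervals $[lo, hi)$ of one percentage point by default, the terminal
bin closed. The bin convention is stated because figure legends in the
literature ("0–1, 1–2, …") do not reveal their closure rule. Range
shares and the gap summary (max intraspecific, min interspecific,
their difference, and the share of interspecific pairs below the 95th
intraspecific percentile) are computed from the raw distances held in
the histogram object, so they are exact, not re-binned.

## Identification scoring

Leave-one-out: each query is removed from the reference pool;
everything else, including its conspecifics, stays. The best-match set
is every reference at the minimum defined distance — ties are kept and
compared exactly (no epsilon), because all distances come from
identical arithmetic and exact zero ties are precisely what produces
the *ambiguous* verdict in haplotype-sharing groups. BCM first
discards references beyond the threshold (default: 95th percentile of
pooled intraspecific distances, linearly interpolated; matches at
exactly the threshold survive); an empty surviving set is *no match*.
Queries from species with fewer than two sequences are excluded from
the denominators.

The BLAST1-style criterion classifies by the species composition of
the top-scoring hit set. The default scorer is the fraction of
matching comparable sites on the aligned sequences — a deterministic,
dependency-free stand-in for a similarity search that preserves the
three-way rule exactly; a tabular hit file from a real BLAST run can
be supplied instead. Replicating any particular published BLAST
success rate against a live database is out of scope. On gap-free data
whose mismatches are all transitions, the similarity ranking and the
K2P ranking coincide including ties, so BM and BLAST1 verdicts agree
exactly; with mixed transition/transversion content, equal mismatch
counts can map to unequal K2P distances, and tie-sets may differ —
the test suite pins down exactly the former regime.

## The simulator

`simulateDataset()` generates alignments under a star-within-star
topology: a uniform random root, genus ancestors, species ancestors,
then individual tips, each branch evolved by a continuous-time K2P
process with transition/transversion rate ratio $\kappa$ (rates
normalised so branch length = expected substitutions/site). Branch
lengths are set from the target divergences: tips at
$\delta_w/2$, species branches at $(\delta_b-\delta_w)/2$, genus
branches at $(\delta_g-\delta_b)/2$, so *expected* pairwise divergence
is exactly $\delta_w$ within species, $\delta_b$ within genera and
$\delta_g$ between genera. A star topology was chosen over a random
birth–death tree precisely because it makes those expectations exact
and testable; tree-shaped simulation is a possible extension, not a
default.

Defaults (chosen once, as the package's reference survey): 7 genera in
3 subfamilies with species counts (10, 3, 2, 6, 1, 4, 12), 1–10
sequences per species drawn uniformly, 250 bp, $\delta_w = 0.01$,
$\delta_b = 0.10$, $\delta_g = 0.30$, $\kappa = 2$. These sit inside
the ranges published for conifer ITS2 surveys (intraspecific means up
to ~0.20, interspecific up to ~0.36, alignment lengths 232–270 bp)
and include a single-species genus so the degenerate single-taxon path
is exercised. Two switches reproduce the pathologies that make
barcoding fail: `zeroVariationComplex` copies one haplotype to every
member of a 5-species complex (the zero-variation regime), and
`shareHaplotypes` plants one identical sequence across two sibling
species, forcing a 0.0000 minimum interspecific distance.

What the simulator does **not** emulate: indels and alignment
uncertainty (no indel process; an optional gap-column injector only
exercises pairwise deletion), rate variation among sites and lineages,
concerted evolution and paralogy of rDNA arrays, and database
mislabelling. Passing tests on synthetic data therefore demonstrate
the correctness of the computations and the qualitative mechanisms
(gap → success, sharing → ambiguity), not the field performance of any
particular marker.

## Numerical choices

* Report percentages are rounded half-up to two decimals at the
  reporting boundary only; internal values stay at full precision.
* The BCM percentile uses R's default linear interpolation
  (type 7 quantiles).
* Undefined pairs are counted and surfaced at every stage
  (`nPairsDropped`, pipeline log lines).
* Group subsetting removes columns that are gap in every remaining
  sequence; under pairwise deletion this provably never changes a
  distance, and the test suite asserts it on random data. Per-group
  re-alignment with an external aligner can be plugged in by writing a
  view out and reading the re-aligned result back; the core stays
  deterministic.
* Test and recovery problem sizes (e.g. 30 species × 4 sequences for
  parameter recovery, 400 pairs for the Monte-Carlo consistency check)
  were chosen so sampling error is a small multiple of the asserted
  tolerances, which the tests derive explicitly.

## Worked example

```{r example, eval = FALSE}
sim <- simulateDataset(synthConfig(seed = 7, shareHaplotypes = TRUE))
aln <- filterValid(sim$alignment)
res <- runBarcodePipeline(aln, levels = c("genus", "family"),
    methods = c("BM", "BCM"), outDir = "reports")
as.data.frame(res$levels$family$all$siteStats)
res$levels$family$all$gap
res$levels$family$all$identification$BM
```

## Known limitations

* The site-category rule is one defensible convention among several;
  tables produced by other software may differ where gaps and
  ambiguities are involved.
* The BLAST1 default scorer is not BLAST: no local alignment, no
  e-values; it is a transparent best-hit criterion over a fixed
  alignment.
* Minimum interspecific distance follows the per-species-average
  reading (see above); users wanting the group-wide minimum can take
  `min` over the exported long-form distances.
* The family-level group is the whole dataset; the package does not
  re-align per group unless the user plugs in an external aligner.
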