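# barcodeEval

Evaluation of DNA barcode marker performance from aligned sequences.

## What this is for

Short standardised markers (ITS2 and friends) are routinely used to
identify plant and animal species by sequence comparison. Whether that
actually works inside a given family — especially among closely
related, hybridising taxa — is an empirical question. `barcodeEval`
implements the full diagnostic battery a barcoding study runs, at four
nested taxonomic levels (species complex, genus, subfamily, family):

- **Alignment variability**: conserved (CS), variable (VS),
  parsimony-informative (PIS) and singleton (SS) site counts plus the
  overall mean distance (OMD), per group.
- **K2P distances**: Kimura two-parameter distances under pairwise
  deletion,
  `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`,
  with per-pair comparable-site counts, transition/transversion
  proportions and explicit undefined-pair flags (saturated pairs are
  missing data, never clamped).
- **Divergence indices**: all/minimum interspecific distance, all
  intraspecific distance, theta (per-species mean conspecific distance,
  averaged with equal species weights) and coalescent depth
  (per-species maximum), each as mean ± SD of its constituents.
- **Barcode gap**: intra/interspecific distance-frequency histograms in
  percent units, range shares, and a gap summary (max intra, min inter,
  their difference, overlap share).
- **Identification scoring**: leave-one-out Best Match, Best Close
  Match (threshold = 95th percentile of intraspecific distances) and a
  BLAST1-style best-hit criterion, with per-query verdicts
  (correct / incorrect / ambiguous / no match) and per-group rates.
- **A seeded simulator** of species/genus-structured alignments under a
  K2P substitution process, with switches for the two classic failure
  modes: a zero-variation species complex and shared haplotypes across
  sibling species.

The package is S4 throughout (`BarcodeAlignment`, `K2PMatrix`,
`SiteStats`, `DivergenceSummary`, `DistanceHistogram`,
`IdentificationReport`) and reads/writes plain FASTA + tab-separated
taxonomy tables.

## Worked example

```r
library(barcodeEval)

sim <- simulateDataset(synthConfig(seed = 7, shareHaplotypes = TRUE))
aln <- filterValid(sim$alignment)
aln
#> BarcodeAlignment: 174 sequences x 250 bp; 33 species, 7 genera, 3 subfamilies
#>   excluded during validation: 5

dm <- k2pMatrix(aln)
divergenceSummary(dm)
#> DivergenceSummary [family / all]
#>   allInterspecific   0.2603 ± 0.0868  (n=14540)
#>   minInterspecific   0.0765 ± 0.0412  (n=33)
#>   allIntraspecific   0.0117 ± 0.0097  (n=511)
#>   theta              0.0133 ± 0.0155  (n=33)
#>   coalescentDepth    0.0205 ± 0.0231  (n=33)

h <- distanceHistogram(dm)
barcodeGapSummary(h)$gap      # negative: the planted shared haplotype
#> [1] -14.0838                # collapses the gap (min inter = 0)
rangeShare(h, "intraspecific", 0, 2)
#> [1] 86.30137                # % of conspecific pairs diverging < 2%

identificationReport(aln, "BM", dm = dm)
#> IdentificationReport [family / all] BM: 174 queries
#>   correct 98.85% | incorrect 1.15% | ambiguous 0.00% | no match 0.00%
```

Reading the output: 5 sequences were dropped by the validation filters
(species left with a single sequence). Interspecific divergence (mean
0.26 substitutions/site) dwarfs intraspecific divergence (0.012), so
Best Match identifies nearly everything — except the two sequences
involved in the planted haplotype sharing, whose nearest neighbours are
heterospecific (the 1.15% incorrect). The gap summary shows the same
event from the distance side: the minimum interspecific distance is
exactly 0.

The one-call orchestrator runs every stage for every group at the
requested levels and writes TSV/CSV/JSON reports:

```r
res <- runBarcodePipeline(aln, levels = c("genus", "family"),
                          methods = c("BM", "BCM"), outDir = "reports")
```

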