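# spatialTCR

Spatially resolved T cell receptor (TCR) repertoire analysis from targeted
in situ sequencing (Xenium-style) data, for researchers studying T cell
clonality in tissue — tumour immunology in particular — without prior TCR
sequencing.

Imaging-based assays read padlock probes, not CDR3 sequences. `spatialTCR`
therefore works with the *TCRVβ/Vα pair*: the co-detection of exactly one
TRAV and one TRBV gene in a single cell, written `TRAVx|TRBVy`, used as a
putative clonotype. The package implements the full workflow around that
object:

* **Probe target design** — enumerate all 30-mers of TCR V/J/C gene
  sequences; screen within-family cross-reactivity by seed-and-extend
  alignment (identity ≥ 0.80 over the 30-mer flags a candidate); apply the
  padlock composition filter (GC ∈ [0.40, 0.60], homopolymer runs ≤ 3, G/C
  at the ligation-junction position 16); screen a transcriptome on both
  strands; group genes no compliant probe can discriminate.
* **Clonotype calling** — the seven-way rule table over distinct detected
  V genes per chain: `orphan_alpha` (1, 0), `orphan_beta` (0, 1),
  `ab_single_pair` (1, 1), `ab_multi_chain` (2, 2), `extra_alpha` (2, ≤ 1),
  `extra_beta` (≤ 1, 2), `ab_unknown` otherwise; the same table for
  gamma/delta. Cells are pre-filtered to ≥ 5 transcripts, ≥ 3 genes, and
  genes to ≥ 3 cells.
* **Spatial maps** — 300-px hexagon binning of TCR transcript density and
  per-family diversity: the *max fraction* (share of the most expressed V
  gene in a bin) flags low diversity at ≥ 50%, with bins under 10 counts
  masked.
* **Neighbourhood enrichment** — fixed-radius (125 px) spatial graphs and
  permutation z-scores, `z = (observed − mean_perm)/sd_perm`, for cell
  types and clone identities versus their neighbours.
* **Diversity statistics** — Gini index
  `G = Σᵢ Σⱼ |xᵢ − xⱼ| / (2 n² x̄)` per T-cell subset with a 15-cell
  cutoff; abundance-based Jaccard
  `J_abd = Σ min(aᵢ, bᵢ) / Σ max(aᵢ, bᵢ)` between time points; paired
  two-tailed t-tests on Gini changes.
* **Synthetic tissues** — a seeded generator with known cell types, planted
  clones, stray transcripts and dropout, so every stage is testable with
  ground truth.

## Worked example

```r
library(spatialTCR)

panel <- defaultPanel()            # reconstructed 98-gene TCR panel
cfg   <- syntheticConfig(seed = 7) # tumour-like tissue, one dominant clone
tt    <- generateTissue(cfg)

x     <- filterMatrix(tt$experiment)        # >=5 counts, >=3 genes, >=3 cells
calls <- callClonotypes(x, panel)
table(calls$ab_type)
#>   orphan_alpha    orphan_beta ab_single_pair ab_multi_chain    extra_alpha
#>             13              9            467              0              2
#>     extra_beta     ab_unknown
#>              2            978

pairSummary(pairAbundances(calls))
#>   stratum n_unique_pairs n_cells     dominant_pair dominant_fraction
#> 1     all            351     467 TRAV29/DV5|TRBV30         0.1263383
```

Of 1471 cells passing the filter, 467 carry exactly one TRAV and one TRBV
gene; the planted dominant clone `TRAV29/DV5|TRBV30` is recovered at 12.6%
of single-pair cells (12.2% planted). Spatial structure follows the same
objects:

```r
div <- binDiversity(tt$transcripts, panel, "TRBV")   # max fraction per hex
g   <- buildGraph(x, radius = 125)
er  <- pairProximity(g, calls, cellLabels(x), min_cells = 5,
                     n_perms = 200, seed = 3)
zMatrix(er)["TRAV29/DV5|TRBV30", "cancer"]
#> [1] 12.67194
```

The strongly positive z-score says cells of the dominant clone neighbour
cancer cells far more often than label-shuffled chance — the planted
peritumoural expansion.

A command-line front end mirrors the API
(`inst/cli/spatial-tcr.R`: `simulate`, `design-panel`, `call-clonotypes`,
`bin-diversity`, `neighbourhood`, `diversity`); every stage is
byte-reproducible given a seed.

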