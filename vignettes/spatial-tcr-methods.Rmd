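---
title: "Methods: spatial TCR repertoire mapping with spatialTCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial TCR repertoire mapping with spatialTCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTCR)
```

# Scope and model

Targeted in situ sequencing (Xenium-style) with a TCR-specific padlock probe
panel produces a table of decoded transcripts — `(x, y, gene, cell_id,
quality)` — in which the *gene* can be a T cell receptor variable (V),
joining (J) or constant (C) segment. Because the assay reads probes rather
than sequences, a clonotype cannot be defined by its CDR3; instead the
package uses the co-detection of exactly one TRAV and one TRBV gene in a
cell as a *putative clonotype*, written `"TRAVx|TRBVy"` with the alpha gene
first. A TCRVb/Va expansion indicates, but does not prove, shared CDR3
sequences: cells with identical CDR3s necessarily share the V-pair, while
the converse does not hold. Everything downstream — abundance tables, maps,
enrichment, diversity — is built on this proxy.

`spatialTCR` covers the full workflow: probe target design from gene
sequences, transcript-table ingestion, rule-based single-cell clonotype
classification, hexagon-binned density/diversity maps, permutation
neighbourhood enrichment, repertoire statistics, and a seeded synthetic
tissue generator that provides ground truth for every stage.

# Probe target design

`designPanel()` enumerates every 30-mer of each input gene
(`enumerateCandidates`), screens for within-family cross-reactivity
(`uniquenessScreen`), applies the padlock composition filter
(`compositionFilter`), and optionally screens a transcriptome
(`transcriptomeScreen`), in that order.

The composition criteria are: GC fraction within `[0.40, 0.60]`
(*inclusive* at both bounds — the interval is a parameter), no homopolymer
run longer than 3 (so any `AAAA` fails; "fewer than four repeated bases" is
the standard padlock reading and the cap is a parameter), and G or C at
1-based position 16 of the 30-mer, the ligation-junction position.

The cross-reactivity screen is a seed-and-extend scan: an exact shared
12-mer between candidates of two different genes triggers gapless extension
at that relative shift, and identity is counted as matches over the *full*
30-mer, so partial overlaps are penalised. The default flagging threshold is
identity ≥ 0.80 (24/30). The transcriptome screen realises the same
gapless contract as Hamming matching at up to 6 mismatches, on both strands,
via `Biostrings`. Thresholds are deliberately expressed as identities so any
aligner (including BLAST) can reproduce the contract.

Genes whose every surviving candidate is cross-reactive only within a fixed
set of same-chain/segment genes are merged into a *gene group* that shares
probes; grouped genes are analysed as one unit everywhere downstream and
counts are never split back to members. Genes with no surviving candidate
are reported untargetable, never dropped silently. Among survivors, targets
are ranked: unflagged first, then GC closest to 50%, then smallest offset —
this ranking is a design choice of this package, since survivor selection is
otherwise underdetermined.

IUPAC ambiguity codes are a hard error in gene sequences (probes are
physical oligos) but merely skip transcriptome records, with a count
attached to the result.

# Panel model

`parseGeneName()` classifies IMGT-style names (`TRAV26-1`, `TRBV20-1`,
`TRAC`) by prefix into chain and segment. Dual alpha/delta variable genes
(`TRAV29/DV5` and friends) are classified alpha with a `dual_alpha_delta`
flag; the clonotyper decides how to count them (below). The shipped default
panel (`defaultPanel()`, 98 genes, 93 groups) is a *reconstruction*: real
panels depend on the IMGT snapshot used at design time, so the table is
labelled synthetic and exists to make every stage runnable out of the box.

# From transcripts to calls

`buildCellMatrix()` aggregates assigned transcripts into a sparse
gene-by-cell matrix (Bioconductor orientation) wrapped in a
`TCRExperiment` (a `SingleCellExperiment` that guarantees counts and
centroids); centroids are means of each cell's transcripts. `filterMatrix()`
applies the quality gate in one pass: cells need ≥ 5 transcripts over ≥ 3
genes, then genes need detection in ≥ 3 surviving cells. The pass is
deliberately not iterated to a fixpoint; re-running the filter may remove
more, and the single pass is the contract. The per-cell totals default to
all panel genes; a `genes =` argument restricts them to TCR genes only,
since "counts per cell" is ambiguous between the two readings.

`classifyAB()` is the seven-way rule table over the numbers of *distinct
detected* V genes per chain (presence, not transcript counts — the rule
table is integer-valued): orphan_alpha (1, 0), orphan_beta (0, 1),
ab_single_pair (1, 1), ab_multi_chain (2, 2), extra_alpha (2, ≤1),
extra_beta (≤1, 2), ab_unknown otherwise. The same table on gamma/delta
counts yields the gd types. Only V genes enter classification; J and C genes
are supporting evidence and QC. Grouped genes count once. Dual TRAV/DV genes
default to alpha-only counting (`dual_policy`), consistent with reporting
them inside alpha/beta pairs; `delta_only` and `both` are available.

Only single-pair cells feed the abundance tables (`pairAbundances`), with
deterministic ordering (cells descending, then pair id — the tie-break is a
package convention). `topPairPersistence` tracks the top-k baseline pairs
into a later repertoire.

# Hexagonal density and diversity maps

Transcripts are binned into hexagons of `grid_size` 300 px measured
flat-to-flat, flat-top orientation. Width and orientation are parameters
because either reading of a "grid size" is defensible; the choice is guarded
by a sanity property — at default synthetic tissue density an occupied
hexagon holds about five cells (asserted as mean ∈ [3, 8]). Assignment uses
axial coordinates with cube rounding, equivalent to nearest hexagon center
(property-tested against brute force).

Density maps count all panel TCR transcripts per bin (transcript-level, with
exact count conservation). Diversity maps are per V family (TRBV, TRAV,
TRGV, TRDV; dual TRAV/DV genes sit in TRAV): per bin, the fraction of each
family gene among family counts, summarised as the *max fraction*; a max
fraction ≥ 0.5 flags low local diversity. Bins with fewer than 10 family
counts are masked — reported with `NA` statistics rather than dropped, so
density and diversity maps share geometry — because a near-empty bin would
otherwise fake clonality. Diversity is computed from transcript counts, not
cell-level calls.

# Neighbourhood enrichment

`buildGraph()` connects cells within a fixed radius, default 125 px
(roughly a two-cell diameter), boundary *inclusive* — a convention this
package fixes since either choice is defensible. A grid-bucket index makes
construction near-linear; the edge set equals brute force by property test.

`enrichment()` counts edges per unordered label pair and compares each count
to a permutation null: labels are fully permuted over nodes (graph fixed,
label multiset conserved exactly), z = (obs − mean)/sd over `n_perms`
permutations (default 1000). Where the permutation spread is zero the z is
`NA`, not infinite. The permutation stream acts on nodes in cell-id order,
so results are bit-identical for a given seed regardless of row order.
Under a random-label null the z-scores are approximately standard normal
(calibration is property-tested).

`pairProximity()` relabels single-pair cells of pairs carried by *more than*
`min_cells` cells (default 5, strict) with their pair identity and runs the
same test against cell-type labels — asking which cancer or stromal
populations a clone preferentially neighbours. A "five-cell radius" variant
maps to 312.5 px under the 125 px ≈ two-cell-diameter calibration; this is
a documented convention, exposed as `radius`, not a measured value.

# Diversity statistics

`giniIndex()` is the population double-sum form, computed by the sorted
identity, bounded by (n−1)/n, with an optional n/(n−1) correction off by
default (no variant is canonical for repertoires). `giniByStratum()` applies
a 15-cell cutoff per stratum (below it the Gini is reported `NA`, since
small subsets fake clonality), always adds a pooled "All T cells" stratum,
and offers two abundance definitions: cells per pair (`pair_counts`,
default — the clonality reading) and transcript counts per TRV gene
(`gene_counts` — the literal transcript-inequality reading). Both are
first-class because the two readings diverge and neither is authoritative.

`jaccardAbundance()` defaults to the Ružička (min/max) form, which reduces
to binary Jaccard on presence/absence vectors; `method = "chao"` delegates
to `vegan`'s Chao abundance-based estimator as an alternative when unseen
shared clones matter. `pairedGiniTest()` is a paired two-tailed Student
t-test on per-stratum Gini values; identical vectors give t = 0, p = 1, and
constant non-zero differences are flagged degenerate rather than reported as
infinite.

# The synthetic tissue generator

Real raw data for this assay class are typically not depositable, so the
generator is first-class, seeded, and defines the package's study
conditions:

* **Geometry**: 5000 × 5000 px tissue, 1600 cells (about five cells per
  300-px hexagon), cancer (35%) and T cells (30%) clustered around shared
  "tumour nest" centers, stroma and B cells scattered. Blob-type cells share
  nest centers so that T cell and cancer compartments interleave as they do
  around tumour nests.
* **Clonal structure**: one planted dominant clone, `TRAV29/DV5|TRBV30`, at
  12.2% of the host type's single-pair cells, seated on the host cells
  nearest the first nest (peritumoural expansion). Remaining T cells draw
  background pairs uniformly from the panel's TRAV × TRBV groups.
* **Expression**: per-segment Poisson counts (V mean 3, J mean 1, C mean 3,
  phenotype mean 6, plus two housekeeping genes at mean 3). V-segment counts
  are realised as 1 + Poisson(mean − 1) so that a T cell carries both
  chains of its pair *before* noise; recovery at zero noise is then exact by
  construction, and any loss is attributable to the configured noise.
* **Noise**: per-transcript dropout (default 0.05) and stray misassignment
  (default 0.1 expected strays per cell), modelled as swapping a
  transcript's cell to a random neighbouring cell — segmentation spillover,
  the dominant artefact for imaging-based assays. Both affect planted and
  background clones symmetrically, so dominant-pair fractions stay unbiased.
* **Timepoints**: `generateTimepointPair()` retains each clone with
  `retention_prob`, redistributes lost clonal mass over Poisson-many new
  clones, and reports the planted-repertoire abundance Jaccard as ground
  truth.

What the generator does *not* emulate: real probe efficiency differences
between genes, cell-shape-dependent segmentation error, optical crowding,
batch effects, or biologically structured background repertoires. Passing
tests therefore demonstrate correctness of the algorithms under a faithful
but idealised data model, not assay-level accuracy on real tissue.

A practical interaction worth knowing: the 3-cells-per-gene detection filter
truncates clones whose V gene appears in fewer than three cells, so planted
clone-size distributions should keep their smallest clone above that
detection limit at the simulated depth — the package's parameter-recovery
tests are constructed that way, and real analyses face the same censoring.

# Numerical and reproducibility choices

* All randomness flows through a seed argument with save/restore of the
  caller's RNG state; the same seed gives byte-identical outputs, including
  through the command-line interface.
* Hexagon boundary points are resolved by cube rounding (nearest center);
  graph radius and GC bounds are inclusive; dominant-gene and dominant-pair
  ties break lexicographically.
* Degenerate inputs are contracts, not crashes: genes shorter than 30 nt
  yield zero candidates; an empty transcriptome yields zero off-target
  hits; an all-zero abundance vector is an error for the Gini (not 0); a
  zero-spread permutation null yields `NA` z.
* Problem sizes in the test-suite properties (for example 10^4 random
  30-mers and hexagon points, 1000-cell calibration fixtures, 10^4-cell
  Gini recovery, 20 enrichment replicates) were chosen to make the
  statistical assertions stable at the package's default tolerances.

# Limitations

The V-pair proxy undercounts true clonal diversity and cannot separate
clones sharing a V-pair. J-segment coverage of real panels is partial, so J
evidence is not required for calls. The enrichment null permutes labels
globally and therefore tests association, not density-adjusted colocation.
The Chao Jaccard option estimates unseen shared species but remains a
stand-in where an exact published formula is unavailable.
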