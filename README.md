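# geysertrack

Genome-resolved source tracking of microbial communities across a geyser
eruption cycle.

A cold, CO2-driven geyser erupts in a multi-day cycle whose phases discharge
groundwater from different depths — intermediate-depth water during the
quiescent recovery phase, deep saline water during minor eruptions, shallow
water during major eruptions. Sampling the discharge through one full cycle
therefore surveys three stratified subsurface microbial communities through
a single borehole. `geysertrack` implements the computational pipeline for
this design, for microbial ecologists working with genome-resolved
metagenomic time series:

- **Genome database**: score bins by single-copy marker genes
  (`score = SCG − 2·MSCG`), filter to draft quality (>70% complete, <3
  multiple single-copy genes), dereplicate at 98% nucleotide identity
  (single linkage, fragment-mapping ANI), and match single amplified
  genomes to metagenome bins (>30% shared content at ≥98% identity).
- **Abundance tracking**: normalized relative abundance
  `A_r = (N_m/N_s) · r·l/g` — fold-coverage rescaled to the deepest
  sample — assembled into an organisms × samples matrix from mapped-read
  counts (SAM or TSV input, edit-distance filtered).
- **Replication rates**: the iRep sorted-coverage estimator — window
  depths sorted, 5% tails trimmed, log2 depth regressed on rank position,
  `iRep = 2^slope`.
- **Source tracking**: per-organism one-way ANOVA across phases with
  Benjamini–Hochberg correction across organisms and a Tukey HSD
  conjunction rule; each organism is sourced to at most one depth.
- **Metabolic capacities**: a genome holds a process when all key enzymes
  are present and ≥60% of the KEGG-style module is covered (hits at
  e-value < 1e-10); capacity abundance is profiled across depths.
- **Ordination**: Bray–Curtis dissimilarity, NMDS, and an exhaustive
  BioENV screen (standardized Euclidean subsets vs. Spearman rank
  correlation).
- **Symbiosis screen**: Pearson correlation of abundance trajectories over
  all organism pairs with FDR control, ranking candidate host–symbiont
  associations.
- **Marker alignments**: occupancy-based column trimming (<5% non-gap
  removed) and taxon span filtering (≥50% required) for concatenated
  ribosomal-protein alignments.

A first-class synthetic-community module generates every input with
planted, recoverable structure (phase enrichment, a host–symbiont pair,
log2-linear replication trends, bins of known completeness and
contamination), so the whole pipeline is testable without external data.
See the methods vignette (`vignettes/geyser-source-tracking.Rmd`) for the
models, assumptions and design decisions.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers. Running them
in order on the default synthetic community:

```sh
Rscript analysis/01_simulate_community.R
Rscript analysis/04_source_tracking.R
Rscript analysis/07_symbiosis_screen.R
```

prints (abridged):

```
community: 500 organisms x 25 samples; read totals 2e+06-9.9e+07
planted enriched: 285 organisms (57%); symbiont pair org0204 ~ org0295

286 of 500 organisms (57.2%) sourced to one depth
        deep intermediate      shallow
         100          121           65
planted enrichment recovered: 100.0% of 285 organisms

124750 pairs tested; 12783 significant at FDR < 0.05
top pair: org0204 ~ org0295 (r = 0.9995, FDR q = 3.96e-31)
planted pair org0204 ~ org0295: r = 0.9995, p = 3.18e-36 over 25 samples
```

That is the study's analysis pattern end to end: roughly 57% of the
community is sourceable to one groundwater depth, the per-depth counts
split across the three phases, and the planted host–symbiont pair is the
top-ranked abundance correlation at extreme significance. The remaining
drivers build and dereplicate the genome database (`02`), recover planted
replication rates (`03`, mean absolute error ≈ 0.01), profile carbon
fixation pathways by depth (`05` — Wood–Ljungdahl flagged deep, reverse
TCA shallow, Calvin–Benson–Bassham intermediate), and ordinate the
25-sample trajectory (`06` — only the time surrogate, not any geochemical
noise variable, tracks community structure). Tables land in `results/`.

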