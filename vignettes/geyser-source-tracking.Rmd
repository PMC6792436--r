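---
title: "Genome-resolved source tracking across an eruption cycle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-resolved source tracking across an eruption cycle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geysertrack)
```

## The system and the question

A cold, CO2-driven geyser erupts in a multi-day cycle whose phases discharge
groundwater from different depths: a quiescent recovery phase dominated by
intermediate-depth water, minor eruptions drawing deep, saline water, and
major eruptions drawing shallow water. Filtering the discharged water
through one cycle therefore samples three subsurface microbial communities
through a single borehole. `geysertrack` implements the computational
pipeline for such a design: building a non-redundant genome database from
assembled bins, tracking each genome's abundance across the time series,
estimating replication rates in situ, assigning organisms and their
metabolic capacities to source depths, ordinating the community trajectory
against environmental measurements, and screening for correlated abundance
trajectories that suggest host–symbiont relationships.

Every stage is exercised end to end on synthetic communities with planted,
recoverable structure, so the pipeline's statistical behaviour is measurable
without any external data.

## Genome database construction

Bins are scored by their single-copy marker gene content,

  score = SCG − 2 × MSCG,

where SCG counts distinct single-copy genes found (out of 51 bacterial or
38 archaeal markers) and MSCG counts those found in multiple copies.
Completeness is SCG divided by the marker-set size. Draft quality requires
completeness strictly above 70% and MSCG ≤ 2; both inequalities are taken
literally ("more than 70%", "fewer than three").

Dereplication clusters bins by single linkage over pairwise alignments with
mean nucleotide identity ≥ 0.98 and aligned fraction ≥ 0.30 of the query.
Single linkage was chosen because it matches common genome-dereplication
practice (any qualifying alignment path merges two bins into one species
cluster); the aligned-fraction floor reuses the value of the SAG-matching
rule, since no separate bin-to-bin threshold is established. Identity is a
whole-genome weighted average over mapped fragments, not a gene-level
statistic. Within a cluster the representative is the highest-scoring bin,
with ties broken by highest N50 and finally lexicographic id so that
results never depend on input order.

`pairwise_identity()` is a fragment-mapping average nucleotide identity:
the query is cut into 1-kb fragments, each placed on the target by shared
15-mer anchors (both strands, offset voting with a ±20 bp indel wobble) and
then globally aligned to its anchored window. The contract is the
(identity, aligned fraction) summary; any aligner meeting it could be
substituted. Fragments below the word size fall back to exact search so
that the identity of a sequence with itself is exactly 1.

Single amplified genomes are matched to metagenome bins when they share
more than 30% of their content at ≥ 98% identity with a bin that is at
least 70% complete; unmatched draft-quality SAGs are flagged for addition
to the database.

## Abundance normalization

Mapped-read counts become normalized relative abundances via

  A_r = (N_m / N_s) × (r · l) / g,

fold-coverage of the genome rescaled to the deepest sample (N_m is the
maximum per-sample read total, N_s the sample's total, r the mapped reads,
l the mean read length, g the genome length). For the deepest sample this
is plain fold-coverage. The mean read length is taken from the data rather
than fixed at 150 bp so the formula generalizes. Reads (not pairs) are
counted, and SAM ingestion discards alignments whose NM edit distance
exceeds 3 (≈ 98% identity at 150 bp); replication-rate estimation uses the
stricter 1-mismatch filter.

## Replication rates (iRep)

In a growing population, sequencing coverage declines from the replication
origin to the terminus. Since assembled fragments carry no positional
information, window depths (5,000-bp windows, 100-bp step) are sorted
ascending, the lowest and highest 5% are discarded, and log2 depth is
regressed on rank position. Rank positions are assigned on the full sorted
set *before* trimming, and the index of replication is the fitted span
extrapolated back to positions 0 and 1: iRep = 2^slope. This makes the
estimator exact on noise-free ramps (a profile spanning one doubling yields
exactly 2.0). A perfectly flat profile is reported as iRep 1 with r² = 1 —
a perfect fit to a zero-slope line — rather than as a degenerate failure.
Estimates pass QC when mean depth ≥ 5× and r² ≥ 0.90; these defaults and
the window geometry follow the method's original description, since only
the mapping stringency is restated here. GC-bias correction is omitted:
the synthetic data carry no GC structure, and the hook can be added where
real data require it.

The estimator has a small positive noise floor: with a flat profile and
realistic window noise, sorting alone creates an apparent slope (≈ 1.04 at
10% sub-window noise). This is a property of all sorted-coverage
estimators, worth remembering when interpreting values near 1.

## Source-depth assignment

Each organism's abundance is tested across the three phases with a
classical one-way ANOVA; p-values are Benjamini–Hochberg corrected across
organisms (that is where the multiplicity lies — hundreds of organisms,
one test each). An organism is sourced to a depth only when its FDR q is
below α, that phase has the highest mean abundance, and both Tukey HSD
comparisons of that phase against the other two are individually
significant. The conjunction rule makes assignment exclusive — at most one
depth per organism — matching the interpretation of "enriched in one
specific phase". Abundances enter untransformed. Degenerate contracts are
explicit: identical observations give F = 0, p = 1; zero within-group
variance with distinct means gives p = 0; constant organisms are untestable
and stay unassigned.

The phase design treats the 7/11/7 samples as independent replicates even
though they are temporally ordered; autocorrelation is not modelled. This
mirrors the study design being reproduced and is a known statistical
caveat, not something the package corrects.

## Metabolic capacities

A genome is credited with a metabolic process when all of the module's key
enzymes are present and at least 60% of the module's enzymes are detected,
after discarding annotation hits with e-values ≥ 1e-10. The source text
states the e-value rule inconsistently in two places; the stricter reading
(1e-10) is the default and both thresholds are arguments. The shipped
module catalog is an explicitly synthetic fixture: it covers the profiled
processes (Wood–Ljungdahl, reverse TCA, Calvin–Benson–Bassham, oxygen
respiration, sulfide oxidation, nitrogen and hydrogen metabolism) with
illustrative enzyme identifiers, because the real analysis depends on a
curated KEGG module list that users must supply. Capacity abundance per
process is the summed A_r of carrying genomes, tested across phases with
the same ANOVA/Tukey machinery; "arrows" mark phases where a process's
cumulative abundance is significantly highest or lowest.

## Ordination and environmental screening

Community structure uses Bray–Curtis dissimilarity and non-metric
multidimensional scaling. NMDS delegates to the standard stress-1
majorization with 20 random starts plus a metric start (k = 2 by default,
matching how such trajectories are plotted); coordinates are centered, and
stress is checked in tests against an independent stress-1 oracle built
from isotonic regression.

BioENV standardizes each environmental variable, computes Euclidean
distances for every variable subset (exhaustive up to 15 variables), and
reports the Spearman rank correlation of each subset's distances with the
community dissimilarities. The in-package implementation exists because
the result contract includes the correlation of *every* evaluated subset,
not only the best model per size; the reference implementation in vegan is
used as a cross-check in the test suite. Ties take average ranks; constant
variables are excluded with a warning.

## Symbiosis screening

Putative host–symbiont pairs are screened by Pearson correlation of
untransformed abundance trajectories — the axes on which such associations
are typically displayed — with two-sided p-values from the t-distribution
at n − 2 degrees of freedom and BH correction over tested pairs. Spearman
is available as an option. Two caveats are documented rather than
corrected, for fidelity to the analysis being reproduced: correlations on
relative abundances are compositional and can be spurious (a CLR transform
is the standard remedy), and with heavy-tailed abundance distributions the
parametric p-values are anticonservative at these sample sizes — in null
simulations with lognormal marginals at n = 25, far more than 5% of
matrices yield a BH discovery. Extreme associations (the planted pair
reaches p ≈ 1e-35) are robust to this; marginal ones are not.

## Marker alignments

Concatenated ribosomal-protein alignments are filtered in two steps:
columns with non-gap occupancy below 5% are removed (this reading —
column-level occupancy — is preferred over per-sequence gap fractions
because the rule describes alignment processing before concatenation, and
it subsumes end trimming), then taxa spanning less than 50% of the
retained columns are moved to a fallback list for classification by other
markers. The 16 proteins concatenate in a fixed documented order. Both
operations are idempotent and commute with taxon reordering.

## The synthetic community generator

The generator's defaults encode the study conditions: 500 organisms over
25 samples in contiguous phase blocks of 7 (intermediate), 11 (deep) and 7
(shallow); about 57% of organisms planted as enriched in exactly one phase
(the fraction observed to be sourceable), split 42/35/23% across
intermediate/deep/shallow; one host–symbiont pair at correlation strength
0.95 within the deep clade; per-sample read totals drawn uniformly from
10^6–10^8 so normalization faces realistically unequal depths.

Abundances follow a lognormal baseline (meanlog log 0.1, sdlog 1.5 —
strictly positive and heavy-tailed like observed relative abundances) with
an 8-fold enrichment effect in the planted phase and mean-preserving
lognormal multiplicative noise (sdlog 0.5). A symbiont trajectory is a
strength-weighted mixture of the normalized host trajectory and its own
independent trajectory, rescaled to the symbiont's baseline, so strength 1
with zero noise gives exact proportionality. Mapped-read counts are
derived by inverting the A_r formula and rounding, so the pipeline's
normalization is exercised rather than bypassed.

Coverage profiles plant a log2-linear origin-to-terminus trend with total
span log2(iRep). Noise is injected per 100-bp block and averaged over each
5,000-bp window: overlapping sliding windows share almost all of their
reads, so window-level noise is strongly autocorrelated in real depth
data, and simulating it as independent per-window draws would misstate the
estimator's operating characteristics. Window order is randomly permuted
because contig order carries no replication information.

Genome bins retain whole contigs up to a target length fraction, with the
contig crossing the target included with probability equal to the
remaining fraction so the expected retained length is exactly the target —
which makes marker retention an (approximately) binomial thinning that
tests can check against a closed-form oracle. Contamination includes each
contig of one randomly chosen donor genome independently with a fixed
probability, so the chance of acquiring a duplicated marker is exactly
enumerable.

What the generator does not emulate: read-level sequencing error and
FASTQ/assembly artefacts, sequence-evolution realism (mutations are
uniform substitutions), GC-dependent coverage bias, temporal
autocorrelation within phases, and compositional closure of real relative
abundances. Passing tests therefore demonstrate the pipeline's correctness
and calibration under the planted model, not robustness to every artefact
of real metagenomes.

## Problem sizes and numerical choices

The test suite and acceptance script run the full community design (500 ×
25) once per scenario, 100 seeds for estimator-recovery curves (5 × 10^5 bp
genomes at 20× depth, 10% sub-window noise), 1,000 replicates for type-I
error calibration and 500 for empirical FDR — sizes chosen to make Monte
Carlo error comfortably smaller than the tolerances being checked while
keeping a full run in the order of a minute. Dereplication fixtures use
5–20 bins of 6–8 kb, large enough for the fragment-mapping ANI to operate
and small enough to compare against brute-force connected components.

Other numerical conventions: 0-based half-open genomic windows; half-open
time windows for environmental averaging; lexicographic row/column order
in assembled matrices; all simulators bit-reproducible under a fixed seed;
p-values validated to [0, 1] before adjustment; and every tie-break
(representative choice, multi-mapped reads, Spearman ties) resolved
deterministically and documented on the function.

## Known limitations

Fragment-mapping ANI underestimates aligned fraction near contig
boundaries for highly fragmented genomes; the ANOVA/Tukey machinery
assumes within-phase homoscedasticity that lognormal abundances violate at
large effect sizes (the tests show the procedure is nevertheless
conservative under the null); BioENV's exhaustive search is exponential in
the variable count and is capped at 15 variables; and the symbiosis screen
inherits the compositional and heavy-tail caveats above.
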