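---
title: "Genetic-map guided scaffold anchoring and bulked-segregant QTL scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-map guided scaffold anchoring and bulked-segregant QTL scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafmap)
```

## The problem

Many plant reference genomes begin life as a few thousand scaffolds. To lift
such an assembly to chromosome scale without long-range sequencing data, one
can genotype large F1 outcross families (a "CP" population: both parents
heterozygous), build one genetic linkage map per family, and use the maps to
assign, order and orient scaffolds along the 17 (in *Pyrus*) linkage groups.
Several maps of unequal reliability are merged by weighting them, and the
resulting pseudo-chromosomes can immediately host downstream analyses such as
bulked-segregant QTL-seq scans for fruit traits.

`scafmap` implements that chain as a set of composable, deterministic R
functions: marker quality control for genotyping-by-sequencing (GBS) calls,
weighted multi-map consensus anchoring, pseudo-chromosome FASTA/AGP
construction with the usual summary statistics, a |Δ(SNP-index)| sliding
window scan, reciprocal-best-hit (RBH) synteny, and a synthetic-data
generator that makes every stage testable without any external data.

## Marker classes and the QC cascade

GBS genotypes of a CP population fall into three informative classes,
`lm × ll` and `nn × np` (testcross markers, offspring segregate 1:1) and
`hk × hk` (intercross, 1:2:1). The QC cascade in `run_marker_qc()` applies,
in order:

1. **Depth masking** (`depth_mask`): calls at depth outside
   `[depth_min, depth_max]` = [5, 1500] (inclusive bounds) become missing,
   as do calls outside their class alphabet ("abnormal bases").
2. **Missingness / integrity** (`missing_and_integrity_filter`): a marker is
   dropped when missing in more than 10 individuals *or* genotyped in less
   than 95% of offspring. The two printed rules overlap for large families
   (for n = 345 the missing-count rule is the stricter one); they are
   treated as independent OR-ed rules so the behaviour is well defined at
   any family size. The integrity denominator counts offspring only.
3. **Segregation distortion** (`chi_square_segregation`): Pearson chi-square
   against the class ratio, no continuity correction (matching common
   mapping-software behaviour), flagged at α = 0.05.
4. **Redundancy reduction** (`reduce_redundancy`): scaffolds with more than
   five qualified markers keep the five nearest to evenly spaced targets.
   "Evenly distributed" is formalised over the *occupied* span (first to
   last marker) rather than the whole scaffold, because markers can only
   exist where SNPs were called; distance ties break toward the lower
   position, and a marker is never selected twice.

The cascade is idempotent, and its type-I behaviour is pinned by a
calibration test: on 2000 undistorted 1:1 markers at n = 345 the flag rate
must sit inside the exact binomial 99% interval around 0.05.

## Weighted consensus anchoring

Each map `k` carries a weight `w_k` (defaults mirror the study design this
package emulates: 2 for each of the two large new maps, 1 for the older,
noisier map). `build_anchor_plan()` then works per scaffold and per
chromosome:

* **Assignment**: the chromosome with the largest Σ w_k × (marker count on
  that LG) wins; exact ties and markerless scaffolds go to chromosome 0
  (unplaced). Markers on a losing LG of a conflicted scaffold are excluded
  from positioning. The conflict rule is a declared stand-in: GA-based
  consensus tools resolve such conflicts implicitly inside their search,
  with no closed-form rule to copy, and a weighted majority is the
  simplest deterministic rule that re-assigns a conflicted scaffold to its
  best-supported linkage group.
* **Positioning** (`consensus_position`): per map, a scaffold sits at the
  mean cM of its markers, normalised by the LG's cM span to [0, 1];
  consensus = weight-averaged over maps containing the scaffold.
* **Ordering** (`order_scaffolds`): maximises J = Σ_k w_k ρ_k, with ρ_k the
  Spearman correlation between map-k marker cM and the marker order induced
  by the scaffold ordering. Groups of ≤ 8 scaffolds are solved exactly by
  enumeration (first optimum in lexicographic scaffold-id order); larger
  groups start at the consensus-position sort and run a steepest-ascent
  hill-climb over all pairwise swaps until no swap improves J. ALLMAPS,
  the field-standard tool for this computation, optimises the same kind of
  weighted-collinearity objective with a stochastic genetic algorithm;
  determinism was preferred here because it makes results reproducible
  bit-for-bit and lets an enumeration oracle check the exact branch, at
  the cost of a (rarely binding) local-optimum risk on large groups.
* **Orientation** (`orient_scaffold`): sign of Σ_k w_k × cor(bp, cM) within
  the scaffold; fewer than two markers at distinct positions, or a zero
  score (e.g. two markers at identical cM), give "?" — which is why a
  fraction of two-marker scaffolds always remains unoriented.

`compare_maps()` reports the per-(map, LG) Spearman correlation between each
input map and the consensus order — the standard collinearity diagnostic for
deciding which map to trust where they disagree.

## Pseudo-chromosome construction

`build_pseudochromosomes()` concatenates each chromosome's scaffolds in plan
order, reverse-complementing "−" scaffolds, with a spacer of 100 `N`
between neighbours. The 100-bp default is the value implied by the reference
build this package models: on every one of its 17 chromosomes, pseudo-
chromosome length minus scaffold length equals 100 × (scaffold count − 1).
"?" scaffolds are written forward in sequence but keep "?" in the AGP, so
the uncertainty survives round trips. Unplaced scaffolds are emitted as
separate records rather than concatenated into a "chr0" object, so nothing
downstream can mistake an artificial join for sequence.

Coordinates are 1-based inclusive everywhere on disk (AGP v2.1); the tiling
invariant (parts cover each object exactly, no holes or overlaps) is
asserted on every write. `assembly_stats()` reports the anchored / oriented
/ unanchored partitions: scaffold counts by marker class (1, 2, 3, ≥ 4),
total bases, N50 and L50 (both conventions are computed, since published
tables sometimes label an L50 count as "N50 scaffolds"), markers/Mb, and
percentage of the genome. `map_stats()` summarises a map per LG; average
marker spacing is LG length / marker count (not markers − 1) — both
conventions round to the same printed value for dense maps, and the simpler
one is used and documented.

## The |Δ(SNP-index)| scan

For two phenotype-contrasted offspring pools, the SNP-index of a pool at a
SNP is alt depth / total depth (the "non-reference-parent allele" reading of
the index is not distinguishable from alt/total without parental phasing,
so alt/total is adopted); rows where either pool has zero depth are
excluded. The scan statistic is |Δ(SNP-index)|, the absolute between-pool
difference — the magnitude is used so that loci segregating in either phase
of a heterozygous cross score equally. `window_scan()` averages it in 1-Mb
windows advanced in 20-kb steps anchored at position 1, with truncated tail
windows; `threshold_top()` takes the genome-wide (1 − 0.005) quantile *of
window means* (the thresholded objects are intervals, not single SNPs); and
`candidate_intervals()` merges overlapping or book-ended above-threshold
windows — so two elevated regions separated by a few Mb of below-threshold
windows stay distinct, as in the study design this models. With an AGP,
each interval is projected back to the scaffold pieces it spans, in 1-based
scaffold coordinates.

## The synthetic-data generator

`simulate_genome()` + `place_markers()` + `simulate_cross()` +
`simulate_bulks()` emulate the statistical structure of the study design:

* a genome of `n_chrom` chromosomes cut into scaffolds at random
  breakpoints, each scaffold with a hidden true orientation;
* markers with a linear genetic:physical rate (default 4.6 cM/Mb, the
  genome-wide average of a ~1850 cM map over a ~400 Mb genome), class mix
  defaulting to 40/40/20% lm×ll / nn×np / hk×hk (the approximate proportions
  observed in GBS marker panels of heterozygous pear crosses), and random
  linkage phases per parent;
* offspring gametes generated with recombination probability
  `kosambi_r(Δ cM)` independently per marker interval. This "no
  interference" crossover model is deliberate: it matches the Kosambi
  distances used in map construction exactly at the two-point level, which
  is all the consensus computation consumes, while avoiding a chiasma-level
  simulation; the slight inconsistency with true Kosambi interference at
  three-point order is accepted and documented here.
* read depths that are negative-binomially overdispersed (mean 30,
  dispersion 0.3 — typical of GBS), per-call missingness, and an optional
  genotyping-error rate (default 0, since no error rate is published for
  the emulated data);
* two bulks under a dominant causal model: for a SNP at recombination
  fraction r from the causal locus the expected alt frequency is (1 − r)/2
  in the carrier pool and r/2 in the non-carrier pool, so the expected
  Δ(SNP-index) is (1 − 2r)/2 — 0.5 at the locus, 0 off-chromosome.
* `perturb_map()` models map-estimation error (Gaussian cM jitter, local
  adjacent swaps, marker drops, optional LG misassignment), which is what
  makes consensus building non-trivial.

What the generator does *not* emulate: linkage-disequilibrium structure of
real recombination (interference), reference bias and paralog collapse in
GBS genotyping, segregation-distorted regions, or assembly chimeras. Tests
passing on this generator therefore certify the computation, not the
robustness of GBS genotyping itself.

All stochastic functions take an explicit seed (default 42) and restore the
caller's RNG state, so the whole pipeline is reproducible bit-for-bit;
`run_pipeline()` derives per-stage seeds from the single config seed.

## Numerical choices and degenerate inputs

* Spearman correlations use average ranks for ties throughout (the same
  convention in the ordering objective, orientation score, concordance and
  synteny correlation). A map contributing fewer than two markers, or
  markers without variance, contributes 0 to J rather than NA.
* Ordering tie-breaks are lexicographic by scaffold id; hill-climb accepts
  only strict improvements (tolerance 1e-12), so it terminates.
* `kosambi_cm`/`kosambi_r` are exact inverses (r = tanh(d/50)/2) to 1e-12.
* Zero-depth SNP rows, empty windows (NA mean), single-marker LGs (length
  and max gap 0), and scaffolds missing sequence (length-only sets) are all
  defined states, exercised in the test suite.
* RBH score ties break by lower e-value then lexicographic subject id, so
  the pair set is deterministic and symmetric in the two genomes. Protein
  isoform collapsing is left to the caller (a flag on the hit tables'
  producer, not re-implemented here).
* Synteny correlations are reported as |ρ| because the relative orientation
  of two independently assembled genomes is arbitrary; gene position is the
  midpoint of its annotated span.

## Problem sizes used in the tests

The suite exercises the pipeline at reduced scale chosen so that every
statistical check is decisive: ordering-oracle equivalence on 200 random
groups of ≤ 6 scaffolds × ≤ 3 maps; anchoring recovery on 24-scaffold
genomes across 20 seeds (zero-noise recovery must be exact; ≥ 95% of
scaffolds correctly ordered under 0.5-cM jitter with 2% local swaps); QTL
recovery on 17 chromosomes × 1000 SNPs at pool depth 20 across 20 seeds
(the causal locus must fall inside a top-0.5% interval in ≥ 18). The
chromosome-build accounting (spacer arithmetic, partition shares, marker
densities, interval lengths) is checked exactly against the published
summary tables shipped in `inst/extdata/`.

## Known limitations

* The hill-climb branch guarantees only a local optimum of J; the exact
  branch covers groups of ≤ 8 scaffolds, and the test oracle covers the
  sizes where enumeration is feasible.
* De novo linkage grouping and map ordering (the mapping software's job) is
  out of scope: maps are inputs, and the simulator stands in for them in
  tests.
* The depth-table reader is deliberately minimal (chrom, pos, two pools'
  ref/alt depths); full VCF support is not attempted — convert with
  standard tools upstream.
* Confidence bands for the SNP-index (simulation-based, as used in some
  QTL-seq implementations) are not computed; the top-quantile rule is the
  only thresholding offered.
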