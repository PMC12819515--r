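---
title: "Methods: super-enhancer landscapes, GGAA microsatellites, and regulatory circuitry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer landscapes, GGAA microsatellites, and regulatory circuitry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameter choices and numerical
conventions behind `secircuitry`, in the spirit of the methods sections of
the Bioconductor packages it resembles. It states no result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Coordinates and formats

All genomic intervals are 0-based half-open (BED convention); every format
the package consumes (BED3/6, narrowPeak, broadPeak, bedGraph, BEDPE) is
BED-family, so 1-based inputs are deliberately unsupported. Chromosome
names pass through verbatim: a `chr1` vs `1` mismatch between inputs
surfaces as zero overlaps plus a warning rather than being silently
renamed, because silent renaming hides data errors. Strand is carried but
ignored by interval arithmetic — H3K27ac enrichment and chromatin loops
are unstranded.

## Super-enhancer calling

The ROSE procedure is re-implemented directly rather than wrapped:

* **Stitching.** Peaks with a gap ≤ `stitch_distance` merge; the default
  12,500 bp is the published ROSE default, the only defensible choice when
  the upstream description cites ROSE without parameters. TSS exclusion
  (peaks fully inside ± 2,500 bp of a TSS dropped before stitching) is
  available but **off** by default: whether the original analyses ran it
  is unstated, and for tumor panels the conventional default is off. Both
  knobs are exposed in `pipeline_params()`.
* **Scoring.** Net signal is treatment coverage minus input coverage,
  summed over the region and floored at zero — negative enrichment after
  input subtraction is noise, not signal.
* **Tangent cutoff.** Regions are ranked ascending; rank and signal are
  min-max scaled to [0, 1]; the discrete slope is a central difference
  (one-sided at the endpoints); the cutoff is the signal at the first rank
  where the slope exceeds 1, regions strictly above are super-enhancers,
  and ties at the cutoff stay typical enhancers. A flat curve has no
  crossing and yields zero super-enhancers; this degenerate case is the
  forced consequence of the geometry and is documented rather than
  special-cased. The implementation is checked against an independent
  brute-force slope scan and against a 1,000-point curve with an
  analytically placed elbow.
* **Normalization and truncation.** Intensities are scaled by the
  per-sample maximum; only the strongest 500 super-enhancers per sample
  are kept, applied after calling and before consensus building.
* **Consensus.** Super-enhancers overlapping by at least 50 % are merged
  transitively. "50 % of which region" is ambiguous in the usual BEDTools
  phrasing; the default interprets it as 50 % of the *smaller* region
  (`of_smaller`), with the stricter reciprocal mode exposed as an option.
  Samples without a super-enhancer at a consensus region contribute 0 to
  the matrix (not `NA`): a missing call is the absence of a strong
  enhancer, which is information, and PCA requires a complete matrix.
* **PCA.** Samples are observations; values are mean-centered, not
  scaled (intensities already live on a common [0, 1] scale). Component
  signs are fixed so each component's largest-magnitude loading is
  positive, making scores reproducible across BLAS builds.

## Microsatellite scanning

The agnostic scan enumerates rotational equivalence classes of repeat
units: 66 classes of 4-mers and 20 of 3-mers after excluding homopolymers
(a run of AAAA is a poly-A tract, not a period-4 microsatellite). Each
class is represented by its lexicographically minimal rotation; GGAA,
GAAG, AAGG and AGGA are one class (canonical AAGG) whose reverse
complement class is CCTT.

A hit is a *maximal* run: a period-`k` tract whose repeat count reaches
the class threshold (4 copies for 4-mers, 5 for 3-mers) yields one hit
with the full copy number — a 7-copy run is one hit with `n_repeats = 7`,
never four overlapping hits. Non-ACGT bases break runs, which avoids
phantom repeats across assembly gaps. The scanner is implemented as a
vectorized period test (`s[i] == s[i+k]`) plus run-length encoding, and is
verified hit-for-hit against a regex oracle (`(unit){r,}` over all
rotations, overlapping matches merged) on thousands of random sequences.

Two open conventions were decided as follows and are configurable:

* "Number of mSats per region, size-normalized" is counted as maximal
  runs per kilobase of region — the standard densitometric choice when no
  formula is given.
* GGAA detection defaults to rotation + reverse-complement mode
  (GGAA/TTCC), because ETS elements occur on both strands of the
  reference; a literal mode (≥ 4 tandem copies of literal GGAA) is
  provided.

Enrichment of super-enhancers over typical enhancers is a two-sided
paired Wilcoxon signed-rank test on per-sample mean densities. Zero
differences are dropped before ranking (the classical treatment); the
exact null is used whenever the remaining differences are tie-free, so
with 10 uniformly positive pairs the smallest attainable p-value is
2/2^10 ≈ 0.00195.

## Circuitry inference

Per sample, super-enhancers are assigned to the closest *active* gene
(expression ≥ `activity_threshold`, default log2 value 1 — the upstream
tool's exact cutoff is not restated anywhere, so this is exposed in the
configuration). Distance is 0 when the TSS lies inside the region; ties
break toward the smaller coordinate, then alphabetically, making
assignment deterministic.

Motifs are scanned over the SE *constituent peaks*, not the full stitched
span — constituents are where the ChIP evidence is — with pseudocounted
log-odds scores against a uniform background and a hit threshold of 85 %
of the maximal attainable score. A TF may carry several motif matrices;
an edge exists if any matrix hits, which buffers motif-database version
differences.

A circuit is a maximal set of TFs in which every member has a self-edge
and every ordered pair is connected — the "interconnected auto-regulatory
loops" definition. Graph-theoretically these are maximal cliques of the
undirected graph on self-looped vertices with bidirectional edges, found
via `igraph::max_cliques` and re-validated edge-by-edge. The scoring of a
clique (used only for ranking) is the mean over members of inbound
motif-hit weight from within the clique; the upstream tool's internal
score is unpublished, so a deterministic, documented ranking was chosen.
The top 10 cliques per sample are kept, and membership is the union over
those cliques (the per-methods reading of "top 10 CRCs were considered").

This definition encodes the central structural claim the package is built
to test: a **hegemonic driver** — a TF with out-edges to every circuit
member but no self-loop and no in-edges — can never appear in any clique,
however strong its binding. The property is exercised both on random
graphs against exhaustive subset enumeration and end-to-end on synthetic
data.

The specificity filter keeps TFs present in ≥ 50 % of case samples and
< 30 % of controls. The two source phrasings ("absent in more than 70 %"
vs "< 30 % presence") are numerically consistent; presence < 30 % is
implemented.

## Promoter–enhancer chains

Loop ends overlapping by ≥ 1 bp merge into anchors (single linkage, union
span). An anchor is a promoter when it overlaps ± 2,500 bp of a TSS (a
standard HiChIP annotation window), else an enhancer when it overlaps an
H3K27ac peak, else `other`. Chains are breadth-first traversals from a TF
promoter through promoter/enhancer anchors only — `other` anchors are not
traversable because the chain is defined as promoter–enhancer and
enhancer–enhancer interactions; promoter–promoter steps are allowed since
nothing in the definition forbids them. Hops are 1-based on interactions
(a directly looped element is at hop 1), the promoter anchor itself (hop
0) is not counted, and the default depth bound of 5 encodes "within the
first five interactions". The minimal hop is checked against exhaustive
simple-path enumeration on small graphs, and is monotone under edge
addition/removal by construction of BFS.

## Master-TF selection

Three boolean criteria per candidate: (1) ≥ 1 flagged fusion-TF mSat peak
inside the TF's associated super-enhancer in at least half of the
evaluable case samples (samples where the TF has no SE are `NA` and do
not count toward the denominator — the source figures show such `NA`s but
give no aggregation rule, so a majority-of-evaluable rule was chosen);
(2) case-specific expression, operationalized as case median ≥ control
95th percentile plus a configurable margin, since the original criterion
("specific across multiple datasets") names no rule; (3) membership in
the lineage dependency list, i.e. negative lineage T-statistic — the
dependency table is consumed precomputed, Chronos/CERES re-estimation is
out of scope. Selection requires ≥ 2 of 3. In the pipeline the criteria
are evaluated on the specificity candidates, mirroring the original
funnel (circuit candidates → evidence integration).

## The synthetic data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with a JSON truth manifest sufficient to recompute every
intermediate:

* Two chromosomes of 2 Mb of i.i.d. uniform sequence. (Gene loci sit
  every 60 kb so that planted SE clusters, standalone enhancers and decoy
  regions always stay more than one stitch distance apart; with 1 Mb
  chromosomes the required layout cannot maintain those gaps.)
* 60 genes, 12 of them TFs. Cases share 20 SE loci (three constituent
  peaks of 1.5 kb, log-normal heights ~ 20× enhancer height, boundary
  jitter SD 100 bp); controls draw 20 loci per sample from a disjoint
  pool of 27. Typical enhancers are per-sample private 1 kb windows drawn
  from the background field, plus the shared windows that loop chains
  need. Private windows keep per-sample microsatellite densities
  independent draws; a single shared enhancer set would make the paired
  control test degenerate, since all samples would share one genome
  realization.
* GGAA runs are planted at 1 per kb inside case SE constituents (each
  case locus is guaranteed at least one) and at 0.1 per kb — a 10×
  enrichment — everywhere else: explicitly in control SE constituents and
  enhancer windows, and as a uniform scatter over the remaining genome at
  the same per-kb rate over the actually available area.
* The circuit TFs TF01–TF03 get two copies of each other's (and their
  own) 10-bp consensus motifs planted in their SE constituents; the
  driver TF04's motif is planted in the circuit TFs' SEs but **nothing**
  is planted in TF04's own SE — out-edges without a self-loop, the
  hegemonic configuration. Fusion-TF (ETS) peaks cover the planted mSats
  in case samples only.
* Loops connect TF promoters to mSat-bound anchors at hops 1, 2, 3
  (circuit TFs), 5 (driver) and 6 (TF05; unreachable at depth 5), plus
  decoy loops between unannotated anchors.
* Expression: circuit TFs and driver high in cases (log2 ≈ 8) and low in
  controls (≈ 0.2); the control pool mirrored; Gaussian noise SD 0.4.
  The dependency table gives the driver the most negative T-statistic and
  the circuit TFs mildly negative ones, plus negative non-SE genes so the
  SE–dependency overlap is a proper fraction.

What the generator does **not** emulate: realistic genome composition
(GC content, repeat families), read-level noise (coverage is
piecewise-constant by construction — super-enhancer calling consumes
coverage, so read simulation would add nothing testable), trans-chromosome
loops, and continuous gradients of circuit membership. Passing tests
therefore demonstrate algorithmic correctness and end-to-end recovery of
a planted truth under realistic-scale noise, not robustness to every
artifact of real ChIP-seq.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on the
default synthetic panel (20 samples, 2 × 2 Mb genome, ~50 stitched
regions per sample), verify the scanner on 1,000 random 10-kb sequences
against the regex oracle, enumerate cliques exhaustively on 100 random
graphs of up to 10 nodes, enumerate simple paths on 100 random graphs of
up to 30 anchors, and run 100 power and 500 size simulations of the
paired test at region level. These sizes were chosen so each oracle
comparison is exhaustive or near-exhaustive while the whole suite stays
comfortably within a development laptop's patience.

Every stage is a pure function of (inputs, parameters, seed): the
generator restores the RNG state it found, rank ties break on genomic
coordinates, clique and path tie-breaks are lexicographic, and PCA signs
are pinned — reruns are bit-identical, which the suite asserts via file
checksums.

## Known limitations

* The tangent cutoff uses the scaled-curve geometry; on very small
  region sets (tens of regions) the discrete slope is coarse and the
  cutoff can move by a rank — the hockey-stick test tolerates ± 1.
* `of_smaller` consensus merging is transitive, so chains of pairwise
  50 % overlaps can merge regions that never directly overlap; the
  reciprocal mode is stricter but shares the property.
* The expression-specificity rule (median vs 95th percentile) is a
  deliberate simplification of "specific across datasets"; with small
  control groups the 95th percentile is effectively the maximum.
* Colocalization requires per-TF ChIP peak sets, which real datasets
  provide but the synthetic generator does not plant; `run_pipeline()`
  therefore exposes `colocalization_top_se()` as a separate step rather
  than running it by default.
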