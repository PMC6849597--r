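---
title: "Recovering rare genomes from bulk and mini-metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering rare genomes from bulk and mini-metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raremag)
```

## The problem

A lineage that makes up ~1% of a diverse soil community is effectively
invisible to ordinary metagenomic binning: its contigs are few, shallow
(2–30× depth) and easily absorbed into larger bins. `raremag` implements a
targeted recovery strategy that combines three information sources:

1. **Composition** — canonical tetranucleotide frequencies (TNF), a
   genome-specific signal that survives fragmentation into contigs of a few
   kilobases.
2. **Differential coverage** — the depth profile of each contig across
   several bulk samples taken at different times; contigs from one genome
   rise and fall together.
3. **Mini-metagenome co-occurrence** — sorted pools of 10–500 cells,
   enriched for the target lineage by labelling and flow sorting, then
   amplified by multiple displacement amplification (MDA) and sequenced.
   A contig repeatedly present in target-enriched wells almost certainly
   belongs to the target genome, however unreliable MDA-distorted depths
   are quantitatively.

Downstream of the binner, the package computes the identity analyses such a
recovery feeds: bin quality statistics (N50, single-copy-marker
completeness/contamination, relative abundance), the percentage of
conserved proteins (POCP) for genus delineation, a neighbor-joining 16S
phylogeny with Jukes–Cantor correction and bootstrap support, and the
design of clade-specific signature oligonucleotides.

## The synthetic community

Real inputs of this kind cannot ship with a package, so the first-class
`simulate_community()` module generates them with the statistical structure
the analysis assumes. The default scenario is the package's standard
benchmark:

* **25 genomes**, each an order-2 Markov chain over A/C/G/T with its own
  random transition preferences. The chain's GC tilt is calibrated against
  its stationary distribution, so realised GC tracks a per-genome target
  (drawn from 0.35–0.65) to within ~0.01. Distinct transition structure is
  what makes TNF binning meaningful; the 3 × 10^5 bp genome length keeps
  the benchmark desk-sized while staying above the 2 × 10^5 bp minimum
  bin size.
* **Contigs** are clean, non-overlapping genome fragments of 1.5–20 kb.
  Assembly is not simulated: the analysis consumes contigs, and assembler
  artifacts (chimeras, repeat collapse) are out of scope. Fragments below
  1.5 kb are never emitted — TNF is unstable below ~1 kb.
* **Abundances**: the single target genome is pinned at 1.0% in each of 3
  bulk samples; non-targets get log-normal base abundances with mild
  per-sample log-normal fluctuation (log-sd 0.6), which creates the
  differential-coverage signal.
* **Coverage** is sampled at the read level: the number of reads on a
  contig is Poisson with mean `depth × length / read_length`
  (read length 100 bp), and depth is reads × read_length / length. This
  matters: drawing depth directly from Poisson(mean depth) would overstate
  the noise of a per-contig *mean* depth by orders of magnitude and destroy
  the coverage signal that real binners rely on. With total depth 40 and 25
  genomes, the 1% target sits near 10×, within the 2.6–32× range such
  studies report.
* **Wells**: 4 sorted wells of 50–480 cells at target enrichment 0.8. Each
  cell is the target with probability 0.8, otherwise a genome drawn by bulk
  abundance. Per-contig depth is cells × 1× multiplied by a log-normal MDA
  bias `exp(N(0, 1.5^2))` — contig-level bias stands in for the extreme
  coverage unevenness of amplified sorted pools without read-level
  simulation. A well is flagged target-enriched when at least one target
  cell was sorted into it (the in-silico analog of a PCR screen of the MDA
  product).
* **Markers**: 100 universal single-copy markers, each planted exactly once
  per genome on a uniformly chosen contig. Marker detection is an input
  table by design — real users supply hits from any scanner; no HMM search
  runs inside.
* **16S fixture**: 8 taxa evolved from a common ancestor at 5% per-site
  divergence; the target carries a 14-bp insertion that appears as residue
  columns in the target and gap columns in every relative.

What the generator does **not** emulate: sequencing error, strain
heterogeneity, horizontally transferred islands of atypical composition,
inter-sample batch effects, and assembly artifacts. Passing the end-to-end
benchmark therefore demonstrates that the machinery is correct and
internally consistent, not that real forest-soil communities will yield
bins of equal purity — real data are harder in exactly the ways listed.

## The binner

Contigs are first **pre-partitioned** into quantile bands of
`log1p(mean coverage)` (3 strata by default, widened 10% per side so
boundary contigs are clustered in both neighbours). Stratifying by
abundance shrinks each clustering problem and prevents a rare genome from
being engulfed by the bulk.

Within a stratum, contigs are clustered by average-linkage agglomeration on

\[
d(a, b) = w\,\frac{\lVert \mathrm{clr}(t_a) - \mathrm{clr}(t_b) \rVert_2}{\sqrt{136}}
        + (1 - w)\,\frac{\lVert \log(1+c_a) - \log(1+c_b) \rVert_2}{\sqrt{S}},
\]

with `w = 0.5`, `t` the 136-dimensional canonical TNF vector and `c` the
coverage profile over `S` samples. Each term is a metric, so the weighted
sum is one. Average linkage with a distance cutoff was chosen over density
or model-based clustering because it is deterministic, parameter-sparse and
adequate at this scale; ties break by lexicographic contig id everywhere, so
results are independent of input order.

Two numerical choices deserve comment:

* **clr smoothing.** The centered log-ratio needs strictly positive
  frequencies. A flat pseudofrequency (e.g. 10^-6) makes zero-count
  tetramers on short contigs dominate the distance — `log(f / 10^-6)` spikes
  of ~8 per empty cell swamp the real compositional signal. The package
  instead Laplace-smooths at the count level,
  `(count + 1) / (windows + 136)`, reconstructing counts from contig
  length. This keeps the penalty for an absent tetramer proportional to how
  surprising its absence actually is at that contig length.
* **The default cutoff.** When `linkage_cutoff` is not set, the cut height
  is chosen from the linkage-height distribution, which is bimodal: a bulk
  of small within-genome merges and a tail of large between-genome merges.
  The package uses Otsu's criterion (the split maximising between-class
  variance) and cuts at the midpoint of the boundary gap. A simpler
  "largest gap" rule is unreliable: the biggest single gap often sits
  between the top two inter-genome merges rather than at the
  within/between boundary.

Clusters below `min_bin_size` (200 kb — smaller fragments cannot be genome
bins) are left unbinned. Overlap duplicates are resolved by assigning the
contig to the bin with the nearest medoid.

## Refinement and association

`refine_bins()` applies the three evidence types to every candidate bin,
iterating each bin to a fixed point (which makes refinement idempotent):

* **Coverage compatibility**: per sample,
  `r = log2((contig + 0.1) / (bin median + 0.1))`; a contig is incompatible
  when `|r| > 1` in even one sample (`tau = 1`, `s_max = 0`). Bins with
  fewer than three contigs have no stable median profile and are trivially
  compatible, with a warning.
* **Taxon consistency** (when a label table is supplied): the bin's
  majority label by summed contig length defines it; labelled dissenters
  are outliers. Unlabelled contigs are never outliers.
* **Well co-occurrence**: a contig is present in a well at ≥ 1× coverage
  (presence/absence because MDA bias makes depth ratios meaningless); with
  `k` presences among `m` enriched wells and background presence rate `p0`,
  the score is `-log10 P(X >= k)`, `X ~ Binomial(m, p0)`. The binomial null
  treats wells as independent sorting experiments, which they are. A taxon
  outlier with score ≥ 2 (p ≤ 0.01) is rescued — the co-occurrence evidence
  outweighs a classifier call.

`associate_unbinned()` then attaches leftover contigs (the route by which a
short rRNA-carrying contig joins its genome): candidate bins are those the
contig is coverage-compatible with; bins that are themselves well-enriched
additionally demand the contig reach the enrichment threshold; the smallest
deviation norm wins, ties by bin id.

## Bin quality and abundance

`bin_qc()` reports size, contig count, N50 (smallest length whose
at-least-that-long contigs cover half the assembly — brute-force checkable),
length-weighted GC, per-contig median coverage per sample, marker
completeness (`% of markers present at least once`), contamination
(`% surplus marker copies`) and relative abundance. Abundance is the bin's
share of length × coverage mass, which approximates read share — the
quantity abundance claims in the literature are stated in. Median coverage
is per-contig (not per-base) median; at fixture scale the two coincide for
practical purposes.

## POCP and genus delineation

The percentage of conserved proteins between proteomes 1 and 2 is
`100 × (C1 + C2) / (T1 + T2)`, where a protein counts as conserved when
some protein of the other proteome aligns with e-value < 10^-5, identity
> 40% and an alignable region > 50% of the query length. Alignments are
Smith–Waterman local alignments under BLOSUM62 with affine gaps
(open 11, extend 1); e-values follow Karlin–Altschul statistics
(λ = 0.267, K = 0.041, the standard gapped BLOSUM62-11-1 values) with the
subject proteome's residue count as database size, because the metric's
thresholds presume a pairwise-proteome search. Proteins shorter than 30
residues are skipped with a warning — their e-values are spurious.

Genus grouping reads "above 50% between all members" literally as
complete linkage: maximal cliques in the >50% graph, peeled off greedily
(largest first, lexicographic ties), so the grouping is deterministic. A
genome in no multi-member group is a singleton novel-genus candidate.

## 16S phylogenetics

`nj_tree()` is the standard Saitou–Nei agglomeration (Q-matrix
minimisation, ties by lexicographic taxon pair) on Jukes–Cantor-corrected
p-distances, `d = -(3/4) ln(1 - 4p/3)`. Gapped or ambiguous columns are
dropped pairwise (pairwise deletion), the common choice for 16S work.
Negative branch estimates are clamped to zero with a warning, keeping the
newick output valid. `bootstrap_support()` resamples alignment columns with
replacement, rebuilds the tree per replicate, and reports the percentage of
replicates containing each internal split of the full-data tree; 2000
replicates is the publication-grade default, and tests use 10–100.
Bootstrap resampling can push a pair past saturation (p ≥ 0.75) even when
the full data are fine, so replicates substitute a configurable ceiling
(default 3 substitutions/site) for saturated pairs.

The implementation is cross-checked in the test suite against exact
three-point solutions, exhaustive additive four-taxon cases, path-length
recovery on random additive trees, and the reference implementations in
`ape` — which serve as oracles only, never as the computation.

## Signature oligos

`find_inserts()` scans a multiple alignment for maximal column runs that
are residues in every target and gaps in every non-target (start positions
are 1-based). `design_oligos()` enumerates k-mers (default k = 20) present
exactly in every target on either strand and requires ≥ 2 mismatches to the
best ungapped match in every non-target; candidates are ranked by
worst-case mismatch count. Mismatch counting is an ungapped sliding window
on both strands — oligo-length windows essentially never need gaps, and the
computation stays brute-force checkable. No melting temperature or
secondary-structure modelling is attempted (such oligos are designed by
alignment inspection in practice), and degenerate bases are rejected rather
than expanded. `identity_screen()` implements the ≥ 98%-identity database
screen with free-end-gap global alignments.

## Problem sizes and determinism

The default benchmark (25 genomes × 300 kb, ~900 contigs, 3 samples, 4
wells, 100 markers, 8-taxon 16S alignment, 100-replicate bootstrap) was
sized so that a full `run_all()` completes in well under a minute on a
single CPU and the entire test suite in a few minutes, while remaining
large enough that the binner faces a genuinely rare (1%) target among
dozens of decoys. Every stochastic step consumes a seed derived from the
single run seed; identical configurations reproduce byte-identical
artifacts, which the manifest checksums make easy to verify.

```{r demo, eval = FALSE}
run <- run_all(list(seed = 1), outdir = "run1")
glance(run)          # recall, precision, completeness, contamination
qc_report(run$qc)    # summary table with conventional row names
autoplot(run$refined, run$features)  # GC vs coverage, coloured by bin
```

## Known limitations

* The binner's defaults are tuned for communities of tens of genomes; at
  thousands of contigs per stratum the O(n²) distance matrix is the
  bottleneck and a sparse or sketching approach would be needed.
* Contamination as "surplus marker copies" is a simplified single-copy
  analog; it does not use lineage-specific marker sets and will
  underestimate contamination by lineages sharing few markers.
* POCP on full real proteomes (thousands of proteins) is desk-feasible but
  slow with the internal aligner; results may shift by a point or two with
  a different search tool, which is consistent with the metric's published
  tolerance of aligner choice.
* The 16S simulator evolves sequences by independent substitutions; it does
  not model rate heterogeneity across sites or indel evolution beyond the
  planted signature insert.
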