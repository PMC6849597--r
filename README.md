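# raremag

Targeted recovery of low-abundance (~1%) bacterial genomes from assembled
metagenomes, combining tetranucleotide composition, differential coverage
across bulk samples, and co-occurrence in cell-sorted, MDA-amplified
"mini-metagenome" wells — plus the downstream identity analyses such a
recovery feeds: bin quality statistics, POCP genus delineation,
neighbor-joining 16S phylogenetics with Jukes–Cantor correction, and design
of clade-specific signature oligonucleotides.

## Who this is for

Microbial ecologists trying to pull the genome of a rare, uncultivated
lineage out of a diverse community. A 1% genome is invisible to ordinary
binning: its contigs are few and shallow, and they get absorbed into larger
bins. The strategy implemented here stratifies contigs by abundance before
clustering, combines compositional and differential-coverage distance, and
then uses sorted-cell mini-metagenomes as an orthogonal line of evidence to
refine the candidate bin and to rescue contigs (such as the rRNA contig)
that composition alone cannot place.

## The core computations

**Binning distance.** Contigs are clustered (average linkage, deterministic
tie-breaks) within abundance strata on

    d(a,b) = w * ||clr(tnf_a) - clr(tnf_b)||2 / sqrt(136)
           + (1-w) * ||log1p(cov_a) - log1p(cov_b)||2 / sqrt(S)

where `tnf` is the 136-dimensional canonical tetranucleotide frequency
vector and `cov` the per-sample depth profile.

**Well co-occurrence.** A contig present (>= 1x) in `k` of `m`
target-enriched wells, against a background presence rate `p0`, scores
`-log10 P(X >= k)` with `X ~ Binomial(m, p0)`.

**Bin QC.** N50; marker completeness `100 * |markers present| / |set|`;
contamination `100 * sum(max(copies - 1, 0)) / |set|`; relative abundance
as the bin's share of length x coverage mass.

**POCP.** `100 * (C1 + C2) / (T1 + T2)`, a protein counting as conserved
when a Smith–Waterman hit in the other proteome has e-value < 1e-5,
identity > 40% and alignable region > 50% of the query; genera are maximal
groups with all pairwise values above 50%.

**Phylogenetics.** Saitou–Nei neighbor joining on Jukes–Cantor distances
`d = -(3/4) ln(1 - 4p/3)` with pairwise deletion and column-bootstrap
support.

Everything is testable without downloads: `simulate_community()` generates
genomes, contigs, coverage tables, sorted wells, planted markers and a 16S
alignment with a 14-bp target-only signature insert, with full ground truth
for scoring.

## Worked example

```r
library(raremag)

run <- run_all(list(seed = 1), outdir = "run1")
glance(run)
#> # A tibble: 1 × 6
#>   target_bin target_precision target_recall completeness contamination abundance_pct_mean
#>   <chr>                 <dbl>         <dbl>        <dbl>         <dbl>              <dbl>
#> 1 bin_19                    1             1          100             0              0.938
```

The benchmark community holds 25 genomes with the target pinned at 1.0% of
each of three bulk samples. The pipeline recovered the target's contigs in
a single bin with perfect length-weighted precision and recall, all 100
planted single-copy markers present exactly once (completeness 100%,
contamination 0%), and an estimated relative abundance of 0.94% — within
sampling noise of the configured 1%.

```r
qc_report(run$qc)
#>                         statistic    value
#>                     Bin size (Mb)     0.29
#>                 Number of contigs    27.00
#>                         N50 value 13745.00
#>                    GC content (%)    46.60
#>                  Completeness (%)   100.00
#>                 Contamination (%)     0.00
#>           Median coverage in MFS1    10.10
#>           Median coverage in MFS2    10.10
#>           Median coverage in MFS3     9.90
#>    Relative abundance (%) in MFS1     0.94
#>    Relative abundance (%) in MFS2     0.94
#>    Relative abundance (%) in MFS3     0.93
#>    Relative abundance (%) in mean     0.94
```

The 16S stage detects the 14-bp target-only insert
(`find_inserts(run$community$rrna$alignment, "target_16S")`) and designs
20-mer oligos that match every target exactly and miss every relative by at
least 8 bases:

```r
head(run$oligos, 3)
#>   name     sequence             orientation position worst_case_mismatches
#> 1 oligo_01 CCTGCTAGCTCATGTTTTGC forward          514                     8
#> 2 oligo_02 TAGCTCATGTTTTGCGCGTG forward          519                     8
#> 3 oligo_03 GTTTTGCGCGTGCGACACAT forward          527                     8
```

Stages are also callable individually — `simulate_community()`,
`build_features()`, `bin_contigs()`, `refine_bins()`, `bin_qc()`,
`pocp()` / `genus_clusters()`, `find_inserts()` / `design_oligos()`,
`nj_tree()` / `bootstrap_support()` — and every result type has
`tidy()` / `glance()` methods and `autoplot()` where a plot makes sense.
See `vignette("rare-genome-recovery")` for the model, parameter and design
discussion.

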