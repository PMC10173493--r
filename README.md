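# txcomplexity

Transcript-model complexity metrics for comparative transcriptomics, computed
directly from genome annotations.

Alternative splicing lets one genomic locus encode many mature transcripts,
and the amount of that structural complexity varies enormously across the
eukaryotic tree — from fungi dominated by single-isoform, single-exon genes to
deuterostomes averaging a dozen exons per transcript. Comparing complexity
across species is confounded by a standard practice: conditioning analyses on
orthologous genes. Young, lineage-specific ("novel") genes have fewer exons
and fewer isoforms than old genes, so restricting to orthologs biases
complexity upward. `txcomplexity` quantifies that bias and provides a metric
that is robust to it.

The package computes, per annotated species:

- **TpG** — transcripts per gene: the number of annotated isoforms.
- **EpT** — exons per transcript: the number of exon features in one
  transcript.
- **EpG** — exons per gene: the number of *distinct* exon coordinate
  intervals in the union over a gene's transcripts.
- **EEN** — Effective Exon Number, a Simpson-type effective number of the
  exon-length partition. With exon-length proportions
  *L<sub>i</sub> = l<sub>i</sub> / Σ<sub>j</sub> l<sub>j</sub>*,

  EEN = 1 / Σ<sub>i</sub> L<sub>i</sub>²

  so EEN = EpT exactly when exons are equal-length and EEN → 1 as one exon
  dominates. Binned EEN-vs-EpT profiles are compared against a **Broken
  Stick** null — a unit interval cut at N−1 simultaneous uniform breakpoints,
  the distribution of exon sizes expected under random intron placement.

Around these metrics sit the full comparative workflow: a validated GTF
reader/writer (RefSeq and FlyBase attribute dialects), OrthoDB-format flat
file parsing and ortholog/novel gene partitioning at a chosen taxonomic
level, a rank-based statistical battery (Wilcoxon rank-sum with Bonferroni,
Kruskal–Wallis across clades, Shapiro–Wilk-gated Pearson/Spearman
correlations, Fisher's combined probability, resampling cross-validation),
and a seeded synthetic-annotation generator so every stage is testable with
no downloads.

## Worked example

Simulate a species in which 30% of genes are novel and carry fewer exons
(mean EpT 2.5 vs 6 for orthologs), write matching OrthoDB-schema tables, and
run the per-species pipeline:

```r
library(txcomplexity)

sim <- simulate_annotation(species_spec(species_label = "demo",
                                        n_genes = 500, seed = 7))
og <- tempfile(); xr <- tempfile()
simulate_ortholog_tables(list(sim$manifest), level = 7742,
                         og2genes_path = og, xrefs_path = xr)
b <- run_species(sim$annotation, og2genes = og, xrefs = xr, level = 7742,
                 null_reps = 50000, max_N = 15, seed = 7)
b$complexity$ortholog
#> species_complexity 'demo_ortholog'
#>   genes: 350  transcripts: 722
#>   mean TpG 2.063  mean EpT 6.104  mean EpG 9.426
#>   inter-gene transcript overlap: 0.0000
b$complexity$novel
#> species_complexity 'demo_novel'
#>   genes: 150  transcripts: 293
#>   mean TpG 1.953  mean EpT 2.485  mean EpG 3.827
#>   inter-gene transcript overlap: 0.0000
```

The novel subset shows the planted complexity deficit (mean EpT 2.49 vs 6.10
for orthologs), so the whole-transcriptome mean (5.06) sits between the two —
the ortholog-conditioning bias this package measures. The EEN profile
classifies each exon-count bin against the Broken Stick null:

```r
b$profiles$whole
#> een_profile: 14 bins (null: 50000 replicates, seed 7)
#>   classification:  below 6, consistent 8
#>   N mean_EEN         SE count null_mean  null_lo  null_hi classification
#> 1 1 1.000000 0.00000000    67  1.000000 1.000000 1.000000     consistent
#> 2 2 1.531021 0.02888547   110  1.571178 1.025378 1.998739     consistent
#> 3 3 2.037544 0.03576245   139  2.119531 1.210345 2.938113          below
#> ...
```

Bins classified `below` have mean EEN more than 2 standard errors under the
null mean: exon sizes more uneven (intron breakpoints more clustered) than
random placement predicts. `run_group()` then merges several such bundles
into a clade report with the full statistical battery; `parse_gtf()` /
`parse_orthodb_tables()` run the same workflow on real RefSeq or FlyBase
annotations and OrthoDB v10.1 flat files.

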