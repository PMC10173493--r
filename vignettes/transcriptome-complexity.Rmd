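---
title: "Transcriptome complexity metrics and the Broken Stick null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome complexity metrics and the Broken Stick null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcomplexity)
```

## The problem

Annotated transcriptomes differ enormously in how much structure one gene
carries: how many isoforms it produces (TpG), how many exons each isoform
splices together (EpT), and how many distinct exonic intervals the gene uses
in total (EpG). These three counts are within-species quantities — they need
no alignment or orthology calls — which makes them attractive traits for
deep-time comparative work. The catch is that comparative pipelines usually
*condition on orthology*, and lineage-specific (novel) genes are
systematically simpler than old genes: fewer exons, fewer isoforms. Dropping
them inflates apparent complexity. This package computes the metrics on the
whole transcriptome, on the ortholog subset and on the novel subset, measures
the bias between them, and provides the Effective Exon Number, whose null
comparison conditions on EpT and is therefore largely immune to the bias.

## The metrics

For a gene $g$ with transcripts $t = 1, \dots, T_g$:

- $\mathrm{TpG}(g) = T_g$;
- $\mathrm{EpT}(t)$ is the number of exon features in transcript $t$;
- $\mathrm{EpG}(g)$ is the number of distinct exon intervals
  (seqid, start, end, strand) in the union over the gene's transcripts.

Exon identity for EpG is exact coordinate identity; partially overlapping
exon variants count separately, because the metric is defined on the *union
of unique exons* with no fuzziness. Species-level summaries average TpG and
EpG over genes, and EpT over transcripts (not over per-gene means): the
per-transcript average is what density plots of EpT display and keeps the
merged table's semantics uniform. Coordinates are 1-based inclusive, so an
exon's length is $end - start + 1$. Only `exon` feature rows define
transcript structure; CDS/UTR rows are ignored since every metric here is
exon-level. Genes on unplaced scaffolds are retained.

The inter-gene transcript overlap fraction reports the share of transcripts
whose genomic span (minimum exon start to maximum exon end) overlaps, by at
least one nucleotide and strand-agnostically, the span of a transcript of a
*different* gene on the same sequence. Span-level overlap is the default
because it captures "transcript overlap between genes" without committing to
exon-level semantics; an exon-level variant is available via
`transcript_overlap_fraction(ann, level = "exon")` and is never larger than
the span-level value.

## Effective Exon Number

With exon length proportions $L_i = l_i / \sum_j l_j$ within a transcript,

$$\mathrm{EEN} = \frac{1}{\sum_{i=1}^{\mathrm{EpT}} L_i^2}.$$

This is the Simpson-type effective number (inverse Simpson concentration) of
the exon-length partition: $\mathrm{EEN} = \mathrm{EpT}$ exactly when all
exons have equal length, $\mathrm{EEN} \to 1$ as one exon dominates, and
$0 < \mathrm{EEN} \le \mathrm{EpT}$ always. Because only proportions enter,
EEN is invariant to absolute transcript length. Proportions are taken over
the *mature* length (sum of exon lengths), not the genomic span — the
quantity of interest is how splice junctions partition the processed
transcript. We implement the uncorrected effective number; no finite-sample
correction is applied, since the per-transcript exon count is the quantity
being conditioned on, not an estimate.

## The Broken Stick null

If introns were placed at random, exon sizes should look like a unit stick
broken at $N-1$ breakpoints drawn simultaneously from a uniform
distribution. `broken_stick_null()` simulates this by sampling fragment
vectors from the exact equivalent representation: the spacings of $N-1$
sorted uniform variates have the same joint law as $N$ independent
$\mathrm{Exp}(1)$ draws normalized by their sum (a flat Dirichlet). This
identity removes the per-replicate sort and makes the null cheap at
$10^5$ replicates per $N$.

Useful closed forms, all verified by the test suite:

- $N = 1$: EEN $= 1$ with zero variance;
- $E[\sum L_i^2] = 2/(N+1)$ (flat-Dirichlet second moment);
- at $N = 2$: $E[\mathrm{EEN}] = \int_0^1 \frac{dx}{2x^2 - 2x + 1} =
  \pi/2$;
- $E[\mathrm{EEN}] \ge (N+1)/2$ for all $N$ (Jensen's inequality applied to
  $1/\sum L^2$).

The null comparison uses the Monte-Carlo mean EEN per $N$, not
$1/E[\sum L^2]$; the two differ by Jensen's inequality and the simulated
mean is the quantity that matches "EEN of randomly broken sticks".

`een_profile()` bins per-transcript records by EpT and classifies each bin:
**below** the null when $\bar{\mathrm{EEN}} + 2\,\mathrm{SE} <
E_{null}[\mathrm{EEN}]$ (intron breakpoints more clustered than random),
**above** when $\bar{\mathrm{EEN}} - 2\,\mathrm{SE} > E_{null}$ (more evenly
spaced than random), otherwise **consistent**. SE is the sample standard
deviation over transcripts divided by $\sqrt{count}$. Bins with fewer than 5
transcripts are reported but flagged unstable. Profiles truncate at
$N = 30$ by default, the usual visualization range for these metrics; pass
`max_N = Inf` for the full range. Because the profile conditions on $N$,
removing low-EpT novel genes barely moves it — the robustness property the
acceptance checks verify on synthetic clades.

## Ortholog partitioning

OrthoDB v10-schema flat files are parsed at a single taxonomic level (the
MRCA node id encoded in each ortholog-group id after `"at"`), keeping
cross-references in the NCBI GeneID namespace by default
(`xref_namespace` exposes others rather than guessing how foreign-namespace
genes should be treated). Matching runs on GeneID — not gene symbol — since
symbols collide across annotations. A gene is *ortholog* when its GeneID is
reachable from any retained group; everything else, including genes whose
GeneID is absent from the xref file, is *novel* at that level (novel means
"not orthologous at the level", so unmatched is a classification, not an
error). 1:Multiple mappings are kept as-is: a gene in several groups is
classified once. The partition emits three annotations (whole, ortholog,
novel) that conserve exon rows exactly; `schema = "v9"` tolerates the
OG2genes column order being reversed for v9-era files.

## Statistical battery

- **Wilcoxon rank-sum** (two-sided, whole vs ortholog per species and
  metric): the exact null distribution for tie-free samples under 50 per
  side, otherwise the normal approximation with midranks, tie-corrected
  variance and continuity correction. Bonferroni adjustment uses one family
  per clade run: every species × metric comparison, with the family size
  recorded in the report.
- **Kruskal–Wallis** across clades on species-level means, tie-corrected;
  all-identical input returns $H = 0$, $p = 1$ rather than an error.
- **Correlations among metrics** across species pass through a Shapiro–Wilk
  gate at $\alpha = 0.05$ on each margin: both normal → Pearson ($r$, $R^2$);
  otherwise Spearman. The branch taken is recorded per run, never assumed.
  Margins over 5000 points gate on an even subsample (the Shapiro–Wilk
  statistic is defined up to n = 5000).
- **Fisher's combined probability**: $X^2 = -2\sum \ln p$ on $2k$ df,
  combining per-species p-values per metric. Zero p-values are an error by
  default; a `floor_p` clip (1e-300 in the pipeline) is applied before
  combining and the number of clipped values recorded.
- **Resampling cross-validation** ("jackknife" in the field's loose sense):
  the null distribution of the subset-sized mean under random subsampling of
  the whole, 10,000 replicates by default, with the observed ortholog-subset
  mean located by its two-sided empirical quantile (mid-quantile with
  add-one smoothing so p stays inside (0,1)). A comparison *validates* when
  this conclusion agrees with the Wilcoxon conclusion at $\alpha$. A
  replicate count in the thousands is incompatible with the classical
  delete-one jackknife (which has exactly n replicates); the classical
  variant remains available via `method = "delete_one"`.

Note the whole-vs-subset comparisons share observations (the ortholog subset
is part of the whole), which makes the rank test conservative under the
null; the acceptance checks bound the realized type-I rate by
$\alpha + 2\,\mathrm{SE}$ rather than asserting exact attainment.

## The synthetic generator

`simulate_annotation()` emulates the statistical structure the analysis
assumes, with every draw flowing through one seeded stream:

- TpG $\sim 1 + \mathrm{Geom}(1/\mu)$, mean $\mu$ = 2 by default; $\mu = 1$
  degenerates to the single-isoform regime many fungal annotations show.
- EpT $\sim 1 + \mathrm{Pois}(\lambda - 1)$ with $\lambda$ = 6 for ortholog
  genes and 2.5 for novel genes by default — novel means in well-annotated
  exemplar species fall roughly between 1.9 and 3.8, and 6 sits in the range
  typical of plant/deuterostome transcriptomes. A `"constant"` option fixes
  EpT for moment checks.
- Mature length $\sim$ log-normal (median 1500 nt, sdlog 0.6), partitioned
  into exon lengths by Broken Stick, symmetric Dirichlet($\alpha$)
  ($\alpha < 1$ clustered, $\alpha > 1$ even) or equal split. Integer
  lengths come from largest-remainder rounding with a 1-nt floor; at these
  lengths the rounding bias on EEN is far below Monte-Carlo error.
- Transcripts after the first reuse an existing exon of their gene with
  probability `exon_sharing` (0.5), so EpG < ΣEpT realistically. Reused
  exons keep the length they were created with, so transcripts of
  exon-sharing genes mix length scales drawn for different totals; exact
  distributional checks against the Broken Stick null therefore set
  `exon_sharing = 0`. Under the `"equal"` partition all exons of a gene
  share one unit length, so EEN = EpT holds exactly even with sharing.
- Genes sit on `syn_chr*` scaffolds 50 kb apart. Inter-gene transcript
  overlap is planted as pairs of relocated single-transcript genes — the
  moved gene's span starts exactly at its partner's span start — with the
  planted pair count being the nearest even number to the target fraction;
  the generator verifies the realized count by direct span comparison and
  refuses infeasible targets.
- Ortholog labels are planted at exactly `round(fraction * n_genes)` genes;
  `simulate_ortholog_tables()` writes OrthoDB-schema files (plus decoy rows
  at a wrong level and in a foreign namespace) from which
  `partition_annotation()` recovers the labels exactly, and genes sharing a
  within-species rank across species land in shared groups to exercise
  1:Multiple mappings.

What the generator does *not* emulate: sequence content, realistic intron
length distributions, gene-family birth–death, annotation errors (collapsed
isoforms, missing genes), or expression support. Passing tests therefore
demonstrate the pipeline's correctness on data satisfying its assumptions,
not the biological conclusions one would draw from real annotations, where
annotation quality dominates.

## Numerical choices and degenerate inputs

- Duplicated exon rows within one transcript collapse with a warning
  (annotation artifact, not complexity); transcripts spanning multiple
  sequences or strands are rejected outright rather than repaired.
- Empty annotations parse and write (header-only GTF) but are refused by the
  metric layer with an explicit error.
- The Broken Stick null records its seed and replicate count in every
  result; profiles built against it are reproducible by construction.
- Test and acceptance problem sizes — $10^5$ null replicates per $N$,
  200-seed calibration loops on 120-gene species, a four-species
  400-gene-per-species effect clade — were chosen so each check's
  Monte-Carlo error is far below the effect it measures while the whole
  suite stays interactive.

## Orchestration

`run_species()` executes parse → partition (when tables are given) →
complexity (whole/ortholog/novel) → EEN profile, returning a bundle whose
manifest echoes the full configuration, seeds and package version (full
echo rather than a hash: strictly more informative for provenance).
`run_group()` consumes bundles, producing the merged long table, the
Wilcoxon/Bonferroni sweep, Kruskal–Wallis per metric, gated correlations,
Fisher combinations and resampling validations; tests whose preconditions
fail (one group, two species) are skipped with a logged reason rather than
aborting the run. Both write TSV/JSON outputs when given an output
directory. There is no shell wrapper: the exported functions plus
`scripts/acceptance.R` are the interface.

## Known limitations

- GTF only (no GFF3), exon features only, no lift-over or polycistronic
  merging.
- Ortholog *inference* is out of scope: the package consumes OrthoDB-format
  tables, it does not compute orthology.
- The overlap statistic is span-level and strand-agnostic by default; the
  exon-level flag exists but no strand-aware variant does.
- EEN profiles condition on annotated exon counts; annotations that collapse
  isoforms bias EEN upward, and no correction for annotation quality is
  attempted.
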