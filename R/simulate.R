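#' Specify a synthetic species annotation
#'
#' Collects the generative parameters for one synthetic species. Defaults
#' describe a moderately spliced eukaryote: transcripts per gene follow
#' 1 + Geometric with mean 2 isoforms, ortholog-gene exon counts follow
#' 1 + Poisson with mean 6 exons per transcript, and novel (lineage-specific)
#' genes draw fewer exons (mean 2.5), matching the field observation that
#' young genes carry few exons and few isoforms. Exon lengths within a
#' transcript are partitioned from the mature length by a Broken Stick
#' process (uniform breakpoints) by default; `"dirichlet"` with
#' concentration < 1 clusters breakpoints (under-dispersed exon evenness) and
#' `"equal"` splits evenly so EEN = EpT exactly.
#'
#' @param species_label label for the species.
#' @param n_genes number of genes.
#' @param tpg_mean mean transcripts per gene (>= 1); TpG ~ 1 + Geom, and a
#'   mean of exactly 1 gives the single-isoform ("fungi-like") regime.
#' @param ept_mean mean exons per transcript for ortholog-class genes (>= 1).
#' @param ept_dist `"poisson"` (1 + Poisson(ept_mean - 1)) or `"constant"`
#'   (every transcript has round(ept_mean) exons).
#' @param exon_partition `"broken_stick"`, `"dirichlet"` or `"equal"`.
#' @param dirichlet_alpha symmetric Dirichlet concentration for
#'   `exon_partition = "dirichlet"` (default 0.2, clustered breakpoints).
#' @param tx_length_meanlog,tx_length_sdlog log-normal parameters of the
#'   mature transcript length in nucleotides (default ~1500 nt median).
#' @param ortholog_fraction fraction of genes labelled ortholog; the realized
#'   count is exactly `round(ortholog_fraction * n_genes)`.
#' @param novel_ept_mean mean exons per transcript for novel-class genes;
#'   NULL uses `ept_mean` (the null regime where novel genes are
#'   indistinguishable).
#' @param novel_tpg_mean mean transcripts per gene for novel-class genes;
#'   NULL uses `tpg_mean`.
#' @param overlap_fraction_target fraction of transcripts that should overlap
#'   a foreign gene's transcript (planted as pairs of relocated
#'   single-transcript genes; 0 disables planting).
#' @param exon_sharing probability that an exon of a non-first transcript
#'   reuses an existing exon of its gene rather than creating a new one;
#'   makes EpG < sum(EpT) realistically.
#' @param seed integer seed; all randomness flows through one stream.
#' @return Object of class `species_spec`.
#' @export
species_spec <- function(species_label = "synthA", n_genes = 1000L,
                         tpg_mean = 2, ept_mean = 6,
                         ept_dist = c("poisson", "constant"),
                         exon_partition = c("broken_stick", "dirichlet",
                                            "equal"),
                         dirichlet_alpha = 0.2,
                         tx_length_meanlog = log(1500),
                         tx_length_sdlog = 0.6,
                         ortholog_fraction = 0.7,
                         novel_ept_mean = 2.5, novel_tpg_mean = NULL,
                         overlap_fraction_target = 0,
                         exon_sharing = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1L, tpg_mean >= 1, ept_mean >= 1,
            ortholog_fraction >= 0, ortholog_fraction <= 1,
            overlap_fraction_target >= 0, overlap_fraction_target <= 1,
            exon_sharing >= 0, exon_sharing <= 1, dirichlet_alpha > 0)
  structure(list(species_label = species_label, n_genes = as.integer(n_genes),
                 tpg_mean = tpg_mean, ept_mean = ept_mean,
                 ept_dist = match.arg(ept_dist),
                 exon_partition = match.arg(exon_partition),
                 dirichlet_alpha = dirichlet_alpha,
                 tx_length_meanlog = tx_length_meanlog,
                 tx_length_sdlog = tx_length_sdlog,
                 ortholog_fraction = ortholog_fraction,
                 novel_ept_mean = novel_ept_mean,
                 novel_tpg_mean = novel_tpg_mean,
                 overlap_fraction_target = overlap_fraction_target,
                 exon_sharing = exon_sharing, seed = as.integer(seed)),
            class = "species_spec")
}

# integer partition of total into n positive parts with given proportions,
# by largest-remainder rounding; steals from the largest part if a part
# rounds to zero
.partition_lengths <- function(total, props) {
  n <- length(props)
  if (total < n) total <- n
  raw <- props * total
  base <- floor(raw)
  rem <- as.integer(total - sum(base))
  if (rem > 0L) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1L
  }
  while (any(base == 0L)) {
    i <- which(base == 0L)[1L]; j <- which.max(base)
    base[i] <- 1L; base[j] <- base[j] - 1L
  }
  as.integer(base)
}

.draw_props <- function(n, partition, alpha) {
  if (n == 1L) return(1)
  switch(partition,
         broken_stick = { e <- rexp(n); e / sum(e) },
         dirichlet = { g <- rgamma(n, shape = alpha); g / sum(g) },
         equal = rep(1 / n, n))
}

#' Simulate a synthetic species annotation with known truth
#'
#' Draws per-gene transcript counts, per-transcript exon counts and mature
#' lengths, partitions each transcript's length into exon lengths by the
#' chosen model, and lays exons on synthetic scaffolds (`syn_chr1`, ...) with
#' wide inter-gene gaps. Later transcripts of a gene reuse existing exons
#' with probability `exon_sharing`, so EpG < sum(EpT). Ortholog/novel class
#' labels are planted at exactly `round(ortholog_fraction * n_genes)`
#' ortholog genes, and gene pairs are relocated to overlap when
#' `overlap_fraction_target > 0`. All results are reproducible from the
#' spec's seed.
#'
#' @param spec a [species_spec()].
#' @return List with `annotation` (an [annotation_set()], RefSeq dialect with
#'   integer GeneIDs) and `manifest` — a list holding the per-gene truth table
#'   (gene_id, ncbi_gene_id, class, TpG, EpG), the per-transcript table
#'   (transcript_id, gene_id, EpT, mature_length), realized totals
#'   (`n_genes`, `n_transcripts`, `n_exon_rows`, `n_ortholog`,
#'   `n_overlapping_transcripts`), the planted spec and `taxid`.
#' @export
simulate_annotation <- function(spec) {
  stopifnot(inherits(spec, "species_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  n_orth <- round(spec$ortholog_fraction * ng)
  class <- rep("novel", ng)
  class[sample.int(ng, n_orth)] <- "ortholog"

  tpg_mean <- ifelse(class == "ortholog", spec$tpg_mean,
                     spec$novel_tpg_mean %||% spec$tpg_mean)
  ept_mean <- ifelse(class == "ortholog", spec$ept_mean,
                     spec$novel_ept_mean %||% spec$ept_mean)
  TpG <- 1L + rgeom(ng, prob = 1 / tpg_mean)

  genes_per_scaffold <- 50L
  gap <- 50000L
  exon_rows <- vector("list", ng)
  tx_rows <- vector("list", ng)
  gene_span <- integer(ng)     # genomic footprint per gene
  gene_epg <- integer(ng)
  for (g in seq_len(ng)) {
    # exon catalogue for this gene: lengths in creation order
    cat_len <- integer(0)
    tx_slots <- vector("list", TpG[g])
    n_ex <- if (spec$ept_dist == "constant") rep(max(1L, round(ept_mean[g])),
                                                 TpG[g])
            else 1L + rpois(TpG[g], ept_mean[g] - 1)
    for (t in seq_len(TpG[g])) {
      N <- n_ex[t]
      n_reuse <- if (t == 1L || !length(cat_len)) 0L
                 else min(rbinom(1L, N, spec$exon_sharing), length(cat_len))
      reuse <- if (n_reuse) sort(sample.int(length(cat_len), n_reuse)) else
        integer(0)
      n_new <- N - n_reuse
      if (n_new > 0L) {
        if (spec$exon_partition == "equal") {
          # one unit length per gene keeps every exon identical in length,
          # so EEN = EpT exactly even when transcripts share exons
          if (!length(cat_len)) {
            unit <- max(1L, as.integer(round(exp(spec$tx_length_meanlog) /
                                               max(1, spec$ept_mean))))
          } else unit <- cat_len[1L]
          new_len <- rep(unit, n_new)
        } else {
          L <- max(N, round(rlnorm(1L, spec$tx_length_meanlog,
                                   spec$tx_length_sdlog)))
          props <- .draw_props(N, spec$exon_partition, spec$dirichlet_alpha)
          new_len <- .partition_lengths(L, props)[seq_len(n_new)]
        }
        new_idx <- length(cat_len) + seq_len(n_new)
        cat_len <- c(cat_len, new_len)
      } else new_idx <- integer(0)
      tx_slots[[t]] <- sort(c(reuse, new_idx))
    }
    # lay catalogue slots along the gene with intron gaps
    introns <- sample(50:500, length(cat_len), replace = TRUE)
    ends <- cumsum(cat_len + introns)
    starts <- ends - cat_len + 1L
    gene_span[g] <- ends[length(ends)]
    gene_epg[g] <- length(cat_len)
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("G%d", g)
    ex_g <- rbindlist(lapply(seq_len(TpG[g]), function(t) {
      sl <- tx_slots[[t]]
      data.table(rel_start = starts[sl], rel_end = ends[sl],
                 strand = strand, gene_id = gid,
                 transcript_id = sprintf("G%d.t%d", g, t))
    }))
    exon_rows[[g]] <- ex_g
    tx_rows[[g]] <- data.table(
      transcript_id = sprintf("G%d.t%d", g, seq_len(TpG[g])),
      gene_id = gid,
      EpT = vapply(tx_slots, length, 1L),
      mature_length = vapply(tx_slots, function(sl) sum(cat_len[sl]), 1L))
  }

  # place genes sequentially on scaffolds with wide gaps
  scaffold <- sprintf("syn_chr%d", (seq_len(ng) - 1L) %/% genes_per_scaffold + 1L)
  offset <- integer(ng)
  pos <- 1000L; cur <- ""
  for (g in seq_len(ng)) {
    if (scaffold[g] != cur) { pos <- 1000L; cur <- scaffold[g] }
    offset[g] <- pos
    pos <- pos + gene_span[g] + gap
  }

  # plant inter-gene transcript overlap by relocating single-transcript genes
  n_tx_total <- sum(TpG)
  # planted overlaps come in pairs of relocated genes: use the nearest
  # feasible even count
  k <- 2L * round(spec$overlap_fraction_target * n_tx_total / 2)
  planted_pairs <- NULL
  if (k > 0L) {
    singles <- which(TpG == 1L)
    if (length(singles) < k)
      stop(sprintf(paste0("infeasible overlap target: need %d ",
                          "single-transcript genes, have %d"),
                   k, length(singles)))
    chosen <- sample(singles, k)
    a_idx <- chosen[seq_len(k / 2)]
    b_idx <- chosen[k / 2 + seq_len(k / 2)]
    # relocate gene B so its transcript span starts exactly at gene A's
    # transcript span start: overlap of >= 1 nt is then guaranteed
    for (i in seq_len(k / 2)) {
      a <- a_idx[i]; b <- b_idx[i]
      scaffold[b] <- scaffold[a]
      aS <- min(exon_rows[[a]]$rel_start)
      bS <- min(exon_rows[[b]]$rel_start)
      offset[b] <- offset[a] + aS - bS
    }
    planted_pairs <- data.table(gene_a = sprintf("G%d", a_idx),
                                gene_b = sprintf("G%d", b_idx))
  }

  ex <- rbindlist(lapply(seq_len(ng), function(g) {
    e <- exon_rows[[g]]
    data.table(seqid = scaffold[g], start = e$rel_start + offset[g],
               end = e$rel_end + offset[g], strand = e$strand,
               gene_id = e$gene_id, transcript_id = e$transcript_id)
  }))

  # realized overlap bookkeeping, by direct span comparison (independent of
  # the package's IRanges-based counter)
  spans <- ex[, .(gene_id = gene_id[1L], seqid = seqid[1L], s = min(start),
                  e = max(end)), by = transcript_id]
  n_overlap <- 0L
  overlapping <- character(0)
  for (sq in unique(spans$seqid)) {
    sp <- spans[seqid == sq]
    if (nrow(sp) < 2L) next
    for (i in seq_len(nrow(sp))) {
      hit <- sp$s <= sp$e[i] & sp$e >= sp$s[i] & sp$gene_id != sp$gene_id[i]
      if (any(hit)) overlapping <- c(overlapping, sp$transcript_id[i])
    }
  }
  n_overlap <- length(unique(overlapping))
  if (k > 0L && n_overlap != k)
    stop(sprintf(paste0("infeasible overlap target: planted %d but realized ",
                        "%d overlapping transcripts (gene spans collided)"),
                 k, n_overlap))

  gene_ids <- sprintf("G%d", seq_len(ng))
  ncbi_ids <- as.character(100000L + seq_len(ng))
  ann <- annotation_set(ex, species_label = spec$species_label,
                        dialect = "refseq",
                        gene_xref = data.table(gene_id = gene_ids,
                                               ncbi_gene_id = ncbi_ids))
  genes_tab <- data.table(gene_id = gene_ids, ncbi_gene_id = ncbi_ids,
                          class = class, TpG = TpG, EpG = gene_epg)
  tx_tab <- rbindlist(tx_rows)
  manifest <- list(species_label = spec$species_label,
                   taxid = 90000L + (abs(spec$seed) %% 1000L),
                   genes = as.data.frame(genes_tab),
                   transcripts = as.data.frame(tx_tab),
                   n_genes = ng, n_transcripts = n_tx_total,
                   n_exon_rows = nrow(ex), n_ortholog = n_orth,
                   n_overlapping_transcripts = n_overlap,
                   planted_pairs = planted_pairs, spec = spec)
  list(annotation = ann, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write OrthoDB-schema tables matching synthetic truth manifests
#'
#' Assigns each ortholog-class gene of each synthetic species to a shared
#' ortholog group at the given taxonomic level and writes the two OrthoDB
#' v10-schema flat files (OG2genes: og_id, orthodb_gene_id; gene_xrefs:
#' orthodb_gene_id, external id, namespace) such that
#' [partition_annotation()] recovers each manifest's ortholog set exactly.
#' Genes holding the same within-species ortholog rank across species land in
#' the same OG, so multi-species runs exercise 1:Multiple mappings. Decoy
#' rows (an OG at a different level, xrefs in a foreign namespace) exercise
#' the parser's filters.
#'
#' @param manifests list of manifests from [simulate_annotation()].
#' @param level taxonomic level id encoded in OG ids.
#' @param og2genes_path,xrefs_path output paths (`.gz` suffix writes gzip).
#' @param decoys add filter-exercising decoy rows (default TRUE).
#' @return Invisible list with the two paths and the og assignment table.
#' @export
simulate_ortholog_tables <- function(manifests, level,
                                     og2genes_path, xrefs_path,
                                     decoys = TRUE) {
  stopifnot(length(manifests) >= 1L)
  og_rows <- list(); xref_rows <- list(); assign_rows <- list()
  for (m in manifests) {
    ge <- as.data.table(m$genes)[class == "ortholog"]
    if (!nrow(ge)) next
    j <- seq_len(nrow(ge))
    odb_gene <- sprintf("%d_0:%06x", m$taxid, j)
    og_id <- sprintf("%dat%s", j, as.character(level))
    og_rows[[length(og_rows) + 1L]] <- data.table(og_id, odb_gene)
    xref_rows[[length(xref_rows) + 1L]] <-
      data.table(odb_gene, xref = ge$ncbi_gene_id, ns = "NCBIgid")
    assign_rows[[length(assign_rows) + 1L]] <-
      data.table(species = m$species_label, gene_id = ge$gene_id,
                 ncbi_gene_id = ge$ncbi_gene_id, og_id = og_id)
  }
  og <- rbindlist(og_rows); xr <- rbindlist(xref_rows)
  if (decoys) {
    og <- rbind(og, data.table(og_id = sprintf("99999at%s0",
                                               as.character(level)),
                               odb_gene = "999999_0:ffffff"))
    xr <- rbind(xr, data.table(odb_gene = xr$odb_gene[1L],
                               xref = "DECOY_PROTEIN", ns = "UniProt"))
  }
  con <- .open_text(og2genes_path, "wt")
  writeLines(paste(og$og_id, og$odb_gene, sep = "\t"), con); close(con)
  con <- .open_text(xrefs_path, "wt")
  writeLines(paste(xr$odb_gene, xr$xref, xr$ns, sep = "\t"), con); close(con)
  invisible(list(og2genes_path = og2genes_path, xrefs_path = xrefs_path,
                 assignment = as.data.frame(rbindlist(assign_rows))))
}
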