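min_gene <- function() annotation_set(
  data.frame(seqid = "chr1", start = 1L, end = 100L, strand = "+",
             gene_id = "g1", transcript_id = "t1"))

test_that("TpG/EpT/EpG follow their definitions on hand-built genes", {
  cx <- compute_complexity(min_gene())
  expect_equal(cx$genes$TpG, 1L)
  expect_equal(cx$transcripts$EpT, 1L)
  expect_equal(cx$genes$EpG, 1L)

  # two transcripts sharing exon A: t1 = {A, B}, t2 = {A, C}
  ann <- annotation_set(data.frame(
    seqid = "chr1",
    start = c(1L, 201L, 1L, 401L), end = c(100L, 300L, 100L, 500L),
    strand = "+", gene_id = "g1",
    transcript_id = c("t1", "t1", "t2", "t2")))
  cx <- compute_complexity(ann)
  expect_equal(cx$genes$TpG, 2L)
  expect_equal(sort(cx$transcripts$EpT), c(2L, 2L))
  expect_equal(cx$genes$EpG, 3L)
})

test_that("metrics equal a naive brute-force counter on random annotations", {
  for (seed in 1:20) {
    sim <- simulate_annotation(species_spec(
      n_genes = sample(3:20, 1L), tpg_mean = 2, ept_mean = 4, seed = seed))
    cx <- compute_complexity(sim$annotation)
    bf <- brute_force_complexity(sim$annotation)
    got_g <- cx$genes[order(cx$genes$gene_id)]
    expect_equal(got_g$TpG, bf$genes$TpG, ignore_attr = TRUE)
    expect_equal(got_g$EpG, bf$genes$EpG, ignore_attr = TRUE)
    got_t <- cx$transcripts[order(cx$transcripts$transcript_id)]
    expect_equal(got_t$EpT, bf$transcripts$EpT, ignore_attr = TRUE)
  }
})

test_that("EpG is bounded by max(EpT) and sum(EpT) per gene", {
  sim <- simulate_annotation(species_spec(n_genes = 200L, seed = 42L))
  cx <- compute_complexity(sim$annotation)
  per_gene <- merge(as.data.frame(cx$genes),
                    aggregate(EpT ~ gene_id, data = cx$transcripts,
                              FUN = function(v) c(mx = max(v), sm = sum(v))),
                    by = "gene_id")
  expect_true(all(per_gene$EpG >= per_gene$EpT[, "mx"]))
  expect_true(all(per_gene$EpG <= per_gene$EpT[, "sm"]))
})

test_that("duplicating a transcript raises TpG by one and leaves EpG unchanged", {
  sim <- simulate_annotation(species_spec(n_genes = 10L, seed = 9L))
  ex <- as.data.frame(sim$annotation$exons)
  tx <- ex$transcript_id[1L]
  dup <- ex[ex$transcript_id == tx, ]
  dup$transcript_id <- paste0(tx, "_copy")
  ann2 <- annotation_set(rbind(ex, dup))
  g <- dup$gene_id[1L]
  cx1 <- compute_complexity(sim$annotation)
  cx2 <- compute_complexity(ann2)
  expect_equal(cx2$genes$TpG[cx2$genes$gene_id == g],
               cx1$genes$TpG[cx1$genes$gene_id == g] + 1L)
  expect_equal(cx2$genes$EpG[cx2$genes$gene_id == g],
               cx1$genes$EpG[cx1$genes$gene_id == g])
})

test_that("transcript overlap fraction follows its span definition", {
  # different seqids: disjoint by construction
  ann <- annotation_set(data.frame(
    seqid = c("chr1", "chr2"), start = c(1L, 1L), end = c(100L, 100L),
    strand = "+", gene_id = c("g1", "g2"), transcript_id = c("t1", "t2")))
  expect_equal(transcript_overlap_fraction(ann), 0)

  # overlapping spans on one seqid: both transcripts count (symmetry)
  ann <- annotation_set(data.frame(
    seqid = "chr1", start = c(1L, 50L), end = c(100L, 150L), strand = "+",
    gene_id = c("g1", "g2"), transcript_id = c("t1", "t2")))
  expect_equal(transcript_overlap_fraction(ann), 1)
  # gene relabeling does not change the fraction
  ex <- as.data.frame(ann$exons)
  ex$gene_id <- c("zzz", "aaa")
  expect_equal(transcript_overlap_fraction(annotation_set(ex)), 1)

  # exon-level variant: spans overlap but exons do not
  ann <- annotation_set(data.frame(
    seqid = "chr1", start = c(1L, 500L, 120L), end = c(100L, 600L, 300L),
    strand = "+", gene_id = c("g1", "g1", "g2"),
    transcript_id = c("t1", "t1", "t2")))
  expect_equal(transcript_overlap_fraction(ann, level = "span"), 1)
  expect_equal(transcript_overlap_fraction(ann, level = "exon"), 0)
})

test_that("generator-planted overlap is recovered exactly", {
  sim <- simulate_annotation(species_spec(
    n_genes = 600L, tpg_mean = 1, ept_mean = 4,
    overlap_fraction_target = 0.05, seed = 21L))
  expect_equal(sim$manifest$n_transcripts, 600L)
  expect_equal(sim$manifest$n_overlapping_transcripts, 30L)
  expect_equal(transcript_overlap_fraction(sim$annotation), 0.05)
})

test_that("generator means are recovered within Monte Carlo error", {
  sim <- simulate_annotation(species_spec(
    n_genes = 2000L, tpg_mean = 2, ept_mean = 6, ortholog_fraction = 1,
    seed = 77L))
  cx <- compute_complexity(sim$annotation)
  # TpG ~ 1 + Geom(1/2): var = 2; EpT ~ 1 + Pois(5): var = 5
  se_tpg <- sqrt(2 / cx$n_genes)
  se_ept <- sqrt(5 / cx$n_transcripts)
  expect_lt(abs(cx$mean_TpG - 2), 3 * se_tpg)
  expect_lt(abs(cx$mean_EpT - 6), 3 * se_ept)
})

test_that("merge_species builds the long grouped table and checks labels", {
  sims <- lapply(1:2, function(i) simulate_annotation(
    species_spec(species_label = paste0("sp", i), n_genes = 30L, seed = i)))
  cxs <- lapply(sims, function(s) compute_complexity(s$annotation))
  tab <- merge_species(cxs, c(sp1 = "cladeA", sp2 = "cladeA"))
  expect_equal(nrow(tab), 6L)  # 2 species x 3 metrics
  expect_setequal(tab$metric, c("TpG", "EpT", "EpG"))
  # merge is lossless on per-species means
  expect_equal(tab$value[tab$species == "sp1" & tab$metric == "EpT"],
               cxs[[1]]$mean_EpT)
  expect_error(merge_species(cxs, c(sp1 = "cladeA")), "sp2")
})

test_that("planted clade ordering shows up in group medians", {
  means <- c(1.1, 1.5, 2, 3)
  cxs <- list(); labels <- character(0)
  for (gi in seq_along(means)) for (si in 1:2) {
    lab <- sprintf("g%ds%d", gi, si)
    sim <- simulate_annotation(species_spec(
      species_label = lab, n_genes = 400L, tpg_mean = means[gi],
      ept_mean = 4, seed = 100L * gi + si))
    cxs[[lab]] <- compute_complexity(sim$annotation)
    labels[lab] <- sprintf("clade%d", gi)
  }
  tab <- merge_species(cxs, labels)
  med <- tapply(tab$value[tab$metric == "TpG"],
                tab$group[tab$metric == "TpG"], median)
  expect_equal(names(sort(med)), sprintf("clade%d", 1:4))
})

test_that("empty annotations are rejected by the metric layer", {
  empty <- annotation_set(data.frame(seqid = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     gene_id = character(),
                                     transcript_id = character()))
  expect_error(compute_complexity(empty), "no genes")
  expect_error(een_records(empty), "no genes")
})
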