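write_toy_tables <- function(og_lines, xref_lines) {
  og <- tempfile(fileext = ".tab")
  xr <- tempfile(fileext = ".tab")
  writeLines(og_lines, og)
  writeLines(xref_lines, xr)
  list(og = og, xr = xr)
}

test_that("OrthoDB tables filter by level and xref namespace", {
  f <- write_toy_tables(
    c("10at7742\t9606_0:0001", "11at7742\t9606_0:0002",
      "20at33208\t9606_0:0003"),
    c("9606_0:0001\t111\tNCBIgid", "9606_0:0002\t222\tNCBIgid",
      "9606_0:0003\t333\tNCBIgid", "9606_0:0001\tP12345\tUniProt"))
  tab <- parse_orthodb_tables(f$og, f$xr, level = 7742)
  expect_equal(length(unique(tab$og_to_genes$og_id)), 2L)
  expect_false(any(tab$xrefs$xref_id == "P12345"))
  expect_error(parse_orthodb_tables(f$og, f$xr, level = 99999), "level")
})

test_that("malformed rows are reported with line numbers", {
  f <- write_toy_tables(c("10at7742\t9606_0:0001", "onlyonecolumn"),
                        "9606_0:0001\t111\tNCBIgid")
  expect_error(parse_orthodb_tables(f$og, f$xr, level = 7742), "line 2")
})

test_that("a gene with two GeneID xrefs keeps both (1:Multiple)", {
  f <- write_toy_tables(
    "10at7742\t9606_0:0001",
    c("9606_0:0001\t111\tNCBIgid", "9606_0:0001\t112\tNCBIgid"))
  tab <- parse_orthodb_tables(f$og, f$xr, level = 7742)
  expect_setequal(tab$xrefs$xref_id, c("111", "112"))
})

test_that("the v9 schema tolerance swaps the OG2genes column order", {
  f <- write_toy_tables(
    "9606_0:0001\t10at7742",
    "9606_0:0001\t111\tNCBIgid")
  tab <- parse_orthodb_tables(f$og, f$xr, level = 7742, schema = "v9")
  expect_equal(tab$og_to_genes$og_id, "10at7742")
})

make_ten_gene_annotation <- function() {
  ex <- data.frame(seqid = "chr1",
                   start = seq(1L, by = 1000L, length.out = 10L),
                   end = seq(100L, by = 1000L, length.out = 10L),
                   strand = "+", gene_id = sprintf("g%d", 1:10),
                   transcript_id = sprintf("t%d", 1:10))
  annotation_set(ex, species_label = "toy", dialect = "refseq",
                 gene_xref = data.frame(gene_id = sprintf("g%d", 1:10),
                                        ncbi_gene_id = as.character(1:10)))
}

test_that("partition splits genes into disjoint, exhaustive classes", {
  ann <- make_ten_gene_annotation()
  f <- write_toy_tables(
    sprintf("%dat7742\t9606_0:%04d", 1:6, 1:6),
    sprintf("9606_0:%04d\t%d\tNCBIgid", 1:6, 1:6))
  tab <- parse_orthodb_tables(f$og, f$xr, level = 7742)
  part <- partition_annotation(ann, tab)
  expect_length(part$ortholog_gene_ids, 6L)
  expect_length(part$novel_gene_ids, 4L)
  expect_length(intersect(part$ortholog_gene_ids, part$novel_gene_ids), 0L)
  expect_setequal(c(part$ortholog_gene_ids, part$novel_gene_ids),
                  sprintf("g%d", 1:10))
  # conservation: exon rows of subsets sum to the whole
  expect_equal(nrow(part$ortholog_subset$exons) + nrow(part$novel_subset$exons),
               nrow(part$whole$exons))
})

test_that("a gene present in two OGs is classified once (idempotent)", {
  ann <- make_ten_gene_annotation()
  f <- write_toy_tables(
    c("1at7742\t9606_0:0001", "2at7742\t9606_0:0001"),
    "9606_0:0001\t1\tNCBIgid")
  part <- partition_annotation(ann, parse_orthodb_tables(f$og, f$xr, 7742))
  expect_equal(part$ortholog_gene_ids, "g1")
  m <- part$manifest
  expect_equal(m$og_ids[m$gene_id == "g1"], "1at7742,2at7742")
})

test_that("unmatchable annotations fail with a dialect hint", {
  ex <- data.frame(seqid = "chr1", start = 1L, end = 100L, strand = "+",
                   gene_id = "g1", transcript_id = "t1")
  ann <- annotation_set(ex, dialect = "generic")
  f <- write_toy_tables("1at7742\t9606_0:0001", "9606_0:0001\t1\tNCBIgid")
  expect_error(partition_annotation(
    ann, parse_orthodb_tables(f$og, f$xr, 7742)), "id_map")
})

test_that("generator-planted ortholog fraction is recovered exactly", {
  sim <- simulate_annotation(species_spec(n_genes = 1000L,
                                          ortholog_fraction = 0.7,
                                          seed = 17L))
  expect_equal(sim$manifest$n_ortholog, 700L)
  f <- tempfile(fileext = ".tab.gz"); f2 <- tempfile(fileext = ".tab.gz")
  simulate_ortholog_tables(list(sim$manifest), level = 7742,
                           og2genes_path = f, xrefs_path = f2)
  tab <- parse_orthodb_tables(f, f2, level = 7742)
  part <- partition_annotation(sim$annotation, tab)
  truth <- sim$manifest$genes
  expect_setequal(part$ortholog_gene_ids,
                  truth$gene_id[truth$class == "ortholog"])
  expect_equal(length(part$ortholog_gene_ids) /
                 (length(part$ortholog_gene_ids) + length(part$novel_gene_ids)),
               0.7)
})

test_that("whole-annotation metrics equal the disjoint union of subset metrics", {
  sim <- simulate_annotation(species_spec(n_genes = 120L, seed = 23L))
  f <- tempfile(fileext = ".tab"); f2 <- tempfile(fileext = ".tab")
  simulate_ortholog_tables(list(sim$manifest), level = 7742,
                           og2genes_path = f, xrefs_path = f2)
  part <- partition_annotation(sim$annotation,
                               parse_orthodb_tables(f, f2, 7742))
  cw <- compute_complexity(part$whole)
  co <- compute_complexity(part$ortholog_subset)
  cn <- compute_complexity(part$novel_subset)
  whole_g <- as.data.frame(cw$genes)
  union_g <- rbind(as.data.frame(co$genes), as.data.frame(cn$genes))
  whole_g <- whole_g[order(whole_g$gene_id), ]
  union_g <- union_g[order(union_g$gene_id), ]
  expect_equal(whole_g, union_g, ignore_attr = TRUE)
})

test_that("novel genes generated with fewer exons show lower mean EpT", {
  sim <- simulate_annotation(species_spec(
    n_genes = 500L, ept_mean = 6, novel_ept_mean = 2, seed = 29L))
  f <- tempfile(fileext = ".tab"); f2 <- tempfile(fileext = ".tab")
  simulate_ortholog_tables(list(sim$manifest), level = 7742,
                           og2genes_path = f, xrefs_path = f2)
  part <- partition_annotation(sim$annotation,
                               parse_orthodb_tables(f, f2, 7742))
  co <- compute_complexity(part$ortholog_subset)
  cn <- compute_complexity(part$novel_subset)
  expect_gt(co$mean_EpT, cn$mean_EpT)
})
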