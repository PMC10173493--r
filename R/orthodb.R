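.read_tab_lines <- function(path, ncol, what) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != ncol))
    stop(sprintf("malformed %s row at line %d: expected %d tab-delimited fields, got %d",
                 what, lineno[which(nf != ncol)[1L]], ncol, nf[nf != ncol][1L]))
  matrix(unlist(fields), ncol = ncol, byrow = TRUE)
}

#' Parse OrthoDB-format ortholog tables at one taxonomic level
#'
#' Reads the two OrthoDB v10-schema flat files — `OG2genes` (ortholog group id,
#' OrthoDB gene id) and `gene_xrefs` (OrthoDB gene id, external id, external
#' database name) — keeping only ortholog groups at the requested taxonomic
#' level (the level taxon id is encoded in the OG id after `"at"`, e.g.
#' `"1234at2759"`), and only cross-references in the requested namespace
#' (default `"NCBIgid"`, the NCBI GeneID namespace). A gene with several
#' retained cross-references keeps all of them (1:Multiple orthologs).
#'
#' @param og2genes_path path to the OG2genes table (optionally gzipped).
#' @param xrefs_path path to the gene_xrefs table (optionally gzipped).
#' @param level taxonomic level id (the MRCA node) whose ortholog groups to
#'   retain.
#' @param xref_namespace external database name to keep (default `"NCBIgid"`).
#' @param schema `"v10"` (default) or `"v9"`; the v9 schema tolerates the
#'   OG2genes column order being (gene, OG).
#' @return Object of class `ortholog_table` with elements `og_to_genes`
#'   (data.frame og_id, odb_gene_id), `xrefs` (data.frame odb_gene_id,
#'   xref_id) and `level`.
#' @export
parse_orthodb_tables <- function(og2genes_path, xrefs_path, level,
                                 xref_namespace = "NCBIgid",
                                 schema = c("v10", "v9")) {
  schema <- match.arg(schema)
  m <- .read_tab_lines(og2genes_path, 2L, "OG2genes")
  og <- data.table(og_id = m[, if (schema == "v10") 1L else 2L],
                   odb_gene_id = m[, if (schema == "v10") 2L else 1L])
  og[, og_level := sub("^.*at", "", og_id)]
  og <- og[og_level == as.character(level)][, og_level := NULL]
  if (!nrow(og))
    stop("no ortholog groups at level ", level)
  m <- .read_tab_lines(xrefs_path, 3L, "gene_xrefs")
  xr <- data.table(odb_gene_id = m[, 1L], xref_id = m[, 2L],
                   namespace = m[, 3L])
  xr <- unique(xr[namespace == xref_namespace,
                  .(odb_gene_id, xref_id)])
  structure(list(og_to_genes = as.data.frame(unique(og)),
                 xrefs = as.data.frame(xr),
                 level = as.character(level),
                 xref_namespace = xref_namespace),
            class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("ortholog_table at level %s: %d OGs, %d OrthoDB genes, %d %s xrefs\n",
              x$level, length(unique(x$og_to_genes$og_id)),
              length(unique(x$og_to_genes$odb_gene_id)),
              nrow(x$xrefs), x$xref_namespace))
  invisible(x)
}

#' Partition an annotation into ortholog and novel gene sets
#'
#' A gene is classified *ortholog* when its NCBI GeneID cross-reference
#' resolves (through the gene_xrefs table) to an OrthoDB gene that belongs to
#' at least one ortholog group retained at the table's taxonomic level;
#' otherwise it is *novel* (lineage-specific at that level). Genes whose
#' GeneID is absent from the xref file are classified novel, not dropped.
#' The partition yields three annotations — the whole transcriptome and the
#' two disjoint subsets — each preserving the parent's transcript/exon
#' structure per gene exactly.
#'
#' @param annotation an [annotation_set()] whose genes carry `ncbi_gene_id`
#'   cross-references (RefSeq dialect, or a generic id map).
#' @param table an [parse_orthodb_tables()] result.
#' @return Object of class `partition_result` with `ortholog_gene_ids`,
#'   `novel_gene_ids`, `whole`, `ortholog_subset`, `novel_subset` and a
#'   per-gene `manifest` data.frame (gene_id, ncbi_gene_id, class, og_ids).
#' @export
partition_annotation <- function(annotation, table) {
  stopifnot(inherits(annotation, "annotation_set"),
            inherits(table, "ortholog_table"))
  xr <- annotation$gene_xref
  if (all(is.na(xr$ncbi_gene_id)))
    stop("no gene in the annotation carries an external gene id; ",
         "re-parse with dialect = 'refseq' or supply an id_map")
  og <- as.data.table(table$og_to_genes)
  xrefs <- as.data.table(table$xrefs)
  # external ids reachable from any retained OG
  in_og <- xrefs[odb_gene_id %in% og$odb_gene_id]
  ortho_ext <- unique(in_og$xref_id)
  cls <- data.table(gene_id = xr$gene_id, ncbi_gene_id = xr$ncbi_gene_id)
  cls[, class := fifelse(!is.na(ncbi_gene_id) & ncbi_gene_id %in% ortho_ext,
                         "ortholog", "novel")]
  # OG membership per gene, for the manifest
  ext2og <- merge(in_og, og, by = "odb_gene_id",
                  allow.cartesian = TRUE)[, .(og_ids = paste(sort(unique(og_id)),
                                                            collapse = ",")),
                                          by = .(ncbi_gene_id = xref_id)]
  cls <- merge(cls, ext2og, by = "ncbi_gene_id", all.x = TRUE, sort = FALSE)
  cls[is.na(og_ids), og_ids := ""]
  setcolorder(cls, c("gene_id", "ncbi_gene_id", "class", "og_ids"))
  ortho_ids <- cls[class == "ortholog", gene_id]
  novel_ids <- cls[class == "novel", gene_id]
  structure(list(
    ortholog_gene_ids = ortho_ids,
    novel_gene_ids = novel_ids,
    whole = annotation,
    ortholog_subset = subset_annotation(
      annotation, ortho_ids,
      species_label = paste0(annotation$species_label, "_ortholog")),
    novel_subset = subset_annotation(
      annotation, novel_ids,
      species_label = paste0(annotation$species_label, "_novel")),
    manifest = as.data.frame(cls)),
    class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  n <- length(x$ortholog_gene_ids) + length(x$novel_gene_ids)
  cat(sprintf("partition_result '%s': %d genes -> %d ortholog, %d novel\n",
              x$whole$species_label, n, length(x$ortholog_gene_ids),
              length(x$novel_gene_ids)))
  invisible(x)
}
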