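#' @import data.table
#' @importFrom stats p.adjust pchisq cor.test kruskal.test shapiro.test
#'   wilcox.test quantile median rbinom rexp rgamma rgeom rlnorm rpois runif
#'   sd setNames
#' @importFrom utils head
NULL

.open_text <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Construct an annotation set
#'
#' An `annotation_set` is the in-memory gene/transcript/exon model the rest of
#' the package operates on: a flat exon table plus a gene-level cross-reference
#' table. Coordinates are 1-based inclusive (GTF convention), so an exon's
#' length is `end - start + 1`.
#'
#' @param exons data.frame with columns `seqid`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`; one row per exon. Duplicated exon rows within
#'   a transcript are collapsed with a warning (annotation artifact, not
#'   complexity).
#' @param species_label character scalar naming the species/annotation.
#' @param dialect one of `"refseq"`, `"flybase"`, `"generic"`; records where
#'   the NCBI GeneID cross-reference came from.
#' @param gene_xref optional data.frame with columns `gene_id`,
#'   `ncbi_gene_id` (NA allowed) used for ortholog matching.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(exons, species_label = "unknown",
                           dialect = c("generic", "refseq", "flybase"),
                           gene_xref = NULL) {
  dialect <- match.arg(dialect)
  ex <- as.data.table(exons)
  req <- c("seqid", "start", "end", "strand", "gene_id", "transcript_id")
  miss <- setdiff(req, names(ex))
  if (length(miss))
    stop("exon table lacks column(s): ", paste(miss, collapse = ", "))
  ex <- ex[, req, with = FALSE]
  ex[, `:=`(seqid = as.character(seqid), strand = as.character(strand),
            gene_id = as.character(gene_id),
            transcript_id = as.character(transcript_id),
            start = as.integer(start), end = as.integer(end))]
  if (nrow(ex)) {
    if (any(ex$start < 1L)) stop("exon with start < 1")
    if (any(ex$end < ex$start)) stop("exon with end < start")
    if (!all(ex$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
    ndup <- nrow(ex) - nrow(unique(ex))
    if (ndup > 0L) {
      warning(sprintf("collapsed %d duplicated exon row(s) within transcripts",
                      ndup))
      ex <- unique(ex)
    }
    # a transcript belongs to exactly one gene, one seqid, one strand
    chk <- ex[, .(ng = uniqueN(gene_id), ns = uniqueN(seqid),
                  nstr = uniqueN(strand)), by = transcript_id]
    bad <- chk[ns > 1L | nstr > 1L, transcript_id]
    if (length(bad))
      stop("transcript(s) with exons on multiple seqids or strands: ",
           paste(head(bad, 5L), collapse = ", "))
    bad <- chk[ng > 1L, transcript_id]
    if (length(bad))
      stop("transcript(s) assigned to multiple genes: ",
           paste(head(bad, 5L), collapse = ", "))
    # exons within one transcript must not overlap one another
    setorder(ex, gene_id, transcript_id, start, end)
    ov <- ex[, .(bad = any(start[-1L] <= cummax(end)[-.N])), by = transcript_id]
    bad <- ov[bad == TRUE, transcript_id]
    if (length(bad))
      stop("transcript(s) with internally overlapping exons: ",
           paste(head(bad, 5L), collapse = ", "))
  }
  if (is.null(gene_xref)) {
    gene_xref <- data.table(gene_id = unique(ex$gene_id),
                            ncbi_gene_id = NA_character_)
  } else {
    gene_xref <- as.data.table(gene_xref)[, .(
      gene_id = as.character(gene_id),
      ncbi_gene_id = as.character(ncbi_gene_id))]
    gene_xref <- unique(gene_xref, by = "gene_id")
    gene_xref <- gene_xref[gene_id %in% unique(ex$gene_id)]
    extra <- setdiff(unique(ex$gene_id), gene_xref$gene_id)
    if (length(extra))
      gene_xref <- rbind(gene_xref,
                         data.table(gene_id = extra,
                                    ncbi_gene_id = NA_character_))
  }
  structure(list(species_label = species_label, dialect = dialect,
                 exons = ex[], gene_xref = gene_xref[]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set '%s' (dialect: %s)\n", x$species_label,
              x$dialect))
  cat(sprintf("  %d genes, %d transcripts, %d exon rows on %d sequence(s)\n",
              uniqueN(x$exons$gene_id), uniqueN(x$exons$transcript_id),
              nrow(x$exons), uniqueN(x$exons$seqid)))
  invisible(x)
}

.attr_value <- function(attrs, key) {
  # first value of `key "value"` in a GTF attribute column; NA when absent
  pat <- sprintf('%s "([^"]*)"', key)
  m <- regexpr(pat, attrs)
  out <- rep(NA_character_, length(attrs))
  hit <- m > 0L
  out[hit] <- sub(pat, "\\1", regmatches(attrs, m))
  out
}

#' Parse a GTF annotation into an annotation set
#'
#' Reads a (optionally gzipped) GTF file and assembles the exon features into
#' the validated gene -> transcript -> exon model. Only `exon` feature rows
#' define transcript structure; CDS/UTR/gene rows are ignored. The RefSeq
#' dialect harvests NCBI GeneID cross-references from `db_xref "GeneID:..."`
#' attributes; the FlyBase dialect uses `gene_id` itself as the external id;
#' the generic dialect takes an explicit `id_map`.
#'
#' @param path path to a GTF file (gzip transparently supported).
#' @param dialect one of `"refseq"`, `"flybase"`, `"generic"`.
#' @param species_label label stored on the result; defaults to the file name.
#' @param id_map for `dialect = "generic"`: named character vector mapping
#'   `gene_id` to an external gene identifier, or NULL.
#' @return An [annotation_set()].
#' @export
parse_gtf <- function(path, dialect = c("refseq", "flybase", "generic"),
                      species_label = basename(path), id_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(annotation_set(
      data.frame(seqid = character(), start = integer(), end = integer(),
                 strand = character(), gene_id = character(),
                 transcript_id = character()),
      species_label = species_label, dialect = dialect))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop(sprintf("malformed GTF line %d: expected 9 tab-delimited fields, got %d",
                 lineno[which(nf != 9L)[1L]], nf[nf != 9L][1L]))
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_exon <- m[, 3L] == "exon"
  if (!any(is_exon))
    return(annotation_set(
      data.frame(seqid = character(), start = integer(), end = integer(),
                 strand = character(), gene_id = character(),
                 transcript_id = character()),
      species_label = species_label, dialect = dialect))
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]
  attrs <- m[, 9L]
  gene_id <- .attr_value(attrs, "gene_id")
  transcript_id <- .attr_value(attrs, "transcript_id")
  if (anyNA(transcript_id))
    stop(sprintf("exon without transcript_id at line %d",
                 lineno[which(is.na(transcript_id))[1L]]))
  if (anyNA(gene_id))
    stop(sprintf("exon without gene_id at line %d",
                 lineno[which(is.na(gene_id))[1L]]))
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("non-numeric coordinate at line %d",
                 lineno[which(is.na(start) | is.na(end))[1L]]))
  ex <- data.table(seqid = m[, 1L], start = start, end = end,
                   strand = m[, 7L], gene_id = gene_id,
                   transcript_id = transcript_id)
  xref <- switch(dialect,
    refseq = {
      # RefSeq may carry several db_xref keys; take the GeneID one
      all_x <- regmatches(attrs, gregexpr('db_xref "GeneID:([0-9]+)"', attrs))
      gid <- vapply(all_x, function(v)
        if (length(v)) sub('db_xref "GeneID:([0-9]+)"', "\\1", v[1L])
        else NA_character_, "")
      unique(data.table(gene_id = gene_id, ncbi_gene_id = gid))[
        , .(ncbi_gene_id = ncbi_gene_id[which(!is.na(ncbi_gene_id))[1L]]),
        by = gene_id]
    },
    flybase = data.table(gene_id = unique(gene_id),
                         ncbi_gene_id = unique(gene_id)),
    generic = {
      g <- unique(gene_id)
      data.table(gene_id = g,
                 ncbi_gene_id = if (is.null(id_map)) NA_character_
                                else unname(id_map[g]))
    })
  annotation_set(ex, species_label = species_label, dialect = dialect,
                 gene_xref = xref)
}

#' Write an annotation set as GTF
#'
#' Emits one `exon` feature row per exon, preserving coordinates, strand,
#' `gene_id` and `transcript_id`, plus a `db_xref "GeneID:..."` attribute where
#' a cross-reference is known. `parse_gtf(write_gtf(a))` reproduces `a`'s
#' metric-relevant content exactly. An empty annotation yields a header-only
#' file.
#'
#' @param annotation an [annotation_set()].
#' @param path output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  ex <- annotation$exons
  con <- .open_text(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("#!annotation %s", annotation$species_label), con)
  if (!nrow(ex)) return(invisible(path))
  xr <- setNames(annotation$gene_xref$ncbi_gene_id,
                 annotation$gene_xref$gene_id)
  gid <- xr[ex$gene_id]
  attr9 <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                   ex$gene_id, ex$transcript_id,
                   ifelse(is.na(gid), "",
                          sprintf(' db_xref "GeneID:%s";', gid)))
  writeLines(paste(ex$seqid, "txcomplexity", "exon", ex$start, ex$end,
                   ".", ex$strand, ".", attr9, sep = "\t"), con)
  invisible(path)
}

#' Subset an annotation set by gene
#'
#' Keeps exactly the listed genes, preserving each retained gene's
#' transcript/exon structure and cross-references unchanged.
#'
#' @param annotation an [annotation_set()].
#' @param gene_ids character vector of gene ids to retain.
#' @param species_label optional new label for the subset.
#' @return An [annotation_set()].
#' @export
subset_annotation <- function(annotation, gene_ids,
                              species_label = annotation$species_label) {
  stopifnot(inherits(annotation, "annotation_set"))
  ex <- annotation$exons[gene_id %in% gene_ids]
  xr <- annotation$gene_xref[gene_id %in% gene_ids]
  annotation_set(ex, species_label = species_label,
                 dialect = annotation$dialect, gene_xref = xr)
}
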