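#' Compute per-gene and per-transcript complexity metrics
#'
#' Quantifies transcript-model complexity of one annotation with three
#' metrics:
#' \describe{
#'   \item{TpG}{transcripts per gene — number of annotated isoforms.}
#'   \item{EpT}{exons per transcript — number of exon features in one
#'     transcript.}
#'   \item{EpG}{exons per gene — number of distinct exon coordinate
#'     intervals (seqid, start, end, strand) in the union over the gene's
#'     transcripts.}
#' }
#' Species-level means average TpG and EpG over genes and EpT over
#' transcripts. The inter-gene transcript overlap fraction (see
#' [transcript_overlap_fraction()]) is computed alongside.
#'
#' @param annotation an [annotation_set()] with at least one gene.
#' @return An object of class `species_complexity`: list with `genes`
#'   (gene_id, TpG, EpG), `transcripts` (transcript_id, gene_id, EpT),
#'   the species means, counts and `overlap_fraction`.
#' @export
compute_complexity <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  ex <- annotation$exons
  if (!nrow(ex)) stop("no genes in annotation")
  tr <- ex[, .(gene_id = gene_id[1L], EpT = .N), by = transcript_id]
  ge <- ex[, .(TpG = uniqueN(transcript_id),
               EpG = uniqueN(paste(seqid, start, end, strand))),
           by = gene_id]
  structure(list(
    species_label = annotation$species_label,
    genes = ge[],
    transcripts = tr[, .(transcript_id, gene_id, EpT)],
    n_genes = nrow(ge),
    n_transcripts = nrow(tr),
    mean_TpG = mean(ge$TpG),
    mean_EpT = mean(tr$EpT),
    mean_EpG = mean(ge$EpG),
    overlap_fraction = transcript_overlap_fraction(annotation)),
    class = "species_complexity")
}

#' @export
print.species_complexity <- function(x, ...) {
  cat(sprintf("species_complexity '%s'\n", x$species_label))
  cat(sprintf("  genes: %d  transcripts: %d\n", x$n_genes, x$n_transcripts))
  cat(sprintf("  mean TpG %.3f  mean EpT %.3f  mean EpG %.3f\n",
              x$mean_TpG, x$mean_EpT, x$mean_EpG))
  cat(sprintf("  inter-gene transcript overlap: %.4f\n", x$overlap_fraction))
  invisible(x)
}

#' @export
summary.species_complexity <- function(object, ...) {
  out <- data.frame(
    metric = c("TpG", "EpT", "EpG"),
    mean = c(object$mean_TpG, object$mean_EpT, object$mean_EpG),
    median = c(median(object$genes$TpG), median(object$transcripts$EpT),
               median(object$genes$EpG)),
    max = c(max(object$genes$TpG), max(object$transcripts$EpT),
            max(object$genes$EpG)))
  out
}

#' @export
plot.species_complexity <- function(x, max_N = 30L, ...) {
  ept <- pmin(x$transcripts$EpT, max_N)
  graphics::hist(ept, breaks = seq(0.5, max_N + 0.5, by = 1), main =
                   sprintf("%s: EpT (truncated at %d)", x$species_label, max_N),
                 xlab = "Exons per transcript", ...)
  invisible(x)
}

.transcript_spans <- function(ex) {
  ex[, .(gene_id = gene_id[1L], seqid = seqid[1L],
         span_start = min(start), span_end = max(end)),
     by = transcript_id]
}

#' Inter-gene transcript overlap fraction
#'
#' Fraction of transcripts whose genomic extent overlaps (by at least one
#' nucleotide, strand-agnostically) the extent of a transcript belonging to a
#' *different* gene on the same sequence. The default compares transcript
#' spans (min exon start to max exon end); `level = "exon"` instead requires
#' an exon of one transcript to overlap an exon of the foreign transcript.
#' Overlap is symmetric: both members of an overlapping pair count.
#'
#' @param annotation an [annotation_set()].
#' @param level `"span"` (default) or `"exon"`.
#' @return A single number in \[0, 1\].
#' @export
transcript_overlap_fraction <- function(annotation,
                                        level = c("span", "exon")) {
  stopifnot(inherits(annotation, "annotation_set"))
  level <- match.arg(level)
  ex <- annotation$exons
  if (!nrow(ex)) stop("no genes in annotation")
  if (level == "span") {
    feats <- .transcript_spans(ex)
    setnames(feats, c("span_start", "span_end"), c("start", "end"))
  } else {
    feats <- ex[, .(transcript_id, gene_id, seqid, start, end)]
  }
  n_tr <- uniqueN(ex$transcript_id)
  hit_tr <- character(0)
  for (sq in unique(feats$seqid)) {
    f <- feats[seqid == sq]
    ir <- IRanges::IRanges(start = f$start, end = f$end)
    h <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
    keep <- f$gene_id[qh] != f$gene_id[sh]
    if (any(keep))
      hit_tr <- c(hit_tr, unique(f$transcript_id[unique(qh[keep])]))
  }
  length(unique(hit_tr)) / n_tr
}

#' Merge species summaries into a long grouped table
#'
#' Consolidates species-level complexity summaries into one long-format table
#' `(species, group, metric, value)` of species means, the shape downstream
#' cross-species statistics (Kruskal–Wallis across clades, correlations)
#' consume.
#'
#' @param summaries list of `species_complexity` objects.
#' @param group_labels named character vector mapping `species_label` to a
#'   group (clade) label; every species must be assigned to exactly one group.
#' @return data.frame with columns species, group, metric, value.
#' @export
merge_species <- function(summaries, group_labels) {
  stopifnot(length(summaries) >= 1L)
  labs <- vapply(summaries, function(s) s$species_label, "")
  missing_grp <- labs[!labs %in% names(group_labels)]
  if (length(missing_grp))
    stop("species without group label: ", paste(missing_grp, collapse = ", "))
  out <- rbindlist(lapply(summaries, function(s) {
    data.table(species = s$species_label,
               group = unname(group_labels[s$species_label]),
               metric = c("TpG", "EpT", "EpG"),
               value = c(s$mean_TpG, s$mean_EpT, s$mean_EpG))
  }))
  as.data.frame(out)
}
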