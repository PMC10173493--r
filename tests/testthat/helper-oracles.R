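# Independent brute-force oracles: naive set-based counting, no shared code
# with the package internals.

brute_force_complexity <- function(ann) {
  ex <- as.data.frame(ann$exons)
  genes <- sort(unique(ex$gene_id))
  tpg <- integer(0); epg <- integer(0)
  tx_ids <- character(0); ept <- integer(0)
  for (g in genes) {
    sub <- ex[ex$gene_id == g, , drop = FALSE]
    txs <- sort(unique(sub$transcript_id))
    tpg <- c(tpg, length(txs))
    keys <- character(0)
    for (i in seq_len(nrow(sub)))
      keys <- union(keys, paste(sub$seqid[i], sub$start[i], sub$end[i],
                                sub$strand[i]))
    epg <- c(epg, length(keys))
    for (t in txs) {
      tx_ids <- c(tx_ids, t)
      ept <- c(ept, sum(sub$transcript_id == t))
    }
  }
  list(genes = data.frame(gene_id = genes, TpG = tpg, EpG = epg),
       transcripts = data.frame(transcript_id = tx_ids, EpT = ept))
}

# Exact two-sided Wilcoxon rank-sum p-value by exhaustive enumeration of all
# choose(n+m, n) assignments of the pooled ranks to sample A.
enumerate_wilcoxon_p <- function(a, b) {
  n <- length(a); m <- length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Tiny literal GTF writer for parser tests.
write_lines_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon_line <- function(seqid, start, end, strand, gene, tx,
                          extra_attr = "") {
  sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
          seqid, start, end, strand, gene, tx, extra_attr)
}
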