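.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full per-species analysis
#'
#' Executes the per-organism workflow: parse (or accept) an annotation,
#' optionally partition it into ortholog/novel subsets from OrthoDB-format
#' tables, compute complexity metrics for the whole transcriptome and each
#' subset, and compute per-transcript EEN records with a binned profile
#' against the Broken Stick null. When ortholog tables are not supplied the
#' partition stage is skipped and whole-transcriptome outputs are produced
#' alone. With `out_dir` set, per-stage TSVs, the three GTFs and a JSON
#' manifest (echoed configuration, seeds, package version) are written.
#'
#' @param gtf path to a GTF file, or an [annotation_set()] directly.
#' @param dialect GTF dialect when `gtf` is a path (see [parse_gtf()]).
#' @param og2genes,xrefs,level optional OrthoDB table paths and taxonomic
#'   level; all three must be given to run the partition stage.
#' @param group group (clade) label carried into cross-species analysis.
#' @param null_reps,max_N,seed Broken Stick null replicates per N, profile
#'   truncation, and seed.
#' @param out_dir optional output directory (created if needed).
#' @return Object of class `species_bundle`: list with `annotation`,
#'   `partition` (or NULL), `complexity` (named list whole/ortholog/novel of
#'   `species_complexity`), `een` (records), `profiles` (named list of
#'   `een_profile`), and `manifest`.
#' @export
run_species <- function(gtf, dialect = "refseq", og2genes = NULL,
                        xrefs = NULL, level = NULL, group = NA_character_,
                        null_reps = 1e5, max_N = 30L, seed = 1L,
                        out_dir = NULL) {
  ann <- if (inherits(gtf, "annotation_set")) gtf
         else parse_gtf(gtf, dialect = dialect)
  part <- NULL
  if (!is.null(og2genes) && !is.null(xrefs) && !is.null(level)) {
    tab <- parse_orthodb_tables(og2genes, xrefs, level)
    part <- partition_annotation(ann, tab)
  }
  cx <- list(whole = compute_complexity(ann))
  if (!is.null(part)) {
    if (length(part$ortholog_gene_ids))
      cx$ortholog <- compute_complexity(part$ortholog_subset)
    if (length(part$novel_gene_ids))
      cx$novel <- compute_complexity(part$novel_subset)
  }
  rec <- een_records(ann)
  null <- broken_stick_null(N_range = 1:max_N, replicates = null_reps,
                            seed = seed)
  profiles <- list(whole = een_profile(rec, max_N = max_N, null = null))
  if (!is.null(part) && length(part$ortholog_gene_ids)) {
    rec_o <- rec[rec$gene_id %in% part$ortholog_gene_ids, , drop = FALSE]
    if (nrow(rec_o))
      profiles$ortholog <- een_profile(rec_o, max_N = max_N, null = null)
  }
  manifest <- list(species_label = ann$species_label, group = group,
                   dialect = ann$dialect, level = level,
                   null_reps = null_reps, max_N = max_N, seed = seed,
                   n_genes = cx$whole$n_genes,
                   n_transcripts = cx$whole$n_transcripts,
                   package_version = as.character(utils::packageVersion("txcomplexity")))
  bundle <- structure(list(annotation = ann, partition = part,
                           complexity = cx, een = rec, profiles = profiles,
                           null = null, manifest = manifest),
                      class = "species_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    .write_tsv(cx$whole$genes, p("genes.tsv"))
    .write_tsv(cx$whole$transcripts, p("transcripts.tsv"))
    .write_tsv(rec, p("een.tsv"))
    .write_tsv(profiles$whole$table, p("een_profile.tsv"))
    write_gtf(ann, p("whole.gtf"))
    if (!is.null(part)) {
      write_gtf(part$ortholog_subset, p("ortholog.gtf"))
      write_gtf(part$novel_subset, p("novel.gtf"))
      .write_tsv(part$manifest, p("partition_manifest.tsv"))
    }
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         null = "null")
  }
  bundle
}

#' @export
print.species_bundle <- function(x, ...) {
  cat(sprintf("species_bundle '%s'%s\n", x$manifest$species_label,
              if (is.null(x$partition)) " (no partition)" else ""))
  print(x$complexity$whole)
  invisible(x)
}

#' Cross-species clade analysis
#'
#' Runs the cross-species statistical battery over a set of per-species
#' bundles: a merged long table of species-level means; per species and
#' metric, the whole-vs-ortholog Wilcoxon rank-sum comparison with Bonferroni
#' adjustment over the full species-by-metric family; Kruskal-Wallis across
#' groups per metric (skipped with a logged reason when fewer than two groups
#' are present); pairwise correlations among metric means with the
#' Shapiro-Wilk normality gate; Fisher's combined probability per metric over
#' the per-species (unadjusted) Wilcoxon p-values; and resampling
#' cross-validation of each Wilcoxon conclusion. Species without a partition
#' stage contribute to the merged table and Kruskal-Wallis only.
#'
#' @param bundles list of `species_bundle` objects (see [run_species()]).
#' @param alpha significance level (default 0.05).
#' @param jackknife_reps resampling replicates per validation (default 10000).
#' @param seed integer seed for the resampling stage.
#' @param out_dir optional output directory for TSV tables and a JSON
#'   summary.
#' @return Object of class `clade_report`: list of data.frames `merged`,
#'   `wilcoxon`, `kruskal`, `correlations`, `fisher`, `jackknife`, plus
#'   `skipped` (named character of skipped tests) and `settings`.
#' @export
run_group <- function(bundles, alpha = 0.05, jackknife_reps = 10000L,
                      seed = 1L, out_dir = NULL) {
  stopifnot(length(bundles) >= 1L)
  labs <- vapply(bundles, function(b) b$manifest$species_label, "")
  groups <- vapply(bundles, function(b)
    if (is.na(b$manifest$group)) "ungrouped" else b$manifest$group, "")
  merged <- merge_species(lapply(bundles, function(b) b$complexity$whole),
                          setNames(groups, labs))
  skipped <- character(0)

  metric_values <- function(cx, metric) switch(metric,
    TpG = cx$genes$TpG, EpG = cx$genes$EpG, EpT = cx$transcripts$EpT)

  # whole vs ortholog per species x metric, one Bonferroni family
  has_part <- !vapply(bundles, function(b) is.null(b$partition), TRUE) &
    vapply(bundles, function(b) !is.null(b$complexity$ortholog), TRUE)
  fam <- sum(has_part) * 3L
  wil_rows <- list(); jk_rows <- list()
  for (i in which(has_part)) {
    b <- bundles[[i]]
    for (metric in c("TpG", "EpT", "EpG")) {
      w <- metric_values(b$complexity$whole, metric)
      o <- metric_values(b$complexity$ortholog, metric)
      tst <- wilcoxon_compare(w, o, bonferroni_m = fam)
      wil_rows[[length(wil_rows) + 1L]] <- data.frame(
        species = labs[i], metric = metric, W = tst$statistic,
        p = tst$p_value, p_bonferroni = tst$p_adjusted,
        significant = tst$p_adjusted < alpha,
        n_whole = tst$n[1L], n_ortholog = tst$n[2L])
      jk <- jackknife_validate(w, o, replicates = jackknife_reps,
                               seed = seed + i, wilcoxon_p = tst$p_value,
                               alpha = alpha)
      jk_rows[[length(jk_rows) + 1L]] <- data.frame(
        species = labs[i], metric = metric, subset_mean = jk$statistic,
        quantile = jk$metadata$quantile, p_empirical = jk$p_value,
        validates = jk$metadata$validates)
    }
  }
  if (!any(has_part))
    skipped["wilcoxon"] <- "no species has an ortholog partition"

  # Kruskal-Wallis across groups per metric (species-level means)
  kw_rows <- list()
  if (length(unique(groups)) >= 2L) {
    for (metric in c("TpG", "EpT", "EpG")) {
      mm <- merged[merged$metric == metric, ]
      tst <- kruskal_groups(split(mm$value, mm$group))
      kw_rows[[length(kw_rows) + 1L]] <- data.frame(
        metric = metric, chi_squared = tst$statistic, df = tst$metadata$df,
        p = tst$p_value)
    }
  } else {
    skipped["kruskal"] <- "fewer than 2 groups"
  }

  # correlations among species-level metric means
  cor_rows <- list()
  if (length(bundles) >= 3L) {
    wide <- data.frame(
      TpG = vapply(bundles, function(b) b$complexity$whole$mean_TpG, 0),
      EpT = vapply(bundles, function(b) b$complexity$whole$mean_EpT, 0),
      EpG = vapply(bundles, function(b) b$complexity$whole$mean_EpG, 0))
    for (pair in list(c("TpG", "EpT"), c("TpG", "EpG"), c("EpT", "EpG"))) {
      tst <- correlation_with_normality_gate(wide[[pair[1L]]],
                                             wide[[pair[2L]]], alpha = alpha)
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        metric_x = pair[1L], metric_y = pair[2L],
        branch = tst$metadata$branch, estimate = tst$statistic,
        r_squared = tst$metadata$r_squared %||% NA_real_, p = tst$p_value)
    }
  } else {
    skipped["correlations"] <- "fewer than 3 species"
  }

  # Fisher's combined probability per metric over per-species p-values
  fi_rows <- list()
  if (length(wil_rows)) {
    wdf <- do.call(rbind, wil_rows)
    for (metric in c("TpG", "EpT", "EpG")) {
      pv <- wdf$p[wdf$metric == metric]
      if (!length(pv)) next
      tst <- fisher_combined(pv, floor_p = 1e-300)
      fi_rows[[length(fi_rows) + 1L]] <- data.frame(
        metric = metric, X2 = tst$statistic, df = tst$metadata$df,
        p_combined = tst$p_value, n_tests = tst$n)
    }
  }

  report <- structure(list(
    merged = merged,
    wilcoxon = if (length(wil_rows)) do.call(rbind, wil_rows) else NULL,
    kruskal = if (length(kw_rows)) do.call(rbind, kw_rows) else NULL,
    correlations = if (length(cor_rows)) do.call(rbind, cor_rows) else NULL,
    fisher = if (length(fi_rows)) do.call(rbind, fi_rows) else NULL,
    jackknife = if (length(jk_rows)) do.call(rbind, jk_rows) else NULL,
    skipped = skipped,
    settings = list(alpha = alpha, bonferroni_family = fam,
                    jackknife_reps = jackknife_reps, seed = seed,
                    package_version =
                      as.character(utils::packageVersion("txcomplexity")))),
    class = "clade_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("merged", "wilcoxon", "kruskal", "correlations", "fisher",
                 "jackknife"))
      if (!is.null(report[[nm]]))
        .write_tsv(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    jsonlite::write_json(
      list(settings = report$settings, skipped = as.list(report$skipped)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, null = "null")
  }
  report
}

#' @export
print.clade_report <- function(x, ...) {
  cat(sprintf("clade_report: %d species, %d group(s)\n",
              length(unique(x$merged$species)),
              length(unique(x$merged$group))))
  if (!is.null(x$kruskal)) {
    cat("Kruskal-Wallis across groups:\n"); print(x$kruskal)
  }
  if (!is.null(x$wilcoxon))
    cat(sprintf("whole-vs-ortholog Wilcoxon: %d/%d significant at adjusted alpha\n",
                sum(x$wilcoxon$significant), nrow(x$wilcoxon)))
  if (!is.null(x$fisher)) { cat("Fisher combined per metric:\n"); print(x$fisher) }
  if (length(x$skipped))
    cat("skipped:", paste(names(x$skipped), x$skipped, sep = ": ",
                          collapse = "; "), "\n")
  invisible(x)
}
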