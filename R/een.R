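#' Effective Exon Number of an exon-length partition
#'
#' The Effective Exon Number (EEN) is the Simpson-type effective number of a
#' transcript's exon-length partition: with exon length proportions
#' \eqn{L_i = l_i / \sum_j l_j},
#' \deqn{EEN = 1 / \sum_i L_i^2 .}
#' EEN equals the exon count when all exons have equal length, and shrinks
#' toward 1 as lengths become skewed, so \eqn{0 < EEN \le EpT} always. Because
#' only proportions enter, EEN is invariant to the transcript's absolute
#' length.
#'
#' @param lengths numeric vector of positive exon lengths (nucleotides), one
#'   per exon.
#' @return A single number in `(0, length(lengths)]`.
#' @examples
#' een(c(100))            # 1
#' een(rep(120, 5))       # 5: equal exons
#' een(c(500, 250, 250))  # 8/3
#' @export
een <- function(lengths) {
  if (!length(lengths)) stop("no exon lengths")
  if (any(lengths <= 0)) stop("exon lengths must be positive")
  p <- lengths / sum(lengths)
  1 / sum(p^2)
}

#' Per-transcript EEN records for an annotation
#'
#' Computes, for every transcript, its exon count (EpT), mature length (sum of
#' exon lengths) and EEN.
#'
#' @param annotation an [annotation_set()].
#' @return data.frame with columns transcript_id, gene_id, EpT,
#'   mature_length, EEN.
#' @export
een_records <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  ex <- annotation$exons
  if (!nrow(ex)) stop("no genes in annotation")
  out <- ex[, {
    len <- end - start + 1L
    p <- len / sum(len)
    .(gene_id = gene_id[1L], EpT = .N,
      mature_length = sum(len), EEN = 1 / sum(p^2))
  }, by = transcript_id]
  as.data.frame(out)
}

#' Broken Stick null distribution of EEN
#'
#' Monte-Carlo null for EEN under uniformly random intron placement: a unit
#' interval is cut at N-1 breakpoints drawn simultaneously from a uniform
#' distribution, giving N fragments whose EEN is recorded per replicate.
#' Fragment lengths are sampled through the exact distributional identity
#' between uniform-spacing fragments and normalized independent Exp(1) draws
#' (a flat Dirichlet), which avoids per-replicate sorting.
#'
#' For reference, the fragment-evenness moment under this null is
#' \eqn{E[\sum L^2] = 2/(N+1)}, and the Monte-Carlo mean EEN exceeds
#' \eqn{(N+1)/2} by Jensen's inequality; \eqn{N = 1} gives EEN = 1 exactly.
#'
#' @param N_range integer vector of exon counts (all >= 1).
#' @param replicates Monte-Carlo replicates per N (default 1e5).
#' @param seed integer seed; recorded in the result.
#' @return Object of class `brokenstick_null`: a table with per-N mean EEN,
#'   its Monte-Carlo standard error, empirical 2.5/97.5% quantiles, and the
#'   mean and SE of the Simpson concentration `sum(L^2)`.
#' @export
broken_stick_null <- function(N_range = 1:30, replicates = 1e5, seed = 1L) {
  N_range <- as.integer(N_range)
  if (any(N_range < 1L)) stop("all N must be >= 1")
  if (replicates < 1L) stop("replicates must be >= 1")
  set.seed(seed)
  rows <- lapply(N_range, function(N) {
    if (N == 1L)
      return(data.table(N = 1L, mean_EEN = 1, se_EEN = 0, lo = 1, hi = 1,
                        mean_sumsq = 1, se_sumsq = 0))
    E <- matrix(rexp(replicates * N), nrow = replicates)
    L <- E / rowSums(E)
    ss <- rowSums(L^2)
    eenr <- 1 / ss
    q <- quantile(eenr, c(0.025, 0.975), names = FALSE)
    data.table(N = N, mean_EEN = mean(eenr),
               se_EEN = sd(eenr) / sqrt(replicates),
               lo = q[1L], hi = q[2L],
               mean_sumsq = mean(ss), se_sumsq = sd(ss) / sqrt(replicates))
  })
  structure(list(table = as.data.frame(rbindlist(rows)),
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "brokenstick_null")
}

#' @export
print.brokenstick_null <- function(x, ...) {
  cat(sprintf("brokenstick_null: N in [%d, %d], %d replicates, seed %d\n",
              min(x$table$N), max(x$table$N), x$replicates, x$seed))
  print(head(x$table, 8L))
  if (nrow(x$table) > 8L) cat("  ...\n")
  invisible(x)
}

.null_lookup <- function(null, N) {
  idx <- match(N, null$table$N)
  if (anyNA(idx))
    stop("broken-stick null lacks N = ",
         paste(N[is.na(idx)], collapse = ", "))
  null$table[idx, , drop = FALSE]
}

#' Binned EEN-vs-EpT profile with Broken Stick classification
#'
#' Groups per-transcript EEN records by exon count N (= EpT), reporting per
#' bin the mean EEN, its standard error (sample SD / sqrt(count)) and count,
#' and classifies each bin against the Broken Stick null: `"below"` when
#' mean + 2SE < null mean EEN(N), `"above"` when mean - 2SE > null mean, else
#' `"consistent"`. Bins with fewer than `min_count` transcripts are retained
#' but flagged unstable.
#'
#' @param records data.frame as from [een_records()] (needs columns EpT, EEN).
#' @param max_N truncate the profile at this exon count (default 30, the
#'   visualization convention for these profiles); `Inf` keeps all bins.
#' @param null a [broken_stick_null()] covering the profile's N values; one
#'   is computed (seed 1, 1e5 replicates) when NULL.
#' @param min_count bins below this count are flagged unstable (default 5).
#' @return Object of class `een_profile`: data.frame with N, mean_EEN, SE,
#'   count, null_mean, null_lo, null_hi, classification, unstable.
#' @export
een_profile <- function(records, max_N = 30L, null = NULL, min_count = 5L) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("no EEN records")
  stopifnot(all(c("EpT", "EEN") %in% names(records)))
  rec <- as.data.table(records)[EpT <= max_N]
  if (!nrow(rec)) stop("no records with EpT <= max_N")
  bins <- rec[, .(mean_EEN = mean(EEN),
                  SE = if (.N > 1L) sd(EEN) / sqrt(.N) else 0,
                  count = .N), by = .(N = EpT)]
  setorder(bins, N)
  if (is.null(null))
    null <- broken_stick_null(N_range = bins$N, replicates = 1e5, seed = 1L)
  nt <- .null_lookup(null, bins$N)
  bins[, `:=`(null_mean = nt$mean_EEN, null_lo = nt$lo, null_hi = nt$hi)]
  bins[, classification := fifelse(mean_EEN + 2 * SE < null_mean, "below",
                            fifelse(mean_EEN - 2 * SE > null_mean, "above",
                                    "consistent"))]
  bins[, unstable := count < min_count]
  structure(list(table = as.data.frame(bins),
                 null_replicates = null$replicates, null_seed = null$seed),
            class = "een_profile")
}

#' @export
print.een_profile <- function(x, ...) {
  cat(sprintf("een_profile: %d bins (null: %d replicates, seed %d)\n",
              nrow(x$table), x$null_replicates, x$null_seed))
  cls <- table(x$table$classification)
  cat("  classification: ",
      paste(sprintf("%s %d", names(cls), cls), collapse = ", "), "\n")
  print(head(x$table, 8L))
  if (nrow(x$table) > 8L) cat("  ...\n")
  invisible(x)
}

#' @export
plot.een_profile <- function(x, ...) {
  tb <- x$table
  ylim <- range(c(tb$mean_EEN - 2 * tb$SE, tb$mean_EEN + 2 * tb$SE,
                  tb$null_mean))
  plot(tb$N, tb$mean_EEN, pch = 19, ylim = ylim,
       xlab = "Exons per transcript (N)", ylab = "Mean EEN ± 2SE", ...)
  graphics::arrows(tb$N, tb$mean_EEN - 2 * tb$SE, tb$N,
                   tb$mean_EEN + 2 * tb$SE, angle = 90, code = 3,
                   length = 0.02)
  graphics::lines(tb$N, tb$null_mean, col = "red", lwd = 2)
  graphics::legend("topleft", legend = c("observed", "Broken Stick null"),
                   pch = c(19, NA), lty = c(NA, 1), col = c("black", "red"),
                   bty = "n")
  invisible(x)
}
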