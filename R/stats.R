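.txc_test <- function(test_name, statistic, p_value, n,
                      p_adjusted = NA_real_, metadata = list()) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), p_adjusted = p_adjusted,
                 n = n, metadata = metadata),
            class = "txc_test")
}

#' @export
print.txc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$test_name, x$statistic,
              x$p_value))
  if (!is.na(x$p_adjusted)) cat(sprintf(" (adjusted %.4g)", x$p_adjusted))
  cat(sprintf("  [n = %s]\n", paste(x$n, collapse = ", ")))
  if (!is.null(x$metadata$branch))
    cat("  branch:", x$metadata$branch, "\n")
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test between two samples of a
#' complexity metric (e.g. per-transcript EpT of the whole transcriptome vs
#' the ortholog subset). Small tie-free samples use the exact null
#' distribution; larger or tied samples use the normal approximation with
#' midranks and tie-corrected variance. When `bonferroni_m` is given the
#' p-value is Bonferroni-adjusted for that family size.
#'
#' @param values_a,values_b numeric samples (each non-empty).
#' @param bonferroni_m optional family size m; `p_adjusted = min(1, m * p)`.
#' @return A `txc_test` with the rank-sum statistic W.
#' @export
wilcoxon_compare <- function(values_a, values_b, bonferroni_m = NULL) {
  if (!length(values_a) || !length(values_b)) stop("empty sample")
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- !ties && length(values_a) < 50L && length(values_b) < 50L
  wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                     exact = exact, correct = TRUE))
  padj <- if (is.null(bonferroni_m)) NA_real_
          else min(1, bonferroni_m * wt$p.value)
  .txc_test("wilcoxon", wt$statistic, wt$p.value,
            n = c(length(values_a), length(values_b)), p_adjusted = padj,
            metadata = list(exact = exact,
                            bonferroni_m = bonferroni_m))
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based comparison of a species-level metric across two or more clades,
#' with midranks and tie-corrected H statistic on k-1 degrees of freedom.
#' When every value is identical across all groups there is nothing to rank:
#' H = 0 and p = 1 (not an error).
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups).
#' @return A `txc_test` with the H (chi-squared) statistic.
#' @export
kruskal_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L)
    return(.txc_test("kruskal_wallis", 0, 1, n = lengths(groups),
                     metadata = list(df = length(groups) - 1L)))
  kt <- kruskal.test(groups)
  .txc_test("kruskal_wallis", kt$statistic, kt$p.value, n = lengths(groups),
            metadata = list(df = unname(kt$parameter)))
}

#' Correlation with a Shapiro-Wilk normality gate
#'
#' Tests each margin for normality with the Shapiro-Wilk test at `alpha`;
#' when both pass, reports the Pearson correlation (r, R-squared, p),
#' otherwise the Spearman rank correlation (rho, p). The result records which
#' branch fired. Constant input leaves the correlation undefined and is
#' flagged rather than an error.
#'
#' @param x,y paired numeric samples, n >= 3.
#' @param alpha normality gate level (default 0.05).
#' @return A `txc_test`; `metadata$branch` is `"pearson"`, `"spearman"` or
#'   `"undefined"`, and `metadata$r_squared` is set for the Pearson branch.
#' @export
correlation_with_normality_gate <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need n >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(.txc_test("correlation", NA_real_, NA_real_, n = length(x),
                     metadata = list(branch = "undefined",
                                     reason = "constant input")))
  # shapiro.test accepts 3 <= n <= 5000; subsample the gate above that
  gate <- function(v) {
    if (length(v) > 5000L) v <- v[seq(1L, length(v), length.out = 5000L)]
    shapiro.test(v)$p.value
  }
  normal <- gate(x) > alpha && gate(y) > alpha
  if (normal) {
    ct <- cor.test(x, y, method = "pearson")
    .txc_test("pearson", ct$estimate, ct$p.value, n = length(x),
              metadata = list(branch = "pearson",
                              r_squared = unname(ct$estimate)^2))
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    .txc_test("spearman", ct$estimate, ct$p.value, n = length(x),
              metadata = list(branch = "spearman"))
  }
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values as X2 = -2 * sum(log p) on 2k degrees of
#' freedom. A p-value of exactly zero has an undefined log; set `floor_p` to
#' clip underflowed values (the clip is recorded in the result's metadata).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param floor_p optional lower clip applied before combining (e.g. 1e-300).
#' @return A `txc_test` with the X2 statistic and combined p.
#' @export
fisher_combined <- function(p_values, floor_p = NULL) {
  if (!length(p_values)) stop("no p-values")
  n_floored <- 0L
  if (!is.null(floor_p)) {
    n_floored <- sum(p_values < floor_p)
    p_values <- pmax(p_values, floor_p)
  }
  if (any(p_values <= 0))
    stop("p-value of 0: log undefined; floor upstream (floor_p)")
  if (any(p_values > 1)) stop("p-values must lie in (0, 1]")
  x2 <- -2 * sum(log(p_values))
  k <- length(p_values)
  .txc_test("fisher_combined", x2, pchisq(x2, df = 2 * k, lower.tail = FALSE),
            n = k, metadata = list(df = 2L * k, n_floored = n_floored))
}

#' Resampling validation of a subset-vs-whole comparison
#'
#' Builds a null distribution of the metric mean by repeatedly drawing random
#' subsamples of `whole_values` of the subset's size, and locates the observed
#' subset mean in that distribution (two-sided empirical p). Used to
#' cross-validate rank-test conclusions: when `wilcoxon_p` is supplied, the
#' result records whether the two conclusions agree at `alpha`
#' (`metadata$validates`). The default is random-subsample resampling with a
#' free replicate count; `method = "delete_one"` instead computes the n
#' classical leave-one-out means.
#'
#' @param whole_values numeric vector, the full sample.
#' @param subset_values numeric vector, a subset-sized sample (|subset| <=
#'   |whole|).
#' @param replicates resamples for the null (default 10000).
#' @param seed integer seed.
#' @param method `"subsample"` (default) or `"delete_one"`.
#' @param wilcoxon_p optional p-value of the paired Wilcoxon comparison whose
#'   conclusion is being cross-validated.
#' @param alpha significance level for concordance (default 0.05).
#' @return A `txc_test`; statistic is the observed subset mean, p the
#'   two-sided empirical p, `metadata$quantile` the empirical quantile.
#' @export
jackknife_validate <- function(whole_values, subset_values,
                               replicates = 10000L, seed = 1L,
                               method = c("subsample", "delete_one"),
                               wilcoxon_p = NULL, alpha = 0.05) {
  method <- match.arg(method)
  n <- length(whole_values); k <- length(subset_values)
  if (k > n) stop("subset larger than whole")
  if (method == "subsample" && replicates < 100L)
    stop("need at least 100 replicates")
  set.seed(seed)
  null_means <- if (method == "subsample") {
    vapply(seq_len(replicates),
           function(i) mean(whole_values[sample.int(n, k)]), 0)
  } else {
    tot <- sum(whole_values)
    (tot - whole_values) / (n - 1)  # n leave-one-out means
  }
  obs <- mean(subset_values)
  # mid-quantile with add-one smoothing keeps p in (0, 1)
  q <- (sum(null_means < obs) + 0.5 * sum(null_means == obs) + 0.5) /
    (length(null_means) + 1)
  p <- min(1, 2 * min(q, 1 - q))
  meta <- list(quantile = q, method = method, replicates = length(null_means),
               seed = seed)
  if (!is.null(wilcoxon_p))
    meta$validates <- (wilcoxon_p < alpha) == (p < alpha)
  .txc_test("jackknife", obs, p, n = c(n, k), metadata = meta)
}
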