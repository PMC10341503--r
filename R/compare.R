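# Pairwise condition comparison: Pearson correlation / R^2 over all genes
# or a gene subset, and the twofold-limit fold-change outlier rule.

#' Pearson correlation between two samples
#'
#' Correlation is computed on linear per-million values by default (no log
#' transform); set `log_scale = TRUE` for a log2(value + pseudocount)
#' comparison. Both `r` and `r^2` are always reported, since published
#' summaries frequently conflate the two.
#'
#' @param m A per-million [expression_matrix()].
#' @param sample_a,sample_b Sample ids to compare.
#' @param subset Optional character vector of gene ids to restrict the
#'   comparison to (at least 3 present in `m`).
#' @param log_scale Compare on log2 scale (default `FALSE`).
#' @param pseudocount Pseudocount used only for `log_scale = TRUE`.
#' @return An object of class `"comparison_result"`: list with
#'   `sample_a`, `sample_b`, `subset_name`, `n_genes_used`, `pearson_r`,
#'   `r_squared` and `zero_variance`. When either vector has zero
#'   variance, `pearson_r` and `r_squared` are `NA` and `zero_variance` is
#'   `TRUE` (no error).
#' @export
pairwise_correlation <- function(m, sample_a, sample_b, subset = NULL,
                                 log_scale = FALSE, pseudocount = 1) {
  .assert_per_million(m, "pairwise_correlation")
  .assert_sample(m, sample_a)
  .assert_sample(m, sample_b)
  ids <- rownames(m$values)
  subset_name <- "all"
  if (!is.null(subset)) {
    ids <- intersect(as.character(subset), ids)
    subset_name <- "subset"
  }
  if (length(ids) < 3L)
    stop("need at least 3 genes to correlate", call. = FALSE)
  x <- m$values[ids, sample_a]
  y <- m$values[ids, sample_b]
  if (log_scale) {
    x <- log2(x + pseudocount)
    y <- log2(y + pseudocount)
  }
  zero_var <- stats::var(x) == 0 || stats::var(y) == 0
  r <- if (zero_var) NA_real_ else stats::cor(x, y)
  structure(list(sample_a = sample_a, sample_b = sample_b,
                 subset_name = subset_name, n_genes_used = length(ids),
                 pearson_r = r, r_squared = r^2, zero_variance = zero_var),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s, n = %d): r = %s, r^2 = %s%s\n",
              x$sample_a, x$sample_b, x$subset_name, x$n_genes_used,
              format(x$pearson_r, digits = 4),
              format(x$r_squared, digits = 4),
              if (x$zero_variance) " [zero variance]" else ""))
  invisible(x)
}

#' Fold-change outliers between two samples
#'
#' Flags genes whose expression ratio between the two samples exceeds
#' `fold_limit` in either direction: `|log2((a + pc) / (b + pc))| >
#' log2(fold_limit)`, a strict inequality, so a gene at exactly the fold
#' limit is not an outlier. The default pseudocount of 1 per-million unit
#' keeps ratios finite for genes detected in only one sample; with
#' `pseudocount = 0` such genes are flagged `infinite = TRUE` rather than
#' causing numeric overflow (genes at zero in both samples are equal and
#' never outliers).
#'
#' @param m A per-million [expression_matrix()].
#' @param sample_a,sample_b Sample ids to compare.
#' @param fold_limit Fold-change limit, > 1 (default 2, the twofold rule).
#' @param pseudocount Pseudocount added to both values, >= 0 (default 1).
#' @return Data frame `gene_id`, `value_a`, `value_b`, `log2_ratio`,
#'   `infinite`, sorted by `|log2_ratio|` descending (infinite ratios
#'   first).
#' @export
fold_change_outliers <- function(m, sample_a, sample_b, fold_limit = 2,
                                 pseudocount = 1) {
  .assert_per_million(m, "fold_change_outliers")
  .assert_sample(m, sample_a)
  .assert_sample(m, sample_b)
  if (!is.numeric(fold_limit) || fold_limit <= 1)
    stop("`fold_limit` must be > 1", call. = FALSE)
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop("`pseudocount` must be >= 0", call. = FALSE)
  a <- m$values[, sample_a]
  b <- m$values[, sample_b]
  lr <- log2((a + pseudocount) / (b + pseudocount))
  lr[a == 0 & b == 0] <- 0   # absent in both: no change, even without pseudocount
  keep <- !is.na(lr) & abs(lr) > log2(fold_limit)
  out <- data.frame(gene_id = rownames(m$values)[keep],
                    value_a = unname(a[keep]), value_b = unname(b[keep]),
                    log2_ratio = unname(lr[keep]),
                    infinite = is.infinite(unname(lr[keep])),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log2_ratio), out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Compare all sample pairs of a matrix
#'
#' Runs [pairwise_correlation()] and [fold_change_outliers()] on every
#' unordered pair of samples, over all genes and, optionally, within each
#' gene set of a collection.
#'
#' @param m A per-million [expression_matrix()] with >= 2 samples.
#' @param sets Optional [gene_set_collection()]; adds one row per pair and
#'   set, correlating only that set's member genes.
#' @param fold_limit,pseudocount Passed to [fold_change_outliers()] (whole
#'   matrix rows only).
#' @return Data frame with one row per pair (and per subset): `sample_a`,
#'   `sample_b`, `subset`, `n_genes_used`, `pearson_r`, `r_squared`,
#'   `n_outliers` (`NA` for subset rows).
#' @export
compare_all_pairs <- function(m, sets = NULL, fold_limit = 2,
                              pseudocount = 1) {
  .assert_per_million(m, "compare_all_pairs")
  smp <- colnames(m$values)
  if (length(smp) < 2L) stop("need at least 2 samples", call. = FALSE)
  pairs <- utils::combn(smp, 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    cc <- pairwise_correlation(m, a, b)
    n_out <- nrow(fold_change_outliers(m, a, b, fold_limit, pseudocount))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_a = a, sample_b = b, subset = "all",
      n_genes_used = cc$n_genes_used, pearson_r = cc$pearson_r,
      r_squared = cc$r_squared, n_outliers = n_out,
      stringsAsFactors = FALSE)
    if (!is.null(sets)) {
      for (nm in names(sets)) {
        members <- intersect(sets[[nm]], rownames(m$values))
        if (length(members) < 3L) next
        sc <- pairwise_correlation(m, a, b, subset = members)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_a = a, sample_b = b, subset = nm,
          n_genes_used = sc$n_genes_used, pearson_r = sc$pearson_r,
          r_squared = sc$r_squared, n_outliers = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
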