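# Transcription effort: the percentage of a sample's total transcription
# attributable to a gene or a group of genes, plus the concentration
# statistics derived from the ranked cumulative-effort curve.

#' Transcription effort of individual genes
#'
#' The effort of a gene in a sample is `100 * value / total`, the
#' percentage of the sample's total per-million-normalized transcription
#' carried by that gene. For a full per-million matrix the total is 10^6 by
#' construction; for a partial matrix the total must be supplied (and
#' defaults to 10^6, the per-million convention).
#'
#' Values are returned at full precision; round to two decimals for
#' reporting.
#'
#' @param m A per-million [expression_matrix()].
#' @param gene_id One or more gene ids present in `m`.
#' @param sample_id A single sample id present in `m`.
#' @param total The sample total the percentages refer to (default 10^6).
#' @return Numeric vector of effort percentages, one per `gene_id`.
#' @examples
#' path <- system.file("extdata", "tbo_top10_tpm.tsv", package = "txeffort")
#' top10 <- read_expression_matrix(path, unit = "per_million", partial = TRUE)
#' round(gene_effort(top10, "990338", "WPG"), 2)   # 5.97
#' @export
gene_effort <- function(m, gene_id, sample_id, total = 1e6) {
  .assert_per_million(m, "gene_effort")
  .assert_sample(m, sample_id)
  stopifnot(is.numeric(total), length(total) == 1L, total > 0)
  missing <- setdiff(gene_id, rownames(m$values))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  unname(100 * m$values[gene_id, sample_id] / total)
}

#' Full effort table of a matrix
#'
#' @param m A per-million [expression_matrix()].
#' @param total Sample total (default 10^6).
#' @return Numeric matrix of effort percentages, genes x samples. For a
#'   full matrix every column sums to 100.
#' @export
effort_table <- function(m, total = 1e6) {
  .assert_per_million(m, "effort_table")
  stopifnot(is.numeric(total), length(total) == 1L, total > 0)
  100 * m$values / total
}

#' Rank genes by expression within a sample
#'
#' Genes are ordered from most to least expressed; ties are broken by
#' ascending (lexicographic) gene id so the ordering is deterministic.
#'
#' @inheritParams gene_effort
#' @return Character vector of gene ids, descending expression order.
#' @export
rank_genes <- function(m, sample_id) {
  stopifnot(inherits(m, "expression_matrix"))
  .assert_sample(m, sample_id)
  v <- m$values[, sample_id]
  ids <- rownames(m$values)
  ids[order(-v, ids)]
}

#' Ranked cumulative effort curve of a sample
#'
#' Orders the genes of a sample from most to least expressed and
#' accumulates their effort percentages. For a full matrix the curve is
#' nondecreasing and ends at 100.
#'
#' @inheritParams gene_effort
#' @return A data frame of class `"cumulative_curve"` with columns `rank`,
#'   `gene_id`, `value` and `cumulative_effort`, plus attributes
#'   `sample_id` and `total`.
#' @seealso [fit_log_curve()]
#' @export
cumulative_effort_curve <- function(m, sample_id, total = 1e6) {
  .assert_per_million(m, "cumulative_effort_curve")
  .assert_sample(m, sample_id)
  stopifnot(is.numeric(total), length(total) == 1L, total > 0)
  ids <- rank_genes(m, sample_id)
  v <- m$values[ids, sample_id]
  out <- data.frame(rank = seq_along(ids), gene_id = ids, value = unname(v),
                    cumulative_effort = unname(100 * cumsum(v) / total),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  attr(out, "total") <- total
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' @export
plot.cumulative_curve <- function(x, ...) {
  graphics::plot(x$rank, x$cumulative_effort, type = "l", log = "x",
                 xlab = "gene rank (descending expression)",
                 ylab = "cumulative effort (%)",
                 main = attr(x, "sample_id"), ...)
  invisible(x)
}

#' Minimal number of top genes reaching an effort threshold
#'
#' The concentration statistic: the smallest `k` such that the `k` most
#' expressed genes of a sample jointly carry at least `threshold` percent
#' of the total transcription.
#'
#' @inheritParams gene_effort
#' @param threshold Effort threshold in percent, in `[0, 100]`.
#' @return Integer `k` (0 for `threshold = 0`). For a partial matrix a
#'   threshold beyond the cumulative effort of the provided genes is an
#'   error ("insufficient data").
#' @examples
#' path <- system.file("extdata", "tbo_top10_tpm.tsv", package = "txeffort")
#' top10 <- read_expression_matrix(path, unit = "per_million", partial = TRUE)
#' min_genes_for_effort(top10, "WPG", 10)   # 3
#' @export
min_genes_for_effort <- function(m, sample_id, threshold, total = 1e6) {
  .assert_per_million(m, "min_genes_for_effort")
  .assert_sample(m, sample_id)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold < 0 || threshold > 100)
    stop("`threshold` must be a percentage in [0, 100]", call. = FALSE)
  if (threshold == 0) return(0L)
  curve <- cumulative_effort_curve(m, sample_id, total = total)
  # tolerance matches the 1e-6 column-sum invariant of full effort tables
  k <- which(curve$cumulative_effort >= threshold - 1e-6)[1L]
  if (is.na(k))
    stop(sprintf(paste0("insufficient data: the %d provided genes reach only ",
                        "%.4f%% cumulative effort in sample '%s', below the ",
                        "%.4g%% threshold"),
                 nrow(curve), max(curve$cumulative_effort), sample_id,
                 threshold), call. = FALSE)
  as.integer(k)
}

#' Expressed-gene counts and catalog fractions
#'
#' A gene is "expressed" in a sample when its value is strictly greater
#' than `detection_threshold` (default 0; the choice of detection cutoff is
#' exposed rather than fixed).
#'
#' @param m An [expression_matrix()] (any unit).
#' @param detection_threshold Strict lower bound for calling a gene
#'   expressed (same unit as `m`).
#' @param catalog_size Number of genes in the reference catalog the
#'   fractions refer to; at least the number of genes in `m` (default).
#' @return Data frame with one row per sample: `sample_id`,
#'   `expressed_genes`, `expressed_fraction` (percent of catalog, full
#'   precision; round to one decimal for reporting).
#' @examples
#' catalog_fraction(10941, 12346)   # 88.6 (to one decimal)
#' @export
expressed_gene_stats <- function(m, detection_threshold = 0,
                                 catalog_size = nrow(m$values)) {
  stopifnot(inherits(m, "expression_matrix"),
            is.numeric(detection_threshold), length(detection_threshold) == 1L)
  if (catalog_size < nrow(m$values))
    stop(sprintf("catalog_size (%d) is smaller than the %d genes in the matrix",
                 catalog_size, nrow(m$values)), call. = FALSE)
  n <- as.integer(colSums(m$values > detection_threshold))
  data.frame(sample_id = colnames(m$values), expressed_genes = n,
             expressed_fraction = catalog_fraction(unname(n), catalog_size),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage of a gene catalog
#'
#' `100 * count / catalog_size`, the form in which expressed-gene and
#' annotation rates are reported.
#'
#' @param count Number of genes.
#' @param catalog_size Catalog (reference genome) gene count, > 0.
#' @return Numeric percentage(s), full precision.
#' @export
catalog_fraction <- function(count, catalog_size) {
  stopifnot(is.numeric(count), is.numeric(catalog_size), catalog_size > 0)
  100 * count / catalog_size
}

#' Pareto-style concentration summary of a sample
#'
#' How many genes, and what fraction of the catalog, carry
#' `effort_threshold` percent of the sample's transcription (the "20% of
#' genes carry 80% of the transcription" statistic at the default
#' threshold).
#'
#' @inheritParams gene_effort
#' @param effort_threshold Effort threshold in percent (default 80).
#' @param catalog_size Catalog size for the gene fraction (defaults to the
#'   number of genes in `m`; `m` must be full).
#' @return List with `genes_for_threshold` (integer k) and `gene_fraction`
#'   (percent of catalog).
#' @export
pareto_summary <- function(m, sample_id, effort_threshold = 80,
                           catalog_size = nrow(m$values), total = 1e6) {
  .assert_per_million(m, "pareto_summary")
  if (m$partial)
    stop("pareto_summary() is defined on full matrices only", call. = FALSE)
  k <- min_genes_for_effort(m, sample_id, effort_threshold, total = total)
  list(genes_for_threshold = k,
       gene_fraction = catalog_fraction(k, catalog_size))
}

#' Per-sample concentration summary table
#'
#' Combines expressed-gene statistics with the minimal top-gene counts at a
#' ladder of effort thresholds, one row per sample.
#'
#' @param m A full per-million [expression_matrix()].
#' @param thresholds Strictly increasing effort thresholds in `(0, 100]`
#'   (default 10, 75, 80).
#' @param detection_threshold Detection cutoff for the expressed-gene
#'   columns.
#' @param catalog_size Reference catalog size (default: genes in `m`).
#' @param total Sample total (default 10^6).
#' @return Data frame with columns `sample_id`, `expressed_genes`,
#'   `expressed_fraction`, one `genes_to_<t>` column per threshold, and
#'   `gene_fraction_at_<last t>`.
#' @export
concentration_summary <- function(m, thresholds = c(10, 75, 80),
                                  detection_threshold = 0,
                                  catalog_size = nrow(m$values),
                                  total = 1e6) {
  .assert_per_million(m, "concentration_summary")
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) ||
      any(thresholds > 100))
    stop("`thresholds` must be strictly increasing within (0, 100]",
         call. = FALSE)
  out <- expressed_gene_stats(m, detection_threshold, catalog_size)
  for (t in thresholds) {
    col <- sprintf("genes_to_%g", t)
    out[[col]] <- vapply(out$sample_id, function(s)
      min_genes_for_effort(m, s, t, total = total), integer(1),
      USE.NAMES = FALSE)
  }
  last <- sprintf("genes_to_%g", thresholds[length(thresholds)])
  out[[sprintf("gene_fraction_at_%g", thresholds[length(thresholds)])]] <-
    catalog_fraction(out[[last]], catalog_size)
  out
}
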