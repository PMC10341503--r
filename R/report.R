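# Assembled analysis report: the full pipeline on one matrix (plus
# optional annotation and gene sets), written as a TSV + JSON bundle.

.tsv_with_header <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full transcription-effort pipeline and write a report bundle
#'
#' Computes, for a full per-million matrix: the per-sample concentration
#' summary, the top-`top_n` gene table, the per-sample log-curve fits, the
#' KOG profile (when an annotation is given), gene-set profiles (when a
#' collection is given) and all pairwise comparisons with twofold-limit
#' outliers. Each table is written as TSV with a provenance header line
#' (package version, parameters, seed) and the whole bundle as
#' `report.json`.
#'
#' @param m A full per-million [expression_matrix()] (raw counts are
#'   normalized first).
#' @param annotation Optional [kog_annotation()].
#' @param sets Optional [gene_set_collection()].
#' @param outdir Output directory (created if needed); `NULL` computes the
#'   report without writing files.
#' @param thresholds Effort thresholds for the concentration summary.
#' @param top_n Genes in the top-gene table per sample.
#' @param detection_threshold,fold_limit,pseudocount Passed through to the
#'   underlying operations.
#' @param catalog_size Reference catalog size (default: genes in `m`).
#' @param seed Optional seed recorded in the provenance header.
#' @return Invisibly, a list with elements `concentration`, `top_genes`,
#'   `log_fits`, `kog` (or `NULL`), `gene_sets` (or `NULL`),
#'   `comparisons`, `outliers`. Every value is reproducible by calling the
#'   underlying operation directly; the report adds no computation.
#' @export
effort_report <- function(m, annotation = NULL, sets = NULL, outdir = NULL,
                          thresholds = c(10, 75, 80), top_n = 10L,
                          detection_threshold = 0, fold_limit = 2,
                          pseudocount = 1, catalog_size = nrow(m$values),
                          seed = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit == "raw_counts") m <- normalize_per_million(m)
  smp <- colnames(m$values)

  conc <- concentration_summary(m, thresholds, detection_threshold,
                                catalog_size)

  top_genes <- do.call(rbind, lapply(smp, function(s) {
    ids <- utils::head(rank_genes(m, s), top_n)
    data.frame(sample_id = s, rank = seq_along(ids), gene_id = ids,
               value = unname(m$values[ids, s]),
               effort = gene_effort(m, ids, s), stringsAsFactors = FALSE)
  }))

  log_fits <- do.call(rbind, lapply(smp, function(s) {
    f <- fit_log_curve(cumulative_effort_curve(m, s))
    data.frame(sample_id = s, a = f$a, b = f$b, r_squared = f$r_squared,
               n_points = f$n_points, stringsAsFactors = FALSE)
  }))

  kog <- NULL
  if (!is.null(annotation))
    kog <- do.call(rbind, lapply(smp, function(s)
      cbind(sample_id = s,
            kog_profile(m, annotation, s, detection_threshold))))

  gene_sets <- NULL
  if (!is.null(sets))
    gene_sets <- do.call(rbind, lapply(names(sets), function(nm)
      do.call(rbind, lapply(smp, function(s) {
        p <- gene_set_effort(m, sets, nm, s)
        data.frame(set_name = nm, sample_id = s,
                   member_count = p$member_count,
                   members_present = p$members_present,
                   members_expressed = p$members_expressed,
                   set_effort = p$set_effort, stringsAsFactors = FALSE)
      }))))

  comparisons <- compare_all_pairs(m, sets, fold_limit, pseudocount)

  pairs <- utils::combn(smp, 2L)
  outliers <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    o <- fold_change_outliers(m, pairs[1L, k], pairs[2L, k], fold_limit,
                              pseudocount)
    if (nrow(o)) cbind(sample_a = pairs[1L, k], sample_b = pairs[2L, k], o)
    else NULL
  }))
  if (is.null(outliers))
    outliers <- data.frame(sample_a = character(0), sample_b = character(0),
                           gene_id = character(0), value_a = numeric(0),
                           value_b = numeric(0), log2_ratio = numeric(0),
                           infinite = logical(0))

  report <- list(concentration = conc, top_genes = top_genes,
                 log_fits = log_fits, kog = kog, gene_sets = gene_sets,
                 comparisons = comparisons, outliers = outliers)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    prov <- sprintf(
      "txeffort %s | thresholds=%s top_n=%d detection=%g fold_limit=%g pseudocount=%g%s",
      as.character(utils::packageVersion("txeffort")),
      paste(thresholds, collapse = ","), top_n, detection_threshold,
      fold_limit, pseudocount,
      if (is.null(seed)) "" else sprintf(" seed=%d", seed))
    .tsv_with_header(conc, file.path(outdir, "concentration_summary.tsv"), prov)
    .tsv_with_header(top_genes, file.path(outdir, "top_genes.tsv"), prov)
    .tsv_with_header(log_fits, file.path(outdir, "log_fits.tsv"), prov)
    if (!is.null(kog))
      .tsv_with_header(kog, file.path(outdir, "kog_profile.tsv"), prov)
    if (!is.null(gene_sets))
      .tsv_with_header(gene_sets, file.path(outdir, "gene_set_profile.tsv"),
                       prov)
    .tsv_with_header(comparisons, file.path(outdir, "pairwise.tsv"), prov)
    .tsv_with_header(outliers, file.path(outdir, "outliers.tsv"), prov)
    jsonlite::write_json(c(list(provenance = prov), report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(report)
}
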