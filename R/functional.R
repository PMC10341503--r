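# Decomposition of transcription effort by KOG functional category and by
# named gene sets (pathways, secondary-metabolite clusters, aroma genes).

# gene -> character vector of KOG letters, for genes of the matrix; genes
# absent from the annotation (or annotated with "") map to character(0).
.kog_lookup <- function(m, annotation) {
  stopifnot(inherits(annotation, "kog_annotation"))
  classes <- strsplit(annotation$kog_class, "")
  names(classes) <- annotation$gene_id
  ids <- rownames(m$values)
  out <- classes[ids]
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  names(out) <- ids
  out
}

#' Expressed-gene counts per KOG category
#'
#' Counts, for one sample, the expressed genes (value strictly above
#' `detection_threshold`) in each of the 25 KOG categories. A gene
#' annotated with several classes is counted once per class; genes absent
#' from the annotation (or with an empty class string) fall into the
#' `unannotated` bucket.
#'
#' @param m An [expression_matrix()].
#' @param annotation A [kog_annotation()] covering (a subset of) the genes
#'   of `m`.
#' @param sample_id A single sample id.
#' @param detection_threshold Strict detection cutoff (default 0).
#' @return Data frame with columns `category` (the 25 letters plus
#'   `"unannotated"`) and `gene_count`.
#' @export
kog_category_counts <- function(m, annotation, sample_id,
                                detection_threshold = 0) {
  stopifnot(inherits(m, "expression_matrix"))
  .assert_sample(m, sample_id)
  classes <- .kog_lookup(m, annotation)
  expressed <- m$values[, sample_id] > detection_threshold
  counts <- structure(integer(length(.KOG_CLASSES)), names = .KOG_CLASSES)
  unannot <- 0L
  for (i in which(expressed)) {
    cl <- classes[[i]]
    if (length(cl)) counts[cl] <- counts[cl] + 1L else unannot <- unannot + 1L
  }
  data.frame(category = c(.KOG_CLASSES, "unannotated"),
             gene_count = c(unname(counts), unannot),
             stringsAsFactors = FALSE)
}

#' Transcription effort per KOG category
#'
#' Decomposes a sample's total effort into the 25 KOG categories plus an
#' `unannotated` remainder. So that the decomposition is a true partition
#' (it sums to 100 for a full matrix), the effort of a multi-class gene is
#' split equally across its classes; gene counts, in contrast, are tallied
#' once per class (see [kog_category_counts()]).
#'
#' @inheritParams kog_category_counts
#' @param m A full per-million [expression_matrix()].
#' @param total Sample total (default 10^6).
#' @return Data frame with columns `category` and `effort` (percent).
#' @export
kog_category_effort <- function(m, annotation, sample_id, total = 1e6) {
  .assert_per_million(m, "kog_category_effort")
  .assert_sample(m, sample_id)
  classes <- .kog_lookup(m, annotation)
  eff <- 100 * m$values[, sample_id] / total
  out <- structure(numeric(length(.KOG_CLASSES)), names = .KOG_CLASSES)
  unannot <- 0
  nz <- which(eff > 0)
  for (i in nz) {
    cl <- classes[[i]]
    if (length(cl)) out[cl] <- out[cl] + eff[i] / length(cl)
    else unannot <- unannot + eff[i]
  }
  data.frame(category = c(.KOG_CLASSES, "unannotated"),
             effort = c(unname(out), unannot), stringsAsFactors = FALSE)
}

#' Combined KOG profile (counts and efforts) of a sample
#'
#' @inheritParams kog_category_effort
#' @param detection_threshold Detection cutoff for the count column.
#' @return Data frame with columns `category`, `gene_count`, `effort`.
#' @export
kog_profile <- function(m, annotation, sample_id, detection_threshold = 0,
                        total = 1e6) {
  counts <- kog_category_counts(m, annotation, sample_id, detection_threshold)
  efforts <- kog_category_effort(m, annotation, sample_id, total)
  merge(counts, efforts, by = "category", sort = FALSE)
}

#' Transcription effort of a named gene set
#'
#' Profiles one gene set in one sample: every member's per-million value,
#' effort percentage and overall expression rank in the sample, plus the
#' set totals. Members absent from the matrix are reported through
#' `members_present`, not an error, so partial matrices can be profiled.
#' Sets are profiles, not partitions: a gene belonging to two sets
#' contributes its full effort to both.
#'
#' @param m A per-million [expression_matrix()].
#' @param sets A [gene_set_collection()].
#' @param set_name Name of the set to profile.
#' @param sample_id A single sample id.
#' @param total Sample total (default 10^6).
#' @return An object of class `"gene_set_profile"`: list with `set_name`,
#'   `sample_id`, `member_count`, `members_present`, `members_expressed`,
#'   `set_effort` (percent) and `per_gene` (data frame `gene_id`, `value`,
#'   `effort`, `rank`, ordered by descending value).
#' @export
gene_set_effort <- function(m, sets, set_name, sample_id, total = 1e6) {
  .assert_per_million(m, "gene_set_effort")
  .assert_sample(m, sample_id)
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!set_name %in% names(sets))
    stop(sprintf("unknown gene set '%s'", set_name), call. = FALSE)
  members <- sets[[set_name]]
  present <- intersect(members, rownames(m$values))
  v <- m$values[, sample_id]
  ids <- rownames(m$values)
  rank_pos <- integer(length(ids))
  rank_pos[order(-v, ids)] <- seq_along(ids)
  names(rank_pos) <- ids
  per_gene <- data.frame(gene_id = present, value = unname(v[present]),
                         effort = unname(100 * v[present] / total),
                         rank = unname(rank_pos[present]),
                         stringsAsFactors = FALSE)
  per_gene <- per_gene[order(-per_gene$value, per_gene$gene_id), ]
  rownames(per_gene) <- NULL
  structure(list(set_name = set_name, sample_id = sample_id,
                 member_count = length(members),
                 members_present = length(present),
                 members_expressed = sum(per_gene$value > 0),
                 set_effort = sum(per_gene$effort), per_gene = per_gene),
            class = "gene_set_profile")
}

#' @export
print.gene_set_profile <- function(x, ...) {
  cat(sprintf(
    "gene set '%s' in sample '%s': %d members (%d present, %d expressed), effort %.4f%%\n",
    x$set_name, x$sample_id, x$member_count, x$members_present,
    x$members_expressed, x$set_effort))
  print(utils::head(x$per_gene, 10L))
  invisible(x)
}

#' Count the expressed members of a gene set
#'
#' @inheritParams gene_set_effort
#' @param m An [expression_matrix()].
#' @param detection_threshold Strict detection cutoff (default 0).
#' @param mode Require expression in `"all_samples"` (default) or in
#'   `"any_sample"`.
#' @return Integer count of member genes expressed under `mode`.
#' @export
count_expressed_in_set <- function(m, sets, set_name, detection_threshold = 0,
                                   mode = c("all_samples", "any_sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expression_matrix"),
            inherits(sets, "gene_set_collection"))
  if (!set_name %in% names(sets))
    stop(sprintf("unknown gene set '%s'", set_name), call. = FALSE)
  present <- intersect(sets[[set_name]], rownames(m$values))
  if (!length(present)) return(0L)
  det <- m$values[present, , drop = FALSE] > detection_threshold
  hit <- if (mode == "all_samples") rowSums(det) == ncol(det)
         else rowSums(det) > 0L
  sum(hit)
}

#' Most expressed genes of a set across all samples
#'
#' Orders the members present in the matrix by their maximum per-million
#' value over samples (ties broken by ascending gene id) and returns the
#' top `n` with their per-sample values.
#'
#' @inheritParams gene_set_effort
#' @param n Number of genes to return (>= 1); if larger than the set, the
#'   whole set is returned.
#' @return Data frame: `gene_id`, `max_value`, one column per sample.
#' @export
top_genes_in_set <- function(m, sets, set_name, n = 10L) {
  .assert_per_million(m, "top_genes_in_set")
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!set_name %in% names(sets))
    stop(sprintf("unknown gene set '%s'", set_name), call. = FALSE)
  if (!is.numeric(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  present <- intersect(sets[[set_name]], rownames(m$values))
  v <- m$values[present, , drop = FALSE]
  mx <- apply(v, 1L, max)
  ord <- order(-mx, present)
  keep <- utils::head(ord, n)
  out <- data.frame(gene_id = present[keep], max_value = unname(mx[keep]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(v[keep, , drop = FALSE], row.names = FALSE))
}
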