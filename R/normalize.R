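#' Per-million normalization of a count matrix
#'
#' Scales every sample column so it sums to 10^6: each value `v` becomes
#' `v * 1e6 / colsum`. This is the per-million scaling used throughout the
#' package ("TPM" in the loose sense of total counts per million); it
#' applies no gene-length term. A length-corrected variant is available by
#' supplying `gene_lengths`, in which case counts are first divided by gene
#' length and then scaled per million (classical transcript-per-million);
#' it is off by default.
#'
#' The operation is idempotent on full per-million input and invariant to
#' rescaling a sample's counts by any positive constant.
#'
#' @param m An [expression_matrix()] (raw counts, or per-million to
#'   renormalize). Must not be partial: the column totals of a gene subset
#'   are not the sample totals.
#' @param gene_lengths Optional named numeric vector of positive gene
#'   lengths covering all genes of `m`; enables length-corrected
#'   normalization.
#' @return An [expression_matrix()] with `unit = "per_million"`, same gene
#'   and sample order.
#' @examples
#' v <- matrix(c(10, 30, 60), ncol = 1, dimnames = list(paste0("g", 1:3), "s1"))
#' normalize_per_million(expression_matrix(v))$values
#' @export
normalize_per_million <- function(m, gene_lengths = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$partial)
    stop("cannot normalize a partial matrix: sample totals are unknown",
         call. = FALSE)
  v <- m$values
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths)) ||
        !all(rownames(v) %in% names(gene_lengths)))
      stop("`gene_lengths` must be named and cover every gene", call. = FALSE)
    len <- gene_lengths[rownames(v)]
    if (any(!is.finite(len)) || any(len <= 0))
      stop("gene lengths must be positive and finite", call. = FALSE)
    v <- v / len
  }
  cs <- colSums(v)
  if (any(cs <= 0))
    stop(sprintf("sample '%s' has zero total expression and cannot be normalized",
                 colnames(v)[which(cs <= 0)[1L]]), call. = FALSE)
  v <- sweep(v, 2L, cs, "/") * 1e6
  expression_matrix(v, unit = "per_million", partial = FALSE)
}

# Guard used by effort/profile operations that are defined on per-million
# values only.
.assert_per_million <- function(m, fun) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "per_million")
    stop(sprintf("%s() needs per-million values; run normalize_per_million() first",
                 fun), call. = FALSE)
  invisible(m)
}

.assert_sample <- function(m, sample_id) {
  if (length(sample_id) != 1L || !sample_id %in% colnames(m$values))
    stop(sprintf("unknown sample '%s'", paste(sample_id, collapse = ",")),
         call. = FALSE)
  invisible(sample_id)
}
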