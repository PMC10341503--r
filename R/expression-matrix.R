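# Gene x sample expression container used by every downstream operation.
# Modeled on the list-of-components style of DGEList/EList objects: the
# matrix itself plus a declared unit, so functions can refuse to compute
# percentages from raw counts.

#' Construct a gene-by-sample expression matrix
#'
#' The basic container of the package: a nonnegative numeric matrix with
#' genes in rows and samples in columns, together with a declared unit.
#' Absence of expression is encoded as 0; missing values are not allowed.
#'
#' A *partial* matrix (e.g. the top-10 genes of each sample, as printed in a
#' publication table) can be declared with `partial = TRUE`; this suspends
#' the column-sum check for per-million matrices. All effort computations on
#' a partial matrix must then be given the sample total explicitly (the
#' `total` argument of the effort functions, 10^6 for per-million data).
#'
#' @param values Numeric matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames. All values must be finite and >= 0.
#' @param unit `"raw_counts"` or `"per_million"`. A full `"per_million"`
#'   matrix must have every column summing to 10^6 (relative tolerance
#'   10^-9).
#' @param partial Logical; declare the matrix as a subset of the genes of a
#'   sample, exempting it from the per-million column-sum invariant.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values`, `unit` and `partial`.
#' @seealso [read_expression_matrix()], [normalize_per_million()]
#' @examples
#' v <- matrix(c(10, 30, 60, 5, 5, 90), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' m <- expression_matrix(v, unit = "raw_counts")
#' m
#' @export
expression_matrix <- function(values, unit = c("raw_counts", "per_million"),
                              partial = FALSE) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite; encode absence as 0, not NA",
         call. = FALSE)
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]),
         call. = FALSE)
  }
  if (unit == "per_million" && !partial) {
    cs <- colSums(values)
    bad <- which(abs(cs - 1e6) > 1e-9 * 1e6)
    if (length(bad))
      stop(sprintf(paste0("per_million columns must sum to 10^6; sample '%s' ",
                          "sums to %.6g (declare partial = TRUE for a gene ",
                          "subset)"), colnames(values)[bad[1L]], cs[bad[1L]]),
           call. = FALSE)
  }
  structure(list(values = values, unit = unit, partial = partial),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param m An [expression_matrix()].
#' @return Character vector of ids, in matrix order.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s%s]\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (x$partial) ", partial" else ""))
  n <- min(5L, nrow(x$values))
  print(utils::head(x$values, n))
  if (nrow(x$values) > n) cat(sprintf("... and %d more genes\n",
                                      nrow(x$values) - n))
  invisible(x)
}

#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  # dropping genes from a full per-million matrix yields a partial one
  partial <- x$partial || (x$unit == "per_million" && nrow(v) < nrow(x$values))
  expression_matrix(v, unit = x$unit, partial = partial)
}

.detect_sep <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    stop("no data lines in '", path, "'", call. = FALSE)
  if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Parses a TSV or CSV file (delimiter auto-detected from the header line)
#' whose first column holds gene ids and whose header row holds sample ids.
#' Decimal points only; no locale-specific decimal commas. Lines starting
#' with `#` are treated as comments.
#'
#' @param path Path to the file.
#' @param unit Declared unit of the stored values, `"raw_counts"` (default)
#'   or `"per_million"`.
#' @param partial Declare a gene subset (see [expression_matrix()]).
#' @return An [expression_matrix()].
#' @examples
#' path <- system.file("extdata", "tbo_top10_tpm.tsv", package = "txeffort")
#' top10 <- read_expression_matrix(path, unit = "per_million", partial = TRUE)
#' dim(top10)
#' @export
read_expression_matrix <- function(path,
                                   unit = c("raw_counts", "per_million"),
                                   partial = FALSE) {
  unit <- match.arg(unit)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("malformed header: need a gene id column plus at least one sample",
         call. = FALSE)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  smp <- colnames(raw)[-1L]
  v <- matrix(NA_real_, nrow(raw), length(smp), dimnames = list(ids, smp))
  for (j in seq_along(smp)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    if (anyNA(col)) {
      i <- which(is.na(col))[1L]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   raw[[j + 1L]][i], ids[i], smp[j]), call. = FALSE)
    }
    v[, j] <- col
  }
  expression_matrix(v, unit = unit, partial = partial)
}

#' Write an expression matrix as delimited text
#'
#' Values are written with `format = "g"` at the requested number of
#' significant digits; `digits = 17` round-trips doubles exactly.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @param digits Significant digits to write (default 12).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, sep = "\t", digits = 12L) {
  stopifnot(inherits(m, "expression_matrix"))
  v <- m$values
  body <- apply(v, 2L, function(col) formatC(col, digits = digits,
                                             format = "g"))
  body <- matrix(trimws(body), nrow = nrow(v))
  lines <- c(paste(c("gene_id", colnames(v)), collapse = sep),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], body[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}
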