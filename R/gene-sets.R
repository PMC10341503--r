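# KOG annotation tables and named gene-set collections (GMT).

# The 25 single-letter KOG functional categories.
.KOG_DESCRIPTIONS <- c(
  A = "RNA processing and modification",
  B = "chromatin structure and dynamics",
  J = "translation",
  K = "transcription",
  L = "replication and repair",
  C = "energy production and conversion",
  E = "amino acid metabolism and transport",
  F = "nucleotide metabolism and transport",
  G = "carbohydrate metabolism and transport",
  H = "coenzyme metabolism",
  I = "lipid metabolism",
  P = "inorganic ion transport and metabolism",
  Q = "secondary metabolites biosynthesis, transport and catabolism",
  D = "cell cycle control and mitosis",
  M = "cell wall/membrane/envelope biogenesis",
  N = "cell motility",
  O = "post-translational modification, protein turnover, chaperone functions",
  R = "general function prediction only",
  S = "unknown function",
  T = "signal transduction",
  U = "intracellular trafficking and secretion",
  V = "defense mechanisms",
  W = "extracellular structures",
  Y = "nuclear structure",
  Z = "cytoskeleton")

.KOG_CLASSES <- names(.KOG_DESCRIPTIONS)

#' The KOG functional category vocabulary
#'
#' @return Named character vector mapping the 25 single-letter KOG
#'   (EuKaryotic Orthologous Groups) categories to their descriptions.
#' @export
kog_categories <- function() .KOG_DESCRIPTIONS

#' Build a KOG annotation table
#'
#' Maps gene ids to zero or more single-letter KOG categories. Multi-class
#' genes carry their letters concatenated (e.g. `"JO"`). An empty string
#' means the gene is recorded but unannotated.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param kog_class Character vector of concatenated KOG letters (may be
#'   `""`); letters outside the 25-letter vocabulary are rejected.
#' @param function_label Free-text function labels (optional; recycled
#'   `"N/A"` if missing).
#' @return A data frame of class `"kog_annotation"` with those three
#'   columns.
#' @export
kog_annotation <- function(gene_id, kog_class,
                           function_label = rep("N/A", length(gene_id))) {
  gene_id <- as.character(gene_id)
  kog_class <- as.character(kog_class)
  kog_class[is.na(kog_class)] <- ""
  function_label <- as.character(function_label)
  function_label[is.na(function_label)] <- "N/A"
  stopifnot(length(kog_class) == length(gene_id),
            length(function_label) == length(gene_id))
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup))
    stop("duplicate gene id(s) in annotation: ", paste(dup, collapse = ", "),
         call. = FALSE)
  letters_used <- unlist(strsplit(kog_class, ""), use.names = FALSE)
  unknown <- setdiff(letters_used, .KOG_CLASSES)
  if (length(unknown)) {
    offender <- gene_id[vapply(strsplit(kog_class, ""),
                               function(l) any(l %in% unknown), logical(1))][1L]
    stop(sprintf("unknown KOG class letter(s) %s (first at gene '%s')",
                 paste(sQuote(unknown), collapse = ", "), offender),
         call. = FALSE)
  }
  structure(data.frame(gene_id = gene_id, kog_class = kog_class,
                       function_label = function_label,
                       stringsAsFactors = FALSE),
            class = c("kog_annotation", "data.frame"))
}

#' Read a KOG annotation table from delimited text
#'
#' Expects columns `gene_id`, `kog_class` (concatenated letters) and,
#' optionally, `function_label`. Delimiter auto-detected (tab or comma).
#'
#' @param path Path to the file.
#' @return A [kog_annotation()] data frame.
#' @export
read_kog_annotation <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "kog_class")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lab <- if ("function_label" %in% colnames(df)) df$function_label
         else rep("N/A", nrow(df))
  kog_annotation(df$gene_id, df$kog_class, lab)
}

#' Write a KOG annotation table
#' @param annotation A [kog_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kog_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a collection of named gene sets
#'
#' Gene sets are profiles, not partitions: a gene may belong to several sets
#' (e.g. succinate dehydrogenase sits in both the TCA-cycle and
#' electron-transport-chain sets).
#'
#' @param sets Named list of character vectors of member gene ids. Names
#'   must be unique and members non-empty.
#' @param descriptions Optional character vector of set descriptions, same
#'   length/order as `sets`.
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named", call. = FALSE)
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop("duplicate set name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set(s): ", paste(empty, collapse = ", "), call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets\n", length(x)))
  sz <- lengths(x)
  for (nm in utils::head(names(x), 12L))
    cat(sprintf("  %-20s %4d genes\n", nm, sz[[nm]]))
  if (length(x) > 12L) cat(sprintf("  ... and %d more sets\n",
                                   length(x) - 12L))
  invisible(x)
}

#' Sizes of the sets in a collection
#' @param sets A [gene_set_collection()].
#' @return Named integer vector of member counts.
#' @export
set_sizes <- function(sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lengths(sets)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name TAB description TAB member1 TAB member2 ...`.
#' Sets may share members; a line with no members or a repeated set name is
#' a parse error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @examples
#' path <- system.file("extdata", "tbo_gene_groups_synthetic.gmt",
#'                     package = "txeffort")
#' sets <- read_gmt(path)
#' set_sizes(sets)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, "", 1L)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d ('%s') declares no member genes", short[1L],
                 nm[short[1L]]), call. = FALSE)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate set name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Write gene sets in GMT format
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
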