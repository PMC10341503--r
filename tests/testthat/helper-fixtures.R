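# Shared fixture builders and independent oracles for the test suite.

# expression matrix from a plain numeric matrix, auto-naming genes/samples
make_matrix <- function(values, unit = "raw_counts", partial = FALSE) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, unit = unit, partial = partial)
}

# full per-million matrix proportional to the given columns
make_pm <- function(values) {
  m <- make_matrix(values, unit = "raw_counts")
  normalize_per_million(m)
}

random_counts <- function(n_genes, n_samples, max_count = 1000) {
  matrix(sample.int(max_count + 1L, n_genes * n_samples, replace = TRUE) - 1L,
         n_genes, n_samples)
}

table3_matrix <- function() {
  read_expression_matrix(
    system.file("extdata", "tbo_top10_tpm.tsv", package = "txeffort"),
    unit = "per_million", partial = TRUE)
}

gene_group_fixture <- function() {
  read_gmt(system.file("extdata", "tbo_gene_groups_synthetic.gmt",
                       package = "txeffort"))
}

# independent least-squares oracle: normal equations computed from raw sums
logfit_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  a <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  b <- (sy - a * sx) / n
  resid <- y - (a * x + b)
  list(a = a, b = b, r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# independent linear-scan oracle for the minimal top-k gene count
min_genes_oracle <- function(v, threshold, total) {
  s <- sort(v, decreasing = TRUE)
  acc <- 0
  for (k in seq_along(s)) {
    acc <- acc + s[k]
    if (100 * acc / total >= threshold - 1e-6) return(k)
  }
  NA_integer_
}

# small synthetic config for structure tests that do not need genome scale
small_config <- function(seed = 1L, ...) {
  synthetic_config(
    n_genes = 2000L, seed = seed,
    set_sizes = c(glycolysis = 20, tca = 12, etc = 6, glyoxylate = 3,
                  aroma = 30, nrps = 2, pks = 1, pks_like_1 = 2),
    aroma_unexpressed = 3L, ...)
}
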