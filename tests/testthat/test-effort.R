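test_that("per-gene efforts reproduce the published worked examples", {
  m <- table3_matrix()
  expect_equal(round(gene_effort(m, "990338", "WPG"), 2), 5.97)
  expect_equal(round(gene_effort(m, "1067414", "PDB"), 2), 2.10)
  expect_equal(round(gene_effort(m, "1067414", "MPY"), 2), 1.37)
  expect_equal(round(gene_effort(m, "957843", "MPY"), 2), 1.95)
  expect_equal(round(gene_effort(m, "957843", "PDB"), 2), 1.36)
  # vectorized over genes, full precision internally
  expect_equal(gene_effort(m, c("990338", "1125059"), "WPG"),
               c(5.97106, 3.79049), tolerance = 1e-12)
})

test_that("effort lookups validate genes, samples and totals", {
  m <- table3_matrix()
  expect_error(gene_effort(m, "nope", "WPG"), "unknown gene")
  expect_error(gene_effort(m, "990338", "XXX"), "unknown sample")
  expect_error(gene_effort(m, "990338", "WPG", total = 0))
  raw <- make_matrix(c(1, 2, 3))
  expect_error(gene_effort(raw, "g001", "s1"), "per-million")
})

test_that("a sample with one expressed gene gives it 100% effort", {
  pm <- make_pm(c(0, 42, 0))
  expect_equal(gene_effort(pm, "g002", "s1"), 100)
})

test_that("effort conservation and scale invariance hold on random matrices", {
  set.seed(19)
  for (i in 1:25) {
    v <- random_counts(sample(5:80, 1), sample(1:4, 1))
    v[rowSums(v) == 0, 1] <- 1
    pm <- normalize_per_million(make_matrix(v))
    eff <- effort_table(pm)
    expect_equal(unname(colSums(eff)), rep(100, ncol(v)), tolerance = 1e-6)
    scl <- normalize_per_million(make_matrix(v * runif(1, 0.5, 20)))
    expect_equal(effort_table(scl), eff, tolerance = 1e-9)
  }
})

test_that("ranking is by descending value with ids breaking ties", {
  m <- table3_matrix()
  expect_identical(head(rank_genes(m, "WPG"), 3),
                   c("990338", "1125059", "985714"))
  tie <- make_matrix(matrix(c(5, 5, 1), dimnames = list(
    c("zeta", "alpha", "mid"), "s1")), unit = "per_million", partial = TRUE)
  expect_identical(rank_genes(tie, "s1"), c("alpha", "zeta", "mid"))

  set.seed(3)
  v <- matrix(sample(0:20, 50, replace = TRUE), ncol = 1)
  pm <- make_matrix(v, unit = "per_million", partial = TRUE)
  rk <- rank_genes(pm, "s1")
  expect_setequal(rk, gene_ids(pm))
  vals <- pm$values[rk, 1]
  for (i in seq_len(49))
    expect_true(vals[i] > vals[i + 1] ||
                  (vals[i] == vals[i + 1] && rk[i] < rk[i + 1]))
})

test_that("cumulative effort curves accumulate correctly", {
  m <- table3_matrix()
  cv <- cumulative_effort_curve(m, "WPG")
  expect_equal(cv$cumulative_effort[3], 11.67912, tolerance = 1e-9)
  expect_true(all(diff(cv$cumulative_effort) >= -1e-12))

  uni <- make_pm(c(1, 1, 1, 1))
  expect_equal(cumulative_effort_curve(uni, "s1")$cumulative_effort,
               c(25, 50, 75, 100))

  set.seed(5)
  full <- make_pm(random_counts(60, 2) + 1)
  for (s in sample_ids(full)) {
    cvf <- cumulative_effort_curve(full, s)
    expect_equal(cvf$cumulative_effort[60], 100, tolerance = 1e-6)
  }
})

test_that("minimal top-k counts match the published values and the scan oracle", {
  m <- table3_matrix()
  expect_identical(min_genes_for_effort(m, "WPG", 10), 3L)
  expect_identical(min_genes_for_effort(m, "PDB", 10), 7L)
  expect_identical(min_genes_for_effort(m, "MPY", 10), 8L)
  expect_identical(min_genes_for_effort(m, "WPG", 0), 0L)

  # nondecreasing in the threshold
  ks <- vapply(1:20, function(t) min_genes_for_effort(m, "WPG", t),
               integer(1))
  expect_true(all(diff(ks) >= 0))

  set.seed(23)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    v <- rlnorm(n, 4, 2)
    pm <- make_matrix(matrix(v, ncol = 1), unit = "per_million",
                      partial = TRUE)
    total <- sum(v) * runif(1, 1, 3)
    for (t in sample(1:99, 5)) {
      expected <- min_genes_oracle(v, t, total)
      if (is.na(expected)) {
        expect_error(min_genes_for_effort(pm, "s1", t, total = total),
                     "insufficient data")
      } else {
        expect_identical(min_genes_for_effort(pm, "s1", t, total = total),
                         expected)
      }
    }
  }
})

test_that("unreachable thresholds on a partial matrix are an explicit error", {
  m <- table3_matrix()
  expect_error(min_genes_for_effort(m, "WPG", 75), "insufficient data")
})

test_that("expressed-gene statistics match the published fractions", {
  expect_equal(round(catalog_fraction(10941, 12346), 1), 88.6)
  expect_equal(round(catalog_fraction(10442, 12346), 1), 84.6)

  pm <- make_matrix(matrix(c(5, 0, 2, 0, 0, 3), 3), unit = "per_million",
                    partial = TRUE)
  st <- expressed_gene_stats(pm, catalog_size = 10)
  expect_identical(st$expressed_genes, c(2L, 1L))
  expect_equal(st$expressed_fraction, c(20, 10))
  expect_identical(expressed_gene_stats(pm, detection_threshold = 10,
                                        catalog_size = 10)$expressed_genes,
                   c(0L, 0L))

  zero <- make_matrix(matrix(0, 3, 1), unit = "per_million", partial = TRUE)
  expect_identical(expressed_gene_stats(zero)$expressed_genes, 0L)
  expect_error(expressed_gene_stats(pm, catalog_size = 2), "catalog_size")
})

test_that("pareto summaries cover the uniform and single-gene edge cases", {
  uni <- make_pm(rep(1, 10))
  ps <- pareto_summary(uni, "s1")
  expect_identical(ps$genes_for_threshold, 8L)   # ceil(0.8 * 10)
  expect_equal(ps$gene_fraction, 80)

  one <- make_pm(5)
  ps1 <- pareto_summary(one, "s1")
  expect_identical(ps1$genes_for_threshold, 1L)
  expect_equal(ps1$gene_fraction, 100)

  expect_error(pareto_summary(table3_matrix(), "WPG"), "full")
})

test_that("concentration summaries assemble per-sample tables", {
  pm <- make_pm(matrix(c(60, 25, 10, 5, 40, 30, 20, 10), 4))
  cs <- concentration_summary(pm, thresholds = c(50, 80))
  expect_identical(cs$genes_to_50, c(1L, 2L))
  expect_identical(cs$genes_to_80, c(2L, 3L))
  expect_equal(cs$gene_fraction_at_80, c(50, 75))
  expect_error(concentration_summary(pm, thresholds = c(50, 50)),
               "strictly increasing")
})
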