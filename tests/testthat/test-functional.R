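test_that("expressed-gene counts per KOG category follow the once-per-class rule", {
  pm <- make_matrix(matrix(c(10, 20, 5, 1), dimnames = list(
    c("g1", "g2", "g3", "g4"), "s1")), unit = "per_million", partial = TRUE)
  ann <- kog_annotation(c("g1", "g2", "g3"), c("J", "J", "O"))
  cc <- kog_category_counts(pm, ann, "s1")
  counts <- setNames(cc$gene_count, cc$category)
  expect_identical(counts[["J"]], 2L)
  expect_identical(counts[["O"]], 1L)
  expect_identical(counts[["unannotated"]], 1L)
  expect_identical(sum(counts), 4L)

  # multi-class genes are counted once per class
  ann2 <- kog_annotation("g1", "JO")
  cc2 <- kog_category_counts(pm, ann2, "s1")
  expect_identical(setNames(cc2$gene_count, cc2$category)[["J"]], 1L)
  expect_identical(setNames(cc2$gene_count, cc2$category)[["O"]], 1L)

  # a threshold above every value empties all categories
  cc3 <- kog_category_counts(pm, ann, "s1", detection_threshold = 100)
  expect_true(all(cc3$gene_count == 0L))
})

test_that("category efforts partition the total", {
  pm <- make_pm(c(a = 3, b = 7))
  dimnames(pm$values) <- list(c("g1", "g2"), "s1")
  ann <- kog_annotation(c("g1", "g2"), c("J", "O"))
  ce <- kog_category_effort(pm, ann, "s1")
  eff <- setNames(ce$effort, ce$category)
  expect_equal(eff[["J"]], 30)
  expect_equal(eff[["O"]], 70)
  expect_equal(sum(ce$effort), 100, tolerance = 1e-6)

  # one class holding everything
  all_o <- kog_annotation(c("g1", "g2"), c("O", "O"))
  ce2 <- kog_category_effort(pm, all_o, "s1")
  expect_equal(setNames(ce2$effort, ce2$category)[["O"]], 100)

  # a two-class gene splits its effort equally across classes
  ann3 <- kog_annotation(c("g1", "g2"), c("JO", ""))
  ce3 <- kog_category_effort(pm, ann3, "s1")
  eff3 <- setNames(ce3$effort, ce3$category)
  expect_equal(eff3[["J"]], 15)
  expect_equal(eff3[["O"]], 15)
  expect_equal(eff3[["unannotated"]], 70)
})

test_that("the partition invariant holds on random annotated matrices", {
  set.seed(47)
  letters25 <- names(kog_categories())
  for (i in 1:20) {
    n <- sample(10:60, 1)
    pm <- make_pm(matrix(rpois(n * 2, 20) + 1, n))
    n_ann <- sample.int(n, 1)
    cls <- replicate(n_ann, paste(sample(letters25, sample(1:3, 1)),
                                  collapse = ""))
    ann <- kog_annotation(sample(gene_ids(pm), n_ann), cls)
    for (s in sample_ids(pm)) {
      ce <- kog_category_effort(pm, ann, s)
      expect_equal(sum(ce$effort), 100, tolerance = 1e-6)
    }
  }
})

test_that("kog_profile combines counts and efforts consistently", {
  pm <- make_pm(c(5, 5, 10))
  ann <- kog_annotation(gene_ids(pm)[1:2], c("J", "G"))
  prof <- kog_profile(pm, ann, "s1")
  expect_identical(colnames(prof), c("category", "gene_count", "effort"))
  expect_equal(sum(prof$effort), 100, tolerance = 1e-6)
  expect_identical(sum(prof$gene_count), 3L)
})

test_that("gene-set efforts sum member efforts and report presence", {
  pm <- make_matrix(matrix(c(10000, 30000, 500), dimnames = list(
    c("g1", "g2", "g3"), "s1")), unit = "per_million", partial = TRUE)
  sets <- gene_set_collection(list(two = c("g1", "g2"),
                                   ghost = c("x1", "x2"),
                                   both = c("g1", "g3")))
  p <- gene_set_effort(pm, sets, "two", "s1")
  expect_equal(p$set_effort, 4.0)
  expect_identical(p$members_present, 2L)
  expect_equal(p$set_effort, sum(p$per_gene$effort), tolerance = 1e-9)
  expect_identical(p$per_gene$gene_id[1], "g2")   # ordered by value
  expect_identical(p$per_gene$rank, c(1L, 2L))

  ghost <- gene_set_effort(pm, sets, "ghost", "s1")
  expect_identical(ghost$members_present, 0L)
  expect_equal(ghost$set_effort, 0)

  # overlap: g1 contributes its full effort to both sets
  both <- gene_set_effort(pm, sets, "both", "s1")
  expect_equal(both$set_effort, (10000 + 500) / 1e4)
  expect_error(gene_set_effort(pm, sets, "nope", "s1"), "unknown gene set")
})

test_that("set efforts are additive over disjoint sets", {
  set.seed(53)
  pm <- make_pm(matrix(rpois(40, 50) + 1, 20))
  ids <- gene_ids(pm)
  a <- ids[1:5]; b <- ids[6:12]
  sets <- gene_set_collection(list(a = a, b = b, union = c(a, b)))
  for (s in sample_ids(pm)) {
    ea <- gene_set_effort(pm, sets, "a", s)$set_effort
    eb <- gene_set_effort(pm, sets, "b", s)$set_effort
    eu <- gene_set_effort(pm, sets, "union", s)$set_effort
    expect_equal(eu, ea + eb, tolerance = 1e-9)
  }
})

test_that("expressed-member counts respect the sample mode", {
  v <- matrix(c(5, 5, 5, 0, 5, 0,
                5, 5, 0, 0, 5, 5), 6,
              dimnames = list(sprintf("g%d", 1:6), c("s1", "s2")))
  pm <- expression_matrix(v, unit = "per_million", partial = TRUE)
  sets <- gene_set_collection(list(grp = sprintf("g%d", 1:6),
                                   ghost = "zzz"))
  expect_identical(count_expressed_in_set(pm, sets, "grp",
                                          mode = "all_samples"), 3L)
  expect_identical(count_expressed_in_set(pm, sets, "grp",
                                          mode = "any_sample"), 5L)
  expect_identical(count_expressed_in_set(pm, sets, "ghost"), 0L)
  expect_gte(count_expressed_in_set(pm, sets, "grp", mode = "any_sample"),
             count_expressed_in_set(pm, sets, "grp", mode = "all_samples"))
})

test_that("top set genes are ordered by cross-sample maximum", {
  v <- matrix(c(200, 1900, 350, 10,
                400, 1200, 300, 20), 4,
              dimnames = list(c("ga", "gb", "gc", "gd"), c("s1", "s2")))
  pm <- expression_matrix(v, unit = "per_million", partial = TRUE)
  sets <- gene_set_collection(list(aroma = c("ga", "gb", "gc", "gd")))
  top <- top_genes_in_set(pm, sets, "aroma", n = 2)
  expect_identical(top$gene_id, c("gb", "ga"))   # 1900 beats max(200, 400)
  expect_equal(top$max_value, c(1900, 400))
  expect_identical(nrow(top_genes_in_set(pm, sets, "aroma", n = 50)), 4L)
  expect_error(top_genes_in_set(pm, sets, "aroma", n = 0), ">= 1")

  set.seed(59)
  pmr <- make_pm(matrix(rpois(60, 30), 20))
  setsr <- gene_set_collection(list(r = sample(gene_ids(pmr), 12)))
  topr <- top_genes_in_set(pmr, setsr, "r", n = 12)
  mx <- apply(pmr$values[topr$gene_id, ], 1, max)
  expect_true(all(diff(mx) <= 1e-12))
})
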