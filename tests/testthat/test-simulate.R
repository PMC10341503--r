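test_that("identical config and seed reproduce the bundle bit for bit", {
  cfg <- small_config(seed = 7)
  b1 <- generate_transcriptome(cfg)
  b2 <- generate_transcriptome(cfg)
  expect_identical(b1$matrix$values, b2$matrix$values)
  expect_identical(b1$annotation, b2$annotation)
  expect_identical(unclass(b1$sets), unclass(b2$sets))
  expect_identical(b1$truth$zero_masks, b2$truth$zero_masks)
  b3 <- generate_transcriptome(small_config(seed = 8))
  expect_false(identical(b1$matrix$values, b3$matrix$values))
})

test_that("expressed fractions land within one percentage point of target", {
  cfg <- synthetic_config(seed = 1)
  b <- generate_transcriptome(cfg)
  frac <- colSums(b$matrix$values > 0) / nrow(b$matrix$values)
  expect_true(all(abs(frac - cfg$frac_expressed[names(frac)]) <= 0.01))
})

test_that("the truth record describes the matrix exactly", {
  cfg <- synthetic_config(seed = 3, planted_outliers = list(
    list(gene = NULL, pair = c("WPG", "WPGY"), fold = 4)))
  b <- generate_transcriptome(cfg)
  cnt <- b$matrix$values
  # masked genes are exactly the zero entries the masks claim
  for (s in colnames(cnt))
    expect_true(all(cnt[b$truth$zero_masks[[s]], s] == 0))
  # the planted outlier is realized at its configured fold within 1%
  tr <- b$truth$outliers
  expect_identical(nrow(tr), 1L)
  expect_lt(abs(tr$realized_fold - tr$fold) / tr$fold, 0.01)
  pm <- normalize_per_million(b$matrix)
  v_a <- pm$values[tr$gene_id, tr$sample_a]
  v_b <- pm$values[tr$gene_id, tr$sample_b]
  expect_equal(v_b / v_a, tr$realized_fold, tolerance = 1e-9)
})

test_that("a planted 4-fold outlier is recovered end to end, exactly", {
  cfg <- synthetic_config(seed = 5, planted_outliers = list(
    list(gene = NULL, pair = c("WPG", "WPGY"), fold = 4)))
  b <- generate_transcriptome(cfg)
  pm <- normalize_per_million(b$matrix)
  det <- fold_change_outliers(pm, "WPG", "WPGY")
  expect_identical(det$gene_id, b$truth$outliers$gene_id)
})

test_that("generated gene sets have the configured structure", {
  cfg <- synthetic_config(seed = 9)
  b <- generate_transcriptome(cfg)
  expect_identical(set_sizes(b$sets), cfg$set_sizes[names(b$sets)])
  expect_identical(length(intersect(b$sets$tca, b$sets$etc)), 2L)

  # aroma: all but aroma_unexpressed members expressed in every condition
  expect_identical(
    count_expressed_in_set(b$matrix, b$sets, "aroma", mode = "all_samples"),
    cfg$set_sizes[["aroma"]] - cfg$aroma_unexpressed)
  expect_identical(
    count_expressed_in_set(b$matrix, b$sets, "aroma", mode = "any_sample"),
    cfg$set_sizes[["aroma"]])

  # secondary-cluster members: low expression, deep ranks, tiny effort
  pm <- normalize_per_million(b$matrix)
  clusters <- b$truth$cluster_sets
  for (s in sample_ids(pm)) {
    profs <- lapply(clusters, function(nm) gene_set_effort(pm, b$sets, nm, s))
    expect_true(all(unlist(lapply(profs, function(p) p$per_gene$value)) <= 60))
    expect_true(all(unlist(lapply(profs, function(p) p$per_gene$rank)) > 2000))
    expect_lte(sum(vapply(profs, `[[`, numeric(1), "set_effort")), 0.1)
  }
})

test_that("tail calibration converges on the defaults and reports its stats", {
  cal <- calibrate_tail(synthetic_config(seed = 2), n_draws = 12)
  expect_true(all(txeffort:::.check_windows(cal$achieved)))
  expect_gt(cal$tail$tail_mass, 0)
  expect_lt(cal$tail$tail_mass, 0.4)
})

test_that("infeasible calibration targets raise errors carrying diagnostics", {
  # a pure lognormal cannot concentrate ~10% of effort on three genes
  cfg0 <- synthetic_config(seed = 2)
  cfg0$tail$tail_mass <- 0
  err <- tryCatch(calibrate_tail(cfg0, n_draws = 6, adjust = "none"),
                  calibration_error = function(e) e)
  expect_s3_class(err, "calibration_error")
  expect_true("top3" %in% names(err$achieved))
  expect_lt(err$achieved[["top3"]], 8)

  # a degenerate 100% top-3 target is unreachable for any tail mass
  cfg100 <- synthetic_config(seed = 2, top3_effort_target = 100)
  expect_error(calibrate_tail(cfg100, n_draws = 4), "outside the achievable")
})

test_that("bundles round-trip through the standard file formats", {
  dir <- withr::local_tempdir()
  b <- generate_transcriptome(small_config(seed = 13))
  write_bundle(b, dir)
  m <- read_expression_matrix(file.path(dir, "matrix.tsv"))
  expect_equal(m$values, b$matrix$values)
  ann <- read_kog_annotation(file.path(dir, "annotation.tsv"))
  expect_identical(ann$gene_id, b$annotation$gene_id)
  expect_identical(ann$kog_class, b$annotation$kog_class)
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  expect_identical(set_sizes(sets), set_sizes(b$sets))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(sort(names(truth$zero_masks)),
                   sort(colnames(b$matrix$values)))
})

test_that("the annotation fraction and class vocabulary are respected", {
  cfg <- synthetic_config(seed = 17)
  b <- generate_transcriptome(cfg)
  expect_equal(nrow(b$annotation) / cfg$n_genes, cfg$kog_fraction,
               tolerance = 1e-3)
  letters_used <- unique(unlist(strsplit(b$annotation$kog_class, "")))
  expect_true(all(letters_used %in% names(kog_categories())))
})
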