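test_that("corpus generation is a pure function of config and seed", {
  cfg <- corpus_config(n_datasets = 4, n_genes = 120, n_planted_stable = 10,
                       n_categories = 2, per_category_planted = 5, seed = 9)
  a <- simulate_corpus(cfg)
  b <- simulate_corpus(cfg)
  for (id in names(a$collection$datasets)) {
    expect_identical(a$collection$datasets[[id]]$values,
                     b$collection$datasets[[id]]$values)
  }
  expect_identical(a$truth, b$truth)
  c2 <- simulate_corpus(corpus_config(n_datasets = 4, n_genes = 120,
                                      n_planted_stable = 10, n_categories = 2,
                                      per_category_planted = 5, seed = 10))
  expect_false(identical(a$collection$datasets[[1]]$values,
                         c2$collection$datasets[[1]]$values))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_corpus(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("emitted corpora satisfy the data-model invariants", {
  sim <- simulate_corpus(corpus_config(n_datasets = 5, n_genes = 150,
                                       n_planted_stable = 12, seed = 3))
  col <- sim$collection
  expect_s3_class(col, "dataset_collection")
  expect_identical(col$gene_universe,
                   sort(unique(unlist(lapply(col$datasets, dataset_genes)))))
  for (ds in col$datasets) {
    expect_true(all(ds$values >= 0, na.rm = TRUE))
    expect_true(all(colSums(!is.na(ds$values)) >= 1))
    # missingness drops whole genes per dataset
    expect_lt(length(dataset_genes(ds)), 150 + 1)
  }
  expect_identical(sort(unlist(datasets_in_category(sim$mesh, "ALL"))),
                   sort(names(col$datasets)))
})

test_that("planted genes out-rank non-planted genes in Ratio_t", {
  sim <- simulate_corpus(corpus_config(n_datasets = 8, n_genes = 400,
                                       n_planted_stable = 30,
                                       n_categories = 0, seed = 13))
  fit <- ref_stability(sim$collection, t = 0.12)
  s <- fit$summaries
  planted <- s$ratio[s$gene %in% sim$truth$universal_stable]
  others <- s$ratio[!s$gene %in% sim$truth$universal_stable]
  expect_gt(median(planted, na.rm = TRUE), median(others, na.rm = TRUE))
  expect_gte(median(planted, na.rm = TRUE), 0.9)
  # planted genes sit in the top decile of expression
  expect_gt(min(s$mean_rank[s$gene %in% sim$truth$universal_stable]), 70)
})

test_that("a noise-free corpus has zero CV everywhere", {
  cfg <- corpus_config(n_datasets = 3, n_genes = 60, n_planted_stable = 60,
                       n_categories = 0, probes_per_gene = c(1, 1),
                       stable_rank_noise_sd = 0, missing_gene_fraction = 0,
                       seed = 2)
  sim <- simulate_corpus(cfg)
  ct <- build_cv_table(sim$collection)
  expect_true(all(abs(ct$cv) < 1e-12, na.rm = TRUE))
})

test_that("qPCR simulation honors its planted structure and seed", {
  a <- simulate_qpcr(planted_unstable = "GENE05", seed = 8)
  b <- simulate_qpcr(planted_unstable = "GENE05", seed = 8)
  expect_identical(a$cq, b$cq)
  expect_identical(attr(a, "planted_unstable"), "GENE05")
  expect_true(all(a$cq > 10 & a$cq < 32))
  expect_true(all(a$efficiency >= 0.85 & a$efficiency <= 1))
  expect_identical(table(a$groups)[c("Liver", "Breast", "Colon")],
                   table(rep(c("Liver", "Breast", "Colon"), c(8, 5, 3)))[
                     c("Liver", "Breast", "Colon")])
  # zero noise and no shifts: every stability measure vanishes
  quiet <- simulate_qpcr(noise_sd_cq = 0, seed = 1)
  fit <- qpcr_stability(quiet)
  expect_equal(unname(fit$scopes$All$cv), rep(0, 17))
  expect_equal(unname(fit$scopes$All$genorm_m), rep(0, 17))
  expect_equal(unname(fit$scopes$All$normfinder), rep(0, 17))
  # group-shifted gene: quiet within groups for geNorm, loud for NormFinder
  shifted <- simulate_qpcr(group_shift_genes = "GENE01", noise_sd_cq = 0.05,
                           seed = 21)
  fit2 <- qpcr_stability(shifted)
  all_sc <- fit2$scopes$All
  i <- which(all_sc$gene == "GENE01")
  expect_identical(all_sc$normfinder_rank[i], 17L)
  # within one tissue the shifted gene is as quiet as the rest (low M),
  # while pooling groups inflates its pairwise variation
  expect_lt(fit2$scopes$Liver$genorm_m[i], 0.5)
  expect_gt(all_sc$genorm_m[i], 2 * fit2$scopes$Liver$genorm_m[i])
})

test_that("infeasible configurations are rejected", {
  expect_error(corpus_config(n_genes = 50, n_planted_stable = 40,
                             n_categories = 2, per_category_planted = 10),
               "exceed")
  expect_error(corpus_config(samples_per_dataset = c(1, 1)), "at least 2")
  expect_error(corpus_config(missing_gene_fraction = 1), "missing_gene_fraction")
  expect_error(simulate_qpcr(planted_unstable = "NOPE"), "unknown gene")
  expect_error(simulate_qpcr(groups = c(L = 1, B = 5)), "at least 2")
})
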