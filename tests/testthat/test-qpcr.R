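test_that("efficiency follows the standard-curve closed form", {
  expect_equal(efficiency_from_slope(-1 / log10(2)), 1.0)
  expect_equal(efficiency_from_slope(-1 / log10(1.9)), 0.9)
  expect_error(efficiency_from_slope(0), "negative")
  expect_error(efficiency_from_slope(3.32), "negative")
})

test_that("relative expression is (1+E)^-dCq against the per-gene minimum", {
  cq <- rbind(GA = c(20, 21, 22), GB = c(25, 25, 27))
  colnames(cq) <- paste0("s", 1:3)
  tbl <- qpcr_table(cq, c(GA = 1, GB = 0.9),
                    c(s1 = "L", s2 = "L", s3 = "B"))
  q <- relative_expression(tbl)
  expect_equal(q["GA", ], c(s1 = 1, s2 = 0.5, s3 = 0.25))  # perfect doubling
  expect_equal(q["GB", "s3"], 1.9^-2, tolerance = 1e-12)    # E = 0.9, dCq = 2
  expect_equal(unname(apply(q, 1, max)), c(1, 1))           # reference sample
  # missing Cq propagates to a missing quantity
  cq["GA", 2] <- NA
  tbl2 <- qpcr_table(cq, c(GA = 1, GB = 0.9), c(s1 = "L", s2 = "L", s3 = "B"))
  expect_true(is.na(relative_expression(tbl2)["GA", "s2"]))
})

test_that("qPCR CV stability matches the two-point closed form and brute force", {
  q <- rbind(GA = c(0.5, 1.0), GB = c(0.7, 0.7))
  colnames(q) <- c("s1", "s2")
  cv <- cv_stability(q)
  expect_equal(unname(cv["GA"]), sd(c(0.5, 1)) / 0.75)  # 0.4714
  expect_equal(unname(cv["GB"]), 0)
  expect_identical(names(cv)[1], "GB")  # sorted ascending, most stable first
  qq <- toy_quantities()
  expect_equal(unname(cv_stability(qq)[rownames(qq)]),
               unname(apply(qq, 1, function(x) oracle_cv(x))),
               tolerance = 1e-12)
})

test_that("geNorm M values, exclusion order and V(n/n+1) match brute force", {
  qq <- toy_quantities()
  gn <- genorm_stability(qq)
  expect_equal(gn$m_values, oracle_genorm_m(qq), tolerance = 1e-12)
  # proportional genes have zero pairwise variation; the noisy one leaves first
  expect_equal(unname(gn$m_values["A"] - gn$m_values["B"]), 0, tolerance = 1e-12)
  expect_identical(gn$exclusion_order[1], "C")
  expect_identical(gn$final_pair, c("A", "B"))

  withr::local_seed(33)
  q5 <- matrix(2^rnorm(5 * 8, 0, 1), 5, 8,
               dimnames = list(paste0("G", 1:5), paste0("s", 1:8)))
  q5 <- q5 / apply(q5, 1, max)
  gn5 <- genorm_stability(q5)
  expect_equal(gn5$m_values, oracle_genorm_m(q5), tolerance = 1e-10)
  pv <- genorm_pairwise_variation(q5, gn5$ranking)
  expect_equal(unname(pv$v), oracle_genorm_v(q5, gn5$ranking), tolerance = 1e-10)
  expect_named(pv$v, c("V2/3", "V3/4", "V4/5"))

  # scaling one gene by a constant changes neither M nor V
  q5b <- q5
  q5b[2, ] <- q5b[2, ] * 7
  expect_equal(genorm_stability(q5b)$m_values, gn5$m_values, tolerance = 1e-10)
  expect_equal(genorm_pairwise_variation(q5b, gn5$ranking)$v, pv$v,
               tolerance = 1e-10)

  # all-proportional panel: every V is zero, two genes suffice
  prop <- outer(c(1, 0.5, 0.25, 0.8), c(1, 0.3, 0.6, 0.9, 0.2))
  dimnames(prop) <- list(paste0("G", 1:4), paste0("s", 1:5))
  gnp <- genorm_stability(prop)
  expect_equal(unname(gnp$m_values), rep(0, 4))
  pvp <- genorm_pairwise_variation(prop, gnp$ranking)
  expect_equal(unname(pvp$v), c(0, 0))
  expect_identical(pvp$n_sufficient, 2L)

  expect_error(genorm_stability(qq[1:2, ]), "at least 3 genes")
  qq_zero <- qq; qq_zero[1, 1] <- 0
  expect_error(genorm_stability(qq_zero), "positive")
})

test_that("NormFinder separates group shifts from noise and matches brute force", {
  withr::local_seed(44)
  groups <- rep(c("L", "B", "C"), c(8, 5, 3))
  n <- length(groups)
  mk <- function(gen) {
    q <- 2^t(vapply(1:6, function(i) gen(i), numeric(n)))
    dimnames(q) <- list(paste0("G", 1:6), paste0("s", 1:n))
    q / apply(q, 1, max)
  }
  # gene 6 carries a large group shift with small within-group noise
  shift <- c(L = 0, B = 3, C = -3)
  q <- mk(function(i) {
    if (i == 6) rnorm(n, 0, 0.1) + shift[groups] else rnorm(n, 0, 0.3)
  })
  nf <- normfinder_stability(q, groups)
  expect_equal(nf, oracle_normfinder(q, groups), tolerance = 1e-10)
  expect_identical(names(nf)[6], "G6")   # shifted gene ranked last
  # within-group geNorm (single group) barely penalizes the shifted gene
  gl <- genorm_stability(q, samples = paste0("s", 1:8))
  expect_false(gl$exclusion_order[1] == "G6")

  # constant table: all stabilities zero
  q0 <- matrix(1, 4, n, dimnames = list(paste0("G", 1:4), paste0("s", 1:n)))
  expect_equal(unname(normfinder_stability(q0, groups)), rep(0, 4))

  # dropping the least stable gene changes the remaining values
  nf_red <- normfinder_stability(q[names(nf)[1:5], ], groups)
  expect_false(isTRUE(all.equal(nf[names(nf)[1:5]], nf_red[names(nf)[1:5]])))

  expect_error(normfinder_stability(q, rep(c("L", "B"), c(15, 1))),
               "fewer than 2 samples")
})

test_that("high-sd genes are excluded on the log2 scale", {
  withr::local_seed(55)
  q <- matrix(2^rnorm(4 * 10, 0, 0.3), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("s", 1:10)))
  q["G3", ] <- 2^rnorm(10, 0, 4)   # one wildly dispersed gene
  q <- q / apply(q, 1, max)
  expect_identical(exclude_high_sd_genes(q, Inf), rownames(q))
  expect_identical(exclude_high_sd_genes(q, 1.42), c("G1", "G2", "G4"))
  expect_error(exclude_high_sd_genes(q, 1e-9), "removes every gene")
})

test_that("the full qPCR fit reports per-scope rankings as permutations", {
  tbl <- simulate_qpcr(planted_unstable = "GENE17", seed = 101)
  fit <- qpcr_stability(tbl)
  expect_named(fit$scopes, c("All", "Breast", "Colon", "Liver"))
  for (sc in fit$scopes) {
    n <- nrow(sc)
    expect_setequal(sc$cv_rank, seq_len(n))
    expect_setequal(sc$genorm_rank, seq_len(n))
    expect_setequal(sc$normfinder_rank, seq_len(n))
  }
  all_sc <- fit$scopes$All
  i <- which(all_sc$gene == "GENE17")
  expect_identical(all_sc$cv_rank[i], 17L)
  expect_identical(all_sc$genorm_rank[i], 17L)
  expect_identical(all_sc$normfinder_rank[i], 17L)
  expect_output(print(fit), "pairwise variation")
  # the stability measures ignore sample order
  perm <- sample(seq_along(tbl$samples))
  tbl2 <- qpcr_table(tbl$cq[, perm], tbl$efficiency,
                     setNames(tbl$groups[perm], tbl$samples[perm]))
  fit2 <- qpcr_stability(tbl2)
  expect_equal(fit2$scopes$All$cv, all_sc$cv, tolerance = 1e-12)
  expect_equal(fit2$scopes$All$genorm_m, all_sc$genorm_m, tolerance = 1e-12)
  expect_equal(fit2$scopes$All$normfinder, all_sc$normfinder, tolerance = 1e-12)
})

test_that("long-format Cq files round-trip with replicate averaging", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("gene\tsample\tgroup\tcq_rep1\tcq_rep2\tslope",
            sprintf("GA\ts%d\tL\t%g\t%g\t%g", 1:2, c(20, 21), c(20.4, 21.6),
                    -1 / log10(2)),
            sprintf("GB\ts%d\tL\t%g\t%g\t%g", 1:2, c(25, 24), c(25, 24),
                    -1 / log10(1.9)))
  writeLines(rows, path)
  tbl <- read_qpcr_table(path)
  expect_equal(tbl$cq["GA", ], c(s1 = 20.2, s2 = 21.3))
  expect_equal(unname(tbl$efficiency), c(1, 0.9), tolerance = 1e-5)
  expect_identical(tbl$groups, c("L", "L"))
})
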