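# A hand-built CV table with fully controlled Ratio_t / PO values: genes
# are rows, datasets columns; NA = unobserved.
manual_cv_table <- function(cv) {
  refrank:::.new_cv_table(cv, ncol(cv))
}

test_that("the classifier gates use >= on Ratio_t and PO, strict CV inside", {
  cv <- rbind(
    HKA = c(0.01, 0.02, 0.03, 0.04, 0.05),   # ratio 1, po 1
    HKB = c(0.01, 0.02, NA,   NA,   0.05),   # ratio 1, po 0.6
    MIX = c(0.01, 0.02, 0.03, 0.04, 0.50),   # ratio 0.8 at t=0.12
    LOW = c(0.50, 0.60, 0.70, 0.80, 0.90))
  colnames(cv) <- paste0("D", 1:5)
  ct <- manual_cv_table(cv)
  expect_identical(classify(ct, t = 0.12), "HKA")           # PO gate drops HKB
  expect_identical(classify(ct, t = 0.12, min_po = 0.6), c("HKA", "HKB"))
  expect_identical(classify(ct, t = 0.12, min_ratio = 0.8), c("HKA", "MIX"))
  # ratio exactly at the gate passes (>=), CV exactly at t does not count
  expect_identical(classify(ct, t = 0.5, min_ratio = 0.8), c("HKA", "MIX"))
  expect_identical(classify(ct, t = 0.5000001, min_ratio = 1), c("HKA", "MIX"))
})

test_that("confusion counts partition the universe", {
  universe <- paste0("G", 1:10)
  truth <- paste0("G", 1:4)
  predicted <- c("G1", "G2", "G9")
  cm <- confusion(predicted, truth, universe)
  expect_identical(cm, c(TP = 2L, FP = 1L, TN = 5L, FN = 2L))
  expect_identical(cm, oracle_confusion(predicted, truth, universe))
  expect_identical(sum(cm), length(universe))
  # degenerate cases
  expect_identical(confusion(universe, universe, universe),
                   c(TP = 10L, FP = 0L, TN = 0L, FN = 0L))
  cm0 <- confusion(character(), truth, universe)
  expect_identical(unname(cm0[["TP"]] / (cm0[["TP"]] + cm0[["FN"]])), 0)
  expect_identical(unname(cm0[["TN"]] / (cm0[["TN"]] + cm0[["FP"]])), 1)
  expect_error(confusion(predicted, truth, character()), "empty")
})

test_that("ROC sweeps are monotone and the trapezoid AUC equals pairwise AUROC", {
  col <- rand_collection(61, max_datasets = 6, max_samples = 7, max_genes = 40)
  fit <- ref_stability(col, 0.12)
  ct <- fit$cv_table
  observed <- ct$genes[ct$n_observed > 0]
  withr::local_seed(62)
  truth <- sample(observed, 12)
  roc <- roc_curve(fit, truth)
  p <- roc$points
  expect_true(all(diff(p$sensitivity) >= 0))
  expect_true(all(diff(p$specificity) <= 0))
  expect_true(all(diff(p$TP) >= 0) && all(diff(p$TN) <= 0))
  expect_true(all(p$TP + p$FP + p$TN + p$FN == roc$universe_size))

  # per-gene entry threshold: smallest t at which the gene is classified is
  # the k-th smallest CV with k = ceiling(0.9 * n_observed); PO-failing
  # genes never enter (score Inf). A grid hitting every entry point makes
  # the trapezoid AUC exactly the pairwise-ranking AUROC.
  po <- ct$n_observed[observed] / ct$n_total
  scores <- vapply(observed, function(g) {
    if (po[[g]] < 0.75) return(Inf)
    cvs <- sort(ct$cv[g, !is.na(ct$cv[g, ])])
    cvs[ceiling(0.9 * length(cvs))]
  }, numeric(1))
  grid <- sort(unique(scores[is.finite(scores)])) + 1e-9
  roc2 <- roc_curve(fit, truth, t_grid = grid)
  expect_equal(roc2$auc, oracle_pairwise_auroc(scores, observed %in% truth),
               tolerance = 1e-10)
})

test_that("random ground truth yields chance-level AUROC", {
  aucs <- vapply(1:8, function(s) {
    col <- rand_collection(200 + s, max_datasets = 6, max_samples = 6,
                           max_genes = 50)
    fit <- ref_stability(col)
    observed <- fit$cv_table$genes[fit$cv_table$n_observed > 0]
    truth <- withr::with_seed(300 + s, sample(observed, 15))
    roc_curve(fit, truth, min_po = 0)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("a saturating threshold classifies everything that passes the gates", {
  cv <- rbind(HKA = c(0.01, 0.02), VAR = c(5, 8), RARE = c(0.1, NA))
  colnames(cv) <- c("D1", "D2")
  ct <- manual_cv_table(cv)
  expect_identical(classify(ct, t = 100, min_po = 0.75), c("HKA", "VAR"))
  cm <- confusion(classify(ct, t = 100, min_po = 0), c("HKA"), rownames(cv))
  expect_identical(unname(cm[["TP"]] / (cm[["TP"]] + cm[["FN"]])), 1)
  expect_identical(unname(cm[["TN"]] / (cm[["TN"]] + cm[["FP"]])), 0)
})

test_that("list emission honors both modes and the sort contract", {
  sim <- simulate_corpus(corpus_config(n_datasets = 8, n_genes = 300,
                                       n_planted_stable = 30,
                                       n_categories = 0, seed = 5))
  fit <- ref_stability(sim$collection, 0.12)
  truth <- sim$truth$universal_stable
  fixed <- emit_reference_lists(fit, truth, mode = "fixed_cv")
  expect_true(all(fixed$gene %in% classify(fit, t = 0.12)))
  expect_true(all(fixed$cv_threshold == 0.12))
  expect_true(all(fixed$ratio >= 0.9 & fixed$po >= 0.75))
  expect_false(is.unsorted(-fixed$ratio))  # descending ratio within equal CV

  sens_mode <- emit_reference_lists(fit, truth, mode = "fixed_sensitivity")
  expect_true(all(sens_mode$sensitivity >= 0.5))
  # the chosen threshold is the smallest grid point reaching the target
  grid <- exp(seq(log(0.01), log(10), length.out = 100))
  roc <- roc_curve(fit, truth)
  t_star <- roc$points$t[which(roc$points$sensitivity >= 0.5)[1]]
  expect_equal(unique(sens_mode$cv_threshold), t_star)

  # unreachable sensitivity errors with the best achieved value
  expect_error(
    emit_reference_lists(fit, truth, mode = "fixed_sensitivity",
                         target_sensitivity = 1.5),
    "max achieved")

  # no gene passing the gates: empty list plus warning
  expect_warning(
    empty <- emit_reference_lists(fit, truth, mode = "fixed_cv",
                                  cv_fixed = 1e-6),
    "empty list")
  expect_identical(nrow(empty), 0L)
})
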