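# The CV-threshold classifier, confusion counts against a ground-truth
# housekeeping list, ROC curves and the two list-emission modes.

#' Classifier settings for the CV-threshold reference-gene classifier
#'
#' @param t CV threshold at which `Ratio_t` is computed.
#' @param min_ratio Minimum `Ratio_t` to call a gene a reference gene
#'   (default 0.9).
#' @param min_po Minimum percentage of occurrence (default 0.75).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(t = 0.12, min_ratio = 0.9, min_po = 0.75) {
  if (!(t > 0)) .stopf("t must be positive")
  if (min_ratio < 0 || min_ratio > 1 || min_po < 0 || min_po > 1) {
    .stopf("min_ratio and min_po must lie in [0, 1]")
  }
  structure(list(t = t, min_ratio = min_ratio, min_po = min_po),
            class = "classifier_config")
}

#' Classify genes as reference genes by Ratio_t and PO gates
#'
#' A gene is called a reference gene when its CV of ranks is below `t` in
#' at least `min_ratio` of the datasets in which it is observed
#' (`Ratio_t >= min_ratio`) and it is observed in at least `min_po` of all
#' datasets (`PO >= min_po`). Both gates use `>=` ("at least"); the CV
#' comparison inside `Ratio_t` is strict.
#'
#' @param fit A [ref_stability()] object (or a bare [build_cv_table()]
#'   result).
#' @param t CV threshold; defaults to the fit's own `t`.
#' @param min_ratio,min_po Classifier gates, see [classifier_config()].
#' @return Character vector of classified gene symbols.
#' @export
classify <- function(fit, t = NULL, min_ratio = 0.9, min_po = 0.75) {
  cv_table <- .as_cv_table(fit)
  if (is.null(t)) t <- if (inherits(fit, "ref_stability")) fit$t else .stopf("t is required")
  ratio <- .ratio_all(cv_table, t)
  po <- cv_table$n_observed / cv_table$n_total
  keep <- !is.na(ratio) & ratio >= min_ratio & po >= min_po
  cv_table$genes[keep]
}

.as_cv_table <- function(fit) {
  if (inherits(fit, "ref_stability")) fit$cv_table
  else if (inherits(fit, "cv_table")) fit
  else .stopf("expected a ref_stability or cv_table object")
}

#' Confusion counts of a predicted gene set against a ground truth
#'
#' The ground truth is intersected with the universe before counting;
#' ground-truth genes found by the classifier are true positives (TP),
#' missed ones false negatives (FN), non-truth genes found are false
#' positives (FP) and the rest true negatives (TN).
#'
#' @param predicted Character vector of predicted reference genes
#'   (subset of `universe`).
#' @param ground_truth Character vector of known housekeeping genes.
#' @param universe Character vector of all genes under consideration.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(predicted, ground_truth, universe) {
  if (!length(universe)) .stopf("empty gene universe")
  predicted <- intersect(predicted, universe)
  truth <- intersect(ground_truth, universe)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' ROC curve of the CV-threshold classifier
#'
#' Sweeps the CV threshold `t` over `t_grid` (by default 100 log-spaced
#' points from 0.01 to 10) with the `Ratio_t` and PO gates fixed, and
#' counts the classifier's confusion against the ground-truth housekeeping
#' list at every threshold. The universe is the set of genes observed in
#' at least one dataset.
#'
#' @param fit A [ref_stability()] object or [build_cv_table()] result.
#' @param ground_truth Character vector of known housekeeping genes.
#' @param t_grid Ascending vector of CV thresholds.
#' @param min_ratio,min_po Fixed classifier gates (defaults 0.9 / 0.75).
#' @return Object of class `ref_roc`: data frame `points` with one row per
#'   threshold (`t`, `TP`, `FP`, `TN`, `FN`, `sensitivity`,
#'   `specificity`), plus `ground_truth_size`, `universe_size` and the
#'   trapezoidal `auc`. Methods: `print`, `plot`.
#' @export
roc_curve <- function(fit, ground_truth,
                      t_grid = exp(seq(log(0.01), log(10), length.out = 100L)),
                      min_ratio = 0.9, min_po = 0.75) {
  cv_table <- .as_cv_table(fit)
  if (is.unsorted(t_grid)) .stopf("t_grid must be ascending")
  universe <- cv_table$genes[cv_table$n_observed > 0L]
  truth <- intersect(toupper(ground_truth), universe)
  if (!length(truth)) .stopf("ground truth is disjoint from the gene universe")
  po <- (cv_table$n_observed / cv_table$n_total)[cv_table$n_observed > 0L]
  cv <- cv_table$cv[cv_table$n_observed > 0L, , drop = FALSE]
  n_obs <- cv_table$n_observed[cv_table$n_observed > 0L]
  is_truth <- universe %in% truth
  pts <- vapply(t_grid, function(t) {
    ratio <- rowSums(cv < t, na.rm = TRUE) / n_obs
    pred <- ratio >= min_ratio & po >= min_po
    tp <- sum(pred & is_truth); fp <- sum(pred & !is_truth)
    fn <- sum(!pred & is_truth); tn <- sum(!pred & !is_truth)
    c(tp, fp, tn, fn)
  }, numeric(4))
  points <- data.frame(t = t_grid, TP = pts[1, ], FP = pts[2, ],
                       TN = pts[3, ], FN = pts[4, ])
  points$sensitivity <- points$TP / (points$TP + points$FN)
  points$specificity <- points$TN / (points$TN + points$FP)
  structure(list(points = points,
                 ground_truth_size = length(truth),
                 universe_size = length(universe),
                 min_ratio = min_ratio, min_po = min_po,
                 auc = .roc_auc(points$sensitivity, points$specificity)),
            class = "ref_roc")
}

# Trapezoidal area under (1 - specificity, sensitivity), with the (0,0)
# and (1,1) corners appended so the sweep's reachable range is closed.
.roc_auc <- function(sens, spec) {
  x <- c(0, 1 - spec, 1)
  y <- c(0, sens, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.ref_roc <- function(x, ...) {
  cat(sprintf("ROC of CV-threshold classifier (Ratio_t >= %g, PO >= %g gates)\n",
              x$min_ratio, x$min_po))
  cat(sprintf("  universe %d genes, ground truth %d genes, %d thresholds\n",
              x$universe_size, x$ground_truth_size, nrow(x$points)))
  cat(sprintf("  AUROC (trapezoid) = %.4f\n", x$auc))
  invisible(x)
}

#' @export
plot.ref_roc <- function(x, ...) {
  plot(1 - x$points$specificity, x$points$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1),
       main = sprintf("CV-threshold classifier ROC (AUROC %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Emit a reference-gene list at a fixed CV or a fixed sensitivity
#'
#' Two modes: `"fixed_cv"` classifies at `cv_fixed` (default CV < 0.12);
#' `"fixed_sensitivity"` searches `t_grid` for the smallest CV threshold
#' whose classification reaches `target_sensitivity` (default 0.5) against
#' the ground truth. Every record carries the emitting threshold's
#' list-level sensitivity and specificity.
#'
#' @param fit A [ref_stability()] object.
#' @param ground_truth Character vector of known housekeeping genes.
#' @param mode `"fixed_cv"` or `"fixed_sensitivity"`.
#' @param cv_fixed CV threshold for `"fixed_cv"` mode.
#' @param target_sensitivity Sensitivity floor for `"fixed_sensitivity"`.
#' @param t_grid Thresholds searched in `"fixed_sensitivity"` mode.
#' @param min_ratio,min_po Classifier gates.
#' @return Data frame of reference-gene records with columns `gene`,
#'   `cv_threshold`, `ratio`, `po`, `mean_rank`, `median_rank`,
#'   `sensitivity`, `specificity`, sorted as in [write_reference_list()].
#' @export
emit_reference_lists <- function(fit, ground_truth,
                                 mode = c("fixed_cv", "fixed_sensitivity"),
                                 cv_fixed = 0.12, target_sensitivity = 0.5,
                                 t_grid = exp(seq(log(0.01), log(10), length.out = 100L)),
                                 min_ratio = 0.9, min_po = 0.75) {
  stopifnot(inherits(fit, "ref_stability"))
  mode <- match.arg(mode)
  truth <- toupper(ground_truth)
  if (mode == "fixed_cv") {
    t_use <- cv_fixed
  } else {
    roc <- roc_curve(fit, truth, t_grid, min_ratio, min_po)
    hit <- which(roc$points$sensitivity >= target_sensitivity)
    if (!length(hit)) {
      .stopf("no threshold on the grid reaches sensitivity >= %g (max achieved: %.4f)",
             target_sensitivity, max(roc$points$sensitivity))
    }
    t_use <- roc$points$t[hit[1L]]
  }
  predicted <- classify(fit, t = t_use, min_ratio = min_ratio, min_po = min_po)
  universe <- fit$cv_table$genes[fit$cv_table$n_observed > 0L]
  cm <- confusion(predicted, truth, universe)
  sens <- if (cm["TP"] + cm["FN"] > 0) cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]) else NA_real_
  spec <- if (cm["TN"] + cm["FP"] > 0) cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]) else NA_real_
  if (!length(predicted)) {
    .warnf("no gene passes the Ratio_t/PO gates at t = %g; emitting an empty list", t_use)
    return(data.frame(gene = character(), cv_threshold = numeric(),
                      ratio = numeric(), po = numeric(), mean_rank = numeric(),
                      median_rank = numeric(), sensitivity = numeric(),
                      specificity = numeric()))
  }
  s <- fit$summaries[match(predicted, fit$summaries$gene), ]
  ratio_use <- ratio_t(fit$cv_table, predicted, t_use)
  rec <- data.frame(gene = predicted,
                    cv_threshold = t_use,
                    ratio = unname(ratio_use),
                    po = s$po,
                    mean_rank = s$mean_rank,
                    median_rank = s$median_rank,
                    sensitivity = sens,
                    specificity = spec,
                    row.names = NULL)
  rec[order(rec$cv_threshold, -rec$ratio, rec$gene), ]
}
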