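# Per-dataset CV of ranks, Ratio_t, percentage of occurrence, f_PO counts
# and the main corpus-screening fit.

#' Coefficient of variation of one gene's ranks in one dataset
#'
#' The CV is the sample (n-1) standard deviation of the gene's non-missing
#' percentile ranks across the dataset's samples, divided by their mean.
#' It is the per-dataset measure of how much a gene's relative expression
#' level moves between samples.
#'
#' @param rank_row Numeric vector of percentile ranks (one gene, one
#'   dataset); `NA` allowed.
#' @return The CV, a non-negative number.
#' @export
gene_dataset_cv <- function(rank_row) {
  x <- rank_row[!is.na(rank_row)]
  if (length(x) < 2L) {
    .stopf("CV needs at least 2 non-missing ranks (got %d)", length(x))
  }
  m <- mean(x)
  if (m <= 0) .stopf("CV undefined: mean rank is not positive")
  stats::sd(x) / m
}

# Rank every dataset of a collection once.
.rank_all <- function(collection) {
  lapply(collection$datasets, rank_dataset)
}

# genes x datasets CV matrix (NA where the gene has < 2 ranks) plus a
# pooled genes x (all samples) rank matrix for mean/median summaries.
.cv_from_ranks <- function(rank_list, universe) {
  n_ds <- length(rank_list)
  ids <- vapply(rank_list, `[[`, character(1), "dataset_id")
  cv <- matrix(NA_real_, length(universe), n_ds, dimnames = list(universe, ids))
  pooled <- vector("list", n_ds)
  for (k in seq_len(n_ds)) {
    rm <- rank_list[[k]]
    full <- matrix(NA_real_, length(universe), length(rm$samples),
                   dimnames = list(universe, paste(ids[k], rm$samples, sep = ":")))
    full[rm$genes, ] <- rm$ranks
    n_obs <- rowSums(!is.na(full))
    mu <- .row_means_na(full)
    sdv <- .row_sds_na(full)
    has_cv <- n_obs >= 2L
    if (any(has_cv & mu <= 0, na.rm = TRUE)) {
      .stopf("dataset %s: gene with non-positive mean rank", ids[k])
    }
    cv[has_cv, k] <- (sdv / mu)[has_cv]
    pooled[[k]] <- full
  }
  list(cv = cv, pooled = do.call(cbind, pooled))
}

#' Build the gene-by-dataset CV table of a collection
#'
#' A gene is *observed* in a dataset when it has at least 2 non-missing
#' rank values there, the minimum for a CV; observation bookkeeping feeds
#' the percentage of occurrence (PO).
#'
#' @param collection A [dataset_collection()].
#' @return Object of class `cv_table`: list with `cv` (gene x dataset
#'   matrix, `NA` where unobserved), `genes`, `dataset_ids`, `n_total`
#'   (number of datasets) and `n_observed` (per-gene observation counts).
#' @export
build_cv_table <- function(collection) {
  stopifnot(inherits(collection, "dataset_collection"))
  res <- .cv_from_ranks(.rank_all(collection), collection$gene_universe)
  .new_cv_table(res$cv, length(collection$datasets))
}

.new_cv_table <- function(cv, n_total) {
  structure(list(cv = cv,
                 genes = rownames(cv),
                 dataset_ids = colnames(cv),
                 n_total = n_total,
                 n_observed = rowSums(!is.na(cv))),
            class = "cv_table")
}

#' @export
print.cv_table <- function(x, ...) {
  cat(sprintf("<cv_table> %d genes x %d datasets (%d gene-dataset CVs)\n",
              length(x$genes), x$n_total, sum(!is.na(x$cv))))
  invisible(x)
}

# Ratio_t for every gene at once (NA for never-observed genes).
.ratio_all <- function(cv_table, t) {
  below <- rowSums(cv_table$cv < t, na.rm = TRUE)
  out <- below / cv_table$n_observed
  out[cv_table$n_observed == 0L] <- NA_real_
  out
}

#' Ratio of observed datasets where a gene's CV is below a threshold
#'
#' `Ratio_t` is the fraction of datasets, among those in which the gene is
#' observed, where its rank CV is strictly below `t`. A gene observed in a
#' single dataset can reach a perfect ratio, which is why `Ratio_t` is
#' always read together with the percentage of occurrence.
#'
#' @param cv_table A [build_cv_table()] result.
#' @param gene Gene symbol(s).
#' @param t CV threshold.
#' @return Numeric vector of ratios in `[0, 1]`, named by gene.
#' @export
ratio_t <- function(cv_table, gene, t) {
  stopifnot(inherits(cv_table, "cv_table"))
  unknown <- setdiff(gene, cv_table$genes)
  if (length(unknown)) .stopf("unknown gene(s): %s", paste(unknown, collapse = ", "))
  out <- .ratio_all(cv_table, t)[gene]
  if (anyNA(out)) {
    .stopf("gene(s) observed in no dataset: %s",
           paste(gene[is.na(out)], collapse = ", "))
  }
  out
}

#' Percentage of occurrence of a gene across the collection
#'
#' @param cv_table A [build_cv_table()] result.
#' @param gene Gene symbol(s); unknown genes count as never observed.
#' @param total Number of datasets in the collection (defaults to the
#'   table's own count).
#' @return Fraction(s) of datasets in which the gene is observed.
#' @export
percentage_occurrence <- function(cv_table, gene, total = cv_table$n_total) {
  stopifnot(inherits(cv_table, "cv_table"))
  n_obs <- stats::setNames(rep(0L, length(gene)), gene)
  known <- gene %in% cv_table$genes
  n_obs[known] <- cv_table$n_observed[gene[known]]
  n_obs / total
}

#' Count genes above a Ratio_t cut at a minimum percentage of occurrence
#'
#' `f_PO(r)` is the number of genes whose `Ratio_t` strictly exceeds `r`
#' among genes observed in at least `po_min` of the datasets. Plotted over
#' `r` it separates housekeeping gene sets (curves staying high as `r`
#' approaches 1) from random gene sets.
#'
#' @param cv_table A [build_cv_table()] result.
#' @param t CV threshold used for `Ratio_t`.
#' @param po_min Minimum percentage of occurrence, in `[0, 1]`.
#' @param r_grid Ascending vector of ratio cut points in `[0, 1]`.
#' @param genes Optional gene subset to count within (default: all genes).
#' @return Integer vector of counts, one per element of `r_grid`.
#' @export
f_po_curve <- function(cv_table, t, po_min, r_grid = seq(0, 1, by = 0.05),
                       genes = NULL) {
  stopifnot(inherits(cv_table, "cv_table"))
  if (is.unsorted(r_grid)) .stopf("r_grid must be ascending")
  ratio <- .ratio_all(cv_table, t)
  po <- cv_table$n_observed / cv_table$n_total
  keep <- !is.na(ratio) & po >= po_min
  if (!is.null(genes)) keep <- keep & cv_table$genes %in% genes
  r_vals <- ratio[keep]
  vapply(r_grid, function(r) sum(r_vals > r), integer(1))
}

#' Per-gene stability summaries (Ratio_t, PO, pooled mean/median rank)
#'
#' Mean and median percentile ranks pool every rank value of the gene over
#' all samples of all datasets in which it appears.
#'
#' @param collection A [dataset_collection()].
#' @param cv_table Optional precomputed [build_cv_table()] result.
#' @param t CV threshold for `Ratio_t`.
#' @return Data frame with columns `gene`, `n_observed`, `po`, `ratio`,
#'   `mean_rank`, `median_rank`.
#' @export
summarize_genes <- function(collection, cv_table = NULL, t = 0.12) {
  stopifnot(inherits(collection, "dataset_collection"))
  res <- .cv_from_ranks(.rank_all(collection), collection$gene_universe)
  if (is.null(cv_table)) cv_table <- .new_cv_table(res$cv, length(collection$datasets))
  .summaries_from(cv_table, res$pooled, t)
}

.summaries_from <- function(cv_table, pooled, t) {
  med <- apply(pooled, 1L, stats::median, na.rm = TRUE)
  data.frame(gene = cv_table$genes,
             n_observed = unname(cv_table$n_observed),
             po = unname(cv_table$n_observed / cv_table$n_total),
             ratio = unname(.ratio_all(cv_table, t)),
             mean_rank = unname(.row_means_na(pooled)),
             median_rank = unname(med),
             row.names = NULL)
}

#' Screen a collection of expression datasets for stable reference genes
#'
#' The main corpus fit: every dataset is percentile-ranked per sample,
#' probe ranks are averaged per gene, a CV of ranks is computed per gene
#' and dataset, and each gene is summarised by its `Ratio_t` (fraction of
#' observed datasets with CV below `t`), percentage of occurrence and
#' pooled mean/median percentile rank.
#'
#' @param collection A [dataset_collection()], or a list of
#'   [expression_dataset()] objects.
#' @param t CV threshold defining `Ratio_t` in the summaries (default
#'   0.12, the threshold used for fixed-CV reference lists).
#' @return Object of class `ref_stability` with elements `cv_table`,
#'   `summaries`, `t` and `n_datasets`. Methods: `print`, `summary`,
#'   `coef` (the summary data frame) and `plot` (an `f_PO` curve).
#' @seealso [classify()], [roc_curve()], [emit_reference_lists()],
#'   [compare_hk_vs_random()]
#' @export
ref_stability <- function(collection, t = 0.12) {
  if (!inherits(collection, "dataset_collection")) {
    collection <- dataset_collection(collection)
  }
  if (!(is.numeric(t) && length(t) == 1L && t > 0)) {
    .stopf("t must be a single positive number")
  }
  res <- .cv_from_ranks(.rank_all(collection), collection$gene_universe)
  cv_table <- .new_cv_table(res$cv, length(collection$datasets))
  structure(list(cv_table = cv_table,
                 summaries = .summaries_from(cv_table, res$pooled, t),
                 t = t,
                 n_datasets = length(collection$datasets),
                 call = match.call()),
            class = "ref_stability")
}

#' @export
print.ref_stability <- function(x, ...) {
  cat(sprintf("Reference-gene stability screen (t = %g)\n", x$t))
  cat(sprintf("  %d datasets, %d genes in universe\n",
              x$n_datasets, nrow(x$summaries)))
  n_perfect <- sum(x$summaries$ratio >= 1 & x$summaries$po >= 0.75, na.rm = TRUE)
  cat(sprintf("  genes with Ratio_t = 1 and PO >= 0.75: %d\n", n_perfect))
  invisible(x)
}

#' @export
summary.ref_stability <- function(object, min_ratio = 0.9, min_po = 0.75, ...) {
  s <- object$summaries
  pass <- !is.na(s$ratio) & s$ratio >= min_ratio & s$po >= min_po
  top <- s[pass, ]
  top <- top[order(-top$ratio, -top$mean_rank), ]
  structure(list(t = object$t, n_datasets = object$n_datasets,
                 n_genes = nrow(s), n_candidates = sum(pass),
                 min_ratio = min_ratio, min_po = min_po,
                 top = utils::head(top, 10L)),
            class = "summary.ref_stability")
}

#' @export
print.summary.ref_stability <- function(x, ...) {
  cat(sprintf("Stability screen at t = %g over %d datasets:\n", x$t, x$n_datasets))
  cat(sprintf("  %d / %d genes pass Ratio_t >= %g and PO >= %g\n",
              x$n_candidates, x$n_genes, x$min_ratio, x$min_po))
  if (nrow(x$top)) {
    cat("  top candidates:\n")
    print(x$top, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.ref_stability <- function(object, ...) object$summaries

#' @export
#' @importFrom graphics plot abline
plot.ref_stability <- function(x, po_min = 0.5, r_grid = seq(0, 1, by = 0.02),
                               ...) {
  counts <- f_po_curve(x$cv_table, x$t, po_min, r_grid)
  plot(r_grid, counts, type = "s", xlab = "r (Ratio_t cut)",
       ylab = sprintf("f_PO(r): genes with Ratio_t > r, PO >= %g", po_min),
       main = sprintf("f_PO curve at t = %g", x$t), ...)
  invisible(data.frame(r = r_grid, count = counts))
}
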