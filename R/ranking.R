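# Per-sample percentile ranking and probe -> gene rank averaging.

#' Percentile ranks of one sample's expression values
#'
#' Mid-rank percentile: among the `N` non-missing values, a value with
#' (average, tie-aware) rank `k` gets `100 * (k - 0.5) / N`, so ranks lie
#' in `[0, 100)` and a full tie maps to 50. Missing entries stay missing
#' and the output keeps the input order. Ranks are invariant under any
#' strictly increasing per-sample transform, which is what makes them
#' comparable across platforms.
#'
#' @param values Numeric vector of expression values; `NA` allowed.
#' @return Numeric vector of percentile ranks, same length and order.
#' @export
#' @examples
#' percentile_rank(c(10, 20, 30, 40))  # 12.5 37.5 62.5 87.5
percentile_rank <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2L) .stopf("percentile ranking needs at least 2 non-missing values (got %d)", n)
  r <- rank(values, ties.method = "average", na.last = "keep")
  100 * (r - 0.5) / n
}

#' Rank all probes of a dataset and average ranks per gene
#'
#' Probe ranks are computed per sample over the full probe set (mapped and
#' unmapped probes alike, so every spot occupies a rank slot). Each gene's
#' rank in a sample is then the arithmetic mean of the ranks of its probes
#' that are non-missing in that sample; the gene is missing in a sample
#' only when all of its probes are.
#'
#' @param dataset An [expression_dataset()].
#' @return Object of class `rank_matrix`: list with `dataset_id`, `genes`,
#'   `samples` and `ranks` (gene x sample matrix of percentile ranks,
#'   `NA` where unobserved).
#' @export
rank_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(dataset$samples) < 2L) {
    .warnf("dataset %s has fewer than 2 samples; rank CVs downstream will be undefined",
           dataset$dataset_id)
  }
  probe_ranks <- apply(dataset$values, 2L, percentile_rank)
  if (is.null(dim(probe_ranks))) {
    probe_ranks <- matrix(probe_ranks, ncol = length(dataset$samples),
                          dimnames = list(dataset$probes, dataset$samples))
  }
  mapped <- !is.na(dataset$probe_to_gene)
  genes <- sort(unique(unname(dataset$probe_to_gene[mapped])))
  if (!length(genes)) {
    ranks <- matrix(NA_real_, 0L, length(dataset$samples),
                    dimnames = list(NULL, dataset$samples))
  } else {
    sub <- probe_ranks[mapped, , drop = FALSE]
    grp <- factor(dataset$probe_to_gene[mapped], levels = genes)
    present <- !is.na(sub)
    sums <- rowsum(ifelse(present, sub, 0), grp)
    counts <- rowsum(present + 0L, grp)
    ranks <- sums / counts
    ranks[counts == 0] <- NA_real_
    dimnames(ranks) <- list(genes, dataset$samples)
  }
  structure(list(dataset_id = dataset$dataset_id, genes = genes,
                 samples = dataset$samples, ranks = ranks),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %s: %d genes x %d samples\n",
              x$dataset_id, length(x$genes), length(x$samples)))
  invisible(x)
}

#' Write a rank matrix as TSV (gene rows, sample columns)
#' @param rank_matrix A [rank_dataset()] result.
#' @param path Output path.
#' @export
write_rank_matrix <- function(rank_matrix, path) {
  stopifnot(inherits(rank_matrix, "rank_matrix"))
  out <- data.frame(gene = rank_matrix$genes,
                    as.data.frame(rank_matrix$ranks),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
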