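#' Construct an expression dataset
#'
#' An `expression_dataset` holds one study: a probe-by-sample matrix of
#' non-negative expression values (missing entries allowed), the probe to
#' gene-symbol map, and a dataset identifier. It is the unit over which
#' per-dataset rank CVs are computed.
#'
#' Gene symbols are upper-cased on ingest so that identifiers from mixed
#' sources collate. Probes with no mapped gene are retained: they take part
#' in per-sample ranking but contribute to no gene.
#'
#' @param dataset_id Single string, e.g. `"GDS1234"`; unique in a collection.
#' @param values Numeric matrix, probes in rows, samples in columns. Row and
#'   column names supply probe and sample IDs unless `probes` / `samples`
#'   are given. `NA` marks missing measurements; finite values must be
#'   non-negative.
#' @param probe_to_gene Named character vector mapping probe ID to gene
#'   symbol (many probes per gene allowed). Probes absent from the names are
#'   treated as unmapped; `NA` values mark unmapped probes explicitly.
#' @param probes,samples Optional character vectors overriding dimnames.
#' @return An object of class `expression_dataset`.
#' @seealso [dataset_collection()], [read_expression_matrix()],
#'   [read_gds_soft()], [global_mean_normalize()]
#' @export
expression_dataset <- function(dataset_id, values, probe_to_gene = character(),
                               probes = rownames(values),
                               samples = colnames(values)) {
  if (!.is_string(dataset_id)) .stopf("dataset_id must be a single string")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probes) || is.null(samples)) {
    .stopf("probe and sample identifiers are required (dimnames or arguments)")
  }
  probes <- as.character(probes)
  samples <- as.character(samples)
  if (nrow(values) != length(probes) || ncol(values) != length(samples)) {
    .stopf("dimensions of 'values' (%d x %d) do not match %d probes x %d samples",
           nrow(values), ncol(values), length(probes), length(samples))
  }
  if (anyDuplicated(probes)) {
    .stopf("duplicate probe IDs in dataset %s: %s", dataset_id,
           paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    .stopf("duplicate sample IDs in dataset %s", dataset_id)
  }
  if (any(values < 0, na.rm = TRUE)) {
    .stopf("negative expression values in dataset %s", dataset_id)
  }
  all_na <- colSums(!is.na(values)) == 0
  if (any(all_na)) {
    .stopf("sample(s) with no non-missing values in dataset %s: %s",
           dataset_id, paste(samples[all_na], collapse = ", "))
  }
  dimnames(values) <- list(probes, samples)

  map <- rep(NA_character_, length(probes))
  names(map) <- probes
  if (length(probe_to_gene)) {
    ptg <- as.character(probe_to_gene)
    names(ptg) <- names(probe_to_gene)
    known <- names(ptg) %in% probes
    if (any(!known)) {
      message(sprintf("dataset %s: ignoring %d mapping entr%s for probes absent from the matrix",
                      dataset_id, sum(!known), if (sum(!known) == 1L) "y" else "ies"))
      ptg <- ptg[known]
    }
    ptg[!is.na(ptg)] <- toupper(ptg[!is.na(ptg)])
    ptg[ptg %in% .missing_tokens] <- NA_character_
    map[names(ptg)] <- unname(ptg)
  }

  structure(list(dataset_id = dataset_id,
                 samples = samples,
                 probes = probes,
                 values = values,
                 probe_to_gene = map),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d probes x %d samples (%d mapped genes, %.1f%% missing)\n",
              x$dataset_id, length(x$probes), length(x$samples),
              length(unique(stats::na.omit(x$probe_to_gene))),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Genes mapped in a dataset
#' @param dataset An `expression_dataset`.
#' @return Character vector of unique gene symbols with at least one probe.
#' @export
dataset_genes <- function(dataset) {
  sort(unique(stats::na.omit(unname(dataset$probe_to_gene))))
}

#' Bundle expression datasets into a collection
#'
#' @param datasets List of [expression_dataset()] objects with unique IDs.
#' @return Object of class `dataset_collection` with elements `datasets`
#'   (named list) and `gene_universe` (union of mapped gene symbols).
#' @export
dataset_collection <- function(datasets) {
  if (!length(datasets)) .stopf("a collection needs at least one dataset")
  ok <- vapply(datasets, inherits, logical(1), "expression_dataset")
  if (!all(ok)) .stopf("all elements must be expression_dataset objects")
  ids <- vapply(datasets, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids)) {
    .stopf("duplicate dataset IDs: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(datasets) <- ids
  universe <- sort(unique(unlist(lapply(datasets, dataset_genes), use.names = FALSE)))
  structure(list(datasets = datasets, gene_universe = universe),
            class = "dataset_collection")
}

#' @export
print.dataset_collection <- function(x, ...) {
  ns <- vapply(x$datasets, function(d) length(d$samples), integer(1))
  cat(sprintf("<dataset_collection> %d datasets, %d samples total, %d genes in universe\n",
              length(x$datasets), sum(ns), length(x$gene_universe)))
  invisible(x)
}

#' @export
length.dataset_collection <- function(x) length(x$datasets)

#' Restrict a collection to a subset of datasets
#' @param collection A `dataset_collection`.
#' @param dataset_ids Character vector of dataset IDs to keep.
#' @return A new `dataset_collection`.
#' @export
subset_collection <- function(collection, dataset_ids) {
  stopifnot(inherits(collection, "dataset_collection"))
  missing_ids <- setdiff(dataset_ids, names(collection$datasets))
  if (length(missing_ids)) {
    .stopf("unknown dataset IDs: %s", paste(missing_ids, collapse = ", "))
  }
  dataset_collection(collection$datasets[dataset_ids])
}

#' Divide each sample by its own mean expression
#'
#' Global mean normalization: every sample (column) is divided by the mean
#' of its non-missing values, so each normalized sample has mean 1. Because
#' the scaling is a strictly increasing transform per sample, downstream
#' percentile ranks are unchanged; the step is kept so that expression
#' values are on a common scale when inspected directly.
#'
#' @param dataset An [expression_dataset()].
#' @return A new `expression_dataset` with normalized values.
#' @export
global_mean_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mu <- colMeans(dataset$values, na.rm = TRUE)
  bad <- !is.finite(mu) | mu <= 0
  if (any(bad)) {
    .stopf("cannot global-mean normalize dataset %s: sample(s) with zero or undefined mean: %s",
           dataset$dataset_id, paste(dataset$samples[bad], collapse = ", "))
  }
  out <- dataset
  out$values <- sweep(dataset$values, 2L, mu, "/")
  out
}
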