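# Grouping datasets by MeSH tree numbers and per-category reference lists.

.mesh_pattern <- "^[A-Z][0-9]+(\\.[0-9]+)*$"

#' Construct / load a dataset-to-MeSH mapping
#'
#' MeSH tree numbers are dotted hierarchical codes (`A11.251` sits under
#' `A11`). `load_mesh_map()` reads a TSV with columns `dataset_id`,
#' `tree_number` and (optionally) `heading`; assignments are aggregated
#' per dataset and malformed tree numbers are rejected with their line
#' number.
#'
#' @param assignments Named list: dataset ID -> character vector of tree
#'   numbers.
#' @param headings Named character vector: tree number -> heading.
#' @return Object of class `mesh_map`.
#' @export
mesh_map <- function(assignments = list(), headings = character()) {
  trees <- unique(unlist(assignments, use.names = FALSE))
  bad <- trees[!grepl(.mesh_pattern, trees)]
  if (length(bad)) {
    .stopf("malformed MeSH tree number(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(assignments = assignments, headings = headings),
            class = "mesh_map")
}

#' @rdname mesh_map
#' @param path TSV path for `load_mesh_map()`.
#' @export
load_mesh_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (!nrow(tab)) {
    .warnf("%s: empty MeSH mapping", path)
    return(mesh_map())
  }
  need <- c("dataset_id", "tree_number")
  if (!all(need %in% colnames(tab))) {
    .stopf("%s: MeSH map needs columns 'dataset_id' and 'tree_number'", path)
  }
  bad <- which(!grepl(.mesh_pattern, tab$tree_number))
  if (length(bad)) {
    .stopf("%s: malformed tree number '%s' on line %d", path,
           tab$tree_number[bad[1L]], bad[1L] + 1L)  # +1 for the header
  }
  assignments <- lapply(split(tab$tree_number, tab$dataset_id), unique)
  headings <- character()
  if ("heading" %in% colnames(tab)) {
    first <- !duplicated(tab$tree_number)
    headings <- stats::setNames(tab$heading[first], tab$tree_number[first])
  }
  mesh_map(assignments, headings)
}

#' @export
print.mesh_map <- function(x, ...) {
  cat(sprintf("<mesh_map> %d datasets, %d distinct tree numbers\n",
              length(x$assignments),
              length(unique(unlist(x$assignments, use.names = FALSE)))))
  invisible(x)
}

#' Datasets belonging to a MeSH category (with hierarchical aggregation)
#'
#' A dataset belongs to `tree_number` when one of its assignments equals
#' it or has it as a dotted prefix (`A11` includes `A11.251`, but `A1`
#' does not: prefixes must align on dot boundaries). The pseudo-category
#' `"ALL"` returns every dataset, including ones with no MeSH assignment
#' when `all_ids` is supplied.
#'
#' @param map A [mesh_map()].
#' @param tree_number A MeSH tree number or `"ALL"`.
#' @param all_ids Full roster of dataset IDs used for `"ALL"`; defaults to
#'   the datasets present in the map.
#' @return Character vector of dataset IDs.
#' @export
datasets_in_category <- function(map, tree_number, all_ids = NULL) {
  stopifnot(inherits(map, "mesh_map"))
  if (identical(tree_number, "ALL")) {
    return(sort(unique(c(names(map$assignments), all_ids))))
  }
  if (!grepl(.mesh_pattern, tree_number)) {
    .stopf("malformed MeSH tree number: %s", tree_number)
  }
  hit <- vapply(map$assignments, function(trees) {
    any(trees == tree_number | startsWith(trees, paste0(tree_number, ".")))
  }, logical(1))
  sort(names(map$assignments)[hit])
}

#' Per-MeSH-category reference-gene lists
#'
#' For every requested category the collection is restricted to the
#' category's datasets (so the PO denominator becomes the category size),
#' the stability screen is re-run, and both list-emission modes of
#' [emit_reference_lists()] are applied with the PO gate at `min_po`.
#' Categories matching no dataset are skipped with a warning.
#'
#' @param collection A [dataset_collection()].
#' @param map A [mesh_map()].
#' @param categories Character vector of tree numbers (may include
#'   `"ALL"`).
#' @param ground_truth Character vector of known housekeeping genes.
#' @param t CV threshold (default 0.12).
#' @param min_ratio,min_po Classifier gates.
#' @param ... Passed on to [emit_reference_lists()].
#' @return Named list: per category, a list with elements `fixed_cv` and
#'   `fixed_sensitivity` (data frames of records; a mode that fails, e.g.
#'   unreachable sensitivity, is returned as `NULL` with a warning) plus
#'   `n_datasets`.
#' @export
per_category_lists <- function(collection, map, categories, ground_truth,
                               t = 0.12, min_ratio = 0.9, min_po = 0.75, ...) {
  stopifnot(inherits(collection, "dataset_collection"), inherits(map, "mesh_map"))
  out <- list()
  for (cat_id in categories) {
    ids <- intersect(datasets_in_category(map, cat_id,
                                          all_ids = names(collection$datasets)),
                     names(collection$datasets))
    if (!length(ids)) {
      .warnf("MeSH category %s matches no dataset; skipped", cat_id)
      next
    }
    fit <- ref_stability(subset_collection(collection, ids), t = t)
    res <- list(n_datasets = length(ids))
    for (mode in c("fixed_cv", "fixed_sensitivity")) {
      res[[mode]] <- tryCatch(
        emit_reference_lists(fit, ground_truth, mode = mode, cv_fixed = t,
                             min_ratio = min_ratio, min_po = min_po, ...),
        error = function(e) {
          .warnf("category %s, mode %s: %s", cat_id, mode, conditionMessage(e))
          NULL
        })
    }
    out[[cat_id]] <- res
  }
  out
}
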