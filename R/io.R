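# Readers and writers for the plain-text formats the pipeline touches:
# tab-delimited expression matrices, GEO SOFT GDS files, probe->gene maps,
# reference-gene lists and ground-truth gene lists.

#' Read a tab-delimited expression matrix with a probe-to-gene map
#'
#' The matrix file has a header row of sample IDs and probe IDs in the
#' first column; cells equal to `""`, `"NA"` or `"null"` are recorded as
#' missing. The mapping file is a two-column TSV with header `probe` and
#' `gene`; probes mapped but absent from the matrix are ignored with a
#' message, and probes without a mapping row stay unmapped.
#'
#' @param path Path to the expression matrix TSV.
#' @param mapping_path Path to the probe/gene TSV. `NULL` leaves all probes
#'   unmapped.
#' @param dataset_id Dataset identifier; defaults to the file name without
#'   extension.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, mapping_path = NULL,
                                   dataset_id = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L) .stopf("%s: expected probe column plus at least one sample", path)
  probes <- tab[[1L]]
  if (anyDuplicated(probes)) {
    .stopf("%s: duplicated probe row(s): %s", path,
           paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  samples <- colnames(tab)[-1L]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  raw[raw %in% .missing_tokens] <- NA_character_
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(values) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    .stopf("%s: non-numeric value '%s' at probe %s, sample %s",
           path, raw[bad[1L, 1L], bad[1L, 2L]], probes[bad[1L, 1L]],
           samples[bad[1L, 2L]])
  }
  dimnames(values) <- list(probes, samples)
  map <- character()
  if (!is.null(mapping_path)) map <- read_probe_map(mapping_path)
  expression_dataset(dataset_id, values, probe_to_gene = map)
}

#' Read a two-column probe-to-gene mapping TSV
#' @param path TSV with header columns `probe` and `gene`.
#' @return Named character vector (probe -> gene symbol).
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  need <- c("probe", "gene")
  if (!all(need %in% colnames(tab))) {
    .stopf("%s: mapping file needs columns 'probe' and 'gene'", path)
  }
  stats::setNames(tab$gene, tab$probe)
}

#' Read a GEO SOFT GDS file
#'
#' Parses the GDS dialect of SOFT: a `^DATASET` header line and a data
#' table between `!dataset_table_begin` and `!dataset_table_end`, whose
#' header holds `ID_REF`, `IDENTIFIER` and one column per GSM sample.
#' `"null"` (and empty) cells become missing values. `IDENTIFIER` entries
#' such as `"--Control"` are kept as probes but left unmapped.
#'
#' @param path Path to an uncompressed SOFT GDS file.
#' @return An [expression_dataset()] whose ID is the `^DATASET` accession.
#' @export
read_gds_soft <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ds_line <- grep("^\\^DATASET", lines, value = TRUE)
  dataset_id <- if (length(ds_line)) {
    sub("^\\^DATASET\\s*=\\s*", "", ds_line[1L])
  } else sub("\\.[^.]*$", "", basename(path))
  beg <- grep("^!dataset_table_begin", lines)
  if (!length(beg)) .stopf("%s: no !dataset_table_begin block found", path)
  end <- grep("^!dataset_table_end", lines)
  end <- end[end > beg[1L]]
  if (!length(end)) .stopf("%s: table block truncated (missing !dataset_table_end)", path)
  block <- lines[(beg[1L] + 1L):(end[1L] - 1L)]
  if (length(block) < 2L) .stopf("%s: dataset table is empty", path)
  header <- strsplit(block[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(c("ID_REF", "IDENTIFIER") %in% header)) {
    .stopf("%s: table header lacks ID_REF/IDENTIFIER columns", path)
  }
  rows <- strsplit(block[-1L], "\t", fixed = TRUE)
  nc <- length(header)
  cells <- vapply(rows, function(r) { length(r) <- nc; r }, character(nc))
  cells <- t(cells)
  colnames(cells) <- header
  probes <- cells[, "ID_REF"]
  idents <- cells[, "IDENTIFIER"]
  idents[grepl("^--", idents)] <- NA_character_
  sample_cols <- setdiff(header, c("ID_REF", "IDENTIFIER"))
  if (length(sample_cols) < 2L) {
    .warnf("%s: dataset has %d sample(s); rank CVs are undefined with fewer than 2",
           path, length(sample_cols))
  }
  raw <- cells[, sample_cols, drop = FALSE]
  raw[raw %in% .missing_tokens] <- NA_character_
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(values) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    .stopf("%s: non-numeric value '%s' at probe %s, sample %s", path,
           raw[bad[1L, 1L], bad[1L, 2L]], probes[bad[1L, 1L]],
           sample_cols[bad[1L, 2L]])
  }
  dimnames(values) <- list(probes, sample_cols)
  expression_dataset(dataset_id, values,
                     probe_to_gene = stats::setNames(idents, probes))
}

#' Write / read a ranked reference-gene list
#'
#' The list is a TSV with columns `gene`, `cv_threshold`, `ratio`, `po`,
#' `mean_rank`, `median_rank`, `sensitivity`, `specificity`, sorted by
#' ascending CV threshold then descending ratio.
#'
#' @param records Data frame with the columns above (one row per gene).
#' @param path Output path.
#' @return `write_reference_list()` returns `path` invisibly;
#'   `read_reference_list()` returns the data frame.
#' @export
write_reference_list <- function(records, path) {
  cols <- c("gene", "cv_threshold", "ratio", "po", "mean_rank",
            "median_rank", "sensitivity", "specificity")
  if (!is.data.frame(records) || !nrow(records)) {
    .stopf("no records to write")
  }
  if (!all(cols %in% colnames(records))) {
    .stopf("records must have columns: %s", paste(cols, collapse = ", "))
  }
  records <- records[order(records$cv_threshold, -records$ratio, records$gene), cols]
  utils::write.table(format(records, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_list
#' @export
read_reference_list <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "")
  tab$gene <- as.character(tab$gene)
  tab
}

#' Read a ground-truth gene list (one symbol per line)
#'
#' Symbols are upper-cased; blank lines and `#` comments are skipped.
#'
#' @param path Path to the list.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(toupper(lines))
}

#' Write one dataset of a collection as matrix + map TSVs
#'
#' Companion to [read_expression_matrix()]: emits `<id>.matrix.tsv` and
#' `<id>.map.tsv` under `dir`. [write_collection()] does so for every
#' dataset and [read_collection()] loads such a directory back.
#'
#' @param dataset An [expression_dataset()].
#' @param dir Output directory (created if needed).
#' @return The matrix path, invisibly.
#' @export
write_expression_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(dir, paste0(dataset$dataset_id, ".matrix.tsv"))
  cells <- matrix(NA_character_, nrow(dataset$values), ncol(dataset$values))
  ok <- !is.na(dataset$values)
  cells[ok] <- formatC(dataset$values[ok], digits = 15, format = "g")
  out <- cbind(probe = dataset$probes, cells)
  colnames(out) <- c("probe", dataset$samples)
  utils::write.table(out, mpath, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  mapped <- !is.na(dataset$probe_to_gene)
  map <- data.frame(probe = names(dataset$probe_to_gene)[mapped],
                    gene = unname(dataset$probe_to_gene[mapped]))
  utils::write.table(map, file.path(dir, paste0(dataset$dataset_id, ".map.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_expression_dataset
#' @param collection A [dataset_collection()].
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "dataset_collection"))
  for (d in collection$datasets) write_expression_dataset(d, dir)
  invisible(dir)
}

#' @rdname write_expression_dataset
#' @export
read_collection <- function(dir) {
  mats <- sort(list.files(dir, pattern = "\\.matrix\\.tsv$", full.names = TRUE))
  if (!length(mats)) .stopf("%s: no *.matrix.tsv files found", dir)
  datasets <- lapply(mats, function(m) {
    id <- sub("\\.matrix\\.tsv$", "", basename(m))
    map <- file.path(dir, paste0(id, ".map.tsv"))
    read_expression_matrix(m, if (file.exists(map)) map else NULL, dataset_id = id)
  })
  dataset_collection(datasets)
}
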