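# Fixture builders. Everything is generated in code; no binary fixtures.

# A tiny deterministic dataset: 5 probes, 2 genes, one unmapped probe.
tiny_dataset <- function(id = "GDS1") {
  values <- matrix(c(1, 2, 4, 8, 16,
                     5, 3, NA, 9, 7),
                   nrow = 5,
                   dimnames = list(paste0("p", 1:5), c("s1", "s2")))
  expression_dataset(id, values,
                     probe_to_gene = c(p1 = "GA", p2 = "GA", p3 = "GB",
                                       p4 = "GB"))  # p5 unmapped
}

# Random small corpus for oracle-equivalence checks: log-normal values,
# cell-level missingness, 1-2 probes per gene, some unmapped probes.
rand_collection <- function(seed, max_datasets = 10, max_samples = 8,
                            max_genes = 50) {
  withr::local_seed(seed)
  n_ds <- sample(2:max_datasets, 1)
  datasets <- lapply(seq_len(n_ds), function(d) {
    n_s <- sample(3:max_samples, 1)
    n_g <- sample(5:max_genes, 1)
    genes <- sprintf("G%03d", seq_len(n_g))
    k <- sample(1:2, n_g, replace = TRUE)
    gene_of <- rep(genes, k)
    n_p <- length(gene_of) + 2L  # two unmapped probes
    gene_of <- c(gene_of, NA, NA)
    probes <- sprintf("P%03d", seq_len(n_p))
    vals <- matrix(2^rnorm(n_p * n_s, 8, 2), n_p, n_s,
                   dimnames = list(probes, paste0("s", seq_len(n_s))))
    # knock out ~5% of cells, keeping >= 2 values per sample
    drop <- which(matrix(runif(n_p * n_s) < 0.05, n_p, n_s), arr.ind = TRUE)
    for (r in seq_len(nrow(drop))) {
      j <- drop[r, 2]
      if (sum(!is.na(vals[, j])) > 2) vals[drop[r, 1], j] <- NA
    }
    map <- setNames(gene_of, probes)
    expression_dataset(sprintf("GDS%03d", d), vals,
                       probe_to_gene = map[!is.na(map)])
  })
  dataset_collection(datasets)
}

# Minimal SOFT GDS text fixture.
soft_lines <- function(truncated = FALSE) {
  lines <- c(
    "^DATABASE = Geo",
    "^DATASET = GDS9001",
    "!dataset_title = toy fixture",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3",
    "p1\tGAPDH\t10.5\t11\t9.5",
    "p2\tactb\t20\tnull\t22",
    "p3\t--Control\t1\t2\t3",
    "!dataset_table_end")
  if (truncated) lines <- lines[1:7]
  lines
}

write_soft_fixture <- function(path, truncated = FALSE) {
  writeLines(soft_lines(truncated), path)
  path
}

# Small qPCR quantity matrix with known structure.
toy_quantities <- function() {
  samples <- paste0("s", 1:6)
  q <- rbind(A = c(1, 0.5, 0.25, 1, 0.5, 0.25),
             B = c(0.8, 0.4, 0.2, 0.8, 0.4, 0.2),   # proportional to A
             C = c(1, 0.9, 1, 0.08, 1, 0.95))        # noisy
  colnames(q) <- samples
  q
}
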