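# Synthetic-data generators: a GEO-like corpus of expression datasets with
# planted stable genes, and a simulated RT-qPCR Cq table. Both are pure
# functions of their configuration and seed.

.mesh_palette <- c(A10.690 = "Muscles", A11.251 = "Cells. Cultured",
                   A15.382 = "Immune System",
                   C04.557 = "Neoplasms by Histologic Type",
                   A11.118 = "Blood Cells", A10.272 = "Epithelium",
                   A15.145 = "Blood", C04.588 = "Neoplasms by Site")

#' Configuration for the synthetic GEO-like corpus
#'
#' Defaults describe the standard study conditions used throughout the
#' package's tests: 20 datasets of 8 samples over 2000 genes, 100 planted
#' universally stable genes and 25 planted stable genes per each of 4
#' MeSH categories.
#'
#' Expression is log-normal: each gene has one baseline log2 level shared
#' across datasets (so genes keep a characteristic rank), drawn from
#' `N(8, 2)`; planted stable genes take baselines in the top decile.
#' Planted genes receive small per-sample noise, calibrated so that a
#' gene in the middle of the planted band moves by about
#' `stable_rank_noise_sd` percentile units per sample. Every other gene
#' receives per-sample noise of 0.3 log2 units plus a dataset-specific
#' condition effect of standard deviation `variable_effect_sd` log2 units
#' applied to a random half of the samples — emulating the
#' treatment/control contrasts that dominate GEO datasets. Each dataset
#' drops a random `missing_gene_fraction` of genes (platform
#' differences), and genes are measured by 1-2 probes with per-dataset
#' probe offsets.
#'
#' @param n_datasets Number of datasets.
#' @param samples_per_dataset Integer range `c(min, max)` of samples per
#'   dataset.
#' @param n_genes Total genes.
#' @param n_planted_stable Universally stable planted genes.
#' @param probes_per_gene Integer range of probes per gene per dataset.
#' @param stable_rank_noise_sd Target per-sample rank movement of planted
#'   genes, in percentile units.
#' @param variable_effect_sd Condition-effect standard deviation for
#'   non-planted genes, log2 units.
#' @param missing_gene_fraction Fraction of genes omitted per dataset.
#' @param n_categories Number of MeSH categories the datasets cycle
#'   through (0 for none).
#' @param per_category_planted Category-specific stable genes per
#'   category: stable within the category's datasets, condition-driven
#'   elsewhere.
#' @param seed Integer seed.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(n_datasets = 20L, samples_per_dataset = c(8L, 8L),
                          n_genes = 2000L, n_planted_stable = 100L,
                          probes_per_gene = c(1L, 2L),
                          stable_rank_noise_sd = 1,
                          variable_effect_sd = 3,
                          missing_gene_fraction = 0.05,
                          n_categories = 4L, per_category_planted = 25L,
                          seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              samples_per_dataset = as.integer(rep(samples_per_dataset, length.out = 2L)),
              n_genes = as.integer(n_genes),
              n_planted_stable = as.integer(n_planted_stable),
              probes_per_gene = as.integer(rep(probes_per_gene, length.out = 2L)),
              stable_rank_noise_sd = stable_rank_noise_sd,
              variable_effect_sd = variable_effect_sd,
              missing_gene_fraction = missing_gene_fraction,
              n_categories = as.integer(n_categories),
              per_category_planted = as.integer(per_category_planted),
              seed = as.integer(seed))
  if (cfg$n_datasets < 1L || cfg$n_genes < 1L) .stopf("counts must be >= 1")
  if (cfg$samples_per_dataset[1L] < 2L) .stopf("datasets need at least 2 samples")
  if (cfg$missing_gene_fraction < 0 || cfg$missing_gene_fraction >= 1) {
    .stopf("missing_gene_fraction must lie in [0, 1)")
  }
  n_planted_total <- cfg$n_planted_stable + cfg$n_categories * cfg$per_category_planted
  if (n_planted_total > cfg$n_genes) {
    .stopf("planted genes (%d) exceed n_genes (%d)", n_planted_total, cfg$n_genes)
  }
  if (cfg$n_categories > length(.mesh_palette)) {
    .stopf("at most %d categories are supported", length(.mesh_palette))
  }
  structure(cfg, class = "corpus_config")
}

#' Simulate a GEO-like corpus with planted stable genes
#'
#' See [corpus_config()] for the generative model. The returned MeSH map
#' assigns each dataset to one category tree number (round-robin), and
#' the planted truth records which genes were made universally or
#' category-specifically stable.
#'
#' @param config A [corpus_config()].
#' @return List with elements `collection` (a [dataset_collection()]),
#'   `mesh` (a [mesh_map()]) and `truth` (list with `universal_stable`,
#'   `category_stable`, `config`, `seed`).
#' @export
simulate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  .with_seed(config$seed, .simulate_corpus_impl(config))
}

.simulate_corpus_impl <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_cat_planted <- cfg$n_categories * cfg$per_category_planted
  universal <- genes[seq_len(cfg$n_planted_stable)]
  cat_trees <- names(.mesh_palette)[seq_len(cfg$n_categories)]
  category_stable <- list()
  if (cfg$n_categories > 0L && cfg$per_category_planted > 0L) {
    for (i in seq_len(cfg$n_categories)) {
      idx <- cfg$n_planted_stable + (i - 1L) * cfg$per_category_planted +
        seq_len(cfg$per_category_planted)
      category_stable[[cat_trees[i]]] <- genes[idx]
    }
  }
  planted_any <- c(universal, unlist(category_stable, use.names = FALSE))
  variable <- setdiff(genes, planted_any)

  base_mu <- 8; base_sd <- 2
  baseline <- stats::setNames(numeric(cfg$n_genes), genes)
  baseline[variable] <- stats::rnorm(length(variable), base_mu, base_sd)
  if (length(universal)) {
    baseline[universal] <- stats::qnorm(seq(0.90, 0.995, length.out = length(universal)),
                                        base_mu, base_sd)
  }
  if (length(category_stable)) {
    for (tr in names(category_stable)) {
      gs <- category_stable[[tr]]
      baseline[gs] <- stats::qnorm(stats::runif(length(gs), 0.90, 0.995),
                                   base_mu, base_sd)
    }
  }
  # log2 noise giving ~stable_rank_noise_sd percentile units of movement
  # for a gene at the centre of the planted band
  dens_mid <- stats::dnorm(stats::qnorm(0.95))
  stable_noise_sd <- cfg$stable_rank_noise_sd / 100 * base_sd / dens_mid
  variable_noise_sd <- 0.3

  ds_cat <- if (cfg$n_categories > 0L) {
    cat_trees[((seq_len(cfg$n_datasets) - 1L) %% cfg$n_categories) + 1L]
  } else rep(NA_character_, cfg$n_datasets)

  datasets <- vector("list", cfg$n_datasets)
  for (d in seq_len(cfg$n_datasets)) {
    ds_id <- sprintf("GDSsim%03d", d)
    n_s <- if (cfg$samples_per_dataset[1L] == cfg$samples_per_dataset[2L]) {
      cfg$samples_per_dataset[1L]
    } else {
      sample(cfg$samples_per_dataset[1L]:cfg$samples_per_dataset[2L], 1L)
    }
    samples <- sprintf("GSM%03d_%02d", d, seq_len(n_s))
    n_miss <- floor(cfg$missing_gene_fraction * cfg$n_genes)
    present <- genes
    if (n_miss > 0L) present <- setdiff(genes, sample(genes, n_miss))
    # which genes behave as stable in this dataset
    stable_here <- union(universal,
                         if (!is.na(ds_cat[d]) && !is.null(category_stable[[ds_cat[d]]]))
                           category_stable[[ds_cat[d]]] else character(0))
    g_stable <- intersect(present, stable_here)
    g_var <- setdiff(present, stable_here)

    lg <- matrix(0, length(present), n_s, dimnames = list(present, samples))
    lg[] <- baseline[present]
    if (length(g_stable)) {
      lg[g_stable, ] <- lg[g_stable, , drop = FALSE] +
        stats::rnorm(length(g_stable) * n_s, 0, stable_noise_sd)
    }
    if (length(g_var)) {
      lg[g_var, ] <- lg[g_var, , drop = FALSE] +
        stats::rnorm(length(g_var) * n_s, 0, variable_noise_sd)
      # condition effect on a random half of the samples
      eff <- stats::rnorm(length(g_var), 0, cfg$variable_effect_sd)
      cond <- sample(n_s, floor(n_s / 2))
      lg[g_var, cond] <- lg[g_var, cond, drop = FALSE] + eff
    }
    # expand genes to probes with per-dataset probe offsets
    k <- if (cfg$probes_per_gene[1L] == cfg$probes_per_gene[2L]) {
      rep(cfg$probes_per_gene[1L], length(present))
    } else {
      sample(cfg$probes_per_gene[1L]:cfg$probes_per_gene[2L],
             length(present), replace = TRUE)
    }
    gene_idx <- rep(seq_along(present), k)
    n_probes <- length(gene_idx)
    probe_ids <- sprintf("P%05d", seq_len(n_probes))
    # constant per-dataset probe affinity offsets: they shift a probe's
    # rank but not its variability, so planted genes stay noise-free when
    # the gene-level noise is zero
    probe_lg <- lg[gene_idx, , drop = FALSE] + stats::rnorm(n_probes, 0, 0.25)
    values <- 2^probe_lg
    dimnames(values) <- list(probe_ids, samples)
    datasets[[d]] <- expression_dataset(
      ds_id, values,
      probe_to_gene = stats::setNames(present[gene_idx], probe_ids))
  }
  collection <- dataset_collection(datasets)
  assignments <- list()
  if (cfg$n_categories > 0L) {
    for (d in seq_len(cfg$n_datasets)) {
      assignments[[datasets[[d]]$dataset_id]] <- ds_cat[d]
    }
  }
  mesh <- mesh_map(assignments, .mesh_palette[seq_len(cfg$n_categories)])
  truth <- list(universal_stable = universal,
                category_stable = category_stable,
                config = cfg, seed = cfg$seed)
  list(collection = collection, mesh = mesh, truth = truth)
}

#' Simulate an RT-qPCR Cq table
#'
#' Emulates a multi-group cell-line panel (default: 8 liver, 5 breast and
#' 3 colon lines over 17 candidate genes). Each gene gets a base Cq drawn
#' uniformly from `[15, 29]` (well-expressed candidates, Cq below 30);
#' `group_shift_genes` additionally get group-level shifts (centred
#' normal, sd `group_shift_sd` cycles) emulating tissue-specific
#' expression; `planted_unstable` genes get 3x the per-measurement noise.
#' Amplification efficiencies are drawn uniformly from `[0.85, 1]`.
#' Gene names are `GENE01`, `GENE02`, ...
#'
#' @param n_genes Number of candidate genes.
#' @param groups Named integer vector: group label -> number of samples
#'   (each at least 2).
#' @param planted_unstable Character vector of gene names given 3x noise.
#' @param group_shift_genes Character vector of genes given group shifts.
#' @param noise_sd_cq Per-measurement Cq noise sd (cycles).
#' @param group_shift_sd Sd of the group-level Cq shifts (cycles).
#' @param seed Integer seed.
#' @return A [qpcr_table()] with attributes `planted_unstable` and
#'   `group_shift_genes`.
#' @export
simulate_qpcr <- function(n_genes = 17L,
                          groups = c(Liver = 8L, Breast = 5L, Colon = 3L),
                          planted_unstable = character(),
                          group_shift_genes = character(),
                          noise_sd_cq = 0.2, group_shift_sd = 2,
                          seed = 1L) {
  if (any(groups < 2L)) .stopf("every group needs at least 2 samples")
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  bad <- setdiff(c(planted_unstable, group_shift_genes), genes)
  if (length(bad)) .stopf("unknown gene name(s): %s", paste(bad, collapse = ", "))
  .with_seed(seed, {
    glab <- rep(names(groups), groups)
    samples <- paste0(glab, unlist(lapply(groups, seq_len)))
    base <- stats::runif(n_genes, 15, 29)
    cq <- matrix(rep(base, length(samples)), n_genes,
                 dimnames = list(genes, samples))
    for (g in group_shift_genes) {
      shift <- stats::rnorm(length(groups), 0, group_shift_sd)
      shift <- shift - mean(shift)
      cq[g, ] <- cq[g, ] + shift[match(glab, names(groups))]
    }
    noise_sd <- ifelse(genes %in% planted_unstable, 3 * noise_sd_cq, noise_sd_cq)
    cq <- cq + matrix(stats::rnorm(length(cq), 0, rep(noise_sd, length(samples))),
                      n_genes)
    eff <- stats::setNames(stats::runif(n_genes, 0.85, 1), genes)
    tbl <- qpcr_table(cq, eff, stats::setNames(glab, samples))
    attr(tbl, "planted_unstable") <- planted_unstable
    attr(tbl, "group_shift_genes") <- group_shift_genes
    attr(tbl, "seed") <- seed
    tbl
  })
}
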