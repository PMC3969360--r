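# RT-qPCR relative quantification and the three stability analyses:
# CV of relative expression, geNorm and a NormFinder-style model.

#' Construct an RT-qPCR Cq table
#'
#' Holds duplicate-averaged Cq values (gene x sample), per-gene
#' amplification efficiencies and a sample-to-group labelling (e.g.
#' Liver / Breast / Colon cell-line panels).
#'
#' @param cq Numeric gene x sample matrix of mean Cq values (`NA`
#'   allowed); dimnames supply gene and sample IDs.
#' @param efficiency Named numeric vector, gene -> fractional
#'   amplification efficiency (1.0 = perfect doubling per cycle).
#' @param groups Named character vector, sample -> group label.
#' @return Object of class `qpcr_table`.
#' @export
qpcr_table <- function(cq, efficiency, groups) {
  cq <- as.matrix(cq)
  storage.mode(cq) <- "double"
  genes <- rownames(cq); samples <- colnames(cq)
  if (is.null(genes) || is.null(samples)) .stopf("cq needs gene and sample dimnames")
  if (any(cq <= 0, na.rm = TRUE)) .stopf("Cq values must be positive")
  if (!all(genes %in% names(efficiency))) {
    .stopf("missing efficiency for gene(s): %s",
           paste(setdiff(genes, names(efficiency)), collapse = ", "))
  }
  efficiency <- efficiency[genes]
  if (any(!is.finite(efficiency) | efficiency <= 0)) {
    .stopf("efficiencies must be positive")
  }
  if (!all(samples %in% names(groups))) {
    .stopf("missing group label for sample(s): %s",
           paste(setdiff(samples, names(groups)), collapse = ", "))
  }
  structure(list(genes = genes, samples = samples, cq = cq,
                 efficiency = efficiency,
                 groups = as.character(groups[samples])),
            class = "qpcr_table")
}

#' @export
print.qpcr_table <- function(x, ...) {
  cat(sprintf("<qpcr_table> %d genes x %d samples, groups: %s\n",
              length(x$genes), length(x$samples),
              paste(sprintf("%s (%d)", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a long-format Cq TSV
#'
#' Columns: `gene`, `sample`, `group`, replicate Cq columns (`cq_rep1`,
#' `cq_rep2`, ... — arithmetic-mean-averaged), and either `efficiency` or
#' `slope` (converted via [efficiency_from_slope()]).
#'
#' @param path TSV path.
#' @return A [qpcr_table()].
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "")
  need <- c("gene", "sample", "group")
  if (!all(need %in% colnames(tab))) {
    .stopf("%s: needs columns gene, sample, group", path)
  }
  rep_cols <- grep("^cq(_rep[0-9]+)?$", colnames(tab), value = TRUE)
  if (!length(rep_cols)) .stopf("%s: no Cq replicate columns (cq_rep1, ...)", path)
  cq_mean <- rowMeans(as.matrix(tab[, rep_cols, drop = FALSE]), na.rm = TRUE)
  cq_mean[is.nan(cq_mean)] <- NA_real_
  genes <- unique(tab$gene); samples <- unique(tab$sample)
  cq <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  cq[cbind(match(tab$gene, genes), match(tab$sample, samples))] <- cq_mean
  if ("efficiency" %in% colnames(tab)) {
    eff <- tab$efficiency[!duplicated(tab$gene)]
  } else if ("slope" %in% colnames(tab)) {
    eff <- vapply(tab$slope[!duplicated(tab$gene)], efficiency_from_slope, numeric(1))
  } else {
    .stopf("%s: needs an 'efficiency' or 'slope' column", path)
  }
  groups <- stats::setNames(tab$group[!duplicated(tab$sample)], samples)
  qpcr_table(cq, stats::setNames(eff, genes), groups)
}

#' Amplification efficiency from a standard-curve slope
#'
#' A dilution-series standard curve regresses Cq on log10 template
#' amount; its slope gives the fractional per-cycle efficiency
#' `10^(-1/slope) - 1`, which is 1.0 (perfect doubling) at the ideal
#' slope `-1/log10(2) ~ -3.32`.
#'
#' @param slope Negative regression slope.
#' @return Efficiency (fractional gain per cycle).
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope >= 0) {
    .stopf("standard-curve slope must be negative (got %s)", format(slope))
  }
  10^(-1 / slope) - 1
}

#' Relative expression from Cq values
#'
#' Per gene, `delta_Cq` is taken against the gene's minimum Cq over
#' samples (the most abundant sample, following the geNorm convention),
#' and the relative quantity is `(1 + efficiency)^(-delta_Cq)`. The base
#' is `1 + efficiency` because the stored efficiency is the fractional
#' gain (1.0 for perfect doubling), while the exponential uses the full
#' per-cycle amplification factor (about 2). Quantities lie in `(0, 1]`
#' with a per-gene maximum of exactly 1; missing Cq gives a missing
#' quantity.
#'
#' @param table A [qpcr_table()].
#' @return Gene x sample matrix of relative quantities.
#' @export
relative_expression <- function(table) {
  stopifnot(inherits(table, "qpcr_table"))
  mins <- apply(table$cq, 1L, min, na.rm = TRUE)
  dcq <- table$cq - mins
  (1 + table$efficiency)^(-dcq)
}

#' Rank genes by the CV of their relative expression
#'
#' @param quantities Gene x sample matrix from [relative_expression()].
#' @param samples Optional subset of sample IDs defining the scope (a
#'   group, or all samples when `NULL`); needs at least 2.
#' @return Named numeric vector of CVs (sd/mean over the scope's samples),
#'   sorted ascending (most stable first).
#' @export
cv_stability <- function(quantities, samples = NULL) {
  q <- if (is.null(samples)) quantities else quantities[, samples, drop = FALSE]
  if (ncol(q) < 2L) .stopf("CV needs at least 2 samples in scope")
  cv <- .row_sds_na(q) / .row_means_na(q)
  sort(cv)
}

# sd over samples of log2(q_j / q_k), the geNorm pairwise variation.
.pairwise_v <- function(q) {
  lg <- log2(q)
  n <- nrow(q)
  V <- matrix(NA_real_, n, n, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      V[j, k] <- V[k, j] <- stats::sd(lg[j, ] - lg[k, ])
    }
  }
  V
}

#' geNorm expression-stability analysis
#'
#' For each gene, the stability measure `M` is the mean over all other
#' genes of the standard deviation (over samples) of the pairwise
#' log2 expression ratio. The least stable gene (highest `M`, ties broken
#' by gene-symbol order) is removed and `M` recomputed, stepwise, until
#' two genes remain; those two are the most stable pair and share rank 1.
#'
#' @param quantities Gene x sample matrix of relative quantities (no
#'   zeros or missing values; at least 3 genes and 2 samples).
#' @param samples Optional sample subset defining the scope.
#' @return Object of class `genorm_fit`: `m_values` (full-set `M` per
#'   gene), `steps` (list of named `M` vectors per exclusion step),
#'   `exclusion_order` (least stable first), `ranking` (most stable
#'   first; the final pair in symbol order) and `final_pair`.
#' @export
genorm_stability <- function(quantities, samples = NULL) {
  q <- if (is.null(samples)) quantities else quantities[, samples, drop = FALSE]
  if (nrow(q) < 3L) .stopf("geNorm needs at least 3 genes")
  if (ncol(q) < 2L) .stopf("geNorm needs at least 2 samples")
  if (any(!is.finite(q) | q <= 0)) {
    .stopf("geNorm needs strictly positive, non-missing quantities (log ratios)")
  }
  V <- .pairwise_v(q)
  m_full <- rowMeans(V, na.rm = TRUE)
  steps <- list()
  exclusion <- character(0)
  keep <- rownames(q)
  Vc <- V
  while (length(keep) > 2L) {
    m <- rowMeans(Vc[keep, keep, drop = FALSE], na.rm = TRUE)
    steps[[length(steps) + 1L]] <- m
    worst <- names(m)[order(-m, names(m))][1L]
    exclusion <- c(exclusion, worst)
    keep <- setdiff(keep, worst)
  }
  final_pair <- sort(keep)
  structure(list(m_values = m_full, steps = steps,
                 exclusion_order = exclusion,
                 ranking = c(final_pair, rev(exclusion)),
                 final_pair = final_pair),
            class = "genorm_fit")
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability ranking (most stable first):\n  ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  cat(sprintf("  full-set M range: %.4f - %.4f\n",
              min(x$m_values), max(x$m_values)))
  invisible(x)
}

#' geNorm pairwise variation V(n/n+1)
#'
#' `NF_n` is the per-sample geometric mean of the `n` most stable genes;
#' `V(n/n+1)` is the standard deviation over samples of
#' `log2(NF_n / NF_(n+1))`. Small `V` means adding the next gene barely
#' changes the normalization factor; the customary cut-off is 0.15, and
#' the smallest `n` with `V < 0.15` is reported as the number of
#' reference genes that suffices.
#'
#' @param quantities Gene x sample matrix of relative quantities.
#' @param ranked_genes Genes ordered most stable first (e.g. the
#'   `ranking` of [genorm_stability()]).
#' @param cutoff Pairwise-variation cut-off (default 0.15).
#' @return List with `v` (named vector `V2/3`, `V3/4`, ...) and
#'   `n_sufficient` (smallest `n` with `V < cutoff`, `NA` if none).
#' @export
genorm_pairwise_variation <- function(quantities, ranked_genes, cutoff = 0.15) {
  if (length(ranked_genes) < 3L) .stopf("pairwise variation needs at least 3 genes")
  q <- quantities[ranked_genes, , drop = FALSE]
  if (any(!is.finite(q) | q <= 0)) .stopf("quantities must be positive and non-missing")
  lg <- log2(q)
  nf_log <- function(n) colMeans(lg[seq_len(n), , drop = FALSE])  # log2 geometric mean
  ns <- 2L:(length(ranked_genes) - 1L)
  v <- vapply(ns, function(n) stats::sd(nf_log(n) - nf_log(n + 1L)), numeric(1))
  names(v) <- sprintf("V%d/%d", ns, ns + 1L)
  hit <- ns[v < cutoff]
  list(v = v, n_sufficient = if (length(hit)) min(hit) else NA_integer_)
}

#' NormFinder-style model-based stability
#'
#' Works on log2 quantities. Each sample is centred by its mean over
#' genes (removing the sample's overall level); per group, a gene's
#' intra-group variance is estimated from the centred values with a
#' correction for the centring (subtracting the group's average variance
#' divided by the number of genes minus one, floored at zero), and its
#' inter-group effect is the deviation of its group mean from its overall
#' mean. Group effects are shrunk towards zero in proportion to their
#' sampling noise (an empirical-Bayes damping), and the stability value
#' is the average over groups of the absolute shrunken group effect plus
#' the intra-group standard error of the group mean. Lower is more
#' stable. Because of the per-sample centring, the values change when
#' the input gene set changes.
#'
#' With a single group the inter-group term vanishes and the stability is
#' the intra-group standard error alone.
#'
#' @param quantities Gene x sample matrix of relative quantities (at
#'   least 3 genes, strictly positive).
#' @param groups Character vector of group labels, one per column; every
#'   group needs at least 2 samples.
#' @return Named numeric vector of stability values, sorted ascending.
#' @export
normfinder_stability <- function(quantities, groups) {
  q <- quantities
  if (nrow(q) < 3L) .stopf("NormFinder needs at least 3 genes")
  if (length(groups) != ncol(q)) .stopf("one group label per sample is required")
  if (any(!is.finite(q) | q <= 0)) .stopf("quantities must be positive and non-missing")
  tab <- table(groups)
  if (any(tab < 2L)) {
    .stopf("group(s) with fewer than 2 samples: %s",
           paste(names(tab)[tab < 2L], collapse = ", "))
  }
  y <- log2(q)
  z <- sweep(y, 2L, colMeans(y))          # remove sample effects
  glev <- names(tab)
  n_genes <- nrow(q)
  gmeans <- sapply(glev, function(g) rowMeans(z[, groups == g, drop = FALSE]))
  gvars <- sapply(glev, function(g) apply(z[, groups == g, drop = FALSE], 1L, stats::var))
  # centring over n genes correlates residuals; correct and floor at zero
  gvars_corr <- pmax(sweep(gvars, 2L, colMeans(gvars) / (n_genes - 1L)), 0)
  m <- as.numeric(tab[glev])
  se2 <- sweep(gvars_corr, 2L, m, "/")    # sampling variance of group means
  if (length(glev) == 1L) {
    stab <- sqrt(se2[, 1L])
    names(stab) <- rownames(q)
    return(sort(stab))
  }
  d <- gmeans - rowMeans(gmeans)          # inter-group deviations
  # variance of the true group effects, estimated by moments
  gamma2 <- max(0, sum(d^2) / ((n_genes - 1L) * (length(glev) - 1L)) - mean(se2))
  shrink <- gamma2 / (gamma2 + se2)
  if (gamma2 == 0) shrink[] <- 0
  d_tilde <- d * shrink
  stab <- rowMeans(abs(d_tilde) + sqrt(se2))
  names(stab) <- rownames(q)
  sort(stab)
}

#' Drop genes whose log2 quantities are too dispersed
#'
#' Removes genes whose standard deviation of log2 relative expression
#' exceeds `sd_cutoff`; used to rerun the stability analyses without the
#' least stable genes.
#'
#' @param quantities Gene x sample matrix of relative quantities.
#' @param sd_cutoff Standard-deviation cut-off on the log2 scale.
#' @return Character vector of retained gene names.
#' @export
exclude_high_sd_genes <- function(quantities, sd_cutoff) {
  sds <- apply(log2(quantities), 1L, stats::sd, na.rm = TRUE)
  keep <- rownames(quantities)[sds <= sd_cutoff]
  if (!length(keep)) .stopf("sd cut-off %g removes every gene", sd_cutoff)
  keep
}

#' Full RT-qPCR stability report
#'
#' Computes relative expression from the Cq table and ranks every gene by
#' the three stability measures — CV of relative expression, geNorm `M`
#' and NormFinder stability — overall ("All") and within each sample
#' group with at least 2 samples. NormFinder uses its grouped model in
#' the "All" scope and the single-group variant within a group. The
#' geNorm pairwise variation `V(n/n+1)` for the "All" scope is attached.
#'
#' @param table A [qpcr_table()].
#' @param v_cutoff Pairwise-variation cut-off (default 0.15).
#' @return Object of class `qpcr_stability`: `scopes` (named list of data
#'   frames with columns `gene`, `cv`, `cv_rank`, `genorm_m`,
#'   `genorm_rank`, `normfinder`, `normfinder_rank`), `pairwise_v`,
#'   `quantities` and the input `table`.
#' @export
qpcr_stability <- function(table, v_cutoff = 0.15) {
  stopifnot(inherits(table, "qpcr_table"))
  q <- relative_expression(table)
  scopes <- c(list(All = table$samples),
              split(table$samples, table$groups))
  scopes <- scopes[vapply(scopes, length, integer(1)) >= 2L]
  reports <- lapply(names(scopes), function(sc) {
    smp <- scopes[[sc]]
    cv <- cv_stability(q, smp)[table$genes]
    gn <- genorm_stability(q, smp)
    gn_rank <- match(table$genes, gn$ranking)
    grp <- if (sc == "All") table$groups else rep(sc, length(smp))
    nf <- normfinder_stability(q[, smp, drop = FALSE], grp)[table$genes]
    # ranks are full permutations; exact ties break by gene symbol
    rank_by <- function(v) order(order(v, table$genes))
    data.frame(gene = table$genes,
               cv = unname(cv),
               cv_rank = rank_by(cv),
               genorm_m = unname(gn$m_values[table$genes]),
               genorm_rank = gn_rank,
               normfinder = unname(nf),
               normfinder_rank = rank_by(nf),
               row.names = NULL)
  })
  names(reports) <- names(scopes)
  gn_all <- genorm_stability(q, scopes[["All"]])
  pv <- genorm_pairwise_variation(q[, scopes[["All"]], drop = FALSE],
                                  gn_all$ranking, cutoff = v_cutoff)
  structure(list(scopes = reports, pairwise_v = pv, quantities = q,
                 table = table, v_cutoff = v_cutoff),
            class = "qpcr_stability")
}

#' @export
print.qpcr_stability <- function(x, ...) {
  cat(sprintf("RT-qPCR stability report: %d genes, %d samples, scopes: %s\n",
              length(x$table$genes), length(x$table$samples),
              paste(names(x$scopes), collapse = ", ")))
  all_sc <- x$scopes[["All"]]
  ord <- order(all_sc$cv_rank)
  cat("  most stable by CV (All): ",
      paste(utils::head(all_sc$gene[ord], 5L), collapse = ", "), "\n", sep = "")
  v <- x$pairwise_v
  cat(sprintf("  pairwise variation: %s; smallest n with V < %g: %s\n",
              paste(sprintf("%s = %.3f", names(v$v), v$v), collapse = ", "),
              x$v_cutoff,
              ifelse(is.na(v$n_sufficient), "none", v$n_sufficient)))
  invisible(x)
}

#' @export
summary.qpcr_stability <- function(object, ...) {
  lapply(object$scopes, function(df) {
    df[order(df$normfinder_rank), c("gene", "cv_rank", "genorm_rank",
                                    "normfinder_rank")]
  })
}
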