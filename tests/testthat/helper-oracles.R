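# Independent brute-force reimplementations used as oracles. These are
# deliberately written as plain loops over the definitions, sharing no code
# with the package internals.

oracle_percentile <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  for (i in which(ok)) {
    below <- sum(values[ok] < values[i])
    ties <- sum(values[ok] == values[i])
    out[i] <- 100 * (below + (ties + 1) / 2 - 0.5) / n
  }
  out
}

# gene x sample rank matrix by looping over samples, probes and genes
oracle_rank_dataset <- function(dataset) {
  pr <- matrix(NA_real_, length(dataset$probes), length(dataset$samples))
  for (j in seq_along(dataset$samples)) {
    pr[, j] <- oracle_percentile(dataset$values[, j])
  }
  genes <- sort(unique(dataset$probe_to_gene[!is.na(dataset$probe_to_gene)]))
  out <- matrix(NA_real_, length(genes), length(dataset$samples),
                dimnames = list(genes, dataset$samples))
  for (g in seq_along(genes)) {
    idx <- which(!is.na(dataset$probe_to_gene) & dataset$probe_to_gene == genes[g])
    for (j in seq_along(dataset$samples)) {
      vals <- pr[idx, j]
      vals <- vals[!is.na(vals)]
      if (length(vals)) out[g, j] <- sum(vals) / length(vals)
    }
  }
  out
}

oracle_cv <- function(x) {
  x <- x[!is.na(x)]
  m <- sum(x) / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / (length(x) - 1)) / m
}

# (gene, dataset) -> CV over all observed pairs, by looping
oracle_cv_entries <- function(collection) {
  out <- list()
  for (d in collection$datasets) {
    rk <- oracle_rank_dataset(d)
    for (g in rownames(rk)) {
      row <- rk[g, ]
      if (sum(!is.na(row)) >= 2) {
        out[[paste(g, d$dataset_id, sep = "|")]] <- oracle_cv(row)
      }
    }
  }
  out
}

oracle_ratio <- function(cv_entries, gene, t) {
  keys <- names(cv_entries)
  mine <- keys[sub("\\|.*", "", keys) == gene]
  if (!length(mine)) return(NA_real_)
  sum(vapply(mine, function(k) cv_entries[[k]] < t, logical(1))) / length(mine)
}

oracle_po <- function(cv_entries, gene, total) {
  keys <- names(cv_entries)
  sum(sub("\\|.*", "", keys) == gene) / total
}

oracle_fpo <- function(cv_entries, genes, t, po_min, r_grid, total) {
  vapply(r_grid, function(r) {
    count <- 0L
    for (g in genes) {
      ratio <- oracle_ratio(cv_entries, g, t)
      if (!is.na(ratio) && ratio > r && oracle_po(cv_entries, g, total) >= po_min) {
        count <- count + 1L
      }
    }
    count
  }, integer(1))
}

oracle_confusion <- function(predicted, truth, universe) {
  tp <- fp <- tn <- fn <- 0L
  for (g in universe) {
    in_p <- g %in% predicted
    in_t <- g %in% truth
    if (in_p && in_t) tp <- tp + 1L
    else if (in_p) fp <- fp + 1L
    else if (in_t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# pairwise-ranking AUROC; smaller score = called positive earlier
oracle_pairwise_auroc <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (p < q) total <- total + 1
      else if (p == q) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  gap <- 0
  for (x in pts) {
    gap <- max(gap, abs(sum(a <= x) / length(a) - sum(b <= x) / length(b)))
  }
  gap
}

oracle_genorm_m <- function(q) {
  genes <- rownames(q)
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in seq_along(genes)) {
    vs <- c()
    for (k in seq_along(genes)) {
      if (k == j) next
      ratios <- log2(q[j, ] / q[k, ])
      mu <- mean(ratios)
      vs <- c(vs, sqrt(sum((ratios - mu)^2) / (length(ratios) - 1)))
    }
    m[j] <- mean(vs)
  }
  m
}

oracle_genorm_v <- function(q, ranked) {
  ns <- 2:(length(ranked) - 1)
  out <- numeric(length(ns))
  for (i in seq_along(ns)) {
    n <- ns[i]
    nf_n <- apply(q[ranked[1:n], , drop = FALSE], 2, function(col) prod(col)^(1 / n))
    nf_n1 <- apply(q[ranked[1:(n + 1)], , drop = FALSE], 2,
                   function(col) prod(col)^(1 / (n + 1)))
    out[i] <- stats::sd(log2(nf_n / nf_n1))
  }
  out
}

# loop-based NormFinder of the documented model
oracle_normfinder <- function(q, groups) {
  y <- log2(q)
  n_genes <- nrow(y)
  for (j in seq_len(ncol(y))) y[, j] <- y[, j] - mean(y[, j])
  glev <- sort(unique(groups))
  gm <- matrix(0, n_genes, length(glev))
  gv <- matrix(0, n_genes, length(glev))
  m_i <- integer(length(glev))
  for (i in seq_along(glev)) {
    cols <- which(groups == glev[i])
    m_i[i] <- length(cols)
    for (g in seq_len(n_genes)) {
      gm[g, i] <- mean(y[g, cols])
      gv[g, i] <- stats::var(y[g, cols])
    }
  }
  gv_corr <- gv
  for (i in seq_along(glev)) {
    gv_corr[, i] <- pmax(gv[, i] - mean(gv[, i]) / (n_genes - 1), 0)
  }
  se2 <- sweep(gv_corr, 2, m_i, "/")
  if (length(glev) == 1) {
    return(sort(stats::setNames(sqrt(se2[, 1]), rownames(q))))
  }
  d <- gm - rowMeans(gm)
  gamma2 <- max(0, sum(d^2) / ((n_genes - 1) * (length(glev) - 1)) - mean(se2))
  shrink <- if (gamma2 == 0) matrix(0, n_genes, length(glev)) else gamma2 / (gamma2 + se2)
  stab <- rowMeans(abs(d * shrink) + sqrt(se2))
  sort(stats::setNames(stab, rownames(q)))
}
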