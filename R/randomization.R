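# Mean-rank-matched random non-housekeeping gene sets and
# Kolmogorov-Smirnov comparisons of Ratio_t distributions.

#' Draw random gene sets matched to a housekeeping set on mean rank
#'
#' Mean percentile ranks are binned (default 5-unit bins over `[0, 100)`);
#' within each bin, every random set samples as many non-housekeeping
#' genes, without replacement within a set, as housekeeping genes fall in
#' that bin. The sets therefore share the housekeeping set's mean-rank
#' distribution to bin resolution, so differences in `Ratio_t` cannot be
#' explained by expression level alone.
#'
#' @param summaries Data frame with columns `gene` and `mean_rank` (e.g.
#'   `coef()` of a [ref_stability()] fit), or a named numeric vector of
#'   mean ranks.
#' @param hk_set Character vector of housekeeping genes.
#' @param n_sets Number of random sets (default 5).
#' @param seed Integer seed; set `k` uses substream `seed + k`.
#' @param bin_width Mean-rank bin width in percentile units (default 5).
#' @return Object of class `matched_sets`: list with `hk_set` (restricted
#'   to genes with a mean rank), `random_sets`, `seed` and `bin_edges`.
#' @export
matched_random_sets <- function(summaries, hk_set, n_sets = 5L, seed = 1L,
                                bin_width = 5) {
  if (is.data.frame(summaries)) {
    mean_rank <- stats::setNames(summaries$mean_rank, summaries$gene)
  } else {
    mean_rank <- summaries
  }
  mean_rank <- mean_rank[!is.na(mean_rank)]
  hk <- intersect(toupper(hk_set), names(mean_rank))
  if (!length(hk)) .stopf("no housekeeping gene has a mean rank")
  pool <- setdiff(names(mean_rank), hk)
  edges <- seq(0, 100, by = bin_width)
  bin_of <- function(g) findInterval(mean_rank[g], edges,
                                     rightmost.closed = FALSE)
  hk_bins <- bin_of(hk)
  pool_bins <- bin_of(pool)
  need <- table(hk_bins)
  for (b in names(need)) {
    avail <- sum(pool_bins == as.integer(b))
    if (avail < need[[b]]) {
      .stopf("bin [%g, %g) has only %d non-housekeeping genes but needs %d",
             edges[as.integer(b)], edges[as.integer(b) + 1L], avail, need[[b]])
    }
  }
  random_sets <- lapply(seq_len(n_sets), function(k) {
    .with_seed(seed + k, {
      picked <- character(0)
      for (b in names(need)) {
        cand <- pool[pool_bins == as.integer(b)]
        picked <- c(picked, sample(cand, need[[b]], replace = FALSE))
      }
      sort(picked)
    })
  })
  structure(list(hk_set = sort(hk), random_sets = random_sets,
                 seed = seed, bin_edges = edges),
            class = "matched_sets")
}

#' @export
print.matched_sets <- function(x, ...) {
  cat(sprintf("<matched_sets> %d housekeeping genes, %d matched random sets (seed %d)\n",
              length(x$hk_set), length(x$random_sets), x$seed))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Returns the KS statistic `D` (maximum gap between the two empirical
#' CDFs) and the two-sided asymptotic p-value.
#'
#' @param ratios_a,ratios_b Numeric vectors (here: per-gene `Ratio_t`
#'   values of two gene sets).
#' @return List with elements `D` and `p`.
#' @export
ks_compare <- function(ratios_a, ratios_b) {
  if (!length(ratios_a) || !length(ratios_b)) .stopf("empty input to KS comparison")
  kt <- suppressWarnings(stats::ks.test(ratios_a, ratios_b,
                                        alternative = "two.sided",
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Compare housekeeping Ratio_t distributions with matched random sets
#'
#' Draws `n_sets` mean-rank-matched random non-housekeeping sets, restricts
#' every set to genes passing the PO gate, and compares the `Ratio_t`
#' distributions: housekeeping vs each random set (unadjusted p-values)
#' and all random-vs-random pairs with Bonferroni adjustment over the
#' `n_sets * (n_sets - 1) / 2` comparisons. `f_PO` counts per set are
#' returned for plotting.
#'
#' @param fit A [ref_stability()] object.
#' @param hk_set Character vector of housekeeping genes.
#' @param t CV threshold for `Ratio_t` (default 0.05).
#' @param po_min PO gate applied before comparing (default 0.5).
#' @param n_sets Number of random sets (default 5).
#' @param seed Integer seed.
#' @param r_grid Ratio cut points for the `f_PO` curves.
#' @param bin_width Mean-rank matching bin width.
#' @return Object of class `hk_randomization`: list with `hk_vs_random`
#'   (data frame: set, n_hk, n_random, D, p), `random_vs_random` (data
#'   frame: set_a, set_b, D, p, p_bonferroni; `NULL` when `n_sets < 2`),
#'   `f_po` (data frame of counts per set over `r_grid`), and the
#'   underlying `matched_sets`.
#' @export
compare_hk_vs_random <- function(fit, hk_set, t = 0.05, po_min = 0.5,
                                 n_sets = 5L, seed = 1L,
                                 r_grid = seq(0, 1, by = 0.02),
                                 bin_width = 5) {
  stopifnot(inherits(fit, "ref_stability"))
  ms <- matched_random_sets(fit$summaries, hk_set, n_sets = n_sets,
                            seed = seed, bin_width = bin_width)
  cv_table <- fit$cv_table
  ratio <- .ratio_all(cv_table, t)
  po <- cv_table$n_observed / cv_table$n_total
  gated_ratio <- function(genes) {
    idx <- match(genes, cv_table$genes)
    idx <- idx[!is.na(idx)]
    r <- ratio[idx]
    r[!is.na(r) & po[idx] >= po_min]
  }
  hk_r <- gated_ratio(ms$hk_set)
  rand_r <- lapply(ms$random_sets, gated_ratio)
  hk_vs <- do.call(rbind, lapply(seq_along(rand_r), function(k) {
    ks <- ks_compare(hk_r, rand_r[[k]])
    data.frame(set = k, n_hk = length(hk_r), n_random = length(rand_r[[k]]),
               D = ks$D, p = ks$p)
  }))
  rand_vs <- NULL
  if (n_sets >= 2L) {
    pairs <- utils::combn(n_sets, 2L)
    m <- ncol(pairs)
    rand_vs <- do.call(rbind, lapply(seq_len(m), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      ks <- ks_compare(rand_r[[a]], rand_r[[b]])
      data.frame(set_a = a, set_b = b, D = ks$D, p = ks$p)
    }))
    rand_vs$p_bonferroni <- pmin(1, rand_vs$p * m)
  }
  fpo <- data.frame(r = r_grid,
                    hk = f_po_curve(cv_table, t, po_min, r_grid, genes = ms$hk_set))
  for (k in seq_along(ms$random_sets)) {
    fpo[[paste0("random_", k)]] <-
      f_po_curve(cv_table, t, po_min, r_grid, genes = ms$random_sets[[k]])
  }
  structure(list(hk_vs_random = hk_vs, random_vs_random = rand_vs,
                 f_po = fpo, matched_sets = ms, t = t, po_min = po_min),
            class = "hk_randomization")
}

#' @export
print.hk_randomization <- function(x, ...) {
  cat(sprintf("Housekeeping vs matched-random Ratio_t comparison (t = %g, PO >= %g)\n",
              x$t, x$po_min))
  print(x$hk_vs_random, row.names = FALSE, digits = 4)
  if (!is.null(x$random_vs_random)) {
    cat(sprintf("  random-vs-random: %d / %d Bonferroni-adjusted p < 0.05\n",
                sum(x$random_vs_random$p_bonferroni < 0.05),
                nrow(x$random_vs_random)))
  }
  invisible(x)
}
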