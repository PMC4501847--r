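#' Per-gene partition-null variance test
#'
#' For each gene, compares the across-cell variance of observed isoform
#' ratios `k1/K` with its distribution under the shared-preference null.
#' Conditioning on each cell's observed total `K_gc` (justified by the exact
#' multinomial collapse: given the totals, the isoform split is
#' `Binomial(K, p)` under per-molecule independence), the null is simulated
#' `n_sim` times by drawing `k1* ~ Binomial(K_gc, p_hat)` per cell with the
#' pooled preference estimate `p_hat = sum(k1) / sum(K)` and recording the
#' across-cell ratio variance. A gene is flagged as exceeding when its
#' observed variance is above the null median, and a one-sided empirical
#' P-value is reported with the add-one rule `(r + 1) / (n_sim + 1)`.
#'
#' @param counts Tibble with `gene_id`, `cell_id`, `k1`, `k2`.
#' @param n_sim Number of null simulations per gene (default 1000).
#' @param min_cells Genes with fewer informative cells (cells with `K >= 1`)
#'   are excluded (default 3).
#' @param seed Random seed; results are a pure function of inputs and seed.
#' @return A tibble with one row per tested gene: `gene_id`, `n_cells`
#'   (informative cells), `p_hat`, `obs_var`, `null_median`, `exceeds`,
#'   `p_value`.
#' @export
partition_null_variance_test <- function(counts, n_sim = 1000L,
                                         min_cells = 3L, seed = 1L) {
  counts <- tibble::as_tibble(counts)
  set.seed(seed)
  counts$K <- counts$k1 + counts$k2
  counts |>
    dplyr::filter(.data$K >= 1) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      if (n < min_cells) return(tibble::tibble())
      p_hat <- sum(g$k1) / sum(g$K)
      obs_var <- var(g$k1 / g$K)
      sims <- matrix(rbinom(n * n_sim, rep(g$K, n_sim), p_hat), nrow = n)
      null_var <- matrixStats_colVars(sims / g$K)
      r_exc <- sum(null_var >= obs_var)
      tibble::tibble(
        n_cells = n, p_hat = p_hat, obs_var = obs_var,
        null_median = median(null_var),
        exceeds = obs_var > median(null_var),
        p_value = (r_exc + 1) / (n_sim + 1)
      )
    }) |>
    dplyr::ungroup()
}

# column variances without an extra dependency
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - colSums(x)^2 / n) / (n - 1)
}

#' Population-level enrichment of variance-exceeding genes
#'
#' Under the shared-preference null, a gene's observed ratio variance
#' exceeds its null median with probability one half, so the number of
#' exceeding genes is `Binomial(n, 0.5)`. A one-sided binomial test reports
#' whether exceeding genes are enriched beyond that.
#'
#' @param exceeds Logical vector of per-gene exceedance flags (e.g. the
#'   `exceeds` column of [partition_null_variance_test()]).
#' @param p_null Null exceedance probability (default 0.5).
#' @return One-sided P-value.
#' @export
enrichment_binomial_test <- function(exceeds, p_null = 0.5) {
  stopifnot(length(exceeds) >= 1)
  binom.test(sum(exceeds), length(exceeds), p = p_null,
             alternative = "greater")$p.value
}

#' Kolmogorov-Smirnov comparison against the partition-only null
#'
#' For direct molecule-count data (e.g. smFISH spot counts, where there is no
#' capture thinning), asks whether the spread of per-cell isoform ratios
#' exceeds what random partitioning alone produces. The null distribution of
#' ratios is built by drawing, `inner_sim` times, each cell's long-isoform
#' count as `Binomial(total_c, p_hat)` conditioned on that cell's observed
#' total, with the pooled preference estimate `p_hat`; the test statistic is
#' the two-sample Kolmogorov-Smirnov distance between the measured ratio
#' distribution and this pooled simulated one. Because per-cell ratios are
#' discrete and heavily tied, and because `p_hat` is estimated from the same
#' data, the asymptotic KS null is unreliable here; the P-value is therefore
#' calibrated by a parametric bootstrap in which each of `n_sim` replicate
#' datasets is drawn from the null, gets its own re-estimated pooled
#' preference and its own simulated reference, and contributes one replicate
#' statistic. The empirical P uses the add-one rule `(r + 1) / (n_sim + 1)`.
#'
#' @param counts Tibble with `cell_id`, `long` (molecules of the long
#'   isoform) and `total` (all molecules of the gene) per cell.
#' @param n_sim Number of bootstrap replicates calibrating the P-value
#'   (default 1000, giving a smallest attainable P of 1/1001).
#' @param inner_sim Simulation rounds pooled into each reference ratio
#'   sample (default 200).
#' @param seed Random seed.
#' @return A list with `statistic` (KS D between measured and simulated
#'   ratios), `p_value` (bootstrap-calibrated), `p_hat`, and the pooled
#'   simulated `null_ratios` for the observed data.
#' @export
ks_partition_test <- function(counts, n_sim = 1000L, inner_sim = 200L,
                              seed = 1L) {
  counts <- tibble::as_tibble(counts)
  counts <- dplyr::filter(counts, .data$total >= 1)
  if (nrow(counts) == 0) stop("all per-cell totals are zero")
  set.seed(seed)
  totals <- counts$total
  n <- length(totals)
  stat_with_own_null <- function(long_vec) {
    ph <- sum(long_vec) / sum(totals)
    pooled <- rbinom(n * inner_sim, rep(totals, inner_sim), ph) /
      rep(totals, inner_sim)
    c(ks_statistic(long_vec / totals, pooled), list(pooled))
  }
  p_hat <- sum(counts$long) / sum(counts$total)
  obs <- stat_with_own_null(counts$long)
  d_obs <- obs[[1]]
  d_rep <- vapply(seq_len(n_sim), function(j) {
    stat_with_own_null(rbinom(n, totals, p_hat))[[1]]
  }, numeric(1))
  list(statistic = d_obs,
       p_value = (sum(d_rep >= d_obs) + 1) / (n_sim + 1),
       p_hat = p_hat, null_ratios = obs[[2]])
}

# two-sample Kolmogorov-Smirnov distance (max absolute ECDF difference),
# valid under ties
ks_statistic <- function(x, y) {
  all_v <- sort(unique(c(x, y)))
  ex <- stats::ecdf(x)(all_v)
  ey <- stats::ecdf(y)(all_v)
  max(abs(ex - ey))
}

#' Fisher's exact test for 3' UTR lengthening between pooled populations
#'
#' For each gene, builds the 2x2 table of pooled (summed over cells) short-
#' and long-isoform molecule counts in two populations and applies a
#' two-sided Fisher's exact test. Genes significant at `alpha` are classed by
#' the direction of the odds ratio: `"long_up"` when the long isoform is
#' relatively more used in population B, `"short_up"` for the reverse, and
#' `"ns"` otherwise (including degenerate tables with a zero margin).
#'
#' @param pooled Tibble with columns `gene_id`, `short_a`, `long_a`,
#'   `short_b`, `long_b` (pooled molecule counts in populations A and B).
#' @param alpha Significance threshold (default 0.05, on raw P-values).
#' @return `pooled` with `odds_ratio`, `p_value` and `class` columns.
#' @export
fisher_lengthening_test <- function(pooled, alpha = 0.05) {
  pooled <- tibble::as_tibble(pooled)
  res <- purrr::pmap_dfr(
    pooled[, c("short_a", "long_a", "short_b", "long_b")],
    function(short_a, long_a, short_b, long_b) {
      tab <- matrix(c(long_a, short_a, long_b, short_b), 2, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        return(tibble::tibble(odds_ratio = NA_real_, p_value = 1,
                              class = "ns"))
      }
      ft <- fisher.test(tab)
      # odds of long vs short in B relative to A: > 1 means long-up in B
      or_ba <- (long_b / short_b) / (long_a / short_a)
      cls <- if (ft$p.value < alpha) {
        if (or_ba > 1) "long_up" else if (or_ba < 1) "short_up" else "ns"
      } else "ns"
      tibble::tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                     class = cls)
    }
  )
  dplyr::bind_cols(pooled, res)
}
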