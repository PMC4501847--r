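#' Estimate per-cell molecular capture efficiency from spike-ins
#'
#' For each cell, the observed spike-in molecule counts are regressed against
#' the known number of molecules present in the reaction. Since capture acts
#' as multiplicative thinning of molecules, the regression is constrained
#' through the origin and its slope is the cell's capture efficiency
#' `beta` (clamped to `[0, 1]`).
#'
#' @param spikes Data frame with columns `cell_id`, `spike_id`, `observed`
#'   (molecule count seen in the cell) and `known` (molecules of that species
#'   per reaction).
#' @param weights `"none"` (default, ordinary least squares) or `"poisson"`
#'   (weights `1/known`, appropriate when counting noise dominates).
#' @return A tibble with one row per cell: `beta`, `se` (slope standard
#'   error), `n_spikes` (distinct species observed), and `missing` (`TRUE`
#'   when fewer than 3 species were available and no estimate is made).
#'   Cells whose observations are all zero get `beta = 0` with a warning.
#' @export
estimate_capture_efficiency <- function(spikes, weights = c("none", "poisson")) {
  weights <- match.arg(weights)
  spikes <- tibble::as_tibble(spikes)
  if (any(spikes$known <= 0)) stop("known spike-in molecule numbers must be > 0")
  if (any(spikes$observed > 10 * spikes$known)) {
    warning("some observed spike-in counts exceed 10x the known input")
  }
  out <- spikes |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(g, key) {
      n_sp <- dplyr::n_distinct(g$spike_id)
      if (n_sp < 3) {
        return(tibble::tibble(beta = NA_real_, se = NA_real_,
                              n_spikes = n_sp, missing = TRUE))
      }
      w <- if (weights == "poisson") 1 / g$known else rep(1, nrow(g))
      # least-squares slope through the origin: sum(w x y) / sum(w x^2)
      slope <- sum(w * g$known * g$observed) / sum(w * g$known^2)
      resid <- g$observed - slope * g$known
      dof <- nrow(g) - 1
      se <- sqrt(sum(w * resid^2) / dof / sum(w * g$known^2))
      if (all(g$observed == 0)) {
        warning("cell ", key$cell_id, ": all spike-in observations are zero")
      }
      tibble::tibble(beta = min(max(slope, 0), 1), se = se,
                     n_spikes = n_sp, missing = FALSE)
    }) |>
    dplyr::ungroup()
  out
}

#' Simulate bulk-vs-summed-single-cell correlations under binomial capture
#'
#' Reproduces the noise-model validation experiment: "true" per-gene
#' expression values are drawn from a two-component log-normal mixture,
#' partitioned at random across cells, and then observed through two
#' independent rounds of binomial subsampling — once as a bulk measurement
#' with efficiency `beta_bulk`, and once as the in-silico sum of per-cell
#' measurements with efficiencies `beta_cells`. The Pearson correlation of
#' the log counts between the two channels quantifies how much of the
#' bulk/single-cell discordance binomial capture noise alone explains, at the
#' gene level and at the isoform level (after splitting each gene's molecules
#' between two isoforms with a fixed per-gene preference).
#'
#' @param n_genes Number of genes to simulate.
#' @param mixture List with elements `meanlog` (length 2), `sdlog` (length
#'   2) and `prob` (mixing weight of the first component) describing the
#'   log-normal mixture of true pooled expression values.
#' @param beta_bulk Capture efficiency of the bulk channel.
#' @param beta_cells Vector of per-cell capture efficiencies (recycled to
#'   `n_cells`).
#' @param n_cells Number of single cells summed in silico.
#' @param seed Random seed.
#' @return A list with `gene_corr`, `isoform_corr`, and the simulated count
#'   tibble `counts` (`gene`, `bulk`, `cells` at gene level).
#' @export
simulate_subsampling_correlation <- function(n_genes = 2000,
                                             mixture = list(meanlog = c(2.5, 6),
                                                            sdlog = c(1, 1),
                                                            prob = 0.5),
                                             beta_bulk = 0.05,
                                             beta_cells = 0.05,
                                             n_cells = 48,
                                             seed = 1L) {
  set.seed(seed)
  stopifnot(beta_bulk > 0, beta_bulk <= 1, all(beta_cells > 0),
            all(beta_cells <= 1))
  beta_cells <- rep_len(beta_cells, n_cells)
  comp <- stats::rbinom(n_genes, 1, mixture$prob) + 1L
  true_total <- round(stats::rlnorm(n_genes,
                                    mixture$meanlog[comp],
                                    mixture$sdlog[comp]))
  # fixed per-gene isoform preference for the isoform-level channel
  pref <- stats::rbeta(n_genes, 2, 2)
  per_cell <- vapply(true_total, function(tt) {
    if (tt == 0) return(rep(0L, n_cells))
    as.integer(stats::rmultinom(1, tt, rep(1, n_cells)))
  }, integer(n_cells))
  # per_cell: n_cells x n_genes
  bulk <- stats::rbinom(n_genes, true_total, beta_bulk)
  cells <- colSums(matrix(
    stats::rbinom(length(per_cell), as.vector(per_cell),
                  rep(beta_cells, n_genes)),
    nrow = n_cells
  ))
  gene_corr <- stats::cor(log(bulk + 1), log(cells + 1))
  # isoform split applied to each observed channel with the same preference
  bulk_iso1 <- stats::rbinom(n_genes, bulk, pref)
  cells_iso1 <- stats::rbinom(n_genes, cells, pref)
  iso_bulk <- c(bulk_iso1, bulk - bulk_iso1)
  iso_cells <- c(cells_iso1, cells - cells_iso1)
  isoform_corr <- stats::cor(log(iso_bulk + 1), log(iso_cells + 1))
  list(gene_corr = gene_corr, isoform_corr = isoform_corr,
       counts = tibble::tibble(gene = seq_len(n_genes), bulk = bulk,
                               cells = cells))
}
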