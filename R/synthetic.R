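#' Build a small synthetic gene annotation with known polyadenylation sites
#'
#' Creates a toy single-chromosome annotation in which genes are laid out far
#' apart (so gene assignment is unambiguous) and each gene carries a set of
#' true polyadenylation sites near its 3' end, well separated relative to the
#' merge window.
#'
#' @param n_genes Number of genes.
#' @param n_sites Polyadenylation sites per gene.
#' @param site_gap Distance in bp between successive sites of a gene (keep
#'   above the merge window; default 200).
#' @param gene_gap Distance in bp between gene ends and the next gene start
#'   (default 60000, beyond the downstream assignment window).
#' @return A list with `genes` (annotation tibble for [assign_gene()]) and
#'   `sites` (tibble `gene_id`, `chrom`, `strand`, `position`).
#' @export
synthetic_gene_annotation <- function(n_genes = 5, n_sites = 2,
                                      site_gap = 200L, gene_gap = 60000L) {
  gene_len <- 5000L + (n_sites + 1L) * site_gap
  starts <- 1L + (seq_len(n_genes) - 1L) * (gene_len + gene_gap)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = "chr1",
    strand = "+",
    start = starts,
    end = starts + gene_len - 1L
  )
  sites <- tidyr::expand_grid(gene_id = genes$gene_id,
                              site_no = seq_len(n_sites)) |>
    dplyr::left_join(genes, by = "gene_id") |>
    dplyr::mutate(position = .data$end - (n_sites - .data$site_no) * site_gap,
                  chrom = "chr1", strand = "+") |>
    dplyr::select("gene_id", "chrom", "strand", "position")
  list(genes = genes, sites = sites)
}

# draw n UMIs of given length whose pairwise Hamming distance exceeds
# max_dist, by rejection; guarantees zero spurious merges in a group
draw_distinct_umis <- function(n, len = 8L, max_dist = 1L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    ok <- TRUE
    for (u in out) {
      d <- sum(strsplit(cand, "")[[1]] != strsplit(u, "")[[1]])
      if (d <= max_dist + 1L) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, cand)
  }
  out
}

mutate_umi <- function(umi) {
  i <- sample.int(nchar(umi), 1)
  old <- substr(umi, i, i)
  repl <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  paste0(substr(umi, 1, i - 1), repl, substr(umi, i + 1, nchar(umi)))
}

#' Simulate a 3' tag table with known ground truth
#'
#' Emulates the output of aligning a 3' tag library: per cell and gene, a
#' Poisson number of true molecules is drawn per polyadenylation site, each
#' molecule receives a distinct UMI and one or more reads at the site
#' position (optionally jittered to mimic 3'-end scatter). Optional
#' perturbations inject UMI sequencing errors (extra reads carrying a
#' one-base-mutated UMI, which the pipeline should merge back) and
#' internal-priming decoy tags at A-rich positions (which the A-content
#' filters should remove). With all error rates at zero, running
#' [run_pa_pipeline()] at default thresholds recovers the truth table
#' exactly.
#'
#' @param annotation A list as returned by [synthetic_gene_annotation()].
#' @param n_cells Number of cells.
#' @param mean_molecules Mean true molecules per cell, gene and site.
#' @param reads_per_molecule Mean extra reads per molecule (the read count is
#'   `1 + rpois(reads_per_molecule)`).
#' @param umi_error_rate Probability that a molecule additionally emits one
#'   read whose UMI carries a single-base error.
#' @param decoy_rate Expected number of internal-priming decoy tags per cell,
#'   planted with downstream A fractions above the filter thresholds.
#' @param end_jitter Maximum absolute jitter (bp) applied to each read's
#'   3'-end position (default 0).
#' @param seed Random seed.
#' @return A list with `tags` (tag table ready for [run_pa_pipeline()]) and
#'   `truth` (tibble `cell_id`, `gene_id`, `position`, `molecules`).
#' @export
simulate_tag_table <- function(annotation, n_cells = 4,
                               mean_molecules = 5,
                               reads_per_molecule = 2,
                               umi_error_rate = 0,
                               decoy_rate = 0,
                               end_jitter = 0L,
                               seed = 1L) {
  set.seed(seed)
  sites <- annotation$sites
  cells <- sprintf("cell%02d", seq_len(n_cells))
  truth <- tidyr::expand_grid(cell_id = cells,
                              sites |> dplyr::select("gene_id", "chrom",
                                                     "strand", "position")) |>
    dplyr::mutate(molecules = stats::rpois(dplyr::n(), mean_molecules))
  tag_rows <- truth |>
    dplyr::filter(.data$molecules > 0) |>
    dplyr::group_by(.data$cell_id, .data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      n_mol <- sum(g$molecules)
      umis <- draw_distinct_umis(n_mol)
      mol_site <- rep(seq_len(nrow(g)), g$molecules)
      purrr::map_dfr(seq_len(n_mol), function(m) {
        pos <- g$position[mol_site[m]]
        jit <- if (end_jitter > 0) sample(seq(-end_jitter, end_jitter), 1) else 0L
        rows <- tibble::tibble(
          chrom = g$chrom[mol_site[m]],
          strand = g$strand[mol_site[m]],
          end3 = as.integer(pos + jit),
          umi = umis[m],
          read_count = 1L + stats::rpois(1, reads_per_molecule)
        )
        if (umi_error_rate > 0 && stats::runif(1) < umi_error_rate) {
          rows <- dplyr::bind_rows(rows, tibble::tibble(
            chrom = rows$chrom[1], strand = rows$strand[1],
            end3 = rows$end3[1], umi = mutate_umi(umis[m]), read_count = 1L
          ))
        }
        rows
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"gene_id")
  tags <- tag_rows |>
    dplyr::mutate(mapq = 60L, read_len = 50L, read_seq_A_frac = 0.3,
                  unique_align = TRUE, a_frac_15 = 0.2, a_frac_50 = 0.2)
  if (decoy_rate > 0) {
    n_decoy <- stats::rpois(n_cells, decoy_rate)
    decoys <- purrr::map_dfr(seq_len(n_cells), function(ci) {
      if (n_decoy[ci] == 0) return(NULL)
      tibble::tibble(
        cell_id = cells[ci],
        chrom = "chr1", strand = "+",
        end3 = as.integer(sample.int(5000L, n_decoy[ci])),
        umi = replicate(n_decoy[ci], paste(
          sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")),
        read_count = 1L, mapq = 60L, read_len = 50L, read_seq_A_frac = 0.5,
        unique_align = TRUE, a_frac_15 = 0.93, a_frac_50 = 0.9
      )
    })
    tags <- dplyr::bind_rows(tags, decoys)
  }
  list(tags = tags,
       truth = truth |> dplyr::select("cell_id", "gene_id", "position",
                                      "molecules"))
}

#' Simulate an isoform-count study at the scale of a 3' tag experiment
#'
#' Convenience wrapper around [simulate_isoforms()] that draws all generative
#' parameters at the scale of a typical single-cell 3' tag study of isoform
#' choice: per-gene isoform mean expressions log-normal within the 8-1000
#' molecules-per-cell band (the selection band for two-isoform genes), gene
#' expression CV 0.6, population preferences implied by the two isoform
#' means, capture efficiencies scattered around 5.4%, and a common
#' cell-level preference SD `sigma` on the logit scale.
#'
#' @param n_genes,n_cells Dimensions (defaults 493 genes, 40 cells).
#' @param sigma True SD of the cell-level logit isoform preference.
#' @param beta_mean Mean capture efficiency (default 0.054).
#' @param seed Integer seed controlling both the parameter draws and the
#'   simulated counts.
#' @return As [simulate_isoforms()].
#' @export
simulate_study <- function(n_genes = 493, n_cells = 40, sigma = 0.7,
                           beta_mean = 0.054, seed = 1L) {
  set.seed(seed + 104729L)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  m1 <- clamp(stats::rlnorm(n_genes, log(89), 0.8), 8, 1000)
  m2 <- clamp(stats::rlnorm(n_genes, log(89), 0.8), 8, 1000)
  beta <- clamp(stats::rnorm(n_cells, beta_mean, 0.01),
                beta_mean / 2, beta_mean * 2)
  simulate_isoforms(n_genes, n_cells,
                    mu = m1 + m2, cv = 0.6, eta = log(m1 / m2),
                    sigma = sigma, beta = beta, seed = seed)
}
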