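#' Demultiplex raw read pairs into cell-tagged molecular reads
#'
#' Implements the barcode layout of the 3' tag protocol: the first seven bases
#' of read 2 identify the library batch, the first six bases of read 1 identify
#' the cell within the batch, and bases 7-14 of read 1 carry the unique
#' molecular identifier (UMI). The remainder of read 2 is the genomic insert;
#' its terminal oligo-A stretch (evidence of the poly-A tail) is trimmed, and
#' reads with fewer than `min_terminal_a` terminal A's are rejected because
#' they cannot be confirmed as polyadenylation events.
#'
#' @param reads Data frame with columns `read1_seq` and `read2_seq`.
#' @param batch_barcodes Named character vector mapping 7-nt batch barcodes to
#'   batch identifiers.
#' @param cell_barcodes Named character vector mapping 6-nt cell barcodes to
#'   within-batch cell identifiers.
#' @param min_terminal_a Minimum number of terminal A's on read 2 for the read
#'   to be retained as a polyadenylation event.
#' @return A tibble with one row per input read pair: `cell_id` (batch and
#'   cell identifier joined by `"_"`, or `NA` when unassigned), `umi`, `seq`
#'   (read 2 insert with batch barcode and terminal A's removed),
#'   `n_terminal_a`, and `status` (`"ok"`, `"unassigned_batch"`,
#'   `"unassigned_cell"`, or `"too_few_terminal_a"`). Unassignable reads are
#'   routed to a bin via `status`, never dropped silently.
#' @export
parse_read_tags <- function(reads, batch_barcodes, cell_barcodes,
                            min_terminal_a = 10) {
  reads <- tibble::as_tibble(reads)
  stopifnot(all(c("read1_seq", "read2_seq") %in% names(reads)))
  if (nrow(reads) > 0 && any(nchar(reads$read1_seq) < 14)) {
    stop("all read1 sequences must be at least 14 nt (6 nt cell barcode + 8 nt UMI)")
  }
  batch_bc <- substr(reads$read2_seq, 1L, 7L)
  cell_bc <- substr(reads$read1_seq, 1L, 6L)
  umi <- substr(reads$read1_seq, 7L, 14L)
  insert <- substr(reads$read2_seq, 8L, nchar(reads$read2_seq))
  n_term_a <- nchar(insert) - nchar(sub("A*$", "", insert))
  trimmed <- sub("A*$", "", insert)

  batch_id <- unname(batch_barcodes[batch_bc])
  cell_id_local <- unname(cell_barcodes[cell_bc])
  status <- dplyr::case_when(
    is.na(batch_id) ~ "unassigned_batch",
    is.na(cell_id_local) ~ "unassigned_cell",
    n_term_a < min_terminal_a ~ "too_few_terminal_a",
    TRUE ~ "ok"
  )
  tibble::tibble(
    cell_id = ifelse(status %in% c("unassigned_batch", "unassigned_cell"),
                     NA_character_,
                     paste(batch_id, cell_id_local, sep = "_")),
    umi = umi,
    seq = trimmed,
    n_terminal_a = n_term_a,
    status = status
  )
}

# A-fraction of the genomic window downstream of a read 3' end, on the read's
# strand. On "+" the window is [end3 + 1, end3 + width] and A counts; on "-"
# it is [end3 - width, end3 - 1] and reference T counts (A on the transcribed
# strand). Windows truncated at contig edges; NA when < min_bases remain.
downstream_a_fraction <- function(genome, chrom, strand, end3, width,
                                  min_bases = 5L) {
  seqs <- genome[chrom]
  len <- nchar(seqs)
  from <- ifelse(strand == "+", end3 + 1L, pmax(1L, end3 - width))
  to <- ifelse(strand == "+", pmin(len, end3 + width), end3 - 1L)
  n <- pmax(0L, to - from + 1L)
  win <- toupper(substr(seqs, from, to))
  target <- ifelse(strand == "+", "A", "T")
  hits <- mapply(function(w, ch) {
    if (nchar(w) == 0) 0L else sum(strsplit(w, "")[[1]] == ch)
  }, win, target, USE.NAMES = FALSE)
  ifelse(n >= min_bases, hits / pmax(n, 1L), NA_real_)
}

#' Alignment-level filters for 3' tag reads
#'
#' Applies the post-alignment filters that remove unreliable polyadenylation
#' evidence: non-unique alignments, mapping quality below `mapq_min`, reads
#' shorter than `len_min`, reads with more than `read_a_max` A content, and
#' internal-priming artifacts recognized by A-rich genomic sequence downstream
#' of the mapped 3' end (> 80% A in 15 bases or > 65% A in 50 bases). Reads on
#' excluded chromosomes (mitochondrial by default) or excluded genes (rRNA)
#' are also removed, since those RNAs are polyadenylated during degradation
#' independently of alternative polyadenylation.
#'
#' @param tags Tag table: a data frame with columns `chrom`, `strand`, `end3`,
#'   `mapq`, `read_len`, `read_seq_A_frac`, and optionally `unique_align`
#'   (logical) and precomputed `a_frac_15` / `a_frac_50` columns.
#' @param genome Optional named character vector (or `Biostrings::DNAStringSet`)
#'   of contig sequences, used to compute downstream A fractions when the tag
#'   table does not carry them. Windows truncated at a contig edge to fewer
#'   than 5 bases are treated as failing (conservative).
#' @param mapq_min,len_min,read_a_max Alignment-level thresholds.
#' @param win_short,win_short_a_max Short downstream window size and maximum
#'   tolerated A fraction (defaults 15 bp, 0.80).
#' @param win_long,win_long_a_max Long downstream window size and maximum
#'   tolerated A fraction (defaults 50 bp, 0.65).
#' @param exclude_chroms Chromosome names removed outright.
#' @return The tag table with logical `keep` and character `reason` columns
#'   (`reason` is `"pass"` for kept reads; otherwise one of `"non_unique"`,
#'   `"low_mapq"`, `"short_read"`, `"read_a_content"`, `"internal_priming_15"`,
#'   `"internal_priming_50"`, `"contig_edge"`, `"excluded_chrom"`). The first
#'   failing filter, in that order, is recorded, so reason counts sum to the
#'   number of discarded reads.
#' @export
filter_tags <- function(tags, genome = NULL,
                        mapq_min = 30, len_min = 20, read_a_max = 0.80,
                        win_short = 15L, win_short_a_max = 0.80,
                        win_long = 50L, win_long_a_max = 0.65,
                        exclude_chroms = c("chrM", "MT")) {
  tags <- tibble::as_tibble(tags)
  if (!is.null(genome) && !is.character(genome)) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.null(tags[["a_frac_15"]])) {
    if (is.null(genome)) stop("need either a genome or precomputed a_frac_15/a_frac_50 columns")
    tags$a_frac_15 <- downstream_a_fraction(genome, tags$chrom, tags$strand,
                                            tags$end3, win_short)
    tags$a_frac_50 <- downstream_a_fraction(genome, tags$chrom, tags$strand,
                                            tags$end3, win_long)
  }
  uniq <- if (is.null(tags[["unique_align"]])) rep(TRUE, nrow(tags)) else tags$unique_align
  reason <- dplyr::case_when(
    !uniq ~ "non_unique",
    tags$mapq < mapq_min ~ "low_mapq",
    tags$read_len < len_min ~ "short_read",
    tags$read_seq_A_frac > read_a_max ~ "read_a_content",
    is.na(tags$a_frac_15) | is.na(tags$a_frac_50) ~ "contig_edge",
    tags$a_frac_15 > win_short_a_max ~ "internal_priming_15",
    tags$a_frac_50 > win_long_a_max ~ "internal_priming_50",
    tags$chrom %in% exclude_chroms ~ "excluded_chrom",
    TRUE ~ "pass"
  )
  tags$keep <- reason == "pass"
  tags$reason <- reason
  tags
}

# Connected components of the Hamming <= max_dist graph over a UMI set,
# via union-find. Returns an integer component label per UMI.
hamming_components <- function(umis, max_dist = 1L) {
  n <- length(umis)
  if (n <= 1) return(rep(1L, n))
  mat <- do.call(rbind, strsplit(umis, ""))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (sum(mat[i, ] != mat[j, ]) <= max_dist) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Collapse UMIs into molecules within each cell and gene
#'
#' Reads sharing a cell and gene whose UMIs are within Hamming distance
#' `max_dist` of one another (connected components of the mismatch graph) are
#' treated as PCR/sequencing copies of one cDNA molecule. Each molecule is
#' anchored at the UMI with the highest read count (ties: lexicographically
#' smallest UMI) and carries the 3'-end position of its highest-read-count
#' constituent read (ties: smallest coordinate). Molecules whose constituent
#' read 3' ends span `max_span` or more base pairs are discarded as likely
#' UMI collisions between distinct transcription units.
#'
#' @param tags Data frame with columns `cell_id`, `gene_id`, `umi`, `end3`,
#'   `read_count`, and optionally `chrom`, `strand` (carried through).
#' @param max_dist Maximum Hamming distance for UMIs to be merged (default 1).
#' @param max_span Molecules spanning at least this many base pairs are
#'   discarded (default 20).
#' @return A tibble with one row per retained molecule: `cell_id`, `gene_id`,
#'   (`chrom`, `strand` if present), `umi` (anchor), `position`, `read_count`
#'   (total reads), and `n_umis` (number of merged raw UMIs). The number of
#'   molecules discarded for excessive span is attached as attribute
#'   `n_discarded_span`.
#' @export
collapse_umis <- function(tags, max_dist = 1L, max_span = 20L) {
  tags <- tibble::as_tibble(tags)
  carry <- intersect(c("chrom", "strand"), names(tags))
  if (nrow(tags) == 0) {
    out <- tibble::tibble(cell_id = character(), gene_id = character(),
                          umi = character(), position = integer(),
                          read_count = integer(), n_umis = integer())
    attr(out, "n_discarded_span") <- 0L
    return(out)
  }
  n_discarded <- 0L
  out <- tags |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("cell_id", "gene_id", carry)))) |>
    dplyr::group_modify(function(g, key) {
      # total reads per raw UMI (may be spread over several positions)
      per_umi <- g |>
        dplyr::group_by(.data$umi) |>
        dplyr::summarise(total = sum(.data$read_count), .groups = "drop")
      comp <- hamming_components(per_umi$umi, max_dist)
      res <- purrr::map_dfr(split(seq_len(nrow(per_umi)), comp), function(idx) {
        members <- per_umi$umi[idx]
        rows <- g[g$umi %in% members, , drop = FALSE]
        span <- diff(range(rows$end3))
        if (span >= max_span) {
          return(tibble::tibble(umi = NA_character_, position = NA_integer_,
                                read_count = 0L, n_umis = 0L))
        }
        anchor_ord <- order(-per_umi$total[idx], members)
        best <- order(-rows$read_count, rows$end3)[1]
        tibble::tibble(
          umi = members[anchor_ord[1]],
          position = rows$end3[best],
          read_count = as.integer(sum(rows$read_count)),
          n_umis = length(members)
        )
      })
      res
    }) |>
    dplyr::ungroup()
  n_discarded <- sum(is.na(out$umi))
  out <- out[!is.na(out$umi), , drop = FALSE]
  attr(out, "n_discarded_span") <- n_discarded
  out
}

# Single greedy elimination pass for one chromosome strand: sites are visited
# in ascending order of their initial molecule count (ties: smaller
# coordinate first); a visited site is absorbed by the surviving neighbor
# within `window` bp that currently has a strictly higher count (ties among
# candidates: higher current count, then smaller coordinate).
greedy_pa_merge <- function(position, molecule_count, window) {
  n <- length(position)
  ord <- order(molecule_count, position)
  cur <- as.numeric(molecule_count)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    cand <- which(alive & abs(position - position[i]) <= window &
                    cur > cur[i])
    cand <- setdiff(cand, i)
    if (length(cand)) {
      j <- cand[order(-cur[cand], position[cand])][1]
      cur[j] <- cur[j] + cur[i]
      alive[i] <- FALSE
    }
  }
  list(position = position[alive], molecule_count = cur[alive])
}

#' Call reference polyadenylation sites by greedy peak merging
#'
#' Molecule counts are pooled over all cells per genomic 3'-end position.
#' Within each chromosome strand, positions are processed from the lowest
#' count upward; a position with a higher-count neighbor within `window` base
#' pairs is eliminated and its count added to that neighbor. This absorbs the
#' small 3'-end scatter around true cleavage sites into a single reference
#' peak while conserving the total molecule count.
#'
#' @param site_counts Data frame with columns `chrom`, `strand`, `position`,
#'   `molecule_count` (pooled over cells).
#' @param window Merge window in base pairs (default 12).
#' @param iterate If `TRUE` (default), repeat the greedy pass until a fixed
#'   point is reached, which makes the operation idempotent even on
#'   pathologically dense position sets; `FALSE` runs the single literal
#'   pass. On realistically sparse data the two are identical.
#' @return Tibble of retained sites with conserved total `molecule_count`.
#' @export
call_pa_sites <- function(site_counts, window = 12L, iterate = TRUE) {
  site_counts <- tibble::as_tibble(site_counts)
  one_pass <- function(df) {
    df |>
      dplyr::group_by(.data$chrom, .data$strand) |>
      dplyr::group_modify(function(g, key) {
        r <- greedy_pa_merge(g$position, g$molecule_count, window)
        tibble::tibble(position = r$position, molecule_count = r$molecule_count)
      }) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$chrom, .data$strand, .data$position)
  }
  out <- one_pass(site_counts)
  if (iterate) {
    repeat {
      nxt <- one_pass(out)
      if (nrow(nxt) == nrow(out) && all(nxt$position == out$position) &&
          all(nxt$molecule_count == out$molecule_count)) break
      out <- nxt
    }
  }
  out
}

#' Assign each molecule to the nearest reference polyadenylation site
#'
#' @param molecules Data frame with `chrom`, `strand`, `position` (per-cell
#'   molecule 3' ends, e.g. from [collapse_umis()]).
#' @param sites Reference sites from [call_pa_sites()].
#' @return `molecules` with a `pa_site` column holding the coordinate of the
#'   nearest reference site on the same chromosome strand (ties: smaller
#'   coordinate); `NA` when the strand has no reference site.
#' @export
assign_to_sites <- function(molecules, sites) {
  molecules <- tibble::as_tibble(molecules)
  molecules$pa_site <- NA_integer_
  key_m <- paste(molecules$chrom, molecules$strand)
  key_s <- paste(sites$chrom, sites$strand)
  for (k in unique(key_m)) {
    s <- sort(sites$position[key_s == k])
    if (!length(s)) next
    idx <- which(key_m == k)
    pos <- molecules$position[idx]
    right <- findInterval(pos, s) # index of largest site <= pos (0 if none)
    left_i <- pmax(right, 1L)
    right_i <- pmin(right + 1L, length(s))
    d_left <- abs(pos - s[left_i])
    d_right <- abs(pos - s[right_i])
    # ties broken toward the smaller coordinate
    pick <- ifelse(right == 0, right_i,
                   ifelse(d_left <= d_right, left_i, right_i))
    molecules$pa_site[idx] <- as.integer(s[pick])
  }
  molecules
}

#' Assign polyadenylation sites (or tag positions) to genes
#'
#' A position is attributed to a gene when it lies inside the gene span on the
#' same strand, or at most `window` base pairs downstream of the gene's
#' transcript termination site (TTS) — the wide window accounts for
#' unannotated 3' UTR extensions. When several genes qualify, the one with the
#' nearest TTS wins. Positions matching no same-strand gene are labelled
#' `"antisense"` when they overlap a gene on the opposite strand, otherwise
#' `"intergenic"`.
#'
#' @param positions Data frame with `chrom`, `strand`, `position`.
#' @param genes Gene annotation: data frame with `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (1-based inclusive; the TTS is `end` on "+", `start` on
#'   "-").
#' @param window Downstream assignment window in base pairs (default 20000).
#' @return `positions` with a `gene_id` column (gene identifier, `"antisense"`
#'   or `"intergenic"`).
#' @export
assign_gene <- function(positions, genes, window = 20000L) {
  positions <- tibble::as_tibble(positions)
  genes <- tibble::as_tibble(genes)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  pos_idx <- tibble::tibble(row = seq_len(nrow(positions)),
                            chrom = positions$chrom,
                            strand = positions$strand,
                            position = positions$position)
  sense <- pos_idx |>
    dplyr::inner_join(genes, by = c("chrom", "strand"),
                      relationship = "many-to-many") |>
    dplyr::mutate(
      downstream_dist = ifelse(.data$strand == "+",
                               .data$position - .data$tts,
                               .data$tts - .data$position),
      hit = (.data$position >= .data$start & .data$position <= .data$end) |
        (.data$downstream_dist > 0 & .data$downstream_dist <= window)
    ) |>
    dplyr::filter(.data$hit) |>
    dplyr::group_by(.data$row) |>
    dplyr::slice_min(abs(.data$position - .data$tts),
                     n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("row", "gene_id")
  anti_strand <- ifelse(positions$strand == "+", "-", "+")
  anti <- tibble::tibble(row = seq_len(nrow(positions)),
                         chrom = positions$chrom,
                         strand = anti_strand,
                         position = positions$position) |>
    dplyr::inner_join(genes, by = c("chrom", "strand"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$position >= .data$start, .data$position <= .data$end) |>
    dplyr::distinct(.data$row)
  positions$gene_id <- "intergenic"
  positions$gene_id[anti$row] <- "antisense"
  positions$gene_id[sense$row] <- sense$gene_id
  positions
}

#' Build the per-cell isoform molecule count matrix
#'
#' Tallies molecules per (gene, polyadenylation site, cell) and drops cells
#' with fewer than `cell_min` gene-assigned molecules, which cannot support
#' isoform-level inference. Spike-in genes are flagged, and sentinel
#' assignments (`"antisense"`, `"intergenic"`) are excluded from the matrix
#' and from the per-cell totals.
#'
#' @param molecules Data frame with `cell_id`, `gene_id`, `pa_site`, and
#'   optionally a `count` column (default one molecule per row).
#' @param cell_min Minimum gene-assigned molecules for a cell to be retained.
#' @param spike_pattern Regular expression identifying spike-in gene ids.
#' @return A long-format tibble with columns `gene_id`, `pa_site`, `cell_id`,
#'   `count`, `spike_in`; per-cell totals are attached as attribute
#'   `cell_totals`.
#' @export
build_count_matrix <- function(molecules, cell_min = 1000L,
                               spike_pattern = "^ERCC") {
  molecules <- tibble::as_tibble(molecules)
  if (is.null(molecules[["count"]])) molecules$count <- 1L
  molecules <- molecules |>
    dplyr::filter(!.data$gene_id %in% c("antisense", "intergenic"))
  counts <- molecules |>
    dplyr::group_by(.data$gene_id, .data$pa_site, .data$cell_id) |>
    dplyr::summarise(count = as.integer(sum(.data$count)), .groups = "drop")
  totals <- counts |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  keep_cells <- totals$cell_id[totals$total >= cell_min]
  if (!length(keep_cells)) {
    stop("no cell reaches the minimum of ", cell_min, " molecules")
  }
  out <- counts |>
    dplyr::filter(.data$cell_id %in% keep_cells) |>
    dplyr::mutate(spike_in = grepl(spike_pattern, .data$gene_id))
  attr(out, "cell_totals") <- totals
  out
}

#' Select genes with two moderately-to-highly expressed isoforms
#'
#' Restricts the count matrix to genes whose two most expressed
#' polyadenylation isoforms both have a capture-corrected mean expression
#' (observed mean molecules per cell divided by the mean capture efficiency)
#' within `[low, high]` true molecules per cell. Returns, per gene and cell,
#' the molecule counts of the major (`k1`) and minor (`k2`) isoform.
#'
#' @param counts Long count matrix from [build_count_matrix()].
#' @param efficiency Data frame with `cell_id` and `beta` (per-cell capture
#'   efficiency), e.g. from [estimate_capture_efficiency()]; used only through
#'   its mean. If `NULL`, no capture correction is applied.
#' @param low,high Expression band, in (corrected) molecules per cell per
#'   isoform (defaults 8 and 1000).
#' @return Tibble with columns `gene_id`, `cell_id`, `site1`, `site2`, `k1`,
#'   `k2` for every retained gene and every cell present in `counts` (absent
#'   counts filled with 0). Genes with a single site are excluded silently.
#' @export
select_isoform_genes <- function(counts, efficiency = NULL,
                                 low = 8, high = 1000) {
  counts <- tibble::as_tibble(counts)
  if (!is.null(counts[["spike_in"]])) {
    counts <- dplyr::filter(counts, !.data$spike_in)
  }
  cells <- unique(counts$cell_id)
  mean_beta <- if (is.null(efficiency)) 1 else mean(efficiency$beta, na.rm = TRUE)
  site_means <- counts |>
    dplyr::group_by(.data$gene_id, .data$pa_site) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(corrected_mean = .data$total / length(cells) / mean_beta)
  top2 <- site_means |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::arrange(dplyr::desc(.data$corrected_mean), .data$pa_site,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 2) |>
    dplyr::summarise(
      site1 = .data$pa_site[1], site2 = .data$pa_site[2],
      m1 = .data$corrected_mean[1], m2 = .data$corrected_mean[2],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$m1 >= low, .data$m1 <= high,
                  .data$m2 >= low, .data$m2 <= high)
  if (nrow(top2) == 0) {
    return(tibble::tibble(gene_id = character(), cell_id = character(),
                          site1 = integer(), site2 = integer(),
                          k1 = integer(), k2 = integer()))
  }
  grid <- tidyr::expand_grid(
    top2 |> dplyr::select("gene_id", "site1", "site2"),
    cell_id = cells
  )
  k1 <- counts |> dplyr::select("gene_id", pa_site_1 = "pa_site",
                                "cell_id", k1 = "count")
  k2 <- counts |> dplyr::select("gene_id", pa_site_2 = "pa_site",
                                "cell_id", k2 = "count")
  grid |>
    dplyr::left_join(k1, by = c("gene_id", "cell_id", site1 = "pa_site_1")) |>
    dplyr::left_join(k2, by = c("gene_id", "cell_id", site2 = "pa_site_2")) |>
    dplyr::mutate(k1 = dplyr::coalesce(.data$k1, 0L),
                  k2 = dplyr::coalesce(.data$k2, 0L)) |>
    dplyr::arrange(.data$gene_id, .data$cell_id)
}

#' Run the full 3' tag processing pipeline on a tag table
#'
#' Chains the individual steps: alignment-level filtering, gene assignment of
#' tag positions, UMI collapsing into molecules, pooled polyadenylation site
#' discovery, reassignment of per-cell molecules to reference sites, and
#' construction of the per-cell count matrix.
#'
#' @param tags Tag table (see [filter_tags()] for required columns, plus
#'   `cell_id`, `umi`, `read_count`).
#' @param genes Gene annotation (see [assign_gene()]).
#' @param genome Optional genome for the internal-priming filters.
#' @param merge_window Polyadenylation site merge window (bp).
#' @param gene_window Downstream gene-assignment window (bp).
#' @param cell_min Minimum molecules per retained cell.
#' @param ... Further arguments passed to [filter_tags()].
#' @return A list with elements `counts` (long count matrix), `sites`
#'   (reference polyadenylation sites with gene assignment), `molecules`
#'   (per-cell molecules), and `filter_tally` (reads per filter reason).
#' @export
run_pa_pipeline <- function(tags, genes, genome = NULL,
                            merge_window = 12L, gene_window = 20000L,
                            cell_min = 1000L, ...) {
  filtered <- filter_tags(tags, genome = genome, ...)
  tally <- filtered |> dplyr::count(.data$reason, name = "reads")
  kept <- dplyr::filter(filtered, .data$keep)
  kept <- kept |>
    dplyr::rename(position = "end3") |>
    assign_gene(genes, window = gene_window) |>
    dplyr::rename(end3 = "position")
  molecules <- collapse_umis(kept)
  pooled <- molecules |>
    dplyr::group_by(.data$chrom, .data$strand, .data$position) |>
    dplyr::summarise(molecule_count = dplyr::n(), .groups = "drop")
  sites <- call_pa_sites(pooled, window = merge_window) |>
    assign_gene(genes, window = gene_window)
  molecules <- assign_to_sites(molecules, sites)
  site_gene <- sites |>
    dplyr::select("chrom", "strand", pa_site = "position",
                  site_gene = "gene_id")
  molecules <- molecules |>
    dplyr::left_join(site_gene, by = c("chrom", "strand", "pa_site")) |>
    dplyr::mutate(gene_id = .data$site_gene) |>
    dplyr::select(-"site_gene")
  counts <- build_count_matrix(molecules, cell_min = cell_min)
  list(counts = counts, sites = sites, molecules = molecules,
       filter_tally = tally)
}

#' Read gene spans from a GTF annotation
#'
#' Thin convenience wrapper around `rtracklayer::import()` that extracts one
#' row per gene with the columns [assign_gene()] expects.
#'
#' @param path Path to a GTF/GFF file.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
read_gtf_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gtf_genes() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", , drop = FALSE]
  }
  tibble::tibble(
    gene_id = as.character(df$gene_id),
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = as.integer(df$start),
    end = as.integer(df$end)
  ) |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
}
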