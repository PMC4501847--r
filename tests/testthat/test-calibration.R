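make_spikes <- function(cells, known, observed_fun) {
  tidyr::expand_grid(cell_id = cells,
                     tibble::tibble(spike_id = sprintf("ERCC-%04d",
                                                       seq_along(known)),
                                    known = known)) |>
    dplyr::mutate(observed = observed_fun(.data$known))
}

test_that("capture efficiency is the origin-constrained regression slope", {
  known <- c(10, 100, 1000, 5000)
  sp <- make_spikes("c1", known, function(k) 0.05 * k)
  out <- estimate_capture_efficiency(sp)
  expect_equal(out$beta, 0.05, tolerance = 1e-12)
  expect_false(out$missing)
  # all-zero observations: beta 0 with a warning
  expect_warning(
    out0 <- estimate_capture_efficiency(
      make_spikes("c1", known, function(k) 0 * k)),
    "zero")
  expect_equal(out0$beta, 0)
  # fewer than 3 spike species: flagged missing
  sp2 <- make_spikes("c1", c(10, 100), function(k) 0.05 * k)
  out2 <- estimate_capture_efficiency(sp2)
  expect_true(out2$missing)
  expect_true(is.na(out2$beta))
})

test_that("efficiency estimate is scale-equivariant in the known counts", {
  set.seed(1)
  known <- round(stats::rlnorm(20, 4, 1)) + 1
  obs <- stats::rpois(20, 0.08 * known)
  sp1 <- tibble::tibble(cell_id = "c", spike_id = as.character(1:20),
                        known = known, observed = obs)
  sp2 <- dplyr::mutate(sp1, known = known * 7)
  b1 <- estimate_capture_efficiency(sp1)$beta
  b2 <- estimate_capture_efficiency(sp2)$beta
  expect_equal(b1 / 7, b2, tolerance = 1e-12)
})

test_that("efficiency estimator is unbiased on binomially thinned spikes", {
  # molecules captured per-molecule with probability beta; slope recovers it
  set.seed(3)
  known <- round(exp(seq(log(5), log(3000), length.out = 30)))
  cells <- sprintf("c%03d", 1:200)
  for (beta_true in c(0.054, 0.2)) {
    sp <- tidyr::expand_grid(cell_id = cells,
                             tibble::tibble(spike_id = as.character(seq_along(known)),
                                            known = known)) |>
      dplyr::mutate(observed = stats::rbinom(dplyr::n(), .data$known, beta_true))
    est <- estimate_capture_efficiency(sp)
    err <- mean(est$beta) - beta_true
    se <- stats::sd(est$beta) / sqrt(nrow(est))
    expect_lt(abs(err), 2 * se + 1e-4)
  }
})

test_that("perfect capture gives perfect bulk/single-cell correlation", {
  out <- simulate_subsampling_correlation(n_genes = 300, beta_bulk = 1,
                                          beta_cells = 1, n_cells = 10,
                                          seed = 2)
  expect_equal(out$gene_corr, 1, tolerance = 1e-12)
})

test_that("gene-level correlation grows with capture efficiency", {
  # common random numbers across beta values via the shared seed
  cors <- vapply(c(0.01, 0.05, 0.3), function(b) {
    simulate_subsampling_correlation(n_genes = 1500, beta_bulk = b,
                                     beta_cells = b, n_cells = 48,
                                     seed = 7)$gene_corr
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_true(all(cors > 0 & cors < 1))
})

test_that("subsampling correlation matches an independent re-simulation", {
  mix <- list(meanlog = c(2.5, 6), sdlog = c(1, 1), prob = 0.5)
  got <- simulate_subsampling_correlation(n_genes = 4000, mixture = mix,
                                          beta_bulk = 0.04,
                                          beta_cells = 0.04, n_cells = 48,
                                          seed = 13)
  # independent two-pass oracle, coded separately and differently seeded:
  # bulk and summed-cell channels are two thinnings of the same truth, so
  # splitting cells is equivalent to one Binomial(T, beta) draw
  set.seed(999)
  n <- 4000
  comp <- stats::rbinom(n, 1, 0.5) + 1
  tt <- round(stats::rlnorm(n, mix$meanlog[comp], mix$sdlog[comp]))
  bulk <- stats::rbinom(n, tt, 0.04)
  cells <- stats::rbinom(n, tt, 0.04)
  want <- stats::cor(log(bulk + 1), log(cells + 1))
  expect_equal(got$gene_corr, want, tolerance = 0.05)
  expect_lt(got$isoform_corr, got$gene_corr + 0.05)
})
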