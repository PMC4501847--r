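test_that("extreme bimodal ratios blow past the partition null", {
  # cells alternate between all-isoform-1 and all-isoform-2 at K = 50
  cnt <- tibble::tibble(gene_id = "g",
                        cell_id = sprintf("c%02d", 1:20),
                        k1 = rep(c(50L, 0L), 10),
                        k2 = rep(c(0L, 50L), 10))
  out <- partition_null_variance_test(cnt, n_sim = 1000, seed = 3)
  expect_equal(out$p_hat, 0.5)
  expect_equal(out$obs_var, stats::var(rep(c(1, 0), 10)))
  expect_true(out$exceeds)
  expect_lte(out$p_value, 1 / 1001 + 1e-12)
  # pure determinism under a fixed seed
  again <- partition_null_variance_test(cnt, n_sim = 1000, seed = 3)
  expect_identical(out, again)
})

test_that("genes with too few informative cells are excluded", {
  cnt <- tibble::tibble(gene_id = c("ok", "ok", "ok", "thin", "thin"),
                        cell_id = c("c1", "c2", "c3", "c1", "c2"),
                        k1 = c(3L, 4L, 2L, 1L, 2L),
                        k2 = c(2L, 1L, 3L, 1L, 0L))
  out <- partition_null_variance_test(cnt, n_sim = 50, seed = 1)
  expect_equal(out$gene_id, "ok")
})

test_that("exceedance under the shared-preference model is calibrated", {
  # data truly generated with one preference per gene: about half the genes
  # should land above their null median, and enrichment is not significant
  s <- simulate_isoforms(200, 30, mu = 150, cv = 0.6,
                         eta = rnorm(200, 0, 1), sigma = 0, beta = 0.1,
                         seed = 77)
  out <- partition_null_variance_test(s$counts, n_sim = 200, seed = 5)
  expect_gt(mean(out$exceeds), 0.4)
  expect_lt(mean(out$exceeds), 0.6)
  expect_gt(enrichment_binomial_test(out$exceeds), 0.05)
})

test_that("enrichment binomial test matches closed forms and the exact tail", {
  expect_equal(enrichment_binomial_test(rep(TRUE, 10)), 2^-10,
               tolerance = 1e-12)
  expect_gt(enrichment_binomial_test(rep(c(TRUE, FALSE), 5)), 0.5)
  # independent exact-tail computation for 300 of 493
  flags <- rep(c(TRUE, FALSE), c(300, 193))
  want <- sum(stats::dbinom(300:493, 493, 0.5))
  expect_equal(enrichment_binomial_test(flags), want, tolerance = 1e-12)
})

test_that("KS partition test detects bimodal ratios and replays exactly", {
  cnt <- tibble::tibble(cell_id = sprintf("c%02d", 1:30),
                        long = rep(c(40L, 0L), 15),
                        total = 40L)
  out <- ks_partition_test(cnt, n_sim = 1000, seed = 2)
  expect_lt(out$p_value, 1e-3)
  out2 <- ks_partition_test(cnt, n_sim = 1000, seed = 2)
  expect_equal(out$statistic, out2$statistic)
  expect_error(ks_partition_test(tibble::tibble(cell_id = "c", long = 0L,
                                                total = 0L)),
               "zero")
})

test_that("KS partition test accepts data drawn from its own null", {
  set.seed(6)
  totals <- stats::rpois(60, 40) + 1L
  cnt <- tibble::tibble(cell_id = sprintf("c%02d", seq_along(totals)),
                        long = stats::rbinom(length(totals), totals, 0.35),
                        total = totals)
  out <- ks_partition_test(cnt, n_sim = 300, seed = 9)
  expect_gt(out$p_value, 0.01)
  expect_equal(out$p_hat, sum(cnt$long) / sum(cnt$total))
})

test_that("Fisher lengthening test classes genes by direction, symmetric", {
  pooled <- tibble::tibble(
    gene_id = c("flat", "len", "short"),
    short_a = c(10L, 20L, 0L),
    long_a = c(10L, 0L, 20L),
    short_b = c(10L, 0L, 20L),
    long_b = c(10L, 20L, 0L)
  )
  out <- fisher_lengthening_test(pooled)
  expect_equal(out$class, c("ns", "long_up", "short_up"))
  expect_equal(out$p_value[1], 1)
  # P-value for the extreme table equals the hypergeometric enumeration
  probs <- stats::dhyper(0:20, 20, 20, 20)
  want <- sum(probs[probs <= probs[21] * (1 + 1e-7)])
  expect_equal(out$p_value[2], want, tolerance = 1e-12)
  # swapping the populations swaps the classes
  swapped <- fisher_lengthening_test(
    dplyr::rename(pooled, short_a = "short_b", short_b = "short_a",
                  long_a = "long_b", long_b = "long_a"))
  expect_equal(swapped$class, c("ns", "short_up", "long_up"))
  expect_equal(swapped$p_value, out$p_value)
  # zero-margin tables are "ns"
  zm <- fisher_lengthening_test(tibble::tibble(gene_id = "z", short_a = 0L,
                                               long_a = 0L, short_b = 5L,
                                               long_b = 5L))
  expect_equal(zm$class, "ns")
})
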