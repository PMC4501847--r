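test_that("the simulator reproduces the stated moments of each noise layer", {
  s <- simulate_isoforms(1, 10000, mu = 50, cv = 0.6, eta = 0.4,
                         sigma = 0, beta = 1, seed = 4)
  Q <- as.numeric(s$truth$Q)
  # mean and CV of the expression layer within 3 standard errors
  se_mean <- stats::sd(Q) / sqrt(length(Q))
  expect_lt(abs(mean(Q) - 50), 3 * se_mean)
  expect_lt(abs(stats::sd(Q) / mean(Q) - 0.6), 0.03)
  # sigma = 0: preferences identical in every cell
  expect_equal(stats::var(as.numeric(s$truth$p)), 0)
  # beta = 1 and p -> 1: isoform 1 carries every molecule
  s2 <- simulate_isoforms(2, 200, mu = 20, cv = 0.8, eta = 20, sigma = 0,
                          beta = 1, seed = 5)
  m2 <- dplyr::mutate(s2$counts, K = k1 + k2)
  expect_equal(sum(m2$k2), 0)
  expect_equal(matrix(m2$K, 2, 200), unname(s2$truth$Q))
  # representability guard
  expect_error(simulate_isoforms(1, 5, mu = 10, cv = 0.1, eta = 0),
               "representability")
})

test_that("collapsed likelihood factorizes over totals and splits", {
  # single observation (1, 0): probability must equal P(K = 1) * p
  mu <- 1.2; cv <- 1.5; b <- 1; p <- 0.5
  r <- mu / (cv^2 * mu - 1)
  cnt <- tibble::tibble(gene_id = "g", cell_id = "c", k1 = 1L, k2 = 0L)
  ll <- isoform_loglik(cnt, list(mu = mu, cv = cv, p = p, beta = b))
  expect_equal(ll, stats::dnbinom(1, size = r, mu = mu, log = TRUE) + log(p),
               tolerance = 1e-12)
  # vanishing capture: all-zero data has probability ~1
  cnt0 <- tibble::tibble(gene_id = "g", cell_id = "c", k1 = 0L, k2 = 0L)
  ll0 <- isoform_loglik(cnt0, list(mu = 5, cv = 0.8, p = 0.5, beta = 1e-12))
  expect_equal(ll0, 0, tolerance = 1e-9)
  # non-integer counts rejected
  expect_error(isoform_loglik(tibble::tibble(gene_id = "g", cell_id = "c",
                                             k1 = 0.5, k2 = 0),
                              list(mu = 5, cv = 0.8, p = 0.5, beta = 0.5)),
               "integer")
})

test_that("collapsed likelihood equals the exhaustive latent-sum oracle", {
  set.seed(8)
  for (i in 1:30) {
    mu <- stats::runif(1, 1, 5)
    cv <- stats::runif(1, sqrt(1 / mu) + 0.2, 1.5)
    p <- stats::runif(1, 0.1, 0.9)
    b <- stats::runif(1, 0.2, 0.9)
    k1 <- stats::rpois(1, 2); k2 <- stats::rpois(1, 2)
    cnt <- tibble::tibble(gene_id = "g", cell_id = "c",
                          k1 = k1, k2 = k2)
    ll <- isoform_loglik(cnt, list(mu = mu, cv = cv, p = p, beta = b))
    expect_equal(ll, oracle_loglik_one(k1, k2, mu, cv, p, b),
                 tolerance = 1e-8)
  }
})

test_that("DIC arithmetic follows Spiegelhalter's definitions", {
  # hand-built deviance trace
  out <- dic_from_trace(c(10, 14), dhat = 11)
  expect_equal(out$dbar, 12)
  expect_equal(out$pd, 1)
  expect_equal(out$dic, 13)
  # degenerate posterior: all draws identical -> pD = 0, DIC = D(theta)
  out2 <- dic_from_trace(rep(27.5, 50), dhat = 27.5)
  expect_equal(out2$pd, 0)
  expect_equal(out2$dic, 27.5)
})

test_that("the variable-preference fit recovers the generative parameters", {
  s <- simulate_isoforms(40, 20, mu = 120, cv = 0.6, eta = rnorm(40, 0, 1),
                         sigma = 0.7, beta = 0.3, seed = 12)
  fit <- fit_preference_model(s$counts, beta = 0.3, model = "variable",
                              chains = 2, adapt = 300, burn = 300,
                              iter = 700, thin = 2, seed = 2)
  # sigma posterior concentrated around the truth at this information level
  s2 <- mean(fit$sigma_draws^2)
  expect_gt(s2, 0.49 * 0.6)
  expect_lt(s2, 0.49 * 1.6)
  # eta recovery: strong correlation with truth
  eta_hat <- unname(fit$posterior_means$eta)
  expect_gt(stats::cor(eta_hat, s$truth$eta), 0.95)
  # mu recovery on the molecule scale despite beta = 0.3 observation
  expect_lt(abs(mean(fit$posterior_means$mu) - 120) / 120, 0.2)
  # DIC computable and pD positive
  dic <- compute_dic(fit)
  expect_gt(dic$pd, 0)
  expect_lt(length(fit$deviance) - fit$mcmc_info$n_kept, 1)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_true(all(c("term", "mean", "rhat", "ess") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$model, "variable")
  expect_equal(gl$n_genes, 40L)
})

test_that("shared model is recovered as the sigma -> 0 limit", {
  s <- simulate_isoforms(25, 15, mu = 100, cv = 0.6,
                         eta = rnorm(25, 0, 1), sigma = 0, beta = 0.3,
                         seed = 14)
  f_sh <- fit_preference_model(s$counts, beta = 0.3, model = "shared",
                               chains = 2, adapt = 300, burn = 300,
                               iter = 600, thin = 2, seed = 3)
  f_va <- fit_preference_model(s$counts, beta = 0.3, model = "variable",
                               chains = 2, adapt = 300, burn = 300,
                               iter = 600, thin = 2, seed = 3)
  # population preferences agree between the nested fits
  expect_lt(max(abs(f_sh$posterior_means$eta - f_va$posterior_means$eta)),
            0.35)
  # the variable fit's sigma concentrates near zero on shared data
  expect_lt(stats::quantile(f_va$sigma_draws, 0.95), 0.35)
  expect_error(autoplot(f_sh), "shared")
  expect_s3_class(autoplot(f_va), "ggplot")
})

test_that("all-zero genes are dropped with a warning, small data guarded", {
  cnt <- tibble::tibble(gene_id = rep(c("g1", "g2"), each = 4),
                        cell_id = rep(sprintf("c%d", 1:4), 2),
                        k1 = c(3L, 1L, 2L, 4L, 0L, 0L, 0L, 0L),
                        k2 = c(1L, 2L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_warning(
    fit <- fit_preference_model(cnt, beta = 0.5, model = "shared",
                                chains = 1, adapt = 100, burn = 100,
                                iter = 200, thin = 1, seed = 1),
    "all-zero")
  expect_equal(fit$data$genes, "g1")
  expect_error(fit_preference_model(dplyr::filter(cnt, cell_id == "c1"),
                                    beta = 0.5),
               "at least 2 cells")
})
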