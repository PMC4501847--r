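test_that("preference PCA handles degenerate and block-structured input", {
  # identical columns: every cell sits at the origin
  pref <- matrix(rep(c(0.3, -1, 2), 4), nrow = 3,
                 dimnames = list(NULL, sprintf("c%d", 1:4)))
  out <- project_preferences_pca(pref)
  expect_true(all(abs(out$PC1) < 1e-12))
  # two exact blocks of columns: PC1 separates them perfectly
  blk <- cbind(matrix(0, 5, 4), matrix(2, 5, 4))
  colnames(blk) <- sprintf("c%d", 1:8)
  out2 <- project_preferences_pca(blk)
  expect_true(max(out2$PC1[1:4]) < min(out2$PC1[5:8]) ||
                min(out2$PC1[1:4]) > max(out2$PC1[5:8]))
})

test_that("preference PCA matches an independent eigendecomposition", {
  set.seed(6)
  pref <- matrix(rnorm(20 * 9), 20, 9,
                 dimnames = list(NULL, sprintf("c%d", 1:9)))
  got <- project_preferences_pca(pref, n_comp = 3)
  centered <- pref - rowMeans(pref)
  # scores from the eigen-decomposition of the cell-cell Gram matrix
  ev <- eigen(crossprod(centered))
  sc <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  for (j in 1:3) {
    a <- got[[paste0("PC", j)]]
    b <- sc[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  # permutation equivariance of the projection
  perm <- sample(9)
  got_p <- project_preferences_pca(pref[, perm], n_comp = 2)
  expect_equal(got_p$PC1, got$PC1[perm], tolerance = 1e-8)
})

test_that("a null factor model keeps loadings near zero", {
  s <- simulate_isoforms(15, 12, mu = 150, cv = 0.6,
                         eta = rnorm(15, 0, 1), sigma = 0.7, beta = 0.3,
                         seed = 18)
  ff <- fit_factor_model(s$counts, beta = 0.3, chains = 2, adapt = 300,
                         burn = 300, iter = 500, thin = 2, seed = 4)
  # with no generative factor most loadings' 95% intervals cover 0
  covers <- ff$loadings$q2.5 <= 0 & ff$loadings$q97.5 >= 0
  expect_gt(mean(covers), 0.8)
  # scores standardized to unit spread
  expect_equal(stats::sd(ff$scores$score) < 1.5, TRUE)
  expect_error(fit_factor_model(dplyr::filter(s$counts, cell_id == "c001"),
                                beta = 0.3),
               "single cell")
  # tidy interfaces
  expect_true(all(c("term", "estimate") %in%
                    names(tidy(ff, type = "loadings"))))
  expect_s3_class(autoplot(ff), "ggplot")
})

test_that("coordinated preference shifts are detected, uncorrelated are not", {
  G <- 40; C <- 24
  lab <- rep(c("A", "B"), each = C / 2)
  sc <- ifelse(lab == "A", 1, -1)
  lam <- c(rep(1.5, G / 2), rep(0, G / 2))
  s_alt <- simulate_isoforms(G, C, mu = 150, cv = 0.6,
                             eta = rnorm(G, 0, 1), sigma = 0.4, beta = 0.05,
                             lambda = lam, scores = sc, seed = 31)
  det_alt <- detect_correlated_component(s_alt$counts, beta = 0.05,
                                         chains = 2, adapt = 300, burn = 300,
                                         iter = 500, thin = 2, seed = 5)
  expect_true(det_alt$evidence)
  s_null <- simulate_isoforms(G, C, mu = 150, cv = 0.6,
                              eta = rnorm(G, 0, 1), sigma = 0.7, beta = 0.05,
                              seed = 32)
  det_null <- detect_correlated_component(s_null$counts, beta = 0.05,
                                          chains = 2, adapt = 300,
                                          burn = 300, iter = 500, thin = 2,
                                          seed = 5)
  expect_false(det_null$evidence)
  expect_gt(det_alt$share_mean, det_null$share_mean)
})
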