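#' Fit the one-factor correlated isoform preference model
#'
#' Extends the variable-preference model with a single latent factor that
#' captures coordinated shifts of isoform preference across genes:
#' `logit(p_gc) = eta_g + lambda_g * s_c + eps_gc`, with per-cell scores
#' `s_c`, per-gene loadings `lambda_g` (logit units per score unit), and
#' residual preference noise `eps_gc ~ Normal(0, sigma_g^2)`. Because the
#' factor lives entirely on the preference scale, cells cluster by 3' isoform
#' usage only — total expression enters the likelihood solely through the
#' per-cell totals, which carry no information about `s_c`.
#'
#' The likelihood is invariant under `(lambda, s) -> (-lambda, -s)` and
#' `(c * lambda, s / c)`; identifiability is restored in post-processing by
#' rescaling every draw so that the scores have unit standard deviation and
#' by anchoring the sign so that the gene with the largest absolute posterior
#' mean loading has a positive loading.
#'
#' @inheritParams fit_preference_model
#' @return An object of class `apa_factor_fit`: list with `scores` (per-cell
#'   tibble: posterior mean, sd, 95% interval of `s_c`), `loadings` (per-gene
#'   tibble for `lambda_g`), `sigma_draws` (residual preference SD),
#'   `share_draws` (posterior draws of the fraction of preference variance
#'   attributed to the factor, averaged over genes), `summary`, `data`, and
#'   `mcmc_info`.
#' @export
fit_factor_model <- function(counts, beta, gene_sigma = FALSE,
                             chains = 2, adapt = 500, burn = 500,
                             iter = 1500, thin = 2,
                             priors = list(), seed = 1L, quiet = TRUE) {
  m <- counts_to_matrices(counts)
  G <- length(m$genes); C <- length(m$cells)
  if (C < 2) stop("factor model is unidentifiable with a single cell")
  b <- align_beta(beta, m$cells)
  pr <- utils::modifyList(list(eta_prec = 0.16, mu_sdlog = 2, cv_sd = 1,
                               sigma_sd = 1, tau_sd = 1, lambda_sd = 1),
                          priors)
  sigma_block <- if (gene_sigma) {
    paste0("    log_sigma_g[g] ~ dnorm(log(sigma), pr_tau_t)\n",
           "    sigma_g[g] <- exp(log_sigma_g[g])\n",
           "    pprec[g] <- 1 / (sigma_g[g] * sigma_g[g])\n")
  } else {
    "    pprec[g] <- 1 / (sigma * sigma)\n"
  }
  globals <- if (gene_sigma) {
    paste0("  sigma ~ dnorm(0, pr_sigma) T(0.001, )\n",
           "  tau ~ dnorm(0, pr_tau) T(0.001, )\n",
           "  pr_tau_t <- 1 / (tau * tau)\n")
  } else {
    "  sigma ~ dnorm(0, pr_sigma) T(0.001, )\n"
  }
  mstr <- paste0(
    "model {\n",
    "  for (g in 1:G) {\n",
    "    for (c in 1:C) {\n",
    "      K[g, c] ~ dnegbin(q[g, c], r[g])\n",
    "      q[g, c] <- r[g] / (r[g] + mu[g] * beta[c])\n",
    "      k1[g, c] ~ dbin(p[g, c], K[g, c])\n",
    "      logit(p[g, c]) <- theta[g, c]\n",
    "      theta[g, c] ~ dnorm(eta[g] + lam[g] * s[c], pprec[g])\n",
    "    }\n",
    "    eta[g] ~ dnorm(0, pr_eta)\n",
    "    lam[g] ~ dnorm(0, pr_lam)\n",
    "    mu[g] ~ dlnorm(mu0, pr_mu)\n",
    "    cvr[g] ~ dnorm(0, pr_cv) T(cvlb[g], )\n",
    "    cvlb[g] <- sqrt(1 / mu[g])\n",
    "    r[g] <- mu[g] / (cvr[g] * cvr[g] * mu[g] - 1)\n",
    sigma_block,
    "  }\n",
    "  for (c in 1:C) {\n",
    "    s[c] ~ dnorm(0, 1)\n",
    "  }\n",
    globals,
    "}\n"
  )
  emp_mu <- pmax(rowMeans(m$K) / mean(b), 0.5)
  emp_eta <- qlogis((rowSums(m$k1) + 1) / (rowSums(m$K) + 2))
  data <- list(K = m$K, k1 = m$k1, G = G, C = C, beta = b,
               mu0 = mean(log(emp_mu)),
               pr_eta = pr$eta_prec, pr_mu = 1 / pr$mu_sdlog^2,
               pr_cv = 1 / pr$cv_sd^2, pr_sigma = 1 / pr$sigma_sd^2,
               pr_lam = 1 / pr$lambda_sd^2)
  if (gene_sigma) data$pr_tau <- 1 / pr$tau_sd^2
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(mu = emp_mu, cvr = pmax(sqrt(1 / emp_mu) * 1.3, 0.8),
                eta = emp_eta, sigma = 0.5,
                lam = rep(0.1, G), s = rnorm(C),
                theta = matrix(rep(emp_eta, C), G, C),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed * 1000L + ch))
    if (gene_sigma) { ini$log_sigma_g <- rep(log(0.5), G); ini$tau <- 0.3 }
    ini
  })
  set.seed(seed)
  monitors <- c("lam", "s", "eta", "sigma")
  if (gene_sigma) monitors <- c(monitors, "sigma_g")
  jm <- rjags::jags.model(textConnection(mstr), data = data, inits = inits,
                          n.chains = chains, n.adapt = adapt, quiet = quiet)
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  n_per_chain <- nrow(as.matrix(samp[[1]]))
  lam_cols <- grep("^lam\\[", colnames(draws))
  s_cols <- grep("^s\\[", colnames(draws))
  sig_cols <- if (gene_sigma) grep("^sigma_g\\[", colnames(draws)) else
    which(colnames(draws) == "sigma")

  # identifiability: per draw, rescale so SD(s) = 1, then fix the sign
  lam_d <- draws[, lam_cols, drop = FALSE]
  s_d <- draws[, s_cols, drop = FALSE]
  sc <- apply(s_d, 1, sd)
  sc[sc == 0] <- 1
  s_d <- s_d / sc
  lam_d <- lam_d * sc
  anchor <- which.max(abs(colMeans(lam_d)))
  flip <- sign(lam_d[, anchor])
  flip[flip == 0] <- 1
  s_d <- s_d * flip
  lam_d <- lam_d * flip

  sigma_d <- draws[, sig_cols, drop = FALSE]
  lam2 <- lam_d^2
  share_draws <- rowMeans(lam2 / (lam2 + if (gene_sigma) sigma_d^2 else
    matrix(sigma_d^2, nrow(lam2), ncol(lam2))))

  qtile <- function(x, p) unname(quantile(x, p))
  scores <- tibble::tibble(
    cell_id = m$cells,
    score = colMeans(s_d),
    sd = apply(s_d, 2, sd),
    q2.5 = apply(s_d, 2, qtile, 0.025),
    q97.5 = apply(s_d, 2, qtile, 0.975)
  )
  loadings <- tibble::tibble(
    gene_id = m$genes,
    loading = colMeans(lam_d),
    sd = apply(lam_d, 2, sd),
    q2.5 = apply(lam_d, 2, qtile, 0.025),
    q97.5 = apply(lam_d, 2, qtile, 0.975)
  )
  rhats <- c(
    score = max(vapply(seq_len(ncol(s_d)), function(j) {
      split_rhat(split(s_d[, j], rep(seq_len(chains), each = n_per_chain)))
    }, numeric(1)), na.rm = TRUE),
    loading = max(vapply(seq_len(ncol(lam_d)), function(j) {
      split_rhat(split(lam_d[, j], rep(seq_len(chains), each = n_per_chain)))
    }, numeric(1)), na.rm = TRUE)
  )
  structure(list(
    scores = scores, loadings = loadings,
    sigma_draws = if (gene_sigma) NULL else as.numeric(sigma_d),
    share_draws = share_draws,
    anchor_gene = m$genes[anchor],
    rhat = rhats,
    data = list(genes = m$genes, cells = m$cells, beta = b),
    mcmc_info = list(chains = chains, adapt = adapt, burn = burn,
                     iter = iter, thin = thin, seed = seed,
                     n_kept = nrow(draws))
  ), class = "apa_factor_fit")
}

#' @export
print.apa_factor_fit <- function(x, ...) {
  cat("One-factor isoform preference fit\n")
  cat("  genes:", length(x$data$genes), " cells:", length(x$data$cells), "\n")
  cat(sprintf("  factor variance share (posterior mean): %.3f\n",
              mean(x$share_draws)))
  cat("  sign anchor gene:", x$anchor_gene, "\n")
  invisible(x)
}

#' Decide whether a correlated preference component is present
#'
#' Fits the one-factor model and summarizes how much of the cell-level
#' preference variance the factor absorbs: per draw, the variance share
#' `lambda_g^2 / (lambda_g^2 + sigma_g^2)` averaged over genes. Evidence for
#' a correlated component is declared when the lower credible bound of this
#' share exceeds `share_min`. Power is limited: fairly strong correlations
#' across a large fraction of the genes are required for detection at
#' realistic data sizes.
#'
#' @inheritParams fit_factor_model
#' @param share_min Minimum variance share for an "evidence" call. The
#'   default 0.25 is calibrated so that uncorrelated data (where a single
#'   factor can still absorb a small share of preference variance by chance)
#'   stays clearly below it, while coordinated shifts across half of the
#'   genes land clearly above it.
#' @param prob One-sided credible level of the lower bound (default 0.95).
#' @param fit Optionally, an existing `apa_factor_fit` (skips refitting).
#' @return A list with `evidence` (logical), `share_mean`, `share_lower`,
#'   `share_min`, and the underlying `fit`.
#' @export
detect_correlated_component <- function(counts = NULL, beta = NULL,
                                        share_min = 0.25, prob = 0.95,
                                        fit = NULL, ...) {
  if (is.null(fit)) fit <- fit_factor_model(counts, beta, ...)
  lower <- unname(quantile(fit$share_draws, 1 - prob))
  list(evidence = lower > share_min,
       share_mean = mean(fit$share_draws),
       share_lower = lower,
       share_min = share_min,
       fit = fit)
}

#' Project cells by principal component analysis of isoform preferences
#'
#' Centers the posterior-mean logit preference of each gene across cells and
#' computes standard PCA scores of the cells on the leading components. Used
#' to visualize whether isoform usage alone separates cell populations.
#'
#' @param pref A genes-by-cells numeric matrix of (posterior mean) logit
#'   isoform preferences, e.g. `qlogis(fit$posterior_means$p)`.
#' @param n_comp Number of components to return (truncated to the matrix
#'   rank).
#' @return Tibble with `cell_id` and score columns `PC1`, `PC2`, ...
#'   (deterministic up to a sign convention: each component is flipped so its
#'   largest-magnitude cell score is positive).
#' @export
project_preferences_pca <- function(pref, n_comp = 2) {
  stopifnot(is.matrix(pref))
  centered <- pref - rowMeans(pref)
  pc <- prcomp(t(centered), center = FALSE)
  k <- min(n_comp, ncol(pc$x), sum(pc$sdev > 1e-12))
  k <- max(k, 1L)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  out <- tibble::as_tibble(scores)
  names(out) <- paste0("PC", seq_len(ncol(out)))
  dplyr::bind_cols(
    tibble::tibble(cell_id = colnames(pref) %||% as.character(seq_len(ncol(pref)))),
    out
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
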