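#' Simulate single-cell isoform counts from the three-layer noise model
#'
#' The generative model has three layers. (1) Expression noise: the true
#' number of molecules of gene g in cell c, `Q_gc`, is negative-binomially
#' distributed with mean `mu_g` and coefficient of variation `cv_g` (variance
#' `(cv_g * mu_g)^2`). (2) Random partitioning: each molecule independently
#' becomes isoform 1 with the cell's preference `p_gc`, where
#' `logit(p_gc) ~ Normal(eta_g, sigma^2)`; `sigma = 0` recovers the
#' shared-preference model in which all cells use `p_gc = plogis(eta_g)`.
#' (3) Technical noise: each molecule is captured and observed with the
#' cell's efficiency `beta_c` (optionally isoform-specific via `iso_beta`).
#'
#' @param n_genes,n_cells Dimensions.
#' @param mu Per-gene mean molecules per cell (recycled to `n_genes`).
#' @param cv Per-gene coefficient of variation of `Q_gc`; must satisfy
#'   `cv^2 > 1/mu` for negative-binomial representability.
#' @param eta Per-gene population-mean isoform-1 preference on the logit
#'   scale.
#' @param sigma Standard deviation of the cell-level logit preference around
#'   `eta_g` (a scalar, or per-gene vector).
#' @param beta Per-cell capture efficiency in (0, 1].
#' @param iso_beta Optional length-2 multiplier `c(f1, f2)` making the
#'   efficiencies isoform-specific (`beta_c * f1` for isoform 1, `beta_c *
#'   f2` for isoform 2), for robustness studies.
#' @param lambda,scores Optional per-gene loadings and per-cell scores of a
#'   coordinated preference component: when given, the cell-level logit
#'   preference is centered at `eta_g + lambda_g * scores_c` instead of
#'   `eta_g`, emulating correlated isoform-usage shifts across genes.
#' @param seed Random seed.
#' @return A list with `counts` (tibble `gene_id`, `cell_id`, `k1`, `k2`)
#'   and `truth` (list of the latent `Q`, `theta`, `p` matrices and all
#'   parameters).
#' @export
simulate_isoforms <- function(n_genes, n_cells, mu, cv, eta,
                              sigma = 0, beta = 0.05, iso_beta = NULL,
                              lambda = NULL, scores = NULL,
                              seed = 1L) {
  set.seed(seed)
  mu <- rep_len(mu, n_genes)
  cv <- rep_len(cv, n_genes)
  eta <- rep_len(eta, n_genes)
  sigma <- rep_len(sigma, n_genes)
  beta <- rep_len(beta, n_cells)
  if (any(cv^2 <= 1 / mu)) {
    stop("negative-binomial representability requires cv^2 > 1/mu for every gene")
  }
  if (any(beta <= 0) || any(beta > 1)) stop("beta must lie in (0, 1]")
  r <- mu / (cv^2 * mu - 1)
  G <- n_genes; C <- n_cells
  Q <- matrix(rnbinom(G * C, size = rep(r, C), mu = rep(mu, C)), G, C)
  center <- matrix(rep(eta, C), G, C)
  if (!is.null(lambda)) {
    stopifnot(!is.null(scores))
    center <- center + outer(rep_len(lambda, G), rep_len(scores, C))
  }
  theta <- matrix(rnorm(G * C, center, rep(sigma, C)), G, C)
  p <- plogis(theta)
  b1 <- if (is.null(iso_beta)) rep(beta, each = G) else rep(beta * iso_beta[1], each = G)
  b2 <- if (is.null(iso_beta)) rep(beta, each = G) else rep(beta * iso_beta[2], each = G)
  n1 <- matrix(rbinom(G * C, Q, p), G, C)
  k1 <- matrix(rbinom(G * C, n1, b1), G, C)
  k2 <- matrix(rbinom(G * C, Q - n1, b2), G, C)
  genes <- sprintf("g%04d", seq_len(G))
  cells <- sprintf("c%03d", seq_len(C))
  counts <- tibble::tibble(
    gene_id = rep(genes, C),
    cell_id = rep(cells, each = G),
    k1 = as.integer(k1),
    k2 = as.integer(k2)
  )
  list(counts = counts,
       truth = list(Q = Q, theta = theta, p = p, mu = mu, cv = cv, eta = eta,
                    sigma = sigma, beta = beta, r = r, lambda = lambda,
                    scores = scores, genes = genes, cells = cells))
}

# long counts tibble -> list of genes, cells, K, k1 matrices (genes x cells)
counts_to_matrices <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("gene_id", "cell_id", "k1", "k2") %in% names(counts)))
  if (any(counts$k1 != round(counts$k1)) || any(counts$k2 != round(counts$k2))) {
    stop("isoform counts must be integers")
  }
  genes <- sort(unique(counts$gene_id))
  cells <- sort(unique(counts$cell_id))
  k1 <- matrix(0L, length(genes), length(cells),
               dimnames = list(genes, cells))
  K <- k1
  gi <- match(counts$gene_id, genes)
  ci <- match(counts$cell_id, cells)
  k1[cbind(gi, ci)] <- as.integer(counts$k1)
  K[cbind(gi, ci)] <- as.integer(counts$k1 + counts$k2)
  list(genes = genes, cells = cells, K = K, k1 = k1)
}

align_beta <- function(beta, cells) {
  if (is.data.frame(beta)) {
    b <- setNames(beta$beta, beta$cell_id)[cells]
  } else if (!is.null(names(beta))) {
    b <- beta[cells]
  } else {
    b <- rep_len(beta, length(cells))
  }
  if (any(is.na(b))) stop("capture efficiencies missing for some cells")
  unname(b)
}

#' Exact collapsed log-likelihood of observed isoform counts
#'
#' Rather than summing over the latent true molecule count `Q_gc`, the
#' likelihood uses the exact collapse implied by per-molecule independence:
#' binomial thinning of a negative binomial leaves a negative binomial with
#' the same dispersion parameter and mean `mu_g * beta_c`, so the observed
#' total `K_gc = k1 + k2` is `NegBin(mu_g * beta_c, r_g)` and, given the
#' total, the isoform split is `k1 | K ~ Binomial(K_gc, p_gc)`.
#'
#' @param counts Tibble with `gene_id`, `cell_id`, `k1`, `k2` (integer
#'   counts).
#' @param params List with elements `mu`, `cv` (per-gene vectors ordered by
#'   sorted gene id), `beta` (per-cell, ordered by sorted cell id or named),
#'   and either `p` (genes-by-cells preference matrix) or `eta` (per-gene
#'   logit preference, used for every cell).
#' @return Scalar log-likelihood.
#' @export
isoform_loglik <- function(counts, params) {
  m <- counts_to_matrices(counts)
  G <- length(m$genes); C <- length(m$cells)
  mu <- rep_len(params$mu, G)
  cv <- rep_len(params$cv, G)
  beta <- align_beta(params$beta, m$cells)
  if (any(cv^2 <= 1 / mu)) {
    stop("negative-binomial representability requires cv^2 > 1/mu")
  }
  p <- if (!is.null(params$p)) {
    matrix(params$p, G, C)
  } else {
    matrix(plogis(rep_len(params$eta, G)), G, C)
  }
  r <- mu / (cv^2 * mu - 1)
  mu_obs <- outer(mu, beta)
  sum(dnbinom(m$K, size = r, mu = mu_obs, log = TRUE)) +
    sum(dbinom(m$k1, m$K, p, log = TRUE))
}

jags_model_string <- function(model, gene_sigma) {
  pref_line <- switch(
    model,
    shared = "      theta[g, c] <- eta[g]",
    variable = "      theta[g, c] ~ dnorm(eta[g], pprec[g])"
  )
  sigma_block <- if (model == "shared") {
    ""
  } else if (gene_sigma) {
    paste0(
      "    log_sigma_g[g] ~ dnorm(log(sigma), 1 / (tau * tau))\n",
      "    sigma_g[g] <- exp(log_sigma_g[g])\n",
      "    pprec[g] <- 1 / (sigma_g[g] * sigma_g[g])\n"
    )
  } else {
    "    pprec[g] <- 1 / (sigma * sigma)\n"
  }
  globals <- if (model == "shared") {
    ""
  } else if (gene_sigma) {
    "  sigma ~ dnorm(0, pr_sigma) T(0.001, )\n  tau ~ dnorm(0, pr_tau) T(0.001, )\n"
  } else {
    "  sigma ~ dnorm(0, pr_sigma) T(0, )\n"
  }
  paste0(
    "model {\n",
    "  for (g in 1:G) {\n",
    "    for (c in 1:C) {\n",
    "      K[g, c] ~ dnegbin(q[g, c], r[g])\n",
    "      q[g, c] <- r[g] / (r[g] + mu[g] * beta[c])\n",
    "      k1[g, c] ~ dbin(p[g, c], K[g, c])\n",
    "      logit(p[g, c]) <- theta[g, c]\n",
    pref_line, "\n",
    "    }\n",
    "    eta[g] ~ dnorm(0, pr_eta)\n",
    "    mu[g] ~ dlnorm(mu0, pr_mu)\n",
    "    cvr[g] ~ dnorm(0, pr_cv) T(cvlb[g], )\n",
    "    cvlb[g] <- sqrt(1 / mu[g])\n",
    "    r[g] <- mu[g] / (cvr[g] * cvr[g] * mu[g] - 1)\n",
    sigma_block,
    "  }\n",
    globals,
    "}\n"
  )
}

split_rhat <- function(draws_by_chain) {
  # split each chain in half -> potential scale reduction factor
  halves <- unlist(lapply(draws_by_chain, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[seq(n + 1, 2 * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical Bayesian isoform preference model by MCMC
#'
#' Fits either the shared-preference model (every cell of the population uses
#' the same isoform preference `plogis(eta_g)`; all cell-to-cell variance in
#' isoform ratios comes from technical noise and random partitioning) or the
#' variable-preference model (cell-level logit preferences scatter around
#' `eta_g` with standard deviation `sigma`, optionally gene-specific
#' `sigma_g` shrunk toward `sigma` on the log scale). Capture efficiencies
#' are treated as known constants estimated from spike-ins. Sampling is done
#' with JAGS via \pkg{rjags} on the exact collapsed likelihood (see
#' [isoform_loglik()]), so the latent true molecule counts never need to be
#' sampled.
#'
#' @param counts Tibble with `gene_id`, `cell_id`, `k1`, `k2`.
#' @param beta Per-cell capture efficiencies: a data frame with `cell_id` and
#'   `beta`, a named vector, or a scalar.
#' @param model `"variable"` (cell-variable preference) or `"shared"`.
#' @param gene_sigma If `TRUE`, use gene-level preference SDs with a
#'   log-normal hyperprior centered on the population `sigma`.
#' @param chains,adapt,burn,iter,thin MCMC configuration: number of chains,
#'   adaptation and burn-in iterations, sampling iterations, and thinning.
#' @param priors Optional list overriding prior hyperparameters: `eta_prec`
#'   (default 0.16, i.e. Normal(0, 2.5^2)), `mu_sdlog` (2), `cv_sd` (1),
#'   `sigma_sd` (1), `tau_sd` (1).
#' @param seed Integer seed; chain seeds are derived from it.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `apa_fit`: list with `summary` (tidy posterior
#'   summaries with split-Rhat and effective sample size), `posterior_means`
#'   (`mu`, `cv`, `eta`, `sigma`, and the preference matrix `p`), `deviance`
#'   (deviance trace over kept draws, computed with [isoform_loglik()]),
#'   `sigma_draws` (for variable models), `draws` (kept draws as a matrix),
#'   `data`, and `mcmc_info`. Convergence is flagged with a warning (not an
#'   error) when any monitored split-Rhat exceeds 1.05.
#' @export
fit_preference_model <- function(counts, beta,
                                 model = c("variable", "shared"),
                                 gene_sigma = FALSE,
                                 chains = 2, adapt = 500, burn = 500,
                                 iter = 1500, thin = 2,
                                 priors = list(), seed = 1L,
                                 quiet = TRUE) {
  model <- match.arg(model)
  m <- counts_to_matrices(counts)
  G <- length(m$genes); C <- length(m$cells)
  if (C < 2 || G < 1) stop("need at least 2 cells and 1 gene")
  all_zero <- rowSums(m$K) == 0
  if (any(all_zero)) {
    warning(sum(all_zero), " gene(s) with all-zero counts dropped")
    m$K <- m$K[!all_zero, , drop = FALSE]
    m$k1 <- m$k1[!all_zero, , drop = FALSE]
    m$genes <- m$genes[!all_zero]
    G <- length(m$genes)
  }
  b <- align_beta(beta, m$cells)
  pr <- utils::modifyList(list(eta_prec = 0.16, mu_sdlog = 2, cv_sd = 1,
                               sigma_sd = 1, tau_sd = 1), priors)
  emp_mu <- pmax(rowMeans(m$K) / mean(b), 0.5)
  data <- list(K = m$K, k1 = m$k1, G = G, C = C, beta = b,
               mu0 = mean(log(emp_mu)),
               pr_eta = pr$eta_prec, pr_mu = 1 / pr$mu_sdlog^2,
               pr_cv = 1 / pr$cv_sd^2)
  if (model == "variable") {
    data$pr_sigma <- 1 / pr$sigma_sd^2
    if (gene_sigma) data$pr_tau <- 1 / pr$tau_sd^2
  }
  emp_eta <- qlogis((rowSums(m$k1) + 1) / (rowSums(m$K) + 2))
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(
      mu = emp_mu, cvr = pmax(sqrt(1 / emp_mu) * 1.3, 0.8), eta = emp_eta,
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = as.integer(seed * 1000L + ch)
    )
    if (model == "variable") {
      ini$sigma <- 0.5
      ini$theta <- matrix(rep(emp_eta, C), G, C)
      if (gene_sigma) { ini$log_sigma_g <- rep(log(0.5), G); ini$tau <- 0.3 }
    }
    ini
  })
  monitors <- c("mu", "cvr", "eta")
  if (model == "variable") {
    monitors <- c(monitors, "sigma", "theta")
    if (gene_sigma) monitors <- c(monitors, "sigma_g", "tau")
  }
  jm <- rjags::jags.model(textConnection(jags_model_string(model, gene_sigma)),
                          data = data, inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = quiet)
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  n_per_chain <- nrow(as.matrix(samp[[1]]))

  col <- function(stub) {
    if (stub %in% colnames(draws)) return(which(colnames(draws) == stub))
    grep(paste0("^", stub, "\\["), colnames(draws))
  }
  post_mean <- colMeans(draws)
  mu_hat <- unname(post_mean[col("mu")])
  cv_hat <- unname(post_mean[col("cvr")])
  eta_hat <- unname(post_mean[col("eta")])
  if (model == "variable") {
    theta_cols <- col("theta")
    p_hat <- matrix(colMeans(plogis(draws[, theta_cols, drop = FALSE])), G, C)
    sigma_draws <- draws[, col("sigma")[1]]
  } else {
    p_hat <- matrix(plogis(colMeans(draws[, col("eta"), drop = FALSE])), G, C)
    sigma_draws <- NULL
  }
  dimnames(p_hat) <- list(m$genes, m$cells)

  # deviance trace: -2 x collapsed log-likelihood at each kept draw
  counts_fit <- tibble::tibble(
    gene_id = rep(m$genes, C), cell_id = rep(m$cells, each = G),
    k1 = as.integer(m$k1), k2 = as.integer(m$K - m$k1)
  )
  r_draws <- draws[, col("mu"), drop = FALSE] /
    (draws[, col("cvr"), drop = FALSE]^2 * draws[, col("mu"), drop = FALSE] - 1)
  deviance <- vapply(seq_len(nrow(draws)), function(d) {
    mu_d <- draws[d, col("mu")]
    r_d <- r_draws[d, ]
    p_d <- if (model == "variable") {
      matrix(plogis(draws[d, col("theta")]), G, C)
    } else {
      matrix(plogis(draws[d, col("eta")]), G, C)
    }
    ll <- sum(dnbinom(m$K, size = r_d, mu = outer(unname(mu_d), b),
                      log = TRUE)) +
      sum(dbinom(m$k1, m$K, p_d, log = TRUE))
    -2 * ll
  }, numeric(1))

  # tidy summary for the interpretable (non-latent) parameters
  summ_cols <- c(col("mu"), col("cvr"), col("eta"))
  if (model == "variable") summ_cols <- c(summ_cols, col("sigma")[1])
  if (gene_sigma) summ_cols <- c(summ_cols, col("sigma_g"), col("tau"))
  qs <- c(0.025, 0.165, 0.835, 0.975)
  summary_tbl <- purrr::map_dfr(summ_cols, function(j) {
    x <- draws[, j]
    by_chain <- split(x, rep(seq_len(chains), each = n_per_chain))
    tibble::tibble(
      parameter = colnames(draws)[j],
      mean = mean(x), sd = sd(x),
      q2.5 = quantile(x, qs[1]), q16.5 = quantile(x, qs[2]),
      q83.5 = quantile(x, qs[3]), q97.5 = quantile(x, qs[4]),
      rhat = split_rhat(by_chain),
      ess = tryCatch(as.numeric(coda::effectiveSize(x)), error = function(e) NA)
    )
  })
  bad <- summary_tbl$rhat > 1.05 & !is.na(summary_tbl$rhat)
  if (any(bad)) {
    warning("split-Rhat > 1.05 for ", sum(bad),
            " parameter(s); consider longer chains")
  }
  structure(list(
    model = model, gene_sigma = gene_sigma,
    summary = summary_tbl,
    posterior_means = list(mu = setNames(mu_hat, m$genes),
                           cv = setNames(cv_hat, m$genes),
                           eta = setNames(eta_hat, m$genes),
                           sigma = if (model == "variable")
                             mean(sigma_draws) else 0,
                           p = p_hat),
    sigma_draws = sigma_draws,
    deviance = deviance,
    draws = draws,
    data = list(genes = m$genes, cells = m$cells, K = m$K, k1 = m$k1,
                beta = b, counts = counts_fit),
    mcmc_info = list(chains = chains, adapt = adapt, burn = burn,
                     iter = iter, thin = thin, seed = seed,
                     n_kept = nrow(draws))
  ), class = "apa_fit")
}

#' @export
print.apa_fit <- function(x, ...) {
  cat("Hierarchical isoform preference fit (", x$model, " preference)\n",
      sep = "")
  cat("  genes: ", length(x$data$genes), ", cells: ", length(x$data$cells),
      ", kept draws: ", x$mcmc_info$n_kept, "\n", sep = "")
  if (x$model == "variable") {
    s2 <- mean(x$sigma_draws^2)
    cat(sprintf("  preference variance (posterior mean of sigma^2): %.4f\n", s2))
  }
  cat(sprintf("  max split-Rhat: %.3f\n", max(x$summary$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Deviance information criterion of a fitted preference model
#'
#' Computes `DIC = Dbar + pD` with `pD = Dbar - Dhat`, where `Dbar` is the
#' posterior mean deviance (from the fit's deviance trace) and `Dhat` the
#' deviance at the posterior means of the continuous parameters, with the
#' cell-level preferences plugged in at their posterior means. Lower DIC
#' indicates better expected predictive fit.
#'
#' @param fit An `apa_fit` from [fit_preference_model()].
#' @return A list with `dic`, `pd`, `dbar`, `dhat`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "apa_fit"))
  if (length(fit$deviance) < 10) stop("need at least 10 posterior draws for DIC")
  pm <- fit$posterior_means
  # posterior means of mu and cv individually satisfy the representability
  # constraint on every draw, but their means may graze it; nudge if needed
  cv_plug <- pmax(pm$cv, sqrt(1 / pm$mu) * (1 + 1e-6))
  dhat <- -2 * isoform_loglik(fit$data$counts,
                              list(mu = pm$mu, cv = cv_plug, p = pm$p,
                                   beta = setNames(fit$data$beta,
                                                   fit$data$cells)))
  dic_from_trace(fit$deviance, dhat)
}

#' DIC from a deviance trace and a plug-in deviance
#'
#' @param deviance Vector of deviances over posterior draws.
#' @param dhat Deviance at the posterior means of the parameters.
#' @return A list with `dic`, `pd`, `dbar`, `dhat`.
#' @export
dic_from_trace <- function(deviance, dhat) {
  dbar <- mean(deviance)
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}
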