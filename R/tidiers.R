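#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a preference model fit
#'
#' @param x An `apa_fit`.
#' @param ... Unused.
#' @return A tibble with one row per monitored parameter: `term`, `mean`,
#'   `sd`, central 66% and 95% interval bounds, split-Rhat and effective
#'   sample size.
#' @method tidy apa_fit
#' @export
tidy.apa_fit <- function(x, ...) {
  dplyr::rename(x$summary, term = "parameter")
}

#' One-row summary of a preference model fit
#'
#' @param x An `apa_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the model type, data dimensions, posterior
#'   mean of the preference variance `sigma^2` (0 for the shared model), DIC
#'   and effective parameter count, and convergence diagnostics.
#' @method glance apa_fit
#' @export
glance.apa_fit <- function(x, ...) {
  dic_res <- compute_dic(x)
  tibble::tibble(
    model = x$model,
    n_genes = length(x$data$genes),
    n_cells = length(x$data$cells),
    sigma2 = if (x$model == "variable") mean(x$sigma_draws^2) else 0,
    dic = dic_res$dic,
    pd = dic_res$pd,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    min_ess = min(x$summary$ess, na.rm = TRUE),
    n_draws = x$mcmc_info$n_kept
  )
}

#' Posterior of the isoform preference variance
#'
#' @param object An `apa_fit` from the variable-preference model.
#' @param ... Unused.
#' @return A ggplot showing the posterior density of `sigma^2`, the variance
#'   of the cell-level logit isoform preference.
#' @method autoplot apa_fit
#' @export
autoplot.apa_fit <- function(object, ...) {
  if (object$model != "variable") {
    stop("the shared-preference model has no preference variance posterior")
  }
  df <- tibble::tibble(sigma2 = object$sigma_draws^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma2)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = mean(df$sigma2), linetype = 2) +
    ggplot2::labs(x = "variance of logit isoform preference",
                  y = "posterior density")
}

#' Tidy scores or loadings of a one-factor fit
#'
#' @param x An `apa_factor_fit`.
#' @param type `"scores"` (per cell) or `"loadings"` (per gene).
#' @param ... Unused.
#' @method tidy apa_factor_fit
#' @export
tidy.apa_factor_fit <- function(x, type = c("scores", "loadings"), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    dplyr::rename(x$scores, term = "cell_id", estimate = "score")
  } else {
    dplyr::rename(x$loadings, term = "gene_id", estimate = "loading")
  }
}

#' One-row summary of a one-factor fit
#'
#' @param x An `apa_factor_fit`.
#' @param ... Unused.
#' @method glance apa_factor_fit
#' @export
glance.apa_factor_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$data$genes),
    n_cells = length(x$data$cells),
    share_mean = mean(x$share_draws),
    share_q5 = unname(quantile(x$share_draws, 0.05)),
    max_rhat = max(x$rhat, na.rm = TRUE),
    n_draws = x$mcmc_info$n_kept
  )
}

#' Cell scores of the correlated preference component
#'
#' @param object An `apa_factor_fit`.
#' @param labels Optional vector or data frame (`cell_id`, `label`) of cell
#'   population labels used for coloring.
#' @param ... Unused.
#' @return A ggplot of posterior mean scores per cell with 95% intervals.
#' @method autoplot apa_factor_fit
#' @export
autoplot.apa_factor_fit <- function(object, labels = NULL, ...) {
  df <- object$scores
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      df <- dplyr::left_join(df, labels, by = "cell_id")
    } else {
      df$label <- labels
    }
  }
  df <- dplyr::arrange(df, .data$score)
  df$rank <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score))
  if (!is.null(df[["label"]])) {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5,
                   colour = .data$label))
  } else {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5))
  }
  p + ggplot2::labs(x = "cell (ranked)", y = "factor score")
}

#' Scatter plot of cells in preference PCA space
#'
#' @param scores Tibble from [project_preferences_pca()].
#' @param labels Optional population labels (vector or data frame with
#'   `cell_id`, `label`).
#' @return A ggplot of the first two components.
#' @export
plot_preference_pca <- function(scores, labels = NULL) {
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      scores <- dplyr::left_join(scores, labels, by = "cell_id")
    } else {
      scores$label <- labels
    }
  }
  aes <- if (is.null(scores[["label"]])) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$label)
  }
  ggplot2::ggplot(scores, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PC1", y = "PC2")
}

#' Observed versus null variance of isoform ratios per gene
#'
#' @param test Result tibble from [partition_null_variance_test()].
#' @return A ggplot comparing each gene's observed across-cell ratio variance
#'   with the median of its partition-null distribution.
#' @export
plot_variance_test <- function(test) {
  ggplot2::ggplot(test, ggplot2::aes(x = .data$null_median,
                                     y = .data$obs_var,
                                     colour = .data$exceeds)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "null median variance (random partitioning)",
                  y = "observed variance of isoform ratios")
}
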