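#' @export
print.lhc_fit <- function(x, ...) {
  cat("<lhc_fit> latent-confounder MR fit\n")
  cat(sprintf("  SNPs: %d   log-likelihood: %.4f   fitted optimum: %s\n",
              x$n_snps, x$loglik, x$primary_label))
  p <- x$primary
  cat(sprintf("  alpha_xy = %.4f  alpha_yx = %.4f\n", p$alpha_xy, p$alpha_yx))
  cat(sprintf("  h2_x = %.4f  h2_y = %.4f  t_x = %.4f  t_y = %.4f  i_xy = %.4f\n",
              p$h2_x, p$h2_y, p$t_x, p$t_y, p$i_xy))
  if (!x$exposure_h2_reliable)
    cat("  note: exposure total heritability < 2.5%;",
        "outgoing causal estimate unreliable\n")
  invisible(x)
}

#' Tidy the primary solution of a latent-confounder MR fit
#'
#' Returns one row per model parameter of the primary solution. When a
#' jackknife result is supplied, standard errors and two-sided normal
#' p-values are attached.
#'
#' @param x An `lhc_fit` object.
#' @param jackknife Optional `lhc_jackknife` object from
#'   [block_jackknife()].
#' @param ... Unused.
#' @return A tibble `term, estimate` (plus `se, p` with a jackknife).
#' @method tidy lhc_fit
#' @export
tidy.lhc_fit <- function(x, jackknife = NULL, ...) {
  p <- x$primary
  terms <- c("pi_x", "pi_y", "h2_x", "h2_y", "t_x", "t_y",
             "alpha_xy", "alpha_yx", "i_x", "i_y", "i_xy")
  out <- tibble::tibble(term = terms, estimate = unlist(p[terms]))
  if (!is.null(jackknife)) {
    out$se <- unname(jackknife$se[out$term])
    out$p <- unname(jackknife$p_values[out$term])
  }
  out
}

#' One-row summary of a latent-confounder MR fit
#'
#' @param x An `lhc_fit` object.
#' @param ... Unused.
#' @return A tibble with the log-likelihood, SNP count, convergence
#'   fraction, primary-solution label, implied genetic correlation and the
#'   exposure-heritability reliability flag.
#' @method glance lhc_fit
#' @export
glance.lhc_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_snps = x$n_snps,
    prop_converged = mean(x$per_start$converged),
    primary_label = x$primary_label,
    rg = rg_from_params(x$primary),
    exposure_h2_reliable = x$exposure_h2_reliable
  )
}

#' Plot a latent-confounder MR fit
#'
#' Shows the per-start optimisation results: causal-effect estimates of
#' every converged start against the attained log-likelihood, with the
#' selected optimum highlighted. Multiple clusters are a sign of the
#' model's two equivalent optima.
#'
#' @param object An `lhc_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lhc_fit
#' @export
autoplot.lhc_fit <- function(object, ...) {
  ps <- dplyr::filter(object$per_start, .data$converged)
  ps_long <- tidyr::pivot_longer(ps, c("alpha_xy", "alpha_yx"),
                                 names_to = "direction",
                                 values_to = "estimate")
  best <- dplyr::filter(ps_long, .data$loglik >= max(.data$loglik) - 1e-4)
  ggplot2::ggplot(ps_long, ggplot2::aes(x = .data$estimate,
                                        y = .data$loglik)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::facet_wrap(~direction, scales = "free_x") +
    ggplot2::labs(x = "causal-effect estimate at optimum",
                  y = "log-likelihood",
                  title = "Per-start optima (selected in red)")
}

#' Scatter plot of paired effect estimates
#'
#' The classic exposure-versus-outcome effect plot: SNP clusters along
#' different slopes correspond to the confounder axis (slope `q_y/q_x`)
#' and the two causal directions.
#'
#' @param paired Paired summary-statistics tibble.
#' @param sample_n Optional maximum number of SNPs drawn (for speed).
#' @return A ggplot object.
#' @export
plot_paired_sumstats <- function(paired, sample_n = 20000) {
  if (nrow(paired) > sample_n)
    paired <- paired[sort(sample.int(nrow(paired), sample_n)), ]
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::labs(x = "effect on exposure (X)", y = "effect on outcome (Y)")
}
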