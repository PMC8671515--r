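#' Model parameters for the latent-confounder MR model
#'
#' Bundles the estimable parameter vector of the bivariate structural model
#' together with the fixed quantities (sample sizes, number of markers,
#' confounder polygenicity). The eleven estimable parameters are the trait
#' polygenicities `pi_x`, `pi_y`, the direct heritabilities `h2_x`, `h2_y`,
#' the confounder effects `t_x = q_x * sqrt(h2_u)` and `t_y = q_y * sqrt(h2_u)`,
#' the bi-directional causal effects `alpha_xy` (X on Y) and `alpha_yx`
#' (Y on X), and the intercept parameters `i_x`, `i_y` (per-trait LD-score
#' regression intercepts) and `i_xy` (cross-trait intercept capturing sample
#' overlap). The confounder polygenicity `pi_u` is not identifiable and is
#' fixed (0.1 by default).
#'
#' @param pi_x,pi_y Trait polygenicities, fractions of markers with a direct
#'   effect, in (0, 1].
#' @param h2_x,h2_y Direct heritabilities in \[0, 1\].
#' @param t_x Confounder effect on X, in \[0, 1\] (its sign is fixed to
#'   resolve the sign indeterminacy of the latent confounder).
#' @param t_y Confounder effect on Y, in \[-1, 1\].
#' @param alpha_xy,alpha_yx Causal effect of X on Y and of Y on X; their
#'   product must be smaller than 1 in absolute value.
#' @param i_x,i_y LD-score regression intercepts (sampling-noise variance
#'   scale of each trait's marginal estimates is `i/n`).
#' @param i_xy Cross-trait intercept, `r_xy * n_overlap / sqrt(n_x * n_y)`.
#' @param n_x,n_y GWAS sample sizes.
#' @param M Number of genome-wide markers.
#' @param pi_u Fixed confounder polygenicity (default 0.1).
#'
#' @return An object of class `lhc_params` (a named list).
#' @export
#' @examples
#' lhc_params(pi_x = 5e-3, pi_y = 1e-2, h2_x = 0.25, h2_y = 0.2,
#'            t_x = 0.16, t_y = 0.11, alpha_xy = 0.3, alpha_yx = 0,
#'            i_x = 1, i_y = 1, i_xy = 0, n_x = 5e4, n_y = 5e4, M = 5e4)
lhc_params <- function(pi_x, pi_y, h2_x, h2_y, t_x, t_y,
                       alpha_xy, alpha_yx, i_x, i_y, i_xy,
                       n_x, n_y, M, pi_u = 0.1) {
  p <- list(pi_x = pi_x, pi_y = pi_y, h2_x = h2_x, h2_y = h2_y,
            t_x = t_x, t_y = t_y, alpha_xy = alpha_xy, alpha_yx = alpha_yx,
            i_x = i_x, i_y = i_y, i_xy = i_xy,
            n_x = as.numeric(n_x), n_y = as.numeric(n_y),
            M = as.numeric(M), pi_u = pi_u)
  validate_lhc_params(p)
  structure(p, class = "lhc_params")
}

validate_lhc_params <- function(p) {
  stopifnot(
    p$pi_x > 0, p$pi_x <= 1, p$pi_y > 0, p$pi_y <= 1,
    p$pi_u > 0, p$pi_u <= 1,
    p$h2_x >= 0, p$h2_x <= 1, p$h2_y >= 0, p$h2_y <= 1,
    p$t_x >= 0, p$t_x <= 1, abs(p$t_y) <= 1,
    abs(p$alpha_xy) <= 1, abs(p$alpha_yx) <= 1,
    p$i_x > 0, p$i_y > 0, abs(p$i_xy) <= 1,
    p$n_x >= 1, p$n_y >= 1, p$M >= 1
  )
  if (abs(p$alpha_xy * p$alpha_yx) >= 1)
    stop("|alpha_xy * alpha_yx| must be < 1", call. = FALSE)
  invisible(p)
}

#' @export
print.lhc_params <- function(x, ...) {
  cat("<lhc_params>\n")
  est <- unlist(x[c("pi_x", "pi_y", "h2_x", "h2_y", "t_x", "t_y",
                    "alpha_xy", "alpha_yx", "i_x", "i_y", "i_xy")])
  print(signif(est, 4))
  cat(sprintf("fixed: n_x = %g, n_y = %g, M = %g, pi_u = %g\n",
              x$n_x, x$n_y, x$M, x$pi_u))
  invisible(x)
}

#' @export
as.data.frame.lhc_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

# Free (step-2) parameter names, in optimisation order.
free_param_names <- function() {
  c("h2_x", "h2_y", "t_x", "t_y", "alpha_xy", "alpha_yx", "i_xy")
}

# Box constraints of the free parameters.
free_param_bounds <- function() {
  list(lower = c(h2_x = 0, h2_y = 0, t_x = 0, t_y = -1,
                 alpha_xy = -1, alpha_yx = -1, i_xy = -1),
       upper = c(h2_x = 1, h2_y = 1, t_x = 1, t_y = 1,
                 alpha_xy = 1, alpha_yx = 1, i_xy = 1))
}

# Replace the free coordinates of an lhc_params object.
set_free_params <- function(theta, values) {
  theta[free_param_names()] <- as.list(unname(values[free_param_names()]))
  theta
}
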