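#' Block-jackknife standard errors for the two-trait fit
#'
#' Splits the genome into `n_blocks` contiguous blocks of (near-)equal SNP
#' count — snapped to LD-block boundaries when the profile carries a
#' `block` column, so no LD straddles a jackknife block — and re-fits the
#' seven free step-2 parameters leaving one block out at a time,
#' warm-started at the full-data optimum (with random fallback starts on
#' non-convergence). The variance of each parameter is the sum of squared
#' deviations of the leave-one-out estimates from the full-data estimate:
#' the textbook block-jackknife prefactor `((m - m/B)/(m/B)) * 1/(B - 1)`
#' equals 1 identically, which is asserted in code.
#'
#' @param paired Paired summary-statistics tibble (position-sorted).
#' @param profile Binned LD-profile tibble aligned with `paired`.
#' @param fit A fitted `lhc_fit` object from [fit_pair()] or [lhc_mr()].
#' @param n_blocks Number of jackknife blocks (default 200).
#' @param n_fallback_starts Random restarts tried when the warm start does
#'   not converge (default 4).
#' @return An object of class `lhc_jackknife`: list with the leave-one-out
#'   estimate tibble, per-parameter `se` and two-sided normal `p_values`,
#'   and the full-data estimates.
#' @export
block_jackknife <- function(paired, profile, fit, n_blocks = 200,
                            n_fallback_starts = 4) {
  stopifnot(inherits(fit, "lhc_fit"))
  if (!("bin" %in% names(profile))) profile <- make_bins(profile)
  K <- nrow(paired)
  stopifnot(n_blocks >= 2, n_blocks <= K)
  # prefactor of the jackknife variance formula is identically 1
  B <- n_blocks
  stopifnot(isTRUE(all.equal(((K - K / B) / (K / B)) * (1 / (B - 1)), 1)))

  # contiguous near-equal blocks, snapped to LD-block boundaries
  targets <- round(seq_len(n_blocks - 1) * K / n_blocks)
  if ("block" %in% names(profile)) {
    ends <- cumsum(rle(profile$block)$lengths) # LD-block end indices
    targets <- vapply(targets, function(t) ends[which.min(abs(ends - t))], 0)
    targets <- unique(pmin(targets, K - 1))
  }
  bounds_idx <- c(0, targets, K)
  jk_block <- rep(seq_len(length(bounds_idx) - 1), diff(bounds_idx))
  n_blocks_eff <- max(jk_block)

  theta <- fit$theta_hat
  free <- free_param_names()
  bounds <- free_param_bounds()
  spec <- fit$spec
  centers_full <- attr(profile, "centers")

  # leave-one-out deviations are small, so both the centre and the
  # leave-out optima are resolved at a tight tolerance; otherwise the
  # optimizer's stopping noise, not the data, drives the variance
  refit <- function(keep, warm, factr = 1e5) {
    sub_paired <- paired[keep, ]
    sub_prof <- profile[keep, ]
    attr(sub_prof, "centers") <- centers_full
    prep <- prepare_likelihood_data(sub_paired, sub_prof)
    obj <- function(par) {
      if (abs(par[5] * par[6]) >= 0.999) return(-1e15)
      cpp_loglik_pair(sub_paired$beta_x, sub_paired$beta_y, prep$weight,
                      prep$bin0, prep$centers$pi_c, prep$centers$sigma_c,
                      theta$pi_x, theta$pi_y, theta$pi_u,
                      par[1], par[2], par[3], par[4], par[5], par[6],
                      theta$i_x, theta$i_y, par[7],
                      theta$n_x, theta$n_y, theta$M,
                      spec$n, spec$half_width[1], spec$half_width[2],
                      spec$floor_log)
    }
    starts <- rbind(warm,
                    as.matrix(make_starts(n_fallback_starts,
                                          anchors = fit$anchors)))
    for (s in seq_len(nrow(starts))) {
      res <- tryCatch(
        optim(starts[s, ], obj, method = "L-BFGS-B",
              lower = bounds$lower, upper = bounds$upper,
              control = list(fnscale = -1, maxit = 1000, factr = factr)),
        error = function(e) NULL)
      if (!is.null(res) && res$convergence == 0)
        return(setNames(res$par, free))
    }
    NULL
  }

  # polish the full-data optimum to the same tolerance as the refits
  warm <- refit(seq_len(K), unlist(theta[free]))
  if (is.null(warm)) warm <- unlist(theta[free])
  theta <- set_free_params(theta, warm)

  rows <- purrr::map(seq_len(n_blocks_eff), function(b) {
    est <- refit(which(jk_block != b), warm)
    if (is.null(est)) return(NULL)
    dplyr::bind_cols(tibble::tibble(block = b), tibble::as_tibble(as.list(est)))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    message(dropped, " leave-one-out fit(s) failed to converge and were ",
            "dropped; the variance is rescaled accordingly")
  leaveout <- dplyr::bind_rows(rows)
  if (nrow(leaveout) < 2)
    stop("too few leave-one-out fits converged", call. = FALSE)

  est_mat <- as.matrix(leaveout[, free])
  # drop-correction: scale the sum of squares up to the planned block count
  scale_fac <- n_blocks_eff / nrow(leaveout)
  se <- jackknife_se(est_mat, warm) * sqrt(scale_fac)
  z <- warm / se
  p <- 2 * pnorm(-abs(z))
  p[se == 0] <- 0 # degenerate: all leave-outs identical

  structure(list(theta_hat = theta, leaveout = leaveout,
                 se = se, p_values = p,
                 n_blocks = n_blocks_eff, degenerate = any(se == 0)),
            class = "lhc_jackknife")
}

# Block-jackknife SE: sqrt of the summed squared deviations of the
# leave-one-out estimates from the full-data estimate (the prefactor of
# the jackknife variance identity is 1 for any block count).
jackknife_se <- function(leaveout_mat, center) {
  sqrt(colSums(sweep(leaveout_mat, 2, center)^2))
}

#' @export
print.lhc_jackknife <- function(x, ...) {
  cat(sprintf("<lhc_jackknife> %d blocks\n", x$n_blocks))
  print(tibble::tibble(term = names(x$se),
                       estimate = unlist(x$theta_hat[names(x$se)]),
                       se = x$se, p = x$p_values))
  invisible(x)
}

#' Wald tests with Bonferroni control
#'
#' Two-sided normal (Z-) tests of each jackknifed parameter against zero,
#' flagged at the Bonferroni-corrected level `0.05 / n_tests` (e.g. 156
#' tests for 13 traits in both directions gives a threshold of 3.2e-4).
#'
#' @param jk An `lhc_jackknife` object.
#' @param n_tests Number of tests for the Bonferroni correction (default:
#'   the number of parameters tested).
#' @return A tibble `term, estimate, se, z, p, significant`.
#' @export
wald_tests <- function(jk, n_tests = length(jk$se)) {
  est <- unlist(jk$theta_hat[names(jk$se)])
  z <- ifelse(jk$se > 0, est / jk$se, Inf)
  p <- ifelse(jk$se > 0, 2 * pnorm(-abs(z)), 0)
  tibble::tibble(term = names(jk$se), estimate = unname(est),
                 se = unname(jk$se), z = unname(z), p = unname(p),
                 significant = unname(p) < 0.05 / n_tests)
}

#' Genetic correlation implied by the model parameters
#'
#' Ratio of the two traits' total genetic covariance to the geometric mean
#' of their total genetic variances, in terms of the fitted parameters
#' (with `h = sqrt(h2)`):
#' \deqn{r_g = \frac{(t_x + a_{yx} t_y)(t_y + a_{xy} t_x) + a_{yx} h_y^2 +
#'   a_{xy} h_x^2}{\sqrt{((t_x + a_{yx} t_y)^2 + a_{yx}^2 h_y^2 + h_x^2)
#'   ((t_y + a_{xy} t_x)^2 + a_{xy}^2 h_x^2 + h_y^2)}}}
#'
#' @param theta An [lhc_params()] object.
#' @return The genetic correlation, in \[-1, 1\].
#' @export
rg_from_params <- function(theta) {
  p <- theta
  Tx <- p$t_x + p$alpha_yx * p$t_y
  Ty <- p$t_y + p$alpha_xy * p$t_x
  vx <- Tx^2 + p$alpha_yx^2 * p$h2_y + p$h2_x
  vy <- Ty^2 + p$alpha_xy^2 * p$h2_x + p$h2_y
  if (vx <= 0 || vy <= 0)
    stop("zero total genetic variance; genetic correlation undefined",
         call. = FALSE)
  (Tx * Ty + p$alpha_yx * p$h2_y + p$alpha_xy * p$h2_x) / sqrt(vx * vy)
}

#' Decompose the genetic correlation into confounder- and causal-led parts
#'
#' Splits the genetic-covariance numerator into the confounder-led term
#' `(t_x + a_yx t_y)(t_y + a_xy t_x)` and the causal-led term
#' `a_yx h_y^2 + a_xy h_x^2`, each normalised by the same denominator, so
#' the two components sum exactly to the total genetic correlation.
#'
#' @param theta An [lhc_params()] object.
#' @return A tibble `confounder, causal, total` (one row).
#' @export
decompose_rg <- function(theta) {
  p <- theta
  Tx <- p$t_x + p$alpha_yx * p$t_y
  Ty <- p$t_y + p$alpha_xy * p$t_x
  vx <- Tx^2 + p$alpha_yx^2 * p$h2_y + p$h2_x
  vy <- Ty^2 + p$alpha_xy^2 * p$h2_x + p$h2_y
  if (vx <= 0 || vy <= 0)
    stop("zero total genetic variance; genetic correlation undefined",
         call. = FALSE)
  den <- sqrt(vx * vy)
  confounder <- Tx * Ty / den
  causal <- (p$alpha_yx * p$h2_y + p$alpha_xy * p$h2_x) / den
  tibble::tibble(confounder = confounder, causal = causal,
                 total = confounder + causal)
}
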