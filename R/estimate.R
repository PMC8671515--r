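#' Step 1: single-trait fit of polygenicity, total heritability and intercept
#'
#' Maximises the single-trait composite likelihood over `pi` (searched on a
#' log10 scale in \[1e-5, 1\]), total heritability `h2` in \[0, 1\] and
#' intercept `i` in (0, 3\], from multiple uniform starting points
#' (log-uniform for `pi`). The fitted `pi` and `i` are frozen for the
#' two-trait fit of step 2; `h2` anchors (but is re-estimated in) step 2,
#' where it becomes the direct heritability.
#'
#' @param betas Marginal effect estimates of the trait.
#' @param profile Binned LD-profile tibble aligned with `betas`.
#' @param n Sample size.
#' @param M Number of markers.
#' @param n_starts Number of starting points (default 20).
#' @param seed Optional seed for the starting points.
#' @param spec Optional grid specification.
#' @return A list `pi, h2, i, loglik, per_start` (tibble of all starts).
#' @export
fit_single_trait <- function(betas, profile, n, M, n_starts = 20,
                             seed = NULL, spec = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!("bin" %in% names(profile))) profile <- make_bins(profile)
  obj <- function(par) {
    loglik_single(10^par[1], par[2], par[3], betas, profile, n, M,
                  spec = spec)
  }
  starts <- cbind(l10pi = runif(n_starts, -5, 0),
                  h2 = runif(n_starts, 0, 1),
                  i = runif(n_starts, 0.01, 3))
  rows <- purrr::map(seq_len(n_starts), function(s) {
    fit <- tryCatch(
      optim(starts[s, ], obj, method = "L-BFGS-B",
            lower = c(-5, 0, 1e-3), upper = c(0, 1, 3),
            control = list(fnscale = -1, maxit = 500, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(start = s, converged = FALSE, loglik = -Inf,
                            pi = NA_real_, h2 = NA_real_, i = NA_real_))
    }
    tibble::tibble(start = s, converged = fit$convergence == 0,
                   loglik = fit$value, pi = 10^fit$par[1],
                   h2 = fit$par[2], i = fit$par[3])
  })
  per_start <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(per_start, .data$converged)
  if (nrow(ok) == 0) stop("no single-trait start converged", call. = FALSE)
  best <- ok[which.max(ok$loglik), ]
  list(pi = best$pi, h2 = best$h2, i = best$i, loglik = best$loglik,
       per_start = per_start)
}

#' Inverse-variance-weighted causal effect estimate
#'
#' Standard IVW ratio meta-analysis over instruments selected at
#' `p < p_thresh` for the exposure:
#' `alpha_hat = sum(beta_x beta_y / se_y^2) / sum(beta_x^2 / se_y^2)`.
#' Used as an initialization anchor for the likelihood fit (and as a
#' conventional-MR baseline).
#'
#' @param paired Paired summary-statistics tibble (exposure = x).
#' @param p_thresh Instrument selection p-value threshold (default 5e-6).
#' @return A list `alpha, se, n_instruments`; `alpha` is `NA` when no SNP
#'   passes the threshold.
#' @export
ivw_estimate <- function(paired, p_thresh = 5e-6) {
  z <- paired$beta_x / paired$se_x
  p <- 2 * pnorm(-abs(z))
  sel <- which(p < p_thresh)
  if (length(sel) == 0)
    return(list(alpha = NA_real_, se = NA_real_, n_instruments = 0L))
  bx <- paired$beta_x[sel]
  by <- paired$beta_y[sel]
  wy <- 1 / paired$se_y[sel]^2
  alpha <- sum(bx * by * wy) / sum(bx^2 * wy)
  se <- sqrt(1 / sum(bx^2 * wy))
  list(alpha = alpha, se = se, n_instruments = length(sel))
}

#' Cross-trait LD-score regression intercept
#'
#' Regresses `sqrt(n_x n_y) * beta_x * beta_y` on the restricted LD score
#' (`1/weight`); the intercept estimates `i_xy`, the sample-overlap-induced
#' correlation of the two traits' sampling noise. Used as a starting-point
#' anchor only.
#'
#' @param paired Paired summary-statistics tibble.
#' @param profile LD-profile tibble aligned with `paired`.
#' @param n_x,n_y Sample sizes (default: attributes of `paired`).
#' @return A list `intercept, slope`.
#' @export
crosstrait_intercept <- function(paired, profile,
                                 n_x = attr(paired, "n_x"),
                                 n_y = attr(paired, "n_y")) {
  ldscore <- 1 / profile$weight
  y <- sqrt(n_x * n_y) * paired$beta_x * paired$beta_y
  fit <- lm(y ~ ldscore, weights = profile$weight)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

#' Starting points for the two-trait likelihood maximisation
#'
#' Draws `n_starts` parameter vectors for the seven free step-2 parameters
#' uniformly within their ranges (`h2_x, h2_y, t_x` in \[0, 1\];
#' `t_y, alpha_xy, alpha_yx, i_xy` in \[-1, 1\]). When anchors are
#' supplied (IVW estimates of the two causal directions and the
#' cross-trait intercept), the corresponding coordinates are drawn as
#' anchor + U(-0.1, 0.1), clipped to range.
#'
#' @param n_starts Number of starting points (50 in the full protocol).
#' @param anchors Optional list with any of `ivw_xy`, `ivw_yx`, `i_xy`.
#' @param seed Optional seed.
#' @return A tibble of starting values, one row per start.
#' @export
make_starts <- function(n_starts, anchors = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anchored <- function(anchor, lo, hi) {
    if (is.null(anchor) || is.na(anchor))
      return(runif(n_starts, lo, hi))
    pmin(pmax(anchor + runif(n_starts, -0.1, 0.1), lo), hi)
  }
  tibble::tibble(
    h2_x = runif(n_starts, 0, 1),
    h2_y = runif(n_starts, 0, 1),
    t_x = runif(n_starts, 0, 1),
    t_y = runif(n_starts, -1, 1),
    alpha_xy = anchored(anchors$ivw_xy, -1, 1),
    alpha_yx = anchored(anchors$ivw_yx, -1, 1),
    i_xy = anchored(anchors$i_xy, -1, 1)
  )
}

#' Step 2: two-trait maximum-likelihood fit
#'
#' Maximises the bivariate composite likelihood over the seven free
#' parameters `h2_x, h2_y, t_x, t_y, alpha_xy, alpha_yx, i_xy` under their
#' box constraints, with `pi_x, i_x, pi_y, i_y` frozen at the step-1
#' estimates and `pi_u` fixed. Each starting point is optimised with
#' box-constrained quasi-Newton iterations (numerical gradients,
#' convergence tolerance 1e-6 on the log-likelihood, at most 500
#' iterations); the best converged optimum is selected, with near-ties
#' (within 1e-4) broken towards the smallest `|alpha_xy| + |alpha_yx|`.
#' The mirror optimum is computed and the primary solution labelled by the
#' direct-versus-indirect heritability rule (`h2_x > t_x^2`).
#'
#' @param paired Paired summary-statistics tibble.
#' @param profile Binned LD-profile tibble aligned with `paired`.
#' @param step1_x,step1_y Results of [fit_single_trait()] for each trait.
#' @param n_starts Number of starting points (default 50).
#' @param seed Optional seed for the starting points.
#' @param anchors Optional anchor list (see [make_starts()]); if `TRUE`
#'   (default), IVW and cross-trait-intercept anchors are computed from the
#'   data.
#' @param spec Optional grid specification.
#' @param pi_u Fixed confounder polygenicity (default 0.1).
#' @param n_x,n_y Sample sizes (default: attributes of `paired`).
#' @param M Number of genome-wide markers the model describes (defaults to
#'   the number of analysed SNPs; supply the pre-thinning count when the
#'   input was thinned).
#' @return An object of class `lhc_fit`.
#' @export
fit_pair <- function(paired, profile, step1_x, step1_y,
                     n_starts = 50, seed = NULL, anchors = TRUE,
                     spec = NULL, pi_u = 0.1,
                     n_x = attr(paired, "n_x"), n_y = attr(paired, "n_y"),
                     M = nrow(paired)) {
  stopifnot(!is.null(n_x), !is.null(n_y))
  if (!("bin" %in% names(profile))) profile <- make_bins(profile)
  spec <- spec %||% grid_spec(paired)
  prep <- prepare_likelihood_data(paired, profile)

  if (isTRUE(anchors)) {
    swapped <- paired
    swapped$beta_x <- paired$beta_y
    swapped$se_x <- paired$se_y
    swapped$beta_y <- paired$beta_x
    swapped$se_y <- paired$se_x
    anchors <- list(
      ivw_xy = ivw_estimate(paired)$alpha,
      ivw_yx = ivw_estimate(swapped)$alpha,
      i_xy = crosstrait_intercept(paired, profile, n_x, n_y)$intercept
    )
  } else if (identical(anchors, FALSE)) anchors <- NULL

  obj <- function(par) {
    if (abs(par[5] * par[6]) >= 0.999) return(-1e15)
    cpp_loglik_pair(paired$beta_x, paired$beta_y, prep$weight, prep$bin0,
                    prep$centers$pi_c, prep$centers$sigma_c,
                    step1_x$pi, step1_y$pi, pi_u,
                    par[1], par[2], par[3], par[4], par[5], par[6],
                    step1_x$i, step1_y$i, par[7],
                    n_x, n_y, M,
                    spec$n, spec$half_width[1], spec$half_width[2],
                    spec$floor_log)
  }
  bounds <- free_param_bounds()
  starts <- make_starts(n_starts, anchors = anchors, seed = seed)

  rows <- purrr::map(seq_len(n_starts), function(s) {
    par0 <- unlist(starts[s, ])
    fit <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(fnscale = -1, maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(dplyr::bind_cols(tibble::tibble(start = s, converged = FALSE,
                                             loglik = -Inf), starts[s, ]))
    }
    out <- tibble::as_tibble(as.list(setNames(fit$par, free_param_names())))
    dplyr::bind_cols(tibble::tibble(start = s,
                                    converged = fit$convergence == 0,
                                    loglik = fit$value), out)
  })
  per_start <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(per_start, .data$converged, is.finite(.data$loglik))
  if (nrow(ok) == 0) stop("no start converged", call. = FALSE)
  if (nrow(ok) < 0.2 * n_starts)
    warning("fewer than 20% of starting points converged")
  near <- ok[ok$loglik >= max(ok$loglik) - 1e-4, ]
  best <- near[which.min(abs(near$alpha_xy) + abs(near$alpha_yx)), ]

  theta_hat <- lhc_params(
    pi_x = step1_x$pi, pi_y = step1_y$pi,
    h2_x = best$h2_x, h2_y = best$h2_y, t_x = best$t_x, t_y = best$t_y,
    alpha_xy = best$alpha_xy, alpha_yx = best$alpha_yx,
    i_x = step1_x$i, i_y = step1_y$i, i_xy = best$i_xy,
    n_x = n_x, n_y = n_y, M = M, pi_u = pi_u)
  mirror <- mirror_optimum(theta_hat)
  sel <- select_primary(theta_hat, mirror)

  structure(list(theta_hat = theta_hat, loglik = best$loglik,
                 per_start = per_start, mirror = mirror,
                 primary = sel$primary, primary_label = sel$label,
                 step1_x = step1_x[c("pi", "h2", "i")],
                 step1_y = step1_y[c("pi", "h2", "i")],
                 anchors = anchors, spec = spec,
                 n_snps = nrow(paired),
                 exposure_h2_reliable = step1_x$h2 >= 0.025),
            class = "lhc_fit")
}

#' Mirror optimum of the latent-confounder model
#'
#' The model admits a second parameter set with an equivalent fit in which
#' the exposure's direct genetic axis and the confounder axis are
#' interchanged: with `Tx = t_x + alpha_yx t_y`, `Ty = t_y + alpha_xy t_x`,
#' `D = 1 - alpha_xy alpha_yx` and `h = sqrt(h2)`, the transformed
#' parameters are `alpha_xy' = Ty/Tx`, `alpha_yx' = alpha_yx`,
#' `h_x' = Tx D'/D`, `h_y' = h_y D'/D` (with `D' = 1 - alpha_xy'
#' alpha_yx'`), `t_x' = h_x` and `t_y' = -h_x t_y / Tx`. The map is an
#' involution and exactly preserves the model-implied distribution of the
#' summary statistics (for matching polygenicity of the swapped
#' components); with no reverse causal effect it reduces to the simpler
#' textbook form `h_x' = t_x`, `t_x' = h_x`, `t_y' = -h_x t_y / t_x`,
#' `alpha_xy' = alpha_xy + t_y/t_x`.
#'
#' @param theta An [lhc_params()] object (the selected optimum).
#' @return The transformed `lhc_params`, or `NULL` when `t_x = 0` (the map
#'   is undefined) or any transformed parameter leaves its allowed range
#'   (the mirror can then be excluded automatically).
#' @export
mirror_optimum <- function(theta) {
  p <- theta
  if (p$t_x == 0) return(NULL)
  Tx <- p$t_x + p$alpha_yx * p$t_y
  Ty <- p$t_y + p$alpha_xy * p$t_x
  if (abs(Tx) < 1e-12) return(NULL)
  D <- 1 - p$alpha_xy * p$alpha_yx
  axy2 <- Ty / Tx
  ayx2 <- p$alpha_yx
  D2 <- 1 - axy2 * ayx2
  hx <- sqrt(p$h2_x)
  hx2new <- Tx * D2 / D
  hy2new <- sqrt(p$h2_y) * D2 / D
  cand <- list(pi_x = p$pi_x, pi_y = p$pi_y,
               h2_x = hx2new^2, h2_y = hy2new^2,
               t_x = hx, t_y = -hx * p$t_y / Tx,
               alpha_xy = axy2, alpha_yx = ayx2,
               i_x = p$i_x, i_y = p$i_y, i_xy = p$i_xy,
               n_x = p$n_x, n_y = p$n_y, M = p$M, pi_u = p$pi_u)
  in_range <- hx2new >= 0 && hy2new >= 0 && cand$h2_x <= 1 &&
    cand$h2_y <= 1 && cand$t_x <= 1 && abs(cand$t_y) <= 1 &&
    abs(cand$alpha_xy) <= 1 && abs(cand$alpha_xy * cand$alpha_yx) < 1
  if (!in_range) return(NULL)
  do.call(lhc_params, cand)
}

#' Label the primary solution among the two model optima
#'
#' Of the two equivalent optima, the one whose direct heritability of the
#' exposure exceeds its confounder-driven (indirect) heritability
#' (`h2_x > t_x^2`) is called primary; the other is the alternative. When
#' the mirror leaves the allowed parameter ranges the fitted optimum is
#' primary by default.
#'
#' @param theta Fitted optimum (`lhc_params`).
#' @param mirror Mirror optimum or `NULL`.
#' @return A list `primary` (the selected `lhc_params`) and `label` (one of
#'   `"primary"`, `"alternative"`, `"mirror_out_of_range"`), where the
#'   label describes the fitted optimum `theta`.
#' @export
select_primary <- function(theta, mirror) {
  if (is.null(mirror))
    return(list(primary = theta, label = "mirror_out_of_range"))
  if (theta$h2_x > theta$t_x^2)
    return(list(primary = theta, label = "primary"))
  if (mirror$h2_x > mirror$t_x^2)
    return(list(primary = mirror, label = "alternative"))
  list(primary = theta, label = "primary")
}

#' Full two-step latent-confounder MR analysis
#'
#' Runs the complete pipeline on a harmonized pair of summary-statistics
#' tables: step-1 single-trait fits for both traits (polygenicity, total
#' heritability, intercept), IVW and cross-trait-intercept anchors, the
#' step-2 seven-parameter likelihood maximisation with multiple starts,
#' the mirror optimum and primary-solution labelling.
#'
#' Exposures with estimated total heritability below 2.5% are flagged: the
#' outgoing causal effect of a barely heritable exposure should not be
#' interpreted.
#'
#' @param paired Paired summary-statistics tibble from [harmonize_pair()]
#'   or [simulate_pair()].
#' @param profile LD-profile tibble aligned with `paired`.
#' @param n_starts Step-2 starting points (default 50).
#' @param n_starts_single Step-1 starting points (default 20).
#' @param seed Seed for all starting-point draws.
#' @param anchors Use IVW/LDSC anchors (default `TRUE`)?
#' @param pi_u Fixed confounder polygenicity (default 0.1).
#' @param n_x,n_y Sample sizes (default: attributes of `paired`).
#' @param M Number of genome-wide markers (defaults to the number of
#'   analysed SNPs).
#' @return An object of class `lhc_fit` (see [fit_pair()]).
#' @export
#' @examples
#' \donttest{
#' ld <- synth_ld_blocks(M = 2000, block_size = 25, rho_decay = 0.8)
#' sim <- simulate_pair(sim_preset("standard", M = 2000, seed = 7), ld)
#' prof <- make_bins(ld_profile(ld))
#' fit <- lhc_mr(sim$sumstats, prof, n_starts = 3, n_starts_single = 5,
#'               seed = 1)
#' tidy(fit)
#' }
lhc_mr <- function(paired, profile, n_starts = 50, n_starts_single = 20,
                   seed = 1, anchors = TRUE, pi_u = 0.1,
                   n_x = attr(paired, "n_x"), n_y = attr(paired, "n_y"),
                   M = nrow(paired)) {
  stopifnot(!is.null(n_x), !is.null(n_y))
  if (!("bin" %in% names(profile))) profile <- make_bins(profile)
  set.seed(seed)
  s1x <- fit_single_trait(paired$beta_x, profile, n_x, M,
                          n_starts = n_starts_single)
  s1y <- fit_single_trait(paired$beta_y, profile, n_y, M,
                          n_starts = n_starts_single)
  fit <- fit_pair(paired, profile, s1x, s1y, n_starts = n_starts,
                  anchors = anchors, pi_u = pi_u, n_x = n_x, n_y = n_y,
                  M = M)
  fit
}
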