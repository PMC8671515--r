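#' Simulation settings for the structural model
#'
#' Collects every generative knob of the bivariate latent-confounder model:
#' polygenicities and direct heritabilities of the two traits and the
#' confounder, confounder-to-trait effects `q_x`, `q_y`, bi-directional
#' causal effects, sample sizes and overlap, effect-size kurtosis, an
#' optional second confounder and an optional three-component architecture
#' for the exposure.
#'
#' Per-SNP slab variances are derived as `sigma^2 = h2 / (M * pi)` so the
#' stated heritabilities are preserved at any `M`. Trait-scale error
#' variances are solved so every trait has unit variance; settings for
#' which that is impossible are rejected.
#'
#' @param M Number of markers.
#' @param n_x,n_y GWAS sample sizes.
#' @param n_overlap Number of individuals in both samples (default 0).
#' @param r_xy Phenotypic correlation of X and Y among overlapping
#'   individuals (default 0).
#' @param pi_x,pi_y,pi_u Polygenicities in (0, 1] (`pi = 0` is accepted and
#'   yields an all-zero effect vector).
#' @param h2_x,h2_y,h2_u Direct heritabilities in \[0, 1).
#' @param q_x,q_y Causal effects of the confounder on X and Y.
#' @param alpha_xy,alpha_yx Causal effects X->Y and Y->X.
#' @param kurtosis `"normal"` or a numeric kurtosis (>= 1.8) for the
#'   symmetric Pearson-family slab distribution (3 = Gaussian).
#' @param second_confounder Optional `list(pi =, h2 =, q_x =, q_y =)` adding
#'   an independent second confounder.
#' @param three_component_x Optional `list(pi_x1 =, pi_x2 =, h2_x1 =,
#'   h2_x2 =)` replacing X's spike-and-slab with a three-component mixture
#'   (null plus two slabs).
#' @param seed Integer seed fixing the whole generation.
#' @return An object of class `lhc_sim_settings`.
#' @export
sim_settings <- function(M = 234000, n_x = 50000, n_y = 50000,
                         n_overlap = 0, r_xy = 0,
                         pi_x = 5e-3, pi_y = 1e-2, pi_u = 5e-2,
                         h2_x = 0.25, h2_y = 0.2, h2_u = 0.3,
                         q_x = 0.3, q_y = 0.2,
                         alpha_xy = 0.3, alpha_yx = 0,
                         kurtosis = "normal",
                         second_confounder = NULL,
                         three_component_x = NULL,
                         seed = 1L) {
  stopifnot(M >= 1, n_x >= 1, n_y >= 1, n_overlap >= 0,
            n_overlap <= min(n_x, n_y), abs(r_xy) <= 1,
            pi_x >= 0, pi_x <= 1, pi_y >= 0, pi_y <= 1, pi_u >= 0, pi_u <= 1,
            h2_x >= 0, h2_x < 1, h2_y >= 0, h2_y < 1, h2_u >= 0, h2_u < 1,
            abs(alpha_xy * alpha_yx) < 1)
  if (!identical(kurtosis, "normal")) {
    stopifnot(is.numeric(kurtosis), kurtosis >= 1.8)
  }
  structure(list(M = as.numeric(M), n_x = as.numeric(n_x),
                 n_y = as.numeric(n_y), n_overlap = as.numeric(n_overlap),
                 r_xy = r_xy, pi_x = pi_x, pi_y = pi_y, pi_u = pi_u,
                 h2_x = h2_x, h2_y = h2_y, h2_u = h2_u,
                 q_x = q_x, q_y = q_y,
                 alpha_xy = alpha_xy, alpha_yx = alpha_yx,
                 kurtosis = kurtosis,
                 second_confounder = second_confounder,
                 three_component_x = three_component_x,
                 seed = as.integer(seed)),
            class = "lhc_sim_settings")
}

#' Named simulation scenario presets
#'
#' Returns the exact parameter bundles of the benchmark simulation
#' scenarios. The `standard` scenario uses 234,000 markers and two
#' non-overlapping cohorts of 50,000, moderate polygenicity
#' (`pi_x = 5e-3, pi_y = 1e-2, pi_u = 5e-2`), direct heritabilities
#' `h2_x = 0.25, h2_y = 0.2, h2_u = 0.3`, confounding `q_x = 0.3,
#' q_y = 0.2` (so `t_x = 0.16, t_y = 0.11`) and a causal effect
#' `alpha_xy = 0.3` with no reverse effect. Other presets modify it:
#'
#' * `no_causal`: `alpha_xy = 0`.
#' * `no_confounder`: `q_x = q_y = 0`.
#' * `small_alpha`: `alpha_xy = 0.1`.
#' * `reverse_causal`: adds `alpha_yx = -0.1`.
#' * `strong_confounder`: `q_x = 0.75, q_y = 0.50`.
#' * `opposite_confounder`: `q_x = 0.3, q_y = -0.2`.
#' * `two_conf_concordant` / `two_conf_discordant`: second confounder with
#'   `t_x2 = 0.22` and `t_y2 = 0.16` / `-0.16` (q's back-solved with
#'   `h2_u = 0.3`).
#' * `high_polygenicity`: `pi_x, pi_y, pi_u = 0.1, 0.15, 0.2`.
#' * `low_piu`: `pi_u = 0.01`.
#' * `kurtosis_2`, `kurtosis_3`, `kurtosis_5`, `kurtosis_10`: non-Gaussian
#'   slab distributions of the stated kurtosis.
#' * `three_component`: third effect component for X (`pi_x1 = 1e-4,
#'   pi_x2 = 1e-2, h2_x1 = 0.15, h2_x2 = 0.1`) with `pi_u = 0.01`.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [sim_settings()] (e.g. `M`, `n_x`, `seed`).
#' @return An `lhc_sim_settings` object.
#' @export
sim_preset <- function(name, ...) {
  base <- list()
  mods <- switch(
    name,
    standard = list(),
    no_causal = list(alpha_xy = 0),
    no_confounder = list(q_x = 0, q_y = 0),
    small_alpha = list(alpha_xy = 0.1),
    reverse_causal = list(alpha_yx = -0.1),
    strong_confounder = list(q_x = 0.75, q_y = 0.50),
    opposite_confounder = list(q_x = 0.3, q_y = -0.2),
    two_conf_concordant = list(second_confounder = list(
      pi = 5e-2, h2 = 0.3, q_x = 0.22 / sqrt(0.3), q_y = 0.16 / sqrt(0.3))),
    two_conf_discordant = list(second_confounder = list(
      pi = 5e-2, h2 = 0.3, q_x = 0.22 / sqrt(0.3), q_y = -0.16 / sqrt(0.3))),
    high_polygenicity = list(pi_x = 0.1, pi_y = 0.15, pi_u = 0.2),
    low_piu = list(pi_u = 0.01),
    kurtosis_2 = list(kurtosis = 2),
    kurtosis_3 = list(kurtosis = 3),
    kurtosis_5 = list(kurtosis = 5),
    kurtosis_10 = list(kurtosis = 10),
    three_component = list(three_component_x = list(
      pi_x1 = 1e-4, pi_x2 = 1e-2, h2_x1 = 0.15, h2_x2 = 0.1), pi_u = 0.01),
    stop("unknown preset: ", name, call. = FALSE)
  )
  do.call(sim_settings, utils::modifyList(c(base, mods), list(...)))
}

# Draw n slab effects with variance sigma2 from the symmetric
# Pearson-family member of the requested kurtosis (type II below 3,
# Gaussian at 3, type VII above 3).
draw_slab <- function(n, sigma2, kurtosis) {
  if (sigma2 == 0 || n == 0) return(numeric(n))
  if (identical(kurtosis, "normal") || isTRUE(all.equal(kurtosis, 3)))
    return(rnorm(n, 0, sqrt(sigma2)))
  if (kurtosis > 3) {
    df <- 4 + 6 / (kurtosis - 3)
    return(rt(n, df) * sqrt(sigma2 * (df - 2) / df))
  }
  if (kurtosis <= 1) stop("kurtosis must exceed 1", call. = FALSE)
  # symmetric beta: kurtosis = 3 - 6/(2b + 3)
  b <- (6 / (3 - kurtosis) - 3) / 2
  a <- sqrt(sigma2 * (2 * b + 1))
  a * (2 * rbeta(n, b, b) - 1)
}

#' Draw per-SNP direct effect vectors
#'
#' Samples the spike-and-slab direct effects of the two traits and the
#' confounder(s): slab membership indicators are independent Bernoulli
#' draws with the trait's polygenicity, slab effects have variance
#' `h2 / (M * pi)` and are Gaussian unless a non-Gaussian kurtosis is
#' requested. The optional three-component architecture assigns each
#' marker to at most one of two slab components for X.
#'
#' @param settings An `lhc_sim_settings` object (`settings$seed` fixes the
#'   draw).
#' @return A list with effect vectors `gamma_x, gamma_y, gamma_u` (and
#'   `gamma_u2` when a second confounder is present) and indicator vectors
#'   `zeta_x, zeta_y, zeta_u` (`zeta_x` holds component labels 0/1/2 under
#'   the three-component architecture).
#' @export
draw_effects <- function(settings) {
  s <- settings
  set.seed(s$seed)
  draw_one <- function(pi, h2) {
    zeta <- rbinom(s$M, 1L, pi)
    gamma <- numeric(s$M)
    nz <- which(zeta == 1L)
    if (pi > 0 && h2 > 0)
      gamma[nz] <- draw_slab(length(nz), h2 / (s$M * pi), s$kurtosis)
    list(zeta = zeta, gamma = gamma)
  }
  if (is.null(s$three_component_x)) {
    ex <- draw_one(s$pi_x, s$h2_x)
  } else {
    tc <- s$three_component_x
    u <- runif(s$M)
    comp <- ifelse(u < tc$pi_x1, 1L, ifelse(u < tc$pi_x1 + tc$pi_x2, 2L, 0L))
    gamma <- numeric(s$M)
    gamma[comp == 1L] <- draw_slab(sum(comp == 1L),
                                   tc$h2_x1 / (s$M * tc$pi_x1), s$kurtosis)
    gamma[comp == 2L] <- draw_slab(sum(comp == 2L),
                                   tc$h2_x2 / (s$M * tc$pi_x2), s$kurtosis)
    ex <- list(zeta = comp, gamma = gamma)
  }
  ey <- draw_one(s$pi_y, s$h2_y)
  eu <- draw_one(s$pi_u, s$h2_u)
  out <- list(gamma_x = ex$gamma, gamma_y = ey$gamma, gamma_u = eu$gamma,
              zeta_x = ex$zeta, zeta_y = ey$zeta, zeta_u = eu$zeta)
  if (!is.null(s$second_confounder)) {
    sc <- s$second_confounder
    eu2 <- draw_one(sc$pi, sc$h2)
    out$gamma_u2 <- eu2$gamma
    out$zeta_u2 <- eu2$zeta
  }
  out
}

# Solve the trait-scale error variances (nu_x^2, nu_y^2) so that
# Var(X) = Var(Y) = 1, and return the implied noise parameters.
solve_error_variances <- function(s) {
  D <- 1 - s$alpha_xy * s$alpha_yx
  confs <- list(list(h2 = s$h2_u, q_x = s$q_x, q_y = s$q_y))
  if (!is.null(s$second_confounder))
    confs <- c(confs, list(s$second_confounder))
  cu_x <- vapply(confs, function(cf) (cf$q_x + s$alpha_yx * cf$q_y) / D, 0)
  cu_y <- vapply(confs, function(cf) (cf$q_y + s$alpha_xy * cf$q_x) / D, 0)
  h2u <- vapply(confs, function(cf) cf$h2, 0)
  nu2_u <- 1 - h2u
  h2x_tot <- if (is.null(s$three_component_x)) s$h2_x else
    s$three_component_x$h2_x1 + s$three_component_x$h2_x2
  gx <- sum(cu_x^2 * h2u) + (s$alpha_yx / D)^2 * s$h2_y + (1 / D)^2 * h2x_tot
  gy <- sum(cu_y^2 * h2u) + (s$alpha_xy / D)^2 * h2x_tot + (1 / D)^2 * s$h2_y
  A <- D^2 * (1 - gx) - sum((cu_x * D)^2 * nu2_u)
  B <- D^2 * (1 - gy) - sum((cu_y * D)^2 * nu2_u)
  det <- 1 - s$alpha_yx^2 * s$alpha_xy^2
  nu2_x <- (A - s$alpha_yx^2 * B) / det
  nu2_y <- (B - s$alpha_xy^2 * A) / det
  if (nu2_x < 0 || nu2_y < 0)
    stop("total trait variance exceeds 1; reduce heritabilities or effects",
         call. = FALSE)
  i_x <- (nu2_x + s$alpha_yx^2 * nu2_y + sum((cu_x * D)^2 * nu2_u)) / D^2
  i_y <- (nu2_y + s$alpha_xy^2 * nu2_x + sum((cu_y * D)^2 * nu2_u)) / D^2
  list(nu2_x = nu2_x, nu2_y = nu2_y, i_x = i_x, i_y = i_y,
       i_xy = s$r_xy * s$n_overlap / sqrt(s$n_x * s$n_y))
}

# Multiply effect vectors by the block-diagonal LD (z = R gamma), batched
# over identical blocks.
ld_multiply <- function(blocks, gamma) {
  z <- numeric(length(gamma))
  len_all <- blocks$end - blocks$start + 1
  groups <- split(seq_along(blocks$start), paste(blocks$rho, len_all))
  for (g in groups) {
    len <- len_all[g[1]]
    R <- blocks$rho[g[1]]^abs(outer(seq_len(len), seq_len(len), "-"))
    idx <- unlist(lapply(g, function(b) blocks$start[b]:blocks$end[b]))
    G <- matrix(gamma[idx], nrow = len)
    z[idx] <- as.vector(R %*% G)
  }
  z
}

# Draw LD-correlated bivariate noise: within a block the (eta_x, eta_y)
# vectors have covariance Sigma2 (x) R_block.
draw_noise <- function(blocks, Sigma2, correlated = TRUE) {
  M <- blocks$M
  E <- matrix(rnorm(2 * M), ncol = 2)
  if (correlated) {
    len_all <- blocks$end - blocks$start + 1
    groups <- split(seq_along(blocks$start), paste(blocks$rho, len_all))
    for (g in groups) {
      len <- len_all[g[1]]
      if (len == 1 || blocks$rho[g[1]] == 0) next
      R <- blocks$rho[g[1]]^abs(outer(seq_len(len), seq_len(len), "-"))
      L <- t(chol(R))
      idx <- unlist(lapply(g, function(b) blocks$start[b]:blocks$end[b]))
      E[idx, 1] <- as.vector(L %*% matrix(E[idx, 1], nrow = len))
      E[idx, 2] <- as.vector(L %*% matrix(E[idx, 2], nrow = len))
    }
  }
  E %*% chol(Sigma2)
}

#' Simulate paired GWAS summary statistics under the structural model
#'
#' Generates marginal effect estimates for both traits directly at the
#' summary-statistic level: per-SNP genetic signals are the block-LD
#' products `z = R gamma` of the drawn direct effects, combined with the
#' confounder and causal loadings of the model, plus sampling noise that is
#' bivariate normal per SNP (variances `i_x/n_x`, `i_y/n_y`, covariance
#' `i_xy / sqrt(n_x n_y)` from sample overlap) and, by default, correlated
#' across SNPs of an LD block with the block's correlation structure.
#'
#' @param settings An `lhc_sim_settings` object.
#' @param ld An `lhc_ld_blocks` object covering `settings$M` SNPs.
#' @param correlated_noise Draw LD-correlated sampling noise? Default
#'   `TRUE`; `FALSE` gives independent per-SNP noise.
#' @return A list with:
#'   * `sumstats`: paired tibble (`snp, chr, pos, beta_x, se_x, beta_y,
#'     se_y`, attributes `n_x`, `n_y`),
#'   * `truth`: the implied [lhc_params()] (with `t = q * sqrt(h2_u)`, the
#'     model-scale intercepts and, as attributes, the total per-SNP effect
#'     vectors `delta_x`, `delta_y` and the second-confounder `t`s if any),
#'   * `effects`: the drawn effect vectors.
#' @export
simulate_pair <- function(settings, ld, correlated_noise = TRUE) {
  s <- settings
  stopifnot(inherits(ld, "lhc_ld_blocks"), ld$M == s$M)
  eff <- draw_effects(s) # seeds the RNG with s$seed
  ev <- solve_error_variances(s)
  D <- 1 - s$alpha_xy * s$alpha_yx

  z_x <- ld_multiply(ld, eff$gamma_x)
  z_y <- ld_multiply(ld, eff$gamma_y)
  z_u <- ld_multiply(ld, eff$gamma_u)

  bx <- ((s$q_x + s$alpha_yx * s$q_y) * z_u + s$alpha_yx * z_y + z_x) / D
  by <- ((s$q_y + s$alpha_xy * s$q_x) * z_u + s$alpha_xy * z_x + z_y) / D
  delta_x <- ((s$q_x + s$alpha_yx * s$q_y) * eff$gamma_u +
                s$alpha_yx * eff$gamma_y + eff$gamma_x) / D
  delta_y <- ((s$q_y + s$alpha_xy * s$q_x) * eff$gamma_u +
                s$alpha_xy * eff$gamma_x + eff$gamma_y) / D
  if (!is.null(s$second_confounder)) {
    sc <- s$second_confounder
    z_u2 <- ld_multiply(ld, eff$gamma_u2)
    bx <- bx + (sc$q_x + s$alpha_yx * sc$q_y) * z_u2 / D
    by <- by + (sc$q_y + s$alpha_xy * sc$q_x) * z_u2 / D
    delta_x <- delta_x + (sc$q_x + s$alpha_yx * sc$q_y) * eff$gamma_u2 / D
    delta_y <- delta_y + (sc$q_y + s$alpha_xy * sc$q_x) * eff$gamma_u2 / D
  }

  Sigma2 <- matrix(c(ev$i_x / s$n_x, ev$i_xy / sqrt(s$n_x * s$n_y),
                     ev$i_xy / sqrt(s$n_x * s$n_y), ev$i_y / s$n_y), 2)
  eta <- draw_noise(ld, Sigma2, correlated = correlated_noise)

  sumstats <- tibble::tibble(
    snp = sprintf("snp_%07d", seq_len(s$M)),
    chr = "1",
    pos = seq_len(s$M) * 1000L,
    beta_x = bx + eta[, 1], se_x = sqrt(ev$i_x / s$n_x),
    beta_y = by + eta[, 2], se_y = sqrt(ev$i_y / s$n_y)
  )
  attr(sumstats, "n_x") <- s$n_x
  attr(sumstats, "n_y") <- s$n_y

  truth <- lhc_params(
    pi_x = max(s$pi_x, 1e-12), pi_y = max(s$pi_y, 1e-12),
    h2_x = if (is.null(s$three_component_x)) s$h2_x else
      s$three_component_x$h2_x1 + s$three_component_x$h2_x2,
    h2_y = s$h2_y,
    t_x = abs(s$q_x) * sqrt(s$h2_u), t_y = s$q_y * sqrt(s$h2_u) *
      (if (s$q_x < 0) -1 else 1),
    alpha_xy = s$alpha_xy, alpha_yx = s$alpha_yx,
    i_x = ev$i_x, i_y = ev$i_y, i_xy = ev$i_xy,
    n_x = s$n_x, n_y = s$n_y, M = s$M,
    pi_u = max(s$pi_u, 1e-12)
  )
  attr(truth, "delta_x") <- delta_x
  attr(truth, "delta_y") <- delta_y
  if (!is.null(s$second_confounder)) {
    sc <- s$second_confounder
    attr(truth, "t_x2") <- sc$q_x * sqrt(sc$h2)
    attr(truth, "t_y2") <- sc$q_y * sqrt(sc$h2)
  }
  list(sumstats = sumstats, truth = truth, effects = eff)
}
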