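#' Characteristic function of one spike-and-slab signal component
#'
#' The genetic signal of a SNP for one trait is `z = rho' gamma`, a sum over
#' `M` markers of products of two independent spike-and-slab variables: the
#' local correlation (nonzero with probability `pi_k`, slab variance
#' `sigma_k^2`) and the direct effect (nonzero with probability `pi_trait`,
#' slab variance `sigma2_trait`). Each product term has the product-normal
#' characteristic function `(1 + sigma_k^2 sigma2_trait t^2)^(-1/2)` when
#' both factors are nonzero, giving the closed form
#' `phi_z(t) = exp(M * log1p(-pi_k pi_trait (1 - (1 + sigma_k^2
#' sigma2_trait t^2)^(-1/2))))`, real-valued and in (0, 1] because the
#' distribution is symmetric.
#'
#' @param t Real argument(s) of the characteristic function.
#' @param pi_k,sigma_k Spike-and-slab summary of the SNP's local LD.
#' @param pi_trait Trait polygenicity.
#' @param sigma2_trait Per-SNP slab variance of the trait's direct effects.
#' @param M Number of markers.
#' @return Numeric vector `phi_z(t)` (the imaginary part is identically 0).
#' @export
cf_signal_component <- function(t, pi_k, sigma_k, pi_trait, sigma2_trait, M) {
  stopifnot(pi_k >= 0, pi_k <= 1, pi_trait >= 0, pi_trait <= 1,
            sigma2_trait >= 0, M >= 1)
  if (pi_trait == 0 || sigma2_trait == 0) return(rep(1, length(t)))
  exp(M * log1p(-pi_k * pi_trait *
                  (1 - 1 / sqrt(1 + sigma_k^2 * sigma2_trait * t^2))))
}

#' Joint characteristic function of a SNP's paired effect estimates
#'
#' Product of the three signal-component characteristic functions
#' (confounder, X-direct, Y-direct) evaluated at the model's loading-
#' transformed arguments, times the bivariate Gaussian noise
#' characteristic function. The confounder component uses unit slab scale
#' (`h2 = 1`, i.e. slab variance `1/(M pi_u)`) with `(t_x, t_y)` as
#' loadings, absorbing the non-identifiable `sigma_u * q`
#' reparameterization.
#'
#' @param v,w Real arguments (vectors of equal length).
#' @param theta An [lhc_params()] object.
#' @param pi_k,sigma_k Local-LD summary of the SNP (or bin centre).
#' @return Numeric vector of the (real-valued) joint CF.
#' @export
cf_joint <- function(v, w, theta, pi_k, sigma_k) {
  p <- theta
  D <- 1 - p$alpha_xy * p$alpha_yx
  if (abs(D) < 1e-12) stop("|alpha_xy * alpha_yx| too close to 1",
                           call. = FALSE)
  arg_u <- (v * (p$t_x + p$alpha_yx * p$t_y) +
              w * (p$t_y + p$alpha_xy * p$t_x)) / D
  arg_x <- (v + p$alpha_xy * w) / D
  arg_y <- (w + p$alpha_yx * v) / D
  noise <- exp(-(p$i_x / p$n_x) * v^2 / 2 - (p$i_y / p$n_y) * w^2 / 2 -
                 (p$i_xy / sqrt(p$n_x * p$n_y)) * v * w)
  cf_signal_component(arg_u, pi_k, sigma_k, p$pi_u, 1 / (p$M * p$pi_u), p$M) *
    cf_signal_component(arg_x, pi_k, sigma_k, p$pi_x,
                        p$h2_x / (p$M * p$pi_x), p$M) *
    cf_signal_component(arg_y, pi_k, sigma_k, p$pi_y,
                        p$h2_y / (p$M * p$pi_y), p$M) *
    noise
}

#' Grid specification for FFT density inversion
#'
#' The density of `(beta_x, beta_y)` is evaluated on a `n x n` lattice
#' (2^7 by default) spanning `[-half_width, half_width]` per axis; the
#' characteristic function is sampled on the dual frequency lattice. The
#' default half-width is 8 robust standard deviations (median absolute
#' deviation about zero) of the observed estimates per trait. Densities
#' below `exp(floor_log)` are floored before taking logs.
#'
#' @param paired Paired summary-statistics tibble (used for default
#'   half-widths); may be `NULL` if `half_width` is given.
#' @param n Grid points per axis (default `2^7`).
#' @param half_width Numeric of length 2 (x, y) or 1 (both axes).
#' @param floor_log Log of the density floor (default `log(1e-30)`).
#' @param mult Half-width multiplier on the robust SD (default 8).
#' @return A list `n, half_width, floor_log`.
#' @export
grid_spec <- function(paired = NULL, n = 2^7, half_width = NULL,
                      floor_log = log(1e-30), mult = 8) {
  if (is.null(half_width)) {
    stopifnot(!is.null(paired))
    hw <- function(b) {
      s <- stats::mad(b, center = 0)
      if (s <= 0) s <- stats::sd(b)
      # cover the largest observed estimate: clipping the biggest effects
      # (the most informative SNPs) to the floor biases the heritability
      max(mult * s, 1.05 * max(abs(b)))
    }
    half_width <- c(hw(paired$beta_x), hw(paired$beta_y))
  }
  if (length(half_width) == 1) half_width <- rep(half_width, 2)
  list(n = as.integer(n), half_width = half_width, floor_log = floor_log)
}

#' Bivariate density grid by FFT inversion of the characteristic function
#'
#' Inverts the joint characteristic function on a regular `n x n` lattice
#' using the 2-D FFT, for one SNP bin (one `(pi_k, sigma_k)` pair). If more
#' than 1% of probability mass falls in the outermost grid ring, the grid
#' is widened (doubling the half-widths) with a warning.
#'
#' @param theta An [lhc_params()] object.
#' @param pi_k,sigma_k Bin-centre local-LD summary.
#' @param spec A [grid_spec()] list.
#' @return An object of class `lhc_pdf_grid`: list with axis point vectors
#'   `x`, `y`, matrix `log_density` (rows index x), spacings `dx`, `dy`
#'   and the floored density floor.
#' @export
pdf_grid <- function(theta, pi_k, sigma_k, spec) {
  for (attempt in 1:6) {
    N <- spec$n
    Lx <- spec$half_width[1]
    Ly <- spec$half_width[2]
    dx <- 2 * Lx / N
    dy <- 2 * Ly / N
    dv <- 2 * pi / (N * dx)
    dw <- 2 * pi / (N * dy)
    v <- (seq_len(N) - 1 - N / 2) * dv
    w <- (seq_len(N) - 1 - N / 2) * dw
    V <- matrix(v, N, N)
    W <- matrix(w, N, N, byrow = TRUE)
    phi <- matrix(cf_joint(as.vector(V), as.vector(W), theta, pi_k, sigma_k),
                  N, N)
    sgn <- outer((-1)^(seq_len(N) - 1), (-1)^(seq_len(N) - 1))
    f <- Re(stats::fft(phi * sgn)) * sgn * dv * dw / (4 * pi^2)
    f <- pmax(f, exp(spec$floor_log))
    ring <- c(f[1, ], f[N, ], f[, 1], f[, N])
    ring_mass <- sum(ring) * dx * dy # outer ring, counted once per cell side
    if (ring_mass <= 0.01) break
    warning("grid too narrow (boundary mass ", signif(ring_mass, 2),
            "); widening half-widths")
    spec$half_width <- spec$half_width * 2
  }
  structure(list(x = (seq_len(N) - 1 - N / 2) * dx,
                 y = (seq_len(N) - 1 - N / 2) * dy,
                 log_density = log(f), dx = dx, dy = dy,
                 floor_log = spec$floor_log),
            class = "lhc_pdf_grid")
}

# Bilinear interpolation of a log-density grid at points (px, py);
# points outside the grid get the floor.
interp_log_density <- function(grid, px, py) {
  N <- length(grid$x)
  gx <- (px - grid$x[1]) / grid$dx
  gy <- (py - grid$y[1]) / grid$dy
  j0 <- floor(gx)
  l0 <- floor(gy)
  inside <- j0 >= 0 & j0 < N - 1 & l0 >= 0 & l0 < N - 1
  out <- rep(grid$floor_log, length(px))
  if (any(inside)) {
    j <- j0[inside] + 1
    l <- l0[inside] + 1
    fx <- gx[inside] - j0[inside]
    fy <- gy[inside] - l0[inside]
    ld <- grid$log_density
    out[inside] <-
      (1 - fx) * (1 - fy) * ld[cbind(j, l)] +
      fx * (1 - fy) * ld[cbind(j + 1, l)] +
      (1 - fx) * fy * ld[cbind(j, l + 1)] +
      fx * fy * ld[cbind(j + 1, l + 1)]
  }
  out
}

# Align paired data with a binned LD profile; returns vectors for the
# likelihood backends (0-based bin index into the centers table).
prepare_likelihood_data <- function(paired, profile) {
  stopifnot(nrow(paired) == nrow(profile))
  if (!("bin" %in% names(profile))) profile <- make_bins(profile)
  if ("snp" %in% names(paired) && "snp" %in% names(profile) &&
      !all(paired$snp == profile$snp))
    stop("paired data and LD profile are not aligned (snp ids differ)",
         call. = FALSE)
  centers <- attr(profile, "centers")
  bin0 <- match(profile$bin, centers$bin) - 1L
  list(centers = centers, bin0 = bin0, weight = profile$weight)
}

#' Weighted composite log-likelihood of paired summary statistics
#'
#' Evaluates `sum_k w_k log f_k(beta_x_k, beta_y_k)` under parameters
#' `theta`: for each non-empty LD bin one density grid is built by FFT
#' inversion at the bin centre and each SNP's log-density is bilinearly
#' interpolated; estimates outside the grid contribute the floor density.
#'
#' @param theta An [lhc_params()] object.
#' @param paired Paired summary-statistics tibble.
#' @param profile Binned LD-profile tibble (rows aligned with `paired`;
#'   [make_bins()] is applied if the `bin` column is absent).
#' @param spec Optional [grid_spec()]; defaults to one derived from
#'   `paired`.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation; identical up to floating-point rounding).
#' @return The scalar weighted log-likelihood.
#' @export
loglik_pair <- function(theta, paired, profile, spec = NULL,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  spec <- spec %||% grid_spec(paired)
  prep <- prepare_likelihood_data(paired, profile)
  if (engine == "cpp") {
    ll <- cpp_loglik_pair(paired$beta_x, paired$beta_y, prep$weight,
                          prep$bin0, prep$centers$pi_c, prep$centers$sigma_c,
                          theta$pi_x, theta$pi_y, theta$pi_u,
                          theta$h2_x, theta$h2_y, theta$t_x, theta$t_y,
                          theta$alpha_xy, theta$alpha_yx,
                          theta$i_x, theta$i_y, theta$i_xy,
                          theta$n_x, theta$n_y, theta$M,
                          spec$n, spec$half_width[1], spec$half_width[2],
                          spec$floor_log)
  } else {
    ll <- 0
    for (b in seq_len(nrow(prep$centers))) {
      idx <- which(prep$bin0 == b - 1L)
      if (length(idx) == 0) next
      g <- suppressWarnings(
        pdf_grid(theta, prep$centers$pi_c[b], prep$centers$sigma_c[b], spec))
      ll <- ll + sum(prep$weight[idx] *
                       interp_log_density(g, paired$beta_x[idx],
                                          paired$beta_y[idx]))
    }
  }
  if (!is.finite(ll))
    stop("non-finite log-likelihood at the supplied parameters",
         call. = FALSE)
  ll
}

#' Single-trait composite log-likelihood
#'
#' One-dimensional analog of [loglik_pair()] for the simplified model with
#' only one trait and no confounder: `beta = z + eta` with
#' `eta ~ N(0, i/n)`. Used by the first estimation step to fit the trait's
#' polygenicity, total heritability and intercept.
#'
#' @param pi_t Trait polygenicity.
#' @param h2 Total heritability.
#' @param intercept LD-score intercept `i`.
#' @param betas Vector of marginal effect estimates.
#' @param profile Binned LD-profile tibble aligned with `betas`.
#' @param n Sample size.
#' @param M Number of markers.
#' @param spec Optional grid specification (half-width taken from the x
#'   axis entry).
#' @param engine `"cpp"` or `"r"`.
#' @return Scalar weighted log-likelihood.
#' @export
loglik_single <- function(pi_t, h2, intercept, betas, profile, n, M,
                          spec = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(spec)) {
    s <- stats::mad(betas, center = 0)
    if (s <= 0) s <- stats::sd(betas)
    spec <- list(n = 2L^7L,
                 half_width = rep(max(8 * s, 1.05 * max(abs(betas))), 2),
                 floor_log = log(1e-30))
  }
  if (!("bin" %in% names(profile))) profile <- make_bins(profile)
  centers <- attr(profile, "centers")
  bin0 <- match(profile$bin, centers$bin) - 1L
  if (engine == "cpp") {
    ll <- cpp_loglik_single(betas, profile$weight, bin0,
                            centers$pi_c, centers$sigma_c,
                            pi_t, h2, intercept, n, M,
                            spec$n, spec$half_width[1], spec$floor_log)
  } else {
    N <- spec$n
    L <- spec$half_width[1]
    dx <- 2 * L / N
    dv <- 2 * pi / (N * dx)
    v <- (seq_len(N) - 1 - N / 2) * dv
    sgn <- (-1)^(seq_len(N) - 1)
    xg <- (seq_len(N) - 1 - N / 2) * dx
    ll <- 0
    for (b in seq_len(nrow(centers))) {
      idx <- which(bin0 == b - 1L)
      if (length(idx) == 0) next
      phi <- cf_signal_component(v, centers$pi_c[b], centers$sigma_c[b],
                                 pi_t, if (pi_t > 0) h2 / (M * pi_t) else 0,
                                 M) * exp(-(intercept / n) * v^2 / 2)
      f <- pmax(Re(stats::fft(phi * sgn)) * sgn * dv / (2 * pi),
                exp(spec$floor_log))
      lf <- log(f)
      gx <- (betas[idx] - xg[1]) / dx
      j0 <- floor(gx)
      inside <- j0 >= 0 & j0 < N - 1
      vals <- rep(spec$floor_log, length(idx))
      fx <- gx[inside] - j0[inside]
      j <- j0[inside] + 1
      vals[inside] <- (1 - fx) * lf[j] + fx * lf[j + 1]
      ll <- ll + sum(profile$weight[idx] * vals)
    }
  }
  if (!is.finite(ll))
    stop("non-finite log-likelihood at the supplied parameters",
         call. = FALSE)
  ll
}
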