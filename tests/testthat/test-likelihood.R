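toy_theta <- function(...) {
  args <- utils::modifyList(
    list(pi_x = 5e-3, pi_y = 1e-2, h2_x = 0.25, h2_y = 0.2,
         t_x = 0.16, t_y = 0.11, alpha_xy = 0.3, alpha_yx = 0,
         i_x = 0.72, i_y = 0.75, i_xy = 0, n_x = 5e4, n_y = 5e4,
         M = 5e4, pi_u = 0.1),
    list(...))
  do.call(lhc_params, args)
}

test_that("signal-component CF has the right limits", {
  expect_equal(cf_signal_component(0, 0.1, 0.3, 0.01, 1e-3, 5000), 1)
  expect_equal(cf_signal_component(c(1, 5, 50), 0.1, 0.3, 0, 1e-3, 5000),
               rep(1, 3))
  phi <- cf_signal_component(seq(0, 100, by = 5), 0.1, 0.3, 0.01, 1e-3, 5000)
  expect_true(all(phi > 0 & phi <= 1))
  expect_true(all(diff(phi) <= 0)) # decreasing in |t| for symmetric z
})

test_that("closed-form CF matches the Monte-Carlo oracle", {
  set.seed(21)
  mc <- mc_cf_signal(c(1, 5, 10, 20), pi_k = 0.1, sigma_k = 0.1,
                     pi_t = 0.01, s2_t = 0.002, M = 5000)
  closed <- cf_signal_component(c(1, 5, 10, 20), 0.1, 0.1, 0.01, 0.002, 5000)
  expect_true(all(abs(closed - mc[1, ]) <= 3 * pmax(mc[2, ], 1e-7)))
})

test_that("joint CF reduces to the Gaussian noise CF without genetics", {
  th <- toy_theta(h2_x = 0, h2_y = 0, t_x = 0, t_y = 0, alpha_xy = 0,
                  i_xy = 0.2)
  expect_equal(cf_joint(0, 0, th, 1e-3, 0.3), 1)
  v <- c(50, 120)
  w <- c(-80, 30)
  expected <- exp(-(th$i_x / th$n_x) * v^2 / 2 -
                    (th$i_y / th$n_y) * w^2 / 2 -
                    (th$i_xy / sqrt(th$n_x * th$n_y)) * v * w)
  expect_equal(cf_joint(v, w, th, 1e-3, 0.3), expected, tolerance = 1e-12)
})

# Monte-Carlo draws from the model's own distribution of (beta_x, beta_y)
# for one LD bin: spike-and-slab local correlations, spike-and-slab direct
# effects, structural loadings and bivariate Gaussian noise.
mc_model_pairs <- function(th, pi_k, sigma_k, n_mc = 2e5) {
  draw_z <- function(pi_t, s2_t) {
    n_terms <- rbinom(n_mc, th$M, pi_k * pi_t)
    tot <- sum(n_terms)
    prods <- rnorm(tot, 0, sigma_k) * rnorm(tot, 0, sqrt(s2_t))
    z <- numeric(n_mc)
    idx <- rep.int(seq_len(n_mc), n_terms)
    if (tot > 0) {
      s <- tapply(prods, idx, sum)
      z[as.integer(names(s))] <- s
    }
    z
  }
  D <- 1 - th$alpha_xy * th$alpha_yx
  z_u <- draw_z(th$pi_u, 1 / (th$M * th$pi_u))
  z_x <- draw_z(th$pi_x, th$h2_x / (th$M * th$pi_x))
  z_y <- draw_z(th$pi_y, th$h2_y / (th$M * th$pi_y))
  Sig <- matrix(c(th$i_x / th$n_x, th$i_xy / sqrt(th$n_x * th$n_y),
                  th$i_xy / sqrt(th$n_x * th$n_y), th$i_y / th$n_y), 2)
  eta <- matrix(rnorm(2 * n_mc), ncol = 2) %*% chol(Sig)
  list(bx = ((th$t_x + th$alpha_yx * th$t_y) * z_u + z_x +
               th$alpha_yx * z_y) / D + eta[, 1],
       by = ((th$t_y + th$alpha_xy * th$t_x) * z_u + th$alpha_xy * z_x +
               z_y) / D + eta[, 2])
}

test_that("joint CF matches a Monte-Carlo oracle of the model", {
  set.seed(22)
  th <- toy_theta(alpha_yx = -0.1, i_xy = 0.1, M = 5000)
  pi_k <- 0.01
  sigma_k <- 0.3
  mc <- mc_model_pairs(th, pi_k, sigma_k)
  sx <- stats::sd(mc$bx)
  sy <- stats::sd(mc$by)
  for (vw in list(c(1 / 2, 0), c(0, 1), c(1, 1), c(2, -1))) {
    v <- vw[1] / sx
    w <- vw[2] / sy
    vals <- cos(v * mc$bx + w * mc$by)
    emp <- mean(vals)
    se <- stats::sd(vals) / sqrt(length(vals))
    model <- cf_joint(v, w, th, pi_k, sigma_k)
    expect_lt(abs(emp - model), 4 * se)
  }
})

test_that("FFT inversion reproduces the analytic Gaussian density", {
  th <- toy_theta(h2_x = 0, h2_y = 0, t_x = 0, t_y = 0, alpha_xy = 0)
  sx <- sqrt(th$i_x / th$n_x)
  sy <- sqrt(th$i_y / th$n_y)
  spec <- grid_spec(half_width = c(8 * sx, 8 * sy))
  g <- pdf_grid(th, 1e-3, 0.3, spec)
  central_x <- which(abs(g$x) <= 2 * sx)
  central_y <- which(abs(g$y) <= 2 * sy)
  analytic <- outer(dnorm(g$x[central_x], 0, sx),
                    dnorm(g$y[central_y], 0, sy))
  expect_lt(max(abs(g$log_density[central_x, central_y] - log(analytic))),
            1e-3)
})

test_that("inverted densities integrate to one", {
  panel <- small_panel()
  s <- sim_preset("standard", M = 2000, seed = 23)
  sim <- simulate_pair(s, panel$blocks)
  spec <- grid_spec(sim$sumstats)
  for (th in list(sim$truth, toy_theta(M = 2000, n_x = 5e4, n_y = 5e4))) {
    g <- pdf_grid(th, 1e-3, 0.35, spec)
    mass <- sum(exp(g$log_density)) * g$dx * g$dy
    expect_gte(mass, 0.98)
    expect_lte(mass, 1.02)
  }
})

test_that("grid densities track the frequencies of model draws", {
  set.seed(24)
  th <- toy_theta(M = 5000)
  pi_k <- 0.01
  sigma_k <- 0.3
  mc <- mc_model_pairs(th, pi_k, sigma_k)
  spec <- grid_spec(half_width = c(1.05 * max(abs(mc$bx)),
                                   1.05 * max(abs(mc$by))))
  g <- pdf_grid(th, pi_k, sigma_k, spec)
  lim <- stats::quantile(abs(c(mc$bx, mc$by)), 0.98)
  brk <- seq(-lim, lim, length.out = 9)
  counts <- table(cut(mc$bx, brk), cut(mc$by, brk))
  mids <- (brk[-1] + brk[-9]) / 2
  dens_at <- function(px, py) exp(lhcmr:::interp_log_density(g, px, py))
  pred <- outer(mids, mids, function(a, b) dens_at(a, b)) *
    diff(brk)[1]^2 * length(mc$bx)
  keep <- counts > 20
  expect_gt(stats::cor(log(as.vector(counts[keep])),
                       log(as.vector(pred[keep]))), 0.95)
})

test_that("compiled and reference likelihoods agree", {
  panel <- small_panel()
  s <- sim_preset("standard", M = 2000, seed = 25)
  sim <- simulate_pair(s, panel$blocks)
  for (th in list(sim$truth, toy_theta(M = 2000, alpha_yx = -0.15,
                                       i_xy = 0.1))) {
    ll_cpp <- loglik_pair(th, sim$sumstats, panel$profile, engine = "cpp")
    ll_r <- loglik_pair(th, sim$sumstats, panel$profile, engine = "r")
    expect_equal(ll_cpp, ll_r, tolerance = 1e-10)
  }
})

test_that("pure-noise likelihood equals the analytic normal log-density", {
  th <- toy_theta(h2_x = 0, h2_y = 0, t_x = 0, t_y = 0, alpha_xy = 0)
  paired <- tibble::tibble(snp = "s1", chr = "1", pos = 1L,
                           beta_x = 0, se_x = 1, beta_y = 0, se_y = 1)
  profile <- tibble::tibble(snp = "s1", pi_k = 1e-3, sigma_k = 0.3,
                            weight = 1, block = 1L)
  sx <- sqrt(th$i_x / th$n_x)
  sy <- sqrt(th$i_y / th$n_y)
  spec <- grid_spec(half_width = c(8 * sx, 8 * sy))
  ll <- loglik_pair(th, paired, suppressMessages(make_bins(profile)),
                    spec = spec)
  expect_equal(ll, log(dnorm(0, 0, sx)) + log(dnorm(0, 0, sy)),
               tolerance = 1e-5)
})

test_that("the likelihood is linear in the weights", {
  panel <- small_panel()
  sim <- simulate_pair(sim_preset("standard", M = 2000, seed = 26),
                       panel$blocks)
  prof2 <- panel$profile
  prof2$weight <- 2 * prof2$weight
  attr(prof2, "centers") <- attr(panel$profile, "centers")
  ll1 <- loglik_pair(sim$truth, sim$sumstats, panel$profile)
  ll2 <- loglik_pair(sim$truth, sim$sumstats, prof2)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("the likelihood is exchangeable within bins", {
  panel <- small_panel()
  sim <- simulate_pair(sim_preset("standard", M = 2000, seed = 27),
                       panel$blocks)
  set.seed(1)
  perm <- unlist(lapply(split(seq_len(2000), panel$profile$bin), sample))
  paired_p <- sim$sumstats[perm, ]
  prof_p <- panel$profile[perm, ]
  attr(prof_p, "centers") <- attr(panel$profile, "centers")
  expect_equal(loglik_pair(sim$truth, paired_p, prof_p),
               loglik_pair(sim$truth, sim$sumstats, panel$profile),
               tolerance = 1e-10)
})

test_that("the truth dominates causal-effect perturbations", {
  panel <- small_panel()
  wins <- 0
  for (r in 1:50) {
    sim <- simulate_pair(sim_preset("standard", M = 2000, seed = 100 + r),
                         panel$blocks)
    ll <- function(th) loglik_pair(th, sim$sumstats, panel$profile)
    up <- sim$truth
    up$alpha_xy <- sim$truth$alpha_xy + 0.2
    dn <- sim$truth
    dn$alpha_xy <- sim$truth$alpha_xy - 0.2
    if (ll(sim$truth) > max(ll(up), ll(dn))) wins <- wins + 1
  }
  expect_gte(wins, 45)
})

test_that("single-trait likelihood has the right noise-only limit", {
  panel <- small_panel()
  set.seed(28)
  betas <- rnorm(2000, 0, sqrt(1 / 5e4))
  ll <- loglik_single(1e-3, 0, 1, betas, panel$profile, n = 5e4, M = 2000)
  analytic <- sum(panel$profile$weight *
                    dnorm(betas, 0, sqrt(1 / 5e4), log = TRUE))
  expect_equal(ll, analytic, tolerance = 1e-3)

  ll_cpp <- loglik_single(5e-3, 0.2, 0.9, betas, panel$profile,
                          n = 5e4, M = 2000, engine = "cpp")
  ll_r <- loglik_single(5e-3, 0.2, 0.9, betas, panel$profile,
                        n = 5e4, M = 2000, engine = "r")
  expect_equal(ll_cpp, ll_r, tolerance = 1e-10)
})

test_that("single-trait truth dominates heritability perturbations", {
  # draws from the likelihood's own model (spike-and-slab local LD) so
  # the supplied parameters are exactly the generative truth; the dense
  # architecture keeps the sampling noise of h2 below the perturbation
  set.seed(219)
  M <- 2000
  pi_t <- 0.05
  h2 <- 0.25
  intercept <- 0.75
  n <- 5e4
  pi_k <- 0.01
  sigma_k <- 0.3
  profile <- suppressMessages(make_bins(tibble::tibble(
    snp = paste0("s", 1:M), pi_k = pi_k, sigma_k = sigma_k,
    weight = 1, block = 1L)))
  wins <- 0
  for (r in 1:50) {
    n_terms <- rbinom(M, M, pi_k * pi_t)
    z <- vapply(n_terms, function(nt)
      sum(rnorm(nt, 0, sigma_k) * rnorm(nt, 0, sqrt(h2 / (M * pi_t)))), 0)
    betas <- z + rnorm(M, 0, sqrt(intercept / n))
    ll <- function(h) loglik_single(pi_t, h, intercept, betas, profile,
                                    n = n, M = M)
    if (ll(h2) > max(ll(h2 + 0.1), ll(h2 - 0.1))) wins <- wins + 1
  }
  expect_gte(wins, 45)
})

test_that("the likelihood is finite over the whole parameter box", {
  panel <- small_panel()
  sim <- simulate_pair(sim_preset("standard", M = 2000, seed = 29),
                       panel$blocks)
  set.seed(30)
  bounds <- lhcmr:::free_param_bounds()
  for (i in 1:200) {
    free <- runif(7, bounds$lower, bounds$upper)
    names(free) <- lhcmr:::free_param_names()
    if (abs(free["alpha_xy"] * free["alpha_yx"]) >= 0.99) next
    th <- lhcmr:::set_free_params(sim$truth, free)
    expect_true(is.finite(loglik_pair(th, sim$sumstats, panel$profile)))
  }
})
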