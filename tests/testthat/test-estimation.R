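test_that("IVW reduces to the ratio estimate and a weighted combination", {
  one <- tibble::tibble(beta_x = 0.05, se_x = 0.001,
                        beta_y = 0.02, se_y = 0.01)
  expect_equal(ivw_estimate(one, p_thresh = 1)$alpha, 0.02 / 0.05)

  two <- tibble::tibble(beta_x = c(0.05, 0.1), se_x = 0.001,
                        beta_y = c(0.015, 0.03), se_y = c(0.01, 0.02))
  expect_equal(ivw_estimate(two, p_thresh = 1)$alpha, 0.3)

  # five-SNP hand-computed oracle (explicit arithmetic, frozen)
  bx <- c(0.04, -0.06, 0.09, 0.05, -0.07)
  by <- c(0.013, -0.020, 0.025, 0.012, -0.028)
  sy <- c(0.010, 0.012, 0.009, 0.015, 0.011)
  tab <- tibble::tibble(beta_x = bx, se_x = 0.001, beta_y = by, se_y = sy)
  num <- 0
  den <- 0
  for (j in 1:5) {
    num <- num + bx[j] * by[j] / sy[j]^2
    den <- den + bx[j]^2 / sy[j]^2
  }
  expect_equal(ivw_estimate(tab, p_thresh = 1)$alpha, num / den)

  weak <- tibble::tibble(beta_x = 1e-4, se_x = 1, beta_y = 0, se_y = 1)
  expect_true(is.na(ivw_estimate(weak, p_thresh = 5e-8)$alpha))
})

test_that("cross-trait intercept recovers overlap and the rg sign", {
  # a panel with spread-out LD scores keeps the intercept extrapolation
  # well conditioned
  panel <- cached("panel_ct", synth_ld_panel(20000, seed = 31))
  null_s <- sim_settings(M = 20000, pi_x = 1e-3, pi_y = 1e-3, pi_u = 1e-3,
                         h2_x = 0, h2_y = 0, h2_u = 0, q_x = 0, q_y = 0,
                         alpha_xy = 0, alpha_yx = 0, seed = 31)
  sim0 <- simulate_pair(null_s, panel$blocks)
  ct0 <- crosstrait_intercept(sim0$sumstats, panel$profile)
  expect_lt(abs(ct0$intercept), 0.05)

  null_s$n_overlap <- 5e4
  null_s$r_xy <- 0.5
  simo <- simulate_pair(null_s, panel$blocks)
  cto <- crosstrait_intercept(simo$sumstats, panel$profile)
  expect_lt(abs(cto$intercept - 0.5), 0.05)

  panel <- test_panel()
  simg <- simulate_pair(sim_preset("standard", M = 50000, seed = 32),
                        panel$blocks)
  ctg <- crosstrait_intercept(simg$sumstats, panel$profile)
  expect_gt(ctg$slope, 0) # positive genetic covariance
})

test_that("starting points are in range, anchored and reproducible", {
  s1 <- make_starts(50, seed = 33)
  expect_equal(nrow(s1), 50)
  expect_equal(nrow(dplyr::distinct(s1)), 50)
  expect_true(all(s1$h2_x >= 0 & s1$h2_x <= 1))
  expect_true(all(s1$t_x >= 0 & s1$t_x <= 1))
  expect_true(all(abs(s1$alpha_xy) <= 1 & abs(s1$i_xy) <= 1))

  s2 <- make_starts(50, anchors = list(ivw_xy = 0.3), seed = 34)
  expect_true(all(s2$alpha_xy >= 0.2 & s2$alpha_xy <= 0.4))

  expect_identical(make_starts(10, seed = 35), make_starts(10, seed = 35))
})

test_that("the mirror map swaps direct and confounder axes", {
  th <- lhc_params(pi_x = 5e-3, pi_y = 1e-2, h2_x = 0.25, h2_y = 0.2,
                   t_x = 0.16, t_y = 0, alpha_xy = 0.3, alpha_yx = 0,
                   i_x = 0.7, i_y = 0.7, i_xy = 0, n_x = 5e4, n_y = 5e4,
                   M = 5e4)
  m <- mirror_optimum(th)
  expect_equal(m$h2_x, 0.16^2)
  expect_equal(m$t_x, sqrt(0.25))
  expect_equal(m$t_y, 0)
  expect_equal(m$alpha_xy, 0.3)

  expect_null(mirror_optimum(lhcmr:::set_free_params(
    th, c(h2_x = 0.25, h2_y = 0.2, t_x = 0, t_y = 0, alpha_xy = 0.3,
          alpha_yx = 0, i_xy = 0))))
})

test_that("the mirror map is an involution on random valid parameters", {
  set.seed(36)
  n_checked <- 0
  while (n_checked < 20) {
    th <- tryCatch(lhc_params(
      pi_x = 10^runif(1, -3, -1), pi_y = 10^runif(1, -3, -1),
      h2_x = runif(1, 0.05, 0.5), h2_y = runif(1, 0.05, 0.5),
      t_x = runif(1, 0.05, 0.5), t_y = runif(1, -0.5, 0.5),
      alpha_xy = runif(1, -0.5, 0.5), alpha_yx = runif(1, -0.5, 0.5),
      i_x = 1, i_y = 1, i_xy = 0, n_x = 5e4, n_y = 5e4, M = 5e4),
      error = function(e) NULL)
    if (is.null(th)) next
    m <- mirror_optimum(th)
    if (is.null(m)) next
    mm <- mirror_optimum(m)
    if (is.null(mm)) next
    n_checked <- n_checked + 1
    for (f in c("h2_x", "h2_y", "t_x", "t_y", "alpha_xy", "alpha_yx"))
      expect_equal(mm[[f]], th[[f]], tolerance = 1e-8)
  }
})

test_that("the mirror optimum leaves the log-likelihood unchanged", {
  # exact fit-equivalence holds when the swapped components carry the same
  # polygenicity, i.e. pi_x equal to the fixed confounder polygenicity
  panel <- small_panel()
  sim <- simulate_pair(sim_preset("standard", M = 2000, seed = 37),
                       panel$blocks)
  th <- lhc_params(pi_x = 0.1, pi_y = 1e-2, h2_x = 0.2, h2_y = 0.15,
                   t_x = 0.3, t_y = 0.2, alpha_xy = 0.2, alpha_yx = -0.1,
                   i_x = 0.8, i_y = 0.8, i_xy = 0.05,
                   n_x = 5e4, n_y = 5e4, M = 2000, pi_u = 0.1)
  m <- mirror_optimum(th)
  expect_false(is.null(m))
  ll_th <- loglik_pair(th, sim$sumstats, panel$profile)
  ll_m <- loglik_pair(m, sim$sumstats, panel$profile)
  expect_lt(abs(ll_th - ll_m), 1e-2)
})

test_that("primary-solution labelling follows the heritability rule", {
  th <- lhc_params(pi_x = 5e-3, pi_y = 1e-2, h2_x = 0.25, h2_y = 0.2,
                   t_x = 0.16, t_y = 0.11, alpha_xy = 0.3, alpha_yx = 0,
                   i_x = 0.7, i_y = 0.7, i_xy = 0, n_x = 5e4, n_y = 5e4,
                   M = 5e4)
  sel <- select_primary(th, mirror_optimum(th))
  expect_equal(sel$label, "primary")
  expect_equal(sel$primary$h2_x, 0.25)

  sel2 <- select_primary(th, NULL)
  expect_equal(sel2$label, "mirror_out_of_range")

  # fitted optimum on the confounder-dominated side: mirror is primary
  flipped <- mirror_optimum(th)
  sel3 <- select_primary(flipped, mirror_optimum(flipped))
  expect_equal(sel3$label, "alternative")
  expect_gt(sel3$primary$h2_x, sel3$primary$t_x^2)
})

test_that("single-trait fits recover polygenicity, heritability, intercept", {
  panel <- test_panel()
  h2_hat <- i_hat <- numeric(4)
  for (r in 1:4) {
    s <- sim_preset("standard", M = 50000, seed = 300 + r)
    sim <- simulate_pair(s, panel$blocks)
    f <- fit_single_trait(sim$sumstats$beta_x, panel$profile, n = 5e4,
                          M = 5e4, n_starts = 6, seed = r)
    h2_hat[r] <- f$h2
    i_hat[r] <- f$i
  }
  h2_total <- 0.25 + 0.16^2 # direct + confounder-mediated
  expect_lt(abs(mean(h2_hat) - h2_total), 0.05)
  expect_lt(abs(mean(i_hat) - 0.723), 0.15)
})

test_that("single-trait fits detect a pure-noise trait", {
  panel <- small_panel()
  set.seed(38)
  betas <- rnorm(2000, 0, sqrt(1 / 5e4))
  f <- fit_single_trait(betas, panel$profile, n = 5e4, M = 2000,
                        n_starts = 6, seed = 39)
  expect_lt(f$h2, 0.01)
  expect_lt(abs(f$i - 1), 0.1)
})

test_that("two-trait fits attain at least the truth's likelihood", {
  fr <- standard_replicate()
  fit <- fr$fit
  expect_s3_class(fit, "lhc_fit")
  expect_true(all(c("theta_hat", "per_start", "primary_label") %in%
                    names(fit)))
  panel <- test_panel()
  truth_free <- unlist(fr$sim$truth[lhcmr:::free_param_names()])
  th_truth <- lhcmr:::set_free_params(fit$theta_hat, truth_free)
  ll_truth <- loglik_pair(th_truth, fr$sim$sumstats, panel$profile,
                          spec = fit$spec)
  expect_gte(fit$loglik, ll_truth - 1e-4)
  # estimates respect the box constraints
  free <- unlist(fit$theta_hat[lhcmr:::free_param_names()])
  b <- lhcmr:::free_param_bounds()
  expect_true(all(free >= b$lower - 1e-12 & free <= b$upper + 1e-12))
})

test_that("tidiers summarise fits as tibbles", {
  fit <- standard_replicate()$fit
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("alpha_xy", "h2_x") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(is.finite(gl$rg))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
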