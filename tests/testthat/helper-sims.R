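# Shared, lazily-built simulation fixtures. Scenario studies follow the
# scaled benchmark protocol: 50,000 markers (per-SNP slab variances scale
# as h2/(M pi), preserving heritabilities), the package's reference
# synthetic LD panel, replicate data generations with fixed seeds, and
# anchored multi-start fits. Results are cached for the session so several
# test files can share one study.

.lhc_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.lhc_test_cache[[key]]))
    .lhc_test_cache[[key]] <- force(expr)
  .lhc_test_cache[[key]]
}

test_panel <- function(M = 50000) {
  cached(paste0("panel_", M), synth_ld_panel(M))
}

# small panel for fast unit-level likelihood checks
small_panel <- function(M = 2000) {
  cached(paste0("panel_", M), synth_ld_panel(M))
}

fit_one_replicate <- function(preset, rep_seed, n = 50000, M = 50000,
                              n_starts = 2, n_starts_single = 3) {
  panel <- test_panel(M)
  sim <- simulate_pair(sim_preset(preset, M = M, n_x = n, n_y = n,
                                  seed = rep_seed), panel$blocks)
  fit <- lhc_mr(sim$sumstats, panel$profile, n_starts = n_starts,
                n_starts_single = n_starts_single, seed = rep_seed + 1000)
  list(fit = fit, sim = sim)
}

# replicate study: matrix of primary-solution estimates, one row per
# replicate data generation
scenario_study <- function(preset, n = 50000, n_reps = 6, M = 50000) {
  key <- paste("study", preset, n, n_reps, M, sep = "_")
  cached(key, {
    rows <- lapply(seq_len(n_reps), function(r) {
      fr <- fit_one_replicate(preset, rep_seed = r, n = n, M = M)
      p <- fr$fit$primary
      c(alpha_xy = p$alpha_xy, alpha_yx = p$alpha_yx,
        h2_x = p$h2_x, h2_y = p$h2_y, t_x = p$t_x, t_y = p$t_y,
        i_xy = p$i_xy)
    })
    do.call(rbind, rows)
  })
}

# one standard-setting replicate kept whole (fit + data) for the jackknife
standard_replicate <- function() {
  cached("standard_rep1", fit_one_replicate("standard", rep_seed = 1))
}

# jackknife of the standard replicate, shared across test files
standard_jackknife <- function(n_blocks = 30) {
  cached(paste0("jk_standard_", n_blocks), {
    fr <- standard_replicate()
    suppressMessages(block_jackknife(fr$sim$sumstats, test_panel()$profile,
                                     fr$fit, n_blocks = n_blocks))
  })
}

# Monte-Carlo characteristic function of z = sum of products of two
# spike-and-slab draws; the independent oracle for the closed form.
mc_cf_signal <- function(t, pi_k, sigma_k, pi_t, s2_t, M, n_mc = 2e5) {
  n_terms <- rbinom(n_mc, M, pi_k * pi_t)
  tot <- sum(n_terms)
  prods <- rnorm(tot, 0, sigma_k) * rnorm(tot, 0, sqrt(s2_t))
  z <- numeric(n_mc)
  idx <- rep.int(seq_len(n_mc), n_terms)
  if (tot > 0) {
    sums <- tapply(prods, idx, sum)
    z[as.integer(names(sums))] <- sums
  }
  vapply(t, function(tt) {
    c(mean(cos(tt * z)), sd(cos(tt * z)) / sqrt(n_mc))
  }, numeric(2))
}
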