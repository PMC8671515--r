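#' Synthetic block-diagonal LD structure
#'
#' Builds a genome-wide block-diagonal correlation structure in which SNPs
#' `i`, `j` of the same block are correlated as `rho^|i-j|` (an AR(1)
#' profile, which is always positive semi-definite). Blocks of `block_size`
#' SNPs partition `1..M`, with a final short block if `M` is not a
#' multiple. An optional jitter draws each block's decay rate from
#' `rho_decay + U(-jitter, jitter)` (clipped to `[0, 0.98]`), deterministic
#' given `seed`.
#'
#' @param M Total number of markers.
#' @param block_size SNPs per block (>= 1).
#' @param rho_decay Within-block correlation decay per SNP, in `[0, 1)`.
#' @param seed Optional integer seed (needed when `jitter > 0`).
#' @param jitter Half-width of the per-block decay jitter (default 0).
#' @return An object of class `lhc_ld_blocks`: list with `M`, per-block
#'   `start`/`end` index vectors and per-block decay `rho`.
#' @export
synth_ld_blocks <- function(M, block_size, rho_decay, seed = NULL,
                            jitter = 0) {
  stopifnot(M >= 1, block_size >= 1, rho_decay >= 0, rho_decay < 1,
            jitter >= 0)
  starts <- seq(1, M, by = block_size)
  ends <- pmin(starts + block_size - 1, M)
  rho <- rep(rho_decay, length(starts))
  if (jitter > 0) {
    if (is.null(seed)) stop("seed required when jitter > 0", call. = FALSE)
    withr_seed(seed, {
      rho <- pmin(pmax(rho + runif(length(rho), -jitter, jitter), 0), 0.98)
    })
  }
  structure(list(M = M, start = starts, end = ends, rho = rho),
            class = "lhc_ld_blocks")
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' @export
print.lhc_ld_blocks <- function(x, ...) {
  cat(sprintf("<lhc_ld_blocks> M = %d, %d blocks (size %d-%d), decay %.3g-%.3g\n",
              x$M, length(x$start), min(x$end - x$start + 1),
              max(x$end - x$start + 1), min(x$rho), max(x$rho)))
  invisible(x)
}

# Correlation matrix of block b.
ld_block_matrix <- function(blocks, b) {
  len <- blocks$end[b] - blocks$start[b] + 1
  blocks$rho[b]^abs(outer(seq_len(len), seq_len(len), "-"))
}

#' Reference synthetic LD panel
#'
#' Bundles the package's default emulation of a realistic reference panel:
#' AR(1) LD blocks of 50 SNPs whose decay rates are jittered around 0.7
#' (`U(0.42, 0.98)`), giving restricted LD scores spanning roughly 1-30 as
#' in imputed human cohort data, together with the per-SNP spike-and-slab
#' LD profile binned for the likelihood. A fixed panel seed plays the role
#' of a fixed external reference panel; simulation replicates vary the
#' trait seed while sharing the panel.
#'
#' @param M Number of markers.
#' @param seed Panel seed (default 2024).
#' @param block_size,rho_decay,jitter Block structure knobs (see
#'   [synth_ld_blocks()]).
#' @param n_pi,n_sigma Bin lattice resolution (see [make_bins()]).
#' @return A list `blocks` (an `lhc_ld_blocks`) and `profile` (binned LD
#'   profile tibble).
#' @export
synth_ld_panel <- function(M, seed = 2024, block_size = 50,
                           rho_decay = 0.7, jitter = 0.28,
                           n_pi = 10, n_sigma = 10) {
  blocks <- synth_ld_blocks(M, block_size, rho_decay, seed = seed,
                            jitter = jitter)
  profile <- make_bins(ld_profile(blocks), n_pi = n_pi, n_sigma = n_sigma)
  list(blocks = blocks, profile = profile)
}

#' Spike-and-slab summary of one SNP's local correlations
#'
#' Approximates the distribution of a SNP's correlations with all panel
#' markers by a spike-and-slab: `pi_k`, the fraction of correlations whose
#' magnitude exceeds `c_mult * null_sd` (the self-correlation of 1 always
#' passes), and `sigma_k`, the root-mean-square of those passing entries
#' (the slab scale; RMS about zero rather than the mean-centred standard
#' deviation because the correlations are symmetric around zero).
#'
#' `null_sd` is the sampling noise scale of an estimated correlation,
#' `1/sqrt(panel size)` for correlations estimated from a reference panel,
#' or 0 for exact (synthetic) correlations.
#'
#' @param correlations Numeric vector of one SNP's correlations to all
#'   panel SNPs, including its self-correlation of 1.
#' @param null_sd Sampling noise standard deviation (>= 0).
#' @param c_mult Threshold multiplier (default 2).
#' @return Named numeric vector `c(pi_k =, sigma_k =)`.
#' @export
fit_spike_slab_ld <- function(correlations, null_sd, c_mult = 2) {
  stopifnot(length(correlations) >= 1, null_sd >= 0)
  thr <- c_mult * null_sd
  pass <- abs(correlations) > thr
  if (!any(pass)) stop("no correlation passes the threshold; the ",
                       "self-correlation of 1 must be included", call. = FALSE)
  c(pi_k = mean(pass),
    sigma_k = sqrt(mean(correlations[pass]^2)))
}

#' Restricted LD-score weights
#'
#' Computes `w_k = 1 / sum_{j in gwas} r_jk^2` for each analysed SNP `k`,
#' the inverse of its LD score restricted to the analysed GWAS SNPs
#' (including the `j = k` self term, so `w_k <= 1`). These weights correct
#' the composite log-likelihood for over-counting of correlated SNPs.
#'
#' @param blocks An `lhc_ld_blocks` object.
#' @param gwas_indices Sorted integer indices (into `1..M`) of the analysed
#'   SNPs. Default: all `M` SNPs.
#' @return Numeric weight vector, one entry per GWAS SNP.
#' @export
restricted_ld_weights <- function(blocks, gwas_indices = seq_len(blocks$M)) {
  stopifnot(all(gwas_indices >= 1), all(gwas_indices <= blocks$M))
  w <- numeric(length(gwas_indices))
  for (b in seq_along(blocks$start)) {
    in_b <- which(gwas_indices >= blocks$start[b] &
                    gwas_indices <= blocks$end[b])
    if (length(in_b) == 0) next
    off <- gwas_indices[in_b] - blocks$start[b] + 1
    r2 <- blocks$rho[b]^(2 * abs(outer(off, off, "-")))
    w[in_b] <- 1 / colSums(r2)
  }
  w
}

#' Per-SNP local-LD profile
#'
#' Builds, for each analysed SNP, the spike-and-slab summary of its local
#' correlations (`pi_k`, `sigma_k`), its restricted LD-score weight and its
#' LD-block id, from a synthetic block-LD structure.
#'
#' @param blocks An `lhc_ld_blocks` object.
#' @param gwas_indices Analysed SNP indices (default all).
#' @param snp_id Optional SNP identifiers (default `snp_<index>`).
#' @param null_sd,c_mult Threshold specification passed to
#'   [fit_spike_slab_ld()]; the default `null_sd = 0` treats the synthetic
#'   correlations as exact.
#' @return A tibble `snp, pi_k, sigma_k, weight, block`, one row per GWAS
#'   SNP in `gwas_indices` order.
#' @export
ld_profile <- function(blocks, gwas_indices = seq_len(blocks$M),
                       snp_id = NULL, null_sd = 0, c_mult = 2) {
  M <- blocks$M
  thr <- c_mult * null_sd
  pi_k <- numeric(length(gwas_indices))
  sigma_k <- numeric(length(gwas_indices))
  block_id <- integer(length(gwas_indices))
  # identical blocks (same decay, same length) share per-offset profiles
  len_all <- blocks$end - blocks$start + 1
  cache <- new.env(parent = emptyenv())
  offset_profile <- function(rho, len) {
    k <- paste(rho, len)
    if (!is.null(cache[[k]])) return(cache[[k]])
    out <- vapply(seq_len(len), function(o) {
      r <- rho^abs(o - seq_len(len))
      pass <- abs(r) > thr
      c(sum(pass) / M, sqrt(mean(r[pass]^2)))
    }, numeric(2))
    cache[[k]] <- out
    out
  }
  for (b in seq_along(blocks$start)) {
    in_b <- which(gwas_indices >= blocks$start[b] &
                    gwas_indices <= blocks$end[b])
    if (length(in_b) == 0) next
    off <- gwas_indices[in_b] - blocks$start[b] + 1
    prof <- offset_profile(blocks$rho[b], len_all[b])
    pi_k[in_b] <- prof[1, off]
    sigma_k[in_b] <- prof[2, off]
    block_id[in_b] <- b
  }
  tibble::tibble(
    snp = snp_id %||% sprintf("snp_%07d", gwas_indices),
    pi_k = pi_k, sigma_k = sigma_k,
    weight = restricted_ld_weights(blocks, gwas_indices),
    block = block_id
  )
}

#' Bin SNPs on their local-LD summaries
#'
#' Assigns each SNP to the nearest centre of an `n_pi` x `n_sigma` lattice
#' of equidistant centres spanning the observed ranges of `pi_k` and
#' `sigma_k`. Distances are Euclidean on min-max-scaled coordinates so the
#' two axes (typically orders of magnitude apart) contribute comparably.
#' The likelihood is later evaluated once per non-empty bin at its centre.
#'
#' @param profile An LD-profile tibble from [ld_profile()].
#' @param n_pi,n_sigma Lattice resolution (default 10 x 10).
#' @return The profile with an added integer `bin` column, and an attribute
#'   `"centers"`: a tibble `bin, pi_c, sigma_c` of the non-empty bins.
#' @export
make_bins <- function(profile, n_pi = 10, n_sigma = 10) {
  stopifnot(nrow(profile) > 0)
  axis_centers <- function(v, n) {
    if (max(v) - min(v) < 1e-15) {
      message("degenerate range; a single bin column is used")
      return(stats::median(v))
    }
    seq(min(v), max(v), length.out = n)
  }
  cp <- axis_centers(profile$pi_k, n_pi)
  cs <- axis_centers(profile$sigma_k, n_sigma)
  nearest <- function(v, centers) {
    if (length(centers) == 1) return(rep(1L, length(v)))
    # equidistant centres: nearest centre is linear snapping
    step <- centers[2] - centers[1]
    pmin(pmax(round((v - centers[1]) / step), 0), length(centers) - 1) + 1L
  }
  ip <- nearest(profile$pi_k, cp)
  is <- nearest(profile$sigma_k, cs)
  bin <- (ip - 1L) * length(cs) + is
  out <- dplyr::mutate(profile, bin = bin)
  centers <- tibble::tibble(
    bin = sort(unique(bin)),
    pi_c = cp[(sort(unique(bin)) - 1L) %/% length(cs) + 1L],
    sigma_c = cs[(sort(unique(bin)) - 1L) %% length(cs) + 1L]
  )
  attr(out, "centers") <- centers
  out
}

#' Write / read an LD profile as TSV
#'
#' Compatible with externally supplied local LD-score files carrying the
#' same columns (`snp, pi_k, sigma_k, weight, block`).
#'
#' @param profile LD-profile tibble.
#' @param path File path.
#' @return `write_ld_profile()` returns `path` invisibly; `read_ld_profile()`
#'   the profile tibble.
#' @export
write_ld_profile <- function(profile, path) {
  readr::write_tsv(dplyr::select(profile, dplyr::any_of(
    c("snp", "pi_k", "sigma_k", "weight", "block"))), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ld_profile
#' @export
read_ld_profile <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("snp", "pi_k", "sigma_k", "weight")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0)
    stop("LD profile lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  stopifnot(all(tbl$pi_k > 0), all(tbl$sigma_k > 0), all(tbl$weight > 0))
  tbl
}
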