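#' Read a GWAS summary-statistics table
#'
#' Reads a delimited (tab or comma separated, header row) file of per-SNP
#' marginal association statistics into the package's native layout. The
#' native column dialect is `snp, chr, pos, a1, a0, beta, se, n, maf, info`
#' (`a1` the effect allele, `a0` the other allele, `beta` the standardized
#' marginal effect). Files using other headers are mapped via `column_map`.
#'
#' Rows with missing or unparseable mandatory fields (`snp`, `beta`, `se`,
#' `pos`) or non-positive `se` are dropped with a reported count; duplicated
#' SNP identifiers keep the first occurrence.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector mapping native field names to the
#'   file's column headers, e.g. `c(snp = "rsid", beta = "BETA")`. Unmapped
#'   fields are taken verbatim from the native dialect.
#' @return A tibble with the native columns, one row per retained SNP.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                           progress = FALSE, guess_max = 1e5)
  native <- c("snp", "chr", "pos", "a1", "a0", "beta", "se", "n", "maf", "info")
  map <- setNames(native, native)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), native)
    if (length(bad) > 0)
      stop("unknown native field(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    map[names(column_map)] <- column_map
  }
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0)
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  tbl <- tibble::tibble(
    snp  = as.character(raw[[map["snp"]]]),
    chr  = as.character(raw[[map["chr"]]]),
    pos  = suppressWarnings(as.integer(raw[[map["pos"]]])),
    a1   = toupper(as.character(raw[[map["a1"]]])),
    a0   = toupper(as.character(raw[[map["a0"]]])),
    beta = suppressWarnings(as.numeric(raw[[map["beta"]]])),
    se   = suppressWarnings(as.numeric(raw[[map["se"]]])),
    n    = suppressWarnings(as.numeric(raw[[map["n"]]])),
    maf  = suppressWarnings(as.numeric(raw[[map["maf"]]])),
    info = suppressWarnings(as.numeric(raw[[map["info"]]]))
  )
  ok <- !is.na(tbl$snp) & !is.na(tbl$beta) & !is.na(tbl$se) &
    !is.na(tbl$pos) & tbl$se > 0
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(n_drop, " row(s) dropped (missing/unparseable mandatory fields)")
  tbl <- tbl[ok, ]
  dup <- duplicated(tbl$snp)
  if (any(dup)) {
    message(sum(dup), " duplicated snp id(s) dropped (first occurrence kept)")
    tbl <- tbl[!dup, ]
  }
  if (nrow(tbl) == 0) stop("no rows survived parsing", call. = FALSE)
  tbl
}

#' Quality-control filter for summary statistics
#'
#' Retains biallelic single-nucleotide variants with imputation quality
#' above `info_min`, minor allele frequency above `maf_min`, and (optionally)
#' position outside the extended HLA region. Row order is preserved.
#'
#' The HLA window is chromosome 6, 25,000,000-34,000,000 bp (GRCh37
#' convention, closed interval on 1-based coordinates).
#'
#' @param tbl A summary-statistics tibble as from [read_sumstats()].
#' @param info_min Minimum imputation quality (exclusive; default 0.99).
#' @param maf_min Minimum minor allele frequency (exclusive; default 0.005).
#' @param exclude_hla Drop SNPs inside the HLA window? Default `TRUE`.
#' @param hla_window `list(chr =, start =, end =)` overriding the default
#'   window.
#' @return The filtered tibble.
#' @export
qc_filter <- function(tbl, info_min = 0.99, maf_min = 0.005,
                      exclude_hla = TRUE,
                      hla_window = list(chr = "6", start = 25e6, end = 34e6)) {
  snv <- tbl$a1 %in% c("A", "C", "G", "T") & tbl$a0 %in% c("A", "C", "G", "T") &
    tbl$a1 != tbl$a0
  keep <- snv &
    (is.na(tbl$info) | tbl$info > info_min) &
    (is.na(tbl$maf) | tbl$maf > maf_min)
  keep[is.na(keep)] <- FALSE
  if (isTRUE(exclude_hla)) {
    in_hla <- tbl$chr == as.character(hla_window$chr) &
      tbl$pos >= hla_window$start & tbl$pos <= hla_window$end
    keep <- keep & !in_hla
  }
  out <- tbl[keep, ]
  if (nrow(out) == 0) warning("all SNPs removed by QC filtering")
  out
}

#' Harmonize two summary-statistics tables into a paired per-SNP table
#'
#' Intersects the two tables on SNP id, aligns the second trait's effects to
#' the first trait's effect allele (flipping the sign of `beta_y` where the
#' allele labels are swapped), and drops strand-ambiguous (A/T, C/G) and
#' allele-incompatible SNPs. The output is sorted by chromosome then
#' position with positions strictly increasing within a chromosome.
#'
#' @param x,y Summary-statistics tibbles for the two traits (QC-filtered).
#' @return A paired tibble with columns `snp, chr, pos, beta_x, se_x,
#'   beta_y, se_y` and attributes `n_x`, `n_y` (median per-table sample
#'   sizes).
#' @export
harmonize_pair <- function(x, y) {
  m <- dplyr::inner_join(x, y, by = "snp", suffix = c("_x", "_y"))
  if (nrow(m) == 0) stop("no overlapping SNPs between the two tables",
                         call. = FALSE)
  comp <- function(a) chartr("ACGT", "TGCA", a)
  palindromic <- m$a1_x == comp(m$a0_x)
  same <- m$a1_y == m$a1_x & m$a0_y == m$a0_x
  swap <- m$a1_y == m$a0_x & m$a0_y == m$a1_x
  incompatible <- !(same | swap)
  if (any(incompatible))
    message(sum(incompatible), " allele-incompatible SNP(s) dropped")
  if (any(palindromic & !incompatible))
    message(sum(palindromic & !incompatible),
            " strand-ambiguous (palindromic) SNP(s) dropped")
  m <- m[!palindromic & !incompatible, ]
  sign_flip <- ifelse(m$a1_y == m$a0_x & m$a0_y == m$a1_x, -1, 1)
  out <- tibble::tibble(
    snp = m$snp, chr = m$chr_x, pos = m$pos_x,
    beta_x = m$beta_x, se_x = m$se_x,
    beta_y = sign_flip * m$beta_y, se_y = m$se_y
  )
  out <- dplyr::arrange(out, .data$chr, .data$pos)
  dup_pos <- duplicated(out[, c("chr", "pos")])
  if (any(dup_pos)) {
    message(sum(dup_pos), " SNP(s) at duplicated positions dropped")
    out <- out[!dup_pos, ]
  }
  attr(out, "n_x") <- stats::median(m$n_x, na.rm = TRUE)
  attr(out, "n_y") <- stats::median(m$n_y, na.rm = TRUE)
  out
}

#' Thin a paired summary-statistics table
#'
#' Keeps every `k`-th SNP of the position-sorted table (indices 1, 1+k,
#' 1+2k, ...). Thinning to every 10th SNP is the recommended speed/power
#' trade-off for real GWAS input.
#'
#' @param paired A paired tibble from [harmonize_pair()].
#' @param k Thinning stride (default 10); `k = 1` returns the input.
#' @return The thinned tibble (attributes preserved).
#' @export
thin_sumstats <- function(paired, k = 10) {
  stopifnot(k >= 1, k == as.integer(k))
  out <- paired[seq(1, nrow(paired), by = k), ]
  attr(out, "n_x") <- attr(paired, "n_x")
  attr(out, "n_y") <- attr(paired, "n_y")
  out
}

#' Write / read a paired summary-statistics table as TSV
#'
#' The sample sizes travel as columns `n_x`, `n_y` so the file round-trips.
#'
#' @param paired Paired tibble.
#' @param path Output path.
#' @return `write_paired()` returns `path` invisibly; `read_paired()` the
#'   paired tibble.
#' @export
write_paired <- function(paired, path) {
  out <- dplyr::mutate(paired,
                       n_x = attr(paired, "n_x") %||% NA_real_,
                       n_y = attr(paired, "n_y") %||% NA_real_)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_paired
#' @export
read_paired <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  n_x <- tbl$n_x[1]
  n_y <- tbl$n_y[1]
  tbl <- dplyr::select(tbl, -dplyr::any_of(c("n_x", "n_y")))
  attr(tbl, "n_x") <- n_x
  attr(tbl, "n_y") <- n_y
  tbl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
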