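#' Filter SNPs on minor allele frequency and call rate
#'
#' Retains SNPs with MAF >= `maf_min` (computed on non-missing calls) and
#' call rate >= `call_rate_min`; both thresholds are inclusive. SNPs with
#' every call missing are removed and counted.
#'
#' @param G A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param call_rate_min Minimum per-SNP call rate (default 0.95).
#' @return A list with `genotypes` (filtered `geno_matrix`) and `report`
#'   (one-row tibble: in/out counts, mean MAF and spacing of retained SNPs).
#' @export
filter_snps <- function(G, maf_min = 0.05, call_rate_min = 0.95) {
  stopifnot(inherits(G, "geno_matrix"),
            maf_min >= 0, maf_min <= 1,
            call_rate_min >= 0, call_rate_min <= 1)
  if (ncol(G$calls) == 0 || nrow(G$calls) == 0) stop("empty genotype matrix")
  maf <- snp_maf(G$calls)
  cr <- snp_call_rate(G$calls)
  keep <- !is.nan(maf) & maf >= maf_min & cr >= call_rate_min
  out <- subset_geno(G, snps = which(keep))
  sp <- if (sum(keep) >= 2) spacing_summary(out$snp_map) else
    tibble::tibble(mean_kb = NA_real_, sd_kb = NA_real_, n_gaps = 0L)
  report <- tibble::tibble(
    n_snps_in = ncol(G$calls), n_snps_out = sum(keep),
    n_animals_in = nrow(G$calls), n_animals_out = nrow(G$calls),
    n_all_missing = sum(is.nan(maf)),
    mean_maf = if (any(keep)) mean(maf[keep]) else NA_real_,
    mean_spacing_kb = sp$mean_kb, sd_spacing_kb = sp$sd_kb,
    fraction_imputed = 0
  )
  list(genotypes = out, report = report)
}

#' Filter animals on genotype missingness
#'
#' Removes animals whose fraction of missing calls strictly exceeds
#' `max_missing` (the threshold itself is retained).
#'
#' @param G A [geno_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.05).
#' @return A filtered `geno_matrix`.
#' @export
filter_animals <- function(G, max_missing = 0.05) {
  stopifnot(inherits(G, "geno_matrix"), max_missing >= 0, max_missing <= 1)
  frac <- rowMeans(is.na(G$calls))
  keep <- frac <= max_missing
  if (!any(keep)) stop("all animals exceed the missingness threshold")
  subset_geno(G, animals = which(keep))
}

#' Impute missing genotype calls
#'
#' Per-locus imputation: `mode` replaces missing calls with the SNP's most
#' frequent observed call; `expected_dosage` with twice the observed allele
#' frequency (real-valued); `sample` with a Hardy-Weinberg draw at the
#' observed frequency (seeded). Observed calls are never altered.
#'
#' @param G A [geno_matrix()], already SNP- and animal-filtered.
#' @param method One of `"mode"`, `"expected_dosage"`, `"sample"`.
#' @param seed Integer seed (used by `"sample"` only).
#' @return A `geno_matrix` with no missing values; the attribute
#'   `fraction_imputed` records the fraction of entries filled.
#' @export
impute_missing <- function(G, method = c("mode", "expected_dosage", "sample"),
                           seed = 1L) {
  stopifnot(inherits(G, "geno_matrix"))
  method <- match.arg(method)
  calls <- G$calls
  miss <- is.na(calls)
  frac <- mean(miss)
  if (frac == 0) {
    out <- G
    attr(out, "fraction_imputed") <- 0
    return(out)
  }
  if (any(colSums(!miss) == 0)) {
    stop("SNPs with all calls missing must be removed (filter_snps) before ",
         "imputation")
  }
  if (method == "sample") set.seed(seed)
  p <- colMeans(calls, na.rm = TRUE) / 2
  fill <- switch(method,
    mode = apply(calls, 2, function(g) {
      tab <- table(g)
      as.numeric(names(tab)[which.max(tab)])
    }),
    expected_dosage = 2 * p,
    sample = NULL
  )
  idx <- which(miss, arr.ind = TRUE)
  if (method == "sample") {
    calls[idx] <- stats::rbinom(nrow(idx), 2L, p[idx[, 2]])
  } else {
    calls[idx] <- fill[idx[, 2]]
  }
  out <- geno_matrix(calls, G$snp_map)
  attr(out, "fraction_imputed") <- frac
  out
}

#' Mean and SD of adjacent-SNP spacing
#'
#' Gaps are computed between adjacent SNPs within each chromosome only
#' (positions must be sorted within chromosome); single-SNP chromosomes
#' contribute no gap.
#'
#' @param snp_map Data frame with `chrom` and `pos_bp`.
#' @return One-row tibble: `mean_kb`, `sd_kb`, `n_gaps`.
#' @export
spacing_summary <- function(snp_map) {
  gaps <- snp_map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(gap = list(diff(.data$pos_bp)), .groups = "drop") |>
    tidyr::unnest("gap") |>
    dplyr::pull("gap")
  if (!length(gaps)) {
    warning("no within-chromosome gaps (all chromosomes have < 2 SNPs)")
    return(tibble::tibble(mean_kb = NA_real_, sd_kb = NA_real_, n_gaps = 0L))
  }
  if (any(gaps < 0)) stop("snp_map is not sorted by position within chromosome")
  tibble::tibble(mean_kb = mean(gaps) / 1000,
                 sd_kb = stats::sd(gaps / 1000),
                 n_gaps = length(gaps))
}
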