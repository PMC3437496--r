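#' Genotype matrix container
#'
#' Bundles an animals-by-SNPs call matrix (additive codes 0/1/2, `NA` for
#' missing) with its SNP map. Rows are animals, columns SNPs; `dimnames` carry
#' animal and SNP identifiers and must agree with the map.
#'
#' @param calls Numeric matrix, animals in rows and SNPs in columns, entries in
#'   `{0, 1, 2}` or `NA` (real-valued dosages are allowed after
#'   expected-dosage imputation). Row names are animal ids, column names SNP
#'   ids.
#' @param snp_map Data frame with columns `snp_id`, `chrom`, `pos_bp`
#'   (1-based base-pair positions). One row per column of `calls`, same order.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (matrix) and `snp_map` (tibble).
#' @export
geno_matrix <- function(calls, snp_map) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  snp_map <- tibble::as_tibble(snp_map)
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(snp_map)))
  if (nrow(snp_map) != ncol(calls)) {
    stop("snp_map has ", nrow(snp_map), " rows but calls has ", ncol(calls),
         " columns")
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("A", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- snp_map$snp_id
  } else if (!identical(colnames(calls), as.character(snp_map$snp_id))) {
    stop("column names of calls do not match snp_map$snp_id")
  }
  bad <- stats::na.omit(unique(snp_map$pos_bp[snp_map$pos_bp < 0]))
  if (length(bad)) stop("snp_map contains negative positions")
  structure(list(calls = calls, snp_map = snp_map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$calls), " animals x ", ncol(x$calls), " SNPs\n",
      sep = "")
  n_chr <- length(unique(x$snp_map$chrom))
  n_miss <- sum(is.na(x$calls))
  cat("  chromosomes: ", n_chr, "; missing calls: ",
      signif(100 * n_miss / length(x$calls), 3), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Animal identifiers of a genotype matrix
#' @param G A [geno_matrix()].
#' @return Character vector of animal ids (row names of the call matrix).
#' @export
animal_ids <- function(G) rownames(G$calls)

#' Subset a genotype matrix
#'
#' @param G A [geno_matrix()].
#' @param animals Animal ids or row indices to keep (default all).
#' @param snps SNP ids or column indices to keep (default all).
#' @return A `geno_matrix` restricted to the requested animals/SNPs.
#' @export
subset_geno <- function(G, animals = NULL, snps = NULL) {
  calls <- G$calls
  map <- G$snp_map
  if (!is.null(animals)) calls <- calls[animals, , drop = FALSE]
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, map$snp_id)
    calls <- calls[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
  }
  geno_matrix(calls, map)
}

# Per-SNP minor allele frequency from non-missing calls. Returns NaN for
# SNPs with every call missing.
snp_maf <- function(calls) {
  p <- colMeans(calls, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

# Per-SNP call rate (fraction non-missing).
snp_call_rate <- function(calls) 1 - colMeans(is.na(calls))

#' Normalize chromosome labels
#'
#' Strips `chr`/`Chr`/`BTA` prefixes and upper-cases `x`/`un` so that labels
#' from different sources ("Chr11", "11", "BTA11") compare equal.
#'
#' @param chrom Character or numeric vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  out <- sub("^(chr|bta)[ _]?", "", as.character(chrom), ignore.case = TRUE)
  out[toupper(out) == "X"] <- "X"
  out[toupper(out) == "UN"] <- "Un"
  out
}
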