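#' Forward selection of SNPs on one chromosome
#'
#' Greedy chromosome-local model building: starting from the weighted
#' intercept model, the candidate SNP with the largest partial F
#' (extra-sum-of-squares test given the SNPs already selected, residual
#' df = n - q - 2 with q SNPs already in the model) is added while its
#' partial F reaches the genome-wide threshold; selection stops when no
#' remaining candidate does. Ties are broken deterministically by (F
#' descending, position ascending, SNP id ascending). Candidates collinear
#' with the current model are flagged and skipped, not fatal.
#'
#' @param ebv Per-animal EBVs (unweighted; weighting is applied internally).
#' @param genos Animals x candidate-SNPs dosage matrix (one chromosome;
#'   unassigned-contig SNPs count as one pseudo-chromosome). Column names are
#'   SNP ids.
#' @param threshold_f Genome-wide F threshold from the permutation stage,
#'   reused at every forward step.
#' @param weights Per-animal weights (default equal).
#' @param positions Optional bp positions of the candidates (for tie-breaks
#'   and reporting).
#' @return Tibble of selected SNPs in selection order: `snp_id`, `step`,
#'   `f_step` (partial F at selection), `pos_bp`. Attribute
#'   `collinear_skipped` lists candidates dropped for collinearity.
#' @export
forward_select_chromosome <- function(ebv, genos, threshold_f,
                                      weights = rep(1, length(ebv)),
                                      positions = NULL) {
  genos <- as.matrix(genos)
  n <- length(ebv)
  stopifnot(nrow(genos) == n, length(weights) == n)
  ids <- colnames(genos)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genos)))
  if (is.null(positions)) positions <- rep(NA_real_, ncol(genos))

  yw <- weights * ebv
  Xw <- weights * genos               # candidate columns, weighted
  base <- matrix(weights, n, 1)       # weighted intercept

  selected <- integer(0)
  f_sel <- numeric(0)
  collinear <- character(0)
  remaining <- seq_len(ncol(genos))

  # Orthonormal basis of the current design, updated by Gram-Schmidt.
  Qb <- qr.Q(qr(base))
  y_res <- yw - Qb %*% crossprod(Qb, yw)
  C_res <- Xw - Qb %*% crossprod(Qb, Xw)

  while (length(remaining)) {
    q <- length(selected)
    df <- n - q - 2
    if (df < 1) break
    cc <- colSums(C_res[, remaining, drop = FALSE]^2)
    cy <- drop(crossprod(C_res[, remaining, drop = FALSE], y_res))
    ok <- cc > 1e-9 * sum(weights^2)
    if (any(!ok)) {
      collinear <- union(collinear, ids[remaining[!ok]])
      remaining <- remaining[ok]
      cc <- cc[ok]; cy <- cy[ok]
      if (!length(remaining)) break
    }
    ssr <- cy^2 / cc
    sse <- sum(y_res^2) - ssr
    f <- ssr / (sse / df)
    fmax <- max(f)
    if (!is.finite(fmax) || fmax < threshold_f) break
    tied <- which(f >= fmax - 1e-9 * max(1, abs(fmax)))
    if (length(tied) > 1) {
      cand <- remaining[tied]
      ord <- order(positions[cand], ids[cand])
      pick <- tied[ord[1]]
    } else {
      pick <- tied
    }
    j <- remaining[pick]
    selected <- c(selected, j)
    f_sel <- c(f_sel, f[pick])
    # Orthogonalize everything against the chosen column.
    v <- C_res[, j]
    v <- v / sqrt(sum(v^2))
    y_res <- y_res - v * sum(v * y_res)
    C_res <- C_res - v %*% crossprod(v, C_res)
    remaining <- remaining[-pick]
  }

  out <- tibble::tibble(snp_id = ids[selected],
                        step = seq_along(selected),
                        f_step = f_sel,
                        pos_bp = positions[selected])
  attr(out, "collinear_skipped") <- collinear
  out
}

#' Chromosome-wise forward selection over a whole scan
#'
#' Takes the single-SNP scan, restricts to candidates exceeding the
#' genome-wide threshold, and runs [forward_select_chromosome()] independently
#' within each chromosome, mirroring the three-step scan / forward-selection /
#' final-model design. Because selection is chromosome-local, the processing
#' order of chromosomes cannot change the union panel.
#'
#' @param scan A [genome_scan()] result.
#' @param ebv An `animal_model` or data frame with `animal_id`, `ebv`,
#'   `accuracy`.
#' @param geno The [geno_matrix()] used for the scan.
#' @param threshold A `perm_threshold` or numeric genome-wide F threshold.
#' @param weights Optional per-animal weights; default accuracies' square
#'   roots.
#' @param trait Optional trait label carried into the output.
#' @return Tibble of class `selected_panel`: `trait`, `snp_id`, `chrom`,
#'   `pos_bp`, `step`, `f_step`, ordered by chromosome then selection step.
#'   Attributes: `threshold_f`, `n_candidates`, `final_r2` (the weighted
#'   multiple-regression R-squared of the final all-SNP model, `NA` when the
#'   panel is empty).
#' @export
forward_select <- function(scan, ebv, geno, threshold, weights = NULL,
                           trait = NA_character_) {
  thr <- if (inherits(threshold, "perm_threshold")) threshold$threshold_f
         else as.numeric(threshold)
  ebv <- resolve_ebv(ebv)
  ebv <- align_ebv_geno(ebv, geno)
  if (is.null(weights)) weights <- weight_vector(ebv$accuracy)

  cand <- scan$snp_id[!is.na(scan$f_stat) & !scan$skipped &
                        scan$f_stat >= thr]
  map <- geno$snp_map
  panel <- tibble::tibble(trait = character(), snp_id = character(),
                          chrom = character(), pos_bp = double(),
                          step = integer(), f_step = double())
  if (length(cand)) {
    cand_map <- map[map$snp_id %in% cand, ]
    for (ch in unique(cand_map$chrom)) {
      snps <- cand_map$snp_id[cand_map$chrom == ch]
      idx <- match(snps, map$snp_id)
      sel <- forward_select_chromosome(
        ebv$ebv, geno$calls[, idx, drop = FALSE], thr, weights,
        positions = map$pos_bp[idx])
      if (nrow(sel)) {
        panel <- dplyr::bind_rows(panel, tibble::tibble(
          trait = trait, snp_id = sel$snp_id, chrom = as.character(ch),
          pos_bp = sel$pos_bp, step = sel$step, f_step = sel$f_step))
      }
    }
  }
  class(panel) <- c("selected_panel", class(panel))
  attr(panel, "threshold_f") <- thr
  attr(panel, "n_candidates") <- length(cand)
  attr(panel, "final_r2") <- if (nrow(panel)) {
    final_model_r2(ebv$ebv, geno$calls[, match(panel$snp_id, map$snp_id),
                                       drop = FALSE], weights)
  } else NA_real_
  panel
}

#' Variance explained by the final joint SNP model
#'
#' Multiple-regression R-squared of the weighted EBVs on all selected SNP
#' dosages jointly (weighted intercept included). This is the fixed-effects
#' ("anova") estimate of the EBV variance captured by the panel; it ignores
#' relationships between animals and is upward-biased for panels chosen by
#' in-sample significance -- compare with [gblup_variance_explained()].
#'
#' @param ebv Per-animal EBVs.
#' @param panel_genos Animals x panel-SNPs dosage matrix.
#' @param weights Per-animal weights (default equal).
#' @return R-squared in `[0, 1]`.
#' @export
final_model_r2 <- function(ebv, panel_genos, weights = rep(1, length(ebv))) {
  panel_genos <- as.matrix(panel_genos)
  n <- length(ebv)
  if (ncol(panel_genos) == 0) stop("panel is empty")
  if (ncol(panel_genos) >= n - 1) stop("saturated model: panel size must be ",
                                       "smaller than n - 1")
  yw <- weights * ebv
  X0 <- matrix(weights, n, 1)
  X1 <- cbind(X0, weights * panel_genos)
  sse0 <- sum(stats::lm.fit(X0, yw)$residuals^2)
  sse1 <- sum(stats::lm.fit(X1, yw)$residuals^2)
  max(0, min(1, 1 - sse1 / sse0))
}
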