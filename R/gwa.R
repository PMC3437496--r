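#' Accuracy weights for the association scan
#'
#' The scan weights each animal by the Cholesky factor of the diagonal matrix
#' of its EBV accuracy, i.e. the elementwise square root.
#'
#' @param accuracies Per-animal EBV accuracies in `[0, 1]`.
#' @return Per-animal weights `sqrt(accuracy)`.
#' @export
weight_vector <- function(accuracies) {
  if (any(accuracies < 0 | accuracies > 1)) {
    stop("accuracies must lie in [0, 1]")
  }
  if (any(accuracies == 0)) {
    warning(sum(accuracies == 0),
            " animal(s) with accuracy 0 receive weight 0 and contribute ",
            "nothing to the scan")
  }
  sqrt(accuracies)
}

# Core weighted single-SNP F statistics for a whole SNP matrix.
#
# Both sides of the regression are premultiplied by the weight vector w, so
# the model is w*y ~ w + w*g (the weighted intercept column is w itself).
# With u = w^2 all per-SNP quantities reduce to three crossproducts, which is
# what makes the permutation scan a handful of DGEMMs.
weighted_f_core <- function(u, uy, Syy, Gm, G2m, n, c1 = NULL, c2 = NULL) {
  S <- sum(u)
  Sy <- sum(uy)
  if (is.null(c1)) c1 <- drop(crossprod(Gm, u))
  if (is.null(c2)) c2 <- drop(crossprod(G2m, u))
  c3 <- drop(crossprod(Gm, uy))
  btb <- c2 - c1^2 / S
  bty <- c3 - c1 * Sy / S
  yty <- Syy - Sy^2 / S
  skip <- btb < 1e-9 * S
  ssr <- bty^2 / btb
  f <- ssr / ((yty - ssr) / (n - 2))
  f[ssr == 0] <- 0        # no covariance with the response: F is exactly 0
  f[skip] <- NA_real_
  list(f = f, skipped = skip)
}

resolve_ebv <- function(ebv) {
  if (inherits(ebv, "animal_model")) ebv <- ebv$ebv
  ebv <- tibble::as_tibble(ebv)
  stopifnot(all(c("animal_id", "ebv") %in% names(ebv)))
  ebv
}

align_ebv_geno <- function(ebv, G) {
  ids_g <- animal_ids(G)
  extra <- setdiff(ebv$animal_id, ids_g)
  miss <- setdiff(ids_g, ebv$animal_id)
  if (length(extra) || length(miss)) {
    stop("animal ids do not align between EBVs and genotypes; ",
         "missing from genotypes: ",
         paste(utils::head(extra, 5), collapse = ", "),
         "; missing from EBVs: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  ebv[match(ids_g, ebv$animal_id), ]
}

#' Weighted F statistic for one SNP
#'
#' Regresses elementwise-weighted EBVs on an intercept and the
#' elementwise-weighted genotype dosage; returns the F statistic for the
#' additive SNP effect, `F = SSreg / (SSE / (n - 2))`.
#'
#' @param ebv Per-animal EBVs.
#' @param genotype Per-animal dosages (0/1/2 or imputed real values).
#' @param weights Per-animal weights (e.g. [weight_vector()] of accuracies).
#' @return The F statistic, or `NA` with a warning when the weighted genotype
#'   variance is zero.
#' @export
snp_f_statistic <- function(ebv, genotype, weights = rep(1, length(ebv))) {
  n <- length(ebv)
  stopifnot(length(genotype) == n, length(weights) == n)
  if (n < 3) stop("at least 3 animals are required")
  u <- weights^2
  out <- weighted_f_core(u, u * ebv, sum(u * ebv^2),
                         matrix(genotype, ncol = 1),
                         matrix(genotype^2, ncol = 1), n)
  if (out$skipped[1]) {
    warning("weighted genotype variance is zero; F undefined")
    return(NA_real_)
  }
  out$f[1]
}

#' Genome-wide accuracy-weighted association scan
#'
#' Computes the weighted single-SNP F statistic of [snp_f_statistic()] for
#' every SNP, plus a nominal p-value from the F(1, n-2) distribution (for
#' reporting only; genome-wide significance decisions should use the
#' permutation threshold of [permutation_threshold()]).
#'
#' @param ebv An `animal_model` fit or a data frame with `animal_id`, `ebv`
#'   and (unless `weights` is given) `accuracy`.
#' @param geno A [geno_matrix()] with no missing calls, same animal set.
#' @param weights Optional per-animal weights; default
#'   `weight_vector(accuracy)`.
#' @return A tibble of class `scan_result`: `snp_id`, `chrom`, `pos_bp`,
#'   `f_stat`, `nominal_p`, `skipped` (SNPs with zero weighted variance get
#'   `NA` statistics and `skipped = TRUE`). Attribute `n_animals`.
#' @export
genome_scan <- function(ebv, geno, weights = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (anyNA(geno$calls)) stop("genotypes contain missing calls; impute first")
  ebv <- resolve_ebv(ebv)
  ebv <- align_ebv_geno(ebv, geno)
  if (is.null(weights)) {
    if (!"accuracy" %in% names(ebv)) {
      stop("supply weights or an accuracy column")
    }
    weights <- weight_vector(ebv$accuracy)
  }
  n <- nrow(ebv)
  u <- weights^2
  core <- weighted_f_core(u, u * ebv$ebv, sum(u * ebv$ebv^2),
                          geno$calls, geno$calls^2, n)
  out <- tibble::tibble(
    snp_id = geno$snp_map$snp_id,
    chrom = geno$snp_map$chrom,
    pos_bp = geno$snp_map$pos_bp,
    f_stat = unname(core$f),
    nominal_p = unname(stats::pf(core$f, 1, n - 2, lower.tail = FALSE)),
    skipped = unname(core$skipped)
  )
  class(out) <- c("scan_result", class(out))
  attr(out, "n_animals") <- n
  out
}

#' Permutation genome-wide significance threshold
#'
#' Estimates the empirical genome-wide threshold controlling family-wise type
#' I error at `alpha`: for each permutation the (EBV, weight) pairs are
#' shuffled across animals while the genotypes stay fixed, the full scan is
#' recomputed, and the genome-wide maximum F recorded; the threshold is the
#' `1 - alpha` empirical quantile of the max-F sample (smallest order
#' statistic with at least `1 - alpha` coverage, a conservative deterministic
#' choice).
#'
#' @inheritParams genome_scan
#' @param n_perm Number of permutations (the study-scale default elsewhere in
#'   the package is 10000; values below 100 give unstable tail quantiles and
#'   trigger a warning).
#' @param alpha Genome-wide type I error rate.
#' @param seed Integer seed; identical seeds give identical thresholds.
#' @param permute `"weighted_pairs"` (default) shuffles EBVs with their
#'   weights attached; `"raw_ebv"` shuffles EBVs while weights stay with the
#'   genotyped animals. The pairing convention is exposed because either
#'   reading of the two-stage design is defensible.
#' @param block Permutations per matrix-product block (memory/speed knob).
#' @return List of class `perm_threshold`: `threshold_f`, `max_f` (the
#'   permutation sample), `n_perm`, `alpha`, `seed`, `permute`.
#' @export
permutation_threshold <- function(ebv, geno, n_perm = 10000, alpha = 0.05,
                                  seed = 1L, weights = NULL,
                                  permute = c("weighted_pairs", "raw_ebv"),
                                  block = 200L) {
  stopifnot(inherits(geno, "geno_matrix"), alpha > 0, alpha <= 1)
  permute <- match.arg(permute)
  if (n_perm < 100) {
    warning("n_perm < 100 gives an unstable tail quantile")
  }
  if (anyNA(geno$calls)) stop("genotypes contain missing calls; impute first")
  ebv <- resolve_ebv(ebv)
  ebv <- align_ebv_geno(ebv, geno)
  if (is.null(weights)) {
    if (!"accuracy" %in% names(ebv)) {
      stop("supply weights or an accuracy column")
    }
    weights <- weight_vector(ebv$accuracy)
  }
  n <- nrow(ebv)
  y <- ebv$ebv
  u <- weights^2
  Gm <- geno$calls
  G2m <- Gm^2
  Syy <- sum(u * y^2)   # invariant under pair permutation
  c1_fix <- drop(crossprod(Gm, u))
  c2_fix <- drop(crossprod(G2m, u))

  set.seed(seed)
  max_f <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    perms <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
    if (permute == "weighted_pairs") {
      Up <- matrix(u[perms], n, b)
      UYp <- matrix((u * y)[perms], n, b)
      C1 <- crossprod(Gm, Up)
      C2 <- crossprod(G2m, Up)
      S <- colSums(Up)
    } else {
      Up <- matrix(u, n, b)
      UYp <- u * matrix(y[perms], n, b)
      C1 <- matrix(c1_fix, ncol(Gm), b)
      C2 <- matrix(c2_fix, ncol(Gm), b)
      S <- rep(sum(u), b)
    }
    C3 <- crossprod(Gm, UYp)
    Sy <- colSums(UYp)
    Syy_b <- if (permute == "weighted_pairs") rep(Syy, b) else
      colSums(u * matrix(y[perms], n, b)^2)

    btb <- C2 - sweep(C1^2, 2, S, "/")
    bty <- C3 - sweep(C1, 2, Sy / S, "*")
    ssr <- bty^2 / btb
    yty <- Syy_b - Sy^2 / S
    fmat <- ssr / (sweep(-ssr, 2, yty, "+") / (n - 2))
    fmat[ssr == 0] <- 0
    fmat[btb < 1e-9 * rep(S, each = nrow(fmat))] <- NA_real_
    max_f[done + seq_len(b)] <- apply(fmat, 2, max, na.rm = TRUE)
    done <- done + b
  }
  k <- max(1L, ceiling((1 - alpha) * n_perm))
  threshold <- sort(max_f)[k]
  structure(list(threshold_f = threshold, max_f = max_f, n_perm = n_perm,
                 alpha = alpha, seed = seed, permute = permute),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("<perm_threshold> F = %.4f (alpha = %g, %d permutations, %s)\n",
              x$threshold_f, x$alpha, x$n_perm, x$permute))
  invisible(x)
}

#' Flag SNPs exceeding a genome-wide threshold
#'
#' @param scan A [genome_scan()] result.
#' @param threshold A `perm_threshold` object or a numeric F threshold.
#' @return The scan tibble with an `exceeds_threshold` column
#'   (`f_stat >= threshold_f`; skipped SNPs are `FALSE`) and the threshold
#'   stored in attribute `threshold_f`.
#' @export
apply_threshold <- function(scan, threshold) {
  thr <- if (inherits(threshold, "perm_threshold")) threshold$threshold_f
         else as.numeric(threshold)
  scan$exceeds_threshold <- !is.na(scan$f_stat) & scan$f_stat >= thr
  attr(scan, "threshold_f") <- thr
  scan
}
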