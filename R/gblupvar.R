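#' Additive variance explained by a SNP panel via the two-model GBLUP contrast
#'
#' Fits two REML models sharing the same genomic relationship matrix: a null
#' model with only a fixed mean, estimating the total additive genetic
#' variance, and a second model that additionally fits the panel SNPs' allele
#' substitution effects as fixed covariates, estimating the residual additive
#' variance not captured by the panel. The proportion explained is
#' `(sigma2_a_null - sigma2_a_snp) / sigma2_a_null`. Because the GRM absorbs
#' family resemblance, this estimate is robust to the winner's-curse inflation
#' that affects the fixed-effects R-squared of [final_model_r2()] on panels
#' selected for in-sample significance.
#'
#' @param y Per-animal response, typically the trait EBVs (weighted when a
#'   weight vector is given, matching the scan stage).
#' @param panel_genos Animals x panel-SNPs dosage matrix (may have zero
#'   columns: the two models are then identical and the proportion is 0).
#' @param grm PSD genomic relationship matrix over the same animals, or a
#'   [grm_eigen()] of it (reused by both fits).
#' @param weights Optional per-animal weights; when supplied, both sides of
#'   each model are premultiplied elementwise (the fixed mean becomes the
#'   weight column), mirroring the weighted association stage.
#' @param convergence_sigfigs,max_iterations REML stopping controls, as in
#'   [fit_animal_model()].
#' @return A one-row tibble of class `variance_contrast`: `sigma2_a_null`,
#'   `sigma2_a_snp`, `sigma2_e_null`, `sigma2_e_snp`, `proportion_explained`,
#'   `n_snps`.
#' @export
gblup_variance_explained <- function(y, panel_genos, grm, weights = NULL,
                                     convergence_sigfigs = 3L,
                                     max_iterations = 2000L) {
  panel_genos <- as.matrix(panel_genos)
  n <- length(y)
  eig <- if (inherits(grm, "grm_eigen")) grm else grm_eigen(grm)
  stopifnot(length(eig$values) == n)
  w <- if (is.null(weights)) rep(1, n) else weights
  yw <- w * y
  X0 <- matrix(w, n, 1, dimnames = list(NULL, "mean"))

  fit0 <- reml_em(yw, X0, eig = eig, sigfigs = convergence_sigfigs,
                  max_iterations = max_iterations)
  if (fit0$sigma2_a <= 2e-8 ||
      fit0$sigma2_a <= 1e-6 * (fit0$sigma2_a + fit0$sigma2_e)) {
    stop("total additive variance is approximately zero; ",
         "proportion explained is undefined")
  }

  if (ncol(panel_genos) > 0) {
    X1 <- cbind(X0, w * panel_genos)
    keep <- qr(X1)$pivot[seq_len(qr(X1)$rank)]
    X1 <- X1[, sort(keep), drop = FALSE]
    fit1 <- reml_em(yw, X1, eig = eig, sigfigs = convergence_sigfigs,
                    max_iterations = max_iterations)
  } else {
    fit1 <- fit0
  }

  prop <- (fit0$sigma2_a - fit1$sigma2_a) / fit0$sigma2_a
  if (prop < 0) {
    warning("panel model estimated more additive variance than the null ",
            "model; proportion floored at 0")
    prop <- 0
  }
  out <- tibble::tibble(
    sigma2_a_null = fit0$sigma2_a, sigma2_a_snp = fit1$sigma2_a,
    sigma2_e_null = fit0$sigma2_e, sigma2_e_snp = fit1$sigma2_e,
    proportion_explained = prop, n_snps = ncol(panel_genos))
  class(out) <- c("variance_contrast", class(out))
  out
}
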