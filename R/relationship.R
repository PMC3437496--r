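#' Pedigree numerator relationship matrix
#'
#' Standard tabular (recursive) computation of expected additive
#' relationships. Parents absent from the pedigree are treated as unrelated,
#' non-inbred base animals.
#'
#' @param pedigree Data frame with columns `animal_id`, `sire_id`, `dam_id`
#'   (`NA` for unknown parents). Must be acyclic.
#' @return Symmetric matrix with animal ids as dimnames and attribute
#'   `kind = "pedigree_A"`.
#' @export
numerator_matrix <- function(pedigree) {
  pedigree <- tibble::as_tibble(pedigree)
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(pedigree)))
  ids <- pedigree$animal_id
  if (anyDuplicated(ids)) stop("duplicated animal_id in pedigree")
  n <- length(ids)
  si <- match(pedigree$sire_id, ids)  # NA = unknown/base parent
  di <- match(pedigree$dam_id, ids)

  # Topological order: place animals whose listed parents are already placed.
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) {
      if (all(placed)) break
      stop("pedigree contains a cycle (an animal is its own ancestor)")
    }
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_along(ord)) {
    i <- ord[k]
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(s) && !is.na(d)) A[s, d] else 0)
    if (k > 1) {
      j <- ord[seq_len(k - 1)]
      as_ <- if (!is.na(s)) A[j, s] else rep(0, length(j))
      ad_ <- if (!is.na(d)) A[j, d] else rep(0, length(j))
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
    }
  }
  attr(A, "kind") <- "pedigree_A"
  A
}

#' Mean identity-by-state allele sharing
#'
#' For each SNP the pairwise share is `1 - |g_i - g_j| / 2`; the matrix entry
#' is the mean share over SNPs, in `[0, 1]`. Requires complete integer 0/1/2
#' calls (impute with the `mode` or `sample` method first; real-valued
#' expected-dosage imputation is not supported by the sharing statistic).
#'
#' @param G A [geno_matrix()] without missing calls.
#' @return Symmetric matrix with attribute `kind = "raw_sharing"`.
#' @export
allele_sharing_matrix <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  calls <- G$calls
  m <- ncol(calls)
  if (m == 0) stop("genotype matrix has zero SNPs")
  if (anyNA(calls)) stop("missing calls present; impute before allele sharing")
  if (!all(calls %in% c(0, 1, 2))) {
    stop("allele sharing requires integer 0/1/2 calls; use mode or sample ",
         "imputation")
  }
  I0 <- (calls == 0) * 1; I1 <- (calls == 1) * 1; I2 <- (calls == 2) * 1
  N01 <- tcrossprod(I0, I1)
  N12 <- tcrossprod(I1, I2)
  N02 <- tcrossprod(I0, I2)
  D <- N01 + t(N01) + N12 + t(N12) + 2 * (N02 + t(N02))
  S <- 1 - D / (2 * m)
  dimnames(S) <- list(rownames(calls), rownames(calls))
  attr(S, "kind") <- "raw_sharing"
  S
}

#' Calibrate allele sharing to numerator relationships
#'
#' Fits an affine map from allele-sharing coefficients to pedigree numerator
#' relationship coefficients over a set of animal pairs (off-diagonal) and,
#' separately, over the diagonal, then applies the maps to every entry,
#' symmetrizes, and conditions the result to positive semi-definiteness by
#' eigenvalue clipping. The map is the classical (inverse) least-squares
#' calibration -- sharing regressed on the error-free pedigree coefficients
#' and inverted -- so the finite-SNP sampling noise of the sharing statistic
#' does not attenuate the calibrated relationships. When the pedigree diagonal is
#' constant (no inbreeding variation) the diagonal slope is unidentifiable and
#' the off-diagonal slope is reused with the intercept chosen to match the
#' mean pedigree diagonal.
#'
#' @param S Allele-sharing matrix from [allele_sharing_matrix()].
#' @param A Numerator relationship matrix over the same animals (same order).
#' @param pairs Two-column integer matrix of off-diagonal index pairs used for
#'   the fit; default all unordered pairs.
#' @return Calibrated genomic relationship matrix with attributes
#'   `kind = "calibrated_G"`, `calibration` (off-diagonal `slope`,
#'   `intercept`) and `calibration_diag`.
#' @export
calibrate_grm <- function(S, A, pairs = NULL) {
  if (!identical(dim(S), dim(A))) stop("S and A have different dimensions")
  if (!is.null(rownames(S)) && !is.null(rownames(A)) &&
      !identical(rownames(S), rownames(A))) {
    stop("S and A have different animal orderings")
  }
  if (is.null(pairs)) {
    pairs <- which(upper.tri(S), arr.ind = TRUE)
  }
  if (!nrow(pairs)) stop("no calibration pairs supplied")
  s <- S[pairs]; a <- A[pairs]
  if (stats::var(s) < .Machine$double.eps || stats::var(a) == 0) {
    stop("allele sharing or pedigree relationship is constant over the ",
         "calibration pairs; slope unidentifiable")
  }
  # Inverse (classical) calibration: regress sharing on the error-free
  # pedigree coefficients and invert, so finite-SNP sampling noise in the
  # sharing statistic does not attenuate the calibrated relationships.
  slope <- stats::var(a) / stats::cov(s, a)
  intercept <- mean(a) - slope * mean(s)

  sd_ <- diag(S); ad_ <- diag(A)
  if (stats::var(sd_) > 1e-12 && stats::var(ad_) > 1e-12) {
    slope_d <- stats::var(ad_) / stats::cov(sd_, ad_)
    int_d <- mean(ad_) - slope_d * mean(sd_)
  } else {
    slope_d <- slope
    int_d <- mean(ad_) - slope_d * mean(sd_)
  }

  Gc <- slope * S + intercept
  diag(Gc) <- slope_d * sd_ + int_d
  Gc <- (Gc + t(Gc)) / 2
  Gc <- make_psd(Gc)
  dimnames(Gc) <- dimnames(S)
  attr(Gc, "kind") <- "calibrated_G"
  attr(Gc, "calibration") <- c(slope = slope, intercept = intercept)
  attr(Gc, "calibration_diag") <- c(slope = slope_d, intercept = int_d)
  Gc
}

#' VanRaden genomic relationship matrix
#'
#' Allele-frequency-centered cross-product scaled by `2 * sum(p * (1 - p))`,
#' with frequencies computed from the data. Provided as a reference
#' alternative to the calibrated construction.
#'
#' @param G A [geno_matrix()] without missing calls.
#' @return Symmetric matrix with attribute `kind = "vanraden_G"`.
#' @export
vanraden_grm <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  calls <- G$calls
  if (anyNA(calls)) stop("missing calls present; impute first")
  p <- colMeans(calls) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNPs present; filter on MAF before vanraden_grm")
  }
  Z <- sweep(calls, 2, 2 * p)
  Gv <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(Gv) <- list(rownames(calls), rownames(calls))
  attr(Gv, "kind") <- "vanraden_G"
  Gv
}

#' Condition a symmetric matrix to positive semi-definiteness
#'
#' Eigenvalue clipping: negative eigenvalues are raised to `1e-6` and the
#' matrix reconstructed (returned unchanged when already PSD).
#'
#' @param M Symmetric matrix.
#' @param floor Replacement value for negative eigenvalues.
#' @return PSD matrix with the same dimnames.
#' @export
make_psd <- function(M, floor = 1e-6) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) >= 0) return(M)
  lam <- e$values
  lam[lam < 0] <- floor
  out <- e$vectors %*% (t(e$vectors) * lam)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(M)
  for (at in c("kind", "calibration", "calibration_diag")) {
    attr(out, at) <- attr(M, at)
  }
  out
}
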