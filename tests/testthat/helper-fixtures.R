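# Shared fixture builders. Everything is generated in code; no stored data.

small_config <- function(...) {
  args <- list(n_sires = 10, n_offspring = 80, n_snps = 200,
               n_chromosomes = 4, n_qtl_per_trait = 5, seed = 42,
               missing_rate = 0)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Hand-built genotype matrix with explicit map.
toy_geno <- function(calls, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  rownames(calls) <- sprintf("A%02d", seq_len(nrow(calls)))
  colnames(calls) <- sprintf("s%02d", seq_len(m))
  geno_matrix(calls, tibble::tibble(snp_id = colnames(calls),
                                    chrom = chrom, pos_bp = pos))
}

# Independent brute-force weighted F via explicit normal equations.
oracle_weighted_f <- function(ebv, genotype, weights) {
  yw <- weights * ebv
  X <- cbind(weights, weights * genotype)
  XtX <- t(X) %*% X
  bh <- solve(XtX, t(X) %*% yw)
  res <- yw - X %*% bh
  sse <- sum(res^2)
  res0 <- yw - X[, 1, drop = FALSE] %*%
    solve(t(X[, 1]) %*% X[, 1], t(X[, 1]) %*% yw)
  sse0 <- sum(res0^2)
  ((sse0 - sse) / 1) / (sse / (length(ebv) - 2))
}

# Independent greedy forward selection using lm() and explicit partial-F
# extra-sum-of-squares tests at each step (no shared code with the package).
oracle_forward_select <- function(ebv, genos, threshold_f, weights,
                                  positions) {
  yw <- weights * ebv
  n <- length(ebv)
  sel <- integer(0)
  remaining <- seq_len(ncol(genos))
  repeat {
    df_res <- n - length(sel) - 2
    if (df_res < 1 || !length(remaining)) break
    X0 <- cbind(weights, weights * genos[, sel, drop = FALSE])
    sse0 <- sum(stats::lm.fit(X0, yw)$residuals^2)
    fs <- sapply(remaining, function(j) {
      X1 <- cbind(X0, weights * genos[, j])
      if (qr(X1)$rank < ncol(X1)) return(NA_real_)
      sse1 <- sum(stats::lm.fit(X1, yw)$residuals^2)
      (sse0 - sse1) / (sse1 / df_res)
    })
    if (all(is.na(fs))) break
    fmax <- max(fs, na.rm = TRUE)
    if (fmax < threshold_f) break
    tied <- which(!is.na(fs) & fs >= fmax - 1e-9 * max(1, abs(fmax)))
    cand <- remaining[tied]
    pick <- cand[order(positions[cand], colnames(genos)[cand])][1]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  sel
}

# Strip all attributes except dim (drop dimnames and kind/calibration tags)
bare <- function(M) { attributes(M) <- list(dim = dim(M)); M }
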