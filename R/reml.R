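#' Eigendecomposition of a relationship matrix
#'
#' Precomputes the spectral decomposition used by the REML engine so that
#' several models sharing one GRM (e.g. the two-model GBLUP contrast) pay the
#' O(n^3) cost once.
#'
#' @param G Symmetric PSD relationship matrix with animal ids as dimnames.
#' @return List of class `grm_eigen` with `values`, `vectors`, `ids`,
#'   `diag` (the diagonal of `G`).
#' @export
grm_eigen <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  structure(list(values = pmax(e$values, 0), vectors = e$vectors,
                 ids = rownames(G), diag = diag(G)),
            class = "grm_eigen")
}

# EM-REML for y = X b + Z u + e with Var(u) = G sigma2_a, Var(e) = I sigma2_e.
#
# Works in the eigenbasis of K = Z G Z' where V is diagonal, so each EM
# iteration is O(n p^2). `z_index` maps records to animals (NULL = one record
# per animal in G's order, the usual animal model). EM updates (one random
# effect, Henderson's equations):
#   sigma2_a' = (u' G^-1 u + tr(G^-1 PEV)) / q
#   sigma2_e' = (y'y - b'X'y - u'Z'y) / (n - p)
# both evaluated without ever inverting G (see the identities in the code).
reml_em <- function(y, X, G = NULL, z_index = NULL, eig = NULL,
                    sigfigs = 3L, max_iterations = 2000L,
                    var_floor = 1e-8) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design matrix is rank deficient")
  identity_z <- is.null(z_index)

  if (identity_z) {
    if (is.null(eig)) {
      stopifnot(!is.null(G), nrow(G) == n)
      eig <- grm_eigen(G)
    }
    stopifnot(length(eig$values) == n)
    d <- eig$values
    U <- eig$vectors
    q <- n
    g_diag <- eig$diag
  } else {
    stopifnot(!is.null(G), length(z_index) == n)
    q <- nrow(G)
    K <- G[z_index, z_index, drop = FALSE]
    eK <- eigen(K, symmetric = TRUE)
    d <- pmax(eK$values, 0)
    U <- eK$vectors
    g_diag <- diag(G)
  }

  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  yy <- sum(yt^2)
  Xty <- drop(crossprod(Xt, yt))

  vy <- stats::var(y)
  s2a <- vy / 2
  s2e <- vy / 2
  h2_traj <- numeric(0)
  floored <- FALSE
  converged <- FALSE
  iter <- 0L

  em_step <- function(s2a, s2e) {
    v <- d * s2a + s2e
    Xv <- Xt / v
    XtVX <- crossprod(Xt, Xv)
    Cmat <- solve(XtVX)
    beta <- drop(Cmat %*% crossprod(Xv, yt))
    rt <- (yt - drop(Xt %*% beta)) / v
    uGu <- s2a^2 * sum(d * rt^2)
    Tm <- crossprod(Xt, Xt * (d / v^2))
    tr_term <- q * s2a - s2a^2 * (sum(d / v) - sum(Cmat * Tm))
    s2a_new <- (uGu + tr_term) / q
    s2e_new <- (yy - sum(beta * Xty) - s2a * sum(d * rt * yt)) / (n - p)
    list(s2a = s2a_new, s2e = s2e_new, beta = beta, rt = rt, v = v,
         Cmat = Cmat)
  }

  # EM map with the variance floor applied.
  em_map <- function(th) {
    st <- em_step(th[1], th[2])
    new <- c(st$s2a, st$s2e)
    if (any(new < var_floor)) {
      if (!floored) {
        warning("variance component hit the lower floor (", var_floor,
                "); estimate lies on the boundary")
        floored <<- TRUE
      }
      new <- pmax(new, var_floor)
    }
    new
  }

  # SQUAREM-accelerated EM: plain EM creeps linearly near the optimum (its
  # rate is the fraction of missing information, close to 1 at low h2), so a
  # significant-figure stopping rule on raw EM iterates would freeze short of
  # the REML optimum. Each cycle composes two EM map evaluations with a
  # safeguarded extrapolation sharing the same fixed point, then one
  # stabilizing EM step; convergence is declared when the heritability agrees
  # across cycles to `sigfigs` significant figures.
  th <- c(s2a, s2e)
  while (iter < max_iterations) {
    iter <- iter + 1L
    th1 <- em_map(th)
    th2 <- em_map(th1)
    r <- th1 - th
    vv <- th2 - th1 - r
    if (sqrt(sum(vv^2)) < 1e-30) {
      th_acc <- th2
    } else {
      alpha <- min(-sqrt(sum(r^2)) / sqrt(sum(vv^2)), -1)
      th_acc <- th - 2 * alpha * r + alpha^2 * vv
      if (any(th_acc <= 0) || any(!is.finite(th_acc))) th_acc <- th2
    }
    th <- em_map(th_acc)
    s2a <- th[1]; s2e <- th[2]
    h2_traj <- c(h2_traj, s2a / (s2a + s2e))
    len <- length(h2_traj)
    if (len >= 3) {
      last3 <- signif(h2_traj[(len - 2):len], sigfigs)
      if (length(unique(last3)) == 1L) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    rlang::abort(
      paste0("REML did not converge in ", max_iterations, " iterations"),
      class = "rfigwas_reml_nonconvergence", trajectory = h2_traj)
  }

  h2 <- s2a / (s2a + s2e)
  bracketed <- any(h2_traj > h2) && any(h2_traj < h2)

  # Final solutions and prediction error variances.
  v <- d * s2a + s2e
  Xv <- Xt / v
  XtVX <- crossprod(Xt, Xv)
  Cmat <- solve(XtVX)
  beta <- drop(Cmat %*% crossprod(Xv, yt))
  res <- yt - drop(Xt %*% beta)
  rt <- res / v
  loglik <- -0.5 * (sum(log(v)) + determinant(XtVX)$modulus[1] +
                      sum(res^2 / v))

  if (identity_z) {
    u <- s2a * drop(U %*% (d * rt))
    Q <- U * rep(d, each = n)           # G U = U D when Z = I
  } else {
    W <- rowsum(U, group = factor(z_index, levels = seq_len(q)))
    u <- s2a * drop(G %*% (W %*% rt))
    Q <- G %*% W
  }
  diag1 <- rowSums(sweep(Q^2, 2, v, "/"))
  B <- Q %*% Xv
  Rc <- chol((Cmat + t(Cmat)) / 2)
  diag2 <- rowSums((B %*% t(Rc))^2)
  pev <- s2a * g_diag - s2a^2 * (diag1 - diag2)
  pev <- pmin(pmax(pev, 0), s2a * g_diag)
  acc <- if (s2a <= var_floor) rep(0, q) else
    sqrt(pmax(0, 1 - pev / (s2a * g_diag)))

  list(sigma2_a = s2a, sigma2_e = s2e, h2 = h2, converged = converged,
       bracketed = bracketed, iterations = iter, h2_trajectory = h2_traj,
       beta = beta, u = u, pev = pev, accuracy = acc, loglik = loglik,
       n = n, p = p)
}

#' Fit a single-trait animal model by EM-REML
#'
#' Fits `y = X b + u + e` with `Var(u) = G sigma2_a` (G a genomic or pedigree
#' relationship matrix) and `Var(e) = I sigma2_e`, estimating the variance
#' components by EM-REML until successive heritability iterates agree to
#' `convergence_sigfigs` significant figures. Returns BLUP breeding values and
#' their accuracies `sqrt(1 - PEV / (sigma2_a * G_ii))`. Fixed factors are
#' fitted with treatment contrasts (first level dropped).
#'
#' @param data Data frame with one row per record: the trait column, the fixed
#'   factor columns and an id column. Repeated ids are allowed (multiple
#'   records per animal).
#' @param trait Name of the trait column.
#' @param grm Relationship matrix with animal ids as dimnames covering every
#'   id in `data`, or a [grm_eigen()] precomputed from it (single-record case
#'   only).
#' @param fixed Character vector of fixed factor column names (default
#'   pen, year, season). Use `character(0)` for a mean-only model.
#' @param convergence_sigfigs Significant figures of heritability agreement
#'   required between successive iterates (default 3).
#' @param max_iterations Iteration cap; non-convergence is an error carrying
#'   the heritability trajectory.
#' @param id_col Name of the animal id column.
#' @return An object of class `animal_model`: trait name, `ebv` tibble
#'   (`animal_id`, `ebv`, `accuracy`), `varcomp` list (variances, h2,
#'   convergence diagnostics including the h2 trajectory and whether it
#'   bracketed the final value from above and below), fixed-effect estimates,
#'   and the REML log-likelihood. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_animal_model <- function(data, trait, grm,
                             fixed = c("pen", "year", "season"),
                             convergence_sigfigs = 3L,
                             max_iterations = 2000L,
                             id_col = "animal_id") {
  data <- tibble::as_tibble(data)
  stopifnot(trait %in% names(data), id_col %in% names(data))
  y <- data[[trait]]
  if (anyNA(y)) stop("trait column contains missing values")

  pre_eig <- inherits(grm, "grm_eigen")
  grm_ids <- if (pre_eig) grm$ids else rownames(grm)
  ids <- as.character(data[[id_col]])
  missing_ids <- setdiff(ids, grm_ids)
  if (length(missing_ids)) {
    stop("animals absent from the relationship matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ...")
  }

  if (length(fixed)) {
    miss <- setdiff(fixed, names(data))
    if (length(miss)) stop("fixed factors not in data: ",
                           paste(miss, collapse = ", "))
    df <- data[fixed]
    df[] <- lapply(df, factor)
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(fixed, collapse = " + "))), df)
  } else {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping aliased fixed-effect columns: ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }

  single <- !anyDuplicated(ids)
  if (single) {
    if (pre_eig) {
      if (!identical(ids, grm_ids)) {
        stop("with a precomputed grm_eigen, data rows must match its ",
             "animal order exactly")
      }
      fit <- reml_em(y, X, eig = grm, sigfigs = convergence_sigfigs,
                     max_iterations = max_iterations)
    } else {
      Gs <- grm[ids, ids, drop = FALSE]
      fit <- reml_em(y, X, G = Gs, sigfigs = convergence_sigfigs,
                     max_iterations = max_iterations)
    }
    anim <- ids
  } else {
    if (pre_eig) stop("repeated records require the full grm matrix")
    anim <- unique(ids)
    Gs <- grm[anim, anim, drop = FALSE]
    fit <- reml_em(y, X, G = Gs, z_index = match(ids, anim),
                   sigfigs = convergence_sigfigs,
                   max_iterations = max_iterations)
  }

  structure(list(
    trait = trait,
    ebv = tibble::tibble(animal_id = anim, ebv = fit$u,
                         accuracy = fit$accuracy),
    varcomp = fit[c("sigma2_a", "sigma2_e", "h2", "converged", "bracketed",
                    "iterations", "h2_trajectory")],
    beta = tibble::tibble(term = colnames(X), estimate = fit$beta),
    pev = fit$pev, loglik = fit$loglik, n = fit$n
  ), class = "animal_model")
}

#' @export
print.animal_model <- function(x, ...) {
  vc <- x$varcomp
  cat("<animal_model> trait:", x$trait, "\n")
  cat(sprintf("  sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3g (%d iterations%s)\n",
              vc$sigma2_a, vc$sigma2_e, vc$h2, vc$iterations,
              if (vc$bracketed) ", bracketed" else ""))
  cat("  ", nrow(x$ebv), " breeding values, mean accuracy ",
      signif(mean(x$ebv$accuracy), 3), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy animal_model
#' @export
tidy.animal_model <- function(x, ...) x$ebv

#' @method glance animal_model
#' @export
glance.animal_model <- function(x, ...) {
  vc <- x$varcomp
  tibble::tibble(trait = x$trait, sigma2_a = vc$sigma2_a,
                 sigma2_e = vc$sigma2_e, h2 = vc$h2,
                 iterations = vc$iterations, converged = vc$converged,
                 bracketed = vc$bracketed, logLik = x$loglik, nobs = x$n)
}

#' EBV accuracy from prediction error variance
#'
#' `sqrt(1 - pev / (sigma2_a * g_ii))`, the standard BLUP reliability on the
#' correlation scale. PEV above its theoretical ceiling is clamped to the
#' ceiling (accuracy 0) with a warning.
#'
#' @param pev Prediction error variance(s).
#' @param sigma2_a Additive genetic variance.
#' @param g_ii Diagonal element(s) of the relationship matrix.
#' @return Accuracies in `[0, 1]`.
#' @export
accuracy_from_pev <- function(pev, sigma2_a, g_ii) {
  if (any(pev < 0)) stop("pev must be non-negative")
  ceiling_ <- sigma2_a * g_ii
  over <- pev > ceiling_
  if (any(over)) {
    warning("PEV exceeds sigma2_a * g_ii for ", sum(over),
            " value(s); accuracy clamped to 0")
    pev <- pmin(pev, ceiling_)
  }
  sqrt(1 - pev / ceiling_)
}
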