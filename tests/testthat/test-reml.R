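# Direct REML oracle: profile restricted log-likelihood computed from first
# principles in the eigenbasis of G, maximized with optimize(). Independent of
# the package's EM iterations.
oracle_reml_h2 <- function(y, X, G) {
  e <- eigen(G, symmetric = TRUE)
  yt <- drop(crossprod(e$vectors, y))
  Xt <- crossprod(e$vectors, X)
  d <- pmax(e$values, 0)
  n <- length(y)
  nll <- function(h2) {
    # profile out the total variance scale analytically
    v0 <- d * h2 + (1 - h2)
    XtVX <- crossprod(Xt, Xt / v0)
    b <- solve(XtVX, crossprod(Xt / v0, yt))
    r <- yt - drop(Xt %*% b)
    quad <- sum(r^2 / v0)
    p <- ncol(X)
    (n - p) * log(quad) + sum(log(v0)) + determinant(XtVX)$modulus[1]
  }
  stats::optimize(nll, c(1e-4, 1 - 1e-4))$minimum
}

test_that("EM-REML matches a direct likelihood-maximization oracle", {
  pop <- simulate_population(small_config(n_sires = 25, n_offspring = 200,
                                          n_snps = 500, h2_afi = 0.3,
                                          seed = 21))
  G <- pop$genotypes
  grm <- vanraden_grm(G)
  fit <- fit_animal_model(pop$traits, "afi", grm)

  df <- pop$traits
  df[c("pen", "year", "season")] <- lapply(df[c("pen", "year", "season")],
                                           factor)
  X <- stats::model.matrix(~ pen + year + season, df)
  h2_star <- oracle_reml_h2(pop$traits$afi, X, grm)
  expect_lt(abs(fit$varcomp$h2 - h2_star), 2e-3)
  expect_true(fit$varcomp$converged)
})

test_that("pure-noise data yields near-zero heritability and shrunken EBVs", {
  pop <- simulate_population(small_config(n_sires = 40, n_offspring = 400,
                                          n_snps = 600, h2_afi = 0,
                                          h2_adg = 0, n_qtl_per_trait = 0,
                                          seed = 22))
  grm <- vanraden_grm(pop$genotypes)
  fit <- suppressWarnings(fit_animal_model(pop$traits, "afi", grm))
  expect_lt(fit$varcomp$h2, 0.02)
  expect_lt(max(abs(fit$ebv$ebv)), 0.1 * stats::sd(pop$traits$afi))
  # truth side of the null: TBVs identically zero
  expect_equal(max(abs(pop$truth$tbv[, "afi"])), 0)
})

test_that("with G = I the BLUPs equal the closed-form ridge solution", {
  set.seed(23)
  n <- 120
  df <- tibble::tibble(animal_id = sprintf("A%03d", 1:n),
                       y = rnorm(n, 10),
                       pen = rep(c("P1", "P2"), each = n / 2))
  G <- diag(n); dimnames(G) <- list(df$animal_id, df$animal_id)
  fit <- fit_animal_model(df, "y", G, fixed = "pen")
  lambda <- fit$varcomp$sigma2_e / fit$varcomp$sigma2_a
  # ridge closed form at the estimated variance ratio, fixed effects = group
  # means absorbed through GLS with V = (1 + 1/lambda)... solved exactly:
  X <- stats::model.matrix(~ pen, df)
  V <- G * fit$varcomp$sigma2_a + diag(n) * fit$varcomp$sigma2_e
  b <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, df$y))
  u <- fit$varcomp$sigma2_a * solve(V, df$y - X %*% b)
  expect_equal(fit$ebv$ebv, unname(drop(u)), tolerance = 1e-6)
})

test_that("parameter recovery at moderate scale with truth correlation", {
  pop <- simulate_population(small_config(n_sires = 50, n_offspring = 800,
                                          n_snps = 800, h2_afi = 0.4,
                                          seed = 24))
  grm <- vanraden_grm(pop$genotypes)
  fit <- fit_animal_model(pop$traits, "afi", grm)
  expect_lt(abs(fit$varcomp$h2 - 0.4), 0.09)
  expect_gt(stats::cor(fit$ebv$ebv, pop$truth$tbv[, "afi"]), 0.5)
  expect_true(all(fit$ebv$accuracy >= 0 & fit$ebv$accuracy <= 1))
})

test_that("duplicating every record increases mean accuracy", {
  pop <- simulate_population(small_config(n_sires = 15, n_offspring = 120,
                                          n_snps = 400, h2_afi = 0.35,
                                          seed = 25))
  grm <- vanraden_grm(pop$genotypes)
  fit1 <- fit_animal_model(pop$traits, "afi", grm)
  dup <- dplyr::bind_rows(pop$traits, pop$traits)
  fit2 <- suppressWarnings(fit_animal_model(dup, "afi", grm))
  expect_equal(nrow(fit2$ebv), nrow(fit1$ebv))
  expect_gt(mean(fit2$ebv$accuracy), mean(fit1$ebv$accuracy))
})

test_that("EBVs are invariant to a constant phenotype shift", {
  pop <- simulate_population(small_config(n_offspring = 100, n_snps = 300,
                                          seed = 26))
  grm <- vanraden_grm(pop$genotypes)
  fit1 <- fit_animal_model(pop$traits, "afi", grm)
  shifted <- dplyr::mutate(pop$traits, afi = afi + 100)
  fit2 <- fit_animal_model(shifted, "afi", grm)
  expect_equal(fit1$ebv$ebv, fit2$ebv$ebv, tolerance = 1e-4)
  expect_equal(fit1$varcomp$h2, fit2$varcomp$h2, tolerance = 1e-4)
})

test_that("accuracy formula and clamping follow the PEV definition", {
  expect_equal(accuracy_from_pev(0, 2, 1), 1)
  expect_equal(accuracy_from_pev(2, 2, 1), 0)
  expect_equal(accuracy_from_pev(0.75 * 2, 2, 1), 0.5)
  expect_warning(a <- accuracy_from_pev(3, 2, 1), "clamped")
  expect_equal(a, 0)
  expect_error(accuracy_from_pev(-1, 2, 1), "non-negative")
})

test_that("tidy and glance expose the fit in broom shape", {
  pop <- simulate_population(small_config(n_offspring = 80, n_snps = 200,
                                          seed = 27))
  fit <- fit_animal_model(pop$traits, "afi", vanraden_grm(pop$genotypes))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("animal_id", "ebv", "accuracy"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("sigma2_a", "sigma2_e", "h2", "iterations",
                    "bracketed") %in% names(gl)))
  expect_equal(gl$h2, gl$sigma2_a / (gl$sigma2_a + gl$sigma2_e))
  # trajectory is recorded and ends at the reported h2
  traj <- fit$varcomp$h2_trajectory
  expect_equal(traj[length(traj)], gl$h2)
})
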