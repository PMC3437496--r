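test_that("accuracy weights are the Cholesky of the diagonal accuracy matrix", {
  expect_equal(weight_vector(1), 1)
  expect_equal(weight_vector(0.25), 0.5)
  expect_equal(weight_vector(c(0.81, 0.49)), c(0.9, 0.7))
  expect_warning(w <- weight_vector(c(0.5, 0)), "weight 0")
  expect_equal(w, c(sqrt(0.5), 0))
  expect_error(weight_vector(1.2), "\\[0, 1\\]")
})

test_that("single-SNP weighted F matches the normal-equations oracle", {
  set.seed(31)
  # 6-animal toy fixture
  ebv <- c(0.4, -0.2, 0.1, 0.7, -0.5, 0.05)
  geno <- c(0, 1, 2, 2, 0, 1)
  w <- c(0.9, 0.7, 0.8, 1, 0.6, 0.75)
  expect_equal(snp_f_statistic(ebv, geno, w),
               oracle_weighted_f(ebv, geno, w), tolerance = 1e-10)

  # orthogonal genotype (zero weighted covariance) -> F = 0
  yw_orth <- c(1, -1, 1, -1)
  g <- c(1, 1, 0, 0)
  wq <- rep(1, 4)
  # construct EBVs orthogonal to the centered genotype
  expect_equal(snp_f_statistic(yw_orth, g, wq), 0, tolerance = 1e-12)

  # constant genotype -> NA with warning
  expect_warning(f <- snp_f_statistic(ebv, rep(2, 6), w), "variance")
  expect_true(is.na(f))
  expect_error(snp_f_statistic(1:2, 1:2, c(1, 1)), "3 animals")
})

test_that("equal weights reproduce the unweighted F exactly", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    ebv <- rnorm(n)
    geno <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(geno) == 0) next
    c0 <- runif(1, 0.2, 3)
    f_eq <- snp_f_statistic(ebv, geno, rep(c0, n))
    f_un <- summary(stats::lm(ebv ~ geno))$fstatistic[["value"]]
    expect_equal(f_eq, f_un, tolerance = 1e-10)
  }
})

test_that("F statistics are invariant to affine rescaling of EBVs", {
  set.seed(33)
  n <- 50
  ebv <- rnorm(n)
  w <- runif(n, 0.5, 1)
  geno <- rbinom(n, 2, 0.3)
  f1 <- snp_f_statistic(ebv, geno, w)
  f2 <- snp_f_statistic(3 * ebv, geno, w)
  expect_equal(f1, f2, tolerance = 1e-10)
  # shifts interact with the weighted intercept only
  f3 <- snp_f_statistic(ebv * 2 + 5, geno, rep(1, n))
  f4 <- snp_f_statistic(ebv, geno, rep(1, n))
  expect_equal(f3, f4, tolerance = 1e-10)
})

test_that("genome scan returns one record per SNP including skipped ones", {
  pop <- simulate_population(small_config(n_offspring = 60, n_snps = 80,
                                          seed = 34))
  G <- pop$genotypes
  G$calls[, 5] <- 2  # monomorphic -> skipped
  ebv <- tibble::tibble(animal_id = animal_ids(G),
                        ebv = rnorm(60), accuracy = runif(60, 0.3, 0.9))
  sc <- genome_scan(ebv, G)
  expect_equal(nrow(sc), 80)
  expect_true(sc$skipped[5])
  expect_true(is.na(sc$f_stat[5]))
  expect_false(any(sc$skipped[-5]))
  # scan F agrees with the single-SNP routine
  w <- sqrt(ebv$accuracy)
  expect_equal(sc$f_stat[1],
               snp_f_statistic(ebv$ebv, G$calls[, 1], w), tolerance = 1e-10)
  # all-equal EBVs -> all F = 0
  ebv0 <- dplyr::mutate(ebv, ebv = 1)
  sc0 <- genome_scan(ebv0, G)
  expect_lt(max(sc0$f_stat, na.rm = TRUE), 1e-18)
  # id mismatch is fatal and names offenders
  bad <- ebv; bad$animal_id[1] <- "ghost"
  expect_error(genome_scan(bad, G), "ghost")
})

test_that("a strong planted QTL tops the scan in nearly all replicates", {
  hits <- 0L
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    pop <- simulate_population(small_config(
      n_sires = 25, n_offspring = 250, n_snps = 150, n_chromosomes = 3,
      n_qtl_per_trait = 0, h2_afi = 0, seed = 600 + i))
    G <- pop$genotypes
    g <- G$calls[, 42]
    y <- scale(rnorm(250))[, 1] + 1 * (g - mean(g)) / stats::sd(g)
    ebv <- tibble::tibble(animal_id = animal_ids(G), ebv = y,
                          accuracy = runif(250, 0.4, 0.9))
    sc <- genome_scan(ebv, G)
    top <- sc$snp_id[which.max(sc$f_stat)]
    # count LD hits on the same chromosome within 10 SNPs as success
    idx <- match(top, sc$snp_id)
    if (abs(idx - 42) <= 10 && sc$chrom[idx] == sc$chrom[42]) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("permutation threshold is seeded, monotone in alpha, and honours
           quantile boundaries", {
  pop <- simulate_population(small_config(n_offspring = 80, n_snps = 100,
                                          seed = 36))
  G <- pop$genotypes
  set.seed(1)
  ebv <- tibble::tibble(animal_id = animal_ids(G), ebv = rnorm(80),
                        accuracy = runif(80, 0.3, 0.9))
  t1 <- permutation_threshold(ebv, G, n_perm = 150, alpha = 0.05, seed = 7)
  t2 <- permutation_threshold(ebv, G, n_perm = 150, alpha = 0.05, seed = 7)
  expect_identical(t1$threshold_f, t2$threshold_f)
  expect_identical(t1$max_f, t2$max_f)

  # alpha = 1 -> minimum of the max-F sample
  tmin <- permutation_threshold(ebv, G, n_perm = 150, alpha = 1, seed = 7)
  expect_equal(tmin$threshold_f, min(t1$max_f))

  # monotone non-increasing in alpha
  alphas <- c(0.01, 0.05, 0.2, 0.5, 1)
  ths <- vapply(alphas, function(a)
    permutation_threshold(ebv, G, n_perm = 150, alpha = a,
                          seed = 7)$threshold_f, 1)
  expect_true(all(diff(ths) <= 0))

  # the "higher" quantile convention: smallest order statistic with
  # >= 1 - alpha coverage
  expect_equal(t1$threshold_f, sort(t1$max_f)[ceiling(0.95 * 150)])

  expect_warning(permutation_threshold(ebv, G, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("blocked and raw-EBV permutation variants work and differ sensibly", {
  pop <- simulate_population(small_config(n_offspring = 60, n_snps = 60,
                                          seed = 37))
  G <- pop$genotypes
  set.seed(2)
  ebv <- tibble::tibble(animal_id = animal_ids(G), ebv = rnorm(60),
                        accuracy = runif(60, 0.3, 0.9))
  # block size must not change the result (same RNG draw order)
  a <- permutation_threshold(ebv, G, n_perm = 120, seed = 5, block = 7)
  b <- permutation_threshold(ebv, G, n_perm = 120, seed = 5, block = 120)
  expect_equal(a$threshold_f, b$threshold_f)
  expect_equal(a$max_f, b$max_f)
  # raw-EBV variant runs and is deterministic too
  r1 <- permutation_threshold(ebv, G, n_perm = 120, seed = 5,
                              permute = "raw_ebv")
  r2 <- permutation_threshold(ebv, G, n_perm = 120, seed = 5,
                              permute = "raw_ebv")
  expect_equal(r1$threshold_f, r2$threshold_f)
})

test_that("exceeds_threshold flags follow f_stat >= threshold", {
  pop <- simulate_population(small_config(n_offspring = 50, n_snps = 40,
                                          seed = 38))
  G <- pop$genotypes
  set.seed(3)
  ebv <- tibble::tibble(animal_id = animal_ids(G), ebv = rnorm(50),
                        accuracy = runif(50, 0.5, 1))
  sc <- genome_scan(ebv, G)
  thr <- stats::quantile(sc$f_stat, 0.9, na.rm = TRUE)
  sc <- apply_threshold(sc, thr)
  expect_identical(sc$exceeds_threshold,
                   !is.na(sc$f_stat) & sc$f_stat >= thr)
  expect_equal(attr(sc, "threshold_f"), unname(thr))
})
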