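test_that("numerator matrix reproduces textbook values", {
  # two unrelated base animals
  ped <- tibble::tibble(animal_id = c("a", "b"),
                        sire_id = NA_character_, dam_id = NA_character_)
  A <- numerator_matrix(ped)
  expect_equal(bare(A), diag(2))

  # paternal half-sibs with unrelated dams
  ped <- tibble::tibble(animal_id = c("s", "x", "y"),
                        sire_id = c(NA, "s", "s"),
                        dam_id = NA_character_)
  A <- numerator_matrix(ped)
  expect_equal(A["x", "y"], 0.25)
  expect_equal(A["s", "x"], 0.5)
  expect_equal(diag(A), c(s = 1, x = 1, y = 1))
})

test_that("numerator matrix matches an independent recursive oracle", {
  # 6-animal, 3-generation pedigree with a full-sib mating (inbred f)
  ped <- tibble::tibble(
    animal_id = c("s1", "d1", "o1", "o2", "o3", "f"),
    sire_id   = c(NA,   NA,   "s1", "s1", "o1", "o1"),
    dam_id    = c(NA,   NA,   "d1", "d1", NA,   "o2")
  )
  # memoized recursion straight from the definition
  sire <- stats::setNames(ped$sire_id, ped$animal_id)
  dam <- stats::setNames(ped$dam_id, ped$animal_id)
  rec <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    oi <- match(i, ped$animal_id); oj <- match(j, ped$animal_id)
    if (oi < oj) { tmp <- i; i <- j; j <- tmp }   # i is the younger
    if (i == j) return(1 + 0.5 * rec(sire[[i]], dam[[i]]))
    0.5 * (rec(sire[[i]], j) + rec(dam[[i]], j))
  }
  A <- numerator_matrix(ped)
  for (i in ped$animal_id) for (j in ped$animal_id) {
    expect_equal(A[i, j], rec(i, j), tolerance = 1e-12,
                 label = paste("A[", i, ",", j, "]"))
  }
  expect_gt(A["f", "f"], 1)  # inbred full-sib offspring

  # cycle detection
  bad <- tibble::tibble(animal_id = c("a", "b"), sire_id = c("b", "a"),
                        dam_id = NA_character_)
  expect_error(numerator_matrix(bad), "cycle")
})

test_that("allele sharing matches hand arithmetic and bounds", {
  # identical genotype vectors share 1; opposite homozygotes share 0
  G <- toy_geno(rbind(c(0, 1, 2), c(0, 1, 2), c(2, 1, 0)))
  S <- allele_sharing_matrix(G)
  expect_equal(S["A01", "A02"], 1)
  expect_equal(diag(S), c(A01 = 1, A02 = 1, A03 = 1))
  # pair with calls (0,1),(2,1),(1,1) -> mean of {0.5, 0.5, 1} = 2/3
  G2 <- toy_geno(rbind(c(0, 2, 1), c(1, 1, 1)))
  expect_equal(allele_sharing_matrix(G2)["A01", "A02"], 2 / 3)
  # all-opposite pair
  G3 <- toy_geno(rbind(c(0, 2), c(2, 0)))
  expect_equal(allele_sharing_matrix(G3)["A01", "A02"], 0)
  # guards
  expect_error(allele_sharing_matrix(toy_geno(rbind(c(0, NA), c(1, 2)))),
               "missing")
  expect_error(allele_sharing_matrix(toy_geno(rbind(c(0.5, 1), c(1, 2)))),
               "integer")
})

test_that("calibration solves the two-point line and identity map", {
  # two-point line: slope 2.5, intercept -1.5
  S <- matrix(c(1, 0.6, 0.7,
                0.6, 1, 0.8,
                0.7, 0.8, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  A <- matrix(c(1, 0.0, 0.25,
                0.0, 1, 0.5,
                0.25, 0.5, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  pairs <- rbind(c(1, 2), c(2, 3))
  Gc <- calibrate_grm(S, A, pairs)
  cal <- attr(Gc, "calibration")
  expect_equal(unname(cal["slope"]), 2.5)
  expect_equal(unname(cal["intercept"]), -1.5)

  # identity calibration: S already equals A (and is PSD) -> unchanged
  Gc2 <- calibrate_grm(A, A, pairs)
  expect_equal(unname(attr(Gc2, "calibration")), c(1, 0), tolerance = 1e-12)
  expect_equal(bare(Gc2), bare(A), tolerance = 1e-12)

  # constant sharing over pairs -> slope unidentifiable
  Sc <- S; Sc[1, 2] <- Sc[2, 1] <- Sc[2, 3] <- Sc[3, 2] <- 0.7
  expect_error(calibrate_grm(Sc, A, pairs), "constant")
})

test_that("calibrated GRM regressed back on A has slope 1 and recovers
           half-sib and sire-offspring relationships", {
  pop <- simulate_population(small_config(n_sires = 20, n_offspring = 150,
                                          n_snps = 600, seed = 5))
  G <- pop$genotypes
  ids <- animal_ids(G)
  A_all <- numerator_matrix(pop$pedigree)
  A <- A_all[ids, ids]
  S <- allele_sharing_matrix(G)
  Gc <- calibrate_grm(S, A)

  pr <- which(upper.tri(A), arr.ind = TRUE)
  slope_back <- stats::cov(Gc[pr], A[pr]) / stats::var(A[pr])
  expect_lt(abs(slope_back - 1), 0.02)

  # half-sib pairs average near 0.25
  ped <- pop$pedigree[match(ids, pop$pedigree$animal_id), ]
  hs <- outer(ped$sire_id, ped$sire_id, "==") & upper.tri(A)
  expect_lt(abs(mean(Gc[hs]) - 0.25), 0.05)

  # sire-offspring calibrated sharing near 0.5, using stored sire genotypes
  comb <- geno_matrix(rbind(G$calls, pop$truth$sire_genotypes), G$snp_map)
  Sc <- allele_sharing_matrix(comb)
  Ac <- A_all[rownames(comb$calls), rownames(comb$calls)]
  Gc2 <- calibrate_grm(Sc, Ac)
  so <- cbind(match(ped$animal_id, rownames(Ac)),
              match(ped$sire_id, rownames(Ac)))
  expect_lt(abs(mean(Gc2[so]) - 0.5), 0.05)
})

test_that("VanRaden GRM matches hand arithmetic and equilibrium scaling", {
  # single SNP, p = 0.5, genotypes {0, 2}: diag 2, off-diag -2
  G <- toy_geno(matrix(c(0, 2), 2, 1))
  Gv <- vanraden_grm(G)
  expect_equal(bare(Gv), matrix(c(2, -2, -2, 2), 2))

  # identical animals: G_ij = G_ii
  G2 <- toy_geno(rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 0)))
  Gv2 <- vanraden_grm(G2)
  expect_equal(Gv2[1, 2], Gv2[1, 1])

  # average diagonal ~ 1 under Hardy-Weinberg equilibrium
  set.seed(10)
  p <- runif(500, 0.1, 0.5)
  calls <- sapply(p, function(pp) rbinom(400, 2, pp))
  Gv3 <- vanraden_grm(toy_geno(calls, chrom = rep("1", 500),
                               pos = seq_len(500) * 1000))
  expect_lt(abs(mean(diag(Gv3)) - 1), 0.05)

  expect_error(vanraden_grm(toy_geno(matrix(c(0, 0), 2, 1))), "monomorphic")
})

test_that("relationship constructions commute with animal permutations", {
  pop <- simulate_population(small_config(n_offspring = 40, n_snps = 120,
                                          seed = 8))
  G <- pop$genotypes
  perm <- sample(nrow(G$calls))
  Gp <- subset_geno(G, animals = perm)

  S <- allele_sharing_matrix(G)
  Sp <- allele_sharing_matrix(Gp)
  expect_equal(bare(Sp), bare(S[perm, perm]), tolerance = 1e-12)

  Gv <- vanraden_grm(G)
  Gvp <- vanraden_grm(Gp)
  expect_equal(bare(Gvp), bare(Gv[perm, perm]), tolerance = 1e-12)
})

test_that("PSD conditioning clips negative eigenvalues only when needed", {
  M <- diag(3); M[1, 2] <- M[2, 1] <- 0.5
  expect_identical(make_psd(M), M)   # already PSD: untouched
  N <- matrix(c(1, 2, 2, 1), 2, 2)   # eigenvalues 3, -1
  Np <- make_psd(N)
  ev <- eigen(Np, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= 0))
  expect_equal(min(ev), 1e-6, tolerance = 1e-3)
})
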