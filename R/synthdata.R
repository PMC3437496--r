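#' Configuration for the synthetic half-sib population generator
#'
#' Defaults emulate the feed-efficiency study design the package targets: a
#' paternal half-sib population of ~700 steers from 100 sires genotyped on a
#' dense SNP panel, with pen/year/season fixed effects, low heritabilities for
#' intake and gain, and a sparse-QTL-plus-polygenic additive architecture. RFI
#' is never simulated directly -- it is derived downstream from AFI, ADG and
#' MMW exactly as in the analysis, so its realized heritability is emergent
#' and `h2_rfi_target` is advisory only.
#'
#' @param n_sires Number of sires (half-sib family count).
#' @param n_offspring Number of genotyped, phenotyped steers.
#' @param n_snps Total SNP count across the genome.
#' @param n_chromosomes Number of chromosomes; when 30, the last is labelled
#'   `"X"` but simulated with autosomal diploid dosage (the population is all
#'   male steers; hemizygous coding is not modelled).
#' @param chrom_length_bp Length of every chromosome in bp.
#' @param maf_beta_params Shape parameters of the Beta distribution of base
#'   allele frequencies, truncated to `maf_range`. The default Beta(1.0, 0.8)
#'   on \[0.05, 0.5\] has mean 0.28, matching a dense bovine assay after MAF
#'   filtering.
#' @param maf_range Truncation interval for the MAF distribution.
#' @param n_qtl_per_trait Number of QTL per trait (0 = purely polygenic). The
#'   locus set is shared across traits (pleiotropy) with correlated per-trait
#'   effects, which is what creates cross-trait QTL-region concordance.
#' @param qtl_var_frac Fraction of each trait's additive variance assigned to
#'   the sampled QTL; the remainder is a genome-wide polygenic term. Both
#'   layers carry the configured genetic correlations.
#' @param h2_afi,h2_adg Narrow-sense heritabilities of average daily feed
#'   intake and average daily gain.
#' @param h2_rfi_target Advisory target for the emergent RFI heritability
#'   (not used by the generator).
#' @param genetic_corr_afi_adg Additive genetic correlation between AFI and
#'   ADG.
#' @param n_pens,n_years,n_seasons Numbers of fixed-effect levels.
#' @param n_feeding_groups Number of feeding groups (pens are nested within
#'   groups); RFI is later derived within each group.
#' @param missing_rate Fraction of genotype calls set missing completely at
#'   random.
#' @param seed Integer seed; identical seeds give bit-identical populations.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 100,
                       n_offspring = 698,
                       n_snps = 40000,
                       n_chromosomes = 30,
                       chrom_length_bp = 1e8,
                       maf_beta_params = c(1.0, 0.8),
                       maf_range = c(0.05, 0.5),
                       n_qtl_per_trait = 20,
                       qtl_var_frac = 0.3,
                       h2_afi = 0.14,
                       h2_adg = 0.09,
                       h2_rfi_target = 0.14,
                       genetic_corr_afi_adg = 0.55,
                       n_pens = 8,
                       n_years = 4,
                       n_seasons = 2,
                       n_feeding_groups = 2,
                       missing_rate = 0.0058,
                       seed = 1L) {
  cfg <- list(
    n_sires = as.integer(n_sires), n_offspring = as.integer(n_offspring),
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    maf_beta_params = as.numeric(maf_beta_params),
    maf_range = as.numeric(maf_range),
    n_qtl_per_trait = as.integer(n_qtl_per_trait),
    qtl_var_frac = as.numeric(qtl_var_frac),
    h2_afi = h2_afi, h2_adg = h2_adg, h2_rfi_target = h2_rfi_target,
    genetic_corr_afi_adg = genetic_corr_afi_adg,
    n_pens = as.integer(n_pens), n_years = as.integer(n_years),
    n_seasons = as.integer(n_seasons),
    n_feeding_groups = as.integer(n_feeding_groups),
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  counts <- c("n_sires", "n_offspring", "n_snps", "n_chromosomes", "n_pens",
              "n_years", "n_seasons", "n_feeding_groups")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop(nm, " must be a positive count")
  }
  props <- c("h2_afi", "h2_adg", "h2_rfi_target", "qtl_var_frac")
  for (nm in props) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (abs(cfg$genetic_corr_afi_adg) > 1) {
    stop("genetic_corr_afi_adg must lie in [-1, 1]")
  }
  if (cfg$n_qtl_per_trait > cfg$n_snps) {
    stop("n_qtl_per_trait cannot exceed n_snps")
  }
  if (length(cfg$maf_beta_params) != 2 || any(cfg$maf_beta_params <= 0)) {
    stop("maf_beta_params must be two positive reals")
  }
  structure(cfg, class = "sim_config")
}

# Trait-level constants of the generator: phenotypic means/SDs on realistic
# kg scales, and the mid-weight trait's genetic parameters. Correlations with
# mid-weight and environmental correlations are fixed at typical literature
# magnitudes; only the AFI-ADG genetic correlation is configurable.
sim_trait_constants <- function(cfg) {
  list(
    traits = c("afi", "adg", "mid_weight"),
    mu = c(afi = 9.5, adg = 1.6, mid_weight = 450),
    sd_p = c(afi = 1.0, adg = 0.2, mid_weight = 35),
    h2 = c(afi = cfg$h2_afi, adg = cfg$h2_adg, mid_weight = 0.35),
    rg = matrix(c(1, cfg$genetic_corr_afi_adg, 0.45,
                  cfg$genetic_corr_afi_adg, 1, 0.55,
                  0.45, 0.55, 1), 3, 3,
                dimnames = list(c("afi", "adg", "mid_weight"),
                                c("afi", "adg", "mid_weight"))),
    re = matrix(c(1, 0.25, 0.25,
                  0.25, 1, 0.35,
                  0.25, 0.35, 1), 3, 3)
  )
}

# Draw from a symmetric-PSD multivariate normal via eigendecomposition
# (tolerates zero variances / singular covariance).
mvn_sample <- function(n, Sigma) {
  k <- ncol(Sigma)
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * k), n, k)
  z %*% (t(e$vectors) * sqrt(lam))
}

# Truncated-beta sampler for base minor allele frequencies (inverse CDF).
sample_maf <- function(n, shape, range) {
  lo <- stats::pbeta(range[1], shape[1], shape[2])
  hi <- stats::pbeta(range[2], shape[1], shape[2])
  stats::qbeta(lo + stats::runif(n) * (hi - lo), shape[1], shape[2])
}

# One gamete per offspring from parental haplotype pair, with crossovers at
# 1 cM/Mb (Haldane) between adjacent SNPs and independent chromosomes.
sample_gametes <- function(hapA, hapB, parent, recomb) {
  n <- length(parent)
  m <- length(recomb)
  switches <- matrix(stats::runif(n * m), n, m) < rep(recomb, each = n)
  phase <- t(apply(switches, 1, cumsum)) %% 2
  hA <- hapA[parent, , drop = FALSE]
  hB <- hapB[parent, , drop = FALSE]
  hA * (1 - phase) + hB * phase
}

#' Simulate a half-sib steer population
#'
#' Generates base-population sires and unrelated dams (one per offspring) with
#' haplotypes drawn at linkage equilibrium from the configured MAF
#' distribution, then creates offspring genotypes by Mendelian sampling of
#' parental gametes with recombination at 1 cM/Mb, so within-chromosome
#' linkage disequilibrium arises from haplotype transmission. Phenotypes for
#' AFI, ADG and mid-weight are the sum of pen/year/season fixed-effect
#' contributions, a sparse-QTL additive term, a genome-wide polygenic term
#' (small correlated allele-substitution effects at every SNP) carrying the
#' configured genetic correlations, and multivariate environmental noise, at
#' the configured heritabilities. Missing genotype
#' calls are injected completely at random at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_population` with elements
#'   \describe{
#'     \item{genotypes}{[geno_matrix()] of offspring calls (with missingness).}
#'     \item{traits}{Tibble of phenotypes and fixed-effect labels per steer.}
#'     \item{pedigree}{Tibble (`animal_id`, `sire_id`, `dam_id`) including
#'       founder rows for sires and dams.}
#'     \item{truth}{Ground truth: QTL positions and effects, true breeding
#'       values for offspring/sires/dams, base allele frequencies, sire
#'       genotypes, and the generating variance components.}
#'   }
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_sires = 5, n_offspring = 30,
#'                                       n_snps = 50, n_chromosomes = 2,
#'                                       seed = 7))
#' pop$genotypes
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- sim_trait_constants(config)
  n_tr <- length(k$traits)
  sd_a <- sqrt(k$h2) * k$sd_p
  qfrac <- if (config$n_qtl_per_trait > 0) config$qtl_var_frac else 0

  # Total additive covariance across traits; the QTL and polygenic layers
  # each carry the same correlation structure (shared pleiotropic QTL loci),
  # so any qtl_var_frac is admissible as long as this matrix is PSD.
  C_total <- k$rg * tcrossprod(sd_a)
  ev <- eigen(C_total, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("impossible heritability/correlation combination: the genetic ",
         "covariance matrix implied by the configured heritabilities and ",
         "correlations is not positive semi-definite")
  }
  C_poly <- (1 - qfrac) * C_total

  set.seed(config$seed)
  m <- config$n_snps
  n_off <- config$n_offspring
  n_s <- config$n_sires

  # SNP map: counts per chromosome as even as possible, uniform positions.
  labs <- as.character(seq_len(config$n_chromosomes))
  if (config$n_chromosomes == 30) labs[30] <- "X"
  m_per <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1)))
  chrom <- rep(labs, m_per)
  pos <- unlist(lapply(m_per, function(mc) {
    sort(sample.int(config$chrom_length_bp, mc))
  }), use.names = FALSE)
  snp_id <- sprintf("snp%05d", seq_len(m))
  snp_map <- tibble::tibble(snp_id = snp_id, chrom = chrom, pos_bp = pos)

  # Recombination fraction before each SNP (0.5 at chromosome starts).
  d <- c(0, diff(pos))
  newchr <- c(TRUE, chrom[-1] != chrom[-m])
  recomb <- 0.5 * (1 - exp(-2 * d * 1e-8))
  recomb[newchr] <- 0.5

  p <- sample_maf(m, config$maf_beta_params, config$maf_range)

  rbern <- function(n) {
    matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  }
  sire_hapA <- rbern(n_s); sire_hapB <- rbern(n_s)
  dam_hapA <- rbern(n_off); dam_hapB <- rbern(n_off)

  sire_of <- sample.int(n_s, n_off, replace = TRUE)
  gam_s <- sample_gametes(sire_hapA, sire_hapB, sire_of, recomb)
  gam_d <- sample_gametes(dam_hapA, dam_hapB, seq_len(n_off), recomb)
  calls <- gam_s + gam_d
  storage.mode(calls) <- "double"

  sire_geno <- sire_hapA + sire_hapB
  dam_geno <- dam_hapA + dam_hapB

  off_id <- sprintf("A%04d", seq_len(n_off))
  sire_id <- sprintf("S%03d", seq_len(n_s))
  dam_id <- sprintf("D%04d", seq_len(n_off))
  rownames(calls) <- off_id; colnames(calls) <- snp_id
  rownames(sire_geno) <- sire_id; colnames(sire_geno) <- snp_id

  # QTL architecture: one shared (pleiotropic) locus set with correlated
  # per-trait allele-substitution effects, scaled so the expected
  # base-population QTL covariance is qfrac * C_total under HWE/LE. Sharing
  # loci across traits is what creates cross-trait QTL-region concordance.
  qtl <- tibble::tibble(trait = character(), snp_index = integer(),
                        snp_id = character(), effect = double())
  if (config$n_qtl_per_trait > 0 && qfrac > 0 && any(sd_a > 0)) {
    qtl_idx <- sort(sample.int(m, config$n_qtl_per_trait))
    denom <- sum(2 * p[qtl_idx] * (1 - p[qtl_idx]))
    B_qtl <- mvn_sample(config$n_qtl_per_trait, qfrac * C_total / denom)
    colnames(B_qtl) <- k$traits
    for (tr in k$traits) {
      qtl <- dplyr::bind_rows(qtl, tibble::tibble(
        trait = tr, snp_index = qtl_idx, snp_id = snp_id[qtl_idx],
        effect = B_qtl[, tr]))
    }
  } else {
    qtl_idx <- integer(0)
    B_qtl <- matrix(0, 0, n_tr, dimnames = list(NULL, k$traits))
  }

  qtl_part <- function(geno) {
    if (!length(qtl_idx)) {
      return(matrix(0, nrow(geno), n_tr, dimnames = list(NULL, k$traits)))
    }
    centered <- sweep(geno[, qtl_idx, drop = FALSE], 2, 2 * p[qtl_idx])
    centered %*% B_qtl
  }

  # Polygenic term: small correlated allele-substitution effects at every
  # SNP, scaled so the expected base-population covariance of the polygenic
  # breeding values equals C_poly. Making the polygenic variance genomic
  # (rather than an abstract pedigree-MVN) is what lets marker-based
  # relationship matrices recover the configured heritability.
  B_poly <- mvn_sample(m, C_poly) / sqrt(sum(2 * p * (1 - p)))
  poly_shift <- drop(crossprod(2 * p, B_poly))
  poly_part <- function(geno) {
    sweep(geno %*% B_poly, 2, poly_shift)
  }

  tbv <- qtl_part(calls) + poly_part(calls)
  sire_tbv <- qtl_part(sire_geno) + poly_part(sire_geno)
  dam_tbv <- qtl_part(dam_geno) + poly_part(dam_geno)
  dimnames(tbv) <- list(off_id, k$traits)
  dimnames(sire_tbv) <- list(sire_id, k$traits)
  dimnames(dam_tbv) <- list(dam_id, k$traits)

  # Fixed-effect structure: random assignment (estimable w.h.p.), pens
  # nested within feeding groups.
  pen <- sample.int(config$n_pens, n_off, replace = TRUE)
  year <- sample.int(config$n_years, n_off, replace = TRUE)
  season <- sample.int(config$n_seasons, n_off, replace = TRUE)
  fg_of_pen <- rep(seq_len(config$n_feeding_groups),
                   length.out = config$n_pens)
  eff <- function(nlev, scale) stats::rnorm(nlev, 0, scale)
  fixed <- matrix(0, n_off, n_tr, dimnames = list(NULL, k$traits))
  for (tr in k$traits) {
    fixed[, tr] <- eff(config$n_pens, 0.3 * k$sd_p[tr])[pen] +
      eff(config$n_years, 0.2 * k$sd_p[tr])[year] +
      eff(config$n_seasons, 0.2 * k$sd_p[tr])[season]
  }

  sd_e <- sqrt(1 - k$h2) * k$sd_p
  C_env <- k$re * tcrossprod(sd_e)
  env <- mvn_sample(n_off, C_env)
  pheno <- sweep(fixed + tbv + env, 2, k$mu, "+")

  fg <- paste0("FG", fg_of_pen[pen])
  traits <- tibble::tibble(
    animal_id = off_id,
    afi = pheno[, "afi"], adg = pheno[, "adg"],
    mid_weight = pheno[, "mid_weight"],
    pen = paste0("P", pen), year = paste0("Y", year),
    season = paste0("S", season),
    feeding_group = fg
  )
  pedigree <- dplyr::bind_rows(
    tibble::tibble(animal_id = sire_id, sire_id = NA_character_,
                   dam_id = NA_character_),
    tibble::tibble(animal_id = dam_id, sire_id = NA_character_,
                   dam_id = NA_character_),
    tibble::tibble(animal_id = off_id, sire_id = sire_id[sire_of],
                   dam_id = dam_id)
  )

  G <- geno_matrix(calls, snp_map)
  if (config$missing_rate > 0) {
    G <- inject_missingness(G, config$missing_rate,
                            seed = config$seed + 1L)
  }

  structure(list(
    genotypes = G,
    traits = traits,
    pedigree = pedigree,
    truth = list(
      qtl = qtl,
      tbv = tbv, sire_tbv = sire_tbv, dam_tbv = dam_tbv,
      allele_freq = p,
      sire_genotypes = sire_geno,
      sire_of = sire_id[sire_of],
      fixed_contrib = fixed,
      variance_components = tibble::tibble(
        trait = k$traits,
        sigma2_a = as.numeric(sd_a^2),
        sigma2_e = as.numeric(sd_e^2),
        h2 = as.numeric(k$h2))
    ),
    config = config
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population> ", nrow(x$genotypes$calls), " offspring, ",
      x$config$n_sires, " sires, ", ncol(x$genotypes$calls), " SNPs\n",
      sep = "")
  invisible(x)
}

#' Inject missing genotype calls completely at random
#'
#' @param G A [geno_matrix()].
#' @param rate Expected fraction of entries set to `NA`, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical masks.
#' @return A `geno_matrix` with the masked calls (`rate = 0` returns the
#'   input unchanged).
#' @export
inject_missingness <- function(G, rate, seed = 1L) {
  stopifnot(inherits(G, "geno_matrix"))
  if (rate >= 1) stop("rate must be < 1")
  if (rate < 0) stop("rate must be >= 0")
  if (rate == 0) return(G)
  set.seed(seed)
  calls <- G$calls
  calls[stats::runif(length(calls)) < rate] <- NA_real_
  geno_matrix(calls, G$snp_map)
}
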