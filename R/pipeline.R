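#' Pipeline configuration
#'
#' Bundles every stage toggle, threshold and seed of the end-to-end analysis.
#' The defaults reproduce the study-scale settings (MAF >= 0.05, call rate >=
#' 95%, animals with > 5% missing calls removed, 10000 permutations at
#' genome-wide alpha 0.05, +/- 0.5 Mb QTL windows); scaled-down permutation
#' counts must be set explicitly so a run is never silently miscalibrated.
#' Stage dependencies are validated at construction time.
#'
#' @param sim A [sim_config()] used when the `simulate` stage is enabled.
#' @param stages Character vector of enabled stages, a subset of
#'   `simulate, qc, rfi, grm, reml, scan, select, gblup, regions` (order is
#'   fixed internally).
#' @param maf_min,call_rate_min SNP filters (inclusive).
#' @param animal_missing_max Animal missingness cut (exclusive, fraction).
#' @param impute_method `"mode"`, `"expected_dosage"` or `"sample"`.
#' @param grm_method `"calibrated"` (allele sharing calibrated to the
#'   pedigree numerator matrix) or `"vanraden"`.
#' @param traits Trait columns to analyse downstream of RFI derivation.
#' @param n_perm,alpha Permutation count and genome-wide type I error rate.
#' @param permute Permutation pairing convention, see
#'   [permutation_threshold()].
#' @param window_bp QTL half-window in bp.
#' @param write_matrices Whether to write the (large) relationship matrices.
#' @param seed Master seed; stage seeds are derived as small offsets.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "qc", "rfi", "grm", "reml",
                                       "scan", "select", "gblup", "regions"),
                            maf_min = 0.05, call_rate_min = 0.95,
                            animal_missing_max = 0.05,
                            impute_method = "mode",
                            grm_method = c("calibrated", "vanraden"),
                            traits = c("afi", "rfi", "adg"),
                            n_perm = 10000, alpha = 0.05,
                            permute = "weighted_pairs",
                            window_bp = 5e5,
                            write_matrices = TRUE,
                            seed = 1L) {
  if (is.list(sim) && !inherits(sim, "sim_config")) {
    sim <- do.call(sim_config, sim)
  }
  all_stages <- c("simulate", "qc", "rfi", "grm", "reml", "scan", "select",
                  "gblup", "regions")
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  deps <- list(rfi = character(0), qc = character(0), grm = "qc",
               reml = c("qc", "rfi", "grm"), scan = c("reml", "qc"),
               select = "scan", gblup = c("select", "grm"),
               regions = "select")
  for (st in stages) {
    need <- setdiff(deps[[st]], stages)
    if (!is.null(deps[[st]]) && length(need)) {
      stop("stage '", st, "' requires disabled stage(s): ",
           paste(need, collapse = ", "))
    }
  }
  grm_method <- match.arg(grm_method)
  structure(list(
    sim = sim, stages = intersect(all_stages, stages),
    maf_min = maf_min, call_rate_min = call_rate_min,
    animal_missing_max = animal_missing_max,
    impute_method = impute_method, grm_method = grm_method,
    traits = traits, n_perm = as.integer(n_perm), alpha = alpha,
    permute = permute, window_bp = window_bp,
    write_matrices = isTRUE(write_matrices), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full feed-efficiency analysis pipeline
#'
#' Executes the enabled stages in order -- synthetic population (or supplied
#' inputs), genotype QC and imputation, RFI derivation, relationship matrices,
#' per-trait EM-REML breeding values, accuracy-weighted genome scan with
#' permutation threshold, chromosome-wise forward selection, the two-model
#' GBLUP variance contrast, and QTL-region concordance -- writing every
#' artifact plus an md5 manifest into `out_dir`. Re-running with the same
#' configuration is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param population Optional pre-built population (a `sim_population` or a
#'   list with `genotypes`, `traits`, `pedigree`); required when the
#'   `simulate` stage is disabled.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results of every stage
#'   (`population`, `qc`, `traits`, `grm`, `models`, `scans`, `thresholds`,
#'   `panels`, `contrasts`, `summary`, `regions`, `concordance`, `out_dir`).
#' @export
run_pipeline <- function(config, population = NULL,
                         out_dir = tempfile("rfigwas_run"), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[rfigwas] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(out_dir = out_dir)
  st <- config$stages

  if ("simulate" %in% st && is.null(population)) {
    say("simulate: ", config$sim$n_offspring, " offspring x ",
        config$sim$n_snps, " SNPs")
    population <- simulate_population(config$sim)
  }
  if (is.null(population)) {
    stop("stage 'simulate' is disabled and no population was supplied")
  }
  res$population <- population
  G <- population$genotypes
  traits <- tibble::as_tibble(population$traits)
  write_genotypes_tsv(G, file.path(out_dir, "genotypes_raw.tsv"))
  readr::write_tsv(population$pedigree, file.path(out_dir, "pedigree.tsv"))

  if ("qc" %in% st) {
    say("qc: filtering and imputing")
    fs <- filter_snps(G, config$maf_min, config$call_rate_min)
    G <- filter_animals(fs$genotypes, config$animal_missing_max)
    G <- impute_missing(G, config$impute_method, seed = config$seed + 11L)
    report <- fs$report
    report$n_animals_out <- nrow(G$calls)
    report$fraction_imputed <- attr(G, "fraction_imputed")
    res$qc <- report
    readr::write_tsv(report, file.path(out_dir, "qc_report.tsv"))
    write_genotypes_tsv(G, file.path(out_dir, "genotypes_qc.tsv"))
    traits <- traits[traits$animal_id %in% animal_ids(G), ]
  }

  if ("rfi" %in% st) {
    say("rfi: within-group regression of AFI on ADG and MMW")
    traits <- derive_rfi(traits)
    res$rfi_models <- rfi_models(traits)
    readr::write_tsv(res$rfi_models, file.path(out_dir, "rfi_models.tsv"))
    write_traits_tsv(traits, file.path(out_dir, "traits.tsv"))
  }
  res$traits <- traits

  eig <- NULL
  if ("grm" %in% st) {
    say("grm: ", config$grm_method)
    if (config$grm_method == "calibrated") {
      A <- numerator_matrix(population$pedigree)
      A <- A[animal_ids(G), animal_ids(G)]
      S <- allele_sharing_matrix(G)
      grm <- calibrate_grm(S, A)
    } else {
      grm <- vanraden_grm(G)
    }
    res$grm <- grm
    if (config$write_matrices) {
      write_matrix_tsv(grm, file.path(out_dir, "grm.tsv"))
    }
    eig <- grm_eigen(grm)
  }

  if ("reml" %in% st) {
    res$models <- list()
    vc <- list()
    for (tr in config$traits) {
      say("reml: ", tr)
      data_tr <- traits[match(eig$ids, traits$animal_id), ]
      fit <- fit_animal_model(data_tr, tr, eig)
      res$models[[tr]] <- fit
      readr::write_tsv(dplyr::mutate(fit$ebv, trait = tr),
                       file.path(out_dir, paste0("ebv_", tr, ".tsv")))
      vc[[tr]] <- glance(fit)
    }
    res$varcomp <- dplyr::bind_rows(vc)
    jsonlite::write_json(res$varcomp, file.path(out_dir, "varcomp.json"),
                         auto_unbox = TRUE, digits = NA)
    ebv_mat <- sapply(res$models, function(m) m$ebv$ebv)
    res$ebv_correlations <- stats::cor(ebv_mat)
    write_matrix_tsv(res$ebv_correlations,
                     file.path(out_dir, "ebv_correlations.tsv"))
  }

  if ("scan" %in% st) {
    res$scans <- list(); res$thresholds <- list()
    for (i in seq_along(config$traits)) {
      tr <- config$traits[i]
      say("scan: ", tr, " (", config$n_perm, " permutations)")
      fit <- res$models[[tr]]
      sc <- genome_scan(fit, G)
      thr <- permutation_threshold(fit, G, n_perm = config$n_perm,
                                   alpha = config$alpha,
                                   seed = config$seed + 100L + i,
                                   permute = config$permute)
      sc <- apply_threshold(sc, thr)
      res$scans[[tr]] <- sc
      res$thresholds[[tr]] <- thr
      readr::write_tsv(sc, file.path(out_dir, paste0("scan_", tr, ".tsv")))
    }
    thr_tbl <- tibble::tibble(
      trait = config$traits,
      threshold_f = vapply(res$thresholds, function(x) x$threshold_f, 1),
      n_perm = config$n_perm, alpha = config$alpha)
    readr::write_tsv(thr_tbl, file.path(out_dir, "thresholds.tsv"))
  }

  if ("select" %in% st) {
    res$panels <- list()
    for (tr in config$traits) {
      say("select: ", tr)
      res$panels[[tr]] <- forward_select(res$scans[[tr]], res$models[[tr]],
                                         G, res$thresholds[[tr]], trait = tr)
      readr::write_tsv(res$panels[[tr]],
                       file.path(out_dir, paste0("panel_", tr, ".tsv")))
    }
  }

  if ("gblup" %in% st) {
    res$contrasts <- list()
    for (tr in config$traits) {
      say("gblup: ", tr)
      fit <- res$models[[tr]]
      panel <- res$panels[[tr]]
      w <- weight_vector(fit$ebv$accuracy)
      pg <- G$calls[, match(panel$snp_id, G$snp_map$snp_id), drop = FALSE]
      res$contrasts[[tr]] <- gblup_variance_explained(
        fit$ebv$ebv, pg, eig, weights = w)
    }
    res$summary <- tibble::tibble(
      trait = config$traits,
      candidate_snps = vapply(res$panels, function(p)
        attr(p, "n_candidates"), 1L)[config$traits],
      final_model_snps = vapply(res$panels, nrow, 1L)[config$traits],
      pct_ebv_variance = 100 * vapply(res$panels, function(p)
        if (is.na(attr(p, "final_r2"))) 0 else attr(p, "final_r2"),
        1)[config$traits],
      pct_gblup_variance = 100 * vapply(res$contrasts, function(x)
        x$proportion_explained, 1)[config$traits]
    )
    readr::write_tsv(res$summary, file.path(out_dir, "variance_summary.tsv"))
  }

  if ("regions" %in% st) {
    say("regions: ", config$window_bp / 1e6 * 2, " Mb windows")
    res$regions <- purrr::map(res$panels, regions_from_panel,
                              window_bp = config$window_bp)
    for (tr in names(res$regions)) {
      windows_to_bed(res$regions[[tr]],
                     file.path(out_dir, paste0("windows_", tr, ".bed")))
    }
    prs <- utils::combn(config$traits, 2, simplify = FALSE)
    res$concordance <- purrr::map_dfr(prs, function(p) {
      tibble::tibble(trait_a = p[1], trait_b = p[2],
                     n_concordant = cross_trait_concordance(
                       res$regions[[p[1]]], res$regions[[p[2]]]))
    })
    readr::write_tsv(res$concordance,
                     file.path(out_dir, "cross_trait_concordance.tsv"))
  }

  write_config_yaml(config, file.path(out_dir, "config.yaml"))
  write_manifest(out_dir, config)
  say("done: ", out_dir)
  invisible(res)
}
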