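#' Write and read genotypes as TSV
#'
#' The genotype TSV has one row per animal (`animal_id` first column, then one
#' column per SNP with 0/1/2 dosages, missing as `NA`); the SNP map is a
#' separate TSV (`snp_id`, `chrom`, `pos_bp`).
#'
#' @param G A [geno_matrix()].
#' @param path Genotype TSV path.
#' @param map_path SNP map TSV path (default `<path>.map.tsv` alongside).
#' @return Invisibly, the paths written.
#' @export
write_genotypes_tsv <- function(G, path, map_path = paste0(path, ".map.tsv")) {
  df <- tibble::as_tibble(G$calls, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(animal_id = animal_ids(G)), df)
  readr::write_tsv(df, path)
  readr::write_tsv(G$snp_map, map_path)
  invisible(c(path, map_path))
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path, map_path = paste0(path, ".map.tsv")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  map <- readr::read_tsv(map_path, show_col_types = FALSE,
                         col_types = readr::cols(snp_id = "c", chrom = "c",
                                                 pos_bp = "d"))
  calls <- as.matrix(df[, -1])
  rownames(calls) <- df$animal_id
  geno_matrix(calls, map)
}

#' Write and read genotypes in PLINK-raw style
#'
#' Space-separated file with header
#' `FID IID PAT MAT SEX PHENOTYPE <snp...>` and one 0/1/2 dosage column per
#' SNP (`NA` for missing), as produced by `plink --recode A`. The SNP map
#' travels in a separate TSV as in [write_genotypes_tsv()].
#'
#' @inheritParams write_genotypes_tsv
#' @param pedigree Optional pedigree tibble used to fill PAT; otherwise 0.
#' @return Invisibly, the paths written.
#' @export
write_genotypes_raw <- function(G, path, map_path = paste0(path, ".map.tsv"),
                                pedigree = NULL) {
  ids <- animal_ids(G)
  pat <- rep("0", length(ids))
  if (!is.null(pedigree)) {
    i <- match(ids, pedigree$animal_id)
    pat <- ifelse(is.na(pedigree$sire_id[i]), "0", pedigree$sire_id[i])
  }
  lead <- tibble::tibble(FID = "0", IID = ids, PAT = pat, MAT = "0",
                         SEX = "1", PHENOTYPE = "-9")
  df <- dplyr::bind_cols(lead,
                         tibble::as_tibble(G$calls, .name_repair = "minimal"))
  readr::write_delim(df, path, delim = " ")
  readr::write_tsv(G$snp_map, map_path)
  invisible(c(path, map_path))
}

#' @rdname write_genotypes_raw
#' @export
read_genotypes_raw <- function(path, map_path = paste0(path, ".map.tsv")) {
  df <- readr::read_delim(path, delim = " ", show_col_types = FALSE)
  map <- readr::read_tsv(map_path, show_col_types = FALSE,
                         col_types = readr::cols(snp_id = "c", chrom = "c",
                                                 pos_bp = "d"))
  calls <- as.matrix(df[, -(1:6)])
  rownames(calls) <- df$IID
  geno_matrix(calls, map)
}

#' Read genotypes from a VCF
#'
#' Converts the GT field to an ALT-allele dosage (0/1/2, `NA` for missing);
#' samples become animals.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return A [geno_matrix()]; `snp_id` is the VCF ID (or `chrom_pos` when
#'   missing).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_real_)
    a <- strsplit(x, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(as.integer(a) > 0)
  })
  fix <- vcfR::getFIX(v)
  id <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
               paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"])
  map <- tibble::tibble(snp_id = unname(id),
                        chrom = unname(fix[, "CHROM"]),
                        pos_bp = as.numeric(fix[, "POS"]))
  calls <- t(dose)
  colnames(calls) <- map$snp_id
  geno_matrix(calls, map)
}

#' Write and read the trait table
#' @param traits Trait tibble.
#' @param path TSV path.
#' @return The tibble (reader) or the path invisibly (writer).
#' @export
write_traits_tsv <- function(traits, path) {
  readr::write_tsv(traits, path)
  invisible(path)
}

#' @rdname write_traits_tsv
#' @export
read_traits_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write and read a relationship matrix as full-matrix TSV
#'
#' Animal ids appear as the header row and the first column.
#'
#' @param M Relationship matrix with dimnames.
#' @param path TSV path.
#' @return The matrix (reader) or the path invisibly (writer).
#' @export
write_matrix_tsv <- function(M, path) {
  df <- tibble::as_tibble(M, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(animal_id = rownames(M)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  M <- as.matrix(df[, -1])
  rownames(M) <- df$animal_id
  M
}

#' Save and load configurations as YAML
#' @param config A `sim_config` or `pipeline_config` list.
#' @param path YAML file path.
#' @return The config list (reader) or the path invisibly (writer).
#' @export
write_config_yaml <- function(config, path) {
  cls <- class(config)
  obj <- unclass(config)
  obj[[".class"]] <- cls[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj[[".class"]]
  obj[[".class"]] <- NULL
  if (identical(cls, "sim_config")) {
    do.call(sim_config, obj)
  } else if (identical(cls, "pipeline_config")) {
    do.call(pipeline_config, obj)
  } else {
    obj
  }
}

#' Write a run manifest
#'
#' Records, for every artifact of a pipeline run, its md5 hash, plus the
#' configuration and package version, so that re-runs can be verified
#' bit-identical.
#'
#' @param dir Run directory.
#' @param config The `pipeline_config` used.
#' @return The manifest list, invisibly; written to `manifest.json` in `dir`.
#' @export
write_manifest <- function(dir, config) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(dir, files)))
  names(hashes) <- files
  plain <- unclass(config)
  if (!is.null(plain$sim)) plain$sim <- unclass(plain$sim)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rfigwas")),
    config = plain,
    files = hashes
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
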