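#' QTL regions around forward-selected SNPs
#'
#' One 1-Mb window (anchor position +/- 0.5 Mb, closed interval, clipped at 0)
#' per selected SNP. SNPs without a mapped position are flagged
#' non-comparable.
#'
#' @param panel A `selected_panel` tibble (or any data frame with `snp_id`,
#'   `chrom`, `pos_bp`, optionally `trait`).
#' @param window_bp Half-window size in bp (default 500000).
#' @return Tibble of class `qtl_regions`: `trait`, `snp_id`, `chrom`,
#'   `center_bp`, `window_start`, `window_end`, `comparable`.
#' @export
regions_from_panel <- function(panel, window_bp = 5e5) {
  panel <- tibble::as_tibble(panel)
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(panel)))
  out <- tibble::tibble(
    trait = if ("trait" %in% names(panel)) panel$trait else NA_character_,
    snp_id = panel$snp_id,
    chrom = normalize_chrom(panel$chrom),
    center_bp = panel$pos_bp,
    window_start = pmax(0, panel$pos_bp - window_bp),
    window_end = panel$pos_bp + window_bp,
    comparable = !is.na(panel$pos_bp)
  )
  class(out) <- c("qtl_regions", class(out))
  out
}

#' Count concordant QTL regions between two traits
#'
#' Two regions are concordant when their windows overlap on the same
#' chromosome (closed-interval overlap: windows whose endpoints touch
#' exactly do overlap). The default counter is the number of overlapping
#' region pairs, which is symmetric in its arguments for any input; the
#' `"anchors"` counter instead counts regions of `a` whose anchor SNP falls
#' inside some window of `b` (not symmetric in general).
#'
#' @param regions_a,regions_b [regions_from_panel()] tibbles on the same
#'   genome build.
#' @param count `"overlap"` (default, region-pair counter) or `"anchors"`.
#' @return Integer count.
#' @export
cross_trait_concordance <- function(regions_a, regions_b,
                                    count = c("overlap", "anchors")) {
  count <- match.arg(count)
  a <- dplyr::filter(tibble::as_tibble(regions_a), .data$comparable)
  b <- dplyr::filter(tibble::as_tibble(regions_b), .data$comparable)
  if (!nrow(a) || !nrow(b)) return(0L)
  n <- 0L
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i]
    if (!any(same)) next
    if (count == "overlap") {
      hit <- b$window_start[same] <= a$window_end[i] &
        b$window_end[same] >= a$window_start[i]
    } else {
      hit <- b$window_start[same] <= a$center_bp[i] &
        b$window_end[same] >= a$center_bp[i]
    }
    n <- n + sum(hit)
  }
  n
}

#' Concordance of a SNP panel with external QTL positions
#'
#' A selected SNP is concordant with a previously published QTL when both lie
#' on the same chromosome and their positions differ by at most `window_bp`
#' (inclusive, 1 Mb window total). Chromosome labels are normalized (e.g.
#' `"Chr11"` and `"11"` compare equal).
#'
#' @param panel Data frame with `snp_id`, `chrom`, `pos_bp` (selected SNPs).
#' @param external Data frame with `chrom`, `position_bp` and optionally
#'   `source` (published QTL positions on the same genome build).
#' @param window_bp Maximum distance in bp (default 500000).
#' @param match `"cross"` (default) tests every same-chromosome panel x
#'   external pair; `"paired"` tests row i of the panel against row i of
#'   `external` (the two must have equal length).
#' @return Tibble of class `concordance_table`: `snp_id`, `chrom`,
#'   `position_bp`, `external_position_bp`, `source`, `distance_bp`,
#'   `concordant`.
#' @export
external_concordance <- function(panel, external, window_bp = 5e5,
                                 match = c("cross", "paired")) {
  match <- match.arg(match)
  panel <- tibble::as_tibble(panel)
  external <- tibble::as_tibble(external)
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(panel)),
            all(c("chrom", "position_bp") %in% names(external)))
  if (!"source" %in% names(external)) external$source <- NA_character_
  pc <- normalize_chrom(panel$chrom)
  ec <- normalize_chrom(external$chrom)

  if (match == "paired") {
    if (nrow(panel) != nrow(external)) {
      stop("paired matching requires equal row counts")
    }
    out <- tibble::tibble(
      snp_id = panel$snp_id, chrom = pc, position_bp = panel$pos_bp,
      external_position_bp = external$position_bp, source = external$source,
      distance_bp = abs(panel$pos_bp - external$position_bp),
      concordant = pc == ec &
        abs(panel$pos_bp - external$position_bp) <= window_bp)
  } else {
    grid <- tidyr::expand_grid(i = seq_len(nrow(panel)),
                               j = seq_len(nrow(external)))
    grid <- grid[pc[grid$i] == ec[grid$j], ]
    out <- tibble::tibble(
      snp_id = panel$snp_id[grid$i], chrom = pc[grid$i],
      position_bp = panel$pos_bp[grid$i],
      external_position_bp = external$position_bp[grid$j],
      source = external$source[grid$j],
      distance_bp = abs(panel$pos_bp[grid$i] -
                          external$position_bp[grid$j]))
    out$concordant <- out$distance_bp <= window_bp
  }
  class(out) <- c("concordance_table", class(out))
  out
}

#' Export QTL windows as BED intervals
#'
#' Converts the internal 1-based closed windows to BED's 0-based half-open
#' convention (`start0 = window_start - 1` clipped at 0, `end = window_end`).
#'
#' @param regions A [regions_from_panel()] tibble.
#' @param path Optional file to write (tab-separated, no header).
#' @return Tibble with `chrom`, `start`, `end`, `name` (invisibly when
#'   written to file).
#' @export
windows_to_bed <- function(regions, path = NULL) {
  bed <- tibble::tibble(
    chrom = regions$chrom,
    start = pmax(0, regions$window_start - 1),
    end = regions$window_end,
    name = regions$snp_id
  )
  if (!is.null(path)) {
    readr::write_tsv(bed, path, col_names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' Read BED intervals back as 1-based closed windows
#'
#' Inverse of [windows_to_bed()].
#'
#' @param path BED file (chrom, start, end, name; no header).
#' @return Tibble with `chrom`, `window_start`, `window_end`, `snp_id`.
#' @export
bed_to_windows <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE)
  tibble::tibble(chrom = as.character(bed$chrom),
                 window_start = bed$start + 1,
                 window_end = bed$end,
                 snp_id = bed$name)
}

#' Published feed-efficiency QTL validation pairs
#'
#' The bundled table of forward-selected SNP positions and the previously
#' published QTL positions (two independent external studies, all coordinates
#' on one bovine genome build) against which they were validated; every pair
#' lies within the +/- 0.5 Mb concordance window.
#'
#' @return Tibble: `trait`, `snp_id`, `chrom`, `position_bp`,
#'   `validation_position_bp`, `source`.
#' @export
published_qtl_pairs <- function() {
  path <- system.file("extdata", "published_qtl_pairs.tsv",
                      package = "rfigwas", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    trait = "c", snp_id = "c", chrom = "c",
                    position_bp = "d", validation_position_bp = "d",
                    source = "c"))
}
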