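#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan plot of a genome scan
#'
#' @param object A [genome_scan()] result (run through [apply_threshold()] to
#'   draw the genome-wide threshold line).
#' @param ... Unused.
#' @return A ggplot object: per-SNP F statistics by cumulative genome
#'   position, chromosomes in alternating shades.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$skipped) |>
    dplyr::mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  offsets <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos_bp), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  df <- dplyr::left_join(df, offsets, by = "chrom") |>
    dplyr::mutate(x = .data$pos_bp + .data$offset,
                  shade = as.integer(.data$chrom) %% 2 == 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$f_stat,
                                        colour = .data$shade)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "genome position", y = "F statistic") +
    ggplot2::theme_minimal()
  thr <- attr(object, "threshold_f")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' Heritability trajectory of an EM-REML fit
#'
#' @param object An [fit_animal_model()] result.
#' @param ... Unused.
#' @return A ggplot object showing the h2 iterates and the converged value.
#' @method autoplot animal_model
#' @export
autoplot.animal_model <- function(object, ...) {
  traj <- object$varcomp$h2_trajectory
  df <- tibble::tibble(iteration = seq_along(traj), h2 = traj)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$h2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$varcomp$h2, linetype = 3) +
    ggplot2::labs(title = paste("EM-REML heritability trajectory:",
                                object$trait),
                  y = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' Null distribution of the permutation maximum F
#'
#' @param object A [permutation_threshold()] result.
#' @param ... Unused.
#' @return A ggplot histogram of the max-F sample with the threshold marked.
#' @method autoplot perm_threshold
#' @export
autoplot.perm_threshold <- function(object, ...) {
  df <- tibble::tibble(max_f = object$max_f)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_f)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold_f, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "genome-wide maximum F (permuted)",
                  y = "permutations") +
    ggplot2::theme_minimal()
}
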