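#' Plot the 5'-start profile around a locus
#'
#' Bar plot of per-position RPM in a window around a genomic locus, the
#' visual signature of a Degradome pile-up.
#'
#' @param track a `start_track`.
#' @param chrom,strand,pos locus.
#' @param halfwidth window half-width in nt.
#' @return a ggplot object.
#' @export
plot_pileup <- function(track, chrom, strand, pos, halfwidth = 25) {
  offs <- -halfwidth:halfwidth
  df <- tibble::tibble(
    offset = offs,
    rpm = track_rpm(track, chrom, strand,
                    pos + ifelse(strand == "+", 1, -1) * offs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$rpm)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = sprintf("offset from %s:%d (%s)", chrom, pos, strand),
                  y = "5' starts (RPM)") +
    ggplot2::theme_minimal()
}

#' Plot an information-bits profile
#'
#' Line/point plot of per-position information content from
#' [information_matrix()], the quantitative backbone of a structure or
#' sequence logo.
#'
#' @param info tibble from [information_matrix()].
#' @return a ggplot object.
#' @export
plot_information_bits <- function(info) {
  ggplot2::ggplot(info, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "cleavage-anchored position",
                  y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Balloon plot of internal-loop sizes by 5-bp stem window
#'
#' Reproduces the internal-loop catalog view: loop size on each arm,
#' positioned by the 5-bp bin of the loop's cleavage-proximal 5'-arm
#' nucleotide; balloon size counts loops.
#'
#' @param loops tibble from [catalog_internal_loops()] rows (may combine
#'   many calls).
#' @return a ggplot object.
#' @export
plot_internal_loops <- function(loops) {
  df <- loops |>
    dplyr::count(.data$bin, .data$size5, .data$size3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin,
                                   y = paste0(.data$size5, "x",
                                              .data$size3),
                                   size = .data$n)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "5-bp stem window", y = "loop size (5' arm x 3' arm)",
                  size = "loops") +
    ggplot2::theme_minimal()
}

#' Feature comparison boxplots by class
#'
#' @param features feature tibble with a `class` column (e.g. a
#'   `drosha_run`'s `$features`).
#' @param vars feature columns to show.
#' @return a ggplot object.
#' @export
plot_feature_comparison <- function(features,
                                    vars = c("mfe", "length",
                                             "bp_frequency",
                                             "ensemble_diversity")) {
  df <- tidyr::pivot_longer(features[, c("class", vars)],
                            dplyr::all_of(vars), names_to = "feature")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Stage-count overview of a pipeline run
#'
#' @param object a `drosha_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot drosha_run
#' @export
autoplot.drosha_run <- function(object, ...) {
  r <- object$report
  df <- tibble::tibble(
    stage = factor(c("planted", "candidates", "pile-ups", "dependent",
                     "resolved"),
                   levels = c("planted", "candidates", "pile-ups",
                              "dependent", "resolved")),
    n = c(r$n_planted, r$n_candidates, r$n_accepted_pileups,
          r$n_dependent, r$n_resolved))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "loci") +
    ggplot2::theme_minimal()
}
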