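#' Plot a binding profile
#'
#' Median signal of each tile against the position of its N-terminal
#' residue, points connected in sequence order, with replicate-SD error
#' bars — the signal-vs-position view of one antigen in one or more
#' experiments.
#'
#' @param profile A [binding_profile()] tibble (optionally stacked over
#'   experiments with an `experiment_id` column).
#' @param threshold Optional horizontal line at the binder threshold.
#' @return A ggplot object.
#' @export
plot_binding_profile <- function(profile, threshold = NULL) {
  has_exp <- "experiment_id" %in% names(profile)
  p <- ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$start, y = .data$median,
    colour = if (has_exp) .data$experiment_id else NULL
  )) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$median - .data$sd,
                   ymax = .data$median + .data$sd),
      width = 0.6, alpha = 0.5
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "N-terminal residue position of 12-mer",
                  y = "median intensity (AU)",
                  colour = "experiment") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  if (length(unique(profile$accession)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$accession),
                                 scales = "free_x")
  }
  p
}

#' Plot a residue-level epitope map
#'
#' One tile per residue along the sequence, filled by the averaged
#' alanine-substitution effect (diverging scale; strongly negative =
#' substitution abolishes binding = key residue) with residues lacking
#' any covering binder peptide in grey, and the residue score drawn as a
#' line above.
#'
#' @param profile A [residue_profile()] tibble (one experiment).
#' @param accessions Optional subset of antigens to show.
#' @return A ggplot object.
#' @export
plot_residue_profile <- function(profile, accessions = NULL) {
  if (!is.null(accessions)) {
    profile <- filter(profile, .data$accession %in% accessions)
  }
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue)) +
    ggplot2::geom_tile(ggplot2::aes(y = 0, fill = .data$ala_effect),
                       height = 0.8) +
    ggplot2::geom_line(ggplot2::aes(
      y = .data$residue_score /
        max(profile$residue_score, na.rm = TRUE) + 0.6
    ), na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(low = "#5e3c99", mid = "white",
                                  high = "#e66101", midpoint = 0,
                                  na.value = "grey80") +
    ggplot2::facet_wrap(ggplot2::vars(.data$accession), ncol = 1,
                        strip.position = "left") +
    ggplot2::labs(x = "residue", fill = "mean log2 FC (Ala)",
                  y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Violin plot of per-peptide median signals
#'
#' The distribution view used to judge the background population: most
#' peptides form a near-normal low-intensity bulk, binders sit in the
#' long upper tail.
#'
#' @param medians A [replicate_median()] tibble, or several stacked with
#'   an `experiment_id` column.
#' @param upper Optional upper display limit (AU).
#' @return A ggplot object.
#' @export
plot_signal_distribution <- function(medians, upper = NULL) {
  if (!"experiment_id" %in% names(medians)) {
    medians$experiment_id <- "experiment"
  }
  if (!is.null(upper)) {
    medians <- filter(medians, .data$median <= upper)
  }
  ggplot2::ggplot(medians, ggplot2::aes(x = .data$experiment_id,
                                        y = .data$median)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "median intensity (AU)") +
    ggplot2::theme_minimal()
}

#' @method autoplot background_model
#' @export
autoplot.background_model <- function(object, medians = NULL, ...) {
  if (is.null(medians)) {
    abort("pass the median tibble the model was fitted on via `medians`")
  }
  wt <- wt_medians(medians)
  ggplot2::ggplot(wt, ggplot2::aes(x = .data$median)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "median intensity (AU)", y = "peptides") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
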