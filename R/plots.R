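# ggplot2 helpers for the main result types

#' Plot a stage profile as per-stage emergence bars
#'
#' @param object A `stage_profile`.
#' @param cumulative Plot the cumulative percentage instead of the per-stage
#'   share.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stage_profile <- function(object, cumulative = FALSE, ...) {
  df <- object$stages
  if (cumulative) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$cumulative_pct)) +
      ggplot2::geom_step() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "hallmark stage", y = "cumulative % of genes",
                    title = sprintf("Cumulative gene emergence (%s)", object$label))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$stage_label, levels = df$stage_label),
                                     y = .data$pct_of_total)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "hallmark stage", y = "% of genes",
                    title = sprintf("Gene emergence per stage (%s)", object$label))
  }
}

#' Cumulative gene-emergence curves on the evolutionary time axis
#'
#' Overlays one cumulative emergence curve per gene class (e.g. all / HK /
#' TE), with one point per lineage clade at its age in Mya; the x axis runs
#' from the origin (oldest) to the present.
#'
#' @param lineage Lineage tibble with clade ages.
#' @param profiles Named list of `stage_profile` objects computed from
#'   assignments (per-clade counts required).
#' @return A ggplot object.
#' @export
plot_emergence_curves <- function(lineage, profiles) {
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    time_axis(lineage, p) |> mutate(class = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_mya, y = .data$cumulative_pct,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Mya)", y = "cumulative % of genes", colour = NULL,
                  title = "Gene emergence along the time-calibrated lineage")
}

#' Plot an HK-versus-TE expression contrast
#'
#' @param object A `class_contrast`.
#' @param labels Length-2 class labels for the two pooled value sets.
#' @param ... Unused.
#' @return A ggplot boxplot of the pooled log2 expression values per class.
#' @export
autoplot.class_contrast <- function(object, labels = c("HK", "TE"), ...) {
  df <- tibble(
    class = rep(labels, c(length(object$values_a), length(object$values_b))),
    value = c(object$values_a, object$values_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "log2(FPKM + 1)",
                  title = sprintf("Expression contrast (mean diff = %.2f)", object$mean_diff))
}

#' Stacked age composition of network modules
#'
#' @param composition Tibble from [module_age_composition()].
#' @return A ggplot stacked-bar chart, one bar per module.
#' @export
plot_module_ages <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$module_id, y = .data$proportion,
                               fill = factor(.data$stage))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of members", fill = "stage",
                  title = "Module age composition") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
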