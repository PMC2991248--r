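#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the distribution of predicted branch-point positions
#'
#' Histogram of best-candidate adenosine positions, anchored either on the
#' 3SS or on the AGEZ-defining AG (compare the genome-wide position
#' distributions of the two anchors).
#'
#' @param object A `bp_predictions` object.
#' @param anchor `"3ss"` (default) or `"defining_ag"`.
#' @param binwidth Histogram bin width in nucleotides.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bp_predictions <- function(object, anchor = c("3ss", "defining_ag"),
                                    binwidth = 1, ...) {
  anchor <- match.arg(anchor)
  h <- position_histogram(object, anchor = anchor)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$position, y = .data$n)) +
    ggplot2::geom_col(width = binwidth, fill = "steelblue") +
    ggplot2::labs(
      x = if (anchor == "3ss") {
        "BP position relative to 3' splice site (nt)"
      } else {
        "BP position relative to AGEZ-defining AG (nt)"
      },
      y = "introns"
    ) +
    ggplot2::theme_minimal()
}

#' Plot benchmark sensitivities with standard errors
#'
#' @param object Tibble from [benchmark_bp_methods()] (columns `method`,
#'   `sensitivity`, `se_sensitivity`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_benchmark <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$method, y = 100 * .data$sensitivity)
  ) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = 100 * (.data$sensitivity - .data$se_sensitivity),
        ymax = 100 * (.data$sensitivity + .data$se_sensitivity)
      ),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "sensitivity (%)") +
    ggplot2::theme_minimal()
}

#' Plot per-position information content of a motif model
#'
#' @param model A `bp_freq_model`.
#' @return A ggplot with one bar per 9-mer position (bits).
#' @export
plot_information_content <- function(model) {
  ic <- information_content(model)
  df <- tibble::tibble(position = factor(1:9), bits = ic$per_position)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::labs(
      x = "9-mer position", y = "information content (bits)",
      subtitle = sprintf("total IC = %.3f bits", ic$total)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the positional profile of a pentamer
#'
#' Distributions of all and of conserved instance start positions over the
#' scanned region, the visual counterpart of the classification tests.
#'
#' @param profiles Tibble from [pentamer_profiles()] or
#'   [classify_pentamers()].
#' @param pentamer The pentamer to plot.
#' @param binwidth Histogram bin width (default 5 nt).
#' @return A ggplot.
#' @export
plot_pentamer_profile <- function(profiles, pentamer, binwidth = 5) {
  row <- profiles[profiles$pentamer == pentamer, ]
  if (nrow(row) != 1L) stop("pentamer not found in profiles")
  df <- dplyr::bind_rows(
    tibble::tibble(set = "all", position = row$positions_all[[1]]),
    tibble::tibble(set = "conserved", position = row$positions_conserved[[1]])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, fill = .data$set)) +
    ggplot2::geom_histogram(
      binwidth = binwidth, position = "identity", alpha = 0.6
    ) +
    ggplot2::labs(
      x = "start position relative to 3' splice site (nt)", y = "instances",
      title = pentamer
    ) +
    ggplot2::theme_minimal()
}
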