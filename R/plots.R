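# ggplot2 views of the three result types. Tables are the contract;
# these plots are conveniences over tidy() output.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col labs
#'   scale_y_continuous sec_axis coord_flip
NULL

#' Plot the ppm-NTF distance distribution
#'
#' Points show log10 gene counts per distance; the line shows the
#' cumulative fraction of genomes (rescaled onto the same axis, with a
#' secondary axis labelling it).
#'
#' @param object A `distance_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_distribution
#' @export
autoplot.distance_distribution <- function(object, ...) {
  h <- object$histogram
  ymax <- max(h$log10_count, 1)
  ggplot(h, aes(x = .data$distance)) +
    geom_point(aes(y = .data$log10_count), colour = "steelblue") +
    geom_line(aes(y = .data$cumulative_fraction * ymax)) +
    scale_y_continuous(
      name = "log10(count)",
      sec.axis = sec_axis(~ . / ymax, name = "cumulative fraction")) +
    labs(x = "gene distance between ppm and nearest NTF gene")
}

#' Plot the fusion inventory
#'
#' Bar chart of fusion-category shares among motif-positive Ppm proteins.
#'
#' @param object A `ppm_inventory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppm_inventory
#' @export
autoplot.ppm_inventory <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$category, y = .data$pct)) +
    geom_col(fill = "firebrick") +
    coord_flip() +
    labs(x = NULL, y = "% of Ppm proteins")
}

#' Plot a kinetic fit
#'
#' Observed initial rates with the fitted rate-law curve.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(S = seq(min(d$S), max(d$S), length.out = 200))
  grid$v <- if (object$model == "MM") {
    mm_rate(grid$S, object$kcat, object$KM, object$E0)
  } else {
    si_rate(grid$S, object$kcat, object$KM, object$KS, object$E0)
  }
  ggplot(d, aes(x = .data$S, y = .data$v)) +
    geom_point() +
    geom_line(data = grid, colour = "firebrick") +
    labs(x = "[S]", y = "initial velocity")
}
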