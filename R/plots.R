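#' Plot a null distribution with observed ANI values
#'
#' Draws the species' same-strain null as a grey kernel density with
#' observed pair ANI values overlaid as coloured vertical lines — the
#' standard way to read where an observed comparison falls relative to
#' same-strain resequencing noise.
#'
#' @param object A `pooled_null`.
#' @param observed Optional numeric vector (optionally named by pair) of
#'   observed ANI values to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pooled_null <- function(object, observed = NULL, ...) {
  kde <- object$kde %||% fit_kde(object$values$ani)
  dens <- tibble::tibble(ani = kde$x, density = kde$y)
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$ani, y = .data$density)) +
    ggplot2::geom_area(fill = "grey70", colour = "grey40") +
    ggplot2::labs(
      x = "ANI (%)", y = "Density",
      title = paste0("Same-strain ANI null distribution: ", object$species)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed) && length(observed) > 0) {
    obs <- tibble::tibble(
      ani = as.numeric(observed),
      pair = names(observed) %||% paste0("pair ", seq_along(observed))
    )
    p <- p +
      ggplot2::geom_vline(
        data = obs,
        ggplot2::aes(xintercept = .data$ani, colour = .data$pair),
        linewidth = 0.8
      ) +
      ggplot2::labs(colour = "Observed pair")
  }
  p
}

#' Plot a study report
#'
#' One panel per species: the grey null density with each classified
#' pair's observed ANI as a vertical line coloured by its category.
#'
#' @param object A `study_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  dens <- dplyr::bind_rows(lapply(names(object$nulls), function(sp) {
    kde <- object$nulls[[sp]]$kde %||% fit_kde(object$nulls[[sp]]$values$ani)
    tibble::tibble(species = sp, ani = kde$x, density = kde$y)
  }))
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$ani, y = .data$density)) +
    ggplot2::geom_area(fill = "grey70", colour = "grey40") +
    ggplot2::facet_wrap(~species, scales = "free") +
    ggplot2::labs(x = "ANI (%)", y = "Density") +
    ggplot2::theme_minimal()
  if (nrow(object$calls) > 0) {
    p <- p +
      ggplot2::geom_vline(
        data = dplyr::rename(object$calls, ani = "observed_ani"),
        ggplot2::aes(xintercept = .data$ani, colour = .data$category),
        linewidth = 0.8
      ) +
      ggplot2::scale_colour_manual(values = c(identical = "#1b9e77",
                                              related = "#7570b3",
                                              different = "#d95f02")) +
      ggplot2::labs(colour = "Call")
  }
  p
}
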