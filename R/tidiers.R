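#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-observation content of a
#' fitted object as a tibble, `glance()` a one-row summary.
#'
#' @param x A `pooled_null`, `strain_anova`, or `study_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name strainani-tidiers
NULL

#' @rdname strainani-tidiers
#' @export
tidy.pooled_null <- function(x, ...) {
  dplyr::mutate(x$values, species = x$species, .before = 1)
}

#' @rdname strainani-tidiers
#' @export
glance.pooled_null <- function(x, ...) {
  tibble::tibble(
    species = x$species,
    n_values = nrow(x$values),
    n_strains = dplyr::n_distinct(x$values$strain),
    mean_ani = mean(x$values$ani),
    sd_ani = sd(x$values$ani),
    bootstrap_B = if (is.null(x$bootstrap)) NA_integer_ else length(x$bootstrap),
    kde_bandwidth = if (is.null(x$kde)) NA_real_ else x$kde$bw,
    anova_f = if (is.null(x$anova)) NA_real_ else x$anova$f_statistic,
    anova_p = if (is.null(x$anova)) NA_real_ else x$anova$p_value
  )
}

#' @rdname strainani-tidiers
#' @export
tidy.strain_anova <- function(x, ...) {
  tibble::tibble(term = "strain", df = x$df_between,
                 statistic = x$f_statistic, p.value = x$p_value)
}

#' @rdname strainani-tidiers
#' @export
glance.strain_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f_statistic, p.value = x$p_value,
                 df_between = x$df_between, df_within = x$df_within)
}

#' @rdname strainani-tidiers
#' @export
tidy.study_report <- function(x, ...) {
  x$calls
}

#' @rdname strainani-tidiers
#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$calls),
    n_identical = x$summary[["identical"]],
    n_related = x$summary[["related"]],
    n_different = x$summary[["different"]],
    p_low = x$config$p_low,
    p_high = x$config$p_high
  )
}
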