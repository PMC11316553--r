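#' Pool same-strain ANI values for one species
#'
#' Concatenates the same-strain replicate-pair ANI values of all strains of
#' a species into one pooled null sample, keeping strain labels so the
#' strain-level ANOVA can be run on the pool.
#'
#' @param values A data frame with columns `strain` and `ani` (percent in
#'   (0, 100\]).
#' @param species Species name the pool belongs to.
#' @return A `pooled_null` object (fields `species`, `values`; `bootstrap`,
#'   `kde` and `anova` are filled by [build_null()]).
#' @seealso [build_null()], [empirical_p()]
#' @export
pool_ani <- function(values, species = "species") {
  stopifnot(is.data.frame(values), all(c("strain", "ani") %in% names(values)))
  values <- tibble::as_tibble(values)[, c("strain", "ani")]
  if (nrow(values) == 0) rlang::abort("cannot pool an empty set of ANI values")
  if (anyNA(values$ani) || any(values$ani <= 0 | values$ani > 100)) {
    rlang::abort("pooled ANI values must lie in (0, 100]")
  }
  structure(
    list(species = species, values = values, bootstrap = NULL, kde = NULL,
         anova = NULL),
    class = "pooled_null"
  )
}

#' @export
print.pooled_null <- function(x, ...) {
  cat(sprintf(
    "<pooled_null> %s: %d ANI values from %d strain(s); bootstrap %s; KDE %s\n",
    x$species, nrow(x$values), dplyr::n_distinct(x$values$strain),
    if (is.null(x$bootstrap)) "not drawn" else format(length(x$bootstrap)),
    if (is.null(x$kde)) "not fitted" else "fitted"
  ))
  invisible(x)
}

#' Bootstrap a sample of ANI values
#'
#' Draws `B` values with replacement (default 10000), enlarging the pooled
#' sample into the empirical distribution that observed ANI values are
#' projected onto.
#'
#' @param values Non-empty numeric vector.
#' @param B Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `B`.
#' @export
bootstrap_sample <- function(values, B = 10000L, seed = NULL) {
  if (length(values) == 0) rlang::abort("cannot bootstrap an empty vector")
  stopifnot(B >= 1)
  # index sampling: safe for length-1 sources (sample() would misread them)
  with_seed_opt(seed, values[sample.int(length(values), B, replace = TRUE)])
}

#' One-way ANOVA for strain-level variation
#'
#' Tests whether mean same-strain ANI differs between the strains pooled
#' into a species null. A significant result indicates that strain-level
#' genetic diversity is represented within the pooled distribution; it is
#' reported as evidence, never used as a gate.
#'
#' @param x A `pooled_null` or a data frame with columns `strain`, `ani`.
#' @return A `strain_anova` object: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`.
#' @export
strain_anova <- function(x) {
  df <- if (inherits(x, "pooled_null")) x$values else tibble::as_tibble(x)
  stopifnot(all(c("strain", "ani") %in% names(df)))
  counts <- table(df$strain)
  if (length(counts) < 2) {
    rlang::abort("strain ANOVA needs >= 2 strains in the pool")
  }
  if (any(counts < 2)) {
    rlang::abort("strain ANOVA needs >= 2 ANI values per strain")
  }
  if (sd(df$ani) == 0) {
    rlang::abort("strain ANOVA undefined: zero total variance in the pool")
  }
  fit <- aov(ani ~ strain, data = transform(df, strain = factor(strain)))
  tab <- summary(fit)[[1]]
  structure(
    list(f_statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
         df_between = tab[["Df"]][1], df_within = tab[["Df"]][2]),
    class = "strain_anova"
  )
}

#' @export
print.strain_anova <- function(x, ...) {
  cat(sprintf("<strain_anova> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Gaussian kernel density estimate of a null distribution
#'
#' Fits a Gaussian KDE with Silverman's rule-of-thumb bandwidth (unless
#' overridden), evaluated exactly (no FFT binning) on a 2048-point grid
#' extending six bandwidths beyond the data range, so the density
#' integrates to 1 within 1e-6. The KDE visualises the null distribution;
#' empirical P-values come from the ECDF, not from density integration.
#'
#' @param values Numeric vector with at least 2 distinct values (unless a
#'   numeric `bandwidth` is supplied).
#' @param bandwidth Optional numeric bandwidth override.
#' @return A `kde_model`: fields `x`, `y` (grid and density), `bw`, `n`.
#' @export
fit_kde <- function(values, bandwidth = NULL) {
  if (length(unique(values)) < 2 && is.null(bandwidth)) {
    rlang::abort(paste0(
      "KDE needs >= 2 distinct values; supply a numeric `bandwidth` to force ",
      "a fit on degenerate data"
    ))
  }
  bw <- bandwidth %||% stats::bw.nrd0(values)
  if (!(is.numeric(bw) && bw > 0)) rlang::abort("bandwidth must be positive")
  x <- seq(min(values) - 6 * bw, max(values) + 6 * bw, length.out = 2048L)
  y <- numeric(length(x))
  for (chunk in split(values, ceiling(seq_along(values) / 1000))) {
    y <- y + rowSums(outer(x, chunk, function(a, b) stats::dnorm(a, b, bw)))
  }
  y <- y / length(values)
  structure(list(x = x, y = y, bw = bw, n = length(values)),
            class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  cat(sprintf("<kde_model> Gaussian KDE of %d values, bandwidth %.4g\n",
              x$n, x$bw))
  invisible(x)
}

#' Evaluate a fitted KDE
#'
#' @param model A `kde_model`.
#' @param x Points at which to evaluate the density (0 outside the grid).
#' @return Numeric vector of density values.
#' @export
kde_density <- function(model, x) {
  stopifnot(inherits(model, "kde_model"))
  out <- stats::approx(model$x, model$y, xout = x, yleft = 0, yright = 0)$y
  out
}

#' Left-tail empirical P-value
#'
#' The empirical probability that a null value is at or below the observed
#' ANI: `P = #\{null <= observed\} / n`. Small ANI (left-tail outlier) gives
#' a small P; an observed value at or above the null maximum gives 1. This
#' is the plain ECDF, the one-sided test of the null hypothesis that the
#' two compared assemblies are the same strain.
#'
#' @param null_values Non-empty numeric vector (typically the bootstrap
#'   sample of a `pooled_null`), or a `pooled_null` object.
#' @param observed Numeric vector of observed ANI values.
#' @return Numeric vector of P-values in \[0, 1\], one per observation.
#' @export
empirical_p <- function(null_values, observed) {
  if (inherits(null_values, "pooled_null")) {
    null_values <- null_values$bootstrap %||% null_values$values$ani
  }
  if (length(null_values) == 0) rlang::abort("empty null sample")
  s <- sort(null_values)
  findInterval(observed, s) / length(s)
}

#' Classify a genome pair from its empirical P-value
#'
#' Three-way call: `P < p_low` is `different`, `P >= p_high` is
#' `identical`, anything between is `related`. Ties follow the operational
#' thresholds: exactly `p_high` (default 0.95) is identical; exactly
#' `p_low` (default 0.05) is related.
#'
#' @param p Numeric vector of empirical P-values.
#' @param p_low,p_high Classification thresholds, `0 <= p_low < p_high <= 1`.
#' @return Character vector over `c("different", "related", "identical")`.
#' @export
classify_pair <- function(p, p_low = 0.05, p_high = 0.95) {
  if (!(p_low >= 0 && p_low < p_high && p_high <= 1)) {
    rlang::abort("need 0 <= p_low < p_high <= 1")
  }
  dplyr::case_when(
    p < p_low ~ "different",
    p >= p_high ~ "identical",
    TRUE ~ "related"
  )
}

#' Build a complete species null distribution
#'
#' Pool, bootstrap, KDE, and strain-level ANOVA in one step. The ANOVA is
#' skipped (with a message) when the pool has fewer than two strains with
#' two values each; a message is also emitted when the ANOVA is not
#' significant at 0.05, since the pool may then under-represent strain
#' diversity.
#'
#' @inheritParams pool_ani
#' @param B Bootstrap draws (default 10000).
#' @param seed Optional integer seed for the bootstrap.
#' @param bandwidth Optional KDE bandwidth override.
#' @return A `pooled_null` with `bootstrap`, `kde`, and (when defined)
#'   `anova` filled in.
#' @export
build_null <- function(values, species = "species", B = 10000L, seed = NULL,
                       bandwidth = NULL) {
  pool <- pool_ani(values, species)
  pool$bootstrap <- bootstrap_sample(pool$values$ani, B, seed)
  pool$kde <- tryCatch(fit_kde(pool$values$ani, bandwidth),
                       error = function(e) NULL)
  pool$anova <- tryCatch(strain_anova(pool), error = function(e) {
    rlang::inform(paste0("strain ANOVA undefined for ", species, ": ",
                         conditionMessage(e)))
    NULL
  })
  if (!is.null(pool$anova) && pool$anova$p_value >= 0.05) {
    rlang::inform(sprintf(
      "strain ANOVA for %s not significant (p = %.3f): the pool may under-represent strain diversity",
      species, pool$anova$p_value
    ))
  }
  pool
}
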