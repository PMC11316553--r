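test_that("pool_ani concatenates per-strain values and keeps labels", {
  df <- tibble::tibble(
    strain = rep(paste0("s", 1:4), each = 25),
    ani = 99.9 + rep(1:4, each = 25) * 0.001 + rep(seq(0, 0.0024, 1e-4), 4)
  )
  pool <- pool_ani(df, species = "L. crispatus")
  expect_s3_class(pool, "pooled_null")
  expect_equal(nrow(pool$values), 100L)
  # grouping the pool by label recovers the input lists
  back <- split(pool$values$ani, pool$values$strain)
  expect_equal(back, split(df$ani, df$strain))

  single <- pool_ani(tibble::tibble(strain = "s1", ani = 99.9))
  expect_equal(nrow(single$values), 1L)
  expect_error(pool_ani(tibble::tibble(strain = character(), ani = numeric())),
               "empty")
  expect_error(pool_ani(tibble::tibble(strain = "s", ani = 101)), "\\(0, 100\\]")
})

test_that("bootstrap_sample: degenerate source, CLT bound, determinism", {
  expect_equal(bootstrap_sample(99.98, B = 10000, seed = 1),
               rep(99.98, 10000))
  set.seed(2)
  vals <- rnorm(40, 99.9, 0.02)
  for (s in 1:50) {
    bs <- bootstrap_sample(vals, B = 10000, seed = s)
    expect_lte(abs(mean(bs) - mean(vals)), 4 * sd(vals) / sqrt(10000))
  }
  expect_identical(bootstrap_sample(vals, 100, seed = 9),
                   bootstrap_sample(vals, 100, seed = 9))
  expect_error(bootstrap_sample(numeric(), 10), "empty")
})

test_that("strain ANOVA matches hand-computed sums of squares", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5, MSW = 1, F = 1.5 on (1, 4) df
  df <- tibble::tibble(strain = rep(c("g1", "g2"), each = 3),
                       ani = c(1, 2, 3, 2, 3, 4))
  a <- strain_anova(df)
  expect_equal(a$f_statistic, 1.5, tolerance = 1e-10)
  expect_equal(a$p_value, stats::pf(1.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)

  # shift invariance: adding a constant leaves F unchanged
  shifted <- strain_anova(dplyr::mutate(df, ani = ani + 42))
  expect_equal(shifted$f_statistic, a$f_statistic, tolerance = 1e-10)

  expect_error(strain_anova(tibble::tibble(strain = "g1", ani = c(1, 2))),
               ">= 2 strains")
  expect_error(strain_anova(tibble::tibble(strain = rep(c("a", "b"), each = 2),
                                           ani = rep(5, 4))),
               "zero total variance")
})

test_that("Gaussian KDE integrates to 1 and behaves like a smoother", {
  set.seed(3)
  vals <- rnorm(60, 99.9, 0.02)
  kde <- fit_kde(vals)
  integral <- sum(diff(kde$x) * (kde$y[-1] + kde$y[-length(kde$y)]) / 2)
  expect_lt(abs(integral - 1), 1e-6)
  # unimodal at scale: density at the mean beats density far out
  expect_gt(kde_density(kde, mean(vals)),
            kde_density(kde, mean(vals) + 10 * sd(vals)))
  # doubling the bandwidth lowers the peak
  kde2 <- fit_kde(vals, bandwidth = 2 * kde$bw)
  expect_lt(max(kde2$y), max(kde$y))
  expect_error(fit_kde(rep(1, 5)), "distinct")
  expect_s3_class(fit_kde(rep(1, 5), bandwidth = 0.1), "kde_model")
})

test_that("empirical_p is the left-tail ECDF (brute-force oracle)", {
  set.seed(4)
  for (i in 1:20) {
    null <- rnorm(50 * i)
    obs <- c(rnorm(20), null[1:3], min(null) - 1, max(null) + 1)
    expect_equal(empirical_p(null, obs), oracle_ecdf_p(null, obs))
  }
  # boundary behaviour
  null <- rnorm(100)
  expect_equal(empirical_p(null, max(null)), 1)
  expect_equal(empirical_p(null, min(null) - 1e-9), 0)
  # equally spaced null: the 50th order statistic has P = 0.50
  grid <- seq(99, 100, length.out = 100)
  expect_equal(empirical_p(grid, sort(grid)[50]), 0.50)
  # monotone in the observed value
  p <- empirical_p(null, seq(-3, 3, length.out = 200))
  expect_true(all(diff(p) >= 0))
})

test_that("classify_pair applies the thresholds with the stated tie rules", {
  expect_equal(classify_pair(0.002), "different")
  expect_equal(classify_pair(1.0), "identical")
  expect_equal(classify_pair(0.5), "related")
  # ties: exactly p_high is identical; exactly p_low is related
  expect_equal(classify_pair(0.95), "identical")
  expect_equal(classify_pair(0.05), "related")
  expect_equal(classify_pair(c(0.01, 0.5, 0.99)),
               c("different", "related", "identical"))
  expect_error(classify_pair(0.5, p_low = 0.9, p_high = 0.1), "p_low")
})

test_that("build_null fills bootstrap, KDE and ANOVA, and is seed-stable", {
  set.seed(6)
  df <- tibble::tibble(strain = rep(paste0("s", 1:3), each = 20),
                       ani = 99.9 + rnorm(60, 0, 0.01))
  nul <- suppressMessages(build_null(df, "sp", B = 5000, seed = 7))
  expect_equal(length(nul$bootstrap), 5000L)
  expect_true(all(nul$bootstrap %in% df$ani))
  expect_s3_class(nul$kde, "kde_model")
  expect_s3_class(nul$anova, "strain_anova")
  nul2 <- suppressMessages(build_null(df, "sp", B = 5000, seed = 7))
  expect_identical(nul$bootstrap, nul2$bootstrap)
  # single-strain pool: ANOVA undefined but flagged, null still built
  expect_message(
    one <- build_null(tibble::tibble(strain = "s1", ani = df$ani), "sp",
                      B = 100, seed = 1),
    "undefined"
  )
  expect_null(one$anova)
})

test_that("empirical P from the bootstrap tracks the pooled ECDF at large B", {
  set.seed(8)
  vals <- rnorm(200, 99.9, 0.02)
  obs <- seq(99.85, 99.95, length.out = 21)
  for (s in 1:5) {
    bs <- bootstrap_sample(vals, B = 10000, seed = s)
    expect_lt(max(abs(empirical_p(bs, obs) - empirical_p(vals, obs))), 0.02)
  }
})

test_that("tidy/glance/autoplot work on fitted objects", {
  set.seed(9)
  df <- tibble::tibble(strain = rep(c("a", "b"), each = 15),
                       ani = 99.9 + rnorm(30, 0, 0.01))
  nul <- suppressMessages(build_null(df, "sp", B = 1000, seed = 1))
  td <- tidy(nul)
  expect_equal(nrow(td), 30L)
  expect_equal(td$species[1], "sp")
  gl <- glance(nul)
  expect_equal(gl$n_strains, 2L)
  expect_equal(gl$bootstrap_B, 1000L)
  ta <- tidy(nul$anova)
  expect_equal(ta$statistic, nul$anova$f_statistic)
  p <- autoplot(nul, observed = c(pair1 = 99.88))
  expect_s3_class(p, "ggplot")
})
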