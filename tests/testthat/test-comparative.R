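test_that("the trait vector of the one-stage model matches closed forms end to end", {
  tv <- compute_traits(one_stage(s = 0.5, lambda = 1))
  expect_identical(names(tv), c("model_id", "species", "kingdom", trait_columns()))
  expect_equal(tv$lro_mean, 2)
  expect_equal(tv$lro_var, 4)
  expect_equal(tv$lro_ofs, 1)
  expect_equal(tv$lng_mean, 2)
  expect_equal(tv$lng_sd, sqrt(2))
  expect_equal(tv$lng_cv, sqrt(2) / 2)
  expect_equal(tv$gt_mean, 1)
  expect_equal(tv$parity, sqrt(2))
  expect_equal(tv$am_mean, 0)
  expect_true(is.na(tv$am_cv))

  sem <- compute_traits(semelparous())
  expect_identical(sem$parity, 0)
  expect_equal(sem$am_sd, 0)
})

test_that("batch trait computation leaves no silent missing values", {
  models <- generate_ensemble("plant_like", 25, seed = 61)
  tb <- compute_trait_table(models)
  expect_identical(nrow(tb), 25L)
  log <- attr(tb, "trait_log")
  outcome_cols <- as.matrix(tb[trait_columns()])
  n_missing <- sum(is.na(outcome_cols))
  # every NA cell has at least one logged reason for that model
  if (n_missing > 0) {
    missing_models <- tb$model_id[rowSums(is.na(outcome_cols)) > 0]
    expect_true(all(missing_models %in% log$model_id))
  } else {
    succeed()
  }
})

test_that("quantile summaries match hand-computed order statistics", {
  tb <- tibble::tibble(x = 1:100)
  qs <- quantile_summary(tb, "x")
  expect_equal(qs$q50, 50.5)
  expect_equal(qs$q25, 25.75)
  expect_equal(qs$q75, 75.25)

  const <- quantile_summary(tibble::tibble(x = rep(3, 10)), "x")
  expect_true(all(unlist(const[paste0("q", c(2.5, 25, 50, 75, 97.5))]) == 3))
  expect_error(quantile_summary(tibble::tibble(x = 1:3), "x"),
               class = "stochlife_validation_error")
  # median invariant under row reordering
  shuffled <- tb[sample(100), , drop = FALSE]
  expect_equal(quantile_summary(shuffled, "x")$q50, 50.5)
})

test_that("trimmed histograms drop exactly the tail quantiles", {
  h0 <- trimmed_histogram(1:100, trim_fraction = 0)
  expect_identical(attr(h0, "n_trimmed"), 0L)
  expect_identical(sum(h0$count), 100L)

  h <- trimmed_histogram(1:100, trim_fraction = 0.2)
  expect_identical(sum(h$count), 80L)
  expect_identical(attr(h, "n_trimmed"), 20L)

  withr::with_seed(601, {
    heavy <- exp(rnorm(2000, 0, 3))
    ht <- trimmed_histogram(heavy, trim_fraction = 0.2)
    trimmed_range <- max(ht$bin_right) - min(ht$bin_left)
    expect_lt(trimmed_range * 10, max(heavy) - min(heavy))
  })
  p <- autoplot(trimmed_histogram(1:100, 0.2))
  expect_s3_class(p, "ggplot")
})

test_that("log-transform policy logs 12 columns for plants, 11 for animals", {
  tb <- compute_trait_table(list(one_stage(0.5, 1), one_stage(0.6, 2),
                                 one_stage(0.7, 1.5)))
  tb$model_id <- sprintf("m%d", 1:3)
  tb$am_mean <- c(1, 2, 3)   # make every loggable column positive
  tb$am_cv <- 0.5

  plants <- log_transform_policy(tb, "plant")
  pol_p <- attr(plants, "log_policy")
  expect_length(pol_p$logged, 12)
  expect_setequal(pol_p$excluded, c("lng_skew", "lng_kurt", "am_sd", "am_cv"))

  animals <- log_transform_policy(tb, "animal")
  pol_a <- attr(animals, "log_policy")
  expect_length(pol_a$logged, 11)
  expect_true("lro_kurt" %in% pol_a$excluded)

  # logged columns are transformed, excluded ones untouched
  expect_equal(plants$lro_mean, log(tb$lro_mean))
  expect_equal(plants$am_cv, tb$am_cv)

  ones <- tb; ones$lro_mean <- 1
  expect_equal(log_transform_policy(ones, "plant")$lro_mean, c(0, 0, 0))

  bad <- tb; bad$lro_mean[2] <- 0
  expect_error(log_transform_policy(bad, "plant"), "m2",
               class = "stochlife_validation_error")
})

test_that("pearson correlations behave on exact and degenerate input", {
  withr::with_seed(602, {
    tb <- generate_planted_traits(50, seed = 62)
    cc <- pearson_correlations(tb)
    expect_equal(unname(diag(cc)), rep(1, 16))
    expect_equal(cc, t(cc))
  })
  tb2 <- tibble::tibble(lro_mean = c(1, 2, 3, 4), lro_var = 2 * c(1, 2, 3, 4) + 1,
                        lng_mean = rep(1, 4))
  expect_warning(cc2 <- pearson_correlations(tb2), "zero-variance")
  expect_equal(cc2["lro_mean", "lro_var"], 1)
  expect_true(is.na(cc2["lng_mean", "lro_mean"]))
})

test_that("PCA of white noise spreads variance evenly across components", {
  withr::with_seed(603, {
    tb <- tibble::as_tibble(as.data.frame(matrix(rnorm(4000 * 16), 4000)))
    names(tb) <- trait_columns()
    pca <- run_pca(tb)
    expect_true(all(pca$explained_fraction > 0.04 &
                    pca$explained_fraction < 0.09))
    expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-10)
    expect_equal(sum(pca$eigenvalues), 16, tolerance = 1e-8)
    expect_equal(crossprod(pca$loadings), diag(16), tolerance = 1e-10,
                 ignore_attr = TRUE)
  })
})

test_that("PCA recovers a rank-1 block and planted factor structure", {
  withr::with_seed(604, {
    # two perfectly correlated variables: their block is one component
    tb <- tibble::as_tibble(as.data.frame(matrix(rnorm(500 * 16), 500)))
    names(tb) <- trait_columns()
    tb$lro_var <- 2 * tb$lro_mean + 1
    pca <- run_pca(tb)
    lead <- pca$loadings[, 1]
    expect_equal(unname(abs(lead["lro_mean"])), unname(abs(lead["lro_var"])),
                 tolerance = 1e-8)

    planted <- generate_planted_traits(300, seed = 64)
    rec <- run_pca(planted)
    L <- attr(planted, "planted_loadings")
    congr <- factor_congruence(rec$loadings[, 1:3], L, match_columns = TRUE)
    expect_true(all(congr > 0.9))
  })
  expect_error(run_pca(generate_planted_traits(10, seed = 1)),
               "more complete rows", class = "stochlife_validation_error")
})

test_that("PCA drops constant outcomes instead of failing on them", {
  tb <- generate_planted_traits(60, seed = 66)
  tb$am_sd <- 0                       # deterministic maturity across the set
  expect_warning(pca <- run_pca(tb), "zero-variance")
  expect_identical(pca$dropped_outcomes, "am_sd")
  expect_identical(nrow(pca$loadings), 15L)
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-10)
})

test_that("tidy, glance and autoplot expose PCA results in broom style", {
  planted <- generate_planted_traits(100, seed = 65)
  pca <- run_pca(planted)
  td <- tidy(pca)
  expect_identical(nrow(td), 16L * 16L)
  expect_named(td, c("outcome", "component", "loading"))
  gl <- glance(pca)
  expect_equal(gl$cumulative[16], 1, tolerance = 1e-10)
  expect_s3_class(autoplot(pca), "ggplot")
})

test_that("variance decomposition follows the equal-weight mixture convention", {
  d <- variance_decomposition(data.frame(mean = c(0, 2), variance = c(1, 3)))
  expect_equal(d$v_within, 2)
  expect_equal(d$v_between, 1)
  expect_equal(d$k_icc, 1 / 3)

  same <- variance_decomposition(data.frame(mean = rep(5, 4), variance = rep(2, 4)))
  expect_equal(same$v_between, 0)
  expect_equal(same$k_icc, 0)

  points <- variance_decomposition(data.frame(mean = c(1, 2, 5), variance = 0))
  expect_equal(points$k_icc, 1)

  expect_error(variance_decomposition(data.frame(mean = 1, variance = 1)),
               class = "stochlife_validation_error")
})
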