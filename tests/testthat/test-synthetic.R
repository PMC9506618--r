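test_that("Leslie construction places survival and fertility where they belong", {
  m <- generate_leslie(survival = c(0.8, 0), fertility = c(0, 3))
  expect_equal(unname(m$U), matrix(c(0, 0.8, 0, 0), 2))
  expect_equal(unname(m$F[1, ]), c(0, 3))

  stasis <- generate_leslie(survival = c(0.5, 0.9), fertility = c(0, 1),
                            terminal_fate = "terminal_stasis")
  expect_equal(unname(stasis$U[2, 2]), 0.9)

  # deterministic lifetime when survival is certain until terminal death
  det <- generate_leslie(survival = c(1, 1, 0), fertility = c(0, 0, 2))
  lm <- longevity_moments(det$U)
  expect_equal(lm$mean, 3)
  expect_equal(lm$sd, 0)

  withr::with_seed(701, {
    for (i in 1:50) {
      n <- sample(2:10, 1)
      m <- generate_leslie(runif(n), runif(n, 0, 4))
      expect_true(all(colSums(m$U) <= 1 + 1e-12))
    }
  })
})

test_that("stage-model construction handles stasis, growth, retrogression, seedlings", {
  m <- generate_stage_model(stasis = rep(0.3, 5), growth = rep(0.4, 5),
                            retrogression = rep(0.05, 5),
                            fertility = c(0, 0, 0, 5, 10),
                            seedling_mortality = 0.95)
  expect_equal(sum(m$U[, 1]), 0.05)
  expect_equal(unname(diag(m$U)[2:5]), rep(0.3, 4))
  expect_error(generate_stage_model(rep(0.6, 4), rep(0.5, 4), rep(0, 4),
                                    rep(1, 4)),
               class = "stochlife_validation_error")

  # no stasis, no retrogression reduces to a Leslie-like chain
  chainlike <- generate_stage_model(rep(0, 4), rep(0.7, 4), rep(0, 4),
                                    c(0, 0, 0, 2))
  expect_equal(unname(chainlike$U[cbind(2:4, 1:3)]), rep(0.7, 3))
  expect_equal(sum(chainlike$U) - sum(chainlike$U[cbind(2:4, 1:3)]), 0)
})

test_that("plant-like life cycles carry more LRO opportunity for selection than animal-like", {
  plant <- generate_ensemble("plant_like", 8, seed = 71)
  animal <- generate_ensemble("animal_like", 8, seed = 72)
  ofs_p <- median(vapply(plant, function(m) lro_stats(m)$ofs, numeric(1)))
  ofs_a <- median(vapply(animal, function(m) lro_stats(m)$ofs, numeric(1)))
  expect_gt(ofs_p, ofs_a)
})

test_that("ensembles are deterministic in the seed and respect dimension ranges", {
  e1 <- generate_ensemble("animal_like", 10, seed = 73)
  e2 <- generate_ensemble("animal_like", 10, seed = 73)
  expect_identical(e1, e2)
  dims_a <- vapply(e1, function(m) length(m$stage_names), integer(1))
  expect_true(all(dims_a >= 5 & dims_a <= 69))
  dims_p <- vapply(generate_ensemble("plant_like", 10, seed = 74),
                   function(m) length(m$stage_names), integer(1))
  expect_true(all(dims_p >= 5 & dims_p <= 26))
  expect_error(generate_ensemble("plant_like", 0), class = "stochlife_validation_error")

  # zero between-population spread collapses to identical copies
  null_ens <- generate_ensemble("plant_like", 5, between_sd = 0, seed = 75)
  for (i in 2:5) expect_equal(null_ens[[i]]$U, null_ens[[1]]$U)
})

test_that("cohorts are deterministic and internally consistent", {
  m <- one_stage(0.6, 1.5)
  c1 <- simulate_cohort(m, 500, seed = 76)
  c2 <- simulate_cohort(m, 500, seed = 76)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  rec <- simulate_cohort(m, 300, seed = 77, record_offspring = TRUE)
  ev <- attr(rec, "offspring_events")
  per_id <- tapply(ev$count, factor(ev$id, levels = rec$id), sum)
  per_id[is.na(per_id)] <- 0
  expect_equal(as.vector(per_id), rec$lro)
  expect_true(all(rec$longevity >= 1))
  ok <- is.na(rec$maturity_age) | rec$maturity_age <= rec$longevity
  expect_true(all(ok))
})

test_that("degenerate cohorts are exact: instant death, fixed offspring ages", {
  m0 <- mpm(matrix(0), matrix(0))
  c0 <- simulate_cohort(m0, 100, seed = 78)
  expect_true(all(c0$longevity == 1))
  expect_true(all(c0$lro == 0))

  sem <- semelparous(p = 1, f = 2)
  cs <- simulate_cohort(sem, 400, seed = 79, record_offspring = TRUE)
  ev <- attr(cs, "offspring_events")
  expect_true(all(ev$age == 1))
  expect_true(all(cs$maturity_age == 1))
})

test_that("the oracle detects a deliberately broken reward convention", {
  # high mortality and high fertility make the dying-step reward visible
  m <- one_stage(s = 0.3, lambda = 5)
  good <- oracle_compare(m, n = 2e4, seed = 80)
  expect_true(all(good$pass))

  broken <- simulate_cohort(m, 2e4, seed = 80, reward_on_death = FALSE)
  an <- lro_stats(m)
  z <- (an$mean - mean(broken$lro)) / (sd(broken$lro) / sqrt(2e4))
  expect_gt(abs(z), 4)
})

test_that("small cohorts flag low power instead of failing", {
  oc <- oracle_compare(one_stage(), n = 100, seed = 81)
  expect_true(attr(oc, "low_power"))
  expect_s3_class(oc, "tbl_df")
})
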