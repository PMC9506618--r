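test_that("one-stage offspring-age moments match scalar series closed forms", {
  s <- 0.5
  tm <- offspring_age_moments(matrix(s), matrix(1))
  expect_equal(tm$gt_mean, s / (1 - s), tolerance = 1e-12)
  expect_equal(tm$gt_sd, sqrt(2), tolerance = 1e-12)
  expect_equal(tm$parity_cv, sqrt(2), tolerance = 1e-12)

  # direct summation oracle at another survival
  s <- 0.8
  t <- 0:20000
  w <- s^t                         # expected offspring at age t, up to lambda
  m1 <- sum(t * w) / sum(w); m2 <- sum(t^2 * w) / sum(w)
  tm2 <- offspring_age_moments(matrix(s), matrix(2.5))
  expect_equal(tm2$gt_mean, m1, tolerance = 1e-10)
  expect_equal(tm2$gt_sd, sqrt(m2 - m1^2), tolerance = 1e-10)
})

test_that("strict fixed-age semelparity has parity CV exactly zero", {
  sem <- semelparous()
  tm <- offspring_age_moments(sem$U, sem$F)
  expect_identical(tm$parity_cv, 0)
  expect_equal(tm$gt_mean, 1)
  expect_equal(tm$gt_sd, 0)
})

test_that("timing is invariant under fertility scaling and shifts with age origin", {
  withr::with_seed(401, {
    m <- random_model(5)
    a <- offspring_age_moments(m$U, m$F)
    b <- offspring_age_moments(m$U, 7.3 * m$F)
    expect_equal(a$gt_mean, b$gt_mean, tolerance = 1e-12)
    expect_equal(a$gt_sd, b$gt_sd, tolerance = 1e-12)
    expect_equal(a$parity_cv, b$parity_cv, tolerance = 1e-12)

    shifted <- offspring_age_moments(m$U, m$F, age_origin = "one")
    expect_equal(shifted$gt_mean, a$gt_mean + 1, tolerance = 1e-12)
    expect_equal(shifted$gt_sd, a$gt_sd, tolerance = 1e-12)
  })
})

test_that("no reachable reproduction is an error, not a zero", {
  U <- matrix(c(0.5, 0, 0, 0.5), 2)       # stage 1 never reaches stage 2
  F_mat <- matrix(c(0, 0, 2, 0), 2)       # only stage 2 reproduces
  expect_error(offspring_age_moments(U, F_mat, start_stage = 1),
               "no reproduction reachable",
               class = "stochlife_validation_error")
})

test_that("reproductive stage set uses strict positivity", {
  F_mat <- matrix(0, 3, 3)
  F_mat[1, 3] <- 2
  expect_identical(reproductive_stage_set(F_mat), 3L)
  expect_identical(reproductive_stage_set(matrix(1, 2, 2)), 1:2)
  F_mat[1, 3] <- 0
  expect_error(reproductive_stage_set(F_mat),
               class = "stochlife_validation_error")
})

test_that("age at maturity conditions on reaching the reproductive set", {
  am <- age_at_maturity(semelparous(p = 0.8)$U, semelparous(p = 0.8)$F)
  expect_equal(am$am_mean, 1)
  expect_equal(am$am_sd, 0)
  expect_equal(am$p_reach, 0.8)

  # starting in a reproductive stage
  am0 <- age_at_maturity(matrix(0.5), matrix(1))
  expect_equal(am0$am_mean, 0)
  expect_equal(am0$am_sd, 0)
  expect_true(is.na(am0$am_cv))
  expect_equal(am0$p_reach, 1)

  # 5-stage age-classified, first reproduction at class 3, no early mortality:
  # exactly 2 steps to maturity
  m <- generate_leslie(survival = c(1, 1, 0.8, 0.7, 0),
                       fertility = c(0, 0, 1, 1, 1))
  am5 <- age_at_maturity(m$U, m$F)
  expect_equal(am5$am_mean, 2, tolerance = 1e-12)
  expect_equal(am5$am_sd, 0, tolerance = 1e-6)
  expect_equal(am5$p_reach, 1, tolerance = 1e-12)
})

test_that("maturity unreachable from the start is an error", {
  U <- matrix(c(0.5, 0, 0, 0.5), 2)
  F_mat <- matrix(c(0, 0, 2, 0), 2)
  expect_error(age_at_maturity(U, F_mat, start_stage = 1),
               "maturity unreachable", class = "stochlife_validation_error")
})

test_that("the conditioned maturity chain is stochastic once its absorption row is added", {
  withr::with_seed(403, {
    for (i in 1:10) {
      n <- sample(5:8, 1)
      surv <- runif(n, 0.3, 0.9)
      fert <- c(rep(0, 3), runif(n - 3, 0.5, 2))
      m <- generate_leslie(surv, fert)
      cond <- stochlife:::.conditional_maturity_chain(m$U, m$F, 1L)
      expect_true(all(is.finite(cond$Uc)))
      expect_true(all(colSums(cond$Uc) <= 1 + 1e-12))
      # absorption into the reproductive set (a_j / b_j) completes each
      # conditioned column to exactly 1
      repro <- reproductive_stage_set(m$F)
      pre <- setdiff(seq_len(n), repro)
      Upre <- m$U[pre, pre, drop = FALSE]
      a <- colSums(m$U[repro, pre, drop = FALSE])
      b <- drop(crossprod(solve(diag(length(pre)) - Upre), a))
      expect_true(all(b > 0))   # Leslie fixture: maturity reachable everywhere
      expect_equal(unname(colSums(cond$Uc) + a / b), rep(1, length(pre)),
                   tolerance = 1e-12)
    }
  })
})

test_that("age at maturity precedes mean offspring age on age-classified models", {
  withr::with_seed(402, {
    for (i in 1:10) {
      n <- sample(5:9, 1)
      mat_age <- sample(2:(n - 1), 1)
      surv <- runif(n, 0.4, 0.95)
      fert <- ifelse(seq_len(n) >= mat_age, runif(n, 0.5, 3), 0)
      m <- generate_leslie(surv, fert)
      am <- age_at_maturity(m$U, m$F)
      gt <- offspring_age_moments(m$U, m$F)
      expect_lte(am$am_mean, gt$gt_mean + 1e-9)
    }
  })
})
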