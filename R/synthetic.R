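#' Build an age-classified (Leslie) model
#'
#' Survival probabilities sit on the subdiagonal of `U` and fertilities in
#' the first row of `F`. After the final age class an individual either dies
#' (`terminal_fate = "death"`) or remains in the final class with its
#' survival probability (`"terminal_stasis"`).
#'
#' @param survival Per-age survival probabilities (length = number of ages;
#'   the last entry is used only under terminal stasis).
#' @param fertility Per-age mean offspring counts.
#' @param terminal_fate `"death"` or `"terminal_stasis"`.
#' @param ... Metadata passed to [mpm()] (`model_id`, `species`, `kingdom`,
#'   `flags`, ...).
#' @return An [mpm] object.
#' @export
#' @examples
#' # 2-stage semelparous fixture: mature with probability 0.8, then one
#' # burst of reproduction at age 1
#' generate_leslie(survival = c(0.8, 0), fertility = c(0, 3))
generate_leslie <- function(survival, fertility,
                            terminal_fate = c("death", "terminal_stasis"),
                            ...) {
  terminal_fate <- match.arg(terminal_fate)
  n <- length(survival)
  stopifnot(n >= 2, length(fertility) == n,
            all(survival >= 0), all(survival <= 1), all(fertility >= 0))
  U <- matrix(0, n, n)
  U[cbind(2:n, 1:(n - 1))] <- survival[-n]
  if (terminal_fate == "terminal_stasis") U[n, n] <- survival[n]
  F_mat <- matrix(0, n, n)
  F_mat[1, ] <- fertility
  mpm(U, F_mat, ...)
}

#' Build a stage-classified model
#'
#' Stage-structured life cycle with stasis (diagonal), growth (subdiagonal)
#' and retrogression / shrinkage (superdiagonal) -- the anatomy typical of
#' size-classified plant models. Reproduction feeds stage 1. An optional
#' seedling-mortality parameter overrides the first column so that its
#' survival is `1 - seedling_mortality`, emulating the extremely high
#' early-stage mortality common in plants.
#'
#' @param stasis,growth,retrogression Per-stage probability masses; `growth`
#'   applies to stages 1..(n-1), `retrogression` to stages 2..n (entries for
#'   the impossible moves are ignored). Column sums must not exceed 1.
#' @param fertility Per-stage mean offspring (into stage 1).
#' @param seedling_mortality Optional; rescales column 1 of `U` to sum to
#'   `1 - seedling_mortality`.
#' @param ... Metadata passed to [mpm()].
#' @return An [mpm] object.
#' @export
generate_stage_model <- function(stasis, growth, retrogression, fertility,
                                 seedling_mortality = NULL, ...) {
  n <- length(stasis)
  stopifnot(n >= 2, length(growth) == n, length(retrogression) == n,
            length(fertility) == n)
  U <- diag(stasis, n)
  U[cbind(2:n, 1:(n - 1))] <- growth[-n]
  U[cbind(1:(n - 1), 2:n)] <- retrogression[-1]
  cs <- colSums(U)
  if (any(cs > 1 + .col_sum_tol)) {
    abort(sprintf("stage masses in column %d sum to %.6g > 1",
                  which.max(cs), max(cs)),
          class = "stochlife_validation_error")
  }
  if (!is.null(seedling_mortality)) {
    stopifnot(seedling_mortality >= 0, seedling_mortality <= 1)
    if (cs[1] > 0) U[, 1] <- U[, 1] * (1 - seedling_mortality) / cs[1]
  }
  F_mat <- matrix(0, n, n)
  F_mat[1, ] <- fertility
  mpm(U, F_mat, ...)
}

# ensemble archetypes: the base life history around which populations vary ----

.animal_archetype <- function() {
  n <- min(69L, 5L + rnbinom(1, size = 3, mu = 7))
  maturity <- max(2L, round(n / 4))
  list(
    n = n, maturity = maturity,
    juv_survival = runif(1, 0.25, 0.6),
    adult_survival = runif(1, 0.6, 0.9),
    fertility = exp(runif(1, log(0.5), log(5))),
    R0 = exp(runif(1, log(0.5), log(3)))
  )
}

.plant_archetype <- function() {
  n <- min(26L, 5L + rpois(1, 2))
  list(
    n = n,
    seedling_mortality = runif(1, 0.3, 0.65),
    survival_lo = runif(1, 0.4, 0.65),    # young-stage survival
    survival_hi = runif(1, 0.84, 0.93),   # late-stage survival
    growth_frac = runif(1, 0.2, 0.45),    # share of survival spent growing
    retro_frac = runif(1, 0.02, 0.1),     # shrinkage share
    fertility = exp(runif(1, log(2), log(30))),
    R0 = exp(runif(1, log(0.5), log(3)))
  )
}

# populations persist near demographic replacement: fertilities are rescaled
# so the net reproductive rate R0 (mean LRO from stage 1) hits the target
.rescale_to_R0 <- function(model, target_R0) {
  r0 <- sum(colSums(model$F) * fundamental_matrix(model$U)[, 1])
  if (r0 > 0) model$F <- model$F * (target_R0 / r0)
  model
}

# between-population shifts are truncated at 2 sd: populations of one species
# differ in rates, not in orders of magnitude
.shift <- function(between_sd) {
  max(-2 * between_sd, min(2 * between_sd, rnorm(1, 0, between_sd)))
}

.animal_from_archetype <- function(arch, between_sd, id, species) {
  n <- max(5L, min(69L, round(arch$n * exp(.shift(between_sd / 2)))))
  maturity <- max(2L, min(n - 1L, round(arch$maturity * n / arch$n)))
  shift_s <- .shift(between_sd)
  surv <- stats::plogis(stats::qlogis(
    ifelse(seq_len(n) < maturity, arch$juv_survival, arch$adult_survival)
  ) + shift_s)
  fert <- ifelse(seq_len(n) >= maturity, arch$fertility, 0)
  m <- generate_leslie(surv, fert, terminal_fate = "death",
                       model_id = id, species = species, kingdom = "animal")
  .rescale_to_R0(m, arch$R0 * exp(.shift(between_sd)))
}

.plant_from_archetype <- function(arch, between_sd, id, species) {
  n <- max(5L, min(26L, round(arch$n * exp(.shift(between_sd / 2)))))
  shift_s <- .shift(between_sd)
  frac <- (seq_len(n) - 1) / (n - 1)
  surv <- stats::plogis(stats::qlogis(
    arch$survival_lo + (arch$survival_hi - arch$survival_lo) * frac
  ) + shift_s)
  growth <- surv * arch$growth_frac * c(rep(1, n - 1), 0)
  retro <- surv * arch$retro_frac * c(0, rep(1, n - 1))
  stasis <- surv - growth - retro
  repro <- seq_len(n) > ceiling(n / 2)
  fert <- ifelse(repro, arch$fertility * (0.25 + 0.75 * frac), 0)
  m <- generate_stage_model(stasis, growth, retro, fert,
                            seedling_mortality = arch$seedling_mortality,
                            model_id = id, species = species, kingdom = "plant")
  .rescale_to_R0(m, arch$R0 * exp(.shift(between_sd)))
}

#' Generate an ensemble of synthetic matrix population models
#'
#' Draws a base life-history archetype for the ensemble (an age-classified
#' animal-like or a stage-classified plant-like life cycle), then one model
#' per population with between-population variation: survival probabilities
#' shifted on the logit scale, fertilities on the log scale, and dimension
#' jittered, all with spread `between_sd`. Setting `between_sd = 0` collapses
#' the ensemble to identical copies of the archetype (the planted null for
#' the variance decomposition). Dimensions are kept inside 5-69 (animal-like)
#' and 5-26 (plant-like).
#'
#' @param kind `"animal_like"` or `"plant_like"`.
#' @param n_models Number of populations (at least 1).
#' @param between_sd Between-population spread (SD of the logit/log shifts);
#'   default 0.5.
#' @param seed Integer seed; fixed seed gives an identical ensemble.
#' @return A list of [mpm] objects.
#' @export
generate_ensemble <- function(kind = c("animal_like", "plant_like"),
                              n_models, between_sd = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  if (n_models < 1) {
    abort("n_models must be at least 1", class = "stochlife_validation_error")
  }
  stopifnot(between_sd >= 0)
  set.seed(seed)
  arch <- if (kind == "animal_like") .animal_archetype() else .plant_archetype()
  species <- sub("_like", "", kind)
  lapply(seq_len(n_models), function(i) {
    id <- sprintf("%s_%03d", species, i)
    if (kind == "animal_like") {
      .animal_from_archetype(arch, between_sd, id, paste0(species, "_sp"))
    } else {
      .plant_from_archetype(arch, between_sd, id, paste0(species, "_sp"))
    }
  })
}

#' Generate a trait table with planted factor structure
#'
#' Synthesizes `n` trait rows as `X = S L' + noise` for three planted,
#' orthogonal-by-construction life-history factors: a life-cycle-length
#' factor (longevity, generation time, age at maturity means and SDs), an
#' uncertainty factor (standardized variance, skewness and kurtosis of LRO
#' and longevity), and a reproductive-timing factor (parity and the
#' variability of age at maturity). Used to verify that PCA recovers known
#' structure; the planted loading matrix (columns normalized, ordered by
#' factor strength) is attached as attribute `"planted_loadings"`.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param factor_sd SDs of the three factor scores (decreasing, so PC order
#'   matches factor order).
#' @param noise_sd SD of the independent noise added to every column.
#' @return A trait-table tibble with attribute `"planted_loadings"` (16 x 3).
#' @export
generate_planted_traits <- function(n, seed = 1L,
                                    factor_sd = c(3, 1.8, 1.1),
                                    noise_sd = 0.3) {
  set.seed(seed)
  cols <- trait_columns()
  L <- matrix(0, 16, 3, dimnames = list(cols, paste0("f", 1:3)))
  L[c("lng_mean", "lng_sd", "gt_mean", "gt_sd", "am_mean"), 1] <- 1
  L[c("lro_ofs", "lro_skew", "lro_kurt", "lng_skew", "lng_kurt"), 2] <- 1
  L[c("parity", "am_sd", "am_cv", "lng_cv"), 3] <- 1
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  # factor scores whitened in-sample so the planted factors are exactly
  # uncorrelated (chance correlations between strong factors would otherwise
  # rotate the leading eigenvectors inside their shared subspace)
  S <- matrix(rnorm(n * 3), n, 3)
  S <- scale(S, center = TRUE, scale = FALSE)
  S <- S %*% backsolve(chol(stats::cov(S)), diag(3)) %*% diag(factor_sd)
  X <- S %*% t(L) + matrix(rnorm(n * 16, 0, noise_sd), n, 16)
  out <- as_tibble(as.data.frame(X))
  names(out) <- cols
  out <- dplyr::bind_cols(
    tibble(model_id = sprintf("planted_%04d", seq_len(n)),
           species = "synthetic", kingdom = "plant"),
    out
  )
  attr(out, "planted_loadings") <- L
  out
}

#' Simulate a cohort of individual life courses
#'
#' The brute-force oracle for every analytic moment in the package. Each of
#' `n` individuals starts in `start_stage` at age 0. At every time step an
#' individual in stage j first draws Poisson(lambda_j) offspring, recorded at
#' its current age (so reproduction happens on every step of life, including
#' the dying one), then draws its next state from column j of the absorbing
#' chain (transient stages plus death). Longevity counts the step of the
#' transition into death; age at maturity is the age at first entry into a
#' reproductive stage (0 when the start stage is reproductive, `NA` when
#' maturity is never reached). These conventions mirror
#' [longevity_moments()], [lro_moments()], [offspring_age_moments()] and
#' [age_at_maturity()] exactly.
#'
#' @param model An [mpm] object.
#' @param n Number of individuals.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param start_stage Starting stage (default 1).
#' @param record_offspring Also return the individual offspring-age records
#'   (long format) as attribute `"offspring_events"`; off by default because
#'   the per-individual age sums suffice for the timing oracle.
#' @param reward_on_death Grant the reproductive reward on the dying
#'   transition (the package convention). `FALSE` exists only to demonstrate
#'   that the oracle detects convention drift.
#' @return A tibble with one row per individual: `id`, `longevity`, `lro`,
#'   `maturity_age`, `off_age_sum` (sum of offspring ages), `off_age_sumsq`.
#'   Attributes: `rng_seed`, `n`.
#' @export
simulate_cohort <- function(model, n, seed = 1L, start_stage = 1L,
                            record_offspring = FALSE, reward_on_death = TRUE) {
  stopifnot(inherits(model, "mpm"), n >= 1)
  set.seed(seed)
  U <- model$U
  tau <- ncol(U)
  stopifnot(start_stage >= 1, start_stage <= tau)
  lam <- colSums(model$F)
  dead_state <- tau + 1L
  death <- pmax(1 - colSums(U), 0)
  cols <- lapply(seq_len(tau), function(j) c(U[, j], death[j]))
  repro <- which(lam > 0)

  state <- rep(as.integer(start_stage), n)
  alive <- seq_len(n)
  longevity <- integer(n)
  lro <- numeric(n)
  off_age_sum <- numeric(n)
  off_age_sumsq <- numeric(n)
  maturity <- rep(NA_integer_, n)
  if (start_stage %in% repro) maturity[] <- 0L
  events <- if (record_offspring) list() else NULL

  age <- 0L
  while (length(alive)) {
    st <- state[alive]
    k <- rpois(length(alive), lam[st])
    # transitions, grouped by current stage
    ns <- integer(length(alive))
    for (j in unique(st)) {
      idx <- which(st == j)
      ns[idx] <- sample.int(dead_state, length(idx), replace = TRUE,
                            prob = cols[[j]])
    }
    if (!reward_on_death) k[ns == dead_state] <- 0L
    has_off <- k > 0L
    if (any(has_off)) {
      ids <- alive[has_off]
      kk <- k[has_off]
      lro[ids] <- lro[ids] + kk
      off_age_sum[ids] <- off_age_sum[ids] + kk * age
      off_age_sumsq[ids] <- off_age_sumsq[ids] + kk * age^2
      if (record_offspring) {
        events[[length(events) + 1]] <- tibble(id = ids, age = age, count = kk)
      }
    }
    age <- age + 1L
    died <- ns == dead_state
    longevity[alive[died]] <- age
    matured <- !died & (ns %in% repro) & is.na(maturity[alive])
    maturity[alive[matured]] <- age
    state[alive] <- ns
    alive <- alive[!died]
  }

  out <- tibble(id = seq_len(n), longevity = longevity, lro = lro,
                maturity_age = maturity,
                off_age_sum = off_age_sum, off_age_sumsq = off_age_sumsq)
  attr(out, "rng_seed") <- seed
  attr(out, "n") <- n
  if (record_offspring) {
    attr(out, "offspring_events") <- if (length(events)) {
      dplyr::bind_rows(events)
    } else tibble(id = integer(), age = integer(), count = integer())
  }
  out
}

.sample_stats <- function(x) {
  n <- length(x)
  m1 <- mean(x)
  xc <- x - m1
  m2c <- mean(xc^2); m3c <- mean(xc^3); m4c <- mean(xc^4)
  list(n = n, mean = m1, var = m2c, sd = sqrt(m2c),
       skew = if (m2c > 0) m3c / m2c^1.5 else NA_real_,
       kurt = if (m2c > 0) m4c / m2c^2 - 3 else NA_real_)
}

# Exact sampling standard errors for the sample mean, variance, skewness and
# excess kurtosis of n iid draws from a distribution whose raw moments
# m[1..8] are known analytically. Skewness and kurtosis are smooth functions
# of the first four raw moments, whose joint sampling covariance is
# Cov(m_j, m_k) = (m_{j+k} - m_j m_k) / n; the delta method does the rest.
# Computing these from the model (not the sample) keeps the z-tests honest
# for heavy-tailed outcomes, where sample- or bootstrap-based SEs are biased
# low exactly when the statistic itself undershoots.
.moment_stat_ses <- function(m, n) {
  mu2 <- m[2] - m[1]^2
  mu4 <- m[4] - 4 * m[1] * m[3] + 6 * m[1]^2 * m[2] - 3 * m[1]^4
  mm <- c(1, m)
  S <- outer(1:4, 1:4, function(j, k) mm[j + k + 1] - mm[j + 1] * mm[k + 1]) / n
  skew_f <- function(v) {
    u2 <- v[2] - v[1]^2
    (v[3] - 3 * v[1] * v[2] + 2 * v[1]^3) / u2^1.5
  }
  kurt_f <- function(v) {
    u2 <- v[2] - v[1]^2
    (v[4] - 4 * v[1] * v[3] + 6 * v[1]^2 * v[2] - 3 * v[1]^4) / u2^2 - 3
  }
  se_delta <- function(fn) {
    g <- numeric(4)
    h <- pmax(abs(m[1:4]), 1e-8) * 1e-6
    for (i in 1:4) {
      vp <- m[1:4]; vm <- m[1:4]
      vp[i] <- vp[i] + h[i]; vm[i] <- vm[i] - h[i]
      g[i] <- (fn(vp) - fn(vm)) / (2 * h[i])
    }
    sqrt(max(drop(t(g) %*% S %*% g), 0))
  }
  list(se_mean = sqrt(max(mu2, 0) / n),
       se_var = sqrt(max(mu4 - mu2^2, 0) / n),
       se_skew = if (mu2 > 0) se_delta(skew_f) else 0,
       se_kurt = if (mu2 > 0) se_delta(kurt_f) else 0)
}

#' Compare analytic moments against the simulation oracle
#'
#' Simulates a cohort and z-scores every analytic statistic against its
#' simulated counterpart: mean, variance, skewness and excess kurtosis of
#' longevity and LRO; generation time and parity (offspring-weighted ratio
#' statistics); and the conditional age-at-maturity mean and SD plus the
#' probability of ever maturing. All standard errors are *exact*: they are
#' computed from the model's own moments (raw moments to order 8 for the
#' scalar outcomes, the closed-form covariance of the per-individual
#' offspring-age sums for the timing ratios) via the delta method, so the
#' z-tests stay calibrated even for heavy-tailed outcomes where sample-based
#' SEs undershoot together with the statistic. A statistic passes at
#' `|z| <= z_max` (default 4). Statistics that are analytically undefined
#' for the model (e.g. skewness of a deterministic longevity) are omitted.
#'
#' @param model An [mpm] object.
#' @param n Cohort size (1e5 gives sharp checks; small n yields wide SEs and
#'   sets the `low_power` flag rather than failing).
#' @param seed Integer seed.
#' @param z_max Pass threshold on |z|.
#' @return A tibble: `outcome`, `analytic`, `simulated`, `se`, `z`, `pass`;
#'   attributes `low_power` and `n`.
#' @export
oracle_compare <- function(model, n = 1e5, seed = 1L, z_max = 4) {
  cohort <- simulate_cohort(model, n = n, seed = seed)
  rows <- list()
  add <- function(outcome, analytic, simulated, se) {
    if (is.na(analytic)) return(invisible(NULL))
    z <- if (se > 0) (analytic - simulated) / se
         else if (abs(analytic - simulated) < 1e-6 * max(1, abs(analytic))) 0
         else Inf
    rows[[length(rows) + 1]] <<- tibble(
      outcome = outcome, analytic = analytic, simulated = simulated,
      se = se, z = z, pass = abs(z) <= z_max)
    invisible(NULL)
  }
  lam <- colSums(model$F)

  for (what in c("lng", "lro")) {
    x <- if (what == "lng") cohort$longevity else cohort$lro
    m8 <- if (what == "lng") .longevity_raw_moments(model$U, 1L, 8)
          else .lro_raw_moments(model$U, lam, 8)[, 1]
    an <- stats_from_raw_moments(m8[1:4])
    ses <- .moment_stat_ses(m8, n)
    ss <- .sample_stats(x)
    add(paste0(what, "_mean"), an$mean, ss$mean, ses$se_mean)
    add(paste0(what, "_var"), an$variance, ss$var, ses$se_var)
    if (!is.na(an$skewness) && ss$var > 0) {
      add(paste0(what, "_skew"), an$skewness, ss$skew, ses$se_skew)
      add(paste0(what, "_kurt"), an$excess_kurtosis, ss$kurt, ses$se_kurt)
    }
  }

  gt_an <- tryCatch(offspring_age_moments(model$U, model$F),
                    error = function(e) NULL)
  if (!is.null(gt_an) && sum(cohort$lro) > 0) {
    tc <- .offspring_age_cov(model$U, model$F, 1L)
    sums <- c(sum(cohort$off_age_sum), sum(cohort$off_age_sumsq),
              sum(cohort$lro))
    gt_f <- function(v) v[1] / v[3]
    parity_f <- function(v) {
      m1 <- v[1] / v[3]
      va <- max(v[2] / v[3] - m1^2, 0)
      if (m1 > 0) sqrt(va) / m1 else 0
    }
    ratio_se <- function(fn) {
      g <- numeric(3)
      h <- pmax(abs(tc$mu), 1e-8) * 1e-6
      for (i in 1:3) {
        vp <- tc$mu; vm <- tc$mu
        vp[i] <- vp[i] + h[i]; vm[i] <- vm[i] - h[i]
        g[i] <- (fn(vp) - fn(vm)) / (2 * h[i])
      }
      sqrt(max(drop(t(g) %*% (tc$Sigma / n) %*% g), 0))
    }
    add("gt_mean", gt_an$gt_mean, gt_f(sums), ratio_se(gt_f))
    add("parity_cv", gt_an$parity_cv, parity_f(sums),
        if (gt_an$gt_sd > 0) ratio_se(parity_f) else 0)
  }

  am_an <- tryCatch(age_at_maturity(model$U, model$F),
                    error = function(e) NULL)
  if (!is.null(am_an)) {
    reached <- !is.na(cohort$maturity_age)
    p <- am_an$p_reach
    add("p_reach", p, mean(reached), sqrt(p * (1 - p) / n))
    if (any(reached)) {
      mt <- cohort$maturity_age[reached]
      M <- length(mt)
      ms <- .sample_stats(mt)
      cond <- .conditional_maturity_chain(model$U, model$F, 1L)
      if (is.null(cond)) {     # start stage reproductive: maturity age 0
        add("am_mean", 0, ms$mean, 0)
        add("am_sd", 0, ms$sd, 0)
      } else {
        m4 <- .longevity_raw_moments(cond$Uc, cond$start_pos, 4)
        cses <- .moment_stat_ses(c(m4, rep(NA_real_, 4)), M)
        mu2 <- m4[2] - m4[1]^2
        mu4 <- m4[4] - 4 * m4[1] * m4[3] + 6 * m4[1]^2 * m4[2] - 3 * m4[1]^4
        add("am_mean", am_an$am_mean, ms$mean, cses$se_mean)
        se_sd <- if (mu2 > 0) sqrt(max(mu4 - mu2^2, 0) / (4 * mu2 * M)) else 0
        add("am_sd", am_an$am_sd, ms$sd, se_sd)
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  attr(out, "low_power") <- n < 1000
  attr(out, "n") <- n
  out
}
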