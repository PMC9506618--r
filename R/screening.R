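#' Condition-number filter for the fundamental matrix
#'
#' Models whose `I - U` is near-singular describe near-immortal life cycles
#' for which the fundamental matrix (and every moment built on it) is
#' numerically unreliable. Such models are dropped when the condition number
#' of `I - U` exceeds `threshold`.
#'
#' @param U Transition matrix (column sums at most 1).
#' @param threshold Keep the model when `cond(I - U) <= threshold`.
#' @param norm `"2"` (SVD-based, default) or `"1"`.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
condition_filter <- function(U, threshold = 1000, norm = c("2", "1")) {
  norm <- match.arg(norm)
  U <- as.matrix(U)
  cs <- colSums(U)
  if (any(cs > 1 + .col_sum_tol)) {
    abort(sprintf("column %d of U sums to %.6g > 1", which.max(cs), max(cs)),
          class = "stochlife_validation_error")
  }
  A <- diag(ncol(U)) - U
  kap <- if (norm == "2") kappa(A, exact = TRUE) else kappa(A, norm = "1", exact = TRUE)
  is.finite(kap) && kap <= threshold
}

#' Eligibility screen for a matrix population model
#'
#' A model enters the analysis only if it is a mean matrix from a natural
#' (unmanipulated) population, single-sex and non-clonal, with an annual
#' projection interval, at least `min_stages` stages, some nonzero fertility,
#' and a well-conditioned `I - U` (see [condition_filter()]). Violations are
#' reported, never thrown.
#'
#' @param model An [mpm] object.
#' @param min_stages Minimum number of stages (default 5).
#' @param cond_threshold Condition-number threshold (default 1000).
#' @return A one-row tibble: `model_id`, `passed`, and a list-column
#'   `failures` of violated rule identifiers drawn from
#'   `not_mean_matrix`, `not_natural`, `two_sex`, `clonal`, `not_annual`,
#'   `zero_fertility`, `too_few_stages`, `ill_conditioned`.
#' @export
check_eligibility <- function(model, min_stages = 5L, cond_threshold = 1000) {
  stopifnot(inherits(model, "mpm"))
  fails <- character()
  if (!("mean_matrix" %in% model$flags)) fails <- c(fails, "not_mean_matrix")
  if (!("natural" %in% model$flags)) fails <- c(fails, "not_natural")
  if ("two_sex" %in% model$flags) fails <- c(fails, "two_sex")
  if ("clonal" %in% model$flags) fails <- c(fails, "clonal")
  if (model$projection_interval_years != 1) fails <- c(fails, "not_annual")
  if (all(model$F == 0)) fails <- c(fails, "zero_fertility")
  if (length(model$stage_names) < min_stages) fails <- c(fails, "too_few_stages")
  if (!condition_filter(model$U, cond_threshold)) fails <- c(fails, "ill_conditioned")
  tibble(model_id = model$model_id,
         passed = length(fails) == 0L,
         failures = list(fails))
}

#' Quartile-based upper outlier limit for skewed data
#'
#' Robust upper bound `Q3 + 2 c (Q3 - Q2)` built from the quartiles of the
#' data; designed for strongly right-skewed quantities where mean +/- k SD
#' rules break down. `c = 5` is the screening default.
#'
#' @param values Numeric vector (at least 4 finite values).
#' @param c Positive multiplier.
#' @param type Quantile algorithm passed to [stats::quantile()] (default 7,
#'   linear interpolation between order statistics).
#' @return A one-row tibble: `c`, `q1`, `q2`, `q3`, `upper_limit`.
#' @export
#' @examples
#' outlier_upper_limit(1:9, c = 5)  # Q2 5, Q3 7, limit 27
outlier_upper_limit <- function(values, c = 5, type = 7) {
  values <- values[is.finite(values)]
  if (length(values) < 4) {
    abort("insufficient data for quartiles (need at least 4 finite values)",
          class = "stochlife_validation_error")
  }
  stopifnot(c >= 0)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = type))
  tibble(c = c, q1 = q[1], q2 = q[2], q3 = q[3],
         upper_limit = q[3] + 2 * c * (q[3] - q[2]))
}

#' Remove LRO outlier models from a trait table
#'
#' Some published life cycles combine enormous per-stage fecundities with
#' minuscule establishment probabilities, producing LRO statistics (variances
#' of order 1e11) that would dominate every comparative analysis. Rows are
#' removed when the LRO mean, variance, or kurtosis *strictly* exceeds its
#' own [outlier_upper_limit()]; limits are computed per statistic, within each
#' kingdom by default.
#'
#' @param table Trait table with `lro_mean`, `lro_var`, `lro_kurt` populated.
#' @param c Outlier multiplier (default 5).
#' @param grouping `"per_kingdom"` (limits computed within each kingdom) or
#'   `"pooled"`.
#' @param type Quantile algorithm (see [outlier_upper_limit()]).
#' @return The screened tibble; the attribute `"exclusion_log"` is a tibble
#'   of removed `model_id`s with the violated statistic(s).
#' @export
apply_lro_outlier_screen <- function(table, c = 5,
                                     grouping = c("per_kingdom", "pooled"),
                                     type = 7) {
  grouping <- match.arg(grouping)
  stats <- c("lro_mean", "lro_var", "lro_kurt")
  stopifnot(all(stats %in% names(table)))
  table <- as_tibble(table)
  groups <- if (grouping == "per_kingdom") table$kingdom else rep("all", nrow(table))
  drop <- rep(FALSE, nrow(table))
  log <- list()
  for (g in unique(groups)) {
    in_g <- which(groups == g)
    for (st in stats) {
      vals <- table[[st]][in_g]
      lim <- outlier_upper_limit(vals, c = c, type = type)$upper_limit
      over <- in_g[!is.na(vals) & vals > lim]
      if (length(over)) {
        drop[over] <- TRUE
        log[[length(log) + 1]] <- tibble(
          model_id = table$model_id[over], statistic = st,
          value = table[[st]][over], upper_limit = lim, group = g
        )
      }
    }
  }
  out <- table[!drop, , drop = FALSE]
  attr(out, "exclusion_log") <- if (length(log)) {
    dplyr::bind_rows(log)
  } else {
    tibble(model_id = character(), statistic = character(),
           value = numeric(), upper_limit = numeric(), group = character())
  }
  out
}
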