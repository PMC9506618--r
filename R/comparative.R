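#' Compute the 16 demographic outcomes for one model
#'
#' Runs the full analytic machinery -- longevity moments from the absorbing
#' chain, LRO moments from the Markov chain with Poisson rewards, generation
#' time and parity from the offspring-age distribution, and age at maturity
#' by conditional absorption -- for an individual starting in the first stage
#' of the life cycle. Outcomes that are undefined for the model (e.g. age at
#' maturity when the start stage is already reproductive) are returned as
#' `NA`, with the reason recorded in the `"trait_log"` attribute rather than
#' silently fabricated.
#'
#' @param model An [mpm] object.
#' @param start_stage Starting stage (default 1).
#' @param age_origin Offspring-age convention, see [offspring_age_moments()].
#' @return A one-row tibble: `model_id`, `species`, `kingdom` and the 16
#'   columns of [trait_columns()].
#' @export
#' @examples
#' compute_traits(mpm(matrix(0.5), matrix(1)))
compute_traits <- function(model, start_stage = 1L, age_origin = "zero") {
  stopifnot(inherits(model, "mpm"))
  log <- list()
  note <- function(field, reason) {
    log[[length(log) + 1]] <<- tibble(model_id = model$model_id,
                                      field = field, reason = reason)
  }
  na_tibble <- function(nms) as_tibble(setNames(as.list(rep(NA_real_, length(nms))), nms))

  lng <- tryCatch(tidy(longevity_moments(model$U, start_stage)),
                  error = function(e) { note("lng", conditionMessage(e)); NULL })
  lro <- tryCatch(tidy(lro_stats(model, start_stage)),
                  error = function(e) { note("lro", conditionMessage(e)); NULL })
  gt <- tryCatch(offspring_age_moments(model$U, model$F, start_stage, age_origin),
                 error = function(e) { note("gt", conditionMessage(e)); NULL })
  am <- tryCatch(age_at_maturity(model$U, model$F, start_stage),
                 error = function(e) { note("am", conditionMessage(e)); NULL })
  if (!is.null(am) && is.na(am$am_cv)) {
    note("am_cv", "undefined: zero or degenerate age at maturity")
  }

  if (is.null(lng)) lng <- na_tibble(c("mean", "sd", "cv", "skewness", "excess_kurtosis"))
  if (is.null(lro)) lro <- na_tibble(c("mean", "variance", "ofs", "skewness", "excess_kurtosis"))
  if (is.null(gt)) gt <- na_tibble(c("gt_mean", "gt_sd", "parity_cv"))
  if (is.null(am)) am <- na_tibble(c("am_mean", "am_sd", "am_cv"))

  out <- tibble(
    model_id = model$model_id, species = model$species, kingdom = model$kingdom,
    lro_mean = lro$mean, lro_var = lro$variance, lro_ofs = lro$ofs,
    lro_skew = lro$skewness, lro_kurt = lro$excess_kurtosis,
    lng_mean = lng$mean, lng_sd = lng$sd, lng_cv = lng$cv,
    lng_skew = lng$skewness, lng_kurt = lng$excess_kurtosis,
    gt_mean = gt$gt_mean, gt_sd = gt$gt_sd, parity = gt$parity_cv,
    am_mean = am$am_mean, am_sd = am$am_sd, am_cv = am$am_cv
  )
  attr(out, "trait_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble(model_id = character(), field = character(), reason = character())
  out
}

#' Assemble a trait table for a batch of models
#'
#' Applies [compute_traits()] to each model; per-model failures become `NA`
#' entries with reasons collected in the `"trait_log"` attribute, so a batch
#' never aborts on one pathological model.
#'
#' @param models A list of [mpm] objects.
#' @inheritParams compute_traits
#' @return A tibble with one row per model (trait-table schema).
#' @export
compute_trait_table <- function(models, start_stage = 1L, age_origin = "zero") {
  rows <- lapply(models, compute_traits, start_stage = start_stage,
                 age_origin = age_origin)
  out <- dplyr::bind_rows(rows)
  attr(out, "trait_log") <- dplyr::bind_rows(lapply(rows, attr, "trait_log"))
  out
}

#' Quantile summary of trait-table outcomes
#'
#' Median and 2.5/25/75/97.5 percent quantiles per outcome: the interquartile
#' range captures the central half of populations, and the 2.5--97.5 band is
#' a robust "range" free of min/max instability.
#'
#' @param table Trait table (or any data frame).
#' @param outcomes Character vector of column names to summarize.
#' @param probs Quantile probabilities.
#' @param type Quantile algorithm.
#' @return A tibble with one row per outcome.
#' @export
quantile_summary <- function(table, outcomes,
                             probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                             type = 7) {
  stopifnot(all(outcomes %in% names(table)))
  rows <- lapply(outcomes, function(oc) {
    v <- table[[oc]]
    v <- v[is.finite(v)]
    if (length(v) < 4) {
      abort(sprintf("insufficient data for quantiles of '%s'", oc),
            class = "stochlife_validation_error")
    }
    q <- quantile(v, probs, type = type)
    as_tibble(c(list(outcome = oc, n = length(v)),
                setNames(as.list(unname(q)), paste0("q", probs * 100))))
  })
  dplyr::bind_rows(rows)
}

#' Quantile-trimmed histogram
#'
#' Heavy-tailed outcome distributions are unreadable on a common axis; the
#' display drops the lowest and highest `trim_fraction / 2` quantiles before
#' binning (trimming 0.2 discards 20% of the values, 10% in each tail).
#'
#' @param values Numeric vector.
#' @param trim_fraction Total fraction trimmed, in `[0, 0.5)`.
#' @param bins Suggested number of bins.
#' @param type Quantile algorithm used for the trim limits.
#' @return A tibble of class `trimmed_histogram` with `bin_left`, `bin_right`,
#'   `count`; attributes `n_trimmed`, `n_total`, `trim_fraction`.
#' @export
trimmed_histogram <- function(values, trim_fraction = 0.2, bins = 30, type = 7) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  values <- values[is.finite(values)]
  if (trim_fraction > 0) {
    lim <- quantile(values, c(trim_fraction / 2, 1 - trim_fraction / 2), type = type)
    kept <- values[values >= lim[1] & values <= lim[2]]
  } else {
    kept <- values
  }
  h <- graphics::hist(kept, breaks = bins, plot = FALSE)
  out <- tibble(bin_left = h$breaks[-length(h$breaks)],
                bin_right = h$breaks[-1],
                count = h$counts)
  structure(out,
            class = c("trimmed_histogram", class(out)),
            n_trimmed = length(values) - length(kept),
            n_total = length(values),
            trim_fraction = trim_fraction)
}

#' @exportS3Method ggplot2::autoplot
autoplot.trimmed_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$bin_left, xmax = .data$bin_right,
      ymin = 0, ymax = .data$count)) +
    ggplot2::labs(
      x = "value", y = "count",
      subtitle = if (attr(object, "n_trimmed") > 0) {
        sprintf("Trimmed data range (%d of %d values dropped)",
                attr(object, "n_trimmed"), attr(object, "n_total"))
      } else NULL
    )
}

#' Log-transform policy for the trait table
#'
#' Before correlation and PCA, outcomes are natural-log transformed except
#' those that can legitimately be zero or negative: longevity skewness and
#' kurtosis, and the SD and CV of age at maturity, always; LRO kurtosis
#' additionally when analyzing animals (its 2.5% quantile sits near zero in
#' that group). Nonpositive values in a column slated for logging indicate a
#' data problem and are reported as an error naming the models.
#'
#' @param table Trait table.
#' @param group `"plant"` or `"animal"`; controls whether `lro_kurt` is logged.
#' @return The transformed tibble; attribute `"log_policy"` records the
#'   logged and excluded columns.
#' @export
log_transform_policy <- function(table, group = c("plant", "animal")) {
  group <- match.arg(group)
  excluded <- c("lng_skew", "lng_kurt", "am_sd", "am_cv")
  if (group == "animal") excluded <- c(excluded, "lro_kurt")
  logged <- setdiff(trait_columns(), excluded)
  table <- as_tibble(table)
  for (col in logged) {
    v <- table[[col]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      ids <- if ("model_id" %in% names(table)) {
        paste(table$model_id[bad], collapse = ", ")
      } else paste(which(bad), collapse = ", ")
      abort(sprintf("nonpositive value(s) in '%s' for model(s): %s", col, ids),
            class = "stochlife_validation_error")
    }
    table[[col]] <- log(v)
  }
  attr(table, "log_policy") <- list(group = group, logged = logged,
                                    excluded = excluded)
  table
}

#' Pairwise Pearson correlations among outcomes
#'
#' Pairwise-complete Pearson product-moment correlations over the 16 outcome
#' columns (or any subset present). Zero-variance columns give `NA` entries
#' with a warning.
#'
#' @param table (Typically log-transformed) trait table.
#' @return A correlation matrix.
#' @export
pearson_correlations <- function(table) {
  cols <- intersect(trait_columns(), names(table))
  x <- as.matrix(as.data.frame(table)[cols])
  sds <- apply(x, 2, sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0)) {
    warn(paste0("zero-variance column(s), correlations undefined: ",
                paste(cols[!is.na(sds) & sds == 0], collapse = ", ")))
  }
  suppressWarnings(cor(x, use = "pairwise.complete.obs"))
}

#' Principal component analysis of the life-history trait space
#'
#' Eigendecomposition of the correlation matrix of the (complete-case)
#' outcome columns -- every outcome standardized to mean 0, SD 1, since the
#' outcomes carry different units. Loadings are signed so that each
#' component's largest-magnitude loading is positive (PCA signs are
#' arbitrary).
#'
#' @param table Trait table, typically after [log_transform_policy()].
#' @param standardize Use the correlation matrix (`TRUE`, default) rather
#'   than the covariance matrix.
#' @param k Number of components to retain in `scores`/`loadings` (default:
#'   all).
#' @return An object of class `lh_pca`: `loadings` (p x k), a full
#'   `explained_fraction` vector, `scores` (n x k), `k`, `n`, and the rows
#'   used. `tidy()` returns the loadings in long form, `glance()` the
#'   explained fractions.
#' @export
run_pca <- function(table, standardize = TRUE, k = NULL) {
  cols <- intersect(trait_columns(), names(table))
  x <- as.matrix(as.data.frame(table)[cols])
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) <= ncol(x)) {
    abort(sprintf("PCA needs more complete rows (%d) than columns (%d)",
                  nrow(x), ncol(x)),
          class = "stochlife_validation_error")
  }
  # constant outcomes (e.g. a deterministic age at maturity across an
  # age-classified ensemble) carry no variation to decompose
  sds <- apply(x, 2, sd)
  dropped <- cols[sds == 0]
  if (length(dropped)) {
    warn(paste0("dropping zero-variance outcome(s) from PCA: ",
                paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
    cols <- cols[sds > 0]
  }
  xs <- scale(x, center = TRUE, scale = standardize)
  S <- if (standardize) cor(x) else stats::cov(x)
  eig <- eigen(S, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  # sign convention: dominant loading of each component is positive
  for (j in seq_len(ncol(vectors))) {
    if (vectors[which.max(abs(vectors[, j])), j] < 0) {
      vectors[, j] <- -vectors[, j]
    }
  }
  if (is.null(k)) k <- length(values)
  loadings <- vectors[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(cols, paste0("PC", seq_len(k)))
  scores <- xs %*% loadings
  structure(
    list(loadings = loadings,
         explained_fraction = values / sum(values),
         eigenvalues = values,
         scores = scores, k = k, n = nrow(x),
         rows_used = which(complete), dropped_outcomes = dropped),
    class = "lh_pca"
  )
}

#' @export
print.lh_pca <- function(x, ...) {
  cat(sprintf("<lh_pca> %d rows, %d components retained\n", x$n, x$k))
  ef <- x$explained_fraction[seq_len(min(3, x$k))]
  cat("explained (first axes): ",
      paste(sprintf("%.1f%%", 100 * ef), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lh_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "outcome") |>
    tidyr::pivot_longer(-"outcome", names_to = "component",
                        values_to = "loading")
}

#' @exportS3Method generics::glance
glance.lh_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained_fraction)),
         eigenvalue = x$eigenvalues,
         explained_fraction = x$explained_fraction,
         cumulative = cumsum(x$explained_fraction))
}

#' @exportS3Method ggplot2::autoplot
autoplot.lh_pca <- function(object, components = c(1, 2), ...) {
  stopifnot(length(components) == 2, max(components) <= object$k)
  d <- as_tibble(object$scores[, components, drop = FALSE],
                 .name_repair = "minimal")
  names(d) <- c("x", "y")
  ef <- object$explained_fraction[components]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1], 100 * ef[1]),
      y = sprintf("PC%d (%.1f%%)", components[2], 100 * ef[2])
    )
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence coefficients (normalized inner products) between
#' recovered and reference loadings; used to check that planted factor
#' structure is recovered. Signs are ignored. With `match_columns = TRUE`
#' each reference factor is greedily paired with its best-matching distinct
#' recovered component first (components of similar strength can swap order
#' between runs without any loss of structure).
#'
#' @param recovered,reference Matrices with the same number of rows and
#'   columns.
#' @param match_columns Pair columns greedily by congruence instead of
#'   comparing in order.
#' @return Numeric vector of absolute congruence coefficients, one per
#'   reference column.
#' @export
factor_congruence <- function(recovered, reference, match_columns = FALSE) {
  stopifnot(nrow(recovered) == nrow(reference),
            ncol(recovered) == ncol(reference))
  norm_cols <- function(m) sweep(m, 2, sqrt(colSums(m^2)), "/")
  phi <- abs(crossprod(norm_cols(recovered), norm_cols(reference)))
  if (!match_columns) return(diag(phi))
  out <- numeric(ncol(reference))
  for (step in seq_len(ncol(reference))) {
    best <- arrayInd(which.max(phi), dim(phi))
    out[best[2]] <- phi[best]
    phi[best[1], ] <- -Inf
    phi[, best[2]] <- -Inf
  }
  out
}

#' Within/between-population variance decomposition
#'
#' For an outcome whose per-population distribution has known mean and
#' variance, the total variance of an equal-weight mixture splits exactly as
#' `V_total = V_within + V_between`: the average of the within-population
#' variances (the contribution of individual stochasticity) plus the
#' population variance of the means, computed with divide-by-n so the mixture
#' identity is exact. The intraclass correlation coefficient
#' `K = V_between / (V_between + V_within)` measures the heterogeneity share.
#'
#' @param per_population Data frame with numeric columns `mean` and
#'   `variance`, one row per population.
#' @return A one-row tibble: `v_within`, `v_between`, `k_icc`,
#'   `n_populations`.
#' @export
#' @examples
#' variance_decomposition(data.frame(mean = c(0, 2), variance = c(1, 3)))
variance_decomposition <- function(per_population) {
  stopifnot(all(c("mean", "variance") %in% names(per_population)))
  mu <- per_population$mean
  v <- per_population$variance
  if (length(mu) < 2) {
    abort("need at least 2 populations", class = "stochlife_validation_error")
  }
  if (!all(is.finite(mu)) || !all(is.finite(v))) {
    abort("non-finite mean or variance", class = "stochlife_validation_error")
  }
  v_within <- mean(v)
  v_between <- mean((mu - mean(mu))^2)
  denom <- v_within + v_between
  tibble(v_within = v_within, v_between = v_between,
         k_icc = if (denom > 0) v_between / denom else 0,
         n_populations = length(mu))
}

#' Table-4-style decomposition of a trait-table outcome
#'
#' Convenience wrapper mapping trait-table columns to
#' [variance_decomposition()]: `outcome = "lro"` uses (`lro_mean`, `lro_var`),
#' `"lng"` uses (`lng_mean`, `lng_sd`^2).
#'
#' @param table Trait table.
#' @param outcome `"lro"` or `"lng"`.
#' @return See [variance_decomposition()].
#' @export
decompose_trait <- function(table, outcome = c("lro", "lng")) {
  outcome <- match.arg(outcome)
  d <- if (outcome == "lro") {
    data.frame(mean = table$lro_mean, variance = table$lro_var)
  } else {
    data.frame(mean = table$lng_mean, variance = table$lng_sd^2)
  }
  d <- d[is.finite(d$mean) & is.finite(d$variance), , drop = FALSE]
  variance_decomposition(d)
}
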