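#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default:
#' quantile algorithm (type 7, linear interpolation), outlier multiplier
#' `c = 5`, condition-number threshold 1000, minimum of 5 stages, the
#' age-origin convention for offspring ages, and the outlier-screen grouping.
#' Values can also be loaded from a YAML file whose keys mirror the argument
#' names; explicit arguments override file values.
#'
#' @param quantile_type Quantile algorithm for all quantile computations.
#' @param outlier_c Outlier-limit multiplier.
#' @param cond_threshold Condition-number filter threshold.
#' @param min_stages Minimum model dimension.
#' @param age_origin `"zero"` or `"one"` (see [offspring_age_moments()]).
#' @param outlier_grouping `"per_kingdom"` or `"pooled"`.
#' @param seed Master RNG seed stamped into every artifact.
#' @param file Optional YAML file of defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(quantile_type = 7, outlier_c = 5,
                            cond_threshold = 1000, min_stages = 5L,
                            age_origin = "zero",
                            outlier_grouping = "per_kingdom",
                            seed = 1L, file = NULL) {
  cfg <- list(quantile_type = quantile_type, outlier_c = outlier_c,
              cond_threshold = cond_threshold, min_stages = min_stages,
              age_origin = age_origin, outlier_grouping = outlier_grouping,
              seed = seed)
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the 'yaml' package is needed to read config files")
    }
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown)) {
      abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    supplied <- names(match.call())[-1]
    for (key in setdiff(names(from_file), supplied)) cfg[[key]] <- from_file[[key]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full comparative pipeline
#'
#' Orchestrates the whole analysis on a list of models: eligibility
#' screening, trait-table assembly, the LRO outlier screen, quantile
#' summaries and trimmed histograms of the LRO and longevity statistics,
#' log-transform + PCA per kingdom (where enough complete rows exist), and
#' the within/between-population variance decomposition of LRO and
#' longevity. Every artifact is stamped with the configuration hash and seed.
#'
#' @param models List of [mpm] objects.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; artifacts are written there as
#'   CSV/JSON.
#' @return A list of class `pipeline_bundle`: `screening`, `traits`,
#'   `traits_screened`, `exclusions`, `quantiles`, `histograms`, `pca`,
#'   `decomposition`, `warnings`, `provenance`.
#' @export
run_pipeline <- function(models, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  screening <- dplyr::bind_rows(lapply(
    models, check_eligibility,
    min_stages = config$min_stages, cond_threshold = config$cond_threshold
  ))
  eligible <- models[screening$passed]
  if (!length(eligible)) {
    abort("screening: no model passed eligibility",
          class = "stochlife_validation_error")
  }
  traits <- compute_trait_table(eligible, age_origin = config$age_origin)
  screened <- apply_lro_outlier_screen(
    traits, c = config$outlier_c,
    grouping = config$outlier_grouping, type = config$quantile_type
  )
  exclusions <- attr(screened, "exclusion_log")

  lro_lng_cols <- c("lro_mean", "lro_var", "lro_ofs", "lro_skew", "lro_kurt",
                    "lng_mean", "lng_sd", "lng_cv", "lng_skew", "lng_kurt")
  quantiles <- screened |>
    dplyr::group_by(.data$kingdom) |>
    dplyr::group_modify(~ quantile_summary(.x, lro_lng_cols,
                                           type = config$quantile_type)) |>
    dplyr::ungroup()

  histograms <- lapply(
    setNames(nm = c("lro_mean", "lro_var", "lro_ofs")),
    function(col) trimmed_histogram(screened[[col]], trim_fraction = 0.2,
                                    type = config$quantile_type)
  )

  pca <- list(); warnings <- character()
  for (kd in intersect(c("animal", "plant"), unique(screened$kingdom))) {
    sub <- screened[screened$kingdom == kd, , drop = FALSE]
    res <- withCallingHandlers(
      tryCatch({
        logged <- log_transform_policy(sub, group = kd)
        run_pca(logged)
      }, error = function(e) {
        warnings <<- c(warnings, sprintf("pca[%s]: %s", kd, conditionMessage(e)))
        NULL
      }),
      warning = function(w) {
        warnings <<- c(warnings, sprintf("pca[%s]: %s", kd, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    if (!is.null(res)) pca[[kd]] <- res
  }

  decomposition <- screened |>
    dplyr::group_by(.data$kingdom) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      dplyr::mutate(decompose_trait(.x, "lng"), outcome = "lng"),
      dplyr::mutate(decompose_trait(.x, "lro"), outcome = "lro")
    )) |>
    dplyr::ungroup()

  provenance <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("stochlife")),
    n_models = length(models), n_eligible = length(eligible),
    n_after_outlier_screen = nrow(screened)
  )
  bundle <- structure(
    list(screening = screening, traits = traits, traits_screened = screened,
         exclusions = exclusions, quantiles = quantiles,
         histograms = histograms, pca = pca, decomposition = decomposition,
         warnings = warnings, provenance = provenance),
    class = "pipeline_bundle"
  )
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- bundle$provenance
  write_trait_table(bundle$traits, file.path(out_dir, "traits.csv"))
  write_trait_table(bundle$traits_screened, file.path(out_dir, "traits_screened.csv"))
  screening <- bundle$screening
  screening$failures <- vapply(screening$failures, paste, "", collapse = ";")
  write.csv(screening, file.path(out_dir, "screening.csv"), row.names = FALSE)
  write.csv(bundle$quantiles, file.path(out_dir, "quantiles.csv"), row.names = FALSE)
  write.csv(bundle$exclusions, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(prov, list(
      decomposition = bundle$decomposition,
      pca = lapply(bundle$pca, function(p) list(
        loadings = p$loadings, explained_fraction = p$explained_fraction, n = p$n
      )),
      warnings = bundle$warnings
    )),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<pipeline_bundle> %d models -> %d eligible -> %d after outlier screen (seed %s, config %s)\n",
    p$n_models, p$n_eligible, p$n_after_outlier_screen, p$seed, p$config_hash))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
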