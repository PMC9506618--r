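#' Construct a matrix population model
#'
#' A matrix population model (MPM) is the unit of analysis: a transition
#' matrix `U` whose (i, j) entry is the probability that a stage-j individual
#' survives and moves to stage i over one projection interval, and a fertility
#' matrix `F` whose (i, j) entry is the mean number of stage-i offspring
#' produced per stage-j individual per interval.
#'
#' Column sums of `U` are survival probabilities and must not exceed 1 (within
#' a tolerance of 1e-8). Published models occasionally violate this; set
#' `allow_survival_excess = TRUE` to proportionally rescale offending columns
#' to sum to 1, which records the `"survival_excess"` flag on the model.
#'
#' @param U Square numeric matrix of transition probabilities.
#' @param F_mat Square numeric matrix of mean offspring counts, same dimension
#'   as `U`. (Named `F_mat` to avoid the `F`/`FALSE` trap.)
#' @param model_id Character scalar identifying the model.
#' @param species Character scalar, species name.
#' @param kingdom One of `"animal"`, `"plant"`, `"other"`.
#' @param stage_names Character vector of stage labels (default `s1`, `s2`, ...).
#' @param projection_interval_years Positive number; length of one time step.
#' @param flags Character vector of metadata flags (e.g. `"mean_matrix"`,
#'   `"natural"`, `"two_sex"`, `"clonal"`).
#' @param allow_survival_excess Rescale columns of `U` summing to more than 1
#'   instead of erroring.
#'
#' @return An object of class `mpm`.
#' @export
#' @examples
#' m <- mpm(U = matrix(0.5), F_mat = matrix(1), model_id = "toy")
#' m$U
mpm <- function(U, F_mat, model_id = "model",
                species = NA_character_,
                kingdom = c("other", "animal", "plant"),
                stage_names = NULL,
                projection_interval_years = 1,
                flags = c("mean_matrix", "natural"),
                allow_survival_excess = FALSE) {
  kingdom <- match.arg(kingdom, c("other", "animal", "plant"))
  U <- as.matrix(U)
  F_mat <- as.matrix(F_mat)
  if (nrow(U) != ncol(U) || nrow(F_mat) != ncol(F_mat) ||
      nrow(U) != nrow(F_mat)) {
    abort(sprintf(
      "dimension mismatch: U is %dx%d, F is %dx%d (both must be square and equal)",
      nrow(U), ncol(U), nrow(F_mat), ncol(F_mat)
    ), class = "stochlife_validation_error")
  }
  tau <- nrow(U)
  if (tau < 1L) abort("model must have at least one stage",
                      class = "stochlife_validation_error")
  if (is.null(stage_names)) stage_names <- paste0("s", seq_len(tau))
  if (length(stage_names) != tau) {
    abort("stage_names length does not match matrix dimension",
          class = "stochlife_validation_error")
  }
  for (nm in c("U", "F")) {
    m <- if (nm == "U") U else F_mat
    if (!all(is.finite(m))) {
      abort(paste0("non-finite entry in ", nm),
            class = "stochlife_validation_error")
    }
    if (any(m < 0)) {
      abort(paste0("negative entry in ", nm),
            class = "stochlife_validation_error")
    }
  }
  if (!is.numeric(projection_interval_years) ||
      length(projection_interval_years) != 1L ||
      !is.finite(projection_interval_years) || projection_interval_years <= 0) {
    abort("projection_interval_years must be a positive number",
          class = "stochlife_validation_error")
  }
  cs <- colSums(U)
  if (any(cs > 1 + .col_sum_tol)) {
    if (allow_survival_excess) {
      bad <- which(cs > 1 + .col_sum_tol)
      U[, bad] <- sweep(U[, bad, drop = FALSE], 2, cs[bad], "/")
      flags <- union(flags, "survival_excess")
    } else if (!("survival_excess" %in% flags)) {
      abort(sprintf(
        "column %d of U sums to %.6g > 1; survival probabilities cannot exceed 1",
        which.max(cs), max(cs)
      ), class = "stochlife_validation_error")
    }
  }
  dimnames(U) <- dimnames(F_mat) <- list(stage_names, stage_names)
  structure(
    list(
      model_id = as.character(model_id),
      species = as.character(species),
      kingdom = kingdom,
      stage_names = as.character(stage_names),
      U = U, F = F_mat,
      projection_interval_years = projection_interval_years,
      flags = as.character(flags)
    ),
    class = "mpm"
  )
}

#' @export
print.mpm <- function(x, ...) {
  cat(sprintf(
    "<mpm> %s  (%s, %s)  %d stages, interval %g yr, flags: %s\n",
    x$model_id, x$species, x$kingdom, length(x$stage_names),
    x$projection_interval_years,
    if (length(x$flags)) paste(x$flags, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Read a matrix population model from disk
#'
#' Two plain-text layouts are supported. `format = "json"` reads a single JSON
#' object with fields `model_id`, `species`, `kingdom`, `stage_names`,
#' `projection_interval_years`, `flags`, `U` and `F` (matrices as row-major
#' nested arrays). `format = "csv"` reads a pair of RFC-4180 CSV files
#' `<path>_U.csv` / `<path>_F.csv` (header row = stage names) plus a sidecar
#' `<path>_meta.json`; `path` is the common prefix.
#'
#' Validation failures are errors, never silent fixes.
#'
#' @param path File path (JSON) or file prefix (CSV pair).
#' @param format `"json"` or `"csv"`.
#' @inheritParams mpm
#' @return A validated [mpm] object.
#' @seealso [write_mpm()]
#' @export
read_mpm <- function(path, format = c("json", "csv"),
                     allow_survival_excess = FALSE) {
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) {
      abort(paste0("no such file: ", path), class = "stochlife_parse_error")
    }
    obj <- tryCatch(
      jsonlite::fromJSON(path, simplifyMatrix = TRUE),
      error = function(e) abort(paste0("malformed JSON in ", path, ": ",
                                       conditionMessage(e)),
                                class = "stochlife_parse_error")
    )
    for (field in c("model_id", "U", "F")) {
      if (is.null(obj[[field]])) {
        abort(paste0("missing required field '", field, "' in ", path),
              class = "stochlife_parse_error")
      }
    }
    mpm(
      U = obj$U, F_mat = obj$F,
      model_id = obj$model_id,
      species = obj$species %||% NA_character_,
      kingdom = obj$kingdom %||% "other",
      stage_names = obj$stage_names,
      projection_interval_years = obj$projection_interval_years %||% 1,
      flags = obj$flags %||% character(),
      allow_survival_excess = allow_survival_excess
    )
  } else {
    files <- paste0(path, c("_U.csv", "_F.csv", "_meta.json"))
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      abort(paste0("missing file(s): ", paste(missing, collapse = ", ")),
            class = "stochlife_parse_error")
    }
    read_mat <- function(f) {
      d <- read.csv(f, check.names = FALSE)
      m <- as.matrix(d)
      storage.mode(m) <- "double"
      rownames(m) <- NULL
      m
    }
    U <- read_mat(files[1])
    F_mat <- read_mat(files[2])
    meta <- jsonlite::fromJSON(files[3])
    mpm(
      U = U, F_mat = F_mat,
      model_id = meta$model_id,
      species = meta$species %||% NA_character_,
      kingdom = meta$kingdom %||% "other",
      stage_names = colnames(U),
      projection_interval_years = meta$projection_interval_years %||% 1,
      flags = meta$flags %||% character(),
      allow_survival_excess = allow_survival_excess
    )
  }
}

#' Write a matrix population model to disk
#'
#' Inverse of [read_mpm()]: matrices are printed with 17 significant digits so
#' that a round trip reproduces `U` and `F` exactly (JSON) or to within one
#' unit in the last place (CSV).
#'
#' @param model An [mpm] object.
#' @param path Destination file (JSON) or file prefix (CSV pair).
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_mpm <- function(model, path, format = c("json", "csv")) {
  stopifnot(inherits(model, "mpm"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      model_id = model$model_id,
      species = model$species,
      kingdom = model$kingdom,
      stage_names = model$stage_names,
      projection_interval_years = model$projection_interval_years,
      flags = model$flags,
      U = unname(model$U),
      F = unname(model$F)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  } else {
    write_mat <- function(m, f) {
      d <- as.data.frame(matrix(sprintf("%.17g", m), nrow(m)))
      names(d) <- model$stage_names
      write.csv(d, f, row.names = FALSE)
    }
    write_mat(model$U, paste0(path, "_U.csv"))
    write_mat(model$F, paste0(path, "_F.csv"))
    meta <- list(
      model_id = model$model_id, species = model$species,
      kingdom = model$kingdom,
      projection_interval_years = model$projection_interval_years,
      flags = model$flags
    )
    jsonlite::write_json(meta, paste0(path, "_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Canonical life-history trait columns
#'
#' The 16 demographic outcomes computed per model, in fixed order: moments of
#' lifetime reproductive output (LRO) and longevity (LNG), generation time
#' (GT), the parity measure, and age at maturity (AM).
#'
#' @return Character vector of length 16.
#' @export
trait_columns <- function() {
  c("lro_mean", "lro_var", "lro_ofs", "lro_skew", "lro_kurt",
    "lng_mean", "lng_sd", "lng_cv", "lng_skew", "lng_kurt",
    "gt_mean", "gt_sd", "parity",
    "am_mean", "am_sd", "am_cv")
}

.trait_table_columns <- function() c("model_id", "species", "kingdom", trait_columns())

.check_trait_schema <- function(table) {
  want <- .trait_table_columns()
  extra <- setdiff(names(table), want)
  miss <- setdiff(want, names(table))
  if (length(extra)) {
    abort(paste0("unknown trait-table column(s): ", paste(extra, collapse = ", ")),
          class = "stochlife_validation_error")
  }
  if (length(miss)) {
    abort(paste0("missing trait-table column(s): ", paste(miss, collapse = ", ")),
          class = "stochlife_validation_error")
  }
  table[want]
}

#' Read / write the life-history trait table
#'
#' The trait table is a CSV with one row per model and a closed schema:
#' `model_id`, `species`, `kingdom` and the 16 columns of [trait_columns()],
#' in that order. Missing outcomes are stored as `NA` and round-trip
#' losslessly (numbers are printed with 17 significant digits).
#'
#' @param path CSV file path.
#' @param table A data frame obeying the schema.
#' @return `read_trait_table()` returns a tibble; `write_trait_table()`
#'   returns `path` invisibly.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "stochlife_parse_error")
  }
  d <- read.csv(path, check.names = FALSE,
                colClasses = c(model_id = "character", species = "character",
                               kingdom = "character"))
  as_tibble(.check_trait_schema(d))
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(table, path) {
  table <- .check_trait_schema(as.data.frame(table))
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.nan(x)] <- "NaN"
    out[is.na(x) & !is.nan(x)] <- NA
    out
  })
  write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}
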