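#' Read and write the survey and census CSV schemas
#'
#' The survey schema has columns \code{gender, age_group, unit, active}
#' (active in 0/1, one row per respondent); the census schema has columns
#' \code{gender, age_group, unit, count} (one row per poststratification
#' cell). Factor labels are strings; unless a [factor_spec()] is supplied,
#' levels are taken as the sorted unique labels in the file, so the coding
#' is deterministic and locale-independent.
#'
#' @param path CSV file path.
#' @param spec optional [factor_spec()]; labels outside it are rejected with
#'   the offending row number.
#' @return \code{read_survey}: a survey data frame; \code{read_census}: a
#'   \code{"poststrat_table"}.
#' @name survey_io
NULL

#' @rdname survey_io
#' @export
read_survey <- function(path, spec = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gender", "age_group", "unit", "active")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("survey file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- factor_spec(sort(unique(df$gender)),
                        sort(unique(df$age_group)),
                        sort(unique(df$unit)))
  }
  align_factors(df[need], spec)
}

#' @rdname survey_io
#' @param allow_incomplete if \code{TRUE}, census cells absent from the file
#'   are completed with zero counts; otherwise an incomplete grid is an
#'   error.
#' @export
read_census <- function(path, spec = NULL, allow_incomplete = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gender", "age_group", "unit", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("census file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$count)) || any(df$count < 0)) {
    stop("census counts must be finite and nonnegative", call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- factor_spec(sort(unique(df$gender)),
                        sort(unique(df$age_group)),
                        sort(unique(df$unit)))
  }
  for (nm in c("gender", "age_group", "unit")) {
    bad <- which(!df[[nm]] %in% spec[[nm]])
    if (length(bad)) {
      stop(sprintf("unknown %s label '%s' at row %d", nm, df[[nm]][bad[1]],
                   bad[1]), call. = FALSE)
    }
  }
  key <- paste(df$gender, df$age_group, df$unit, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate census cell: ", key[which(duplicated(key))[1]],
         call. = FALSE)
  }
  grid <- cell_grid(spec)
  pos <- match(cell_key(grid), key)
  if (anyNA(pos) && !allow_incomplete) {
    stop(sprintf(
      "census grid incomplete: %d of %d cells missing (e.g. %s); set allow_incomplete = TRUE to zero-fill",
      sum(is.na(pos)), nrow(grid), cell_key(grid)[which(is.na(pos))[1]]),
      call. = FALSE)
  }
  grid$count <- ifelse(is.na(pos), 0L, as.integer(round(df$count[pos])))
  if (sum(grid$count) <= 0) {
    stop("census table must have positive total population", call. = FALSE)
  }
  structure(grid, spec = spec, class = c("poststrat_table", "data.frame"))
}

#' @rdname survey_io
#' @param data survey data frame to write.
#' @export
write_survey <- function(data, path) {
  utils::write.csv(data[c("gender", "age_group", "unit", "active")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname survey_io
#' @param table \code{"poststrat_table"} to write.
#' @export
write_census <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("gender", "age_group", "unit",
                                          "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write subpopulation estimates to CSV
#'
#' One row per group: grouping columns, posterior mean, interval bounds
#' (named by the interval level, e.g. \code{lower_90}), and population.
#'
#' @param estimates a \code{"subpop_estimates"} data frame.
#' @param path output CSV path.
#' @export
write_estimates <- function(estimates, path) {
  lev <- round(100 * (attr(estimates, "level") %||% 0.90))
  df <- as.data.frame(estimates)
  names(df)[names(df) == "lower"] <- sprintf("lower_%d", lev)
  names(df)[names(df) == "upper"] <- sprintf("upper_%d", lev)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize ground-truth parameters to and from JSON
#'
#' @param truth a [draw_true_params()] object.
#' @param path JSON file path.
#' @export
write_true_params <- function(truth, path) {
  stopifnot(inherits(truth, "true_params"))
  obj <- list(
    intercept = truth$intercept,
    gender_effects = as.list(truth$gender_effects),
    age_effects = as.list(truth$age_effects),
    unit_effects = as.list(truth$unit_effects),
    unit_sd = truth$unit_sd,
    seed = truth$seed
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_true_params
#' @export
read_true_params <- function(path) {
  obj <- jsonlite::fromJSON(path)
  spec <- factor_spec(names(obj$gender_effects), names(obj$age_effects),
                      names(obj$unit_effects))
  structure(
    list(intercept = obj$intercept,
         gender_effects = unlist(obj$gender_effects),
         age_effects = unlist(obj$age_effects),
         unit_effects = unlist(obj$unit_effects),
         unit_sd = obj$unit_sd, seed = as.integer(obj$seed), spec = spec),
    class = "true_params"
  )
}

#' Write posterior draws and diagnostics for a fit
#'
#' Draws go to a CSV (one row per retained draw, one column per parameter);
#' factor labels and diagnostics to a JSON sidecar.
#'
#' @param fit an [mrp_fit()].
#' @param draws_path CSV path for the draws matrix.
#' @param meta_path JSON path for labels and diagnostics.
#' @export
write_fit <- function(fit, draws_path, meta_path) {
  utils::write.csv(as.data.frame(fit$draws), draws_path, row.names = FALSE)
  meta <- list(
    model = fit$model,
    levels = unclass(fit$spec),
    nobs = fit$nobs,
    control = unclass(fit$control),
    diagnostics = list(rhat = as.list(fit$diagnostics$rhat),
                       converged = fit$diagnostics$converged,
                       divergences = fit$diagnostics$divergences,
                       notices = fit$diagnostics$notices)
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), meta_path)
  invisible(draws_path)
}

# JSON run manifest sufficient to re-run a pipeline stage bit-reproducibly.
write_manifest <- function(path, stage, args) {
  meta <- list(
    stage = stage,
    arguments = args,
    package_version = as.character(utils::packageVersion("mrpstrat")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), path)
  invisible(path)
}

#' Write cross-validation results to CSV files plus a manifest
#'
#' @param cv an \code{"mrp_cv"} result.
#' @param dir output directory (created if needed).
#' @param long_errors also write the full replicate-level error matrices in
#'   long format.
#' @return The directory, invisibly.
#' @export
write_cv <- function(cv, dir, long_errors = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cv$mae_unit, file.path(dir, "mae_by_unit.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$mae_overall, file.path(dir, "mae_overall.csv"),
                   row.names = FALSE)
  if (long_errors) {
    long <- do.call(rbind, lapply(names(cv$errors), function(meth) {
      do.call(rbind, lapply(names(cv$errors[[meth]]), function(f) {
        m <- cv$errors[[meth]][[f]]
        data.frame(method = meth, fraction = f,
                   replicate = rep(seq_len(nrow(m)), ncol(m)),
                   unit = rep(colnames(m), each = nrow(m)),
                   abs_error = as.vector(m))
      }))
    }))
    utils::write.csv(long, file.path(dir, "errors_long.csv"),
                     row.names = FALSE)
  }
  write_manifest(
    file.path(dir, "manifest.json"), "crossval",
    list(seed = cv$design$seed, n_reps = cv$design$n_reps,
         fractions = cv$design$fractions,
         profile = cv$design$profile,
         refit_split = cv$design$refit_split,
         control = unclass(cv$design$control),
         convergence_rate = cv$convergence)
  )
  invisible(dir)
}
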