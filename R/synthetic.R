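#' Generate a synthetic census poststratification table
#'
#' Produces a population count for every gender x age-group x unit cell, the
#' stand-in for a national census cross-tabulation. The default count law is
#' log-normal (median 10,000 people per cell, sdlog 1), mimicking the strongly
#' skewed population sizes of state capitals so that census weighting is
#' exercised under realistic imbalance.
#'
#' @param spec a [factor_spec()].
#' @param counts how to populate cells: \code{NULL} for the default log-normal
#'   law; a single number for a constant count per cell; a numeric vector with
#'   one count per cell (canonical [cell_grid()] order); or a
#'   \code{function(n)} returning \code{n} nonnegative counts.
#' @param meanlog,sdlog parameters of the default log-normal law.
#' @param seed integer seed; the table is reproducible bit-for-bit given the
#'   seed.
#' @return A data frame of class \code{"poststrat_table"}: the canonical cell
#'   grid plus an integer \code{count} column, with the spec attached as
#'   attribute \code{"spec"}.
#' @examples
#' tab <- make_census(factor_spec(2, 7, 27), counts = 100, seed = 1)
#' nrow(tab)        # 378
#' sum(tab$count)   # 37800
#' @export
make_census <- function(spec, counts = NULL, meanlog = log(10000), sdlog = 1,
                        seed = 1L) {
  stopifnot(inherits(spec, "factor_spec"))
  grid <- cell_grid(spec)
  n_cells <- nrow(grid)
  set.seed(as.integer(seed))
  cnt <- if (is.null(counts)) {
    round(stats::rlnorm(n_cells, meanlog = meanlog, sdlog = sdlog))
  } else if (is.function(counts)) {
    counts(n_cells)
  } else if (is.numeric(counts) && length(counts) == 1L) {
    rep(counts, n_cells)
  } else if (is.numeric(counts) && length(counts) == n_cells) {
    counts
  } else {
    stop("'counts' must be NULL, a scalar, a function, or one value per cell",
         call. = FALSE)
  }
  if (any(cnt < 0) || any(!is.finite(cnt))) {
    stop("cell counts must be finite and nonnegative", call. = FALSE)
  }
  grid$count <- as.integer(round(cnt))
  if (sum(grid$count) <= 0) {
    stop("census table must have positive total population", call. = FALSE)
  }
  structure(grid, spec = spec, class = c("poststrat_table", "data.frame"))
}

#' Draw ground-truth generative parameters
#'
#' Samples the "true" logistic-regression parameters from which synthetic
#' surveys are generated: a fixed intercept, zero-reference gender and age
#' effects drawn from zero-centered normals, and i.i.d. normal(0, unit_sd)
#' geographic-unit effects. The first level of gender and age is the
#' reference (effect exactly 0), matching the identifiable dummy coding used
#' when fitting.
#'
#' @param spec a [factor_spec()].
#' @param intercept true intercept on the logit scale. The default puts the
#'   overall outcome prevalence near 40%, the ballpark of leisure-time
#'   physical activity in the motivating survey.
#' @param gender_scale,age_scale standard deviations of the zero-centered
#'   normals for the non-reference gender/age effects (must be >= 0).
#' @param unit_sd standard deviation of the unit effects (>= 0); this is the
#'   between-capital heterogeneity that partial pooling estimates.
#' @param seed integer seed.
#' @return An object of class \code{"true_params"} with components
#'   \code{intercept}, \code{gender_effects}, \code{age_effects},
#'   \code{unit_effects}, \code{unit_sd}, \code{seed}, \code{spec}.
#' @export
draw_true_params <- function(spec, intercept = stats::qlogis(0.4),
                             gender_scale = 0.5, age_scale = 0.5,
                             unit_sd = 0.3, seed = 1L) {
  stopifnot(inherits(spec, "factor_spec"))
  if (gender_scale < 0 || age_scale < 0 || unit_sd < 0) {
    stop("effect scales must be nonnegative", call. = FALSE)
  }
  n <- n_levels(spec)
  set.seed(as.integer(seed))
  ge <- c(0, stats::rnorm(n["gender"] - 1L, 0, gender_scale))
  ae <- c(0, stats::rnorm(n["age_group"] - 1L, 0, age_scale))
  ue <- stats::rnorm(n["unit"], 0, unit_sd)
  structure(
    list(
      intercept = intercept,
      gender_effects = stats::setNames(ge, spec$gender),
      age_effects = stats::setNames(ae, spec$age_group),
      unit_effects = stats::setNames(ue, spec$unit),
      unit_sd = unit_sd,
      seed = as.integer(seed),
      spec = spec
    ),
    class = "true_params"
  )
}

#' @export
print.true_params <- function(x, ...) {
  cat("Ground-truth logistic parameters\n")
  cat(sprintf("  intercept: %.3f (baseline prob %.3f)\n",
              x$intercept, stats::plogis(x$intercept)))
  cat(sprintf("  unit effect SD (generative): %.3f\n", x$unit_sd))
  invisible(x)
}

#' True outcome probability in every cell
#'
#' Applies the inverse-logit link to the ground-truth linear predictor,
#' intercept + gender + age + unit effect, for every poststratification cell.
#' The result is a one-draw cell-prediction object, so the same
#' poststratification code that handles posterior draws also handles the
#' truth.
#'
#' @param truth a [draw_true_params()] object.
#' @param spec a [factor_spec()]; defaults to the one stored in \code{truth}.
#' @return A \code{"mrp_cellpred"} matrix with 1 row (the single "draw") and
#'   one column per cell in canonical order.
#' @export
true_cell_probs <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "true_params"), inherits(spec, "factor_spec"))
  grid <- cell_grid(spec)
  lp <- truth$intercept +
    truth$gender_effects[as.integer(grid$gender)] +
    truth$age_effects[as.integer(grid$age_group)] +
    truth$unit_effects[as.integer(grid$unit)]
  theta <- matrix(stats::plogis(lp), nrow = 1,
                  dimnames = list(NULL, cell_key(grid)))
  new_cellpred(theta, grid, spec)
}

#' True subpopulation proportions under the generative model
#'
#' Census-weighted true outcome proportions for any grouping of the factors:
#' for each group, sum(N_c * theta_c) / sum(N_c) over its cells, with theta_c
#' the true cell probability. These are the known answers that estimators are
#' judged against in simulation.
#'
#' @param truth a [draw_true_params()] object.
#' @param table a [make_census()] poststratification table.
#' @param by character subset of \code{c("gender", "age_group", "unit")};
#'   empty for the single population-wide proportion.
#' @return A data frame with the grouping columns, \code{prop}, and the group
#'   \code{population}.
#' @export
true_subpop_props <- function(truth, table, by = "unit") {
  stopifnot(inherits(truth, "true_params"),
            inherits(table, "poststrat_table"))
  spec <- attr(table, "spec")
  theta <- as.numeric(true_cell_probs(truth, spec))
  group_weighted_mean(theta, table, by)
}

# Shared N_c-weighted aggregation of one per-cell vector.
group_weighted_mean <- function(theta, table, by) {
  by <- check_group_by(by)
  if (length(by) == 0L) {
    pop <- sum(table$count)
    if (pop == 0) stop("population is zero", call. = FALSE)
    return(data.frame(prop = sum(table$count * theta) / pop,
                      population = as.integer(pop)))
  }
  key <- interaction(table[by], drop = FALSE, lex.order = TRUE)
  pop <- tapply(table$count, key, sum)
  if (any(pop == 0)) {
    stop("group(s) with zero population: ",
         paste(names(pop)[pop == 0], collapse = ", "), call. = FALSE)
  }
  wsum <- tapply(table$count * theta, key, sum)
  groups <- unique(table[by])
  groups <- groups[do.call(order, unname(as.list(groups))), , drop = FALSE]
  out <- data.frame(groups, row.names = NULL)
  out$prop <- as.numeric(wsum / pop)
  out$population <- as.integer(pop)
  out
}

check_group_by <- function(by) {
  ok <- c("gender", "age_group", "unit")
  if (length(by) && !all(by %in% ok)) {
    stop("grouping factors must be among: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  by
}

#' Describe how survey respondents are sampled from the population
#'
#' Three sampling designs are supported: \code{"proportional"} (inclusion
#' probability proportional to cell population, i.e. simple random sampling
#' from the census), \code{"quota"} (a fixed number of respondents per
#' geographic unit, allocated across that unit's cells proportionally to
#' population — the design of the motivating telephone survey, which
#' interviews ~2,000 adults per capital regardless of capital size), and
#' \code{"multiplier"} (proportional sampling with a per-cell inclusion
#' multiplier, modelling non-outcome-dependent selection bias such as uneven
#' telephone coverage).
#'
#' @param mode one of \code{"proportional"}, \code{"quota"},
#'   \code{"multiplier"}.
#' @param quota for mode \code{"quota"}: respondents per unit, a scalar or a
#'   per-unit vector (>= 0).
#' @param multipliers for mode \code{"multiplier"}: strictly positive
#'   inclusion multiplier per cell (canonical order).
#' @return An object of class \code{"sampling_scheme"}.
#' @export
sampling_scheme <- function(mode = c("proportional", "quota", "multiplier"),
                            quota = NULL, multipliers = NULL) {
  mode <- match.arg(mode)
  if (mode == "quota") {
    if (is.null(quota) || any(quota < 0)) {
      stop("quota mode needs a nonnegative per-unit quota", call. = FALSE)
    }
  }
  if (mode == "multiplier") {
    if (is.null(multipliers) || any(multipliers <= 0)) {
      stop("multiplier mode needs strictly positive multipliers",
           call. = FALSE)
    }
  }
  structure(list(mode = mode, quota = quota, multipliers = multipliers),
            class = "sampling_scheme")
}

#' Simulate a survey from known truth
#'
#' Draws respondents' cells according to a sampling scheme and their binary
#' outcomes as Bernoulli(theta_cell) under the ground-truth parameters.
#' Deterministic given the seed.
#'
#' @param truth a [draw_true_params()] object.
#' @param table a [make_census()] table (defines cell populations).
#' @param n number of respondents (proportional/multiplier modes; ignored for
#'   quota mode, where n is the quota total).
#' @param scheme a [sampling_scheme()]; default proportional.
#' @param seed integer seed.
#' @return A survey data frame: factor columns \code{gender},
#'   \code{age_group}, \code{unit} and integer \code{active} (0/1), one row
#'   per respondent.
#' @examples
#' spec <- factor_spec(2, 3, 4)
#' tab <- make_census(spec, counts = 500, seed = 1)
#' tr <- draw_true_params(spec, seed = 2)
#' head(simulate_survey(tr, tab, n = 100, seed = 3))
#' @export
simulate_survey <- function(truth, table, n = NULL,
                            scheme = sampling_scheme("proportional"),
                            seed = 1L) {
  stopifnot(inherits(truth, "true_params"),
            inherits(table, "poststrat_table"),
            inherits(scheme, "sampling_scheme"))
  spec <- attr(table, "spec")
  theta <- as.numeric(true_cell_probs(truth, spec))
  n_cells <- nrow(table)
  set.seed(as.integer(seed))

  if (scheme$mode %in% c("proportional", "multiplier")) {
    if (is.null(n) || n < 1) stop("n must be >= 1", call. = FALSE)
    w <- as.numeric(table$count)
    if (scheme$mode == "multiplier") {
      if (length(scheme$multipliers) != n_cells) {
        stop("need one multiplier per cell", call. = FALSE)
      }
      w <- w * scheme$multipliers
    }
    if (sum(w) <= 0) stop("no cell has positive sampling weight", call. = FALSE)
    idx <- sample.int(n_cells, size = n, replace = TRUE, prob = w)
  } else {
    units <- attr(table, "spec")$unit
    quota <- scheme$quota
    if (length(quota) == 1L) quota <- rep(quota, length(units))
    if (length(quota) != length(units)) {
      stop("quota must be scalar or one value per unit", call. = FALSE)
    }
    idx_list <- vector("list", length(units))
    for (u in seq_along(units)) {
      rows <- which(as.integer(table$unit) == u)
      wu <- as.numeric(table$count[rows])
      if (quota[u] > 0 && sum(wu) <= 0) {
        stop("positive quota for unit '", units[u],
             "' with zero population", call. = FALSE)
      }
      if (quota[u] > 0) {
        alloc <- as.vector(stats::rmultinom(1, size = quota[u], prob = wu))
        idx_list[[u]] <- rep(rows, alloc)
      }
    }
    idx <- unlist(idx_list)
    if (!length(idx)) stop("all quotas are zero", call. = FALSE)
  }

  out <- data.frame(
    gender = table$gender[idx],
    age_group = table$age_group[idx],
    unit = table$unit[idx]
  )
  out$active <- stats::rbinom(length(idx), 1L, theta[idx])
  out
}
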