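#' Split-sample cross-validation design
#'
#' Configures the cross-validation experiment that compares the MRP and
#' complete-pooling estimators. Half the survey defines the per-unit
#' baseline ("true") proportions via disaggregation; from the other half,
#' random subsamples at each fraction are drawn Q times, both models are
#' fitted to each subsample, and per-unit estimates are scored by absolute
#' error against the baseline.
#'
#' The \code{"reference"} profile uses the reference design: fractions
#' 2.5%, 10%, 25%, 50% of the estimation pool and Q = 300 replicates. The
#' \code{"test"} profile (fractions 2.5% and 10%, Q = 25, fast sampler
#' settings) keeps desk-scale runtime.
#'
#' Per-replicate child seeds are derived from the master seed by the fixed
#' counter rule \code{(seed \%\% 100000) * 10007 + fraction_index * 1000 + q},
#' so any single replicate can be re-run in isolation.
#'
#' @param profile \code{"reference"} or \code{"test"}; explicit arguments
#'   override the profile.
#' @param fractions subsample proportions of the estimation pool, in (0, 1].
#' @param n_reps number of replicate subsamples Q per fraction.
#' @param seed master seed.
#' @param control [mrp_control()] used for every model fit.
#' @param refit_split if \code{TRUE}, a fresh baseline/pool split is drawn
#'   for every replicate instead of one fixed split (the fixed split is the
#'   reference design).
#' @return An object of class \code{"cv_design"}.
#' @export
cv_design <- function(profile = c("reference", "test"), fractions = NULL,
                      n_reps = NULL, seed = 1L, control = NULL,
                      refit_split = FALSE) {
  profile <- match.arg(profile)
  if (is.null(fractions)) {
    fractions <- if (profile == "reference") c(0.025, 0.10, 0.25, 0.50)
                 else c(0.025, 0.10)
  }
  if (is.null(n_reps)) n_reps <- if (profile == "reference") 300L else 25L
  if (is.null(control)) control <- mrp_control(profile)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  structure(
    list(fractions = fractions, n_reps = as.integer(n_reps),
         seed = as.integer(seed), control = control,
         refit_split = refit_split, profile = profile),
    class = "cv_design"
  )
}

child_seed <- function(master, fraction_index, q) {
  (master %% 100000L) * 10007L + fraction_index * 1000L + q
}

#' Randomly split a survey into a baseline half and an estimation pool
#'
#' Uniform random partition into two disjoint halves (sizes differ by at
#' most one row); deterministic given the seed. The baseline half defines
#' the disaggregated "true" proportions; subsamples for estimation are drawn
#' from the pool.
#'
#' @param data survey data frame with >= 2 rows.
#' @param seed integer seed.
#' @return A list of class \code{"cv_split"} with elements \code{baseline},
#'   \code{pool}, \code{seed}.
#' @export
split_baseline <- function(data, seed = 1L) {
  n <- nrow(data)
  if (is.null(n) || n < 2) {
    stop("need at least 2 rows to split", call. = FALSE)
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n_base <- n %/% 2L
  structure(
    list(baseline = data[sort(perm[seq_len(n_base)]), , drop = FALSE],
         pool = data[sort(perm[(n_base + 1L):n]), , drop = FALSE],
         seed = as.integer(seed)),
    class = "cv_split"
  )
}

#' Per-unit absolute errors of estimates against a baseline
#'
#' @param estimates named numeric vector of per-unit estimated proportions.
#' @param baseline named numeric vector of per-unit baseline proportions;
#'   must cover exactly the same units.
#' @return Named vector |estimate - baseline|, in the baseline's unit order.
#' @export
abs_error <- function(estimates, baseline) {
  if (is.null(names(estimates)) || is.null(names(baseline)) ||
      !setequal(names(estimates), names(baseline))) {
    stop("estimates and baseline must be named over the same units",
         call. = FALSE)
  }
  abs(estimates[names(baseline)] - baseline)
}

#' Mean absolute error summaries of a replicate-by-unit error matrix
#'
#' \code{mae_by_unit} averages each unit's errors across replicates (column
#' means); \code{overall_mae} averages over every replicate and unit (grand
#' mean), collapsing the experiment to one number per method and fraction.
#'
#' @param errors a Q x n_unit numeric matrix of absolute errors.
#' @return \code{mae_by_unit}: named per-unit means; \code{overall_mae}: a
#'   single number.
#' @export
mae_by_unit <- function(errors) {
  if (!length(errors)) stop("empty error matrix", call. = FALSE)
  colMeans(as.matrix(errors))
}

#' @rdname mae_by_unit
#' @export
overall_mae <- function(errors) {
  if (!length(errors)) stop("empty error matrix", call. = FALSE)
  mean(as.matrix(errors))
}

#' Run the split-sample cross-validation experiment
#'
#' Executes the full design: split, repeated subsampling, fitting both the
#' multilevel (MRP) and single-level models on every subsample, per-unit
#' poststratification against the census table, and absolute-error scoring
#' versus the baseline half's disaggregated proportions. Both methods are
#' aggregated with identical census weighting, so the comparison isolates
#' the modelling difference (partial vs complete pooling). Point estimates
#' entering the errors are posterior means.
#'
#' Units absent from the baseline half are excluded from scoring (with a
#' notice). Replicates whose fit fails the split-R-hat gate are flagged in
#' \code{convergence} but still scored.
#'
#' @param data survey data frame.
#' @param table a \code{"poststrat_table"} for poststratification.
#' @param design a [cv_design()].
#' @param spec a [factor_spec()]; defaults to the table's.
#' @return An object of class \code{"mrp_cv"}: \describe{
#'   \item{errors}{nested list \code{[[method]][[fraction]]} of Q x n_unit
#'     absolute-error matrices}
#'   \item{widths}{matching matrices of per-unit 90% credible-interval
#'     widths}
#'   \item{mae_unit, mae_overall}{data-frame summaries (exact re-aggregations
#'     of \code{errors})}
#'   \item{baseline}{per-unit baseline proportions}
#'   \item{convergence, subsample_sizes, design}{bookkeeping}}
#' @export
run_cv <- function(data, table, design = cv_design("test"),
                   spec = attr(table, "spec")) {
  stopifnot(inherits(design, "cv_design"),
            inherits(table, "poststrat_table"))
  data <- align_factors(data, spec)
  if (nlevels(droplevels(data$unit)) < 2) {
    stop("cross-validation needs data covering at least 2 units",
         call. = FALSE)
  }
  methods <- c("MRP", "single_level")
  frac_lab <- format_fraction(design$fractions)

  split0 <- split_baseline(data, design$seed)
  base0 <- baseline_props(split0$baseline, spec)

  units_all <- spec$unit
  Q <- design$n_reps
  empty_mats <- function() {
    m <- lapply(frac_lab, function(f)
      matrix(NA_real_, Q, length(units_all),
             dimnames = list(NULL, units_all)))
    stats::setNames(m, frac_lab)
  }
  errors <- list(MRP = empty_mats(), single_level = empty_mats())
  widths <- list(MRP = empty_mats(), single_level = empty_mats())
  converged <- list(MRP = empty_mats(), single_level = empty_mats())
  sizes <- matrix(NA_integer_, Q, length(frac_lab),
                  dimnames = list(NULL, frac_lab))

  for (fi in seq_along(design$fractions)) {
    for (q in seq_len(Q)) {
      cs <- child_seed(design$seed, fi, q)
      if (design$refit_split) {
        spl <- split_baseline(data, cs + 499L)
        base <- baseline_props(spl$baseline, spec)
        pool <- spl$pool
      } else {
        base <- base0
        pool <- split0$pool
      }
      m <- max(1L, round(design$fractions[fi] * nrow(pool)))
      set.seed(cs)
      sub <- pool[sample.int(nrow(pool), m), , drop = FALSE]
      sizes[q, fi] <- m

      for (meth in methods) {
        ctl <- design$control
        ctl$seed <- cs + if (meth == "MRP") 0L else 1L
        fit <- suppressWarnings(mrp_fit(
          sub, spec,
          model = if (meth == "MRP") "multilevel" else "single_level",
          control = ctl))
        est <- poststratify(fit, table, by = "unit", level = 0.90)
        v <- stats::setNames(est$mean, as.character(est$unit))
        w <- stats::setNames(est$upper - est$lower, as.character(est$unit))
        scored <- names(base)
        errors[[meth]][[fi]][q, scored] <-
          abs_error(v[scored], base)
        widths[[meth]][[fi]][q, names(w)] <- w
        converged[[meth]][[fi]][q, 1] <- fit$diagnostics$converged
      }
    }
  }

  # drop units never scored (absent from baseline)
  scored_units <- names(base0)
  if (design$refit_split) {
    complete <- Reduce(`&`, lapply(methods, function(meth)
      Reduce(`&`, lapply(errors[[meth]], function(m) !colSums(is.na(m))))))
    scored_units <- intersect(scored_units, units_all[complete])
  }
  dropped <- setdiff(units_all, scored_units)
  if (length(dropped)) {
    message("run_cv: unit(s) absent from baseline excluded from scoring: ",
            paste(dropped, collapse = ", "))
  }
  for (meth in methods) {
    for (f in frac_lab) {
      errors[[meth]][[f]] <- errors[[meth]][[f]][, scored_units, drop = FALSE]
    }
  }

  mae_unit <- do.call(rbind, lapply(methods, function(meth) {
    do.call(rbind, lapply(frac_lab, function(f) {
      data.frame(method = meth, fraction = f,
                 unit = scored_units,
                 mae = as.numeric(mae_by_unit(errors[[meth]][[f]])),
                 row.names = NULL)
    }))
  }))
  mae_overall <- do.call(rbind, lapply(methods, function(meth) {
    do.call(rbind, lapply(seq_along(frac_lab), function(fi) {
      data.frame(method = meth, fraction = frac_lab[fi],
                 mae = overall_mae(errors[[meth]][[fi]]),
                 row.names = NULL)
    }))
  }))

  structure(
    list(errors = errors, widths = widths, mae_unit = mae_unit,
         mae_overall = mae_overall, baseline = base0,
         convergence = lapply(converged, function(x)
           vapply(x, function(m) mean(m[, 1]), numeric(1))),
         subsample_sizes = sizes, design = design,
         scored_units = scored_units),
    class = "mrp_cv"
  )
}

baseline_props <- function(baseline_half, spec) {
  dis <- suppressMessages(disaggregate(baseline_half, by = "unit"))
  stats::setNames(dis$prop, as.character(dis$unit))
}

format_fraction <- function(f) sprintf("%g%%", 100 * f)

#' @export
print.mrp_cv <- function(x, ...) {
  cat("Split-sample cross-validation: MRP vs single-level regression\n")
  cat(sprintf("  %d replicates x %d fraction(s); %d scored units\n",
              x$design$n_reps, length(x$design$fractions),
              length(x$scored_units)))
  wide <- stats::reshape(x$mae_overall, idvar = "method",
                         timevar = "fraction", direction = "wide")
  names(wide) <- sub("^mae\\.", "MAE @ ", names(wide))
  print.data.frame(wide, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mrp_cv <- function(object, ...) {
  list(mae_overall = object$mae_overall, mae_unit = object$mae_unit,
       convergence_rate = object$convergence)
}

#' Plot overall MAE against subsample fraction for both methods
#'
#' @param x an \code{"mrp_cv"} result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mrp_cv <- function(x, ...) {
  fr <- x$design$fractions
  m <- matrix(x$mae_overall$mae, nrow = length(fr))
  graphics::matplot(fr, m, type = "b", pch = 19, lty = 1,
                    xlab = "subsample fraction of estimation pool",
                    ylab = "overall mean absolute error", ...)
  graphics::legend("topright", legend = unique(x$mae_overall$method),
                   col = seq_len(ncol(m)), lty = 1, pch = 19, bty = "n")
  invisible(x)
}
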