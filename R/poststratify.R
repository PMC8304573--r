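#' Census-weighted subpopulation estimates (poststratification)
#'
#' The aggregation stage of MRP: within each group defined by a subset of
#' the factors, every posterior draw's cell probabilities are averaged with
#' census population weights, y_group = sum(N_c * theta_c) / sum(N_c) over
#' the group's cells. The per-draw group values are then summarized by their
#' mean and a central credible interval. Aggregating per draw (rather than
#' aggregating posterior summaries) propagates uncertainty correctly.
#'
#' @param x an \code{"mrp_fit"} or an \code{"mrp_cellpred"} matrix.
#' @param table a \code{"poststrat_table"} giving the cell counts N_c.
#' @param by character subset of \code{c("gender", "age_group", "unit")};
#'   \code{character(0)} gives the single population-wide estimate.
#'   Grouping by \code{"unit"} yields the per-capital estimates; grouping by
#'   all three factors yields one estimate per poststratification cell.
#' @param level central credible-interval level (default 0.90).
#' @param ... passed between methods.
#' @return A data frame of class \code{"subpop_estimates"}: grouping
#'   columns, posterior \code{mean}, interval bounds \code{lower} and
#'   \code{upper}, and group \code{population}.
#' @examples
#' spec <- factor_spec(2, 2, 3)
#' tab <- make_census(spec, counts = 100, seed = 1)
#' tr <- draw_true_params(spec, seed = 1)
#' poststratify(true_cell_probs(tr), tab, by = "unit")
#' @export
poststratify <- function(x, ...) UseMethod("poststratify")

#' @rdname poststratify
#' @export
poststratify.mrp_fit <- function(x, table, by = "unit", level = 0.90, ...) {
  poststratify(predict(x, table), table, by = by, level = level)
}

#' @rdname poststratify
#' @export
poststratify.mrp_cellpred <- function(x, table, by = "unit", level = 0.90,
                                      ...) {
  stopifnot(inherits(table, "poststrat_table"))
  by <- check_group_by(by)
  cells <- attr(x, "cells")
  if (!identical(cell_key(cells), cell_key(table))) {
    stop("cell order of predictions does not match the census table",
         call. = FALSE)
  }
  if (length(by) == 0L) {
    key <- factor(rep("all", nrow(table)))
    groups <- data.frame(row.names = 1L)
  } else {
    key <- interaction(table[by], drop = FALSE, lex.order = TRUE)
    groups <- unique(table[by])
    groups <- groups[order(interaction(groups, lex.order = TRUE)), ,
                     drop = FALSE]
  }
  pop <- tapply(table$count, key, sum)
  if (any(pop == 0)) {
    stop("group(s) with zero population: ",
         paste(names(pop)[pop == 0], collapse = ", "), call. = FALSE)
  }
  # C x G normalized weight matrix, then one matrix product for all draws
  G <- nlevels(key)
  W <- matrix(0, ncol(x), G)
  W[cbind(seq_len(ncol(x)), as.integer(key))] <- table$count
  W <- sweep(W, 2, colSums(W), "/")
  per_draw <- unclass(x) %*% W   # draws x groups

  sums <- t(apply(per_draw, 2, summarize_draws, level = level))
  out <- data.frame(groups, row.names = NULL)
  out$mean <- sums[, 1]
  out$lower <- sums[, 2]
  out$upper <- sums[, 3]
  out$population <- as.integer(pop)
  structure(out, level = level, per_draw = per_draw,
            class = c("subpop_estimates", "data.frame"))
}

#' Summarize a vector of posterior draws
#'
#' Arithmetic mean and central quantile interval. Quantiles use R's default
#' type-7 rule (linear interpolation between order statistics); this rule is
#' pinned so results are reproducible across implementations.
#'
#' @param values numeric vector of draws (length >= 1).
#' @param level interval level in (0, 1).
#' @return Named numeric vector \code{c(mean, lower, upper)}.
#' @export
summarize_draws <- function(values, level = 0.90) {
  if (!length(values)) stop("no draws to summarize", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  qs <- stats::quantile(values, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7, names = FALSE)
  c(mean = mean(values), lower = qs[1], upper = qs[2])
}

#' Disaggregated (no-pooling) group proportions
#'
#' The empirical proportion of positive outcomes per group, using only that
#' group's respondents — the "no pooling" estimator. In the cross-validation
#' design these proportions, computed on the held-out baseline half, define
#' the estimation target. Groups with no respondents are omitted from the
#' output (a notice reports how many).
#'
#' @param data survey data frame (\code{gender}, \code{age_group},
#'   \code{unit}, \code{active}).
#' @param by character subset of \code{c("gender", "age_group", "unit")}.
#' @return A data frame of class \code{"disagg_estimates"}: grouping
#'   columns, empirical \code{prop}, respondent count \code{n}.
#' @export
disaggregate <- function(data, by = "unit") {
  by <- check_group_by(by)
  if (!nrow(data)) stop("survey data is empty", call. = FALSE)
  if (length(by) == 0L) {
    out <- data.frame(prop = mean(data$active), n = nrow(data))
    return(structure(out, class = c("disagg_estimates", "data.frame")))
  }
  out <- stats::aggregate(list(prop = data$active), by = data[by], FUN = mean)
  out$n <- stats::aggregate(list(n = data$active), by = data[by],
                            FUN = length)$n
  # deterministic order: first grouping factor slowest
  out <- out[do.call(order, out[by]), , drop = FALSE]
  row.names(out) <- NULL
  n_empty <- prod(vapply(data[by], nlevels, integer(1))) - nrow(out)
  if (n_empty > 0) {
    message(sprintf("disaggregate: %d group(s) with no respondents omitted",
                    n_empty))
  }
  structure(out, class = c("disagg_estimates", "data.frame"))
}

#' @export
print.subpop_estimates <- function(x, digits = 4, ...) {
  lev <- attr(x, "level")
  cat(sprintf("Poststratified subpopulation estimates (%d%% credible intervals)\n",
              round(100 * lev)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot subpopulation estimates with credible intervals
#'
#' @param x a \code{"subpop_estimates"} data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.subpop_estimates <- function(x, ...) {
  idx <- seq_len(nrow(x))
  graphics::plot(idx, x$mean, ylim = range(x$lower, x$upper),
                 xlab = "group", ylab = "estimated proportion",
                 pch = 19, ...)
  graphics::segments(idx, x$lower, idx, x$upper)
  invisible(x)
}
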