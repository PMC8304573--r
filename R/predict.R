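# Cell-prediction container: draws x cells probability matrix with the
# canonical cell grid attached.
new_cellpred <- function(theta, cells, spec) {
  stopifnot(is.matrix(theta), ncol(theta) == nrow(cells))
  structure(theta, cells = cells, spec = spec,
            class = c("mrp_cellpred", "matrix", "array"))
}

#' @export
print.mrp_cellpred <- function(x, ...) {
  cat(sprintf("Cell predictions: %d posterior draw(s) x %d cells\n",
              nrow(x), ncol(x)))
  cat(sprintf("  theta range: [%.4f, %.4f]\n", min(x), max(x)))
  invisible(x)
}

# Expand an mrp_fit's draws into full per-level effect matrices
# (reference levels as zero columns), draws x levels.
fit_effects <- function(fit) {
  spec <- fit$spec
  d <- fit$draws
  n_draws <- nrow(d)
  grab <- function(prefix, levels) {
    m <- matrix(0, n_draws, length(levels),
                dimnames = list(NULL, levels))
    for (i in seq_along(levels)) {
      col <- paste0(prefix, levels[i])
      if (col %in% colnames(d)) m[, i] <- d[, col]
    }
    m
  }
  list(
    intercept_draws = d[, "(Intercept)"],
    gender = grab("gender:", spec$gender),
    age = grab("age:", spec$age_group),
    unit = grab("unit:", spec$unit)
  )
}

#' Posterior cell probabilities for every poststratification cell
#'
#' The prediction stage of MRP: for every retained posterior draw and every
#' cell of the poststratification grid, evaluate
#' theta_c = inverse-logit(intercept + gender + age + unit effect).
#' Reference levels contribute exactly 0 to the linear predictor. The
#' returned columns follow the canonical [cell_grid()] order, so they align
#' with a [make_census()] table built from the same spec.
#'
#' @param object an [mrp_fit()] of either model kind.
#' @param table optional \code{"poststrat_table"}; if supplied, its spec is
#'   checked against the fit's.
#' @param ... unused.
#' @return A \code{"mrp_cellpred"} matrix, retained draws x cells, all
#'   entries strictly in (0, 1).
#' @export
predict.mrp_fit <- function(object, table = NULL, ...) {
  spec <- object$spec
  if (!is.null(table)) {
    tspec <- attr(table, "spec")
    if (!identical(unclass(tspec), unclass(spec))) {
      stop("poststratification table's factor spec does not match the fit",
           call. = FALSE)
    }
  }
  grid <- cell_grid(spec)
  eff <- fit_effects(object)
  lp <- eff$intercept_draws +
    eff$gender[, as.integer(grid$gender), drop = FALSE] +
    eff$age[, as.integer(grid$age_group), drop = FALSE] +
    eff$unit[, as.integer(grid$unit), drop = FALSE]
  theta <- stats::plogis(lp)
  colnames(theta) <- cell_key(grid)
  new_cellpred(theta, grid, spec)
}
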