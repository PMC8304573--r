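#' Define the demographic-geographic factor structure
#'
#' A factor specification fixes the levels of the three adjustment variables
#' used throughout the package: gender, age group, and geographic unit
#' (state capital in the motivating survey). Every survey dataset,
#' poststratification table, and model fit refers to one of these.
#'
#' @param gender character vector of gender labels, or a single integer count
#'   (labels are then generated).
#' @param age_group character vector of age-group labels, or an integer count.
#' @param unit character vector of geographic-unit labels, or an integer count.
#' @return An object of class \code{"factor_spec"}: a named list of label
#'   vectors with components \code{gender}, \code{age_group}, \code{unit}.
#' @examples
#' factor_spec(2, 7, 27)        # the default survey shape: 378 cells
#' factor_spec(c("m", "f"), 3, 5)
#' @seealso [vigitel_spec()] for the 2 x 7 x 27 default, [cell_grid()] for the
#'   canonical cell ordering.
#' @export
factor_spec <- function(gender = 2L, age_group = 7L, unit = 27L) {
  expand <- function(x, prefix) {
    if (is.numeric(x) && length(x) == 1L) {
      if (x < 1 || x != round(x)) {
        stop("factor level counts must be positive integers", call. = FALSE)
      }
      sprintf("%s%02d", prefix, seq_len(x))
    } else if (is.character(x) && length(x) >= 1L) {
      x
    } else {
      stop("factor levels must be a count or a character vector", call. = FALSE)
    }
  }
  spec <- list(
    gender = expand(gender, "gender"),
    age_group = expand(age_group, "age"),
    unit = expand(unit, "unit")
  )
  for (nm in names(spec)) {
    if (anyDuplicated(spec[[nm]])) {
      stop("duplicate levels in factor '", nm, "'", call. = FALSE)
    }
  }
  structure(spec, class = "factor_spec")
}

#' Default survey-shaped factor specification
#'
#' The 2 gender x 7 age-group x 27 geographic-unit layout of the motivating
#' national telephone survey (VIGITEL, sampled per Brazilian state capital),
#' giving the 378-cell poststratification grid. The survey questionnaire bins
#' age into six groups with an open-ended top bin; the modelled grid uses
#' seven, splitting the top bin, so the default labels do the same.
#'
#' @param age_labels optional length-7 character vector overriding the default
#'   age-bin labels (the definition of the top bins is a modelling choice).
#' @return A \code{"factor_spec"} with 2 x 7 x 27 levels.
#' @export
vigitel_spec <- function(age_labels = NULL) {
  if (is.null(age_labels)) {
    age_labels <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
  }
  stopifnot(length(age_labels) == 7L)
  factor_spec(
    gender = c("male", "female"),
    age_group = age_labels,
    unit = sprintf("capital%02d", 1:27)
  )
}

n_levels <- function(spec) {
  vapply(spec, length, integer(1))
}

#' Canonical poststratification cell grid
#'
#' Enumerates every gender x age-group x unit combination in the package's
#' canonical order (gender varying fastest, unit slowest). All cell-indexed
#' objects (poststratification tables, cell-prediction matrices) follow this
#' order, so row \code{c} always refers to the same cell.
#'
#' @param spec a [factor_spec()].
#' @return A data frame with factor columns \code{gender}, \code{age_group},
#'   \code{unit}; one row per cell.
#' @export
cell_grid <- function(spec) {
  stopifnot(inherits(spec, "factor_spec"))
  g <- expand.grid(
    gender = factor(spec$gender, levels = spec$gender),
    age_group = factor(spec$age_group, levels = spec$age_group),
    unit = factor(spec$unit, levels = spec$unit),
    KEEP.OUT.ATTRS = FALSE
  )
  g
}

cell_key <- function(cells) {
  paste(cells$gender, cells$age_group, cells$unit, sep = "|")
}

#' @export
print.factor_spec <- function(x, ...) {
  n <- n_levels(x)
  cat(sprintf(
    "Factor specification: %d gender x %d age-group x %d unit levels (%d cells)\n",
    n["gender"], n["age_group"], n["unit"], prod(n)
  ))
  invisible(x)
}

# Coerce a survey data frame's columns to the spec's factor levels,
# failing loudly (with the offending row) on labels outside the spec.
align_factors <- function(data, spec, outcome = "active") {
  need <- c("gender", "age_group", "unit", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("survey data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("gender", "age_group", "unit")) {
    vals <- as.character(data[[nm]])
    bad <- which(!vals %in% spec[[nm]])
    if (length(bad)) {
      stop(sprintf("unknown %s label '%s' at row %d", nm, vals[bad[1]], bad[1]),
           call. = FALSE)
    }
    data[[nm]] <- factor(vals, levels = spec[[nm]])
  }
  y <- data[[outcome]]
  if (!all(y %in% c(0L, 1L))) {
    bad <- which(!y %in% c(0L, 1L))[1]
    stop(sprintf("outcome must be 0/1; found '%s' at row %d", y[bad], bad),
         call. = FALSE)
  }
  data[[outcome]] <- as.integer(y)
  data
}
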