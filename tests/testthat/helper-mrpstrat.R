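# Shared fixtures, built in code.

small_spec <- function() factor_spec(2, 3, 5)

fast_control <- function(seed = 1L, ...) {
  mrp_control("test", seed = seed, ...)
}

# Ground-truth parameter object with explicitly chosen effects (the
# generator draws them; tests sometimes need exact values).
manual_truth <- function(spec, intercept = 0,
                         gender_effects = rep(0, length(spec$gender)),
                         age_effects = rep(0, length(spec$age_group)),
                         unit_effects = rep(0, length(spec$unit)),
                         unit_sd = 0) {
  structure(
    list(intercept = intercept,
         gender_effects = stats::setNames(gender_effects, spec$gender),
         age_effects = stats::setNames(age_effects, spec$age_group),
         unit_effects = stats::setNames(unit_effects, spec$unit),
         unit_sd = unit_sd, seed = NA_integer_, spec = spec),
    class = "true_params"
  )
}

# Hand-built posterior "fit" whose draws are fully specified, for
# closed-form prediction checks. `effects` is a named list of draw vectors,
# e.g. list(`(Intercept)` = 0, `gender:male` = 1.2).
manual_fit <- function(spec, effects, model = "multilevel") {
  n_draws <- max(vapply(effects, length, integer(1)))
  draws <- do.call(cbind, lapply(effects, rep_len, n_draws))
  colnames(draws) <- names(effects)
  structure(
    list(model = model, draws = draws, spec = spec,
         control = mrp_control("test"), nobs = 0L,
         diagnostics = list(rhat = NULL, converged = TRUE,
                            divergences = NA_integer_, notices = character())),
    class = "mrp_fit"
  )
}

# A quick simulated dataset + census on the small spec.
small_world <- function(seed = 1L, n = 2500, unit_sd = 0.4) {
  spec <- small_spec()
  tab <- make_census(spec, counts = 1000, seed = seed)
  truth <- draw_true_params(spec, unit_sd = unit_sd, seed = seed + 1L)
  svy <- simulate_survey(truth, tab, n = n, seed = seed + 2L)
  list(spec = spec, table = tab, truth = truth, survey = svy)
}
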