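test_that("retained draw count is chains x (iterations - warmup) for both models", {
  w <- small_world(n = 600)
  ctl <- mrp_control(chains = 2, iterations = 60, warmup = 30, seed = 1)
  for (model in c("multilevel", "single_level")) {
    fit <- suppressWarnings(mrp_fit(w$survey, w$spec, model = model,
                                    control = ctl))
    expect_equal(nrow(fit$draws), 2 * 30)
    expect_true(all(is.finite(fit$draws)))
    if (model == "multilevel") {
      expect_true(all(fit$draws[, "sigma_unit"] > 0))
    }
  }
})

test_that("sampler seeds near the 32-bit limit are handled", {
  w <- small_world(n = 300)
  ctl <- mrp_control(chains = 1, iterations = 40, warmup = 20,
                     seed = 2100000000L)
  fit <- suppressWarnings(mrp_fit(w$survey, w$spec, control = ctl))
  expect_equal(nrow(fit$draws), 20)
})

test_that("control validation rejects inconsistent sampler settings", {
  expect_error(mrp_control(warmup = 500, iterations = 500), "warmup")
  expect_error(mrp_control(prior_scale = 0), "positive")
  expect_error(mrp_control(chains = 0), "chain")
})

test_that("fits are invariant to survey row order", {
  w <- small_world(n = 1200)
  ctl <- fast_control(seed = 8)
  f1 <- suppressWarnings(mrp_fit(w$survey, w$spec, control = ctl))
  shuffled <- w$survey[rev(seq_len(nrow(w$survey))), ]
  f2 <- suppressWarnings(mrp_fit(shuffled, w$spec, control = ctl))
  # aggregation to cells makes the likelihood literally identical
  expect_equal(f1$draws, f2$draws, tolerance = 1e-12)
})

test_that("null data leave single-level coefficients centred on zero", {
  spec <- small_spec()
  tab <- make_census(spec, counts = 2000, seed = 1)
  flat <- manual_truth(spec, intercept = 0)
  svy <- simulate_survey(flat, tab, n = 8000, seed = 14)
  fit <- suppressWarnings(
    mrp_fit(svy, spec, model = "single_level",
            control = mrp_control(chains = 2, iterations = 400, warmup = 200,
                                  seed = 2)))
  # with 7 null coefficients, individual 90% intervals miss zero ~10% of the
  # time by construction; require the wide intervals to always cover and the
  # 90% ones to cover in the clear majority
  s99 <- summary(fit, level = 0.99)
  coefs99 <- s99[s99$parameter != "(Intercept)", ]
  expect_true(all(coefs99$lower <= 0 & coefs99$upper >= 0))
  s90 <- summary(fit, level = 0.90)
  coefs90 <- s90[s90$parameter != "(Intercept)", ]
  expect_gte(mean(coefs90$lower <= 0 & coefs90$upper >= 0), 0.7)
})

test_that("a sparsely sampled unit is shrunk toward the mean (partial pooling)", {
  spec <- small_spec()
  tab <- make_census(spec, counts = 1000, seed = 2)
  truth <- draw_true_params(spec, unit_sd = 0.5, seed = 3)
  svy <- simulate_survey(
    truth, tab, scheme = sampling_scheme("quota", quota = c(5, 400, 400, 400, 400)),
    seed = 17)
  fit <- suppressWarnings(mrp_fit(svy, spec, control = fast_control(seed = 5)))

  p1 <- mean(svy$active[svy$unit == spec$unit[1]])
  p1 <- min(max(p1, 0.05), 0.95)   # keep the no-pooling logit finite
  no_pool_dev <- qlogis(p1) - qlogis(mean(svy$active))
  post_u1 <- mean(fit$draws[, paste0("unit:", spec$unit[1])])
  expect_lt(abs(post_u1), abs(no_pool_dev))
})

test_that("units with no data fall back to their prior", {
  spec <- small_spec()
  tab <- make_census(spec, counts = 1000, seed = 2)
  truth <- draw_true_params(spec, unit_sd = 0.4, seed = 3)
  # unit 2 gets no respondents (unit 1 is the single-level reference level,
  # whose contrast is fixed at zero, so it cannot carry a prior)
  svy <- simulate_survey(
    truth, tab, scheme = sampling_scheme("quota", quota = c(500, 0, 500, 500, 500)),
    seed = 19)
  ctl <- mrp_control(chains = 3, iterations = 700, warmup = 200, seed = 6)
  absent <- paste0("unit:", spec$unit[2])

  single <- suppressWarnings(
    mrp_fit(svy, spec, model = "single_level", control = ctl))
  # posterior for the absent unit's coefficient is essentially its prior
  expect_lt(abs(sd(single$draws[, absent]) - ctl$prior_scale),
            0.25 * ctl$prior_scale)

  multi <- suppressWarnings(mrp_fit(svy, spec, control = ctl))
  expect_lte(sd(multi$draws[, absent]),
             1.5 * mean(multi$draws[, "sigma_unit"]))
})

test_that("small-unit deviations are smaller under partial than complete pooling", {
  spec <- factor_spec(2, 3, 8)
  tab <- make_census(spec, counts = 800, seed = 4)
  truth <- draw_true_params(spec, unit_sd = 0.5, seed = 5)
  quota <- c(rep(8, 4), rep(400, 4))   # four units with n < 20
  svy <- simulate_survey(truth, tab,
                         scheme = sampling_scheme("quota", quota = quota),
                         seed = 23)
  ctl <- mrp_control(chains = 2, iterations = 500, warmup = 250, seed = 7)
  multi <- suppressWarnings(mrp_fit(svy, spec, control = ctl))
  single <- suppressWarnings(mrp_fit(svy, spec, model = "single_level",
                                     control = ctl))
  small_units <- paste0("unit:", spec$unit[1:4])
  # compare centred deviations: single-level contrasts are relative to the
  # reference unit, multilevel deviations to the global intercept
  eff_m <- colMeans(multi$draws[, small_units])
  eff_s_all <- mrpstrat:::fit_effects(single)$unit
  eff_s <- colMeans(eff_s_all) - mean(colMeans(eff_s_all))
  expect_lt(mean(abs(eff_m - mean(eff_m))),
            mean(abs(eff_s[1:4])))
})

test_that("a degenerate all-identical outcome still yields a proper fit", {
  spec <- small_spec()
  svy <- data.frame(
    gender = spec$gender[1], age_group = spec$age_group[1],
    unit = rep(spec$unit, each = 10), active = 1L)
  expect_message(
    fit <- suppressWarnings(mrp_fit(svy, spec, control = fast_control())),
    "identical")
  expect_true(all(is.finite(fit$draws)))
})

test_that("cell predictions follow the closed-form inverse-logit link", {
  spec <- vigitel_spec()
  null_fit <- manual_fit(spec, list(`(Intercept)` = 0))
  pr <- predict(null_fit)
  expect_equal(dim(pr), c(1, 378))
  expect_true(all(as.numeric(pr) == 0.5))

  fit <- manual_fit(spec, list(`(Intercept)` = 0, `gender:male` = 1.2))
  th <- predict(fit)
  male <- attr(th, "cells")$gender == "male"
  expect_equal(round(unique(as.numeric(th)[male]), 4), 0.7685)
  expect_equal(unique(as.numeric(th)[!male]), 0.5)
})

test_that("cell predictions match an independent per-cell recomputation", {
  spec <- factor_spec(2, 3, 4)
  set.seed(99)
  n_draws <- 7
  effects <- c(
    list(`(Intercept)` = rnorm(n_draws)),
    setNames(lapply(spec$gender[-1], function(x) rnorm(n_draws)),
             paste0("gender:", spec$gender[-1])),
    setNames(lapply(spec$age_group[-1], function(x) rnorm(n_draws)),
             paste0("age:", spec$age_group[-1])),
    setNames(lapply(spec$unit, function(x) rnorm(n_draws)),
             paste0("unit:", spec$unit))
  )
  fit <- manual_fit(spec, effects)
  th <- predict(fit)
  grid <- cell_grid(spec)
  d <- fit$draws
  for (dr in seq_len(n_draws)) {
    for (cc in seq_len(nrow(grid))) {
      lp <- d[dr, "(Intercept)"]
      gcol <- paste0("gender:", grid$gender[cc])
      acol <- paste0("age:", grid$age_group[cc])
      ucol <- paste0("unit:", grid$unit[cc])
      if (gcol %in% colnames(d)) lp <- lp + d[dr, gcol]
      if (acol %in% colnames(d)) lp <- lp + d[dr, acol]
      if (ucol %in% colnames(d)) lp <- lp + d[dr, ucol]
      expect_equal(th[dr, cc], plogis(lp), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("prediction refuses a census table from a different spec", {
  w <- small_world(n = 500)
  fit <- suppressWarnings(mrp_fit(w$survey, w$spec, control = fast_control()))
  other <- make_census(factor_spec(2, 3, 6), counts = 10, seed = 1)
  expect_error(predict(fit, other), "spec")
})

test_that("simulate and residuals methods are coherent with the fit", {
  w <- small_world(n = 1500)
  fit <- suppressWarnings(mrp_fit(w$survey, w$spec, control = fast_control()))
  sims <- simulate(fit, nsim = 3, seed = 1, newdata = w$survey)
  expect_length(sims, 3)
  expect_true(all(vapply(sims, function(s) all(s %in% 0:1), logical(1))))

  res <- residuals(fit, w$survey)
  expect_true(all(is.finite(res$pearson)))
  expect_lt(mean(abs(res$pearson)), 2)  # posterior-mean fit tracks the cells
})
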