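test_that("census tables cover the full factor grid with the requested counts", {
  tab <- make_census(factor_spec(2, 7, 27), counts = 100, seed = 1)
  expect_equal(nrow(tab), 378)
  expect_equal(sum(tab$count), 37800)

  # arbitrary spec sizes
  for (dims in list(c(1, 1, 2), c(3, 2, 4))) {
    spec <- factor_spec(dims[1], dims[2], dims[3])
    expect_equal(nrow(make_census(spec, seed = 3)), prod(dims))
  }
})

test_that("census generation is deterministic given the seed", {
  spec <- small_spec()
  expect_identical(make_census(spec, seed = 42), make_census(spec, seed = 42))
  expect_false(identical(make_census(spec, seed = 42)$count,
                         make_census(spec, seed = 43)$count))
})

test_that("explicit cell counts give the expected population shares", {
  spec <- factor_spec(1, 1, 2)
  tab <- make_census(spec, counts = c(10, 30), seed = 1)
  shares <- tapply(tab$count, tab$unit, sum) / sum(tab$count)
  expect_equal(as.numeric(shares), c(0.25, 0.75))
})

test_that("degenerate truth parameters collapse as they should", {
  spec <- small_spec()
  tr0 <- draw_true_params(spec, unit_sd = 0, seed = 1)
  expect_true(all(tr0$unit_effects == 0))

  flat <- draw_true_params(spec, intercept = 0, gender_scale = 0,
                           age_scale = 0, unit_sd = 0, seed = 1)
  expect_true(all(as.numeric(true_cell_probs(flat)) == 0.5))
  expect_error(draw_true_params(spec, unit_sd = -1), "nonnegative")
})

test_that("generated unit effects follow the stated normal law", {
  spec <- factor_spec(2, 2, 10000)
  tr <- draw_true_params(spec, unit_sd = 0.5, seed = 7)
  expect_lt(abs(sd(tr$unit_effects) - 0.5) / 0.5, 0.02)
  expect_lt(abs(mean(tr$unit_effects)), 0.02)
})

test_that("true cell probabilities follow the inverse-logit closed form", {
  spec <- small_spec()
  tr <- manual_truth(spec, intercept = 1)
  expect_equal(as.numeric(true_cell_probs(tr)),
               rep(plogis(1), nrow(cell_grid(spec))), tolerance = 1e-12)
  expect_equal(round(as.numeric(true_cell_probs(tr))[1], 4), 0.7311)

  # raising one unit's effect raises exactly that unit's cells
  tr2 <- manual_truth(spec, intercept = 0.2)
  tr2$unit_effects[3] <- 0.8
  th1 <- as.numeric(true_cell_probs(manual_truth(spec, intercept = 0.2)))
  th2 <- as.numeric(true_cell_probs(tr2))
  in_unit3 <- as.integer(cell_grid(spec)$unit) == 3L
  expect_true(all(th2[in_unit3] > th1[in_unit3]))
  expect_equal(th2[!in_unit3], th1[!in_unit3])
})

test_that("true subpopulation proportions are census-weighted cell means", {
  spec <- factor_spec(1, 1, 2)
  tr <- manual_truth(spec, intercept = 0,
                     unit_effects = qlogis(c(0.2, 0.4)))
  tab <- make_census(spec, counts = c(100, 100), seed = 1)
  props <- true_subpop_props(tr, tab, by = character(0))
  expect_equal(props$prop, 0.3)

  # single-cell group returns that cell's probability exactly
  by_unit <- true_subpop_props(tr, tab, by = "unit")
  expect_equal(by_unit$prop, c(0.2, 0.4))
})

test_that("grouped true proportions match a brute-force loop over cells", {
  spec <- factor_spec(2, 3, 4)
  set.seed(11)
  tab <- make_census(spec, counts = function(n) sample(50:500, n, TRUE),
                     seed = 5)
  tr <- draw_true_params(spec, unit_sd = 0.6, seed = 6)
  theta <- as.numeric(true_cell_probs(tr))
  grid <- cell_grid(spec)

  for (by in list("unit", "gender", c("gender", "age_group"),
                  c("gender", "age_group", "unit"))) {
    got <- true_subpop_props(tr, tab, by = by)
    for (r in seq_len(nrow(got))) {
      sel <- rep(TRUE, nrow(grid))
      for (nm in by) sel <- sel & grid[[nm]] == got[[nm]][r]
      expect_equal(got$prop[r],
                   sum(tab$count[sel] * theta[sel]) / sum(tab$count[sel]))
      expect_equal(got$population[r], sum(tab$count[sel]))
    }
  }
})

test_that("conservation: group estimates re-aggregate to the global estimate", {
  w <- small_world(seed = 3)
  per_unit <- true_subpop_props(w$truth, w$table, by = "unit")
  overall <- true_subpop_props(w$truth, w$table, by = character(0))
  expect_equal(sum(per_unit$prop * per_unit$population) /
                 sum(per_unit$population),
               overall$prop)
})

test_that("simulated surveys honour sample size and outcome law extremes", {
  w <- small_world()
  svy <- simulate_survey(w$truth, w$table, n = 5000, seed = 9)
  expect_equal(nrow(svy), 5000)

  sure <- manual_truth(w$spec, intercept = 20)
  svy1 <- simulate_survey(sure, w$table, n = 300, seed = 9)
  expect_true(all(svy1$active == 1L))

  expect_identical(simulate_survey(w$truth, w$table, n = 200, seed = 4),
                   simulate_survey(w$truth, w$table, n = 200, seed = 4))
})

test_that("proportional sampling reproduces per-unit active shares", {
  w <- small_world(seed = 21)
  n <- 100000
  svy <- simulate_survey(w$truth, w$table, n = n, seed = 22)
  truth <- true_subpop_props(w$truth, w$table, by = "unit")
  emp <- tapply(svy$active, svy$unit, mean)
  n_u <- tapply(rep(1, n), svy$unit, sum)
  se <- sqrt(truth$prop * (1 - truth$prop) / n_u)
  expect_true(all(abs(emp - truth$prop) < 3 * se))
})

test_that("proportional sampling matches census cell frequencies (chi-square)", {
  w <- small_world(seed = 31)
  n <- 50000
  svy <- simulate_survey(w$truth, w$table, n = n, seed = 32)
  key <- factor(mrpstrat:::cell_key(svy[c("gender", "age_group", "unit")]),
                levels = mrpstrat:::cell_key(w$table))
  obs <- table(key)
  gof <- suppressWarnings(
    chisq.test(obs, p = w$table$count / sum(w$table$count)))
  expect_gt(gof$p.value, 0.001)
})

test_that("quota sampling fills each unit's quota from its cells", {
  spec <- small_spec()
  tab <- make_census(spec, counts = 200, seed = 2)
  tr <- draw_true_params(spec, seed = 3)
  svy <- simulate_survey(tr, tab, scheme = sampling_scheme("quota", quota = 40),
                         seed = 4)
  expect_equal(as.numeric(table(svy$unit)), rep(40, 5))

  # quota against an empty unit is a configuration error
  tab0 <- tab
  tab0$count[as.integer(tab0$unit) == 2L] <- 0L
  expect_error(
    simulate_survey(tr, tab0, scheme = sampling_scheme("quota", quota = 40),
                    seed = 4),
    "zero population")
})

test_that("multiplier schemes distort inclusion, not outcomes", {
  spec <- factor_spec(1, 1, 2)
  tab <- make_census(spec, counts = c(1000, 1000), seed = 1)
  tr <- manual_truth(spec, intercept = 0)
  m <- sampling_scheme("multiplier", multipliers = c(3, 1))
  svy <- simulate_survey(tr, tab, n = 20000, scheme = m, seed = 5)
  share1 <- mean(svy$unit == spec$unit[1])
  expect_gt(share1, 0.70)   # 3:1 inclusion odds -> expected share 0.75
  expect_lt(share1, 0.80)
  expect_error(sampling_scheme("multiplier", multipliers = c(1, -1)),
               "positive")
})
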