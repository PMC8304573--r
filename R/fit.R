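#' Sampler and prior configuration
#'
#' Bundles the priors and MCMC settings shared by both model kinds. The
#' defaults are the reference analysis settings: normal(0, 10) priors
#' (standard deviation 10) on all population-level coefficients, an
#' exponential(1) prior on the between-unit standard deviation, and three
#' chains of 500 iterations each with 250 discarded as warmup, retaining
#' 3 x 250 = 750 draws. The \code{"test"} profile trades Monte Carlo error
#' for speed (one chain, 400/200) and is intended for simulation studies
#' that refit the model hundreds of times.
#'
#' @param profile \code{"reference"} for the reference settings, \code{"test"}
#'   for the fast profile. Explicit arguments override the profile.
#' @param prior_scale standard deviation of the normal prior on
#'   population-level effects.
#' @param sd_prior_rate rate of the exponential prior on the group-level
#'   (between-unit) standard deviation.
#' @param chains number of MCMC chains.
#' @param iterations total iterations per chain (including warmup).
#' @param warmup warmup iterations per chain, discarded; must be
#'   < \code{iterations}.
#' @param seed integer seed for the sampler (per-chain RNG streams are
#'   derived from it).
#' @param rhat_max convergence gate: any parameter with split-R-hat above
#'   this triggers a warning and flags the fit (it is still returned).
#' @return An object of class \code{"mrp_control"}.
#' @export
mrp_control <- function(profile = c("reference", "test"), prior_scale = 10,
                        sd_prior_rate = 1, chains = NULL, iterations = NULL,
                        warmup = NULL, seed = 1L, rhat_max = 1.05) {
  profile <- match.arg(profile)
  def <- if (profile == "reference") c(3L, 500L, 250L) else c(1L, 400L, 200L)
  chains <- as.integer(if (is.null(chains)) def[1] else chains)
  iterations <- as.integer(if (is.null(iterations)) def[2] else iterations)
  warmup <- as.integer(if (is.null(warmup)) def[3] else warmup)
  if (prior_scale <= 0 || sd_prior_rate <= 0) {
    stop("prior scale and rate must be positive", call. = FALSE)
  }
  if (chains < 1) stop("need at least one chain", call. = FALSE)
  if (warmup >= iterations) {
    stop("warmup must be smaller than iterations", call. = FALSE)
  }
  structure(
    list(prior_scale = prior_scale, sd_prior_rate = sd_prior_rate,
         chains = chains, iterations = iterations, warmup = warmup,
         seed = as.integer(seed), rhat_max = rhat_max, profile = profile),
    class = "mrp_control"
  )
}

# JAGS model code. The likelihood is expressed per observed cell as a
# binomial on the aggregated counts -- identical to the row-wise Bernoulli
# likelihood but independent of survey row order and much cheaper.
jags_code <- function(model, J, K, L) {
  prior <- "prec_b"
  lines <- c(
    "model {",
    "  for (c in 1:C) {",
    "    y[c] ~ dbin(theta[c], n[c])",
    "    logit(theta[c]) <- b0 + bg[g[c]] + ba[a[c]] + bl[l[c]]",
    "  }",
    sprintf("  b0 ~ dnorm(0, %s)", prior),
    "  bg[1] <- 0",
    if (J > 1) sprintf("  for (j in 2:%d) { bg[j] ~ dnorm(0, %s) }", J, prior),
    "  ba[1] <- 0",
    if (K > 1) sprintf("  for (k in 2:%d) { ba[k] ~ dnorm(0, %s) }", K, prior)
  )
  if (model == "multilevel") {
    lines <- c(lines,
      sprintf("  for (s in 1:%d) { bl[s] ~ dnorm(0, tau_u) }", L),
      "  sigma_unit ~ dexp(rate_u)",
      "  tau_u <- pow(sigma_unit, -2)")
  } else {
    lines <- c(lines,
      "  bl[1] <- 0",
      if (L > 1) sprintf("  for (s in 2:%d) { bl[s] ~ dnorm(0, %s) }",
                         L, prior))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Fit a Bayesian logistic regression for MRP
#'
#' Fits one of two competing models for a binary survey outcome on the
#' gender x age-group x unit factor structure, by MCMC:
#' \describe{
#'   \item{\code{"multilevel"}}{partial pooling: intercept, gender, and age
#'     as population-level effects with normal(0, \code{prior_scale}) priors;
#'     geographic-unit intercepts as zero-mean group-level effects with
#'     standard deviation \code{sigma_unit ~ exponential(sd_prior_rate)}.
#'     This is the regression stage of MRP.}
#'   \item{\code{"single_level"}}{complete pooling: every factor, including
#'     unit, enters as dummy-coded population-level effects under the same
#'     normal prior; no variance component.}
#' }
#' The first level of each factor is the reference (coefficient fixed at 0);
#' multilevel unit effects are deviations around the global intercept.
#' Individual Bernoulli responses are aggregated to binomial counts per
#' observed cell before sampling, so fits are exactly invariant to the row
#' order of the survey data.
#'
#' Convergence is assessed by split-R-hat on every retained parameter; any
#' value above \code{control$rhat_max} raises a warning and sets
#' \code{fit$diagnostics$converged = FALSE}, but the fit is still returned.
#' A degenerate outcome (all responses identical) is legal: the priors keep
#' the posterior proper, and a notice is emitted.
#'
#' @param data survey data frame with columns \code{gender},
#'   \code{age_group}, \code{unit}, \code{active} (0/1).
#' @param spec a [factor_spec()]; levels present in \code{spec} but absent
#'   from \code{data} keep their prior.
#' @param model \code{"multilevel"} or \code{"single_level"}.
#' @param control an [mrp_control()].
#' @return An object of class \code{"mrp_fit"} with the retained posterior
#'   draws (matrix \code{chains x (iterations - warmup)} rows by parameter),
#'   the factor spec, and diagnostics (split-R-hat per parameter, convergence
#'   flag; divergence count is \code{NA}: the conditional samplers used here
#'   have no divergence concept).
#' @examples
#' \donttest{
#' spec <- factor_spec(2, 3, 5)
#' tab <- make_census(spec, counts = 1000, seed = 1)
#' tr <- draw_true_params(spec, seed = 2)
#' svy <- simulate_survey(tr, tab, n = 2000, seed = 3)
#' fit <- mrp_fit(svy, spec, control = mrp_control("test"))
#' fit
#' }
#' @seealso [predict.mrp_fit()], [poststratify()]
#' @export
mrp_fit <- function(data, spec, model = c("multilevel", "single_level"),
                    control = mrp_control()) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "factor_spec"), inherits(control, "mrp_control"))
  if (!nrow(data)) stop("survey data is empty", call. = FALSE)
  data <- align_factors(data, spec)
  nl <- n_levels(spec)
  J <- nl["gender"]; K <- nl["age_group"]; L <- nl["unit"]

  notices <- character(0)
  if (length(unique(data$active)) == 1L) {
    notices <- c(notices, "degenerate outcome: all responses identical")
    message("mrp_fit: all outcomes identical; priors regularize the fit")
  }

  # aggregate Bernoulli rows -> binomial cells
  g <- as.integer(data$gender); a <- as.integer(data$age_group)
  l <- as.integer(data$unit)
  cell <- (l - 1L) * (J * K) + (a - 1L) * J + g
  succ <- rowsum(data$active, cell)
  trials <- rowsum(rep(1L, nrow(data)), cell)
  ids <- as.integer(rownames(succ))
  gg <- ((ids - 1L) %% J) + 1L
  aa <- ((ids - 1L) %/% J) %% K + 1L
  ll <- (ids - 1L) %/% (J * K) + 1L

  jdata <- list(C = length(ids), y = as.vector(succ), n = as.vector(trials),
                g = gg, a = aa, l = ll,
                prec_b = 1 / control$prior_scale^2)
  if (model == "multilevel") jdata$rate_u <- control$sd_prior_rate

  inits <- lapply(seq_len(control$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(control$seed) * 97 + ch) %%
                                  2147483647))
  })
  monitors <- c("b0",
                if (J > 1) "bg", if (K > 1) "ba",
                "bl", if (model == "multilevel") "sigma_unit")

  jm <- suppress_adapt_warning(
    rjags::jags.model(textConnection(jags_code(model, J, K, L)),
                      data = jdata, inits = inits,
                      n.chains = control$chains,
                      n.adapt = control$warmup, quiet = TRUE)
  )
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = control$iterations - control$warmup,
                              progress.bar = "none")

  draws_by_chain <- lapply(samp, as.matrix)
  draws <- do.call(rbind, draws_by_chain)
  draws <- rename_draws(draws, model, spec)
  for (i in seq_along(draws_by_chain)) {
    draws_by_chain[[i]] <- rename_draws(draws_by_chain[[i]], model, spec)
  }

  rhat <- apply_split_rhat(draws_by_chain)
  converged <- all(is.na(rhat) | rhat <= control$rhat_max)
  if (!converged) {
    warning(sprintf(
      "possible non-convergence: max split-R-hat %.3f > %.2f (fit returned)",
      max(rhat, na.rm = TRUE), control$rhat_max), call. = FALSE)
  }

  structure(
    list(model = model, draws = draws, spec = spec, control = control,
         nobs = nrow(data),
         diagnostics = list(rhat = rhat, converged = converged,
                            divergences = NA_integer_, notices = notices),
         call = match.call()),
    class = "mrp_fit"
  )
}

suppress_adapt_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("[Aa]daptation incomplete", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# canonical parameter names: (Intercept), gender:<lvl>, age:<lvl>,
# unit:<lvl>, sigma_unit
rename_draws <- function(m, model, spec) {
  nl <- n_levels(spec)
  nm <- colnames(m)
  map <- character(length(nm))
  for (i in seq_along(nm)) {
    p <- nm[i]
    map[i] <- if (p == "b0") "(Intercept)"
    else if (p == "sigma_unit") "sigma_unit"
    else if (grepl("^bg\\[", p)) {
      paste0("gender:", spec$gender[idx_of(p)])
    } else if (grepl("^ba\\[", p)) {
      paste0("age:", spec$age_group[idx_of(p)])
    } else if (grepl("^bl\\[", p)) {
      paste0("unit:", spec$unit[idx_of(p)])
    } else p
  }
  colnames(m) <- map
  drop_ref <- c(paste0("gender:", spec$gender[1]),
                paste0("age:", spec$age_group[1]))
  if (model == "single_level") {
    drop_ref <- c(drop_ref, paste0("unit:", spec$unit[1]))
  }
  keep <- !(colnames(m) %in% drop_ref & apply(m == 0, 2, all))
  m[, keep, drop = FALSE]
}

idx_of <- function(p) as.integer(sub("^[a-z]+\\[(\\d+)\\]$", "\\1", p))

# Split-R-hat (each chain halved, then standard between/within ratio).
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    h <- n %/% 2
    if (h < 2) return(NA_real_)
    halves <- c(halves, list(ch[1:h]), list(ch[(n - h + 1):n]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

apply_split_rhat <- function(draws_by_chain) {
  params <- colnames(draws_by_chain[[1]])
  out <- vapply(params, function(p) {
    split_rhat(lapply(draws_by_chain, function(m) m[, p]))
  }, numeric(1))
  stats::setNames(out, params)
}

#' @export
print.mrp_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s logistic fit (MRP %s)\n",
              gsub("_", "-", x$model),
              if (x$model == "multilevel") "regression stage"
              else "complete-pooling comparator"))
  cat(sprintf("  %d respondents; %d retained draws (%d chain(s) x %d post-warmup)\n",
              x$nobs, nrow(x$draws), x$control$chains,
              x$control$iterations - x$control$warmup))
  cat(sprintf("  max split-R-hat: %.3f%s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              if (x$diagnostics$converged) "" else "  [CONVERGENCE FLAGGED]"))
  invisible(x)
}

#' @export
coef.mrp_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' Summarize an MRP model fit
#'
#' @param object an [mrp_fit()] object.
#' @param level central credible-interval level (default 0.90).
#' @param ... unused.
#' @return A data frame with posterior mean, SD, central interval bounds and
#'   split-R-hat per parameter.
#' @export
summary.mrp_fit <- function(object, level = 0.90, ...) {
  d <- object$draws
  qs <- apply(d, 2, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), type = 7)
  out <- data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    lower = qs[1, ],
    upper = qs[2, ],
    rhat = object$diagnostics$rhat[colnames(d)],
    row.names = NULL
  )
  attr(out, "level") <- level
  out
}

#' Posterior-predictive simulation of survey outcomes
#'
#' Draws replicate binary outcome vectors for the covariate rows of
#' \code{newdata} (default: cells of the canonical grid are not assumed --
#' the caller supplies respondent rows), using one posterior draw per
#' simulation.
#'
#' @param object an [mrp_fit()].
#' @param nsim number of replicate outcome vectors.
#' @param seed integer seed.
#' @param newdata data frame with \code{gender}, \code{age_group},
#'   \code{unit} columns.
#' @param ... unused.
#' @return A list of integer 0/1 vectors, one per simulation.
#' @export
simulate.mrp_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  nd <- align_factors_covariates(newdata, object$spec)
  eff <- fit_effects(object)
  lp_base <- eff$intercept_draws  # draws vector
  pick <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  lapply(pick, function(dr) {
    lp <- eff$intercept_draws[dr] +
      eff$gender[dr, as.integer(nd$gender)] +
      eff$age[dr, as.integer(nd$age_group)] +
      eff$unit[dr, as.integer(nd$unit)]
    stats::rbinom(nrow(nd), 1L, stats::plogis(lp))
  })
}

#' Pearson residuals at the posterior mean
#'
#' Residuals are defined on the aggregated cells actually observed:
#' (successes - trials * theta_hat) / sqrt(trials * theta_hat *
#' (1 - theta_hat)), with theta_hat the posterior-mean cell probability.
#'
#' @param object an [mrp_fit()].
#' @param data the survey data frame the model was fitted to.
#' @param ... unused.
#' @return A data frame of observed cells with counts and Pearson residuals.
#' @export
residuals.mrp_fit <- function(object, data, ...) {
  data <- align_factors(data, object$spec)
  key <- interaction(data$gender, data$age_group, data$unit, drop = TRUE)
  succ <- tapply(data$active, key, sum)
  trials <- tapply(rep(1L, nrow(data)), key, sum)
  first <- !duplicated(key)
  cells <- data[first, c("gender", "age_group", "unit")]
  cells <- cells[order(key[first]), , drop = FALSE]
  eff <- fit_effects(object)
  th <- stats::plogis(
    mean(eff$intercept_draws) +
      colMeans(eff$gender)[as.integer(cells$gender)] +
      colMeans(eff$age)[as.integer(cells$age_group)] +
      colMeans(eff$unit)[as.integer(cells$unit)]
  )
  out <- data.frame(cells, successes = as.integer(succ),
                    trials = as.integer(trials), row.names = NULL)
  out$pearson <- (out$successes - out$trials * th) /
    sqrt(pmax(out$trials * th * (1 - th), .Machine$double.eps))
  out
}

align_factors_covariates <- function(data, spec) {
  data$active <- 0L
  align_factors(data, spec)
}
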