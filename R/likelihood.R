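#' Log-likelihood of a trial table under a model
#'
#' For each condition the defective RT densities are computed once (two
#' forward solves per evaluation) and each trial contributes the log of its
#' branch density at its RT, evaluated by linear interpolation on the
#' solver grid. Densities are floored at `floor` before taking logs so that
#' exploratory optimizer candidates with zero predicted density yield a
#' finite (very poor) objective rather than `-Inf`.
#'
#' @param p A `cdm_parameters` object.
#' @param trials A trial table (see [read_trials()]); all RTs must lie
#'   within the solver horizon.
#' @param grids A [cdm_grids()] object (fitting convention:
#'   `dt = dx = 0.002`, seconds, `sigma = 1`).
#' @param floor Density floor before the log (default `1e-10`).
#' @return The summed log-likelihood (a single number).
#' @export
log_likelihood <- function(p, trials, grids = cdm_grids(),
                           floor = 1e-10) {
  obj <- make_loglik(trials, grids, floor = floor)
  obj(p)
}

# returns a closure p -> log-likelihood with per-dataset quantities
# (interpolation indices and weights) precomputed once
make_loglik <- function(trials, grids, floor = 1e-10) {
  validate_trials(trials)
  if (nrow(trials) == 0) stop_config("trial table is empty")
  bad <- trials$rt_s > grids$t_max
  if (any(bad))
    stop_config("%d trial RT(s) exceed the horizon t_max = %g (max rt %.3f)",
                sum(bad), grids$t_max, max(trials$rt_s))
  # the forward solution up to time T does not depend on the horizon, so
  # the likelihood grid can stop just past the slowest trial: identical
  # density values at every RT, at a fraction of the cost
  dt <- grids$dt
  t_need <- min(grids$t_max, max(trials$rt_s) + 0.05)
  nt <- as.integer(ceiling(t_need / dt))
  times <- (0:nt) * dt
  cond_data <- lapply(c("congruent", "incongruent"), function(cond) {
    sub <- trials[trials$condition == cond, ]
    idx <- pmin(pmax(findInterval(sub$rt_s, times), 1L), nt)
    list(n = nrow(sub), idx = idx,
         w = (sub$rt_s - times[idx]) / dt,
         correct = sub$response == "correct")
  })
  names(cond_data) <- c("congruent", "incongruent")

  t_half <- times[-length(times)] + dt / 2

  # lean evaluation path: same numerical primitives as solve_forward() /
  # convolve_nondecision() without the per-call object plumbing, since DE
  # calls this thousands of times per fit
  function(p) {
    if (p$t0 - p$s_t0 / 2 < 0) return(-Inf)
    nx <- 2L * as.integer(ceiling(p$b / grids$dx)) + 1L
    kern <- uniform_kernel(p$t0, p$s_t0, dt)
    ji <- as.integer(kern$j)
    ll <- 0
    for (cond in c("congruent", "incongruent")) {
      cd <- cond_data[[cond]]
      if (cd$n == 0) next
      mu <- if (p$variant == "dmc") dmc_drift(t_half, p, cond)
            else rdmc_drift(t_half, p, cond)
      sol <- cn_forward(mu, p$b, p$sigma, nx, dt,
                        startup_steps(p$b, p$sigma, dt))
      gu <- shift_convolve_cpp(sol$g_upper, ji, kern$w)
      gl <- shift_convolve_cpp(sol$g_lower, ji, kern$w)
      g <- ifelse(cd$correct,
                  gu[cd$idx] * (1 - cd$w) + gu[cd$idx + 1] * cd$w,
                  gl[cd$idx] * (1 - cd$w) + gl[cd$idx + 1] * cd$w)
      ll <- ll + sum(log(pmax(g, floor)))
    }
    ll
  }
}

#' Information criteria
#'
#' `aic(ll, k) = 2k - 2 ll`; `bic(ll, k, n) = k log(n) - 2 ll`.
#'
#' @param log_lik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of trials, `>= 1`.
#' @return The criterion value (smaller is better).
#' @export
aic <- function(log_lik, k) 2 * k - 2 * log_lik

#' @rdname aic
#' @export
bic <- function(log_lik, k, n) {
  if (n < 1) stop_config("n must be >= 1")
  k * log(n) - 2 * log_lik
}

#' Optimizer settings for model fitting
#'
#' Differential-evolution hyperparameters (the published analyses name the
#' algorithm and its box bounds but no hyperparameters; these defaults are
#' conventional).
#'
#' @param pop_factor Population size as a multiple of the dimension
#'   (default 10).
#' @param max_gens Generation cap (default 200).
#' @param F Differential weight (default 0.8).
#' @param CR Crossover probability (default 0.9).
#' @param reltol Relative improvement threshold for early stopping
#'   (default 1e-6).
#' @param steptol Stop after this many consecutive generations without a
#'   `reltol` improvement (default 20).
#' @param floor Per-trial density floor (default 1e-10).
#' @return A `cdm_fit_settings` object.
#' @export
fit_settings <- function(pop_factor = 10, max_gens = 200, F = 0.8,
                         CR = 0.9, reltol = 1e-6, steptol = 20,
                         floor = 1e-10) {
  structure(list(pop_factor = pop_factor, max_gens = max_gens, F = F,
                 CR = CR, reltol = reltol, steptol = steptol,
                 floor = floor),
            class = "cdm_fit_settings")
}

# Differential evolution, best/1/bin with binomial crossover and bound
# clamping. fn is minimized over the box [lower, upper]; deterministic
# under the caller's RNG state.
de_optimize <- function(fn, lower, upper, settings) {
  d <- length(lower)
  np <- max(4 * d, ceiling(settings$pop_factor * d))
  pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, ncol = d,
                byrow = TRUE)
  cost <- apply(pop, 1, fn)
  if (all(!is.finite(cost)))
    stop_config("optimizer failure: objective not finite anywhere")
  stagnant <- 0L
  gens <- 0L
  for (gen in seq_len(settings$max_gens)) {
    gens <- gen
    best <- pop[which.min(cost), ]
    best_cost <- min(cost)
    for (i in seq_len(np)) {
      r <- sample.int(np, 2)
      v <- best + settings$F * (pop[r[1], ] - pop[r[2], ])
      jrand <- sample.int(d, 1)
      cross <- stats::runif(d) < settings$CR
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      u <- pmin(pmax(u, lower), upper)
      cu <- fn(u)
      if (is.finite(cu) && cu <= cost[i]) {
        pop[i, ] <- u
        cost[i] <- cu
      }
    }
    improve <- best_cost - min(cost)
    if (improve < settings$reltol * (abs(min(cost)) + 1e-12))
      stagnant <- stagnant + 1L
    else stagnant <- 0L
    if (stagnant >= settings$steptol) break
  }
  ib <- which.min(cost)
  list(par = pop[ib, ], value = cost[ib], generations = gens,
       pop_size = np, converged = stagnant >= settings$steptol,
       pop = pop, cost = cost)
}

#' Fit a model to a trial table by maximum likelihood
#'
#' Minimizes the negative log-likelihood over the search box by
#' differential evolution (no starting values; only bounds). Fixed
#' parameters in `ranges` are held at their fixed values.
#'
#' @param model `"dmc"` or `"rdmc"`.
#' @param trials A non-empty trial table.
#' @param ranges A [parameter_ranges()] object supplying search bounds and
#'   fixed values.
#' @param seed Integer seed; recorded in the result.
#' @param grids A [cdm_grids()] object.
#' @param settings A [fit_settings()] object.
#' @return A `cdm_fit` object: `parameters`, `log_lik`, `n_trials`, `k`,
#'   `aic`, `bic`, and optimizer metadata.
#' @export
fit_model <- function(model = c("dmc", "rdmc"), trials, ranges, seed,
                      grids = cdm_grids(), settings = fit_settings()) {
  model <- match.arg(model)
  stopifnot(inherits(ranges, "cdm_ranges"), ranges$model == model)
  obj <- make_loglik(trials, grids, floor = settings$floor)
  free <- ranges$free
  lower <- vapply(ranges$search, `[`, numeric(1), 1)
  upper <- vapply(ranges$search, `[`, numeric(1), 2)
  template <- params_from_vector(model, stats::setNames((lower + upper) / 2,
                                                        free), ranges$fixed)
  neg <- function(v) {
    p <- set_free(template, stats::setNames(v, free))
    -obj(p)
  }
  res <- with_local_seed(seed, de_optimize(neg, lower, upper, settings))
  p_hat <- set_free(template, stats::setNames(res$par, free))
  ll <- -res$value
  k <- length(free)
  n <- nrow(trials)
  structure(list(parameters = p_hat, log_lik = ll, n_trials = n, k = k,
                 aic = aic(ll, k), bic = bic(ll, k, n),
                 optimizer = list(method = "differential_evolution",
                                  generations = res$generations,
                                  pop_size = res$pop_size, seed = seed,
                                  converged = res$converged),
                 free = free),
            class = "cdm_fit")
}

params_from_vector <- function(model, v, fixed) {
  do.call(model_parameters,
          c(list(variant = model), as.list(v), fixed))
}

#' @export
print.cdm_fit <- function(x, ...) {
  cat(sprintf("<%s fit> logLik = %.2f, AIC = %.2f, BIC = %.2f (n = %d, k = %d)\n",
              toupper(x$parameters$variant), x$log_lik, x$aic, x$bic,
              x$n_trials, x$k))
  print(round(free_values(x$parameters, x$free), 4))
  invisible(x)
}

#' Per-participant model comparison tallies
#'
#' Given one fit per model per participant, tallies for each criterion
#' (log-likelihood: larger is better; AIC/BIC: smaller is better) how many
#' participants each model wins, and reports criterion means averaged
#' across *all* participants. Exact ties count for neither model and are
#' reported separately.
#'
#' @param fits A data.frame with columns `participant`, `model`,
#'   `log_lik`, `aic`, `bic` (e.g. built from `cdm_fit` objects), exactly
#'   two models and both fitted for every participant.
#' @return List with `tally` (per criterion and model: wins, ties) and
#'   `means` (per model: mean log-likelihood, AIC, BIC).
#' @export
compare_models <- function(fits) {
  need <- c("participant", "model", "log_lik", "aic", "bic")
  if (!all(need %in% names(fits)))
    stop_config("fits must have columns %s", paste(need, collapse = ", "))
  models <- sort(unique(fits$model))
  if (length(models) != 2) stop_config("exactly two models are required")
  parts <- unique(fits$participant)
  tab <- lapply(models, function(m) fits[fits$model == m, ])
  names(tab) <- models
  for (m in models) {
    if (!setequal(tab[[m]]$participant, parts) ||
        nrow(tab[[m]]) != length(parts))
      stop_config("model '%s' must be fitted exactly once per participant", m)
    tab[[m]] <- tab[[m]][match(parts, tab[[m]]$participant), ]
  }
  criteria <- c(log_lik = 1, aic = -1, bic = -1)  # sign: larger-is-better
  tally <- do.call(rbind, lapply(names(criteria), function(cr) {
    a <- tab[[models[1]]][[cr]] * criteria[[cr]]
    b <- tab[[models[2]]][[cr]] * criteria[[cr]]
    data.frame(criterion = cr,
               model = c(models, "tie"),
               n_best = c(sum(a > b), sum(b > a), sum(a == b)))
  }))
  means <- do.call(rbind, lapply(models, function(m)
    data.frame(model = m,
               log_lik = mean(tab[[m]]$log_lik),
               aic = mean(tab[[m]]$aic),
               bic = mean(tab[[m]]$bic))))
  list(tally = tally, means = means, n_participants = length(parts))
}
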