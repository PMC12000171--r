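# fpt_solver: Crank-Nicolson densities, non-decision convolution, CDFs

test_that("zero drift gives symmetric branches and P(upper) = 1/2", {
  d <- solve_forward(const_drift(0), b = 0.6, sigma = 1,
                     grids = cdm_grids(0.002, 0.002, 4.0))
  cp <- choice_probability(d)
  expect_equal(cp$p_upper, 0.5, tolerance = 1e-3)
  expect_equal(cp$p_lower, 0.5, tolerance = 1e-3)
  expect_lt(max(abs(d$g_upper - d$g_lower)), 1e-10)
})

test_that("constant drift matches closed-form absorption probability and
           mean first-passage time at dx = dt = 0.002", {
  d <- solve_forward(const_drift(0.5), b = 0.6, sigma = 1,
                     grids = cdm_grids(0.002, 0.002, 4.0))
  cp <- choice_probability(d)
  expect_equal(cp$p_upper, wiener_p_upper(0.5, 0.6), tolerance = 1e-3)
  expect_equal(mean_decision_time(d), wiener_mean_fpt(0.5, 0.6),
               tolerance = 1e-3)
  expect_lt(cp$deficit, 1e-3)
})

test_that("negating the drift swaps the branches exactly", {
  p <- canon_rdmc()
  g <- cdm_grids(0.005, 0.005, 2.0)
  fwd <- drift_function(p, "incongruent")
  d1 <- solve_forward(fwd, p$b, 1, g, deficit_warn = NA)
  d2 <- solve_forward(function(t) -fwd(t), p$b, 1, g, deficit_warn = NA)
  # "exact up to floating point": the tridiagonal elimination direction
  # breaks bitwise symmetry, nothing more
  expect_lt(max(abs(d1$g_upper - d2$g_lower)), 1e-10)
  expect_lt(max(abs(d1$g_lower - d2$g_upper)), 1e-10)
})

test_that("mass is conserved step by step and in total", {
  for (mu in c(0, 0.5, 3)) {
    d <- solve_forward(const_drift(mu), b = 0.6, sigma = 1,
                       grids = cdm_grids(0.002, 0.002, 4.0))
    cp <- choice_probability(d)
    # absorbed + interior accounts for everything
    expect_equal(cp$p_upper + cp$p_lower + d$mass_interior, 1,
                 tolerance = 1e-4)
    expect_lt(d$max_step_imbalance, 1e-6)
  }
})

test_that("a too-short horizon leaves a mass deficit and warns", {
  expect_warning(
    d <- solve_forward(const_drift(0.1), b = 0.6, sigma = 1,
                       grids = cdm_grids(0.002, 0.002, 0.3)),
    "mass deficit")
  cp <- choice_probability(d)
  expect_lt(cp$p_upper + cp$p_lower, 0.999)
})

test_that("ill-conditioned grids and bad drift functions are rejected", {
  expect_error(cdm_grids(dt = 0), class = "cdm_config_error")
  expect_error(cdm_grids(dx = -1), class = "cdm_config_error")
  expect_error(solve_forward(const_drift(0), b = 0.001, sigma = 1,
                             grids = cdm_grids(0.002, 0.002, 1)),
               class = "cdm_config_error")
  expect_error(solve_forward(function(t) rep(NaN, length(t)), b = 0.6,
                             sigma = 1, grids = cdm_grids(0.01, 0.01, 1)),
               class = "cdm_config_error")
})

test_that("non-decision convolution shifts, preserves mass, and adds t0
           to the mean", {
  # horizon long enough that the slow exponential tail is negligible,
  # so convolution mass preservation is tested, not tail truncation
  g <- cdm_grids(0.002, 0.002, 5.0)
  d <- solve_forward(const_drift(0.5), b = 0.6, sigma = 1, grids = g)
  # degenerate uniform: exact grid shift by t0 (t0 a grid multiple)
  d_shift <- convolve_nondecision(d, t0 = 0.3, s_t0 = 0)
  k <- round(0.3 / d$dt)
  expect_equal(d_shift$g_upper[(k + 1):length(d$g_upper)],
               d$g_upper[1:(length(d$g_upper) - k)], tolerance = 1e-14)
  # mass preserved per branch
  d_rt <- convolve_nondecision(d, t0 = 0.3, s_t0 = 0.07)
  expect_equal(choice_probability(d_rt)$p_upper,
               choice_probability(d)$p_upper, tolerance = 1e-6)
  # mean RT = mean decision time + t0 (absolute tolerance, seconds)
  expect_lt(abs(branch_mean(d_rt, "upper") -
                  (wiener_mean_fpt(0.5, 0.6) + 0.3)), 2e-3)
  # negative support rejected
  expect_error(convolve_nondecision(d, t0 = 0.02, s_t0 = 0.07),
               class = "cdm_invalid_parameter")
})

test_that("defective CDFs start at zero, end at branch masses, and are
           monotone", {
  p <- canon_dmc()
  d <- solve_forward(drift_function(p, "incongruent"), p$b, 1,
                     cdm_grids(0.002, 0.002, 3.0))
  d <- convolve_nondecision(d, p$t0, p$s_t0)
  cdf <- cdf_from_density(d)
  cp <- choice_probability(d)
  expect_equal(cdf$F_upper[1], 0)
  expect_equal(cdf$F_lower[1], 0)
  expect_equal(cdf$F_upper[length(cdf$F_upper)], cp$p_upper,
               tolerance = 1e-9)
  expect_equal(cdf$F_lower[length(cdf$F_lower)], cp$p_lower,
               tolerance = 1e-9)
  expect_true(all(diff(cdf$F_upper) > -1e-15))
  expect_true(all(diff(cdf$F_lower) > -1e-15))
})

test_that("solver agrees with the Euler-Maruyama simulation oracle", {
  # median of the normalized upper-branch decision-time CDF
  d <- solve_forward(const_drift(0.5), b = 0.6, sigma = 1,
                     grids = cdm_grids(0.002, 0.002, 4.0))
  cdf <- cdf_from_density(d)
  med_pde <- conflictdm:::invert_cdf(
    cdf$times, cdf$F_upper / max(cdf$F_upper), 0.5)
  sim <- simulate_paths(const_drift(0.5), 0.6, 1, n_paths = 1e5,
                        dt = 0.001, t_max = 4, seed = 99)
  med_sim <- stats::median(sim$rt[sim$boundary == 1])
  expect_lt(abs(med_pde - med_sim), 2e-3)
  expect_lt(abs(mean(sim$boundary == 1) - wiener_p_upper(0.5, 0.6)), 4e-3)
})

test_that("halving the grid steps changes the log-likelihood of a fixed
           dataset by less than 0.1", {
  p <- canon_dmc()
  trials <- generate_dataset(p, 100, seed = 31,
                             grids = cdm_grids(0.002, 0.002, 3.0))
  ll_coarse <- log_likelihood(p, trials, cdm_grids(0.004, 0.004, 3.0))
  ll_fine <- log_likelihood(p, trials, cdm_grids(0.002, 0.002, 3.0))
  expect_lt(abs(ll_coarse - ll_fine), 0.1)
})

test_that("densities export as two-column delimited text per branch", {
  d <- solve_forward(const_drift(0.5), b = 0.6, sigma = 1,
                     grids = cdm_grids(0.01, 0.01, 1), deficit_warn = NA)
  stem <- file.path(withr::local_tempdir(), "dens")
  paths <- write_density(d, stem)
  expect_true(all(file.exists(paths)))
  tab <- utils::read.delim(paths[1])
  expect_identical(names(tab), c("time", "value"))
  expect_equal(tab$value, d$g_upper)
})
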