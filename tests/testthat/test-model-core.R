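# model_core: drift rates, activation curves, parameter transforms

test_that("DMC Gamma pulse has amplitude A at peak latency (a-1)*tau", {
  expect_equal(dmc_expected_automatic(80, A = 20, tau = 80, a = 2), 20)
  expect_equal(dmc_expected_automatic(0, A = 20, tau = 80, a = 2), 0)
  # frozen from the closed form 10 * exp(0.5); cross-checked below by
  # integrating the automatic drift
  expect_equal(dmc_expected_automatic(40, A = 20, tau = 80, a = 2),
               16.4872127070013, tolerance = 1e-12)
  # peak location by grid search for assorted shapes
  tg <- seq(0.1, 1200, by = 0.1)
  for (pars in list(c(A = 20, tau = 80, a = 2), c(A = 5, tau = 30, a = 3),
                    c(A = 1, tau = 150, a = 2.5))) {
    act <- dmc_expected_automatic(tg, pars["A"], pars["tau"], pars["a"])
    expect_equal(tg[which.max(act)], (pars[["a"]] - 1) * pars[["tau"]],
                 tolerance = 1e-3)
    expect_equal(max(act), pars[["A"]], tolerance = 1e-6)
  }
})

test_that("automatic drift is the pulse derivative and integrates back", {
  p <- fig_dmc_ms()
  # vanishes at the peak: superimposed drift reduces to mu_c
  expect_equal(dmc_drift(80, p, "congruent"), p$mu_c)
  expect_equal(dmc_drift(80, p, "incongruent"), p$mu_c)
  # oracle: central finite difference of the expected activation
  for (t in c(10, 40, 200, 500)) {
    h <- 1e-4
    num <- (dmc_expected_automatic(t + h, 20, 80, 2) -
            dmc_expected_automatic(t - h, 20, 80, 2)) / (2 * h)
    expect_equal(dmc_drift(t, p, "congruent"), p$mu_c + num,
                 tolerance = 1e-6)
    expect_equal(dmc_drift(t, p, "incongruent"), p$mu_c - num,
                 tolerance = 1e-6)
  }
  expect_equal(dmc_drift(40, p, "congruent"), 0.70609016, tolerance = 1e-7)
  expect_equal(dmc_drift(40, p, "incongruent"), 0.29390984,
               tolerance = 1e-7)
  # sign change exactly once, at the peak (before the pulse underflows)
  tg <- seq(0.5, 600, by = 1)   # offset grid avoids the exact zero at 80
  mu_a <- dmc_drift(tg, p, "congruent") - p$mu_c
  expect_equal(sum(diff(sign(mu_a)) != 0), 1)
  # the pulse fades: integral of (drift - mu_c) over a long window returns
  # to zero (trapezoid quadrature at step 0.25 ms)
  tg <- seq(0, 2000, by = 0.25)
  mu_a <- dmc_drift(tg, p, "congruent") - p$mu_c
  expect_lt(abs(sum(diff(tg) * (head(mu_a, -1) + mu_a[-1]) / 2)), 1e-3)
  expect_lt(dmc_expected_automatic(2500, 20, 80, 2), 1e-10)
  # t = 0 right limit for a = 2 is A*e/tau, not zero
  expect_equal(dmc_drift(0, p, "congruent") - p$mu_c, 20 * exp(1) / 80)
})

test_that("RDMC attention weight decays from A0 and stays in (0, A0]", {
  expect_equal(rdmc_weight_automatic(0, A0 = 0.8, k = 10), 0.8)
  expect_equal(rdmc_weight_automatic(0.1, A0 = 0.8, k = 10),
               0.294303552936, tolerance = 1e-10)
  expect_lt(rdmc_weight_automatic(100, A0 = 0.8, k = 10), 1e-12)
  tg <- seq(0, 2, by = 0.01)
  for (pars in list(c(0.8, 10), c(0.3, 2), c(1.0, 25))) {
    w <- rdmc_weight_automatic(tg, pars[1], pars[2])
    expect_true(all(diff(w) < 0))
    expect_true(all(w > 0 & w <= pars[1]))
  }
})

test_that("RDMC drift starts at the weighted mix and relaxes to d_c", {
  p <- fig_rdmc_s()
  expect_equal(rdmc_drift(0, p, "congruent"), 0.44)
  # (1 - 0.8)*0.6 - 0.8*0.4; the incongruent start is negative
  expect_equal(rdmc_drift(0, p, "incongruent"), -0.20)
  expect_equal(rdmc_drift(5, p, "congruent"), p$d_c, tolerance = 1e-8)
  expect_equal(rdmc_drift(5, p, "incongruent"), p$d_c, tolerance = 1e-8)
  # condition-specific rates: congruent uses k_c, incongruent k_i
  t <- 0.05
  wc <- rdmc_weight_automatic(t, p$A0, p$k_c)
  wi <- rdmc_weight_automatic(t, p$A0, p$k_i)
  expect_equal(rdmc_drift(t, p, "congruent"),
               (1 - wc) * p$d_c + wc * p$d_a)
  expect_equal(rdmc_drift(t, p, "incongruent"),
               (1 - wi) * p$d_c - wi * p$d_a)
})

test_that("expected activation integrates the drift; RDMC automatic
           channel has asymptote d_a*A0/k", {
  pr <- fig_rdmc_s()
  expect_equal(expected_activation(pr, "congruent", 10, "automatic"),
               0.4 * 0.8 / 10)
  expect_equal(expected_activation(pr, "incongruent", 10, "automatic"),
               -0.4 * 0.8 / 30)
  expect_equal(expected_activation(pr, "congruent", 0), 0)
  pd <- fig_dmc_ms()
  expect_equal(expected_activation(pd, "congruent", 0), 0)
  # DMC automatic channel returns to zero at long times
  expect_lt(abs(expected_activation(pd, "congruent", 5000, "automatic")),
            1e-12)
  # oracle: numerical quadrature of the drift for both models
  for (setup in list(list(p = pd, t = 120), list(p = pr, t = 0.25))) {
    p <- setup$p
    up <- stats::integrate(function(s) drift_function(p, "incongruent")(s),
                           0, setup$t, rel.tol = 1e-10)$value
    expect_equal(expected_activation(p, "incongruent", setup$t), up,
                 tolerance = 1e-7)
  }
  # congruent asymptote magnitude exceeds incongruent when k_c < k_i
  expect_gt(abs(expected_activation(pr, "congruent", 10, "automatic")),
            abs(expected_activation(pr, "incongruent", 10, "automatic")))
})

test_that("parameter transforms are exact, invertible, and
           distribution-preserving", {
  pd <- fig_dmc_ms()
  # identity
  expect_equal(transform_parameters(pd), pd)
  # original DMC (sigma = 4, ms) to canonical (sigma = 1, s) and back
  ps <- transform_parameters(pd, sigma_target = 1,
                             time_unit_target = "seconds")
  expect_equal(ps$t0, 0.3)
  expect_equal(ps$tau, 0.08)
  expect_equal(ps$b, 75 * sqrt(1e-3) / 4)
  back <- transform_parameters(ps, 4, "milliseconds")
  for (nm in conflictdm:::model_param_names("dmc"))
    expect_equal(back[[nm]], pd[[nm]], tolerance = 1e-12)
  # round trip for RDMC (sigma = 0.1 convention)
  pr <- fig_rdmc_s()
  pr1 <- transform_parameters(pr, 1, "seconds")
  expect_equal(pr1$d_c, 6)  # drifts scale by sigma ratio
  pr2 <- transform_parameters(pr1, 0.1, "seconds")
  for (nm in conflictdm:::model_param_names("rdmc"))
    expect_equal(pr2[[nm]], pr[[nm]], tolerance = 1e-12)
  # choice probabilities are invariant under the convention change
  g_ms <- cdm_grids(1, 1, 1500)
  g_s <- cdm_grids(0.002, 0.002, 1.5)
  d_ms <- solve_forward(drift_function(pd, "incongruent"), pd$b, pd$sigma,
                        g_ms, deficit_warn = NA)
  d_s <- solve_forward(drift_function(ps, "incongruent"), ps$b, ps$sigma,
                       g_s, deficit_warn = NA)
  expect_equal(choice_probability(d_ms)$p_upper,
               choice_probability(d_s)$p_upper, tolerance = 2e-3)
})

test_that("invalid parameters are rejected with typed errors", {
  expect_error(model_parameters("dmc", A = -1, tau = 80, mu_c = 0.5,
                                b = 75, t0 = 300, s_t0 = 50),
               class = "cdm_invalid_parameter")
  expect_error(model_parameters("dmc", A = 20, tau = 80, a = 1,
                                mu_c = 0.5, b = 75, t0 = 300, s_t0 = 50),
               class = "cdm_invalid_parameter")
  expect_error(model_parameters("rdmc", A0 = 1.2, k_c = 10, k_i = 30,
                                d_c = 0.6, d_a = 0.4, b = 0.1, t0 = 0.3),
               class = "cdm_invalid_parameter")
  expect_error(model_parameters("dmc", A = 20, tau = 80, mu_c = 0.5,
                                b = 75, t0 = 0.02, s_t0 = 0.07),
               class = "cdm_invalid_parameter")
  expect_error(rdmc_weight_automatic(0.1, A0 = 0.8, k = -2),
               class = "cdm_invalid_parameter")
  expect_error(dmc_expected_automatic(-1, 20, 80, 2),
               class = "cdm_invalid_parameter")
  p <- canon_dmc()
  expect_error(transform_parameters(p, sigma_target = -1),
               class = "cdm_invalid_parameter")
})

test_that("parameter sets round-trip through the flat key-value format", {
  for (p in list(canon_dmc(), fig_rdmc_s())) {
    path <- withr::local_tempfile(fileext = ".json")
    write_parameters(p, path)
    q <- read_parameters(path)
    expect_equal(q, p)
  }
})
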