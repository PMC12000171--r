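# Shared fixtures. Grids and optimizer settings for the scaled recovery
# studies: generation at dt = dx = 0.002 (the published protocol uses
# 0.001), fitting at dt = 0.0025, dx = 0.0075 (published: 0.002 both; the
# time step is what must stay fine, or fast Gamma pulses are unresolved
# and the likelihood is biased toward the tau search bound), 20 parameter
# sets (published: 100), DE capped at 100 generations with early
# stopping. Scaling keeps the default test run inside a CI budget; the
# full-scale protocol is available through the same functions.

grids_gen_scaled <- function() cdm_grids(0.002, 0.002, 3.0)
grids_fit_scaled <- function() cdm_grids(0.0025, 0.0075, 3.0)
settings_scaled <- function() fit_settings(max_gens = 100, reltol = 1e-5,
                                           steptol = 10)
n_sets_scaled <- 20L
seed_dmc_study <- 101L
seed_rdmc_study <- 202L

# illustration-convention parameter sets (original publications' scales)
fig_dmc_ms <- function(b = 75, t0 = 300, s_t0 = 50)
  model_parameters("dmc", A = 20, tau = 80, mu_c = 0.5, b = b, t0 = t0,
                   s_t0 = s_t0, sigma = 4, time_unit = "milliseconds")

fig_rdmc_s <- function(b = 0.1, t0 = 0.3, s_t0 = 0.07)
  model_parameters("rdmc", A0 = 0.8, k_c = 10, k_i = 30, d_c = 0.6,
                   d_a = 0.4, b = b, t0 = t0, s_t0 = s_t0, sigma = 0.1)

# canonical-convention (seconds, sigma = 1) sets used across tests
canon_dmc <- function()
  model_parameters("dmc", A = 0.16, tau = 0.08, mu_c = 4, b = 0.6,
                   t0 = 0.3, s_t0 = 0.07)

canon_rdmc <- function()
  model_parameters("rdmc", A0 = 0.8, k_c = 10, k_i = 14, d_c = 4,
                   d_a = 3, b = 0.6, t0 = 0.3, s_t0 = 0.07)

const_drift <- function(mu) function(t) rep(mu, length(t))

# closed forms for a constant-drift Wiener process started midway between
# absorbing boundaries at +-b (independent oracles)
wiener_p_upper <- function(mu, b, sigma = 1) {
  1 / (1 + exp(-2 * mu * b / sigma^2))
}
wiener_mean_fpt <- function(mu, b, sigma = 1) {
  (b / mu) * tanh(mu * b / sigma^2)
}

mean_decision_time <- function(d) {
  g <- d$g_upper + d$g_lower
  p <- choice_probability(d)
  sum(diff(d$times) * (head(d$times * g, -1) + (d$times * g)[-1]) / 2) /
    (p$p_upper + p$p_lower)
}
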