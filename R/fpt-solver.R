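#' Discretization grids for the forward solver
#'
#' @param dt Time step (time units), `> 0`.
#' @param dx Evidence step (evidence units), `> 0`. The evidence grid spans
#'   exactly `[-b, b]` with an odd node count `2*ceiling(b/dx) + 1`, so the
#'   realized step is at most `dx` (never coarser than requested) and
#'   `x = 0` is a node.
#' @param t_max Time horizon, several times the slowest expected RT.
#' @return A `cdm_grids` object.
#' @export
cdm_grids <- function(dt = 0.002, dx = 0.002, t_max = 3.0) {
  if (!is.finite(dt) || dt <= 0) stop_config("dt must be > 0")
  if (!is.finite(dx) || dx <= 0) stop_config("dx must be > 0")
  if (!is.finite(t_max) || t_max <= dt) stop_config("t_max must exceed dt")
  structure(list(dt = dt, dx = dx, t_max = t_max), class = "cdm_grids")
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cdm_config_error", "error")))
}

#' Defective first-passage-time densities by Crank-Nicolson
#'
#' Solves the Kolmogorov forward equation
#' \deqn{\partial_t f = -\mu(t)\,\partial_x f + \tfrac{\sigma^2}{2}\,\partial_x^2 f}
#' on `[-b, b]` with absorbing boundaries and all initial mass at `x = 0`,
#' and returns the outward probability flux at each boundary: the defective
#' decision-time densities `g_upper` (correct) and `g_lower` (error).
#' The Dirac initial condition is damped with a few fully implicit startup
#' steps before switching to Crank-Nicolson; the boundary flux is obtained
#' from a third-order one-sided difference at the absorbing nodes.
#'
#' @param drift_fn Function `t -> drift` (evidence/time), finite on
#'   `[0, t_max]`; evaluated at the half steps `t + dt/2`.
#' @param b Boundary half-width, `> 0`.
#' @param sigma Diffusion constant, `> 0`.
#' @param grids A [cdm_grids()] object; `dx` must not exceed `b`.
#' @param n_startup Maximum number of steps after which the analytic
#'   short-time solution seeds the scheme (default 4); automatically
#'   shortened so the warm-start Gaussian stays well inside the
#'   boundaries.
#' @param deficit_warn Warn if total absorbed mass falls short of 1 by more
#'   than this (default `1e-3`); set `NA` to disable.
#' @return A `cdm_densities` object: `times`, `g_upper`, `g_lower`,
#'   `kind = "decision_time"`, plus solver metadata.
#' @examples
#' d <- solve_forward(function(t) rep(0.5, length(t)), b = 0.6, sigma = 1,
#'                    grids = cdm_grids(0.005, 0.005, 2.5))
#' choice_probability(d)
#' @export
solve_forward <- function(drift_fn, b, sigma, grids = cdm_grids(),
                          n_startup = 4, deficit_warn = 1e-3) {
  if (!is.finite(b) || b <= 0) stop_config("b must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop_config("sigma must be > 0")
  if (grids$dx > b) stop_config("dx must not exceed b")
  nt <- as.integer(ceiling(grids$t_max / grids$dt))
  dt <- grids$t_max / nt
  nx <- 2L * as.integer(ceiling(b / grids$dx)) + 1L
  times <- seq(0, grids$t_max, length.out = nt + 1L)
  mu <- drift_fn(times[-length(times)] + dt / 2)
  if (length(mu) != nt || any(!is.finite(mu)))
    stop_config("drift_fn must return one finite value per half step")
  sol <- cn_forward(mu, b, sigma, nx, dt,
                    startup_steps(b, sigma, dt, n_startup))
  d <- structure(list(times = times,
                      g_upper = sol$g_upper, g_lower = sol$g_lower,
                      kind = "decision_time",
                      dt = dt, b = b, sigma = sigma,
                      mass_interior = sol$mass_interior,
                      max_step_imbalance = sol$max_step_imbalance),
                 class = "cdm_densities")
  deficit <- 1 - sum(unlist(choice_probability(d)[c("p_upper", "p_lower")]))
  if (!is.na(deficit_warn) && deficit > deficit_warn)
    warning(sprintf(
      "mass deficit %.3g exceeds %.3g: horizon t_max = %g may be too short",
      deficit, deficit_warn, grids$t_max))
  d
}

#' Convolve decision-time densities with the uniform non-decision time
#'
#' Both defective branches are convolved with a uniform residual latency on
#' `[t0 - s_t0/2, t0 + s_t0/2]` (mean `t0`, range `s_t0`), yielding RT
#' densities on the same time grid. The discrete kernel assigns each grid
#' cell the fraction of the uniform window it overlaps and is renormalized
#' to unit mass, so the mean shift equals `t0` and a degenerate window
#' (`s_t0 = 0`) reduces to an interpolated shift by `t0`.
#'
#' @param d A `cdm_densities` object of kind `"decision_time"`.
#' @param t0 Mean non-decision time; `t0 - s_t0/2 >= 0` required.
#' @param s_t0 Range of the uniform non-decision time, `>= 0`.
#' @return A `cdm_densities` object of kind `"rt"`.
#' @export
convolve_nondecision <- function(d, t0, s_t0 = 0) {
  stopifnot(inherits(d, "cdm_densities"))
  if (d$kind != "decision_time")
    stop_config("densities have already been convolved")
  if (!is.finite(t0) || !is.finite(s_t0) || s_t0 < 0 || t0 - s_t0 / 2 < 0)
    stop_invalid("uniform non-decision support must be non-negative")
  w <- uniform_kernel(t0, s_t0, d$dt)
  d$g_upper <- shift_convolve(d$g_upper, w)
  d$g_lower <- shift_convolve(d$g_lower, w)
  d$kind <- "rt"
  d$t0 <- t0
  d$s_t0 <- s_t0
  d
}

# warm-start length: at most n_max steps, but keep the free-diffusion
# standard deviation sigma*sqrt(t) below b/4 so the image-corrected
# Gaussian is still essentially unabsorbed
startup_steps <- function(b, sigma, dt, n_max = 4) {
  n <- floor((b / (4 * sigma))^2 / dt)
  as.integer(max(1, min(n_max, n)))
}

# discrete uniform kernel: offsets (in grid steps) and overlap weights
uniform_kernel <- function(t0, s_t0, dt) {
  lo <- t0 - s_t0 / 2
  hi <- t0 + s_t0 / 2
  j0 <- floor(lo / dt + 0.5)
  j1 <- ceiling(hi / dt - 0.5)
  j <- j0:j1
  if (s_t0 == 0) {
    # point mass split linearly between the two neighbouring nodes
    jf <- floor(t0 / dt)
    fr <- t0 / dt - jf
    if (fr < 1e-12) return(list(j = jf, w = 1))
    return(list(j = c(jf, jf + 1), w = c(1 - fr, fr)))
  }
  cell_lo <- pmax((j - 0.5) * dt, lo)
  cell_hi <- pmin((j + 0.5) * dt, hi)
  w <- pmax(cell_hi - cell_lo, 0)
  keep <- w > 0
  list(j = j[keep], w = w[keep] / sum(w[keep]))
}

shift_convolve <- function(g, kern) {
  shift_convolve_cpp(g, as.integer(kern$j), kern$w)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Choice probabilities (branch masses) of defective densities
#'
#' Trapezoidal masses of the upper (correct) and lower (error) branch,
#' together with the mass deficit `1 - p_upper - p_lower` left beyond the
#' horizon.
#'
#' @param d A `cdm_densities` object.
#' @return List with `p_upper`, `p_lower`, `deficit`.
#' @export
choice_probability <- function(d) {
  stopifnot(inherits(d, "cdm_densities"))
  pu <- trapz(d$times, d$g_upper)
  pl <- trapz(d$times, d$g_lower)
  list(p_upper = pu, p_lower = pl, deficit = 1 - pu - pl)
}

#' Defective cumulative distribution functions per branch
#'
#' Cumulative trapezoidal integrals of the two defective densities; each
#' branch CDF starts at 0 and terminates at the branch mass.
#'
#' @param d A `cdm_densities` object.
#' @return A `cdm_cdfs` object: `times`, `F_upper`, `F_lower`, `kind`.
#' @export
cdf_from_density <- function(d) {
  stopifnot(inherits(d, "cdm_densities"))
  cum <- function(g) c(0, cumsum(diff(d$times) * (head(g, -1) + g[-1]) / 2))
  structure(list(times = d$times, F_upper = cum(d$g_upper),
                 F_lower = cum(d$g_lower), kind = d$kind),
            class = "cdm_cdfs")
}

#' Mean of one defective branch (normalized)
#'
#' @param d A `cdm_densities` object.
#' @param branch `"upper"` or `"lower"`.
#' @return Mean time of the branch, conditional on absorption there.
#' @export
branch_mean <- function(d, branch = c("upper", "lower")) {
  branch <- match.arg(branch)
  g <- if (branch == "upper") d$g_upper else d$g_lower
  trapz(d$times, d$times * g) / trapz(d$times, g)
}

#' Export densities or CDFs as two-column delimited text
#'
#' Writes one file per branch (`<stem>_upper.tsv`, `<stem>_lower.tsv`) with
#' columns `time` and `value`.
#'
#' @param d A `cdm_densities` or `cdm_cdfs` object.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_density <- function(d, stem) {
  vals <- if (inherits(d, "cdm_cdfs")) list(upper = d$F_upper, lower = d$F_lower)
          else list(upper = d$g_upper, lower = d$g_lower)
  paths <- character(2)
  for (i in 1:2) {
    br <- names(vals)[i]
    paths[i] <- paste0(stem, "_", br, ".tsv")
    utils::write.table(data.frame(time = d$times, value = vals[[br]]),
                       paths[i], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(paths)
}

#' Simulate first-passage times by Euler-Maruyama
#'
#' Stochastic path simulation between absorbing boundaries, with a
#' Brownian-bridge crossing correction that removes the leading-order
#' discretization bias. Entirely independent of the PDE route; used as a
#' cross-validation oracle.
#'
#' @param drift_fn Function `t -> drift`.
#' @param b Boundary half-width.
#' @param sigma Diffusion constant.
#' @param n_paths Number of simulated paths.
#' @param dt Simulation step.
#' @param t_max Horizon; paths alive at `t_max` are returned censored.
#' @param bridge Apply the bridge correction (default `TRUE`).
#' @param seed Optional integer seed (local to this call).
#' @return Data frame with `rt` and `boundary` (+1 upper, -1 lower,
#'   0 censored).
#' @export
simulate_paths <- function(drift_fn, b, sigma, n_paths, dt = 0.001,
                           t_max = 3.0, bridge = TRUE, seed = NULL) {
  nsteps <- as.integer(ceiling(t_max / dt))
  mu <- drift_fn((seq_len(nsteps) - 1) * dt)
  run <- function() em_simulate(mu, b, sigma, dt, as.integer(n_paths), bridge)
  sim <- if (is.null(seed)) run() else with_local_seed(seed, run())
  data.frame(rt = sim$rt, boundary = sim$boundary)
}

# evaluate a seeded expression without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
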