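#' Model parameter sets for conflict-task diffusion models
#'
#' Construct a validated parameter set for one of the two supported model
#' variants. Both variants share a boundary separation half-width `b`
#' (absorbing boundaries at `-b` and `+b`, accumulation starts at 0), a
#' uniform non-decision time with mean `t0` and range `s_t0`, a diffusion
#' constant `sigma`, and a time unit.
#'
#' The DMC variant describes the automatic channel's expected activation as
#' a rescaled Gamma pulse with amplitude `A`, scale `tau` and shape `a`
#' (fixed to 2 in typical applications), superimposed on a constant
#' controlled drift `mu_c`. The RDMC variant weights two constant base
#' drifts, controlled `d_c` and automatic `d_a`, by an exponentially
#' decaying automatic attention weight with initial value `A0` and
#' condition-specific shift rates `k_c` (congruent) and `k_i` (incongruent).
#'
#' @param variant `"dmc"` or `"rdmc"`.
#' @param A,tau,a,mu_c DMC parameters: pulse amplitude (evidence units),
#'   Gamma scale (time units), Gamma shape (dimensionless, `> 1`), and
#'   controlled drift (evidence/time).
#' @param A0,k_c,k_i,d_c,d_a RDMC parameters: initial automatic attention
#'   weight in `(0, 1]`, attention-shift rates (1/time) for congruent and
#'   incongruent trials, and controlled/automatic base drifts
#'   (evidence/time; `d_a` is stored unsigned, the sign is applied per
#'   condition).
#' @param b Boundary half-width (evidence units), `> 0`.
#' @param t0 Mean non-decision time (time units).
#' @param s_t0 Range of the uniform non-decision time; the support
#'   `[t0 - s_t0/2, t0 + s_t0/2]` must not extend below zero.
#' @param sigma Diffusion constant (evidence per square-root time).
#' @param time_unit `"seconds"` or `"milliseconds"`; bookkeeping only, all
#'   numeric values are interpreted in this unit.
#' @return An object of class `cdm_parameters` (a named list).
#' @examples
#' p <- model_parameters("dmc", A = 0.16, tau = 0.08, mu_c = 4,
#'                       b = 0.6, t0 = 0.3, s_t0 = 0.07)
#' p
#' @export
model_parameters <- function(variant = c("dmc", "rdmc"),
                             A = NULL, tau = NULL, a = 2, mu_c = NULL,
                             A0 = NULL, k_c = NULL, k_i = NULL,
                             d_c = NULL, d_a = NULL,
                             b, t0, s_t0 = 0.07, sigma = 1,
                             time_unit = c("seconds", "milliseconds")) {
  variant <- match.arg(variant)
  time_unit <- match.arg(time_unit)
  p <- list(variant = variant, b = b, t0 = t0, s_t0 = s_t0,
            sigma = sigma, time_unit = time_unit)
  if (variant == "dmc") {
    p <- c(p, list(A = A, tau = tau, a = a, mu_c = mu_c))
  } else {
    p <- c(p, list(A0 = A0, k_c = k_c, k_i = k_i, d_c = d_c, d_a = d_a))
  }
  class(p) <- "cdm_parameters"
  validate_parameters(p)
  p
}

#' @export
print.cdm_parameters <- function(x, ...) {
  cat(sprintf("<%s parameters> (%s, sigma = %g)\n",
              toupper(x$variant), x$time_unit, x$sigma))
  vals <- unlist(x[model_param_names(x$variant)])
  print(round(vals, 6))
  invisible(x)
}

# free + shared numeric parameter names per variant, in canonical order
model_param_names <- function(variant) {
  if (variant == "dmc") c("A", "tau", "a", "mu_c", "b", "t0", "s_t0")
  else c("A0", "k_c", "k_i", "d_c", "d_a", "b", "t0", "s_t0")
}

stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cdm_invalid_parameter", "error")))
}

validate_parameters <- function(p) {
  chk <- function(val, name, positive = TRUE) {
    if (is.null(val) || length(val) != 1 || !is.finite(val))
      stop_invalid("parameter '%s' must be a single finite number", name)
    if (positive && val <= 0)
      stop_invalid("parameter '%s' must be > 0 (got %g)", name, val)
  }
  chk(p$b, "b"); chk(p$sigma, "sigma")
  chk(p$t0, "t0"); chk(p$s_t0, "s_t0", positive = FALSE)
  if (p$s_t0 < 0) stop_invalid("s_t0 must be >= 0")
  if (p$t0 - p$s_t0 / 2 < 0)
    stop_invalid("non-decision time support dips below zero (t0 - s_t0/2 < 0)")
  if (p$variant == "dmc") {
    chk(p$A, "A"); chk(p$tau, "tau"); chk(p$a, "a"); chk(p$mu_c, "mu_c")
    if (p$a <= 1) stop_invalid("shape parameter a must be > 1")
  } else {
    chk(p$A0, "A0"); chk(p$k_c, "k_c"); chk(p$k_i, "k_i")
    chk(p$d_c, "d_c"); chk(p$d_a, "d_a")
    if (p$A0 > 1) stop_invalid("A0 must lie in (0, 1]")
  }
  invisible(p)
}

#' Convert a parameter set between diffusion-constant and time-unit
#' conventions
#'
#' Diffusion-model parameters are only identified up to an arbitrary
#' evidence scale and a choice of time unit. Published parameterizations
#' differ: the original DMC used `sigma = 4` in milliseconds, the original
#' RDMC `sigma = 0.1` in seconds, and the fitting convention used here is
#' `sigma = 1` in seconds. This function maps a parameter set to an
#' equivalent one under a new convention, leaving every predicted choice
#' probability and (unit-converted) RT distribution unchanged.
#'
#' With time rescaled by `u` (e.g. `u = 1000` for seconds to milliseconds)
#' and evidence rescaled by `c = (sigma_target/sigma) * sqrt(u)`:
#' boundaries scale as `c`, drifts and base drifts as `c/u`, amplitudes as
#' `c`, time scales (`tau`, `t0`, `s_t0`) as `u`, rates (`k_c`, `k_i`) as
#' `1/u`, and dimensionless parameters (`a`, `A0`) are untouched.
#'
#' @param p A `cdm_parameters` object.
#' @param sigma_target Target diffusion constant, `> 0`.
#' @param time_unit_target `"seconds"` or `"milliseconds"`.
#' @return The equivalent `cdm_parameters` under the target convention.
#' @examples
#' p <- model_parameters("dmc", A = 0.158, tau = 0.08, mu_c = 3.95,
#'                       b = 0.593, t0 = 0.3, s_t0 = 0.07)
#' transform_parameters(p, sigma_target = 4, time_unit_target = "milliseconds")
#' @export
transform_parameters <- function(p, sigma_target = p$sigma,
                                 time_unit_target = p$time_unit) {
  validate_parameters(p)
  time_unit_target <- match.arg(time_unit_target,
                                c("seconds", "milliseconds"))
  if (!is.finite(sigma_target) || sigma_target <= 0)
    stop_invalid("sigma_target must be > 0")
  u <- time_factor(p$time_unit, time_unit_target)
  cc <- (sigma_target / p$sigma) * sqrt(u)
  q <- p
  q$sigma <- sigma_target
  q$time_unit <- time_unit_target
  q$b <- cc * p$b
  q$t0 <- u * p$t0
  q$s_t0 <- u * p$s_t0
  if (p$variant == "dmc") {
    q$A <- cc * p$A
    q$tau <- u * p$tau
    q$mu_c <- (cc / u) * p$mu_c
  } else {
    q$k_c <- p$k_c / u
    q$k_i <- p$k_i / u
    q$d_c <- (cc / u) * p$d_c
    q$d_a <- (cc / u) * p$d_a
  }
  validate_parameters(q)
  q
}

time_factor <- function(from, to) {
  scale <- c(seconds = 1, milliseconds = 1000)
  unname(scale[[to]] / scale[[from]])
}

#' Serialize parameters to and from a flat key-value list
#'
#' `parameters_to_list()` flattens a parameter set to a plain named list
#' (suitable for JSON); `parameters_from_list()` inverts it.
#' `write_parameters()`/`read_parameters()` do the same through a JSON file.
#'
#' @param p A `cdm_parameters` object.
#' @param x A named list as produced by `parameters_to_list()`.
#' @param path File path.
#' @return A list, a `cdm_parameters` object, or (invisibly) the path.
#' @export
parameters_to_list <- function(p) {
  keep <- c("variant", model_param_names(p$variant), "sigma", "time_unit")
  p_un <- unclass(p)
  p_un[keep]
}

#' @rdname parameters_to_list
#' @export
parameters_from_list <- function(x) {
  x <- as.list(x)
  variant <- match.arg(tolower(x$variant), c("dmc", "rdmc"))
  args <- x[setdiff(names(x), "variant")]
  do.call(model_parameters, c(list(variant = variant), args))
}

#' @rdname parameters_to_list
#' @export
write_parameters <- function(p, path) {
  jsonlite::write_json(parameters_to_list(p), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname parameters_to_list
#' @export
read_parameters <- function(path) {
  parameters_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Extract the free (fitted) parameter values of a set
#'
#' @param p A `cdm_parameters` object.
#' @param free Character vector of free parameter names.
#' @return Named numeric vector.
#' @keywords internal
free_values <- function(p, free) {
  vapply(free, function(nm) p[[nm]], numeric(1))
}

# replace free parameters in template p with values in named vector v
set_free <- function(p, v) {
  for (nm in names(v)) p[[nm]] <- unname(v[[nm]])
  p
}
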