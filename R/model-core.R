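#' Expected automatic activation of DMC (rescaled Gamma pulse)
#'
#' The DMC automatic channel's expected activation follows a Gamma-shaped
#' pulse, rescaled so that its peak value equals the amplitude `A` and its
#' peak latency is `(a - 1) * tau`:
#' \deqn{E[X_a(t)] = A \, e^{-t/\tau} \left(\frac{t\,e}{(a-1)\tau}\right)^{a-1}.}
#' The normalization constant is isolated in this one function; an
#' alternative convention would be a one-line change here.
#'
#' @param t Time (vectorized), `>= 0`.
#' @param A Amplitude, `> 0` (sign per condition is applied by callers).
#' @param tau Gamma scale, `> 0`.
#' @param a Gamma shape, `> 1`.
#' @return Expected activation at `t`; 0 at `t = 0`, peak `A` at
#'   `(a - 1) * tau`, decaying to 0 as `t` grows.
#' @examples
#' dmc_expected_automatic(80, A = 20, tau = 80, a = 2)  # peak: exactly 20
#' @export
dmc_expected_automatic <- function(t, A, tau, a = 2) {
  check_dmc_args(t, A, tau, a)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- A * exp(-tp / tau) * (tp * exp(1) / ((a - 1) * tau))^(a - 1)
  out
}

check_dmc_args <- function(t, A, tau, a) {
  if (any(!is.finite(t)) || any(t < 0)) stop_invalid("t must be finite and >= 0")
  if (!is.finite(A) || A <= 0) stop_invalid("A must be > 0")
  if (!is.finite(tau) || tau <= 0) stop_invalid("tau must be > 0")
  if (!is.finite(a) || a <= 1) stop_invalid("a must be > 1")
  invisible(TRUE)
}

#' Superimposed drift rate of DMC
#'
#' The controlled channel contributes the constant drift `mu_c`; the
#' automatic channel contributes the time derivative of its expected
#' activation,
#' \deqn{\mu_a(t) = E[X_a(t)]\left(\frac{a-1}{t} - \frac{1}{\tau}\right),}
#' signed positive on congruent and negative on incongruent trials. The
#' automatic drift vanishes at the pulse peak `(a - 1) * tau` and changes
#' sign there. At `t = 0` the right limit is used (`A e / tau` for `a = 2`,
#' 0 for `a > 2`).
#'
#' @param t Time (vectorized), `>= 0`.
#' @param p A `cdm_parameters` object with `variant = "dmc"`.
#' @param condition `"congruent"` or `"incongruent"`.
#' @return Drift rate `mu_c + s * mu_a(t)` with `s = +1/-1` by condition.
#' @export
dmc_drift <- function(t, p, condition = c("congruent", "incongruent")) {
  condition <- match.arg(condition)
  stopifnot(p$variant == "dmc")
  s <- condition_sign(condition)
  p$mu_c + s * dmc_drift_automatic(t, p$A, p$tau, p$a)
}

dmc_drift_automatic <- function(t, A, tau, a = 2) {
  check_dmc_args(t, A, tau, a)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  e_act <- A * exp(-tp / tau) * (tp * exp(1) / ((a - 1) * tau))^(a - 1)
  out[pos] <- e_act * ((a - 1) / tp - 1 / tau)
  if (any(!pos)) {
    # right limit of mu_a at 0: ~ t^(a-2)
    lim0 <- if (abs(a - 2) < 1e-12) A * exp(1) / tau else if (a > 2) 0 else Inf
    out[!pos] <- lim0
  }
  out
}

condition_sign <- function(condition) {
  if (condition == "congruent") 1 else -1
}

#' Automatic attention weight of RDMC (exponential decay)
#'
#' RDMC assumes the automatic channel's contribution decays exponentially,
#' `w_a(t) = A0 * exp(-k * t)`, with the controlled channel taking up the
#' complement `w_c(t) = 1 - w_a(t)`. The shift rate `k` differs between
#' congruent (`k_c`) and incongruent (`k_i`) trials.
#'
#' @param t Time (vectorized), `>= 0`.
#' @param A0 Initial weight in `(0, 1]`.
#' @param k Attention-shift rate, `> 0` (1/time).
#' @return Weight in `(0, A0]`, strictly decreasing in `t`.
#' @export
rdmc_weight_automatic <- function(t, A0, k) {
  if (any(!is.finite(t)) || any(t < 0)) stop_invalid("t must be finite and >= 0")
  if (!is.finite(A0) || A0 <= 0 || A0 > 1) stop_invalid("A0 must lie in (0, 1]")
  if (!is.finite(k) || k <= 0) stop_invalid("k must be > 0")
  A0 * exp(-k * t)
}

#' Superimposed drift rate of RDMC
#'
#' The two channels' base drifts are weighted by the decaying automatic
#' attention weight: `v(t) = (1 - w_a(t)) d_c + w_a(t) * s * d_a`, with
#' `s = +1` (congruent, `k = k_c`) or `-1` (incongruent, `k = k_i`).
#' As `t` grows the automatic weight vanishes and the drift approaches
#' `d_c` from either side.
#'
#' @inheritParams dmc_drift
#' @param p A `cdm_parameters` object with `variant = "rdmc"`.
#' @return Drift rate at `t`.
#' @export
rdmc_drift <- function(t, p, condition = c("congruent", "incongruent")) {
  condition <- match.arg(condition)
  stopifnot(p$variant == "rdmc")
  s <- condition_sign(condition)
  k <- if (condition == "congruent") p$k_c else p$k_i
  w <- rdmc_weight_automatic(t, p$A0, k)
  (1 - w) * p$d_c + w * s * p$d_a
}

#' Time-dependent drift function for either model
#'
#' Returns a vectorized function of time giving the superimposed drift for
#' the given parameters and condition; the form consumed by
#' [solve_forward()].
#'
#' @param p A `cdm_parameters` object.
#' @param condition `"congruent"` or `"incongruent"`.
#' @return A function `t -> drift`.
#' @export
drift_function <- function(p, condition = c("congruent", "incongruent")) {
  condition <- match.arg(condition)
  validate_parameters(p)
  if (p$variant == "dmc") function(t) dmc_drift(t, p, condition)
  else function(t) rdmc_drift(t, p, condition)
}

#' Expected accumulated activation
#'
#' Integral of the superimposed (or per-channel) drift from 0 to `t`; the
#' curves plotted in textbook illustrations of both models. Closed forms:
#' for DMC the automatic channel's integral is the Gamma pulse itself; for
#' RDMC the automatic channel approaches the asymptote
#' `s * d_a * A0 / k` and the controlled channel approaches `d_c * t`.
#'
#' @param p A `cdm_parameters` object.
#' @param condition `"congruent"` or `"incongruent"`.
#' @param t Time (vectorized), `>= 0`.
#' @param channel `"superimposed"`, `"automatic"`, or `"controlled"`.
#' @return Expected activation at `t` (0 at `t = 0`).
#' @export
expected_activation <- function(p, condition = c("congruent", "incongruent"),
                                t,
                                channel = c("superimposed", "automatic",
                                            "controlled")) {
  condition <- match.arg(condition)
  channel <- match.arg(channel)
  validate_parameters(p)
  if (any(!is.finite(t)) || any(t < 0)) stop_invalid("t must be finite and >= 0")
  s <- condition_sign(condition)
  if (p$variant == "dmc") {
    auto <- s * dmc_expected_automatic(t, p$A, p$tau, p$a)
    ctrl <- p$mu_c * t
  } else {
    k <- if (condition == "congruent") p$k_c else p$k_i
    ramp <- p$A0 * (1 - exp(-k * t)) / k   # integral of w_a
    auto <- s * p$d_a * ramp
    ctrl <- p$d_c * (t - ramp)
  }
  switch(channel,
         superimposed = auto + ctrl,
         automatic = auto,
         controlled = ctrl)
}
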