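#' Parameter ranges for generation and search
#'
#' Box bounds per free parameter, kept separately for *generation*
#' (drawing true parameter sets in a recovery study) and *search* (the
#' optimizer's box). Generation bounds must lie strictly inside search
#' bounds, so that a generating value never sits on the search boundary.
#' Fixed parameters (by default the non-decision range `s_t0 = 0.07` s and,
#' for DMC, the Gamma shape `a = 2`) are excluded from both.
#'
#' The numeric ranges shipped with the package
#' (`inst/extdata/ranges_*_synthetic.json`) are plausible stand-ins on the
#' canonical seconds / `sigma = 1` scale, chosen from published parameter
#' values of both models; they are data, not code, and can be replaced by
#' any transcription via [read_ranges()].
#'
#' @param model `"dmc"` or `"rdmc"`.
#' @param gen Named list of `c(lower, upper)` generation bounds.
#' @param search Named list of `c(lower, upper)` search bounds.
#' @param fixed Named list of fixed parameter values.
#' @return A `cdm_ranges` object.
#' @export
parameter_ranges <- function(model = c("dmc", "rdmc"), gen, search,
                             fixed = list(s_t0 = 0.07)) {
  model <- match.arg(model)
  free <- setdiff(model_param_names(model), names(fixed))
  for (nm in free) {
    g <- gen[[nm]]; s <- search[[nm]]
    if (is.null(g) || is.null(s))
      stop_config("missing bounds for parameter '%s'", nm)
    if (length(g) != 2 || length(s) != 2 || g[1] >= g[2] || s[1] >= s[2])
      stop_config("bounds for '%s' must be (lower < upper)", nm)
    if (g[1] < s[1] || g[2] > s[2])
      stop_config("generation bounds for '%s' must lie inside search bounds",
                  nm)
  }
  structure(list(model = model, free = free,
                 gen = gen[free], search = search[free], fixed = fixed),
            class = "cdm_ranges")
}

#' Load the ranges shipped with the package
#'
#' @param model `"dmc"` or `"rdmc"`.
#' @return A `cdm_ranges` object.
#' @export
default_ranges <- function(model = c("dmc", "rdmc")) {
  model <- match.arg(model)
  read_ranges(system.file("extdata",
                          sprintf("ranges_%s_synthetic.json", model),
                          package = "conflictdm", mustWork = TRUE))
}

#' @rdname parameter_ranges
#' @param path JSON file with fields `model`, `gen`, `search`, `fixed`.
#' @export
read_ranges <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  parameter_ranges(x$model, gen = as.list(x$gen),
                   search = as.list(x$search), fixed = as.list(x$fixed))
}

#' @rdname parameter_ranges
#' @param ranges A `cdm_ranges` object to serialize.
#' @export
write_ranges <- function(ranges, path) {
  jsonlite::write_json(unclass(ranges)[c("model", "gen", "search", "fixed")],
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Draw random parameter sets from uniform generation ranges
#'
#' Each free parameter is drawn independently from a uniform distribution
#' over its generation bounds; fixed parameters are filled in as constants.
#'
#' @param ranges A [parameter_ranges()] object.
#' @param n_sets Number of sets to draw, `>= 1`.
#' @param seed Integer seed (local to this call).
#' @return List of `cdm_parameters` objects, length `n_sets`.
#' @export
draw_parameter_sets <- function(ranges, n_sets, seed) {
  stopifnot(inherits(ranges, "cdm_ranges"))
  if (n_sets < 1) stop_config("n_sets must be >= 1")
  draws <- with_local_seed(seed, {
    vapply(ranges$free,
           function(nm) stats::runif(n_sets, ranges$gen[[nm]][1],
                                     ranges$gen[[nm]][2]),
           numeric(n_sets))
  })
  draws <- matrix(draws, nrow = n_sets,
                  dimnames = list(NULL, ranges$free))
  lapply(seq_len(n_sets), function(i) {
    args <- c(as.list(draws[i, ]), ranges$fixed)
    do.call(model_parameters, c(list(variant = ranges$model), args))
  })
}

#' Sample a trial table from defective RT CDFs by inverse transform
#'
#' For each trial a uniform deviate `u` on `(0, total mass)` is drawn; the
#' response is correct (upper boundary) when `u` falls below the upper
#' branch mass, and the RT is the linear-interpolation inverse of the
#' corresponding defective CDF at `u`.
#'
#' @param cdfs Named list of `cdm_cdfs` (kind `"rt"`), one per condition
#'   (`congruent`, `incongruent`).
#' @param n_per_condition Trials per condition, `>= 0`.
#' @param seed Integer seed.
#' @param participant Participant label stored with the trials.
#' @param mass_min Minimum acceptable total mass per condition (default
#'   0.999); below it sampling aborts with a horizon error.
#' @return A trial table: data.frame with columns `participant`,
#'   `condition`, `rt_s`, `response` (`correct`/`error`).
#' @export
sample_trials <- function(cdfs, n_per_condition, seed,
                          participant = "synthetic", mass_min = 0.999) {
  stopifnot(all(c("congruent", "incongruent") %in% names(cdfs)))
  if (n_per_condition == 0) return(empty_trials())
  out <- with_local_seed(seed, {
    lapply(c("congruent", "incongruent"), function(cond) {
      cdf <- cdfs[[cond]]
      pu <- cdf$F_upper[length(cdf$F_upper)]
      pl <- cdf$F_lower[length(cdf$F_lower)]
      if (pu + pl < mass_min)
        stop_config(
          "condition '%s': total mass %.4f < %.4f, extend the horizon",
          cond, pu + pl, mass_min)
      u <- stats::runif(n_per_condition, 0, pu + pl)
      correct <- u < pu
      rt <- numeric(n_per_condition)
      rt[correct] <- invert_cdf(cdf$times, cdf$F_upper, u[correct])
      rt[!correct] <- invert_cdf(cdf$times, cdf$F_lower, u[!correct] - pu)
      data.frame(participant = participant, condition = cond, rt_s = rt,
                 response = ifelse(correct, "correct", "error"))
    })
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

empty_trials <- function() {
  data.frame(participant = character(), condition = character(),
             rt_s = numeric(), response = character())
}

# inverse of a nondecreasing defective CDF by linear interpolation;
# ties broken toward the earlier node
invert_cdf <- function(times, F, u) {
  if (length(u) == 0) return(numeric(0))
  idx <- findInterval(u, F, left.open = TRUE)  # earliest node with F >= u
  idx <- pmin(pmax(idx, 1), length(F) - 1)
  F0 <- F[idx]; F1 <- F[idx + 1]
  frac <- ifelse(F1 > F0, (u - F0) / (F1 - F0), 0)
  frac <- pmin(pmax(frac, 0), 1)
  times[idx] + frac * (times[idx + 1] - times[idx])
}

#' Model-implied RT CDFs for both conditions
#'
#' Solves the forward equation per condition, convolves with the uniform
#' non-decision time, and returns defective RT CDFs — the objects consumed
#' by [sample_trials()].
#'
#' @param p A `cdm_parameters` object.
#' @param grids A [cdm_grids()] object.
#' @return Named list of `cdm_cdfs` (`congruent`, `incongruent`).
#' @export
model_cdfs <- function(p, grids = cdm_grids()) {
  validate_parameters(p)
  out <- lapply(c("congruent", "incongruent"), function(cond) {
    d <- solve_forward(drift_function(p, cond), p$b, p$sigma, grids,
                       deficit_warn = NA)
    cdf_from_density(convolve_nondecision(d, p$t0, p$s_t0))
  })
  names(out) <- c("congruent", "incongruent")
  out
}

#' Generate a synthetic trial table from a parameter set
#'
#' Composition of [model_cdfs()] and [sample_trials()]: both conditions are
#' generated from the same parameter set with condition-specific drift.
#'
#' @inheritParams sample_trials
#' @param p A `cdm_parameters` object.
#' @param grids A [cdm_grids()] object (recovery-study convention:
#'   `dt = dx = 0.001`).
#' @return A trial table (see [sample_trials()]).
#' @export
generate_dataset <- function(p, n_per_condition, seed,
                             grids = cdm_grids(0.001, 0.001, 3.0),
                             participant = "synthetic") {
  if (n_per_condition == 0) return(empty_trials())
  sample_trials(model_cdfs(p, grids), n_per_condition, seed,
                participant = participant)
}

#' Read and write trial tables
#'
#' The pipeline's single data interchange format: tab-delimited text with
#' header `participant`, `condition` (`congruent`/`incongruent`), `rt_s`
#' (seconds), `response` (`correct`/`error`).
#'
#' @param trials A trial table data.frame.
#' @param path File path.
#' @return `read_trials()` the validated data.frame; `write_trials()` the
#'   path, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_trials(trials)
  trials
}

validate_trials <- function(trials) {
  need <- c("participant", "condition", "rt_s", "response")
  if (!all(need %in% names(trials)))
    stop_config("trial table must have columns %s",
                paste(need, collapse = ", "))
  if (nrow(trials) > 0) {
    if (!all(trials$condition %in% c("congruent", "incongruent")))
      stop_config("condition must be 'congruent' or 'incongruent'")
    if (!all(trials$response %in% c("correct", "error")))
      stop_config("response must be 'correct' or 'error'")
    if (any(!is.finite(trials$rt_s)) || any(trials$rt_s <= 0))
      stop_config("rt_s must be finite and > 0")
  }
  invisible(trials)
}
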