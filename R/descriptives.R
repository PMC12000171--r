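#' RT quantiles of observed trials or a predicted distribution
#'
#' Empirical quantiles use linear interpolation of order statistics
#' (`stats::quantile` type 7). Predicted quantiles invert the normalized
#' correct-branch defective CDF. By convention quantiles are computed on
#' correct responses only (the standard for delta plots); pass
#' `correct_only = FALSE` to pool.
#'
#' @param x Either a trial table restricted to one condition, a numeric
#'   vector of RTs, or a `cdm_cdfs` object.
#' @param probs Increasing probabilities in `(0, 1)`; default
#'   `c(.1, .3, .5, .7, .9)`.
#' @param correct_only For trial tables: use correct responses only
#'   (default `TRUE`).
#' @return Numeric vector of quantiles (time units).
#' @export
rt_quantiles <- function(x, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         correct_only = TRUE) {
  if (any(probs <= 0 | probs >= 1) || is.unsorted(probs, strictly = TRUE))
    stop_config("probs must be strictly increasing within (0, 1)")
  if (inherits(x, "cdm_cdfs")) {
    mass <- x$F_upper[length(x$F_upper)]
    return(invert_cdf(x$times, x$F_upper / mass, probs))
  }
  rts <- if (is.data.frame(x)) {
    validate_trials(x)
    if (correct_only) x$rt_s[x$response == "correct"] else x$rt_s
  } else as.numeric(x)
  if (length(rts) < 2) stop_config("need at least 2 RTs for quantiles")
  unname(stats::quantile(rts, probs, type = 7))
}

#' Delta function from paired condition quantiles
#'
#' At each probability level, pairs the mean of the congruent and
#' incongruent quantiles with their difference (incongruent minus
#' congruent). Plotting `delta` against `mean_rt` gives the delta plot;
#' a negative slope means the congruency effect shrinks for slow
#' responses.
#'
#' @param q_congruent,q_incongruent Quantile vectors at the same `probs`.
#' @param probs The shared probability levels.
#' @return A `data.frame` with `prob`, `mean_rt`, `delta`.
#' @export
delta_function <- function(q_congruent, q_incongruent,
                           probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (length(q_congruent) != length(q_incongruent) ||
      length(q_congruent) != length(probs))
    stop_config("quantile vectors and probs must have equal length")
  data.frame(prob = probs,
             mean_rt = (q_congruent + q_incongruent) / 2,
             delta = q_incongruent - q_congruent)
}

#' Conditional accuracy function
#'
#' Pools correct and error RTs of one condition into `n_bins`
#' equal-count bins (ordered by RT; remainder trials go to the earliest
#' bins) and reports the proportion of correct responses per bin. The
#' count-weighted mean of bin accuracies equals overall accuracy exactly.
#'
#' @param trials Trial table restricted to one condition, non-empty.
#' @param n_bins Number of RT bins, `>= 2`; must not exceed the trial
#'   count.
#' @return A `data.frame` with `bin`, `n`, `mean_rt`, `accuracy`.
#' @export
caf <- function(trials, n_bins = 5) {
  validate_trials(trials)
  if (n_bins < 2) stop_config("n_bins must be >= 2")
  n <- nrow(trials)
  if (n < n_bins) stop_config("fewer trials (%d) than bins (%d)", n, n_bins)
  ord <- order(trials$rt_s)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1, extra), rep(0, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)
  rt_sorted <- trials$rt_s[ord]
  correct_sorted <- trials$response[ord] == "correct"
  data.frame(bin = seq_len(n_bins),
             n = sizes,
             mean_rt = as.numeric(tapply(rt_sorted, bin, mean)),
             accuracy = as.numeric(tapply(correct_sorted, bin, mean)))
}

#' Per-participant and group-averaged descriptives
#'
#' Computes RT quantiles per condition, the delta function, and CAFs for
#' every participant, then averages curves across participants (group
#' curves are means of per-participant curves, not pooled-trial curves).
#'
#' @param trials A trial table, possibly with several participants.
#' @param probs Quantile levels.
#' @param n_bins CAF bins.
#' @return List with `quantiles`, `delta`, `caf` (each a data.frame with a
#'   `participant` column, `"average"` rows included).
#' @export
describe_trials <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            n_bins = 5) {
  validate_trials(trials)
  parts <- unique(trials$participant)
  qs <- list(); ds <- list(); cs <- list()
  for (pp in parts) {
    tt <- trials[trials$participant == pp, ]
    qc <- rt_quantiles(tt[tt$condition == "congruent", ], probs)
    qi <- rt_quantiles(tt[tt$condition == "incongruent", ], probs)
    qs[[pp]] <- data.frame(participant = pp,
                           prob = rep(probs, 2),
                           condition = rep(c("congruent", "incongruent"),
                                           each = length(probs)),
                           quantile = c(qc, qi))
    ds[[pp]] <- cbind(participant = pp, delta_function(qc, qi, probs))
    cs[[pp]] <- do.call(rbind, lapply(c("congruent", "incongruent"),
      function(cond) cbind(participant = pp, condition = cond,
                           caf(tt[tt$condition == cond, ], n_bins))))
  }
  avg <- function(df, by, value) {
    agg <- stats::aggregate(df[value], df[by], mean)
    cbind(participant = "average", agg)
  }
  q_all <- do.call(rbind, qs); d_all <- do.call(rbind, ds)
  c_all <- do.call(rbind, cs)
  rownames(q_all) <- rownames(d_all) <- rownames(c_all) <- NULL
  list(quantiles = rbind(q_all, avg(q_all, c("prob", "condition"),
                                    "quantile")),
       delta = rbind(d_all, avg(d_all, "prob", c("mean_rt", "delta"))),
       caf = rbind(c_all, avg(c_all, c("condition", "bin"),
                              c("n", "mean_rt", "accuracy"))))
}
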