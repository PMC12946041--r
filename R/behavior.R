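#' Minimum correct responses to exceed chance
#'
#' One-tailed binomial criterion at level `alpha` against p = 0.5. The
#' default `"quantile"` rule returns the (1 - alpha) quantile of
#' Binomial(n_trials, 0.5) -- the smallest k whose cumulative probability is
#' at least 1 - alpha. The `"strict"` rule returns the smallest k with
#' P(X >= k) < alpha (the conventional rejection region); the two differ by
#' at most one count.
#'
#' @param n_trials Number of trials.
#' @param alpha Significance level.
#' @param rule `"quantile"` (default) or `"strict"`.
#' @return List with `min_correct` and `accuracy_fraction`.
#' @examples
#' chance_criterion(120) # 69 correct, accuracy 0.575
#' @export
chance_criterion <- function(n_trials, alpha = 0.05,
                             rule = c("quantile", "strict")) {
  rule <- match.arg(rule)
  if (n_trials < 1) abort("`n_trials` must be >= 1", class = "spnlab_parameter_error")
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)", class = "spnlab_parameter_error")
  }
  k <- if (rule == "quantile") {
    qbinom(1 - alpha, n_trials, 0.5)
  } else {
    # smallest k with P(X >= k) < alpha
    which(pbinom(0:n_trials - 1, n_trials, 0.5, lower.tail = FALSE) < alpha)[1] - 1
  }
  list(min_correct = as.integer(k), accuracy_fraction = k / n_trials)
}

clamp_rate <- function(count, n) {
  pmin(pmax(count / n, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Signal-detection metrics from a confusion count
#'
#' Equal-variance Gaussian model: `d' = z(H) - z(FA)` and
#' `c = -(z(H) + z(FA))/2`, with hit and false-alarm rates clamped to
#' `[1/(2N), 1 - 1/(2N)]` within each stimulus class before the
#' inverse-normal transform.
#'
#' @param hits,misses Counts on signal (symmetric) trials.
#' @param fas,crs Counts on noise (asymmetric) trials (false alarms /
#'   correct rejections).
#' @return Tibble: `hit_rate`, `fa_rate`, `dprime`, `criterion`, `n_signal`,
#'   `n_noise`.
#' @examples
#' sdt_metrics(10, 0, 0, 10) # clamped to H = .95, FA = .05
#' @export
sdt_metrics <- function(hits, misses, fas, crs) {
  n_signal <- hits + misses
  n_noise <- fas + crs
  if (any(n_signal < 1) || any(n_noise < 1)) {
    abort("need >= 1 signal and >= 1 noise trial", class = "spnlab_parameter_error")
  }
  h <- clamp_rate(hits, n_signal)
  f <- clamp_rate(fas, n_noise)
  tibble::tibble(hit_rate = h, fa_rate = f,
                 dprime = qnorm(h) - qnorm(f),
                 criterion = -(qnorm(h) + qnorm(f)) / 2,
                 n_signal = n_signal, n_noise = n_noise)
}

#' Per-participant signal-detection metrics from a behavior table
#'
#' "Symmetric" is the signal class: a hit is responding "symmetric" on a
#' symmetric trial, a false alarm is responding "symmetric" on an asymmetric
#' trial.
#'
#' @param behavior Tibble with `participant`, `condition`, `response`.
#' @return Tibble with one row per participant: `participant`, `n_correct`,
#'   `accuracy`, plus the [sdt_metrics()] columns.
#' @export
sdt_from_behavior <- function(behavior) {
  counts <- dplyr::group_by(behavior, .data$participant) |>
    dplyr::summarise(
      n_correct = sum(.data$response == .data$condition),
      accuracy = mean(.data$response == .data$condition),
      hits = sum(.data$condition == "symmetric" & .data$response == "symmetric"),
      misses = sum(.data$condition == "symmetric" & .data$response == "asymmetric"),
      fas = sum(.data$condition == "asymmetric" & .data$response == "symmetric"),
      crs = sum(.data$condition == "asymmetric" & .data$response == "asymmetric"),
      .groups = "drop")
  dplyr::bind_cols(
    counts[, c("participant", "n_correct", "accuracy")],
    sdt_metrics(counts$hits, counts$misses, counts$fas, counts$crs)
  )
}

#' One-sample t test with one- or two-sided intervals
#'
#' Thin, tidy wrapper around the standard one-sample t test, flagging the
#' zero-variance degenerate case instead of erroring.
#'
#' @param values Numeric vector (n >= 2, finite).
#' @param mu Null value.
#' @param alternative `"two.sided"`, `"less"`, or `"greater"`.
#' @param conf Confidence level.
#' @return Tibble: `estimate`, `t`, `df`, `p`, `ci_low`, `ci_high`,
#'   `alternative`. Zero variance yields `NA` statistics with a warning.
#' @export
one_sample_t <- function(values, mu = 0,
                         alternative = c("two.sided", "less", "greater"),
                         conf = 0.95) {
  alternative <- match.arg(alternative)
  values <- values[!is.na(values)]
  if (length(values) < 2 || any(!is.finite(values))) {
    abort("need >= 2 finite values", class = "spnlab_parameter_error")
  }
  if (sd(values) == 0) {
    warn("zero variance; t undefined")
    return(tibble::tibble(estimate = mean(values), t = NA_real_,
                          df = length(values) - 1, p = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          alternative = alternative))
  }
  tt <- t.test(values, mu = mu, alternative = alternative, conf.level = conf)
  tibble::tibble(estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 alternative = alternative)
}

#' Probability-scale summary of a logit-scale estimate
#'
#' Back-transforms a logit intercept and its standard error (e.g., from an
#' intercept-only mixed logistic model) to the probability scale:
#' `plogis(intercept)` with Wald CI endpoints `plogis(intercept -+ z * se)`.
#'
#' @param intercept Logit-scale estimate.
#' @param se Standard error (>= 0).
#' @param conf Confidence level.
#' @return Tibble: `estimate`, `ci_low`, `ci_high`.
#' @examples
#' logit_summary(1.554, 0.123) # 0.825 [0.788, 0.858]
#' @export
logit_summary <- function(intercept, se, conf = 0.95) {
  if (se < 0) abort("`se` must be >= 0", class = "spnlab_parameter_error")
  z <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(estimate = stats::plogis(intercept),
                 ci_low = stats::plogis(intercept - z * se),
                 ci_high = stats::plogis(intercept + z * se))
}

#' Expected accuracy under the equal-variance SDT model
#'
#' With equal condition frequencies, accuracy =
#' `(pnorm(d'/2 - c) + pnorm(d'/2 + c)) / 2`.
#'
#' @param dprime Sensitivity.
#' @param criterion Bias.
#' @param p_symmetric Proportion of signal (symmetric) trials.
#' @return Expected proportion correct.
#' @export
sdt_expected_accuracy <- function(dprime, criterion, p_symmetric = 0.5) {
  p_symmetric * pnorm(dprime / 2 - criterion) +
    (1 - p_symmetric) * pnorm(dprime / 2 + criterion)
}
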