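#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile form of the exact interval; lower bound 0 when
#' `successes = 0`, upper bound 1 when `successes = n`.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level.
#' @return Tibble: `lower`, `upper`.
#' @examples
#' clopper_pearson(891, 1000) # about (0.87, 0.91)
#' @export
clopper_pearson <- function(successes, n, conf = 0.95) {
  if (any(n < 1) || any(successes < 0) || any(successes > n)) {
    abort("require 0 <= successes <= n, n >= 1", class = "spnlab_parameter_error")
  }
  a <- 1 - conf
  lower <- ifelse(successes == 0, 0, qbeta(a / 2, successes, n - successes + 1))
  upper <- ifelse(successes == n, 1, qbeta(1 - a / 2, successes + 1, n - successes))
  tibble::tibble(lower = lower, upper = upper)
}

#' Per-trial ROI window means
#'
#' Collapses each epoch to a single scalar: the mean over the ROI electrodes
#' and window samples. Computing these once makes the subsampling analysis a
#' cheap resampling of scalars (mathematically identical to re-averaging the
#' epochs).
#'
#' @param epochs An `eeg_epochs` (baseline-corrected, correct-only).
#' @param roi An `roi_spec`.
#' @return Tibble: `participant`, `trial`, `condition`, `roi_mean_uv`.
#' @export
trial_roi_means <- function(epochs, roi = canonical_roi()) {
  ch <- match(roi$electrodes, epochs$channels)
  if (anyNA(ch)) {
    abort(sprintf("ROI electrode(s) absent from data: %s",
                  paste(roi$electrodes[is.na(ch)], collapse = ", ")),
          class = "spnlab_parameter_error")
  }
  s <- window_index(epochs$times_ms, roi$window_ms)
  sub <- epochs$data[ch, s, , drop = FALSE]
  vals <- colMeans(matrix(sub, prod(dim(sub)[1:2]), dim(sub)[3]))
  tibble::tibble(epochs$epoch_table[, c("participant", "trial", "condition")],
                 roi_mean_uv = vals)
}

#' Fixed-cohort trial-subsampling reliability of the SPN
#'
#' For each per-condition count `m` and each of `n_perm` permutations, draws
#' without replacement `m` symmetric and `m` asymmetric trials within every
#' participant, computes each participant's SPN as `mean(S) - mean(A)`, and
#' tests the across-participant mean against zero with a one-tailed
#' one-sample t test (H1: SPN < 0). Reliability at `m` is the proportion of
#' permutations with p < `alpha`, with an exact Clopper-Pearson interval;
#' the mean SPN across permutations and its 2.5-97.5% percentile band are
#' reported alongside.
#'
#' The cohort is fixed and balanced: every participant must have at least
#' `max(m_values)` trials in each condition, otherwise an error names the
#' offenders.
#'
#' @param trial_means Tibble from [trial_roi_means()].
#' @param m_values Per-condition counts to test (default 5, 10, 15, 20, 25).
#' @param n_perm Permutations per m (default 1000).
#' @param alpha Test level for the one-tailed t test.
#' @param seed Master seed; each (m, permutation, participant) draw uses a
#'   derived substream, so any subset is reproducible.
#' @return An `spn_reliability` object; `tidy()` gives the curve tibble
#'   (`m`, `reliability`, `ci_low`, `ci_high`, `mean_spn`, `band_low`,
#'   `band_high`).
#' @export
subsample_reliability <- function(trial_means, m_values = c(5, 10, 15, 20, 25),
                                  n_perm = 1000, alpha = 0.05, seed = 1) {
  counts <- dplyr::count(trial_means, .data$participant, .data$condition)
  wide <- tidyr::pivot_wider(counts, names_from = "condition",
                             values_from = "n", values_fill = 0)
  m_max <- max(m_values)
  short <- wide$participant[wide$symmetric < m_max | wide$asymmetric < m_max]
  if (length(short) > 0) {
    abort(sprintf("participant(s) with fewer than %d epochs in a condition: %s",
                  m_max, paste(short, collapse = ", ")),
          class = "spnlab_cohort_error")
  }
  participants <- sort(unique(trial_means$participant))
  by_pc <- split(trial_means$roi_mean_uv,
                 list(trial_means$participant, trial_means$condition))
  sym <- lapply(participants, function(p) by_pc[[paste(p, "symmetric", sep = ".")]])
  asym <- lapply(participants, function(p) by_pc[[paste(p, "asymmetric", sep = ".")]])

  rows <- purrr::map_dfr(seq_along(m_values), function(mi) {
    m <- m_values[mi]
    stats_m <- vapply(seq_len(n_perm), function(b) {
      spns <- vapply(seq_along(participants), function(pi) {
        with_seed(substream_seed(seed, mi, b, pi), {
          s_draw <- sample(sym[[pi]], m)
          a_draw <- sample(asym[[pi]], m)
          mean(s_draw) - mean(a_draw)
        })
      }, numeric(1))
      tt <- one_sample_t(spns, alternative = "less")
      c(p = tt$p, spn = mean(spns))
    }, c(p = 0, spn = 0))
    k <- sum(stats_m["p", ] < alpha)
    ci <- clopper_pearson(k, n_perm)
    band <- stats::quantile(stats_m["spn", ], c(0.025, 0.975), names = FALSE)
    tibble::tibble(m = m, reliability = k / n_perm,
                   ci_low = ci$lower, ci_high = ci$upper,
                   mean_spn = mean(stats_m["spn", ]),
                   band_low = band[1], band_high = band[2])
  })
  structure(list(curve = rows, m_values = m_values, n_perm = n_perm,
                 alpha = alpha, seed = seed,
                 n_participants = length(participants)),
            class = "spn_reliability")
}

#' @export
print.spn_reliability <- function(x, ...) {
  cat(sprintf("<spn_reliability> %d participants, %d permutations per m\n",
              x$n_participants, x$n_perm))
  print(x$curve)
  invisible(x)
}

#' @export
tidy.spn_reliability <- function(x, ...) x$curve

#' @export
glance.spn_reliability <- function(x, ...) {
  tibble::tibble(n_m = length(x$m_values), n_perm = x$n_perm,
                 alpha = x$alpha,
                 reliability_max_m = x$curve$reliability[nrow(x$curve)],
                 n_participants = x$n_participants)
}

#' Analytic power of a Pearson correlation test
#'
#' Two-sided power via the Fisher-z approximation:
#' `Phi(lambda - z_{1-alpha/2}) + Phi(-lambda - z_{1-alpha/2})` with
#' `lambda = atanh(rho) * sqrt(n - 3)`.
#'
#' @param rho Population correlation, |rho| < 1.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided test level.
#' @return Power.
#' @examples
#' correlation_power(0.30, 23) # about 0.28
#' @export
correlation_power <- function(rho, n, alpha = 0.05) {
  if (any(abs(rho) >= 1)) abort("|rho| must be < 1", class = "spnlab_parameter_error")
  if (any(n < 4)) abort("`n` must be >= 4", class = "spnlab_parameter_error")
  lambda <- atanh(rho) * sqrt(n - 3)
  zcrit <- qnorm(1 - alpha / 2)
  pnorm(lambda - zcrit) + pnorm(-lambda - zcrit)
}
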