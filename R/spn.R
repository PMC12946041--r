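#' Region-of-interest specification
#'
#' @param electrodes Electrode labels.
#' @param window_ms Time window `(start, end)` in ms, start < end.
#' @param origin `"canonical"` or `"cluster-derived"`.
#' @return List of class `roi_spec`.
#' @export
roi_spec <- function(electrodes, window_ms, origin = "canonical") {
  if (length(electrodes) == 0) {
    abort("ROI must contain at least one electrode",
          class = "spnlab_parameter_error")
  }
  if (!(window_ms[1] < window_ms[2])) {
    abort("ROI window must have start < end", class = "spnlab_parameter_error")
  }
  structure(list(electrodes = as.character(electrodes),
                 window_ms = as.numeric(window_ms), origin = origin),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %s: %d electrodes, %g-%g ms\n", x$origin,
              length(x$electrodes), x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Canonical posterior SPN region of interest
#'
#' The literature-standard posterior set (O1, O2, Oz, PO3, PO4, PO7, PO8)
#' with the conventional 250-600 ms window.
#'
#' @return An `roi_spec`.
#' @export
canonical_roi <- function() {
  roi_spec(c("O1", "O2", "Oz", "PO3", "PO4", "PO7", "PO8"), c(250, 600),
           origin = "canonical")
}

#' Cluster-derived region of interest
#'
#' Builds an ROI from a significant cluster of a [permutation_test()]: the
#' union of the cluster's electrodes and its time window. By default the
#' most massive significant negative cluster is used.
#'
#' @param test A `cluster_test`.
#' @param sign `"negative"` or `"positive"`.
#' @return An `roi_spec` with origin `"cluster-derived"`, or `NULL` if no
#'   significant cluster of that sign exists.
#' @export
cluster_roi <- function(test, sign = "negative") {
  cl <- test$clusters[test$clusters$significant & test$clusters$sign == sign, ]
  if (nrow(cl) == 0) return(NULL)
  cl <- cl[which.max(abs(cl$mass)), ]
  roi_spec(cl$electrodes[[1]], c(cl$window_start_ms, cl$window_end_ms),
           origin = "cluster-derived")
}

roi_indices <- function(erps, roi) {
  missing_el <- setdiff(roi$electrodes, erps$channels)
  if (length(missing_el) > 0) {
    abort(sprintf("ROI electrode(s) absent from data: %s",
                  paste(missing_el, collapse = ", ")),
          class = "spnlab_parameter_error")
  }
  list(ch = match(roi$electrodes, erps$channels),
       s = window_index(erps$times_ms, roi$window_ms))
}

#' Per-participant SPN amplitude in an ROI
#'
#' Follows the standard order of operations: window mean per electrode per
#' condition, electrode-wise condition difference (S - A), then mean of the
#' differences across ROI electrodes. (All steps are linear, so the order
#' does not affect the value; it is fixed for reproducibility.)
#'
#' @param erps A `subject_erps`.
#' @param roi An `roi_spec`.
#' @param minuend,subtrahend Condition labels (default S - A).
#' @return Tibble of class `spn_estimate`: `participant`, `amplitude_uv`;
#'   the ROI is attached as attribute `roi`.
#' @export
spn_amplitude <- function(erps, roi = canonical_roi(),
                          minuend = "symmetric", subtrahend = "asymmetric") {
  ri <- roi_indices(erps, roi)
  mi <- match(minuend, erps$conditions)
  si <- match(subtrahend, erps$conditions)
  # window mean per electrode x participant x condition
  wm <- apply(erps$data[ri$ch, ri$s, , , drop = FALSE], c(1, 3, 4), mean)
  diffs <- wm[, , mi, drop = FALSE] - wm[, , si, drop = FALSE] # electrode x participant
  amp <- colMeans(matrix(diffs, length(ri$ch)))
  out <- tibble::tibble(participant = erps$participants, amplitude_uv = amp)
  attr(out, "roi") <- roi
  class(out) <- c("spn_estimate", class(out))
  out
}

#' Peak latency of the group difference wave in an ROI
#'
#' Averages the S - A difference over participants and ROI electrodes and
#' locates the sample in the window with the minimal (most negative) value;
#' ties break to the earliest time. Set `direction = "max"` to search for a
#' maximum instead.
#'
#' @param erps A `subject_erps`.
#' @param roi An `roi_spec`.
#' @param direction `"min"` (negativity, default) or `"max"`.
#' @return List with `time_ms` and `amplitude_uv`.
#' @export
peak_latency <- function(erps, roi = canonical_roi(), direction = c("min", "max")) {
  direction <- match.arg(direction)
  ri <- roi_indices(erps, roi)
  d <- subject_differences(erps)
  g <- apply(d[ri$ch, ri$s, , drop = FALSE], 2, mean) # ROI+group mean per sample
  k <- if (direction == "min") which.min(g) else which.max(g)
  list(time_ms = erps$times_ms[ri$s[k]], amplitude_uv = g[k])
}

#' Split ROI electrodes into hemispheric sets
#'
#' Left = odd 10-20 numeric suffix, right = even; midline (z-suffix)
#' excluded.
#'
#' @param electrodes Character vector of 10-20 labels.
#' @return List with `left` and `right`.
#' @export
split_hemispheres <- function(electrodes) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", electrodes)))
  list(left = electrodes[!is.na(num) & num %% 2 == 1],
       right = electrodes[!is.na(num) & num %% 2 == 0])
}

li_value <- function(left, right) {
  den <- abs(left) + abs(right)
  ifelse(den > 0, (right - left) / den, NA_real_)
}

#' Lateralization index of the SPN or of condition means
#'
#' Both variants normalize a right-minus-left difference by the sum of the
#' absolute hemispheric means, bounding defined values in [-1, 1].
#' \itemize{
#'   \item `"spn"`: per participant, SPN (S - A) computed separately on the
#'     left and right electrode sets; LI = (SPN_R - SPN_L)/(|SPN_L| +
#'     |SPN_R|). One value per participant.
#'   \item `"condition"`: per participant and condition, hemispheric means of
#'     the raw ERP; LI = (mean_R - mean_L)/(|mean_L| + |mean_R|). Two values
#'     per participant.
#' }
#' Zero denominators yield `NA` with a warning.
#'
#' @param erps A `subject_erps`.
#' @param roi An `roi_spec` whose electrodes are split by
#'   [split_hemispheres()].
#' @param type `"spn"` or `"condition"`.
#' @return Tibble: `participant`, (`condition`,) `li`.
#' @export
lateralization <- function(erps, roi, type = c("spn", "condition")) {
  type <- match.arg(type)
  hemi <- split_hemispheres(roi$electrodes)
  if (length(hemi$left) == 0 || length(hemi$right) == 0) {
    abort("ROI must contain electrodes in both hemispheres",
          class = "spnlab_parameter_error")
  }
  roi_l <- roi_spec(hemi$left, roi$window_ms, roi$origin)
  roi_r <- roi_spec(hemi$right, roi$window_ms, roi$origin)
  if (type == "spn") {
    l <- spn_amplitude(erps, roi_l)$amplitude_uv
    r <- spn_amplitude(erps, roi_r)$amplitude_uv
    out <- tibble::tibble(participant = erps$participants,
                          li = li_value(l, r))
  } else {
    il <- roi_indices(erps, roi_l)
    ir <- roi_indices(erps, roi_r)
    rows <- list()
    for (cj in seq_along(erps$conditions)) {
      ml <- apply(erps$data[il$ch, il$s, , cj, drop = FALSE], 3, mean)
      mr <- apply(erps$data[ir$ch, ir$s, , cj, drop = FALSE], 3, mean)
      rows[[cj]] <- tibble::tibble(participant = erps$participants,
                                   condition = erps$conditions[cj],
                                   li = li_value(ml, mr))
    }
    out <- dplyr::bind_rows(rows)
  }
  if (anyNA(out$li)) {
    warn(sprintf("%d lateralization value(s) undefined (zero denominator)",
                 sum(is.na(out$li))))
  }
  out
}

#' Within-subject effect size from a t statistic
#'
#' `d_z = t / sqrt(n)`.
#'
#' @param t_value t statistic.
#' @param n Number of subjects (>= 2).
#' @return d_z.
#' @examples
#' dz_from_t(-3.390, 23) # about -0.71
#' @export
dz_from_t <- function(t_value, n) {
  if (any(n < 2)) abort("`n` must be >= 2", class = "spnlab_parameter_error")
  t_value / sqrt(n)
}

#' Correlate SPN amplitude with a behavioral metric
#'
#' Pearson correlation with a Fisher-z 95% confidence interval (standard
#' error `1/sqrt(n - 3)`) and a two-sided p from the t transform.
#'
#' @param spn An `spn_estimate` (or tibble with `participant`,
#'   `amplitude_uv`).
#' @param metric Tibble with `participant` and one metric column, or a
#'   numeric vector aligned to `spn$participant`.
#' @param conf Confidence level.
#' @return Tibble: `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
correlate_spn_behavior <- function(spn, metric, conf = 0.95) {
  x <- spn$amplitude_uv
  y <- if (is.numeric(metric)) metric else {
    pos <- match(spn$participant, metric$participant)
    mcol <- setdiff(names(metric), "participant")[1]
    metric[[mcol]][pos]
  }
  n <- length(x)
  if (n < 4 || length(y) != n) {
    abort("need >= 4 paired observations", class = "spnlab_parameter_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance; correlation undefined")
    return(tibble::tibble(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zcrit <- qnorm(1 - (1 - conf) / 2)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble::tibble(r = r,
                 ci_low = tanh(z - zcrit * se),
                 ci_high = tanh(z + zcrit * se),
                 p = 2 * pt(-abs(tstat), n - 2),
                 n = n)
}
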