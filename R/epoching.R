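#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the samples inside
#' `window_ms` (endpoints inclusive of the nearest sample at or inside each
#' bound). After correction that mean is 0 to within 1e-9; applying the
#' operation twice equals applying it once.
#'
#' @param epochs An `eeg_epochs`.
#' @param window_ms Baseline interval, default -200 to 0 ms.
#' @return Baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-200, 0)) {
  idx <- window_index(epochs$times_ms, window_ms)
  d <- dim(epochs$data)
  means <- colMeans(aperm(epochs$data[, idx, , drop = FALSE], c(2, 1, 3)))
  x <- epochs$data
  # per-epoch in-place updates on contiguous slices (one array copy total)
  for (e in seq_len(d[3])) {
    x[, , e] <- x[, , e] - means[, e]
  }
  out <- epochs
  out$data <- x
  out
}

#' Re-reference epochs to the common average
#'
#' Subtracts, per sample and epoch, the mean across scalp channels, so the
#' channel mean is 0 at every sample. Idempotent.
#'
#' @param epochs An `eeg_epochs`.
#' @param channels Channels over which the average is computed (and from
#'   which it is subtracted); defaults to all, matching a scalp-only montage.
#' @return Re-referenced `eeg_epochs`.
#' @export
rereference_average <- function(epochs, channels = NULL) {
  if (dim(epochs$data)[1] < 2) {
    abort("common-average reference needs >= 2 channels",
          class = "spnlab_parameter_error")
  }
  ci <- if (is.null(channels)) seq_along(epochs$channels) else
    match(channels, epochs$channels)
  all_ch <- length(ci) == dim(epochs$data)[1]
  avg <- if (all_ch) colMeans(epochs$data) else
    colMeans(epochs$data[ci, , , drop = FALSE])
  x <- epochs$data
  # per-epoch in-place updates on contiguous slices (one array copy total)
  for (e in seq_len(dim(x)[3])) {
    if (all_ch) {
      x[, , e] <- x[, , e] - rep(avg[, e], each = length(ci))
    } else {
      x[ci, , e] <- x[ci, , e] - rep(avg[, e], each = length(ci))
    }
  }
  out <- epochs
  out$data <- x
  out
}

#' Automated epoch quality screen
#'
#' Flags and removes epochs by three criteria computed on scalp channels:
#' \itemize{
#'   \item amplitude: any sample inside `amp_window_ms` exceeds
#'     `amp_limit_uv` in absolute value on any channel;
#'   \item trend: on any channel, the least-squares line over the full epoch
#'     has total fitted change exceeding `trend_delta_uv` (microvolts across
#'     the epoch) together with R-squared above `trend_r2`;
#'   \item kurtosis: per channel/epoch excess kurtosis, z-scored within
#'     participant either per channel across epochs ("local") or as the
#'     across-channel mean per epoch ("global"); an epoch is flagged when
#'     any |z| exceeds `kurt_z`.
#' }
#' An epoch is removed iff at least one flag is set.
#'
#' @param epochs An `eeg_epochs`.
#' @param amp_limit_uv Amplitude limit, uV (default 120).
#' @param amp_window_ms Window for the amplitude criterion (default -200 to
#'   600 ms).
#' @param trend_delta_uv Total fitted change limit, uV (default 75).
#' @param trend_r2 R-squared threshold for the trend flag (default 0.50).
#' @param kurt_z Kurtosis z-score threshold in SD units (default 7).
#' @param channels Channel subset used for screening (hook for excluding
#'   non-scalp channels); default all.
#' @return List with `epochs` (retained) and `report` (a `screen_report`:
#'   per-epoch flag table plus per-participant counts).
#' @export
screen_epochs <- function(epochs, amp_limit_uv = 120,
                          amp_window_ms = c(-200, 600),
                          trend_delta_uv = 75, trend_r2 = 0.50, kurt_z = 7,
                          channels = NULL) {
  assert_positive(amp_limit_uv, "amp_limit_uv")
  assert_positive(trend_delta_uv, "trend_delta_uv")
  assert_positive(kurt_z, "kurt_z")
  ci <- if (is.null(channels)) seq_along(epochs$channels) else
    match(channels, epochs$channels)
  x <- epochs$data[ci, , , drop = FALSE]
  n_e <- dim(x)[3]

  # amplitude
  widx <- window_index(epochs$times_ms, amp_window_ms)
  flag_amp <- apply(abs(x[, widx, , drop = FALSE]), 3, max) > amp_limit_uv

  # linear trend: OLS on the full epoch per channel; |slope| * span = total
  # fitted change; R^2 from the same fit
  t_c <- epochs$times_ms - mean(epochs$times_ms)
  sxx <- sum(t_c^2)
  n_s <- length(t_c)
  span <- max(epochs$times_ms) - min(epochs$times_ms)
  Y <- matrix(aperm(x, c(2, 1, 3)), n_s, length(ci) * n_e) # one column per (ch, epoch)
  slopes <- colSums(Y * t_c) / sxx
  delta <- abs(slopes) * span
  sst <- colSums(Y^2) - n_s * colMeans(Y)^2
  r2 <- ifelse(sst > 0, slopes^2 * sxx / sst, 0)
  flag_trend <- apply(matrix(delta > trend_delta_uv & r2 > trend_r2,
                             length(ci), n_e), 2, any)

  # kurtosis (excess, moment-based g2), z-scored within participant;
  # vectorized over (channel, epoch), reusing the trend design matrix
  mu <- colMeans(Y)
  Yc <- Y - rep(mu, each = n_s)
  m2 <- colMeans(Yc^2)
  m4 <- colMeans(Yc^4)
  kvec <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
  kmat <- matrix(kvec, length(ci), n_e)
  kmat[!is.finite(kmat)] <- 0
  rm(Y, Yc)
  flag_kloc <- rep(FALSE, n_e)
  flag_kglob <- rep(FALSE, n_e)
  for (p in unique(epochs$epoch_table$participant)) {
    pe <- which(epochs$epoch_table$participant == p)
    if (length(pe) < 2) next
    kp <- kmat[, pe, drop = FALSE]
    zs <- t(scale(t(kp)))          # per channel across this participant's epochs
    zs[!is.finite(zs)] <- 0
    flag_kloc[pe] <- apply(abs(zs) > kurt_z, 2, any)
    gm <- colMeans(kp)             # global: across-channel mean per epoch
    gz <- as.numeric(scale(gm))
    gz[!is.finite(gz)] <- 0
    flag_kglob[pe] <- abs(gz) > kurt_z
  }

  removed <- flag_amp | flag_trend | flag_kloc | flag_kglob
  report_tbl <- tibble::tibble(
    epochs$epoch_table[, c("participant", "trial", "condition")],
    flag_amplitude = flag_amp, flag_trend = flag_trend,
    flag_kurtosis_local = flag_kloc, flag_kurtosis_global = flag_kglob,
    removed = removed
  )
  counts <- dplyr::summarise(
    dplyr::group_by(report_tbl, .data$participant),
    n_in = dplyr::n(), n_removed = sum(.data$removed),
    n_retained = sum(!.data$removed), .groups = "drop"
  )
  report <- structure(list(flags = report_tbl, counts = counts,
                           params = list(amp_limit_uv = amp_limit_uv,
                                         amp_window_ms = amp_window_ms,
                                         trend_delta_uv = trend_delta_uv,
                                         trend_r2 = trend_r2,
                                         kurt_z = kurt_z)),
                      class = "screen_report")
  list(epochs = subset_epochs(epochs, !removed), report = report)
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d epochs in, %d removed (%.1f%%)\n",
              sum(x$counts$n_in), sum(x$counts$n_removed),
              100 * sum(x$counts$n_removed) / max(sum(x$counts$n_in), 1)))
  invisible(x)
}

#' @export
tidy.screen_report <- function(x, ...) x$flags

#' Retain only correct trials
#'
#' Keeps exactly the epochs whose (participant, trial) is marked correct in
#' the behavior table; errors if any epoch has no behavior row.
#'
#' @param epochs An `eeg_epochs`.
#' @param behavior Behavior tibble with `participant`, `trial`, `correct`.
#' @return Filtered `eeg_epochs`.
#' @export
filter_correct <- function(epochs, behavior) {
  key_e <- paste(epochs$epoch_table$participant, epochs$epoch_table$trial)
  key_b <- paste(behavior$participant, behavior$trial)
  pos <- match(key_e, key_b)
  if (anyNA(pos)) {
    abort("epoch(s) without a matching behavior row: misaligned trial indices",
          class = "spnlab_alignment_error")
  }
  keep <- behavior$correct[pos]
  if (!any(keep)) {
    warn("no correct trials; returning an empty epoch set")
  }
  subset_epochs(epochs, keep)
}

#' Average epochs into per-participant, per-condition ERPs
#'
#' @param epochs An `eeg_epochs` (typically baseline-corrected, re-referenced,
#'   correct-only, screened).
#' @param conditions Condition labels expected (default symmetric /
#'   asymmetric). Participants missing any condition are excluded with a
#'   warning and listed in the result.
#' @return A `subject_erps`: list with `data` (channels x samples x
#'   participants x conditions array), `channels`, `times_ms`, `fs_hz`,
#'   `participants`, `conditions`, `n_trials` (tibble), `excluded`.
#' @export
average_conditions <- function(epochs,
                               conditions = c("symmetric", "asymmetric")) {
  tbl <- epochs$epoch_table
  participants <- sort(unique(tbl$participant))
  have <- table(factor(tbl$participant, participants),
                factor(tbl$condition, conditions))
  complete <- participants[apply(have > 0, 1, all)]
  excluded <- setdiff(participants, complete)
  if (length(excluded) > 0) {
    warn(sprintf("participant(s) with an empty condition excluded: %s",
                 paste(excluded, collapse = ", ")))
  }
  n_ch <- dim(epochs$data)[1]; n_s <- dim(epochs$data)[2]
  erp <- array(NA_real_, c(n_ch, n_s, length(complete), length(conditions)),
               dimnames = list(epochs$channels, NULL, NULL, conditions))
  counts <- list()
  for (pi in seq_along(complete)) {
    for (cj in seq_along(conditions)) {
      sel <- tbl$participant == complete[pi] & tbl$condition == conditions[cj]
      erp[, , pi, cj] <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
      counts[[length(counts) + 1]] <- tibble::tibble(
        participant = complete[pi], condition = conditions[cj],
        n_trials = sum(sel))
    }
  }
  structure(
    list(data = erp, channels = epochs$channels, times_ms = epochs$times_ms,
         fs_hz = epochs$fs_hz, participants = complete,
         conditions = conditions, n_trials = dplyr::bind_rows(counts),
         excluded = excluded),
    class = "subject_erps"
  )
}

#' @export
print.subject_erps <- function(x, ...) {
  cat(sprintf("<subject_erps> %d participants x %d conditions, %d channels x %d samples\n",
              length(x$participants), length(x$conditions),
              dim(x$data)[1], dim(x$data)[2]))
  invisible(x)
}

#' Tidy subject ERPs into a long tibble
#'
#' @param x A `subject_erps`.
#' @param channels Optional channel subset.
#' @param ... Unused.
#' @return Tibble with `participant`, `condition`, `channel`, `time_ms`,
#'   `amplitude_uv`.
#' @export
tidy.subject_erps <- function(x, channels = NULL, ...) {
  chans <- if (is.null(channels)) x$channels else intersect(channels, x$channels)
  ci <- match(chans, x$channels)
  d <- x$data[ci, , , , drop = FALSE]
  grid <- expand.grid(channel = chans, time_ms = x$times_ms,
                      participant = x$participants, condition = x$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::tibble(grid[, c("participant", "condition", "channel", "time_ms")],
                 amplitude_uv = as.vector(d))
}
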