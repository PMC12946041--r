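#' Epoched EEG container
#'
#' Holds epoched multi-channel EEG as a `channels x samples x epochs` array
#' (microvolts) together with the sample grid and an epoch metadata table.
#' Epochs from all participants are stacked along the third dimension so
#' per-participant trial counts may differ (as they do after correctness
#' filtering and quality screening).
#'
#' @param data Numeric array `channels x samples x epochs`.
#' @param times_ms Sample times in ms relative to stimulus onset.
#' @param fs_hz Sampling rate.
#' @param channels Channel labels (length = dim 1).
#' @param epoch_table Tibble with one row per epoch: `participant`, `trial`,
#'   `condition` (`"symmetric"`/`"asymmetric"`), `correct` (logical).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times_ms, fs_hz, channels, epoch_table) {
  if (length(dim(data)) != 3) {
    abort("`data` must be a 3-D array (channels x samples x epochs)",
          class = "spnlab_format_error")
  }
  if (dim(data)[1] != length(channels)) {
    abort("channel label count does not match data", class = "spnlab_format_error")
  }
  if (dim(data)[2] != length(times_ms)) {
    abort("time grid length does not match data", class = "spnlab_format_error")
  }
  if (dim(data)[3] != nrow(epoch_table)) {
    abort("epoch table row count does not match data", class = "spnlab_format_error")
  }
  needed <- c("participant", "trial", "condition", "correct")
  missing_cols <- setdiff(needed, names(epoch_table))
  if (length(missing_cols) > 0) {
    abort(sprintf("epoch table is missing field(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "spnlab_format_error")
  }
  dimnames(data) <- NULL # labels live in `channels`; avoids array copies
  structure(
    list(data = data, times_ms = as.numeric(times_ms), fs_hz = fs_hz,
         channels = as.character(channels),
         epoch_table = tibble::as_tibble(epoch_table)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d channels x %d samples x %d epochs, %g Hz, %g..%g ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs_hz,
              min(x$times_ms), max(x$times_ms)))
  cat(sprintf("participants: %d; conditions: %s\n",
              length(unique(x$epoch_table$participant)),
              paste(names(table(x$epoch_table$condition)), collapse = "/")))
  invisible(x)
}

n_epochs <- function(epochs) dim(epochs$data)[3]

subset_epochs <- function(epochs, keep) {
  eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$times_ms,
             epochs$fs_hz, epochs$channels, epochs$epoch_table[keep, ])
}

#' Tidy epoched EEG into a long tibble
#'
#' One row per (epoch, channel, sample); intended for plotting and for small
#' data only.
#'
#' @param x An `eeg_epochs`.
#' @param channels Optional channel subset.
#' @param ... Unused.
#' @return Tibble with `participant`, `trial`, `condition`, `correct`,
#'   `channel`, `time_ms`, `amplitude_uv`.
#' @export
tidy.eeg_epochs <- function(x, channels = NULL, ...) {
  chans <- if (is.null(channels)) x$channels else intersect(channels, x$channels)
  ci <- match(chans, x$channels)
  n_s <- length(x$times_ms); n_e <- n_epochs(x)
  meta <- x$epoch_table[rep(seq_len(n_e), each = length(ci) * n_s), ]
  tibble::tibble(
    meta,
    channel = rep(rep(chans, each = 1), times = n_s * n_e),
    time_ms = rep(rep(x$times_ms, each = length(ci)), times = n_e),
    amplitude_uv = as.vector(x$data[ci, , , drop = FALSE])
  )
}

#' Write epoched EEG to disk
#'
#' Serializes the full container (data array, time grid, channel labels,
#' participants, trial table) losslessly as a single structured file with a
#' fixed schema; [read_epochs()] validates the schema on load.
#'
#' @param epochs An `eeg_epochs`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  payload <- list(
    format = "spnlab-epochs-v1",
    data = unclass(epochs$data),
    times_ms = epochs$times_ms,
    fs_hz = epochs$fs_hz,
    channels = epochs$channels,
    participants = unique(epochs$epoch_table$participant),
    trial_table = as.data.frame(epochs$epoch_table)
  )
  saveRDS(payload, path)
  invisible(path)
}

#' Read epoched EEG from disk
#'
#' @param path File produced by [write_epochs()].
#' @return An `eeg_epochs`.
#' @export
read_epochs <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$format, "spnlab-epochs-v1")) {
    abort("not an spnlab epochs file (missing format marker)",
          class = "spnlab_format_error")
  }
  for (field in c("data", "times_ms", "fs_hz", "channels", "trial_table")) {
    if (is.null(payload[[field]])) {
      abort(sprintf("epochs file is missing field '%s'", field),
            class = "spnlab_format_error")
    }
  }
  tt <- tibble::as_tibble(payload$trial_table)
  if (!"condition" %in% names(tt)) {
    abort("epochs file is missing field 'trial_table$condition'",
          class = "spnlab_format_error")
  }
  eeg_epochs(payload$data, payload$times_ms, payload$fs_hz,
             payload$channels, tt)
}
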