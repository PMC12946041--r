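#' Simulate epoched EEG with an injected posterior symmetry effect
#'
#' Each epoch is the sum of (i) 1/f^chi noise, independent per channel and
#' trial, spectrally shaped so log-power falls linearly in log-frequency with
#' slope -chi; (ii) condition-common P1- and N1-like Gaussian deflections
#' with a posterior topography; and (iii) on symmetric trials only, a
#' subject-specific sustained posterior negativity: amplitude
#' `A_i ~ Normal(spn_amp_mean, spn_amp_sd)` scaled by a Gaussian spatial
#' profile over sensor distance to the ROI centroid (re-centered to zero mean
#' across the montage, as for an average-referenced field) and a raised
#' cosine (or boxcar) temporal profile on `spn_window_ms` peaking at
#' `spn_peak_ms`. Profiles are normalized so the mean over the configured ROI
#' electrodes and window equals `A_i` exactly, making the injected amplitude
#' directly recoverable downstream. Baseline-window means are left free so
#' baseline correction is genuinely exercised.
#'
#' @param cfg A [sim_config()].
#' @param montage An `eeg_montage` providing channel labels and positions;
#'   must contain every `roi_center_labels` entry.
#' @param behavior Trial table from [simulate_behavior()] (same config).
#' @return An [eeg_epochs()] whose epoch table matches `behavior` row order.
#' @export
simulate_epochs <- function(cfg, montage = acticap64(),
                            behavior = simulate_behavior(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  missing_roi <- setdiff(cfg$roi_center_labels, montage$label)
  if (length(missing_roi) > 0) {
    abort(sprintf("ROI label(s) not in montage: %s",
                  paste(missing_roi, collapse = ", ")),
          class = "spnlab_parameter_error")
  }
  times_ms <- epoch_times(cfg)
  n_s <- length(times_ms)
  n_ch <- nrow(montage)
  subj <- participant_params(cfg)

  w_spatial <- spn_spatial_profile(montage, cfg$roi_center_labels,
                                   cfg$spatial_sigma_mm)
  u_temporal <- spn_temporal_profile(times_ms, cfg$spn_window_ms,
                                     cfg$spn_peak_ms, cfg$temporal_profile)
  spn_shape <- outer(w_spatial, u_temporal) # channels x samples, ROI-window mean 1
  common <- outer(w_spatial, evoked_profile(times_ms, cfg))

  parts <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    rows <- behavior[behavior$participant == i, ]
    n_tr <- nrow(rows)
    noise <- with_seed(
      substream_seed(cfg$seed, 3L, i),
      pink_noise(n_s, n_ch * n_tr, cfg$fs_hz, cfg$noise_exponent,
                 cfg$noise_sd_uv)
    )
    x <- aperm(array(noise, c(n_s, n_ch, n_tr)), c(2, 1, 3))
    inject <- rows$condition == "symmetric"
    if (cfg$inject_correct_only) inject <- inject & rows$correct
    x <- x + as.vector(common) # recycled per trial
    if (any(inject)) {
      x[, , inject] <- x[, , inject] +
        subj$spn_amp[i] * as.vector(spn_shape)
    }
    parts[[i]] <- x
  }
  data <- array(0, c(n_ch, n_s, nrow(behavior)))
  at <- 0
  for (i in seq_len(cfg$n_participants)) {
    k <- dim(parts[[i]])[3]
    data[, , at + seq_len(k)] <- parts[[i]]
    at <- at + k
  }
  eeg_epochs(data, times_ms, cfg$fs_hz, montage$label,
             behavior[, c("participant", "trial", "condition", "correct")])
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper returning montage, behavior, and epochs from one
#' config.
#'
#' @param cfg A [sim_config()].
#' @param montage An `eeg_montage`.
#' @return List with `cfg`, `montage`, `behavior`, `epochs`.
#' @export
simulate_study <- function(cfg = sim_config(), montage = acticap64()) {
  behavior <- simulate_behavior(cfg)
  epochs <- simulate_epochs(cfg, montage, behavior)
  list(cfg = cfg, montage = montage, behavior = behavior, epochs = epochs)
}

epoch_times <- function(cfg) {
  step <- 1000 / cfg$fs_hz
  n_s <- round((cfg$epoch_span_ms[2] - cfg$epoch_span_ms[1]) / step)
  cfg$epoch_span_ms[1] + step * (0:(n_s - 1))
}

# 1/f^chi noise, one column per (channel, trial): Gaussian noise synthesized
# directly in the frequency domain with amplitude proportional to
# f^(-chi/2), deterministically normalized to variance sd_uv^2 per sample.
# Every non-DC bin carries an independent circular complex Gaussian, so the
# real and imaginary parts of each inverse FFT are two independent
# realizations with the target spectrum -- one transform yields two
# columns. DC is zero, so each column's full-epoch mean is ~0 while window
# means stay free.
pink_noise <- function(n_s, n_cols, fs_hz, chi, sd_uv) {
  if (sd_uv == 0) return(matrix(0, n_s, n_cols))
  freqs <- c(0, seq_len(n_s - 1)) * fs_hz / n_s
  freqs <- pmin(freqs, fs_hz - freqs) # two-sided spectrum, symmetric
  shape <- ifelse(freqs > 0, freqs^(-chi / 2), 0)
  shape <- shape * sd_uv / sqrt(mean(shape^2))
  m <- ceiling(n_cols / 2)
  z <- matrix(complex(real = rnorm(n_s * m), imaginary = rnorm(n_s * m)),
              n_s, m)
  z <- z * (shape * sqrt(n_s) / n_s)
  z <- stats::mvfft(z, inverse = TRUE)
  out <- matrix(0, n_s, n_cols)
  odd <- seq(1, n_cols, 2)
  out[, odd] <- Re(z[, seq_along(odd), drop = FALSE])
  if (n_cols > 1) {
    even <- seq(2, n_cols, 2)
    out[, even] <- Im(z[, seq_along(even), drop = FALSE])
  }
  out
}

# Gaussian spatial profile over distance to the ROI centroid, centered to
# zero mean across the montage and scaled so its mean over ROI electrodes
# is exactly 1.
spn_spatial_profile <- function(montage, roi_labels, sigma_mm) {
  coords <- montage_coords(montage)
  center <- colMeans(coords[roi_labels, , drop = FALSE])
  d2 <- rowSums(sweep(coords, 2, center)^2)
  g <- exp(-d2 / (2 * sigma_mm^2))
  g0 <- g - mean(g)
  denom <- mean(g0[match(roi_labels, montage$label)])
  if (denom <= 0) {
    abort("degenerate spatial profile: ROI mean not positive after centering",
          class = "spnlab_parameter_error")
  }
  g0 / denom
}

# Temporal profile on [onset, offset], zero elsewhere, normalized so its
# mean over the window samples is exactly 1. "cosine" rises as a half
# raised-cosine from onset to the peak and falls from the peak to offset.
spn_temporal_profile <- function(times_ms, window_ms, peak_ms, kind) {
  u <- numeric(length(times_ms))
  idx <- window_index(times_ms, window_ms)
  if (kind == "boxcar") {
    u[idx] <- 1
  } else {
    t <- times_ms[idx]
    rise <- t <= peak_ms
    u[idx][rise] <- 0.5 * (1 - cos(pi * (t[rise] - window_ms[1]) /
                                     max(peak_ms - window_ms[1], 1e-9)))
    u[idx][!rise] <- 0.5 * (1 + cos(pi * (t[!rise] - peak_ms) /
                                      max(window_ms[2] - peak_ms, 1e-9)))
  }
  u[idx] <- u[idx] / mean(u[idx])
  u
}

# Condition-common P1/N1-like deflections (cancel exactly in S - A).
evoked_profile <- function(times_ms, cfg) {
  cfg$p1_amp_uv * exp(-(times_ms - cfg$p1_latency_ms)^2 / (2 * cfg$p1_sigma_ms^2)) +
    cfg$n1_amp_uv * exp(-(times_ms - cfg$n1_latency_ms)^2 / (2 * cfg$n1_sigma_ms^2))
}
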