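#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study generator. Defaults
#' reproduce the study conditions: 23 participants, 120 trials with a 50/50
#' symmetric/asymmetric split, behavioral sensitivity d' = 1.88 (SD 0.65)
#' with criterion c = -0.14 (SD 0.23) under the equal-variance Gaussian
#' signal-detection model, and a sustained posterior negativity of -0.45 uV
#' group mean (between-subject SD 0.63 uV) over occipito-parietal sensors in
#' the 250-600 ms window, on top of 1/f noise and condition-common P1/N1
#' deflections. Epochs span -500 to +1000 ms at 256 Hz.
#'
#' `spn_amp_mean` is calibrated as the ROI-window mean of the injected
#' effect: the spatial profile (Gaussian in sensor distance to the ROI
#' centroid, re-centered to zero mean across the montage as for an
#' average-referenced field) and the temporal profile are both normalized so
#' that the mean over `roi_center_labels` x `spn_window_ms` equals
#' `spn_amp_mean` exactly.
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_trials Trials per participant.
#' @param p_symmetric Probability a trial is symmetric.
#' @param dprime_mean,dprime_sd Population mean/SD of d' (draws truncated at
#'   d' >= 0).
#' @param criterion_mean,criterion_sd Population mean/SD of the criterion c.
#' @param spn_amp_mean Group-mean injected SPN amplitude, uV (negative).
#' @param spn_amp_sd Between-subject SD of the SPN amplitude, uV.
#' @param spn_window_ms Onset/offset of the SPN temporal profile, ms.
#' @param spn_peak_ms Latency of maximal (most negative) SPN, ms.
#' @param roi_center_labels Electrodes whose centroid anchors the spatial
#'   profile and over which the amplitude is calibrated.
#' @param spatial_sigma_mm Gaussian spatial spread of the effect, mm.
#' @param p1_amp_uv,p1_latency_ms,p1_sigma_ms Condition-common P1-like bump.
#' @param n1_amp_uv,n1_latency_ms,n1_sigma_ms Condition-common N1-like bump.
#' @param noise_sd_uv Per-channel, per-trial noise standard deviation, uV.
#' @param noise_exponent Spectral exponent chi of the 1/f^chi noise.
#' @param fs_hz Sampling rate, Hz.
#' @param epoch_span_ms Epoch start/end relative to stimulus onset, ms.
#' @param temporal_profile `"cosine"` (raised cosine rising to
#'   `spn_peak_ms`, falling to offset) or `"boxcar"` (for analytic tests).
#' @param inject_correct_only If `TRUE`, the SPN is injected only on trials
#'   answered correctly; default injects on every symmetric trial.
#' @param seed Master seed expanded into per-participant/per-trial
#'   substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 23,
                       n_trials = 120,
                       p_symmetric = 0.5,
                       dprime_mean = 1.88, dprime_sd = 0.65,
                       criterion_mean = -0.14, criterion_sd = 0.23,
                       spn_amp_mean = -0.45, spn_amp_sd = 0.63,
                       spn_window_ms = c(250, 600),
                       spn_peak_ms = 390,
                       roi_center_labels = c("O1", "O2", "Oz", "PO3", "PO4",
                                             "PO7", "PO8"),
                       spatial_sigma_mm = 45,
                       p1_amp_uv = 2.5, p1_latency_ms = 110, p1_sigma_ms = 25,
                       n1_amp_uv = -3, n1_latency_ms = 170, n1_sigma_ms = 30,
                       noise_sd_uv = 5,
                       noise_exponent = 1,
                       fs_hz = 256,
                       epoch_span_ms = c(-500, 1000),
                       temporal_profile = c("cosine", "boxcar"),
                       inject_correct_only = FALSE,
                       seed = 1) {
  temporal_profile <- match.arg(temporal_profile)
  if (n_participants < 2) {
    abort("`n_participants` must be >= 2", class = "spnlab_parameter_error")
  }
  if (p_symmetric <= 0 || p_symmetric >= 1) {
    abort("`p_symmetric` must lie strictly in (0, 1)",
          class = "spnlab_parameter_error")
  }
  assert_positive(fs_hz, "fs_hz")
  if (!(spn_window_ms[1] < spn_window_ms[2]) ||
      spn_window_ms[1] < epoch_span_ms[1] ||
      spn_window_ms[2] > epoch_span_ms[2]) {
    abort("`spn_window_ms` must be an increasing interval inside `epoch_span_ms`",
          class = "spnlab_parameter_error")
  }
  structure(
    list(n_participants = n_participants, n_trials = n_trials,
         p_symmetric = p_symmetric,
         dprime_mean = dprime_mean, dprime_sd = dprime_sd,
         criterion_mean = criterion_mean, criterion_sd = criterion_sd,
         spn_amp_mean = spn_amp_mean, spn_amp_sd = spn_amp_sd,
         spn_window_ms = spn_window_ms, spn_peak_ms = spn_peak_ms,
         roi_center_labels = roi_center_labels,
         spatial_sigma_mm = spatial_sigma_mm,
         p1_amp_uv = p1_amp_uv, p1_latency_ms = p1_latency_ms,
         p1_sigma_ms = p1_sigma_ms,
         n1_amp_uv = n1_amp_uv, n1_latency_ms = n1_latency_ms,
         n1_sigma_ms = n1_sigma_ms,
         noise_sd_uv = noise_sd_uv, noise_exponent = noise_exponent,
         fs_hz = fs_hz, epoch_span_ms = epoch_span_ms,
         temporal_profile = temporal_profile,
         inject_correct_only = inject_correct_only, seed = seed),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' Any field of [sim_config()] may be given; others keep their defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
          class = "spnlab_format_error")
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d participants x %d trials, d'=%.2f (SD %.2f), ",
                     "c=%.2f (SD %.2f), SPN %.2f uV (SD %.2f) in %g-%g ms\n"),
              x$n_participants, x$n_trials, x$dprime_mean, x$dprime_sd,
              x$criterion_mean, x$criterion_sd, x$spn_amp_mean, x$spn_amp_sd,
              x$spn_window_ms[1], x$spn_window_ms[2]))
  invisible(x)
}
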