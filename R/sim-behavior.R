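#' Simulate trial-level behavior from the signal-detection model
#'
#' Each participant receives (d'_i, c_i) drawn from the population normals in
#' the config (d' truncated at 0). Trials are symmetric with probability
#' `p_symmetric`; under the equal-variance Gaussian model the probability of
#' responding "symmetric" is `pnorm(d'/2 - c)` on symmetric trials and
#' `pnorm(-d'/2 - c)` on asymmetric trials. A response is correct when it
#' matches the condition.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `participant`, `trial`, `condition`,
#'   `response`, `correct`.
#' @examples
#' b <- simulate_behavior(sim_config(n_participants = 4, seed = 2))
#' mean(b$correct)
#' @export
simulate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  subj <- participant_params(cfg)
  purrr::map_dfr(seq_len(cfg$n_participants), function(i) {
    with_seed(substream_seed(cfg$seed, 1L, i), {
      sym <- runif(cfg$n_trials) < cfg$p_symmetric
      p_say_sym <- ifelse(sym,
                          pnorm(subj$dprime[i] / 2 - subj$criterion[i]),
                          pnorm(-subj$dprime[i] / 2 - subj$criterion[i]))
      resp_sym <- runif(cfg$n_trials) < p_say_sym
      tibble::tibble(
        participant = i,
        trial = seq_len(cfg$n_trials),
        condition = ifelse(sym, "symmetric", "asymmetric"),
        response = ifelse(resp_sym, "symmetric", "asymmetric"),
        correct = sym == resp_sym
      )
    })
  })
}

# Per-participant latent parameters: SDT sensitivity/criterion and the
# subject-specific SPN amplitude, all from dedicated substreams so behavior
# and EEG generation can be called independently yet stay consistent.
participant_params <- function(cfg) {
  n <- cfg$n_participants
  dprime <- numeric(n); criterion <- numeric(n); spn_amp <- numeric(n)
  for (i in seq_len(n)) {
    with_seed(substream_seed(cfg$seed, 2L, i), {
      d <- rnorm(1, cfg$dprime_mean, cfg$dprime_sd)
      while (d < 0) d <- rnorm(1, cfg$dprime_mean, cfg$dprime_sd)
      dprime[i] <- d
      criterion[i] <- rnorm(1, cfg$criterion_mean, cfg$criterion_sd)
      spn_amp[i] <- rnorm(1, cfg$spn_amp_mean, cfg$spn_amp_sd)
    })
  }
  tibble::tibble(participant = seq_len(n), dprime = dprime,
                 criterion = criterion, spn_amp = spn_amp)
}
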