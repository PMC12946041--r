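cfg_small <- function(...) {
  sim_config(n_participants = 2, n_trials = 10, seed = 1, ...)
}

test_that("behavioral generator matches signal-detection closed forms", {
  # d' = 0, c = 0: chance responding
  cfg <- sim_config(n_participants = 2, n_trials = 4000,
                    dprime_mean = 0, dprime_sd = 0,
                    criterion_mean = 0, criterion_sd = 0, seed = 3)
  b <- simulate_behavior(cfg)
  expect_equal(mean(b$correct), 0.5, tolerance = 0.03)

  # fixed d' = 1.88, c = -0.14: accuracy = (pnorm(1.08) + pnorm(0.80)) / 2
  cfg <- sim_config(n_participants = 4, n_trials = 5000,
                    dprime_sd = 0, criterion_sd = 0, seed = 4)
  b <- simulate_behavior(cfg)
  expected <- (pnorm(1.88 / 2 + 0.14) + pnorm(1.88 / 2 - 0.14)) / 2
  expect_equal(expected, 0.824, tolerance = 5e-4) # closed-form sanity
  expect_equal(mean(b$correct), expected, tolerance = 0.01)

  # pure liberal bias: c = -0.5, d' = 0 -> P("symmetric") = pnorm(0.5) everywhere
  cfg <- sim_config(n_participants = 2, n_trials = 5000,
                    dprime_mean = 0, dprime_sd = 0,
                    criterion_mean = -0.5, criterion_sd = 0, seed = 5)
  b <- simulate_behavior(cfg)
  rate <- tapply(b$response == "symmetric", b$condition, mean)
  expect_lt(abs(rate[["symmetric"]] - pnorm(0.5)), 0.02)
  expect_lt(abs(rate[["asymmetric"]] - pnorm(0.5)), 0.02)
})

test_that("sdt estimation recovers the generating parameters", {
  cfg <- sim_config(n_participants = 2, n_trials = 10000,
                    dprime_mean = 1.5, dprime_sd = 0,
                    criterion_mean = -0.2, criterion_sd = 0, seed = 6)
  sdt <- sdt_from_behavior(simulate_behavior(cfg))
  expect_equal(mean(sdt$dprime), 1.5, tolerance = 0.05)
  expect_equal(mean(sdt$criterion), -0.2, tolerance = 0.05)
})

test_that("behavior is deterministic and substream-stable under one seed", {
  cfg <- sim_config(n_participants = 3, n_trials = 20, seed = 11)
  expect_identical(simulate_behavior(cfg), simulate_behavior(cfg))
  # participant 2's trials do not depend on how many participants precede it
  cfg2 <- sim_config(n_participants = 2, n_trials = 20, seed = 11)
  b3 <- simulate_behavior(cfg)
  b2 <- simulate_behavior(cfg2)
  expect_identical(b3[b3$participant == 2, ], b2[b2$participant == 2, ])
})

test_that("null and noise-free configurations inject exactly what they claim", {
  # null SPN: S - A group difference is pure noise around zero
  cfg <- sim_config(n_participants = 8, n_trials = 24, spn_amp_mean = 0,
                    spn_amp_sd = 0, noise_sd_uv = 2, seed = 21)
  st <- simulate_study(cfg)
  erps <- average_conditions(st$epochs)
  spn <- spn_amplitude(erps)
  tt <- one_sample_t(spn$amplitude_uv)
  expect_gt(tt$p, 0.001) # no systematic effect

  # noise-free boxcar at -1 uV: ROI window mean difference exactly -1
  cfg <- sim_config(n_participants = 2, n_trials = 10, spn_amp_mean = -1,
                    spn_amp_sd = 0, noise_sd_uv = 0,
                    temporal_profile = "boxcar", seed = 1)
  st <- simulate_study(cfg)
  erps <- average_conditions(st$epochs)
  spn <- spn_amplitude(erps)
  expect_equal(spn$amplitude_uv, c(-1, -1), tolerance = 1e-12)
  # invariant under baseline correction and re-referencing (by construction)
  erps2 <- average_conditions(rereference_average(baseline_correct(st$epochs)))
  expect_equal(spn_amplitude(erps2)$amplitude_uv, c(-1, -1), tolerance = 1e-9)
})

test_that("noise spectrum has the configured 1/f slope and amplitude", {
  ns <- spnlab:::pink_noise(384, 400, 256, 1, 5)
  expect_equal(sd(ns), 5, tolerance = 0.1)
  P <- rowMeans(abs(stats::mvfft(ns))^2)
  f <- (0:383) * 256 / 384
  sel <- f >= 1 & f <= 40
  slope <- unname(coef(lm(log(P[sel]) ~ log(f[sel])))[2])
  expect_equal(slope, -1, tolerance = 0.3)

  ns2 <- spnlab:::pink_noise(384, 400, 256, 1.5, 5)
  P2 <- rowMeans(abs(stats::mvfft(ns2))^2)
  slope2 <- unname(coef(lm(log(P2[sel]) ~ log(f[sel])))[2])
  expect_equal(slope2, -1.5, tolerance = 0.3)
})

test_that("epochs with and without effect differ by exactly the injected profile", {
  base <- list(n_participants = 2, n_trials = 8, noise_sd_uv = 3, seed = 9,
               spn_amp_sd = 0)
  st0 <- simulate_study(do.call(sim_config, c(base, list(spn_amp_mean = 0))))
  st1 <- simulate_study(do.call(sim_config, c(base, list(spn_amp_mean = -1))))
  d <- st1$epochs$data - st0$epochs$data
  sym <- st0$epochs$epoch_table$condition == "symmetric"
  expect_equal(max(abs(d[, , !sym])), 0, tolerance = 1e-12)
  # injected difference is identical across symmetric trials, nonzero in window
  ref <- d[, , which(sym)[1]]
  for (k in which(sym)) expect_equal(d[, , k], ref, tolerance = 1e-12)
  widx <- st0$epochs$times_ms >= 250 & st0$epochs$times_ms <= 600
  expect_equal(mean(ref[match(c("O1", "O2", "Oz", "PO3", "PO4", "PO7", "PO8"),
                              st0$epochs$channels), widx]),
               -1, tolerance = 1e-9)
  expect_equal(max(abs(ref[, !widx])), 0, tolerance = 1e-12)
})

test_that("epoch files round-trip losslessly and malformed files are rejected", {
  st <- simulate_study(cfg_small())
  path <- tempfile(fileext = ".rds")
  write_epochs(st$epochs, path)
  back <- read_epochs(path)
  expect_identical(back$data, st$epochs$data)
  expect_identical(back$times_ms, st$epochs$times_ms)
  expect_identical(back$channels, st$epochs$channels)
  expect_identical(as.data.frame(back$epoch_table),
                   as.data.frame(st$epochs$epoch_table))

  # missing condition labels
  payload <- readRDS(path)
  payload$trial_table$condition <- NULL
  bad1 <- tempfile(fileext = ".rds"); saveRDS(payload, bad1)
  expect_error(read_epochs(bad1), "condition", class = "spnlab_format_error")

  # truncated data array vs declared metadata
  payload <- readRDS(path)
  payload$data <- payload$data[, , -1, drop = FALSE]
  bad2 <- tempfile(fileext = ".rds"); saveRDS(payload, bad2)
  expect_error(read_epochs(bad2), class = "spnlab_format_error")

  # not an epochs file at all
  bad3 <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), bad3)
  expect_error(read_epochs(bad3), class = "spnlab_format_error")
})

test_that("unknown ROI labels and config fields are rejected", {
  cfg <- cfg_small(roi_center_labels = c("Oz", "NOPE"))
  expect_error(simulate_epochs(cfg, acticap64(), simulate_behavior(cfg)),
               "NOPE", class = "spnlab_parameter_error")
  expect_error(sim_config(p_symmetric = 1), class = "spnlab_parameter_error")
  expect_error(sim_config(spn_window_ms = c(600, 250)),
               class = "spnlab_parameter_error")
  y <- tempfile(fileext = ".yaml")
  writeLines(c("n_participants: 3", "bogus_field: 2"), y)
  expect_error(read_sim_config(y), "bogus_field", class = "spnlab_format_error")
  y2 <- tempfile(fileext = ".yaml")
  writeLines(c("n_participants: 5", "noise_sd_uv: 2.5"), y2)
  cfg2 <- read_sim_config(y2)
  expect_equal(cfg2$n_participants, 5)
  expect_equal(cfg2$noise_sd_uv, 2.5)
  expect_equal(cfg2$dprime_mean, 1.88) # defaults retained
})
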