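test_that("baseline correction subtracts the window mean and is idempotent", {
  x <- array(5, c(2, 384, 3)) # constant epochs
  e <- toy_epochs(x)
  b <- baseline_correct(e)
  expect_equal(max(abs(b$data)), 0)

  # 2 uV baseline stepping to 7 uV after t = 0 -> post-stimulus value 5 uV
  # (the baseline window is endpoint-inclusive, so the t = 0 sample belongs
  # to the baseline)
  step <- array(2, c(1, 384, 1))
  times <- -500 + (0:383) * 1000 / 256
  step[1, times > 0, 1] <- 7
  e2 <- baseline_correct(toy_epochs(step))
  expect_equal(unique(e2$data[1, times > 0, 1]), 5)
  bidx <- times >= -200 & times <= 0
  expect_lt(abs(mean(e2$data[1, bidx, 1])), 1e-9)

  e3 <- baseline_correct(e2)
  expect_equal(e3$data, e2$data, tolerance = 1e-12)

  expect_error(baseline_correct(toy_epochs(x), window_ms = c(-2000, -1900)),
               class = "spnlab_parameter_error")
})

test_that("common-average reference zeroes the channel mean and is idempotent", {
  x <- array(c(1, -1), c(2, 10, 2)) # channels +1/-1: already average-referenced
  e <- toy_epochs(x, t0_ms = 0)
  r <- rereference_average(e)
  expect_equal(r$data, x)

  x2 <- array(3, c(4, 10, 2)) # all equal -> all zero
  r2 <- rereference_average(toy_epochs(x2, t0_ms = 0))
  expect_equal(max(abs(r2$data)), 0)
  expect_lt(max(abs(colMeans(r2$data))), 1e-9)

  x3 <- array(rnorm(4 * 10 * 2), c(4, 10, 2))
  r3 <- rereference_average(toy_epochs(x3, t0_ms = 0))
  expect_equal(rereference_average(r3)$data, r3$data, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(r3$data))), 1e-9)

  expect_error(rereference_average(toy_epochs(array(1, c(1, 5, 1)))),
               class = "spnlab_parameter_error")
})

test_that("baseline correction and re-referencing commute", {
  x <- array(rnorm(6 * 384 * 4, sd = 10), c(6, 384, 4))
  e <- toy_epochs(x)
  ab <- rereference_average(baseline_correct(e))
  ba <- baseline_correct(rereference_average(e))
  expect_equal(ab$data, ba$data, tolerance = 1e-9)
})

test_that("amplitude screen removes epochs exceeding the limit inside its window", {
  x <- array(0, c(2, 384, 4))
  times <- -500 + (0:383) * 1000 / 256
  x[1, which(times >= 0)[1], 2] <- 130    # inside -200..600 -> flagged
  x[2, which(times > 700)[1], 3] <- 130   # outside window -> not flagged
  sc <- screen_epochs(toy_epochs(x))
  expect_equal(which(sc$report$flags$flag_amplitude), 2)
  expect_equal(sc$report$flags$removed, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(n_distinct_epochs <- dim(sc$epochs$data)[3], 3)
  expect_equal(sum(sc$report$counts$n_removed) +
                 sum(sc$report$counts$n_retained),
               sum(sc$report$counts$n_in))
})

test_that("trend screen matches the closed-form ramp criterion", {
  times <- -500 + (0:383) * 1000 / 256
  ramp <- (times - min(times)) / (max(times) - min(times)) # 0..1, R^2 = 1
  x <- array(0, c(1, 384, 3))
  x[1, , 1] <- 100 * ramp - 50 # total change 100 uV -> removed
  x[1, , 2] <- 50 * ramp - 25  # total change 50 uV -> retained
  sc <- screen_epochs(toy_epochs(x))
  expect_equal(which(sc$report$flags$flag_trend), 1)
  expect_equal(which(sc$report$flags$removed), 1)
})

test_that("kurtosis screen flags epochs with aberrant spikiness", {
  withr::with_seed(8, {
    x <- array(rnorm(2 * 384 * 40), c(2, 384, 40))
    x[1, 100, 40] <- 40 # one extreme spike -> huge excess kurtosis
  })
  sc <- screen_epochs(toy_epochs(x), kurt_z = 3)
  expect_true(sc$report$flags$flag_kurtosis_local[40])
  expect_false(any(sc$report$flags$flag_kurtosis_local[1:39]))
})

test_that("screen flags are monotone in the amplitude threshold", {
  withr::with_seed(10, x <- array(rnorm(3 * 384 * 30, sd = 60), c(3, 384, 30)))
  e <- toy_epochs(x)
  r1 <- screen_epochs(e, amp_limit_uv = 100)$report
  r2 <- screen_epochs(e, amp_limit_uv = 140)$report
  expect_true(all(r2$flags$flag_amplitude <= r1$flags$flag_amplitude))
})

test_that("correct-trial filtering retains exactly the correct trials", {
  x <- array(seq_len(2 * 10 * 6), c(2, 10, 6))
  e <- toy_epochs(x, t0_ms = 0)
  beh <- tibble::tibble(participant = 1L, trial = 1:6,
                        correct = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  f <- filter_correct(e, beh)
  expect_equal(dim(f$data)[3], 4)
  expect_equal(f$epoch_table$trial, c(1L, 3L, 4L, 6L))
  expect_identical(f$data[, , 2], x[, , 3])

  allwrong <- dplyr::mutate(beh, correct = FALSE)
  expect_warning(f0 <- filter_correct(e, allwrong), "no correct")
  expect_equal(dim(f0$data)[3], 0)

  misaligned <- dplyr::mutate(beh, trial = trial + 100)
  expect_error(filter_correct(e, misaligned), class = "spnlab_alignment_error")
})

test_that("filtering before screening can differ from screening first", {
  # the kurtosis z-scores depend on which epochs are present, so removing
  # incorrect trials first changes what counts as an outlier
  withr::with_seed(12, {
    x <- array(rnorm(1 * 384 * 30), c(1, 384, 30))
    x[1, 50, 1] <- 30  # extreme spike on an *incorrect* trial
    x[1, 60, 2] <- 12  # milder spike on a correct trial
  })
  correct <- rep(TRUE, 30); correct[1] <- FALSE
  e <- toy_epochs(x, t0_ms = 0, correct = correct)
  beh <- e$epoch_table

  paper_order <- screen_epochs(filter_correct(e, beh), kurt_z = 3)
  swapped <- filter_correct(screen_epochs(e, kurt_z = 3)$epochs, beh)
  expect_false(dim(paper_order$epochs$data)[3] == dim(swapped$data)[3])
})

test_that("condition averaging reproduces hand-computable means and is linear", {
  x <- array(0, c(2, 5, 4))
  x[, , 1] <- 1; x[, , 2] <- -1 # symmetric trials average to 0
  x[, , 3] <- 4; x[, , 4] <- 6  # asymmetric trials average to 5
  e <- toy_epochs(x, t0_ms = 0,
                  condition = c("symmetric", "symmetric",
                                "asymmetric", "asymmetric"))
  erps <- average_conditions(e)
  expect_equal(unique(as.vector(erps$data[, , 1, "symmetric"])), 0)
  expect_equal(unique(as.vector(erps$data[, , 1, "asymmetric"])), 5)
  expect_equal(erps$n_trials$n_trials, c(2, 2))

  # single trial per condition: average is that trial
  e1 <- toy_epochs(x[, , 1:2, drop = FALSE], t0_ms = 0,
                   condition = c("symmetric", "asymmetric"))
  erps1 <- average_conditions(e1)
  expect_equal(erps1$data[, , 1, "symmetric"], x[, , 1], ignore_attr = TRUE)

  # linearity
  y <- x + array(rnorm(length(x)), dim(x))
  ex <- average_conditions(toy_epochs(x, t0_ms = 0))
  ey <- average_conditions(toy_epochs(y, t0_ms = 0))
  exy <- average_conditions(toy_epochs(x + y, t0_ms = 0))
  expect_equal(exy$data, ex$data + ey$data, tolerance = 1e-12)

  # participant with an empty condition is excluded with a warning
  e2 <- toy_epochs(x, t0_ms = 0,
                   participant = c(1L, 1L, 1L, 2L),
                   condition = c("symmetric", "asymmetric",
                                 "asymmetric", "asymmetric"))
  expect_warning(erps2 <- average_conditions(e2), "excluded")
  expect_equal(erps2$participants, 1L)
  expect_equal(erps2$excluded, 2L)
})
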