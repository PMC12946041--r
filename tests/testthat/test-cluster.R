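chain_graph <- function(labels = c("A", "B", "C")) {
  # A-B-C chain at 30 mm spacing
  m <- new_montage_tsv(labels, cbind((seq_along(labels) - 1) * 30, 0, 0))
  build_neighbor_graph(m, 35)
}

test_that("pointwise paired t matches hand computation and is antisymmetric", {
  # identical conditions -> t = 0 everywhere
  arr <- array(rnorm(3 * 4 * 5), c(3, 4, 5, 2))
  arr[, , , 2] <- arr[, , , 1]
  expect_warning(tm0 <- pointwise_paired_t(toy_erps(arr)), "zero variance")
  expect_equal(max(abs(tm0$t)), 0)

  # differences {1, 2, 3} at one point: t = 2 / (1 / sqrt(3)) = 3.464
  dd <- array(c(1, rnorm(1), 2, rnorm(1), 3, rnorm(1)), c(1, 2, 3))
  tm <- pointwise_paired_t(dd)
  expect_equal(tm$t[1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tm$df, 2)

  tm_neg <- pointwise_paired_t(-dd)
  expect_equal(tm_neg$t, -tm$t, tolerance = 1e-12)

  expect_error(pointwise_paired_t(dd[, , 1, drop = FALSE]),
               class = "spnlab_parameter_error")
})

test_that("cluster formation follows the declared spatiotemporal connectivity", {
  g <- chain_graph()
  thr_t <- qt(0.975, 10) # ~2.23 for df = 10

  # {A@t1, B@t1, B@t2} connected -> one cluster of size 3
  tmat <- matrix(0, 3, 4, dimnames = NULL)
  tmat[1, 1] <- 3; tmat[2, 1] <- 3; tmat[2, 2] <- 3
  cl <- form_clusters(toy_tmap(tmat, df = 10, channels = c("A", "B", "C")), g)
  expect_length(cl, 1)
  expect_equal(length(cl[[1]]$cells), 3)
  expect_equal(cl[[1]]$mass, 9)
  expect_setequal(cl[[1]]$channels, c("A", "B"))
  expect_equal(cl[[1]]$max_extent$n_channels, 2) # two channels at t1
  expect_equal(cl[[1]]$max_extent$time_ms, 1)

  # {A@t1, C@t1}: A and C are not neighbors -> two clusters
  tmat2 <- matrix(0, 3, 4)
  tmat2[1, 1] <- 3; tmat2[3, 1] <- 3
  cl2 <- form_clusters(toy_tmap(tmat2, df = 10, channels = c("A", "B", "C")), g)
  expect_length(cl2, 2)

  # mixed signs at adjacent cells never merge
  tmat3 <- matrix(0, 3, 4)
  tmat3[1, 1] <- 3; tmat3[2, 1] <- -3; tmat3[2, 2] <- -3
  cl3 <- form_clusters(toy_tmap(tmat3, df = 10, channels = c("A", "B", "C")), g)
  expect_length(cl3, 2)
  expect_setequal(vapply(cl3, function(c) c$sign, numeric(1)), c(1, -1))

  # all-zero map -> no clusters
  expect_length(form_clusters(toy_tmap(matrix(0, 3, 4), df = 10,
                                       channels = c("A", "B", "C")), g), 0)
})

test_that("identity permutation reproduces the observed statistics", {
  d <- null_diffs(4, 8, 6, seed = 31)
  g <- build_neighbor_graph(grid_montage(2), 35)
  tm <- pointwise_paired_t(d)
  Dmat <- matrix(d, 32, 6)
  tvec <- spnlab:::flip_tmat(Dmat, rep(1, 6), rowSums(Dmat^2), 6)
  expect_equal(matrix(tvec, 4, 8), tm$t, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("monte carlo p values converge to the exhaustive oracle", {
  d <- null_diffs(4, 6, 8, seed = 5)
  d[1:2, 2:4, ] <- d[1:2, 2:4, ] + 1.1 # a real effect on a small patch
  g <- build_neighbor_graph(grid_montage(2), 35)

  ex <- exhaustive_null(d, g)
  expect_length(ex$null_max_mass, 256)
  obs_masses <- vapply(ex$clusters, function(c) c$mass, numeric(1))
  expect_gt(length(obs_masses), 0)

  ct500 <- permutation_test(d, g, n_perm = 500, seed = 101)
  ct5000 <- permutation_test(d, g, n_perm = 5000, seed = 102)
  for (k in seq_along(ex$clusters)) {
    row5000 <- which(abs(ct5000$clusters$mass - obs_masses[k]) < 1e-9)
    row500 <- which(abs(ct500$clusters$mass - obs_masses[k]) < 1e-9)
    expect_lt(abs(ct5000$clusters$p_corrected[row5000] - ex$clusters[[k]]$p_exact),
              0.02)
    expect_lt(abs(ct500$clusters$p_corrected[row500] - ex$clusters[[k]]$p_exact),
              0.06)
  }
})

test_that("exhaustive null has the discrete support and symmetries it must", {
  g <- chain_graph()
  d <- null_diffs(3, 4, 3, seed = 77)
  dimnames(d)[[1]] <- c("A", "B", "C")
  ex <- exhaustive_null(d, g)
  for (cl in ex$clusters) {
    expect_true(any(abs(cl$p_exact - (1:8) / 8) < 1e-12))
  }

  # a subject with an all-zero difference map halves the null pairwise
  d0 <- d; d0[, , 2] <- 0
  ex0 <- exhaustive_null(d0, g)
  nm <- sort(ex0$null_max_mass)
  expect_equal(nm[seq(1, 8, 2)], nm[seq(2, 8, 2)], tolerance = 1e-12)

  expect_error(exhaustive_null(null_diffs(2, 2, 17, seed = 1), g),
               class = "spnlab_parameter_error")
})

test_that("negating the data swaps cluster signs and preserves p values", {
  d <- null_diffs(4, 8, 7, seed = 41)
  d[1:2, 3:6, ] <- d[1:2, 3:6, ] - 1.3
  g <- build_neighbor_graph(grid_montage(2), 35)
  ct_pos <- permutation_test(d, g, n_perm = 400, seed = 11)
  ct_neg <- permutation_test(-d, g, n_perm = 400, seed = 11)
  expect_equal(ct_neg$clusters$mass, -ct_pos$clusters$mass, tolerance = 1e-9)
  expect_equal(ct_neg$clusters$p_corrected, ct_pos$clusters$p_corrected,
               tolerance = 1e-12)
  expect_equal(ct_neg$null_max_mass, ct_pos$null_max_mass, tolerance = 1e-9)
})

test_that("cluster membership is invariant to channel reordering", {
  d <- null_diffs(4, 8, 6, seed = 51)
  d[c(1, 3), 2:5, ] <- d[c(1, 3), 2:5, ] + 1.4
  m <- grid_montage(2)
  g <- build_neighbor_graph(m, 35)
  ct1 <- permutation_test(d, g, n_perm = 200, seed = 9)

  perm <- c(3, 1, 4, 2)
  d2 <- d[perm, , , drop = FALSE]
  dimnames(d2)[[1]] <- dimnames(d)[[1]][perm]
  attr(d2, "times_ms") <- attr(d, "times_ms")
  ct2 <- permutation_test(d2, g, n_perm = 200, seed = 9)
  expect_equal(ct1$clusters$mass, ct2$clusters$mass, tolerance = 1e-9)
  expect_identical(ct1$clusters$electrodes, ct2$clusters$electrodes)
  expect_equal(ct1$clusters$p_corrected, ct2$clusters$p_corrected)
})

test_that("a posterior symmetry effect yields a negative posterior cluster", {
  # strong effect at reduced cohort size so detection is near-certain
  st <- simulate_study(sim_config(n_participants = 10, n_trials = 40,
                                  spn_amp_mean = -0.8, spn_amp_sd = 0.25,
                                  seed = 73))
  e <- filter_correct(rereference_average(baseline_correct(st$epochs)),
                      st$behavior)
  erps <- average_conditions(e)
  g <- build_neighbor_graph(st$montage, 35)
  ct <- permutation_test(erps, g, n_perm = 500, seed = 3)
  neg <- ct$clusters[ct$clusters$significant & ct$clusters$sign == "negative", ]
  expect_gte(nrow(neg), 1)
  # overlaps the injected 250-600 ms window and posterior sensors
  expect_lt(neg$window_start_ms[1], 600)
  expect_gt(neg$window_end_ms[1], 250)
  expect_true(any(c("Oz", "O1", "O2", "POz") %in% neg$electrodes[[1]]))
  roi <- cluster_roi(ct)
  expect_s3_class(roi, "roi_spec")
  expect_equal(roi$origin, "cluster-derived")
})
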