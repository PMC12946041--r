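#' Per-subject condition difference maps
#'
#' @param erps A `subject_erps` with both conditions.
#' @param minuend,subtrahend Condition labels; default symmetric minus
#'   asymmetric (S - A).
#' @return Array `channels x samples x participants` of difference
#'   waveforms, with channel dimnames; carries `times_ms` as an attribute.
#' @export
subject_differences <- function(erps, minuend = "symmetric",
                                subtrahend = "asymmetric") {
  mi <- match(minuend, erps$conditions)
  si <- match(subtrahend, erps$conditions)
  if (anyNA(c(mi, si))) {
    abort("requested conditions not present in ERPs",
          class = "spnlab_parameter_error")
  }
  d <- erps$data[, , , mi, drop = FALSE] - erps$data[, , , si, drop = FALSE]
  d <- array(d, dim(d)[1:3], dimnames = list(erps$channels, NULL, NULL))
  attr(d, "times_ms") <- erps$times_ms
  d
}

#' Mass-univariate paired t map
#'
#' One-sample t statistic of the per-subject condition differences against
#' zero at every (channel, sample); equivalent to the paired t between
#' conditions. Points with zero variance across subjects get t = 0 with a
#' warning.
#'
#' @param x A `subject_erps` or a difference array from
#'   [subject_differences()].
#' @return A `tmap`: list with `t` (channels x samples matrix), `df`,
#'   `times_ms`, `channels`.
#' @export
pointwise_paired_t <- function(x) {
  d <- if (inherits(x, "subject_erps")) subject_differences(x) else x
  n <- dim(d)[3]
  if (n < 2) {
    abort("need >= 2 participants with both conditions",
          class = "spnlab_parameter_error")
  }
  m <- rowMeans(d, dims = 2)
  v <- (rowSums(d^2, dims = 2) - n * m^2) / (n - 1)
  v[v < 0] <- 0 # guard tiny negative values from cancellation
  tmat <- m / sqrt(v / n)
  zero_var <- v == 0
  if (any(zero_var)) {
    warn(sprintf("%d point(s) with zero variance; t set to 0", sum(zero_var)))
    tmat[zero_var] <- 0
  }
  structure(list(t = tmat, df = n - 1,
                 times_ms = attr(d, "times_ms"),
                 channels = dimnames(d)[[1]]),
            class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf("<tmap> %d channels x %d samples, df = %d, |t| max = %.2f\n",
              nrow(x$t), ncol(x$t), x$df, max(abs(x$t))))
  invisible(x)
}

# Precompute the graph structure needed for fast repeated clustering:
# integer spatial edge list aligned to a channel vector.
graph_edges_idx <- function(graph, channels) {
  miss <- setdiff(channels, graph$labels)
  if (length(miss) > 0) {
    abort(sprintf("channel(s) missing from neighbor graph: %s",
                  paste(miss, collapse = ", ")),
          class = "spnlab_parameter_error")
  }
  edges <- tidy.neighbor_graph(graph)
  edges <- edges[edges$from %in% channels & edges$to %in% channels, ]
  cbind(match(edges$from, channels), match(edges$to, channels))
}

# Connected-component labels of the suprathreshold cells, via union-find
# with path halving. Hand-rolled because this runs once per permutation
# inside the Monte Carlo loop, where building a graph object per call
# dominates the runtime; the edge lists here are small (tens to a few
# thousand edges).
# Returns NULL when nothing is suprathreshold, else list(supra, labels).
supra_components <- function(tmat, thr, sedges) {
  n_ch <- nrow(tmat); n_s <- ncol(tmat)
  supra <- which(abs(tmat) > thr)
  if (length(supra) == 0) return(NULL)
  sgn <- sign(tmat)
  keep <- logical(n_ch * n_s)
  keep[supra] <- TRUE

  # temporal edges: same channel, adjacent samples, same sign
  left <- supra[supra <= n_ch * (n_s - 1)]
  right <- left + n_ch
  tmask <- keep[right] & sgn[left] == sgn[right]
  ea <- left[tmask]; eb <- right[tmask]

  # spatial edges: neighbor channels at the same sample, same sign
  if (nrow(sedges) > 0) {
    off <- rep((0:(n_s - 1)) * n_ch, each = nrow(sedges))
    a <- rep(sedges[, 1], n_s) + off
    b <- rep(sedges[, 2], n_s) + off
    smask <- keep[a] & keep[b] & sgn[a] == sgn[b]
    ea <- c(ea, a[smask]); eb <- c(eb, b[smask])
  }

  vid <- integer(n_ch * n_s)
  vid[supra] <- seq_along(supra) # dense ids for supra cells
  parent <- seq_along(supra)
  if (length(ea) > 0) {
    ea <- vid[ea]; eb <- vid[eb]
    for (k in seq_along(ea)) {
      ru <- ea[k]
      while (parent[ru] != ru) {
        parent[ru] <- parent[parent[ru]]
        ru <- parent[ru]
      }
      rv <- eb[k]
      while (parent[rv] != rv) {
        parent[rv] <- parent[parent[rv]]
        rv <- parent[rv]
      }
      if (ru != rv) parent[ru] <- rv
    }
    repeat { # vectorized final resolution to the roots
      pp <- parent[parent]
      if (identical(pp, parent)) break
      parent <- pp
    }
  }
  list(supra = supra, labels = parent)
}

# Per-cluster member indices and masses. Connectivity: spatial neighbors at
# the same sample, plus adjacent samples at the same channel; members share
# sign and exceed +-thr.
cluster_components <- function(tmat, thr, sedges) {
  sc <- supra_components(tmat, thr, sedges)
  if (is.null(sc)) return(list())
  lapply(split(sc$supra, sc$labels), function(cells) {
    list(cells = cells, mass = sum(tmat[cells]))
  })
}

# Max |cluster mass| of a t matrix -- the permutation statistic. Avoids
# building cluster metadata; used in the Monte Carlo and exhaustive nulls.
max_cluster_mass <- function(tmat, thr, sedges) {
  sc <- supra_components(tmat, thr, sedges)
  if (is.null(sc)) return(0)
  max(abs(rowsum(tmat[sc$supra], sc$labels)))
}

#' Form spatiotemporal clusters from a t map
#'
#' Suprathreshold samples (two-tailed p below `alpha_forming` for the map's
#' degrees of freedom) are partitioned into same-sign connected components.
#' Connectivity joins spatial neighbors at the same sample and adjacent
#' samples at the same channel (no diagonal links). Clusters are returned
#' sorted by |mass| descending, without corrected p values.
#'
#' @param tmap A `tmap`.
#' @param graph A `neighbor_graph` covering the map's channels.
#' @param alpha_forming Two-tailed cluster-forming significance level.
#' @return List of clusters; each has `cells` (indices into the t matrix),
#'   `channels`, `sample_range`, `time_window_ms`, `sign`, `mass`,
#'   `max_extent` (list: `time_ms`, `n_channels`).
#' @export
form_clusters <- function(tmap, graph, alpha_forming = 0.05) {
  thr <- qt(1 - alpha_forming / 2, tmap$df)
  sedges <- graph_edges_idx(graph, tmap$channels)
  comps <- cluster_components(tmap$t, thr, sedges)
  n_ch <- nrow(tmap$t)
  out <- lapply(comps, function(cl) {
    ch_i <- (cl$cells - 1) %% n_ch + 1
    s_i <- (cl$cells - 1) %/% n_ch + 1
    ext <- table(s_i)
    peak_s <- as.integer(names(ext)[which.max(ext)])
    list(cells = cl$cells,
         channels = sort(unique(tmap$channels[ch_i])),
         sample_range = range(s_i),
         time_window_ms = if (!is.null(tmap$times_ms))
           range(tmap$times_ms[s_i]) else NULL,
         sign = unname(sign(cl$mass)),
         mass = cl$mass,
         max_extent = list(
           time_ms = if (!is.null(tmap$times_ms)) tmap$times_ms[peak_s]
                     else peak_s,
           n_channels = max(ext)))
  })
  out[order(-abs(vapply(out, function(c) c$mass, numeric(1))))]
}

# t matrix from a (channels*samples) x n difference matrix and a sign vector,
# vectorized for permutation speed. vv = rowSums(D^2) precomputed.
flip_tmat <- function(Dmat, s, vv, n) {
  mu <- as.numeric(Dmat %*% s) / n
  sd2 <- (vv - n * mu^2) / (n - 1)
  tvec <- ifelse(sd2 > 0, mu / sqrt(sd2 / n), 0)
  tvec
}

#' Spatiotemporal cluster-based permutation test
#'
#' Tests condition differences against zero with family-wise error control by
#' the max-statistic permutation scheme: each permutation multiplies every
#' subject's difference map by an independent random sign (condition labels
#' exchanged within participants), the t map is recomputed, and the maximum
#' absolute cluster mass is recorded. An observed cluster's corrected p is
#' `(1 + #[null >= |mass|]) / (n_perm + 1)`; significance is declared at
#' `p <= alpha` (two-sided control through the absolute-mass null).
#'
#' @param x A `subject_erps`, or a difference array from
#'   [subject_differences()].
#' @param graph A `neighbor_graph`.
#' @param n_perm Number of random sign assignments (default 5000).
#' @param alpha Cluster-level significance level.
#' @param alpha_forming Cluster-forming (pointwise, two-tailed) level.
#' @param seed RNG seed for the permutation draw.
#' @return A `cluster_test` object: `clusters` (tibble: sign, mass,
#'   p_corrected, significant, window, electrodes, max extent), `tmap`,
#'   `null_max_mass`, `n_perm`, `alpha`, `threshold`, plus the raw cluster
#'   list in `cluster_details`.
#' @export
permutation_test <- function(x, graph, n_perm = 5000, alpha = 0.05,
                             alpha_forming = 0.05, seed = 1) {
  if (n_perm < 1) abort("`n_perm` must be >= 1", class = "spnlab_parameter_error")
  d <- if (inherits(x, "subject_erps")) subject_differences(x) else x
  tmap <- pointwise_paired_t(d)
  thr <- qt(1 - alpha_forming / 2, tmap$df)
  sedges <- graph_edges_idx(graph, tmap$channels)
  observed <- form_clusters(tmap, graph, alpha_forming)

  n <- dim(d)[3]
  n_ch <- dim(d)[1]; n_s <- dim(d)[2]
  Dmat <- matrix(d, n_ch * n_s, n)
  vv <- rowSums(Dmat^2)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      tvec <- flip_tmat(Dmat, s, vv, n)
      max_cluster_mass(matrix(tvec, n_ch, n_s), thr, sedges)
    }, numeric(1))
  })

  ps <- vapply(observed, function(cl) {
    (1 + sum(null_max >= abs(cl$mass))) / (n_perm + 1)
  }, numeric(1))
  clusters <- purrr::map2_dfr(observed, ps, function(cl, p) {
    tibble::tibble(
      sign = ifelse(cl$sign < 0, "negative", "positive"),
      mass = cl$mass,
      p_corrected = p,
      significant = p <= alpha,
      n_cells = length(cl$cells),
      n_electrodes = length(cl$channels),
      window_start_ms = if (!is.null(cl$time_window_ms)) cl$time_window_ms[1] else NA_real_,
      window_end_ms = if (!is.null(cl$time_window_ms)) cl$time_window_ms[2] else NA_real_,
      max_extent_time_ms = cl$max_extent$time_ms,
      max_extent_n_electrodes = cl$max_extent$n_channels,
      electrodes = list(cl$channels)
    )
  })
  structure(
    list(clusters = clusters, cluster_details = observed, tmap = tmap,
         null_max_mass = null_max, n_perm = n_perm, alpha = alpha,
         alpha_forming = alpha_forming, threshold = thr, seed = seed),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), %d permutations, forming |t| > %.3f (df %d)\n",
              nrow(x$clusters), x$n_perm, x$threshold, x$tmap$df))
  if (nrow(x$clusters) > 0) {
    top <- x$clusters[x$clusters$significant, ]
    cat(sprintf("significant at alpha %.3g: %d\n", x$alpha, nrow(top)))
  }
  invisible(x)
}

#' Tidy a cluster test into a tibble of clusters
#'
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return The cluster tibble (one row per cluster, sorted by |mass|).
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' One-line summary of a cluster test
#'
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return Tibble with counts, permutation settings, and the smallest
#'   corrected p.
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters) > 0) min(x$clusters$p_corrected) else NA_real_,
    n_perm = x$n_perm, alpha = x$alpha, df = x$tmap$df
  )
}

#' Exhaustive sign-flip null (oracle)
#'
#' Enumerates all 2^n sign assignments of the per-subject difference maps and
#' computes exact cluster p values: the proportion of assignments whose
#' maximum |cluster mass| is >= the observed cluster's |mass| (the observed
#' assignment is included by construction). Intended as a ground-truth check
#' of the Monte Carlo engine; refuses n > 16.
#'
#' @param x A `subject_erps` or difference array.
#' @param graph A `neighbor_graph`.
#' @param alpha_forming Cluster-forming level.
#' @return List with `clusters` (as in [form_clusters()], plus `p_exact` per
#'   cluster), `null_max_mass` (length 2^n), `n`.
#' @export
exhaustive_null <- function(x, graph, alpha_forming = 0.05) {
  d <- if (inherits(x, "subject_erps")) subject_differences(x) else x
  n <- dim(d)[3]
  if (n > 16) {
    abort("exhaustive enumeration limited to n <= 16 participants",
          class = "spnlab_parameter_error")
  }
  tmap <- pointwise_paired_t(d)
  thr <- qt(1 - alpha_forming / 2, tmap$df)
  sedges <- graph_edges_idx(graph, tmap$channels)
  observed <- form_clusters(tmap, graph, alpha_forming)
  n_ch <- dim(d)[1]; n_s <- dim(d)[2]
  Dmat <- matrix(d, n_ch * n_s, n)
  vv <- rowSums(Dmat^2)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- vapply(seq_len(nrow(signs)), function(b) {
    tvec <- flip_tmat(Dmat, signs[b, ], vv, n)
    max_cluster_mass(matrix(tvec, n_ch, n_s), thr, sedges)
  }, numeric(1))
  p_exact <- vapply(observed, function(cl) {
    mean(null_max >= abs(cl$mass) - 1e-12)
  }, numeric(1))
  list(clusters = purrr::map2(observed, p_exact,
                              function(cl, p) c(cl, list(p_exact = p))),
       null_max_mass = null_max, n = n)
}

#' Export cluster results as JSON
#'
#' One record per cluster: sign, mass, corrected p, window, electrodes, and
#' maximal spatial extent.
#'
#' @param test A `cluster_test`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_results <- function(test, path) {
  recs <- purrr::pmap(test$clusters, function(sign, mass, p_corrected,
                                              significant, n_cells,
                                              n_electrodes, window_start_ms,
                                              window_end_ms,
                                              max_extent_time_ms,
                                              max_extent_n_electrodes,
                                              electrodes) {
    list(sign = sign, mass = mass, p = p_corrected,
         window_ms = c(window_start_ms, window_end_ms),
         electrodes = electrodes,
         max_extent = list(time_ms = max_extent_time_ms,
                           n_electrodes = max_extent_n_electrodes))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
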