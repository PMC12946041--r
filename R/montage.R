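#' Load an electrode montage from a TSV table
#'
#' Reads a sensor table with columns `label`, `x`, `y`, `z` (3-D positions in
#' millimetres, head-centered) and validates it: labels must be unique and
#' non-empty, coordinates numeric, and all pairwise distances strictly
#' positive. Row order is preserved.
#'
#' @param path Path to a tab-separated file with header
#'   `label<TAB>x<TAB>y<TAB>z`.
#' @return A tibble of class `eeg_montage` with columns `label`, `x`, `y`,
#'   `z`.
#' @examples
#' m <- acticap64()
#' nrow(m)
#' @export
load_montage <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("label", "x", "y", "z")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("montage file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "spnlab_format_error")
  }
  for (col in c("x", "y", "z")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s coordinate in row %d (label '%s')",
                    col, bad[1], raw$label[bad[1]]),
            class = "spnlab_format_error")
    }
    raw[[col]] <- vals
  }
  new_montage(raw$label, as.matrix(raw[, c("x", "y", "z")]))
}

new_montage <- function(labels, coords) {
  labels <- as.character(labels)
  if (any(is.na(labels) | labels == "")) {
    abort("montage labels must be non-empty", class = "spnlab_format_error")
  }
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated electrode label(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "spnlab_format_error")
  }
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(labels, c("x", "y", "z")))
  if (nrow(coords) > 1) {
    d <- stats::dist(coords)
    if (any(d <= 0)) {
      abort("montage contains coincident sensors (zero pairwise distance)",
            class = "spnlab_format_error")
    }
  }
  out <- tibble::tibble(label = labels, x = unname(coords[, 1]),
                        y = unname(coords[, 2]), z = unname(coords[, 3]))
  class(out) <- c("eeg_montage", class(out))
  out
}

#' Packaged synthetic 64-channel montage
#'
#' An idealized actiCAP-style 64-channel extended 10-20 montage on a 94 mm
#' sphere, built from standard proportional-system geometry (TP9/TP10 at
#' mastoid level, as mounted on the physical cap). Shipped as a plain-text
#' fixture; coordinates are synthetic idealizations, not digitized positions.
#'
#' @return An `eeg_montage` tibble with 64 rows.
#' @export
acticap64 <- function() {
  load_montage(system.file("extdata", "acticap64_synthetic.tsv",
                           package = "spnlab", mustWork = TRUE))
}

montage_coords <- function(montage) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$label
  m
}

#' Build the spatial neighbor graph of a montage
#'
#' Two sensors are neighbors when their 3-D Euclidean distance is strictly
#' less than `threshold_mm`. The resulting adjacency defines spatial
#' contiguity for cluster formation. Sensors with no neighbor remain in the
#' graph (they can form single-sensor clusters but never join multi-sensor
#' ones).
#'
#' @param montage An `eeg_montage`.
#' @param threshold_mm Distance cut-off in millimetres (default 35, the
#'   conventional high-density spacing criterion).
#' @return A `neighbor_graph`: list with `threshold_mm`, `labels`,
#'   `adjacency` (named list of character vectors), `mean_degree`, and
#'   `isolated` (labels with no neighbors).
#' @examples
#' g <- build_neighbor_graph(acticap64(), 35)
#' g$mean_degree
#' g$isolated
#' @export
build_neighbor_graph <- function(montage, threshold_mm = 35) {
  assert_positive(threshold_mm, "threshold_mm")
  coords <- montage_coords(montage)
  labels <- montage$label
  n <- length(labels)
  adj <- stats::setNames(vector("list", n), labels)
  if (n >= 2) {
    D <- as.matrix(stats::dist(coords))
    for (i in seq_len(n)) {
      nb <- labels[D[i, ] < threshold_mm]
      adj[[i]] <- setdiff(nb, labels[i])
    }
  } else {
    adj <- stats::setNames(rep(list(character(0)), n), labels)
  }
  deg <- vapply(adj, length, integer(1))
  structure(
    list(threshold_mm = threshold_mm, labels = labels, adjacency = adj,
         mean_degree = if (n > 0) mean(deg) else NA_real_,
         isolated = labels[deg == 0]),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d sensors, threshold %g mm, mean degree %.2f\n",
              length(x$labels), x$threshold_mm, x$mean_degree))
  if (length(x$isolated) > 0) {
    cat("isolated:", paste(x$isolated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a neighbor graph into an edge table
#'
#' @param x A `neighbor_graph`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to` (one row per undirected edge,
#'   `from` < `to` lexicographically by montage order).
#' @export
tidy.neighbor_graph <- function(x, ...) {
  ord <- stats::setNames(seq_along(x$labels), x$labels)
  edges <- purrr::map_dfr(x$labels, function(a) {
    to <- x$adjacency[[a]]
    to <- to[ord[to] > ord[a]]
    if (length(to) == 0) return(tibble::tibble())
    tibble::tibble(from = a, to = to)
  })
  edges
}

#' Export a neighbor graph as JSON
#'
#' Writes `{threshold_mm, adjacency: {label: [labels...]}}`.
#'
#' @param graph A `neighbor_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_neighbor_graph <- function(graph, path) {
  jsonlite::write_json(
    list(threshold_mm = graph$threshold_mm, adjacency = graph$adjacency),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
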